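---
title: "Methods: RL fragment design and BLI kinetics in fragforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RL fragment design and BLI kinetics in fragforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What the package computes

`fragforge` implements a desk-scale fragment-discovery campaign of the
kind used to find aromatic moieties for installation onto a covalent
parent scaffold (here an isothiocyanate, sulforaphene-like warhead
targeting the nuclear export receptor CRM1/XPO1), followed by the
biolayer-interferometry (BLI) computation used to rank fragment binders.
The pipeline has five computational stages:

1. a character-level **GRU language model** over SMILES, pretrained by
   maximum likelihood on a molecule corpus;
2. **augmented-likelihood reinforcement learning** that tunes a copy of
   that model (the *agent*) against a frozen copy (the *prior*) and a
   composite reward;
3. a **composite reward**: modest-similarity band + descriptor-RMSD
   proximity, gated by validity, structure alerts, and aromaticity;
4. a **triage funnel**: validity, alert filter, deduplication, top-K,
   and a high-threshold Tanimoto search of a commercial-style fragment
   library, ending in graph-level installation of a fragment onto the
   parent scaffold;
5. **BLI kinetics**: 1:1 Langmuir sensorgram simulation, four-sensor
   double referencing `(a - c) - (b - d)`, and a global nonlinear
   least-squares fit yielding kon, koff and Kd.

Every input is produced by seeded synthetic generators, so the whole
workflow runs hermetically and deterministically.

# The generator

## Model

The language model is a single-layer GRU: token embedding (64), hidden
state (256), softmax output. SMILES are tokenized so that bracket atoms
(`[nH]`), two-character halogens (`Cl`, `Br`) and `%nn` ring closures
are single tokens; sequences are framed by `<SOS>`/`<EOS>` markers. The
start marker is masked out of every output distribution — it can never
be a continuation — so the next-token probabilities normalize over the
legal vocabulary and the enumerated probability mass of all sequences
up to `max_length` is exactly 1 (a property the tests verify by brute
enumeration on toy vocabularies).

Training is teacher-forced cross-entropy with Adam (learning rate
2e-3, multiplicative decay 0.8 per epoch, global gradient-norm clip 5),
10 epochs, batch size 64, with length-bucketed batches to keep padding
waste low. A 5% held-out split monitors mean per-token NLL; the history
is stored on the model object. All randomness — initialization,
shuffling, sampling — flows from R's RNG, so one integer seed
reproduces a run bit-for-bit on one platform. These sizes were chosen
as the smallest configuration that learns the synthetic corpus's
grammar to high sampled validity in CPU minutes; nothing in the method
depends on them, and the same interface trains on database-scale `.smi`
corpora.

Sampling is ancestral; a sampling temperature rescales logits, but
reported log-probabilities are always the model's own (temperature-1)
likelihoods. Sequences that hit `max_length` (100 tokens) without
emitting `<EOS>` are counted invalid downstream.

## Reinforcement learning

We use the augmented-likelihood formulation: for a sampled sequence
with prior log-likelihood `lp_prior` and reward `s` in [0, 1], the
target is

    aug = lp_prior + sigma * s

and the agent minimizes `mean((aug - lp_agent)^2)` over each sampled
batch (batch 64, Adam at 5e-4, sigma 20, at most 150 steps with early
stop once the rolling mean reward changes by <1% over 20 steps). With a
zero reward the loss gradient vanishes identically when agent == prior,
so the agent provably does not drift — the tests assert probe-set NLL
moves by < 1e-6 over 10 steps. sigma = 20 makes `sigma * s`
commensurate with the log-likelihoods of corpus-sized sequences
(roughly -10 to -30 nats), large enough to move mass and small enough
to keep the agent anchored to chemically sensible SMILES.

# The reward

Invalid SMILES, molecules matching a structure alert, and (by default)
molecules without an aromatic ring score 0 — the award-or-penalty gate.
Otherwise

    total = 0.5 * sim_score + 0.5 * desc_score

* `sim_score` is a trapezoidal band over the *maximum* Tanimoto
  similarity (ECFP4 circular fingerprints, radius 2, 4096-bit folding)
  to the positive set: 0 up to 0.2, rising to 1 at 0.4, flat to 0.6,
  falling to 0 at 0.8. The band encodes "modest similarity": an exact
  positive-set analogue (similarity 1) scores 0, as does unrelated
  chemistry. The defaults are symmetric and exclude near-duplicates;
  the four knots are configurable.
* `desc_score = exp(-RMSD)`, where RMSD is the root-mean-square
  deviation between the molecule's descriptor vector and the
  positive-set centroid, computed in z-scored descriptor space. The
  descriptor set is fixed and ordered: molecular weight, calculated
  logP, TPSA, H-bond donors, H-bond acceptors, ring count, aromatic
  ring count; the z-frame comes from a 2,000-molecule seeded subsample
  of the pretraining corpus (descriptor means are stable at that size,
  and it keeps the stage fast). A descriptor-space RMSD is the only
  RMSD computable in a SMILES-only workflow — no 3D conformers are
  generated anywhere — and the equal 0.5/0.5 weighting of the two terms
  is the package's choice; both are explicit `ScoringConfig` fields.

The alert list is a small packaged SMARTS catalogue of reactive or
unstable motifs (acyl halides, peroxides, aldehydes, alkyl halides,
N-halogens) plus an isothiocyanate pattern so the campaign proposes new
aromatic fragments rather than duplicating the parent warhead itself.

# Chemistry substrate and its numerical choices

Parsing, canonicalization, fingerprints, SMARTS matching and
descriptors stand on OpenBabel (through ChemmineR/ChemmineOB and the
`obabel` batch interface, which skips unparseable entries instead of
aborting a batch). Two choices deserve note:

* **Validity** means: OpenBabel parses the string *and* a valence
  screen passes. OpenBabel itself tolerates hypervalent atoms, so the
  package recomputes total bond order per atom from the kekulized
  connection table and rejects neutral atoms exceeding their allowed
  valence (C 4, N 3, O 2, S 6, P 5, halogens 1, ...). Formally charged
  bracket atoms are exempt from the neutral-atom table. This
  approximates "chemically sensible" as a structure checker would.
* **Canonical SMILES** are whatever the pinned OpenBabel version emits;
  cross-toolkit canonical equality is not promised. The toolkit version
  is recorded in the run manifest.
* **Tanimoto** on two all-zero fingerprints is defined as 1.

# The triage funnel

Designs are filtered to valid structures, alert hits are removed,
duplicates collapse by canonical SMILES (first occurrence wins), and
the survivors are ranked by reward with deterministic lexicographic
tie-breaks; the top 50 seed a library search at Tanimoto >= 0.97 — at
fingerprint granularity effectively "the catalogue carries this exact
fragment or a registration variant of it". Fragment installation is a
pure graph operation: both partners carry one `[*]` dummy-atom marker;
the marker is rewritten as a ring-closure label on its neighbour atom
so that joining the two fragment strings with `.` forms a single bond,
and the product is validated and substructure-checked against both
inputs. No synthetic route is implied.

# Synthetic data: what it emulates, and what it does not

* **Corpus**: molecules assembled from a curated template grammar
  (aromatic and aliphatic scaffolds, compositional substituent chains),
  canonicalized, deduplicated, and filtered to an 8–30 heavy-atom
  window; the aromatic fraction (default 0.75) is met exactly by
  per-class quotas. This emulates a drug-like pretraining set's
  regularities — valence-correct strings, branching, ring closures,
  heteroaromatics — but *not* the long-tail diversity of a real
  database: the language is simpler, so sampled-validity figures here
  say "the model has learned this grammar", not "it would reach the
  same validity on PubChem".
* **Positive set**: decorated isothiocyanates (`N=C=S` warhead) with
  sulfinyl/aromatic/aliphatic variation, mirroring the class of the
  parent compound.
* **Library**: decoys drawn from the corpus grammar, verified below
  Tanimoto 0.5 to every seed, plus planted near-duplicates verified at
  >= 0.97. At fragment size, single-atom edits (halogen swap, methyl
  addition) measurably drop circular-fingerprint similarity to
  0.45–0.75, far below 0.97 — so planted "near-duplicates" are realized
  as stereochemistry/registration variants (E/Z assignment or an exact
  duplicate under a different catalogue name): fingerprint-identical,
  distinct entries, which is exactly what a >= 0.97 search against a
  vendor catalogue returns in practice. Both margins are verified at
  generation time, not assumed.
* **Plates**: per concentration, four sensorgrams sharing one drift
  realization; the ligand-sensor well carries signal + nonspecific +
  drift + noise, the blank analyte well nonspecific + drift + noise,
  the buffer wells drift + noise. Double referencing then cancels drift
  and nonspecific signal exactly in the noiseless case. Default series:
  7 two-fold dilutions bracketing the generating Kd (2^-3 to 2^3), the
  instrument-typical design.

# BLI kinetics

The 1:1 Langmuir model is used throughout: during association
`R(t) = Req (1 - exp(-(kon C + koff) t))` with
`Req = Rmax C / (C + Kd)`; during dissociation exponential decay at
`koff`; `Kd = koff/kon`. The tests verify this closed form against
direct numerical integration of `dR/dt = kon C (Rmax - R) - koff R`.
The global fit shares kon, koff, Rmax across all concentrations and
runs Levenberg–Marquardt in log10 parameter space with bounds
(kon in [1e2, 1e8] 1/M/s, koff in [1e-6, 1] 1/s), from a data-driven
start (koff from the log-linear dissociation decay, Rmax/Kd from the
plateau-versus-concentration curve) plus five log-spaced grid starts;
the best residual sum of squares wins and `Kd = koff/kon` by
construction. Only association and dissociation phases enter the
residual; baseline is reference-subtracted anyway. An equilibrium-only
route (fitting plateaus to `Req(C)`) is kept as an independent
cross-check of the kinetic Kd. Mass-transport limitation and avidity
are out of scope, matching the instrument software's standard 1:1
analysis.

Schedule defaults are the assay's: baseline 120 s, association 180 s,
dissociation 180 s, sampled at 2 Hz. At extreme picomolar affinity the
180-s window determines kobs mostly through kon; recovery there leans
on the global, multi-concentration structure of the fit, which the
noiseless grid tests cover down to Kd = 1e-11 M. With realistic noise
the same window stops resolving picomolar off-rates altogether: at
koff ~ 1e-5 1/s only ~0.2% of the signal decays during dissociation,
below a 5% noise floor, so the fit can only bound koff (and Kd) from
above. The analysis scripts report this case as "tighter than the
window resolves" rather than as a number.

# Problem sizes and design notes

The shipped campaign scale — 20,000-molecule corpus, 10,000-sample
validity draw, 3,000-design campaign, top 50, 10 planted neighbours in
a 1,000-entry library — was chosen so the full workflow completes in
CPU minutes while keeping every stage's statistics meaningful; the
interfaces accept arbitrary sizes. The unit-test fixtures are smaller
(hundreds of molecules, narrower GRU) because they exercise contracts,
not capacity.

Known limitations: the generator's validity figure is grammar-relative
(see above); reward weights and the similarity band are heuristic
defaults, not fitted quantities; fragment installation checks graph
validity only; the kinetic fit assumes the 1:1 model that generated the
data, so model misspecification is untested by construction; and
OpenBabel's aromaticity/valence model is the arbiter of "chemically
sensible", which differs in corner cases from other toolkits.
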