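# fragforge

Reinforcement-learning design of aromatic fragments, with the
biolayer-interferometry (BLI) kinetics used to rank fragment binders.

## The problem

Fragment-based design of covalent inhibitors — here the motivating case
is a sulforaphene-like isothiocyanate warhead aimed at the nuclear
export receptor CRM1/XPO1 — needs aromatic moieties that are *related
to* known inhibitors without being close analogues of them. `fragforge`
implements that discovery loop end to end for R users:

1. **Generator.** A character-level GRU language model over SMILES
   tokens, pretrained by maximum likelihood on a molecule corpus, with
   exact sequence likelihoods and seeded, reproducible sampling.
2. **Reinforcement learning.** Augmented-likelihood fine-tuning: for a
   sampled sequence, the agent's log-likelihood is pulled toward
   `lp_prior + sigma * score`, by minimizing the squared gap, so
   high-reward chemistry gains probability mass while the frozen prior
   anchors syntax.
3. **Reward.** `total = w_sim * band(max Tanimoto to positives) +
   w_desc * exp(-RMSD)` with hard zero gates for invalid SMILES,
   structure alerts, and non-aromatic molecules. The trapezoidal band
   (default knots 0.2/0.4/0.6/0.8) encodes *modest* similarity: exact
   analogues of the positive set score 0. The RMSD is taken in z-scored
   descriptor space (MW, logP, TPSA, HBD, HBA, rings, aromatic rings)
   against the positive-set centroid.
4. **Triage.** Validity rate, alert filtering, canonical-SMILES
   deduplication, deterministic top-K ranking, Tanimoto >= 0.97 search
   of a commercial-style fragment library, and graph-level installation
   of a `[*]`-marked fragment onto the parent scaffold.
5. **BLI kinetics.** 1:1 Langmuir sensorgram simulation (baseline
   120 s / association 180 s / dissociation 180 s), four-sensor double
   referencing `(a − c) − (b − d)`, and bounded multi-start global
   least squares recovering kon, koff, Rmax and `Kd = koff/kon`.

Synthetic-data generators (corpus, positive set, planted library, BLI
plates) make every stage testable offline; each is a pure function of
its arguments and one integer seed.

## Worked example

```r
library(fragforge)

corpus    <- generate_corpus(2000, seed = 11)
model     <- pretrain(corpus, epochs = 8, seed = 2)
positives <- generate_positive_set(20, seed = 13)
scorer    <- make_scorer(scoring_config(
               positives, mol_descriptors(corpus$canonical_smiles[1:500])))

campaign  <- run_campaign(model, scorer,
                          rl_config(steps = 40, campaign_size = 500,
                                    seed = 14))
mean(campaign$rewards)                      # e.g. 0.158 vs prior ~0.011

plate <- generate_sensorgram_plate(kon = 1e6, koff = 1.25e-5, Rmax = 2,
                                   seed = 1)
fit_kinetics(plate$referenced)
#> 1:1 kinetic fit: kon 1e+06 1/M/s, koff 1.25e-05 1/s, Kd 1.25e-11 M
#>   Rmax 2, rss 1.5e-21, converged: TRUE
```

The campaign numbers mean: after 40 RL steps the mean composite reward
of sampled designs rose an order of magnitude over the pretrained
prior's, i.e. the agent now proposes valid, alert-free aromatic
fragments sitting in the modest-similarity band around the positive
set. The kinetic fit recovers the generating constants of the simulated
plate essentially exactly; on noisy plates it stays within the
tolerance expected of instrument software.

The `analysis/` directory holds the same workflow as numbered,
narrative scripts (`01_synthetic_inputs.R` ... `05_bli_kinetics.R`)
writing their tables under `results/`.

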