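#' @section Synthetic inputs:
#' Every input the pipeline needs can be generated hermetically: a
#' drug-like SMILES corpus assembled from a curated fragment grammar (a
#' stand-in for database-scale pretraining sets), a positive set sharing
#' an isothiocyanate-like warhead, a commercial-style fragment library
#' with planted near-duplicates of seed structures plus dissimilar decoys,
#' and four-sensor BLI plates (see [generate_sensorgram_plate()]). Every
#' generator is a pure function of its arguments and seed.
#' @name synthetic_data
NULL

# Substituent pieces: linear SMILES fragments whose first atom is the
# attachment point. "Extensible" pieces end in an atom with a free
# valence, so random chains of pieces (optionally closed by a terminal
# piece) form a combinatorially rich substituent space; every junction is
# a single bond, valence-correct by construction.
.pieces <- list(
  extensible = c("C", "CC", "C(C)C", "CO", "CN", "COC", "OC", "OCC",
                 "N(C)C", "NC", "O", "N", "S(=O)C", "CC(C)C", "OCC(C)C",
                 "C=C", "CC=C"),
  terminal = c("C#N", "F", "Cl", "Br", "C(F)(F)F", "S(C)(=O)=O",
               "C(=O)OC", "C(=O)N(C)C", "C(=O)NC", "CC#N"),
  carbon_first = c("C", "CC", "C(C)C", "CO", "CN", "COC", "CC(C)C",
                   "C=C", "CC=C", "C#N", "C(F)(F)F", "C(=O)OC",
                   "C(=O)N(C)C", "C(=O)NC", "CC#N"),
  carbonyl_first = c("OC", "OCC", "NC", "N(C)C", "C", "CC", "C(C)C"))

# Random substituent cap of a given class: a chain of 1-3 pieces; all
# pieces before the last must be extensible.
random_cap <- function(class = c("any", "carbon", "carbonyl")) {
  class <- match.arg(class)
  L <- sample(1:3, 1L, prob = c(0.45, 0.4, 0.15))
  first_set <- switch(class,
    any = if (L == 1L) c(.pieces$extensible, .pieces$terminal)
          else .pieces$extensible,
    carbon = if (L == 1L) .pieces$carbon_first
             else intersect(.pieces$carbon_first, .pieces$extensible),
    carbonyl = .pieces$carbonyl_first)
  cap <- sample(first_set, 1L)
  if (L >= 3L) cap <- paste0(cap, sample(.pieces$extensible, 1L))
  if (L >= 2L) cap <- paste0(cap, sample(c(.pieces$extensible,
                                           .pieces$terminal), 1L))
  cap
}

# Molecule templates: sprintf patterns with one %s per slot; `slots` gives
# the cap class per slot, `aromatic` whether the scaffold carries an
# aromatic ring.
.templates <- list(
  list(pat = "c1ccc(%s)cc1",                slots = "any",              aromatic = TRUE),
  list(pat = "c1ccc(%s)cc1%s",              slots = c("any", "any"),    aromatic = TRUE),
  list(pat = "c1cc(%s)ccc1%s",              slots = c("any", "any"),    aromatic = TRUE),
  list(pat = "c1c(%s)cccc1%s",              slots = c("any", "any"),    aromatic = TRUE),
  list(pat = "Cc1ccc(%s)cc1%s",             slots = c("any", "any"),    aromatic = TRUE),
  list(pat = "c1ccc(%s)nc1",                slots = "any",              aromatic = TRUE),
  list(pat = "c1ccc(%s)nc1%s",              slots = c("any", "carbon"), aromatic = TRUE),
  list(pat = "c1cc(%s)co1",                 slots = "any",              aromatic = TRUE),
  list(pat = "c1cc(%s)cs1",                 slots = "any",              aromatic = TRUE),
  list(pat = "c1cc(%s)cn1C",                slots = "any",              aromatic = TRUE),
  list(pat = "Cn1nnnc1%s",                  slots = "carbon",           aromatic = TRUE),
  list(pat = "c1ncc(%s)o1",                 slots = "carbon",           aromatic = TRUE),
  list(pat = "c1ccc2cc(%s)ccc2c1",          slots = "any",              aromatic = TRUE),
  list(pat = "c1ccc2[nH]ccc2c1%s",          slots = "carbon",           aromatic = TRUE),
  list(pat = "c1ccc(-c2ccc(%s)cc2)cc1",     slots = "any",              aromatic = TRUE),
  list(pat = "c1ccc(Cc2ccc(%s)cc2)cc1",     slots = "any",              aromatic = TRUE),
  list(pat = "c1ccc(NC(=O)%s)cc1",          slots = "carbonyl",         aromatic = TRUE),
  list(pat = "c1ccc(C(=O)%s)cc1",           slots = "carbonyl",         aromatic = TRUE),
  list(pat = "c1ccc(OC%s)cc1",              slots = "carbon",           aromatic = TRUE),
  list(pat = "C1CCC(%s)CC1",                slots = "any",              aromatic = FALSE),
  list(pat = "C1CCC(%s)CC1%s",              slots = c("any", "carbon"), aromatic = FALSE),
  list(pat = "C1CCN(C%s)CC1",               slots = "carbon",           aromatic = FALSE),
  list(pat = "O1CCN(C%s)CC1",               slots = "carbon",           aromatic = FALSE),
  list(pat = "CC(%s)CC%s",                  slots = c("any", "carbon"), aromatic = FALSE),
  list(pat = "CCC(%s)CC",                   slots = "any",              aromatic = FALSE),
  list(pat = "CC(C)(%s)C%s",                slots = c("any", "carbon"), aromatic = FALSE),
  list(pat = "CCNC(=O)%s",                  slots = "carbonyl",         aromatic = FALSE),
  list(pat = "CCOC(=O)C%s",                 slots = "carbon",           aromatic = FALSE),
  list(pat = "C1CCC(CC1)C%s",               slots = "carbon",           aromatic = FALSE))

count_heavy_atoms <- function(smiles) {
  vapply(smiles_tokenize(smiles), function(tk) {
    tk <- tk[!tk %in% c(START_TOKEN, END_TOKEN)]
    sum(grepl("^\\[(?!H)", tk, perl = TRUE) |
          tk %in% c("B", "C", "N", "O", "P", "S", "F", "I", "Cl", "Br",
                    "b", "c", "n", "o", "p", "s"))
  }, 0L)
}

assemble_one <- function(tmpl) {
  fills <- vapply(tmpl$slots, random_cap, "")
  do.call(sprintf, c(list(tmpl$pat), as.list(fills)))
}

#' Generate a synthetic pretraining corpus
#'
#' Assembles molecules by seeded random substitution of a curated template
#' grammar (aromatic and aliphatic scaffolds decorated with substituent
#' caps), canonicalizes them, and keeps unique valid molecules inside the
#' heavy-atom window. The aromatic fraction is controlled exactly by
#' per-class quotas.
#'
#' @param n number of molecules.
#' @param seed integer seed; the corpus is a pure function of the
#'   arguments.
#' @param min_heavy,max_heavy heavy-atom window.
#' @param aromatic_fraction target fraction of molecules containing an
#'   aromatic ring.
#' @param max_rounds assembly rounds before an unreachable specification
#'   is reported as an error.
#' @return Molecule records (all valid, canonical-unique), with a
#'   `aromatic` logical column.
#' @export
generate_corpus <- function(n, seed = 1L, min_heavy = 8L, max_heavy = 30L,
                            aromatic_fraction = 0.75, max_rounds = 40L) {
  set.seed(seed)
  quota <- c(arom = round(n * aromatic_fraction))
  quota <- c(quota, ali = n - quota[["arom"]])
  arom_t <- .templates[vapply(.templates, `[[`, TRUE, "aromatic")]
  ali_t <- .templates[!vapply(.templates, `[[`, TRUE, "aromatic")]
  got <- list(arom = character(0), ali = character(0))
  for (round in seq_len(max_rounds)) {
    need <- c(arom = quota[["arom"]] - length(got$arom),
              ali = quota[["ali"]] - length(got$ali))
    if (all(need <= 0)) break
    for (cls in c("arom", "ali")) {
      if (need[[cls]] <= 0) next
      tset <- if (cls == "arom") arom_t else ali_t
      raw <- vapply(sample(seq_along(tset), ceiling(need[[cls]] * 1.6),
                           replace = TRUE),
                    function(i) assemble_one(tset[[i]]), "")
      can <- ob_canonical(raw)
      ok <- !is.na(can)
      can <- can[ok]
      hv <- count_heavy_atoms(can)
      can <- can[hv >= min_heavy & hv <= max_heavy]
      can <- setdiff(unique(can), got[[cls]])
      got[[cls]] <- c(got[[cls]], head(can, need[[cls]]))
    }
  }
  if (length(got$arom) < quota[["arom"]] || length(got$ali) < quota[["ali"]])
    stop("corpus specification unreachable after ", max_rounds,
         " assembly rounds (heavy-atom window too tight?)")
  smiles <- c(got$arom, got$ali)
  rec <- data.frame(raw_smiles = smiles, canonical_smiles = smiles,
                    valid = TRUE, source = "corpus", name = NA_character_,
                    stringsAsFactors = FALSE)
  rec$aromatic <- rep(c(TRUE, FALSE), times = c(length(got$arom),
                                                length(got$ali)))
  # shuffle so train/holdout splits see both classes
  rec <- rec[sample.int(nrow(rec)), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Generate a synthetic positive set
#'
#' Molecules sharing an isothiocyanate-like warhead (`N=C=S`, the
#' sulforaphane/sulforaphene class motif) with varied aliphatic, sulfinyl
#' and aromatic decorations.
#'
#' @param n number of molecules (>= 2).
#' @param warhead warhead SMILES suffix; also used as the SMARTS check.
#' @param seed integer seed.
#' @return Annotated molecule records (`source = "positive_set"`).
#' @export
generate_positive_set <- function(n = 20L, warhead = "N=C=S", seed = 1L) {
  stopifnot(n >= 2)
  set.seed(seed)
  prefixes <- c("CS(=O)C=CC", "CS(=O)CCC", "CS(=O)CCCC", "CSCCC",
                "CS(=O)(=O)CCC", "CCS(=O)CCC", "CCCC", "CCCCC", "CC(C)CC",
                "c1ccc(cc1)C", "c1ccc(cc1)CC", "Cc1ccc(cc1)CC",
                "COc1ccc(cc1)CC", "c1ccc2cc(ccc2c1)CC")
  linkers <- c("", "C", "CC", "C=CC")
  combos <- expand.grid(p = prefixes, l = linkers,
                        stringsAsFactors = FALSE)
  combos <- combos[sample.int(nrow(combos)), ]
  raw <- paste0(combos$p, combos$l, warhead)
  can <- ob_canonical(raw)
  keep <- !is.na(can) & !duplicated(can)
  if (sum(keep) < n)
    stop("cannot build ", n, " unique positives from the template set")
  rec <- validate_and_canonicalize(raw[keep][seq_len(n)],
                                   source = "positive_set", annotate = TRUE)
  stopifnot(all(rec$valid))
  if (!all(matches_smarts(rec$canonical_smiles, warhead)))
    stop("positive-set member lost the warhead substructure")
  rec
}

# try to build a stereochemical variant of a seed: same molecular graph
# (identical circular fingerprint) but a different canonical SMILES, the
# way a catalogue lists separate E/Z or enantiopure entries
stereo_variant <- function(canonical_smiles) {
  cands <- character(0)
  if (grepl("C=C", canonical_smiles, fixed = TRUE)) {
    cands <- c(sub("C=C", "/C=C/", canonical_smiles, fixed = TRUE),
               sub("C=C", "/C=C\\\\", canonical_smiles, fixed = TRUE))
  }
  for (cd in cands) {
    can <- suppressWarnings(ob_canonical(cd))
    if (is.na(can) || can == canonical_smiles) next
    fp_pair <- ob_ecfp4(c(canonical_smiles, can))
    if (is.null(fp_pair[[1]]) || is.null(fp_pair[[2]])) next
    if (tanimoto(fp_pair[[1]], fp_pair[[2]]) >= 0.97) return(can)
  }
  NA_character_
}

#' Generate a commercial-style fragment library with planted neighbors
#'
#' Plants `n_planted` near-duplicates of the given seed structures
#' (stereochemical variants where the seed allows one, otherwise exact
#' registration duplicates under a catalogue name) among `n_decoys`
#' dissimilar decoys drawn from the corpus grammar. Both margins are
#' verified at generation time: every planted entry has Tanimoto >= 0.97
#' to its seed, every decoy < `decoy_max_sim` to all seeds; violating
#' decoys are resampled.
#'
#' @param seed_smiles character vector of (canonical) seed SMILES.
#' @param n_planted number of planted entries (seeds recycled if fewer).
#' @param n_decoys number of decoys.
#' @param decoy_max_sim decoy similarity ceiling against every seed.
#' @param seed integer seed.
#' @param max_rounds decoy resampling rounds before error.
#' @return List: `library` (a [library_index()]), `manifest` (data frame
#'   of entry name, role, and seed index for planted rows).
#' @export
generate_library <- function(seed_smiles, n_planted = 10L, n_decoys = 990L,
                             decoy_max_sim = 0.5, seed = 1L,
                             max_rounds = 40L) {
  stopifnot(length(seed_smiles) >= 1)
  set.seed(seed)
  seed_fp <- ob_ecfp4(seed_smiles)
  if (any(vapply(seed_fp, is.null, TRUE)))
    stop("planted seeds must be valid SMILES")

  src <- rep_len(seq_along(seed_smiles), n_planted)
  planted <- character(n_planted)
  for (k in seq_len(n_planted)) {
    sv <- stereo_variant(seed_smiles[src[k]])
    planted[k] <- if (!is.na(sv)) sv else seed_smiles[src[k]]
    fp <- ob_ecfp4(planted[k])[[1]]
    if (tanimoto(fp, seed_fp[[src[k]]]) < 0.97)
      stop("planted entry failed the 0.97 similarity invariant")
  }

  decoys <- character(0)
  for (round in seq_len(max_rounds)) {
    need <- n_decoys - length(decoys)
    if (need <= 0) break
    cand <- generate_corpus(ceiling(need * 1.3), seed = seed + round * 1000L,
                            aromatic_fraction = 0.75)$canonical_smiles
    cand <- setdiff(cand, c(decoys, seed_smiles, planted))
    if (!length(cand)) next
    fps <- ob_ecfp4(cand)
    ok <- vapply(seq_along(cand), function(i) {
      !is.null(fps[[i]]) &&
        max(vapply(seed_fp, tanimoto, 0, b = fps[[i]])) < decoy_max_sim
    }, TRUE)
    decoys <- c(decoys, head(cand[ok], need))
  }
  if (length(decoys) < n_decoys)
    stop("could not build ", n_decoys, " decoys below similarity ",
         decoy_max_sim, " after ", max_rounds, " rounds")

  names_all <- c(sprintf("PLANT-%03d", seq_len(n_planted)),
                 sprintf("DECOY-%04d", seq_len(n_decoys)))
  smiles_all <- c(planted, decoys)
  ord <- sample.int(length(smiles_all))
  lib <- library_index(smiles_all[ord], name = names_all[ord])
  manifest <- data.frame(name = names_all[ord],
                         smiles = smiles_all[ord],
                         role = ifelse(startsWith(names_all[ord], "PLANT"),
                                       "planted", "decoy"),
                         seed_idx = c(src, rep(NA_integer_, n_decoys))[ord],
                         stringsAsFactors = FALSE)
  list(library = lib, manifest = manifest)
}
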