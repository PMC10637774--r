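#' @section The composite reward:
#' The campaign scorer combines two continuous terms and three hard gates.
#' The similarity term is a trapezoidal band-pass over the maximum Tanimoto
#' similarity to the positive set: the campaign should propose structures
#' with *modest* similarity to known inhibitors, not close analogues, so
#' both dissimilar junk (below the band) and near-duplicates (above it)
#' score zero. The descriptor term is exp(-RMSD) where RMSD is the
#' root-mean-square deviation, in z-scored descriptor space, from the
#' positive-set centroid. Invalid molecules, structure-alert hits and
#' (by default) non-aromatic molecules are gated to total 0.
#' @name reward
NULL

#' Default structure-alert SMARTS patterns
#'
#' A small catalogue of reactive / unstable motifs excluded from design
#' campaigns: acyl halides, peroxides, aldehydes, alkyl halide
#' electrophiles, N-halogen bonds, and an isothiocyanate pattern so the
#' campaign does not simply duplicate the parent warhead.
#'
#' @return Named character vector of SMARTS patterns.
#' @export
default_alerts <- function() {
  c(acyl_halide = "[CX3](=O)[F,Cl,Br,I]",
    peroxide = "[OX2][OX2]",
    aldehyde = "[CX3H1](=O)[#6]",
    alkyl_halide = "[CX4][Cl,Br,I]",
    n_halogen = "[#7][F,Cl,Br,I]",
    warhead_duplicate = "N=C=S")
}

#' Read a structure-alert file
#'
#' One SMARTS pattern per line, optionally followed by a whitespace-
#' separated name; `#` comment lines are skipped.
#'
#' @param path text file of SMARTS patterns.
#' @return Named character vector of SMARTS.
#' @export
read_alerts <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  pats <- sub("\\s.*$", "", lines)
  nms <- ifelse(grepl("\\s", lines), sub("^\\S+\\s+", "", lines), "")
  names(pats) <- nms
  pats
}

#' Build a scoring configuration
#'
#' Precomputes everything the scorer needs: positive-set fingerprints, the
#' z-scoring frame (corpus descriptor means/sds), and the positive-set
#' descriptor centroid in that frame.
#'
#' @param positives annotated molecule records of the positive set (known
#'   inhibitors).
#' @param corpus_descriptors numeric matrix of descriptors for the
#'   pretraining corpus, defining the z-score frame.
#' @param band numeric length-4 `(s_lo, s_peak_lo, s_peak_hi, s_hi)`,
#'   nondecreasing in \[0, 1\]: the modest-similarity trapezoid.
#' @param weights numeric length-2 `(w_sim, w_desc)`, nonnegative, summing
#'   to 1.
#' @param alerts character vector of structure-alert SMARTS.
#' @param require_aromatic gate non-aromatic molecules to score 0.
#' @return A `scoring_config` list.
#' @export
scoring_config <- function(positives, corpus_descriptors,
                           band = c(0.2, 0.4, 0.6, 0.8),
                           weights = c(0.5, 0.5),
                           alerts = default_alerts(),
                           require_aromatic = TRUE) {
  stopifnot(length(band) == 4, all(diff(band) >= 0),
            band[1] >= 0, band[4] <= 1,
            length(weights) == 2, all(weights >= 0),
            abs(sum(weights) - 1) < 1e-9)
  if (!all(positives$valid)) stop("positive set contains invalid molecules")
  if (is.null(positives$fingerprint)) positives <- annotate_records(positives)
  mu <- colMeans(corpus_descriptors)
  sdv <- apply(corpus_descriptors, 2, sd)
  sdv[sdv < 1e-12] <- 1
  zpos <- sweep(sweep(do.call(rbind, positives$descriptors), 2, mu), 2, sdv, "/")
  structure(list(positive_fps = positives$fingerprint,
                 desc_mean = mu, desc_sd = sdv,
                 positive_centroid = colMeans(zpos),
                 band = band, weights = weights, alerts = alerts,
                 require_aromatic = require_aromatic),
            class = "scoring_config")
}

#' Trapezoidal modest-similarity band score
#'
#' 0 at or below `s_lo`, rising linearly to 1 at `s_peak_lo`, flat 1 up to
#' `s_peak_hi`, falling linearly to 0 at `s_hi`, 0 beyond. An exact
#' positive-set analogue (similarity 1) therefore scores 0.
#'
#' @param max_tanimoto numeric vector in \[0, 1\].
#' @param band length-4 nondecreasing band as in [scoring_config()].
#' @return Scores in \[0, 1\].
#' @export
similarity_band_score <- function(max_tanimoto, band = c(0.2, 0.4, 0.6, 0.8)) {
  stopifnot(all(max_tanimoto >= 0 & max_tanimoto <= 1))
  s <- numeric(length(max_tanimoto))
  x <- max_tanimoto
  rise <- x > band[1] & x < band[2]
  if (band[2] > band[1])
    s[rise] <- (x[rise] - band[1]) / (band[2] - band[1])
  s[x >= band[2] & x <= band[3]] <- 1
  fall <- x > band[3] & x < band[4]
  if (band[4] > band[3])
    s[fall] <- (band[4] - x[fall]) / (band[4] - band[3])
  s
}

#' Descriptor-RMSD proximity score
#'
#' `exp(-RMSD)` where RMSD is the root-mean-square deviation between a
#' z-scored descriptor vector and the positive-set centroid.
#'
#' @param desc numeric vector or matrix (rows = molecules) in z-scored
#'   descriptor space.
#' @param centroid numeric vector of the same dimension.
#' @return Scores in (0, 1].
#' @export
descriptor_rmsd_score <- function(desc, centroid) {
  if (is.null(dim(desc))) desc <- matrix(desc, nrow = 1)
  if (ncol(desc) != length(centroid))
    stop("descriptor dimension ", ncol(desc),
         " does not match centroid dimension ", length(centroid))
  rmsd <- sqrt(rowMeans(sweep(desc, 2, centroid)^2))
  exp(-rmsd)
}

#' Score molecules with the composite reward
#'
#' @param records molecule records (annotated or not; invalid rows allowed
#'   and scored 0).
#' @param config a [scoring_config()].
#' @return data frame with one row per record: `total`, `sim_score`,
#'   `desc_score`, `max_tanimoto`, `alert_hit`, `aromatic`, `valid`. Gates:
#'   `total` is 0 whenever `valid` is FALSE, an alert matches, or (if
#'   required) the molecule has no aromatic ring; otherwise
#'   `total = w_sim * sim_score + w_desc * desc_score`.
#' @export
score_molecules <- function(records, config) {
  stopifnot(inherits(config, "scoring_config"))
  n <- nrow(records)
  out <- data.frame(total = numeric(n), sim_score = numeric(n),
                    desc_score = numeric(n), max_tanimoto = NA_real_,
                    alert_hit = FALSE, aromatic = FALSE,
                    valid = records$valid)
  v <- which(records$valid)
  if (!length(v)) return(out)
  if (is.null(records$fingerprint) ||
      any(vapply(records$fingerprint[v], is.null, TRUE)))
    records <- annotate_records(records)
  can <- records$canonical_smiles[v]

  hit <- rep(FALSE, length(v))
  for (al in config$alerts) hit <- hit | matches_smarts(can, al)
  out$alert_hit[v] <- hit
  out$aromatic[v] <- is_aromatic(can)

  maxsim <- vapply(records$fingerprint[v], function(fp)
    max(vapply(config$positive_fps, tanimoto, 0, b = fp)), 0)
  out$max_tanimoto[v] <- maxsim
  out$sim_score[v] <- similarity_band_score(maxsim, config$band)

  desc <- do.call(rbind, records$descriptors[v])
  z <- sweep(sweep(desc, 2, config$desc_mean), 2, config$desc_sd, "/")
  out$desc_score[v] <- descriptor_rmsd_score(z, config$positive_centroid)

  gate_ok <- !out$alert_hit[v] & (!config$require_aromatic | out$aromatic[v])
  out$total[v] <- ifelse(gate_ok,
                         config$weights[1] * out$sim_score[v] +
                           config$weights[2] * out$desc_score[v], 0)
  out
}

#' A memoizing raw-SMILES scorer for the RL loop
#'
#' Wraps [score_molecules()] into a function `f(raw_smiles) -> numeric`
#' suitable for [run_campaign()]. Scores are cached by raw SMILES string,
#' which pays off as the agent's output distribution concentrates.
#'
#' @param config a [scoring_config()].
#' @return A closure returning total scores in \[0, 1\]; details of the
#'   last scored batch are kept in `attr(f, "env")$last`.
#' @export
make_scorer <- function(config) {
  cache <- new.env(parent = emptyenv())
  env <- new.env(parent = emptyenv())
  f <- function(raw_smiles) {
    res <- rep(NA_real_, length(raw_smiles))
    degenerate <- is.na(raw_smiles) | !nzchar(raw_smiles)
    res[degenerate] <- 0
    known <- !degenerate &
      vapply(raw_smiles, function(s) nzchar(s) && exists(s, envir = cache),
             TRUE)
    res[known] <- vapply(raw_smiles[known], get, 0, envir = cache)
    todo <- which(!known & !degenerate)
    if (length(todo)) {
      rec <- validate_and_canonicalize(raw_smiles[todo], source = "generated",
                                       annotate = TRUE)
      sc <- score_molecules(rec, config)
      env$last <- cbind(rec[c("raw_smiles", "canonical_smiles", "valid")], sc)
      for (k in seq_along(todo))
        assign(raw_smiles[todo[k]], sc$total[k], envir = cache)
      res[todo] <- sc$total
    }
    res
  }
  attr(f, "env") <- env
  attr(f, "config") <- config
  f
}
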