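#' @section The triage funnel:
#' After a campaign the designs are funneled: validity (and structure
#' alerts, applied inside the reward as a zero gate), deduplication by
#' canonical SMILES, top-K ranking by reward, Tanimoto search of a
#' commercial fragment library at a high threshold (default 0.97, i.e.
#' near-exact catalogue matches), and finally installation of a chosen
#' fragment onto the parent scaffold.
#' @name triage
NULL

#' Fraction of valid molecules in a batch
#'
#' @param records molecule record data frame (or logical vector of
#'   validity flags).
#' @return Fraction in \[0, 1\].
#' @export
validity_rate <- function(records) {
  v <- if (is.data.frame(records)) records$valid else as.logical(records)
  if (!length(v)) stop("empty batch")
  mean(v)
}

#' Deduplicate records by canonical SMILES
#'
#' First occurrence wins; invalid records are dropped.
#'
#' @param records molecule records.
#' @param rewards optional score vector carried along.
#' @return List with `records` and `rewards` (if given).
#' @export
dedup_records <- function(records, rewards = NULL) {
  keep <- which(records$valid)[!duplicated(records$canonical_smiles[records$valid])]
  list(records = records[keep, , drop = FALSE],
       rewards = if (is.null(rewards)) NULL else rewards[keep],
       index = keep)
}

#' Top-K designs by reward
#'
#' @param records deduplicated molecule records.
#' @param rewards numeric vector of total scores, one per record.
#' @param k number of candidates to keep.
#' @return The k highest-scoring records (descending score; ties broken by
#'   canonical SMILES lexicographic order), with columns `reward` and
#'   `rank` added. If fewer than `k` records are available, all are
#'   returned with attribute `short = TRUE` and a warning.
#' @export
rank_top_k <- function(records, rewards, k) {
  stopifnot(k >= 1, nrow(records) == length(rewards))
  if (anyDuplicated(records$canonical_smiles))
    stop("records must be deduplicated by canonical SMILES")
  ord <- order(-rewards, records$canonical_smiles, method = "radix")
  short <- k > length(ord)
  if (short) warning("requested top ", k, " but only ", length(ord),
                     " records available")
  ord <- ord[seq_len(min(k, length(ord)))]
  out <- records[ord, , drop = FALSE]
  out$reward <- rewards[ord]
  out$rank <- seq_len(nrow(out))
  attr(out, "short") <- short
  out
}

#' Build a searchable library index
#'
#' Validates and fingerprints library entries; invalid entries are dropped
#' with a recorded count.
#'
#' @param smiles character vector of library SMILES.
#' @param name entry names.
#' @return A `library_index` list: `records` (annotated, valid only),
#'   `n_dropped`.
#' @export
library_index <- function(smiles, name = NULL) {
  rec <- validate_and_canonicalize(smiles, source = "library", name = name)
  n_dropped <- sum(!rec$valid)
  rec <- annotate_records(rec[rec$valid, , drop = FALSE])
  structure(list(records = rec, n_dropped = n_dropped),
            class = "library_index")
}

#' Tanimoto search of a fragment library
#'
#' Finds all (seed, library entry) pairs with fingerprint Tanimoto
#' similarity at or above the threshold, the fragment-catalogue analogue
#' of a ~97% similarity search.
#'
#' @param seeds annotated molecule records (e.g. the top-K designs).
#' @param library a [library_index()].
#' @param threshold similarity cutoff in (0, 1\].
#' @return data frame with `seed`, `seed_smiles`, `library_name`,
#'   `library_smiles`, `similarity`, sorted per seed by descending
#'   similarity.
#' @export
library_search <- function(seeds, library, threshold = 0.97) {
  stopifnot(inherits(library, "library_index"),
            threshold > 0, threshold <= 1)
  if (!nrow(library$records)) stop("empty library")
  if (is.null(seeds$fingerprint) ||
      any(vapply(seeds$fingerprint[seeds$valid], is.null, TRUE)))
    seeds <- annotate_records(seeds)
  out <- list()
  lib <- library$records
  for (i in which(seeds$valid)) {
    sim <- vapply(lib$fingerprint, tanimoto, 0, b = seeds$fingerprint[[i]])
    hit <- which(sim >= threshold)
    if (!length(hit)) next
    hit <- hit[order(-sim[hit], lib$canonical_smiles[hit], method = "radix")]
    out[[length(out) + 1L]] <-
      data.frame(seed = i, seed_smiles = seeds$canonical_smiles[i],
                 library_idx = hit,
                 library_name = lib$name[hit],
                 library_smiles = lib$canonical_smiles[hit],
                 similarity = sim[hit], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(seed = integer(0), seed_smiles = character(0),
                      library_idx = integer(0), library_name = character(0),
                      library_smiles = character(0),
                      similarity = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# Replace a single terminal [*] attachment marker with a %98 ring-closure
# label on its neighbour atom, so two marked fragments joined with '.'
# form a single bond across the dot. The closure label is inserted right
# after the neighbour atom (and its own ring digits), before any branches,
# as SMILES requires.
splice_marker <- function(smiles) {
  toks <- smiles_tokenize(smiles)[[1]]
  toks <- toks[!toks %in% c(START_TOKEN, END_TOKEN)]
  pos <- which(toks == "*" | grepl("^\\[\\*", toks))
  if (length(pos) != 1L)
    stop("'", smiles, "' must carry exactly one [*] attachment marker, found ",
         length(pos))
  p <- pos
  is_atom <- function(t) grepl("^\\[", t) ||
    t %in% c("B", "C", "N", "O", "P", "S", "F", "I", "Cl", "Br",
             "b", "c", "n", "o", "p", "s")
  is_ring_digit <- function(t) grepl("^[0-9]$|^%", t)
  if (p == 1L) {
    rest <- toks[-1]
    if (!length(rest) || !is_atom(rest[1]))
      stop("no atom adjacent to the attachment marker in '", smiles, "'")
    j <- 1L
    while (j < length(rest) && is_ring_digit(rest[j + 1L])) j <- j + 1L
    return(paste(append(rest, "%98", after = j), collapse = ""))
  }
  if (toks[p - 1L] == "(" && p < length(toks) && toks[p + 1L] == ")") {
    drop <- c(p - 1L, p, p + 1L); q <- p - 2L
  } else if (p == length(toks)) {
    drop <- p; q <- p - 1L
  } else {
    stop("attachment marker in '", smiles,
         "' is not terminal; a [*] with two neighbours is not a single ",
         "attachment point")
  }
  # scan back over ring digits and complete branch groups to the atom the
  # marker is bonded to
  while (q >= 1L) {
    if (is_ring_digit(toks[q])) { q <- q - 1L }
    else if (toks[q] == ")") {
      depth <- 1L; q <- q - 1L
      while (q >= 1L && depth > 0L) {
        if (toks[q] == ")") depth <- depth + 1L
        else if (toks[q] == "(") depth <- depth - 1L
        q <- q - 1L
      }
    } else break
  }
  if (q < 1L || !is_atom(toks[q]))
    stop("no atom adjacent to the attachment marker in '", smiles, "'")
  j <- q
  while (j < length(toks) && is_ring_digit(toks[j + 1L])) j <- j + 1L
  toks <- append(toks, "%98", after = j)
  drop <- drop + 1L                      # drop positions always follow j
  paste(toks[-drop], collapse = "")
}

#' Install a fragment onto a parent scaffold
#'
#' Both SMILES must carry exactly one `[*]` dummy-atom attachment marker.
#' A single bond is formed between the two marked positions (a graph
#' operation; no reaction chemistry is modelled) and the product is
#' validated and checked to contain both inputs as substructures.
#'
#' @param parent_smiles,fragment_smiles SMILES with one `[*]` each.
#' @return Molecule record (one row) of the product.
#' @export
#' @examples
#' \donttest{install_fragment("CCC[*]", "[*]c1ccccc1")$canonical_smiles}
install_fragment <- function(parent_smiles, fragment_smiles) {
  joined <- paste0(splice_marker(parent_smiles), ".",
                   splice_marker(fragment_smiles))
  rec <- validate_and_canonicalize(joined, source = "generated")
  if (!rec$valid)
    stop("fragment installation produced an invalid structure: ", joined)
  for (part in c(parent_smiles, fragment_smiles)) {
    bare <- gsub("\\(\\[\\*\\]\\)|\\[\\*\\]", "", part)
    if (!matches_smarts(rec$canonical_smiles, bare))
      stop("product does not contain '", bare, "' as a substructure")
  }
  rec
}

#' Summarize a campaign as a triage funnel
#'
#' @param campaign a `campaign_result` from [run_campaign()].
#' @param library a [library_index()].
#' @param k top-K cutoff (the candidate moieties taken forward).
#' @param threshold library-search similarity threshold.
#' @param alerts structure-alert SMARTS applied as the filter stage.
#' @return A `funnel_report` list: counts `n_generated >= n_valid >=
#'   n_post_alert >= n_unique >= n_top` plus `n_matched`, the per-stage
#'   record lists, and the library matches.
#' @export
funnel_report <- function(campaign, library, k = 50L, threshold = 0.97,
                          alerts = default_alerts()) {
  designs <- campaign$designs
  rewards <- campaign$rewards
  n_generated <- nrow(designs)
  valid <- designs[designs$valid, , drop = FALSE]
  rew_valid <- rewards[designs$valid]
  hit <- rep(FALSE, nrow(valid))
  for (al in alerts) hit <- hit | matches_smarts(valid$canonical_smiles, al)
  post_alert <- valid[!hit, , drop = FALSE]
  rew_post <- rew_valid[!hit]
  dd <- dedup_records(post_alert, rew_post)
  unique_rec <- annotate_records(dd$records)
  top <- rank_top_k(unique_rec, dd$rewards, k)
  matches <- library_search(top, library, threshold)
  structure(list(n_generated = n_generated,
                 n_valid = nrow(valid),
                 n_post_alert = nrow(post_alert),
                 n_unique = nrow(unique_rec),
                 n_top = nrow(top),
                 n_matched = length(unique(matches$library_idx)),
                 top = top, matches = matches,
                 library_dropped = library$n_dropped),
            class = "funnel_report")
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("Design campaign funnel\n",
      sprintf("  generated:  %d\n", x$n_generated),
      sprintf("  valid:      %d\n", x$n_valid),
      sprintf("  post-alert: %d\n", x$n_post_alert),
      sprintf("  unique:     %d\n", x$n_unique),
      sprintf("  top-K:      %d\n", x$n_top),
      sprintf("  library matches: %d entries\n", x$n_matched), sep = "")
  invisible(x)
}
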