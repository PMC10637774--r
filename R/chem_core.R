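#' @section Molecule records:
#' Molecules travel through the pipeline as plain data frames ("molecule
#' record" tables) with one row per input SMILES and columns
#' `raw_smiles`, `canonical_smiles` (NA when invalid), `valid`, `source`,
#' `name`, plus list-columns `fingerprint` and `descriptors` once
#' annotated. Invalidity is a value, never an error: unparseable or
#' chemically impossible strings simply get `valid = FALSE`.
#' @name chem_core
NULL

START_TOKEN <- "<SOS>"
END_TOKEN <- "<EOS>"

.single_tokens <- c("B", "C", "N", "O", "P", "S", "F", "I",
                    "b", "c", "n", "o", "p", "s",
                    as.character(0:9),
                    "(", ")", "=", "#", "-", "+", "/", "\\", ".", "*", "@")

#' Tokenize SMILES strings
#'
#' Splits a SMILES string into chemically meaningful tokens: bracket atoms
#' (`[nH]`, `[O-]`, ...), two-character halogens (`Cl`, `Br`) and `%nn`
#' ring-closure labels are single tokens; everything else is one character.
#' Start/end markers are prepended/appended so the sequences can feed the
#' language model directly.
#'
#' @param smiles character vector of SMILES strings.
#' @param vocab optional character vector of allowed tokens; tokens outside
#'   it raise an error naming the offending token and position.
#' @return A list of character vectors, each beginning with `<SOS>` and
#'   ending with `<EOS>`.
#' @export
#' @examples
#' smiles_tokenize("CCl")[[1]]   # "Cl" is a single token
smiles_tokenize <- function(smiles, vocab = NULL) {
  stopifnot(is.character(smiles), all(nzchar(smiles)))
  lapply(smiles, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    n <- length(chars)
    toks <- character(0)
    i <- 1L
    while (i <= n) {
      ch <- chars[i]
      if (ch == "[") {
        j <- i
        while (j <= n && chars[j] != "]") j <- j + 1L
        if (j > n) stop("unclosed bracket atom in '", s, "' at position ", i)
        toks <- c(toks, paste(chars[i:j], collapse = ""))
        i <- j + 1L
      } else if (ch == "C" && i < n && chars[i + 1L] == "l") {
        toks <- c(toks, "Cl"); i <- i + 2L
      } else if (ch == "B" && i < n && chars[i + 1L] == "r") {
        toks <- c(toks, "Br"); i <- i + 2L
      } else if (ch == "%") {
        if (i + 2L > n || !all(grepl("[0-9]", chars[i + 1:2])))
          stop("malformed %nn ring closure in '", s, "' at position ", i)
        toks <- c(toks, paste(chars[i:(i + 2L)], collapse = "")); i <- i + 3L
      } else if (ch %in% .single_tokens) {
        toks <- c(toks, ch); i <- i + 1L
      } else {
        stop("character '", ch, "' at position ", i,
             " of '", s, "' is outside the SMILES token set")
      }
    }
    if (!is.null(vocab)) {
      bad <- which(!toks %in% vocab)
      if (length(bad))
        stop("token '", toks[bad[1]], "' at position ", bad[1],
             " of '", s, "' is not in the vocabulary")
    }
    c(START_TOKEN, toks, END_TOKEN)
  })
}

#' Reassemble a SMILES string from a token sequence
#'
#' Inverse of [smiles_tokenize()]: drops the start/end markers and
#' concatenates the remaining tokens.
#'
#' @param tokens character vector as produced by [smiles_tokenize()].
#' @return A single SMILES string.
#' @export
smiles_detokenize <- function(tokens) {
  paste(tokens[!tokens %in% c(START_TOKEN, END_TOKEN)], collapse = "")
}

# Allowed total bond order (excluding implicit H) for neutral atoms.
.max_valence <- c(B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 5,
                  S = 6, Cl = 1, Br = 1, I = 1, H = 1)

# Valence screen on an SDF file written by OpenBabel (kekulized bond
# orders). Returns a logical vector indexed by the i<index> titles.
# Molecules carrying formally charged bracket atoms are exempted: the
# neutral-atom table does not apply to them.
sdf_valence_ok <- function(sdf_path, n, charged_exempt = rep(FALSE, n)) {
  ok <- rep(NA, n)
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(sdf_path))
  ids <- ChemmineR::sdfid(sdfs)
  for (k in seq_along(sdfs)) {
    i <- suppressWarnings(as.integer(sub("^i", "", ids[k])))
    if (is.na(i) || i < 1L || i > n) next
    if (charged_exempt[i]) { ok[i] <- TRUE; next }
    ab <- ChemmineR::atomblock(sdfs[[k]])
    bb <- ChemmineR::bondblock(sdfs[[k]])
    if (!is.null(bb) && is.null(dim(bb))) bb <- matrix(bb, nrow = 1)
    elem <- sub("_.*$", "", rownames(ab))
    val <- numeric(nrow(ab))
    if (!is.null(bb) && nrow(bb) > 0 && ncol(bb) >= 3) {
      for (r in seq_len(nrow(bb))) {
        o <- bb[r, 3]
        val[bb[r, 1]] <- val[bb[r, 1]] + o
        val[bb[r, 2]] <- val[bb[r, 2]] + o
      }
    }
    lim <- .max_valence[elem]
    lim[is.na(lim)] <- Inf          # uncommon elements: no opinion
    ok[i] <- all(val <= lim)
  }
  ok
}

#' Validate and canonicalize SMILES strings
#'
#' Parses each string with OpenBabel and applies a valence screen on the
#' kekulized structure (total bond order per neutral atom must not exceed
#' its allowed valence), so that hypervalent strings such as pentavalent
#' carbon are rejected even though the parser tolerates them. Validity is
#' reported as a value; no input raises an error.
#'
#' @param smiles character vector of SMILES strings.
#' @param source provenance label: one of `"corpus"`, `"generated"`,
#'   `"library"`, `"positive_set"`.
#' @param name optional molecule names (recycled NA otherwise).
#' @param annotate if `TRUE`, fingerprints and descriptors are computed for
#'   the valid rows (see [annotate_records()]).
#' @return A molecule record data frame; see [chem_core].
#' @export
#' @examples
#' validate_and_canonicalize(c("CCO", "C1CC"))$valid   # TRUE FALSE
validate_and_canonicalize <- function(smiles,
                                      source = c("corpus", "generated",
                                                 "library", "positive_set"),
                                      name = NULL, annotate = FALSE) {
  source <- match.arg(source)
  n <- length(smiles)
  rec <- data.frame(raw_smiles = as.character(smiles),
                    canonical_smiles = NA_character_,
                    valid = FALSE,
                    source = source,
                    name = if (is.null(name)) NA_character_ else as.character(name),
                    stringsAsFactors = FALSE)
  if (n == 0) return(rec)
  can <- ob_canonical(smiles)
  parsed <- !is.na(can) & nzchar(can)
  if (any(parsed)) {
    idx <- which(parsed)
    charged <- grepl("\\[[^]]*[+-][^]]*\\]", smiles[idx])
    sdf <- ob_to_sdf(smiles[idx])
    on.exit(unlink(sdf))
    vok <- sdf_valence_ok(sdf, length(idx), charged)
    vok[is.na(vok)] <- FALSE
    rec$valid[idx] <- vok
    rec$canonical_smiles[idx[vok]] <- can[idx][vok]
  }
  if (annotate) rec <- annotate_records(rec)
  rec
}

#' Attach fingerprints and descriptors to molecule records
#'
#' Adds list-columns `fingerprint` (ECFP4 circular fingerprint, radius 2,
#' 4096 bits, stored as sorted set-bit indices) and `descriptors` (the
#' fixed 7-descriptor vector of [mol_descriptors()]) for every valid row.
#' Invalid rows keep `NULL` entries.
#'
#' @param records molecule record data frame.
#' @return The same data frame with the two list-columns filled in.
#' @export
annotate_records <- function(records) {
  n <- nrow(records)
  fp <- vector("list", n)
  ds <- vector("list", n)
  v <- which(records$valid)
  if (length(v)) {
    fp[v] <- ob_ecfp4(records$canonical_smiles[v])
    dm <- mol_descriptors(records$canonical_smiles[v])
    for (k in seq_along(v)) ds[[v[k]]] <- dm[k, ]
  }
  records$fingerprint <- I(fp)
  records$descriptors <- I(ds)
  records
}

#' Circular fingerprint of a single molecule
#'
#' ECFP4 (radius-2 circular fingerprint, 4096-bit folding) as computed by
#' OpenBabel, returned as sorted set-bit indices with a `nbits` attribute.
#'
#' @param smiles a single valid SMILES string.
#' @return An object of class `fragforge_fp`.
#' @export
mol_fingerprint <- function(smiles) {
  stopifnot(length(smiles) == 1L)
  fp <- ob_ecfp4(smiles)[[1]]
  if (is.null(fp)) stop("cannot fingerprint invalid SMILES '", smiles, "'")
  fp
}

#' Tanimoto similarity of two fingerprints
#'
#' Intersection over union of the set bits. Two all-zero fingerprints are
#' defined to have similarity 1.
#'
#' @param a,b fingerprints from [mol_fingerprint()] / [annotate_records()]
#'   (sorted set-bit index vectors with matching `nbits`).
#' @return Similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  na <- attr(a, "nbits"); nb <- attr(b, "nbits")
  if (!is.null(na) && !is.null(nb) && na != nb)
    stop("fingerprint lengths differ (", na, " vs ", nb, " bits)")
  a <- as.integer(a); b <- as.integer(b)
  if (length(a) == 0 && length(b) == 0) return(1.0)
  inter <- length(intersect(a, b))
  inter / (length(a) + length(b) - inter)
}

#' Molecular descriptors
#'
#' The fixed, ordered descriptor vector used throughout the pipeline:
#' molecular weight (g/mol), calculated logP, topological polar surface
#' area (A^2), hydrogen-bond donor count, hydrogen-bond acceptor count,
#' ring count, and aromatic ring count.
#'
#' @param smiles character vector of valid SMILES strings.
#' @return A numeric matrix with one row per molecule and columns
#'   `MW`, `logP`, `TPSA`, `HBD`, `HBA`, `rings`, `aromatic_rings`.
#' @export
#' @examples
#' \donttest{mol_descriptors("c1ccccc1")[, c("MW", "aromatic_rings")]}
mol_descriptors <- function(smiles) {
  stopifnot(length(smiles) >= 1L)
  out <- matrix(NA_real_, nrow = length(smiles), ncol = 7,
                dimnames = list(NULL, c("MW", "logP", "TPSA", "HBD", "HBA",
                                        "rings", "aromatic_rings")))
  # molecules with fewer than three heavy atoms cannot carry a ring, and
  # their degenerate connection tables trip the SDF batch path; they go
  # through the per-molecule interface instead
  tiny <- count_heavy_atoms(smiles) < 3L
  for (i in which(tiny)) {
    p <- ChemmineOB::prop_OB(ChemmineOB::forEachMol("SMILES", smiles[i],
                                                    identity))
    out[i, ] <- c(p$MW, p$logP, p$TPSA, p$HBD, p$HBA1, 0, 0)
  }
  big <- which(!tiny)
  if (length(big)) {
    sdf_path <- ob_to_sdf(smiles[big])
    on.exit(unlink(sdf_path))
    sdfs <- suppressWarnings(ChemmineR::read.SDFset(sdf_path))
    if (length(sdfs) != length(big))
      stop("descriptor computation requires valid SMILES; ",
           length(big) - length(sdfs), " molecule(s) failed to parse")
    idx <- big[as.integer(sub("^i", "", ChemmineR::sdfid(sdfs)))]
    pr <- ChemmineR::propOB(sdfs)
    out[idx, "MW"] <- pr$MW
    out[idx, "logP"] <- pr$logP
    out[idx, "TPSA"] <- pr$TPSA
    out[idx, "HBD"] <- pr$HBD
    out[idx, "HBA"] <- pr$HBA1
    rg <- ChemmineR::rings(sdfs, type = "count", arom = TRUE)
    if (is.null(dim(rg)))
      rg <- matrix(rg, nrow = 1, dimnames = list(NULL, names(rg)))
    out[idx, "rings"] <- rg[, "RINGS"]
    out[idx, "aromatic_rings"] <- rg[, "AROMATIC"]
  }
  out
}

#' Which molecules contain an aromatic ring?
#'
#' @param smiles character vector of valid SMILES.
#' @return Logical vector.
#' @export
is_aromatic <- function(smiles) {
  seq_along(smiles) %in% ob_smarts_match(smiles, "a")
}

#' SMARTS substructure test
#'
#' @param smiles character vector of valid SMILES.
#' @param smarts a single SMARTS pattern.
#' @return Logical vector: does each molecule match the pattern?
#' @export
matches_smarts <- function(smiles, smarts) {
  seq_along(smiles) %in% ob_smarts_match(smiles, smarts)
}
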