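# Internal wrappers around the OpenBabel command line (obabel) for batch
# work: canonicalization, SDF export, ECFP4 fingerprints and SMARTS
# filtering. The CLI is used instead of in-process ChemmineOB calls because
# it skips unparseable entries (-e) instead of aborting the batch, and a
# single process handles tens of thousands of molecules per second.
# Entries are tagged with an index title so results realign with the input
# even when invalid molecules are dropped.

obabel_path <- function() {
  p <- Sys.which("obabel")
  if (!nzchar(p)) stop("OpenBabel 'obabel' executable not found on PATH")
  p
}

ob_run <- function(args, stdin_file = NULL) {
  out <- suppressWarnings(system2(obabel_path(), args = args,
                                  stdout = TRUE, stderr = FALSE,
                                  stdin = if (is.null(stdin_file)) "" else stdin_file))
  out
}

ob_write_smi_input <- function(smiles) {
  f <- tempfile(fileext = ".smi")
  keep <- nzchar(smiles) & !grepl("[[:space:]]", smiles)
  writeLines(paste(smiles[keep], paste0("i", which(keep))), f)
  f
}

# Batch canonical SMILES. Returns a character vector aligned with `smiles`;
# NA for entries OpenBabel cannot parse.
ob_canonical <- function(smiles) {
  if (length(smiles) == 0) return(character(0))
  f <- ob_write_smi_input(smiles)
  on.exit(unlink(f))
  out <- ob_run(c(f, "-ocan", "-e"))
  res <- rep(NA_character_, length(smiles))
  if (length(out)) {
    parts <- strsplit(out, "\t", fixed = TRUE)
    keep <- vapply(parts, length, 1L) >= 2L
    parts <- parts[keep]
    idx <- as.integer(sub("^i", "", vapply(parts, `[`, "", 2L)))
    ok <- !is.na(idx) & idx >= 1L & idx <= length(smiles)
    res[idx[ok]] <- vapply(parts[ok], `[`, "", 1L)
  }
  res
}

# Batch SMILES -> SDF file; returns the path. Titles are i<index>.
ob_to_sdf <- function(smiles, sdf_path = tempfile(fileext = ".sdf")) {
  f <- ob_write_smi_input(smiles)
  on.exit(unlink(f))
  suppressWarnings(system2(obabel_path(), c(f, "-osdf", "-e", "-O", sdf_path),
                           stdout = FALSE, stderr = FALSE))
  sdf_path
}

# Batch ECFP4 fingerprints (OpenBabel circular fingerprint, radius 2,
# 4096-bit folding), returned as a list of sorted set-bit indices aligned
# with the input; NULL where the molecule is unparseable.
ob_ecfp4 <- function(smiles) {
  if (length(smiles) == 0) return(list())
  f <- ob_write_smi_input(smiles)
  on.exit(unlink(f))
  out <- ob_run(c(f, "-ofpt", "-xfECFP4", "-xh", "-e"))
  res <- vector("list", length(smiles))
  hdr <- grepl("^>", out)
  if (!any(hdr)) return(res)
  grp <- cumsum(hdr)
  titles <- sub("^>(\\S+).*", "\\1", out[hdr])
  idx <- as.integer(sub("^i", "", titles))
  hexmap <- hex_nibble_map()
  starts <- which(hdr)
  ends <- c(starts[-1] - 1L, length(out))
  for (k in seq_along(starts)) {
    i <- idx[k]
    if (is.na(i) || i < 1L || i > length(smiles)) next
    if (ends[k] <= starts[k]) { res[[i]] <- new_fp(integer(0)); next }
    hex <- gsub(" ", "", paste(out[(starts[k] + 1L):ends[k]], collapse = ""))
    res[[i]] <- new_fp(hex_to_bits(hex, hexmap))
  }
  res
}

hex_nibble_map <- function() {
  m <- vector("list", 16L)
  for (v in 0:15) m[[v + 1L]] <- which(bitwAnd(v, c(1L, 2L, 4L, 8L)) > 0L)
  m
}

# Map a hex string to set-bit indices; the mapping only needs to be a fixed
# injection from (nibble position, bit) to 1..4*nchar, since Tanimoto only
# compares fingerprints produced by the same function.
hex_to_bits <- function(hex, hexmap = hex_nibble_map()) {
  ch <- strsplit(tolower(hex), "", fixed = TRUE)[[1]]
  v <- match(ch, c(0:9, letters[1:6])) - 1L
  bits <- integer(0)
  for (b in 1:4) {
    pos <- which(bitwAnd(v, bitwShiftL(1L, b - 1L)) > 0L)
    if (length(pos)) bits <- c(bits, (pos - 1L) * 4L + b)
  }
  sort(bits)
}

new_fp <- function(bits, nbits = 4096L) {
  structure(as.integer(bits), nbits = nbits, class = "fragforge_fp")
}

# Indices (into `smiles`) of molecules matching a SMARTS pattern.
ob_smarts_match <- function(smiles, smarts) {
  if (length(smiles) == 0) return(integer(0))
  f <- ob_write_smi_input(smiles)
  on.exit(unlink(f))
  out <- ob_run(c(f, "-osmi", "-e", "-s", shQuote(smarts)))
  if (!length(out)) return(integer(0))
  parts <- strsplit(out, "\t", fixed = TRUE)
  keep <- vapply(parts, length, 1L) >= 2L
  idx <- as.integer(sub("^i", "", vapply(parts[keep], `[`, "", 2L)))
  sort(idx[!is.na(idx)])
}
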