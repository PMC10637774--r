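# .smi and SDF import/export: one SMILES per line, optional
# whitespace-separated name, '#' comment lines ignored.

#' Read a .smi file
#'
#' @param path file with one SMILES per line; anything after the first
#'   whitespace is the molecule name; lines starting with `#` and blank
#'   lines are skipped.
#' @return data frame with columns `smiles` and `name`.
#' @export
read_smi <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    return(data.frame(smiles = character(0), name = character(0),
                      stringsAsFactors = FALSE))
  sm <- sub("\\s.*$", "", lines)
  nm <- ifelse(grepl("\\s", lines), sub("^\\S+\\s+", "", lines), NA_character_)
  data.frame(smiles = sm, name = nm, stringsAsFactors = FALSE)
}

#' Write a .smi file
#'
#' @param smiles character vector of SMILES.
#' @param path output path.
#' @param name optional names written after a tab.
#' @export
write_smi <- function(smiles, path, name = NULL) {
  if (is.null(name)) writeLines(smiles, path)
  else writeLines(paste(smiles, name, sep = "\t"), path)
  invisible(path)
}

#' Import a fragment library from an SDF file
#'
#' Converts each record's first molecule block to SMILES (via OpenBabel);
#' the record title is kept as the name, other SDF properties are ignored.
#'
#' @param path SDF file.
#' @return data frame with columns `smiles` and `name`.
#' @export
read_library_sdf <- function(path) {
  out <- suppressWarnings(system2(obabel_path(), c(path, "-osmi", "-e"),
                                  stdout = TRUE, stderr = FALSE))
  if (!length(out))
    return(data.frame(smiles = character(0), name = character(0),
                      stringsAsFactors = FALSE))
  parts <- strsplit(out, "\t", fixed = TRUE)
  data.frame(smiles = vapply(parts, `[`, "", 1L),
             name = vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, ""),
             stringsAsFactors = FALSE)
}
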