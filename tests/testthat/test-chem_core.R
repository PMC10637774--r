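test_that("tokenizer maps multi-character symbols to single tokens", {
  expect_equal(smiles_tokenize("CCO")[[1]],
               c("<SOS>", "C", "C", "O", "<EOS>"))
  expect_equal(smiles_tokenize("CCl")[[1]],
               c("<SOS>", "C", "Cl", "<EOS>"))
  expect_length(smiles_tokenize("c1ccccc1")[[1]], 10L)  # 8 + 2 markers
  expect_equal(smiles_tokenize("C[nH]1cccc1")[[1]][3], "[nH]")
  expect_equal(smiles_tokenize("C%12CC%12")[[1]][3], "%12")
})

test_that("tokenizer round-trips every corpus molecule", {
  smi <- small_corpus()$canonical_smiles
  back <- vapply(smiles_tokenize(smi), smiles_detokenize, "")
  expect_identical(back, smi)
})

test_that("tokenizer errors name the offending character and position", {
  expect_error(smiles_tokenize("CC?O"), "'\\?' at position 3")
  expect_error(smiles_tokenize("C[unclosed"), "unclosed bracket")
  expect_error(smiles_tokenize("CO", vocab = c("C")), "not in the vocabulary")
})

test_that("validation flags unparseable and hypervalent strings as values", {
  rec <- validate_and_canonicalize(
    c("CCO", "C1CC", "C(C)(C)(C)(C)C", "c1ccccc1", "xyz", "FF"))
  expect_equal(rec$valid, c(TRUE, FALSE, FALSE, TRUE, FALSE, TRUE))
  expect_true(all(is.na(rec$canonical_smiles[!rec$valid])))
  expect_false(any(is.na(rec$canonical_smiles[rec$valid])))
})

test_that("canonicalization is invariant to atom ordering and idempotent", {
  rec <- validate_and_canonicalize(c("CCO", "OCC"))
  expect_identical(rec$canonical_smiles[1], rec$canonical_smiles[2])

  smi <- small_corpus(200)$canonical_smiles
  again <- validate_and_canonicalize(smi)
  expect_true(all(again$valid))
  expect_identical(again$canonical_smiles, smi)
})

test_that("fingerprints are deterministic and structure-sensitive", {
  f1 <- mol_fingerprint("c1ccccc1")
  f2 <- mol_fingerprint("c1ccccc1")
  f3 <- mol_fingerprint("C1CCCCC1")
  expect_identical(f1, f2)
  expect_false(identical(f1, f3))
  expect_lte(length(f1), attr(f1, "nbits"))
  expect_true(all(f1 >= 1 & f1 <= attr(f1, "nbits")))
})

test_that("tanimoto matches a brute-force bit-count oracle", {
  # sparse index representation of a=1100, b=1010
  a <- fragforge:::new_fp(c(1L, 2L), nbits = 4L)
  b <- fragforge:::new_fp(c(1L, 3L), nbits = 4L)
  expect_equal(tanimoto(a, b), 1 / 3)
  expect_equal(tanimoto(a, a), 1)
  expect_equal(tanimoto(a, fragforge:::new_fp(c(3L, 4L), nbits = 4L)), 0)
  expect_equal(tanimoto(fragforge:::new_fp(integer(0), nbits = 4L),
                        fragforge:::new_fp(integer(0), nbits = 4L)), 1)
  expect_error(tanimoto(a, fragforge:::new_fp(1L, nbits = 8L)), "differ")

  # symmetry + identity + agreement with dense popcount arithmetic on all
  # 4-bit vector pairs
  dense_tani <- function(x, y) {
    u <- sum(x | y)
    if (u == 0) 1 else sum(x & y) / u
  }
  grid <- expand.grid(replicate(4, c(FALSE, TRUE), simplify = FALSE))
  for (i in seq_len(nrow(grid))) for (j in seq_len(nrow(grid))) {
    x <- unlist(grid[i, ]); y <- unlist(grid[j, ])
    fx <- fragforge:::new_fp(which(x), 4L)
    fy <- fragforge:::new_fp(which(y), 4L)
    expect_equal(tanimoto(fx, fy), dense_tani(x, y))
    expect_equal(tanimoto(fx, fy), tanimoto(fy, fx))
    if (!identical(which(x), which(y))) expect_lt(tanimoto(fx, fy), 1)
  }
})

test_that("descriptors reproduce structure-forced values", {
  d <- mol_descriptors("c1ccccc1")
  expect_equal(unname(d[1, "MW"]), 78.11, tolerance = 0.01 / 78.11)
  expect_equal(unname(d[1, "aromatic_rings"]), 1)
  expect_equal(unname(d[1, "HBD"]), 0)
  expect_equal(unname(d[1, "HBA"]), 0)
  expect_equal(unname(d[1, "TPSA"]), 0)
  d2 <- mol_descriptors("CCCCCC")
  expect_equal(unname(d2[1, "TPSA"]), 0)
  expect_equal(unname(d2[1, "rings"]), 0)
})

test_that("record invariants hold: canonical iff valid, annotation iff valid", {
  rec <- validate_and_canonicalize(c("CCO", "C1CC", "c1ccncc1"),
                                   annotate = TRUE)
  expect_identical(rec$valid, !is.na(rec$canonical_smiles))
  expect_identical(vapply(rec$fingerprint, is.null, TRUE), !rec$valid)
  expect_identical(vapply(rec$descriptors, is.null, TRUE), !rec$valid)
})

test_that("SDF libraries import with names via the first molecule block", {
  smi <- tempfile(fileext = ".smi"); sdf <- tempfile(fileext = ".sdf")
  writeLines(c("CCO frag_a", "c1ccccc1 frag_b"), smi)
  system2(Sys.which("obabel"), c(smi, "-osdf", "-O", sdf),
          stdout = FALSE, stderr = FALSE)
  df <- read_library_sdf(sdf)
  expect_equal(df$name, c("frag_a", "frag_b"))
  rec <- validate_and_canonicalize(df$smiles, source = "library")
  expect_true(all(rec$valid))
  expect_equal(rec$canonical_smiles[1],
               validate_and_canonicalize("CCO")$canonical_smiles)
})

test_that(".smi files round-trip including comments and names", {
  f <- tempfile(fileext = ".smi")
  writeLines(c("# a comment", "CCO ethanol", "c1ccccc1", ""), f)
  df <- read_smi(f)
  expect_equal(df$smiles, c("CCO", "c1ccccc1"))
  expect_equal(df$name, c("ethanol", NA))
  write_smi(df$smiles, f, name = c("a", "b"))
  expect_equal(read_smi(f)$name, c("a", "b"))
})
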