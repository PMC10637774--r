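test_that("similarity band is a trapezoid with zero at both extremes", {
  band <- c(0.2, 0.4, 0.6, 0.8)
  expect_equal(similarity_band_score(1.0, band), 0)   # exact analogue
  expect_equal(similarity_band_score(0.0, band), 0)
  expect_equal(similarity_band_score(0.5, band), 1)   # plateau midpoint
  expect_equal(similarity_band_score(0.3, band), 0.5) # linear rise
  expect_equal(similarity_band_score(0.7, band), 0.5) # linear fall
  expect_equal(similarity_band_score(c(0.2, 0.4, 0.6, 0.8), band),
               c(0, 1, 1, 0))
  expect_error(similarity_band_score(1.2, band))
})

test_that("band score is unimodal on a dense similarity grid", {
  x <- seq(0, 1, by = 0.001)
  s <- similarity_band_score(x)
  d <- diff(s)
  peak <- which.max(s)
  expect_true(all(d[seq_len(peak - 1)] >= 0))
  expect_true(all(d[peak:length(d)] <= 0))
})

test_that("descriptor RMSD score follows the closed form", {
  cen <- rep(0, 7)
  expect_equal(descriptor_rmsd_score(cen, cen), 1)
  expect_equal(descriptor_rmsd_score(rep(1, 7), cen), exp(-1))
  # strict monotone decrease as one coordinate moves away
  offs <- seq(0, 3, by = 0.25)
  sc <- vapply(offs, function(o) {
    v <- cen; v[3] <- o
    descriptor_rmsd_score(v, cen)
  }, 0)
  expect_true(all(diff(sc) < 0))
  expect_error(descriptor_rmsd_score(rep(0, 5), cen), "dimension")
})

test_that("alert files read as named SMARTS vectors", {
  f <- tempfile(fileext = ".smarts")
  writeLines(c("# reactive motifs", "[CX3](=O)[F,Cl,Br,I] acyl_halide",
               "[OX2][OX2]"), f)
  al <- read_alerts(f)
  expect_equal(unname(al), c("[CX3](=O)[F,Cl,Br,I]", "[OX2][OX2]"))
  expect_equal(names(al)[1], "acyl_halide")
  expect_true(matches_smarts("CC(=O)Cl", al[[1]]))
})

test_that("composite score applies validity, alert and aromatic gates", {
  cfg <- small_scoring_config()
  rec <- validate_and_canonicalize(
    c("C1CC",                       # invalid
      "CC(=O)Cl",                   # acyl halide alert
      "CCCCCCCC",                   # valid but non-aromatic
      "c1ccc(CCNC(=O)C)cc1"),       # clean aromatic
    annotate = TRUE)
  sc <- score_molecules(rec, cfg)
  expect_equal(sc$total[1], 0)
  expect_false(sc$valid[1])
  expect_true(sc$alert_hit[2])
  expect_equal(sc$total[2], 0)
  expect_false(sc$aromatic[3])
  expect_equal(sc$total[3], 0)
  expect_true(sc$aromatic[4])
  expect_gt(sc$total[4], 0)
  expect_equal(sc$total[4],
               0.5 * sc$sim_score[4] + 0.5 * sc$desc_score[4])
})

test_that("a positive-set member scores only through the descriptor term", {
  cfg <- small_scoring_config()
  pos <- small_positives()
  sc <- score_molecules(pos[1, , drop = FALSE], cfg)
  expect_equal(sc$max_tanimoto[1], 1)
  expect_equal(sc$sim_score[1], 0)
  # positives carry the isothiocyanate warhead, which the default alert
  # list gates out -- exactly the "no warhead duplicates" behaviour
  expect_true(sc$alert_hit[1])
  expect_equal(sc$total[1], 0)
  # without the alert gate the total reduces to the descriptor half
  cfg2 <- scoring_config(pos,
                         mol_descriptors(small_corpus()$canonical_smiles[1:100]),
                         alerts = character(0), require_aromatic = FALSE)
  sc2 <- score_molecules(pos[1, , drop = FALSE], cfg2)
  expect_equal(sc2$total[1], 0.5 * sc2$desc_score[1])
})

test_that("total reward is bounded, pure, and zero-safe under fuzzing", {
  cfg <- small_scoring_config()
  corp <- small_corpus()
  set.seed(42)
  # mix of valid corpus molecules and corrupted strings
  raw <- c(corp$canonical_smiles[sample.int(nrow(corp), 150)],
           paste0(substr(corp$canonical_smiles[1:50], 1, 6), "1(("))
  rec <- validate_and_canonicalize(raw, annotate = TRUE)
  sc1 <- score_molecules(rec, cfg)
  sc2 <- score_molecules(rec, cfg)
  expect_true(all(sc1$total >= 0 & sc1$total <= 1))
  expect_identical(sc1, sc2)
  expect_true(all(sc1$total[!sc1$valid] == 0))
})
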