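test_that("next-token distributions give unit total sequence mass", {
  m <- toy_model(max_length = 4L)
  mass <- enumerate_mass(m)
  expect_equal(mass$total, 1, tolerance = 1e-6)
  expect_gt(mass$terminated, 0)
})

test_that("sequence log-probability is the closed form for a uniform model", {
  m <- toy_model()
  # zero all weights: every next-token distribution is uniform over the
  # legal next tokens (the start marker is never a continuation)
  m$params <- lapply(m$params, function(p) p * 0)
  V <- length(m$vocab) - 1L
  # "CC" = <SOS> C C <EOS>: 3 prediction steps
  expect_equal(sequence_log_prob(m, "CC"), 3 * log(1 / V), tolerance = 1e-12)
  expect_equal(sequence_log_prob(m, "C"), 2 * log(1 / V), tolerance = 1e-12)
  expect_error(sequence_log_prob(m, "CO"), "not in the vocabulary")
})

test_that("sampling is reproducible under a fixed seed", {
  m <- toy_model()
  s1 <- sample_smiles(m, 25, seed = 31)
  s2 <- sample_smiles(m, 25, seed = 31)
  expect_identical(s1, s2)
  s3 <- sample_smiles(m, 25, seed = 32)
  expect_false(identical(s1$smiles, s3$smiles))
})

test_that("sampled log-probs agree with independent likelihood evaluation", {
  m <- small_model()
  s <- sample_smiles(m, 40, seed = 5)
  ok <- s$terminated & nzchar(s$smiles)
  lp <- sequence_log_prob(m, s$smiles[ok])
  expect_equal(lp, s$log_probs[ok], tolerance = 1e-10)
  expect_true(all(s$log_probs <= 0))
})

test_that("empirical sampling frequencies match enumerated probabilities", {
  m <- toy_model(max_length = 3L, seed = 12)
  n <- 100000L
  s <- sample_smiles(m, n, seed = 77)
  # all terminated sequences over this vocabulary: "", "C" (plus truncated)
  for (seq_ids in list(c(1L, 2L), c(1L, 3L, 2L))) {
    p <- toy_seq_prob(m, seq_ids)
    smi <- paste(m$vocab[seq_ids[-c(1, length(seq_ids))]], collapse = "")
    obs <- sum(s$smiles == smi & s$terminated) / n
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(obs - p), 3 * se + 1e-12)
  }
})

test_that("low temperature collapses sampling onto the modal sequence", {
  m <- small_model()
  s <- sample_smiles(m, 30, temperature = 0.001, seed = 3)
  expect_gte(max(table(s$smiles)) / 30, 0.9)
})

test_that("pretraining reduces held-out NLL and is seed-deterministic", {
  m <- small_model()
  expect_lt(tail(m$nll_history, 1), m$nll_history[1])
  m2 <- pretrain(small_corpus(), epochs = 1, batch_size = 64, hidden = 48,
                 embedding = 16, seed = 9)
  m3 <- pretrain(small_corpus(), epochs = 1, batch_size = 64, hidden = 48,
                 embedding = 16, seed = 9)
  expect_identical(m2$nll_history, m3$nll_history)
  expect_identical(m2$params, m3$params)
})

test_that("a single-molecule corpus is memorized at low temperature", {
  one <- rep("CCOC(=O)CC", 60)
  m <- pretrain(one, epochs = 25, batch_size = 16, hidden = 32,
                embedding = 8, lr_decay = 1, holdout_frac = 0.1, seed = 4)
  s <- sample_smiles(m, 20, temperature = 0.01, seed = 5)
  expect_true(all(s$smiles == "CCOC(=O)CC"))
})

test_that("pretraining rejects empty and invalid corpora", {
  expect_error(pretrain(character(0)), "empty corpus")
  bad <- validate_and_canonicalize(c("CCO", "C1CC"))
  expect_error(pretrain(bad), "invalid")
})

test_that("model checkpoints round-trip through a versioned archive", {
  m <- toy_model()
  f <- tempfile(fileext = ".ckpt")
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(m2$params, m$params)
  expect_identical(sample_smiles(m, 5, seed = 1),
                   sample_smiles(m2, 5, seed = 1))
  saveRDS(list(magic = "other"), f)
  expect_error(load_model(f), "not a fragforge model checkpoint")
})
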