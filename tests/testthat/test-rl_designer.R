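test_that("augmented log-likelihood is prior plus sigma times score", {
  expect_equal(augmented_log_likelihood(-10, 0.5, 20), 0)
  expect_equal(augmented_log_likelihood(-3.2, 0, 20), -3.2)
  expect_equal(augmented_log_likelihood(-3.2, 0.9, 0), -3.2)
  expect_equal(augmented_log_likelihood(c(-1, -2), c(0.25, 0.5), 4),
               c(0, 0))
  expect_error(augmented_log_likelihood(-1, 1.5, 20), "\\[0, 1\\]")
})

test_that("a zero scorer is a fixed point: the agent does not drift", {
  prior <- small_model()
  agent <- prior
  zero_scorer <- function(smiles) rep(0, length(smiles))
  cfg <- rl_config(steps = 10, batch_size = 16, seed = 11)
  probe <- small_corpus()$canonical_smiles[1:30]
  nll0 <- -mean(sequence_log_prob(agent, probe))
  set.seed(cfg$seed)
  st <- NULL
  for (i in 1:10) {
    st <- rl_step(agent, prior, zero_scorer, cfg,
                  if (is.null(st)) NULL else st$opt_state)
    agent <- st$agent
  }
  nll1 <- -mean(sequence_log_prob(agent, probe))
  expect_lt(abs(nll1 - nll0), 1e-6)
  expect_equal(st$mean_reward, 0)
})

test_that("one step with a targeted scorer raises that sequence's log-prob", {
  prior <- small_model()
  # reward a sequence the batch actually contains: peek at the batch the
  # seed will produce, then replay the same seed through rl_step
  peek <- sample_smiles(prior, 48, seed = 21)
  target <- names(which.max(table(peek$smiles[nzchar(peek$smiles) &
                                                peek$terminated])))
  scorer <- function(smiles) as.numeric(smiles == target)
  cfg <- rl_config(sigma = 20, steps = 1, batch_size = 48, lr = 1e-3,
                   seed = 21)
  lp0 <- sequence_log_prob(prior, target)
  set.seed(cfg$seed)
  st <- rl_step(prior, prior, scorer, cfg)
  expect_true(st$mean_reward >= 0 && st$mean_reward <= 1)
  expect_gt(st$mean_reward, 0)
  lp1 <- sequence_log_prob(st$agent, target)
  expect_gt(lp1, lp0)
})

test_that("rl_step rejects models with mismatched vocabularies", {
  prior <- small_model()
  other <- toy_model()
  expect_error(rl_step(other, prior, function(s) rep(0, length(s)),
                       rl_config()), "vocabularies differ")
})

test_that("a zero-step campaign is a pure prior sample and seeds reproduce", {
  prior <- small_model()
  scorer <- function(smiles) rep(0.5, length(smiles))
  cfg <- rl_config(steps = 0, campaign_size = 40, seed = 13)
  c1 <- run_campaign(prior, scorer, cfg)
  c2 <- run_campaign(prior, scorer, cfg)
  expect_identical(c1$designs, c2$designs)
  expect_identical(c1$rewards, c2$rewards)
  expect_equal(nrow(c1$designs), 40)
  expect_identical(c1$agent$params, prior$params)
  expect_equal(nrow(c1$history), 0)
  # the same seed drives plain sampling identically
  direct <- sample_smiles(prior, 40, seed = cfg$seed)
  expect_identical(c1$designs$raw_smiles, direct$smiles)
})

test_that("RL shifts probability mass toward rewarded molecules", {
  prior <- small_model()
  # ungated composite scorer: the small fixture model emits few aromatic
  # molecules, so the aromatic-gated reward is too sparse to learn from
  # at this scale (the gated campaign-scale uplift is checked elsewhere)
  cfg <- scoring_config(small_positives(),
                        mol_descriptors(small_corpus()$canonical_smiles[1:150]),
                        require_aromatic = FALSE)
  scorer <- make_scorer(cfg)
  rcfg <- rl_config(sigma = 30, steps = 100, batch_size = 32,
                    campaign_size = 200, lr = 2e-3, plateau_window = 50,
                    seed = 17)
  camp <- run_campaign(prior, scorer, rcfg)
  expect_equal(nrow(camp$designs), 200)
  expect_true(all(camp$rewards >= 0 & camp$rewards <= 1))
  prior_samp <- sample_smiles(prior, 200, seed = 18)
  prior_rew <- scorer(prior_samp$smiles)
  prior_rew[!prior_samp$terminated] <- 0
  tt <- t.test(camp$rewards, prior_rew, alternative = "greater")
  expect_lt(tt$p.value, 0.01)
})
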