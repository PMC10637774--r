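#' @section Augmented-likelihood reinforcement learning:
#' The design loop keeps two copies of the pretrained language model: a
#' frozen *prior* and a trainable *agent*. For each sampled sequence the
#' augmented log-likelihood is the prior's log-likelihood plus
#' `sigma * score`, and the agent is trained to minimize the squared gap
#' between its own log-likelihood and that target. High-scoring sequences
#' therefore gain probability mass while the prior anchors the agent to
#' chemically sensible SMILES.
#' @name rl_designer
NULL

#' RL campaign configuration
#'
#' @param sigma reward scale (>= 0) multiplying the score inside the
#'   augmented likelihood.
#' @param steps maximum number of policy-update steps.
#' @param batch_size sequences sampled per step.
#' @param campaign_size designs sampled from the final agent.
#' @param lr Adam learning rate for the agent.
#' @param plateau_window,plateau_tol early stop when the rolling mean
#'   reward changes by less than `plateau_tol` (relative) over
#'   `plateau_window` steps.
#' @param seed integer seed for the whole campaign.
#' @return An `rl_config` list.
#' @export
rl_config <- function(sigma = 20, steps = 150L, batch_size = 64L,
                      campaign_size = 3000L, lr = 5e-4,
                      plateau_window = 20L, plateau_tol = 0.01,
                      seed = 1L) {
  stopifnot(is.finite(sigma), sigma >= 0, campaign_size >= 1)
  structure(list(sigma = sigma, steps = as.integer(steps),
                 batch_size = as.integer(batch_size),
                 campaign_size = as.integer(campaign_size), lr = lr,
                 plateau_window = as.integer(plateau_window),
                 plateau_tol = plateau_tol, seed = as.integer(seed)),
            class = "rl_config")
}

#' Augmented log-likelihood
#'
#' `prior_lp + sigma * score` -- the RL target for the agent's sequence
#' log-likelihood.
#'
#' @param prior_lp prior log-likelihood(s) of the sequence(s).
#' @param score score(s) in \[0, 1\].
#' @param sigma reward scale.
#' @return Numeric vector.
#' @export
augmented_log_likelihood <- function(prior_lp, score, sigma) {
  if (any(score < 0 | score > 1)) stop("score must lie in [0, 1]")
  prior_lp + sigma * score
}

#' One policy-update step
#'
#' Samples a batch from the agent, scores it, and performs one Adam update
#' on the loss `mean((augmented_lp - agent_lp)^2)`.
#'
#' @param agent,prior `smiles_lm` models sharing a vocabulary; the prior
#'   is not modified.
#' @param scorer function mapping raw SMILES to scores in \[0, 1\] (see
#'   [make_scorer()]).
#' @param config an [rl_config()].
#' @param opt_state Adam state (created on first use).
#' @return List with the updated `agent`, `opt_state`, `mean_reward`,
#'   `mean_loss`, and the sampled batch.
#' @export
rl_step <- function(agent, prior, scorer, config, opt_state = NULL) {
  if (!identical(agent$vocab, prior$vocab))
    stop("agent and prior vocabularies differ")
  if (is.null(opt_state)) opt_state <- adam_init(agent$params)

  batch <- sample_smiles(agent, config$batch_size, temperature = 1.0)
  scores <- scorer(batch$smiles)
  scores[!batch$terminated] <- 0          # truncated sequences are invalid

  ids <- encode_sequences(batch$tokens, agent$vocab)
  pm <- pad_matrix(ids)
  agent_lp <- cpp_gru_logprob_grad(agent$params, pm$X, pm$len,
                                   rep(0, nrow(pm$X)), FALSE)$lp
  prior_lp <- cpp_gru_logprob_grad(prior$params, pm$X, pm$len,
                                   rep(0, nrow(pm$X)), FALSE)$lp
  aug <- augmented_log_likelihood(prior_lp, scores, config$sigma)

  B <- length(aug)
  # d/dtheta mean_b (aug_b - lp_b)^2 = sum_b [2 (aug_b - lp_b) / B] * d(-lp_b)/dtheta
  seqw <- 2 * (aug - agent_lp) / B
  grad <- cpp_gru_logprob_grad(agent$params, pm$X, pm$len, seqw, TRUE)$grad
  up <- adam_step(agent$params, grad, opt_state, lr = config$lr)
  agent$params <- up$params

  list(agent = agent, opt_state = up$state,
       mean_reward = mean(scores),
       mean_loss = mean((aug - agent_lp)^2),
       batch = data.frame(smiles = batch$smiles, score = scores,
                          agent_lp = agent_lp, prior_lp = prior_lp))
}

#' Run a design campaign
#'
#' Fine-tunes a copy of the prior with [rl_step()] for up to
#' `config$steps` updates (early-stopping on a reward plateau), then
#' samples `config$campaign_size` designs from the final agent and scores
#' them all.
#'
#' @param prior a pretrained `smiles_lm`.
#' @param scorer as in [rl_step()].
#' @param config an [rl_config()].
#' @param verbose print progress every 10 steps.
#' @return A `campaign_result` list: `designs` (molecule records with raw
#'   and canonical SMILES), `rewards` (scores of the designs), `agent`,
#'   `history` (per-step mean reward and loss), `config`.
#' @export
run_campaign <- function(prior, scorer, config = rl_config(),
                         verbose = FALSE) {
  set.seed(config$seed)
  agent <- prior
  opt_state <- NULL
  hist_reward <- numeric(0); hist_loss <- numeric(0)
  if (config$steps > 0) {
    for (s in seq_len(config$steps)) {
      st <- rl_step(agent, prior, scorer, config, opt_state)
      agent <- st$agent; opt_state <- st$opt_state
      hist_reward <- c(hist_reward, st$mean_reward)
      hist_loss <- c(hist_loss, st$mean_loss)
      if (verbose && s %% 10 == 0)
        message(sprintf("step %d: mean reward %.3f, loss %.2f",
                        s, st$mean_reward, st$mean_loss))
      w <- config$plateau_window
      if (s >= 2 * w) {
        recent <- mean(hist_reward[(s - w + 1):s])
        before <- mean(hist_reward[(s - 2 * w + 1):(s - w)])
        if (before > 0 && abs(recent - before) / before < config$plateau_tol)
          break
      }
    }
  }
  samp <- sample_smiles(agent, config$campaign_size, temperature = 1.0)
  rewards <- scorer(samp$smiles)
  rewards[!samp$terminated] <- 0
  designs <- validate_and_canonicalize(samp$smiles, source = "generated")
  structure(list(designs = designs, rewards = rewards, agent = agent,
                 history = data.frame(step = seq_along(hist_reward),
                                      mean_reward = hist_reward,
                                      mean_loss = hist_loss),
                 config = config),
            class = "campaign_result")
}
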