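#' @section The SMILES language model:
#' `smiles_lm` objects are single-layer GRU character language models over
#' SMILES tokens: an embedding layer, a GRU cell and a softmax output
#' layer. They are trained by teacher-forced maximum likelihood
#' ([pretrain()]), sampled ancestrally ([sample_smiles()]), and expose
#' exact per-sequence log-likelihoods ([sequence_log_prob()]). All
#' randomness (initialization, shuffling, sampling) flows from R's RNG, so
#' a single `set.seed()`-style integer seed reproduces results
#' bit-for-bit on one platform.
#' @name generator
NULL

#' Build a token vocabulary from a corpus
#'
#' @param smiles character vector of (valid) SMILES strings.
#' @return character vector of tokens; the start and end markers occupy
#'   the first two positions, the rest is sorted for stability.
#' @export
build_vocab <- function(smiles) {
  toks <- unique(unlist(smiles_tokenize(smiles)))
  toks <- setdiff(toks, c(START_TOKEN, END_TOKEN))
  c(START_TOKEN, END_TOKEN, sort(toks))
}

encode_sequences <- function(token_lists, vocab) {
  lapply(token_lists, function(tk) {
    id <- match(tk, vocab)
    if (anyNA(id)) stop("token '", tk[which(is.na(id))[1]],
                        "' is not in the vocabulary")
    id
  })
}

pad_matrix <- function(id_lists) {
  lens <- lengths(id_lists)
  X <- matrix(0L, nrow = length(id_lists), ncol = max(lens))
  for (b in seq_along(id_lists)) X[b, seq_len(lens[b])] <- id_lists[[b]]
  list(X = X, len = as.integer(lens))
}

init_gru_params <- function(vocab_size, embedding = 64L, hidden = 256L) {
  rmat <- function(nr, nc, scale) matrix(rnorm(nr * nc, sd = scale), nr, nc)
  list(E  = rmat(vocab_size, embedding, 0.1),
       Wz = rmat(embedding, hidden, sqrt(1 / embedding)),
       Wr = rmat(embedding, hidden, sqrt(1 / embedding)),
       Wh = rmat(embedding, hidden, sqrt(1 / embedding)),
       Uz = rmat(hidden, hidden, sqrt(1 / hidden)),
       Ur = rmat(hidden, hidden, sqrt(1 / hidden)),
       Uh = rmat(hidden, hidden, sqrt(1 / hidden)),
       bz = matrix(0, 1, hidden), br = matrix(0, 1, hidden),
       bh = matrix(0, 1, hidden),
       Wo = rmat(hidden, vocab_size, sqrt(1 / hidden)),
       bo = matrix(0, 1, vocab_size))
}

new_smiles_lm <- function(params, vocab, hyper, seed) {
  structure(list(params = params, vocab = vocab, hyper = hyper, seed = seed),
            class = "smiles_lm")
}

#' @export
print.smiles_lm <- function(x, ...) {
  cat("SMILES GRU language model\n",
      " vocabulary: ", length(x$vocab), " tokens\n",
      " hidden: ", x$hyper$hidden, ", embedding: ", x$hyper$embedding,
      ", max_length: ", x$hyper$max_length, "\n", sep = "")
  invisible(x)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, clip = 5) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), 0)))
  if (is.finite(gn) && gn > clip) grads <- lapply(grads, function(g) g * (clip / gn))
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / corr1) / (sqrt(state$v[[nm]] / corr2) + eps)
  }
  list(params = params, state = state)
}

# mean per-token negative log-likelihood of encoded sequences
batch_nll <- function(params, id_lists, batch_size = 256L) {
  tot <- 0; ntok <- 0
  for (start in seq(1, length(id_lists), by = batch_size)) {
    chunk <- id_lists[start:min(start + batch_size - 1L, length(id_lists))]
    pm <- pad_matrix(chunk)
    lp <- cpp_gru_logprob_grad(params, pm$X, pm$len,
                               rep(0, nrow(pm$X)), FALSE)$lp
    tot <- tot - sum(lp)
    ntok <- ntok + sum(pm$len - 1L)
  }
  tot / ntok
}

#' Pretrain the SMILES language model by maximum likelihood
#'
#' Teacher-forced cross-entropy training with Adam and global gradient-norm
#' clipping. A held-out split monitors mean per-token negative
#' log-likelihood (NLL) per epoch.
#'
#' @param corpus molecule record data frame (all rows must be valid) or a
#'   character vector of valid SMILES.
#' @param epochs,batch_size,hidden,embedding,lr training hyperparameters.
#' @param lr_decay multiplicative learning-rate decay applied after each
#'   epoch (1 = constant rate).
#' @param max_length maximum sequence length (tokens, including markers);
#'   longer corpus molecules are rejected, longer samples count invalid.
#' @param holdout_frac fraction of the corpus held out for NLL monitoring.
#' @param seed integer seed governing initialization and shuffling.
#' @param verbose print per-epoch NLL.
#' @return A `smiles_lm` with an `nll_history` element: the held-out mean
#'   per-token NLL at initialization and after each epoch.
#' @export
pretrain <- function(corpus, epochs = 10, batch_size = 64L, hidden = 256L,
                     embedding = 64L, lr = 2e-3, lr_decay = 0.8,
                     max_length = 100L, holdout_frac = 0.05, seed = 1L,
                     verbose = FALSE) {
  if (is.data.frame(corpus)) {
    if (!all(corpus$valid))
      stop("corpus contains invalid molecules at rows: ",
           paste(head(which(!corpus$valid), 10), collapse = ", "))
    smiles <- corpus$canonical_smiles
  } else smiles <- as.character(corpus)
  if (!length(smiles)) stop("empty corpus")

  set.seed(seed)
  vocab <- build_vocab(smiles)
  ids <- encode_sequences(smiles_tokenize(smiles), vocab)
  if (any(lengths(ids) > max_length))
    stop("corpus molecules exceed max_length = ", max_length)

  n <- length(ids)
  n_hold <- max(1L, floor(holdout_frac * n))
  hold <- sample.int(n, n_hold)
  train <- setdiff(seq_len(n), hold)

  params <- init_gru_params(length(vocab), embedding, hidden)
  st <- adam_init(params)
  nll_hist <- batch_nll(params, ids[hold])
  if (verbose) message(sprintf("epoch 0: held-out NLL %.4f", nll_hist))

  for (ep in seq_len(epochs)) {
    # length-bucketed batches (random within ties), in random order:
    # keeps padding waste low without biasing the batch composition much
    ord <- sample(train)
    ord <- ord[order(lengths(ids)[ord])]
    starts <- sample(seq(1, length(ord), by = batch_size))
    for (start in starts) {
      bidx <- ord[start:min(start + batch_size - 1L, length(ord))]
      pm <- pad_matrix(ids[bidx])
      ntok <- sum(pm$len - 1L)
      res <- cpp_gru_logprob_grad(params, pm$X, pm$len,
                                  rep(1 / ntok, nrow(pm$X)), TRUE)
      up <- adam_step(params, res$grad, st, lr = lr * lr_decay^(ep - 1))
      params <- up$params; st <- up$state
    }
    nll <- batch_nll(params, ids[hold])
    nll_hist <- c(nll_hist, nll)
    if (verbose) message(sprintf("epoch %d: held-out NLL %.4f", ep, nll))
  }

  model <- new_smiles_lm(params, vocab,
                         hyper = list(hidden = hidden, embedding = embedding,
                                      max_length = max_length, epochs = epochs,
                                      batch_size = batch_size, lr = lr,
                                      lr_decay = lr_decay),
                         seed = seed)
  model$nll_history <- nll_hist
  model
}

#' Sample SMILES sequences from the model
#'
#' Ancestral sampling, optionally at a temperature != 1; reported
#' log-probabilities are always evaluated at temperature 1 (the model's
#' own likelihood of the sampled sequence).
#'
#' @param model a `smiles_lm`.
#' @param n number of sequences.
#' @param temperature softmax temperature (> 0) used for sampling.
#' @param seed optional integer seed (calls `set.seed`); with a fixed seed
#'   the batch is reproducible bit-for-bit.
#' @param chunk internal batch width for the sampler.
#' @return A list with `smiles` (character), `tokens` (list of token
#'   vectors including markers), `log_probs`, and `terminated` (reached the
#'   end marker before `max_length`; unterminated samples count invalid
#'   downstream).
#' @export
sample_smiles <- function(model, n, temperature = 1.0, seed = NULL,
                          chunk = 2000L) {
  stopifnot(n >= 1, temperature > 0)
  if (!is.null(seed)) set.seed(seed)
  smiles <- character(0); lp <- numeric(0); term <- logical(0)
  tokens <- list()
  remaining <- n
  while (remaining > 0) {
    b <- min(chunk, remaining)
    out <- cpp_gru_sample(model$params, b, model$hyper$max_length,
                          temperature, 1L, 2L)
    for (r in seq_len(b)) {
      tk <- model$vocab[out$X[r, seq_len(out$len[r])]]
      tokens[[length(tokens) + 1L]] <- tk
      smiles <- c(smiles, smiles_detokenize(tk))
    }
    lp <- c(lp, out$lp)
    term <- c(term, out$terminated)
    remaining <- remaining - b
  }
  list(smiles = smiles, tokens = tokens, log_probs = lp, terminated = term)
}

#' Exact sequence log-probability under the model
#'
#' @param model a `smiles_lm`.
#' @param smiles character vector of SMILES (tokenized against the model's
#'   vocabulary; out-of-vocabulary tokens are an error).
#' @return Numeric vector of natural-log probabilities (each <= 0).
#' @export
sequence_log_prob <- function(model, smiles) {
  ids <- encode_sequences(smiles_tokenize(smiles, vocab = model$vocab),
                          model$vocab)
  pm <- pad_matrix(ids)
  cpp_gru_logprob_grad(model$params, pm$X, pm$len,
                       rep(0, nrow(pm$X)), FALSE)$lp
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single-file archive (RDS) holding a magic header,
#' format version, vocabulary, hyperparameters, weights and seed.
#'
#' @param model a `smiles_lm`.
#' @param path checkpoint file.
#' @export
save_model <- function(model, path) {
  saveRDS(list(magic = "fragforge-smiles-lm", version = 1L, model = model),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- readRDS(path)
  if (!identical(x$magic, "fragforge-smiles-lm"))
    stop("not a fragforge model checkpoint: ", path)
  x$model
}
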