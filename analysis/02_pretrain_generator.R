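#!/usr/bin/env Rscript
# Stage 2 -- pretrain the SMILES language model.
# Maximum-likelihood (teacher-forced) training of the single-layer GRU on
# the synthetic corpus, then a 10,000-sample draw to measure the fraction
# of chemically valid structures -- the generator's headline figure.

suppressMessages(library(fragforge))
dir.create("results", showWarnings = FALSE)

corpus <- read_smi("scratch/campaign/corpus.smi")$smiles
model <- pretrain(corpus, seed = 2, verbose = TRUE)
save_model(model, "scratch/campaign/model.ckpt")

samp <- sample_smiles(model, 10000, temperature = 1.0, seed = 9)
rec <- validate_and_canonicalize(samp$smiles, source = "generated")
rec$valid[!samp$terminated] <- FALSE

nll <- data.frame(epoch = seq_along(model$nll_history) - 1,
                  holdout_nll = model$nll_history)
write.csv(nll, "results/02_nll_history.csv", row.names = FALSE)
summary <- data.frame(quantity = c("n_sampled", "validity_pct",
                                   "unique_pct_of_valid"),
                      value = c(10000, 100 * validity_rate(rec),
                                100 * length(unique(
                                  rec$canonical_smiles[rec$valid])) /
                                  sum(rec$valid)))
write.csv(summary, "results/02_generator_summary.csv", row.names = FALSE)
print(summary, row.names = FALSE)
cat("\nHeld-out NLL fell from", round(nll$holdout_nll[1], 3), "to",
    round(tail(nll$holdout_nll, 1), 3), "over", nrow(nll) - 1, "epochs.\n")
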