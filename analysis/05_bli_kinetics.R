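#!/usr/bin/env Rscript
# Stage 5 -- biolayer-interferometry kinetics.
# Simulates four-sensor plates at the two reported affinities (a
# picomolar lead, Kd 1.25e-11 M, and a nanomolar comparator, Kd
# 5.29e-9 M), applies the (a-c)-(b-d) double referencing, and fits the
# global 1:1 Langmuir model to recover kon, koff and Kd -- once
# noiseless and once at 5% noise with drift and nonspecific signal.

suppressMessages(library(fragforge))
dir.create("results", showWarnings = FALSE)

cases <- data.frame(compound = c("lead", "comparator"),
                    Kd = c(1.25e-11, 5.29e-9),
                    kon = c(1e6, 1e6))
rows <- list()
for (i in seq_len(nrow(cases))) {
  kon <- cases$kon[i]; koff <- cases$Kd[i] * kon
  for (noisy in c(FALSE, TRUE)) {
    plate <- generate_sensorgram_plate(
      kon, koff, Rmax = 2,
      noise_sd = if (noisy) 0.1 else 0,
      drift_rate = if (noisy) 0.002 else 0,
      nonspecific_rate = if (noisy) 50 else 0,
      seed = 100 + i)
    fit <- fit_kinetics(plate$referenced)
    rows[[length(rows) + 1L]] <- data.frame(
      compound = cases$compound[i], noisy = noisy,
      kon_true = kon, koff_true = koff, Kd_true = cases$Kd[i],
      kon_fit = fit$kon, koff_fit = fit$koff, Kd_fit = fit$Kd,
      Kd_rel_err = abs(fit$Kd - cases$Kd[i]) / cases$Kd[i],
      rss = fit$rss, converged = fit$converged)
  }
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/05_bli_fits.csv", row.names = FALSE)
print(tab[, c("compound", "noisy", "Kd_true", "Kd_fit", "Kd_rel_err",
              "converged")], row.names = FALSE)

cat("\nNoiseless fits recover the generating constants essentially",
    "exactly.\n")
for (i in which(tab$noisy)) {
  frac_decay <- 1 - exp(-tab$koff_true[i] * 180)
  if (tab$Kd_rel_err[i] <= 0.2) {
    cat(sprintf("Noisy %s fit: Kd within %.1f%% of truth.\n",
                tab$compound[i], 100 * tab$Kd_rel_err[i]))
  } else {
    cat(sprintf(paste0(
      "Noisy %s fit: Kd not identifiable -- at koff = %.3g 1/s only %.2f%%\n",
      "of the signal decays during the 180 s dissociation window, below the\n",
      "5%% noise floor, so koff (hence Kd) is bounded above, not measured.\n",
      "The instrument-style takeaway is 'tighter than the window resolves'.\n"),
      tab$compound[i], tab$koff_true[i], 100 * frac_decay))
  }
}
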