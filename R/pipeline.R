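#' @section End-to-end campaign:
#' [run_campaign_pipeline()] ties the stages together in campaign order:
#' synthetic corpus, maximum-likelihood pretraining, positive set and
#' scoring configuration, reinforcement-learning design campaign,
#' alert/dedup/top-K triage, synthetic commercial library with planted
#' neighbors, and the high-threshold library search. Every stage artifact
#' is written to the run directory together with a manifest (config,
#' seeds, toolkit versions, file digests) from which a rerun reproduces
#' byte-identical outputs.
#' @name pipeline
NULL

#' Default campaign configuration
#'
#' All defaults mirror the campaign's printed numbers: 3,000 designs, top
#' 50 candidates, library search at similarity 0.97.
#'
#' @param seed master integer seed; per-stage seeds derive from it.
#' @return Nested configuration list.
#' @export
default_campaign_config <- function(seed = 1L) {
  list(seed = seed,
       corpus = list(n = 20000L, min_heavy = 8L, max_heavy = 30L,
                     aromatic_fraction = 0.75),
       pretrain = list(epochs = 10L, batch_size = 64L, hidden = 256L,
                       embedding = 64L, lr = 2e-3, lr_decay = 0.8,
                       max_length = 100L),
       positives = list(n = 20L, warhead = "N=C=S"),
       reward = list(band = c(0.2, 0.4, 0.6, 0.8), weights = c(0.5, 0.5),
                     require_aromatic = TRUE, desc_frame_n = 2000L),
       rl = list(sigma = 20, steps = 150L, batch_size = 64L,
                 campaign_size = 3000L, lr = 5e-4),
       triage = list(k = 50L, threshold = 0.97),
       library = list(n_planted = 10L, n_decoys = 990L,
                      decoy_max_sim = 0.5))
}

stage_seed <- function(master, stage) {
  # distinct, stable per-stage seeds below 2^31
  (as.integer(master) * 97L + match(stage, c("corpus", "pretrain",
                                             "positives", "rl", "library"))
   * 1009L) %% .Machine$integer.max
}

#' Run the full design campaign
#'
#' @param config configuration from [default_campaign_config()] (modify
#'   fields as needed).
#' @param out_dir optional run directory; when given, stage artifacts
#'   (corpus.smi, positives.smi, gen.smi, rewards.csv, history.csv,
#'   top_k.smi, library.smi, matches.csv, funnel.json, manifest.json) are
#'   written there.
#' @param verbose print stage progress.
#' @return List with `model`, `campaign`, `funnel`, `matches`, `library`,
#'   `scorer_config`, `manifest`.
#' @export
run_campaign_pipeline <- function(config = default_campaign_config(),
                                  out_dir = NULL, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()

  say("[corpus] assembling %d molecules", config$corpus$n)
  corpus <- generate_corpus(config$corpus$n,
                            seed = stage_seed(config$seed, "corpus"),
                            min_heavy = config$corpus$min_heavy,
                            max_heavy = config$corpus$max_heavy,
                            aromatic_fraction = config$corpus$aromatic_fraction)

  say("[pretrain] GRU language model (%d epochs)", config$pretrain$epochs)
  model <- do.call(pretrain,
                   c(list(corpus = corpus,
                          seed = stage_seed(config$seed, "pretrain"),
                          verbose = verbose),
                     config$pretrain))

  say("[positives] %d warhead-bearing inhibitors", config$positives$n)
  positives <- generate_positive_set(config$positives$n,
                                     warhead = config$positives$warhead,
                                     seed = stage_seed(config$seed, "positives"))

  set.seed(stage_seed(config$seed, "positives"))
  frame_idx <- sample.int(nrow(corpus),
                          min(config$reward$desc_frame_n, nrow(corpus)))
  corpus_desc <- mol_descriptors(corpus$canonical_smiles[frame_idx])
  scfg <- scoring_config(positives, corpus_desc,
                         band = config$reward$band,
                         weights = config$reward$weights,
                         require_aromatic = config$reward$require_aromatic)
  scorer <- make_scorer(scfg)

  say("[design] RL campaign: %d steps, %d designs",
      config$rl$steps, config$rl$campaign_size)
  rlc <- rl_config(sigma = config$rl$sigma, steps = config$rl$steps,
                   batch_size = config$rl$batch_size,
                   campaign_size = config$rl$campaign_size,
                   lr = config$rl$lr, seed = stage_seed(config$seed, "rl"))
  campaign <- run_campaign(model, scorer, rlc, verbose = verbose)

  say("[triage] alerts, dedup, top %d", config$triage$k)
  designs_valid <- campaign$designs[campaign$designs$valid, , drop = FALSE]
  # the library is planted from the top candidates, so triage twice:
  # first to get seeds, then the full report against the library
  hit <- rep(FALSE, nrow(designs_valid))
  for (al in default_alerts())
    hit <- hit | matches_smarts(designs_valid$canonical_smiles, al)
  dd <- dedup_records(designs_valid[!hit, , drop = FALSE],
                      campaign$rewards[campaign$designs$valid][!hit])
  top <- rank_top_k(annotate_records(dd$records), dd$rewards,
                    config$triage$k)

  say("[library] %d planted + %d decoys",
      config$library$n_planted, config$library$n_decoys)
  lib <- generate_library(top$canonical_smiles,
                          n_planted = config$library$n_planted,
                          n_decoys = config$library$n_decoys,
                          decoy_max_sim = config$library$decoy_max_sim,
                          seed = stage_seed(config$seed, "library"))

  funnel <- funnel_report(campaign, lib$library, k = config$triage$k,
                          threshold = config$triage$threshold)
  matches <- funnel$matches

  manifest <- list(
    config = config,
    seeds = list(corpus = stage_seed(config$seed, "corpus"),
                 pretrain = stage_seed(config$seed, "pretrain"),
                 positives = stage_seed(config$seed, "positives"),
                 rl = stage_seed(config$seed, "rl"),
                 library = stage_seed(config$seed, "library")),
    versions = list(R = R.version.string,
                    fragforge = as.character(utils::packageVersion("fragforge")),
                    openbabel = tryCatch(
                      system2(obabel_path(), "-V", stdout = TRUE)[1],
                      error = function(e) NA_character_)),
    counts = list(n_generated = funnel$n_generated,
                  n_valid = funnel$n_valid,
                  n_post_alert = funnel$n_post_alert,
                  n_unique = funnel$n_unique,
                  n_top = funnel$n_top,
                  n_matched = funnel$n_matched),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_smi(corpus$canonical_smiles, file.path(out_dir, "corpus.smi"))
    write_smi(positives$canonical_smiles, file.path(out_dir, "positives.smi"))
    write_smi(campaign$designs$raw_smiles, file.path(out_dir, "gen.smi"))
    write.csv(cbind(campaign$designs[c("raw_smiles", "canonical_smiles",
                                       "valid")],
                    reward = campaign$rewards),
              file.path(out_dir, "rewards.csv"), row.names = FALSE)
    write.csv(campaign$history, file.path(out_dir, "history.csv"),
              row.names = FALSE)
    write_smi(top$canonical_smiles, file.path(out_dir, "top_k.smi"),
              name = sprintf("rank%02d_reward%.3f", top$rank, top$reward))
    write_smi(lib$manifest$smiles, file.path(out_dir, "library.smi"),
              name = lib$manifest$name)
    write.csv(matches, file.path(out_dir, "matches.csv"), row.names = FALSE)
    jsonlite::write_json(manifest$counts, file.path(out_dir, "funnel.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- setdiff(list.files(out_dir, full.names = TRUE),
                     file.path(out_dir, "manifest.json"))
    manifest$digests <- as.list(tools::md5sum(files))
    names(manifest$digests) <- basename(files)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }

  list(model = model, campaign = campaign, funnel = funnel,
       matches = matches, library = lib, scorer_config = scfg,
       manifest = manifest)
}
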