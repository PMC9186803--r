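#' Default pipeline configuration
#'
#' Nested list mirroring the YAML schema accepted by [run_pipeline()]:
#' sections `task`, `agent`, `neural`, `spectral`, `stats`, `connectivity`,
#' plus `n_trials`, `n_subjects` and the global `seed`. Every stochastic
#' stage derives its own seed deterministically from the global seed and
#' the stage name, so a rerun with the same config is bit-identical.
#'
#' @return The default configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    n_trials = 200L,
    n_subjects = 1L,
    task = list(validity = 0.7, cue_duration = 0.2, isi = 0.6, max_cues = 10L),
    agent = list(model = "M1", lambda = 0, omega = 0,
                 stop_rule = "threshold", threshold = 3,
                 stop_beta = c(-1, 0.5, 0.5)),
    neural = list(fs = 300, beta_freq = 21.5, base_amp = 1,
                  b_same_diff = 0.5, b_absev = 0.25, b_cuenum = 0.25,
                  b_norm = 0, coupling = "lagged", coupling_lag = pi / 2,
                  coupling_gain_same = 0.5, coupling_gain_diff = 1,
                  noise_exponent = 1, noise_amp = 0.5),
    spectral = list(band = "beta", mode = "center", window = 0.4,
                    hop = 0.05, hp_freq = 0.5),
    stats = list(n_perm = 500L, cluster_alpha = 0.05, alpha = 0.05,
                 carryover = 1L),
    connectivity = list(enabled = TRUE, n_perm = 200L,
                        freqs = 1:30, halfbw = 2.5)
  )
}

# deterministic per-stage seed below 2^31
stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 100000L) * 10007L + sum(utf8ToInt(stage)) %% 9973L
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Run the full synthetic analysis pipeline
#'
#' Orchestrates simulate -> fit -> regressors -> recording -> band power ->
#' GLM -> same/different contrast -> coherence as one reproducible run.
#' Artifacts written to `out_dir`: `behavior_s<k>.csv`, `fits_s<k>.json`,
#' `regressors_s<k>.csv`, `recording_s<k>.bin/.json`,
#' `glm_clusters_s<k>.json`, `contrast_s<k>.json`,
#' `contrast_trace_s<k>.csv`, `coherence_s<k>.csv`,
#' `coherence_contrast_s<k>.json`, and a `manifest.json` with the resolved
#' config, per-stage seeds, package version and MD5 checksums of every
#' artifact. With four or more subjects a group-level sign-flip contrast is
#' added (`contrast_group.json`).
#'
#' @param config Configuration list (see [default_config()]); partial lists
#'   are merged over the defaults.
#' @param config_path Optional YAML file merged over `config`.
#' @param seed Optional override of the global seed.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with the per-subject results and the manifest.
#' @export
run_pipeline <- function(config = list(), config_path = NULL, seed = NULL,
                         out_dir = tempfile("accubeta_run")) {
  cfg <- merge_config(default_config(), config)
  if (!is.null(config_path))
    cfg <- merge_config(cfg, yaml::read_yaml(config_path))
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  task <- task_config(cfg$task$validity, cfg$task$cue_duration,
                      cfg$task$isi, cfg$task$max_cues)
  pars <- accumulator_params(cfg$agent$model, cfg$agent$lambda,
                             cfg$agent$omega)
  agent <- agent_spec(pars, cfg$agent$stop_rule, cfg$agent$threshold,
                      cfg$agent$stop_beta, cfg$task$max_cues)
  nspec <- do.call(neural_sim_spec,
                   cfg$neural[names(cfg$neural) %in%
                                names(formals(neural_sim_spec))])
  seeds <- list()
  results <- list()
  files <- character(0)
  emit <- function(path) { files <<- c(files, path); path }

  diff_traces <- NULL
  for (s in seq_len(cfg$n_subjects)) {
    tag <- paste0("_s", s)
    sb <- stage_seed(cfg$seed, paste0("behavior", s))
    sr <- stage_seed(cfg$seed, paste0("recording", s))
    sp <- stage_seed(cfg$seed, paste0("stats", s))
    seeds[[paste0("subject", s)]] <- list(behavior = sb, recording = sr,
                                          stats = sp)
    trials <- simulate_behavior(task, agent, cfg$n_trials, seed = sb)
    write_trials(trials, emit(file.path(out_dir, paste0("behavior", tag, ".csv"))))
    beh <- summarize_behavior(trials, task)

    fits <- select_model(trials)
    write_fits(fits, emit(file.path(out_dir, paste0("fits", tag, ".json"))))
    win <- fits[[1]]$params

    reg <- cue_regressors(trials, win, validity = task$validity)
    write_regressors(reg, emit(file.path(out_dir, paste0("regressors", tag, ".csv"))))
    commit <- commitment_regression(trials)

    rec <- simulate_recording(trials, reg, nspec, task, seed = sr)
    write_recording(rec, file.path(out_dir, paste0("recording", tag)))
    emit(file.path(out_dir, paste0("recording", tag, ".bin")))
    emit(file.path(out_dir, paste0("recording", tag, ".json")))

    pts <- continuous_band_power(rec, cfg$spectral$band,
                                 window = cfg$spectral$window,
                                 hop = cfg$spectral$hop,
                                 mode = cfg$spectral$mode,
                                 hp_freq = cfg$spectral$hp_freq)
    ep <- epoch_power(pts, window = c(-0.5, 0.8), channel = "stn")
    glm_res <- band_power_glm(ep, reg, n_perm = cfg$stats$n_perm,
                              cluster_alpha = cfg$stats$cluster_alpha,
                              alpha = cfg$stats$alpha, seed = sp)
    write_cluster_result(glm_res$clusters,
                         emit(file.path(out_dir, paste0("glm_clusters", tag, ".json"))),
                         times = glm_res$times)

    ctr <- same_different_contrast(pts, carryover = cfg$stats$carryover,
                                   channel = "stn",
                                   n_perm = cfg$stats$n_perm,
                                   cluster_alpha = cfg$stats$cluster_alpha,
                                   alpha = cfg$stats$alpha, seed = sp)
    write_cluster_result(ctr$cluster,
                         emit(file.path(out_dir, paste0("contrast", tag, ".json"))),
                         times = ctr$times)
    utils::write.csv(
      data.frame(time = ctr$times, difference = ctr$difference,
                 ci_low = ctr$ci_low, ci_high = ctr$ci_high),
      emit(file.path(out_dir, paste0("contrast_trace", tag, ".csv"))),
      row.names = FALSE)
    diff_traces <- rbind(diff_traces, ctr$difference)

    coh_res <- NULL
    if (isTRUE(cfg$connectivity$enabled)) {
      cs <- epoch_cross_spectra(rec, "stn", "cortex",
                                freqs = cfg$connectivity$freqs,
                                halfbw = cfg$connectivity$halfbw)
      usable <- !cs$labels$is_first & !cs$labels$is_last &
        !is.na(cs$labels$condition)
      cs_sub <- cs
      for (f in c("sxy", "sxx", "syy"))
        cs_sub[[f]] <- cs[[f]][usable, , , drop = FALSE]
      cs_sub$labels <- cs$labels[usable, , drop = FALSE]
      coh <- time_resolved_coherence(cs_sub, cs_sub$labels$condition)
      write_connectivity(coh, emit(file.path(out_dir, paste0("coherence", tag, ".csv"))))
      coh_ctr <- coherence_contrast(cs_sub,
                                    factor(cs_sub$labels$condition,
                                           c("same", "different")),
                                    n_perm = cfg$connectivity$n_perm,
                                    seed = sp)
      jsonlite::write_json(
        list(measure = coh_ctr$measure, n_perm = coh_ctr$n_perm,
             clusters = coh_ctr$clusters),
        emit(file.path(out_dir, paste0("coherence_contrast", tag, ".json"))),
        auto_unbox = TRUE, digits = NA, dataframe = "rows")
      coh_res <- list(coherence = coh, contrast = coh_ctr)
    }
    results[[s]] <- list(behavior = beh, fits = fits, commitment = commit,
                         glm = glm_res, contrast = ctr,
                         connectivity = coh_res)
  }

  if (cfg$n_subjects >= 4) {
    grp <- cluster_permutation_test(diff_traces, "signflip",
                                    n_perm = cfg$stats$n_perm,
                                    cluster_alpha = cfg$stats$cluster_alpha,
                                    alpha = cfg$stats$alpha,
                                    seed = stage_seed(cfg$seed, "group"))
    write_cluster_result(grp, emit(file.path(out_dir, "contrast_group.json")),
                         times = results[[1]]$contrast$times)
    results$group_contrast <- grp
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("accubeta")),
    config = cfg, stage_seeds = seeds,
    artifacts = lapply(stats::setNames(files, basename(files)),
                       function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(results = results, manifest = manifest, out_dir = out_dir))
}
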