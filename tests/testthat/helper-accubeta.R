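# shared fixture builders -- everything is generated in code at test time

# trials whose choices follow the logistic link over a chosen accumulator,
# with sequence length independent of the cues (keeps the link likelihood
# well specified for parameter-recovery checks)
gen_link_trials <- function(n, model = "M1", lambda = 0, omega = 0,
                            beta1 = 2, beta0 = 0, validity = 0.7, seed = 1) {
  set.seed(seed)
  pars <- accumulator_params(model, lambda, omega)
  ns <- sample(2:10, n, replace = TRUE)
  lapply(seq_len(n), function(i) {
    truth <- if (stats::runif(1) < 0.5) "L" else "R"
    tsgn <- if (truth == "R") 1 else -1
    s <- tsgn * ifelse(stats::runif(ns[i]) < validity, 1, -1)
    d <- compute_dv(s, pars)$dv
    pR <- stats::plogis(beta0 + beta1 * d[ns[i]])
    trial_record(i, truth, s,
                 choice = if (stats::runif(1) < pR) "R" else "L", rt = 0.5)
  })
}

# random cue sequences (no behaviour attached)
random_cue_seqs <- function(n, seed = 1, len = NULL) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    k <- if (is.null(len)) sample(2:10, 1) else len
    sample(c(-1, 1), k, replace = TRUE)
  })
}

# small behaviour + recording fixture for pipeline-level tests
quick_recording <- function(n_trials = 40, seed = 3, spec = neural_sim_spec(),
                            threshold = 3) {
  cfg <- task_config()
  trials <- simulate_behavior(cfg, agent_spec(threshold = threshold),
                              n_trials, seed = seed)
  reg <- cue_regressors(trials)
  rec <- simulate_recording(trials, reg, spec, cfg, seed = seed + 1000L)
  list(cfg = cfg, trials = trials, reg = reg, rec = rec)
}

# cross-spectra restricted to categorizable cues (drops first/last)
usable_cross_spectra <- function(cs) {
  ok <- !cs$labels$is_first & !cs$labels$is_last & !is.na(cs$labels$condition)
  for (f in c("sxy", "sxx", "syy")) cs[[f]] <- cs[[f]][ok, , , drop = FALSE]
  cs$labels <- cs$labels[ok, , drop = FALSE]
  cs
}
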