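#' Specification of a simulated decision agent
#'
#' An agent accumulates evidence according to an accumulator model and stops
#' sampling according to a stopping rule:
#' \describe{
#'   \item{`"threshold"`}{stop at the first cue where `|DV_t| >= threshold`.}
#'   \item{`"logistic"`}{stop after cue *t* with probability
#'     `plogis(b0 + b1 |DV_t| + b2 SA_t)` (`stop_beta = c(b0, b1, b2)`;
#'     `SA_1 = 0`). With `b1 = b2 = 0` this is a fixed-probability stopper
#'     whose commitment is independent of the cues.}
#' }
#' If the rule has not fired by `max_cues` the agent is forced to respond
#' (or, with `force_choice = FALSE`, records no choice). The response is the
#' sign of the final decision variable (ties broken by a fair coin) unless
#' `choice_policy = "random"`, in which case the agent guesses.
#'
#' @param params [accumulator_params()] for the agent's accumulator.
#' @param stop_rule `"threshold"` or `"logistic"`.
#' @param threshold Positive threshold on `|DV|` (threshold rule).
#' @param stop_beta Length-3 coefficients for the logistic rule.
#' @param max_cues Maximum cues per trial; at least 2.
#' @param choice_policy `"dv"` (sign of DV) or `"random"` (pure guess).
#' @param force_choice Commit at `max_cues` even if the rule never fired.
#' @return An `agent_spec` object.
#' @export
agent_spec <- function(params = accumulator_params("M1"),
                       stop_rule = c("threshold", "logistic"),
                       threshold = 2, stop_beta = c(-1, 0.5, 0.5),
                       max_cues = 10L,
                       choice_policy = c("dv", "random"),
                       force_choice = TRUE) {
  stop_rule <- match.arg(stop_rule)
  choice_policy <- match.arg(choice_policy)
  if (stop_rule == "threshold" && threshold < 1)
    stop("`threshold` must be >= 1 (|DV| after one cue is already 1)")
  if (max_cues < 2) stop("`max_cues` must be >= 2")
  structure(list(params = params, stop_rule = stop_rule,
                 threshold = threshold, stop_beta = stop_beta,
                 max_cues = as.integer(max_cues),
                 choice_policy = choice_policy,
                 force_choice = force_choice),
            class = "agent_spec")
}

#' Simulate behaviour of an agent on the expanded judgment task
#'
#' Each trial draws a true direction by a fair coin and a stream of cues
#' that independently match it with probability `cfg$validity`; the agent
#' accumulates and stops per its [agent_spec()]. Response latencies are
#' drawn from a log-normal with median ~0.5 s. Identical seeds give
#' bit-identical output.
#'
#' @param cfg [task_config()].
#' @param agent [agent_spec()].
#' @param n_trials Number of trials.
#' @param seed Integer seed.
#' @return List of [trial_record()]s, one per trial.
#' @export
simulate_behavior <- function(cfg, agent, n_trials, seed = 1L) {
  set.seed(seed)
  maxc <- agent$max_cues
  truth <- ifelse(stats::runif(n_trials) < 0.5, -1, 1)
  valid <- matrix(stats::runif(n_trials * maxc) < cfg$validity,
                  n_trials, maxc)
  S <- truth * ifelse(valid, 1, -1)
  SA <- matrix(0, n_trials, maxc)
  SA[, 2:maxc] <- (S[, 2:maxc, drop = FALSE] == S[, 1:(maxc - 1), drop = FALSE]) * 1
  lam <- agent$params$lambda; ome <- agent$params$omega
  DV <- matrix(0, n_trials, maxc)
  prev <- numeric(n_trials)
  for (t in seq_len(maxc)) {
    prev <- (1 - lam) * prev + (1 + ome * SA[, t]) * S[, t]
    DV[, t] <- prev
  }
  if (agent$stop_rule == "threshold") {
    fired <- abs(DV) >= agent$threshold
  } else {
    b <- agent$stop_beta
    p_stop <- stats::plogis(b[1] + b[2] * abs(DV) + b[3] * SA)
    fired <- matrix(stats::runif(n_trials * maxc), n_trials, maxc) < p_stop
  }
  n_stop <- apply(fired, 1, function(f) {
    w <- which(f)
    if (length(w)) w[1] else NA_integer_
  })
  committed <- !is.na(n_stop)
  n_stop[!committed] <- maxc
  dv_fin <- DV[cbind(seq_len(n_trials), n_stop)]
  coin <- ifelse(stats::runif(n_trials) < 0.5, -1, 1)
  ch_sign <- ifelse(dv_fin == 0, coin, sign(dv_fin))
  if (agent$choice_policy == "random")
    ch_sign <- ifelse(stats::runif(n_trials) < 0.5, -1, 1)
  rts <- stats::rlnorm(n_trials, log(0.5), 0.15)
  lapply(seq_len(n_trials), function(i) {
    has_choice <- committed[i] || agent$force_choice
    trial_record(i,
                 true_direction = if (truth[i] > 0) "R" else "L",
                 cues = S[i, seq_len(n_stop[i])],
                 choice = if (has_choice) {
                   if (ch_sign[i] > 0) "R" else "L"
                 } else "none",
                 rt = if (has_choice) rts[i] else NA_real_)
  })
}

#' Specification of the synthetic two-channel neural recording
#'
#' The generator writes a subthalamic ("stn") and a cortical ("cortex")
#' channel. The stn channel carries a beta-band oscillation whose per-cue
#' burst amplitude is a baseline plus a weighted sum of z-scored trial
#' regressors (same/different cue identity, absolute evidence, cue number,
#' Bayesian normalization); the cue-identity effect uses a two-lobed gain
#' window (an early dip followed by a late rise that carries over past the
#' next cue onset) so that "different" cues first suppress and then boost
#' beta power. The cortex channel shares the beta carrier with a fixed
#' phase lag and a condition-dependent gain when `coupling = "lagged"`.
#' Both channels receive independent 1/f noise.
#'
#' @param fs Sampling rate, Hz (default 300).
#' @param beta_freq Beta carrier, Hz (default 21.5, the 13-30 Hz band
#'   centre).
#' @param theta_freq Theta carrier, Hz (default 5); reserved, no theta
#'   effect is injected by default.
#' @param base_amp Baseline burst amplitude on every cue.
#' @param b_same_diff,b_absev,b_cuenum,b_norm Effect weights on the
#'   z-scored regressors.
#' @param coupling `"lagged"` (default) or `"none"`.
#' @param coupling_lag Phase lag of the cortical beta copy, radians.
#' @param coupling_gain_same,coupling_gain_diff Cortical coupling gain for
#'   cues that repeat / differ from their predecessor.
#' @param noise_exponent Spectral exponent of the 1/f background.
#' @param noise_amp Standard deviation of the background noise.
#' @return A `neural_sim_spec` object.
#' @export
neural_sim_spec <- function(fs = 300, beta_freq = 21.5, theta_freq = 5,
                            base_amp = 1, b_same_diff = 0.5, b_absev = 0.25,
                            b_cuenum = 0.25, b_norm = 0,
                            coupling = c("lagged", "none"),
                            coupling_lag = pi / 2,
                            coupling_gain_same = 0.5,
                            coupling_gain_diff = 1,
                            noise_exponent = 1, noise_amp = 0.5) {
  coupling <- match.arg(coupling)
  if (fs <= 2 * beta_freq) stop("`fs` must exceed twice the beta carrier")
  structure(as.list(environment()), class = "neural_sim_spec")
}

#' 1/f (power-law) background noise
#'
#' White Gaussian noise spectrally shaped so that power falls off as
#' `1/f^exponent`, then rescaled to unit standard deviation. The DC bin is
#' zeroed.
#'
#' @param n Number of samples.
#' @param exponent Spectral exponent (1 = pink).
#' @return Numeric vector of length `n`, SD 1.
#' @export
pink_noise <- function(n, exponent = 1) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- c(1, seq_len(n - 1))          # guard f = 0
  f <- pmin(f, n - f + 1)            # mirrored frequency index
  X <- X * f^(-exponent / 2)
  X[1] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  y / stats::sd(y)
}

# Hann lobe on [t0, t1] seconds relative to cue onset, sampled at fs;
# returns list(offset_samples, values)
hann_lobe <- function(t0, t1, fs) {
  i0 <- round(t0 * fs); i1 <- round(t1 * fs)
  n <- i1 - i0 + 1
  list(offset = i0, values = 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = n))))
}

#' Simulate a continuous two-channel recording for a set of trials
#'
#' Lays the trials out on a continuous timeline (cues at the task's SOA,
#' 2 s of silence between trials, 2 s padding at both ends), injects
#' amplitude-modulated beta bursts per [neural_sim_spec()], and returns a
#' `continuous_recording` with cue-onset markers. Negative envelope
#' excursions are clipped at zero and counted in `rec$log$n_clipped`.
#'
#' @param trials List of [trial_record()]s.
#' @param regressors Per-cue regressor table from [cue_regressors()] for
#'   the same trials.
#' @param spec [neural_sim_spec()].
#' @param cfg [task_config()] supplying the SOA.
#' @param seed Integer seed.
#' @return A `continuous_recording`: `data` (samples x 2 matrix), `fs`,
#'   `channels`, `markers` (data.frame: `sample` 1-based, `time`, `trial`,
#'   `cue_index`, `is_first`, `is_last`, `condition`), `log`.
#' @export
simulate_recording <- function(trials, regressors, spec = neural_sim_spec(),
                               cfg = task_config(), seed = 1L) {
  set.seed(seed)
  done <- Filter(function(tr) tr$choice != "none", trials)
  fs <- spec$fs
  soa_n <- round(cfg$soa * fs)
  gap_n <- round(2 * fs)
  pad_n <- round(2 * fs)
  ns <- vapply(done, function(tr) tr$n_sampled, integer(1))
  starts <- pad_n + c(0, cumsum(utils::head(ns * soa_n + gap_n, -1)))
  total_n <- pad_n + sum(ns * soa_n + gap_n) + pad_n

  # marker table: one row per presented cue
  mk <- do.call(rbind, lapply(seq_along(done), function(i) {
    tr <- done[[i]]
    idx <- seq_len(tr$n_sampled)
    data.frame(sample = starts[i] + (idx - 1) * soa_n + 1L,
               trial = tr$trial_id, cue_index = idx,
               is_first = idx == 1L, is_last = idx == tr$n_sampled,
               condition = c(NA, ifelse(tr$s[-1] == tr$s[-tr$n_sampled],
                                        "same", "different")))
  }))
  mk$time <- (mk$sample - 1) / fs

  # z-score the modulating regressors across usable (non-first) cues
  reg <- regressors[order(regressors$trial, regressors$cue_index), ]
  stopifnot(nrow(reg) == nrow(mk))
  zs <- function(x) {
    x <- x - mean(x, na.rm = TRUE)
    s <- stats::sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0) x * 0 else x / s
  }
  z_sd <- zs(1 - reg$cue_identity_same)   # +: "different" (conflict)
  z_ev <- zs(reg$abs_evidence)
  z_cn <- zs(reg$cue_number)
  z_no <- zs(reg$bayes_norm)

  base_lobe <- hann_lobe(0.10, 0.45, fs)
  dip_lobe  <- hann_lobe(0.05, 0.35, fs)
  rise_lobe <- hann_lobe(0.55, 1.15, fs)   # extends past the next cue onset
  coup_lobe <- hann_lobe(0.10, 0.90, fs)

  env_stn <- numeric(total_n)
  env_ctx <- numeric(total_n)
  add_lobe <- function(env, at, lobe, amp) {
    i <- at + lobe$offset + seq_along(lobe$values) - 1L
    keep <- i >= 1 & i <= total_n
    env[i[keep]] <- env[i[keep]] + amp * lobe$values[keep]
    env
  }
  for (j in seq_len(nrow(mk))) {
    at <- mk$sample[j]
    amp <- spec$base_amp +
      spec$b_absev * z_ev[j] + spec$b_cuenum * z_cn[j] + spec$b_norm * z_no[j]
    env_stn <- add_lobe(env_stn, at, base_lobe, amp)
    if (!is.na(mk$condition[j]) && spec$b_same_diff != 0) {
      sd_amp <- spec$b_same_diff * max(z_sd[j], 0)  # conflict cues only
      if (sd_amp > 0) {
        env_stn <- add_lobe(env_stn, at, dip_lobe, -0.5 * sd_amp)
        env_stn <- add_lobe(env_stn, at, rise_lobe, sd_amp)
      }
    }
    if (spec$coupling == "lagged") {
      g <- if (!is.na(mk$condition[j]) && mk$condition[j] == "different")
        spec$coupling_gain_diff else spec$coupling_gain_same
      env_ctx <- add_lobe(env_ctx, at, coup_lobe, g)
    }
  }
  n_clipped <- sum(env_stn < 0)
  env_stn <- pmax(env_stn, 0)
  env_ctx <- pmax(env_ctx, 0)

  tvec <- (seq_len(total_n) - 1) / fs
  # common beta carrier with a fresh phase per trial (breaks spurious
  # long-range phase locking across trials)
  phase <- numeric(total_n)
  for (i in seq_along(done)) {
    i0 <- starts[i]
    i1 <- if (i < length(done)) starts[i + 1] - 1L else total_n
    phase[i0:i1] <- stats::runif(1, 0, 2 * pi)
  }
  carrier <- cos(2 * pi * spec$beta_freq * tvec + phase)
  carrier_lag <- cos(2 * pi * spec$beta_freq * tvec + phase - spec$coupling_lag)

  stn <- env_stn * carrier + spec$noise_amp * pink_noise(total_n, spec$noise_exponent)
  ctx <- env_ctx * carrier_lag + spec$noise_amp * pink_noise(total_n, spec$noise_exponent)

  structure(list(
    data = cbind(stn = stn, cortex = ctx),
    fs = fs, channels = c("stn", "cortex"),
    markers = mk[, c("sample", "time", "trial", "cue_index",
                     "is_first", "is_last", "condition")],
    log = list(n_clipped = n_clipped, seed = seed)
  ), class = "continuous_recording")
}

#' Construct a continuous recording from raw components
#'
#' @param data Samples x channels numeric matrix.
#' @param fs Sampling rate in Hz.
#' @param markers Optional marker data.frame with at least a `sample`
#'   column (1-based sample indices).
#' @param channels Channel names; default the column names of `data`.
#' @return A `continuous_recording`.
#' @export
continuous_recording <- function(data, fs, markers = NULL, channels = colnames(data)) {
  data <- as.matrix(data)
  if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(data)))
  colnames(data) <- channels
  structure(list(data = data, fs = fs, channels = channels,
                 markers = markers, log = list()),
            class = "continuous_recording")
}

#' Write / read a recording as float32 binary plus JSON sidecar
#'
#' The signal matrix is stored channel-interleaved as little-endian float32
#' in `<prefix>.bin`; `<prefix>.json` documents `fs`, `channels`,
#' `n_samples` and the marker list with 0-based sample indices.
#'
#' @param rec A `continuous_recording`.
#' @param prefix Path prefix (without extension).
#' @return `write_recording` returns `prefix` invisibly; `read_recording`
#'   returns the `continuous_recording`.
#' @export
write_recording <- function(rec, prefix) {
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(rec$data)), con, size = 4, endian = "little")
  mk <- rec$markers
  side <- list(fs = rec$fs, channels = as.list(rec$channels),
               n_samples = nrow(rec$data), dtype = "float32",
               order = "channel-interleaved",
               markers = if (is.null(mk)) list() else {
                 mk0 <- mk; mk0$sample <- mk0$sample - 1L; mk0
               })
  jsonlite::write_json(side, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows")
  invisible(prefix)
}

#' @rdname write_recording
#' @export
read_recording <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  nch <- length(side$channels)
  con <- file(paste0(prefix, ".bin"), "rb")
  on.exit(close(con))
  x <- readBin(con, numeric(), n = side$n_samples * nch, size = 4,
               endian = "little")
  data <- matrix(x, ncol = nch, byrow = TRUE)
  mk <- side$markers
  if (is.data.frame(mk) && nrow(mk)) mk$sample <- mk$sample + 1L else mk <- NULL
  continuous_recording(data, side$fs, markers = mk,
                       channels = unlist(side$channels))
}
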