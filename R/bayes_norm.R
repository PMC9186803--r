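# overflow-safe log(exp(a) + exp(b))
logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  m + log(exp(a - m) + exp(b - m))
}

#' Bayesian normalization trace of a cue sequence
#'
#' Two cortical integrators \eqn{Y_L} and \eqn{Y_R} accumulate the left and
#' right cue indicators, each step subtracting the previous normalization
#' term; the normalization term itself is the log-sum-exp of the two
#' integrators,
#' \eqn{STN_t = \ln(e^{Y_{L,t}} + e^{Y_{R,t}})}.
#' Both integrators start at \eqn{\ln 0.5} (equal priors), so
#' \eqn{STN_0 = 0}. Forgetting and repetition-bonus terms of the selected
#' accumulator model are applied to the integrators so that
#' \eqn{Y_{R,t} - Y_{L,t}} always equals the decision variable \eqn{DV_t}
#' of [compute_dv()] under the same parameters:
#'
#' \deqn{Y_{L,t} = (1-\lambda) Y_{L,t-1} + (1+\omega SA_t) L_t - STN_{t-1}}
#' \deqn{Y_{R,t} = (1-\lambda) Y_{R,t-1} + (1+\omega SA_t) R_t - STN_{t-1}}
#'
#' with \eqn{L_t, R_t \in \{0, 1\}} the cue indicators. The normalization
#' term is the model-derived regressor for subthalamic activity; its
#' negative per-cue log-probability counterpart is [cue_surprise()].
#'
#' @param cues Cue sequence (`"L"`/`"R"` or -1/+1).
#' @param params An [accumulator_params()]; typically the BIC winner from
#'   [select_model()] for the participant being modelled.
#' @return A `normalization_trace` list with per-cue vectors `y_left`,
#'   `y_right`, `stn`, plus `stn0 = 0` for the pre-cue state.
#' @export
normalization_trace <- function(cues, params = accumulator_params("M1")) {
  s <- encode_cues(cues)
  n <- length(s)
  if (n == 0) stop("`cues` must be non-empty")
  sa <- c(0, as.numeric(s[-1] == s[-n]))
  gain <- 1 + params$omega * sa
  yl <- yr <- stn <- numeric(n)
  yl_prev <- yr_prev <- log(0.5)
  stn_prev <- logsumexp2(yl_prev, yr_prev)  # = 0
  for (t in seq_len(n)) {
    Lt <- as.numeric(s[t] < 0)
    Rt <- as.numeric(s[t] > 0)
    yl[t] <- (1 - params$lambda) * yl_prev + gain[t] * Lt - stn_prev
    yr[t] <- (1 - params$lambda) * yr_prev + gain[t] * Rt - stn_prev
    stn[t] <- logsumexp2(yl[t], yr[t])
    yl_prev <- yl[t]; yr_prev <- yr[t]; stn_prev <- stn[t]
  }
  structure(list(y_left = yl, y_right = yr, stn = stn, stn0 = 0),
            class = "normalization_trace")
}

#' Shannon surprise of each cue in a sequence
#'
#' Surprise of cue *i* is \eqn{-\ln P(cue_i \mid cue_1 \ldots cue_{i-1})}
#' under the task's generative model: a uniform prior over the two
#' directions updated by Bayes' rule with conditionally independent cues of
#' the given validity. Writing \eqn{q_i} for the posterior probability that
#' the true direction matches cue *i*'s identity,
#' \eqn{P(cue_i) = q_i v + (1 - q_i)(1 - v)}. The first cue always has
#' surprise \eqn{-\ln 0.5}; cues agreeing with the running majority are
#' less surprising than cues opposing it. This is the "global conflict"
#' regressor, the negative of the Bayesian normalization increment of the
#' task's ideal observer.
#'
#' @param cues Cue sequence (`"L"`/`"R"` or -1/+1).
#' @param validity Cue validity used by the observer; default the task's
#'   generative value 0.7.
#' @return Numeric vector of per-cue surprise values (nats).
#' @export
#' @examples
#' cue_surprise(c("R", "R"), 0.7)  # -log(0.5), -log(0.58)
cue_surprise <- function(cues, validity = 0.7) {
  if (validity <= 0.5 || validity >= 1)
    stop("`validity` must lie in (0.5, 1)")
  s <- encode_cues(cues)
  n <- length(s)
  llr_unit <- log(validity / (1 - validity))
  # posterior log-odds of direction R before each cue
  prior_lr <- c(0, cumsum(s))[seq_len(n)] * llr_unit
  p_right <- stats::plogis(prior_lr)
  q <- ifelse(s > 0, p_right, 1 - p_right)
  -log(q * validity + (1 - q) * (1 - validity))
}

#' Per-cue regressor table for neural analyses
#'
#' Builds, across a set of completed trials, the four per-cue regressors
#' used to model band power: cue identity (same = 1 / different = 0
#' relative to the preceding cue), the Bayesian normalization term, absolute
#' accumulated evidence, and the within-trial cue number, plus Shannon
#' surprise. The first cue of every trial (no preceding cue) and the final
#' sampled cue (overlapping the response) are flagged for exclusion
#' downstream but kept in the table.
#'
#' @param trials List of [trial_record()]s.
#' @param params [accumulator_params()] for the DV / normalization model.
#' @param validity Validity used for the surprise regressor.
#' @return A data.frame with columns `trial`, `cue_index`, `cue`,
#'   `cue_identity_same`, `abs_evidence`, `cue_number`, `bayes_norm`,
#'   `surprise`, `is_first`, `is_last`.
#' @export
cue_regressors <- function(trials, params = accumulator_params("M1"),
                           validity = 0.7) {
  done <- Filter(function(tr) tr$choice != "none", trials)
  out <- lapply(done, function(tr) {
    n <- tr$n_sampled
    dv <- compute_dv(tr$s, params)
    nt <- normalization_trace(tr$s, params)
    sur <- cue_surprise(tr$s, validity)
    data.frame(trial = tr$trial_id,
               cue_index = seq_len(n),
               cue = tr$cues,
               cue_identity_same = c(NA, as.numeric(tr$s[-1] == tr$s[-n])),
               abs_evidence = abs(dv$dv),
               cue_number = seq_len(n),
               bayes_norm = nt$stn,
               surprise = sur,
               is_first = seq_len(n) == 1L,
               is_last = seq_len(n) == n)
  })
  do.call(rbind, out)
}

#' Write a regressor table alongside the behaviour table
#'
#' @param regressors Output of [cue_regressors()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_regressors <- function(regressors, path) {
  utils::write.csv(regressors, path, row.names = FALSE, na = "")
  invisible(path)
}
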