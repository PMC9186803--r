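#' Evidence-accumulation model parameters
#'
#' Four nested accumulator models describe how a signed decision variable
#' (DV) is updated by each cue \eqn{S_t \in \{-1, +1\}} (left = -1,
#' right = +1), starting from \eqn{DV_0 = 0}:
#'
#' \describe{
#'   \item{M1 (perfect integrator)}{\eqn{DV_t = DV_{t-1} + S_t}}
#'   \item{M2 (forgetting)}{\eqn{DV_t = (1-\lambda) DV_{t-1} + S_t}}
#'   \item{M3 (repetition bonus)}{\eqn{DV_t = DV_{t-1} + (1+\omega SA_t) S_t}}
#'   \item{M4 (both)}{\eqn{DV_t = (1-\lambda) DV_{t-1} + (1+\omega SA_t) S_t}}
#' }
#'
#' where \eqn{SA_t = 1} if cue *t* repeats cue *t-1* and 0 otherwise. The
#' bonus is never applied to the first cue of a trial, for which a
#' repetition is undefined.
#'
#' @param model_id One of `"M1"`, `"M2"`, `"M3"`, `"M4"`.
#' @param lambda Forgetting rate in \[0, 1\]; forced to 0 for M1/M3.
#' @param omega Repetition-bonus weight; forced to 0 for M1/M2.
#' @return An `accumulator_params` object.
#' @export
#' @examples
#' compute_dv(c("R", "R", "L"), accumulator_params("M1"))$dv  # 1 2 1
accumulator_params <- function(model_id = c("M1", "M2", "M3", "M4"),
                               lambda = 0, omega = 0) {
  model_id <- match.arg(model_id)
  if (!is.numeric(lambda) || lambda < 0 || lambda > 1)
    stop("`lambda` must lie in [0, 1]")
  if (!is.finite(omega)) stop("`omega` must be finite")
  if (!model_id %in% c("M2", "M4")) lambda <- 0
  if (!model_id %in% c("M3", "M4")) omega <- 0
  structure(list(model_id = model_id, lambda = lambda, omega = omega),
            class = "accumulator_params")
}

# free parameters of the accumulator (on top of the two link coefficients)
free_params <- function(model_id)
  switch(model_id, M1 = character(0), M2 = "lambda", M3 = "omega",
         M4 = c("lambda", "omega"))

#' Decision-variable trace for a single cue sequence
#'
#' @param cues Cue sequence (`"L"`/`"R"` or -1/+1).
#' @param params An [accumulator_params()] object.
#' @return A `dv_trace` list with `dv` (DV after each cue), `s` (signed
#'   cues) and `sa` (repetition indicator, `NA` for the first cue).
#' @export
compute_dv <- function(cues, params = accumulator_params("M1")) {
  s <- encode_cues(cues)
  n <- length(s)
  if (n == 0) stop("`cues` must be non-empty")
  sa <- c(NA, as.numeric(s[-1] == s[-n]))
  gain <- 1 + params$omega * ifelse(is.na(sa), 0, sa)
  dv <- numeric(n)
  prev <- 0
  for (t in seq_len(n)) {
    prev <- (1 - params$lambda) * prev + gain[t] * s[t]
    dv[t] <- prev
  }
  structure(list(dv = dv, s = s, sa = sa), class = "dv_trace")
}

# --- vectorized internals over a padded trial matrix ------------------------

# pack completed trials into matrices: S (n x Tmax, 0-padded), SA, n_sampled,
# choice sign (+1 = R). Used by the likelihood and the regressor builders.
pack_trials <- function(trials) {
  done <- Filter(function(tr) tr$choice != "none", trials)
  if (length(done) == 0) stop("no completed trials")
  ns <- vapply(done, function(tr) tr$n_sampled, integer(1))
  tmax <- max(ns)
  S <- matrix(0, length(done), tmax)
  for (i in seq_along(done)) S[i, seq_len(ns[i])] <- done[[i]]$s
  SA <- matrix(0, length(done), tmax)
  if (tmax >= 2)
    SA[, 2:tmax] <- (S[, 2:tmax, drop = FALSE] ==
                       S[, 1:(tmax - 1), drop = FALSE]) &
      S[, 2:tmax, drop = FALSE] != 0
  ch <- vapply(done, function(tr) if (tr$choice == "R") 1 else -1, numeric(1))
  list(S = S, SA = SA * 1, n = ns, choice = ch, trials = done)
}

# full DV matrix (n x Tmax) under (lambda, omega); entries past n_sampled are
# meaningless (padding decays) and must not be read.
dv_matrix <- function(packed, lambda, omega) {
  S <- packed$S
  gain <- 1 + omega * packed$SA
  DV <- matrix(0, nrow(S), ncol(S))
  prev <- numeric(nrow(S))
  for (t in seq_len(ncol(S))) {
    prev <- (1 - lambda) * prev + gain[, t] * S[, t]
    DV[, t] <- prev
  }
  DV
}

dv_final <- function(packed, lambda, omega) {
  DV <- dv_matrix(packed, lambda, omega)
  DV[cbind(seq_len(nrow(DV)), packed$n)]
}

#' Log-likelihood of observed choices under the logistic link
#'
#' The probability of a rightward choice is
#' \eqn{P(R) = \mathrm{logit}^{-1}(\beta_0 + \beta_1 DV_T)} evaluated at the
#' final decision variable of each trial; the log-likelihood sums the
#' Bernoulli log-probabilities of the observed choices.
#'
#' @param trials List of [trial_record()]s (trials without a choice are
#'   ignored).
#' @param params [accumulator_params()] defining the DV recurrence.
#' @param beta0,beta1 Intercept and DV slope of the logistic link.
#' @return The summed log-likelihood.
#' @export
choice_loglik <- function(trials, params, beta0, beta1) {
  packed <- pack_trials(trials)
  loglik_packed(packed, params$lambda, params$omega, beta0, beta1)
}

loglik_packed <- function(packed, lambda, omega, beta0, beta1) {
  dvT <- dv_final(packed, lambda, omega)
  eta <- beta0 + beta1 * dvT
  # log P(observed): plogis on the signed linear predictor is numerically safe
  sum(stats::plogis(packed$choice * eta, log.p = TRUE))
}

#' Maximum-likelihood fit of one accumulator model
#'
#' Fits the link coefficients \eqn{(\beta_0, \beta_1)} together with the
#' model's free accumulator parameters (\eqn{\lambda} and/or \eqn{\omega})
#' by bounded quasi-Newton optimization (L-BFGS-B) from five fixed starting
#' points; the best converged run is returned. BIC is
#' \eqn{k \ln n - 2 \ln \hat L} with *k* the number of free parameters and
#' *n* the number of completed trials.
#'
#' @param trials List of [trial_record()]s; at least 20 completed trials.
#' @param model_id `"M1"`..`"M4"`.
#' @return A `choice_model_fit` list: `params`, `beta0`, `beta1`, `se`
#'   (Hessian-based standard errors of the fitted parameters), `loglik`,
#'   `bic`, `n_obs`, `k`, `convergence` (per-start optimizer codes).
#' @export
fit_choice_model <- function(trials, model_id = c("M1", "M2", "M3", "M4")) {
  model_id <- match.arg(model_id)
  packed <- pack_trials(trials)
  if (length(packed$n) < 20)
    stop("need at least 20 completed trials for a stable fit")
  fp <- free_params(model_id)
  lower <- c(beta0 = -20, beta1 = -20,
             lambda = 0, omega = -2)[c("beta0", "beta1", fp)]
  upper <- c(beta0 = 20, beta1 = 20,
             lambda = 1, omega = 2)[c("beta0", "beta1", fp)]
  negll <- function(par) {
    lam <- if ("lambda" %in% fp) par[["lambda"]] else 0
    ome <- if ("omega" %in% fp) par[["omega"]] else 0
    -loglik_packed(packed, lam, ome, par[["beta0"]], par[["beta1"]])
  }
  starts <- list(c(beta0 = 0, beta1 = 0.5, lambda = 0.1, omega = 0),
                 c(beta0 = 0, beta1 = 1,   lambda = 0.3, omega = 0.5),
                 c(beta0 = 0, beta1 = 2,   lambda = 0.5, omega = -0.5),
                 c(beta0 = 0, beta1 = 5,   lambda = 0.05, omega = 1),
                 c(beta0 = 0, beta1 = 0.1, lambda = 0.8, omega = 0.2))
  best <- NULL
  codes <- integer(0)
  for (st in starts) {
    par0 <- st[c("beta0", "beta1", fp)]
    fit <- tryCatch(
      stats::optim(par0, negll, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) { codes <- c(codes, NA_integer_); next }
    codes <- c(codes, fit$convergence)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best) || !any(codes == 0, na.rm = TRUE))
    stop("fit_choice_model: no start converged for ", model_id,
         " (codes: ", paste(codes, collapse = ","), ")")
  par <- best$par
  H <- stats::optimHess(par, negll)
  se <- tryCatch({
    v <- diag(solve(H))
    ifelse(v > 0, sqrt(pmax(v, 0)), NA_real_)
  }, error = function(e) rep(NA_real_, length(par)))
  names(se) <- names(par)
  k <- 2 + length(fp)
  n <- length(packed$n)
  ll <- -best$value
  structure(list(
    params = accumulator_params(
      model_id,
      lambda = if ("lambda" %in% fp) par[["lambda"]] else 0,
      omega = if ("omega" %in% fp) par[["omega"]] else 0),
    beta0 = par[["beta0"]], beta1 = par[["beta1"]],
    se = se, loglik = ll, k = k, n_obs = n,
    bic = k * log(n) - 2 * ll,
    convergence = codes
  ), class = "choice_model_fit")
}

#' Fit all four accumulator models and rank them by BIC
#'
#' @param trials List of [trial_record()]s.
#' @return A list of `choice_model_fit`s in ascending BIC order (the winner
#'   first); models whose fit fails are dropped with a warning.
#' @export
select_model <- function(trials) {
  fits <- list()
  for (m in c("M1", "M2", "M3", "M4")) {
    f <- tryCatch(fit_choice_model(trials, m), error = function(e) {
      warning("model ", m, " failed to fit: ", conditionMessage(e))
      NULL
    })
    if (!is.null(f)) fits[[m]] <- f
  }
  if (length(fits) == 0) stop("all models failed to fit")
  bics <- vapply(fits, `[[`, numeric(1), "bic")
  ks <- vapply(fits, `[[`, numeric(1), "k")
  fits[order(bics, ks)]  # ties broken toward the simpler model
}

#' Serialize model fits to JSON
#'
#' @param fits A single `choice_model_fit` or a list of them (as returned by
#'   [select_model()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fits <- function(fits, path) {
  if (inherits(fits, "choice_model_fit")) fits <- list(fits)
  out <- lapply(fits, function(f) list(
    model_id = f$params$model_id, lambda = f$params$lambda,
    omega = f$params$omega, beta0 = f$beta0, beta1 = f$beta1,
    loglik = f$loglik, bic = f$bic, n_obs = f$n_obs,
    convergence = f$convergence))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Choice-commitment logistic regression
#'
#' For every cue after the first on each completed trial, predicts whether
#' the choice was committed after that cue (`D_t = 1` on the final sampled
#' cue, 0 before) from two factors: the evidence accumulated for the
#' eventually chosen option (the decision variable signed toward the final
#' choice) and the repetition indicator `SA_t`. Each factor's Wald test at
#' `alpha` classifies the responder as `evidence_only`, `same_only`, `both`
#' or `neither`.
#'
#' Complete or quasi-complete separation (unbounded coefficients) is
#' detected and the model is refitted with a small ridge penalty; the fit is
#' then flagged in `separation`.
#'
#' @param trials List of [trial_record()]s.
#' @param params Accumulator used to form the evidence predictor; default
#'   the perfect integrator M1.
#' @param alpha Significance level for the classification. Default 0.05.
#' @return A `commitment_fit` list: `coef_evidence`, `coef_same`,
#'   `p_evidence`, `p_same`, `classification`, `separation`, `n_obs`.
#' @export
commitment_regression <- function(trials, params = accumulator_params("M1"),
                                  alpha = 0.05) {
  packed <- pack_trials(trials)
  DV <- dv_matrix(packed, params$lambda, params$omega)
  rows <- which(packed$n >= 2)
  d <- do.call(rbind, lapply(rows, function(i) {
    ts <- 2:packed$n[i]
    data.frame(D = as.numeric(ts == packed$n[i]),
               ev = DV[i, ts] * packed$choice[i],
               sa = packed$SA[i, ts])
  }))
  if (is.null(d) || nrow(d) < 10) stop("too few observations for regression")
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(D ~ ev + sa, family = stats::binomial(), data = d),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (sep || any(abs(stats::coef(fit)[-1]) > 15) || !fit$converged) {
    sep <- TRUE
    fit <- ridge_logistic(cbind(1, d$ev, d$sa), d$D, penalty = 1)
    co <- fit$coef; se <- fit$se
  } else {
    sm <- summary(fit)$coefficients
    co <- sm[, "Estimate"]; se <- sm[, "Std. Error"]
  }
  z <- co / se
  p <- 2 * stats::pnorm(-abs(z))
  sig_ev <- p[2] < alpha
  sig_sa <- p[3] < alpha
  cls <- if (sig_ev && sig_sa) "both" else if (sig_ev) "evidence_only"
  else if (sig_sa) "same_only" else "neither"
  structure(list(coef_evidence = unname(co[2]), coef_same = unname(co[3]),
                 p_evidence = unname(p[2]), p_same = unname(p[3]),
                 classification = cls, separation = sep, n_obs = nrow(d)),
            class = "commitment_fit")
}

# ridge-penalized logistic regression by IRLS (intercept unpenalized);
# used as the fallback under separation, where the MLE is unbounded
ridge_logistic <- function(X, y, penalty = 1, maxit = 100, tol = 1e-9) {
  p <- ncol(X)
  P <- diag(c(0, rep(penalty, p - 1)))
  beta <- numeric(p)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X, X * w) + P
    g <- crossprod(X, y - mu) - P %*% beta
    step <- solve(H, g)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  V <- solve(crossprod(X, X * pmax(stats::plogis(drop(X %*% beta)) *
                                     (1 - stats::plogis(drop(X %*% beta))),
                                   1e-10)) + P)
  list(coef = beta, se = sqrt(diag(V)))
}
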