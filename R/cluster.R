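# contiguous supra-threshold runs of a statistic series, split by sign.
# returns data.frame(start, end, mass)
find_clusters <- function(stat, threshold) {
  out <- list()
  for (sgn in c(1, -1)) {
    above <- sgn * stat > threshold
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (i in which(r$values)) {
      idx <- starts[i]:ends[i]
      out[[length(out) + 1]] <- data.frame(
        start = starts[i], end = ends[i], mass = sum(stat[idx]))
    }
  }
  if (length(out) == 0)
    return(data.frame(start = integer(0), end = integer(0), mass = numeric(0)))
  do.call(rbind, out)
}

# max |cluster mass| of one series (0 when no cluster forms)
max_cluster_mass <- function(stat, threshold) {
  cl <- find_clusters(stat, threshold)
  if (nrow(cl) == 0) 0 else max(abs(cl$mass))
}

# vectorized two-sample t per column for many permutations.
# Y: n x T; G: n_perm x n 0/1 membership of group 1. returns n_perm x T.
perm_t_two_sample <- function(Y, G) {
  n <- nrow(Y)
  n1 <- rowSums(G)
  n0 <- n - n1
  tot <- colSums(Y)
  tot2 <- colSums(Y^2)
  S1 <- G %*% Y
  S1sq <- G %*% Y^2
  m1 <- S1 / n1
  m0 <- (matrix(tot, nrow(G), ncol(Y), byrow = TRUE) - S1) / n0
  SS1 <- S1sq - n1 * m1^2
  SS0 <- (matrix(tot2, nrow(G), ncol(Y), byrow = TRUE) - S1sq) - n0 * m0^2
  sp2 <- pmax((SS1 + SS0) / (n - 2), 1e-300)
  (m1 - m0) / sqrt(sp2 * (1 / n1 + 1 / n0))
}

#' Per-timepoint ordinary least squares of band power on regressors
#'
#' Fits, independently at every timepoint of the epoch window, an OLS
#' regression of log band power on the design matrix, returning the
#' coefficient, standard error and t statistic of each regressor.
#'
#' @param Y Epochs x timepoints matrix of (log) power, or a
#'   `band_power_epochs` object.
#' @param X Design matrix (epochs x regressors) including an intercept
#'   column named `(Intercept)` — see [design_matrix()].
#' @return A `timepoint_glm` list with `coef`, `se`, `t` (regressors x
#'   timepoints matrices), `df` and the regressor names.
#' @export
timepoint_glm <- function(Y, X) {
  if (inherits(Y, "band_power_epochs")) Y <- Y$data
  X <- as.matrix(X)
  if (nrow(Y) != nrow(X)) stop("epochs and design have different row counts")
  if (nrow(Y) <= ncol(X) + 10)
    stop("too few epochs for a ", ncol(X), "-column design")
  if (anyNA(Y) || anyNA(X)) stop("missing values in power or design")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  A <- chol2inv(chol(crossprod(X)))
  XtY <- crossprod(X, Y)
  B <- A %*% XtY
  RSS <- colSums(Y^2) - colSums(XtY * B)
  df <- nrow(Y) - ncol(X)
  sigma2 <- pmax(RSS / df, 1e-300)
  se <- sqrt(outer(diag(A), sigma2))
  rownames(B) <- rownames(se) <- colnames(X)
  structure(list(coef = B, se = se, t = B / se, df = df,
                 regressors = colnames(X)),
            class = "timepoint_glm")
}

#' Build the z-scored design matrix from a regressor table
#'
#' Takes the per-cue regressor table of [cue_regressors()], drops the first
#' and last cue of every trial, and z-scores the four power regressors
#' (cue identity, Bayesian normalization, absolute evidence, cue number)
#' across the remaining epochs. Cue identity is coded 1 = "different"
#' (local conflict), 0 = "same" before scaling.
#'
#' @param regressors Data.frame from [cue_regressors()].
#' @param columns Regressor columns to include.
#' @return List: `X` (design with intercept), `keys` (trial / cue_index of
#'   each row, for alignment with epochs).
#' @export
design_matrix <- function(regressors,
                          columns = c("cue_identity_different", "bayes_norm",
                                      "abs_evidence", "cue_number")) {
  d <- regressors[!regressors$is_first & !regressors$is_last, , drop = FALSE]
  d$cue_identity_different <- 1 - d$cue_identity_same
  Z <- vapply(columns, function(cn) {
    x <- d[[cn]]
    (x - mean(x)) / stats::sd(x)
  }, numeric(nrow(d)))
  X <- cbind(`(Intercept)` = 1, Z)
  list(X = X, keys = d[, c("trial", "cue_index")])
}

#' Cluster-based permutation test on a statistic time series
#'
#' Forms clusters as contiguous runs where |t| exceeds the two-sided
#' parametric critical value at `cluster_alpha`, takes the summed t within
#' each run as the cluster mass, and compares each observed mass against
#' the permutation null distribution of the maximum |mass|; the family-wise
#' p value is `(1 + #{null >= observed}) / (1 + n_perm)`.
#'
#' Three exchangeability schemes are supported:
#' \describe{
#'   \item{`"labels"`}{`Y` holds one epoch per row and `labels` a two-level
#'     condition factor; the statistic is the two-sample t (second factor
#'     level minus first; for a character vector, alphabetical order) and
#'     permutations shuffle the labels.}
#'   \item{`"design"`}{`Y` epochs x time, `design` a full design matrix;
#'     the statistic is the OLS t of each non-intercept regressor and
#'     permutations shuffle the design rows jointly (preserving the
#'     inter-regressor correlation).}
#'   \item{`"signflip"`}{`Y` holds one participant-level difference trace
#'     per row; the statistic is the one-sample t and permutations flip
#'     row signs (group-level test).}
#' }
#'
#' @param Y Numeric matrix, rows exchangeable units, columns timepoints.
#' @param scheme `"labels"`, `"design"` or `"signflip"`.
#' @param labels Two-level factor/vector (labels scheme).
#' @param design Design matrix with intercept (design scheme).
#' @param n_perm Number of permutations (default 1000; < 100 warns).
#' @param cluster_alpha Two-sided alpha of the cluster-forming threshold.
#' @param alpha Family-wise significance level reported in `significant`.
#' @param seed Integer seed for the permutation draw.
#' @return A `cluster_result` (or, for `"design"`, a named list of them,
#'   one per non-intercept regressor): `stat` per timepoint, `threshold`,
#'   `clusters` data.frame (`start`, `end`, `mass`, `p_fwe`, `cohen_d`,
#'   `significant`), `null_max`, `n_perm`, `df`.
#' @export
cluster_permutation_test <- function(Y, scheme = c("labels", "design", "signflip"),
                                     labels = NULL, design = NULL,
                                     n_perm = 1000, cluster_alpha = 0.05,
                                     alpha = 0.05, seed = 1L) {
  scheme <- match.arg(scheme)
  if (inherits(Y, "band_power_epochs")) Y <- Y$data
  Y <- as.matrix(Y)
  if (n_perm < 100) warning("n_perm < 100 gives a coarse p-value grid")
  set.seed(seed)
  n <- nrow(Y)

  if (scheme == "labels") {
    lv <- if (is.factor(labels)) levels(labels) else sort(unique(as.character(labels)))
    if (length(lv) != 2) stop("`labels` must have exactly two levels")
    g <- as.numeric(as.character(labels) == lv[2])
    if (min(sum(g), n - sum(g)) < 10)
      stop("a condition has fewer than 10 epochs")
    df <- n - 2
    thr <- stats::qt(1 - cluster_alpha / 2, df)
    t_obs <- drop(perm_t_two_sample(Y, matrix(g, 1)))
    G <- t(vapply(seq_len(n_perm), function(i) sample(g), numeric(n)))
    Tp <- perm_t_two_sample(Y, G)
    null_max <- apply(Tp, 1, max_cluster_mass, threshold = thr)
    res <- finalize_clusters(t_obs, thr, null_max, n_perm, alpha)
    res$df <- df
    # Cohen's d: cluster-mean difference / pooled SD of cluster means
    if (nrow(res$clusters)) {
      res$clusters$cohen_d <- vapply(seq_len(nrow(res$clusters)), function(i) {
        idx <- res$clusters$start[i]:res$clusters$end[i]
        ym <- rowMeans(Y[, idx, drop = FALSE])
        sp <- sqrt(((sum(g == 1) - 1) * stats::var(ym[g == 1]) +
                      (sum(g == 0) - 1) * stats::var(ym[g == 0])) / (n - 2))
        (mean(ym[g == 1]) - mean(ym[g == 0])) / sp
      }, numeric(1))
    }
    return(res)
  }

  if (scheme == "signflip") {
    df <- n - 1
    thr <- stats::qt(1 - cluster_alpha / 2, df)
    one_t <- function(S) {  # S: n_perm x n of +-1
      M <- S %*% Y / n
      V <- (matrix(colSums(Y^2), nrow(S), ncol(Y), byrow = TRUE) - n * M^2) / df
      M / sqrt(pmax(V, 1e-300) / n)
    }
    t_obs <- drop(one_t(matrix(1, 1, n)))
    S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    null_max <- apply(one_t(S), 1, max_cluster_mass, threshold = thr)
    res <- finalize_clusters(t_obs, thr, null_max, n_perm, alpha)
    res$df <- df
    if (nrow(res$clusters)) {
      res$clusters$cohen_d <- vapply(seq_len(nrow(res$clusters)), function(i) {
        ym <- rowMeans(Y[, res$clusters$start[i]:res$clusters$end[i],
                         drop = FALSE])
        mean(ym) / stats::sd(ym)
      }, numeric(1))
    }
    return(res)
  }

  # scheme == "design": one result per non-intercept regressor
  X <- as.matrix(design)
  fit <- timepoint_glm(Y, X)
  thr <- stats::qt(1 - cluster_alpha / 2, fit$df)
  regs <- setdiff(seq_len(ncol(X)), which(colnames(X) == "(Intercept)"))
  A <- chol2inv(chol(crossprod(X)))     # row-permutation invariant
  tot2 <- colSums(Y^2)
  null_max <- matrix(0, n_perm, length(regs))
  for (p in seq_len(n_perm)) {
    Xp <- X[sample(n), , drop = FALSE]
    XtY <- crossprod(Xp, Y)
    B <- A %*% XtY
    sigma2 <- pmax((tot2 - colSums(XtY * B)) / fit$df, 1e-300)
    for (ri in seq_along(regs)) {
      j <- regs[ri]
      tp <- B[j, ] / sqrt(A[j, j] * sigma2)
      null_max[p, ri] <- max_cluster_mass(tp, thr)
    }
  }
  out <- list()
  for (ri in seq_along(regs)) {
    j <- regs[ri]
    res <- finalize_clusters(fit$t[j, ], thr, null_max[, ri], n_perm, alpha)
    res$df <- fit$df
    if (nrow(res$clusters)) {
      # standardized partial effect per cluster (t-to-d conversion)
      res$clusters$cohen_d <- vapply(seq_len(nrow(res$clusters)), function(i) {
        idx <- res$clusters$start[i]:res$clusters$end[i]
        mean(fit$t[j, idx]) / sqrt(n)
      }, numeric(1))
    }
    out[[colnames(X)[j]]] <- res
  }
  out
}

# assemble a cluster_result from observed stat, threshold and null maxima
finalize_clusters <- function(t_obs, threshold, null_max, n_perm, alpha) {
  cl <- find_clusters(t_obs, threshold)
  if (nrow(cl)) {
    cl$p_fwe <- vapply(cl$mass, function(m)
      (1 + sum(null_max >= abs(m))) / (1 + n_perm), numeric(1))
    cl$cohen_d <- NA_real_
    cl$significant <- cl$p_fwe < alpha
    cl <- cl[order(cl$p_fwe, -abs(cl$mass)), , drop = FALSE]
  } else {
    cl$p_fwe <- numeric(0); cl$cohen_d <- numeric(0)
    cl$significant <- logical(0)
  }
  structure(list(stat = t_obs, threshold = threshold, clusters = cl,
                 null_max = null_max, n_perm = n_perm, alpha = alpha),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Cluster permutation test: %d timepoints, |t| > %.2f, %d permutations\n",
              length(x$stat), x$threshold, x$n_perm))
  if (nrow(x$clusters) == 0) cat("  no clusters formed\n")
  else print(x$clusters, row.names = FALSE)
  invisible(x)
}

#' Combined GLM of band power with cluster correction
#'
#' Aligns epoched band power with the per-cue regressor table (dropping
#' first/last cues), z-scores the regressors, fits the per-timepoint OLS
#' and runs the cluster permutation test for every regressor.
#'
#' @param epochs A `band_power_epochs` from [epoch_power()].
#' @param regressors Table from [cue_regressors()].
#' @param n_perm,cluster_alpha,alpha,seed Passed to
#'   [cluster_permutation_test()].
#' @return List: `glm` (the [timepoint_glm()] fit), `clusters` (named list
#'   of `cluster_result` per regressor), `times` (epoch timebase, s).
#' @export
band_power_glm <- function(epochs, regressors, n_perm = 1000,
                           cluster_alpha = 0.05, alpha = 0.05, seed = 1L) {
  dm <- design_matrix(regressors)
  lab <- epochs$labels
  key_e <- paste(lab$trial, lab$cue_index)
  key_x <- paste(dm$keys$trial, dm$keys$cue_index)
  keep_e <- match(key_x, key_e)
  if (anyNA(keep_e)) {
    ok <- !is.na(keep_e)
    dm$X <- dm$X[ok, , drop = FALSE]
    keep_e <- keep_e[ok]
  }
  Y <- epochs$data[keep_e, , drop = FALSE]
  # re-z-score after any epoch loss so columns stay mean 0 / SD 1
  for (j in seq(2, ncol(dm$X)))
    dm$X[, j] <- (dm$X[, j] - mean(dm$X[, j])) / stats::sd(dm$X[, j])
  list(glm = timepoint_glm(Y, dm$X),
       clusters = cluster_permutation_test(Y, "design", design = dm$X,
                                           n_perm = n_perm,
                                           cluster_alpha = cluster_alpha,
                                           alpha = alpha, seed = seed),
       times = epochs$times_rel)
}

#' Same/different condition contrast with carry-over epochs
#'
#' Categorizes every cue (excluding each trial's first and last) as "same"
#' or "different" relative to its predecessor, extracts the band-power
#' epoch locked to that cue and, with `carryover > 0`, also the epochs
#' locked to the following cue(s) labelled by the relation at the original
#' cue. The per-cue segments are concatenated on a common 0 to
#' `0.8 * (carryover + 1)` s timebase (e.g. 0-1600 ms for cue i and
#' cue i+1), the mean difference trace (different minus same) and its 95%
#' CI are computed, and the cluster permutation test is applied.
#'
#' `mode = "pooled"` treats epochs as exchangeable units (label shuffle);
#' `mode = "group"` averages the difference trace within each subject and
#' sign-flips across subjects.
#'
#' @param pts A filtered `power_timeseries` carrying markers with `trial`,
#'   `cue_index`, `is_first`, `is_last`, `condition` columns (and
#'   optionally `subject` for group mode).
#' @param carryover Number of following cues to append (default 1).
#' @param channel Channel to analyse.
#' @param mode `"pooled"` or `"group"`.
#' @param n_perm,cluster_alpha,alpha,seed Passed to
#'   [cluster_permutation_test()].
#' @return List: `times` (s, concatenated timebase), `difference` trace,
#'   `ci_low`/`ci_high`, `n_same`/`n_different`, `cluster` (a
#'   `cluster_result`).
#' @export
same_different_contrast <- function(pts, carryover = 1, channel = 1,
                                    mode = c("pooled", "group"),
                                    n_perm = 1000, cluster_alpha = 0.05,
                                    alpha = 0.05, seed = 1L) {
  mode <- match.arg(mode)
  mk <- pts$markers
  if (is.null(mk)) stop("power series carries no markers")
  hop <- 1 / pts$fs_power
  seg_idx <- 0:(round(0.8 / hop) - 1)          # 0 .. 750 ms per segment
  usable <- which(!mk$is_first & !mk$is_last & !is.na(mk$condition))
  onset_t <- (mk$sample - 1) / pts$fs_raw
  centre <- vapply(onset_t, function(tt) which.min(abs(pts$times - tt)),
                   integer(1))
  segs <- list(); labs <- character(0); subj <- character(0); trial <- integer(0)
  for (i in usable) {
    cols <- NULL
    ok <- TRUE
    for (o in 0:carryover) {
      j <- which(mk$trial == mk$trial[i] & mk$cue_index == mk$cue_index[i] + o)
      if ("subject" %in% names(mk))
        j <- j[mk$subject[j] == mk$subject[i]]
      if (length(j) != 1) { ok <- FALSE; break }
      idx <- centre[j] + seg_idx
      if (any(idx < 1 | idx > length(pts$times))) { ok <- FALSE; break }
      cols <- c(cols, pts$logpower[idx, channel])
    }
    if (!ok) next
    segs[[length(segs) + 1]] <- cols
    labs <- c(labs, mk$condition[i])
    trial <- c(trial, mk$trial[i])
    subj <- c(subj, if ("subject" %in% names(mk)) mk$subject[i] else "s1")
  }
  if (length(segs) < 20) stop("too few usable cue epochs for the contrast")
  Y <- do.call(rbind, segs)
  times <- rep(seg_idx * hop, carryover + 1) +
    rep(0.8 * (0:carryover), each = length(seg_idx))
  n_same <- sum(labs == "same"); n_diff <- sum(labs == "different")
  if (min(n_same, n_diff) < 10) stop("a condition has fewer than 10 epochs")
  diff_trace <- colMeans(Y[labs == "different", , drop = FALSE]) -
    colMeans(Y[labs == "same", , drop = FALSE])
  se_tr <- sqrt(apply(Y[labs == "different", , drop = FALSE], 2, stats::var) / n_diff +
                  apply(Y[labs == "same", , drop = FALSE], 2, stats::var) / n_same)
  if (mode == "pooled") {
    cl <- cluster_permutation_test(Y, "labels",
                                   labels = factor(labs, c("same", "different")),
                                   n_perm = n_perm,
                                   cluster_alpha = cluster_alpha,
                                   alpha = alpha, seed = seed)
  } else {
    us <- unique(subj)
    if (length(us) < 4) stop("group mode needs at least 4 subjects")
    D <- t(vapply(us, function(s) {
      colMeans(Y[subj == s & labs == "different", , drop = FALSE]) -
        colMeans(Y[subj == s & labs == "same", , drop = FALSE])
    }, numeric(ncol(Y))))
    cl <- cluster_permutation_test(D, "signflip", n_perm = n_perm,
                                   cluster_alpha = cluster_alpha,
                                   alpha = alpha, seed = seed)
  }
  list(times = times, difference = diff_trace,
       ci_low = diff_trace - 1.96 * se_tr,
       ci_high = diff_trace + 1.96 * se_tr,
       n_same = n_same, n_different = n_diff, mode = mode, cluster = cl)
}

#' Serialize a cluster result (or list of them) to JSON
#'
#' @param x `cluster_result` or named list of them.
#' @param path Output file.
#' @param times Optional timebase (s) used to convert cluster extents to ms.
#' @return `path`, invisibly.
#' @export
write_cluster_result <- function(x, path, times = NULL) {
  as_item <- function(r) {
    cl <- r$clusters
    if (!is.null(times) && nrow(cl)) {
      cl$start_ms <- round(1000 * times[cl$start])
      cl$end_ms <- round(1000 * times[cl$end])
    }
    list(threshold = r$threshold, n_perm = r$n_perm, alpha = r$alpha,
         clusters = cl)
  }
  out <- if (inherits(x, "cluster_result")) as_item(x) else lapply(x, as_item)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
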