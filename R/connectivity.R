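#' Epoched sliding-window cross-spectra between two channels
#'
#' Runs the sliding multitaper transform (same engine as
#' [continuous_band_power()]) on both channels over a 1-30 Hz grid at 1 Hz
#' spacing with +/-2.5 Hz smoothing, then epochs the complex coefficients
#' around each marker (default -1 to 1 s, widened relative to the power
#' epochs to give the coherence analysis more support). Taper-summed
#' cross- and auto-spectra are accumulated per epoch.
#'
#' @param rec A `continuous_recording` with at least two channels.
#' @param chx,chy Channel names or indices (default the first two).
#' @param markers Marker data.frame (defaults to `rec$markers`).
#' @param window Epoch window in seconds, default `c(-1, 1)`.
#' @param freqs Frequency grid in Hz, default `1:30`.
#' @param halfbw Spectral half-bandwidth in Hz, default 2.5.
#' @param mt_window Sliding window length in seconds, default 0.4.
#' @param hop Window step, seconds, default 0.05.
#' @return A `cross_spectra` object: complex array `sxy` and real arrays
#'   `sxx`, `syy` (epoch x time x frequency), `times_rel`, `freqs`,
#'   `labels` (marker rows kept), `n_dropped`, `k` (tapers).
#' @export
epoch_cross_spectra <- function(rec, chx = 1, chy = 2, markers = rec$markers,
                                window = c(-1, 1), freqs = 1:30,
                                halfbw = 2.5, mt_window = 0.4, hop = 0.05) {
  if (is.null(markers)) stop("no markers available")
  nw <- mt_window * halfbw
  k <- max(floor(2 * nw) - 1, 1)
  cx <- sliding_mt_coef(rec$data[, chx], rec$fs, freqs, mt_window, hop, nw, k)
  cy <- sliding_mt_coef(rec$data[, chy], rec$fs, freqs, mt_window, hop, nw, k)
  nf <- length(freqs); nwin <- length(cx$times)
  rel_idx <- round(window[1] / hop):round(window[2] / hop)
  onset_t <- (markers$sample - 1) / rec$fs
  centre <- vapply(onset_t, function(tt) which.min(abs(cx$times - tt)),
                   integer(1))
  ok <- centre + min(rel_idx) >= 1 & centre + max(rel_idx) <= nwin
  ne <- sum(ok); nt <- length(rel_idx)
  sxy <- array(0 + 0i, c(ne, nt, nf))
  sxx <- syy <- array(0, c(ne, nt, nf))
  which_ok <- which(ok)
  for (e in seq_len(ne)) {
    cols <- centre[which_ok[e]] + rel_idx
    for (fi in seq_len(nf)) {
      rows <- (fi - 1) * k + seq_len(k)
      X <- cx$coef[rows, cols, drop = FALSE]
      Y <- cy$coef[rows, cols, drop = FALSE]
      sxy[e, , fi] <- colSums(X * Conj(Y))
      sxx[e, , fi] <- colSums(abs(X)^2)
      syy[e, , fi] <- colSums(abs(Y)^2)
    }
  }
  structure(list(sxy = sxy, sxx = sxx, syy = syy,
                 times_rel = rel_idx * hop, freqs = freqs,
                 labels = markers[ok, , drop = FALSE],
                 n_dropped = sum(!ok), k = k),
            class = "cross_spectra")
}

# sum an (epoch x time x freq) array over a subset of epochs -> time x freq
sum_epochs <- function(arr, idx) {
  m <- matrix(arr[idx, , , drop = FALSE], length(idx), dim(arr)[2] * dim(arr)[3])
  matrix(colSums(m), dim(arr)[2], dim(arr)[3])
}

#' Time-resolved magnitude coherence between two channels
#'
#' Trial-based estimator: at every (time, frequency) cell,
#' \eqn{Coh = |\sum_e S_{xy}| / \sqrt{\sum_e S_{xx} \sum_e S_{yy}}}
#' with the sums running over epochs (and tapers). With `labels`, one
#' coherence surface per condition is returned. Cells with zero
#' auto-spectrum are masked to `NA` and counted.
#'
#' @param cs A `cross_spectra` from [epoch_cross_spectra()].
#' @param labels Optional per-epoch condition labels.
#' @return A `coherence_result`: `coherence` (time x freq matrix, or named
#'   list per condition), `n_epochs`, `times`, `freqs`, `n_masked`.
#' @export
time_resolved_coherence <- function(cs, labels = NULL) {
  one <- function(idx) {
    num <- abs(sum_epochs(cs$sxy, idx))
    den2 <- Re(sum_epochs(cs$sxx, idx)) * Re(sum_epochs(cs$syy, idx))
    bad <- den2 <= 0
    num[bad] <- NA
    den2[bad] <- 1
    list(coh = num / sqrt(den2), masked = sum(bad))
  }
  if (is.null(labels)) {
    r <- one(seq_len(dim(cs$sxy)[1]))
    return(structure(list(coherence = r$coh, n_epochs = dim(cs$sxy)[1],
                          times = cs$times_rel, freqs = cs$freqs,
                          n_masked = r$masked),
                     class = "coherence_result"))
  }
  lv <- sort(unique(as.character(labels)))
  rs <- lapply(lv, function(l) one(which(labels == l)))
  structure(list(coherence = stats::setNames(lapply(rs, `[[`, "coh"), lv),
                 n_epochs = stats::setNames(
                   vapply(lv, function(l) sum(labels == l), numeric(1)), lv),
                 times = cs$times_rel, freqs = cs$freqs,
                 n_masked = sum(vapply(rs, `[[`, numeric(1), "masked"))),
            class = "coherence_result")
}

#' Debiased weighted phase-lag index
#'
#' Debiased WPLI-square estimator from the imaginary parts of the
#' epoch-wise cross-spectra: with \eqn{I_e = \Im S_{xy,e}},
#' \deqn{dwPLI = \frac{(\sum_e I_e)^2 - \sum_e I_e^2}
#'                    {(\sum_e |I_e|)^2 - \sum_e I_e^2},}
#' reported with the sign of \eqn{\sum_e I_e} attached so that the value
#' lies in \[-1, 1\] and flips when the lag direction flips.
#' Insensitive to zero-lag (volume-conduction-like) coupling, and its
#' expectation does not depend on the number of epochs, which makes it
#' robust to unequal trial counts across conditions. Cells where every
#' imaginary part is zero are returned as 0 and counted as degenerate.
#'
#' @param cs A `cross_spectra`.
#' @param labels Optional per-epoch condition labels.
#' @return A `dwpli_result`: `dwpli` (time x freq, or named list per
#'   condition), `times`, `freqs`, `n_degenerate`.
#' @export
debiased_wpli <- function(cs, labels = NULL) {
  I <- Im(cs$sxy)
  one <- function(idx) {
    s1 <- sum_epochs(I, idx)
    s2 <- sum_epochs(I^2, idx)
    sa <- sum_epochs(abs(I), idx)
    num <- s1^2 - s2
    den <- sa^2 - s2
    deg <- den <= 0
    # signed variant: debiased square with the sign of the summed
    # imaginary part, so the value tracks the direction of the lag
    out <- sign(s1) * num / ifelse(deg, 1, den)
    out[deg] <- 0
    list(v = out, deg = sum(deg))
  }
  if (is.null(labels)) {
    r <- one(seq_len(dim(I)[1]))
    return(structure(list(dwpli = r$v, times = cs$times_rel,
                          freqs = cs$freqs, n_degenerate = r$deg),
                     class = "dwpli_result"))
  }
  lv <- sort(unique(as.character(labels)))
  rs <- lapply(lv, function(l) one(which(labels == l)))
  structure(list(dwpli = stats::setNames(lapply(rs, `[[`, "v"), lv),
                 times = cs$times_rel, freqs = cs$freqs,
                 n_degenerate = sum(vapply(rs, `[[`, numeric(1), "deg"))),
            class = "dwpli_result")
}

# 4-connected components of a logical matrix; returns integer label matrix
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (j in seq_len(ncol(mask))) for (i in seq_len(nrow(mask))) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    stack <- list(c(i, j))
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      pi <- p[1]; pj <- p[2]
      if (pi < 1 || pj < 1 || pi > nrow(mask) || pj > ncol(mask)) next
      if (!mask[pi, pj] || lab[pi, pj] != 0L) next
      lab[pi, pj] <- cur
      stack <- c(stack, list(c(pi - 1, pj), c(pi + 1, pj),
                             c(pi, pj - 1), c(pi, pj + 1)))
    }
  }
  lab
}

# clusters of a 2D z map: contiguous cells with z beyond +-threshold,
# sign-consistent; mass = sum z
find_clusters_2d <- function(z, threshold) {
  out <- list()
  for (sgn in c(1, -1)) {
    lab <- label_components(sgn * z > threshold)
    for (l in seq_len(max(lab))) {
      idx <- which(lab == l)
      out[[length(out) + 1]] <- list(cells = idx, mass = sum(z[idx]))
    }
  }
  out
}

#' Condition contrast of coherence (or dwPLI) with 2D cluster correction
#'
#' Computes the per-condition estimate at each (time, frequency) cell,
#' takes the difference (second factor level minus first; pass
#' `factor(labels, c("same", "different"))` for a different-minus-same
#' contrast), and tests it by shuffling epoch labels. Each cell is z-scored against
#' its permutation distribution, clusters are 4-connected regions with
#' |z| above the `cluster_alpha` two-sided normal critical value, cluster
#' mass is the summed z, and the family-wise p compares each mass to the
#' permutation null of the maximum |mass|.
#'
#' @param cs A `cross_spectra`.
#' @param labels Two-level condition labels, one per epoch.
#' @param measure `"coherence"` or `"dwpli"`.
#' @param n_perm Number of permutations, default 500.
#' @param cluster_alpha,alpha Cluster-forming and family-wise levels.
#' @param seed Integer seed.
#' @return A `coherence_contrast` list: `difference` (time x freq), `z`,
#'   `clusters` (data.frame with `mass`, `p_fwe`, `significant`, time and
#'   frequency extents), `cluster_cells` (list of cell indices), `times`,
#'   `freqs`, `n_perm`.
#' @export
coherence_contrast <- function(cs, labels, measure = c("coherence", "dwpli"),
                               n_perm = 500, cluster_alpha = 0.05,
                               alpha = 0.05, seed = 1L) {
  measure <- match.arg(measure)
  set.seed(seed)
  lv <- if (is.factor(labels)) levels(labels) else sort(unique(as.character(labels)))
  if (length(lv) != 2) stop("`labels` must have exactly two levels")
  g <- as.character(labels) == lv[2]
  ne <- dim(cs$sxy)[1]
  if (min(sum(g), ne - sum(g)) < 20)
    stop("need at least 20 epochs per condition")
  est <- function(idx) {
    if (measure == "coherence") {
      num <- abs(sum_epochs(cs$sxy, idx))
      den2 <- Re(sum_epochs(cs$sxx, idx)) * Re(sum_epochs(cs$syy, idx))
      num / sqrt(pmax(den2, 1e-300))
    } else {
      I <- Im(cs$sxy)
      s1 <- sum_epochs(I, idx); s2 <- sum_epochs(I^2, idx)
      sa <- sum_epochs(abs(I), idx)
      den <- sa^2 - s2
      out <- (s1^2 - s2) / ifelse(den <= 0, 1, den)
      out[den <= 0] <- 0
      out
    }
  }
  obs <- est(which(g)) - est(which(!g))
  nt <- dim(cs$sxy)[2]; nf <- dim(cs$sxy)[3]
  perm <- matrix(0, n_perm, nt * nf)
  for (p in seq_len(n_perm)) {
    gp <- sample(g)
    perm[p, ] <- as.vector(est(which(gp)) - est(which(!gp)))
  }
  mu <- colMeans(perm)
  sdv <- pmax(apply(perm, 2, stats::sd), 1e-12)
  z_obs <- matrix((as.vector(obs) - mu) / sdv, nt, nf)
  zthr <- stats::qnorm(1 - cluster_alpha / 2)
  null_max <- vapply(seq_len(n_perm), function(p) {
    zp <- matrix((perm[p, ] - mu) / sdv, nt, nf)
    cl <- find_clusters_2d(zp, zthr)
    if (length(cl)) max(abs(vapply(cl, `[[`, numeric(1), "mass"))) else 0
  }, numeric(1))
  cl <- find_clusters_2d(z_obs, zthr)
  if (length(cl)) {
    df <- do.call(rbind, lapply(cl, function(c1) {
      rc <- arrayInd(c1$cells, c(nt, nf))
      data.frame(mass = c1$mass,
                 t_min = cs$times_rel[min(rc[, 1])],
                 t_max = cs$times_rel[max(rc[, 1])],
                 f_min = cs$freqs[min(rc[, 2])],
                 f_max = cs$freqs[max(rc[, 2])],
                 p_fwe = (1 + sum(null_max >= abs(c1$mass))) / (1 + n_perm))
    }))
    df$significant <- df$p_fwe < alpha
    ord <- order(df$p_fwe, -abs(df$mass))
    df <- df[ord, , drop = FALSE]
    cells <- lapply(cl, `[[`, "cells")[ord]
  } else {
    df <- data.frame(mass = numeric(0), t_min = numeric(0),
                     t_max = numeric(0), f_min = numeric(0),
                     f_max = numeric(0), p_fwe = numeric(0),
                     significant = logical(0))
    cells <- list()
  }
  structure(list(difference = obs, z = z_obs, clusters = df,
                 cluster_cells = cells, times = cs$times_rel,
                 freqs = cs$freqs, n_perm = n_perm, measure = measure,
                 levels = lv),
            class = "coherence_contrast")
}

#' Write a coherence / dwPLI grid as long-format CSV
#'
#' @param x A `coherence_result` or `dwpli_result`.
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_connectivity <- function(x, path) {
  grids <- if (inherits(x, "coherence_result")) x$coherence else x$dwpli
  if (!is.list(grids)) grids <- list(all = grids)
  rows <- do.call(rbind, lapply(names(grids), function(cond) {
    g <- grids[[cond]]
    data.frame(condition = cond,
               time = rep(x$times, times = length(x$freqs)),
               freq = rep(x$freqs, each = length(x$times)),
               value = as.vector(g))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
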