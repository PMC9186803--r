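#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` with time half-bandwidth
#' product `nw`, via the standard symmetric tridiagonal eigenproblem; the
#' eigenvectors are unit-energy and sign-normalized so each taper has a
#' non-negative mean (even orders) or a positive initial slope (odd orders).
#'
#' @param n Taper length in samples.
#' @param nw Time half-bandwidth product `T * W` (dimensionless).
#' @param k Number of tapers.
#' @return An `n` x `k` matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw, k) {
  if (k < 1 || k > n) stop("invalid taper count")
  w <- nw / n
  t0 <- 0:(n - 1)
  diag_el <- ((n - 1 - 2 * t0) / 2)^2 * cos(2 * pi * w)
  off_el <- t0[-1] * (n - t0[-1]) / 2
  M <- diag(diag_el)
  M[cbind(1:(n - 1), 2:n)] <- off_el
  M[cbind(2:n, 1:(n - 1))] <- off_el
  e <- eigen(M, symmetric = TRUE)
  tapers <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    v <- tapers[, j]
    if (j %% 2 == 1) { if (sum(v) < 0) tapers[, j] <- -v }
    else { if (v[2] - v[1] < 0) tapers[, j] <- -v }
  }
  tapers
}

# frequency bands used throughout: centre and half-bandwidth in Hz
band_def <- function(band) {
  if (is.list(band)) return(band)
  switch(band,
         beta = list(name = "beta", center = 21.5, halfbw = 8.5),
         theta = list(name = "theta", center = 5, halfbw = 3),
         stop("unknown band; give list(center=, halfbw=)"))
}

# sliding-window multitaper complex coefficients at arbitrary frequencies.
# x: signal vector; returns list(times, coef[k x nfreq x nwin]) with
# unit-energy tapers; |coef|^2 averaged over k estimates band power.
sliding_mt_coef <- function(x, fs, freqs, window = 0.4, hop = 0.05, nw, k) {
  win_n <- round(window * fs)
  hop_n <- round(hop * fs)
  if (length(x) < win_n) stop("recording shorter than one analysis window")
  starts <- seq(1, length(x) - win_n + 1, by = hop_n)
  tapers <- dpss_tapers(win_n, nw, k)
  tt <- (0:(win_n - 1)) / fs
  # basis: win_n x (k * nfreq), complex demodulators taper_k * e^{-i 2 pi f t}
  basis <- matrix(0 + 0i, win_n, k * length(freqs))
  for (fi in seq_along(freqs)) {
    dem <- exp(-2i * pi * freqs[fi] * tt)
    basis[, (fi - 1) * k + seq_len(k)] <- tapers * dem
  }
  idx <- outer(0:(win_n - 1), starts, `+`)
  W <- matrix(x[idx], win_n, length(starts))
  coef <- crossprod(basis, W)  # (k*nfreq) x nwin; basis already holds e^{-i2pift}
  times <- (starts - 1 + (win_n - 1) / 2) / fs
  list(times = times, coef = coef, k = k, freqs = freqs)
}

#' Continuous band-limited log power (baseline-free pipeline)
#'
#' Estimates band power on the continuous signal with the multitaper method
#' in a 400 ms sliding window stepped by 50 ms, log-transforms the power
#' time series, and (by default) high-pass filters the log power at 0.5 Hz
#' (Butterworth fifth order, zero-phase) to remove fluctuations slower than
#' the task's stimulus rate — the step that substitutes for a pre-stimulus
#' baseline when no baseline exists.
#'
#' Two estimation modes are available: `"center"` evaluates a single
#' multitaper estimate at the band centre with DPSS half-bandwidth spanning
#' the band (beta: 21.5 +/- 8.5 Hz, 5 tapers; theta: 5 +/- 3 Hz, 1 taper);
#' `"bins"` averages narrowband estimates on a grid across the band.
#'
#' @param rec A `continuous_recording`.
#' @param band `"beta"`, `"theta"`, or `list(center=, halfbw=)` in Hz.
#' @param window,hop Analysis window length and step, seconds.
#' @param mode `"center"` or `"bins"`.
#' @param highpass Apply the 0.5 Hz high-pass to the log power.
#' @param hp_freq High-pass cutoff in Hz.
#' @return A `power_timeseries`: `times` (s, window centres), `logpower`
#'   (time x channel matrix), `band`, `fs_power`, `filtered`, `mode`, and
#'   the raw-recording `fs` / `markers` carried over for epoching.
#' @export
continuous_band_power <- function(rec, band = "beta", window = 0.4,
                                  hop = 0.05, mode = c("center", "bins"),
                                  highpass = TRUE, hp_freq = 0.5) {
  mode <- match.arg(mode)
  bd <- band_def(band)
  if (rec$fs < 2 * (bd$center + bd$halfbw))
    stop("sampling rate below twice the band's upper edge")
  if (mode == "center") {
    nw <- window * bd$halfbw
    k <- max(floor(2 * nw) - 1, 1)
    freqs <- bd$center
  } else {
    freqs <- seq(bd$center - bd$halfbw, bd$center + bd$halfbw, by = 1 / window)
    nw <- 1
    k <- 1
  }
  fs_power <- 1 / hop
  lp <- NULL
  for (ch in seq_along(rec$channels)) {
    sm <- sliding_mt_coef(rec$data[, ch], rec$fs, freqs, window, hop, nw, k)
    pow <- colMeans(abs(sm$coef)^2)  # mean over tapers (x frequencies)
    if (is.null(lp)) {
      lp <- matrix(0, length(pow), length(rec$channels))
      times <- sm$times
    }
    lp[, ch] <- log(pmax(pow, 1e-300))
  }
  colnames(lp) <- rec$channels
  if (highpass) {
    bf <- signal::butter(5, hp_freq / (fs_power / 2), type = "high")
    # demean first: the filter removes DC anyway, and a large log-power
    # offset would otherwise leak edge transients into the series
    for (ch in seq_len(ncol(lp)))
      lp[, ch] <- signal::filtfilt(bf, lp[, ch] - mean(lp[, ch]))
  }
  structure(list(times = times, logpower = lp, band = bd,
                 fs_power = fs_power, filtered = highpass, mode = mode,
                 fs_raw = rec$fs, markers = rec$markers),
            class = "power_timeseries")
}

#' Raw-signal preprocessing: downsample and high-pass filter
#'
#' Downsamples the recording to `fs_target` (integer decimation after an
#' 8th-order Butterworth anti-alias low-pass) and applies a zero-phase
#' fifth-order Butterworth high-pass at `hp_freq`. Marker sample indices
#' are rescaled to the new rate.
#'
#' @param rec A `continuous_recording`.
#' @param fs_target Target rate, Hz (default 300).
#' @param hp_freq High-pass cutoff, Hz (default 1).
#' @return The preprocessed `continuous_recording`.
#' @export
preprocess_recording <- function(rec, fs_target = 300, hp_freq = 1) {
  data <- rec$data
  fs <- rec$fs
  mk <- rec$markers
  if (fs != fs_target) {
    dec <- fs / fs_target
    if (abs(dec - round(dec)) > 1e-9)
      stop("fs must be an integer multiple of fs_target")
    dec <- round(dec)
    aa <- signal::butter(8, 0.8 / dec, type = "low")
    keep <- seq(1, nrow(data), by = dec)
    data <- apply(data, 2, function(x) signal::filtfilt(aa, x)[keep])
    if (!is.null(mk)) mk$sample <- pmax(1L, as.integer(round((mk$sample - 1) / dec) + 1L))
    fs <- fs_target
  }
  bf <- signal::butter(5, hp_freq / (fs / 2), type = "high")
  data <- apply(data, 2, function(x) signal::filtfilt(bf, x))
  out <- continuous_recording(data, fs, markers = mk, channels = rec$channels)
  out$log <- rec$log
  out
}

#' Epoch a power time series around cue onsets
#'
#' Markers (raw-recording sample indices) are snapped to the 50 ms power
#' grid by nearest neighbour, and a window of log power relative to each
#' onset is extracted. Epochs that would overlap the edges of the power
#' series are dropped and counted. The power series must already be
#' high-pass filtered.
#'
#' @param pts A `power_timeseries` (with `filtered = TRUE`).
#' @param markers Marker data.frame (defaults to the markers carried on
#'   `pts`); a `sample` column in raw samples is required.
#' @param window Epoch window in seconds relative to onset, default
#'   `c(-0.5, 0.8)`.
#' @param channel Channel to epoch (name or index), default 1.
#' @return A `band_power_epochs`: `data` (epoch x time matrix),
#'   `times_rel` (s), `labels` (marker rows kept, with `is_first` /
#'   `is_last` flags for downstream exclusion), `n_dropped`, `band`.
#' @export
epoch_power <- function(pts, markers = pts$markers, window = c(-0.5, 0.8),
                        channel = 1) {
  if (!isTRUE(pts$filtered))
    stop("power series must be high-pass filtered before epoching")
  if (is.null(markers)) stop("no markers available")
  hop <- 1 / pts$fs_power
  rel_idx <- round(window[1] / hop):round(window[2] / hop)
  onset_t <- (markers$sample - 1) / pts$fs_raw
  centre <- vapply(onset_t, function(tt) which.min(abs(pts$times - tt)),
                   integer(1))
  rows <- lapply(seq_along(centre), function(i) {
    idx <- centre[i] + rel_idx
    if (any(idx < 1 | idx > length(pts$times))) NULL
    else pts$logpower[idx, channel]
  })
  keep <- !vapply(rows, is.null, logical(1))
  data <- do.call(rbind, rows[keep])
  structure(list(data = data, times_rel = rel_idx * hop,
                 labels = markers[keep, , drop = FALSE],
                 n_dropped = sum(!keep), band = pts$band,
                 channel = if (is.numeric(channel))
                   colnames(pts$logpower)[channel] else channel),
            class = "band_power_epochs")
}

#' Average log power across contacts
#'
#' Arithmetic mean of the log-power series across the contacts of each
#' group (e.g. per hemisphere), plus an `all` channel averaging every
#' contact; mirrors collapsing a multi-contact electrode to one channel per
#' hemisphere and one combined channel.
#'
#' @param pts A `power_timeseries` with one column per contact.
#' @param grouping Named list mapping group name to contact names/indices.
#' @return A `power_timeseries` whose channels are the groups plus `all`.
#' @export
average_channels <- function(pts, grouping) {
  if (length(grouping) == 0) stop("empty grouping")
  cols <- lapply(grouping, function(g) {
    if (length(g) == 0) stop("empty contact group")
    m <- pts$logpower[, g, drop = FALSE]
    rowMeans(m)
  })
  all_mean <- rowMeans(pts$logpower[, unique(unlist(grouping)), drop = FALSE])
  lp <- cbind(do.call(cbind, cols), all = all_mean)
  colnames(lp) <- c(names(grouping), "all")
  out <- pts
  out$logpower <- lp
  out
}

#' Bipolar montage between adjacent contacts
#'
#' Re-references a multi-contact recording to differences between adjacent
#' contacts within each group (contact 0 minus 1, 1 minus 2, ...), limiting
#' volume conduction from distant sources. Channels listed together in
#' `rings` are averaged first (segmented-lead rings treated as one ring
#' contact).
#'
#' @param rec A `continuous_recording`.
#' @param groups Named list: group name -> ordered contact names.
#' @param rings Optional list of character vectors of channels to average
#'   into a single virtual contact before differencing; the virtual contact
#'   takes the first listed name.
#' @return A `continuous_recording` with channels `<group><i><i+1>`.
#' @export
bipolar_montage <- function(rec, groups, rings = NULL) {
  data <- rec$data
  if (!is.null(rings)) {
    for (r in rings) {
      data[, r[1]] <- rowMeans(data[, r, drop = FALSE])
      data <- data[, !colnames(data) %in% r[-1], drop = FALSE]
    }
  }
  out <- list()
  for (g in names(groups)) {
    cc <- intersect(groups[[g]], colnames(data))
    if (length(cc) < 2) stop("group ", g, " needs at least 2 contacts")
    for (i in seq_len(length(cc) - 1))
      out[[paste0(g, i - 1, i)]] <- data[, cc[i]] - data[, cc[i + 1]]
  }
  continuous_recording(do.call(cbind, out), rec$fs, markers = rec$markers)
}
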