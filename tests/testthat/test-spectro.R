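make_rec <- function(x, fs = 300, markers = NULL) {
  continuous_recording(cbind(sig = x), fs, markers = markers)
}

test_that("DPSS tapers are orthonormal and counted from the bandwidth product", {
  tp <- dpss_tapers(120, nw = 3.4, k = 5)
  expect_equal(crossprod(tp), diag(5), tolerance = 1e-8)
  # beta band at 400 ms: 2*0.4*8.5 - 1 = 5 tapers; theta: 2*0.4*3 - 1 = 1
  rec <- make_rec(stats::rnorm(3000))
  expect_error(continuous_band_power(make_rec(stats::rnorm(50)), "beta"),
               "shorter than one")
})

test_that("a pure band-centre sinusoid gives flat log power that the high-pass removes", {
  fs <- 300
  t <- (0:(fs * 30 - 1)) / fs
  x <- sin(2 * pi * 21.5 * t)
  raw <- continuous_band_power(make_rec(x, fs), "beta", highpass = FALSE)
  mid <- 20:(length(raw$times) - 20)
  # flat up to taper sidelobe ripple (image of the carrier at -f0)
  expect_lt(stats::sd(raw$logpower[mid, 1]), 0.01)
  filt <- continuous_band_power(make_rec(x, fs), "beta", highpass = TRUE)
  expect_lt(max(abs(filt$logpower[mid, 1])), 0.01)
})

test_that("theta and beta estimates separate widely spaced oscillations", {
  fs <- 300
  t <- (0:(fs * 20 - 1)) / fs
  x <- sin(2 * pi * 5 * t)
  b <- continuous_band_power(make_rec(x, fs), "beta", highpass = FALSE)
  th <- continuous_band_power(make_rec(x, fs), "theta", highpass = FALSE)
  mid <- 20:(length(b$times) - 20)
  expect_gt(mean(th$logpower[mid, 1]) - mean(b$logpower[mid, 1]), log(100))
})

test_that("SOA-rate amplitude modulation survives the 0.5 Hz power high-pass", {
  fs <- 300
  t <- (0:(fs * 60 - 1)) / fs
  x <- (1 + 0.5 * cos(2 * pi * 1.25 * t)) * sin(2 * pi * 21.5 * t)
  raw <- continuous_band_power(make_rec(x, fs), "beta", highpass = FALSE)
  filt <- continuous_band_power(make_rec(x, fs), "beta", highpass = TRUE)
  mid <- 50:(length(raw$times) - 50)
  amp_raw <- stats::sd(raw$logpower[mid, 1] - mean(raw$logpower[mid, 1]))
  amp_filt <- stats::sd(filt$logpower[mid, 1])
  expect_gt(amp_filt / amp_raw, 0.9)
})

test_that("multitaper power across a dense grid tracks white-noise variance", {
  set.seed(30)
  fs <- 300
  x <- stats::rnorm(fs * 10, sd = 2)
  grid <- seq(5, 145, by = 2.5)
  est <- vapply(grid, function(f0) {
    p <- continuous_band_power(make_rec(x, fs), list(center = f0, halfbw = 2.5),
                               highpass = FALSE)
    mean(exp(p$logpower[, 1]))
  }, numeric(1))
  # unit-energy tapers: E|c(f)|^2 = signal variance at every frequency
  expect_lt(abs(mean(est) / 4 - 1), 0.05)
})

test_that("log power is shift-invariant to amplitude rescaling after filtering", {
  set.seed(31)
  fs <- 300
  x <- stats::rnorm(fs * 20)
  f1 <- continuous_band_power(make_rec(x, fs), "beta")
  f2 <- continuous_band_power(make_rec(5 * x, fs), "beta")
  expect_equal(f1$logpower, f2$logpower, tolerance = 1e-6)
})

test_that("epoching snaps markers to the 50 ms grid and drops edge epochs", {
  fs <- 300
  set.seed(32)
  x <- stats::rnorm(fs * 60)
  mk <- data.frame(sample = c(1L, as.integer(fs * c(10, 20, 30)) + 1L),
                   trial = 1:4, cue_index = 1L,
                   is_first = FALSE, is_last = FALSE, condition = "same")
  pts <- continuous_band_power(make_rec(x, fs, markers = mk), "beta")
  ep <- epoch_power(pts, window = c(-0.5, 0.8))
  expect_equal(ncol(ep$data), 27)          # -500..800 ms at 50 ms steps
  expect_equal(ep$n_dropped, 1)            # marker at the recording start
  expect_equal(nrow(ep$data), 3)
  raw <- continuous_band_power(make_rec(x, fs), "beta", highpass = FALSE)
  expect_error(epoch_power(raw, mk), "filtered")
})

test_that("an injected burst raises epoch power in its own window only", {
  fs <- 300
  dur <- 120
  set.seed(33)
  x <- 0.3 * stats::rnorm(fs * dur)
  onsets <- as.integer(fs * seq(5, dur - 5, by = 4)) + 1L
  t_burst <- seq(0, 0.35, by = 1 / fs)
  lobe <- 0.5 * (1 - cos(2 * pi * t_burst / 0.35))
  for (o in onsets) {
    idx <- o + as.integer(0.1 * fs) + seq_along(t_burst) - 1L
    x[idx] <- x[idx] + lobe * sin(2 * pi * 21.5 * (idx / fs))
  }
  mk <- data.frame(sample = onsets, trial = seq_along(onsets), cue_index = 1L,
                   is_first = FALSE, is_last = FALSE, condition = "same")
  pts <- continuous_band_power(make_rec(x, fs, markers = mk), "beta")
  ep <- epoch_power(pts)
  in_win <- ep$times_rel >= 0.1 & ep$times_rel <= 0.45
  base <- ep$times_rel < -0.1
  expect_gt(mean(ep$data[, in_win]), mean(ep$data[, base]))
})

test_that("contact averaging is idempotent, linear, and honours exclusions", {
  set.seed(34)
  fs <- 300
  x <- stats::rnorm(fs * 10)
  rec <- continuous_recording(cbind(c0 = x, c1 = x, c2 = -x), fs)
  pts <- continuous_band_power(rec, "beta", highpass = FALSE)
  avg <- average_channels(pts, list(left = c("c0", "c1")))
  expect_equal(avg$logpower[, "left"], pts$logpower[, "c0"],
               ignore_attr = TRUE)
  # log-powers x and -x are identical for these channels (power is even)
  both <- average_channels(pts, list(hemi = c("c0", "c2")))
  expect_equal(both$logpower[, "hemi"],
               (pts$logpower[, "c0"] + pts$logpower[, "c2"]) / 2,
               ignore_attr = TRUE)
  # excluding a noisy contact leaves the mean over the remaining ones
  excl <- average_channels(pts, list(right = c("c0", "c1")))
  expect_equal(excl$logpower[, "right"],
               rowMeans(pts$logpower[, c("c0", "c1")]), ignore_attr = TRUE)
  expect_error(average_channels(pts, list()), "empty")
})

test_that("bipolar montage differences adjacent contacts and averages rings", {
  set.seed(35)
  fs <- 300
  m <- matrix(stats::rnorm(fs * 5 * 4), ncol = 4,
              dimnames = list(NULL, c("L0", "L1", "L2a", "L2b")))
  rec <- continuous_recording(m, fs)
  bp <- bipolar_montage(rec, groups = list(L = c("L0", "L1", "L2a")),
                        rings = list(c("L2a", "L2b")))
  expect_identical(colnames(bp$data), c("L01", "L12"))
  expect_equal(bp$data[, "L01"], m[, "L0"] - m[, "L1"], ignore_attr = TRUE)
  expect_equal(bp$data[, "L12"],
               m[, "L1"] - (m[, "L2a"] + m[, "L2b"]) / 2, ignore_attr = TRUE)
})

test_that("raw preprocessing decimates with marker rescaling and removes drift", {
  fs <- 600
  t <- (0:(fs * 20 - 1)) / fs
  x <- sin(2 * pi * 21.5 * t) + 3 * sin(2 * pi * 0.1 * t)
  mk <- data.frame(sample = c(601L, 6001L))
  rec <- continuous_recording(cbind(ch = x), fs, markers = mk)
  out <- preprocess_recording(rec, fs_target = 300, hp_freq = 1)
  expect_equal(out$fs, 300)
  expect_equal(nrow(out$data), length(x) / 2)
  expect_equal(out$markers$sample, c(301L, 3001L))
  # the 0.1 Hz drift is attenuated while the beta carrier survives
  drift <- stats::lm(out$data[, 1] ~ sin(2 * pi * 0.1 * (1:6000) / 300))
  expect_lt(abs(stats::coef(drift)[2]), 0.1)
  expect_gt(stats::sd(out$data[, 1]), 0.5)
})
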