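# two-channel recording with markers on a regular grid; signal builders
# take the time vector and return each channel
make_two_channel <- function(fx, fy, dur = 120, fs = 300, step = 2) {
  t <- (0:(fs * dur - 1)) / fs
  onsets <- as.integer(fs * seq(3, dur - 3, by = step)) + 1L
  mk <- data.frame(sample = onsets, trial = seq_along(onsets), cue_index = 2L,
                   is_first = FALSE, is_last = FALSE,
                   condition = rep(c("same", "different"),
                                   length.out = length(onsets)))
  continuous_recording(cbind(x = fx(t), y = fy(t)), fs, markers = mk)
}

test_that("a channel is perfectly coherent with itself", {
  set.seed(60)
  sig <- NULL
  rec <- make_two_channel(function(t) { sig <<- stats::rnorm(length(t)); sig },
                          function(t) sig)
  cs <- epoch_cross_spectra(rec, "x", "y", window = c(-0.5, 0.5))
  coh <- time_resolved_coherence(cs)
  expect_true(all(abs(coh$coherence - 1) < 1e-10))
})

test_that("independent noise coherence matches the 1/n bias oracle", {
  set.seed(61)
  rec <- make_two_channel(function(t) stats::rnorm(length(t)),
                          function(t) stats::rnorm(length(t)), dur = 200)
  cs <- epoch_cross_spectra(rec, "x", "y", window = c(-0.5, 0.5))
  n <- dim(cs$sxy)[1]
  coh <- time_resolved_coherence(cs)
  # thin to approximately independent cells (400 ms, 5 Hz apart)
  ti <- seq(1, length(cs$times_rel), by = 8)
  fi <- seq(1, length(cs$freqs), by = 5)
  c2 <- as.vector(coh$coherence[ti, fi]^2)
  se <- stats::sd(c2) / sqrt(length(c2))
  expect_lt(abs(mean(c2) - 1 / n), 3 * se)
})

test_that("coherence is invariant to channel rescaling; dwPLI ignores zero-lag mixing", {
  set.seed(62)
  shared <- NULL
  rec <- make_two_channel(
    function(t) { shared <<- sin(2 * pi * 21.5 * t) *
      (1 + 0.3 * stats::rnorm(length(t))); shared + 0.7 * stats::rnorm(length(t)) },
    function(t) 3 * shared + 2.1 * stats::rnorm(length(t)))
  cs <- epoch_cross_spectra(rec, "x", "y", window = c(-0.5, 0.5))
  coh <- time_resolved_coherence(cs)
  fi <- which(cs$freqs %in% 20:23)
  expect_gt(mean(coh$coherence[, fi]), 0.5)      # strong zero-lag coupling
  dw <- debiased_wpli(cs)
  expect_lt(mean(abs(dw$dwpli[, fi])), 0.1)      # invisible to dwPLI
  # rescaling either channel leaves coherence untouched
  rec2 <- rec
  rec2$data[, "y"] <- 10 * rec2$data[, "y"]
  cs2 <- epoch_cross_spectra(rec2, "x", "y", window = c(-0.5, 0.5))
  expect_equal(time_resolved_coherence(cs2)$coherence, coh$coherence,
               tolerance = 1e-9)
})

test_that("quarter-cycle lagged coupling drives dwPLI high with the lag's sign", {
  set.seed(63)
  lagged <- function(lag) make_two_channel(
    function(t) sin(2 * pi * 21.5 * t) + 0.5 * stats::rnorm(length(t)),
    function(t) sin(2 * pi * 21.5 * t - lag) + 0.5 * stats::rnorm(length(t)))
  cs_p <- epoch_cross_spectra(lagged(pi / 2), "x", "y", window = c(-0.5, 0.5))
  fi <- which(cs_p$freqs %in% 20:23)
  dw_p <- debiased_wpli(cs_p)
  expect_gt(mean(dw_p$dwpli[, fi]), 0.5)
  set.seed(63)
  cs_m <- epoch_cross_spectra(lagged(-pi / 2), "x", "y", window = c(-0.5, 0.5))
  dw_m <- debiased_wpli(cs_m)
  expect_lt(mean(dw_m$dwpli[, fi]), -0.5)
})

test_that("dwPLI expectation is stable when one condition loses half its epochs", {
  set.seed(64)
  rec <- make_two_channel(
    function(t) sin(2 * pi * 21.5 * t) + 1.2 * stats::rnorm(length(t)),
    function(t) sin(2 * pi * 21.5 * t - pi / 2) + 1.2 * stats::rnorm(length(t)),
    dur = 240)
  cs <- epoch_cross_spectra(rec, "x", "y", window = c(-0.5, 0.5))
  n <- dim(cs$sxy)[1]
  fi <- which(cs$freqs %in% 20:23)
  full <- debiased_wpli(cs)
  half <- cs
  keep <- seq_len(n %/% 2)
  for (f in c("sxy", "sxx", "syy")) half[[f]] <- cs[[f]][keep, , , drop = FALSE]
  half$labels <- cs$labels[keep, , drop = FALSE]
  dhalf <- debiased_wpli(half)
  cells_full <- as.vector(full$dwpli[, fi])
  cells_half <- as.vector(dhalf$dwpli[, fi])
  se <- sqrt(stats::var(cells_half) / length(cells_half) +
               stats::var(cells_full) / length(cells_full))
  expect_lt(abs(mean(cells_half) - mean(cells_full)), 4 * se)
})

test_that("condition-dependent lagged coupling yields a positive beta contrast cluster", {
  fx <- quick_recording(n_trials = 60, seed = 3)
  cs <- usable_cross_spectra(epoch_cross_spectra(fx$rec, "stn", "cortex"))
  cc <- coherence_contrast(cs, factor(cs$labels$condition,
                                      c("same", "different")),
                           n_perm = 200, seed = 65)
  sig <- cc$clusters[cc$clusters$significant, ]
  expect_gte(nrow(sig), 1)
  top <- sig[which.max(abs(sig$mass)), ]
  expect_gt(top$mass, 0)
  expect_true(top$f_max >= 13 && top$f_min <= 30)    # beta band
  expect_true(top$t_max >= 0.1 && top$t_min <= 0.9)  # injected window
})

test_that("connectivity grids serialize to long CSV", {
  set.seed(66)
  rec <- make_two_channel(function(t) stats::rnorm(length(t)),
                          function(t) stats::rnorm(length(t)), dur = 60)
  cs <- epoch_cross_spectra(rec, "x", "y", window = c(-0.5, 0.5))
  coh <- time_resolved_coherence(cs, cs$labels$condition)
  path <- withr::local_tempfile(fileext = ".csv")
  write_connectivity(coh, path)
  back <- utils::read.csv(path)
  expect_setequal(unique(back$condition), c("same", "different"))
  expect_equal(nrow(back),
               2 * length(cs$times_rel) * length(cs$freqs))
})
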