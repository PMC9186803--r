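test_that("per-timepoint OLS recovers exact and injected effects", {
  set.seed(40)
  n <- 80; T <- 27
  X <- cbind(`(Intercept)` = 1, r1 = stats::rnorm(n), r2 = stats::rnorm(n),
             r3 = stats::rnorm(n), r4 = stats::rnorm(n))
  # near-exact fit: power IS r1 -> t enormous on r1, noise-level elsewhere
  Yx <- matrix(X[, "r1"], n, T) + 0
  fit <- timepoint_glm(Yx + 1e-6 * stats::rnorm(n * T), X)
  expect_true(all(abs(fit$t["r1", ]) > 1e4))
  expect_true(all(abs(fit$t["r3", ]) < 10))
  # injected weights at chosen timepoints: signs recovered
  w <- c(1, 0, 0.5, -0.5)
  Y <- X[, 2:5] %*% matrix(rep(w, T), 4, T) + 0.5 * matrix(stats::rnorm(n * T), n)
  fit2 <- timepoint_glm(Y, X)
  expect_true(all(fit2$coef["r1", ] > 0))
  expect_true(all(fit2$coef["r3", ] > 0))
  expect_true(all(fit2$coef["r4", ] < 0))
  # constant shifts are absorbed by the intercept
  fit3 <- timepoint_glm(Y + 7, X)
  expect_equal(fit2$coef["r1", ], fit3$coef["r1", ], tolerance = 1e-9)
})

test_that("rank-deficient designs are refused with the offending column named", {
  set.seed(41)
  X <- cbind(`(Intercept)` = 1, a = stats::rnorm(30))
  X <- cbind(X, b = 2 * X[, "a"])
  expect_error(timepoint_glm(matrix(stats::rnorm(30 * 5), 30), X),
               "collinear.*b")
  expect_error(timepoint_glm(matrix(stats::rnorm(10 * 5), 10),
                             cbind(1, stats::rnorm(10))), "too few")
})

test_that("design matrix columns are z-scored and affine-invariant", {
  trials <- simulate_behavior(task_config(), agent_spec(threshold = 3),
                              100, seed = 42)
  reg <- cue_regressors(trials)
  dm <- design_matrix(reg)
  for (j in 2:ncol(dm$X)) {
    expect_lt(abs(mean(dm$X[, j])), 1e-9)
    expect_lt(abs(stats::sd(dm$X[, j]) - 1), 1e-9)
  }
  reg2 <- reg
  reg2$abs_evidence <- 3 * reg2$abs_evidence + 10   # affine rescale
  expect_equal(design_matrix(reg2)$X, dm$X, tolerance = 1e-9)
})

test_that("cluster permutation p-values respect their estimator bounds", {
  set.seed(43)
  n <- 60; T <- 27
  Y <- matrix(stats::rnorm(n * T), n)
  lab <- rep(c("same", "different"), each = n / 2)
  # massive injected effect -> observed mass above every permuted maximum
  Y2 <- Y
  Y2[lab == "different", 10:18] <- Y2[lab == "different", 10:18] + 3
  r <- cluster_permutation_test(Y2, "labels",
                                labels = factor(lab, c("same", "different")),
                                n_perm = 199, seed = 2)
  expect_equal(min(r$clusters$p_fwe), 1 / 200)
  expect_gt(r$clusters$mass[1], 0)     # different minus same
  # degenerate constant series -> no clusters
  rc <- cluster_permutation_test(matrix(5, n, T), "labels", labels = lab,
                                 n_perm = 120, seed = 3)
  expect_equal(nrow(rc$clusters), 0)
  expect_warning(
    cluster_permutation_test(Y, "labels", labels = lab, n_perm = 50, seed = 4),
    "coarse")
})

test_that("cluster masses flip sign with the data, p-values unchanged", {
  set.seed(44)
  n <- 50
  Y <- matrix(stats::rnorm(n * 27), n)
  Y[1:25, 5:12] <- Y[1:25, 5:12] + 1.5
  lab <- rep(c("a", "b"), each = 25)
  r1 <- cluster_permutation_test(Y, "labels", labels = lab, n_perm = 300,
                                 seed = 5)
  r2 <- cluster_permutation_test(-Y, "labels", labels = lab, n_perm = 300,
                                 seed = 5)
  expect_equal(r1$clusters$mass, -r2$clusters$mass, tolerance = 1e-9)
  expect_equal(r1$clusters$p_fwe, r2$clusters$p_fwe)
})

test_that("false-positive rate of the label-shuffle test is near nominal", {
  set.seed(45)
  hits <- vapply(1:120, function(i) {
    Y <- matrix(stats::rnorm(40 * 27), 40)
    r <- cluster_permutation_test(Y, "labels",
                                  labels = rep(c("a", "b"), each = 20),
                                  n_perm = 250, seed = i)
    any(r$clusters$p_fwe < 0.05)
  }, logical(1))
  expect_gte(mean(hits), 0.005)
  expect_lte(mean(hits), 0.12)
})

test_that("sign-flip scheme detects a group-level difference", {
  set.seed(46)
  D <- matrix(stats::rnorm(12 * 27, sd = 0.5), 12)
  D[, 8:14] <- D[, 8:14] + 1
  r <- cluster_permutation_test(D, "signflip", n_perm = 500, seed = 6)
  sig <- r$clusters[r$clusters$significant, ]
  expect_gte(nrow(sig), 1)
  expect_true(any(sig$start <= 14 & sig$end >= 8))
  expect_true(all(is.finite(r$clusters$cohen_d)))
})

test_that("design-scheme permutation flags only truly coupled regressors", {
  set.seed(47)
  n <- 120
  X <- cbind(`(Intercept)` = 1, hit = stats::rnorm(n), null = stats::rnorm(n))
  Y <- matrix(stats::rnorm(n * 27), n)
  Y[, 10:16] <- Y[, 10:16] + X[, "hit"]
  res <- cluster_permutation_test(Y, "design", design = X, n_perm = 300,
                                  seed = 7)
  expect_true(any(res$hit$clusters$significant))
  expect_false(any(res$null$clusters$significant))
})

test_that("same/different contrast recovers the injected dip-then-rise shape", {
  fx <- quick_recording(n_trials = 60, seed = 3)
  pts <- continuous_band_power(fx$rec, "beta")
  ctr <- same_different_contrast(pts, channel = "stn", n_perm = 400, seed = 8)
  tm <- ctr$times
  # negative early within cue i, positive late, positive early in cue i+1
  expect_lt(mean(ctr$difference[tm >= 0.05 & tm <= 0.35]), 0)
  expect_gt(mean(ctr$difference[tm >= 0.55 & tm <= 0.75]), 0)
  expect_gt(mean(ctr$difference[tm >= 0.8 & tm <= 1.15]), 0)
  sig <- ctr$cluster$clusters[ctr$cluster$clusters$significant, ]
  expect_gte(nrow(sig), 1)
})

test_that("an exchangeable pool yields a difference trace inside its own CI", {
  # condition labels reassigned at random: epochs become one exchangeable pool
  set.seed(49)
  fx <- quick_recording(n_trials = 50, seed = 50)
  pts <- continuous_band_power(fx$rec, "beta")
  usable <- !is.na(pts$markers$condition)
  pts$markers$condition[usable] <- sample(pts$markers$condition[usable])
  ctr <- same_different_contrast(pts, channel = "stn", n_perm = 300, seed = 9)
  covered <- mean(ctr$ci_low <= 0 & 0 <= ctr$ci_high)
  expect_gt(covered, 0.8)
  expect_error(
    same_different_contrast(
      continuous_band_power(
        simulate_recording(fx$trials[1:3], fx$reg[fx$reg$trial <= 3, ],
                           neural_sim_spec(), fx$cfg, seed = 1),
        "beta"), channel = "stn"),
    "too few|fewer than")
})

test_that("cluster results serialize with millisecond extents", {
  set.seed(51)
  Y <- matrix(stats::rnorm(40 * 27), 40)
  Y[1:20, 10:15] <- Y[1:20, 10:15] + 2
  r <- cluster_permutation_test(Y, "labels", labels = rep(c("a", "b"), 20),
                                n_perm = 200, seed = 10)
  path <- withr::local_tempfile(fileext = ".json")
  write_cluster_result(r, path, times = seq(-0.5, 0.8, by = 0.05))
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$n_perm, 200)
  expect_true(all(c("start_ms", "end_ms") %in% names(back$clusters)))
})
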