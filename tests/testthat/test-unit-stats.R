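# Single-unit and pairwise statistics.

test_that("modulation is the population SD, with exact analytic cases", {
  expect_equal(modulation(rep(7, 100)), 0)
  # Pure sinusoid of amplitude a over whole cycles: RMS a/sqrt(2), exact
  # for equally spaced samples over complete cycles.
  th <- seq(0, 4, length.out = 401)[-401]
  expect_equal(modulation(3 * sin(2 * pi * th)), 3 / sqrt(2),
               tolerance = 1e-12)
  # Concatenation of two conditions with different means includes the
  # between-condition variance (brute-force oracle).
  x <- c(5 + sin(2 * pi * th), 15 + sin(2 * pi * th))
  expect_equal(modulation(x), sqrt(mean((x - mean(x))^2)))
  expect_gt(modulation(x), modulation(x[seq_along(th)]))
  expect_error(modulation(numeric(0)), "empty")
})

test_that("arm preference index follows the defining formula", {
  expect_equal(arm_preference_index(4, 4)$index, 0)
  expect_equal(arm_preference_index(4, 0)$index, 1)
  expect_equal(arm_preference_index(0, 4)$index, -1)
  expect_equal(arm_preference_index(3, 5)$index, -0.25)
  expect_true(is.na(arm_preference_index(0, 0)$index))
  expect_error(arm_preference_index(-1, 2), "nonnegative")
})

test_that("response correlation handles phase-shifted sinusoids exactly", {
  th <- seq(0, 4, length.out = 400 + 1)[-401]
  s <- sin(2 * pi * th)
  expect_equal(response_correlation(s, s), 1)
  expect_equal(response_correlation(s, cos(2 * pi * th)), 0,
               tolerance = 1e-12)
  expect_equal(response_correlation(s, -s), -1)
  expect_true(is.na(response_correlation(s, rep(1, length(s)))))
  expect_error(response_correlation(s, s[-1]), "length")
})

test_that("per-unit statistics stay within their defined ranges", {
  us <- unit_stats_table(small_rates())
  expect_true(all(us$api >= -1 & us$api <= 1, na.rm = TRUE))
  expect_true(all(abs(us$r_arm) <= 1, na.rm = TRUE))
  # Start-position control correlations are high: behavior is identical up
  # to the half-cycle phase shift the analysis removes.
  expect_gt(median(us$r_startpos), 0.6)
  ms <- muscle_stats_table(small_rates())
  expect_gt(median(ms$api), 0.9)     # muscles are strongly lateralized
})

test_that("shuffle null behaves for independent and duplicated populations", {
  set.seed(2)
  n <- 60; len <- 200
  mk <- function() {
    t(vapply(seq_len(n), function(i) {
      ph <- runif(2)
      sin(2 * pi * (seq_len(len) / 50 + ph[1])) +
        0.5 * sin(2 * pi * (2 * seq_len(len) / 50 + ph[2]))
    }, numeric(len)))
  }
  d <- mk(); nd <- mk()
  res <- shuffle_null_mean_correlation(d, nd, n_resamples = 500, seed = 4)
  expect_length(res$null, 500)
  expect_false(res$significant)
  expect_lt(abs(res$observed), 0.3)
  # Duplicated responses: observed mean is 1 and beats every resample.
  res2 <- shuffle_null_mean_correlation(d, d, n_resamples = 200, seed = 4)
  expect_equal(res2$observed, 1)
  expect_equal(res2$p, 0)
  expect_true(res2$significant)
})

test_that("shuffle-null mean vanishes for large arm-independent populations", {
  set.seed(5)
  n <- 200; len <- 200
  tt <- seq_len(len) / 50
  mk <- function() t(vapply(seq_len(n), function(i) {
    sin(2 * pi * (tt + runif(1))) + 0.4 * sin(2 * pi * (2 * tt + runif(1)))
  }, numeric(len)))
  res <- shuffle_null_mean_correlation(mk(), mk(), n_resamples = 500,
                                       seed = 6)
  expect_lt(abs(mean(res$null)), 0.05)
  expect_lt(abs(res$observed), 0.05)
})

test_that("pairwise correlation matrices are symmetric with unit diagonal", {
  pc <- pairwise_correlation_analysis(small_rates())
  m <- pc$matrices[[1]]$driven
  expect_equal(m, t(m))
  expect_equal(diag(m), rep(1, nrow(m)))
  expect_true(abs(pc$meta_correlation) <= 1)
  expect_equal(nrow(pc$pairs),
               2 * 4 * choose(10, 2))    # hemispheres x cond pairs x pairs
})

test_that("meta-correlation is 1 when correlations are preserved and ~0 for
           arm-specific random patterns", {
  arr <- random_responses(20, seed = 31)
  # Copy each left-arm condition's response to the matching right-arm
  # condition: correlations preserved exactly across arms.
  arr2 <- arr
  arr2[, , 5:8] <- arr[, , 1:4]
  r_pres <- make_rates(arr2, rep(c("left", "right"), each = 10))
  expect_equal(pairwise_correlation_analysis(r_pres)$meta_correlation, 1,
               tolerance = 1e-9)
  # Independent patterns per arm: meta-correlation near zero.
  big <- random_responses(100, seed = 32)
  r_ind <- make_rates(big, rep(c("left", "right"), each = 50))
  expect_lt(abs(pairwise_correlation_analysis(r_ind)$meta_correlation),
            0.1)
})

test_that("speed-split test is null-calibrated and respects the trial floor", {
  r <- small_rates()
  ss <- speed_split_test(r, n_perm = 250, seed = 8)
  expect_true(abs(ss$flagged_fraction - 0.05) < 0.02)
  expect_equal(ss$n_points, 300 * 20 * 8)
  # Fewer than min_trials: no result for that condition.
  ss2 <- speed_split_test(r, n_perm = 10, min_trials = 11, seed = 8)
  expect_null(ss2$by_unit)
  expect_true(is.na(ss2$flagged_fraction))
})

test_that("rates coupled to non-performing-arm speed are flagged heavily", {
  cfg <- generator_config(n_units_per_hemisphere = 4,
                          n_muscles_per_arm = 1,
                          n_trials_per_condition = 16,
                          speed_coupling = 2, seed = 19)
  r <- preprocess_session(generate_session(cfg)$session)
  ss <- speed_split_test(r, n_perm = 300, seed = 9)
  expect_gt(ss$flagged_fraction, 0.2)
})

test_that("Fano regression matches the law of total variance", {
  set.seed(10)
  lam <- runif(100, 2, 20)
  counts <- matrix(rpois(100 * 200, rep(lam, each = 200)), 200)
  fit <- fano_regression(colMeans(counts), apply(counts, 2, var))
  expect_gt(fit$slope, 0.9); expect_lt(fit$slope, 1.1)
  # Identical counts on every trial: slope 0.
  flat <- matrix(rep(seq(2, 20, length.out = 50), each = 30), 30)
  fit0 <- fano_regression(colMeans(flat), apply(flat, 2, var))
  expect_equal(fit0$slope, 0)
  # Doubly stochastic gain (rate scaled 1 +/- 0.5 per trial): the law of
  # total variance gives var = lam + 0.25 lam^2, so the slope exceeds 1.
  g <- sample(c(0.5, 1.5), 200 * 100, replace = TRUE)
  counts2 <- matrix(rpois(100 * 200, rep(lam, each = 200) * g), 200)
  fit2 <- fano_regression(colMeans(counts2), apply(counts2, 2, var))
  expect_gt(fit2$slope, 1.2)
  expect_error(fano_regression(1, 1), "qualifying")
})

test_that("required magnification solves the median-index equation", {
  expect_equal(required_magnification(c(4, 6), c(1, 2),
               target_median_api = median(c(3 / 5, 4 / 8))), 1)
  # One muscle with d = 12, n = 1: k = 12 drives its index to 0.
  k <- required_magnification(12, 1, 0)
  expect_equal(k, 12, tolerance = 1e-4)
  set.seed(12)
  d <- runif(10, 5, 20); n <- runif(10, 0.1, 2)
  target <- 0.2
  k <- required_magnification(d, n, target)
  med <- function(k) median((d - k * n) / (d + k * n))
  grid <- seq(1, 50, by = 0.01)
  k_grid <- grid[min(which(vapply(grid, med, 0) <= target))]
  expect_equal(k, k_grid, tolerance = 0.01)
  # Median index is monotonically nonincreasing in k.
  expect_true(all(diff(vapply(grid, med, 0)) <= 1e-12))
  expect_error(required_magnification(c(3, 4), c(0, 0), 0), "unreachable")
})
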