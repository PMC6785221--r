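# Decoding: population R^2, SIMPLS, rank selection, cross-hemisphere
# prediction, perturbation controls, wrong-arm generalization.

test_that("population R^2 satisfies its identities and a hand-computed case", {
  y <- matrix(c(1, 0, -1, 2, 0, 2, 1, -1), 4, 2)
  expect_equal(population_r2(y, y), 1)
  expect_equal(population_r2(y, 0 * y), 0)
  y_pred <- y / 2
  # ||Y - Y/2||^2 = ||Y||^2 / 4, so R^2 = 0.75 by hand.
  expect_equal(population_r2(y, y_pred), 0.75)
  expect_lt(population_r2(y, -y), 0)       # can be negative
  expect_error(population_r2(y, y[1:2, ]), "shape")
  expect_error(population_r2(0 * y, y), "zero variance")
})

test_that("SIMPLS at full rank matches least squares", {
  set.seed(31)
  x <- scale(matrix(rnorm(40 * 6), 40), scale = FALSE)
  b_true <- matrix(rnorm(6 * 3), 6)
  y <- x %*% b_true
  coefs <- cyclepop:::simpls(x, y, 6)
  expect_equal(x %*% coefs[[6]], y, tolerance = 1e-6)
  # Noisy well-conditioned case against lm.
  y2 <- y + matrix(rnorm(120, sd = 0.3), 40)
  y2 <- scale(y2, scale = FALSE)
  coefs2 <- cyclepop:::simpls(x, y2, 6)
  bols <- qr.solve(x, y2)
  expect_equal(max(abs(x %*% coefs2[[6]] - x %*% bols)), 0,
               tolerance = 1e-6)
})

test_that("SIMPLS agrees with an independent PLS implementation on a
           univariate response", {
  set.seed(32)
  x <- scale(matrix(rnorm(50 * 8), 50), scale = FALSE)
  colnames(x) <- paste0("x", 1:8)
  y <- scale(x %*% rnorm(8) + rnorm(50, sd = 0.5), scale = FALSE)
  coefs <- cyclepop:::simpls(x, y, 4)
  ref <- mixOmics::pls(x, y, ncomp = 4, mode = "regression", scale = FALSE)
  pred <- predict(ref, newdata = x)$predict
  for (r in 1:4) {
    expect_equal(as.vector(x %*% coefs[[r]]), as.vector(pred[, 1, r]),
                 tolerance = 1e-6)
  }
})

test_that("decoder recovery: exact low-rank linear targets are found", {
  set.seed(33)
  lat <- cbind(sin(2 * pi * seq_len(120) / 50),
               cos(2 * pi * seq_len(120) / 50))
  x <- scale(lat %*% matrix(rnorm(2 * 15), 2) +
             matrix(rnorm(120 * 15, sd = 1e-8), 120), scale = FALSE)
  y <- scale(lat %*% matrix(rnorm(2 * 4), 2), scale = FALSE)
  dec <- fit_muscle_decoder(x[1:60, ], y[1:60, ], x[61:80, ], y[61:80, ])
  expect_lte(dec$rank, 4)
  expect_gt(population_r2(y[81:120, ], x[81:120, ] %*% dec$weights), 0.99)
})

test_that("decoders cannot predict shuffled targets", {
  set.seed(34)
  x <- scale(matrix(rnorm(100 * 12), 100), scale = FALSE)
  y <- scale(matrix(rnorm(100 * 3), 100), scale = FALSE)
  dec <- fit_muscle_decoder(x[1:60, ], y[1:60, ], x[61:80, ], y[61:80, ])
  expect_lt(population_r2(y[81:100, ], x[81:100, ] %*% dec$weights), 0.3)
})

test_that("decoder contracts: rank trimming and degenerate requests", {
  x <- scale(matrix(rnorm(30 * 5), 30), scale = FALSE)
  y <- scale(matrix(rnorm(30 * 2), 30), scale = FALSE)
  expect_warning(fit_muscle_decoder(x[1:20, ], y[1:20, ], x[21:30, ],
                                    y[21:30, ], ranks = 1:50), "trimmed")
  expect_error(fit_muscle_decoder(x, y, x, y,
                                  train_condition = "left_forward_top",
                                  test_condition = "left_forward_top"),
               "differ")
})

test_that("muscle activity decodes from either hemisphere", {
  chd <- cross_hemisphere_muscle_decode(small_rates())
  expect_equal(nrow(chd), 16)          # 8 conditions x 2 sources
  expect_equal(sort(unique(chd$source)), c("driving", "non_driving"))
  med <- tapply(chd$r2, chd$source, median)
  expect_gt(med[["driving"]], 0.5)
  expect_gt(med[["non_driving"]], 0.5)
  # Both hemispheres carry the muscle-potent latents: paired performance.
  expect_lt(abs(med[["driving"]] - med[["non_driving"]]), 0.1)
})

test_that("PC regression recovers full-rank self prediction and private
           latent deficits", {
  set.seed(35)
  tt <- seq_len(200) / 50
  # Distinct frequencies make the latent dimensions linearly independent.
  mk_lat <- function(k, ph) vapply(seq_len(k), function(d) {
    sin(2 * pi * (d * tt + ph[d])) }, numeric(200))
  ph_tr <- runif(5); ph_te <- runif(5)
  a_src <- matrix(rnorm(4 * 15), 4)
  a_tgt_shared <- matrix(rnorm(4 * 12), 4)
  w_priv <- rnorm(12)
  build <- function(ph, priv_scale) {
    lat <- mk_lat(5, ph)
    # Small regularizing noise keeps PCs beyond the latent rank
    # well-defined.
    src <- lat[, 1:4] %*% a_src + matrix(rnorm(200 * 15, sd = 0.02), 200)
    tgt <- lat[, 1:4] %*% a_tgt_shared +
      priv_scale * lat[, 5] %*% t(w_priv) +
      matrix(rnorm(200 * 12, sd = 0.02), 200)
    list(src = scale(src, scale = FALSE), tgt = scale(tgt, scale = FALSE))
  }
  tr <- build(ph_tr, 0); te <- build(ph_te, 0)
  r_cross <- pc_regression_predict(tr$src, tr$tgt, te$src, te$tgt,
                                   ranks = c(4, 8))
  expect_gt(r_cross$r2[r_cross$rank == 8], 0.99)
  # Target identical to source at full rank: perfect prediction.
  r_self_ident <- pc_regression_predict(tr$src, tr$src, te$src, te$src,
                                        ranks = 8)
  expect_gt(r_self_ident$r2, 0.99)
  # Give the target a private latent carrying ~30% of its variance: the
  # cross prediction loses exactly that share, the leave-one-out self
  # prediction keeps it.
  shared_var <- mean(apply(build(ph_tr, 0)$tgt, 2, var))
  priv_scale <- sqrt(0.3 / 0.7 * shared_var / mean(w_priv^2) * 2)
  tr2 <- build(ph_tr, priv_scale); te2 <- build(ph_te, priv_scale)
  cross2 <- pc_regression_predict(tr2$src, tr2$tgt, te2$src, te2$tgt,
                                  ranks = 8)$r2
  self2 <- pc_regression_predict(tr2$tgt, tr2$tgt, te2$tgt, te2$tgt,
                                 ranks = 8, mode = "leave_one_out_self")$r2
  deficit <- self2 - cross2
  expect_gt(deficit, 0.15)
  expect_lt(deficit, 0.45)
  expect_error(pc_regression_predict(tr$src, tr$tgt, te$src, te$tgt,
                                     ranks = 99), "rank")
})

test_that("hemisphere shuffle test calibrates under exchangeable labels", {
  r <- small_rates()
  sh <- hemisphere_shuffle_test(r, n_resamples = 30, seed = 3, rank = 6)
  expect_length(sh$null, 30)
  # The generator mixes signals across hemispheres, so label identity
  # carries little information: across a few seeds the gap should rarely
  # be significant.
  sig <- vapply(1:4, function(s) {
    hemisphere_shuffle_test(r, n_resamples = 20, seed = s,
                            rank = 6)$significant
  }, NA)
  expect_lte(sum(sig), 1)
})

test_that("a private high-variance signal in one hemisphere is detected", {
  arr <- random_responses(24, seed = 41)
  # Add a large private latent to the left-hemisphere units only.
  tt <- seq_len(300) / 50
  priv <- 3 * sin(2 * pi * (3 * tt + 0.2))
  for (ci in 1:8) {
    arr[, 1:12, ci] <- arr[, 1:12, ci] +
      priv %*% t(runif(12, 0.5, 1.5))
  }
  r <- make_rates(arr, rep(c("left", "right"), each = 12))
  sh <- hemisphere_shuffle_test(r, n_resamples = 30, seed = 7, rank = 5)
  expect_true(sh$significant)
})

test_that("perturbation controls reconstruct, remove and rescale exactly", {
  set.seed(36)
  lat <- random_responses(10, n_conds = 1, seed = 42)[, , 1]
  x <- lat + matrix(rnorm(3000, sd = 0.05), 300)
  pc <- signal_perturbation_controls(x)
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  full <- sweep(xc %*% pc$basis %*% t(pc$basis), 2, ctr, "+")
  expect_equal(full, x, tolerance = 1e-10)
  # Removing PC1 removes exactly its eigenvalue share of the variance.
  ev <- svd(xc)$d^2
  var_removed <- sum(xc^2) - sum(sweep(pc$remove_pc1, 2, ctr)^2)
  expect_equal(var_removed, ev[1], tolerance = 1e-8)
  expect_error(signal_perturbation_controls(x[, 1:3]), "4 principal")
})

test_that("removing the top source signal degrades cross prediction", {
  set.seed(37)
  tt <- seq_len(200) / 50
  lat <- vapply(c(0.1, 0.4, 0.7), function(ph) sin(2 * pi * (tt + ph)),
                numeric(200))
  lat <- sweep(lat, 2, c(3, 1, 0.5), "*")   # dominant first latent
  src <- lat %*% matrix(rnorm(3 * 10), 3) +
    matrix(rnorm(2000, sd = 0.02), 200)
  tgt <- lat %*% matrix(rnorm(3 * 8), 3)
  src <- scale(src, scale = FALSE); tgt <- scale(tgt, scale = FALSE)
  half <- 1:100
  base <- pc_regression_predict(src[half, ], tgt[half, ],
                                src[-half, ], tgt[-half, ], ranks = 2)$r2
  pert <- signal_perturbation_controls(src)$remove_pc1
  pert <- scale(pert, scale = FALSE)
  degraded <- pc_regression_predict(pert[half, ], tgt[half, ],
                                    pert[-half, ], tgt[-half, ],
                                    ranks = 2)$r2
  expect_gt(base - degraded, 0.1)
})

test_that("wrong-arm generalization mirrors the subspace separation", {
  r <- small_rates()
  wa <- wrong_arm_generalization(r, "train_performing")
  # 12 muscles, each tested in its arm's 4 direction x start combinations.
  expect_equal(nrow(wa$table), 12 * 4)
  expect_gt(median(wa$r2_performing$r2), 0.7)
  # Decoded activity for the non-performing arm is much weaker than for
  # the performing arm.
  ratio <- median(wa$table$mod_decoded_nonperf /
                  wa$table$mod_decoded_perf)
  expect_lt(ratio, 0.6)
  # Decoded arm preference is right-shifted relative to unit preference.
  us <- unit_stats_table(r)
  expect_gt(median(wa$table$api_decoded) - median(us$api, na.rm = TRUE),
            0)
  wb <- wrong_arm_generalization(r, "train_both")
  expect_lte(median(wb$table$mod_decoded_nonperf /
                    wb$table$mod_decoded_perf), ratio)
})

test_that("unlateralized populations spread decoder weight across
           hemispheres", {
  cfg <- small_cfg(lateralization = 0, n_units_per_hemisphere = 12,
                   seed = 88)
  r <- rates_from_expected(expected_rate_tensor(cfg))
  wa <- wrong_arm_generalization(r, "train_performing")
  med <- tapply(wa$weights$magnitude, wa$weights$cortex, median)
  expect_lt(max(med) / min(med), 2)
})
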