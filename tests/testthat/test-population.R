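# Population geometry: normalization, subspaces, variance capture,
# contribution weights, and trajectory tangling.

test_that("soft normalization follows the defining formula", {
  x <- cbind(seq(0, 95, length.out = 50), rep(3, 50))
  sn <- soft_normalize(x, c = 5)
  expect_equal(max(sn[, 1]), 95 / 100)     # range 95, peak value 95 -> 0.95
  expect_equal(sn[, 2], rep(0, 50))        # zero-range channel maps to 0
  expect_equal(attr(sn, "ranges"), c(95, 0))
  rn <- soft_normalize(cbind(rep(2, 20), seq(0, 1, length.out = 20)), 0)
  expect_equal(rn[, 1], rep(0, 20))
  expect_equal(range(rn[, 2]), c(0, 1))
})

test_that("soft normalization compresses dynamic-range differences", {
  th <- seq(0, 4, length.out = 200)
  big <- 50 + 50 * sin(2 * pi * th)     # range 100
  small <- 10 + 10 * sin(2 * pi * th)   # range 20
  sn <- soft_normalize(cbind(big, small), c = 5)
  ratio_raw <- stats::var(big) / stats::var(small)
  ratio_sn <- stats::var(sn[, 1]) / stats::var(sn[, 2])
  expect_equal(ratio_raw, 25, tolerance = 1e-9)
  expect_lt(ratio_sn, 1.5)              # pulled from 25x toward parity
  expect_gt(ratio_sn, 0.5)
})

test_that("condition subspaces reproduce exact low-rank structure", {
  set.seed(21)
  basis <- qr.Q(qr(matrix(rnorm(12 * 2), 12)))[, 1:2]
  z <- cbind(sin(2 * pi * seq_len(100) / 50),
             cos(2 * pi * seq_len(100) / 50))
  x <- z %*% t(basis)
  sp <- fit_condition_subspace(x)
  expect_equal(sum(sp$evals[1:2]) / sum(sp$evals), 1, tolerance = 1e-10)
  expect_equal(crossprod(sp$basis), diag(ncol(sp$basis)),
               tolerance = 1e-10)
  # Projecting the training data onto its own full basis captures 100%.
  curve <- variance_capture_curve(sp, x)
  expect_equal(curve[length(curve)], 1, tolerance = 1e-10)
  expect_true(all(diff(curve) >= -1e-12))
  expect_error(fit_condition_subspace(x, rank = 50), "rank")
  expect_error(variance_capture_curve(sp, x[, 1:5]), "unit set")
})

test_that("isotropic noise yields an approximately flat eigen-spectrum", {
  set.seed(22)
  x <- matrix(rnorm(4000), 200, 20)
  sp <- fit_condition_subspace(x)
  ev <- sp$evals[1:20]
  expect_lt(max(ev) / min(ev), 4)   # Marchenko-Pastur-ish spread, no spikes
})

test_that("triplet sweep covers every training condition once and is
           order invariant", {
  sw <- triplet_sweep(small_rates())
  expect_equal(sum(sw$curves$n_components == 1 &
                   sw$curves$type == "same_arm"), 8)
  expect_equal(sum(sw$curves$n_components == 1 &
                   sw$curves$type == "opposite_arm"), 8)
  expect_true(all(sw$summary$mean_captured >= 0 &
                  sw$summary$mean_captured <= 1))
  # Summaries do not depend on unit order.
  r <- small_rates()
  perm <- rev(seq_len(nrow(r$units)))
  r2 <- r
  r2$neural$mean <- r$neural$mean[, perm, , drop = FALSE]
  r2$units <- r$units[perm, ]
  sw2 <- triplet_sweep(r2)
  expect_equal(sw$summary$mean_captured, sw2$summary$mean_captured,
               tolerance = 1e-10)
})

test_that("identical arm bases make cross-arm capture match same-arm
           capture", {
  # Clean construction: shared bases, no lateralization asymmetry, no
  # rectification (high baseline) and no observation noise, so the only
  # difference between the arms is the latent phases.
  cfg <- small_cfg(subspace_overlap = 1, lateralization = 0,
                   n_units_per_hemisphere = 15, baseline_rate = 40,
                   seed = 66)
  r <- rates_from_expected(expected_rate_tensor(cfg))
  s <- triplet_sweep(r)$summary
  expect_lt(abs(s$mean_captured[s$type == "opposite_arm"] -
                s$mean_captured[s$type == "same_arm"]), 0.05)
})

test_that("fully lateralized ground truth puts no weight on the silent
           hemisphere", {
  cfg <- small_cfg(lateralization = 1, n_units_per_hemisphere = 8)
  r <- rates_from_expected(expected_rate_tensor(cfg))
  w <- subspace_contribution_weights(r, arm = "left", n_pcs = 3)
  # Left-arm subspace: the left (non-driving) hemisphere is silent.
  expect_lt(w$medians[["left"]], 1e-8)
  expect_gt(w$medians[["right"]], 0.01)
})

test_that("neuron count sweep reduces the orthogonality bias", {
  cfg <- small_cfg(subspace_overlap = 0, n_units_per_hemisphere = 30,
                   seed = 77)
  r <- rates_from_expected(expected_rate_tensor(cfg))
  ns <- neuron_count_sweep(r, counts = c(10, 60), n_draws = 3, seed = 5)
  agg <- tapply(ns$opposite_arm, ns$count, mean)
  expect_lt(agg[["60"]], agg[["10"]])
  # Full population equals the unsubsampled analysis.
  full <- triplet_sweep(r)$summary
  expect_equal(mean(ns$opposite_arm[ns$count == 60]),
               full$mean_captured[full$type == "opposite_arm"],
               tolerance = 1e-10)
})

test_that("tangling matches the closed form for a planar circle", {
  n <- 400
  ang <- 2 * pi * seq(0, 1, length.out = n + 1)[-(n + 1)]
  R <- 2
  dt <- 0.01
  omega <- 2 * pi / (n * dt)          # one revolution per n steps
  x <- R * cbind(cos(ang), sin(ang))
  q <- tangling(x, dt_s = dt)$q
  # Rotational symmetry: Q constant in time (away from the open ends where
  # one-sided derivatives break the symmetry).
  interior <- q[10:(n - 10)]
  expect_lt(stats::sd(interior) / mean(interior), 0.01)
  # Closed form: max at the antipode, with eps = 0.1 * R^2 (variance of a
  # uniformly sampled circle is R^2/2 per coordinate).
  q_theory <- 4 * omega^2 * R^2 / (4 * R^2 + 0.1 * R^2)
  expect_equal(mean(interior), q_theory, tolerance = 0.01)
})

test_that("fast tangling equals the brute-force oracle", {
  set.seed(23)
  trajs <- list(matrix(rnorm(80 * 3), 80), matrix(rnorm(60 * 3), 60))
  fast <- tangling(trajs)$q
  slow <- tangling_brute(trajs)
  expect_equal(fast, slow, tolerance = 1e-13)
  expect_error(tangling(matrix(1, 1, 2)), "two time points")
})

test_that("opposite traversals of one circle are heavily tangled", {
  n <- 200
  ang <- 2 * pi * seq(0, 1, length.out = n + 1)[-(n + 1)]
  x1 <- cbind(cos(ang), sin(ang))
  x2 <- x1[n:1, ]                      # same circle, reversed direction
  q_single <- tangling(x1)$q
  q_both <- tangling(list(x1, x2))$q
  expect_gt(min(q_both), 10 * max(q_single))
})

test_that("tangling is invariant to rotation and uniform rescaling", {
  set.seed(24)
  trajs <- list(matrix(rnorm(100 * 4), 100), matrix(rnorm(100 * 4), 100))
  rot <- qr.Q(qr(matrix(rnorm(16), 4)))
  q0 <- tangling(trajs)$q
  q_rot <- tangling(lapply(trajs, function(m) m %*% rot))$q
  expect_equal(q0, q_rot, tolerance = 1e-10)
  q_scl <- tangling(lapply(trajs, function(m) 3.7 * m))$q
  expect_equal(q0, q_scl, tolerance = 1e-10)
})

test_that("tangling distributions pool the expected sample counts and
           muscles tangle more than cortex", {
  cfg <- small_cfg(n_units_per_hemisphere = 12, seed = 55)
  r <- rates_from_expected(expected_rate_tensor(cfg))
  tc <- tangling_comparison(r)
  # time points x conditions, pooled across the two hemispheres / arms.
  expect_equal(tc$summary$n, rep(2 * 4 * 200, 3))
  s <- tc$summary
  expect_gt(s$mean[s$group == "muscle"],
            s$mean[s$group == "driving_cortex"])
  expect_gt(s$mean[s$group == "muscle"],
            s$mean[s$group == "non_driving_cortex"])
  # Duplicating one hemisphere's responses into the other makes the two
  # cortical populations identical, so the pooled driving and non-driving
  # distributions coincide.
  r2 <- r
  left <- which(r$units$hemisphere == "left")
  right <- which(r$units$hemisphere == "right")
  r2$neural$mean[, right, ] <- r$neural$mean[, left, ]
  tc2 <- tangling_comparison(r2)
  expect_equal(sort(tc2$distributions$driving_cortex),
               sort(tc2$distributions$non_driving_cortex),
               tolerance = 1e-9)
})
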