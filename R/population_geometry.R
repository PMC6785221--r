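# Population geometry: soft normalization, per-condition PCA subspaces,
# cross-arm variance capture, contribution weights, neuron-count sweep, and
# trajectory tangling.

#' Soft-normalize a rate tensor
#'
#' Rescales each channel by its firing-rate range (across all times and
#' conditions) plus a constant: `(FR - min(FR)) / (range(FR) + c)`. The
#' constant (default 5 on the spikes/s scale) keeps very low-rate channels
#' from being magnified; `c = 0` gives plain range normalization (used for
#' EMG). Subtracting the per-channel minimum pins a zero-range channel at
#' zero and is inconsequential downstream, where responses are centered
#' per condition.
#'
#' @param x Array (time x channel x condition) or matrix (time x channel).
#' @param c Soft-normalization constant, `>= 0`.
#' @return Normalized array of the same shape, with attribute `ranges`.
#' @export
soft_normalize <- function(x, c = 5) {
  check_scalar(c, "c", 0, Inf)
  dims <- dim(x)
  mat <- if (length(dims) == 3L) {
    matrix(aperm(x, c(1, 3, 2)), ncol = dims[2])
  } else as.matrix(x)
  lo <- apply(mat, 2, min)
  rng <- apply(mat, 2, function(v) diff(range(v)))
  denom <- rng + c
  denom[denom == 0] <- 1          # zero-range channel with c = 0 maps to 0
  out <- if (length(dims) == 3L) {
    sweep(sweep(x, 2, lo), 2, denom, "/")
  } else sweep(sweep(as.matrix(x), 2, lo), 2, denom, "/")
  attr(out, "ranges") <- rng
  out
}

#' Fit a PCA subspace to one condition's population response
#'
#' PCA of the time x unit matrix of (soft-normalized) firing rates, after
#' centering each unit by its temporal mean within the condition.
#'
#' @param x Time x unit matrix.
#' @param rank Number of components to retain (default: full).
#' @return A `cp_subspace`: `basis` (unit x rank, orthonormal), `evals`
#'   (variances of all components), `center` (the column means removed),
#'   `rank`, and `condition` (optional label).
#' @param condition Optional training-condition label.
#' @export
fit_condition_subspace <- function(x, rank = NULL, condition = NULL) {
  x <- as.matrix(x)
  full <- min(dim(x) - c(1L, 0L))
  rank <- rank %||% full
  if (rank > full) {
    stop(sprintf("rank %d exceeds min(time samples - 1, units) = %d",
                 rank, full), call. = FALSE)
  }
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  sv <- svd(xc)
  out <- list(basis = sv$v[, seq_len(rank), drop = FALSE],
              evals = sv$d^2 / (nrow(x) - 1),
              center = ctr, rank = rank, condition = condition)
  class(out) <- "cp_subspace"
  out
}

#' Cumulative variance captured by a subspace
#'
#' Projects a test response onto the subspace basis and reports, per number
#' of leading components, the fraction of the test response's centered sum
#' of squares that the projection captures. The test matrix is centered by
#' its own temporal mean (per unit), so curves from different spaces are
#' comparable.
#'
#' @param space A `cp_subspace`.
#' @param x_test Time x unit matrix on the same unit set/order.
#' @param center `"self"` (default) centers the test data by its own mean;
#'   `"train"` uses the training-condition mean stored in the space.
#' @return Nondecreasing vector of cumulative captured fractions, length
#'   `space$rank`.
#' @export
variance_capture_curve <- function(space, x_test,
                                   center = c("self", "train")) {
  center <- match.arg(center)
  x_test <- as.matrix(x_test)
  if (ncol(x_test) != nrow(space$basis)) {
    stop("test matrix and subspace disagree on the unit set", call. = FALSE)
  }
  ctr <- if (center == "self") colMeans(x_test) else space$center
  xc <- sweep(x_test, 2, ctr)
  total <- sum(xc^2)
  if (total == 0) stop("test response has zero variance", call. = FALSE)
  proj <- xc %*% space$basis
  cumsum(colSums(proj^2)) / total
}

# Matrix of one condition's middle-cycle soft-normalized response.
condition_matrix <- function(sn_neural, ci, idx) sn_neural[idx, , ci]

#' Variance capture across all condition triplets
#'
#' For every condition serving as the training condition once, fits a PCA
#' subspace and measures cumulative variance capture for the same-arm test
#' condition (same arm and direction, opposite start) and the opposite-arm
#' test condition (same direction and start, other arm).
#'
#' @param rates A `cp_rates` object.
#' @param n_pcs Component count at which summaries are reported.
#' @param max_rank Components retained in each curve.
#' @param soft_c Soft-normalization constant applied to the neural tensor.
#' @param units Optional subset of unit indices.
#' @return List with `curves` (data frame: train condition, test type,
#'   component count, captured fraction) and `summary` (mean and SD of the
#'   captured fraction at `n_pcs`, per test type).
#' @export
triplet_sweep <- function(rates, n_pcs = 5, max_rank = 10, soft_c = 5,
                          units = NULL) {
  conds <- rates$conditions
  if (nrow(conds) != 8L) stop("all 8 conditions required", call. = FALSE)
  units <- units %||% seq_len(nrow(rates$units))
  sn <- soft_normalize(rates$neural$mean[, units, , drop = FALSE], soft_c)
  idx <- middle_window_index(2, 5, 0, rates$dt_ms)
  max_rank <- min(max_rank, length(idx) - 1L, length(units))
  rows <- list()
  for (ci in seq_len(nrow(conds))) {
    tr <- conds[ci, ]
    same <- which(conds$arm == tr$arm & conds$direction == tr$direction &
                  conds$start == other_start(tr$start))
    opp <- which(conds$arm == other_arm(tr$arm) &
                 conds$direction == tr$direction & conds$start == tr$start)
    space <- fit_condition_subspace(condition_matrix(sn, ci, idx),
                                    rank = max_rank,
                                    condition = tr$condition_id)
    for (test in list(c(same, 1), c(opp, 2))) {
      curve <- variance_capture_curve(space,
                                      condition_matrix(sn, test[1], idx))
      rows[[length(rows) + 1L]] <- data.frame(
        train = tr$condition_id,
        test = conds$condition_id[test[1]],
        type = c("same_arm", "opposite_arm")[test[2]],
        n_components = seq_along(curve), captured = curve)
    }
  }
  curves <- do.call(rbind, rows)
  at <- curves[curves$n_components == min(n_pcs, max_rank), ]
  summary <- do.call(rbind, lapply(split(at, at$type), function(d) {
    data.frame(type = d$type[1], n_pcs = min(n_pcs, max_rank),
               mean_captured = mean(d$captured),
               sd_captured = stats::sd(d$captured), n = nrow(d))
  }))
  rownames(summary) <- NULL
  list(curves = curves, summary = summary)
}

#' Per-hemisphere contribution weights to an arm subspace
#'
#' Magnitudes of the unit weights in the top principal components of each
#' arm-condition subspace fitted on the unified two-hemisphere population,
#' grouped by the hemisphere of the contributing unit (each unit
#' contributes conditions x components values per arm).
#'
#' @param rates A `cp_rates` object.
#' @param arm Which arm's subspaces to analyze.
#' @param n_pcs Components whose weights are pooled.
#' @param soft_c Soft-normalization constant.
#' @return List with `weights` (data frame: unit, hemisphere, condition,
#'   component, magnitude) and `medians` (per hemisphere).
#' @export
subspace_contribution_weights <- function(rates, arm = c("left", "right"),
                                          n_pcs = 5, soft_c = 5) {
  arm <- match.arg(arm)
  conds <- rates$conditions
  sn <- soft_normalize(rates$neural$mean, soft_c)
  idx <- middle_window_index(2, 5, 0, rates$dt_ms)
  rows <- list()
  for (ci in which(conds$arm == arm)) {
    space <- fit_condition_subspace(condition_matrix(sn, ci, idx),
                                    rank = n_pcs)
    w <- abs(space$basis)
    for (k in seq_len(ncol(w))) {
      rows[[length(rows) + 1L]] <- data.frame(
        unit = rates$units$unit_id, hemisphere = rates$units$hemisphere,
        condition = conds$condition_id[ci], component = k,
        magnitude = w[, k])
    }
  }
  weights <- do.call(rbind, rows)
  med <- tapply(weights$magnitude, weights$hemisphere, stats::median)
  list(weights = weights, medians = med)
}

#' Opposite-arm variance capture versus neuron count
#'
#' Repeats the triplet sweep on random unit subsets of increasing size to
#' show how limited populations bias subspace-overlap estimates away from
#' orthogonality.
#'
#' @param rates A `cp_rates` object.
#' @param counts Unit counts to test.
#' @param n_draws Random subsets per count.
#' @param seed RNG seed.
#' @param n_pcs Component count for the summaries.
#' @return Data frame: count, draw, mean same-arm and opposite-arm capture.
#' @export
neuron_count_sweep <- function(rates, counts, n_draws = 5, seed = 1,
                               n_pcs = 5) {
  n <- nrow(rates$units)
  if (any(counts > n)) stop("counts exceed population size", call. = FALSE)
  rows <- list()
  for (cnt in counts) {
    for (d in seq_len(n_draws)) {
      sel <- if (cnt == n) seq_len(n) else
        with_seed(child_seed(seed, paste("ncs", cnt, d)),
                  sort(sample.int(n, cnt)))
      sw <- triplet_sweep(rates, n_pcs = n_pcs, units = sel)
      s <- sw$summary
      rows[[length(rows) + 1L]] <- data.frame(
        count = cnt, draw = d,
        same_arm = s$mean_captured[s$type == "same_arm"],
        opposite_arm = s$mean_captured[s$type == "opposite_arm"])
    }
  }
  do.call(rbind, rows)
}

#' Trajectory tangling
#'
#' For every state `x(t)` in a set of state-space trajectories, the maximum
#' over all other states (pooled across the supplied conditions) of
#' `||xdot(t) - xdot(t')||^2 / (||x(t) - x(t')||^2 + eps)`. High values
#' mean similar states with very different derivatives. `eps` is
#' `epsilon_fraction` times the total variance of the pooled states.
#' Derivatives use central differences (one-sided at trajectory ends).
#'
#' @param trajectories List of time x dimension matrices (one per
#'   condition), already reduced to the analysis dimensions.
#' @param dt_s Time step in seconds.
#' @param epsilon_fraction Fraction of total pooled variance added to the
#'   denominator.
#' @return Data frame with `condition` (list index), `t` (sample index) and
#'   `q`.
#' @export
tangling <- function(trajectories, dt_s = 0.01, epsilon_fraction = 0.1) {
  if (!is.list(trajectories)) trajectories <- list(trajectories)
  trajectories <- lapply(trajectories, as.matrix)
  if (any(vapply(trajectories, nrow, 0L) < 2L)) {
    stop("each trajectory needs at least two time points", call. = FALSE)
  }
  deriv <- lapply(trajectories, function(x) {
    n <- nrow(x)
    d <- x
    if (n > 2L) d[2:(n - 1), ] <- (x[3:n, , drop = FALSE] -
                                   x[1:(n - 2), , drop = FALSE]) / (2 * dt_s)
    d[1, ] <- (x[2, ] - x[1, ]) / dt_s
    d[n, ] <- (x[n, ] - x[n - 1, ]) / dt_s
    d
  })
  xs <- do.call(rbind, trajectories)
  xd <- do.call(rbind, deriv)
  eps <- epsilon_fraction * sum(apply(xs, 2, stats::var))
  m <- nrow(xs)
  q <- numeric(m)
  for (i in seq_len(m)) {
    num <- rowSums((xd - rep(xd[i, ], each = m))^2)
    den <- rowSums((xs - rep(xs[i, ], each = m))^2) + eps
    q[i] <- max(num / den)
  }
  lens <- vapply(trajectories, nrow, 0L)
  data.frame(condition = rep(seq_along(trajectories), lens),
             t = unlist(lapply(lens, seq_len), use.names = FALSE), q = q)
}

# Reduce a set of conditions' middle-cycle responses to their top principal
# components, fitting PCA once on the stacked (per-condition centered)
# matrices.
pca_reduce_conditions <- function(tensor, cond_idx, idx, n_dims = 8) {
  mats <- lapply(cond_idx, function(ci) {
    x <- tensor[idx, , ci]
    sweep(x, 2, colMeans(x))
  })
  stacked <- do.call(rbind, mats)
  n_dims <- min(n_dims, ncol(stacked), nrow(stacked) - 1L)
  basis <- svd(stacked)$v[, seq_len(n_dims), drop = FALSE]
  lapply(mats, function(m) m %*% basis)
}

#' Compare trajectory tangling across cortices and muscles
#'
#' Computes tangling separately per hemisphere and per arm-condition set
#' (each hemisphere's four driven-arm and four non-driven-arm conditions,
#' soft-normalized, reduced to the top PCs), pools time points across
#' hemispheres into one distribution for the driving cortex and one for the
#' non-driving cortex, and does the same for the muscle populations (range
#' normalized, conditions where each arm performs).
#'
#' @param rates A `cp_rates` object.
#' @param n_dims State-space dimensions retained (default 8; capped by the
#'   population size).
#' @param epsilon_fraction See [tangling()].
#' @param soft_c Soft-normalization constant for the neural tensors.
#' @return List with `distributions` (named list of pooled Q samples) and
#'   `summary` (mean, SD, n per group).
#' @export
tangling_comparison <- function(rates, n_dims = 8, epsilon_fraction = 0.1,
                                soft_c = 5) {
  conds <- rates$conditions
  idx <- middle_window_index(2, 5, 0, rates$dt_ms)
  dt_s <- rates$dt_ms / 1000
  sn <- soft_normalize(rates$neural$mean, soft_c)
  emg <- soft_normalize(rates$emg$mean, 0)
  dist <- list(driving_cortex = numeric(0),
               non_driving_cortex = numeric(0),
               muscle = numeric(0))
  for (h in c("left", "right")) {
    units <- which(rates$units$hemisphere == h)
    for (set_arm in c("left", "right")) {
      ci <- which(conds$arm == set_arm)
      traj <- pca_reduce_conditions(sn[, units, , drop = FALSE], ci, idx,
                                    n_dims)
      q <- tangling(traj, dt_s, epsilon_fraction)$q
      grp <- if (driving_hemisphere(set_arm) == h) "driving_cortex" else
        "non_driving_cortex"
      dist[[grp]] <- c(dist[[grp]], q)
    }
  }
  for (arm in c("left", "right")) {
    chans <- which(rates$muscles$arm == arm)
    ci <- which(conds$arm == arm)
    traj <- pca_reduce_conditions(emg[, chans, , drop = FALSE], ci, idx,
                                  min(n_dims, length(chans)))
    dist$muscle <- c(dist$muscle, tangling(traj, dt_s, epsilon_fraction)$q)
  }
  summary <- data.frame(
    group = names(dist),
    mean = vapply(dist, mean, 0),
    sd = vapply(dist, stats::sd, 0),
    n = vapply(dist, length, 0L), row.names = NULL)
  list(distributions = dist, summary = summary)
}
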