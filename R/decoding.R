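# Reduced-rank linear decoding of muscle activity from population rates,
# cross-hemisphere prediction, perturbation controls, and the wrong-arm
# generalization analyses.

#' Population variance explained
#'
#' `R^2 = 1 - ||Y - Ypred||_F^2 / ||Y||_F^2` on (per-condition centered)
#' targets: 1 for a perfect prediction, exactly 0 for the zero prediction,
#' negative for predictions worse than predicting zero.
#'
#' @param y,y_pred Matched time x channel matrices; `y` centered as during
#'   training.
#' @return Scalar `<= 1`.
#' @export
population_r2 <- function(y, y_pred) {
  y <- as.matrix(y); y_pred <- as.matrix(y_pred)
  if (!all(dim(y) == dim(y_pred))) stop("shape mismatch", call. = FALSE)
  total <- sum(y^2)
  if (total == 0) stop("target has zero variance", call. = FALSE)
  1 - sum((y - y_pred)^2) / total
}

# SIMPLS partial-least-squares regression (de Jong 1993): returns weight
# matrices predicting Y from X at every rank up to `rank`. X and Y must be
# centered. PLS maximizes covariance between projections, so the extracted
# directions are both correlated with Y and high variance.
simpls <- function(x, y, rank) {
  x <- as.matrix(x); y <- as.matrix(y)
  n <- ncol(x); m <- ncol(y)
  rank <- min(rank, n, nrow(x) - 1L)
  s <- crossprod(x, y)
  rr <- matrix(0, n, rank)
  qq <- matrix(0, m, rank)
  vv <- matrix(0, n, rank)
  for (a in seq_len(rank)) {
    r <- svd(s, nu = 1, nv = 0)$u
    t_sc <- x %*% r
    nt <- sqrt(sum(t_sc^2))
    if (nt < 1e-12) { rank <- a - 1L; break }
    t_sc <- t_sc / nt
    r <- r / nt
    p <- crossprod(x, t_sc)
    q <- crossprod(y, t_sc)
    v <- p
    if (a > 1L) {
      vprev <- vv[, seq_len(a - 1L), drop = FALSE]
      v <- v - vprev %*% crossprod(vprev, p)
    }
    v <- v / sqrt(sum(v^2))
    s <- s - v %*% crossprod(v, s)
    rr[, a] <- r; qq[, a] <- q; vv[, a] <- v
  }
  coefs <- vector("list", rank)
  for (a in seq_len(rank)) {
    coefs[[a]] <- rr[, seq_len(a), drop = FALSE] %*%
      t(qq[, seq_len(a), drop = FALSE])
  }
  coefs
}

#' Fit a reduced-rank PLS muscle decoder with rank selection
#'
#' Runs SIMPLS partial-least-squares regression of muscle activity on
#' population rates over a set of candidate ranks and keeps the rank
#' maximizing `R^2` on held-out validation data.
#'
#' @param x_train,y_train Centered training matrices (time x units,
#'   time x muscles).
#' @param x_val,y_val Centered validation data (e.g. one held-out cycle of
#'   the test condition).
#' @param ranks Candidate ranks; values exceeding the data dimensions are
#'   trimmed with a warning.
#' @param train_condition,test_condition Optional labels; supplying the
#'   same condition for both is rejected (validation must be held out).
#' @return A `cp_decoder`: `weights` (units x muscles), `rank`,
#'   `validation` (data frame of rank and validation R^2), `ranks`.
#' @export
fit_muscle_decoder <- function(x_train, y_train, x_val, y_val,
                               ranks = NULL, train_condition = NULL,
                               test_condition = NULL) {
  if (!is.null(train_condition) && !is.null(test_condition) &&
      any(train_condition == test_condition)) {
    stop("test condition must differ from the training condition",
         call. = FALSE)
  }
  x_train <- as.matrix(x_train); y_train <- as.matrix(y_train)
  max_rank <- min(ncol(x_train), nrow(x_train) - 1L, 4L * ncol(y_train), 20L)
  ranks <- ranks %||% seq_len(max_rank)
  if (any(ranks > max_rank)) {
    warning("rank candidates exceeding the data dimensions were trimmed")
    ranks <- ranks[ranks <= max_rank]
  }
  if (!length(ranks)) stop("no admissible rank candidates", call. = FALSE)
  coefs <- simpls(x_train, y_train, max(ranks))
  ranks <- ranks[ranks <= length(coefs)]
  val_r2 <- vapply(ranks, function(r) {
    population_r2(y_val, as.matrix(x_val) %*% coefs[[r]])
  }, 0)
  best <- ranks[which.max(val_r2)]
  out <- list(weights = coefs[[best]], rank = best,
              validation = data.frame(rank = ranks, r2 = val_r2),
              ranks = ranks, method = "simpls")
  class(out) <- "cp_decoder"
  out
}

# Centered middle-cycle matrix for a condition, restricted to channels.
centered_cond <- function(tensor, ci, idx, channels) {
  x <- tensor[idx, channels, ci, drop = FALSE]
  x <- matrix(x, nrow = length(idx))
  sweep(x, 2, colMeans(x))
}

# Time indices (within the cycles 2-5 window) of the validation cycle
# (cycle 2, the first middle cycle) and the remaining test cycles.
val_test_split <- function(dt_ms) {
  win <- middle_window_index(2, 5, 0, dt_ms)
  cyc <- middle_window_index(2, 2, 0, dt_ms)
  list(val = match(cyc, win), test = which(!win %in% cyc))
}

#' Predict performing-arm muscle activity from either hemisphere
#'
#' For each of the 8 conditions (as the test condition), trains a PLS
#' decoder of the performing arm's muscle activity on the corresponding
#' condition with the opposite starting position, using either the driving
#' (contralateral) or non-driving (ipsilateral) cortex units, and reports
#' generalization R^2 on the test condition's non-validation cycles.
#'
#' @param rates A `cp_rates` object.
#' @param soft_c Soft-normalization constant for the neural tensor.
#' @param ranks Candidate decoder ranks.
#' @return Data frame: condition, source (`driving` / `non_driving`),
#'   selected rank, generalization `r2`.
#' @export
cross_hemisphere_muscle_decode <- function(rates, soft_c = 5, ranks = NULL) {
  conds <- rates$conditions
  sn <- soft_normalize(rates$neural$mean, soft_c)
  emg <- soft_normalize(rates$emg$mean, 0)
  idx <- middle_window_index(2, 5, 0, rates$dt_ms)
  split <- val_test_split(rates$dt_ms)
  rows <- list()
  for (ci in seq_len(nrow(conds))) {
    test <- conds[ci, ]
    tr_ci <- which(conds$arm == test$arm &
                   conds$direction == test$direction &
                   conds$start == other_start(test$start))
    mus <- which(rates$muscles$arm == test$arm)
    for (source in c("driving", "non_driving")) {
      hemi <- if (source == "driving") driving_hemisphere(test$arm) else
        test$arm
      uu <- which(rates$units$hemisphere == hemi)
      if (!length(uu)) stop("hemisphere with zero units", call. = FALSE)
      xtr <- centered_cond(sn, tr_ci, idx, uu)
      ytr <- centered_cond(emg, tr_ci, idx, mus)
      xte <- centered_cond(sn, ci, idx, uu)
      yte <- centered_cond(emg, ci, idx, mus)
      dec <- fit_muscle_decoder(xtr, ytr,
                                xte[split$val, , drop = FALSE],
                                yte[split$val, , drop = FALSE],
                                ranks)
      r2 <- population_r2(yte[split$test, , drop = FALSE],
                          xte[split$test, , drop = FALSE] %*% dec$weights)
      rows[[length(rows) + 1L]] <- data.frame(
        condition = test$condition_id, source = source, rank = dec$rank,
        r2 = r2)
    }
  }
  do.call(rbind, rows)
}

#' Principal-components regression prediction
#'
#' Cross mode regresses the target population on the top principal
#' component projections of the source population and evaluates
#' generalization `R^2` on test data. Self mode predicts each target unit
#' from the top PCs of all *other* target units (leave-one-out), assembling
#' a population prediction.
#'
#' @param x_train,x_test Source matrices (time x source units), centered.
#' @param y_train,y_test Target matrices (time x target units), centered.
#'   In self mode, pass the target population as both source and target.
#' @param ranks PC counts to evaluate (default 1..10).
#' @param mode `"cross"` or `"leave_one_out_self"`.
#' @return Data frame with `rank` and generalization `r2`.
#' @export
pc_regression_predict <- function(x_train, y_train, x_test, y_test,
                                  ranks = 1:10,
                                  mode = c("cross", "leave_one_out_self")) {
  mode <- match.arg(mode)
  x_train <- as.matrix(x_train); y_train <- as.matrix(y_train)
  x_test <- as.matrix(x_test); y_test <- as.matrix(y_test)
  if (max(ranks) > ncol(x_train) - (mode == "leave_one_out_self")) {
    stop("rank exceeds source dimension", call. = FALSE)
  }
  if (mode == "cross") {
    w <- svd(x_train)$v
    r2 <- vapply(ranks, function(r) {
      wr <- w[, seq_len(r), drop = FALSE]
      b <- wr %*% qr.solve(x_train %*% wr, y_train)
      population_r2(y_test, x_test %*% b)
    }, 0)
  } else {
    n <- ncol(y_train)
    preds <- lapply(ranks, function(r) matrix(0, nrow(y_test), n))
    for (p in seq_len(n)) {
      xo_tr <- x_train[, -p, drop = FALSE]
      xo_te <- x_test[, -p, drop = FALSE]
      w <- svd(xo_tr)$v
      for (k in seq_along(ranks)) {
        wr <- w[, seq_len(ranks[k]), drop = FALSE]
        b <- wr %*% qr.solve(xo_tr %*% wr, y_train[, p])
        preds[[k]][, p] <- xo_te %*% b
      }
    }
    r2 <- vapply(seq_along(ranks), function(k) {
      population_r2(y_test, preds[[k]])
    }, 0)
  }
  data.frame(rank = ranks, r2 = r2)
}

# Internal: self and cross PCR generalization averaged over the 8
# conditions, for a given hemisphere labelling.
signal_compare_for_labels <- function(rates, hemis, ranks, sn, idx) {
  conds <- rates$conditions
  acc <- NULL
  for (ci in seq_len(nrow(conds))) {
    test <- conds[ci, ]
    tr_ci <- which(conds$arm == test$arm &
                   conds$direction == test$direction &
                   conds$start == other_start(test$start))
    drv <- which(hemis == driving_hemisphere(test$arm))
    nd <- which(hemis == test$arm)
    xs_tr <- centered_cond(sn, tr_ci, idx, nd)
    ys_tr <- centered_cond(sn, tr_ci, idx, drv)
    xs_te <- centered_cond(sn, ci, idx, nd)
    ys_te <- centered_cond(sn, ci, idx, drv)
    cross <- pc_regression_predict(xs_tr, ys_tr, xs_te, ys_te, ranks,
                                   "cross")$r2
    self <- pc_regression_predict(ys_tr, ys_tr, ys_te, ys_te, ranks,
                                  "leave_one_out_self")$r2
    acc <- if (is.null(acc)) cbind(self, cross) else
      acc + cbind(self, cross)
  }
  acc / nrow(conds)
}

#' Compare self- and cross-hemisphere signal prediction
#'
#' For each condition, predicts driving-cortex activity from the top PCs
#' of the non-driving cortex (cross) and from the other driving-cortex
#' units' PCs (leave-one-out self), averaging generalization R^2 across
#' the 8 conditions at each rank.
#'
#' @param rates A `cp_rates` object.
#' @param ranks PC counts (default 1..10, capped by the population).
#' @param soft_c Soft-normalization constant.
#' @return Data frame: rank, `self_r2`, `cross_r2`.
#' @export
cross_hemisphere_signal_compare <- function(rates, ranks = NULL,
                                            soft_c = 5) {
  sn <- soft_normalize(rates$neural$mean, soft_c)
  idx <- middle_window_index(2, 5, 0, rates$dt_ms)
  n_min <- min(table(rates$units$hemisphere))
  ranks <- ranks %||% seq_len(min(10L, n_min - 1L))
  acc <- signal_compare_for_labels(rates, rates$units$hemisphere, ranks,
                                   sn, idx)
  data.frame(rank = ranks, self_r2 = acc[, "self"],
             cross_r2 = acc[, "cross"])
}

#' Hemisphere-shuffle test for the self-vs-cross prediction gap
#'
#' Randomly reassigns units to hemispheres (preserving counts), recomputes
#' the self-minus-cross generalization gap at the top rank, and reports the
#' observed gap against this null. The gap is deemed significant when it
#' exceeds 95% of the resampled gaps.
#'
#' @param rates A `cp_rates` object.
#' @param n_resamples Label shuffles.
#' @param seed RNG seed.
#' @param rank PC count at which the gap is measured (default 10, capped).
#' @param soft_c Soft-normalization constant.
#' @return List with `observed`, `null` (length `n_resamples`), `p`,
#'   `significant`.
#' @export
hemisphere_shuffle_test <- function(rates, n_resamples = 100, seed = 1,
                                    rank = 10, soft_c = 5) {
  sn <- soft_normalize(rates$neural$mean, soft_c)
  idx <- middle_window_index(2, 5, 0, rates$dt_ms)
  hemis <- rates$units$hemisphere
  n_min <- min(table(hemis))
  rank <- min(rank, n_min - 1L)
  gap_of <- function(labels) {
    acc <- signal_compare_for_labels(rates, labels, rank, sn, idx)
    acc[1, "self"] - acc[1, "cross"]
  }
  observed <- gap_of(hemis)
  null <- with_seed(child_seed(seed, "hemishuffle"), {
    vapply(seq_len(n_resamples), function(i) gap_of(sample(hemis)), 0)
  })
  p <- mean(null >= observed)
  list(observed = observed, null = null, p = p,
       significant = observed > stats::quantile(null, 0.95, names = FALSE))
}

#' Perturbation controls on a population response
#'
#' Returns the response reconstructed without its first principal
#' component, and a variant whose first two PC projections are halved and
#' third and fourth doubled. Reconstruction with all PCs is exact.
#'
#' @param x Time x unit matrix.
#' @return List with `remove_pc1`, `rescale_pcs`, and `basis`.
#' @export
signal_perturbation_controls <- function(x) {
  x <- as.matrix(x)
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  w <- svd(xc)$v
  if (ncol(w) < 4L) {
    stop("rescale control needs at least 4 principal components",
         call. = FALSE)
  }
  w1 <- w[, -1, drop = FALSE]
  remove_pc1 <- sweep(xc %*% w1 %*% t(w1), 2, ctr, "+")
  z <- xc %*% w
  z[, 1:2] <- z[, 1:2] / 2
  z[, 3:4] <- z[, 3:4] * 2
  rescale <- sweep(z %*% t(w), 2, ctr, "+")
  list(remove_pc1 = remove_pc1, rescale_pcs = rescale, basis = w)
}

#' Wrong-arm generalization of muscle-activity decoders
#'
#' Trains decoders of each arm's muscle activity on the whole two-
#' hemisphere population and asks how much spurious muscle modulation they
#' predict when the *other* arm performs the task. For each (muscle arm,
#' direction, test start): training uses the same arm/direction with the
#' opposite start (`train_performing`), plus the matching other-arm
#' condition (`train_both`); validation is cycle 2 of the performing test
#' condition; testing uses the remaining cycles of the performing test
#' condition and of the other-arm (non-performing) condition.
#'
#' @param rates A `cp_rates` object.
#' @param strategy `"train_performing"` or `"train_both"`.
#' @param soft_c Soft-normalization constant.
#' @param ranks Candidate decoder ranks.
#' @return List with `table` (per muscle x condition: actual and decoded
#'   modulation for performing/non-performing arms plus arm-preference
#'   indices), `weights` (per-unit weight magnitudes with hemisphere and
#'   driving-cortex tag), `r2_performing` (generalization R^2 per
#'   condition).
#' @export
wrong_arm_generalization <- function(rates,
                                     strategy = c("train_performing",
                                                  "train_both"),
                                     soft_c = 5, ranks = NULL) {
  strategy <- match.arg(strategy)
  conds <- rates$conditions
  sn <- soft_normalize(rates$neural$mean, soft_c)
  emg <- soft_normalize(rates$emg$mean, 0)
  idx <- middle_window_index(2, 5, 0, rates$dt_ms)
  split <- val_test_split(rates$dt_ms)
  uu <- seq_len(nrow(rates$units))
  rows <- list(); wts <- list(); r2s <- list()
  for (arm in c("left", "right")) {
    mus <- which(rates$muscles$arm == arm)
    for (direction in c("forward", "backward")) {
      for (s_test in c("top", "bottom")) {
        cond_of <- function(a, s) which(conds$arm == a &
                                        conds$direction == direction &
                                        conds$start == s)
        tr_perf <- cond_of(arm, other_start(s_test))
        te_perf <- cond_of(arm, s_test)
        te_non <- cond_of(other_arm(arm), s_test)
        if (!length(tr_perf) || !length(te_perf) || !length(te_non)) {
          stop("required condition missing", call. = FALSE)
        }
        xtr <- centered_cond(sn, tr_perf, idx, uu)
        ytr <- centered_cond(emg, tr_perf, idx, mus)
        if (strategy == "train_both") {
          tr_other <- cond_of(other_arm(arm), other_start(s_test))
          xtr <- rbind(xtr, centered_cond(sn, tr_other, idx, uu))
          ytr <- rbind(ytr, centered_cond(emg, tr_other, idx, mus))
        }
        xte <- centered_cond(sn, te_perf, idx, uu)
        yte <- centered_cond(emg, te_perf, idx, mus)
        xnon <- centered_cond(sn, te_non, idx, uu)
        ynon <- centered_cond(emg, te_non, idx, mus)
        dec <- fit_muscle_decoder(xtr, ytr,
                                  xte[split$val, , drop = FALSE],
                                  yte[split$val, , drop = FALSE], ranks)
        pred_perf <- xte[split$test, , drop = FALSE] %*% dec$weights
        pred_non <- xnon[split$test, , drop = FALSE] %*% dec$weights
        r2s[[length(r2s) + 1L]] <- data.frame(
          muscle_arm = arm, direction = direction, start = s_test,
          rank = dec$rank,
          r2 = population_r2(yte[split$test, , drop = FALSE], pred_perf))
        for (m in seq_along(mus)) {
          mp <- modulation(pred_perf[, m])
          mn <- modulation(pred_non[, m])
          ap <- modulation(yte[split$test, m])
          an <- modulation(ynon[split$test, m])
          rows[[length(rows) + 1L]] <- data.frame(
            muscle = rates$muscles$channel_id[mus[m]],
            direction = direction, start = s_test,
            mod_actual_perf = ap, mod_actual_nonperf = an,
            mod_decoded_perf = mp, mod_decoded_nonperf = mn,
            api_actual = arm_preference_index(ap, an)$index,
            api_decoded = arm_preference_index(mp, mn)$index)
        }
        wmag <- sqrt(rowSums(dec$weights^2))
        wts[[length(wts) + 1L]] <- data.frame(
          unit = rates$units$unit_id,
          hemisphere = rates$units$hemisphere,
          cortex = ifelse(rates$units$hemisphere ==
                            driving_hemisphere(arm),
                          "driving", "non_driving"),
          muscle_arm = arm, direction = direction, start = s_test,
          magnitude = wmag)
      }
    }
  }
  list(strategy = strategy,
       table = do.call(rbind, rows),
       weights = do.call(rbind, wts),
       r2_performing = do.call(rbind, r2s))
}
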