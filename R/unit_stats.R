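# Single-unit and pairwise statistics: modulation, arm-preference index,
# response correlations with shuffle nulls, pairwise correlation structure
# and its meta-correlation, the median-speed-split randomization test, the
# Fano factor, and the required-magnification solver.

#' Concatenated middle-cycle response of one channel
#'
#' Builds the response vector used by the lateralization statistics: the
#' middle-cycle (default cycles 2-5) trace of one unit or muscle channel,
#' concatenated across a set of four conditions, optionally mean-centered
#' per condition before concatenation.
#'
#' @param rates A `cp_rates` object.
#' @param channel Unit index or `unit_id` (or muscle channel when
#'   `what = "emg"`).
#' @param set One of `"driven"`, `"non_driven"` (the four conditions
#'   performed with the channel's driven / non-driven arm), `"top"` or
#'   `"bottom"` (the four top-start or bottom-start conditions; the bottom
#'   set uses cycles 1.5-4.5 so both sets cover the same pedal positions).
#' @param center Mean-center each condition's segment before concatenation.
#' @param what `"neural"` or `"emg"`.
#' @return Numeric vector with attributes `boundaries` (segment ends) and
#'   `conditions`.
#' @export
concat_response <- function(rates, channel, set = c("driven", "non_driven",
                                                    "top", "bottom"),
                            center = TRUE, what = c("neural", "emg")) {
  set <- match.arg(set)
  what <- match.arg(what)
  meta <- if (what == "neural") rates$units else rates$muscles
  id_col <- if (what == "neural") "unit_id" else "channel_id"
  if (is.character(channel)) channel <- match(channel, meta[[id_col]])
  arm_of <- if (what == "neural") driven_arm(meta$hemisphere[channel]) else
    meta$arm[channel]
  conds <- rates$conditions
  offset <- 0
  sel <- switch(set,
    driven = conds$arm == arm_of,
    non_driven = conds$arm == other_arm(arm_of),
    top = conds$start == "top",
    bottom = conds$start == "bottom")
  if (set == "bottom") offset <- -0.5
  idx <- middle_window_index(2, 5, offset, rates$dt_ms)
  segs <- lapply(which(sel), function(ci) {
    v <- rates[[what]]$mean[idx, channel, ci]
    if (center) v - mean(v) else v
  })
  out <- unlist(segs, use.names = FALSE)
  attr(out, "boundaries") <- cumsum(lengths(segs))
  attr(out, "conditions") <- conds$condition_id[sel]
  out
}

#' Response modulation
#'
#' Population standard deviation of a concatenated response across all
#' samples (times and conditions).
#'
#' @param resp Numeric vector (e.g. from [concat_response()]).
#' @return Modulation in the units of `resp` (spikes/s for rates).
#' @export
modulation <- function(resp) {
  resp <- as.numeric(resp)
  if (!length(resp)) stop("empty response", call. = FALSE)
  sqrt(mean((resp - mean(resp))^2))
}

#' Arm preference index
#'
#' `(driven - non_driven) / (driven + non_driven)` on the two modulations;
#' +1 indicates complete preference for the driven arm, -1 for the
#' non-driven arm.
#'
#' @param mod_driven,mod_non_driven Nonnegative modulations.
#' @return List with `modulation_driven`, `modulation_non_driven`, `index`
#'   (`NA` when both modulations are zero).
#' @export
arm_preference_index <- function(mod_driven, mod_non_driven) {
  if (mod_driven < 0 || mod_non_driven < 0) {
    stop("modulations must be nonnegative", call. = FALSE)
  }
  idx <- if (mod_driven + mod_non_driven == 0) NA_real_ else
    (mod_driven - mod_non_driven) / (mod_driven + mod_non_driven)
  list(modulation_driven = mod_driven,
       modulation_non_driven = mod_non_driven, index = idx)
}

#' Pearson correlation between two concatenated responses
#'
#' @param x,y Concatenated (per-condition centered) response vectors of
#'   equal length.
#' @return Pearson r, or `NA` if either vector has zero variance.
#' @export
response_correlation <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("responses differ in length", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Per-unit lateralization statistics
#'
#' For every unit: modulation for the driven and non-driven arms, the arm
#' preference index, the correlation between driven and non-driven response
#' patterns, and the top-start versus bottom-start control correlation.
#'
#' @param rates A `cp_rates` object.
#' @return Data frame, one row per unit.
#' @export
unit_stats_table <- function(rates) {
  n <- nrow(rates$units)
  out <- rates$units
  out$modulation_driven <- out$modulation_non_driven <- out$api <-
    out$r_arm <- out$r_startpos <- NA_real_
  for (u in seq_len(n)) {
    rd <- concat_response(rates, u, "driven", center = FALSE)
    rn <- concat_response(rates, u, "non_driven", center = FALSE)
    api <- arm_preference_index(modulation(rd), modulation(rn))
    out$modulation_driven[u] <- api$modulation_driven
    out$modulation_non_driven[u] <- api$modulation_non_driven
    out$api[u] <- api$index
    out$r_arm[u] <- response_correlation(
      concat_response(rates, u, "driven"),
      concat_response(rates, u, "non_driven"))
    out$r_startpos[u] <- response_correlation(
      concat_response(rates, u, "top"),
      concat_response(rates, u, "bottom"))
  }
  out
}

#' Per-muscle lateralization statistics
#'
#' As [unit_stats_table()] but for EMG channels; a muscle's driven arm is
#' the arm it acts on.
#'
#' @param rates A `cp_rates` object.
#' @return Data frame, one row per muscle channel.
#' @export
muscle_stats_table <- function(rates) {
  n <- nrow(rates$muscles)
  out <- rates$muscles
  out$modulation_driven <- out$modulation_non_driven <- out$api <- NA_real_
  for (m in seq_len(n)) {
    rd <- concat_response(rates, m, "driven", center = FALSE, what = "emg")
    rn <- concat_response(rates, m, "non_driven", center = FALSE,
                          what = "emg")
    api <- arm_preference_index(modulation(rd), modulation(rn))
    out$modulation_driven[m] <- api$modulation_driven
    out$modulation_non_driven[m] <- api$modulation_non_driven
    out$api[m] <- api$index
  }
  out
}

#' Shuffle null for the mean driven/non-driven response correlation
#'
#' Replaces each unit's driven and non-driven responses with the driven
#' response of one randomly selected unit and the non-driven response of
#' another (drawn with replacement), recomputes the population-mean
#' correlation, and repeats. The observed mean is deemed significant when
#' it exceeds 95% of the resampled means.
#'
#' @param driven,non_driven Matrices (unit x sample) of concatenated,
#'   per-condition-centered responses.
#' @param n_resamples Number of resampled populations.
#' @param seed RNG seed.
#' @return List with `observed` (mean r), `null` (length `n_resamples`),
#'   `p` (fraction of resampled means >= observed) and `significant`.
#' @export
shuffle_null_mean_correlation <- function(driven, non_driven,
                                          n_resamples = 1000, seed = 1) {
  driven <- as.matrix(driven); non_driven <- as.matrix(non_driven)
  n <- nrow(driven)
  if (n < 2L) stop("need at least two units", call. = FALSE)
  row_cor <- function(a, b) {
    a <- a - rowMeans(a); b <- b - rowMeans(b)
    num <- rowSums(a * b)
    den <- sqrt(rowSums(a^2) * rowSums(b^2))
    ifelse(den == 0, NA_real_, num / den)
  }
  observed <- mean(row_cor(driven, non_driven), na.rm = TRUE)
  null <- with_seed(seed, {
    vapply(seq_len(n_resamples), function(i) {
      mean(row_cor(driven[sample.int(n, n, replace = TRUE), , drop = FALSE],
                   non_driven[sample.int(n, n, replace = TRUE), ,
                              drop = FALSE]), na.rm = TRUE)
    }, 0)
  })
  p <- mean(null >= observed)
  list(observed = observed, null = null, p = p,
       significant = observed > stats::quantile(null, 0.95, names = FALSE))
}

#' Pairwise correlation structure and its meta-correlation
#'
#' For each hemisphere and each (direction, start) pair of matched
#' conditions, computes the unit-unit correlation matrix of middle-cycle
#' responses when the units' driven arm performs the task and when the
#' non-driven arm performs it. Every unit pair then contributes one point
#' per condition pair; the meta-correlation is the Pearson correlation
#' over all points between the two coordinates.
#'
#' @param rates A `cp_rates` object.
#' @return List with `matrices` (per hemisphere/condition-pair), `pairs`
#'   (data frame of scatter points) and `meta_correlation`.
#' @export
pairwise_correlation_analysis <- function(rates) {
  conds <- rates$conditions
  idx <- middle_window_index(2, 5, 0, rates$dt_ms)
  matrices <- list()
  pts <- list()
  for (h in c("left", "right")) {
    units <- which(rates$units$hemisphere == h)
    darm <- driven_arm(h)
    combos <- unique(conds[, c("direction", "start")])
    for (k in seq_len(nrow(combos))) {
      ci_d <- which(conds$arm == darm &
                    conds$direction == combos$direction[k] &
                    conds$start == combos$start[k])
      ci_n <- which(conds$arm == other_arm(darm) &
                    conds$direction == combos$direction[k] &
                    conds$start == combos$start[k])
      xd <- rates$neural$mean[idx, units, ci_d]
      xn <- rates$neural$mean[idx, units, ci_n]
      ok <- apply(xd, 2, stats::sd) > 0 & apply(xn, 2, stats::sd) > 0
      if (sum(ok) < 2L) next
      cd <- stats::cor(xd[, ok, drop = FALSE])
      cn <- stats::cor(xn[, ok, drop = FALSE])
      key <- paste(h, combos$direction[k], combos$start[k], sep = "_")
      matrices[[key]] <- list(driven = cd, non_driven = cn,
                              dropped = sum(!ok))
      ut <- upper.tri(cd)
      pts[[key]] <- data.frame(hemisphere = h,
                               direction = combos$direction[k],
                               start = combos$start[k],
                               r_driven = cd[ut], r_non_driven = cn[ut])
    }
  }
  pairs <- do.call(rbind, pts)
  meta <- if (is.null(pairs) || nrow(pairs) < 2L) NA_real_ else
    stats::cor(pairs$r_driven, pairs$r_non_driven)
  list(matrices = matrices, pairs = pairs, meta_correlation = meta)
}

#' Median-speed-split randomization test
#'
#' For each unit and condition, splits trials at the median per-trial mean
#' speed of the non-performing arm (ties go below), compares the two mean
#' rate traces pointwise, and flags time points where the absolute
#' difference exceeds that of 95% of random trial divisions.
#'
#' @param rates A `cp_rates` object built with `keep_trials = TRUE`.
#' @param n_perm Random divisions per unit/condition.
#' @param alpha Pointwise significance level.
#' @param min_trials Conditions with fewer trials return no result.
#' @param seed RNG seed.
#' @param units Optional subset of unit indices.
#' @return List with `by_unit` (data frame: unit, condition, flagged
#'   fraction, n_trials), `flagged_fraction` (overall), `n_points`
#'   (total time points tested), and `flags` (list of logical vectors).
#' @export
speed_split_test <- function(rates, n_perm = 1000, alpha = 0.05,
                             min_trials = 8, seed = 1, units = NULL) {
  if (is.null(rates$neural$trials)) {
    stop("per-trial aligned rates required (keep_trials = TRUE)",
         call. = FALSE)
  }
  units <- units %||% seq_len(nrow(rates$units))
  conds <- rates$conditions
  rows <- list()
  flags <- list()
  total_flagged <- 0L
  total_pts <- 0L
  for (ci in seq_len(nrow(conds))) {
    arr <- rates$neural$trials[[conds$condition_id[ci]]]
    tri <- rates$trials[rates$trials$condition_id == conds$condition_id[ci], ]
    n <- dim(arr)[1]
    if (n < min_trials) next
    hi <- tri$np_speed > stats::median(tri$np_speed)
    n_hi <- sum(hi); n_lo <- n - n_hi
    if (n_hi == 0L || n_lo == 0L) next
    w_obs <- ifelse(hi, 1 / n_hi, -1 / n_lo)
    for (u in units) {
      x <- arr[, , u]                                  # trials x time
      obs <- abs(drop(crossprod(w_obs, x)))
      perm_w <- with_seed(
        child_seed(seed, paste("split", conds$condition_id[ci], u)), {
          vapply(seq_len(n_perm), function(p) {
            w <- rep(-1 / n_lo, n)
            w[sample.int(n, n_hi)] <- 1 / n_hi
            w
          }, numeric(n))
        })
      null <- abs(crossprod(perm_w, x))                # n_perm x time
      exceed <- colMeans(sweep(null, 2, obs, ">=") * 1)
      fl <- exceed < alpha
      flags[[paste(conds$condition_id[ci], u, sep = ".")]] <- fl
      rows[[length(rows) + 1L]] <- data.frame(
        unit = rates$units$unit_id[u],
        condition_id = conds$condition_id[ci],
        flagged_fraction = mean(fl), n_trials = n)
      total_flagged <- total_flagged + sum(fl)
      total_pts <- total_pts + length(fl)
    }
  }
  by_unit <- if (length(rows)) do.call(rbind, rows) else NULL
  list(by_unit = by_unit,
       flagged_fraction = if (total_pts) total_flagged / total_pts else
         NA_real_,
       n_points = total_pts, flags = flags)
}

#' Regression of spike-count variance on mean
#'
#' Ordinary least squares of variance against mean across units, conditions
#' and windows; the slope is the Fano-factor estimate for the dataset.
#'
#' @param means,vars Matched vectors of spike-count means and variances.
#' @param through_origin Force a zero intercept.
#' @return List with `slope`, `intercept` and `n`.
#' @export
fano_regression <- function(means, vars, through_origin = FALSE) {
  ok <- is.finite(means) & is.finite(vars)
  means <- means[ok]; vars <- vars[ok]
  if (length(means) < 2L) stop("no qualifying spike counts", call. = FALSE)
  if (through_origin) {
    list(slope = sum(means * vars) / sum(means^2), intercept = 0,
         n = length(means))
  } else {
    fit <- stats::lm.fit(cbind(1, means), vars)
    list(slope = unname(fit$coefficients[2]),
         intercept = unname(fit$coefficients[1]), n = length(means))
  }
}

#' Fano factor of a session
#'
#' Counts spikes in two fixed windows on unwarped trials, one preceding and
#' one following the moment the pedal crosses the trial's middle cycle
#' (3.5 cycles of unsigned progress), then regresses the across-trial
#' spike-count variance on the mean across units, conditions and windows.
#'
#' @param session A `cp_session`.
#' @param window_ms Window length in ms.
#' @param min_trials Minimum trials per unit/condition.
#' @param through_origin Passed to [fano_regression()].
#' @return List with `slope`, `intercept`, `n`, and the `points` table of
#'   (mean, variance) pairs.
#' @export
fano_factor <- function(session, window_ms = 250, min_trials = 10,
                        through_origin = FALSE) {
  stopifnot(inherits(session, "cp_session"))
  conds <- session$conditions
  n_units <- nrow(session$units)
  pts <- list()
  for (ci in seq_len(nrow(conds))) {
    sel <- which(session$trials$condition_id == conds$condition_id[ci])
    if (length(sel) < min_trials) next
    counts_pre <- matrix(0, length(sel), n_units)
    counts_post <- matrix(0, length(sel), n_units)
    for (j in seq_along(sel)) {
      i <- sel[j]
      pedal <- session$traces[[i]][, paste0("pedal_", conds$arm[ci])]
      u <- c(0, cumsum(abs(diff(pedal))))
      tt <- (seq_along(pedal) - 1L) / session$fs
      t_mid <- stats::approx(u[!duplicated(u)], tt[!duplicated(u)],
                             xout = 3.5)$y
      w <- window_ms / 1000
      for (uu in seq_len(n_units)) {
        sp <- session$spikes[[i]][[uu]]
        counts_pre[j, uu] <- sum(sp >= t_mid - w & sp < t_mid)
        counts_post[j, uu] <- sum(sp >= t_mid & sp < t_mid + w)
      }
    }
    for (win in list(counts_pre, counts_post)) {
      pts[[length(pts) + 1L]] <- data.frame(
        condition_id = conds$condition_id[ci],
        unit = session$units$unit_id,
        mean = colMeans(win), var = apply(win, 2, stats::var))
    }
  }
  if (!length(pts)) stop("no qualifying unit/condition", call. = FALSE)
  tab <- do.call(rbind, pts)
  fit <- fano_regression(tab$mean, tab$var, through_origin)
  c(fit, list(points = tab))
}

#' Magnification required to match a target arm-preference median
#'
#' Finds the smallest factor `k >= 1` by which non-driven-arm muscle
#' modulation must be multiplied so that the median muscle arm-preference
#' index drops to the target. The median index is monotonically
#' nonincreasing in `k`, so the solution is found by bisection.
#'
#' @param mod_driven,mod_non_driven Per-muscle modulations.
#' @param target_median_api Target median index.
#' @param tol Bisection tolerance on `k`.
#' @return The scale factor `k`, or an error if the target is unreachable.
#' @export
required_magnification <- function(mod_driven, mod_non_driven,
                                   target_median_api, tol = 1e-6) {
  stopifnot(length(mod_driven) == length(mod_non_driven))
  med <- function(k) {
    stats::median((mod_driven - k * mod_non_driven) /
                  (mod_driven + k * mod_non_driven))
  }
  if (all(mod_non_driven == 0)) {
    stop("target unreachable: all non-driven modulations are zero",
         call. = FALSE)
  }
  if (med(1) <= target_median_api) return(1)
  hi <- 2
  while (med(hi) > target_median_api) {
    hi <- hi * 2
    if (hi > 1e12) stop("target unreachable", call. = FALSE)
  }
  lo <- hi / 2
  while (hi - lo > tol * max(1, lo)) {
    mid <- (lo + hi) / 2
    if (med(mid) <= target_median_api) hi <- mid else lo <- mid
  }
  hi
}
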