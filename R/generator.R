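# Synthetic session generator.
#
# Emulates the statistical structure of bilateral motor-cortex recordings
# during unimanual cycling: 8 conditions (2 performing arms x 2 cycling
# directions x 2 starting pedal positions), ~2 Hz cycling with trial-to-trial
# speed jitter, rhythmic latent signals (cycle fundamental plus one harmonic)
# living in per-arm subspaces with controllable overlap, per-unit mixed
# lateralization, Poisson spiking, and EMG as a rectified readout of the
# performing arm's latents.

#' Configuration for the synthetic session generator
#'
#' The defaults define the simulated study conditions: 8 unimanual
#' conditions, 7-cycle trials at a mean rate of 2 cycles/s with mild
#' trial-to-trial speed jitter, latent rhythmic signals confined to
#' low-dimensional per-arm subspaces, and Poisson spiking around realistic
#' cortical rates.
#'
#' @param n_units_per_hemisphere Units recorded in each hemisphere.
#' @param n_muscles_per_arm EMG channels implanted in each arm.
#' @param n_trials_per_condition Trials simulated per condition.
#' @param cycle_rate_mean,cycle_rate_sd Mean and SD (cycles/s) of the
#'   constant within-trial cycling speed, drawn per trial from a normal
#'   truncated at +/- 2.5 SD.
#' @param n_cycles Cycles per trial (the task distance between targets).
#' @param lateralization Scalar in \[0, 1\]. 0 makes every unit respond
#'   identically for either arm; 1 silences units (down to baseline) when
#'   their non-driven (ipsilateral) arm performs the task.
#' @param subspace_overlap Scalar in \[0, 1\]. 0 makes the left-arm and
#'   right-arm latent bases exactly orthogonal; 1 makes them identical. The
#'   principal angles between the ground-truth bases are all
#'   `(1 - subspace_overlap) * 90` degrees.
#' @param latent_dim_per_arm Latent dimensions per arm.
#' @param harmonic_weight Relative amplitude of the second-harmonic component
#'   of each latent (0 = purely sinusoidal at the cycle fundamental).
#' @param baseline_rate,rate_gain Baseline firing rate and per-unit
#'   modulation scale (spikes/s); the latent drive is normalized so a
#'   typical unit's modulation is `rate_gain` regardless of population
#'   size. Intensities are rectified at zero after linear mixing.
#' @param nonperforming_jitter_amplitude Maximum amplitude (cycles) of the
#'   non-performing pedal's residual wiggle about the bottom of the cycle.
#' @param emg_noise_sd SD of additive broadband noise on raw EMG voltages
#'   (intensity units).
#' @param speed_coupling Couples firing-rate gain to the (standardized)
#'   per-trial mean speed of the non-performing arm. 0 (the default) makes
#'   rates statistically independent of those small movements, the null
#'   hypothesis of the speed-split randomization test.
#' @param stopping_emg_amplitude Amplitude of the weak end-of-movement EMG
#'   in the non-performing arm ("tensing when stopping"). Set to 0 to turn
#'   the feature off.
#' @param emg_rectified If `TRUE` (default) muscle readouts carry small
#'   offsets so rectification at zero is active, as for real EMG envelopes.
#'   If `FALSE` a large offset keeps the readout in its linear range, which
#'   is useful for noiseless decoder-recovery tests.
#' @param seed Root seed. Every stochastic sub-step derives a named child
#'   stream from it, so identical configurations reproduce sessions exactly.
#' @return A `cp_generator_config` list.
#' @export
generator_config <- function(n_units_per_hemisphere = 25,
                             n_muscles_per_arm = 6,
                             n_trials_per_condition = 25,
                             cycle_rate_mean = 2.0,
                             cycle_rate_sd = 0.15,
                             n_cycles = 7,
                             lateralization = 0.15,
                             subspace_overlap = 0.1,
                             latent_dim_per_arm = 4,
                             harmonic_weight = 0.3,
                             baseline_rate = 12,
                             rate_gain = 8,
                             nonperforming_jitter_amplitude = 0.02,
                             emg_noise_sd = 0.05,
                             speed_coupling = 0,
                             stopping_emg_amplitude = 0.1,
                             emg_rectified = TRUE,
                             seed = 1L) {
  check_scalar(n_units_per_hemisphere, "n_units_per_hemisphere", 1, Inf, TRUE)
  check_scalar(n_muscles_per_arm, "n_muscles_per_arm", 1, Inf, TRUE)
  check_scalar(n_trials_per_condition, "n_trials_per_condition", 1, Inf, TRUE)
  check_scalar(cycle_rate_mean, "cycle_rate_mean", 1e-6, Inf)
  check_scalar(cycle_rate_sd, "cycle_rate_sd", 0, Inf)
  check_scalar(n_cycles, "n_cycles", 7, Inf, TRUE)
  check_scalar(lateralization, "lateralization", 0, 1)
  check_scalar(subspace_overlap, "subspace_overlap", 0, 1)
  check_scalar(latent_dim_per_arm, "latent_dim_per_arm", 1, Inf, TRUE)
  check_scalar(harmonic_weight, "harmonic_weight", 0, Inf)
  check_scalar(baseline_rate, "baseline_rate", 0, Inf)
  check_scalar(rate_gain, "rate_gain", 0, Inf)
  check_scalar(nonperforming_jitter_amplitude,
               "nonperforming_jitter_amplitude", 0, 0.49)
  check_scalar(emg_noise_sd, "emg_noise_sd", 0, Inf)
  check_scalar(speed_coupling, "speed_coupling", 0, Inf)
  check_scalar(stopping_emg_amplitude, "stopping_emg_amplitude", 0, Inf)
  if (!is.logical(emg_rectified) || length(emg_rectified) != 1L ||
      is.na(emg_rectified)) {
    stop_named("emg_rectified", "must be TRUE or FALSE")
  }
  check_scalar(seed, "seed", -2^31, 2^31, TRUE)
  if (2 * latent_dim_per_arm > 2 * n_units_per_hemisphere) {
    stop_named("latent_dim_per_arm",
               "two orthogonal bases need 2*latent_dim <= total units")
  }
  cfg <- list(
    n_units_per_hemisphere = as.integer(n_units_per_hemisphere),
    n_muscles_per_arm = as.integer(n_muscles_per_arm),
    n_trials_per_condition = as.integer(n_trials_per_condition),
    cycle_rate_mean = cycle_rate_mean, cycle_rate_sd = cycle_rate_sd,
    n_cycles = as.integer(n_cycles), lateralization = lateralization,
    subspace_overlap = subspace_overlap,
    latent_dim_per_arm = as.integer(latent_dim_per_arm),
    harmonic_weight = harmonic_weight, baseline_rate = baseline_rate,
    rate_gain = rate_gain,
    nonperforming_jitter_amplitude = nonperforming_jitter_amplitude,
    emg_noise_sd = emg_noise_sd, speed_coupling = speed_coupling,
    stopping_emg_amplitude = stopping_emg_amplitude,
    emg_rectified = emg_rectified, seed = as.integer(seed))
  class(cfg) <- "cp_generator_config"
  cfg
}

condition_table <- function() {
  g <- expand.grid(start = c("top", "bottom"),
                   direction = c("forward", "backward"),
                   arm = c("left", "right"),
                   stringsAsFactors = FALSE)
  g <- g[, c("arm", "direction", "start")]
  g$condition_id <- paste(g$arm, g$direction, g$start, sep = "_")
  g[, c("condition_id", "arm", "direction", "start")]
}

# Random orthonormal n x k basis.
random_orthonormal <- function(n, k) {
  qr.Q(qr(matrix(stats::rnorm(n * k), n, k)))[, seq_len(k), drop = FALSE]
}

# Two bases whose principal angles are all (1 - overlap) * 90 degrees.
make_arm_bases <- function(n, k, overlap) {
  u <- random_orthonormal(n, 2 * k)
  ul <- u[, seq_len(k), drop = FALSE]
  v <- u[, k + seq_len(k), drop = FALSE]
  alpha <- (1 - overlap) * pi / 2
  ur <- cos(alpha) * ul + sin(alpha) * v
  list(left = ul, right = ur)
}

# Ground truth drawn deterministically from the config's child streams.
make_ground_truth <- function(config) {
  n <- 2L * config$n_units_per_hemisphere
  k <- config$latent_dim_per_arm
  m <- config$n_muscles_per_arm
  bases <- with_seed(child_seed(config$seed, "bases"),
                     make_arm_bases(n, k, config$subspace_overlap))
  # Latent phases are shared between starting positions (latents are
  # functions of absolute pedal position), but differ across arms and
  # cycling directions.
  phases <- with_seed(child_seed(config$seed, "phases"), {
    a <- array(stats::runif(2 * 2 * k * 2), dim = c(2, 2, k, 2),
               dimnames = list(arm = c("left", "right"),
                               direction = c("forward", "backward"),
                               NULL, c("fund", "harm")))
    a
  })
  muscle_readout <- with_seed(child_seed(config$seed, "muscles"), {
    out <- list()
    for (arm in c("left", "right")) {
      cmat <- matrix(stats::rnorm(k * m), k, m)
      cmat <- sweep(cmat, 2, sqrt(colSums(cmat^2)), "/")
      offset <- if (config$emg_rectified) stats::runif(m, 0, 0.8) else rep(3, m)
      stop_factor <- stats::runif(m, 0.5, 1)
      out[[arm]] <- list(weights = cmat, offset = offset,
                         stop_factor = stop_factor)
    }
    out
  })
  # Per-unit gain applied when a given arm performs: full for the driven
  # (contralateral) arm, attenuated by lateralization otherwise.
  hemi <- rep(c("left", "right"), each = config$n_units_per_hemisphere)
  gain <- cbind(left = ifelse(driven_arm(hemi) == "left",
                              1, 1 - config$lateralization),
                right = ifelse(driven_arm(hemi) == "right",
                               1, 1 - config$lateralization))
  gt <- list(left_arm_basis = bases$left, right_arm_basis = bases$right,
             phases = phases, muscle_readout = muscle_readout,
             unit_hemisphere = hemi, arm_gain = gain, config = config)
  class(gt) <- "cp_ground_truth"
  gt
}

# Latent time courses z(pos): one column per latent dimension, evaluated at
# absolute pedal positions `pos` (cycles), normalized to unit SD over a cycle.
latent_values <- function(pos, phases_arm_dir, harmonic_weight) {
  if (!is.matrix(phases_arm_dir)) {
    phases_arm_dir <- matrix(phases_arm_dir, ncol = 2)
  }
  k <- nrow(phases_arm_dir)
  z <- matrix(0, length(pos), k)
  norm <- sqrt(0.5 * (1 + harmonic_weight^2))
  for (d in seq_len(k)) {
    z[, d] <- (sin(2 * pi * (pos + phases_arm_dir[d, 1])) +
               harmonic_weight * sin(2 * pi * (2 * pos + phases_arm_dir[d, 2]))) / norm
  }
  z
}

start_offset <- function(start) ifelse(start == "top", 0, 0.5)
direction_sign <- function(direction) ifelse(direction == "forward", 1, -1)

# Unit intensities (spikes/s) for one condition at given absolute pedal
# positions; `gain_scale` carries the optional speed coupling.
unit_intensity <- function(gt, arm, direction, pos, gain_scale = 1) {
  cfg <- gt$config
  basis <- if (arm == "left") gt$left_arm_basis else gt$right_arm_basis
  z <- latent_values(pos, gt$phases[arm, direction, , , drop = TRUE],
                     cfg$harmonic_weight)
  # Scale so each unit's modulation is independent of the population size
  # (rows of an orthonormal basis shrink as 1/sqrt(n)).
  scale <- sqrt(nrow(basis) / ncol(basis))
  drive <- scale * (z %*% t(basis))           # time x units
  drive <- sweep(drive, 2, gt$arm_gain[, arm], "*")
  pmax(cfg$baseline_rate + cfg$rate_gain * gain_scale * drive, 0)
}

# Muscle intensities (arbitrary units) for all 2m channels; only the
# performing arm's muscles read out the latents, the other arm carries at
# most a weak end-of-movement bump. `progress` is unsigned cycles completed.
muscle_intensity <- function(gt, arm, direction, pos, progress) {
  cfg <- gt$config
  m <- cfg$n_muscles_per_arm
  out <- matrix(0, length(pos), 2 * m)
  ro <- gt$muscle_readout[[arm]]
  z <- latent_values(pos, gt$phases[arm, direction, , , drop = TRUE],
                     cfg$harmonic_weight)
  act <- pmax(sweep(z %*% ro$weights, 2, ro$offset, "+"), 0)
  cols_perf <- if (arm == "left") seq_len(m) else m + seq_len(m)
  cols_np <- if (arm == "left") m + seq_len(m) else seq_len(m)
  out[, cols_perf] <- act
  if (cfg$stopping_emg_amplitude > 0) {
    np <- gt$muscle_readout[[other_arm(arm)]]
    bump <- exp(-0.5 * ((progress - (cfg$n_cycles - 0.25)) / 0.12)^2)
    out[, cols_np] <- cfg$stopping_emg_amplitude *
      outer(bump, np$stop_factor)
  }
  out
}

#' Generate a synthetic recording session
#'
#' Simulates all trials of one session: spike trains from an inhomogeneous
#' Poisson process whose intensity is baseline plus mixed rhythmic latents,
#' pedal position traces for both arms, and raw multi-channel EMG voltages
#' (intensity-modulated broadband noise). Identical configurations produce
#' identical sessions.
#'
#' @param config A [generator_config()].
#' @return A list with elements `session` (a `cp_session`) and
#'   `ground_truth` (a `cp_ground_truth` holding the latent bases, mixing
#'   weights, readout weights and per-trial speed profiles).
#' @export
generate_session <- function(config) {
  if (!inherits(config, "cp_generator_config")) {
    config <- do.call(generator_config, as.list(config))
  }
  cfg <- config
  gt <- make_ground_truth(cfg)
  conds <- condition_table()
  n_units <- 2L * cfg$n_units_per_hemisphere
  m2 <- 2L * cfg$n_muscles_per_arm
  fs <- 1000
  dt <- 1 / fs

  units <- data.frame(
    unit_id = sprintf("u%03d", seq_len(n_units)),
    hemisphere = gt$unit_hemisphere,
    unit_type = "single",
    stringsAsFactors = FALSE)
  muscles <- data.frame(
    channel_id = c(sprintf("emg_left_%d", seq_len(cfg$n_muscles_per_arm)),
                   sprintf("emg_right_%d", seq_len(cfg$n_muscles_per_arm))),
    arm = rep(c("left", "right"), each = cfg$n_muscles_per_arm),
    stringsAsFactors = FALSE)

  # Pass 1: kinematics for every trial (speeds and non-performing wiggle
  # parameters), so the speed coupling can be standardized per condition.
  kin <- vector("list", nrow(conds) * cfg$n_trials_per_condition)
  trial_rows <- list()
  idx <- 0L
  for (ci in seq_len(nrow(conds))) {
    for (k in seq_len(cfg$n_trials_per_condition)) {
      idx <- idx + 1L
      lab <- paste("kin", conds$condition_id[ci], k)
      kin[[idx]] <- with_seed(child_seed(cfg$seed, lab), {
        u <- stats::runif(1, stats::pnorm(-2.5), stats::pnorm(2.5))
        speed <- cfg$cycle_rate_mean + cfg$cycle_rate_sd * stats::qnorm(u)
        list(condition = ci, k = k, speed = speed,
             np_amp = stats::runif(1, 0, cfg$nonperforming_jitter_amplitude),
             np_freq = stats::runif(1, 0.8, 1.2),
             np_phase = stats::runif(1, 0, 2 * pi))
      })
    }
  }
  np_true <- vapply(kin, function(x) 4 * x$np_amp * x$np_freq, 0)
  cond_of <- vapply(kin, function(x) x$condition, 0L)
  np_std <- np_true
  for (ci in seq_len(nrow(conds))) {
    sel <- cond_of == ci
    s <- stats::sd(np_true[sel])
    np_std[sel] <- if (is.na(s) || s == 0) 0 else
      (np_true[sel] - mean(np_true[sel])) / s
  }

  # Pass 2: traces and spikes.
  traces <- vector("list", length(kin))
  spikes <- vector("list", length(kin))
  for (i in seq_along(kin)) {
    kk <- kin[[i]]
    cond <- conds[kk$condition, ]
    dur <- cfg$n_cycles / kk$speed
    tt <- seq(0, dur, by = dt)
    progress <- kk$speed * tt
    pos_perf <- start_offset(cond$start) +
      direction_sign(cond$direction) * progress
    pos_np <- 0.5 + kk$np_amp * sin(2 * pi * kk$np_freq * tt + kk$np_phase)
    gain_scale <- 1 + cfg$speed_coupling * np_std[i]
    lam <- unit_intensity(gt, cond$arm, cond$direction, pos_perf, gain_scale)
    emg_int <- muscle_intensity(gt, cond$arm, cond$direction,
                                pos_perf, progress)
    obs <- with_seed(child_seed(cfg$seed,
                                paste("obs", cond$condition_id, kk$k)), {
      counts <- matrix(stats::rpois(length(lam), lam * dt),
                       nrow(lam), ncol(lam))
      sp <- vector("list", n_units)
      for (u in seq_len(n_units)) {
        nz <- which(counts[, u] > 0L)
        if (length(nz)) {
          reps <- counts[nz, u]
          sp[[u]] <- sort(rep(tt[nz], reps) +
                          stats::runif(sum(reps), 0, dt))
        } else sp[[u]] <- numeric(0)
      }
      emg_raw <- emg_int * matrix(stats::rnorm(length(emg_int)),
                                  nrow(emg_int)) +
        cfg$emg_noise_sd * matrix(stats::rnorm(length(emg_int)),
                                  nrow(emg_int))
      list(spikes = sp, emg = emg_raw)
    })
    tr <- cbind(pedal_left = if (cond$arm == "left") pos_perf else pos_np,
                pedal_right = if (cond$arm == "right") pos_perf else pos_np,
                obs$emg)
    colnames(tr) <- c("pedal_left", "pedal_right", muscles$channel_id)
    traces[[i]] <- tr
    spikes[[i]] <- obs$spikes
    trial_rows[[i]] <- data.frame(
      trial_id = sprintf("t%04d", i),
      condition_id = cond$condition_id, arm = cond$arm,
      direction = cond$direction, start = cond$start,
      speed = kk$speed,
      np_speed = mean(abs(diff(pos_np))) * fs,
      duration_s = dur, stringsAsFactors = FALSE)
  }
  trials <- do.call(rbind, trial_rows)
  gt$trials <- trials

  session <- list(config = cfg, units = units, muscles = muscles,
                  conditions = conds, trials = trials, fs = fs,
                  traces = traces, spikes = spikes)
  class(session) <- "cp_session"
  list(session = session, ground_truth = gt)
}

#' Noise-free trial-averaged tensors implied by the ground truth
#'
#' Evaluates the generator's expected unit intensities and muscle
#' intensities directly on the canonical aligned time base (no spiking, no
#' EMG carrier noise, no speed jitter). Used for recovery tests where the
#' analysis should reproduce the generating model exactly.
#'
#' @param config A [generator_config()].
#' @param ground_truth Optional `cp_ground_truth`; regenerated from
#'   `config` when omitted.
#' @param dt_ms Canonical grid step in ms.
#' @return List with `neural` and `emg` arrays (time x channel x condition),
#'   `time_ms`, and the unit/muscle/condition tables.
#' @export
expected_rate_tensor <- function(config, ground_truth = NULL, dt_ms = 10) {
  if (!inherits(config, "cp_generator_config")) {
    config <- do.call(generator_config, as.list(config))
  }
  gt <- ground_truth %||% make_ground_truth(config)
  conds <- condition_table()
  tc <- canonical_grid(dt_ms)
  theta <- 0.5 + tc / .CYCLE_MS          # unsigned cycles completed
  n_units <- 2L * config$n_units_per_hemisphere
  m2 <- 2L * config$n_muscles_per_arm
  neural <- array(0, c(length(tc), n_units, nrow(conds)))
  emg <- array(0, c(length(tc), m2, nrow(conds)))
  for (ci in seq_len(nrow(conds))) {
    cond <- conds[ci, ]
    pos <- start_offset(cond$start) + direction_sign(cond$direction) * theta
    neural[, , ci] <- unit_intensity(gt, cond$arm, cond$direction, pos)
    emg[, , ci] <- muscle_intensity(gt, cond$arm, cond$direction, pos, theta)
  }
  hemi <- gt$unit_hemisphere
  list(neural = neural, emg = emg, time_ms = tc,
       units = data.frame(unit_id = sprintf("u%03d", seq_len(n_units)),
                          hemisphere = hemi, stringsAsFactors = FALSE),
       muscles = data.frame(
         channel_id = c(sprintf("emg_left_%d",
                                seq_len(config$n_muscles_per_arm)),
                        sprintf("emg_right_%d",
                                seq_len(config$n_muscles_per_arm))),
         arm = rep(c("left", "right"), each = config$n_muscles_per_arm),
         stringsAsFactors = FALSE),
       conditions = conds)
}

#' Principal angles between two orthonormal bases
#'
#' @param basis_a,basis_b Matrices with orthonormal columns in the same
#'   ambient dimension.
#' @return Angles in degrees, sorted ascending, each in \[0, 90\].
#' @export
principal_angles <- function(basis_a, basis_b) {
  basis_a <- as.matrix(basis_a)
  basis_b <- as.matrix(basis_b)
  if (nrow(basis_a) != nrow(basis_b)) {
    stop("bases must share the same ambient dimension", call. = FALSE)
  }
  for (nm in c("basis_a", "basis_b")) {
    b <- get(nm)
    g <- crossprod(b)
    if (max(abs(g - diag(ncol(b)))) > 1e-8) {
      stop_named(nm, "columns must be orthonormal")
    }
  }
  d <- svd(crossprod(basis_a, basis_b))$d
  sort(acos(pmin(1, pmax(-1, d))) * 180 / pi)
}

#' Write a session (and optional ground truth) to a directory
#'
#' Plain-text layout: `session.json` (units, muscles, conditions, trial
#' table, config), `spikes.csv` (`unit_id, trial_id, spike_time_s`),
#' `traces.csv` (`trial_id, time_s, channel_id, value`), and optionally
#' `ground_truth.json`.
#'
#' @param session A `cp_session`.
#' @param dir Output directory (created if needed).
#' @param ground_truth Optional `cp_ground_truth` to serialize alongside.
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir, ground_truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(config = unclass(session$config), units = session$units,
               muscles = session$muscles, conditions = session$conditions,
               trials = session$trials, fs = session$fs)
  jsonlite::write_json(meta, file.path(dir, "session.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  sp <- list()
  for (i in seq_along(session$spikes)) {
    for (u in seq_along(session$spikes[[i]])) {
      times <- session$spikes[[i]][[u]]
      if (length(times)) {
        sp[[length(sp) + 1L]] <- data.frame(
          unit_id = session$units$unit_id[u],
          trial_id = session$trials$trial_id[i],
          spike_time_s = times, stringsAsFactors = FALSE)
      }
    }
  }
  utils::write.csv(do.call(rbind, sp), file.path(dir, "spikes.csv"),
                   row.names = FALSE)
  tr <- list()
  for (i in seq_along(session$traces)) {
    m <- session$traces[[i]]
    tt <- (seq_len(nrow(m)) - 1L) / session$fs
    tr[[i]] <- data.frame(
      trial_id = session$trials$trial_id[i],
      time_s = rep(tt, ncol(m)),
      channel_id = rep(colnames(m), each = nrow(m)),
      value = as.vector(m), stringsAsFactors = FALSE)
  }
  utils::write.csv(do.call(rbind, tr), file.path(dir, "traces.csv"),
                   row.names = FALSE)
  if (!is.null(ground_truth)) {
    g <- ground_truth
    jsonlite::write_json(
      list(left_arm_basis = g$left_arm_basis,
           right_arm_basis = g$right_arm_basis,
           phases = g$phases, arm_gain = g$arm_gain,
           unit_hemisphere = g$unit_hemisphere,
           muscle_readout = g$muscle_readout,
           trials = g$trials, config = unclass(g$config)),
      file.path(dir, "ground_truth.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  invisible(dir)
}

#' Read a session directory written by [write_session()]
#'
#' @param dir Directory containing `session.json`, `spikes.csv` and
#'   `traces.csv`.
#' @return A `cp_session`.
#' @export
read_session <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "session.json"),
                              simplifyVector = TRUE)
  spikes_df <- utils::read.csv(file.path(dir, "spikes.csv"),
                               stringsAsFactors = FALSE)
  traces_df <- utils::read.csv(file.path(dir, "traces.csv"),
                               stringsAsFactors = FALSE)
  trials <- as.data.frame(meta$trials, stringsAsFactors = FALSE)
  units <- as.data.frame(meta$units, stringsAsFactors = FALSE)
  muscles <- as.data.frame(meta$muscles, stringsAsFactors = FALSE)
  channels <- c("pedal_left", "pedal_right", muscles$channel_id)
  traces <- vector("list", nrow(trials))
  spikes <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    tid <- trials$trial_id[i]
    sub <- traces_df[traces_df$trial_id == tid, ]
    tt <- sort(unique(sub$time_s))
    m <- matrix(0, length(tt), length(channels),
                dimnames = list(NULL, channels))
    for (ch in channels) {
      m[, ch] <- sub$value[sub$channel_id == ch][order(sub$time_s[sub$channel_id == ch])]
    }
    traces[[i]] <- m
    sp <- vector("list", nrow(units))
    ssub <- spikes_df[spikes_df$trial_id == tid, ]
    for (u in seq_len(nrow(units))) {
      sp[[u]] <- sort(ssub$spike_time_s[ssub$unit_id == units$unit_id[u]])
    }
    spikes[[i]] <- sp
  }
  cfg <- do.call(generator_config, meta$config)
  session <- list(config = cfg, units = units, muscles = muscles,
                  conditions = as.data.frame(meta$conditions,
                                             stringsAsFactors = FALSE),
                  trials = trials, fs = meta$fs,
                  traces = traces, spikes = spikes)
  class(session) <- "cp_session"
  session
}
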