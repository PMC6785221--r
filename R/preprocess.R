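# Preprocessing: spike smoothing, EMG conditioning, two-step position-based
# trial alignment onto the canonical 2 Hz time base, and trial averaging.
#
# Conventions: smoothing and alignment run on a 1 ms grid; aligned traces
# are returned on a 10 ms analysis grid covering the six middle cycles
# (0-3000 ms, 500 ms per cycle). The Gaussian kernel width is its standard
# deviation, truncated at +/- 4 SD.

# Discretized Gaussian kernel in units of 1/s, on a grid with step dt_ms.
gauss_kernel <- function(sd_ms, dt_ms) {
  half <- ceiling(4 * sd_ms / dt_ms)
  stats::dnorm(seq(-half, half) * dt_ms / 1000, sd = sd_ms / 1000)
}

# Convolve each column of `x` with `kernel` (centered), via FFT.
conv_centered <- function(x, kernel) {
  x <- as.matrix(x)
  nk <- length(kernel)
  half <- (nk - 1L) / 2L
  n <- nrow(x) + nk - 1L
  nfft <- stats::nextn(n, 2)
  pad <- function(m, len) rbind(m, matrix(0, len - nrow(m), ncol(m)))
  fx <- stats::mvfft(pad(x, nfft))
  fk <- stats::fft(c(kernel, rep(0, nfft - nk)))
  out <- Re(stats::mvfft(fx * fk, inverse = TRUE)) / nfft
  out[half + seq_len(nrow(x)), , drop = FALSE]
}

#' Smooth a spike train into a continuous firing rate
#'
#' Convolves spike times with a Gaussian kernel (default SD 25 ms). The
#' resulting trace integrates to the number of spikes: an isolated spike
#' contributes unit mass, peaking at `1/(sqrt(2*pi)*sd)` spikes/s.
#'
#' @param spike_times Spike times in seconds (sorted or not).
#' @param grid_ms Uniform time grid in ms on which to evaluate the rate.
#' @param kernel_sd Gaussian SD in ms.
#' @return Nonnegative rate trace (spikes/s) on `grid_ms`.
#' @export
smooth_spike_train <- function(spike_times, grid_ms, kernel_sd = 25) {
  check_scalar(kernel_sd, "kernel_sd", 1e-9, Inf)
  if (length(grid_ms) < 2L) stop("grid must have at least two points")
  dt <- diff(grid_ms)
  if (max(abs(dt - dt[1])) > 1e-9) stop("grid must be uniform")
  dt <- dt[1]
  spike_times <- sort(spike_times)
  counts <- bin_spikes(spike_times, grid_ms, dt)
  rate <- conv_centered(matrix(counts, ncol = 1), gauss_kernel(kernel_sd, dt))
  pmax(0, as.vector(rate))
}

# Count spikes into bins centered on the grid points; spikes within 4 SD
# outside the grid still land in the nearest edge bin so their tail mass
# contributes.
bin_spikes <- function(spike_times, grid_ms, dt_ms) {
  if (!length(spike_times)) return(numeric(length(grid_ms)))
  idx <- round((spike_times * 1000 - grid_ms[1]) / dt_ms) + 1L
  idx <- pmin(pmax(idx, 1L), length(grid_ms))
  tabulate(idx, nbins = length(grid_ms))
}

# Smooth per-unit spike trains of one trial onto a 1 ms grid. Returns a
# time x unit matrix of rates.
smooth_trial_spikes <- function(spike_list, grid_ms, kernel_sd = 25) {
  counts <- vapply(spike_list, bin_spikes, numeric(length(grid_ms)),
                   grid_ms = grid_ms, dt_ms = 1)
  pmax(conv_centered(counts, gauss_kernel(kernel_sd, 1)), 0)
}

#' Convert raw EMG voltage to an intensity trace
#'
#' High-pass filters at 40 Hz (zero-phase 4th-order Butterworth), rectifies,
#' and smooths with a Gaussian kernel (default SD 25 ms).
#'
#' @param raw Raw voltage trace (uniformly sampled).
#' @param fs Sampling rate in Hz; must exceed twice the 40 Hz corner.
#' @param kernel_sd Gaussian SD in ms.
#' @return Nonnegative intensity trace on the input grid.
#' @export
preprocess_emg <- function(raw, fs, kernel_sd = 25) {
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 80) {
    stop_named("fs", "sampling rate must exceed twice the 40 Hz corner")
  }
  bf <- signal::butter(4, 40 / (fs / 2), type = "high")
  hp <- signal::filtfilt(bf, as.numeric(raw))
  rect <- abs(hp)
  dt_ms <- 1000 / fs
  out <- conv_centered(matrix(rect, ncol = 1), gauss_kernel(kernel_sd, dt_ms))
  pmax(0, as.vector(out)) * dt_ms / 1000
}

#' Mean angular speed of a pedal trace
#'
#' The magnitude of the angular velocity, averaged over the trial.
#'
#' @param angle Pedal angle trace in cycles, uniformly sampled.
#' @param fs Sampling rate in Hz.
#' @return Mean speed in cycles/s.
#' @export
trial_mean_speed <- function(angle, fs) {
  if (length(angle) < 2L) return(0)
  mean(abs(diff(angle))) * fs
}

#' Align one trial onto the canonical 2 Hz time base
#'
#' Two-step alignment: trials are anchored at the completion of the first
#' half-cycle (the first crossing of 0.5 cycles of unsigned cumulative pedal
#' angle), then rates are treated as functions of unsigned cumulative angle
#' over the middle six cycles and resampled onto the canonical grid
#' (500 ms per cycle, 0-3000 ms). Rate values are never altered, only the
#' times at which they occur.
#'
#' @param rates Time x channel matrix of continuous traces on a uniform
#'   grid (1 ms by default).
#' @param pedal Performing-arm pedal angle (cycles) on the same grid.
#' @param fs Sampling rate of `rates` and `pedal` in Hz.
#' @param dt_out Canonical grid step in ms.
#' @param trial_id Identifier used in error messages.
#' @return List with `values` (canonical time x channel), `time_ms`,
#'   `angle` (unsigned cumulative pedal angle at each canonical time, in
#'   cycles from movement start) and `warped_position` (absolute pedal
#'   angle resampled the same way).
#' @export
align_trial <- function(rates, pedal, fs = 1000, dt_out = 10,
                        trial_id = "trial") {
  rates <- as.matrix(rates)
  if (nrow(rates) != length(pedal)) {
    stop("rates and pedal angle must share a time grid", call. = FALSE)
  }
  tt <- (seq_along(pedal) - 1L) / fs
  # Unsigned cumulative angle: magnitudes are accumulated so backward
  # cycling and tiny non-monotonic jitter both warp identically.
  u <- c(0, cumsum(abs(diff(pedal))))
  need <- 0.5 + .N_ALIGN_CYCLES
  if (max(u) < need - 1e-6) {
    stop(sprintf("%s: pedal angle does not complete six middle cycles",
                 trial_id), call. = FALSE)
  }
  tc <- canonical_grid(dt_out)
  theta <- 0.5 + tc / .CYCLE_MS
  keep <- !duplicated(u)
  times_c <- stats::approx(u[keep], tt[keep], xout = theta)$y
  fi <- times_c * fs + 1
  i0 <- pmin(pmax(floor(fi), 1), nrow(rates) - 1L)
  fr <- fi - i0
  values <- rates[i0, , drop = FALSE] * (1 - fr) +
    rates[i0 + 1L, , drop = FALSE] * fr
  warped_pos <- pedal[i0] * (1 - fr) + pedal[i0 + 1L] * fr
  list(values = values, time_ms = tc, angle = theta,
       warped_position = warped_pos, trial_id = trial_id)
}

#' Average aligned trials of one condition
#'
#' @param aligned List of aligned trials (as from [align_trial()]) or of
#'   plain time x channel matrices on a shared grid.
#' @return List with `mean` and `sem` (time x channel) and `n_trials`.
#' @export
trial_average <- function(aligned) {
  mats <- lapply(aligned, function(a) if (is.list(a)) a$values else a)
  if (!length(mats)) stop("need at least one aligned trial", call. = FALSE)
  arr <- simplify2array(mats)                 # time x channel x trial
  if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
  n <- dim(arr)[3]
  mu <- apply(arr, c(1, 2), mean)
  sem <- if (n > 1) apply(arr, c(1, 2), stats::sd) / sqrt(n) else
    matrix(0, dim(arr)[1], dim(arr)[2])
  list(mean = mu, sem = sem, n_trials = n)
}

#' Slice a canonical-time tensor down to a middle-cycle window
#'
#' Cycle `k` of the canonical window occupies `[(k-1)*500, k*500)` ms; the
#' default window (cycles 2-5) is the 2000 ms slice starting 500 ms in. A
#' phase offset in cycles shifts the window (e.g. -0.5 selects cycles
#' 1.5-4.5, used when comparing top-start against bottom-start responses).
#'
#' @param x Matrix or array whose first dimension is canonical time.
#' @param first_cycle,last_cycle Window bounds (inclusive cycle labels).
#' @param phase_offset Shift in cycles.
#' @param dt_ms Canonical grid step of `x`.
#' @return The contiguous slice of `x` along time.
#' @export
extract_middle_cycles <- function(x, first_cycle = 2, last_cycle = 5,
                                  phase_offset = 0, dt_ms = 10) {
  if (first_cycle > last_cycle) {
    stop("first_cycle must not exceed last_cycle", call. = FALSE)
  }
  t0 <- ((first_cycle - 1) + phase_offset) * .CYCLE_MS
  t1 <- (last_cycle + phase_offset) * .CYCLE_MS
  if (t0 < -1e-9 || t1 > .CANON_MS + 1e-9) {
    stop("requested window lies outside the canonical six middle cycles",
         call. = FALSE)
  }
  idx <- which(canonical_grid(dt_ms) >= t0 - 1e-9 &
               canonical_grid(dt_ms) < t1 - 1e-9)
  nd <- length(dim(x)) %||% 0L
  if (is.matrix(x)) x[idx, , drop = FALSE]
  else if (is.array(x) && length(dim(x)) == 3L) x[idx, , , drop = FALSE]
  else x[idx]
}

middle_window_index <- function(first_cycle = 2, last_cycle = 5,
                                phase_offset = 0, dt_ms = 10) {
  t0 <- ((first_cycle - 1) + phase_offset) * .CYCLE_MS
  t1 <- (last_cycle + phase_offset) * .CYCLE_MS
  which(canonical_grid(dt_ms) >= t0 - 1e-9 & canonical_grid(dt_ms) < t1 - 1e-9)
}

#' Preprocess a full session into aligned rate tensors
#'
#' Smooths spikes (Gaussian SD `kernel_sd` on a 1 ms grid), conditions EMG
#' (40 Hz high-pass, rectify, smooth), aligns every trial onto the canonical
#' time base via the two-step position warp, and averages within condition.
#'
#' @param session A `cp_session` (from [generate_session()] or
#'   [read_session()]).
#' @param kernel_sd Gaussian smoothing SD in ms.
#' @param dt_out Canonical analysis grid step in ms.
#' @param keep_trials Keep per-trial aligned rates (needed by the
#'   speed-split test); `TRUE` by default.
#' @return A `cp_rates` list: `time_ms`; `units`, `muscles`, `conditions`,
#'   `trials` tables; `neural` and `emg`, each holding `mean` and `sem`
#'   arrays (time x channel x condition) and, when `keep_trials`, a
#'   `trials` list of per-condition arrays (trial x time x channel).
#' @export
preprocess_session <- function(session, kernel_sd = 25, dt_out = 10,
                               keep_trials = TRUE) {
  stopifnot(inherits(session, "cp_session"))
  fs <- session$fs
  conds <- session$conditions
  n_units <- nrow(session$units)
  n_emg <- nrow(session$muscles)
  aligned_neural <- vector("list", nrow(conds))
  aligned_emg <- vector("list", nrow(conds))
  names(aligned_neural) <- names(aligned_emg) <- conds$condition_id
  for (ci in seq_len(nrow(conds))) {
    sel <- which(session$trials$condition_id == conds$condition_id[ci])
    an <- vector("list", length(sel))
    ae <- vector("list", length(sel))
    for (j in seq_along(sel)) {
      i <- sel[j]
      tr <- session$traces[[i]]
      grid_ms <- (seq_len(nrow(tr)) - 1L) * 1000 / fs
      rates <- smooth_trial_spikes(session$spikes[[i]], grid_ms, kernel_sd)
      emg_int <- vapply(session$muscles$channel_id,
                        function(ch) preprocess_emg(tr[, ch], fs, kernel_sd),
                        numeric(nrow(tr)))
      pedal <- tr[, paste0("pedal_", conds$arm[ci])]
      an[[j]] <- align_trial(rates, pedal, fs, dt_out,
                             session$trials$trial_id[i])$values
      ae[[j]] <- align_trial(emg_int, pedal, fs, dt_out,
                             session$trials$trial_id[i])$values
    }
    aligned_neural[[ci]] <- an
    aligned_emg[[ci]] <- ae
  }
  tc <- canonical_grid(dt_out)
  pack <- function(aligned, nch) {
    mu <- array(0, c(length(tc), nch, nrow(conds)))
    sem <- array(0, c(length(tc), nch, nrow(conds)))
    trials <- vector("list", nrow(conds))
    names(trials) <- conds$condition_id
    for (ci in seq_len(nrow(conds))) {
      avg <- trial_average(aligned[[ci]])
      mu[, , ci] <- avg$mean
      sem[, , ci] <- avg$sem
      if (keep_trials) {
        trials[[ci]] <- aperm(simplify2array(aligned[[ci]]), c(3, 1, 2))
      }
    }
    out <- list(mean = mu, sem = sem)
    if (keep_trials) out$trials <- trials
    out
  }
  out <- list(time_ms = tc, dt_ms = dt_out,
              units = session$units, muscles = session$muscles,
              conditions = conds, trials = session$trials,
              neural = pack(aligned_neural, n_units),
              emg = pack(aligned_emg, n_emg))
  class(out) <- "cp_rates"
  out
}

#' Build a `cp_rates` object directly from noise-free expected tensors
#'
#' Wraps the output of [expected_rate_tensor()] in the container used by the
#' downstream analyses, for recovery tests that bypass spiking noise.
#'
#' @param tensors Output of [expected_rate_tensor()].
#' @return A `cp_rates` object without per-trial data.
#' @export
rates_from_expected <- function(tensors) {
  zero <- function(a) array(0, dim(a))
  out <- list(time_ms = tensors$time_ms,
              dt_ms = diff(tensors$time_ms[1:2]),
              units = tensors$units, muscles = tensors$muscles,
              conditions = tensors$conditions, trials = NULL,
              neural = list(mean = tensors$neural,
                            sem = zero(tensors$neural)),
              emg = list(mean = tensors$emg, sem = zero(tensors$emg)))
  class(out) <- "cp_rates"
  out
}
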