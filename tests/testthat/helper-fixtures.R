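# Shared fixtures, built once per test run.

small_cfg <- function(...) {
  args <- list(n_units_per_hemisphere = 10, n_trials_per_condition = 10,
               seed = 42)
  args[names(list(...))] <- list(...)
  do.call(generator_config, args)
}

# One small Poisson session + preprocessed rates, cached across test files.
.fixture_cache <- new.env(parent = emptyenv())

small_session <- function() {
  if (is.null(.fixture_cache$gs)) {
    .fixture_cache$gs <- generate_session(small_cfg())
  }
  .fixture_cache$gs
}

small_rates <- function() {
  if (is.null(.fixture_cache$rates)) {
    .fixture_cache$rates <- preprocess_session(small_session()$session)
  }
  .fixture_cache$rates
}

# Build a cp_rates object directly from arrays, for analyses that do not
# need the spiking path.
make_rates <- function(neural, hemispheres, emg = NULL, emg_arm = NULL,
                       dt_ms = 10) {
  conds <- expand.grid(start = c("top", "bottom"),
                       direction = c("forward", "backward"),
                       arm = c("left", "right"),
                       stringsAsFactors = FALSE)
  conds <- conds[, c("arm", "direction", "start")]
  conds$condition_id <- paste(conds$arm, conds$direction, conds$start,
                              sep = "_")
  conds <- conds[, c("condition_id", "arm", "direction", "start")]
  stopifnot(dim(neural)[3] == nrow(conds))
  n <- dim(neural)[2]
  if (is.null(emg)) {
    emg <- array(0, c(dim(neural)[1], 2, nrow(conds)))
    emg_arm <- c("left", "right")
  }
  out <- list(
    time_ms = seq(0, by = dt_ms, length.out = dim(neural)[1]),
    dt_ms = dt_ms,
    units = data.frame(unit_id = sprintf("u%03d", seq_len(n)),
                       hemisphere = hemispheres,
                       stringsAsFactors = FALSE),
    muscles = data.frame(channel_id = sprintf("m%02d", seq_len(dim(emg)[2])),
                         arm = emg_arm, stringsAsFactors = FALSE),
    conditions = conds, trials = NULL,
    neural = list(mean = neural, sem = array(0, dim(neural))),
    emg = list(mean = emg, sem = array(0, dim(emg))))
  class(out) <- "cp_rates"
  out
}

# Smooth random per-condition responses (sum of random-phase harmonics of
# the 2 Hz cycle) on the canonical 300-point grid.
random_responses <- function(n_units, n_conds = 8, seed = 1,
                             n_time = 300) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); code
  }
  withr_seed({
    tt <- seq_len(n_time) / 50      # cycles at 10 ms, 500 ms per cycle
    arr <- array(0, c(n_time, n_units, n_conds))
    for (ci in seq_len(n_conds)) {
      for (u in seq_len(n_units)) {
        ph <- stats::runif(2)
        amp <- stats::runif(2, 0.5, 1.5)
        arr[, u, ci] <- amp[1] * sin(2 * pi * (tt + ph[1])) +
          amp[2] * sin(2 * pi * (2 * tt + ph[2]))
      }
    }
    arr
  })
}

# O(T^2) brute-force tangling oracle (double loop), independent of the
# package implementation.
tangling_brute <- function(trajectories, dt_s = 0.01,
                           epsilon_fraction = 0.1) {
  if (!is.list(trajectories)) trajectories <- list(trajectories)
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
    best <- 0
    for (j in seq_len(m)) {
      num <- sum((xd[i, ] - xd[j, ])^2)
      den <- sum((xs[i, ] - xs[j, ])^2) + eps
      if (num / den > best) best <- num / den
    }
    q[i] <- best
  }
  q
}
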