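# Internal helpers shared across modules.

# Canonical alignment constants: six middle cycles mapped to 0-3000 ms at
# 500 ms per cycle, analyzed on a 10 ms grid.
.CYCLE_MS <- 500
.N_ALIGN_CYCLES <- 6L
.CANON_MS <- 3000

canonical_grid <- function(dt_ms = 10) seq(0, .CANON_MS - dt_ms, by = dt_ms)

# Deterministic child seed for a named stochastic sub-step. Every stochastic
# operation derives its own stream from the root seed plus a label, so
# re-ordering operations cannot silently change results.
child_seed <- function(root, label) {
  v <- utf8ToInt(label)
  h <- (as.numeric(root) %% 1e6) * 1013904223 + sum(v * seq_along(v)) * 69069
  as.integer(h %% 2147483629) + 1L
}

# Evaluate `code` under a seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_named <- function(name, msg) {
  stop(sprintf("invalid '%s': %s", name, msg), call. = FALSE)
}

check_scalar <- function(x, name, lo = -Inf, hi = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_named(name, "must be a single finite number")
  }
  if (x < lo || x > hi) {
    stop_named(name, sprintf("must be in [%s, %s]", format(lo), format(hi)))
  }
  if (integer && x != round(x)) stop_named(name, "must be a whole number")
  invisible(x)
}

other_arm <- function(arm) ifelse(arm == "left", "right", "left")
other_start <- function(start) ifelse(start == "top", "bottom", "top")

# Driven arm of a unit is contralateral to its hemisphere.
driven_arm <- function(hemisphere) other_arm(hemisphere)

# Hemisphere driving a given performing arm (the contralateral cortex).
driving_hemisphere <- function(arm) other_arm(arm)
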