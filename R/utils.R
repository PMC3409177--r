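#' @keywords internal
"_PACKAGE"

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library calls never perturb user-level randomness.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv(), inherits = FALSE)
    else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, field, min = -Inf, max = Inf,
                         integer = FALSE, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("parameter '%s' must be a single finite number", field)
  if (strict_min && x <= min)
    stopf("parameter '%s' must be > %g (got %g)", field, min, x)
  if (!strict_min && x < min)
    stopf("parameter '%s' must be >= %g (got %g)", field, min, x)
  if (x > max)
    stopf("parameter '%s' must be <= %g (got %g)", field, max, x)
  if (integer && x != round(x))
    stopf("parameter '%s' must be an integer (got %g)", field, x)
  invisible(x)
}

# Status levels for punctum traces; shared by the simulator, tracker and
# constancy statistics.
trace_status_levels <- c("tracked", "lost", "rejected_split_merge")

trace_columns <- c("experiment", "neuron", "punctum", "t_min",
                   "fluorescence", "status")
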