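#' Low-pass smooth a fluorescence trace
#'
#' Centered moving average of odd width (default 5 points). At the
#' boundaries the window is truncated symmetrically, so the first and last
#' points are returned unchanged and the half-width grows toward the
#' interior.
#'
#' @param x numeric fluorescence trace.
#' @param width odd window width, points.
#' @return Smoothed numeric vector of the same length.
#' @export
smooth_trace <- function(x, width = 5L) {
  check_number(width, "width", min = 1, integer = TRUE)
  if (width %% 2L == 0L) stopf("smoothing width must be odd (got %d)", width)
  n <- length(x)
  if (width == 1L || n == 0L) return(x)
  h <- (width - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    hi <- min(h, i - 1L, n - i)
    mean(x[(i - hi):(i + hi)])
  }, numeric(1L))
}

#' Range over mean of a smoothed trace
#'
#' Per-punctum content-instability statistic: the trace is smoothed with a
#' `width`-point low-pass filter, then
#' \deqn{(F_{max} - F_{min}) / \bar F} is computed on the smoothed series.
#' Invariant to global rescaling and to time reversal; 0 exactly for a
#' constant trace.
#'
#' @param x numeric fluorescence trace (length >= 2, non-negative).
#' @param width smoothing width passed to [smooth_trace()].
#' @return Object of class `range_over_mean`: list with `value` and the
#'   post-smoothing `f_max`, `f_min`, `f_mean`.
#' @export
range_over_mean <- function(x, width = 5L) {
  if (length(x) < 2L) stopf("trace must have at least 2 points")
  s <- smooth_trace(x, width)
  m <- mean(s)
  if (m <= 0) stopf("smoothed trace has non-positive mean")
  structure(list(value = (max(s) - min(s)) / m,
                 f_max = max(s), f_min = min(s), f_mean = m),
            class = "range_over_mean")
}

#' @export
print.range_over_mean <- function(x, ...) {
  cat(sprintf("range over mean: %.4f (%.1f%%)\n", x$value, 100 * x$value))
  invisible(x)
}

#' Similarity Index between two synaptic configurations
#'
#' The cosine of the angle between the vector of punctum fluorescence
#' values at a reference time and at a later time:
#' \deqn{SI = \frac{g_0 \cdot g_t}{\|g_0\|\,\|g_t\|}.}
#' A value of 1 means no change in puncta brightness relative to each
#' other; smaller values indicate reconfiguration of relative synaptic
#' sizes. Multiplying either vector by a positive scalar (e.g. global
#' photobleaching) leaves SI unchanged.
#'
#' @param g0,gt numeric vectors of equal length (>= 2), not all zero.
#' @return The cosine similarity, in `[-1, 1]` (in `(0, 1]` for positive
#'   data).
#' @export
similarity_index <- function(g0, gt) {
  if (length(g0) != length(gt)) stopf("vectors must have equal length")
  if (length(g0) < 2L) stopf("vectors must have length >= 2")
  n0 <- sqrt(sum(g0^2)); nt <- sqrt(sum(gt^2))
  if (n0 == 0 || nt == 0) stopf("zero vector has no direction")
  sum(g0 * gt) / (n0 * nt)
}

#' Shuffled-SI normalization floor
#'
#' The minimum attainable SI for a neuron, estimated by cyclically
#' permuting the final-time fluorescence vector against the unshuffled
#' `t = 0` vector: the average of `SI(g0, rotate(g_last, k))` over
#' `n_shuffles` distinct nonzero offsets `k` (all of them when fewer than
#' `n_shuffles` exist, a seeded uniform sample without replacement
#' otherwise).
#'
#' @param g0 fluorescence vector at time 0.
#' @param g_last fluorescence vector at the final time point.
#' @param n_shuffles number of cyclic permutations averaged (default 10).
#' @param seed optional integer seed for offset sampling.
#' @return The mean shuffled SI (<= 1).
#' @export
shuffled_si_floor <- function(g0, g_last, n_shuffles = 10L, seed = NULL) {
  n <- length(g0)
  if (length(g_last) != n) stopf("vectors must have equal length")
  if (n < 3L) stopf("need vectors of length >= 3 to permute cyclically")
  check_number(n_shuffles, "n_shuffles", min = 1, integer = TRUE)
  offsets <- if (n - 1L <= n_shuffles) seq_len(n - 1L) else
    with_seed(seed, sample(seq_len(n - 1L), n_shuffles))
  mean(vapply(offsets, function(k) {
    similarity_index(g0, c(g_last[(k + 1L):n], g_last[seq_len(k)]))
  }, numeric(1L)))
}

#' Per-neuron normalized Similarity-Index curve
#'
#' Builds the puncta-by-time fluorescence matrix of one neuron (restricted
#' to puncta tracked over the full window), computes the raw SI of each
#' time point against `t = 0`, the shuffled floor from the final time
#' point, and the normalized curve
#' \deqn{SI_{norm}(t) = \frac{SI(t) - SI_{shuffled}}{1 - SI_{shuffled}},}
#' clipped below at 0. The raw SI is always returned alongside the
#' normalized values.
#'
#' @param traces trace data frame for one neuron (schema of
#'   [simulate_trace_population()]).
#' @param n_shuffles,seed passed to [shuffled_si_floor()].
#' @return Object of class `si_curve`: data frame with columns `t_min`,
#'   `si_raw`, `si_norm`; attributes `si_shuffled` and `n_puncta`.
#' @export
normalized_si_curve <- function(traces, n_shuffles = 10L, seed = 1L) {
  m <- trace_matrix(traces, full_window_only = TRUE)
  if (nrow(m$f) < 3L)
    stopf("need at least 3 puncta tracked over the full window (got %d)",
          nrow(m$f))
  g0 <- m$f[, 1L]
  if (any(colSums(m$f^2) == 0)) stopf("fluorescence vectors must be nonzero")
  si_raw <- vapply(seq_len(ncol(m$f)),
                   function(k) similarity_index(g0, m$f[, k]), numeric(1L))
  floor <- shuffled_si_floor(g0, m$f[, ncol(m$f)], n_shuffles, seed)
  denom <- 1 - floor
  si_norm <- if (denom < 1e-12)
    ifelse(si_raw > 1 - 1e-9, 1, NA_real_)
  else pmax(0, (si_raw - floor) / denom)
  out <- data.frame(t_min = m$t, si_raw = si_raw, si_norm = si_norm)
  attr(out, "si_shuffled") <- floor
  attr(out, "n_puncta") <- nrow(m$f)
  class(out) <- c("si_curve", "data.frame")
  out
}

#' @export
print.si_curve <- function(x, ...) {
  cat(sprintf(
    "SI curve: %d time points, %d puncta, shuffle floor %.3f, endpoint SI_norm %.3f\n",
    nrow(x), attr(x, "n_puncta"), attr(x, "si_shuffled"),
    x$si_norm[nrow(x)]))
  invisible(x)
}

#' @export
plot.si_curve <- function(x, ...) {
  graphics::plot(x$t_min, x$si_norm, type = "l", ylim = c(0, 1),
                 xlab = "time (min)", ylab = "normalized SI", ...)
  graphics::lines(x$t_min, x$si_raw, lty = 2)
  graphics::legend("bottomleft", legend = c("normalized", "raw"),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}

# puncta-by-time matrix for one neuron; optionally keep only puncta whose
# status is "tracked" at every time point.
trace_matrix <- function(traces, full_window_only = TRUE) {
  stopifnot(is.data.frame(traces))
  if (length(unique(traces$neuron)) > 1L)
    stopf("expected traces for a single neuron")
  tvec <- sort(unique(traces$t_min))
  ids <- unique(traces$punctum)
  keep <- vapply(ids, function(id) {
    st <- traces$status[traces$punctum == id]
    if (full_window_only) all(st == "tracked")
    else !any(st == "rejected_split_merge")
  }, logical(1L))
  ids <- ids[keep]
  f <- matrix(NA_real_, length(ids), length(tvec),
              dimnames = list(ids, NULL))
  for (i in seq_along(ids)) {
    tr <- traces[traces$punctum == ids[i], ]
    f[i, ] <- tr$fluorescence[order(tr$t_min)]
  }
  list(f = f, t = tvec, ids = ids)
}

#' Punctum loss rate of a neuron
#'
#' Fraction of reliably tracked puncta that disappeared during the
#' session: `n_lost / (n_tracked + n_lost)`. Puncta rejected for splitting
#' or merging are excluded from both numerator and denominator.
#'
#' @param traces trace data frame for one neuron.
#' @return A fraction in `[0, 1]`.
#' @export
loss_rate <- function(traces) {
  stopifnot(is.data.frame(traces))
  ids <- unique(traces$punctum)
  cls <- vapply(ids, function(id) {
    st <- traces$status[traces$punctum == id]
    if (any(st == "rejected_split_merge")) "rejected"
    else if (any(st == "lost")) "lost" else "tracked"
  }, character(1L))
  eligible <- sum(cls != "rejected")
  if (eligible == 0L) stopf("no eligible (tracked or lost) puncta")
  sum(cls == "lost") / eligible
}

#' Compare SI-decay curves between two groups
#'
#' For each neuron's curve the final three normalized SI values are
#' averaged; the per-neuron endpoint values are pooled by group and
#' compared with a two-sample two-sided Kolmogorov-Smirnov test.
#'
#' @param group_a,group_b lists of `si_curve` objects (>= 2 per group, each
#'   with >= 3 time points).
#' @param label_a,label_b group labels for printing.
#' @return Object of class `constancy_test`: list with `statistic`,
#'   `p.value`, per-group endpoint `values`, means and SDs.
#' @export
compare_si_curves <- function(group_a, group_b, label_a = "A",
                              label_b = "B") {
  endpoint <- function(cu) {
    if (nrow(cu) < 3L) stopf("each SI curve needs >= 3 time points")
    mean(utils::tail(cu$si_norm, 3L))
  }
  if (length(group_a) < 2L || length(group_b) < 2L)
    stopf("need at least 2 curves per group")
  va <- vapply(group_a, endpoint, numeric(1L))
  vb <- vapply(group_b, endpoint, numeric(1L))
  compare_distributions(va, vb, label_a, label_b,
                        what = "SI endpoint (mean of final 3 values)")
}

#' Two-sample Kolmogorov-Smirnov comparison with group summaries
#'
#' The generic distribution comparison used throughout: a two-sided
#' two-sample KS test (exact p-values where `stats::ks.test` supports
#' them) plus per-group mean and SD.
#'
#' @param values_a,values_b numeric samples (>= 2 each).
#' @param label_a,label_b group labels.
#' @param what description of the compared quantity.
#' @return Object of class `constancy_test`.
#' @export
compare_distributions <- function(values_a, values_b, label_a = "A",
                                  label_b = "B", what = "value") {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stopf("need at least 2 values per group")
  ks <- suppressWarnings(stats::ks.test(values_a, values_b,
                                        alternative = "two.sided"))
  structure(list(statistic = unname(ks$statistic), p.value = ks$p.value,
                 what = what,
                 labels = c(label_a, label_b),
                 values = stats::setNames(list(values_a, values_b),
                                          c(label_a, label_b)),
                 means = c(mean(values_a), mean(values_b)),
                 sds = c(stats::sd(values_a), stats::sd(values_b)),
                 n = c(length(values_a), length(values_b))),
            class = "constancy_test")
}

#' @export
print.constancy_test <- function(x, ...) {
  cat(sprintf("Two-sample KS comparison of %s\n", x$what))
  for (i in 1:2)
    cat(sprintf("  %-12s mean %.4f, SD %.4f (n = %d)\n", x$labels[i],
                x$means[i], x$sds[i], x$n[i]))
  cat(sprintf("  D = %.4f, p = %.4g%s\n", x$statistic, x$p.value,
              if (x$p.value > 0.05) " (not significant at 0.05)" else ""))
  invisible(x)
}
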