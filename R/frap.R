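#' Two-pool FRAP recovery model
#'
#' Normalized fluorescence recovery after photobleaching as a weighted sum
#' of two exponentials,
#' \deqn{F(t) = F_{bl} + (1 - F_{bl})\left[P_f (1 - e^{-t/\tau_f}) +
#'   (1 - P_f)(1 - e^{-t/\tau_s})\right],}
#' where `F_bl` is the normalized fluorescence immediately after
#' photobleaching, `P_f` the fractional size of the fast pool, and `tau_f`,
#' `tau_s` the fast- and slow-pool recovery time constants (minutes). The
#' model starts at `F_bl` at `t = 0` and recovers toward the pre-bleach
#' level 1.
#'
#' @param t time since photobleaching, minutes.
#' @param F_bl normalized post-bleach fluorescence, in `[0, 1)`.
#' @param P_f fast-pool fraction, in `[0, 1]`.
#' @param tau_f,tau_s fast and slow time constants, minutes,
#'   `0 < tau_f <= tau_s`.
#' @return Normalized fluorescence at `t`.
#' @export
frap_model <- function(t, F_bl, P_f, tau_f, tau_s) {
  F_bl + (1 - F_bl) *
    (P_f * (1 - exp(-t / tau_f)) + (1 - P_f) * (1 - exp(-t / tau_s)))
}

#' Container for one FRAP experiment
#'
#' Holds the pre-bleach baseline and post-bleach series of a bleached
#' punctum together with the series of non-bleached reference puncta used
#' for the photobleaching correction.
#'
#' @param F0 pre-bleach fluorescence of the bleached punctum, AU (> 0).
#' @param t post-bleach sample times, minutes, strictly increasing.
#' @param F_t bleached-punctum fluorescence at `t`, AU.
#' @param F_nb matrix of reference series (reference puncta in rows,
#'   time in columns), AU.
#' @param F_nb0 pre-bleach values of the reference puncta, AU (> 0);
#'   defaults to their first column.
#' @return An object of class `frap_record`.
#' @export
frap_record <- function(F0, t, F_t, F_nb, F_nb0 = NULL) {
  check_number(F0, "F0", min = 0, strict_min = TRUE)
  if (any(diff(t) <= 0)) stopf("times must be strictly increasing")
  if (length(F_t) != length(t)) stopf("F_t and t lengths differ")
  F_nb <- as.matrix(F_nb)
  if (ncol(F_nb) != length(t))
    stopf("reference matrix must have one column per time point")
  if (is.null(F_nb0)) F_nb0 <- F_nb[, 1L]
  if (any(F_nb0 <= 0)) stopf("reference pre-bleach values must be positive")
  structure(list(F0 = F0, t = as.numeric(t), F_t = as.numeric(F_t),
                 F_nb = F_nb, F_nb0 = as.numeric(F_nb0)),
            class = "frap_record")
}

#' @export
print.frap_record <- function(x, ...) {
  cat(sprintf(
    "FRAP record: %d post-bleach time points (%g-%g min), %d reference puncta\n",
    length(x$t), min(x$t), max(x$t), nrow(x$F_nb)))
  invisible(x)
}

#' Normalize a FRAP series and correct for ongoing photobleaching
#'
#' Computes the normalized, bleaching-corrected recovery curve
#' \deqn{F_{norm}(t) = \frac{F_t}{F_0} \cdot \frac{F_{nb0}}{F_{nbt}},}
#' where `F_nbt` is the across-reference average fluorescence at time `t`
#' and `F_nb0` the same average before bleaching. Any per-time-point factor
#' shared by the bleached and reference series (acquisition photobleaching)
#' cancels exactly.
#'
#' @param record a [frap_record()].
#' @return A `recovery_curve`: data frame with columns `t` (minutes) and
#'   `value` (normalized fluorescence, 1 = pre-bleach level).
#' @export
bleach_correct <- function(record) {
  stopifnot(inherits(record, "frap_record"))
  ref_t <- colMeans(record$F_nb)
  ref_0 <- mean(record$F_nb0)
  if (ref_0 <= 0 || any(ref_t <= 0))
    stopf("bleach correction failed: non-positive reference average")
  if (record$F0 <= 0)
    stopf("bleach correction failed: non-positive pre-bleach baseline")
  recovery_curve(record$t, (record$F_t / record$F0) * (ref_0 / ref_t))
}

#' @rdname bleach_correct
#' @param t,value time (minutes) and normalized fluorescence vectors.
#' @param sem,n optional pointwise SEM and sample size (for averaged
#'   curves).
#' @export
recovery_curve <- function(t, value, sem = NULL, n = NULL) {
  if (length(t) != length(value)) stopf("t and value lengths differ")
  df <- data.frame(t = as.numeric(t), value = as.numeric(value))
  if (!is.null(sem)) df$sem <- sem
  if (!is.null(n)) df$n <- n
  class(df) <- c("recovery_curve", "data.frame")
  df
}

#' Fit the two-pool FRAP model to a recovery curve
#'
#' Bounded nonlinear least squares for the [frap_model()] parameters.
#' Internally the model is parameterized as `(F_bl, P_f, log tau_f,
#' log(tau_s/tau_f))` with `tau_s/tau_f >= 1`, which enforces the pool
#' ordering and removes label switching; optimization uses `L-BFGS-B` with
#' up to `n_starts` starting points (the default start sets `tau_f` at the
#' half-recovery time, `tau_s = 10 tau_f`, `P_f = 0.5` and `F_bl` at the
#' first post-bleach value). A constant (degenerate) curve is flagged and
#' returned with `P_f = NA`; fits in which `tau_s < 2 tau_f` are flagged
#' `"poor_separation"` because the two pools are then barely identifiable.
#'
#' @param object a `recovery_curve`, a [frap_record()] (corrected first),
#'   or a data frame with columns `t` and `value`.
#' @param n_starts number of optimization starts.
#' @param ... passed to methods.
#' @return An object of class `frap_fit` with components `coefficients`
#'   (`F_bl`, `P_f`, `tau_f`, `tau_s`), `fitted.values`, `residuals`,
#'   `rss`, `sigma`, `converged`, `flags`, `data`.
#' @examples
#' tt <- c(seq(0, 30, 5), seq(40, 180, 10))
#' curve <- recovery_curve(tt, frap_model(tt, 0.1, 0.3, 18, 432))
#' fit <- frap_fit(curve)
#' coef(fit)
#' @export
frap_fit <- function(object, ...) UseMethod("frap_fit")

#' @rdname frap_fit
#' @export
frap_fit.frap_record <- function(object, ...) frap_fit(bleach_correct(object), ...)

#' @rdname frap_fit
#' @export
frap_fit.data.frame <- function(object, n_starts = 3L, ...) {
  if (!all(c("t", "value") %in% names(object)))
    stopf("need columns 't' and 'value'")
  t <- object$t; y <- object$value
  if (length(t) < 6L) stopf("need at least 6 time points to fit")
  if (any(diff(t) <= 0)) stopf("times must be strictly increasing")

  # degenerate: nothing recovers / nothing was bleached
  if (stats::sd(y) < 1e-10) {
    return(new_frap_fit(
      coef = c(F_bl = mean(y), P_f = NA_real_, tau_f = NA_real_,
               tau_s = NA_real_),
      fitted = rep(mean(y), length(y)), data = object,
      converged = FALSE, flags = "degenerate"))
  }

  f_bl0 <- min(max(y[1L], 0), 0.999)
  f_end <- mean(utils::tail(y, 3L))
  half <- f_bl0 + (f_end - f_bl0) / 2
  above <- which(y >= half & t > 0)
  tau0 <- if (length(above)) max(t[above[1L]], min(t[t > 0])) else
    stats::median(t[t > 0])

  obj_fun <- function(par) {
    mu <- frap_model(t, par[1L], par[2L], exp(par[3L]),
                     exp(par[3L] + par[4L]))
    sum((y - mu)^2)
  }
  lower <- c(0, 0, log(1e-3), 0)
  upper <- c(1, 1, log(1e7), log(1e7))
  starts <- list(c(f_bl0, 0.5, log(tau0), log(10)),
                 c(f_bl0, 0.3, log(tau0 / 3), log(30)),
                 c(f_bl0, 0.7, log(tau0 * 3), log(3)))
  best <- NULL
  for (s in utils::head(starts, max(1L, n_starts))) {
    opt <- tryCatch(
      stats::optim(s, obj_fun, method = "L-BFGS-B", lower = lower,
                   upper = upper,
                   control = list(factr = 1e2, pgtol = 1e-12,
                                  maxit = 2000L)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    return(new_frap_fit(
      coef = c(F_bl = f_bl0, P_f = NA_real_, tau_f = NA_real_,
               tau_s = NA_real_),
      fitted = rep(NA_real_, length(y)), data = object,
      converged = FALSE, flags = "non_convergence"))

  cf <- c(F_bl = best$par[1L], P_f = best$par[2L],
          tau_f = exp(best$par[3L]),
          tau_s = exp(best$par[3L] + best$par[4L]))
  flags <- character()
  if (best$convergence != 0L) flags <- c(flags, "non_convergence")
  if (is.finite(cf["tau_s"]) && cf["tau_s"] < 2 * cf["tau_f"])
    flags <- c(flags, "poor_separation")
  new_frap_fit(coef = cf,
               fitted = frap_model(t, cf[1L], cf[2L], cf[3L], cf[4L]),
               data = object, converged = best$convergence == 0L,
               flags = flags)
}

#' @rdname frap_fit
#' @export
frap_fit.default <- frap_fit.data.frame

new_frap_fit <- function(coef, fitted, data, converged, flags) {
  res <- data$value - fitted
  n <- length(res)
  structure(list(coefficients = coef, fitted.values = fitted,
                 residuals = res, rss = sum(res^2, na.rm = TRUE),
                 sigma = sqrt(sum(res^2, na.rm = TRUE) / max(1L, n - 4L)),
                 converged = converged, flags = flags, data = data),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, digits = 4, ...) {
  cat("Two-pool FRAP recovery fit\n")
  print(round(x$coefficients, digits))
  if (length(x$flags)) cat("Flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.frap_fit <- function(object, ...) {
  cf <- object$coefficients
  cat("Two-pool FRAP recovery fit\n")
  cat(sprintf("  post-bleach level F_bl : %.4f\n", cf["F_bl"]))
  cat(sprintf("  fast-pool fraction P_f : %.4f\n", cf["P_f"]))
  cat(sprintf("  tau_fast  : %.2f min\n", cf["tau_f"]))
  cat(sprintf("  tau_slow  : %.2f min (%.2f h)\n", cf["tau_s"],
              cf["tau_s"] / 60))
  cat(sprintf("  residual SD: %.4g on %d points; converged: %s\n",
              object$sigma, length(object$residuals), object$converged))
  if ("poor_separation" %in% object$flags)
    cat("  note: tau_s < 2 tau_f - pools poorly separated,",
        "pool fractions are unreliable\n")
  if ("degenerate" %in% object$flags)
    cat("  note: constant curve - nothing was bleached, P_f undetermined\n")
  invisible(object)
}

#' @export
coef.frap_fit <- function(object, ...) object$coefficients

#' @export
fitted.frap_fit <- function(object, ...) object$fitted.values

#' @export
residuals.frap_fit <- function(object, ...) object$residuals

#' @export
deviance.frap_fit <- function(object, ...) object$rss

#' @export
predict.frap_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$t else
    if (is.data.frame(newdata)) newdata$t else as.numeric(newdata)
  cf <- object$coefficients
  frap_model(t, cf["F_bl"], cf["P_f"], cf["tau_f"], cf["tau_s"])
}

#' @export
plot.frap_fit <- function(x, ...) {
  graphics::plot(x$data$t, x$data$value, xlab = "time since bleach (min)",
                 ylab = "normalized fluorescence",
                 ylim = c(0, max(1, x$data$value)), ...)
  tt <- seq(min(x$data$t), max(x$data$t), length.out = 200L)
  graphics::lines(tt, predict(x, tt), lwd = 2)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}

#' @export
simulate.frap_fit <- function(object, nsim = 1, seed = NULL, noise_sd = 0.02,
                              ...) {
  cf <- as.list(object$coefficients)
  with_seed(seed, {
    out <- lapply(seq_len(nsim), function(i) {
      mu <- predict(object)
      recovery_curve(object$data$t,
                     mu + stats::rnorm(length(mu), 0, noise_sd))
    })
    if (nsim == 1L) out[[1L]] else out
  })
}

#' Fractional recovery at the end of observation
#'
#' The average of the final three values of a normalized recovery curve:
#' the fraction of pre-bleach fluorescence regained by the end of the
#' recording.
#'
#' @param curve a `recovery_curve` (or data frame with a `value` column).
#' @return A single fraction.
#' @export
fractional_recovery <- function(curve) {
  v <- curve$value
  if (length(v) < 3L) stopf("need at least 3 time points")
  mean(utils::tail(v, 3L))
}

#' Average recovery curves point-wise
#'
#' Point-wise mean and SEM over curves sharing one time base (the averaged
#' population recovery curve shown with error bars).
#'
#' @param curves list of `recovery_curve`s with identical `t`.
#' @return A `recovery_curve` with columns `t`, `value`, `sem`, `n`.
#' @export
average_frap_curves <- function(curves) {
  if (!length(curves)) stopf("no curves supplied")
  t0 <- curves[[1L]]$t
  for (cu in curves)
    if (!isTRUE(all.equal(cu$t, t0)))
      stopf("curves must share an identical time base")
  vals <- sapply(curves, function(cu) cu$value)
  vals <- matrix(vals, nrow = length(t0))
  n <- ncol(vals)
  m <- rowMeans(vals)
  sem <- if (n > 1L) apply(vals, 1L, stats::sd) / sqrt(n) else rep(0, length(t0))
  recovery_curve(t0, m, sem = sem, n = rep(n, length(t0)))
}

#' Printed two-pool parameter sets for the experimental genotypes
#'
#' Generating truths for simulation-based validation: the knockout
#' parameter set (tau_f = 18 min, tau_s = 7.2 h, P_f = 0.30) and the
#' wild-type set (tau_f = 20 min, tau_s = 4.7 h, P_f = 0.24), with a
#' conventional post-bleach residual `F_bl = 0.1`.
#'
#' @param name `"ko"` or `"wt"`.
#' @return Named list with `F_bl`, `P_f`, `tau_f`, `tau_s` (minutes).
#' @export
frap_presets <- function(name) {
  switch(name,
    ko = list(F_bl = 0.1, P_f = 0.30, tau_f = 18, tau_s = 7.2 * 60),
    wt = list(F_bl = 0.1, P_f = 0.24, tau_f = 20, tau_s = 4.7 * 60),
    stopf("unknown FRAP preset '%s' (use 'ko' or 'wt')", name))
}

#' Post-bleach sampling schedule of a standard FRAP session
#'
#' Three hours of recovery sampled at 5-minute intervals for the first half
#' hour and 10-minute intervals thereafter.
#'
#' @return Numeric vector of minutes starting at 0.
#' @export
frap_schedule <- function() c(seq(0, 30, by = 5), seq(40, 180, by = 10))
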