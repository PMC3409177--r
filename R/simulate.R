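#' Parameters for the synthetic punctum-trajectory generator
#'
#' Bundles every knob of the stochastic model used to emulate long-term
#' time-lapse recordings of fluorescently tagged synaptic puncta. Each
#' punctum carries a slowly drifting setpoint (a random walk in log
#' intensity, step SD `reconfiguration_sd`) around which the observed
#' intensity fluctuates with discrete mean-reverting multiplicative noise
#' (per-step log SD `fluctuation_sd`, pull `reversion_rate` per minute).
#' All puncta of a neuron share a global exponential photobleaching factor
#' `exp(-bleach_rate * t)`. Loss events follow an exponential waiting time
#' scaled so that the probability of loss within the experiment equals
#' `loss_prob`.
#'
#' @param n_puncta number of puncta per neuron (>= 2).
#' @param n_timepoints number of frames (>= 2).
#' @param dt frame interval, minutes (> 0).
#' @param mean_intensity typical punctum intensity, arbitrary fluorescence
#'   units (AU).
#' @param size_sd between-punctum SD of log setpoints (heterogeneity of
#'   punctum sizes; drives the shuffled-SI floor below 1).
#' @param fluctuation_sd per-step multiplicative log-scale SD of the
#'   observed intensity around its setpoint.
#' @param reversion_rate pull toward the setpoint, per minute; the per-step
#'   pull is `min(1, reversion_rate * dt)`.
#' @param reconfiguration_sd per-step log-scale SD of the setpoint random
#'   walk (drives Similarity-Index decay).
#' @param bleach_rate global photobleaching rate, per minute.
#' @param loss_prob probability that a punctum is lost during the
#'   experiment, in `[0, 1]`.
#' @param measurement_noise_sd additive Gaussian measurement noise, AU.
#' @param seed integer seed; identical parameters and seed give
#'   bit-identical output.
#'
#' @return An object of class `sim_params` (a validated named list).
#' @seealso [simulate_trace_population()], [genotype_presets()]
#' @export
sim_params <- function(n_puncta = 75, n_timepoints = 73, dt = 10,
                       mean_intensity = 1000, size_sd = 0.5,
                       fluctuation_sd = 0.025, reversion_rate = 0.02,
                       reconfiguration_sd = 0.03, bleach_rate = 1e-4,
                       loss_prob = 0.06, measurement_noise_sd = 10,
                       seed = 1L) {
  check_number(n_puncta, "n_puncta", min = 2, integer = TRUE)
  check_number(n_timepoints, "n_timepoints", min = 2, integer = TRUE)
  check_number(dt, "dt", min = 0, strict_min = TRUE)
  check_number(mean_intensity, "mean_intensity", min = 0, strict_min = TRUE)
  check_number(size_sd, "size_sd", min = 0)
  check_number(fluctuation_sd, "fluctuation_sd", min = 0)
  check_number(reversion_rate, "reversion_rate", min = 0)
  check_number(reconfiguration_sd, "reconfiguration_sd", min = 0)
  check_number(bleach_rate, "bleach_rate", min = 0)
  check_number(loss_prob, "loss_prob", min = 0, max = 1)
  check_number(measurement_noise_sd, "measurement_noise_sd", min = 0)
  check_number(seed, "seed", integer = TRUE)
  structure(list(
    n_puncta = as.integer(n_puncta), n_timepoints = as.integer(n_timepoints),
    dt = dt, mean_intensity = mean_intensity, size_sd = size_sd,
    fluctuation_sd = fluctuation_sd, reversion_rate = reversion_rate,
    reconfiguration_sd = reconfiguration_sd, bleach_rate = bleach_rate,
    loss_prob = loss_prob, measurement_noise_sd = measurement_noise_sd,
    seed = as.integer(seed)), class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Synthetic trajectory generator parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-20s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Genotype / condition presets for the generator
#'
#' Named parameter bundles encoding the qualitative contrasts between the
#' experimental groups: knockout (`"ko"`) populations get larger intensity
#' fluctuations, faster setpoint reconfiguration and higher punctum loss
#' than wild type (`"wt"`), while under activity blockade
#' (`"wt_blocked"`, `"ko_blocked"`) the fluctuation ordering reverses
#' (knockout smaller than wild type). Presets differ only in
#' `fluctuation_sd`, `reconfiguration_sd` and `loss_prob`; absolute
#' magnitudes are calibration choices documented in the methods vignette —
#' the presets encode orderings, not mechanistic biology.
#'
#' @param name one of `"wt"`, `"ko"`, `"wt_blocked"`, `"ko_blocked"`.
#' @param seed seed stored in the returned bundle.
#' @return A [sim_params()] object.
#' @export
genotype_presets <- function(name, seed = 1L) {
  if (!is.character(name) || length(name) != 1L)
    stopf("preset name must be a single string")
  knobs <- switch(name,
    wt         = list(fluctuation_sd = 0.025, reconfiguration_sd = 0.030,
                      loss_prob = 0.062),
    ko         = list(fluctuation_sd = 0.028, reconfiguration_sd = 0.035,
                      loss_prob = 0.091),
    wt_blocked = list(fluctuation_sd = 0.022, reconfiguration_sd = 0.024,
                      loss_prob = 0.050),
    ko_blocked = list(fluctuation_sd = 0.019, reconfiguration_sd = 0.024,
                      loss_prob = 0.050),
    stopf("unknown preset '%s' (use wt, ko, wt_blocked or ko_blocked)", name)
  )
  do.call(sim_params, c(knobs, list(seed = seed)))
}

#' Simulate a population of punctum fluorescence trajectories
#'
#' Generates per-punctum intensity traces for one or more neurons under the
#' stochastic model of [sim_params()], together with the ground truth
#' needed to validate downstream estimators. All randomness is drawn from a
#' single generator seeded with `params$seed`, so identical inputs give
#' bit-identical output.
#'
#' @param params a [sim_params()] object.
#' @param genotype_label text label stored in the `experiment` column.
#' @param n_neurons number of neurons (fields of view) to simulate.
#' @return A list of class `trace_population` with elements
#'   \describe{
#'     \item{traces}{data frame with columns `experiment`, `neuron`,
#'       `punctum`, `t_min`, `fluorescence`, `status` (one row per punctum
#'       per time point).}
#'     \item{truth}{list with per-neuron setpoint matrices (AU, puncta x
#'       time, photobleaching not applied), per-neuron loss times (minutes,
#'       `NA` if never lost) and the generating `params`.}
#'   }
#' @export
simulate_trace_population <- function(params, genotype_label = "wt",
                                      n_neurons = 1L) {
  if (!inherits(params, "sim_params"))
    stopf("'params' must be created by sim_params()")
  check_number(n_neurons, "n_neurons", min = 1, integer = TRUE)
  n <- params$n_puncta
  nt <- params$n_timepoints
  tvec <- (seq_len(nt) - 1L) * params$dt
  total_t <- tvec[nt]
  pull <- min(1, params$reversion_rate * params$dt)
  bleach <- exp(-params$bleach_rate * tvec)

  with_seed(params$seed, {
    traces <- vector("list", n_neurons)
    setpoints <- vector("list", n_neurons)
    loss_times <- vector("list", n_neurons)
    for (j in seq_len(n_neurons)) {
      log_s <- matrix(0, n, nt)
      log_s[, 1L] <- log(params$mean_intensity) + rnorm(n, 0, params$size_sd)
      if (nt > 1L) for (k in 2:nt)
        log_s[, k] <- log_s[, k - 1L] +
          rnorm(n, 0, params$reconfiguration_sd)
      log_f <- matrix(0, n, nt)
      log_f[, 1L] <- log_s[, 1L]
      if (nt > 1L) for (k in 2:nt)
        log_f[, k] <- log_f[, k - 1L] +
          pull * (log_s[, k] - log_f[, k - 1L]) +
          rnorm(n, 0, params$fluctuation_sd)

      # exponential waiting time; rate chosen so P(loss <= total_t) = loss_prob
      if (params$loss_prob <= 0) {
        loss_t <- rep(Inf, n)
      } else if (params$loss_prob >= 1) {
        loss_t <- runif(n, 0, total_t)
      } else {
        rate <- -log1p(-params$loss_prob) / total_t
        loss_t <- stats::rexp(n, rate)
      }

      f <- exp(log_f) * rep(bleach, each = n)
      lost_mask <- outer(loss_t, tvec, function(l, t) t >= l)
      f[lost_mask] <- 0
      obs <- f + matrix(rnorm(n * nt, 0, params$measurement_noise_sd), n, nt)
      obs <- pmax(obs, 0)

      status <- matrix("tracked", n, nt)
      status[lost_mask] <- "lost"
      traces[[j]] <- data.frame(
        experiment = genotype_label,
        neuron = sprintf("%s_n%02d", genotype_label, j),
        punctum = rep(sprintf("p%04d", seq_len(n)), times = nt),
        t_min = rep(tvec, each = n),
        fluorescence = as.vector(obs),
        status = as.vector(status),
        stringsAsFactors = FALSE)
      setpoints[[j]] <- exp(log_s)
      loss_times[[j]] <- ifelse(is.finite(loss_t) & loss_t <= total_t,
                                loss_t, NA_real_)
    }
    traces <- do.call(rbind, traces)
    traces <- traces[order(traces$neuron, traces$punctum, traces$t_min), ]
    rownames(traces) <- NULL
    structure(list(traces = traces,
                   truth = list(setpoints = setpoints,
                                loss_times = loss_times,
                                params = params)),
              class = "trace_population")
  })
}

#' @export
print.trace_population <- function(x, ...) {
  nn <- length(unique(x$traces$neuron))
  np <- length(unique(paste(x$traces$neuron, x$traces$punctum)))
  cat(sprintf(
    "Synthetic trace population: %d neuron(s), %d puncta, %d time points\n",
    nn, np, length(unique(x$traces$t_min))))
  invisible(x)
}

#' Simulate a FRAP experiment from known recovery parameters
#'
#' Forward model for fluorescence recovery after photobleaching: the
#' bleached punctum follows the two-pool recovery model
#' ([frap_model()]) evaluated on `schedule`, multiplied by a global
#' `exp(-bleach_rate * t)` acquisition-photobleaching factor, plus additive
#' Gaussian noise; reference (non-bleached) puncta are constant baselines
#' under the same bleaching factor plus noise.
#'
#' @param true_fit list or [frap_fit] coefficients with elements `F_bl`,
#'   `P_f`, `tau_f`, `tau_s` (see [frap_model()]).
#' @param schedule post-bleach sample times in minutes, strictly
#'   increasing, starting at 0.
#' @param noise_sd additive noise SD on the normalized scale (>= 0).
#' @param bleach_rate acquisition photobleaching rate, per minute.
#' @param n_reference number of non-bleached reference puncta (>= 10, the
#'   number conventionally used for the correction).
#' @param baseline pre-bleach fluorescence of the bleached punctum, AU.
#' @param seed integer seed.
#' @return A [frap_record()] object.
#' @export
simulate_frap_experiment <- function(true_fit, schedule, noise_sd = 0.02,
                                     bleach_rate = 0, n_reference = 10L,
                                     baseline = 1000, seed = 1L) {
  p <- as.list(true_fit)
  for (nm in c("F_bl", "P_f", "tau_f", "tau_s"))
    if (is.null(p[[nm]])) stopf("true_fit is missing '%s'", nm)
  if (length(schedule) < 1L) stopf("schedule must be non-empty")
  if (schedule[1L] != 0) stopf("schedule must start at 0")
  if (any(diff(schedule) <= 0)) stopf("schedule must be strictly increasing")
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(bleach_rate, "bleach_rate", min = 0)
  check_number(n_reference, "n_reference", min = 10, integer = TRUE)

  model <- frap_model(schedule, p$F_bl, p$P_f, p$tau_f, p$tau_s)
  decay <- exp(-bleach_rate * schedule)
  with_seed(seed, {
    f_t <- baseline * model * decay +
      rnorm(length(schedule), 0, noise_sd * baseline)
    ref_baselines <- baseline * exp(rnorm(n_reference, 0, 0.3))
    f_nb <- outer(ref_baselines, decay) +
      matrix(rnorm(n_reference * length(schedule), 0, noise_sd * baseline),
             n_reference)
    frap_record(F0 = baseline, t = schedule, F_t = f_t, F_nb = f_nb,
                F_nb0 = ref_baselines)
  })
}

#' Render a synthetic time-lapse image stack of fluorescent puncta
#'
#' Draws each punctum as an isotropic 2-D Gaussian spot whose integrated
#' intensity equals its trace value at that frame, on a noisy constant
#' background, with optional uniform per-frame drift. Ground-truth spot
#' centers are recorded per frame so tracking can be validated.
#'
#' @param traces trace data frame for a single neuron (schema of
#'   [simulate_trace_population()]).
#' @param dim image height and width in pixels, length-2 integer.
#' @param psf_sd Gaussian spot SD in pixels.
#' @param drift_per_frame length-2 numeric, pixels of (x, y) translation
#'   per frame.
#' @param background constant background level, AU.
#' @param noise_sd background Gaussian noise SD, AU.
#' @param min_separation minimum initial center-to-center distance enforced
#'   when placing puncta; a denser request warns and proceeds.
#' @param t_min frame times; defaults to the times in `traces` (required
#'   when `traces` has no rows).
#' @param seed integer seed for placement and noise.
#' @return An object of class `image_stack`: list with `frames`
#'   (height x width x time array, AU, non-negative), `positions`
#'   (puncta x 2 x time array of (x, y) centers, pixels), `t_min`,
#'   `psf_sd`, `background`, `punctum_ids`.
#' @export
render_image_stack <- function(traces, dim = c(64L, 64L), psf_sd = 1.2,
                               drift_per_frame = c(0, 0), background = 50,
                               noise_sd = 5, min_separation = NULL,
                               t_min = NULL, seed = 1L) {
  stopifnot(is.data.frame(traces), length(dim) == 2L)
  check_number(psf_sd, "psf_sd", min = 0, strict_min = TRUE)
  check_number(background, "background", min = 0)
  check_number(noise_sd, "noise_sd", min = 0)
  h <- as.integer(dim[1L]); w <- as.integer(dim[2L])
  tvec <- if (is.null(t_min)) sort(unique(traces$t_min)) else t_min
  if (!length(tvec)) stopf("no frame times: supply traces rows or t_min")
  nt <- length(tvec)
  ids <- unique(traces$punctum)
  n <- length(ids)
  if (is.null(min_separation)) min_separation <- 4 * psf_sd

  intens <- matrix(0, n, nt, dimnames = list(ids, NULL))
  for (i in seq_len(n)) {
    tr <- traces[traces$punctum == ids[i], ]
    tr <- tr[order(tr$t_min), ]
    intens[i, ] <- tr$fluorescence
  }

  margin <- 4 * psf_sd
  drift_total <- abs(drift_per_frame) * (nt - 1L)
  lo <- margin + pmax(0, -drift_per_frame * (nt - 1L))
  hi <- c(w, h) - margin - pmax(0, drift_per_frame * (nt - 1L))
  if (any(hi <= lo))
    stopf("frame %dx%d too small for psf_sd=%g with requested drift",
          h, w, psf_sd)

  with_seed(seed, {
    pos0 <- if (n > 0) place_spots(n, lo, hi, min_separation)
            else matrix(0, 0, 2)
    positions <- array(NA_real_, c(n, 2L, nt))
    frames <- array(0, c(h, w, nt))
    for (k in seq_len(nt)) {
      img <- matrix(background, h, w)
      if (noise_sd > 0)
        img <- img + matrix(rnorm(h * w, 0, noise_sd), h, w)
      shift <- drift_per_frame * (k - 1L)
      for (i in seq_len(n)) {
        cx <- pos0[i, 1L] + shift[1L]
        cy <- pos0[i, 2L] + shift[2L]
        positions[i, , k] <- c(cx, cy)
        img <- add_gaussian_spot(img, cx, cy, intens[i, k], psf_sd)
      }
      frames[, , k] <- pmax(img, 0)
    }
    structure(list(frames = frames, positions = positions, t_min = tvec,
                   psf_sd = psf_sd, background = background,
                   punctum_ids = ids),
              class = "image_stack")
  })
}

# Rejection-sample n spot centers in [lo, hi] at pairwise distance >=
# min_sep; if space is too dense, warn and fall back to unconstrained
# placement for the remaining spots.
place_spots <- function(n, lo, hi, min_sep, max_tries = 200L) {
  pos <- matrix(NA_real_, n, 2L)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (k in seq_len(max_tries)) {
      cand <- c(stats::runif(1, lo[1L], hi[1L]),
                stats::runif(1, lo[2L], hi[2L]))
      if (i == 1L ||
          min(sqrt(colSums((t(pos[seq_len(i - 1L), , drop = FALSE]) -
                            cand)^2))) >= min_sep) {
        pos[i, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      warning("puncta too dense to respect min_separation; placing anyway",
              call. = FALSE)
      pos[i, ] <- c(stats::runif(1, lo[1L], hi[1L]),
                    stats::runif(1, lo[2L], hi[2L]))
    }
  }
  pos
}

# Add a Gaussian spot of integrated intensity `total` at (cx, cy) (x =
# column, y = row; pixel centers at integer coordinates).
add_gaussian_spot <- function(img, cx, cy, total, psf_sd) {
  if (total <= 0) return(img)
  half <- ceiling(5 * psf_sd)
  rows <- max(1L, floor(cy - half)):min(nrow(img), ceiling(cy + half))
  cols <- max(1L, floor(cx - half)):min(ncol(img), ceiling(cx + half))
  gy <- stats::dnorm(rows, cy, psf_sd)
  gx <- stats::dnorm(cols, cx, psf_sd)
  img[rows, cols] <- img[rows, cols] + total * outer(gy, gx)
  img
}

#' Write / read tidy trace tables
#'
#' Trace tables are plain CSV with columns `experiment`, `neuron`,
#' `punctum`, `t_min`, `fluorescence`, `status`
#' (one row per punctum per time point). `read_trace_csv()` validates the
#' schema and reports offending row numbers.
#'
#' @param traces trace data frame.
#' @param path file path.
#' @return `read_trace_csv()` returns the validated data frame.
#' @export
write_trace_csv <- function(traces, path) {
  validate_traces(traces)
  utils::write.csv(traces, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_traces(df)
  df
}

validate_traces <- function(df) {
  if (!is.data.frame(df) || nrow(df) == 0L)
    stopf("trace table is empty or not a data frame")
  missing_cols <- setdiff(trace_columns, names(df))
  if (length(missing_cols))
    stopf("trace table missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  bad <- which(!is.finite(df$t_min) | !is.finite(df$fluorescence) |
                 df$fluorescence < 0 | !(df$status %in% trace_status_levels))
  if (length(bad))
    stopf("invalid trace rows (non-finite time/fluorescence, negative
 fluorescence, or unknown status) at row(s): %s",
          paste(utils::head(bad, 10L), collapse = ", "))
  invisible(df)
}

#' Write an image stack as a multi-frame TIFF with a ground-truth sidecar
#'
#' Frames are scaled to the unit range required by the TIFF writer; the
#' scale factor, frame times and true spot centers go to a JSON sidecar
#' (`<path>.json`).
#'
#' @param stack an `image_stack` from [render_image_stack()].
#' @param path output TIFF path.
#' @return The TIFF path, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  mx <- max(stack$frames)
  frames <- lapply(seq_len(dim(stack$frames)[3L]),
                   function(k) stack$frames[, , k] / mx)
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  sidecar <- list(scale = mx, t_min = stack$t_min, psf_sd = stack$psf_sd,
                  background = stack$background,
                  punctum_ids = stack$punctum_ids,
                  positions = stack$positions)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_image_stack
#' @param path path to a TIFF written by [write_image_stack()].
#' @export
read_image_stack <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  sidecar_path <- paste0(path, ".json")
  meta <- if (file.exists(sidecar_path))
    jsonlite::read_json(sidecar_path, simplifyVector = TRUE) else list(scale = 1)
  arr <- array(0, c(dim(frames[[1L]])[1:2], length(frames)))
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    if (length(dim(f)) == 3L) f <- f[, , 1L]
    arr[, , k] <- f * meta$scale
  }
  pos <- meta$positions
  if (!is.null(pos)) pos <- array(unlist(pos), dim = c(length(meta$punctum_ids), 2L,
                                                       length(frames)))
  structure(list(frames = arr, positions = pos,
                 t_min = meta$t_min %||% (seq_along(frames) - 1),
                 psf_sd = meta$psf_sd, background = meta$background,
                 punctum_ids = meta$punctum_ids),
            class = "image_stack")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
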