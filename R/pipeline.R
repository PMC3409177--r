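#' Configuration for an end-to-end analysis run
#'
#' Bundles every tunable of the pipelines: input mode, group definitions,
#' metric parameters and the seed. In `"simulate"` mode group values are
#' generator preset names (see [genotype_presets()]) or [sim_params()]
#' objects; in `"traces"` mode they are paths to trace CSV files.
#'
#' @param mode `"simulate"` or `"traces"`.
#' @param groups named list (>= 2 entries) mapping group label to preset
#'   name / params / file path.
#' @param n_neurons neurons per group (simulate mode).
#' @param n_frap FRAP experiments per group ([run_frap_pipeline()]).
#' @param smoothing_width low-pass filter width, points.
#' @param n_shuffles cyclic permutations for the SI floor.
#' @param alpha significance threshold for reporting.
#' @param box measurement box side, pixels (tracking input).
#' @param frap_noise_sd,frap_bleach_rate noise SD (normalized units) and
#'   acquisition bleach rate (per minute) for simulated FRAP experiments.
#' @param seed master seed; all per-group / per-record seeds derive from it.
#' @param output_dir directory for CSV/JSON outputs (`NULL`: keep results
#'   in memory only).
#' @param make_figures write PNG figures into `output_dir/figures`.
#' @return Object of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "traces"),
                       groups = list(wt = "wt", ko = "ko"),
                       n_neurons = 20L, n_frap = 25L, smoothing_width = 5L,
                       n_shuffles = 10L, alpha = 0.05, box = 7L,
                       frap_noise_sd = 0.02, frap_bleach_rate = 1e-3,
                       seed = 1L, output_dir = NULL, make_figures = FALSE) {
  mode <- match.arg(mode)
  if (length(groups) < 2L || is.null(names(groups)) ||
      any(!nzchar(names(groups))))
    stopf("'groups' must be a named list with at least 2 entries")
  check_number(n_neurons, "n_neurons", min = 1, integer = TRUE)
  check_number(n_frap, "n_frap", min = 2, integer = TRUE)
  check_number(alpha, "alpha", min = 0, max = 1)
  check_number(seed, "seed", integer = TRUE)
  if (mode == "traces")
    for (g in names(groups))
      if (!is.character(groups[[g]]) || !file.exists(groups[[g]]))
        stopf("group '%s': trace file '%s' does not exist", g,
              as.character(groups[[g]]))
  structure(list(mode = mode, groups = groups,
                 n_neurons = as.integer(n_neurons),
                 n_frap = as.integer(n_frap),
                 smoothing_width = as.integer(smoothing_width),
                 n_shuffles = as.integer(n_shuffles), alpha = alpha,
                 box = as.integer(box), frap_noise_sd = frap_noise_sd,
                 frap_bleach_rate = frap_bleach_rate,
                 seed = as.integer(seed), output_dir = output_dir,
                 make_figures = isTRUE(make_figures)),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file with fields of `run_config()`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

group_seed <- function(config, gi, offset = 0L) {
  # deterministic, collision-free within a run, < 2^31
  (config$seed * 10000L + gi * 1000L + offset) %% .Machine$integer.max
}

group_traces <- function(config) {
  out <- list()
  for (gi in seq_along(config$groups)) {
    g <- names(config$groups)[gi]
    spec <- config$groups[[gi]]
    if (config$mode == "simulate") {
      params <- if (inherits(spec, "sim_params")) spec
                else genotype_presets(spec)
      params$seed <- group_seed(config, gi)
      out[[g]] <- simulate_trace_population(params, g,
                                            config$n_neurons)$traces
    } else {
      df <- read_trace_csv(spec)
      df$experiment <- g
      out[[g]] <- df
    }
  }
  out
}

#' Run the content-constancy analysis pipeline
#'
#' Full workflow on trace tables: per-punctum range over mean (after
#' low-pass smoothing), per-neuron normalized SI curves and loss rates,
#' exclusion accounting, and pairwise Kolmogorov-Smirnov comparisons of
#' range-over-mean distributions, SI endpoints and loss rates between all
#' group pairs. Deterministic given the config (including its seed).
#'
#' @param config a [run_config()].
#' @return Object of class `constancy_report`: list with `per_punctum`,
#'   `per_neuron`, `si_curves` (per-group mean +/- SEM data frame),
#'   `comparisons`, `exclusions`, `config`.
#' @export
run_constancy_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  traces_by_group <- group_traces(config)

  per_punctum <- list(); per_neuron <- list(); si_curves <- list()
  curves_by_group <- list()
  exclusions <- list()
  for (g in names(traces_by_group)) {
    tr <- traces_by_group[[g]]
    excl <- c(rejected_split_merge = 0L, lost = 0L, zero_mean = 0L,
              too_few_for_si = 0L)
    curves_by_group[[g]] <- list()
    for (nrn in unique(tr$neuron)) {
      ntr <- tr[tr$neuron == nrn, ]
      ids <- unique(ntr$punctum)
      cls <- vapply(ids, function(id) {
        st <- ntr$status[ntr$punctum == id]
        if (any(st == "rejected_split_merge")) "rejected"
        else if (any(st == "lost")) "lost" else "tracked"
      }, character(1L))
      excl["rejected_split_merge"] <- excl["rejected_split_merge"] +
        sum(cls == "rejected")
      excl["lost"] <- excl["lost"] + sum(cls == "lost")

      rom <- rep(NA_real_, sum(cls == "tracked"))
      kept <- ids[cls == "tracked"]
      for (i in seq_along(kept)) {
        f <- ntr$fluorescence[ntr$punctum == kept[i]][order(
          ntr$t_min[ntr$punctum == kept[i]])]
        if (mean(smooth_trace(f, config$smoothing_width)) <= 0) {
          excl["zero_mean"] <- excl["zero_mean"] + 1L
          next
        }
        rom[i] <- range_over_mean(f, config$smoothing_width)$value
      }
      ok <- !is.na(rom)
      if (any(ok))
        per_punctum[[length(per_punctum) + 1L]] <- data.frame(
          group = g, neuron = nrn, punctum = kept[ok],
          range_over_mean = rom[ok], stringsAsFactors = FALSE)

      lr <- loss_rate(ntr)
      si <- tryCatch(
        normalized_si_curve(ntr, config$n_shuffles, seed = config$seed),
        error = function(e) NULL)
      if (is.null(si)) {
        excl["too_few_for_si"] <- excl["too_few_for_si"] + 1L
        si_end <- NA_real_
      } else {
        curves_by_group[[g]][[length(curves_by_group[[g]]) + 1L]] <- si
        si_end <- mean(utils::tail(si$si_norm, 3L))
        si_curves[[length(si_curves) + 1L]] <- data.frame(
          group = g, neuron = nrn, t_min = si$t_min, si_raw = si$si_raw,
          si_norm = si$si_norm, stringsAsFactors = FALSE)
      }
      per_neuron[[length(per_neuron) + 1L]] <- data.frame(
        group = g, neuron = nrn, n_puncta = length(ids),
        n_tracked_full = sum(cls == "tracked"), loss_rate = lr,
        si_endpoint = si_end, stringsAsFactors = FALSE)
    }
    exclusions[[g]] <- excl
  }
  per_punctum <- do.call(rbind, per_punctum)
  per_neuron <- do.call(rbind, per_neuron)
  si_curves <- if (length(si_curves)) do.call(rbind, si_curves) else NULL

  gnames <- names(traces_by_group)
  comparisons <- list()
  for (i in seq_along(gnames)) for (j in seq_along(gnames)) {
    if (j <= i) next
    a <- gnames[i]; b <- gnames[j]
    key <- paste(a, "vs", b)
    comparisons[[key]] <- list(
      range_over_mean = compare_distributions(
        per_punctum$range_over_mean[per_punctum$group == a],
        per_punctum$range_over_mean[per_punctum$group == b],
        a, b, what = "range over mean"),
      si_endpoint = if (length(curves_by_group[[a]]) >= 2L &&
                        length(curves_by_group[[b]]) >= 2L)
        compare_si_curves(curves_by_group[[a]], curves_by_group[[b]], a, b),
      loss_rate = compare_distributions(
        per_neuron$loss_rate[per_neuron$group == a],
        per_neuron$loss_rate[per_neuron$group == b],
        a, b, what = "loss rate"))
  }

  report <- structure(list(per_punctum = per_punctum,
                           per_neuron = per_neuron, si_curves = si_curves,
                           comparisons = comparisons,
                           exclusions = exclusions, config = config),
                      class = "constancy_report")
  if (!is.null(config$output_dir)) write_constancy_report(report)
  report
}

#' @export
print.constancy_report <- function(x, ...) {
  cat("Content-constancy report\n")
  for (g in unique(x$per_neuron$group)) {
    rom <- x$per_punctum$range_over_mean[x$per_punctum$group == g]
    lr <- x$per_neuron$loss_rate[x$per_neuron$group == g]
    se <- x$per_neuron$si_endpoint[x$per_neuron$group == g]
    cat(sprintf(
      "  %-10s %4d neurons, %5d puncta | range over mean %.1f+/-%.1f%% | loss rate %.1f+/-%.1f%% | SI endpoint %.2f\n",
      g, length(lr), length(rom), 100 * mean(rom), 100 * stats::sd(rom),
      100 * mean(lr), 100 * stats::sd(lr), mean(se, na.rm = TRUE)))
  }
  for (key in names(x$comparisons)) {
    cmp <- x$comparisons[[key]]
    cat(sprintf("  %s:\n", key))
    for (nm in names(cmp))
      if (!is.null(cmp[[nm]]))
        cat(sprintf("    %-16s D = %.3f, p = %.3g\n", nm,
                    cmp[[nm]]$statistic, cmp[[nm]]$p.value))
  }
  invisible(x)
}

write_constancy_report <- function(report) {
  dir.create(report$config$output_dir, recursive = TRUE,
             showWarnings = FALSE)
  out <- function(f) file.path(report$config$output_dir, f)
  utils::write.csv(report$per_punctum, out("per_punctum.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(report$per_neuron, out("per_neuron.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(report$si_curves))
    utils::write.csv(report$si_curves, out("si_curves.csv"),
                     row.names = FALSE, quote = FALSE)
  cmp <- lapply(report$comparisons, function(pair)
    lapply(Filter(Negate(is.null), pair), function(ct)
      list(statistic = ct$statistic, p = ct$p.value, means = ct$means,
           sds = ct$sds, n = ct$n)))
  jsonlite::write_json(cmp, out("comparisons.json"), auto_unbox = TRUE,
                       digits = NA)
  write_provenance(report$config)
  if (report$config$make_figures) write_constancy_figures(report)
  invisible(report)
}

write_provenance <- function(config) {
  prov <- unclass(config)
  prov$groups <- lapply(prov$groups, function(g)
    if (inherits(g, "sim_params")) unclass(g) else g)
  prov$package_version <- as.character(utils::packageVersion("puncta"))
  prov$r_version <- as.character(getRversion())
  jsonlite::write_json(prov, file.path(config$output_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

write_constancy_figures <- function(report) {
  figdir <- file.path(report$config$output_dir, "figures")
  dir.create(figdir, recursive = TRUE, showWarnings = FALSE)
  grDevices::png(file.path(figdir, "range_over_mean.png"), 600, 450)
  groups <- unique(report$per_punctum$group)
  vals <- split(report$per_punctum$range_over_mean,
                report$per_punctum$group)
  graphics::boxplot(vals, ylab = "range over mean",
                    main = "Range over mean by group")
  grDevices::dev.off()
  if (!is.null(report$si_curves)) {
    grDevices::png(file.path(figdir, "si_decay.png"), 600, 450)
    graphics::plot(NULL, xlim = range(report$si_curves$t_min),
                   ylim = c(0, 1), xlab = "time (min)",
                   ylab = "normalized SI", main = "SI decay by group")
    for (gi in seq_along(groups)) {
      sc <- report$si_curves[report$si_curves$group == groups[gi], ]
      m <- tapply(sc$si_norm, sc$t_min, mean)
      graphics::lines(as.numeric(names(m)), m, col = gi, lwd = 2)
    }
    graphics::legend("bottomleft", legend = groups,
                     col = seq_along(groups), lwd = 2, bty = "n")
    grDevices::dev.off()
  }
  invisible(NULL)
}

#' Run the FRAP analysis pipeline
#'
#' Per-record photobleaching correction, individual and group-average
#' two-pool model fits, fractional-recovery distributions and pairwise KS
#' comparisons. In simulate mode each group's records are generated from
#' its [frap_presets()] parameter set on the standard sampling schedule.
#'
#' @param config a [run_config()]; group values must be FRAP preset names
#'   (`"ko"`, `"wt"`), parameter lists, or (mode `"traces"`) paths to FRAP
#'   table CSVs.
#' @return Object of class `frap_report`: list with `fits` (per-record
#'   coefficient data frame), `avg_fits` (per-group fits to the averaged
#'   curve), `avg_curves`, `fractional_recovery`, `comparisons`, `config`.
#' @export
run_frap_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  records <- list()
  for (gi in seq_along(config$groups)) {
    g <- names(config$groups)[gi]
    spec <- config$groups[[gi]]
    if (config$mode == "simulate") {
      truth <- if (is.character(spec)) frap_presets(spec) else as.list(spec)
      records[[g]] <- lapply(seq_len(config$n_frap), function(r)
        simulate_frap_experiment(truth, frap_schedule(),
                                 noise_sd = config$frap_noise_sd,
                                 bleach_rate = config$frap_bleach_rate,
                                 seed = group_seed(config, gi, r)))
    } else {
      records[[g]] <- read_frap_csv(spec)
    }
  }

  fits <- list(); frac <- list(); avg_curves <- list(); avg_fits <- list()
  for (g in names(records)) {
    curves <- lapply(records[[g]], bleach_correct)
    gfits <- lapply(curves, frap_fit)
    fits[[g]] <- data.frame(group = g,
                            record = seq_along(gfits),
                            t(vapply(gfits, coef, numeric(4L))),
                            converged = vapply(gfits, `[[`, logical(1L),
                                               "converged"),
                            stringsAsFactors = FALSE)
    frac[[g]] <- vapply(curves, fractional_recovery, numeric(1L))
    avg_curves[[g]] <- average_frap_curves(curves)
    avg_fits[[g]] <- frap_fit(avg_curves[[g]])
  }
  fits <- do.call(rbind, fits)

  gnames <- names(records)
  comparisons <- list()
  for (i in seq_along(gnames)) for (j in seq_along(gnames)) {
    if (j <= i) next
    key <- paste(gnames[i], "vs", gnames[j])
    comparisons[[key]] <- list(fractional_recovery = compare_distributions(
      frac[[gnames[i]]], frac[[gnames[j]]], gnames[i], gnames[j],
      what = "fractional recovery"))
  }

  report <- structure(list(fits = fits, avg_fits = avg_fits,
                           avg_curves = avg_curves,
                           fractional_recovery = frac,
                           comparisons = comparisons, config = config),
                      class = "frap_report")
  if (!is.null(config$output_dir)) write_frap_report(report)
  report
}

#' @export
print.frap_report <- function(x, ...) {
  cat("FRAP report\n")
  for (g in names(x$avg_fits)) {
    cf <- coef(x$avg_fits[[g]])
    cat(sprintf(
      "  %-10s avg-curve fit: F_bl %.3f, P_f %.3f, tau_f %.1f min, tau_s %.2f h | fractional recovery %.3f+/-%.3f (n = %d)\n",
      g, cf["F_bl"], cf["P_f"], cf["tau_f"], cf["tau_s"] / 60,
      mean(x$fractional_recovery[[g]]), stats::sd(x$fractional_recovery[[g]]),
      length(x$fractional_recovery[[g]])))
  }
  for (key in names(x$comparisons)) {
    ct <- x$comparisons[[key]]$fractional_recovery
    cat(sprintf("  %s fractional recovery: D = %.3f, p = %.3g\n", key,
                ct$statistic, ct$p.value))
  }
  invisible(x)
}

write_frap_report <- function(report) {
  dir.create(report$config$output_dir, recursive = TRUE,
             showWarnings = FALSE)
  out <- function(f) file.path(report$config$output_dir, f)
  utils::write.csv(report$fits, out("frap_fits.csv"), row.names = FALSE,
                   quote = FALSE)
  fr <- do.call(rbind, lapply(names(report$fractional_recovery), function(g)
    data.frame(group = g, value = report$fractional_recovery[[g]])))
  utils::write.csv(fr, out("fractional_recovery.csv"), row.names = FALSE,
                   quote = FALSE)
  ac <- do.call(rbind, lapply(names(report$avg_curves), function(g)
    cbind(group = g, as.data.frame(report$avg_curves[[g]]))))
  utils::write.csv(ac, out("average_curves.csv"), row.names = FALSE,
                   quote = FALSE)
  write_provenance(report$config)
  invisible(report)
}

#' Read a FRAP table
#'
#' CSV with columns `role` (`bleached` or `reference`), `punctum`, `t_min`
#' and `fluorescence`; rows with `t_min < 0` are pre-bleach baselines. One
#' bleached punctum per file; all references must share the bleached
#' punctum's post-bleach time base.
#'
#' @param path CSV path.
#' @return A list with one [frap_record()] (kept as a list so multi-record
#'   group files can extend the format).
#' @export
read_frap_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("role", "punctum", "t_min", "fluorescence")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stopf("FRAP table missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  bl <- df[df$role == "bleached", ]
  if (nrow(bl) == 0L) stopf("no bleached punctum in FRAP table")
  pre <- bl[bl$t_min < 0, ]
  post <- bl[bl$t_min >= 0, ]
  if (nrow(pre) == 0L) stopf("no pre-bleach (t_min < 0) rows")
  post <- post[order(post$t_min), ]
  refs <- df[df$role == "reference" & df$t_min >= 0, ]
  ref_ids <- unique(refs$punctum)
  f_nb <- t(vapply(ref_ids, function(id) {
    rr <- refs[refs$punctum == id, ]
    rr$fluorescence[order(rr$t_min)]
  }, numeric(nrow(post))))
  ref_pre <- df[df$role == "reference" & df$t_min < 0, ]
  f_nb0 <- if (nrow(ref_pre)) vapply(ref_ids, function(id)
    mean(ref_pre$fluorescence[ref_pre$punctum == id]), numeric(1L))
  else f_nb[, 1L]
  list(frap_record(F0 = mean(pre$fluorescence), t = post$t_min,
                   F_t = post$fluorescence, F_nb = f_nb, F_nb0 = f_nb0))
}
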