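#' Maximal-intensity projection of a Z stack
#'
#' Collapses the Z dimension by the pixelwise maximum, producing the 2-D
#' frame sequence on which all punctum measurements are made. A 3-D input
#' (`height x width x time`, already projected) is returned unchanged.
#'
#' @param stack numeric array `height x width x Z x time` (or
#'   `height x width x time`), or an `image_stack`.
#' @return Array `height x width x time`.
#' @export
max_project <- function(stack) {
  if (inherits(stack, "image_stack")) stack <- stack$frames
  d <- dim(stack)
  if (is.null(d) || length(d) < 3L) stopf("expected an array with >= 3 dims")
  if (length(d) == 3L) return(stack)
  if (length(d) == 4L) {
    if (d[3L] < 1L) stopf("empty stack: no Z sections")
    return(apply(stack, c(1L, 2L, 4L), max))
  }
  stopf("unsupported stack dimensionality: %d", length(d))
}

#' Detect puncta as pruned local intensity maxima
#'
#' Finds strict 8-neighborhood local maxima above `min_intensity`, sorts
#' them by brightness, and greedily discards any maximum closer than
#' `min_separation` pixels to an already accepted (brighter) one.
#'
#' @param frame 2-D numeric image.
#' @param min_intensity absolute intensity threshold, AU.
#' @param min_separation minimum center-to-center distance, pixels.
#' @return Matrix with columns `x`, `y`, `intensity` (possibly 0 rows),
#'   sorted by decreasing intensity. `x` indexes columns, `y` rows.
#' @export
detect_puncta <- function(frame, min_intensity, min_separation = 4) {
  stopifnot(is.matrix(frame))
  h <- nrow(frame); w <- ncol(frame)
  if (h < 3L || w < 3L) return(cbind(x = numeric(), y = numeric(),
                                     intensity = numeric()))
  ctr <- frame[2:(h - 1L), 2:(w - 1L)]
  is_max <- ctr > min_intensity
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    nb <- frame[(2:(h - 1L)) + dy, (2:(w - 1L)) + dx]
    is_max <- is_max & (ctr >= nb)
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(cbind(x = numeric(), y = numeric(),
                                    intensity = numeric()))
  ys <- idx[, 1L] + 1L; xs <- idx[, 2L] + 1L
  vals <- frame[cbind(ys, xs)]
  ord <- order(vals, decreasing = TRUE)
  xs <- xs[ord]; ys <- ys[ord]; vals <- vals[ord]
  keep <- logical(length(xs))
  for (i in seq_along(xs)) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    d2 <- (xs[keep] - xs[i])^2 + (ys[keep] - ys[i])^2
    if (min(d2) >= min_separation^2) keep[i] <- TRUE
  }
  cbind(x = xs[keep], y = ys[keep], intensity = vals[keep])
}

#' Box-mean punctum intensity
#'
#' Mean pixel value in an odd `box x box` region centered on the
#' integer-rounded center (the 7 x 7 pixel convention, ~1 x 1 um). Boxes
#' reaching beyond the frame are clipped with a warning.
#'
#' @param frame 2-D numeric image.
#' @param center length-2 numeric `(x, y)` in pixels.
#' @param box odd box side, pixels.
#' @return Mean intensity, AU.
#' @export
measure_intensity <- function(frame, center, box = 7L) {
  check_number(box, "box", min = 1, integer = TRUE)
  if (box %% 2L == 0L) stopf("box side must be odd (got %d)", box)
  cx <- round(center[1L]); cy <- round(center[2L])
  if (cx < 1 || cx > ncol(frame) || cy < 1 || cy > nrow(frame))
    stopf("center (%g, %g) outside frame", center[1L], center[2L])
  half <- (box - 1L) %/% 2L
  rows <- (cy - half):(cy + half)
  cols <- (cx - half):(cx + half)
  if (min(rows) < 1L || max(rows) > nrow(frame) ||
      min(cols) < 1L || max(cols) > ncol(frame)) {
    warning("measurement box clipped at frame edge", call. = FALSE)
    rows <- rows[rows >= 1L & rows <= nrow(frame)]
    cols <- cols[cols >= 1L & cols <= ncol(frame)]
  }
  mean(frame[rows, cols])
}

#' Track puncta across a time-lapse frame sequence
#'
#' Deterministic nearest-local-maximum tracker: each track is recentered,
#' frame by frame, on the brightest pixel within `search_radius` of its
#' previous center, and its box-mean intensity is measured there. Loss is
#' flagged when the background-subtracted box mean stays below
#' `loss_k` background-noise SDs for `loss_m` consecutive frames
#' (operationalizing "clearly disappeared"); a merge is flagged when two
#' track centers coincide within `merge_distance`; a split is flagged when
#' a track's search neighborhood contains a second comparably bright
#' maximum (ratio >= `split_ratio`). Split/merged tracks are excluded from
#' downstream statistics.
#'
#' @param frames array `height x width x time` (use [max_project()] first
#'   for Z stacks).
#' @param seeds matrix with columns `x`, `y`: punctum positions in frame 1
#'   (e.g. from [detect_puncta()]).
#' @param box odd measurement box side, pixels.
#' @param search_radius maximum per-frame displacement, pixels.
#' @param background,background_sd background level and noise SD; estimated
#'   from the first frame (median / MAD) when `NULL`.
#' @param loss_k,loss_m loss criterion: box mean below
#'   `background + loss_k * background_sd` for `loss_m` consecutive frames.
#' @param merge_distance center distance below which two tracks are
#'   considered merged, pixels.
#' @param split_ratio background-subtracted brightness ratio above which a
#'   secondary maximum flags a split.
#' @return List of class `punctum_tracks`; each element has `id`, `center`
#'   (time x 2 matrix), `intensity` (box means), and per-frame `status`
#'   (`ok`, `lost`, `split`, `merged`).
#' @export
track_puncta <- function(frames, seeds, box = 7L, search_radius = 5,
                         background = NULL, background_sd = NULL,
                         loss_k = 2, loss_m = 3L, merge_distance = 3,
                         split_ratio = 0.6) {
  d <- dim(frames)
  if (is.null(d) || length(d) != 3L)
    stopf("frames must be a height x width x time array")
  seeds <- as.matrix(seeds)
  if (nrow(seeds) == 0L) stopf("empty seed list")
  nt <- d[3L]; n <- nrow(seeds)
  if (is.null(background)) background <- stats::median(frames[, , 1L])
  if (is.null(background_sd)) background_sd <- stats::mad(frames[, , 1L])

  centers <- array(NA_real_, c(nt, 2L, n))
  intens <- matrix(NA_real_, nt, n)
  status <- matrix("ok", nt, n)
  below <- integer(n)  # consecutive below-threshold run length
  excluded <- logical(n)

  for (k in seq_len(nt)) {
    fr <- frames[, , k]
    for (i in seq_len(n)) {
      prev <- if (k == 1L) c(seeds[i, 1L], seeds[i, 2L]) else centers[k - 1L, , i]
      if (excluded[i]) {
        centers[k, , i] <- prev
        intens[k, i] <- measure_intensity(fr, prev, box)
        status[k, i] <- status[k - 1L, i]
        next
      }
      lost_now <- k > 1L && status[k - 1L, i] == "lost"
      if (lost_now) {
        ctr <- prev  # stop recentering once lost; keep watching the site
      } else {
        peak <- brightest_in_radius(fr, prev, search_radius)
        ctr <- peak$center
        if (!is.null(peak$second) && background_sd > 0) {
          # a split needs two clearly significant peaks: both must stand
          # well above the noise floor, or noise maxima after a loss event
          # would masquerade as splits
          prim <- peak$value - background
          sec <- peak$second_value - background
          if (prim > 5 * background_sd &&
              sec > 5 * background_sd &&
              sec >= split_ratio * prim &&
              sum((peak$second - ctr)^2) >= 4) {
            status[k, i] <- "split"
            excluded[i] <- TRUE
          }
        }
      }
      centers[k, , i] <- ctr
      intens[k, i] <- measure_intensity(fr, ctr, box)
      if (!excluded[i]) {
        if (intens[k, i] - background < loss_k * background_sd)
          below[i] <- below[i] + 1L
        else below[i] <- 0L
        if (lost_now || below[i] >= loss_m) {
          first <- k - max(0L, below[i] - 1L)
          status[first:k, i] <- "lost"
        }
      }
    }
    # merge detection among non-excluded, non-lost tracks
    active <- which(!excluded & status[k, ] == "ok")
    if (length(active) > 1L) {
      pc <- matrix(centers[k, , active], nrow = 2L)
      dists <- as.matrix(stats::dist(t(pc)))
      diag(dists) <- Inf
      merged <- active[apply(dists < merge_distance, 1L, any)]
      if (length(merged)) {
        status[k, merged] <- "merged"
        excluded[merged] <- TRUE
      }
    }
  }

  structure(lapply(seq_len(n), function(i) {
    list(id = sprintf("p%04d", i),
         center = centers[, , i, drop = TRUE],
         intensity = intens[, i],
         status = status[, i])
  }), class = "punctum_tracks",
     background = background, background_sd = background_sd)
}

# Brightest pixel (and second local maximum, if any) within `radius` of
# `center`; used by the tracker for recentering and split detection.
brightest_in_radius <- function(frame, center, radius) {
  h <- nrow(frame); w <- ncol(frame)
  cx <- round(center[1L]); cy <- round(center[2L])
  r <- ceiling(radius)
  rows <- max(1L, cy - r):min(h, cy + r)
  cols <- max(1L, cx - r):min(w, cx + r)
  sub <- frame[rows, cols, drop = FALSE]
  dy <- rows - center[2L]; dx <- cols - center[1L]
  mask <- outer(dy^2, dx^2, `+`) <= radius^2
  sub[!mask] <- -Inf
  best <- which(sub == max(sub), arr.ind = TRUE)[1L, ]
  out <- list(center = c(cols[best[2L]], rows[best[1L]]),
              value = max(sub))
  # secondary local maximum within the window (3x3 strict)
  loc <- detect_puncta(sub, min_intensity = -Inf,
                       min_separation = 2)
  if (nrow(loc) >= 2L) {
    out$second <- c(cols[loc[2L, "x"]], rows[loc[2L, "y"]])
    out$second_value <- loc[2L, "intensity"]
  }
  out
}

#' @export
print.punctum_tracks <- function(x, ...) {
  final <- vapply(x, function(tr) tr$status[length(tr$status)], character(1L))
  cat(sprintf("%d punctum tracks over %d frames (%s)\n", length(x),
              length(x[[1L]]$status),
              paste(sprintf("%s: %d", names(table(final)), table(final)),
                    collapse = ", ")))
  invisible(x)
}

#' Convert tracker output to the tidy trace schema
#'
#' Maps per-frame tracker statuses to trace statuses (`ok` to `tracked`,
#' `split`/`merged` to `rejected_split_merge`) and subtracts the estimated
#' background from the box-mean intensities, so tracker output feeds the
#' constancy statistics directly.
#'
#' @param tracks a `punctum_tracks` object.
#' @param t_min frame times in minutes.
#' @param experiment,neuron identifiers for the output table.
#' @return Trace data frame in the schema of
#'   [simulate_trace_population()].
#' @export
tracks_to_traces <- function(tracks, t_min, experiment = "tracked",
                             neuron = "n01") {
  stopifnot(inherits(tracks, "punctum_tracks"))
  nt <- length(tracks[[1L]]$status)
  if (length(t_min) != nt) stopf("t_min length must match frame count")
  bg <- attr(tracks, "background") %||% 0
  do.call(rbind, lapply(tracks, function(tr) {
    st <- c(ok = "tracked", lost = "lost", split = "rejected_split_merge",
            merged = "rejected_split_merge")[tr$status]
    data.frame(experiment = experiment, neuron = neuron, punctum = tr$id,
               t_min = t_min, fluorescence = pmax(0, tr$intensity - bg),
               status = unname(st), stringsAsFactors = FALSE)
  }))
}

#' Image stacks straight to trace tables
#'
#' Convenience wrapper chaining [max_project()], [detect_puncta()] on the
#' first frame, [track_puncta()] and [tracks_to_traces()]: the standard
#' measurement path from a time-lapse stack to the tidy trace schema.
#'
#' @param stack an `image_stack`, a raw array, or a TIFF path readable by
#'   [read_image_stack()].
#' @param box,search_radius tracker settings (see [track_puncta()]).
#' @param min_intensity detection threshold; defaults to
#'   `background + 5 * background_sd` estimated from the first frame.
#' @param min_separation minimum detection separation, pixels.
#' @param experiment,neuron identifiers for the output table.
#' @return Trace data frame.
#' @export
stack_to_traces <- function(stack, box = 7L, search_radius = 5,
                            min_intensity = NULL, min_separation = 6,
                            experiment = "images", neuron = "n01") {
  if (is.character(stack)) stack <- read_image_stack(stack)
  t_min <- if (inherits(stack, "image_stack")) stack$t_min else NULL
  frames <- max_project(stack)
  bg <- stats::median(frames[, , 1L])
  sbg <- stats::mad(frames[, , 1L])
  if (is.null(min_intensity)) min_intensity <- bg + 5 * sbg
  det <- detect_puncta(frames[, , 1L], min_intensity, min_separation)
  if (nrow(det) == 0L) stopf("no puncta detected in first frame")
  tracks <- track_puncta(frames, det[, c("x", "y"), drop = FALSE],
                         box = box, search_radius = search_radius,
                         background = bg, background_sd = sbg)
  tracks_to_traces(tracks, t_min %||% (seq_len(dim(frames)[3L]) - 1),
                   experiment, neuron)
}
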