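#' Scan geometry of a serially acquired imaging experiment
#'
#' Describes how a raster-scanning microscope visits lines within each frame,
#' so that the exact acquisition time of any ROI sample can be reconstructed
#' from its line position.
#'
#' @param frame_period Time between frame starts, seconds.
#' @param line_period Time to acquire one line, seconds.
#' @param lines_per_frame Number of lines per frame
#'   (`line_period * lines_per_frame <= frame_period`).
#' @param n_frames Number of frames (used when `frame_start_times` is not
#'   given; starts are then `0, frame_period, 2 frame_period, ...`).
#' @param bidirectional If `TRUE`, odd frames are scanned with mirrored line
#'   order.
#' @param frame_start_times Optional strictly increasing vector of measured
#'   frame-start times (e.g. from hardware triggers); overrides the uniform
#'   assumption.
#' @return An object of class `scan_geometry`.
#' @export
scan_geometry <- function(frame_period, line_period, lines_per_frame,
                          n_frames = NULL, bidirectional = FALSE,
                          frame_start_times = NULL) {
  stopifnot(frame_period > 0, line_period > 0, lines_per_frame >= 1)
  if (line_period * lines_per_frame > frame_period + 1e-12)
    stop("line_period * lines_per_frame exceeds frame_period")
  if (is.null(frame_start_times)) {
    stopifnot(!is.null(n_frames), n_frames >= 1)
    frame_start_times <- (seq_len(n_frames) - 1L) * frame_period
  }
  if (any(diff(frame_start_times) <= 0))
    stop("frame_start_times must be strictly increasing")
  structure(
    list(frame_period = frame_period, line_period = line_period,
         lines_per_frame = as.integer(lines_per_frame),
         bidirectional = isTRUE(bidirectional),
         frame_start_times = frame_start_times),
    class = "scan_geometry"
  )
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf("# scan_geometry: %d frames @ %g s, %d lines @ %g s%s\n",
              length(x$frame_start_times), x$frame_period,
              x$lines_per_frame, x$line_period,
              if (x$bidirectional) ", bidirectional" else ""))
  invisible(x)
}

#' Per-sample acquisition times of an ROI from scan geometry
#'
#' The sample time of line `l` (0-based) in frame `k` is
#' `frame_start_times[k] + l * line_period`; for bidirectional scanning the
#' line order is mirrored on odd frames. Given per-line ROI values (a frames x
#' lines matrix) this returns one [timed_samples()] per ROI line, each with
#' `integration_time = line_period`. Given per-frame mean values, a single
#' [timed_samples()] at the ROI's centre-line time is returned, with
#' `integration_time = line_period * number of ROI lines` (the ROI dwell).
#'
#' @param geom A [scan_geometry()].
#' @param line_indices 0-based line indices the ROI occupies.
#' @param values Either a numeric matrix (frames x ROI lines) of per-line
#'   values, or a numeric vector of per-frame means.
#' @return A named list of [timed_samples()] (one per line), or a single
#'   [timed_samples()] for per-frame means.
#' @export
sample_times_from_scan <- function(geom, line_indices, values) {
  stopifnot(inherits(geom, "scan_geometry"))
  line_indices <- as.integer(line_indices)
  if (any(line_indices < 0L | line_indices >= geom$lines_per_frame))
    stop("line index out of range for this scan geometry")
  starts <- geom$frame_start_times
  n_frames <- length(starts)
  line_time <- function(l) {
    eff <- rep(l, n_frames)
    if (geom$bidirectional) {
      odd <- (seq_len(n_frames) - 1L) %% 2L == 1L
      eff[odd] <- geom$lines_per_frame - 1L - l
    }
    starts + eff * geom$line_period
  }
  if (is.matrix(values)) {
    stopifnot(nrow(values) == n_frames, ncol(values) == length(line_indices))
    out <- lapply(seq_along(line_indices), function(j) {
      tt <- line_time(line_indices[j])
      ord <- order(tt)
      timed_samples(tt[ord], values[ord, j],
                    integration_time = geom$line_period)
    })
    names(out) <- paste0("line", line_indices)
    out
  } else {
    stopifnot(length(values) == n_frames)
    centre <- line_indices[ceiling(length(line_indices) / 2)]
    tt <- line_time(centre)
    ord <- order(tt)
    timed_samples(tt[ord], values[ord],
                  integration_time = geom$line_period * length(line_indices))
  }
}

#' Convert a raw fluorescence trace to dF/F
#'
#' Fits a single-exponential baseline `F(t) = A exp(-t / tau_b) + C` to the
#' entire trace by least squares (bleaching model), then returns
#' `(raw - F) / F` at each sample time. If the exponential fit fails, a
#' constant baseline equal to the trace mean is used and flagged in the
#' `"baseline"` attribute.
#'
#' @param samples A [timed_samples()] of raw fluorescence (>= 4 samples).
#' @return A [timed_samples()] of dF/F with a `"baseline"` attribute listing
#'   the fitted `A`, `tau_b`, `C` and a `fallback` flag.
#' @export
dff <- function(samples) {
  stopifnot(inherits(samples, "timed_samples"))
  if (nrow(samples) < 4L) stop("dF/F baseline fit needs at least 4 samples")
  t <- samples$time
  y <- samples$value
  fit <- tryCatch({
    span <- max(t) - min(t)
    st <- list(A = max(y) - min(y), tau_b = span / 3, C = min(y))
    minpack.lm::nlsLM(y ~ A * exp(-(t - min(t)) / tau_b) + C,
                      start = st,
                      lower = c(A = -Inf, tau_b = span * 1e-4, C = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }, error = function(e) NULL)
  if (is.null(fit)) {
    base <- rep(mean(y), length(y))
    info <- list(A = NA_real_, tau_b = NA_real_, C = mean(y), fallback = TRUE)
  } else {
    base <- as.numeric(stats::predict(fit))
    cf <- stats::coef(fit)
    info <- list(A = unname(cf["A"]), tau_b = unname(cf["tau_b"]),
                 C = unname(cf["C"]), fallback = FALSE)
  }
  if (any(base <= 0)) stop("fitted baseline is not positive; cannot form dF/F")
  out <- timed_samples(t, (y - base) / base,
                       integration_time = integration_time(samples))
  attr(out, "baseline") <- info
  out
}

#' Keep every k-th response sample
#'
#' Emulates a slower acquisition by keeping samples whose index is congruent
#' to `phase` modulo `k`; times are untouched, so e.g. every 6th sample of a
#' 13 Hz train gives a ~2.2 Hz train.
#'
#' @param samples A [timed_samples()].
#' @param k Keep-one-in-`k` factor (`k = 1` is the identity).
#' @param phase 0-based phase in `[0, k)`.
#' @return A [timed_samples()].
#' @export
subsample_every <- function(samples, k, phase = 0L) {
  stopifnot(inherits(samples, "timed_samples"), k >= 1, phase >= 0, phase < k)
  idx <- seq_len(nrow(samples))
  keep <- (idx - 1L) %% k == phase
  timed_samples(samples$time[keep], samples$value[keep],
                integration_time = integration_time(samples))
}

#' Downsample a dense trace by bin averaging
#'
#' Averages source bins into target bins of width `target_dt`, so every
#' frequency retained in the downsampled trace keeps stimulus power (bin-mean,
#' not decimation). A non-integer rate ratio falls back to nearest-bin
#' assignment with a warning.
#'
#' @param trace A [stim_trace()].
#' @param target_dt Target bin width (`>= stim_dt(trace)`).
#' @return A [stim_trace()] on the target grid.
#' @export
downsample_dense <- function(trace, target_dt) {
  stopifnot(inherits(trace, "stim_trace"))
  dt <- stim_dt(trace)
  if (target_dt < dt - 1e-12) stop("target_dt must be >= the source dt")
  if (abs(target_dt - dt) < 1e-12 * dt) return(trace)
  ratio <- target_dt / dt
  v <- stim_values(trace)
  n <- nrow(v)
  if (abs(ratio - round(ratio)) < 1e-9) {
    k <- as.integer(round(ratio))
    n_out <- n %/% k
    grp <- rep(seq_len(n_out), each = k)
    keep <- seq_len(n_out * k)
    out <- apply(v[keep, , drop = FALSE], 2L,
                 function(col) tapply(col, grp, mean))
  } else {
    warning("non-integer downsampling ratio: using nearest-bin assignment")
    grp <- floor((trace$time - trace$time[1]) / target_dt + 1e-9) + 1L
    n_out <- max(grp)
    out <- apply(v, 2L, function(col) {
      m <- tapply(col, grp, mean)
      as.numeric(m[as.character(seq_len(n_out))])
    })
  }
  out <- as.matrix(out)
  colnames(out) <- setdiff(names(trace), "time")
  stim_trace(out, dt = target_dt, t0 = trace$time[1])
}

#' Binary stimulus-onset indicator trace
#'
#' Builds, per pixel/channel, a 0/1 trace that is 1 in every grid bin during
#' which at least one event of the requested polarity occurred (an indicator,
#' not a count). Events are binned half-open, `[t, t + dt)`; events outside
#' the grid are dropped and counted in the `"n_dropped"` attribute.
#'
#' @param events A data frame with columns `time` (seconds), optional `pixel`
#'   (channel label, default a single channel) and optional `polarity`.
#' @param dt Grid bin width, seconds.
#' @param duration Grid duration, seconds.
#' @param t0 Grid start time (default 0).
#' @param polarity If given, only events with this `polarity` value are used.
#' @return A [stim_trace()] with one 0/1 channel per pixel.
#' @export
onset_trace <- function(events, dt, duration, t0 = 0, polarity = NULL) {
  stopifnot(is.data.frame(events), "time" %in% names(events))
  if (!is.null(polarity) && "polarity" %in% names(events))
    events <- events[events$polarity == polarity, , drop = FALSE]
  pix <- if ("pixel" %in% names(events)) as.character(events$pixel)
         else rep("value", nrow(events))
  n <- round(duration / dt)
  levels_pix <- if (length(pix)) unique(pix) else "value"
  bins <- floor((events$time - t0) / dt + 1e-9) + 1L
  inside <- bins >= 1L & bins <= n
  n_dropped <- sum(!inside)
  M <- matrix(0, n, length(levels_pix), dimnames = list(NULL, levels_pix))
  if (any(inside)) {
    for (i in which(inside)) M[bins[i], pix[i]] <- 1
  }
  out <- stim_trace(M, dt = dt, t0 = t0)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Average per-line filters into one ROI filter
#'
#' Element-wise mean of filters estimated from each scanned line of an ROI;
#' when at least 3 lines are available the across-line dispersion provides a
#' standard error (`sd / sqrt(n)`), per lag.
#'
#' @param filters A list of [vt_filter()] objects on identical lag grids.
#' @return A [vt_filter()] with `method = "line_average"`.
#' @export
per_line_filter_average <- function(filters) {
  stopifnot(length(filters) >= 1L,
            all(vapply(filters, inherits, logical(1), "vt_filter")))
  lg <- filter_lags(filters[[1L]])
  for (f in filters[-1L]) {
    if (!same_lag_grid(filter_lags(f), lg))
      stop("all per-line filters must share the same lag grid")
  }
  V <- vapply(filters, filter_values, numeric(length(lg$taus)))
  V <- matrix(V, nrow = length(lg$taus))
  m <- rowMeans(V)
  se <- if (ncol(V) >= 3L) apply(V, 1L, stats::sd) / sqrt(ncol(V)) else NULL
  vt_filter(m, lg, method = "line_average", se = se,
            meta = list(n_lines = ncol(V)))
}

#' Mean ROI fluorescence from a multi-frame TIFF stack and a label mask
#'
#' Convenience reader: extracts the per-frame mean value of each labelled
#' region from an image stack. No segmentation or motion correction is
#' performed; the mask must be supplied.
#'
#' @param path Path to a multi-frame grayscale TIFF.
#' @param mask Integer matrix of the same frame size; 0 = background, values
#'   `1..K` label ROIs.
#' @return A tibble with columns `roi`, `frame`, `value`.
#' @export
roi_means_from_stack <- function(path, mask) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to read TIFF stacks")
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  mask <- as.matrix(mask)
  rois <- sort(unique(mask[mask > 0]))
  purrr::map_dfr(seq_along(frames), function(k) {
    fr <- frames[[k]]
    if (length(dim(fr)) == 3L) fr <- fr[, , 1L]
    tibble::tibble(
      roi = rois,
      frame = k,
      value = vapply(rois, function(rr) mean(fr[mask == rr]), numeric(1))
    )
  })
}
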