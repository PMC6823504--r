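#' Smoothing kernels for filter estimates
#'
#' Symmetric, unit-sum discrete kernels on the filter's lag grid, used to
#' trade temporal resolution for noise in a filter estimate. `gaussian_kernel`
#' discretizes a Gaussian of the given standard deviation; [triangle_kernel()]
#' builds the triangle whose application to the voxel-timing filter reproduces
#' the linear-interpolation baseline; `delta_kernel` is the identity;
#' `lowpass_kernel` is a zero-phase Hamming-windowed-sinc low-pass on the lag
#' axis.
#'
#' @param sd Gaussian standard deviation in seconds.
#' @param dt Lag grid spacing in seconds.
#' @param radius Kernel half-width in units of `sd` (default 4).
#' @return An object of class `smoothing_kernel`: list with `kind`, `width`,
#'   and unit-sum symmetric `taps`.
#' @export
gaussian_kernel <- function(sd, dt, radius = 4) {
  stopifnot(sd > 0, dt > 0)
  h <- max(1L, ceiling(radius * sd / dt))
  taps <- stats::dnorm((-h:h) * dt, sd = sd)
  new_smoothing_kernel("gaussian", sd, taps / sum(taps))
}

#' @rdname gaussian_kernel
#' @export
delta_kernel <- function() new_smoothing_kernel("delta", 0, 1)

#' @rdname gaussian_kernel
#' @param cutoff_hz Low-pass cutoff frequency in Hz.
#' @param n_taps Odd number of taps (default spans 4 cutoff periods).
#' @export
lowpass_kernel <- function(cutoff_hz, dt, n_taps = NULL) {
  stopifnot(cutoff_hz > 0, dt > 0)
  if (is.null(n_taps)) n_taps <- 2L * ceiling(2 / (cutoff_hz * dt)) + 1L
  if (n_taps %% 2L == 0L) n_taps <- n_taps + 1L
  h <- (n_taps - 1L) / 2L
  m <- -h:h
  x <- 2 * cutoff_hz * m * dt
  taps <- ifelse(m == 0, 1, sin(pi * x) / (pi * x))
  w <- 0.54 + 0.46 * cos(pi * m / h)  # Hamming window
  taps <- taps * w
  new_smoothing_kernel("lowpass", 1 / cutoff_hz, taps / sum(taps))
}

#' Triangle kernel equivalent to linear interpolation
#'
#' The symmetric triangle of base width `2 * sample_interval` on the lag grid.
#' Smoothing the voxel-timing filter with this kernel corresponds to the
#' implicit smoothing performed when the response is linearly interpolated to
#' the stimulus grid before fitting: for regular sampling the two agree
#' exactly in expectation, so the super-resolution filter can be degraded in a
#' controlled way down to the interpolation (imaging-rate) filter.
#'
#' @param sample_interval Response sampling interval in seconds
#'   (`>= dt`).
#' @param dt Lag grid spacing (stimulus bin width) in seconds.
#' @return A `smoothing_kernel` with unit-sum triangular taps; a single tap of
#'   1 (delta) when `sample_interval == dt`.
#' @examples
#' triangle_kernel(0.02, 0.01)$taps  # 0.25 0.50 0.25
#' @export
triangle_kernel <- function(sample_interval, dt) {
  stopifnot(dt > 0)
  if (sample_interval < dt - 1e-12)
    stop("sample_interval must be >= the lag grid spacing dt")
  h <- ceiling(sample_interval / dt - 1e-9) - 1L
  taps <- pmax(0, 1 - abs((-h:h) * dt) / sample_interval)
  new_smoothing_kernel("triangle", sample_interval, taps / sum(taps))
}

new_smoothing_kernel <- function(kind, width, taps) {
  stopifnot(abs(sum(taps) - 1) < 1e-12, length(taps) %% 2L == 1L)
  stopifnot(max(abs(taps - rev(taps))) < 1e-12)
  structure(list(kind = kind, width = width, taps = as.numeric(taps)),
            class = "smoothing_kernel")
}

#' @export
print.smoothing_kernel <- function(x, ...) {
  cat(sprintf("# smoothing_kernel [%s]: %d taps, width parameter %g s\n",
              x$kind, length(x$taps), x$width))
  invisible(x)
}

#' Smooth a filter estimate in time
#'
#' Discrete convolution of the filter values with the kernel taps, returning a
#' filter of the same length on the same lag grid. Edges are zero-padded
#' (filters decay to zero at the window edges by construction). The delta
#' kernel is the identity.
#'
#' @param f A [vt_filter()].
#' @param kernel A `smoothing_kernel` (see [gaussian_kernel()],
#'   [triangle_kernel()]).
#' @return A smoothed [vt_filter()]; the method label gains a
#'   `+smooth:<kind>` suffix.
#' @export
smooth_filter <- function(f, kernel) {
  stopifnot(inherits(f, "vt_filter"), inherits(kernel, "smoothing_kernel"))
  taps <- kernel$taps
  if (length(taps) > 10L * nrow(f))
    stop("kernel is more than 10x longer than the filter")
  v <- filter_values(f)
  vm <- if (is.matrix(v)) v else matrix(v, ncol = 1L)
  out <- apply(vm, 2L, convolve_same, taps = taps)
  vt_filter(if (ncol(vm) == 1L) drop(out) else out, filter_lags(f),
            method = paste0(filter_method(f), "+smooth:", kernel$kind),
            meta = c(filter_meta(f),
                     list(smooth_kind = kernel$kind, smooth_width = kernel$width)))
}

convolve_same <- function(x, taps) {
  h <- (length(taps) - 1L) / 2L
  xp <- c(rep(0, h), x, rep(0, h))
  out <- as.numeric(stats::filter(xp, taps, method = "convolution", sides = 2L))
  out[(h + 1L):(h + length(x))]
}
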