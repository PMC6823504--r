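#' Voxel-timing cross-correlation estimate of the filter
#'
#' Computes, at every lag `tau` on the stimulus-resolution grid,
#' `c_tau = (1/N) * sum_i S[i, tau] * r[i]`: the mean over response samples of
#' the (centered) stimulus at that lag times the (centered) response. For a
#' white stimulus this is proportional to the underlying linear filter, with
#' proportionality constant equal to the stimulus variance. The lag resolution
#' is set by the stimulus bin width, independent of how often the response was
#' sampled.
#'
#' @param pairs A [build_pairs()] result.
#' @return A [vt_filter()] with `method = "xcorr"`.
#' @export
vt_xcorr <- function(pairs) {
  stopifnot(inherits(pairs, "vt_pairs"))
  if (n_pairs(pairs) < 1L) stop("empty pair set")
  cc <- drop(crossprod(pairs$S, pairs$r)) / n_pairs(pairs)
  vt_filter(cc, pairs$lags, method = "xcorr",
            meta = list(n = n_pairs(pairs)))
}

#' Ordinary least-squares (optionally ridge) voxel-timing filter
#'
#' Solves the normal equations `(S'S + ridge * N * I) f = S'r` for the filter
#' that best predicts each response sample from its stimulus history. This is
#' the cross-correlation deconvolved by the stimulus autocorrelation; with
#' `ridge = 0` it is exact OLS. A singular `S'S` with `ridge = 0` raises a
#' conditioning error rather than silently regularizing.
#'
#' @param pairs A [build_pairs()] result.
#' @param ridge Non-negative ridge penalty, scaled by the number of samples
#'   (default 0).
#' @return A [vt_filter()] with `method = "ols"` (or `"ridge"`).
#' @export
vt_ols <- function(pairs, ridge = 0) {
  stopifnot(inherits(pairs, "vt_pairs"), ridge >= 0)
  N <- n_pairs(pairs)
  if (N < 1L) stop("empty pair set")
  L <- ncol(pairs$S)
  if (ridge == 0 && N < L)
    stop(sprintf("S'S is rank deficient (%d samples < %d lags); supply ridge > 0", N, L))
  G <- crossprod(pairs$S) + ridge * N * diag(L)
  b <- crossprod(pairs$S, pairs$r)
  ch <- tryCatch(chol(G), error = function(e) NULL)
  if (is.null(ch) || min(diag(ch)) < sqrt(.Machine$double.eps) * max(diag(ch))) {
    if (ridge == 0)
      stop("S'S is numerically singular (collinear stimulus histories); supply ridge > 0")
    f <- qr.solve(G, b, tol = 1e-12)
  } else {
    f <- backsolve(ch, forwardsolve(t(ch), b))
  }
  vt_filter(drop(f), pairs$lags,
            method = if (ridge > 0) "ridge" else "ols",
            meta = list(n = N, ridge = ridge))
}

#' Interpolation-baseline filter (resolution limited by the sampling rate)
#'
#' Upsamples the sparse response to the stimulus grid with the named
#' interpolant, then fits an OLS filter to the dense series. This reproduces
#' the common practice of interpolating slow imaging data before reverse
#' correlation; the result is implicitly smoothed and cannot resolve structure
#' faster than the response sampling interval. Provided as the baseline against
#' which the voxel-timing estimators are compared.
#'
#' @param stim A [stim_trace()].
#' @param samples A [timed_samples()] with at least 2 samples.
#' @param lags A [lag_grid()].
#' @param method One of `"linear"`, `"nearest"`, `"pchip"`, `"spline"`.
#' @param ridge Optional ridge penalty passed to the dense OLS fit.
#' @param channel Stimulus channel (default 1).
#' @return A [vt_filter()] with `method = "ols_interp:<kind>"`.
#' @export
vt_interp_filter <- function(stim, samples, lags,
                             method = c("linear", "nearest", "pchip", "spline"),
                             ridge = 0, channel = 1L) {
  method <- match.arg(method)
  if (nrow(samples) < 2L) stop("interpolation needs at least 2 samples")
  dense <- interpolate_response(stim, samples, method)
  p <- build_pairs(stim, dense, lags, channel = channel)
  f <- vt_ols(p, ridge = ridge)
  vt_filter(filter_values(f), lags, method = paste0("ols_interp:", method),
            meta = c(filter_meta(f), list(interp = method)))
}

# upsample sparse samples onto the stimulus bin times spanned by them
interpolate_response <- function(stim, samples, method) {
  dt <- stim_dt(stim)
  t0 <- stim$time[1]
  x <- samples$time
  y <- samples$value
  xo <- stim$time[stim$time >= min(x) - 1e-12 & stim$time <= max(x) + 1e-12]
  yo <- switch(method,
    linear = stats::approx(x, y, xout = xo, rule = 2)$y,
    nearest = {
      cuts <- (x[-1] + x[-length(x)]) / 2
      y[findInterval(xo, cuts) + 1L]
    },
    pchip = signal::pchip(x, y, xo),
    spline = stats::spline(x, y, xout = xo, method = "fmm")$y,
    stop(sprintf("unknown interpolation method '%s'", method))
  )
  timed_samples(xo, yo, integration_time = 0)
}

#' Predict the dense response implied by a filter
#'
#' Discrete convolution of the (optionally centered) stimulus with the filter,
#' evaluated at every stimulus bin: `pred[b] = sum_k f_k * s[b - k]` over the
#' filter's lag steps. Bins whose lag window extends outside the record are
#' `NA`. Used to form residuals `r_i - pred(t_i)`.
#'
#' @param object A [vt_filter()].
#' @param stim A [stim_trace()] with bin width equal to the filter's lag
#'   spacing.
#' @param center Either `TRUE` (subtract the stimulus record mean, default),
#'   `FALSE`, or a numeric mean to subtract (e.g. the mean stored in a
#'   `vt_pairs`).
#' @param channel Stimulus channel (default 1).
#' @param ... Unused.
#' @return A numeric vector of predictions, one per stimulus bin (`NA` where
#'   the history is incomplete).
#' @export
predict.vt_filter <- function(object, stim, center = TRUE, channel = 1L, ...) {
  stopifnot(inherits(stim, "stim_trace"))
  lg <- filter_lags(object)
  dt <- stim_dt(stim)
  if (abs(lg$dt - dt) > 1e-9 * dt)
    stop("filter lag spacing does not match the stimulus bin width")
  s <- stim_values(stim)[, channel]
  mu <- if (isTRUE(center)) mean(s) else if (identical(center, FALSE)) 0 else as.numeric(center)
  s <- s - mu
  f <- filter_values(object)
  steps <- lg$steps
  n <- length(s)
  pred <- rep(NA_real_, n)
  lo <- 1L + max(steps)
  hi <- n + min(steps)
  if (lo <= hi) {
    b <- lo:hi
    acc <- numeric(length(b))
    for (j in seq_along(steps)) acc <- acc + f[j] * s[b - steps[j]]
    pred[b] <- acc
  }
  pred
}

#' @rdname tidy.vt_pairs
#' @export
tidy.vt_filter <- function(x, ...) {
  tb <- tibble::as_tibble(x)
  tb$method <- filter_method(x)
  tb
}

#' @rdname tidy.vt_pairs
#' @export
glance.vt_filter <- function(x, ...) {
  lg <- filter_lags(x)
  meta <- filter_meta(x)
  tibble::tibble(
    method = filter_method(x),
    n_lags = length(lg$taus),
    n_causal = lg$n_causal,
    n_acausal = lg$n_acausal,
    dt = lg$dt,
    n_samples = if (!is.null(meta$n)) meta$n else NA_integer_,
    peak_lag = x$lag[which.max(abs(filter_values(x)))],
    rms = sqrt(mean(filter_values(x)^2))
  )
}
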