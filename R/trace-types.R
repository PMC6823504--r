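#' Uniform-grid stimulus (or any fast variable) trace
#'
#' A `stim_trace` is a tibble with a `time` column (bin start times on a
#' strictly uniform grid) and one or more value columns (channels). It is the
#' "fast" variable: a stimulus, behavioural trace, or densely simulated
#' response. Bin `k` covers the half-open interval `[t0 + k*dt, t0 + (k+1)*dt)`.
#'
#' @param x A data frame with a `time` column and at least one numeric value
#'   column, or a numeric vector/matrix of values (then `dt` and `t0` are
#'   required).
#' @param dt Bin width in seconds (required when `x` is not a data frame;
#'   otherwise inferred from `time` and checked for uniformity).
#' @param t0 Time of the first bin in seconds (default 0 when `x` is a vector).
#'
#' @return A tibble of class `stim_trace` with attribute `dt`.
#' @examples
#' s <- stim_trace(rnorm(100), dt = 0.001)
#' @export
stim_trace <- function(x, dt = NULL, t0 = 0) {
  if (is.data.frame(x)) {
    stopifnot("time" %in% names(x))
    tb <- tibble::as_tibble(x)
    tt <- tb$time
    if (length(tt) < 1L) stop("stimulus trace must have at least one bin")
    if (length(tt) > 1L) {
      steps <- diff(tt)
      dt_est <- stats::median(steps)
      if (any(abs(steps - dt_est) > 1e-9 * max(dt_est, 1)))
        stop("non-uniform stimulus grid: bin spacing must be constant")
      if (!is.null(dt) && abs(dt - dt_est) > 1e-9 * dt)
        stop("supplied dt disagrees with the time column")
      dt <- dt_est
    } else if (is.null(dt)) {
      stop("dt is required for a single-bin trace")
    }
  } else {
    if (is.null(dt)) stop("dt is required when values are given as a vector or matrix")
    vals <- if (is.matrix(x)) x else matrix(x, ncol = 1L)
    if (nrow(vals) < 1L) stop("stimulus trace must have at least one bin")
    cn <- colnames(vals)
    if (is.null(cn)) cn <- if (ncol(vals) == 1L) "value" else paste0("value", seq_len(ncol(vals)))
    tb <- tibble::as_tibble(as.data.frame(vals, optional = TRUE), .name_repair = "minimal")
    names(tb) <- cn
    tb <- dplyr::bind_cols(tibble::tibble(time = t0 + (seq_len(nrow(vals)) - 1) * dt), tb)
  }
  if (dt <= 0) stop("dt must be positive")
  vals <- stim_values(tb)
  if (!all(is.finite(vals))) stop("stimulus values must be finite")
  attr(tb, "dt") <- dt
  class(tb) <- c("stim_trace", class(tibble::tibble()))
  tb
}

#' @export
print.stim_trace <- function(x, ...) {
  cat(sprintf("# stim_trace: %d bins x %d channel(s), dt = %g s, t0 = %g s\n",
              nrow(x), n_channels(x), stim_dt(x), x$time[1]))
  NextMethod()
}

#' Value matrix, bin width and channel count of a `stim_trace`
#'
#' @param x A `stim_trace`.
#' @return `stim_values()` the bins-by-channels numeric matrix; `stim_dt()` the
#'   bin width in seconds; `n_channels()` the channel count.
#' @export
stim_values <- function(x) {
  as.matrix(x[setdiff(names(x), "time")])
}

#' @rdname stim_values
#' @export
stim_dt <- function(x) {
  dt <- attr(x, "dt")
  if (is.null(dt)) dt <- stats::median(diff(x$time))
  dt
}

#' @rdname stim_values
#' @export
n_channels <- function(x) ncol(x) - 1L

#' Sparse, precisely timed response samples
#'
#' A `timed_samples` is a tibble with columns `time` (strictly increasing
#' acquisition times in seconds, one per sample) and `value`. The
#' `integration_time` attribute records the duration over which each value was
#' averaged (e.g. the voxel or line dwell time); `0` means an instantaneous
#' point sample.
#'
#' @param x A data frame with `time` and `value` columns, or a numeric vector
#'   of times (then `value` is required).
#' @param value Sample values when `x` is a time vector.
#' @param integration_time Averaging window of each sample, in seconds
#'   (default 0).
#'
#' @return A tibble of class `timed_samples`.
#' @export
timed_samples <- function(x, value = NULL, integration_time = 0) {
  if (is.data.frame(x)) {
    stopifnot(all(c("time", "value") %in% names(x)))
    tb <- tibble::as_tibble(x)[c("time", "value",
                                 setdiff(names(x), c("time", "value")))]
  } else {
    if (is.null(value)) stop("value is required when x is a vector of times")
    tb <- tibble::tibble(time = as.numeric(x), value = as.numeric(value))
  }
  if (nrow(tb) > 0 && any(diff(tb$time) <= 0))
    stop("sample times must be strictly increasing")
  if (!all(is.finite(tb$value))) stop("sample values must be finite")
  if (integration_time < 0) stop("integration_time must be >= 0")
  attr(tb, "integration_time") <- integration_time
  class(tb) <- c("timed_samples", class(tibble::tibble()))
  tb
}

#' @export
print.timed_samples <- function(x, ...) {
  cat(sprintf("# timed_samples: %d samples, integration_time = %g s\n",
              nrow(x), integration_time(x)))
  NextMethod()
}

#' @rdname timed_samples
#' @param samples A `timed_samples` object.
#' @export
integration_time <- function(samples) {
  it <- attr(samples, "integration_time")
  if (is.null(it)) 0 else it
}

#' Lag grid for filter estimates
#'
#' Lags are spaced exactly at the stimulus bin width `dt`. The sign convention
#' is that positive lags mean the stimulus *preceding* the response, so causal
#' filters live at `tau >= 0`; negative (acausal) lags index stimulus bins
#' after the sample time and are useful as a sanity check (a real causal system
#' should show nothing there).
#'
#' @param dt Lag spacing in seconds; must equal the stimulus bin width used in
#'   pairing.
#' @param n_causal Number of lags with `tau >= 0`.
#' @param n_acausal Number of lags with `tau < 0` (default 0).
#'
#' @return An object of class `lag_grid` with elements `taus` (ascending),
#'   `dt`, `n_causal`, `n_acausal`.
#' @examples
#' lag_grid(0.01, n_causal = 50, n_acausal = 10)
#' @export
lag_grid <- function(dt, n_causal, n_acausal = 0) {
  stopifnot(dt > 0, n_causal >= 0, n_acausal >= 0, n_causal + n_acausal >= 1)
  steps <- seq.int(-n_acausal, n_causal - 1L)
  structure(
    list(taus = steps * dt, steps = steps, dt = dt,
         n_causal = as.integer(n_causal), n_acausal = as.integer(n_acausal)),
    class = "lag_grid"
  )
}

#' @export
print.lag_grid <- function(x, ...) {
  cat(sprintf("# lag_grid: %d lags (%d causal, %d acausal), dt = %g s, range [%g, %g] s\n",
              length(x$taus), x$n_causal, x$n_acausal, x$dt, min(x$taus), max(x$taus)))
  invisible(x)
}

#' @export
length.lag_grid <- function(x) length(x$taus)

same_lag_grid <- function(a, b, tol = 1e-9) {
  length(a$taus) == length(b$taus) &&
    abs(a$dt - b$dt) <= tol * a$dt &&
    all(abs(a$taus - b$taus) <= tol * max(a$dt, 1))
}

#' Filter (receptive-field) estimate on a lag grid
#'
#' A `vt_filter` is a tibble with columns `lag` (seconds), `value`, and
#' optionally `se` (bootstrap standard error). The lag spacing always equals
#' the stimulus bin width, never the response sampling interval: this is the
#' defining property of the voxel-timing estimators. Attributes: `lags`
#' (the [lag_grid()]), `method` (estimator label) and `meta` (parameter list).
#'
#' @param values Numeric vector (or matrix, lags x channels) of filter values.
#' @param lags A [lag_grid()].
#' @param method Estimator label, e.g. `"xcorr"`, `"ols"`, `"asd"`.
#' @param se Optional per-lag standard errors (same shape as `values`).
#' @param meta Optional named list of estimator parameters.
#'
#' @return A tibble of class `vt_filter`.
#' @export
vt_filter <- function(values, lags, method = "custom", se = NULL, meta = list()) {
  stopifnot(inherits(lags, "lag_grid"))
  vals <- if (is.matrix(values)) values else matrix(as.numeric(values), ncol = 1L)
  if (nrow(vals) != length(lags$taus))
    stop("filter values must have one row per lag")
  if (!all(is.finite(vals))) stop("filter values must be finite")
  cn <- if (ncol(vals) == 1L) "value" else paste0("value", seq_len(ncol(vals)))
  tb <- tibble::tibble(lag = lags$taus)
  for (j in seq_len(ncol(vals))) tb[[cn[j]]] <- vals[, j]
  if (!is.null(se)) {
    sev <- if (is.matrix(se)) se else matrix(as.numeric(se), ncol = 1L)
    stopifnot(nrow(sev) == nrow(vals), all(sev >= 0 | is.na(sev)))
    sn <- if (ncol(sev) == 1L) "se" else paste0("se", seq_len(ncol(sev)))
    for (j in seq_len(ncol(sev))) tb[[sn[j]]] <- sev[, j]
  }
  attr(tb, "lags") <- lags
  attr(tb, "method") <- method
  attr(tb, "meta") <- meta
  class(tb) <- c("vt_filter", class(tibble::tibble()))
  tb
}

#' @export
print.vt_filter <- function(x, ...) {
  lg <- filter_lags(x)
  cat(sprintf("# vt_filter [%s]: %d lags, dt = %g s (positive lag = stimulus before response)\n",
              filter_method(x), length(lg$taus), lg$dt))
  NextMethod()
}

#' Accessors for `vt_filter` objects
#'
#' @param f A [vt_filter()].
#' @return `filter_values()` the numeric value vector (or matrix for
#'   multi-channel filters); `filter_lags()` the [lag_grid()];
#'   `filter_method()` the estimator label; `filter_meta()` the parameter list.
#' @export
filter_values <- function(f) {
  cols <- grep("^value", names(f), value = TRUE)
  v <- as.matrix(f[cols])
  if (ncol(v) == 1L) drop(v) else v
}

#' @rdname filter_values
#' @export
filter_lags <- function(f) attr(f, "lags")

#' @rdname filter_values
#' @export
filter_method <- function(f) attr(f, "method")

#' @rdname filter_values
#' @export
filter_meta <- function(f) attr(f, "meta")
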