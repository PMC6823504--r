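#' Pair response samples with their stimulus histories
#'
#' The heart of voxel-timing analysis: each response sample taken at time
#' `t_i` is paired with the vector of stimulus values at lags `tau` before it,
#' giving a design matrix `S` (samples x lags) and target `r`. Sample times are
#' mapped to stimulus bins by flooring `(t_i - t0)/dt`; ties at bin edges round
#' down. Samples whose lag window falls outside the stimulus record are dropped
#' (not zero-padded) and counted in `n_dropped`. Both the design columns and
#' the responses are mean-subtracted over the retained rows, with the means
#' stored so predictions can be un-centered.
#'
#' @param stim A [stim_trace()] (single channel for filter estimation; for
#'   multi-channel stimuli pair each channel via [selection_index()] or build
#'   pairs per channel).
#' @param samples A [timed_samples()].
#' @param lags A [lag_grid()] whose `dt` equals the stimulus bin width.
#' @param channel Stimulus channel to pair (default 1).
#' @param integrate If `TRUE`, each design entry is the overlap-weighted mean
#'   of the stimulus over the sample's integration window centred on
#'   `t_i - tau` (see [integrate_sample_window()]); the default `FALSE` takes a
#'   point sample at the window centre, appropriate when the integration time
#'   is short compared to the stimulus update.
#'
#' @return An object of class `vt_pairs`: a list with elements `S` (centered
#'   design matrix), `r` (centered responses), `lags`, `times` (retained sample
#'   times), `n_dropped`, and `means` (list with `stimulus` column means and
#'   `response` mean).
#' @examples
#' s <- stim_trace(rnorm(200), dt = 0.01)
#' y <- timed_samples(seq(0.5, 1.8, by = 0.1), rnorm(14))
#' p <- build_pairs(s, y, lag_grid(0.01, n_causal = 20))
#' @export
build_pairs <- function(stim, samples, lags, channel = 1L, integrate = FALSE) {
  stopifnot(inherits(stim, "stim_trace") || is.data.frame(stim))
  if (!inherits(stim, "stim_trace")) stim <- stim_trace(stim)
  stopifnot(inherits(lags, "lag_grid"))
  dt <- stim_dt(stim)
  if (abs(lags$dt - dt) > 1e-9 * dt)
    stop("lag grid spacing must equal the stimulus bin width dt")
  vals <- stim_values(stim)[, channel]
  n_bins <- length(vals)
  t0 <- stim$time[1]
  N <- nrow(samples)
  if (N == 0L) stop("no pairable samples: empty sample set")

  bins <- floor((samples$time - t0) / dt + 1e-9) + 1L  # 1-based bin index
  steps <- lags$steps
  # a row is retained iff bin - step is inside [1, n_bins] for every lag
  keep <- (bins - max(steps) >= 1L) & (bins - min(steps) <= n_bins)
  keep <- keep & bins >= 1L & bins <= n_bins
  n_dropped <- sum(!keep)
  if (!any(keep)) stop("no pairable samples: every sample lacks a complete stimulus history")

  kb <- bins[keep]
  L <- length(steps)
  if (integrate && integration_time(samples) > 0) {
    w <- integration_time(samples)
    tk <- samples$time[keep]
    S <- matrix(0, length(kb), L)
    for (j in seq_len(L)) {
      S[, j] <- window_means(vals, t0, dt, tk - steps[j] * dt, w)
    }
  } else {
    # S[i, j] = stimulus value in the bin containing (t_i - tau_j)
    S <- outer(kb, steps, function(b, s) vals[b - s])
  }
  r <- samples$value[keep]
  col_means <- colMeans(S)
  r_mean <- mean(r)
  structure(
    list(S = sweep(S, 2, col_means), r = r - r_mean, lags = lags,
         times = samples$time[keep], n_dropped = as.integer(n_dropped),
         means = list(stimulus = col_means, response = r_mean), dt = dt),
    class = "vt_pairs"
  )
}

#' @export
print.vt_pairs <- function(x, ...) {
  cat(sprintf("# vt_pairs: %d retained samples x %d lags (%d dropped for incomplete history)\n",
              nrow(x$S), ncol(x$S), x$n_dropped))
  invisible(x)
}

n_pairs <- function(pairs) nrow(pairs$S)

#' Construct a `vt_pairs` object directly
#'
#' Low-level constructor for an already-built (and, if desired, centered)
#' design. Useful for oracle tests and for estimating summary statistics whose
#' design is not a lagged stimulus (e.g. a column of ones to bootstrap a mean).
#'
#' @param S Numeric design matrix, samples x lags.
#' @param r Numeric response vector, `length(r) == nrow(S)`.
#' @param lags A [lag_grid()] with `length(lags) == ncol(S)`; defaults to unit
#'   causal lags.
#' @param times Optional sample times (defaults to row order).
#' @param center If `TRUE` (default `FALSE`), center columns of `S` and `r`.
#' @return A `vt_pairs` object.
#' @export
new_vt_pairs <- function(S, r, lags = NULL, times = NULL, center = FALSE) {
  S <- as.matrix(S)
  stopifnot(nrow(S) == length(r))
  if (is.null(lags)) lags <- lag_grid(1, n_causal = ncol(S))
  stopifnot(length(lags$taus) == ncol(S))
  if (is.null(times)) times <- seq_len(nrow(S))
  cm <- if (center) colMeans(S) else rep(0, ncol(S))
  rm_ <- if (center) mean(r) else 0
  structure(
    list(S = sweep(S, 2, cm), r = r - rm_, lags = lags, times = times,
         n_dropped = 0L, means = list(stimulus = cm, response = rm_),
         dt = lags$dt),
    class = "vt_pairs"
  )
}

#' Overlap-weighted mean of a stimulus over a time window
#'
#' Returns the mean of the stimulus over `[t - width/2, t + width/2]`, with
#' each bin weighted by its overlap with the window. `width = 0` reduces to
#' the value of the bin containing `t`. Supports modelling of finite voxel
#' integration times.
#'
#' @param stim A [stim_trace()].
#' @param t Window centre time (seconds).
#' @param width Window width (seconds, `>= 0`).
#' @param channel Stimulus channel (default 1).
#' @return The overlap-weighted mean stimulus value (scalar).
#' @export
integrate_sample_window <- function(stim, t, width, channel = 1L) {
  stopifnot(width >= 0)
  dt <- stim_dt(stim)
  vals <- stim_values(stim)[, channel]
  t0 <- stim$time[1]
  n <- length(vals)
  if (width == 0) {
    b <- floor((t - t0) / dt + 1e-9) + 1L
    if (b < 1L || b > n) stop("window outside the stimulus record")
    return(vals[b])
  }
  lo <- t - width / 2
  hi <- t + width / 2
  if (lo < t0 - 1e-12 || hi > t0 + n * dt + 1e-12)
    stop("window outside the stimulus record")
  b_lo <- max(1L, floor((lo - t0) / dt + 1e-9) + 1L)
  b_hi <- min(n, floor((hi - t0) / dt - 1e-9) + 1L)
  idx <- b_lo:b_hi
  bin_start <- t0 + (idx - 1L) * dt
  overlap <- pmin(hi, bin_start + dt) - pmax(lo, bin_start)
  sum(vals[idx] * overlap) / sum(overlap)
}

# vectorized overlap-weighted window means over a plain value vector
window_means <- function(vals, t0, dt, times, width) {
  n <- length(vals)
  if (width == 0) {
    b <- floor((times - t0) / dt + 1e-9) + 1L
    if (any(b < 1L | b > n)) stop("window outside the stimulus record")
    return(vals[b])
  }
  lo <- times - width / 2
  hi <- times + width / 2
  if (any(lo < t0 - 1e-12) || any(hi > t0 + n * dt + 1e-12))
    stop("window outside the stimulus record")
  b_lo <- pmax(1L, floor((lo - t0) / dt + 1e-9) + 1L)
  b_hi <- pmin(n, floor((hi - t0) / dt - 1e-9) + 1L)
  acc <- numeric(length(times))
  wsum <- numeric(length(times))
  for (k in 0:max(b_hi - b_lo)) {
    idx <- b_lo + k
    ok <- idx <= b_hi
    bin_start <- t0 + (idx - 1L) * dt
    w <- pmin(hi, bin_start + dt) - pmax(lo, bin_start)
    w[!ok] <- 0
    acc <- acc + vals[pmin(idx, n)] * w
    wsum <- wsum + w
  }
  acc / wsum
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a `vt_pairs` object into long format
#'
#' @param x A `vt_pairs` object.
#' @param ... Unused.
#' @return A tibble with columns `sample` (index), `time`, `lag`, `stimulus`
#'   (centered design value) and `response` (centered response).
#' @export
tidy.vt_pairs <- function(x, ...) {
  tibble::tibble(
    sample = rep(seq_len(nrow(x$S)), each = ncol(x$S)),
    time = rep(x$times, each = ncol(x$S)),
    lag = rep(x$lags$taus, nrow(x$S)),
    stimulus = as.vector(t(x$S)),
    response = rep(x$r, each = ncol(x$S))
  )
}

#' @rdname tidy.vt_pairs
#' @return `glance()` returns a one-row tibble with `n_kept`, `n_dropped`,
#'   `n_lags`, `dt`.
#' @export
glance.vt_pairs <- function(x, ...) {
  tibble::tibble(n_kept = nrow(x$S), n_dropped = x$n_dropped,
                 n_lags = ncol(x$S), dt = x$dt)
}
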