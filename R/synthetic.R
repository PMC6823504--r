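#' Canonical simulated temporal filters
#'
#' Families of causal temporal filters used throughout the simulation suite,
#' evaluated at lag-bin centres `t = (k + 1/2) * dt`, `k >= 0` (zero for
#' `t < 0`):
#' * `damped_osc`: `f(t) = (1/Z) exp(-t/tau1) sin(2 pi t / tau2)` — a damped
#'   oscillation (with the defaults `tau1 = 0.1`, `tau2 = 0.05` s it rings at
#'   20 Hz).
#' * `exponential`: `f(t) = exp(-t/tau1) / tau1`.
#' * `bilobed`: `f(t) = (1 - exp(-t/tau1)) * ((1/tau2) exp(-t/tau2) -
#'   (t/tau3^2) exp(-t/tau3))` — a biphasic kernel with a rise time.
#' * `custom`: values supplied directly via `params$values`.
#'
#' @param kind One of `"damped_osc"`, `"exponential"`, `"bilobed"`,
#'   `"custom"`.
#' @param params Named list of time constants in seconds (`tau1`, `tau2`,
#'   `tau3` as the family requires; `values` for `"custom"`).
#' @param dt Lag grid step in seconds.
#' @param length Number of causal lag bins.
#' @param normalize `"none"` or `"unit_mean_square"` (scale so that the mean
#'   squared value over the window is exactly 1).
#' @return A [vt_filter()] with `method = "true"` (causal lag grid).
#' @examples
#' f <- make_filter("damped_osc", list(tau1 = 0.1, tau2 = 0.05),
#'                  dt = 0.001, length = 400, normalize = "unit_mean_square")
#' @export
make_filter <- function(kind = c("damped_osc", "exponential", "bilobed", "custom"),
                        params = list(), dt, length,
                        normalize = c("none", "unit_mean_square")) {
  kind <- match.arg(kind)
  normalize <- match.arg(normalize)
  need <- function(p) {
    for (nm in p) if (is.null(params[[nm]]))
      stop(sprintf("filter kind '%s' requires parameter '%s'", kind, nm))
  }
  t <- (seq_len(length) - 0.5) * dt  # bin centres, all t >= 0 (causal)
  v <- switch(kind,
    damped_osc = {
      need(c("tau1", "tau2"))
      exp(-t / params$tau1) * sin(2 * pi * t / params$tau2)
    },
    exponential = {
      need("tau1")
      exp(-t / params$tau1) / params$tau1
    },
    bilobed = {
      need(c("tau1", "tau2", "tau3"))
      (1 - exp(-t / params$tau1)) *
        ((1 / params$tau2) * exp(-t / params$tau2) -
           (t / params$tau3^2) * exp(-t / params$tau3))
    },
    custom = {
      need("values")
      stopifnot(length(params$values) == length)
      as.numeric(params$values)
    }
  )
  if (normalize == "unit_mean_square") v <- v / sqrt(mean(v^2))
  vt_filter(v, lag_grid(dt, n_causal = length), method = "true",
            meta = list(kind = kind, params = params, normalize = normalize))
}

#' Generate a synthetic stimulus trace
#'
#' Reproducible stochastic stimuli on a uniform grid:
#' * `gaussian_white`: iid `N(0, 1)` per bin.
#' * `binary`: iid `+/- contrast` per bin (full-field flicker).
#' * `impulse_train`: unit impulses, either at a fixed spacing with a random
#'   phase (`spacing_mode = "fixed"`, the default) or as a Poisson train
#'   (`spacing_mode = "poisson"`), at the given `rate` (events/s).
#' * `sparse_onset`: iid 0/1 onset indicator per bin with probability
#'   `rate * dt`.
#'
#' @param kind Stimulus family (see above).
#' @param dt Bin width in seconds.
#' @param duration Total duration in seconds.
#' @param contrast Contrast for `binary` (default 0.9).
#' @param rate Event rate in events/s for `impulse_train` / `sparse_onset`.
#' @param spacing_mode `"fixed"` or `"poisson"` for `impulse_train`.
#' @param seed Integer seed; equal seeds give identical traces.
#' @return A [stim_trace()] starting at `t0 = 0`. Fixed-spacing impulse
#'   trains carry a `"period"` attribute (seconds) used by [sample_scheme()]
#'   to warn about phase-locked acquisition.
#' @export
generate_stimulus <- function(kind = c("gaussian_white", "binary",
                                       "impulse_train", "sparse_onset"),
                              dt, duration, contrast = 0.9, rate = 1,
                              spacing_mode = c("fixed", "poisson"),
                              seed = NULL) {
  kind <- match.arg(kind)
  spacing_mode <- match.arg(spacing_mode)
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration / dt)
  stopifnot(n >= 1)
  period <- NULL
  v <- switch(kind,
    gaussian_white = stats::rnorm(n),
    binary = sample(c(-contrast, contrast), n, replace = TRUE),
    impulse_train = {
      v <- numeric(n)
      if (spacing_mode == "fixed") {
        spacing <- max(1L, round(1 / (rate * dt)))
        phase <- sample.int(spacing, 1L)
        v[seq.int(phase, n, by = spacing)] <- 1
        period <- spacing * dt
      } else {
        n_ev <- stats::rpois(1L, rate * duration)
        if (n_ev > 0) v[unique(ceiling(stats::runif(n_ev) * n))] <- 1
      }
      v
    },
    sparse_onset = as.numeric(stats::runif(n) < rate * dt)
  )
  out <- stim_trace(v, dt = dt)
  if (!is.null(period)) attr(out, "period") <- period
  out
}

#' Simulate a dense linear response to a stimulus
#'
#' The dense response is the causal convolution of the stimulus with the
#' filter plus iid Gaussian noise whose standard deviation is set by the
#' signal-to-noise convention:
#' * `peak_over_sd`: `sd(noise) = max(|clean response|) / snr`.
#' * `sd_over_sd`: `sd(noise) = sd(clean response) / snr`.
#'
#' @param stim A [stim_trace()].
#' @param f A causal [vt_filter()] on the stimulus grid.
#' @param snr Positive signal-to-noise ratio; `Inf` (default) for a noiseless
#'   response.
#' @param convention `"peak_over_sd"` or `"sd_over_sd"`.
#' @param seed Optional integer seed for the noise stream.
#' @return A [stim_trace()] holding the dense response on the stimulus grid.
#' @export
simulate_response <- function(stim, f, snr = Inf,
                              convention = c("peak_over_sd", "sd_over_sd"),
                              seed = NULL) {
  convention <- match.arg(convention)
  stopifnot(inherits(stim, "stim_trace"), inherits(f, "vt_filter"))
  lg <- filter_lags(f)
  dt <- stim_dt(stim)
  if (abs(lg$dt - dt) > 1e-9 * dt) stop("stimulus and filter grids do not match")
  if (lg$n_acausal > 0L) stop("simulated filters must be causal")
  s <- stim_values(stim)[, 1L]
  fv <- filter_values(f)
  clean <- causal_convolve(s, fv)
  if (is.finite(snr)) {
    stopifnot(snr > 0)
    if (!is.null(seed)) set.seed(seed)
    noise_sd <- switch(convention,
      peak_over_sd = max(abs(clean)) / snr,
      sd_over_sd = stats::sd(clean) / snr
    )
    clean <- clean + stats::rnorm(length(clean), sd = noise_sd)
  }
  out <- stim_trace(clean, dt = dt, t0 = stim$time[1])
  attr(out, "period") <- attr(stim, "period")
  out
}

# zero-padded causal convolution: out[n] = sum_k f[k+1] * s[n - k]
causal_convolve <- function(s, f) {
  L <- length(f)
  xp <- c(rep(0, L - 1L), s)
  out <- as.numeric(stats::filter(xp, f, method = "convolution", sides = 1L))
  out[L:(L + length(s) - 1L)]
}

#' Sample a dense trace with an imaging acquisition scheme
#'
#' Emulates how scanning microscopy samples one ROI:
#' * `continuous`: every bin (value = bin value).
#' * `volumetric`: one sample per `frame_interval` at the ROI's phase within
#'   the volume, each value averaged over `integration_time` (overlap-weighted
#'   over bins); the ROI is revisited at the slow volume rate for the whole
#'   record.
#' * `plane_by_plane`: dense sampling at the fast plane rate
#'   (`frame_interval / n_planes`) for one contiguous block whose sample count
#'   equals what the matched volumetric acquisition would collect over the
#'   whole record, so designs can be compared at equal numbers of samples.
#'
#' @param dense A [stim_trace()] holding the dense response.
#' @param scheme `"volumetric"`, `"plane_by_plane"`, or `"continuous"`.
#' @param frame_interval Time between successive measurements of the same
#'   voxel (inverse volume rate), seconds.
#' @param integration_time Averaging window per sample, seconds
#'   (`<= frame_interval`).
#' @param phase Offset of this ROI's acquisition within the frame, in
#'   `[0, frame_interval)`, or `"random"`.
#' @param n_planes Number of planes per volume (`plane_by_plane`).
#' @param block_start Start time of the plane-by-plane block, or `"random"`.
#' @param seed Optional integer seed (random phase / block placement).
#' @return A [timed_samples()]; sample times are the centres of the
#'   integration windows.
#' @export
sample_scheme <- function(dense,
                          scheme = c("volumetric", "plane_by_plane", "continuous"),
                          frame_interval = NULL, integration_time = 0,
                          phase = 0, n_planes = NULL, block_start = "random",
                          seed = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(dense, "stim_trace"))
  dt <- stim_dt(dense)
  t0 <- dense$time[1]
  n <- nrow(dense)
  t_end <- t0 + n * dt
  if (!is.null(seed)) set.seed(seed)
  if (scheme == "continuous") {
    return(timed_samples(dense$time, stim_values(dense)[, 1L],
                         integration_time = dt))
  }
  stopifnot(!is.null(frame_interval), frame_interval > 0,
            integration_time >= 0, integration_time <= frame_interval)
  period <- attr(dense, "period")
  if (!is.null(period)) {
    k <- frame_interval / period
    if (abs(k - round(k)) < 1e-9 && round(k) >= 1)
      warning(paste("frame_interval is an integer multiple of the stimulus",
                    "repeat period: not all stimulus phases will be sampled"))
  }
  if (scheme == "volumetric") {
    if (identical(phase, "random")) phase <- stats::runif(1L, 0, frame_interval)
    stopifnot(phase >= 0, phase < frame_interval)
    k_max <- floor((t_end - integration_time / 2 - t0 - phase) /
                     frame_interval - 1e-9)
    if (k_max < 0) stop("record too short for the sampling scheme")
    times <- t0 + phase + (0:k_max) * frame_interval
    times <- times[times >= t0 + integration_time / 2]
    if (length(times) == 0L) stop("record too short for the sampling scheme")
    vals <- window_means(stim_values(dense)[, 1L], t0, dt, times,
                         integration_time)
    return(timed_samples(times, vals, integration_time = integration_time))
  }
  # plane_by_plane: fast dwell on one plane for a contiguous block
  stopifnot(!is.null(n_planes), n_planes >= 1)
  fast_interval <- frame_interval / n_planes
  if (integration_time > fast_interval)
    stop("integration_time exceeds the plane interval")
  n_match <- floor((t_end - integration_time - t0) / frame_interval - 1e-9) + 1L
  block_len <- (n_match - 1L) * fast_interval + integration_time
  if (block_len > n * dt) stop("matched block longer than the record")
  if (identical(block_start, "random")) {
    block_start <- t0 + stats::runif(1L, 0, n * dt - block_len - 1e-12)
  }
  times <- block_start + integration_time / 2 +
    (seq_len(n_match) - 1L) * fast_interval
  vals <- window_means(stim_values(dense)[, 1L], t0, dt, times,
                       integration_time)
  timed_samples(times, vals, integration_time = integration_time)
}

#' Simulate a cell whose receptive field flips sign over time
#'
#' Responses are `a(t) * (f * s)(t) + noise` where the amplitude `a(t)` is
#' piecewise constant over epochs of `epoch_length` seconds, drawn iid per
#' epoch: `+/-1` (default) or `N(0, 1)`. Because the receptive field's sign
#' changes throughout the simulation the first-order (mean) filter is zero
#' regardless of sampling rate, but the response-weighted stimulus covariance
#' recovers the field through its dominant eigenvector.
#'
#' @param stim A [stim_trace()].
#' @param f A causal [vt_filter()] on the stimulus grid; `epoch_length` must
#'   be at least the filter duration.
#' @param epoch_length Epoch duration in seconds.
#' @param snr,convention Noise level as in [simulate_response()].
#' @param amplitude `"sign"` (iid +/-1 per epoch) or `"gaussian"`.
#' @param seed Optional integer seed (amplitudes and noise).
#' @return A [stim_trace()] holding the dense modulated response.
#' @export
amplitude_modulated_cell <- function(stim, f, epoch_length, snr = Inf,
                                     convention = c("sd_over_sd", "peak_over_sd"),
                                     amplitude = c("sign", "gaussian"),
                                     seed = NULL) {
  convention <- match.arg(convention)
  amplitude <- match.arg(amplitude)
  stopifnot(inherits(stim, "stim_trace"), inherits(f, "vt_filter"))
  dt <- stim_dt(stim)
  lg <- filter_lags(f)
  if (epoch_length < length(lg$taus) * dt)
    stop("epoch_length must be at least the filter duration")
  if (!is.null(seed)) set.seed(seed)
  s <- stim_values(stim)[, 1L]
  clean <- causal_convolve(s, filter_values(f))
  n <- length(s)
  epoch_bins <- max(1L, round(epoch_length / dt))
  n_epochs <- ceiling(n / epoch_bins)
  a_ep <- switch(amplitude,
    sign = sample(c(-1, 1), n_epochs, replace = TRUE),
    gaussian = stats::rnorm(n_epochs)
  )
  a <- rep(a_ep, each = epoch_bins)[seq_len(n)]
  out <- a * clean
  if (is.finite(snr)) {
    stopifnot(snr > 0)
    noise_sd <- switch(convention,
      peak_over_sd = max(abs(clean)) / snr,
      sd_over_sd = stats::sd(clean) / snr
    )
    out <- out + stats::rnorm(n, sd = noise_sd)
  }
  stim_trace(out, dt = dt, t0 = stim$time[1])
}
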