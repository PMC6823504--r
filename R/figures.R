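#' Regenerate the package's demonstration analyses end to end
#'
#' Self-contained synthetic demonstrations of the voxel-timing method, each
#' returning the objects and a ggplot:
#' * `"impulse"`: a 20 Hz damped-oscillation response sampled 1 ms every
#'   100 ms under Gaussian white noise stimulation; the cross-correlation
#'   recovers the filter at 1 ms resolution.
#' * `"exponential"`: noiseless exponential-filter system sampled every 10
#'   steps; voxel-timing OLS recovers the filter exactly while interpolation
#'   does not.
#' * `"noise"`: bilobed filter at SNR 1 sampled 10 ms every 500 ms;
#'   interpolation variants, smoothing, Laguerre and ASD regularization.
#' * `"secondorder"`: a sign-modulated cell whose mean filter vanishes but
#'   whose response-weighted covariance eigenvector recovers the field.
#' * `"schemes"`: volumetric versus plane-by-plane sampling at matched sample
#'   counts under AR(1) noise.
#'
#' @param which Demonstration name (see above).
#' @param seed Integer seed.
#' @param n_samples Approximate number of response samples to simulate
#'   (default scales per demonstration).
#' @return A list with the inputs, fitted filters and a `plot` element.
#' @export
run_demo <- function(which = c("impulse", "exponential", "noise",
                               "secondorder", "schemes"),
                     seed = 1L, n_samples = NULL) {
  which <- match.arg(which)
  set.seed(seed)
  switch(which,
    impulse = demo_impulse(seed, n_samples %||% 10000L),
    exponential = demo_exponential(seed, n_samples %||% 500L),
    noise = demo_noise(seed, n_samples %||% 600L),
    secondorder = demo_secondorder(seed, n_samples %||% 20000L),
    schemes = demo_schemes(seed)
  )
}

demo_impulse <- function(seed, n_samples) {
  dt <- 0.001
  truth <- make_filter("damped_osc", list(tau1 = 0.1, tau2 = 0.05),
                       dt = dt, length = 400L, normalize = "unit_mean_square")
  dur <- n_samples * 0.1 + 1
  s <- generate_stimulus("gaussian_white", dt = dt, duration = dur, seed = seed)
  dense <- simulate_response(s, truth, snr = 60, convention = "peak_over_sd",
                             seed = seed + 1L)
  samp <- sample_scheme(dense, "volumetric", frame_interval = 0.1,
                        integration_time = 0.001, phase = 0.5)
  lags <- lag_grid(dt, n_causal = 400L)
  p <- build_pairs(s, samp, lags)
  est <- vt_xcorr(p)
  list(truth = truth, stimulus = s, samples = samp, estimate = est,
       correlation = stats::cor(filter_values(est), filter_values(truth)),
       peak_frequency_hz = dominant_frequency(est),
       plot = autoplot(est, truth = truth))
}

demo_exponential <- function(seed, n_samples) {
  dt <- 1
  truth <- make_filter("exponential", list(tau1 = 10), dt = dt, length = 60L)
  dur <- n_samples * 10 + 100
  s <- generate_stimulus("gaussian_white", dt = dt, duration = dur, seed = seed)
  dense <- simulate_response(s, truth, snr = Inf)
  samp <- sample_scheme(dense, "volumetric", frame_interval = 10, phase = 0)
  lags <- lag_grid(dt, n_causal = 60L)
  p <- build_pairs(s, samp, lags)
  vox <- vt_ols(p)
  interp <- vt_interp_filter(s, samp, lags, method = "linear")
  list(truth = truth, stimulus = s, samples = samp,
       estimate = vox, interpolated = interp,
       max_abs_error = max(abs(filter_values(vox) - filter_values(truth))),
       plot = autoplot(vox, interpolated = interp, truth = truth))
}

demo_noise <- function(seed, n_samples) {
  dt <- 0.01
  truth <- make_filter("bilobed", list(tau1 = 0.02, tau2 = 0.1, tau3 = 0.2),
                       dt = dt, length = 70L)
  dur <- n_samples * 0.5 + 2
  s <- generate_stimulus("gaussian_white", dt = dt, duration = dur, seed = seed)
  dense <- simulate_response(s, truth, snr = 1, convention = "sd_over_sd",
                             seed = seed + 1L)
  samp <- sample_scheme(dense, "volumetric", frame_interval = 0.5,
                        integration_time = 0.01, phase = 0.75)
  lags <- lag_grid(dt, n_causal = 70L)
  p <- build_pairs(s, samp, lags)
  ols <- vt_ols(p)
  smoothed <- smooth_filter(ols, gaussian_kernel(0.02, dt))
  lag5 <- vt_laguerre(p, n_funcs = 5, alpha = 0.7)
  asd <- vt_asd(p)
  interp <- vt_interp_filter(s, samp, lags, method = "linear")
  list(truth = truth, stimulus = s, samples = samp,
       pairs = p, ols = ols, smoothed = smoothed,
       laguerre = lag5, asd = asd, interpolated = interp,
       errors = tibble::tibble(
         estimator = c("ols", "smoothed", "laguerre", "asd", "interp"),
         rms_error = vapply(list(ols, smoothed, lag5, asd, interp),
                            filter_rms_error, numeric(1), truth = truth)),
       plot = autoplot(ols, smoothed = smoothed, laguerre = lag5,
                       asd = asd, truth = truth))
}

demo_secondorder <- function(seed, n_samples) {
  dt <- 0.01
  truth <- make_filter("damped_osc", list(tau1 = 0.08, tau2 = 0.06),
                       dt = dt, length = 30L, normalize = "unit_mean_square")
  dur <- n_samples * 0.05 + 2
  s <- generate_stimulus("gaussian_white", dt = dt, duration = dur, seed = seed)
  dense <- amplitude_modulated_cell(s, truth, epoch_length = 0.5, snr = 4,
                                    seed = seed + 1L)
  samp <- sample_scheme(dense, "volumetric", frame_interval = 0.05,
                        integration_time = 0, phase = 0.033)
  lags <- lag_grid(dt, n_causal = 30L)
  p <- build_pairs(s, samp, lags)
  first_order <- bootstrap_se(p, "xcorr", n_boot = 200, seed = seed)
  cov <- response_weighted_covariance(p)
  ev1 <- covariance_eigenfilter(cov, 1L)
  list(truth = truth, stimulus = s, samples = samp,
       first_order = first_order, covariance = cov,
       eigenfilter = ev1,
       eigen_correlation = stats::cor(filter_values(ev1),
                                      filter_values(truth)),
       plot = autoplot(ev1, first_order = first_order, truth = truth))
}

demo_schemes <- function(seed) {
  dt <- 1 / 30
  truth <- make_filter("bilobed", list(tau1 = 0.05, tau2 = 0.15, tau3 = 0.3),
                       dt = dt, length = 24L)
  rep_ar1 <- compare_schemes(truth, lag_grid(dt, n_causal = 24L),
                             n_cells = 12, duration = 240,
                             frame_interval = 0.5, n_planes = 15,
                             snr = 1, noise = "ar1", seed = seed)
  list(report = rep_ar1, summary = glance(rep_ar1), plot = autoplot(rep_ar1))
}

#' Dominant frequency of a filter estimate
#'
#' Frequency (Hz) at the maximum of the filter's power spectrum, computed by
#' zero-padded FFT of the causal part so the spectral resolution is about
#' 1 Hz regardless of kernel length.
#'
#' @param f A [vt_filter()].
#' @param pad_to Zero-padded FFT length (default at least `1/dt` bins for
#'   ~1 Hz resolution).
#' @return Peak frequency in Hz.
#' @export
dominant_frequency <- function(f, pad_to = NULL) {
  lg <- filter_lags(f)
  v <- filter_values(f)[lg$taus >= -1e-12]
  dt <- lg$dt
  if (is.null(pad_to)) pad_to <- max(2L * length(v), 2^ceiling(log2(1 / dt)))
  x <- c(v - mean(v), rep(0, pad_to - length(v)))
  pw <- Mod(stats::fft(x))^2
  half <- seq_len(floor(pad_to / 2))
  freqs <- (half - 1) / (pad_to * dt)
  freqs[which.max(pw[half])]
}
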