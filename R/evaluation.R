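#' Bias-corrected bootstrap standard errors for a filter estimate
#'
#' Resamples rows of the paired design `(S, r)` with replacement, re-estimates
#' the filter on each replicate, and reports per-lag bias-corrected (BC)
#' 1-SEM intervals: the interval endpoints are the bootstrap quantiles at
#' `pnorm(2 z0 -/+ 1)` where `z0` corrects for median bias, and the reported
#' `se` is half the interval width. Replicates on which the estimator fails
#' are dropped and counted. Seeded and reproducible; invariant to the row
#' order of the pair set.
#'
#' @param pairs A [build_pairs()] result.
#' @param estimator `"xcorr"`, `"ols"`, `"ridge"`, `"laguerre"`, or `"asd"`
#'   (ASD replicates reuse hyperparameters fitted once on the full data unless
#'   `estimator_args$refit = TRUE`).
#' @param n_boot Number of bootstrap replicates (>= 100).
#' @param seed Integer seed.
#' @param estimator_args Named list of extra arguments for the estimator.
#' @return The point-estimate [vt_filter()] with an `se` column;
#'   `filter_meta()` gains `n_boot`, `n_failed`, and the BC interval bounds
#'   `boot_lo` / `boot_hi` (matrices lags x 1).
#' @export
bootstrap_se <- function(pairs, estimator = "xcorr", n_boot = 1000,
                         seed = 1L, estimator_args = list()) {
  stopifnot(inherits(pairs, "vt_pairs"), n_boot >= 100)
  est_fun <- make_estimator(estimator, pairs, estimator_args)
  hat_f <- est_fun(pairs)
  hat <- filter_values(hat_f)
  N <- n_pairs(pairs)
  L <- length(hat)
  set.seed(seed)
  reps <- matrix(NA_real_, n_boot, L)
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(N, N, replace = TRUE)
    # resampled rows keep the centering of the full pair set
    bp <- new_vt_pairs(pairs$S[idx, , drop = FALSE], pairs$r[idx],
                       lags = pairs$lags, times = pairs$times[idx])
    fb <- tryCatch(filter_values(est_fun(bp)), error = function(e) NULL)
    if (is.null(fb)) n_failed <- n_failed + 1L else reps[b, ] <- fb
  }
  reps <- reps[stats::complete.cases(reps), , drop = FALSE]
  if (nrow(reps) < 2L) stop("too few successful bootstrap replicates")
  lo <- hi <- se <- numeric(L)
  alpha <- stats::pnorm(-1)  # 1-SEM coverage
  for (j in seq_len(L)) {
    rj <- reps[, j]
    if (stats::sd(rj) == 0) { lo[j] <- hi[j] <- hat[j]; se[j] <- 0; next }
    p_less <- (sum(rj < hat[j]) + 0.5 * sum(rj == hat[j])) / length(rj)
    z0 <- stats::qnorm(min(max(p_less, 1 / (2 * length(rj))),
                           1 - 1 / (2 * length(rj))))
    lo[j] <- stats::quantile(rj, stats::pnorm(2 * z0 - 1), names = FALSE, type = 6)
    hi[j] <- stats::quantile(rj, stats::pnorm(2 * z0 + 1), names = FALSE, type = 6)
    se[j] <- (hi[j] - lo[j]) / 2
  }
  vt_filter(hat, pairs$lags, method = filter_method(hat_f), se = se,
            meta = c(filter_meta(hat_f),
                     list(n_boot = nrow(reps), n_failed = n_failed,
                          boot_lo = lo, boot_hi = hi, boot_seed = seed)))
}

make_estimator <- function(estimator, pairs, args) {
  if (is.function(estimator)) return(estimator)
  switch(estimator,
    xcorr = function(p) vt_xcorr(p),
    ols = function(p) do.call(vt_ols, c(list(p), args)),
    ridge = function(p) vt_ols(p, ridge = args$ridge %||% 1e-3),
    laguerre = function(p) do.call(vt_laguerre, c(list(p), args)),
    asd = {
      if (isTRUE(args$refit)) {
        function(p) vt_asd(p)
      } else {
        full <- vt_asd(pairs)
        hyper <- filter_meta(full)[c("sigma2", "rho", "delta")]
        function(p) vt_asd(p, hyper = hyper)
      }
    },
    stop(sprintf("unknown estimator '%s'", estimator))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Scaled RMS error between a filter and a reference
#'
#' Root-mean-squared deviation of the estimate from the reference filter,
#' divided by the maximum value of the reference — a scale-free error used to
#' compare estimates across cells and sampling designs.
#'
#' @param f,reference [vt_filter()] objects on identical lag grids.
#' @return A non-negative scalar.
#' @export
scaled_error <- function(f, reference) {
  stopifnot(inherits(f, "vt_filter"), inherits(reference, "vt_filter"))
  if (!same_lag_grid(filter_lags(f), filter_lags(reference)))
    stop("filters must share the same lag grid")
  ref <- filter_values(reference)
  mx <- max(ref)
  if (mx == 0) stop("reference filter has zero maximum; scaled error undefined")
  sqrt(mean((filter_values(f) - ref)^2)) / mx
}

#' Filter-estimate error versus number of samples
#'
#' Runs the full synthetic pipeline (stimulus -> dense response -> sparse
#' sampling -> pairing -> estimation) at each requested sample count, with
#' `n_reps` fresh realizations per count, and fits the log-log slope of mean
#' RMS error (to the true filter) against sample count. For an estimate that
#' is limited by measurement noise the expected slope is `-1/2` — each
#' response sample contributes one stimulus-response pair, so errors shrink
#' like `N^(-1/2)`.
#'
#' @param true_filter The generating [vt_filter()].
#' @param lags [lag_grid()] for estimation.
#' @param n_values Sample counts (>= 4 values spanning at least a decade for
#'   a meaningful slope).
#' @param n_reps Realizations per count.
#' @param frame_interval,integration_time Sampling scheme parameters
#'   (see [sample_scheme()]).
#' @param snr,convention Noise level (see [simulate_response()]).
#' @param stim_kind Stimulus family for [generate_stimulus()].
#' @param estimator Estimator label as in [bootstrap_se()].
#' @param estimator_args Extra estimator arguments.
#' @param seed Integer seed.
#' @return A list with `table` (tibble: `n`, `mean_error`, `sd_error`),
#'   `slope`, `slope_se`; `slope` is `NA` with a note when errors sit at
#'   machine precision (noiseless degenerate case).
#' @export
error_vs_n <- function(true_filter, lags, n_values, n_reps = 20,
                       frame_interval, integration_time = 0,
                       snr = 1, convention = "sd_over_sd",
                       stim_kind = "gaussian_white",
                       estimator = "xcorr", estimator_args = list(),
                       seed = 1L) {
  stopifnot(length(n_values) >= 2)
  dt <- filter_lags(true_filter)$dt
  burn <- (length(lags$taus) + 2) * dt
  set.seed(seed)
  rows <- purrr::map_dfr(sort(n_values), function(nv) {
    errs <- vapply(seq_len(n_reps), function(rep) {
      dur <- burn + nv * frame_interval + frame_interval
      s <- generate_stimulus(stim_kind, dt = dt, duration = dur)
      dense <- simulate_response(s, true_filter, snr = snr,
                                 convention = convention)
      samp <- sample_scheme(dense, "volumetric",
                            frame_interval = frame_interval,
                            integration_time = integration_time,
                            phase = (burn + integration_time / 2) %% frame_interval)
      keep <- which(samp$time >= burn)[seq_len(nv)]
      samp <- timed_samples(samp$time[keep], samp$value[keep],
                            integration_time = integration_time)
      p <- build_pairs(s, samp, lags)
      est <- make_estimator(estimator, p, estimator_args)(p)
      filter_rms_error(est, true_filter)
    }, numeric(1))
    tibble::tibble(n = nv, mean_error = mean(errs), sd_error = stats::sd(errs))
  })
  if (max(rows$mean_error) < 1e-10) {
    return(list(table = rows, slope = NA_real_, slope_se = NA_real_,
                note = "errors at machine precision; slope undefined"))
  }
  fit <- stats::lm(log(mean_error) ~ log(n), data = rows)
  list(table = rows, slope = unname(stats::coef(fit)[2]),
       slope_se = summary(fit)$coefficients[2, 2])
}

# RMS deviation on the overlap of the two lag grids (the estimation grid may
# include acausal lags absent from the true causal filter, where truth = 0)
filter_rms_error <- function(est, truth) {
  et <- filter_lags(est)$taus
  tt <- filter_lags(truth)$taus
  tv <- filter_values(truth)
  ev <- filter_values(est)
  truth_on_est <- vapply(et, function(tau) {
    k <- which(abs(tt - tau) < 1e-9 * max(filter_lags(truth)$dt, 1e-12))
    if (length(k) == 1L) tv[k] else 0
  }, numeric(1))
  sqrt(mean((ev - truth_on_est)^2))
}

#' Autocorrelation of prediction residuals at sample lags
#'
#' Orders the residuals `r_i - S[i, ] %*% f` by sample time and returns their
#' normalized autocorrelation at integer sample-lags `0..max_lag` (lag 0 is
#' exactly 1). Correlated residuals between neighbouring samples are the
#' mechanism by which fast plane-by-plane sampling loses fidelity relative to
#' slow volumetric sampling.
#'
#' @param pairs A [build_pairs()] result.
#' @param f A [vt_filter()] on the pair set's lag grid.
#' @param max_lag Maximum sample-lag (needs at least `max_lag + 2` samples).
#' @return Numeric vector of length `max_lag + 1`.
#' @export
residual_autocorrelation <- function(pairs, f, max_lag) {
  stopifnot(inherits(pairs, "vt_pairs"), inherits(f, "vt_filter"))
  if (!same_lag_grid(filter_lags(f), pairs$lags))
    stop("filter and pair set lag grids differ")
  N <- n_pairs(pairs)
  if (N < max_lag + 2L) stop("too few samples for the requested max_lag")
  res <- pairs$r - drop(pairs$S %*% filter_values(f))
  res <- res[order(pairs$times)]
  ac <- stats::acf(res, lag.max = max_lag, plot = FALSE, demean = TRUE)
  drop(ac$acf)
}

#' Cohen's d for paired differences
#'
#' `mean(x - y) / sd(x - y)`: the paired effect size used to compare sampling
#' designs cell by cell.
#'
#' @param x,y Paired numeric vectors.
#' @return A scalar (positive when `x` exceeds `y` on average).
#' @export
cohens_d_paired <- function(x, y) {
  d <- x - y
  mean(d) / stats::sd(d)
}

#' Compare volumetric and plane-by-plane sampling designs
#'
#' For each simulated cell, draws a fresh stimulus and noisy dense response,
#' samples it both volumetrically (slow revisits over the whole record) and
#' plane-by-plane (fast dwell in one contiguous block, matched sample count),
#' estimates the filter by raw OLS, OLS followed by low-pass smoothing, and
#' ASD, and scores each estimate by [scaled_error()] against the generating
#' filter. Measurement noise may be white or AR(1)-correlated at the fast
#' plane rate: correlated noise makes neighbouring plane-by-plane samples
#' redundant, which smoothing and ASD exploit in the volumetric design but
#' cannot repair in the plane-by-plane design.
#'
#' @param true_filter Generating [vt_filter()].
#' @param lags Estimation [lag_grid()].
#' @param n_cells Number of simulated cells.
#' @param duration Record duration per cell, seconds.
#' @param frame_interval Volume revisit interval, seconds.
#' @param n_planes Planes per volume (fast rate = `n_planes / frame_interval`).
#' @param snr Signal-to-noise (sd over sd).
#' @param noise `"ar1"` or `"white"`; `ar1_corr` is the residual correlation
#'   between neighbouring fast-rate samples.
#' @param ar1_corr AR(1) correlation at the fast sampling interval.
#' @param lowpass_hz Cutoff of the smoothing applied in the "smoothed"
#'   estimator, Hz.
#' @param seed Integer seed.
#' @return A tibble of class `vt_error_report` with columns `cell`, `scheme`,
#'   `estimator`, `scaled_error`; `glance()` gives per-estimator Cohen's d
#'   (plane-by-plane minus volumetric; positive favours volumetric) and
#'   paired Wilcoxon signed-rank p-values.
#' @export
compare_schemes <- function(true_filter, lags, n_cells = 20,
                            duration = 300, frame_interval = 0.5,
                            n_planes = 15, snr = 1,
                            noise = c("ar1", "white"), ar1_corr = 0.8,
                            lowpass_hz = 7.5, seed = 1L) {
  noise <- match.arg(noise)
  dt <- filter_lags(true_filter)$dt
  fast_interval <- frame_interval / n_planes
  set.seed(seed)
  cell_seeds <- sample.int(.Machine$integer.max, n_cells)
  rows <- purrr::map_dfr(seq_len(n_cells), function(cell) {
    set.seed(cell_seeds[cell])
    s <- generate_stimulus("gaussian_white", dt = dt, duration = duration)
    clean <- simulate_response(s, true_filter, snr = Inf)
    cv <- stim_values(clean)[, 1L]
    noise_sd <- stats::sd(cv) / snr
    eps <- if (noise == "white") {
      stats::rnorm(length(cv), sd = noise_sd)
    } else {
      # AR(1) on the stimulus grid with the target correlation at the fast
      # sampling interval; neighbouring volumetric samples are ~independent
      phi <- ar1_corr^(dt / fast_interval)
      as.numeric(stats::arima.sim(list(ar = phi), n = length(cv),
                                  sd = noise_sd * sqrt(1 - phi^2)))
    }
    dense <- stim_trace(cv + eps, dt = dt, t0 = clean$time[1])
    burn <- (length(lags$taus) + 2) * dt
    vol <- sample_scheme(dense, "volumetric", frame_interval = frame_interval,
                         integration_time = 0,
                         phase = burn %% frame_interval)
    pbp <- sample_scheme(dense, "plane_by_plane",
                         frame_interval = frame_interval,
                         integration_time = 0, n_planes = n_planes,
                         block_start = "random")
    n_use <- min(nrow(vol), nrow(pbp))
    per_scheme <- function(samples, label) {
      samples <- timed_samples(samples$time[seq_len(n_use)],
                               samples$value[seq_len(n_use)])
      p <- build_pairs(dense_stim_for(s), samples, lags)
      f_ols <- vt_ols(p)
      f_sm <- smooth_filter(f_ols, lowpass_kernel(lowpass_hz, dt))
      f_asd <- vt_asd(p)
      tibble::tibble(
        cell = cell, scheme = label,
        estimator = c("ols", "ols_lowpass", "asd"),
        scaled_error = c(scaled_error(f_ols, true_filter),
                         scaled_error(f_sm, true_filter),
                         scaled_error(f_asd, true_filter))
      )
    }
    dplyr::bind_rows(per_scheme(vol, "volumetric"),
                     per_scheme(pbp, "plane_by_plane"))
  })
  class(rows) <- c("vt_error_report", class(rows))
  attr(rows, "noise") <- noise
  rows
}

dense_stim_for <- function(s) s  # pairing always uses the stimulus record

#' @rdname tidy.vt_pairs
#' @export
glance.vt_error_report <- function(x, ...) {
  wide <- tidyr::pivot_wider(tibble::as_tibble(x),
                             names_from = "scheme",
                             values_from = "scaled_error")
  dplyr::group_by(wide, .data$estimator) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      mean_volumetric = mean(.data$volumetric),
      mean_plane_by_plane = mean(.data$plane_by_plane),
      cohens_d = cohens_d_paired(.data$plane_by_plane, .data$volumetric),
      p_signed_rank = stats::wilcox.test(.data$plane_by_plane,
                                         .data$volumetric,
                                         paired = TRUE, exact = FALSE)$p.value
    )
}

#' Stimulus-correlation selection index for responsive cells
#'
#' For every stimulus pixel, sums over lags the Pearson correlation between
#' the pixel's lagged stimulus and the response samples, yielding one index
#' per pixel; a cell is selected when the maximum pixel index strictly
#' exceeds the threshold (default 1).
#'
#' @param stim A multi-channel [stim_trace()] (one column per pixel).
#' @param samples A [timed_samples()].
#' @param lags A [lag_grid()].
#' @param threshold Selection threshold (strict `>`; default 1).
#' @return A tibble with columns `pixel`, `index`; attributes `max_index` and
#'   `selected` (logical).
#' @export
selection_index <- function(stim, samples, lags, threshold = 1) {
  stopifnot(inherits(stim, "stim_trace"))
  channels <- setdiff(names(stim), "time")
  idx <- vapply(seq_along(channels), function(ch) {
    p <- build_pairs(stim, samples, lags, channel = ch)
    if (stats::sd(p$r) == 0) return(0)
    cors <- apply(p$S, 2L, function(col) {
      if (stats::sd(col) == 0) 0 else stats::cor(col, p$r)
    })
    sum(cors)
  }, numeric(1))
  out <- tibble::tibble(pixel = channels, index = idx)
  attr(out, "max_index") <- max(idx)
  attr(out, "selected") <- max(idx) > threshold
  out
}
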