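# Small synthetic fixtures shared across test files. Everything is generated
# in code under fixed seeds; no data files.

# white-stimulus linear system with regular sparse sampling
make_linear_system <- function(n_bins = 4000, dt = 1, tau = 8, flen = 30,
                               sample_every = 10, snr = Inf, seed = 11,
                               phase = 0) {
  set.seed(seed)
  truth <- make_filter("exponential", list(tau1 = tau), dt = dt, length = flen)
  s <- generate_stimulus("gaussian_white", dt = dt, duration = n_bins * dt)
  dense <- simulate_response(s, truth, snr = snr, convention = "sd_over_sd")
  samp <- sample_scheme(dense, "volumetric", frame_interval = sample_every * dt,
                        phase = phase)
  list(truth = truth, stim = s, dense = dense, samples = samp, dt = dt)
}

# brute-force pairing oracle: direct double loop over samples and lags
oracle_pairs <- function(stim_values, t0, dt, times, values, steps) {
  bins <- floor((times - t0) / dt + 1e-9) + 1
  keep <- bins - max(steps) >= 1 & bins - min(steps) <= length(stim_values)
  S <- matrix(NA_real_, sum(keep), length(steps))
  kb <- bins[keep]
  for (i in seq_along(kb)) {
    for (j in seq_along(steps)) S[i, j] <- stim_values[kb[i] - steps[j]]
  }
  list(S = S, r = values[keep], n_dropped = sum(!keep))
}

rel_rms <- function(a, b) sqrt(mean((a - b)^2)) / sqrt(mean(b^2))

`%||%` <- function(a, b) if (is.null(a)) b else a
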