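test_that("filter formulas evaluate correctly at bin centres and are causal", {
  # exponential: f(0.5) = exp(-0.05)/10 for tau1 = 10, dt = 1
  f <- make_filter("exponential", list(tau1 = 10), dt = 1, length = 5)
  expect_equal(filter_values(f)[1], exp(-0.05) / 10, tolerance = 1e-14)
  expect_equal(filter_values(f),
               exp(-((1:5) - 0.5) / 10) / 10, tolerance = 1e-14)
  expect_equal(filter_lags(f)$n_acausal, 0L)

  # bilobed vanishes at the origin like (1 - e^0) = 0
  g <- function(t) (1 - exp(-t / 0.02)) *
    ((1 / 0.1) * exp(-t / 0.1) - (t / 0.2^2) * exp(-t / 0.2))
  fb <- make_filter("bilobed", list(tau1 = 0.02, tau2 = 0.1, tau3 = 0.2),
                    dt = 0.01, length = 70)
  expect_equal(filter_values(fb), g((1:70 - 0.5) * 0.01), tolerance = 1e-14)
  expect_equal(g(0), 0)

  # damped oscillation with unit mean square normalization
  fo <- make_filter("damped_osc", list(tau1 = 0.1, tau2 = 0.05),
                    dt = 0.001, length = 400, normalize = "unit_mean_square")
  expect_equal(mean(filter_values(fo)^2), 1, tolerance = 1e-10)
  raw <- exp(-((1:400 - 0.5) * 0.001) / 0.1) *
    sin(2 * pi * ((1:400 - 0.5) * 0.001) / 0.05)
  expect_equal(filter_values(fo), raw / sqrt(mean(raw^2)), tolerance = 1e-12)

  expect_error(make_filter("damped_osc", list(tau1 = 0.1), dt = 1, length = 10),
               "tau2")
})

test_that("stimulus generators are reproducible and respect their families", {
  a <- generate_stimulus("gaussian_white", dt = 0.01, duration = 5, seed = 41)
  b <- generate_stimulus("gaussian_white", dt = 0.01, duration = 5, seed = 41)
  expect_identical(stim_values(a), stim_values(b))

  bin <- generate_stimulus("binary", dt = 1 / 120, duration = 10,
                           contrast = 0.9, seed = 42)
  expect_setequal(unique(stim_values(bin)[, 1]), c(-0.9, 0.9))

  gw <- generate_stimulus("gaussian_white", dt = 0.001, duration = 200,
                          seed = 43)
  v <- stim_values(gw)[, 1]
  expect_lt(abs(mean(v)), 4 / sqrt(length(v)))
  expect_lt(abs(var(v) - 1), 0.01)

  it <- generate_stimulus("impulse_train", dt = 0.01, duration = 20,
                          rate = 2, seed = 44)
  iv <- stim_values(it)[, 1]
  expect_setequal(unique(iv), c(0, 1))
  expect_equal(unique(diff(which(iv == 1))), 50)   # fixed spacing at rate 2
  expect_equal(attr(it, "period"), 0.5)

  so <- generate_stimulus("sparse_onset", dt = 1 / 30, duration = 400,
                          rate = 1, seed = 45)
  sv <- stim_values(so)[, 1]
  expect_true(all(sv %in% c(0, 1)))
  expect_equal(mean(sv), 1 / 30, tolerance = 0.15)
})

test_that("simulated responses honour noise conventions and convolution", {
  truth <- make_filter("exponential", list(tau1 = 5), dt = 1, length = 25)
  s <- generate_stimulus("gaussian_white", dt = 1, duration = 30000, seed = 46)
  clean <- simulate_response(s, truth, snr = Inf)

  # sd-over-sd convention: noise SD equals clean SD within 2 percent
  noisy <- simulate_response(s, truth, snr = 1, convention = "sd_over_sd",
                             seed = 47)
  noise <- stim_values(noisy)[, 1] - stim_values(clean)[, 1]
  expect_equal(sd(noise) / sd(stim_values(clean)[, 1]), 1, tolerance = 0.02)

  # peak-over-sd convention
  noisy2 <- simulate_response(s, truth, snr = 60, convention = "peak_over_sd",
                              seed = 48)
  noise2 <- stim_values(noisy2)[, 1] - stim_values(clean)[, 1]
  expect_equal(sd(noise2), max(abs(stim_values(clean)[, 1])) / 60,
               tolerance = 0.02)

  # an isolated impulse reproduces the filter shape at the impulse offset
  imp <- numeric(100); imp[40] <- 1
  si <- stim_trace(imp, dt = 1)
  ri <- stim_values(simulate_response(si, truth, snr = Inf))[, 1]
  expect_equal(ri[40:64], filter_values(truth), tolerance = 1e-12)
  expect_true(all(ri[1:39] == 0))
})

test_that("sampling schemes produce the documented times and counts", {
  dense <- stim_trace(rnorm(10000), dt = 0.001)  # 10 s record at 1 kHz
  samp <- sample_scheme(dense, "volumetric", frame_interval = 0.1,
                        integration_time = 0.001, phase = 0.05)
  expect_equal(nrow(samp), 100)
  expect_equal(diff(samp$time), rep(0.1, 99), tolerance = 1e-12)
  expect_equal(integration_time(samp), 0.001)

  # continuous limit: every bin
  cont <- sample_scheme(dense, "continuous")
  expect_equal(nrow(cont), 10000)
  expect_equal(cont$value, stim_values(dense)[, 1])

  # frame_interval = dt with integration dt is also every bin
  all_bins <- sample_scheme(dense, "volumetric", frame_interval = 0.001,
                            integration_time = 0.001, phase = 0.0005)
  expect_equal(nrow(all_bins), 9999)

  # matched-count contract between volumetric and plane-by-plane
  vol <- sample_scheme(dense, "volumetric", frame_interval = 0.5,
                       integration_time = 0.01, phase = 0.005)
  pbp <- sample_scheme(dense, "plane_by_plane", frame_interval = 0.5,
                       integration_time = 0.01, n_planes = 15,
                       block_start = 1.0)
  expect_equal(nrow(pbp), nrow(vol))
  expect_equal(diff(pbp$time), rep(0.5 / 15, nrow(pbp) - 1), tolerance = 1e-9)
  # a block pushed past the end of the record fails loudly
  expect_error(sample_scheme(dense, "plane_by_plane", frame_interval = 0.5,
                             integration_time = 0.01, n_planes = 15,
                             block_start = 9.8),
               "outside")
})

test_that("phase-locked acquisition of a periodic stimulus warns", {
  s <- generate_stimulus("impulse_train", dt = 0.01, duration = 50,
                         rate = 2, seed = 49)  # period 0.5 s
  truth <- make_filter("exponential", list(tau1 = 0.05), dt = 0.01, length = 20)
  dense <- simulate_response(s, truth, snr = Inf)
  expect_warning(
    sample_scheme(dense, "volumetric", frame_interval = 1.0, phase = 0.1),
    "phases"
  )
  expect_silent(
    sample_scheme(dense, "volumetric", frame_interval = 0.73, phase = 0.1)
  )
})

test_that("amplitude modulation degenerates to a plain response for one epoch", {
  truth <- make_filter("exponential", list(tau1 = 3), dt = 1, length = 12)
  s <- generate_stimulus("gaussian_white", dt = 1, duration = 200, seed = 50)
  plain <- simulate_response(s, truth, snr = Inf)
  # epoch as long as the record: amplitude is a single +/-1 draw
  set.seed(51)
  mod <- amplitude_modulated_cell(s, truth, epoch_length = 200, snr = Inf)
  ratio <- stim_values(mod)[, 1] / stim_values(plain)[, 1]
  ratio <- ratio[is.finite(ratio)]
  expect_true(all(abs(abs(ratio) - 1) < 1e-12))
  expect_error(amplitude_modulated_cell(s, truth, epoch_length = 5),
               "epoch_length")
})

test_that("sign-modulated cells have null first-order filters at long records", {
  truth <- make_filter("damped_osc", list(tau1 = 0.08, tau2 = 0.06),
                       dt = 0.01, length = 30, normalize = "unit_mean_square")
  s <- generate_stimulus("gaussian_white", dt = 0.01, duration = 600,
                         seed = 52)
  dense <- amplitude_modulated_cell(s, truth, epoch_length = 0.5, snr = Inf,
                                    seed = 53)
  samp <- sample_scheme(dense, "volumetric", frame_interval = 0.05,
                        phase = 0.031)
  p <- build_pairs(s, samp, lag_grid(0.01, n_causal = 30))
  f1 <- filter_values(vt_xcorr(p))
  # Monte-Carlo scale of the first-order estimate: sd(r)/sqrt(N) per lag
  mc <- sd(p$r) / sqrt(nrow(p$S))
  expect_lt(max(abs(f1)), 5 * mc)
  # the whole first-order filter sits at the Monte-Carlo noise floor,
  # far below the unit-RMS generating field
  expect_lt(sqrt(mean(f1^2)), 3 * mc)
  expect_lt(sqrt(mean(f1^2)), 0.2 * sqrt(mean(filter_values(truth)^2)))
})
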