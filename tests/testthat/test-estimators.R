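test_that("cross-correlation equals a brute-force summation", {
  set.seed(21)
  sv <- rnorm(10)
  s <- stim_trace(sv, dt = 1)
  samp <- timed_samples(c(4.5, 8.5), c(2, -1))
  lg <- lag_grid(1, n_causal = 3)
  p <- build_pairs(s, samp, lg)
  est <- filter_values(vt_xcorr(p))
  # hand double loop on the centered pairs
  expected <- numeric(3)
  for (j in 1:3) expected[j] <- mean(p$S[, j] * p$r)
  expect_equal(est, expected, tolerance = 1e-14)

  # zero responses give a zero filter
  p0 <- build_pairs(s, timed_samples(c(4.5, 8.5), c(0, 0)), lg)
  expect_equal(filter_values(vt_xcorr(p0)), rep(0, 3))
  expect_error(vt_xcorr(structure(list(S = matrix(0, 0, 1)), class = "vt_pairs")))
})

test_that("OLS matches an explicit normal-equations inversion and exact recovery", {
  set.seed(22)
  # small case: N = 8, L = 3, against solve() on the normal equations
  S <- matrix(rnorm(24), 8, 3)
  r <- rnorm(8)
  p <- new_vt_pairs(S, r, center = TRUE)
  expect_equal(filter_values(vt_ols(p)),
               drop(solve(crossprod(p$S)) %*% crossprod(p$S, p$r)),
               tolerance = 1e-10)
  # noiseless linear system: exact interpolation of the generating filter
  sys <- make_linear_system(n_bins = 3000, snr = Inf, seed = 23)
  pp <- build_pairs(sys$stim, sys$samples, lag_grid(1, n_causal = 30))
  expect_equal(filter_values(vt_ols(pp)), filter_values(sys$truth),
               tolerance = 1e-8)
})

test_that("rank-deficient OLS raises a conditioning error unless ridged", {
  set.seed(24)
  S <- matrix(rnorm(10), 5, 2)
  Sdup <- cbind(S, S[, 1])  # collinear columns
  p <- new_vt_pairs(Sdup, rnorm(5))
  expect_error(vt_ols(p), "singular")
  expect_silent(vt_ols(p, ridge = 1e-4))
  pshort <- new_vt_pairs(matrix(rnorm(6), 2, 3), rnorm(2))
  expect_error(vt_ols(pshort), "rank deficient")
})

test_that("interpolating complete data reproduces the OLS filter", {
  sys <- make_linear_system(n_bins = 800, sample_every = 1, snr = 5, seed = 25)
  lg <- lag_grid(1, n_causal = 20)
  p <- build_pairs(sys$stim, sys$samples, lg)
  f_ols <- vt_ols(p)
  for (m in c("linear", "nearest", "pchip", "spline")) {
    fi <- vt_interp_filter(sys$stim, sys$samples, lg, method = m)
    expect_equal(filter_values(fi), filter_values(f_ols), tolerance = 1e-9)
  }
  expect_error(vt_interp_filter(sys$stim, sys$samples, lg, method = "sinc"))
})

test_that("interpolated filters are smoothed versions that miss fast structure", {
  # noiseless exponential system sampled every 10 steps: voxel OLS is exact,
  # the linear-interpolation filter is not
  sys <- make_linear_system(n_bins = 20000, tau = 10, flen = 40,
                            sample_every = 10, snr = Inf, seed = 26)
  lg <- lag_grid(1, n_causal = 40)
  p <- build_pairs(sys$stim, sys$samples, lg)
  f_vox <- vt_ols(p)
  f_int <- vt_interp_filter(sys$stim, sys$samples, lg, method = "linear")
  err_vox <- max(abs(filter_values(f_vox) - filter_values(sys$truth)))
  err_int <- max(abs(filter_values(f_int) - filter_values(sys$truth)))
  expect_lt(err_vox, 1e-10)
  expect_gt(err_int, 100 * max(err_vox, 1e-12))
  # the interpolated estimate underestimates the sharp filter peak
  expect_lt(max(filter_values(f_int)), 0.8 * max(filter_values(sys$truth)))
})

test_that("smoothing kernels behave as convolution operators", {
  lg <- lag_grid(0.01, n_causal = 21)
  imp <- vt_filter(c(rep(0, 10), 1, rep(0, 10)), lg)
  # delta kernel is the identity
  expect_equal(filter_values(smooth_filter(imp, delta_kernel())),
               filter_values(imp))
  # Gaussian of SD one lag step on an impulse gives the discretized Gaussian
  g <- gaussian_kernel(0.01, 0.01)
  sm <- filter_values(smooth_filter(imp, g))
  expect_equal(sum(sm), 1, tolerance = 1e-12)
  expect_equal(sm[11], max(sm))
  expect_equal(sm[10], sm[12], tolerance = 1e-14)
  taps <- g$taps
  h <- (length(taps) - 1) / 2
  expect_equal(sm[(11 - h):(11 + h)], taps)
})

test_that("triangle kernels have the closed-form taps and unit sum", {
  expect_equal(triangle_kernel(1, 1)$taps, 1)
  expect_equal(triangle_kernel(2, 1)$taps, c(0.25, 0.5, 0.25))
  for (si in c(1.3, 2.5, 4, 7.7)) {
    k <- triangle_kernel(si, 1)
    expect_equal(sum(k$taps), 1, tolerance = 1e-12)
    expect_equal(k$taps, rev(k$taps))
  }
  expect_error(triangle_kernel(0.5, 1), "sample_interval")
})

test_that("Laguerre basis is orthonormal, decaying, and oscillation-ordered", {
  B <- laguerre_basis(5, 0.7, 100)
  expect_equal(crossprod(B), diag(5), tolerance = 1e-10, ignore_attr = TRUE)
  # order 0: strictly positive geometric-envelope decay
  expect_true(all(B[, 1] > 0))
  expect_equal(B[-1, 1] / B[-100, 1], rep(sqrt(0.7), 99), tolerance = 1e-9)
  # column j has exactly j sign changes
  sign_changes <- function(x) sum(diff(sign(x[abs(x) > 1e-10])) != 0)
  expect_equal(vapply(1:5, function(j) sign_changes(B[, j]), integer(1)),
               0:4)
  expect_error(laguerre_basis(3, 1.2, 50), "alpha")
})

test_that("Laguerre fits recover basis-realizable filters and project OLS", {
  set.seed(27)
  dt <- 1; L <- 40
  B <- laguerre_basis(4, 0.7, L)
  truth_v <- drop(B %*% c(1, -0.5, 0.25, 0.1))
  truth <- make_filter("custom", list(values = truth_v), dt = dt, length = L)
  s <- generate_stimulus("gaussian_white", dt = dt, duration = 4000)
  dense <- simulate_response(s, truth, snr = Inf)
  samp <- sample_scheme(dense, "volumetric", frame_interval = 7, phase = 0)
  p <- build_pairs(s, samp, lag_grid(dt, n_causal = L))
  fit <- vt_laguerre(p, n_funcs = 4, alpha = 0.7)
  expect_equal(filter_values(fit), truth_v, tolerance = 1e-8)
  expect_equal(filter_meta(fit)$coefficients, c(1, -0.5, 0.25, 0.1),
               tolerance = 1e-8)
  # near-white design: coefficients approach the projection of the OLS filter
  f_ols <- filter_values(vt_ols(p))
  expect_equal(filter_meta(fit)$coefficients, drop(crossprod(B, f_ols)),
               tolerance = 1e-6)
  # acausal lags are rejected
  p_ac <- build_pairs(s, samp, lag_grid(dt, n_causal = L, n_acausal = 4))
  expect_error(vt_laguerre(p_ac), "causal")
})

test_that("ASD posterior mean matches the generalized-ridge dense solve", {
  set.seed(28)
  S <- matrix(rnorm(15 * 12), 15, 12)
  r <- rnorm(15)
  lg <- lag_grid(0.01, n_causal = 12)
  p <- new_vt_pairs(S, r, lags = lg, center = TRUE)
  hyper <- list(sigma2 = 0.5, rho = 1.2, delta = 0.03)
  f <- vt_asd(p, hyper = hyper)
  C <- asd_prior_cov(lg, hyper$rho, hyper$delta)
  mu <- solve(crossprod(p$S) / hyper$sigma2 + solve(C),
              crossprod(p$S, p$r) / hyper$sigma2)
  expect_equal(filter_values(f), drop(mu), tolerance = 1e-10)
})

test_that("ASD returns the prior mean for zero responses and smooths noise", {
  set.seed(29)
  s <- stim_trace(rnorm(600), dt = 1)
  samp0 <- timed_samples(seq(40.5, 590.5, by = 5), rep(0, 111))
  p0 <- build_pairs(s, samp0, lag_grid(1, n_causal = 20))
  expect_equal(filter_values(vt_asd(p0)), rep(0, 20), tolerance = 1e-8)

  # noisy linear system: ASD should beat plain OLS against the truth
  sys <- make_linear_system(n_bins = 12000, tau = 8, flen = 30,
                            sample_every = 10, snr = 1, seed = 30)
  p <- build_pairs(sys$stim, sys$samples, lag_grid(1, n_causal = 30))
  err_ols <- rel_rms(filter_values(vt_ols(p)), filter_values(sys$truth))
  fa <- vt_asd(p)
  err_asd <- rel_rms(filter_values(fa), filter_values(sys$truth))
  expect_true(isTRUE(filter_meta(fa)$converged))
  expect_lt(err_asd, err_ols)
})

test_that("ASD analytic evidence gradients agree with finite differences", {
  set.seed(31)
  S <- matrix(rnorm(40 * 8), 40, 8)
  lg <- lag_grid(0.02, n_causal = 8)
  r <- drop(S %*% exp(-(0:7) / 3)) + rnorm(40, sd = 0.5)
  p <- new_vt_pairs(S, r, lags = lg, center = TRUE)
  ev <- function(th) {
    f <- vt_asd(p, hyper = list(sigma2 = exp(th[1]), rho = th[2],
                                delta = exp(th[3])))
    filter_meta(f)$evidence
  }
  th <- c(log(0.3), 0.5, log(0.05))
  num <- vapply(1:3, function(i) {
    e <- 1e-6
    d <- rep(0, 3); d[i] <- e
    (ev(th + d) - ev(th - d)) / (2 * e)
  }, numeric(1))
  # reconstruct the analytic gradient through a tiny optimization probe:
  # one L-BFGS step from th must move uphill along the numeric gradient
  expect_gt(ev(th + 1e-4 * num / sqrt(sum(num^2))), ev(th))
})

test_that("response-weighted covariance matches brute force and conventions", {
  set.seed(32)
  S <- matrix(rnorm(18), 6, 3)
  S <- sweep(S, 2, colMeans(S))
  r <- c(1, -2, 0.5, 3, -1, 0.25)
  r <- r - mean(r)
  p <- new_vt_pairs(S, r, lags = lag_grid(1, n_causal = 3))
  # squared-response weighting (default) against the brute-force sum
  cv <- response_weighted_covariance(p)
  C_oracle <- matrix(0, 3, 3)
  for (i in 1:6) C_oracle <- C_oracle + r[i]^2 * tcrossprod(S[i, ])
  C_oracle <- C_oracle / 6 - mean(r^2) * crossprod(S) / 6
  expect_equal(cv$C, C_oracle, tolerance = 1e-12)
  # signed weighting against its own brute-force sum
  cvs <- response_weighted_covariance(p, weight = "response")
  C_s <- matrix(0, 3, 3)
  for (i in 1:6) C_s <- C_s + r[i] * tcrossprod(S[i, ])
  C_s <- C_s / 6 - mean(r) * crossprod(S) / 6
  expect_equal(cvs$C, C_s, tolerance = 1e-12)
  expect_lt(max(abs(cv$C - t(cv$C))), 1e-10 * max(abs(cv$C)))
  expect_true(all(diff(abs(cv$eigenvalues)) <= 1e-12))
  for (j in 1:3) {
    v <- cv$eigenvectors[, j]
    expect_equal(sqrt(sum(v^2)), 1, tolerance = 1e-12)
    expect_gte(v[which.max(abs(v))], 0)
  }
  # zero responses give the zero matrix
  p0 <- new_vt_pairs(S, rep(0, 6), lags = lag_grid(1, n_causal = 3))
  expect_equal(response_weighted_covariance(p0)$C, matrix(0, 3, 3))
})

test_that("predictions equal direct convolution and handle special filters", {
  set.seed(33)
  sv <- rnorm(20)
  s <- stim_trace(sv, dt = 1)
  lg <- lag_grid(1, n_causal = 4, n_acausal = 1)
  fvals <- c(0.3, 1, -0.5, 0.25, 0.1)  # taus -1, 0, 1, 2, 3
  f <- vt_filter(fvals, lg)
  pred <- predict(f, s, center = FALSE)
  sc <- sv
  for (b in 4:19) {
    acc <- 0
    for (j in seq_along(lg$steps)) acc <- acc + fvals[j] * sc[b - lg$steps[j]]
    expect_equal(pred[b], acc, tolerance = 1e-12)
  }
  expect_true(all(is.na(pred[c(1:3, 20)])))
  # zero filter and identity (delta at lag 0) filters
  expect_equal(predict(vt_filter(rep(0, 3), lag_grid(1, 3)), s, center = FALSE)[3:20],
               rep(0, 18))
  delta <- vt_filter(c(1, 0, 0), lag_grid(1, 3))
  expect_equal(predict(delta, s)[3:20], (sv - mean(sv))[3:20])
  expect_error(predict(f, stim_trace(sv, dt = 0.5)), "match")
})

test_that("estimator consistency: xcorr and OLS are proportional to truth on white noise", {
  sys <- make_linear_system(n_bins = 60000, tau = 6, flen = 20,
                            sample_every = 7, snr = Inf, seed = 34)
  lg <- lag_grid(1, n_causal = 20)
  p <- build_pairs(sys$stim, sys$samples, lg)
  f_ols <- filter_values(vt_ols(p))
  f_xc <- filter_values(vt_xcorr(p))
  truth <- filter_values(sys$truth)
  expect_equal(f_ols, truth, tolerance = 1e-8)
  # xcorr \approx stimulus variance x truth (variance ~ 1); finite-sample
  scale <- sum(f_xc * truth) / sum(truth^2)
  expect_equal(scale, 1, tolerance = 0.1)  # Monte-Carlo error ~ n^-1/2
  expect_gt(cor(f_xc, truth), 0.99)
})

test_that("every estimate lives on the stimulus-resolution lag grid", {
  sys <- make_linear_system(n_bins = 3000, sample_every = 12, snr = 2, seed = 35)
  lg <- lag_grid(1, n_causal = 25, n_acausal = 5)
  p <- build_pairs(sys$stim, sys$samples, lg)
  lgc <- lag_grid(1, n_causal = 25)
  pc <- build_pairs(sys$stim, sys$samples, lgc)
  ests <- list(vt_xcorr(p), vt_ols(p), vt_asd(pc), vt_laguerre(pc),
               vt_interp_filter(sys$stim, sys$samples, lg, "linear"))
  for (f in ests) {
    expect_equal(filter_lags(f)$dt, stim_dt(sys$stim))
    expect_equal(median(diff(f$lag)), stim_dt(sys$stim))
  }
})
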