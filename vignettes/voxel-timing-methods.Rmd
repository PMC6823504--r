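---
title: "Temporal super-resolution receptive fields: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal super-resolution receptive fields: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxfilt)
```

## The problem

Scanning microscopy (two-photon, confocal, light-sheet) acquires voxels
serially. Each neuron is therefore measured over a brief integration window —
a line or voxel dwell of a millisecond or less — but revisited only once per
frame or volume, often at 10 Hz or slower. Meanwhile the experimental
variables we want to relate to neural activity (visual stimuli at 60–120 Hz,
behaviour at video rate, electrical signals at kHz) are recorded densely.
Matching the two rates by downsampling the fast variable, or by interpolating
the slow one, caps the temporal resolution of any cross-correlation or
receptive-field estimate at the Nyquist frequency of the *response* sampling.

The key observation behind this package is that the limit is unnecessary:
each response sample has a precisely known acquisition time, so it can be
paired with the exact high-resolution stimulus history preceding it. Pooled
over many samples whose phases relative to the stimulus vary, these pairs
estimate the stimulus–response relationship on the *stimulus* time grid. We
call the resulting estimators voxel-timing estimators.

## Model and estimators

Let the stimulus live on a uniform grid of width $\Delta t$ and let responses
$r_{t_i}$ be measured at arbitrary times $t_i$. Write
$\mathbf{s}_{t_i} = (s_{t_i}, s_{t_i-\Delta t}, \dots)$ for the stimulus
history at lags $\tau \ge 0$ (positive lag = stimulus before response; an
optional acausal margin, default 25% of the causal window, provides a
falsification check, since a causal system must show nothing there). Both
stimulus and response are mean-subtracted over the retained pairs
(`build_pairs()` stores the means so predictions can be un-centered).

* **Cross-correlation** (`vt_xcorr()`):
  $c_\tau = \frac{1}{N}\sum_i s_{t_i-\tau}\, r_{t_i}$.
  For a white stimulus, $c_\tau$ is proportional to the linear filter, with
  constant equal to the stimulus variance.
* **OLS** (`vt_ols()`): $\hat f = (S^\top S + \lambda N I)^{-1} S^\top r$ —
  the cross-correlation deconvolved by the stimulus autocorrelation. The
  ridge $\lambda$ defaults to 0; a singular $S^\top S$ raises a conditioning
  error rather than silently regularizing, so the analyst must opt in.
* **Laguerre regression** (`vt_laguerre()`): OLS on the first few discrete
  Laguerre functions (orthonormalized over the lag window; decay parameter
  $\alpha = 0.7$ by default, chosen as a mid-range value giving basis support
  comparable to typical indicator kernels — the basis is re-orthonormalized,
  so moderate changes in $\alpha$ mostly re-parameterize the same subspace).
* **ASD** (`vt_asd()`): empirical Bayes with squared-exponential prior
  $C_{ab} = e^{-\rho}\exp(-(\tau_a-\tau_b)^2/2\delta^2)$ over lags.
  Hyperparameters $(\sigma^2, \rho, \delta)$ maximize the evidence; the
  estimate is the posterior mean. We optimize jointly by L-BFGS on
  $(\log\sigma^2, \rho, \log\delta)$ with analytic gradients (at most 200
  iterations, relative tolerance $10^{-6}$); joint quasi-Newton proved more
  robust than coordinate ascent on these objectives, and the fixed-point is
  the same. Initialization: $\sigma^2$ from OLS (or lightly ridged) residual
  variance, $\delta = 2\Delta t$, $e^{-\rho}$ matched to the pilot filter
  power. A $10^{-7}$ diagonal jitter keeps the prior invertible at large
  $\delta$. No separate DC term is included: pairs are centered, which absorbs
  the offset.
* **Second-order structure** (`response_weighted_covariance()`): the
  covariance of the response-weighted stimulus,
  $C = \frac{1}{N}\sum_i w_i\, \mathbf{s}_{t_i}\mathbf{s}_{t_i}^\top -
  \bar w\, S^\top S / N$ with $w_i = r_i^2$ by default. The squared weight is
  deliberate: for a cell whose receptive field flips sign over time, a signed
  weight averages to zero by symmetry (for Gaussian stimuli the odd moment
  vanishes identically), whereas the squared weight isolates the
  variance-carrying direction, and the dominant eigenvector recovers the
  field at stimulus resolution. A signed weighting (`weight = "response"`)
  remains available for non-negative responses such as spike counts.
  Eigenvalues are ordered by magnitude; eigenvector signs are fixed so the
  largest-magnitude element is positive.

Sample times map to stimulus bins by flooring $(t_i - t_0)/\Delta t$, ties at
bin edges rounding down; the stimulus bin $k$ covers
$[t_0 + k\Delta t, t_0 + (k+1)\Delta t)$. Samples whose lag window leaves the
record are dropped, never zero-padded — padding would bias edge lags. Finite
voxel integration can be modelled at pairing time (`integrate = TRUE`,
overlap-weighted bin means); the default is a point sample at the window
centre, appropriate when the dwell is short relative to the stimulus update.

## Interpolation baselines, smoothing, and the triangle correspondence

`vt_interp_filter()` reproduces the common practice this method replaces:
upsample the response to the stimulus grid (linear, nearest, pchip or
spline), then fit OLS to the dense series. The result is implicitly smoothed
and resolution-limited by the sampling interval.

`smooth_filter()` makes the implicit smoothing explicit. Smoothing the
voxel-timing filter with a triangle of base twice the sampling interval
(`triangle_kernel()`) corresponds to the smoothing performed by linear
interpolation: at the cross-correlation level, the interpolated estimate *is*
the triangle-convolved voxel-timing estimate, and for OLS the correspondence
holds in expectation for white stimuli. In any finite record the two
estimators see different realizations of the stimulus autocorrelation, so
their difference shrinks stochastically (we measure $\approx 2\times10^{-2}$
relative RMS at $5\times10^4$ stimulus bins, decreasing with record length as
roughly $N^{-1/2}$) rather than vanishing to machine precision. The test
suite therefore asserts two things separately: close agreement at a fixed
record length, and monotone tightening with more data; an exact
finite-sample identity is *not* claimed, and the corresponding
machine-precision check in the acceptance suite documents this limit by
failing at its nominal tolerance. Smoothing edges are zero-padded, which is
consistent with filters that decay to zero inside the window; kernels wider
than the window will visibly lose mass at the edges.

## The synthetic generator: what it emulates

`make_filter()`, `generate_stimulus()`, `simulate_response()`,
`sample_scheme()` and `amplitude_modulated_cell()` encode the simulated
experiments used throughout:

* Filters: a damped oscillation $e^{-t/\tau_1}\sin(2\pi t/\tau_2)$ with
  $\tau_1 = 100$ ms, $\tau_2 = 50$ ms (a 20 Hz ringer, unit mean square); an
  exponential $e^{-t/\tau_1}/\tau_1$ with $\tau_1 = 10$ steps; and a bilobed
  kernel $(1-e^{-t/\tau_1})\big(\tau_2^{-1}e^{-t/\tau_2} -
  (t/\tau_3^2)e^{-t/\tau_3}\big)$ with $\tau = 20/100/200$ ms. All are causal
  and evaluated at bin centres $(k+\tfrac12)\Delta t$, avoiding the $t = 0$
  ambiguity of the product forms.
* Stimuli: iid Gaussian white noise per bin; binary full-field flicker at
  contrast $\pm 0.9$; impulse trains (fixed spacing with random phase by
  default, Poisson optional); sparse 0/1 onset indicators.
* Noise: additive iid Gaussian, with two SNR conventions — peak of the clean
  response over noise SD (used at SNR $\approx 60$ for the oscillator
  demonstrations) and SD over SD (used at SNR 1 for the noise studies).
* Sampling: `volumetric` revisits the ROI once per frame interval for the
  whole record (100 ms interval with 1 ms integration in the oscillator
  demonstration; 500 ms with 10 ms integration in the noise studies);
  `plane_by_plane` dwells at the fast plane rate for one contiguous block
  whose sample count matches the volumetric run, enabling equal-sample
  design comparisons. If the acquisition interval is an integer multiple of a
  periodic stimulus' repeat period, the generator warns that not all phases
  will be sampled.
* The sign-modulated cell multiplies the filtered stimulus by a piecewise
  constant amplitude, iid $\pm1$ per epoch (0.5 s epochs, and SD-over-SD
  SNR 4 in the packaged demonstration — values we fixed once as plausible
  for a strongly modulated cell, since the source text leaves the epoch
  statistics and noise level unstated; a Gaussian amplitude option exists).

What the generator does **not** emulate: indicator nonlinearity and kinetics,
photon shot noise, motion, bleed-through, or adaptation. Passing tests
demonstrate correctness of the estimators under the stated linear-Gaussian
conditions; they do not certify behaviour on real recordings, where the
imaging utilities (`scan_geometry()`, `dff()`, `subsample_every()`,
`per_line_filter_average()`) supply the timing and preprocessing but the
linearity assumption is the analyst's to check (the acausal margin and
`residual_autocorrelation()` help).

## Evaluation machinery

* `bootstrap_se()` resamples pairs with replacement and reports bias-corrected
  (BC, no acceleration — median-bias correction only) 1-SEM intervals per lag;
  OLS-style parametric errors underestimate kernel uncertainty on real data.
* `scaled_error()` is RMS deviation from a reference filter divided by the
  reference maximum.
* `error_vs_n()` measures the $N^{-1/2}$ error law by refitting across sample
  counts (each sample contributes one pair, so precision grows with the
  number of samples, not the sampling rate).
* `compare_schemes()` contrasts volumetric and plane-by-plane designs at
  matched per-cell sample counts, with white or AR(1) measurement noise. The
  AR(1) process lives on the stimulus grid with correlation `ar1_corr`
  (default 0.8) at the fast plane interval, so neighbouring plane-by-plane
  samples share noise while volumetric revisits are nearly independent —
  the mechanism by which smoothing and ASD preferentially rescue the
  volumetric design. Scaled errors are taken against the generating filter
  (known here, unlike in real data, where a full-dataset filter stands in).
  Cohen's d is the paired effect size (plane-by-plane minus volumetric);
  the signed-rank p-value is reporting via `stats::wilcox.test`.
* `selection_index()` sums stimulus–response correlations over lags per
  pixel; a cell passes when the maximum pixel index strictly exceeds 1
  (boundary values are excluded).

## Numerical choices and degenerate inputs

* OLS solves use Cholesky with an explicit conditioning check; rank
  deficiency is an error naming the remedy (ridge), never silent shrinkage.
* The Laguerre recursion is re-orthonormalized by QR over the finite window;
  column signs are fixed positive at the first element.
* The dense causal convolution is zero-padded before the record; samples
  earlier than one filter length are excluded from estimation by the
  pairing's incomplete-history rule, so the padding never reaches a fit.
* Bootstrap replicates on which an estimator fails are dropped and counted;
  degenerate zero-variance replicates produce SE = 0.
* `dff()` falls back to a constant (mean) baseline with a flag when the
  exponential fit diverges, and refuses to divide by a non-positive baseline.
* Problem sizes in the packaged tests and demonstrations (e.g. $10^4$ samples
  for the oscillator recovery, 20 repetitions across a decade of sample
  counts for the error-scaling law, 200 simulated cells for the
  design comparison) were chosen as the smallest sizes at which the
  corresponding statistical statements are stable across seeds.

## Known limitations

* The triangle correspondence is an expectation-level identity (see above);
  irregular sampling intervals have no single equivalent kernel and are not
  asserted.
* ASD's evidence surface can be multimodal for very few samples; the
  optimizer then returns the best iterate with `converged = FALSE` in the
  metadata.
* Pair construction materializes the design matrix (samples × lags); at
  $10^5$ samples × $10^3$ lags this is ~1 GB, so very long experiments
  should restrict the lag window or chunk by ROI.
* Correlations *between* neurons remain limited by the frame rate: relative
  voxel timing within a frame is fixed by scan position, so only
  correlations with a fast external variable gain resolution.
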