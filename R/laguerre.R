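#' Discrete Laguerre basis
#'
#' Columns are the lowest-order discrete Laguerre functions with decay
#' parameter `alpha`, generated by the standard recursion
#' `b_j(n) = sqrt(alpha) b_j(n-1) + sqrt(alpha) b_{j-1}(n) - b_{j-1}(n-1)`
#' with `b_0(n) = sqrt(1 - alpha) alpha^{n/2}`, then re-orthonormalized (QR)
#' over the finite window so that `t(B) %*% B == I` exactly. The basis is
#' causal and decaying: order `j` has exactly `j` sign changes, making a
#' handful of coefficients an efficient parameterization of smooth, decaying
#' receptive fields.
#'
#' @param n_funcs Number of basis functions (columns).
#' @param alpha Decay parameter in (0, 1); larger values give slower decay.
#' @param length Window length in lag bins (rows); must be `>= n_funcs`.
#' @return A `length` x `n_funcs` matrix with orthonormal columns, first
#'   element of each column non-negative.
#' @export
laguerre_basis <- function(n_funcs, alpha, length) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie strictly in (0, 1)")
  stopifnot(n_funcs >= 1, length >= n_funcs)
  sa <- sqrt(alpha)
  B <- matrix(0, length, n_funcs)
  n_idx <- 0:(length - 1L)
  B[, 1L] <- sqrt(1 - alpha) * sa^n_idx
  if (n_funcs > 1L) {
    for (j in 2:n_funcs) {
      # b_j(0) = sqrt(1 - alpha) alpha^(j/2): all orders start positive
      B[1L, j] <- sqrt(1 - alpha) * sa^(j - 1)
      for (n in 2:length) {
        B[n, j] <- sa * B[n - 1L, j] + sa * B[n, j - 1L] - B[n - 1L, j - 1L]
      }
    }
  }
  qr_ <- qr(B)
  Q <- qr.Q(qr_)
  # QR may flip column signs; restore the positive-start convention
  for (j in seq_len(n_funcs)) if (Q[1L, j] < 0) Q[, j] <- -Q[, j]
  Q
}

#' Laguerre-regularized voxel-timing filter
#'
#' Projects the lagged-stimulus design onto the first `n_funcs` discrete
#' Laguerre functions and solves the OLS problem for the basis coefficients;
#' the returned filter is `B %*% coef`. With far fewer parameters than lags,
#' this strongly reduces estimate noise when the true filter is smooth and
#' decaying. Requires a causal-only lag grid (the basis is causal).
#'
#' @param pairs A [build_pairs()] result whose lag grid has no acausal lags.
#' @param n_funcs Number of basis functions (default 5).
#' @param alpha Decay parameter in (0, 1) (default 0.7).
#' @return A [vt_filter()] with `method = "laguerre"`; the basis coefficients
#'   are stored in `filter_meta()$coefficients`.
#' @export
vt_laguerre <- function(pairs, n_funcs = 5, alpha = 0.7) {
  stopifnot(inherits(pairs, "vt_pairs"))
  if (pairs$lags$n_acausal > 0L)
    stop("the Laguerre basis is causal: build pairs with a causal-only lag grid")
  L <- ncol(pairs$S)
  B <- laguerre_basis(n_funcs, alpha, L)
  X <- pairs$S %*% B
  G <- crossprod(X)
  ch <- tryCatch(chol(G), error = function(e)
    stop("ill-conditioned Laguerre design (too few samples?)"))
  coef <- backsolve(ch, forwardsolve(t(ch), crossprod(X, pairs$r)))
  vt_filter(drop(B %*% coef), pairs$lags, method = "laguerre",
            meta = list(n = n_pairs(pairs), n_funcs = n_funcs, alpha = alpha,
                        coefficients = drop(coef)))
}
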