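#' Response-weighted stimulus covariance (second-order receptive field)
#'
#' The continuous-response analogue of spike-triggered covariance:
#' `C = (1/N) * sum_i r[i] * S[i, ] %o% S[i, ]`, optionally minus the
#' unweighted stimulus covariance scaled by the mean response. Its leading
#' eigenvectors reveal stimulus directions that drive large responses even
#' when the mean (first-order) filter is zero — e.g. a cell whose receptive
#' field flips sign over time. Resolution is again set by the stimulus grid,
#' not the response sampling rate.
#'
#' @param pairs A [build_pairs()] result (design columns centered).
#' @param weight `"square"` (default) weights each stimulus outer product by
#'   the squared response — the covariance of the response-weighted stimulus,
#'   which reveals fields whose sign flips over time (for such cells a signed
#'   weighting averages to zero by symmetry). `"response"` weights by the
#'   signed response itself, appropriate for non-negative responses such as
#'   spike counts.
#' @param subtract_baseline If `TRUE` (default), subtract the unweighted
#'   stimulus covariance scaled by the mean weight, `mean(w) * (S'S / N)`,
#'   so that purely stimulus-driven structure cancels.
#' @return An object of class `vt_covariance`: list with the symmetric matrix
#'   `C`, `eigenvalues` (sorted by decreasing magnitude), unit-norm
#'   `eigenvectors` (columns, sign fixed so the largest-magnitude element is
#'   positive), `lags`, and `n_samples`.
#' @export
response_weighted_covariance <- function(pairs,
                                         weight = c("square", "response"),
                                         subtract_baseline = TRUE) {
  weight <- match.arg(weight)
  stopifnot(inherits(pairs, "vt_pairs"))
  N <- n_pairs(pairs)
  if (N < 1L) stop("empty pair set")
  S <- pairs$S
  w <- if (weight == "square") pairs$r^2 else pairs$r
  C <- crossprod(S, S * w) / N
  if (subtract_baseline) C <- C - mean(w) * crossprod(S) / N
  C <- (C + t(C)) / 2
  eg <- eigen(C, symmetric = TRUE)
  ord <- order(abs(eg$values), decreasing = TRUE)
  vals <- eg$values[ord]
  vecs <- eg$vectors[, ord, drop = FALSE]
  for (j in seq_len(ncol(vecs))) {
    k <- which.max(abs(vecs[, j]))
    if (vecs[k, j] < 0) vecs[, j] <- -vecs[, j]
  }
  structure(
    list(C = C, eigenvalues = vals, eigenvectors = vecs,
         lags = pairs$lags, n_samples = N),
    class = "vt_covariance"
  )
}

#' @export
print.vt_covariance <- function(x, ...) {
  cat(sprintf("# vt_covariance: %d x %d, n = %d, leading |eigenvalues|: %s\n",
              nrow(x$C), ncol(x$C), x$n_samples,
              paste(signif(utils::head(x$eigenvalues, 3), 3), collapse = ", ")))
  invisible(x)
}

#' Extract an eigenvector of a `vt_covariance` as a filter
#'
#' @param x A [response_weighted_covariance()] result.
#' @param which Eigenvector index in magnitude order (default 1, the
#'   dominant one).
#' @return A [vt_filter()] on the covariance's lag grid.
#' @export
covariance_eigenfilter <- function(x, which = 1L) {
  stopifnot(inherits(x, "vt_covariance"))
  vt_filter(x$eigenvectors[, which], x$lags,
            method = sprintf("rwc_eigenvector_%d", which),
            meta = list(eigenvalue = x$eigenvalues[which], n = x$n_samples))
}

#' @rdname tidy.vt_pairs
#' @export
tidy.vt_covariance <- function(x, ...) {
  tibble::tibble(index = seq_along(x$eigenvalues),
                 eigenvalue = x$eigenvalues)
}

#' @rdname tidy.vt_pairs
#' @export
glance.vt_covariance <- function(x, ...) {
  tibble::tibble(n_samples = x$n_samples, n_lags = nrow(x$C),
                 lambda1 = x$eigenvalues[1],
                 lambda2 = x$eigenvalues[2])
}
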