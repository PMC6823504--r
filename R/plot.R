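#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a filter estimate
#'
#' Line plot of filter value against time lag (positive lag = stimulus before
#' response), with a ribbon of +/- 1 bootstrap SEM when an `se` column is
#' present and a dashed zero line.
#'
#' @param object A [vt_filter()].
#' @param ... Additional filters to overlay, named in `...` or labelled by
#'   their method.
#' @return A ggplot object.
#' @export
autoplot.vt_filter <- function(object, ...) {
  extra <- list(...)
  extra <- extra[vapply(extra, inherits, logical(1), "vt_filter")]
  all_f <- c(list(object), extra)
  labs <- names(all_f)
  if (is.null(labs)) labs <- rep("", length(all_f))
  labs <- ifelse(labs == "",
                 vapply(all_f, filter_method, character(1)), labs)
  dat <- purrr::map2_dfr(all_f, labs, function(f, lb) {
    tb <- tibble::as_tibble(f)[, intersect(c("lag", "value", "se"), names(f))]
    tb$estimate <- lb
    tb
  })
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$lag, y = .data$value,
                                         colour = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line()
  if ("se" %in% names(dat) && any(!is.na(dat$se))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$value - .data$se,
                   ymax = .data$value + .data$se,
                   fill = .data$estimate),
      alpha = 0.2, colour = NA)
  }
  p + ggplot2::labs(x = "time lag (s; stimulus precedes response)",
                    y = "filter value") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = if (length(all_f) > 1L) "bottom" else "none")
}

#' Plot a stimulus or dense-response trace
#'
#' @param object A [stim_trace()].
#' @param channels Channels to show (default all, up to 5).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stim_trace <- function(object, channels = NULL, ...) {
  cols <- setdiff(names(object), "time")
  if (is.null(channels)) channels <- utils::head(cols, 5L)
  dat <- tidyr::pivot_longer(tibble::as_tibble(object)[c("time", channels)],
                             -"time", names_to = "channel")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~channel, ncol = 1L, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "value") +
    ggplot2::theme_minimal()
}

#' Plot the eigenvalue spectrum of a response-weighted covariance
#'
#' @param object A [response_weighted_covariance()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vt_covariance <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$index, y = .data$eigenvalue)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::labs(x = "eigenvalue rank (by magnitude)", y = "eigenvalue") +
    ggplot2::theme_minimal()
}

#' Plot per-cell scaled errors by sampling scheme and estimator
#'
#' @param object A [compare_schemes()] report.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vt_error_report <- function(object, ...) {
  dat <- tibble::as_tibble(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$scheme, y = .data$scaled_error)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$cell),
                       alpha = 0.25, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar",
                          width = 0.4, colour = "red") +
    ggplot2::facet_wrap(~estimator) +
    ggplot2::labs(x = NULL, y = "scaled error (RMS / max of reference)") +
    ggplot2::theme_minimal()
}
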