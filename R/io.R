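#' Read and write stimulus traces, samples and filters as delimited text
#'
#' Plain-text interchange formats:
#' * stimulus: TSV with header `time` + one column per channel;
#' * samples: TSV with header `roi, time, value`, integration time in a YAML
#'   sidecar (`<path>.meta.yaml`);
#' * filter: TSV with header `lag_s, value[, se]`, method and parameters in a
#'   YAML sidecar.
#'
#' @param path File path.
#' @param x Object to write.
#' @return Readers return the corresponding object ([stim_trace()], a named
#'   list of [timed_samples()] keyed by ROI, or [vt_filter()]); writers
#'   return `path` invisibly.
#' @name voxfilt-io
NULL

#' @rdname voxfilt-io
#' @export
write_stimulus <- function(x, path) {
  stopifnot(inherits(x, "stim_trace"))
  readr::write_tsv(tibble::as_tibble(x), path)
  invisible(path)
}

#' @rdname voxfilt-io
#' @export
read_stimulus <- function(path) {
  stim_trace(readr::read_tsv(path, show_col_types = FALSE))
}

#' @rdname voxfilt-io
#' @param integration_time Integration time recorded in the sidecar.
#' @export
write_samples <- function(x, path, integration_time = NULL) {
  if (inherits(x, "timed_samples")) x <- list(roi1 = x)
  stopifnot(is.list(x), length(x) >= 1L)
  tb <- purrr::map_dfr(names(x), function(nm)
    tibble::tibble(roi = nm, time = x[[nm]]$time, value = x[[nm]]$value))
  readr::write_tsv(tb, path)
  it <- integration_time %||% integration_time(x[[1L]])
  yaml::write_yaml(list(integration_time_s = it), sidecar_path(path))
  invisible(path)
}

#' @rdname voxfilt-io
#' @export
read_samples <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("roi", "time", "value") %in% names(tb)))
  it <- 0
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- yaml::read_yaml(sc)
    if (!is.null(meta$integration_time_s)) it <- meta$integration_time_s
  }
  split(tb, tb$roi) |>
    purrr::map(function(d) timed_samples(d$time, d$value, integration_time = it))
}

#' @rdname voxfilt-io
#' @param seed Optional seed recorded in the sidecar metadata.
#' @export
write_filter <- function(x, path, seed = NULL) {
  stopifnot(inherits(x, "vt_filter"))
  tb <- tibble::as_tibble(x)
  names(tb)[names(tb) == "lag"] <- "lag_s"
  readr::write_tsv(tb, path)
  lg <- filter_lags(x)
  meta <- list(method = filter_method(x),
               dt_s = lg$dt, n_causal = lg$n_causal, n_acausal = lg$n_acausal,
               lag_convention = "positive lag = stimulus before response",
               seed = seed,
               parameters = serializable_meta(filter_meta(x)))
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

#' @rdname voxfilt-io
#' @export
read_filter <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot("lag_s" %in% names(tb), "value" %in% names(tb))
  meta <- list()
  method <- "custom"
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    m <- yaml::read_yaml(sc)
    method <- m$method %||% "custom"
    meta <- m$parameters %||% list()
  }
  dtau <- stats::median(diff(tb$lag_s))
  n_acausal <- sum(tb$lag_s < -1e-12)
  lg <- lag_grid(dtau, n_causal = nrow(tb) - n_acausal, n_acausal = n_acausal)
  vt_filter(tb$value, lg, method = method,
            se = if ("se" %in% names(tb)) tb$se else NULL, meta = meta)
}

sidecar_path <- function(path) paste0(path, ".meta.yaml")

# drop non-scalar entries that YAML cannot represent usefully
serializable_meta <- function(meta) {
  keep <- vapply(meta, function(v)
    (is.atomic(v) && length(v) <= 16L) || is.character(v), logical(1))
  meta[keep]
}
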