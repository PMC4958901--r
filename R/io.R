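## Plain-text external interfaces: region time-series and event tables as
## TSV, study configuration as YAML, inversion results as JSON + TSV.

#' Read a region time-series table
#'
#' TSV with a \code{time_s} column and one column per region.
#'
#' @param path file path
#' @param regions expected region names (checked when given)
#' @return list with \code{data} (matrix), \code{time_s}, \code{TR}
#' @export
read_timeseries <- function(path, regions = NULL) {
  df <- read_tsv_strict(path)
  if (!"time_s" %in% names(df)) stop("timeseries TSV needs a time_s column")
  t_s <- df$time_s
  y <- as.matrix(df[, setdiff(names(df), "time_s"), drop = FALSE])
  if (!is.null(regions)) {
    if (!all(regions %in% colnames(y)))
      stop("missing region column(s): ",
           paste(setdiff(regions, colnames(y)), collapse = ", "))
    y <- y[, regions, drop = FALSE]
  }
  TR <- if (length(t_s) > 1) diff(t_s)[1] else NA_real_
  list(data = y, time_s = t_s, TR = TR)
}

#' Read a BIDS-events-style table
#'
#' @param path TSV with columns \code{onset}, \code{duration},
#'   \code{trial_type}
#' @export
read_events <- function(path) {
  df <- read_tsv_strict(path)
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(df)))
    stop("events TSV needs columns: ", paste(need, collapse = ", "))
  df
}

#' Load a study configuration from YAML
#'
#' Recognized top-level blocks: \code{acquisition} (TR, n_volumes,
#' microtime_bins), \code{balloon} (overrides for
#' \code{\link{balloon_constants}}) and \code{cohort} (overrides for
#' \code{\link{cohort_config}}).
#'
#' @param path YAML file
#' @return list with \code{acquisition}, \code{constants}, \code{cohort}
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  acq <- if (!is.null(cfg$acquisition)) do.call(acquisition, cfg$acquisition)
  constants <- do.call(balloon_constants, cfg$balloon %||% list())
  cohort <- do.call(cohort_config, cfg$cohort %||% list())
  list(acquisition = acq, constants = constants, cohort = cohort)
}

#' Serialize an inversion result
#'
#' Posterior means, SDs, noise precisions and the free energy go to JSON;
#' the full posterior covariance to a TSV alongside.
#'
#' @param fit a \code{dcm} fit
#' @param path JSON output path (covariance written next to it)
#' @export
write_inversion <- function(fit, path) {
  out <- list(model = fit$spec$id, F = fit$F, accuracy = fit$accuracy,
              complexity = fit$complexity, converged = fit$converged,
              iterations = fit$iterations,
              lambda = as.numeric(fit$lambda),
              posterior_mean = as.list(fit$theta),
              posterior_sd = as.list(sqrt(pmax(diag(fit$Sigma), 0))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  cov_path <- sub("\\.json$", "_cov.tsv", path)
  df <- data.frame(parameter = rownames(fit$Sigma), fit$Sigma,
                   check.names = FALSE)
  write_tsv(df, cov_path)
  invisible(path)
}
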