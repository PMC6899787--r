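#' Forest-plot input table from MR reports
#'
#' Flattens one or more \code{mr_suite} reports into one row per
#' (outcome, method) with the estimate, 95% confidence interval and
#' p-value. Estimates for binary outcomes (log odds ratios) are
#' exponentiated to odds ratios for display, CI bounds included. Rows whose
#' method could not be run (instrument-count precondition unmet) carry
#' status \code{"not applicable (<3 SNPs)"}. Row order is deterministic:
#' outcome label, then method.
#'
#' @param reports list of \code{mr_suite} objects (a single one is
#'   accepted).
#' @param labels optional outcome labels overriding each report's own.
#' @return data.frame \code{outcome, method, beta, ci_low, ci_high, p,
#'   n_snps, status, scale} (scale is \code{"beta"} or \code{"OR"}).
#' @export
forest_table <- function(reports, labels = NULL) {
  if (inherits(reports, "mr_suite")) reports <- list(reports)
  stopifnot(length(reports) >= 1)
  labels <- labels %||% vapply(reports, `[[`, "", "label")
  rows <- do.call(rbind, lapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    df <- r$estimates
    binary <- identical(r$outcome_type, "binary")
    out <- data.frame(
      outcome = labels[i], method = df$method,
      beta = if (binary) exp(df$beta) else df$beta,
      ci_low = if (binary) exp(df$ci_low) else df$ci_low,
      ci_high = if (binary) exp(df$ci_high) else df$ci_high,
      p = df$p, n_snps = df$n_snps, status = df$status,
      scale = if (binary) "OR" else "beta",
      stringsAsFactors = FALSE
    )
    out
  }))
  rows <- rows[order(rows$outcome, rows$method), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' Plot a forest table
#'
#' Base-graphics forest plot of the (outcome, method) estimates with their
#' 95% intervals; odds-ratio rows are drawn on the log scale around 1,
#' effect-size rows around 0.
#'
#' @param x a data.frame from \code{\link{forest_table}}.
#' @param ... passed to \code{plot}.
#' @export
plot_forest <- function(x, ...) {
  x <- x[x$status == "ok" & is.finite(x$beta), , drop = FALSE]
  if (!nrow(x)) stop("nothing to plot")
  est <- ifelse(x$scale == "OR", log(x$beta), x$beta)
  lo <- ifelse(x$scale == "OR", log(x$ci_low), x$ci_low)
  hi <- ifelse(x$scale == "OR", log(x$ci_high), x$ci_high)
  y <- rev(seq_len(nrow(x)))
  graphics::plot(est, y, xlim = range(lo, hi, 0), yaxt = "n",
                 ylab = "", xlab = "causal estimate (log OR / SD)",
                 pch = 15, ...)
  graphics::segments(lo, y, hi, y)
  graphics::abline(v = 0, lty = 2)
  graphics::axis(2, at = y, labels = paste(x$outcome, x$method), las = 1,
                 cex.axis = 0.7)
  invisible(x)
}

#' Read / write a run configuration
#'
#' A nested key-value text file (YAML) holding input paths, QC thresholds,
#' locus window, MR options, coloc priors, the seed and the output
#' directory. Round-trips read -> write -> read identically.
#'
#' @param path file path.
#' @return named list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("run configuration must set a seed")
  cfg
}

#' @rdname read_run_config
#' @param config named list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the configuration hash, seed, package version and input file
#' checksums alongside an analysis output tree, so identical manifests
#' imply byte-identical numeric outputs.
#'
#' @param config named list (as from \code{\link{read_run_config}}).
#' @param inputs character vector of input file paths to checksum.
#' @param path output JSON path.
#' @export
write_manifest <- function(config, inputs = character(), path) {
  checksum <- function(f) {
    if (!file.exists(f)) return(NA_character_)
    as.character(tools::md5sum(f))
  }
  manifest <- list(
    config_hash = as.character(tools::md5sum(
      write_run_config(config, tempfile(fileext = ".yaml")))),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("gwasmr")),
    r_version = as.character(getRversion()),
    inputs = stats::setNames(lapply(inputs, checksum), inputs)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write an MR suite report as JSON and TSV
#'
#' @param suite an \code{mr_suite}.
#' @param json_path,tsv_path output paths (either may be NULL to skip).
#' @export
write_mr_report <- function(suite, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path)) {
    payload <- list(label = suite$label, outcome_type = suite$outcome_type,
                    estimates = suite$estimates, wald = suite$wald,
                    radial = if (!is.null(suite$radial))
                      suite$radial[c("per_snp", "outliers", "q_total", "alpha")],
                    steiger = suite$steiger)
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  if (!is.null(tsv_path)) {
    df <- suite$estimates
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], signif, digits = 6)
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(suite)
}
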