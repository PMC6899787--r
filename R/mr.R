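# Two-sample Mendelian randomization estimators. All operate on a
# harmonized_set (see harmonize_pair) whose rows are independent instruments
# with exposure and outcome effects on the same effect allele.

#' @keywords internal
mr_estimate <- function(method, beta, se, n_snps, q = NA_real_,
                        q_p = NA_real_) {
  structure(list(method = method, beta = beta, se = se,
                 ci_low = beta - 1.96 * se, ci_high = beta + 1.96 * se,
                 p = z_pvalue(beta, se), n_snps = n_snps, q = q, q_p = q_p),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("MR estimate [%s, %d SNP%s]: beta = %.4f (SE %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n",
              x$method, x$n_snps, if (x$n_snps == 1) "" else "s",
              x$beta, x$se, x$ci_low, x$ci_high, x$p))
  if (is.finite(x$q) && x$n_snps > 1) {
    cat(sprintf("  instrument heterogeneity: Q = %.3f, p = %.3g\n", x$q, x$q_p))
  }
  invisible(x)
}

# Per-SNP Wald ratios and their delta-method SEs.
#' @keywords internal
wald_ratios <- function(h, second_order = FALSE) {
  stopifnot(all(h$beta_exp != 0))
  ratio <- h$beta_out / h$beta_exp
  se <- h$se_out / abs(h$beta_exp)
  if (second_order) {
    se <- se * sqrt(1 + (h$beta_out^2 * h$se_exp^2) /
                      (h$beta_exp^2 * h$se_out^2))
  }
  list(ratio = ratio, se = se)
}

#' Wald ratio causal estimate from a single instrument
#'
#' The outcome effect divided by the exposure effect, with a delta-method
#' standard error: first order \eqn{se_{out}/|\beta_{exp}|}, or with
#' \code{second_order = TRUE} additionally propagating the exposure-side
#' uncertainty by the factor
#' \eqn{\sqrt{1 + \beta_{out}^2 se_{exp}^2 / (\beta_{exp}^2 se_{out}^2)}}.
#'
#' @param h one-row \code{harmonized_set} (or any row-like list with
#'   \code{beta_exp, se_exp, beta_out, se_out}).
#' @param second_order use the second-order delta SE.
#' @return An \code{mr_result}.
#' @export
wald_ratio <- function(h, second_order = FALSE) {
  h <- as.data.frame(h)
  stopifnot(nrow(h) == 1)
  if (h$beta_exp == 0) stop("Wald ratio undefined for a null exposure effect")
  wr <- wald_ratios(h, second_order)
  mr_estimate("wald", wr$ratio, wr$se, 1L)
}

#' Inverse-variance-weighted causal estimate
#'
#' Zero-intercept weighted regression of outcome on exposure effects with
#' weights \eqn{1/se_{out}^2} — algebraically the inverse-variance-weighted
#' mean of the per-SNP Wald ratios. The fixed-effects SE is
#' \eqn{(\sum \beta_{exp}^2/se_{out}^2)^{-1/2}}; the random-effects
#' (multiplicative over-dispersion) SE inflates it by
#' \eqn{\max(1, \sqrt{Q/(k-1)})} where Q is the Cochran heterogeneity of the
#' ratio estimates.
#'
#' @param h a \code{harmonized_set}; dropped rows are excluded.
#' @param mode \code{"random"} (default, the common two-sample convention)
#'   or \code{"fixed"}.
#' @return An \code{mr_result} (method \code{ivw_fixed} or
#'   \code{ivw_random}).
#' @export
mr_ivw <- function(h, mode = c("random", "fixed")) {
  mode <- match.arg(mode)
  h <- harmonized_kept(h)
  k <- nrow(h)
  if (k < 1) stop("IVW needs at least one instrument")
  w <- 1 / h$se_out^2
  theta <- sum(w * h$beta_exp * h$beta_out) / sum(w * h$beta_exp^2)
  se_fixed <- 1 / sqrt(sum(w * h$beta_exp^2))
  het <- mr_heterogeneity(h, theta, df = k - 1)
  se <- if (mode == "random" && k >= 2) {
    se_fixed * max(1, sqrt(het[["q"]] / (k - 1)))
  } else se_fixed
  mr_estimate(paste0("ivw_", mode), theta, se, k, het[["q"]], het[["q_p"]])
}

#' MR-Egger regression
#'
#' Weighted regression of outcome effects on exposure effects with a free
#' intercept, after re-orienting every instrument so its exposure effect is
#' positive (the outcome effect is sign-flipped in tandem). The slope is the
#' pleiotropy-adjusted causal estimate; a non-zero intercept indicates
#' directional horizontal pleiotropy. Weights are \eqn{1/se_{out}^2};
#' multiplicative over-dispersion inflates both SEs by
#' \eqn{\max(1, \sqrt{Q/(k-2)})}.
#'
#' @param h a \code{harmonized_set} with at least 3 kept instruments.
#' @return list with \code{slope} and \code{intercept}, both
#'   \code{mr_result}s (methods \code{egger_slope}, \code{egger_intercept}).
#' @export
mr_egger <- function(h) {
  h <- harmonized_kept(h)
  k <- nrow(h)
  if (k < 3) stop("MR-Egger needs at least 3 instruments")
  flip <- sign(h$beta_exp)
  bx <- h$beta_exp * flip
  by <- h$beta_out * flip
  w <- 1 / h$se_out^2
  X <- cbind(1, bx)
  XtWX <- crossprod(X, w * X)
  co <- solve(XtWX, crossprod(X, w * by))
  resid <- by - X %*% co
  q <- sum(w * resid^2)
  q_p <- stats::pchisq(q, df = k - 2, lower.tail = FALSE)
  se_fixed <- sqrt(diag(solve(XtWX)))
  infl <- max(1, sqrt(q / (k - 2)))
  list(
    slope = mr_estimate("egger_slope", co[2], se_fixed[2] * infl, k, q, q_p),
    intercept = mr_estimate("egger_intercept", co[1], se_fixed[1] * infl, k,
                            q, q_p)
  )
}

#' Weighted median causal estimate
#'
#' Orders the per-SNP Wald ratios and takes the inverse-variance-weighted
#' median: with normalized weights \eqn{w_j} in ratio order, cumulative
#' midpoints \eqn{p_j = \sum_{k \le j} w_k - w_j/2} are formed and the
#' estimate is the linear interpolation of the ordered ratios at p = 0.5.
#' Consistent when instruments carrying at least half the weight are valid.
#' The SE is the standard deviation of the estimate over parametric
#' bootstrap resamples of the exposure and outcome effects.
#'
#' @param h a \code{harmonized_set} with at least 3 kept instruments.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap (required for reproducibility).
#' @return An \code{mr_result} (method \code{weighted_median}).
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed) {
  h <- harmonized_kept(h)
  k <- nrow(h)
  if (k < 3) stop("weighted median needs at least 3 instruments")
  if (missing(seed)) stop("a bootstrap seed is required")
  est <- function(bx, by, se_r) {
    r <- by / bx
    w <- (1 / se_r^2) / sum(1 / se_r^2)
    ord <- order(r)
    r <- r[ord]; w <- w[ord]
    pj <- cumsum(w) - w / 2
    stats::approx(pj, r, xout = 0.5, rule = 2)$y
  }
  wr <- wald_ratios(h)
  theta <- est(h$beta_exp, h$beta_out, wr$se)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  boots <- replicate(n_boot, {
    bx <- stats::rnorm(k, h$beta_exp, h$se_exp)
    by <- stats::rnorm(k, h$beta_out, h$se_out)
    est(bx, by, h$se_out / abs(bx))
  })
  mr_estimate("weighted_median", theta, stats::sd(boots), k)
}

# Preserve/restore the caller's RNG state so seeded internals do not
# perturb an enclosing simulation.
#' @keywords internal
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
}
#' @keywords internal
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Cochran Q heterogeneity of the instruments
#'
#' \eqn{Q = \sum_j (r_j - \hat\theta)^2 / se_{r_j}^2} over the per-SNP Wald
#' ratios \eqn{r_j} with first-order ratio SEs, compared against the
#' chi-square distribution on \code{df} degrees of freedom (k-1 for IVW,
#' k-2 for Egger).
#'
#' @param h a \code{harmonized_set}.
#' @param theta the fitted causal estimate.
#' @param df degrees of freedom (default k-1).
#' @return Named vector \code{q, q_p}.
#' @export
mr_heterogeneity <- function(h, theta, df = nrow(h) - 1) {
  h <- harmonized_kept(h)
  wr <- wald_ratios(h)
  q <- sum((wr$ratio - theta)^2 / wr$se^2)
  c(q = q,
    q_p = if (df >= 1) stats::pchisq(q, df = df, lower.tail = FALSE) else NA_real_)
}

#' Radial (modified Q) outlier detection
#'
#' Fits the radial IVW model — regression through the origin of
#' \eqn{\beta_{out,j}\sqrt{w_j}} on \eqn{\beta_{exp,j}\sqrt{w_j}} with
#' first-order weights \eqn{w_j = \beta_{exp,j}^2/se_{out,j}^2} (its slope
#' equals the IVW estimate) — and decomposes Cochran's Q into per-SNP
#' contributions \eqn{q_j = w_j (r_j - \hat\theta)^2}. Instruments whose
#' upper-tail chi-square(1) p-value falls below \code{alpha} are flagged as
#' outliers.
#'
#' @param h a \code{harmonized_set} with at least 3 kept instruments.
#' @param alpha per-SNP outlier threshold (default 0.05).
#' @return A \code{radial_report}: data.frame \code{per_snp} (rsid, q_j, p),
#'   \code{outliers} (rsids), \code{q_total}, \code{theta}, \code{alpha}.
#' @export
radial_outliers <- function(h, alpha = 0.05) {
  h <- harmonized_kept(h)
  if (nrow(h) < 3) stop("radial outlier detection needs at least 3 instruments")
  wr <- wald_ratios(h)
  w <- h$beta_exp^2 / h$se_out^2
  theta <- sum(w * wr$ratio) / sum(w)
  q_j <- w * (wr$ratio - theta)^2
  p_j <- stats::pchisq(q_j, df = 1, lower.tail = FALSE)
  structure(list(
    per_snp = data.frame(rsid = h$rsid, q_j = q_j, p = p_j,
                         stringsAsFactors = FALSE),
    outliers = h$rsid[p_j < alpha],
    q_total = sum(q_j), theta = theta, alpha = alpha
  ), class = "radial_report")
}

#' @export
print.radial_report <- function(x, ...) {
  cat(sprintf("Radial MR outlier scan: %d instruments, total Q = %.3f\n",
              nrow(x$per_snp), x$q_total))
  if (length(x$outliers)) {
    cat("  outliers (p <", x$alpha, "):", paste(x$outliers, collapse = ", "), "\n")
  } else cat("  no outliers at alpha =", x$alpha, "\n")
  invisible(x)
}

#' Run the full two-sample MR analysis for one direction
#'
#' Orchestrates harmonization, optional Steiger directionality filtering,
#' every estimator whose instrument-count precondition holds (per-SNP Wald
#' ratios always; IVW from 1 SNP; Egger, weighted median and radial outlier
#' detection from 3), and an optional IVW re-fit after removing radial
#' outliers. A bidirectional analysis is two calls with the exposure and
#' outcome swapped and the reverse-direction instrument set.
#'
#' @param exposure instrument-level exposure summary statistics.
#' @param outcome outcome summary statistics (looked up by variant key).
#' @param label direction label carried into the report.
#' @param outcome_type \code{"quantitative"} or \code{"binary"} (binary
#'   outcome effects are log odds ratios; \code{\link{forest_table}}
#'   exponentiates them for display).
#' @param steiger apply Steiger filtering before estimation.
#' @param steiger_alpha optional p-value gate for the Steiger filter.
#' @param remove_outliers re-fit IVW after removing radial outliers.
#' @param palindrome_policy,eaf_ambiguity_band passed to
#'   \code{\link{harmonize_pair}}.
#' @param n_boot,seed weighted-median bootstrap controls.
#' @param alpha_radial radial outlier threshold.
#' @param ivw_mode IVW flavour, \code{"random"} or \code{"fixed"}.
#' @return An \code{mr_suite} list: \code{label, outcome_type, harmonized,
#'   steiger, estimates} (data.frame of all methods incl. not-applicable
#'   stubs), \code{wald} (per-SNP), \code{radial}, \code{ivw_outlier_removed}.
#' @export
run_mr_suite <- function(exposure, outcome, label = "exposure->outcome",
                         outcome_type = c("quantitative", "binary"),
                         steiger = FALSE, steiger_alpha = NULL,
                         remove_outliers = TRUE,
                         palindrome_policy = "infer",
                         eaf_ambiguity_band = c(0.42, 0.58),
                         n_boot = 1000, seed = 1L, alpha_radial = 0.05,
                         ivw_mode = "random") {
  outcome_type <- match.arg(outcome_type)
  h <- harmonize_pair(exposure, outcome, palindrome_policy,
                      eaf_ambiguity_band)
  steiger_res <- NULL
  if (steiger) {
    sf <- steiger_filter(h, alpha = steiger_alpha)
    steiger_res <- sf$steiger
    h <- sf$retained
  }
  hk <- harmonized_kept(h)
  k <- nrow(hk)
  if (k == 0) stop("no usable instruments after harmonization",
                   if (steiger) " and Steiger filtering" else "")
  ests <- list(mr_ivw(hk, mode = ivw_mode))
  na_stub <- function(method) {
    structure(list(method = method, beta = NA_real_, se = NA_real_,
                   ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                   n_snps = k, q = NA_real_, q_p = NA_real_,
                   status = "not applicable (<3 SNPs)"), class = "mr_result")
  }
  radial <- NULL
  ivw_rm <- NULL
  if (k >= 3) {
    eg <- mr_egger(hk)
    ests <- c(ests, list(eg$slope, eg$intercept,
                         mr_weighted_median(hk, n_boot, seed = seed)))
    radial <- radial_outliers(hk, alpha_radial)
    if (remove_outliers && length(radial$outliers)) {
      ivw_rm <- mr_ivw(hk[!(hk$rsid %in% radial$outliers), , drop = FALSE],
                       mode = ivw_mode)
      ivw_rm$method <- paste0(ivw_rm$method, "_outlier_removed")
    }
  } else {
    ests <- c(ests, list(na_stub("egger_slope"), na_stub("egger_intercept"),
                         na_stub("weighted_median")))
  }
  if (!is.null(ivw_rm)) ests <- c(ests, list(ivw_rm))
  wald <- do.call(rbind, lapply(seq_len(k), function(i) {
    e <- wald_ratio(hk[i, , drop = FALSE])
    data.frame(rsid = hk$rsid[i], beta = e$beta, se = e$se,
               ci_low = e$ci_low, ci_high = e$ci_high, p = e$p,
               stringsAsFactors = FALSE)
  }))
  est_df <- do.call(rbind, lapply(ests, function(e) {
    data.frame(method = e$method, beta = e$beta, se = e$se,
               ci_low = e$ci_low, ci_high = e$ci_high, p = e$p,
               n_snps = e$n_snps, q = e$q, q_p = e$q_p,
               status = e$status %||% "ok", stringsAsFactors = FALSE)
  }))
  structure(list(label = label, outcome_type = outcome_type,
                 harmonized = h, steiger = steiger_res, estimates = est_df,
                 wald = wald, radial = radial,
                 ivw_outlier_removed = ivw_rm),
            class = "mr_suite")
}

#' @export
print.mr_suite <- function(x, ...) {
  cat("Two-sample MR report:", x$label, "\n")
  cat("  instruments:", nrow(harmonized_kept(x$harmonized)),
      if (!is.null(x$steiger)) "(after Steiger filtering)" else "", "\n")
  df <- x$estimates
  df[, c("beta", "se", "ci_low", "ci_high")] <-
    round(df[, c("beta", "se", "ci_low", "ci_high")], 4)
  print(df, row.names = FALSE)
  if (!is.null(x$radial) && length(x$radial$outliers)) {
    cat("  radial outliers:", paste(x$radial$outliers, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.mr_suite <- function(object, ...) {
  print(object)
  if (!is.null(object$steiger)) {
    cat(sprintf("  Steiger: %d of %d instruments in the correct direction\n",
                sum(object$steiger$correct_direction), nrow(object$steiger)))
  }
  invisible(object$estimates)
}
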