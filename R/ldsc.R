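#' LD scores from a correlation matrix
#'
#' The LD score of variant j is the sum of squared correlations with every
#' variant within \code{window_bp} of it, including itself, so every score
#' is at least 1.
#'
#' @param ld list with \code{snps} and correlation matrix \code{r}.
#' @param positions base-pair positions matching \code{ld$snps}; when
#'   omitted, all pairs are in-window.
#' @param window_bp window half-width (default 1 Mb).
#' @return data.frame with \code{snp} and \code{ell}.
#' @export
ld_scores <- function(ld, positions = NULL, window_bp = 1e6) {
  validate_ld(ld)
  r2 <- ld$r^2
  if (!is.null(positions)) {
    stopifnot(length(positions) == length(ld$snps))
    inwin <- abs(outer(positions, positions, "-")) <= window_bp
    r2 <- r2 * inwin
  }
  data.frame(snp = ld$snps, ell = rowSums(r2), stringsAsFactors = FALSE)
}

#' Simplified LD-score regression
#'
#' Fits the polygenic model \eqn{E[\chi^2_j] = a + (N h^2 / M) \ell_j}
#' by (optionally weighted) least squares of per-variant association
#' chi-square statistics on LD scores. The intercept a captures confounding
#' inflation; the slope times M/N is the SNP heritability. Standard errors
#' come from a delete-one-block jackknife over contiguous blocks of
#' variants. Heteroskedasticity weights \eqn{1/(2 (a + N h^2 \ell/M)^2)} are
#' applied in a second pass using first-pass estimates (the variance of a
#' scaled chi-square); \code{weighted = FALSE} gives plain OLS, under which
#' noise-free linear inputs are recovered exactly.
#'
#' @param chisq per-variant chi-square statistics.
#' @param ell matching LD scores.
#' @param n GWAS sample size.
#' @param m number of variants the heritability is spread over
#'   (default \code{length(chisq)}).
#' @param n_blocks jackknife blocks (default 200, capped at the number of
#'   variants).
#' @param weighted apply two-pass LDSC weights (default TRUE).
#' @return An \code{ldsc_fit} list: \code{intercept, h2, se_intercept,
#'   se_h2, m, n, n_blocks, flag} (flag notes an h2 outside [0, 1]).
#' @export
ldsc_fit <- function(chisq, ell, n, m = length(chisq), n_blocks = 200,
                     weighted = TRUE) {
  stopifnot(length(chisq) == length(ell), n > 0, m > 0)
  keep <- is.finite(chisq) & is.finite(ell)
  chisq <- chisq[keep]; ell <- ell[keep]
  n_blocks <- max(2L, min(as.integer(n_blocks), length(chisq) %/% 2L))
  if (length(chisq) < n_blocks) stop("fewer variants than jackknife blocks")
  if (stats::sd(ell) == 0) stop("degenerate design: constant LD scores")

  fit_once <- function(x, y, w) {
    f <- stats::lm.wfit(cbind(1, x), y, w)
    f$coefficients
  }
  w <- rep(1, length(ell))
  co <- fit_once(ell, chisq, w)
  if (weighted) {
    mu <- pmax(co[1] + co[2] * ell, 0.1) # guard non-positive fitted means
    w <- 1 / (2 * mu^2)
    co <- fit_once(ell, chisq, w)
  }
  blocks <- cut(seq_along(chisq), breaks = n_blocks, labels = FALSE)
  jack <- vapply(seq_len(n_blocks), function(b) {
    keep_b <- blocks != b
    fit_once(ell[keep_b], chisq[keep_b], w[keep_b])
  }, numeric(2))
  # delete-one-block jackknife variance of the coefficients
  jk_se <- sqrt((n_blocks - 1) / n_blocks *
                  rowSums((jack - rowMeans(jack))^2))
  h2 <- co[2] * m / n
  structure(list(intercept = unname(co[1]), h2 = unname(h2),
                 se_intercept = unname(jk_se[1]),
                 se_h2 = unname(jk_se[2] * m / n),
                 m = m, n = n, n_blocks = n_blocks,
                 flag = if (h2 < 0 || h2 > 1) "h2 outside [0,1]" else NA_character_),
            class = "ldsc_fit")
}

#' @export
print.ldsc_fit <- function(x, ...) {
  cat("LD-score regression fit (", x$m, " SNPs, N = ", x$n, ")\n", sep = "")
  cat(sprintf("  intercept: %.4f (SE %.4f)\n", x$intercept, x$se_intercept))
  z <- x$h2 / x$se_h2
  cat(sprintf("  SNP heritability h2: %.4f (SE %.4f, p = %.3g)\n",
              x$h2, x$se_h2, 2 * stats::pnorm(-abs(z))))
  if (!is.na(x$flag)) cat("  note:", x$flag, "\n")
  invisible(x)
}

#' Write or read an LDSC input table / fit report
#'
#' The table dialect is TSV with columns \code{SNP, L2, CHISQ, N}; the fit
#' report is JSON with the intercept, heritability, jackknife SEs and block
#' count.
#'
#' @param snps,ell,chisq,n vectors/scalar forming the table.
#' @param path output path.
#' @export
write_ldsc_table <- function(snps, ell, chisq, n, path) {
  utils::write.table(
    data.frame(SNP = snps, L2 = ell, CHISQ = chisq, N = n),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ldsc_table
#' @param fit an \code{ldsc_fit}.
#' @export
write_ldsc_report <- function(fit, path) {
  jsonlite::write_json(unclass(fit)[c("intercept", "h2", "se_intercept",
                                      "se_h2", "m", "n", "n_blocks")],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
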