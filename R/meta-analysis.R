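#' Inverse-variance meta-analysis of aligned cohort effects
#'
#' Pools per-variant cohort effects with inverse-variance weights. The fixed
#' effects model uses weights \eqn{w_i = 1/se_i^2}; the random-effects model
#' adds the DerSimonian-Laird between-study variance
#' \eqn{\tau^2 = \max(0, (Q - (k-1)) / (\sum w_i - \sum w_i^2/\sum w_i))} and
#' re-weights with \eqn{1/(se_i^2 + \tau^2)}. Heterogeneity per variant is
#' summarised by Cochran's Q, its chi-square p-value on k-1 degrees of
#' freedom, and \eqn{I^2 = \max(0, (Q-(k-1))/Q)}. Two-sided p-values come
#' from the normal approximation to beta/SE; \code{log10p} is also reported
#' so extreme associations do not underflow. Pooled EAF is the
#' sample-size-weighted mean across cohorts.
#'
#' @param aligned an \code{aligned_sumstats} object from
#'   \code{\link{intersect_and_align}}, or a list with matrices
#'   \code{beta}, \code{se} (and optionally \code{eaf}, \code{n}).
#' @param method \code{"fixed"} or \code{"random"}.
#' @return A \code{gwas_meta} data.frame, one row per variant, with columns
#'   \code{rsid, chrom, pos, ea, oa, eaf, beta, se, p, log10p, n, k, q, q_p,
#'   i2, tau2}. Variants with any non-finite input are skipped with a
#'   warning.
#' @seealso \code{\link{heterogeneity}}, \code{\link{define_loci}}
#' @export
meta_gwas <- function(aligned, method = c("fixed", "random")) {
  method <- match.arg(method)
  B <- as.matrix(aligned$beta)
  S <- as.matrix(aligned$se)
  stopifnot(all(dim(B) == dim(S)))
  k_all <- ncol(B)
  if (method == "random" && k_all < 2) {
    stop("random-effects pooling needs >= 2 cohorts; use method = \"fixed\"")
  }
  ok <- apply(is.finite(B) & is.finite(S) & S > 0, 1, all)
  if (any(!ok)) warning(sum(!ok), " variant(s) skipped: non-finite inputs")
  fits <- t(vapply(which(ok), function(i) {
    pool_effects(B[i, ], S[i, ], method = method)
  }, numeric(7)))
  v <- if (!is.null(aligned$variants)) aligned$variants[ok, , drop = FALSE] else
    data.frame(rsid = paste0("snp", which(ok)), chrom = NA, pos = NA,
               ea = NA, oa = NA)
  nmat <- if (!is.null(aligned$n)) as.matrix(aligned$n)[ok, , drop = FALSE] else
    matrix(NA_real_, sum(ok), k_all)
  eafm <- if (!is.null(aligned$eaf)) as.matrix(aligned$eaf)[ok, , drop = FALSE] else
    matrix(NA_real_, sum(ok), k_all)
  eaf_pooled <- rowSums(eafm * nmat) / rowSums(nmat)
  out <- data.frame(
    v,
    eaf = eaf_pooled,
    beta = fits[, 1], se = fits[, 2],
    p = z_pvalue(fits[, 1], fits[, 2]),
    log10p = z_log10p(fits[, 1], fits[, 2]),
    n = rowSums(nmat), k = k_all,
    q = fits[, 3], q_p = fits[, 4], i2 = fits[, 5], tau2 = fits[, 6],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out, method = method, class = c("gwas_meta", "data.frame"))
}

# One variant: pooled (beta, se, Q, Q_P, I2, tau2, k).
#' @keywords internal
pool_effects <- function(betas, ses, method = "fixed") {
  k <- length(betas)
  w <- 1 / ses^2
  beta_fe <- sum(w * betas) / sum(w)
  het <- heterogeneity(betas, ses)
  tau2 <- 0
  if (method == "random" && k >= 2) {
    denom <- sum(w) - sum(w^2) / sum(w)
    tau2 <- if (denom > 0) max(0, (het[["q"]] - (k - 1)) / denom) else 0
    w <- 1 / (ses^2 + tau2)
  }
  beta <- sum(w * betas) / sum(w)
  se <- sqrt(1 / sum(w))
  c(beta, se, het[["q"]], het[["q_p"]], het[["i2"]], tau2, k)
}

#' Cochran's Q, its p-value, and the I-squared statistic
#'
#' \eqn{Q = \sum w_i (\beta_i - \bar\beta)^2} with \eqn{w_i = 1/se_i^2} and
#' \eqn{\bar\beta} the fixed-effects pooled estimate; the p-value is the
#' upper chi-square tail on k-1 degrees of freedom;
#' \eqn{I^2 = \max(0, (Q - (k-1))/Q)} (0 when Q = 0). A single study returns
#' Q = 0, I2 = 0.
#'
#' @param betas,ses numeric vectors of per-study effects and SEs.
#' @return Named vector \code{q, q_p, i2}.
#' @export
heterogeneity <- function(betas, ses) {
  stopifnot(length(betas) == length(ses), all(ses > 0))
  k <- length(betas)
  if (k < 2) return(c(q = 0, q_p = NA_real_, i2 = 0))
  w <- 1 / ses^2
  pooled <- sum(w * betas) / sum(w)
  q <- sum(w * (betas - pooled)^2)
  c(q = q,
    q_p = stats::pchisq(q, df = k - 1, lower.tail = FALSE),
    i2 = i_squared(q, k))
}

#' @rdname heterogeneity
#' @param q Cochran's Q statistic.
#' @param k number of studies.
#' @export
i_squared <- function(q, k) {
  ifelse(q > 0, pmax(0, (q - (k - 1)) / q), 0)
}

#' Genomic inflation factor lambda
#'
#' The median association chi-square statistic divided by the median of the
#' chi-square distribution with one degree of freedom
#' (\code{qchisq(0.5, 1)} = 0.4549). Values near 1 indicate no systematic
#' inflation of test statistics.
#'
#' @param z per-variant z-scores (beta/SE); alternatively supply \code{p}.
#' @param p per-variant two-sided p-values (used when \code{z} missing).
#' @return lambda, a positive scalar.
#' @export
genomic_inflation <- function(z = NULL, p = NULL) {
  chisq <- if (!is.null(z)) z^2 else if (!is.null(p))
    stats::qchisq(p, df = 1, lower.tail = FALSE) else
    stop("supply z-scores or p-values")
  chisq <- chisq[is.finite(chisq)]
  if (!length(chisq)) stop("no finite statistics")
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Variance in the phenotype explained by a single variant
#'
#' For a standardized phenotype, \eqn{r^2 = \beta^2 / (\beta^2 + N se^2)}:
#' the squared association z-score against z-squared plus the sample size.
#'
#' @param beta effect in phenotype SD units.
#' @param se its standard error (> 0).
#' @param n sample size (> 0).
#' @return Fraction of variance in [0, 1).
#' @export
variance_explained <- function(beta, se, n) {
  stopifnot(all(se > 0), all(n > 0))
  beta^2 / (beta^2 + n * se^2)
}

#' Define genome-wide significant loci by greedy clumping
#'
#' Repeatedly takes the unassigned variant with the smallest p-value below
#' the significance threshold and assigns to its locus every significant
#' variant on the same chromosome within \code{window_bp} of it, until no
#' significant variant remains. Each locus is represented by its lead, the
#' member with the strongest association.
#'
#' @param meta a \code{gwas_meta} table (needs \code{chrom, pos, p}).
#' @param p_threshold genome-wide significance threshold (default 5e-8).
#' @param window_bp half-width of the clumping window in base pairs
#'   (default 500 kb).
#' @return List of loci; each has \code{lead} (one-row data.frame),
#'   \code{members} (data.frame of significant members incl. the lead) and
#'   \code{label} (\code{chrom:pos} of the lead).
#' @export
define_loci <- function(meta, p_threshold = 5e-8, window_bp = 5e5) {
  sig <- as.data.frame(meta)[meta$p < p_threshold, , drop = FALSE]
  loci <- list()
  while (nrow(sig)) {
    lead <- sig[which.min(sig$p), , drop = FALSE]
    near <- sig$chrom == lead$chrom & abs(sig$pos - lead$pos) <= window_bp
    members <- sig[near, , drop = FALSE]
    rownames(members) <- rownames(lead) <- NULL
    loci[[length(loci) + 1L]] <- list(
      lead = lead, members = members,
      label = paste0(lead$chrom, ":",
                     format(lead$pos, scientific = FALSE, trim = TRUE))
    )
    sig <- sig[!near, , drop = FALSE]
  }
  loci
}

#' Summarise loci as a one-row-per-locus table
#'
#' @param loci output of \code{\link{define_loci}}.
#' @return data.frame with lead rsid, chrom, pos, beta, se, p, n_members.
#' @export
loci_table <- function(loci) {
  if (!length(loci)) {
    return(data.frame(rsid = character(), chrom = character(), pos = numeric(),
                      beta = numeric(), se = numeric(), p = numeric(),
                      n_members = integer()))
  }
  grab <- function(l, f) if (!is.null(l$lead[[f]])) l$lead[[f]] else NA_real_
  do.call(rbind, lapply(loci, function(l) {
    data.frame(rsid = l$lead$rsid, chrom = l$lead$chrom, pos = l$lead$pos,
               beta = grab(l, "beta"), se = grab(l, "se"), p = l$lead$p,
               n_members = nrow(l$members), stringsAsFactors = FALSE)
  }))
}

#' Approximate conditional scan around a lead variant
#'
#' Conditions each variant's marginal association on the locus lead using an
#' external LD correlation matrix, in the spirit of approximate joint/
#' conditional summary-statistics analysis. Effects are first moved to the
#' standardized-genotype scale (\eqn{b \sqrt{2 f (1-f)}} using the effect
#' allele frequency f) when \code{eaf} is supplied; for a variant j with
#' correlation r to the lead,
#' \deqn{\beta_{j|lead} = (\beta_j - r \beta_{lead}) / (1 - r^2), \quad
#'       se_{j|lead} = se_j / \sqrt{1 - r^2}.}
#' Variants in high collinearity with the lead (\eqn{r^2} above
#' \code{collinear_r2}) are flagged \code{ignored}; variants farther than
#' \code{indep_bp} from the lead are assumed in linkage equilibrium and
#' returned unconditioned (status \code{unconditioned}).
#'
#' @param meta \code{gwas_meta} table for the region (rows must match
#'   \code{ld} order via rsid).
#' @param ld list with \code{snps} (rsids) and \code{r} (correlation matrix),
#'   e.g. from \code{\link{simulate_region}} or \code{\link{read_ld_matrix}}.
#' @param lead rsid of the variant conditioned on.
#' @param collinear_r2 collinearity cutoff (default 0.9).
#' @param indep_bp independence distance in bp (default 10 Mb).
#' @return data.frame with \code{rsid, beta_cond, se_cond, p_cond, status}
#'   (\code{conditioned / ignored / unconditioned / lead}).
#' @export
conditional_scan <- function(meta, ld, lead, collinear_r2 = 0.9,
                             indep_bp = 1e7) {
  meta <- as.data.frame(meta)
  idx <- match(meta$rsid, ld$snps)
  if (anyNA(idx)) stop("meta table contains variants absent from the LD matrix")
  lead_i <- match(lead, meta$rsid)
  if (is.na(lead_i)) stop("lead variant not present in the region")
  std <- if (!is.null(meta$eaf) && all(is.finite(meta$eaf))) {
    sqrt(2 * meta$eaf * (1 - meta$eaf))
  } else rep(1, nrow(meta))
  b <- meta$beta * std
  s <- meta$se * std
  r <- ld$r[idx, idx[lead_i]]
  far <- if (!is.null(meta$pos) && all(is.finite(meta$pos))) {
    abs(meta$pos - meta$pos[lead_i]) > indep_bp
  } else rep(FALSE, nrow(meta))
  one_minus_r2 <- 1 - r^2
  ignored <- !far & (r^2 > collinear_r2 | one_minus_r2 < 1e-8)
  b_c <- ifelse(far, b, (b - r * b[lead_i]) / one_minus_r2)
  s_c <- ifelse(far, s, s / sqrt(one_minus_r2))
  b_c[ignored] <- NA_real_
  s_c[ignored] <- NA_real_
  status <- ifelse(far, "unconditioned", ifelse(ignored, "ignored", "conditioned"))
  status[lead_i] <- "lead"
  b_c[lead_i] <- NA_real_
  s_c[lead_i] <- NA_real_
  # back to the allele-dosage scale
  data.frame(rsid = meta$rsid,
             beta_cond = b_c / std, se_cond = s_c / std,
             p_cond = z_pvalue(b_c, s_c), status = status,
             stringsAsFactors = FALSE)
}

#' @export
print.gwas_meta <- function(x, ...) {
  cat("GWAS meta-analysis (", attr(x, "method"), " effects): ",
      nrow(x), " variants, k = ", x$k[1], " cohorts\n", sep = "")
  top <- as.data.frame(x)[order(x$p), ][seq_len(min(5, nrow(x))), ]
  rownames(top) <- NULL
  cat("Top associations:\n")
  print(top[, intersect(c("rsid", "chrom", "pos", "beta", "se", "p", "i2"),
                        names(top))], ...)
  invisible(x)
}

#' Read / write a whitespace-delimited LD correlation matrix
#'
#' First row holds SNP identifiers; following rows the square correlation
#' matrix. Symmetry, unit diagonal and near positive semi-definiteness are
#' checked on read.
#'
#' @param path file path.
#' @return list with \code{snps} and \code{r}.
#' @export
read_ld_matrix <- function(path) {
  snps <- scan(path, what = "", nlines = 1, quiet = TRUE)
  r <- as.matrix(utils::read.table(path, skip = 1))
  dimnames(r) <- list(snps, snps)
  validate_ld(list(snps = snps, r = r))
}

#' @rdname read_ld_matrix
#' @param ld list with \code{snps} and \code{r}.
#' @export
write_ld_matrix <- function(ld, path) {
  writeLines(paste(ld$snps, collapse = " "), path)
  utils::write.table(ld$r, path, append = TRUE, col.names = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @keywords internal
validate_ld <- function(ld, tol = 1e-6) {
  r <- ld$r
  stopifnot(nrow(r) == ncol(r), length(ld$snps) == nrow(r))
  if (max(abs(r - t(r))) > tol) stop("LD matrix is not symmetric")
  if (max(abs(diag(r) - 1)) > tol) stop("LD matrix diagonal is not 1")
  ev <- min(eigen(r, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -tol) stop("LD matrix is not positive semi-definite")
  ld
}
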