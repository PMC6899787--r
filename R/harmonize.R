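#' Harmonize exposure and outcome summary statistics
#'
#' Aligns outcome associations to the exposure's effect allele for every
#' variant present on both sides, producing the instrument table consumed by
#' the MR estimators. Outcomes reported on the opposite allele have their
#' beta negated and EAF complemented (action \code{flipped}). Non-palindromic
#' allele mismatches are also tested against the strand complement before
#' being dropped (\code{dropped_mismatch}). Palindromic variants (A/T, C/G),
#' whose strand cannot be resolved from the alleles alone, are handled per
#' \code{palindrome_policy}: under \code{"infer"} the orientation is chosen
#' so the two EAFs fall on the same side of 0.5, unless either EAF lies
#' inside the ambiguity band, in which case the variant is dropped
#' (\code{dropped_palindrome}); under \code{"drop"} all palindromes are
#' dropped.
#'
#' @param exposure,outcome data.frames with columns \code{rsid} (or
#'   \code{chrom}+\code{pos}), \code{ea, oa, eaf, beta, se} and optionally
#'   \code{n} — e.g. \code{cohort_panel}s or \code{gwas_meta} rows.
#' @param palindrome_policy \code{"infer"} or \code{"drop"}.
#' @param eaf_ambiguity_band frequencies within this open interval around
#'   0.5 are deemed too close to call strand (default \code{c(0.42, 0.58)}).
#' @return A \code{harmonized_set} data.frame: \code{rsid, ea, oa, beta_exp,
#'   se_exp, eaf_exp, n_exp, beta_out, se_out, eaf_out, n_out, action}. All
#'   shared variants are returned; rows with a \code{dropped_*} action are
#'   excluded by the estimators. Use \code{\link{harmonized_kept}} for the
#'   analysis-ready subset.
#' @export
harmonize_pair <- function(exposure, outcome,
                           palindrome_policy = c("infer", "drop"),
                           eaf_ambiguity_band = c(0.42, 0.58)) {
  palindrome_policy <- match.arg(palindrome_policy)
  exposure <- as.data.frame(exposure)
  outcome <- as.data.frame(outcome)
  key_e <- variant_key(norm_side(exposure))
  key_o <- variant_key(norm_side(outcome))
  shared <- intersect(key_e, key_o)
  if (!length(shared)) stop("exposure and outcome share no variants")
  e <- exposure[match(shared, key_e), , drop = FALSE]
  o <- outcome[match(shared, key_o), , drop = FALSE]
  comp <- function(a) chartr("ACGT", "TGCA", a)
  is_palin <- e$ea == comp(e$oa)
  n <- length(shared)
  beta_out <- o$beta; eaf_out <- o$eaf
  action <- rep("kept", n)
  for (i in seq_len(n)) {
    same <- o$ea[i] == e$ea[i] && o$oa[i] == e$oa[i]
    swap <- o$ea[i] == e$oa[i] && o$oa[i] == e$ea[i]
    if (!is_palin[i]) {
      if (!same && !swap) { # strand-complement rescue
        same <- comp(o$ea[i]) == e$ea[i] && comp(o$oa[i]) == e$oa[i]
        swap <- comp(o$ea[i]) == e$oa[i] && comp(o$oa[i]) == e$ea[i]
      }
      if (swap) {
        beta_out[i] <- -beta_out[i]; eaf_out[i] <- 1 - eaf_out[i]
        action[i] <- "flipped"
      } else if (!same) action[i] <- "dropped_mismatch"
    } else {
      if (!same && !swap) { action[i] <- "dropped_mismatch"; next }
      if (palindrome_policy == "drop") { action[i] <- "dropped_palindrome"; next }
      if (swap) { beta_out[i] <- -beta_out[i]; eaf_out[i] <- 1 - eaf_out[i] }
      ambiguous <- (e$eaf[i] > eaf_ambiguity_band[1] & e$eaf[i] < eaf_ambiguity_band[2]) ||
        (eaf_out[i] > eaf_ambiguity_band[1] & eaf_out[i] < eaf_ambiguity_band[2])
      if (is.na(ambiguous) || ambiguous) { action[i] <- "dropped_palindrome"; next }
      if ((e$eaf[i] < 0.5) != (eaf_out[i] < 0.5)) { # opposite strand inferred
        beta_out[i] <- -beta_out[i]; eaf_out[i] <- 1 - eaf_out[i]
      }
      action[i] <- "palindrome_inferred"
    }
  }
  out <- data.frame(
    rsid = shared, ea = e$ea, oa = e$oa,
    beta_exp = e$beta, se_exp = e$se, eaf_exp = e$eaf,
    n_exp = e$n %||% rep(NA_real_, n),
    beta_out = beta_out, se_out = o$se, eaf_out = eaf_out,
    n_out = o$n %||% rep(NA_real_, n),
    action = action, stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out, class = c("harmonized_set", "data.frame"))
}

# Ensure the key columns exist so variant_key() works on arbitrary frames.
#' @keywords internal
norm_side <- function(df) {
  n <- nrow(df)
  if (is.null(df$rsid)) df$rsid <- rep(NA_character_, n)
  if (is.null(df$chrom)) df$chrom <- rep(NA_character_, n)
  if (is.null(df$pos)) df$pos <- rep(NA_real_, n)
  df
}

#' @rdname harmonize_pair
#' @param h a \code{harmonized_set}.
#' @export
harmonized_kept <- function(h) {
  h[h$action %in% c("kept", "flipped", "palindrome_inferred",
                    "proxy_substituted"), , drop = FALSE]
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat("Harmonized exposure-outcome set:", nrow(x), "shared variants\n")
  print(table(x$action))
  invisible(x)
}

#' Find the best LD proxy for a variant
#'
#' Returns the candidate with the largest squared correlation to the target
#' among candidates at \eqn{r^2 \ge} \code{r2_min}; the target itself (when a
#' candidate) trivially wins with r2 = 1. Ties are broken by smaller
#' base-pair distance, then lexicographic rsid.
#'
#' @param target rsid of the variant needing a proxy.
#' @param ld list with \code{snps} and correlation matrix \code{r}
#'   containing the target and candidates.
#' @param candidates rsids available in the outcome data (default: all of
#'   \code{ld$snps}).
#' @param r2_min minimum squared correlation (default 0.8).
#' @param positions base-pair positions matching \code{ld$snps}, used only
#'   for tie-breaking.
#' @return The proxy rsid, or \code{NA_character_} when no candidate
#'   qualifies.
#' @export
find_proxies <- function(target, ld, candidates = ld$snps, r2_min = 0.8,
                         positions = NULL) {
  ti <- match(target, ld$snps)
  if (is.na(ti)) stop("target variant absent from the LD matrix")
  ci <- match(candidates, ld$snps)
  ci <- ci[!is.na(ci)]
  if (!length(ci)) return(NA_character_)
  r2 <- ld$r[ci, ti]^2
  dist <- if (!is.null(positions)) abs(positions[ci] - positions[ti]) else
    rep(0, length(ci))
  ok <- r2 >= r2_min
  if (!any(ok)) return(NA_character_)
  ord <- order(-r2, dist, ld$snps[ci])
  ld$snps[ci][ord][which(ok[ord])[1]]
}

#' Variance explained by a single association z-score
#'
#' For a standardized trait, the squared correlation between genotype and
#' phenotype implied by a z-score at sample size n: \eqn{r^2 = z^2/(z^2+n)}.
#' The workhorse of Steiger directionality comparisons.
#'
#' @param z association z-score (beta/SE).
#' @param n sample size (> 2).
#' @return r-squared in [0, 1).
#' @export
steiger_r2 <- function(z, n) {
  stopifnot(all(n > 2))
  z^2 / (z^2 + n)
}

#' Steiger directionality filtering of harmonized instruments
#'
#' For each instrument, compares the variance explained in the exposure with
#' the variance explained in the outcome. Instruments are retained when they
#' explain strictly more variance in the exposure (their "primary effect"),
#' guarding against reverse causation. The difference is tested with the
#' Fisher-z statistic
#' \deqn{z = \frac{\mathrm{atanh}(r_{exp}) - \mathrm{atanh}(r_{out})}
#'            {\sqrt{1/(n_{exp}-3) + 1/(n_{out}-3)}}.}
#'
#' @param h a \code{harmonized_set} (or its kept subset).
#' @param n_exp,n_out sample sizes; default to the per-SNP columns of
#'   \code{h}.
#' @param alpha optional significance gate: when non-NULL an instrument must
#'   additionally have Steiger p below \code{alpha} to be retained.
#' @return list with \code{retained} (the filtered harmonized set) and
#'   \code{steiger}, a per-SNP data.frame of \code{rsid, r2_exp, r2_out, z,
#'   p, correct_direction}.
#' @export
steiger_filter <- function(h, n_exp = NULL, n_out = NULL, alpha = NULL) {
  h <- harmonized_kept(h)
  n_exp <- n_exp %||% h$n_exp
  n_out <- n_out %||% h$n_out
  if (any(!is.finite(n_exp)) || any(!is.finite(n_out)) ||
      any(n_exp <= 3) || any(n_out <= 3)) {
    stop("Steiger filtering needs sample sizes > 3 on both sides")
  }
  r2_exp <- steiger_r2(h$beta_exp / h$se_exp, n_exp)
  r2_out <- steiger_r2(h$beta_out / h$se_out, n_out)
  z <- (atanh(sqrt(r2_exp)) - atanh(sqrt(r2_out))) /
    sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  res <- data.frame(
    rsid = h$rsid, r2_exp = r2_exp, r2_out = r2_out, z = z,
    p = 2 * stats::pnorm(-abs(z)),
    correct_direction = r2_exp > r2_out,
    stringsAsFactors = FALSE
  )
  keep <- res$correct_direction
  if (!is.null(alpha)) keep <- keep & res$p < alpha
  list(retained = h[keep, , drop = FALSE], steiger = res)
}
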