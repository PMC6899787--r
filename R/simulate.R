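# Synthetic-GWAS generator: every input the inference chain consumes, with
# known ground truth, so parameter recovery can be tested end to end.
# Summary statistics are simulated directly on the standardized-phenotype
# scale (no individual-level genotypes), with an optional small-n
# individual-level mode that serves as the oracle for the conditional scan.

#' Simulation configuration
#'
#' Bundles the generator's parameters with their defaults: the default
#' cohort sizes are the four-study design of a ~10.6k-participant
#' protein GWAS (7292, 1041, 1316, 935); LD is AR(1) within blocks with
#' correlation \code{rho}; \code{theta} is the true causal effect of the
#' exposure on the outcome in SD-per-SD units; \code{alpha_pleio} and
#' \code{pleio_sd} control directional horizontal pleiotropy;
#' \code{h2_exp} is the exposure variance jointly explained by the causal
#' variants; \code{n_out} is the outcome-GWAS size (default 426824, a
#' biobank-scale quantitative outcome).
#'
#' @param m_variants number of variants in the region.
#' @param n_blocks number of independent LD blocks.
#' @param rho within-block AR(1) correlation, |rho| < 1.
#' @param maf_range MAFs are drawn uniformly on this interval.
#' @param cohort_ns exposure cohort sample sizes.
#' @param theta causal effect of exposure on outcome.
#' @param alpha_pleio mean directional pleiotropic effect on the outcome.
#' @param pleio_sd SD of per-variant pleiotropy.
#' @param h2_exp exposure variance explained by the causal variants.
#' @param n_causal number of causal variants (placed in distinct blocks).
#' @param n_out outcome GWAS sample size.
#' @param seed default RNG seed for generators using this config.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(m_variants = 60, n_blocks = 6, rho = 0.5,
                       maf_range = c(0.05, 0.5),
                       cohort_ns = c(ALSPAC = 7292, FourD = 1041,
                                     GOOD = 1316, MANOLIS = 935),
                       theta = -0.12, alpha_pleio = 0, pleio_sd = 0,
                       h2_exp = 0.02, n_causal = 2, n_out = 426824,
                       seed = 1L) {
  stopifnot(abs(rho) < 1, all(cohort_ns > 0), h2_exp >= 0, pleio_sd >= 0,
            m_variants >= n_blocks, n_causal <= n_blocks)
  structure(as.list(environment()), class = "sim_config")
}

#' @keywords internal
with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  expr
}

#' Simulate an LD-blocked genomic region with planted causal variants
#'
#' Builds a block-diagonal AR(1) LD correlation matrix
#' (\eqn{r_{jk} = \rho^{|j-k|}} within a block, 0 across blocks), uniform
#' MAFs, evenly spaced positions, and a ground-truth record: \code{n_causal}
#' causal variants in distinct blocks with standardized joint effects
#' scaled so they jointly explain \code{h2_exp} of the exposure variance;
#' the marginal (LD-convolved) effects are \eqn{R b}.
#'
#' @param config a \code{sim_config}.
#' @param seed RNG seed (default \code{config$seed}).
#' @return list with \code{ld} (\code{snps}, \code{r}), \code{positions},
#'   \code{mafs}, \code{snps}, \code{blocks} and \code{truth}
#'   (\code{causal_idx}, \code{joint}, \code{marginal} on the
#'   standardized-genotype scale, and \code{theta}).
#' @export
simulate_region <- function(config, seed = config$seed) {
  m <- config$m_variants
  blocks <- sort(rep_len(seq_len(config$n_blocks), m))
  r <- matrix(0, m, m)
  for (b in unique(blocks)) {
    i <- which(blocks == b)
    r[i, i] <- config$rho^abs(outer(seq_along(i), seq_along(i), "-"))
  }
  snps <- sprintf("rs%05d", seq_len(m))
  dimnames(r) <- list(snps, snps)
  with_seed(seed, {
    mafs <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    # one causal variant per sampled block, mid-block
    causal_blocks <- sample(unique(blocks), config$n_causal)
    causal_idx <- vapply(causal_blocks, function(b) {
      i <- which(blocks == b)
      i[ceiling(length(i) / 2)]
    }, integer(1))
    joint <- numeric(m)
    if (config$n_causal > 0 && config$h2_exp > 0) {
      joint[causal_idx] <- sqrt(config$h2_exp / config$n_causal) *
        sample(c(-1, 1), config$n_causal, replace = TRUE)
    }
    list(
      ld = list(snps = snps, r = r),
      positions = seq_len(m) * 5000,
      mafs = mafs, snps = snps, blocks = blocks,
      truth = list(causal_idx = sort(causal_idx), joint = joint,
                   marginal = as.numeric(r %*% joint), theta = config$theta)
    )
  })
}

#' Simulate per-cohort exposure GWAS summary statistics
#'
#' For each cohort of size n, the allele-dosage-scale standard error of a
#' variant with MAF f on a standardized phenotype is
#' \eqn{se_j = 1/\sqrt{2 f (1-f) n}}; the estimate is drawn
#' \eqn{\hat\beta_j \sim N(\beta_j^{marg}, se_j^2)} around the LD-convolved
#' truth, the reported EAF adds binomial resampling noise at 2n draws, and
#' the p-value follows from \eqn{\hat\beta/se}. Per-cohort seeds are derived
#' deterministically from (seed, cohort label). The last cohort is emitted
#' without an imputation-quality score (a sequenced cohort); the others get
#' scores near 1.
#'
#' @param region output of \code{\link{simulate_region}}.
#' @param cohort_ns named vector of cohort sizes.
#' @param seed base RNG seed.
#' @return list of \code{cohort_panel} objects.
#' @export
simulate_exposure_gwas <- function(region, cohort_ns, seed = 1L) {
  m <- length(region$snps)
  labels <- names(cohort_ns) %||% paste0("cohort", seq_along(cohort_ns))
  std <- sqrt(2 * region$mafs * (1 - region$mafs))
  beta_marg <- region$truth$marginal / std  # allele-dosage scale
  panels <- lapply(seq_along(cohort_ns), function(ci) {
    n <- cohort_ns[[ci]]
    with_seed(derive_seed(seed, labels[ci]), {
      se <- 1 / (std * sqrt(n))
      bhat <- stats::rnorm(m, beta_marg, se)
      eaf <- stats::rbinom(m, 2 * n, region$mafs) / (2 * n)
      info <- if (ci == length(cohort_ns)) rep(NA_real_, m) else
        stats::runif(m, 0.85, 1)
      new_cohort_panel(data.frame(
        rsid = region$snps, chrom = "1", pos = region$positions,
        ea = "A", oa = "G", eaf = eaf, beta = bhat, se = se,
        p = pmax(z_pvalue(bhat, se), .Machine$double.xmin),
        n = n, info = info, stringsAsFactors = FALSE
      ), label = labels[ci])
    })
  })
  names(panels) <- labels
  panels
}

#' Simulate outcome GWAS summary statistics with a planted causal effect
#'
#' Outcome marginal effects are \eqn{\theta} times the exposure's marginal
#' effects plus LD-convolved per-variant pleiotropy (joint pleiotropic
#' effects drawn \eqn{N(\alpha, pleio\_sd^2)} at the causal variants) plus
#' sampling noise at size \code{n_out}. With \code{binary = TRUE} the
#' effects are interpreted as log odds ratios; the generative mechanics are
#' identical (effects are already on a per-SD-of-exposure scale).
#'
#' @param region output of \code{\link{simulate_region}}.
#' @param theta true causal effect.
#' @param alpha_pleio,pleio_sd directional pleiotropy mean and SD.
#' @param n_out outcome sample size.
#' @param seed RNG seed.
#' @param binary flag the panel as a case-control outcome.
#' @return A \code{cohort_panel} with attribute \code{truth} (the outcome
#'   marginal effects and the per-variant pleiotropy actually drawn) and
#'   \code{binary}.
#' @export
simulate_outcome_gwas <- function(region, theta, alpha_pleio = 0,
                                  pleio_sd = 0, n_out = 426824, seed = 2L,
                                  binary = FALSE) {
  m <- length(region$snps)
  std <- sqrt(2 * region$mafs * (1 - region$mafs))
  with_seed(derive_seed(seed, "outcome"), {
    pleio_joint <- numeric(m)
    ci <- region$truth$causal_idx
    if (length(ci) && (alpha_pleio != 0 || pleio_sd > 0)) {
      pleio_joint[ci] <- stats::rnorm(length(ci), alpha_pleio, pleio_sd)
    }
    marg_out_std <- theta * region$truth$marginal +
      as.numeric(region$ld$r %*% pleio_joint)
    beta_marg <- marg_out_std / std
    se <- 1 / (std * sqrt(n_out))
    bhat <- stats::rnorm(m, beta_marg, se)
    eaf <- stats::rbinom(m, 2 * n_out, region$mafs) / (2 * n_out)
    panel <- new_cohort_panel(data.frame(
      rsid = region$snps, chrom = "1", pos = region$positions,
      ea = "A", oa = "G", eaf = eaf, beta = bhat, se = se,
      p = pmax(z_pvalue(bhat, se), .Machine$double.xmin),
      n = n_out, info = NA_real_, stringsAsFactors = FALSE
    ), label = "outcome")
    attr(panel, "truth") <- list(marginal_std = marg_out_std,
                                 pleio_joint = pleio_joint, theta = theta)
    attr(panel, "binary") <- binary
    panel
  })
}

#' Simulate an instrument-level harmonized set directly
#'
#' Bypasses the regional machinery to produce k independent instruments for
#' estimator recovery studies: true exposure effects are spaced so the
#' instruments jointly explain \code{h2_exp} of the exposure; observed
#' effects add sampling noise at sizes \code{n_exp} and \code{n_out}; the
#' outcome effect of instrument j is
#' \eqn{\theta \beta_{x,j} + \alpha_j} with pleiotropy
#' \eqn{\alpha_j \sim N(\alpha, pleio\_sd^2)}.
#'
#' @param k number of instruments.
#' @param theta true causal effect.
#' @param n_exp,n_out exposure / outcome GWAS sizes.
#' @param h2_exp exposure variance jointly explained by the instruments.
#' @param alpha_pleio,pleio_sd directional pleiotropy mean and SD.
#' @param invalid_frac fraction of instruments given extra large-magnitude
#'   pleiotropy (for median-robustness studies).
#' @param invalid_effect pleiotropic offset of the invalid instruments.
#' @param seed RNG seed.
#' @return A \code{harmonized_set} with attribute \code{truth}.
#' @export
simulate_mr_instruments <- function(k, theta, n_exp = 10584, n_out = 426824,
                                    h2_exp = 0.05, alpha_pleio = 0,
                                    pleio_sd = 0, invalid_frac = 0,
                                    invalid_effect = 0, seed = 1L) {
  with_seed(derive_seed(seed, "instruments"), {
    maf <- stats::runif(k, 0.1, 0.5)
    std <- sqrt(2 * maf * (1 - maf))
    # instruments oriented to the exposure-increasing allele (the two-sample
    # convention), so directional pleiotropy keeps a coherent sign;
    # per-instrument variance contributions are exponential (heavy-tailed
    # effect sizes, as in real GWAS hit lists) so instrument strength varies
    g <- stats::rexp(k)
    bx_std <- sqrt(h2_exp * g / sum(g))
    bx <- bx_std / std
    se_x <- 1 / (std * sqrt(n_exp))
    se_y <- 1 / (std * sqrt(n_out))
    # pleiotropic effects act directly on the outcome, allele-dosage scale
    alpha <- if (alpha_pleio != 0 || pleio_sd > 0)
      stats::rnorm(k, alpha_pleio, pleio_sd) else numeric(k)
    n_bad <- round(invalid_frac * k)
    if (n_bad > 0) alpha[seq_len(n_bad)] <- alpha[seq_len(n_bad)] + invalid_effect
    by <- theta * bx + alpha
    bx_hat <- stats::rnorm(k, bx, se_x)
    by_hat <- stats::rnorm(k, by, se_y)
    h <- data.frame(
      rsid = sprintf("iv%03d", seq_len(k)), ea = "A", oa = "G",
      beta_exp = bx_hat, se_exp = se_x, eaf_exp = maf, n_exp = n_exp,
      beta_out = by_hat, se_out = se_y, eaf_out = maf, n_out = n_out,
      action = "kept", stringsAsFactors = FALSE
    )
    attr(h, "truth") <- list(theta = theta, bx = bx, alpha = alpha)
    class(h) <- c("harmonized_set", "data.frame")
    h
  })
}

#' Simulate a pair of regional traits for colocalization
#'
#' Plants a causal variant with association z-score \code{z1} in trait 1
#' and \code{z2} in trait 2 — at the same variant when \code{shared}, at
#' variants in distinct LD blocks otherwise — and propagates the signal
#' through LD (a SNP correlated r with the causal variant has expected
#' z-score \eqn{r z}). z = 0 gives a null trait.
#'
#' @param region output of \code{\link{simulate_region}}.
#' @param shared one shared causal variant (TRUE) or distinct ones (FALSE).
#' @param z1,z2 causal-variant z-scores for the two traits.
#' @param se0 per-SNP standard error for both traits (default 0.02).
#' @param seed RNG seed.
#' @return list of two \code{regional_trait} data.frames
#'   (\code{snp, beta, se}) with attribute \code{causal_idx}.
#' @export
simulate_coloc_pair <- function(region, shared = TRUE, z1 = 12, z2 = 12,
                                se0 = 0.02, seed = 3L) {
  m <- length(region$snps)
  stopifnot(shared || m >= 2)
  with_seed(derive_seed(seed, "coloc"), {
    blocks <- region$blocks
    i1 <- sample(m, 1)
    i2 <- if (shared) i1 else {
      other <- which(blocks != blocks[i1])
      if (!length(other)) stop("need >= 2 LD blocks for distinct causal variants")
      other[sample(length(other), 1)]
    }
    one_trait <- function(ci, z) {
      mu <- region$ld$r[, ci] * z * se0
      if (z == 0) mu <- rep(0, m)
      b <- stats::rnorm(m, mu, se0)
      structure(data.frame(snp = region$snps, beta = b, se = se0,
                           stringsAsFactors = FALSE),
                class = c("regional_trait", "data.frame"))
    }
    out <- list(trait1 = one_trait(i1, z1), trait2 = one_trait(i2, z2))
    attr(out, "causal_idx") <- c(trait1 = i1, trait2 = i2)
    out
  })
}

#' Simulate individual-level genotypes and phenotype for a small region
#'
#' The small-n oracle mode: multivariate-normal liability genotypes with the
#' region's LD structure (standardized scale), phenotype
#' \eqn{y = X b_{joint} + e} with unit total variance. Used to cross-check
#' summary-statistic operations (marginal betas, the conditional scan)
#' against ordinary least squares on real data rows.
#'
#' @param region output of \code{\link{simulate_region}}.
#' @param n individuals.
#' @param seed RNG seed.
#' @return list with standardized genotype matrix \code{X} (n x m) and
#'   phenotype \code{y}.
#' @export
simulate_individual_level <- function(region, n, seed = 4L) {
  r <- region$ld$r
  m <- ncol(r)
  with_seed(derive_seed(seed, "individual"), {
    ev <- eigen(r, symmetric = TRUE)
    A <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
    X <- matrix(stats::rnorm(n * m), n, m) %*% A
    g <- as.numeric(X %*% region$truth$joint)
    e <- stats::rnorm(n, 0, sqrt(max(1e-8, 1 - sum(region$truth$joint^2))))
    list(X = X, y = g + e)
  })
}

#' Write a complete demo fixture tree
#'
#' Emits, under \code{dir}, the exact file dialects the pipeline consumes:
#' per-cohort exposure summary statistics (\code{<label>.tsv}), an outcome
#' file (\code{outcome.tsv}), the region's LD matrix (\code{ld.txt}) and an
#' aligned coloc region pair (\code{trait1.tsv}, \code{trait2.tsv}).
#'
#' @param dir output directory (created if needed).
#' @param config a \code{sim_config}.
#' @param seed RNG seed (default \code{config$seed}).
#' @return \code{dir}, invisibly.
#' @export
write_fixture_set <- function(dir, config = sim_config(),
                              seed = config$seed) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  region <- simulate_region(config, seed)
  panels <- simulate_exposure_gwas(region, config$cohort_ns, seed)
  outcome <- simulate_outcome_gwas(region, config$theta, config$alpha_pleio,
                                   config$pleio_sd, config$n_out, seed)
  for (p in panels) {
    write_sumstats(p, file.path(dir, paste0(attr(p, "label"), ".tsv")))
  }
  write_sumstats(outcome, file.path(dir, "outcome.tsv"))
  write_ld_matrix(region$ld, file.path(dir, "ld.txt"))
  pair <- simulate_coloc_pair(region, shared = TRUE, seed = seed)
  for (nm in names(pair)) {
    utils::write.table(pair[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
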