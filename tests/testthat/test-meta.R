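test_that("fixed-effects pooling matches hand-computed and k=1 passthrough", {
  # identical studies: pooled SE = SE/sqrt(2)
  f <- gwasmr:::pool_effects(c(0.2, 0.2), c(0.02, 0.02), "fixed")
  expect_equal(f[1], 0.2)
  expect_equal(f[2], 0.02 / sqrt(2), tolerance = 1e-10)
  # equal weights: simple mean, Q = 2
  f2 <- gwasmr:::pool_effects(c(0.1, 0.3), c(0.1, 0.1), "fixed")
  expect_equal(f2[1], 0.2)
  expect_equal(f2[2], 0.1 / sqrt(2), tolerance = 1e-10)
  expect_equal(f2[3], 2.0)
  # single cohort passthrough
  f3 <- gwasmr:::pool_effects(0.205, 0.014, "fixed")
  expect_equal(f3[1:2], c(0.205, 0.014))
  expect_equal(f3[c(3, 5)], c(0, 0)) # Q, I2
})

test_that("DerSimonian-Laird random effects: hand value, truncation, monotonicity", {
  # (0.1, 0.1), (0.3, 0.1): Q = 2, tau2 = (2-1)/(200-100) = 0.01
  r <- gwasmr:::pool_effects(c(0.1, 0.3), c(0.1, 0.1), "random")
  expect_equal(r[6], 0.01)
  expect_equal(r[1], 0.2)
  expect_equal(r[2], sqrt(1 / (2 / (0.01 + 0.01))), tolerance = 1e-10) # 0.1
  # homogeneous input: tau2 = 0, equals fixed effects
  hom <- gwasmr:::pool_effects(c(0.2, 0.21), c(0.1, 0.1), "random")
  fix <- gwasmr:::pool_effects(c(0.2, 0.21), c(0.1, 0.1), "fixed")
  expect_equal(hom[6], 0)
  expect_equal(hom[1:2], fix[1:2])
  # pooled beta strictly increases when one study effect increases
  b1 <- gwasmr:::pool_effects(c(0.1, 0.3), c(0.1, 0.2), "random")[1]
  b2 <- gwasmr:::pool_effects(c(0.1, 0.4), c(0.1, 0.2), "random")[1]
  expect_gt(b2, b1)
})

test_that("pooled estimates agree with an independent meta-analysis library", {
  skip_if_not_installed("metafor")
  set.seed(7)
  yi <- rnorm(4, 0.1, 0.05)
  sei <- runif(4, 0.02, 0.08)
  fe <- metafor::rma(yi = yi, sei = sei, method = "FE")
  f <- gwasmr:::pool_effects(yi, sei, "fixed")
  expect_equal(f[1], unname(fe$beta[1]), tolerance = 1e-8)
  expect_equal(f[2], fe$se, tolerance = 1e-8)
  expect_equal(f[3], fe$QE, tolerance = 1e-8)
  dl <- metafor::rma(yi = yi, sei = sei, method = "DL")
  r <- gwasmr:::pool_effects(yi, sei, "random")
  expect_equal(r[1], unname(dl$beta[1]), tolerance = 1e-8)
  expect_equal(r[2], dl$se, tolerance = 1e-8)
  expect_equal(r[6], dl$tau2, tolerance = 1e-8)
})

test_that("heterogeneity reproduces published-scale I2 values and invariances", {
  # printed four-cohort Q statistics and their I2
  expect_equal(i_squared(13.43, 4), 0.777, tolerance = 5e-4)
  expect_equal(i_squared(0.955, 4), 0)
  expect_equal(i_squared(6.416, 4), 0.532, tolerance = 1e-3)
  # perfect homogeneity
  h <- heterogeneity(rep(0.3, 4), rep(0.05, 4))
  expect_equal(unname(h[c("q", "i2")]), c(0, 0))
  # I2 invariant to common rescaling of (beta, se)
  set.seed(1)
  b <- rnorm(4); s <- runif(4, 0.05, 0.2)
  expect_equal(heterogeneity(b, s)[["i2"]],
               heterogeneity(3.7 * b, 3.7 * s)[["i2"]], tolerance = 1e-12)
})

test_that("meta_gwas pools an aligned table and random SE >= fixed SE", {
  cfg <- sim_config(m_variants = 40, n_blocks = 4)
  region <- simulate_region(cfg, 9)
  panels <- simulate_exposure_gwas(region, cfg$cohort_ns, 9)
  al <- intersect_and_align(panels)
  mf <- meta_gwas(al, "fixed")
  mr <- meta_gwas(al, "random")
  expect_equal(nrow(mf), 40)
  expect_true(all(mr$se >= mf$se - 1e-12))
  # fixed pooled SE never exceeds the smallest cohort SE
  expect_true(all(mf$se <= apply(al$se, 1, min) + 1e-12))
  # pooled EAF is the N-weighted cohort mean
  i <- 5
  expect_equal(mf$eaf[i],
               sum(al$eaf[i, ] * al$n[i, ]) / sum(al$n[i, ]))
  # p and log10p agree where p does not underflow
  expect_equal(log10(mf$p[i]), mf$log10p[i], tolerance = 1e-8)
})

test_that("genomic inflation: calibration point, derived value, null Monte Carlo", {
  expect_equal(genomic_inflation(z = rep(sqrt(qchisq(0.5, 1)), 5)), 1.0)
  expect_equal(genomic_inflation(z = sqrt(c(1, 2, 3))),
               2 / qchisq(0.5, 1), tolerance = 1e-10)
  # p-value interface matches the z interface
  z <- c(0.5, 1.5, 2.5)
  expect_equal(genomic_inflation(p = 2 * pnorm(-abs(z))),
               genomic_inflation(z = z), tolerance = 1e-10)
  set.seed(2024)
  lam <- genomic_inflation(z = rnorm(1e4))
  expect_gt(lam, 0.9); expect_lt(lam, 1.1)
})

test_that("variance explained reproduces the published two-decimal values", {
  expect_equal(round(100 * variance_explained(0.205, 0.014, 10584), 2), 1.99)
  expect_equal(round(100 * variance_explained(0.109, 0.017, 10584), 2), 0.39)
  expect_equal(round(100 * variance_explained(0.074, 0.014, 10584), 2), 0.26)
  expect_equal(variance_explained(0, 0.01, 1000), 0)
})

test_that("greedy locus definition: leads, windows, separation", {
  meta <- data.frame(
    rsid = paste0("rs", 1:6), chrom = c("1", "1", "1", "1", "2", "2"),
    pos = c(1e6, 1.4e6, 1.9e6, 9e6, 1e6, 1.2e6),
    p = c(1e-9, 1e-10, 1e-8, 1e-12, 1e-9, 0.5)
  )
  loci <- define_loci(meta, p_threshold = 5e-8, window_bp = 5e5)
  tab <- loci_table(loci)
  # rs4 (1e-12) seeds first but is isolated; rs2 seeds chr1 cluster
  expect_setequal(tab$rsid, c("rs2", "rs4", "rs5"))
  chr1 <- loci[[which(tab$rsid == "rs2")]]
  expect_equal(sort(chr1$members$rsid), c("rs1", "rs2", "rs3"))
  expect_equal(chr1$lead$rsid, "rs2")
  # lead has the smallest p among members
  for (l in loci) expect_equal(min(l$members$p), l$lead$p)
  # leads on the same chromosome are separated by more than the window
  for (ch in unique(tab$chrom)) {
    pos <- sort(tab$pos[tab$chrom == ch])
    if (length(pos) > 1) expect_true(all(diff(pos) > 5e5))
  }
  # nothing significant -> empty
  expect_length(define_loci(data.frame(rsid = "a", chrom = "1", pos = 1,
                                       p = 1e-4)), 0)
})

test_that("conditional scan: independence, shadow signals, collinearity flag", {
  ld <- list(snps = c("lead", "shadow", "indep", "collinear"),
             r = matrix(c(1, 0.5, 0, 0.96,
                          0.5, 1, 0, 0.45,
                          0, 0, 1, 0,
                          0.96, 0.45, 0, 1), 4, 4))
  # make it PSD enough for validation-free use; conditional_scan only reads
  # the lead column
  meta <- data.frame(rsid = ld$snps, chrom = "1",
                     pos = c(1e6, 1.01e6, 1.02e6, 1.03e6),
                     beta = c(0.3, 0.15, 0.15, 0.29),
                     se = c(0.01, 0.01, 0.01, 0.01))
  cs <- conditional_scan(meta, ld, lead = "lead")
  expect_equal(cs$status, c("lead", "conditioned", "conditioned", "ignored"))
  # shadow: marginal exactly r * lead -> conditional effect 0
  expect_equal(cs$beta_cond[2], 0, tolerance = 1e-12)
  expect_equal(cs$se_cond[2], 0.01 / sqrt(1 - 0.25), tolerance = 1e-12)
  # independent SNP untouched
  expect_equal(cs$beta_cond[3], 0.15)
  expect_equal(cs$se_cond[3], 0.01)
  # collinear (r^2 = 0.9216 > 0.9) flagged, no estimate
  expect_true(is.na(cs$beta_cond[4]))
  # beyond the independence distance: returned unconditioned
  meta2 <- meta; meta2$pos[3] <- 2e7
  cs2 <- conditional_scan(meta2, ld, lead = "lead")
  expect_equal(cs2$status[3], "unconditioned")
})

test_that("conditional scan agrees with two-SNP OLS on individual-level data", {
  for (r in c(0, 0.3, 0.5, 0.8)) {
    cfg <- sim_config(m_variants = 2, n_blocks = 1, rho = r, n_causal = 1,
                      h2_exp = 0.05)
    region <- simulate_region(cfg, 100 + round(100 * r))
    iv <- simulate_individual_level(region, n = 5000, seed = 3)
    # marginal summary statistics from the simulated individuals
    marg <- lapply(1:2, function(j) {
      f <- summary(lm(iv$y ~ iv$X[, j]))$coefficients[2, 1:2]
      f
    })
    meta <- data.frame(rsid = region$snps, chrom = "1", pos = region$positions,
                       beta = vapply(marg, `[`, 0, 1),
                       se = vapply(marg, `[`, 0, 2))
    cs <- conditional_scan(meta, region$ld, lead = region$snps[1])
    joint <- summary(lm(iv$y ~ iv$X[, 1] + iv$X[, 2]))$coefficients
    expect_lt(abs(cs$beta_cond[2] - joint[3, 1]), 2 * joint[3, 2])
  }
})

test_that("LD matrix file round-trip and validation", {
  cfg <- sim_config(m_variants = 6, n_blocks = 2, rho = 0.4)
  region <- simulate_region(cfg, 5)
  path <- tempfile(fileext = ".txt")
  write_ld_matrix(region$ld, path)
  ld2 <- read_ld_matrix(path)
  expect_equal(ld2$snps, region$ld$snps)
  expect_equal(unname(ld2$r), unname(region$ld$r), tolerance = 1e-12)
  bad <- region$ld
  bad$r[1, 2] <- 0.9 # breaks symmetry
  expect_error(gwasmr:::validate_ld(bad), "symmetric")
})
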