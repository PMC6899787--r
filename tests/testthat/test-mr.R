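test_that("Wald ratio: value, SE, orientation invariance, second-order delta", {
  h <- make_hset(bx = 0.2, by = -0.05, se_x = 0.005, se_y = 0.01)
  w <- wald_ratio(h)
  expect_equal(w$beta, -0.25)
  expect_equal(w$se, 0.05)
  expect_equal(w$ci_low, -0.25 - 1.96 * 0.05)
  # simultaneous sign flip leaves the estimate unchanged
  h_flip <- make_hset(bx = -0.2, by = 0.05, se_x = 0.005, se_y = 0.01)
  expect_equal(wald_ratio(h_flip)$beta, w$beta)
  expect_equal(wald_ratio(h_flip)$se, w$se)
  expect_error(wald_ratio(make_hset(0, 0.1, 0.01, 0.01)), "null exposure")

  # second-order SE against a Monte-Carlo delta oracle (z_x = 40: the
  # ratio distribution is effectively normal)
  h2 <- make_hset(bx = 0.2, by = -0.05, se_x = 0.005, se_y = 0.01)
  w2 <- wald_ratio(h2, second_order = TRUE)
  expect_equal(w2$se, 0.05 * sqrt(1 + (0.05^2 * 0.005^2) / (0.2^2 * 0.01^2)),
               tolerance = 1e-12)
  set.seed(99)
  draws <- rnorm(1e5, -0.05, 0.01) / rnorm(1e5, 0.2, 0.005)
  expect_equal(w2$se, sd(draws), tolerance = 0.05)
})

test_that("IVW: single-SNP identity, hand-computed two-SNP case, ratio-mean identity", {
  h1 <- make_hset(bx = 0.2, by = -0.05, se_x = 0.005, se_y = 0.01)
  expect_equal(mr_ivw(h1, "fixed")$beta, wald_ratio(h1)$beta, tolerance = 1e-12)
  expect_equal(mr_ivw(h1, "fixed")$se, wald_ratio(h1)$se, tolerance = 1e-12)

  # two SNPs engineered so the ratio estimates are -0.25 and -0.15 with
  # ratio SE 0.05 each
  h2 <- make_hset(bx = c(0.2, 0.2), by = c(-0.05, -0.03),
                  se_x = 0.005, se_y = 0.01)
  fe <- mr_ivw(h2, "fixed")
  expect_equal(fe$beta, -0.20, tolerance = 1e-12)
  expect_equal(fe$se, 0.05 / sqrt(2), tolerance = 1e-10)
  expect_equal(fe$q, 2.0, tolerance = 1e-10)
  expect_equal(fe$q_p, pchisq(2, 1, lower.tail = FALSE), tolerance = 1e-10)
  re <- mr_ivw(h2, "random")
  expect_equal(re$beta, fe$beta)
  expect_equal(re$se, fe$se * sqrt(2), tolerance = 1e-10) # = 0.05

  # algebraic identity: IVW(fixed) = inverse-variance-weighted mean of the
  # Wald ratios with weights beta_exp^2 / se_out^2
  set.seed(3)
  h3 <- make_hset(bx = runif(8, 0.05, 0.3), by = rnorm(8, 0.02, 0.05),
                  se_x = 0.01, se_y = runif(8, 0.005, 0.02))
  wr <- h3$beta_out / h3$beta_exp
  wts <- h3$beta_exp^2 / h3$se_out^2
  expect_equal(mr_ivw(h3, "fixed")$beta, sum(wts * wr) / sum(wts),
               tolerance = 1e-12)
  expect_error(mr_ivw(h3[0, ]), "at least one")
})

test_that("IVW matches an independent fixed-effects pooling of the ratios", {
  skip_if_not_installed("metafor")
  set.seed(5)
  h <- make_hset(bx = runif(10, 0.1, 0.3), by = rnorm(10, -0.03, 0.02),
                 se_x = 0.01, se_y = runif(10, 0.005, 0.02))
  fe <- metafor::rma(yi = h$beta_out / h$beta_exp,
                     sei = h$se_out / abs(h$beta_exp), method = "FE")
  expect_equal(mr_ivw(h, "fixed")$beta, unname(fe$beta[1]), tolerance = 1e-10)
  expect_equal(mr_ivw(h, "fixed")$se, fe$se, tolerance = 1e-10)
})

test_that("Egger regression: exact line, zero-intercept reduction, preconditions", {
  bx <- c(0.1, 0.15, 0.2, 0.3)
  h <- make_hset(bx = bx, by = 0.01 + 0.3 * bx, se_x = 0.005, se_y = 0.01)
  eg <- mr_egger(h)
  expect_equal(eg$intercept$beta, 0.01, tolerance = 1e-10)
  expect_equal(eg$slope$beta, 0.3, tolerance = 1e-10)
  expect_equal(eg$slope$q, 0, tolerance = 1e-10)
  # through-origin points: Egger intercept ~ 0 and slope ~ IVW
  h0 <- make_hset(bx = bx, by = 0.3 * bx, se_x = 0.005, se_y = 0.01)
  eg0 <- mr_egger(h0)
  expect_equal(eg0$intercept$beta, 0, tolerance = 1e-10)
  expect_equal(eg0$slope$beta, mr_ivw(h0, "fixed")$beta, tolerance = 1e-10)
  expect_error(mr_egger(h[1:2, ]), "at least 3")
  # sign-flipping any instrument leaves the fit unchanged
  h_flip <- h
  h_flip$beta_exp[2] <- -h$beta_exp[2]
  h_flip$beta_out[2] <- -h$beta_out[2]
  egf <- mr_egger(h_flip)
  expect_equal(egf$slope$beta, eg$slope$beta, tolerance = 1e-12)
  expect_equal(egf$intercept$beta, eg$intercept$beta, tolerance = 1e-12)
})

test_that("Egger recovers planted directional pleiotropy and the causal slope", {
  reps <- 40
  ints <- numeric(reps); slopes <- numeric(reps)
  for (i in seq_len(reps)) {
    h <- simulate_mr_instruments(k = 50, theta = 0.2, n_exp = 50000,
                                 n_out = 100000, alpha_pleio = 0.05,
                                 pleio_sd = 0.01, seed = i)
    eg <- mr_egger(h)
    ints[i] <- eg$intercept$beta
    slopes[i] <- eg$slope$beta
  }
  expect_lt(abs(mean(ints) - 0.05), 3 * sd(ints) / sqrt(reps) + 0.002)
  expect_lt(abs(mean(slopes) - 0.2), 3 * sd(slopes) / sqrt(reps) + 0.01)
  # balanced pleiotropy: intercept centred at zero
  ints0 <- vapply(seq_len(reps), function(i) {
    h <- simulate_mr_instruments(k = 50, theta = 0.2, n_exp = 50000,
                                 n_out = 100000, alpha_pleio = 0,
                                 pleio_sd = 0.02, seed = 1000 + i)
    mr_egger(h)$intercept$beta
  }, 0)
  expect_lt(abs(mean(ints0)), 3 * sd(ints0) / sqrt(reps) + 0.002)
})

test_that("weighted median: interpolation point, degenerate set, robustness", {
  # equal weights, ratios 0.1 / 0.2 / 0.4: cumulative midpoint hits 0.5
  # exactly at the middle ratio
  h <- make_hset(bx = c(1, 1, 1), by = c(0.1, 0.2, 0.4),
                 se_x = 0.01, se_y = 0.05)
  wm <- mr_weighted_median(h, n_boot = 200, seed = 1)
  expect_equal(wm$beta, 0.2, tolerance = 1e-10)
  # identical ratios: estimate is that constant, bootstrap SE small
  hc <- make_hset(bx = c(0.1, 0.2, 0.4), by = c(0.03, 0.06, 0.12),
                  se_x = 1e-5, se_y = 1e-4)
  wmc <- mr_weighted_median(hc, n_boot = 200, seed = 2)
  expect_equal(wmc$beta, 0.3, tolerance = 1e-6)
  expect_lt(wmc$se, 0.01)
  expect_error(mr_weighted_median(h[1:2, ], seed = 1), "at least 3")
  expect_error(mr_weighted_median(h, n_boot = 10), "seed")

  # up to 49% wildly invalid instruments: median stays near truth, IVW drifts
  h_bad <- simulate_mr_instruments(k = 21, theta = 0.2, n_exp = 50000,
                                   n_out = 200000, invalid_frac = 0.45,
                                   invalid_effect = 0.08, seed = 11)
  wm_bad <- mr_weighted_median(h_bad, n_boot = 100, seed = 3)
  ivw_bad <- mr_ivw(h_bad)
  expect_lt(abs(wm_bad$beta - 0.2), abs(ivw_bad$beta - 0.2))
})

test_that("instrument heterogeneity Q: zero at homogeneity, hand value, calibration", {
  hc <- make_hset(bx = c(0.1, 0.2, 0.4), by = c(0.03, 0.06, 0.12),
                  se_x = 0.01, se_y = 0.01)
  expect_equal(unname(mr_heterogeneity(hc, 0.3)["q"]), 0, tolerance = 1e-12)
  h2 <- make_hset(bx = c(0.2, 0.2), by = c(-0.05, -0.03),
                  se_x = 0.005, se_y = 0.01)
  het <- mr_heterogeneity(h2, mr_ivw(h2, "fixed")$beta)
  expect_equal(unname(het["q"]), 2, tolerance = 1e-10)
  expect_equal(unname(het["q_p"]), 0.1573, tolerance = 1e-3)
  # null calibration: Q_P approximately uniform
  set.seed(42)
  ps <- replicate(500, {
    k <- 10
    bx <- runif(k, 0.1, 0.3)
    by <- 0.1 * bx + rnorm(k, 0, 0.01)
    h <- make_hset(bx = bx, by = by, se_x = 1e-6, se_y = 0.01)
    unname(mr_heterogeneity(h, mr_ivw(h, "fixed")$beta)["q_p"])
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("radial outlier detection: decomposition, planted outlier, Q reduction", {
  set.seed(8)
  k <- 21
  bx <- runif(k, 0.1, 0.3)
  by <- 0.2 * bx + rnorm(k, 0, 0.008)
  h <- make_hset(bx = bx, by = by, se_x = 1e-6, se_y = 0.008)
  rad <- radial_outliers(h)
  # per-SNP contributions sum to the model's total Q
  expect_equal(sum(rad$per_snp$q_j), rad$q_total, tolerance = 1e-12)
  expect_equal(rad$q_total,
               unname(mr_heterogeneity(h, mr_ivw(h, "fixed")$beta)["q"]),
               tolerance = 1e-10)
  # displace one ratio by 10 ratio-SEs: exactly that SNP flagged at its own q
  h_out <- h
  h_out$beta_out[5] <- h$beta_out[5] + 10 * h$se_out[5]
  rad_out <- radial_outliers(h_out, alpha = 0.05 / k) # Bonferroni-sharp
  expect_equal(rad_out$outliers, "iv5")
  # removing flagged outliers reduces total Q
  h_clean <- h_out[h_out$rsid != "iv5", ]
  expect_lt(radial_outliers(h_clean)$q_total, rad_out$q_total)
  # homogeneous set: nothing flagged at alpha 0.05/k
  expect_length(radial_outliers(h, alpha = 0.05 / k)$outliers, 0)
})

test_that("the orchestrated suite degrades gracefully and composes the stages", {
  # 2-instrument setting: IVW and per-SNP Wald only, Egger/median stubs
  region <- simulate_region(sim_config(m_variants = 40, n_blocks = 4,
                                       h2_exp = 0.03), 21)
  panels <- simulate_exposure_gwas(region, c(a = 7292, b = 1041, c = 1316,
                                             d = 935), 21)
  meta <- meta_gwas(intersect_and_align(panels), "fixed")
  outcome <- simulate_outcome_gwas(region, theta = -0.12, n_out = 4e5,
                                   seed = 21)
  instruments <- meta[meta$rsid %in%
                        region$snps[region$truth$causal_idx], ]
  suite <- run_mr_suite(instruments, outcome, label = "exp->out", seed = 4)
  expect_s3_class(suite, "mr_suite")
  expect_equal(nrow(suite$wald), 2)
  est <- suite$estimates
  expect_equal(est$status[est$method == "egger_slope"],
               "not applicable (<3 SNPs)")
  expect_true(is.finite(est$beta[est$method == "ivw_random"]))

  # 33-instrument synthetic reverse-direction set: every method present
  h33 <- simulate_mr_instruments(k = 33, theta = 0.167, n_exp = 32961,
                                 n_out = 10584, seed = 12)
  exp_tab <- data.frame(rsid = h33$rsid, ea = h33$ea, oa = h33$oa,
                        eaf = h33$eaf_exp, beta = h33$beta_exp,
                        se = h33$se_exp, n = h33$n_exp)
  out_tab <- data.frame(rsid = h33$rsid, ea = h33$ea, oa = h33$oa,
                        eaf = h33$eaf_out, beta = h33$beta_out,
                        se = h33$se_out, n = h33$n_out)
  suite33 <- run_mr_suite(exp_tab, out_tab, label = "BMD->protein",
                          steiger = TRUE, n_boot = 100, seed = 7)
  expect_setequal(
    intersect(c("ivw_random", "egger_slope", "egger_intercept",
                "weighted_median"), suite33$estimates$method),
    c("ivw_random", "egger_slope", "egger_intercept", "weighted_median"))
  expect_false(is.null(suite33$steiger))
  expect_true(all(suite33$estimates$n_snps <= 33))

  # empty instrument set: stage-specific failure
  empty <- exp_tab[0, ]
  expect_error(run_mr_suite(empty, out_tab), "share no variants|no usable")
})
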