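# Shared fixture builders. Everything is generated in code at test time.

options(gwasmr.verbose = FALSE)

# A tiny well-formed panel data.frame (not yet validated/classed).
make_panel_df <- function(n = 3, label = "toy") {
  data.frame(
    rsid = sprintf("rs%d", seq_len(n)),
    chrom = "1", pos = seq_len(n) * 1000,
    ea = rep(c("A", "C", "G"), length.out = n),
    oa = rep(c("G", "T", "A"), length.out = n),
    eaf = seq(0.2, 0.45, length.out = n),
    beta = seq(0.05, 0.2, length.out = n),
    se = rep(0.01, n), p = rep(1e-4, n), n = 1000, info = 0.95,
    stringsAsFactors = FALSE
  )
}

write_panel_file <- function(df, path = tempfile(fileext = ".tsv")) {
  out <- df
  names(out) <- c("SNP", "CHR", "POS", "EA", "OA", "EAF", "BETA", "SE",
                  "P", "N", "INFO")[seq_along(out)]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

as_panel <- function(df, label = "toy") {
  gwasmr:::new_cohort_panel(df, label = label)
}

# Minimal harmonized_set from vectors.
make_hset <- function(bx, by, se_x, se_y, eaf = 0.3, n_exp = 10000,
                      n_out = 50000) {
  k <- length(bx)
  structure(data.frame(
    rsid = sprintf("iv%d", seq_len(k)), ea = "A", oa = "G",
    beta_exp = bx, se_exp = rep_len(se_x, k), eaf_exp = rep_len(eaf, k),
    n_exp = n_exp, beta_out = by, se_out = rep_len(se_y, k),
    eaf_out = rep_len(eaf, k), n_out = n_out, action = "kept",
    stringsAsFactors = FALSE
  ), class = c("harmonized_set", "data.frame"))
}

# Brute-force colocalization oracle: enumerates every single-variant
# configuration in plain (non-log) arithmetic. Independent of coloc_abf's
# log-sum-exp path; valid for small regions and moderate z-scores.
coloc_enumerate <- function(t1, t2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                            sd1 = 0.15, sd2 = 0.15) {
  abf <- function(beta, se, w_sd) {
    V <- se^2; W <- w_sd^2; z <- beta / se
    sqrt(V / (V + W)) * exp(z^2 * W / (V + W) / 2)
  }
  a1 <- abf(t1$beta, t1$se, sd1)
  a2 <- abf(t2$beta, t2$se, sd2)
  m <- length(a1)
  s <- c(h0 = 1, h1 = 0, h2 = 0, h3 = 0, h4 = 0)
  for (i in seq_len(m)) {
    s["h1"] <- s["h1"] + p1 * a1[i]
    s["h2"] <- s["h2"] + p2 * a2[i]
    s["h4"] <- s["h4"] + p12 * a1[i] * a2[i]
    for (j in seq_len(m)) {
      if (i != j) s["h3"] <- s["h3"] + p1 * p2 * a1[i] * a2[j]
    }
  }
  s / sum(s)
}
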