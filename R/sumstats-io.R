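#' Read a GWAS summary-statistics file into a cohort panel
#'
#' Parses a header-bearing delimited text file (tab or general whitespace;
#' gzip is handled transparently) of per-variant association results into a
#' validated cohort panel. Each row carries a variant key (rsid and/or
#' chromosome + 1-based GRCh37 position), effect and other allele, effect
#' allele frequency, effect size in phenotype SD units, its standard error,
#' p-value, sample size and optionally an imputation quality score.
#'
#' Malformed rows (non-positive SE, frequency outside [0,1], identical
#' alleles, missing effect estimate, p outside (0,1]) are dropped and
#' counted; alleles are uppercased. Within-panel duplicate variant keys are
#' resolved by keeping the record with the smallest SE.
#'
#' @param path file path (plain or .gz).
#' @param column_map named character vector mapping canonical field names
#'   (\code{rsid, chrom, pos, ea, oa, eaf, beta, se, p, n, info}) to the
#'   file's column names. Defaults to the canonical names themselves
#'   (\code{SNP CHR POS EA OA EAF BETA SE P N INFO}).
#' @param label study label attached to the panel.
#' @param n_default fallback sample size used when the file has no N column.
#' @return A \code{cohort_panel}: a data.frame with columns
#'   \code{rsid, chrom, pos, ea, oa, eaf, beta, se, p, n, info} and
#'   attributes \code{label} and \code{n_dropped}.
#' @export
read_sumstats <- function(path, column_map = NULL, label = basename(path),
                          n_default = NA_real_) {
  if (!file.exists(path)) stop("summary statistics file not found: ", path)
  canonical <- c(rsid = "SNP", chrom = "CHR", pos = "POS", ea = "EA",
                 oa = "OA", eaf = "EAF", beta = "BETA", se = "SE",
                 p = "P", n = "N", info = "INFO")
  if (!is.null(column_map)) canonical[names(column_map)] <- column_map
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  raw <- utils::read.table(con, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE, comment.char = "")
  mandatory <- c("ea", "oa", "eaf", "beta", "se", "p")
  missing_cols <- mandatory[!(canonical[mandatory] %in% names(raw))]
  if (length(missing_cols)) {
    stop("mandatory column(s) missing from ", path, ": ",
         paste(canonical[missing_cols], collapse = ", "))
  }
  has_rsid <- canonical["rsid"] %in% names(raw)
  has_pos <- all(canonical[c("chrom", "pos")] %in% names(raw))
  if (!has_rsid && !has_pos) {
    stop("need an rsid column or chromosome+position columns in ", path)
  }
  grab <- function(field, default = NA) {
    col <- canonical[[field]]
    if (col %in% names(raw)) raw[[col]] else rep(default, nrow(raw))
  }
  panel <- data.frame(
    rsid = as.character(grab("rsid", NA_character_)),
    chrom = as.character(grab("chrom", NA_character_)),
    pos = as.numeric(grab("pos")),
    ea = toupper(as.character(grab("ea"))),
    oa = toupper(as.character(grab("oa"))),
    eaf = as.numeric(grab("eaf")),
    beta = as.numeric(grab("beta")),
    se = as.numeric(grab("se")),
    p = as.numeric(grab("p")),
    n = as.numeric(grab("n", n_default)),
    info = as.numeric(grab("info")),
    stringsAsFactors = FALSE
  )
  new_cohort_panel(panel, label = label)
}

# Validate rows, resolve duplicates, stamp class/attributes.
#' @keywords internal
new_cohort_panel <- function(panel, label) {
  ok <- !is.na(panel$ea) & !is.na(panel$oa) & panel$ea != panel$oa &
    grepl("^[ACGT]+$", panel$ea) & grepl("^[ACGT]+$", panel$oa) &
    is.finite(panel$beta) & is.finite(panel$se) & panel$se > 0 &
    is.finite(panel$eaf) & panel$eaf >= 0 & panel$eaf <= 1 &
    is.finite(panel$p) & panel$p > 0 & panel$p <= 1 &
    (!is.na(panel$rsid) | (!is.na(panel$chrom) & is.finite(panel$pos) & panel$pos >= 1))
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    msg_log(label, ": dropped ", n_dropped, " malformed row(s)")
  }
  panel <- panel[ok, , drop = FALSE]
  if (!nrow(panel)) stop("no valid summary-statistics rows for ", label)
  key <- variant_key(panel)
  if (anyDuplicated(key)) {
    ord <- order(key, panel$se)
    panel <- panel[ord, , drop = FALSE][!duplicated(sort(key)), , drop = FALSE]
    msg_log(label, ": resolved duplicate keys, kept smallest-SE record")
  }
  rownames(panel) <- NULL
  structure(panel, label = label, n_dropped = n_dropped,
            class = c("cohort_panel", "data.frame"))
}

# Variant key: rsid when present, else chrom:pos (1-based, GRCh37).
#' @keywords internal
variant_key <- function(panel) {
  ifelse(!is.na(panel$rsid) & nzchar(panel$rsid), panel$rsid,
         paste0(panel$chrom, ":", format(panel$pos, scientific = FALSE, trim = TRUE)))
}

#' @export
print.cohort_panel <- function(x, ...) {
  cat("Cohort panel '", attr(x, "label"), "': ", nrow(x), " variants (",
      attr(x, "n_dropped"), " malformed rows dropped at read)\n", sep = "")
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Apply marker-level quality-control filters to a cohort panel
#'
#' Retains variants with minor-allele frequency strictly above
#' \code{maf_min} and imputation quality strictly above \code{info_min}.
#' Boundary values are removed (strict inequalities). Records with a missing
#' imputation score (e.g. a sequenced cohort) are kept only when
#' \code{info_min} is 0.
#'
#' @param panel a \code{cohort_panel}.
#' @param maf_min minimum minor-allele frequency (default 0.01).
#' @param info_min minimum imputation quality (default 0.8).
#' @return The filtered panel with attribute \code{qc_removed}, a named
#'   count per filter.
#' @export
apply_qc <- function(panel, maf_min = 0.01, info_min = 0.8) {
  stopifnot(nrow(panel) > 0, maf_min >= 0, maf_min < 0.5,
            info_min >= 0, info_min <= 1)
  maf <- pmin(panel$eaf, 1 - panel$eaf)
  pass_maf <- maf > maf_min
  pass_info <- ifelse(is.na(panel$info), info_min == 0, panel$info > info_min)
  removed <- c(maf = sum(!pass_maf), info = sum(pass_maf & !pass_info))
  keep <- pass_maf & pass_info
  if (!any(keep)) {
    stop("QC removed every variant (maf filter: ", removed["maf"],
         ", info filter: ", removed["info"], ")")
  }
  out <- panel[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "label") <- attr(panel, "label")
  attr(out, "n_dropped") <- attr(panel, "n_dropped")
  attr(out, "qc_removed") <- removed
  class(out) <- class(panel)
  out
}

#' Intersect cohort panels and align effect alleles to a reference
#'
#' Restricts to variants present in every panel and orients all cohorts to
#' the reference panel's effect/other alleles: a cohort reporting the
#' reference's other allele as its effect allele has its beta negated and
#' its EAF replaced by 1 - EAF. Variants whose allele pair does not match
#' the reference pair even after the swap are dropped as mismatches (no
#' strand-complement rescue is attempted here: inputs are expected on the
#' forward strand already).
#'
#' @param panels list of \code{cohort_panel} objects (>= 2).
#' @param reference index of the panel fixing allele orientation (default 1).
#' @return An \code{aligned_sumstats} object: list with \code{variants}
#'   (rsid/chrom/pos/ea/oa data.frame) and m x k matrices \code{beta},
#'   \code{se}, \code{eaf}, \code{n}, plus \code{labels} and
#'   \code{n_mismatch}.
#' @export
intersect_and_align <- function(panels, reference = 1L) {
  stopifnot(length(panels) >= 2)
  keys <- lapply(panels, variant_key)
  shared <- Reduce(intersect, keys)
  if (!length(shared)) stop("no variants are common to all panels")
  ref <- panels[[reference]]
  ref_idx <- match(shared, keys[[reference]])
  k <- length(panels)
  m <- length(shared)
  beta <- se <- eaf <- nmat <- matrix(NA_real_, m, k)
  mismatch <- logical(m)
  for (j in seq_len(k)) {
    idx <- match(shared, keys[[j]])
    pj <- panels[[j]][idx, , drop = FALSE]
    same <- pj$ea == ref$ea[ref_idx] & pj$oa == ref$oa[ref_idx]
    swapped <- pj$ea == ref$oa[ref_idx] & pj$oa == ref$ea[ref_idx]
    mismatch <- mismatch | !(same | swapped)
    beta[, j] <- ifelse(swapped, -pj$beta, pj$beta)
    eaf[, j] <- ifelse(swapped, 1 - pj$eaf, pj$eaf)
    se[, j] <- pj$se
    nmat[, j] <- pj$n
  }
  if (sum(mismatch)) {
    msg_log("dropped ", sum(mismatch), " variant(s) with allele-pair mismatch")
  }
  keep <- !mismatch
  if (!any(keep)) stop("all shared variants had allele mismatches")
  labels <- vapply(panels, function(p) attr(p, "label") %||% NA_character_, "")
  variants <- data.frame(
    rsid = ref$rsid[ref_idx], chrom = ref$chrom[ref_idx], pos = ref$pos[ref_idx],
    ea = ref$ea[ref_idx], oa = ref$oa[ref_idx], stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(variants) <- NULL
  sub <- function(x) {
    x <- x[keep, , drop = FALSE]
    colnames(x) <- labels
    x
  }
  structure(list(variants = variants, beta = sub(beta), se = sub(se),
                 eaf = sub(eaf), n = sub(nmat), labels = labels,
                 n_mismatch = sum(mismatch)),
            class = "aligned_sumstats")
}

#' @export
print.aligned_sumstats <- function(x, ...) {
  cat("Aligned summary statistics: ", nrow(x$variants), " variants x ",
      length(x$labels), " cohorts (", x$n_mismatch,
      " allele mismatches dropped)\n", sep = "")
  cat("Cohorts:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Write a cohort panel or meta-analysis table as canonical TSV
#'
#' Columns are written in the fixed canonical order
#' \code{SNP CHR POS EA OA EAF BETA SE P N INFO}, followed by any extra
#' columns present (e.g. heterogeneity fields of a meta-analysis table).
#'
#' @param x a \code{cohort_panel} or \code{gwas_meta} data.frame.
#' @param path output path; a \code{.gz} suffix compresses.
#' @return \code{path}, invisibly.
#' @export
write_sumstats <- function(x, path) {
  canon_in <- c("rsid", "chrom", "pos", "ea", "oa", "eaf", "beta", "se",
                "p", "n", "info")
  canon_out <- c("SNP", "CHR", "POS", "EA", "OA", "EAF", "BETA", "SE",
                 "P", "N", "INFO")
  df <- as.data.frame(x)
  present <- canon_in[canon_in %in% names(df)]
  extra <- setdiff(names(df), canon_in)
  out <- df[, c(present, extra), drop = FALSE]
  names(out)[seq_along(present)] <- canon_out[match(present, canon_in)]
  if (length(extra)) names(out)[(length(present) + 1):ncol(out)] <- toupper(extra)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
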