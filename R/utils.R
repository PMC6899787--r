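# Internal numeric helpers shared across modules.

#' @keywords internal
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, stable for large magnitudes
#' @keywords internal
logdiffexp <- function(a, b) {
  if (b == -Inf) return(a)
  stopifnot(a >= b)
  if (a == b) return(-Inf)
  a + log1p(-exp(b - a))
}

# Two-sided normal p-value from an effect and its SE; log10 variant avoids
# underflow for very large |z| (p below ~1e-308).
#' @keywords internal
z_pvalue <- function(beta, se) {
  2 * stats::pnorm(-abs(beta / se))
}

#' @keywords internal
z_log10p <- function(beta, se) {
  (stats::pnorm(-abs(beta / se), log.p = TRUE) + log(2)) / log(10)
}

# Deterministic per-stream seed derivation: offset a base seed by a hashed
# label so cohorts/stages get independent, reproducible streams. Kept below
# .Machine$integer.max.
#' @keywords internal
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587L)
}

#' @keywords internal
`%||%` <- function(x, y) if (is.null(x)) y else x

#' @keywords internal
msg_log <- function(..., verbose = getOption("gwasmr.verbose", TRUE)) {
  if (isTRUE(verbose)) message("[gwasmr] ", ...)
}
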