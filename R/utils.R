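#' @keywords internal
"_PACKAGE"

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Benjamini-Hochberg adjustment preserving input order
#'
#' Step-up false-discovery-rate control. Thin wrapper over
#' [stats::p.adjust()] with input validation; adjusted values are returned
#' in the original input order.
#'
#' @param pvalues numeric vector of raw p-values in (0, 1].
#' @return numeric vector of BH-adjusted p-values, same length and order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(pvalues) {
  stopifnot(is.numeric(pvalues), length(pvalues) >= 1)
  if (any(!is.finite(pvalues) | pvalues <= 0 | pvalues > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

# normal two-sided p from estimate and se
z_pvalue <- function(beta, se) 2 * stats::pnorm(-abs(beta / se))

# condition-style message, suppressible via options(mrmediate.quiet = TRUE)
mr_note <- function(...) {
  if (!isTRUE(getOption("mrmediate.quiet", FALSE))) message(...)
  invisible(NULL)
}
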