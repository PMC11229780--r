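# Instrument selection: significance thresholding, greedy LD clumping and
# F-statistic filtering.

#' Construct an LD matrix object
#'
#' @param r2 square symmetric matrix of squared correlations in `[0,1]` with
#'   unit diagonal; dimnames give the SNP ids (or pass `snp_ids`).
#' @param snp_ids character vector of SNP identifiers (defaults to rownames).
#' @param positions base-pair positions aligned to `snp_ids` (used for the
#'   clumping window; optional if records carry positions).
#' @return object of class `ld_matrix`.
#' @export
ld_matrix <- function(r2, snp_ids = rownames(r2), positions = NULL) {
  r2 <- as.matrix(r2)
  if (is.null(snp_ids)) stop("snp_ids required (or set dimnames on r2)")
  if (nrow(r2) != ncol(r2) || nrow(r2) != length(snp_ids))
    stop("r2 must be square and match snp_ids")
  if (max(abs(r2 - t(r2))) > 1e-8) stop("LD matrix must be symmetric")
  if (max(abs(diag(r2) - 1)) > 1e-8) stop("LD matrix diagonal must be 1")
  if (min(r2) < -1e-8 || max(r2) > 1 + 1e-8)
    stop("LD r2 values must lie in [0,1]")
  dimnames(r2) <- list(snp_ids, snp_ids)
  structure(list(snp_ids = as.character(snp_ids), r2 = r2,
                 positions = positions), class = "ld_matrix")
}

#' Read an LD matrix from TSV
#'
#' Accepts either a square matrix with SNP ids as header row and first
#' column, or a long-format triplet file with columns `snp_a`, `snp_b`, `r2`.
#' @param path file path.
#' @return `ld_matrix`.
#' @export
read_ld_matrix <- function(path) {
  head1 <- utils::read.table(path, header = TRUE, sep = "\t", nrows = 1,
                             check.names = FALSE)
  if (all(c("snp_a", "snp_b", "r2") %in% names(head1))) {
    long <- utils::read.table(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    ids <- sort(unique(c(long$snp_a, long$snp_b)))
    m <- diag(length(ids))
    dimnames(m) <- list(ids, ids)
    m[cbind(long$snp_a, long$snp_b)] <- long$r2
    m[cbind(long$snp_b, long$snp_a)] <- long$r2
    return(ld_matrix(m))
  }
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   row.names = 1, check.names = FALSE))
  ld_matrix(m)
}

#' Write an LD matrix as a square TSV
#' @param ld `ld_matrix`.
#' @param path output path.
#' @export
write_ld_matrix <- function(ld, path) {
  utils::write.table(data.frame(snp_id = ld$snp_ids, ld$r2,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Select records by association p-value
#'
#' Strict comparison: rows with `pvalue < threshold` are kept, input order
#' preserved.
#' @param records `sumstats` table.
#' @param threshold significance threshold in (0,1), e.g. `5e-8` genome-wide
#'   or `1e-5` for traits with few genome-wide hits.
#' @return filtered `sumstats` table (possibly empty, with a note).
#' @export
select_by_pvalue <- function(records, threshold) {
  stopifnot(is.numeric(threshold), threshold > 0, threshold < 1)
  out <- records[records$pvalue < threshold, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0)
    mr_note("no records pass p < ", format(threshold))
  out
}

#' Greedy LD clumping
#'
#' PLINK-style clumping on summary statistics: SNPs are visited in order of
#' ascending p-value (ties broken by `snp_id`); each accepted index SNP
#' removes all not-yet-accepted SNPs on the same chromosome within
#' `window_kb` kilobases (center to center) whose squared correlation with
#' it is at least `r2_threshold`. SNPs absent from the LD matrix are
#' retained with a warning.
#'
#' @param records `sumstats` table.
#' @param ld `ld_matrix`.
#' @param r2_threshold squared-correlation cutoff (default 0.01).
#' @param window_kb window size in kilobases (default 10000).
#' @return accepted SNPs as a `sumstats` table in genomic order.
#' @export
clump <- function(records, ld, r2_threshold = 0.01, window_kb = 10000) {
  if (nrow(records) == 0) return(records)
  if (!inherits(ld, "ld_matrix")) stop("ld must be an ld_matrix")
  missing_ld <- setdiff(records$snp_id, ld$snp_ids)
  if (length(missing_ld) > 0)
    warning(length(missing_ld),
            " SNP(s) absent from LD matrix retained unclumped")

  ord <- order(records$pvalue, records$snp_id)
  status <- rep("pending", nrow(records))  # pending / accepted / removed
  window_bp <- window_kb * 1000
  for (i in ord) {
    if (status[i] != "pending") next
    status[i] <- "accepted"
    if (!(records$snp_id[i] %in% ld$snp_ids)) next
    cand <- which(status == "pending" &
                    records$chrom == records$chrom[i] &
                    abs(records$pos - records$pos[i]) <= window_bp &
                    records$snp_id %in% ld$snp_ids)
    if (length(cand) == 0) next
    r2 <- ld$r2[records$snp_id[i], records$snp_id[cand]]
    status[cand[r2 >= r2_threshold]] <- "removed"
  }
  out <- records[status == "accepted", , drop = FALSE]
  out <- out[order(out$chrom, out$pos, out$snp_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Instrument-strength F statistics
#'
#' Per-SNP strength is approximated from summary data as F = (beta/se)^2;
#' instruments below `min_f` are conventionally considered weak and removed.
#' An alternative form based on variance explained,
#' F = r2 (n-2) / (1 - r2) with r2 = 2 beta^2 maf (1-maf), is available when
#' allele frequencies are present.
#'
#' @param records `sumstats` table.
#' @param min_f weak-instrument cutoff (default 10).
#' @param method `"wald"` for (beta/se)^2 (default) or `"r2"` for the
#'   variance-explained form.
#' @return list with `retained` (filtered `sumstats`) and `diagnostics`
#'   (list: `per_snp_f` named vector over the input, `mean_f` over retained,
#'   `n_selected`, `threshold_used`).
#' @export
f_statistics <- function(records, min_f = 10, method = c("wald", "r2")) {
  method <- match.arg(method)
  stopifnot(all(records$se > 0))
  if (method == "wald") {
    f <- (records$beta / records$se)^2
  } else {
    r2 <- 2 * records$beta^2 * records$eaf * (1 - records$eaf)
    r2 <- pmin(r2, 1 - 1e-12)
    f <- r2 * (records$n - 2) / (1 - r2)
  }
  names(f) <- records$snp_id
  keep <- f >= min_f
  retained <- records[keep, , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained,
       diagnostics = list(per_snp_f = f,
                          mean_f = if (any(keep)) mean(f[keep]) else NA_real_,
                          n_selected = sum(keep),
                          threshold_used = min_f))
}

#' Full instrument-selection step
#'
#' p-value thresholding, then LD clumping (if an LD matrix is supplied),
#' then F-statistic filtering.
#' @param records `sumstats` for the exposure.
#' @param p_threshold significance threshold.
#' @param ld optional `ld_matrix`.
#' @param r2_threshold,window_kb clumping parameters.
#' @param min_f weak-instrument cutoff.
#' @return list `instruments` (sumstats) and `diagnostics` (from
#'   [f_statistics()]).
#' @export
select_instruments <- function(records, p_threshold = 5e-8, ld = NULL,
                               r2_threshold = 0.01, window_kb = 10000,
                               min_f = 10) {
  sel <- select_by_pvalue(records, p_threshold)
  if (!is.null(ld) && nrow(sel) > 1)
    sel <- clump(sel, ld, r2_threshold = r2_threshold, window_kb = window_kb)
  fs <- f_statistics(sel, min_f = min_f)
  list(instruments = fs$retained, diagnostics = fs$diagnostics)
}
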