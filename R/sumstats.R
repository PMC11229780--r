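# GWAS summary-statistic data model, file I/O and allele harmonization.
#
# A sumstats table is a plain data.frame with one row per SNP and the
# canonical columns below; validate_sumstats() enforces the invariants.

SUMSTAT_COLS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                  "eaf", "beta", "se", "pvalue", "n")

VALID_ALLELES <- c("A", "C", "G", "T")

#' Construct a validated GWAS summary-statistics table
#'
#' @param df data.frame carrying the canonical columns: `snp_id`, `chrom`,
#'   `pos` (1-based), `effect_allele`, `other_allele` (single characters in
#'   A/C/G/T), `eaf` (effect-allele frequency), `beta`, `se`, `pvalue`, `n`.
#' @param drop_invalid drop rows violating invariants (with a note) rather
#'   than erroring.
#' @return data.frame of class `sumstats`; attribute `n_dropped` counts rows
#'   removed during validation.
#' @export
sumstats <- function(df, drop_invalid = TRUE) {
  missing_cols <- setdiff(SUMSTAT_COLS, names(df))
  if (length(missing_cols) > 0)
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  df <- df[SUMSTAT_COLS]
  df$snp_id <- as.character(df$snp_id)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("eaf", "beta", "se", "pvalue")) df[[col]] <- as.numeric(df[[col]])
  df$n <- as.integer(df$n)

  ok <- !is.na(df$snp_id) & nzchar(df$snp_id) &
    df$effect_allele %in% VALID_ALLELES &
    df$other_allele %in% VALID_ALLELES &
    df$effect_allele != df$other_allele &
    !is.na(df$se) & df$se > 0 &
    !is.na(df$eaf) & df$eaf >= 0 & df$eaf <= 1 &
    !is.na(df$beta) &
    !is.na(df$pvalue) & df$pvalue > 0 & df$pvalue <= 1 &
    !is.na(df$n) & df$n > 0
  n_bad <- sum(!ok)
  if (n_bad > 0) {
    if (!drop_invalid) stop(n_bad, " row(s) violate sumstats invariants")
    mr_note("dropped ", n_bad, " invalid row(s) during sumstats validation")
    df <- df[ok, , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("sumstats", "data.frame")
  attr(df, "n_dropped") <- n_bad
  df
}

#' Read GWAS summary statistics from a delimited text file
#'
#' TSV/CSV is autodetected from the file extension (gzip-transparent).
#' `column_map` renames file columns to the canonical schema, so files with
#' arbitrary headers and column order can be ingested.
#'
#' @param path file path; `.csv`/`.csv.gz` is read as comma-separated,
#'   anything else as tab-separated.
#' @param column_map named character vector mapping canonical field names
#'   (see [sumstats()]) to column names in the file, e.g.
#'   `c(snp_id = "SNP", beta = "Effect")`. Unmapped canonical names are
#'   assumed to appear verbatim in the header.
#' @return validated `sumstats` data.frame; invalid rows are dropped with a
#'   note and counted in attribute `n_dropped`.
#' @export
read_sumstats <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv(\\.gz)?$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0) stop("empty summary-statistics file: ", path)
  map <- stats::setNames(SUMSTAT_COLS, SUMSTAT_COLS)
  if (!is.null(column_map)) {
    unknown <- setdiff(names(column_map), SUMSTAT_COLS)
    if (length(unknown) > 0)
      stop("column_map has unknown canonical field(s): ",
           paste(unknown, collapse = ", "))
    map[names(column_map)] <- column_map
  }
  absent <- map[!map %in% names(df)]
  if (length(absent) > 0)
    stop("mapped column(s) absent from file: ",
         paste(sprintf("%s (for %s)", absent, names(absent)), collapse = ", "))
  out <- df[unname(map)]
  names(out) <- names(map)
  sumstats(out)
}

#' Write a summary-statistics table to TSV
#' @param x `sumstats` data.frame.
#' @param path output file path.
#' @export
write_sumstats <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

maf <- function(eaf) pmin(eaf, 1 - eaf)

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome effects to the exposure's effect allele, SNP by SNP
#' (matched on `snp_id`). Swapped allele labels are resolved by negating the
#' outcome beta and complementing its allele frequency. Palindromic SNPs
#' (A/T or C/G) cannot be aligned from allele labels: those with minor-allele
#' frequency above `palindrome_maf_cutoff` are dropped as ambiguous, the
#' rest are aligned by comparing allele frequencies to 0.5. Duplicate rsIDs
#' keep the row with the smallest exposure p-value.
#'
#' @param exposure,outcome `sumstats` tables (or data.frames coercible via
#'   [sumstats()]).
#' @param palindrome_maf_cutoff palindromic SNPs whose MAF exceeds this are
#'   dropped (default 0.3).
#' @param exposure_name,outcome_name trait labels carried into the result.
#' @return object of class `harmonized_set`: a list with `exposure_name`,
#'   `outcome_name`, `records` (data.frame with `snp_id`, `beta_exposure`,
#'   `se_exposure`, `beta_outcome`, `se_outcome`, `eaf`, `n_exposure`,
#'   `n_outcome`) and `dropped` (data.frame `snp_id`, `reason`).
#' @export
harmonize <- function(exposure, outcome, palindrome_maf_cutoff = 0.3,
                      exposure_name = "exposure", outcome_name = "outcome") {
  if (!inherits(exposure, "sumstats")) exposure <- sumstats(exposure)
  if (!inherits(outcome, "sumstats")) outcome <- sumstats(outcome)
  if (nrow(exposure) == 0 || nrow(outcome) == 0)
    stop("exposure and outcome tables must be non-empty")

  dedupe <- function(x) {
    x <- x[order(x$pvalue, x$snp_id), , drop = FALSE]
    x[!duplicated(x$snp_id), , drop = FALSE]
  }
  exposure <- dedupe(exposure)
  outcome <- outcome[order(outcome$pvalue, outcome$snp_id), , drop = FALSE]
  outcome <- outcome[!duplicated(outcome$snp_id), , drop = FALSE]

  dropped <- data.frame(snp_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  drop <- function(ids, reason) {
    if (length(ids) > 0)
      dropped <<- rbind(dropped, data.frame(snp_id = ids, reason = reason,
                                            stringsAsFactors = FALSE))
  }

  shared <- intersect(exposure$snp_id, outcome$snp_id)
  drop(setdiff(union(exposure$snp_id, outcome$snp_id), shared), "unmatched")
  ex <- exposure[match(shared, exposure$snp_id), , drop = FALSE]
  ou <- outcome[match(shared, outcome$snp_id), , drop = FALSE]

  keep <- rep(TRUE, length(shared))
  beta_out <- ou$beta
  eaf_out <- ou$eaf

  same <- ex$effect_allele == ou$effect_allele &
    ex$other_allele == ou$other_allele
  swapped <- ex$effect_allele == ou$other_allele &
    ex$other_allele == ou$effect_allele
  beta_out[swapped] <- -beta_out[swapped]
  eaf_out[swapped] <- 1 - eaf_out[swapped]

  mismatch <- !(same | swapped)
  drop(shared[mismatch], "allele-mismatch")
  keep[mismatch] <- FALSE

  pal <- is_palindromic(ex$effect_allele, ex$other_allele) & keep
  ambiguous <- pal & (maf(ex$eaf) > palindrome_maf_cutoff |
                        maf(eaf_out) > palindrome_maf_cutoff)
  drop(shared[ambiguous], "palindromic-ambiguous")
  keep[ambiguous] <- FALSE

  # resolvable palindromes: allele labels carry no strand information, so
  # alignment comes from frequency — flip when eaf sits on opposite sides of 0.5
  pal_ok <- pal & !ambiguous
  flip <- pal_ok & ((ex$eaf < 0.5) != (eaf_out < 0.5))
  beta_out[flip] <- -beta_out[flip]
  eaf_out[flip] <- 1 - eaf_out[flip]

  records <- data.frame(
    snp_id = shared[keep],
    beta_exposure = ex$beta[keep],
    se_exposure = ex$se[keep],
    beta_outcome = beta_out[keep],
    se_outcome = ou$se[keep],
    eaf = ex$eaf[keep],
    n_exposure = ex$n[keep],
    n_outcome = ou$n[keep],
    stringsAsFactors = FALSE
  )
  rownames(records) <- NULL

  if (nrow(records) == 0) {
    dominant <- names(sort(table(dropped$reason), decreasing = TRUE))[1]
    stop("harmonization retained zero SNPs (dominant drop reason: ",
         dominant, ")")
  }
  structure(list(exposure_name = exposure_name, outcome_name = outcome_name,
                 records = records, dropped = dropped),
            class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("Harmonized instrument set: %s -> %s\n  %d SNP(s) retained, %d dropped\n",
              x$exposure_name, x$outcome_name, nrow(x$records), nrow(x$dropped)))
  invisible(x)
}

#' Write a harmonized set (and its drop audit) to TSV
#' @param x `harmonized_set`.
#' @param path output TSV for retained pairs; the audit table goes to
#'   `<path>.dropped.tsv`.
#' @export
write_harmonized <- function(x, path) {
  utils::write.table(x$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$dropped, paste0(path, ".dropped.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# internal: build a harmonized_set directly from aligned vectors (used by
# the simulator and tests where alleles are already consistent)
harmonized_set <- function(bx, sx, by, sy, snp_id = NULL, eaf = NA_real_,
                           n_exposure = NA_integer_, n_outcome = NA_integer_,
                           exposure_name = "exposure",
                           outcome_name = "outcome") {
  k <- length(bx)
  if (is.null(snp_id)) snp_id <- paste0("snp", seq_len(k))
  records <- data.frame(snp_id = snp_id, beta_exposure = bx, se_exposure = sx,
                        beta_outcome = by, se_outcome = sy,
                        eaf = rep_len(eaf, k),
                        n_exposure = rep_len(as.integer(n_exposure), k),
                        n_outcome = rep_len(as.integer(n_outcome), k),
                        stringsAsFactors = FALSE)
  structure(list(exposure_name = exposure_name, outcome_name = outcome_name,
                 records = records,
                 dropped = data.frame(snp_id = character(0),
                                      reason = character(0))),
            class = "harmonized_set")
}
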