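# Pipeline driver: forward MR screen, reverse MR, mediation, report tables.

#' Assemble a pipeline configuration
#'
#' Exposures/mediators are named lists of `sumstats` tables or file paths
#' (read via [read_sumstats()]); the outcome is a single table or path.
#' Instrument thresholds default to the dual-threshold policy: a permissive
#' 1e-5 for microbial-trait exposures (few genome-wide hits) and genome-wide
#' 5e-8 for mediators and the outcome.
#'
#' @param exposures named list of `sumstats`/paths.
#' @param mediators named list of `sumstats`/paths (may be empty).
#' @param outcome `sumstats` or path.
#' @param ld optional `ld_matrix` or path.
#' @param p_threshold_exposure,p_threshold_mediator,p_threshold_outcome
#'   instrument-selection thresholds per trait class.
#' @param r2_threshold,window_kb clumping parameters.
#' @param min_f weak-instrument cutoff.
#' @param presso_nsim MR-PRESSO resampling count.
#' @param coloc_priors numeric `c(p1, p2, p12)`.
#' @param bh_alpha family-wise FDR level for the screen.
#' @param het_gate Cochran-Q p-value below which an exposure that remains
#'   heterogeneous after PRESSO correction is excluded from mediation.
#' @param seed integer seed for all stochastic components.
#' @param out_dir optional output directory for report TSVs and audit log.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(exposures, mediators = list(), outcome,
                            ld = NULL,
                            p_threshold_exposure = 1e-5,
                            p_threshold_mediator = 5e-8,
                            p_threshold_outcome = 5e-8,
                            r2_threshold = 0.01, window_kb = 10000,
                            min_f = 10, presso_nsim = 1000,
                            coloc_priors = c(1e-4, 1e-4, 1e-5),
                            bh_alpha = 0.05, het_gate = 0.05,
                            seed = 1L, out_dir = NULL) {
  load_tab <- function(x) if (is.character(x)) read_sumstats(x) else x
  if (is.null(names(exposures)) || any(!nzchar(names(exposures))))
    stop("exposures must be a named list")
  exposures <- lapply(exposures, load_tab)
  mediators <- lapply(mediators, load_tab)
  outcome <- load_tab(outcome)
  if (is.character(ld)) ld <- read_ld_matrix(ld)
  stopifnot(p_threshold_exposure > 0, p_threshold_exposure < 1,
            bh_alpha > 0, bh_alpha < 1)
  structure(list(exposures = exposures, mediators = mediators,
                 outcome = outcome, ld = ld,
                 p_threshold_exposure = p_threshold_exposure,
                 p_threshold_mediator = p_threshold_mediator,
                 p_threshold_outcome = p_threshold_outcome,
                 r2_threshold = r2_threshold, window_kb = window_kb,
                 min_f = min_f, presso_nsim = presso_nsim,
                 coloc_priors = coloc_priors, bh_alpha = bh_alpha,
                 het_gate = het_gate, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

# rbind a list of data.frames, ignoring NULL fragments
rbind_frags <- function(lst) {
  lst <- Filter(Negate(is.null), lst)
  if (length(lst) == 0) return(NULL)
  do.call(rbind, c(lst, list(make.row.names = FALSE)))
}

audit_entry <- function(id, code, detail = "") {
  data.frame(id = id, code = code, detail = detail, stringsAsFactors = FALSE)
}

# one exposure -> outcome analysis: instruments, harmonize, estimators,
# sensitivity suite; returns NULL-safe fragments
analyse_pair <- function(name, exp_tab, out_tab, cfg, p_threshold,
                         steiger_filter = FALSE) {
  audit <- list()
  sel <- select_instruments(exp_tab, p_threshold, cfg$ld,
                            r2_threshold = cfg$r2_threshold,
                            window_kb = cfg$window_kb, min_f = cfg$min_f)
  iv <- sel$instruments
  if (nrow(iv) == 0)
    return(list(status = "no-IV", forest = NULL, sens = NULL,
                audit = audit_entry(name, "no-IV",
                                    "no instruments after filters")))
  h <- harmonize(iv, out_tab[out_tab$snp_id %in% iv$snp_id, , drop = FALSE],
                 exposure_name = name, outcome_name = "outcome")
  if (steiger_filter) {
    # keep only SNPs explaining more variance in the exposure than in the
    # outcome (per-SNP Steiger), so instruments truly belong to the exposure
    r <- h$records
    r2x <- (r$beta_exposure / r$se_exposure)^2 /
      ((r$beta_exposure / r$se_exposure)^2 + r$n_exposure - 2)
    r2y <- (r$beta_outcome / r$se_outcome)^2 /
      ((r$beta_outcome / r$se_outcome)^2 + r$n_outcome - 2)
    bad <- r2x <= r2y
    if (any(bad))
      audit <- c(audit, list(audit_entry(r$snp_id[bad], "steiger-filtered",
                                         name)))
    if (all(bad))
      return(list(status = "no-IV", forest = NULL, sens = NULL,
                  audit = do.call(rbind, c(audit, list(
                    audit_entry(name, "no-IV",
                                "all instruments Steiger-filtered"))))))
    h$records <- r[!bad, , drop = FALSE]
  }
  if (nrow(h$dropped) > 0)
    audit <- c(audit, list(audit_entry(h$dropped$snp_id, "snp-dropped",
                                       h$dropped$reason)))
  k <- nrow(h$records)
  forest <- mr_all_methods(h, seed = cfg$seed)
  ivw_fit <- mr_ivw(h)
  het <- ivw_fit$heterogeneity

  egger_int_p <- NA_real_
  if (k >= 3) egger_int_p <- mr_egger(h)$intercept$pvalue

  presso_gp <- NA_real_; n_out <- NA_integer_; q_p_corrected <- NA_real_
  if (k >= 4) {
    pr <- mr_presso(h, n_sim = cfg$presso_nsim, seed = cfg$seed)
    presso_gp <- pr$global_p
    n_out <- length(pr$outliers)
    if (n_out > 0) {
      keep <- !(h$records$snp_id %in% pr$outliers)
      h2 <- h; h2$records <- h$records[keep, , drop = FALSE]
      if (nrow(h2$records) >= 2)
        q_p_corrected <- mr_ivw(h2)$heterogeneity$pvalue
      audit <- c(audit, list(audit_entry(pr$outliers, "presso-outlier",
                                         name)))
    }
  }

  st <- tryCatch(steiger(h), error = function(e) NULL)
  cl <- tryCatch(
    suppressWarnings(coloc_abf(
      exp_tab[exp_tab$snp_id %in% out_tab$snp_id, , drop = FALSE],
      out_tab[out_tab$snp_id %in% exp_tab$snp_id, , drop = FALSE],
      priors = cfg$coloc_priors, sd_prior1 = 0.15, sd_prior2 = 0.2)),
    error = function(e) NULL)

  q_p <- if (!is.null(het)) het$pvalue else NA_real_
  # hard gate: heterogeneous and PRESSO could not fix it
  gated <- !is.na(q_p) && q_p < cfg$het_gate &&
    (is.na(q_p_corrected) || q_p_corrected < cfg$het_gate)
  if (gated)
    audit <- c(audit, list(audit_entry(name, "excluded-heterogeneity",
                                       sprintf("Q p = %.3g", q_p))))

  sens <- data.frame(
    exposure = name, nsnp = k,
    q = if (!is.null(het)) het$q else NA_real_, q_pvalue = q_p,
    egger_intercept_p = egger_int_p,
    presso_global_p = presso_gp, presso_n_outliers = n_out,
    steiger_direction = if (!is.null(st)) st$direction else NA_character_,
    steiger_p = if (!is.null(st)) st$pvalue else NA_real_,
    coloc_pp_h4 = if (!is.null(cl)) unname(cl$pp["H4"]) else NA_real_,
    gated = gated, stringsAsFactors = FALSE)

  list(status = "ok", forest = forest, sens = sens,
       audit = if (length(audit)) do.call(rbind, audit) else NULL,
       ivw_p = ivw_fit$estimate$pvalue)
}

#' Forward MR screen across the exposure family
#'
#' Runs instrument selection, harmonization, all estimators and the
#' sensitivity suite for every exposure against the outcome, then applies
#' Benjamini-Hochberg across the family to the primary (IVW / Wald-ratio)
#' p-values. Exposures that are heterogeneous (Cochran-Q p below the gate)
#' and not rescued by PRESSO outlier removal are flagged `gated` and
#' excluded from downstream mediation. Per-exposure failures are logged,
#' not fatal.
#'
#' @param config `pipeline_config`.
#' @return list of class `study_report` fragment: `forest` (per
#'   exposure x method, with `p_adjust` on the primary rows), `sensitivity`,
#'   `passed` (exposure names passing BH and gates), `audit`.
#' @export
run_forward_screen <- function(config) {
  frags <- lapply(names(config$exposures), function(nm) {
    tryCatch(
      analyse_pair(nm, config$exposures[[nm]], config$outcome, config,
                   config$p_threshold_exposure),
      error = function(e)
        list(status = "error", forest = NULL, sens = NULL,
             audit = audit_entry(nm, "error", conditionMessage(e))))
  })
  names(frags) <- names(config$exposures)

  forest <- rbind_frags(lapply(frags, `[[`, "forest"))
  sens <- rbind_frags(lapply(frags, `[[`, "sens"))
  audit <- rbind_frags(lapply(frags, `[[`, "audit"))

  ok <- vapply(frags, function(f) identical(f$status, "ok"), logical(1))
  p_primary <- vapply(frags[ok], `[[`, numeric(1), "ivw_p")
  passed <- character(0)
  if (length(p_primary) > 0 && !is.null(forest)) {
    p_adj <- bh_adjust(p_primary)
    primary <- forest$method %in% c("ivw_mre", "wald_ratio")
    forest$p_adjust <- NA_real_
    forest$p_adjust[primary] <-
      p_adj[match(forest$exposure[primary], names(p_primary))]
    gated_names <- sens$exposure[sens$gated]
    passed <- setdiff(names(p_primary)[p_adj < config$bh_alpha], gated_names)
  }
  structure(list(forest = forest, sensitivity = sens, passed = passed,
                 audit = audit),
            class = "study_report")
}

#' Reverse MR: outcome as exposure
#'
#' Re-runs the MR machinery with the outcome as exposure against each
#' original exposure, using the outcome's (genome-wide) threshold. Per-SNP
#' Steiger filtering removes instruments that explain more variance in the
#' original exposure than in the outcome (those belong to the forward
#' direction); the set-level Steiger direction is reported alongside.
#' Traits with no outcome instruments get status `"not-assessable"`.
#'
#' @param config `pipeline_config`.
#' @return `study_report` fragment with `forest`, `sensitivity`, `audit`.
#' @export
run_reverse_mr <- function(config) {
  sel <- select_instruments(config$outcome, config$p_threshold_outcome,
                            config$ld, r2_threshold = config$r2_threshold,
                            window_kb = config$window_kb,
                            min_f = config$min_f)
  if (nrow(sel$instruments) == 0) {
    return(structure(list(
      forest = NULL, sensitivity = NULL,
      audit = audit_entry("outcome", "not-assessable",
                          "no genome-wide-significant outcome instruments")),
      class = "study_report"))
  }
  frags <- lapply(names(config$exposures), function(nm) {
    tryCatch(
      analyse_pair(paste0("outcome->", nm), config$outcome,
                   config$exposures[[nm]], config,
                   config$p_threshold_outcome, steiger_filter = TRUE),
      error = function(e)
        list(status = "error", forest = NULL, sens = NULL,
             audit = audit_entry(nm, "reverse-error", conditionMessage(e))))
  })
  structure(list(
    forest = rbind_frags(lapply(frags, `[[`, "forest")),
    sensitivity = rbind_frags(lapply(frags, `[[`, "sens")),
    audit = rbind_frags(lapply(frags, `[[`, "audit"))),
    class = "study_report")
}

#' Mediation stage over screened exposure-mediator pairs
#'
#' Runs [mediate()] for every requested (exposure, mediator) pair; failures
#' are reported per pair, not fatal. One report row per attempted pair.
#'
#' @param config `pipeline_config`.
#' @param pairs data.frame with columns `exposure`, `mediator` (names into
#'   the config lists); defaults to all combinations of screened exposures
#'   and mediators.
#' @param passed exposure names passing the forward screen (used for the
#'   default `pairs`).
#' @return `study_report` fragment with `mediation` table and `results`
#'   (list of `mediation_result` / error messages).
#' @export
run_mediation <- function(config, pairs = NULL, passed = NULL) {
  if (is.null(pairs)) {
    exps <- if (is.null(passed)) names(config$exposures) else passed
    pairs <- expand.grid(exposure = exps,
                         mediator = names(config$mediators),
                         stringsAsFactors = FALSE)
  }
  results <- vector("list", nrow(pairs))
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    en <- pairs$exposure[i]; mn <- pairs$mediator[i]
    res <- tryCatch(
      mediate(config$exposures[[en]], config$mediators[[mn]],
              config$outcome, ld = config$ld,
              p_threshold_exposure = config$p_threshold_exposure,
              p_threshold_mediator = config$p_threshold_mediator,
              min_f = config$min_f, exposure_name = en, mediator_name = mn,
              outcome_name = "outcome", seed = config$seed),
      error = function(e) conditionMessage(e))
    results[[i]] <- res
    rows[[i]] <- if (inherits(res, "mediation_result")) mediation_table(res)
      else data.frame(pathway = paste(en, mn, "outcome", sep = "->"),
                      exposure = en, mediator = mn, total_effect = NA_real_,
                      two_step_effect = NA_real_,
                      two_step_prop_mediated = NA_real_,
                      mvmr_effect = NA_real_, mvmr_prop_mediated = NA_real_,
                      conditional_f_min = NA_real_, q_pvalue_mvmr = NA_real_,
                      stringsAsFactors = FALSE)
  }
  structure(list(mediation = rbind_frags(rows),
                 results = results),
            class = "study_report")
}

#' Run the full pipeline: forward screen, reverse MR, mediation
#'
#' @param config `pipeline_config`. When `config$out_dir` is set, writes
#'   `forest.tsv`, `sensitivity.tsv`, `reverse.tsv`, `mediation.tsv`,
#'   `audit.tsv` and a JSON run manifest there.
#' @return list of class `study_report` with all fragments.
#' @export
run_pipeline <- function(config) {
  fwd <- run_forward_screen(config)
  rev <- run_reverse_mr(config)
  med <- run_mediation(config, passed = fwd$passed)
  audit <- rbind_frags(list(fwd$audit, rev$audit))
  report <- structure(list(forest = fwd$forest,
                           sensitivity = fwd$sensitivity,
                           passed = fwd$passed,
                           reverse = rev$forest,
                           reverse_sensitivity = rev$sensitivity,
                           mediation = med$mediation,
                           mediation_results = med$results,
                           audit = audit),
                      class = "study_report")
  if (!is.null(config$out_dir)) write_report(report, config)
  report
}

write_report <- function(report, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) if (!is.null(x) && nrow(x) > 0)
    utils::write.table(x, file.path(config$out_dir, f), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  wt(report$forest, "forest.tsv")
  wt(report$sensitivity, "sensitivity.tsv")
  wt(report$reverse, "reverse.tsv")
  wt(report$mediation, "mediation.tsv")
  wt(report$audit, "audit.tsv")
  manifest <- list(
    seed = config$seed,
    n_exposures = length(config$exposures),
    n_mediators = length(config$mediators),
    p_threshold_exposure = config$p_threshold_exposure,
    p_threshold_mediator = config$p_threshold_mediator,
    bh_alpha = config$bh_alpha,
    passed = as.list(report$passed),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(config$out_dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report\n")
  if (!is.null(x$forest))
    cat("  forest table:", nrow(x$forest), "rows\n")
  if (!is.null(x$sensitivity))
    cat("  sensitivity table:", nrow(x$sensitivity), "rows\n")
  if (!is.null(x$passed))
    cat("  exposures passing screen:",
        if (length(x$passed)) paste(x$passed, collapse = ", ") else "none",
        "\n")
  if (!is.null(x$mediation))
    cat("  mediation table:", nrow(x$mediation), "rows\n")
  invisible(x)
}
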