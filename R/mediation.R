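# Mediation decomposition: two-step MR (product of coefficients) and
# multivariable MR (difference in coefficients), with proportion mediated.

#' Indirect effect by the product of coefficients
#'
#' Two-step MR indirect effect theta1 * theta2 with the delta-method
#' standard error sqrt(theta2^2 se1^2 + theta1^2 se2^2) (first order; the
#' exact-variance extra term se1^2 se2^2 is available via `exact`).
#'
#' @param theta1 list/vector with `beta` and `se`: exposure-to-mediator
#'   effect (step 1).
#' @param theta2 list/vector with `beta` and `se`: mediator-to-outcome
#'   effect (step 2).
#' @param exact include the second-order se1^2 se2^2 variance term.
#' @return list with `beta`, `se`, `ci_low`, `ci_high`, `pvalue`.
#' @export
two_step_indirect <- function(theta1, theta2, exact = FALSE) {
  b1 <- theta1[["beta"]]; s1 <- theta1[["se"]]
  b2 <- theta2[["beta"]]; s2 <- theta2[["se"]]
  stopifnot(s1 > 0, s2 > 0)
  beta <- b1 * b2
  v <- b2^2 * s1^2 + b1^2 * s2^2
  if (exact) v <- v + s1^2 * s2^2
  se <- sqrt(v)
  list(beta = beta, se = se,
       ci_low = beta - stats::qnorm(0.975) * se,
       ci_high = beta + stats::qnorm(0.975) * se,
       pvalue = z_pvalue(beta, se))
}

#' Multivariable IVW regression
#'
#' Weighted regression (no intercept) of per-SNP outcome effects on a matrix
#' of exposure effects with weights 1/se_outcome^2, giving the *direct*
#' effect of each exposure conditional on the others. Coefficient SEs carry
#' the multiplicative overdispersion factor max(1, sqrt(Q/df)) with
#' df = n_snp - n_exposures. Conditional instrument strength per exposure is
#' the mean squared standardized residual of that exposure's instrument
#' effects after regressing them on the other exposures' effects (requires
#' `se_exposure`).
#'
#' @param beta_outcome,se_outcome per-SNP outcome effects and SEs.
#' @param beta_exposure numeric matrix, one column per exposure (column
#'   names are the exposure names).
#' @param se_exposure optional matrix of exposure-effect SEs (same shape);
#'   needed for conditional F, otherwise conditional F is NA.
#' @return object of class `mvmr_result`: data.frame `estimates` (exposure,
#'   beta, se, ci, pvalue), `q` and `q_pvalue` (heterogeneity in the joint
#'   model), `conditional_f` named vector.
#' @export
mvmr_ivw <- function(beta_outcome, se_outcome, beta_exposure,
                     se_exposure = NULL) {
  X <- as.matrix(beta_exposure)
  if (is.null(colnames(X))) colnames(X) <- paste0("exposure", seq_len(ncol(X)))
  k <- nrow(X); p <- ncol(X)
  stopifnot(length(beta_outcome) == k, length(se_outcome) == k,
            all(se_outcome > 0), !anyNA(X))
  if (k <= p + 1)
    stop("insufficient instruments: need n_snp > n_exposures + 1")
  if (qr(X)$rank < p) {
    cors <- stats::cor(X)
    diag(cors) <- 0
    worst <- which(abs(cors) == max(abs(cors)), arr.ind = TRUE)[1, ]
    stop("collinear exposure matrix (worst pair: ",
         colnames(X)[worst[1]], " / ", colnames(X)[worst[2]], ")")
  }
  w <- 1 / se_outcome^2
  xtwx <- crossprod(X, X * w)
  bhat <- solve(xtwx, crossprod(X, beta_outcome * w))[, 1]
  resid <- beta_outcome - X %*% bhat
  q <- sum(w * resid^2)
  df <- k - p
  q_pvalue <- stats::pchisq(q, df, lower.tail = FALSE)
  infl <- max(1, sqrt(q / df))
  se <- sqrt(diag(solve(xtwx))) * infl

  cond_f <- rep(NA_real_, p)
  names(cond_f) <- colnames(X)
  if (!is.null(se_exposure)) {
    S <- as.matrix(se_exposure)
    for (j in seq_len(p)) {
      others <- X[, -j, drop = FALSE]
      e <- if (ncol(others) == 0) X[, j]
           else stats::residuals(stats::lm.fit(others, X[, j]))
      cond_f[j] <- mean((e / S[, j])^2)
    }
  }

  estimates <- data.frame(
    exposure = colnames(X), beta = bhat, se = se,
    ci_low = bhat - stats::qnorm(0.975) * se,
    ci_high = bhat + stats::qnorm(0.975) * se,
    pvalue = z_pvalue(bhat, se),
    stringsAsFactors = FALSE)
  rownames(estimates) <- NULL
  structure(list(estimates = estimates, q = q, df = df,
                 q_pvalue = q_pvalue, conditional_f = cond_f,
                 n_snp = k),
            class = "mvmr_result")
}

#' @export
print.mvmr_result <- function(x, ...) {
  cat(sprintf("Multivariable IVW (%d SNPs, Q = %.3g on %d df, p = %.3g)\n",
              x$n_snp, x$q, x$df, x$q_pvalue))
  print(x$estimates)
  invisible(x)
}

#' Proportion of the total effect that is mediated
#'
#' 100 * indirect / total when the two effects share a sign; when signs
#' disagree the proportion is not interpretable and NA is returned with
#' reason `"inconsistent-sign"` (attribute). A zero indirect effect gives
#' 0%. Values above 100% (possible through estimation noise) are returned
#' as-is with attribute `flag = "gt-100"`.
#'
#' @param total list/vector with `beta` (and optionally `se`): total effect
#'   of the exposure on the outcome.
#' @param indirect list/vector with `beta`: mediated (indirect) effect.
#' @return percentage (numeric scalar) or NA.
#' @export
proportion_mediated <- function(total, indirect) {
  tb <- total[["beta"]]; ib <- indirect[["beta"]]
  if (is.na(tb) || tb == 0)
    stop("undefined proportion: total effect is zero")
  if (is.na(ib)) return(NA_real_)
  if (ib == 0) return(0)
  if (sign(ib) != sign(tb)) {
    out <- NA_real_
    attr(out, "reason") <- "inconsistent-sign"
    return(out)
  }
  out <- 100 * ib / tb
  if (out > 100) attr(out, "flag") <- "gt-100"
  out
}

#' Full mediation decomposition for one exposure-mediator-outcome triplet
#'
#' Runs the two-step and multivariable decompositions from three summary-
#' statistic tables sharing a SNP panel:
#' \enumerate{
#'   \item step 1 — exposure instruments, exposure-to-mediator IVW (theta1);
#'   \item step 2 — mediator instruments, mediator-to-outcome IVW (theta2);
#'   \item total — exposure instruments, exposure-to-outcome IVW;
#'   \item product indirect = theta1 * theta2, delta-method SE;
#'   \item MVMR — joint instruments, direct exposure effect conditional on
#'     the mediator; difference indirect = total - direct;
#'   \item proportion mediated under both decompositions (NA on sign
#'     inconsistency).
#' }
#'
#' @param exposure,mediator,outcome `sumstats` tables.
#' @param ld optional `ld_matrix` for clumping.
#' @param p_threshold_exposure,p_threshold_mediator instrument significance
#'   thresholds (microbial traits conventionally 1e-5, others 5e-8).
#' @param min_f weak-instrument cutoff.
#' @param exposure_name,mediator_name,outcome_name labels.
#' @param seed seed for bootstrap-based components.
#' @return object of class `mediation_result` with fields `total_effect`,
#'   `theta1`, `theta2`, `indirect_product`, `direct_mvmr`,
#'   `indirect_difference`, `prop_mediated_product`,
#'   `prop_mediated_difference`, `conditional_f`, `q_pvalue_mvmr`, plus the
#'   underlying sub-results for audit.
#' @export
mediate <- function(exposure, mediator, outcome, ld = NULL,
                    p_threshold_exposure = 1e-5,
                    p_threshold_mediator = 5e-8,
                    min_f = 10,
                    exposure_name = "exposure", mediator_name = "mediator",
                    outcome_name = "outcome", seed = 1L) {
  stage <- function(label, expr) {
    tryCatch(expr, error = function(e)
      stop("mediation stage [", label, "]: ", conditionMessage(e),
           call. = FALSE))
  }
  iv_exp <- stage("exposure-instruments",
                  select_instruments(exposure, p_threshold_exposure, ld,
                                     min_f = min_f)$instruments)
  iv_med <- stage("mediator-instruments",
                  select_instruments(mediator, p_threshold_mediator, ld,
                                     min_f = min_f)$instruments)
  # the two instrument sets of the mediation diagram are disjoint: SNPs
  # instrumenting the exposure act on the mediator through the exposure and
  # would bias the mediator-to-outcome step
  iv_med <- iv_med[!iv_med$snp_id %in% iv_exp$snp_id, , drop = FALSE]
  if (nrow(iv_exp) == 0) stop("mediation stage [exposure-instruments]: no instruments")
  if (nrow(iv_med) == 0) stop("mediation stage [mediator-instruments]: no instruments")

  subset_on <- function(tab, ids) tab[tab$snp_id %in% ids, , drop = FALSE]

  h1 <- stage("step1-harmonize",
              harmonize(iv_exp, subset_on(mediator, iv_exp$snp_id),
                        exposure_name = exposure_name,
                        outcome_name = mediator_name))
  step1 <- stage("step1-ivw", mr_ivw(h1))

  h2 <- stage("step2-harmonize",
              harmonize(iv_med, subset_on(outcome, iv_med$snp_id),
                        exposure_name = mediator_name,
                        outcome_name = outcome_name))
  step2 <- stage("step2-ivw", mr_ivw(h2))

  ht <- stage("total-harmonize",
              harmonize(iv_exp, subset_on(outcome, iv_exp$snp_id),
                        exposure_name = exposure_name,
                        outcome_name = outcome_name))
  total_fit <- stage("total-ivw", mr_ivw(ht))

  theta1 <- list(beta = step1$estimate$beta, se = step1$estimate$se)
  theta2 <- list(beta = step2$estimate$beta, se = step2$estimate$se)
  total <- list(beta = total_fit$estimate$beta, se = total_fit$estimate$se)
  indirect_prod <- two_step_indirect(theta1, theta2)

  # MVMR over the union of exposure and mediator instruments: align all
  # three traits on the shared ids with the exposure's allele orientation
  union_ids <- union(iv_exp$snp_id, iv_med$snp_id)
  exp_rows <- subset_on(exposure, union_ids)
  med_al <- stage("mvmr-harmonize-mediator",
                  harmonize(exp_rows, subset_on(mediator, union_ids)))
  out_al <- stage("mvmr-harmonize-outcome",
                  harmonize(exp_rows, subset_on(outcome, union_ids)))
  ids <- intersect(med_al$records$snp_id, out_al$records$snp_id)
  if (length(ids) < 4)
    stop("mediation stage [mvmr]: fewer than 4 SNPs shared across traits")
  mrec <- med_al$records[match(ids, med_al$records$snp_id), ]
  orec <- out_al$records[match(ids, out_al$records$snp_id), ]
  Bx <- cbind(mrec$beta_exposure, mrec$beta_outcome)
  Sx <- cbind(mrec$se_exposure, mrec$se_outcome)
  colnames(Bx) <- colnames(Sx) <- c(exposure_name, mediator_name)
  mvmr <- stage("mvmr-ivw",
                mvmr_ivw(orec$beta_outcome, orec$se_outcome, Bx, Sx))
  direct <- as.list(mvmr$estimates[mvmr$estimates$exposure == exposure_name,
                                   c("beta", "se")])
  indirect_diff <- list(
    beta = total$beta - direct$beta,
    se = sqrt(total$se^2 + direct$se^2))
  indirect_diff$ci_low <- indirect_diff$beta -
    stats::qnorm(0.975) * indirect_diff$se
  indirect_diff$ci_high <- indirect_diff$beta +
    stats::qnorm(0.975) * indirect_diff$se
  indirect_diff$pvalue <- z_pvalue(indirect_diff$beta, indirect_diff$se)

  structure(list(
    exposure = exposure_name, mediator = mediator_name,
    outcome = outcome_name,
    total_effect = total,
    theta1 = theta1, theta2 = theta2,
    indirect_product = indirect_prod,
    direct_mvmr = direct,
    indirect_difference = indirect_diff,
    prop_mediated_product = proportion_mediated(total, indirect_prod),
    prop_mediated_difference = proportion_mediated(total, indirect_diff),
    conditional_f = mvmr$conditional_f,
    q_pvalue_mvmr = mvmr$q_pvalue,
    n_snp_step1 = step1$estimate$n_snp,
    n_snp_step2 = step2$estimate$n_snp,
    n_snp_mvmr = mvmr$n_snp,
    audit = list(step1 = step1, step2 = step2, total = total_fit,
                 mvmr = mvmr)),
    class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  fmt <- function(e) sprintf("%.3e (se %.2e)", e$beta, e$se)
  cat(sprintf("Mediation: %s -> %s -> %s\n", x$exposure, x$mediator,
              x$outcome))
  cat("  total effect:      ", fmt(x$total_effect), "\n")
  cat("  indirect (product):", fmt(x$indirect_product),
      sprintf(" prop. mediated %.2f%%\n", x$prop_mediated_product))
  cat("  indirect (diff.):  ", fmt(x$indirect_difference),
      sprintf(" prop. mediated %.2f%%\n", x$prop_mediated_difference))
  invisible(x)
}

#' Serialize mediation results to the report-table schema
#'
#' One row per result: pathway, exposure, mediator, total effect, two-step
#' indirect effect + proportion, MVMR difference effect + proportion.
#' @param results list of `mediation_result` objects (or a single one).
#' @return data.frame.
#' @export
mediation_table <- function(results) {
  if (inherits(results, "mediation_result")) results <- list(results)
  rows <- lapply(results, function(x) {
    data.frame(
      pathway = paste(x$exposure, x$mediator, x$outcome, sep = "->"),
      exposure = x$exposure, mediator = x$mediator,
      total_effect = x$total_effect$beta,
      two_step_effect = x$indirect_product$beta,
      two_step_prop_mediated = as.numeric(x$prop_mediated_product),
      mvmr_effect = x$indirect_difference$beta,
      mvmr_prop_mediated = as.numeric(x$prop_mediated_difference),
      conditional_f_min = min(x$conditional_f),
      q_pvalue_mvmr = x$q_pvalue_mvmr,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
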