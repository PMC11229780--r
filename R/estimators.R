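# Univariable two-sample MR estimators and heterogeneity statistics.
#
# All estimators consume a harmonized_set and return mr_estimate objects
# sharing a common row schema (method, nsnp, beta, se, CI, p, OR scale).

mr_estimate <- function(method, beta, se, n_snp, pvalue = NULL, df = NULL) {
  stopifnot(se > 0)
  crit <- if (is.null(df)) stats::qnorm(0.975) else stats::qt(0.975, df)
  if (is.null(pvalue)) {
    pvalue <- if (is.null(df)) z_pvalue(beta, se)
              else 2 * stats::pt(-abs(beta / se), df)
  }
  structure(list(method = method, beta = beta, se = se,
                 ci_low = beta - crit * se, ci_high = beta + crit * se,
                 pvalue = max(pvalue, .Machine$double.xmin),
                 n_snp = as.integer(n_snp),
                 or = exp(beta),
                 or_ci_low = exp(beta - crit * se),
                 or_ci_high = exp(beta + crit * se)),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: beta = %.4g (se %.4g), 95%% CI [%.4g, %.4g], p = %.3g, nSNP = %d\n",
              x$method, x$beta, x$se, x$ci_low, x$ci_high, x$pvalue, x$n_snp))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, nsnp = x$n_snp, beta = x$beta, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, pvalue = x$pvalue,
             or = x$or, or_ci_low = x$or_ci_low, or_ci_high = x$or_ci_high,
             stringsAsFactors = FALSE)
}

heterogeneity_result <- function(q, df) {
  structure(list(q = q, df = as.integer(df),
                 pvalue = stats::pchisq(q, df, lower.tail = FALSE),
                 scale_factor = max(1, sqrt(q / df))),
            class = "heterogeneity_result")
}

unpack <- function(set) {
  if (!inherits(set, "harmonized_set")) stop("expected a harmonized_set")
  as.list(set$records[c("beta_exposure", "se_exposure",
                        "beta_outcome", "se_outcome")])
}

#' Wald ratio estimate from a single SNP
#'
#' Causal effect by/bx with first-order delta-method standard error
#' sy/|bx| (exposure-side uncertainty ignored at first order).
#'
#' @param bx,sx exposure effect and SE.
#' @param by,sy outcome effect and SE.
#' @return `mr_estimate` with method `"wald_ratio"`.
#' @export
wald_ratio <- function(bx, sx, by, sy) {
  if (bx == 0) stop("undefined Wald ratio: exposure effect is zero")
  mr_estimate("wald_ratio", beta = by / bx, se = sy / abs(bx), n_snp = 1)
}

#' Inverse-variance weighted estimate (multiplicative random effects)
#'
#' Weighted least squares of outcome effects on exposure effects through the
#' origin with weights 1/se_outcome^2. Cochran's Q over the per-SNP ratios is
#' the weighted residual sum of squares; when Q/df exceeds 1 the fixed-effect
#' SE is inflated by sqrt(Q/df) (the multiplicative random-effects model —
#' the SE is never deflated). A single SNP delegates to [wald_ratio()].
#'
#' @param set `harmonized_set`.
#' @return list with `estimate` (`mr_estimate`, method `"ivw_mre"`) and
#'   `heterogeneity` (`heterogeneity_result`, NULL for a single SNP).
#' @export
mr_ivw <- function(set) {
  d <- unpack(set)
  k <- length(d$beta_exposure)
  if (k < 1) stop("insufficient instruments: IVW needs at least 1 SNP")
  if (k == 1) {
    est <- wald_ratio(d$beta_exposure, d$se_exposure,
                      d$beta_outcome, d$se_outcome)
    return(list(estimate = est, heterogeneity = NULL))
  }
  w <- 1 / d$se_outcome^2
  bhat <- sum(w * d$beta_exposure * d$beta_outcome) /
    sum(w * d$beta_exposure^2)
  se_fe <- sqrt(1 / sum(w * d$beta_exposure^2))
  q <- sum(w * (d$beta_outcome - bhat * d$beta_exposure)^2)
  het <- heterogeneity_result(q, k - 1)
  se <- se_fe * het$scale_factor
  list(estimate = mr_estimate("ivw_mre", bhat, se, k),
       heterogeneity = het)
}

#' Maximum-likelihood MR estimate
#'
#' Bivariate-normal likelihood with the true per-SNP exposure effects as
#' nuisance parameters: bx_j ~ N(g_j, sx_j^2), by_j ~ N(beta * g_j, sy_j^2),
#' errors independent with known SEs. The g_j are profiled out analytically
#' and the profile likelihood maximized over beta; the SE comes from the
#' numerical observed information of the profile log-likelihood. Falls back
#' to IVW with a warning if the optimizer fails.
#'
#' @param set `harmonized_set` with at least 2 SNPs.
#' @return `mr_estimate` with method `"max_likelihood"`.
#' @export
mr_max_likelihood <- function(set) {
  d <- unpack(set)
  k <- length(d$beta_exposure)
  if (k < 2) stop("insufficient instruments: maximum likelihood needs >= 2 SNPs")
  vx <- d$se_exposure^2
  vy <- d$se_outcome^2
  # profile log-likelihood: for fixed beta the MLE of g_j is a precision-
  # weighted combination of bx_j and by_j/beta
  nll <- function(beta) {
    g <- (d$beta_exposure / vx + beta * d$beta_outcome / vy) /
      (1 / vx + beta^2 / vy)
    sum((d$beta_exposure - g)^2 / vx + (d$beta_outcome - beta * g)^2 / vy) / 2
  }
  ivw0 <- mr_ivw(set)$estimate
  opt <- tryCatch(
    stats::optim(ivw0$beta, nll, method = "BFGS", hessian = TRUE),
    error = function(e) NULL)
  if (is.null(opt) || opt$convergence != 0 || !is.finite(opt$value) ||
      opt$hessian[1, 1] <= 0) {
    warning("maximum-likelihood optimizer failed; falling back to IVW")
    est <- ivw0
    est$method <- "max_likelihood"
    return(est)
  }
  mr_estimate("max_likelihood", opt$par, sqrt(1 / opt$hessian[1, 1]), k)
}

# per-SNP Wald ratios and their first-order variances
ratio_stats <- function(d) {
  ratio <- d$beta_outcome / d$beta_exposure
  var_ratio <- d$se_outcome^2 / d$beta_exposure^2 +
    d$beta_outcome^2 * d$se_exposure^2 / d$beta_exposure^4
  list(ratio = ratio, var = var_ratio)
}

# weighted 50th percentile with cumulative-weight interpolation
weighted_median_point <- function(ratio, weight) {
  ord <- order(ratio)
  r <- ratio[ord]
  w <- weight[ord] / sum(weight)
  cw <- cumsum(w) - w / 2
  if (cw[1] >= 0.5) return(r[1])
  if (cw[length(cw)] <= 0.5) return(r[length(r)])
  stats::approx(cw, r, xout = 0.5, rule = 2)$y
}

#' Weighted-median MR estimate
#'
#' Weighted 50th percentile of the per-SNP Wald ratios with inverse-variance
#' weights (first-order ratio variances), consistent when at least half the
#' weight comes from valid instruments. The SE is a seeded parametric
#' bootstrap: exposure and outcome effects are perturbed by their SEs,
#' the weighted median recomputed, and the SD taken.
#'
#' @param set `harmonized_set` with at least 3 SNPs.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap (required for reproducibility).
#' @return `mr_estimate` with method `"weighted_median"`.
#' @export
mr_weighted_median <- function(set, n_boot = 1000, seed) {
  d <- unpack(set)
  k <- length(d$beta_exposure)
  if (k < 3) stop("insufficient instruments: weighted median needs >= 3 SNPs")
  if (missing(seed)) stop("seed is required for the weighted-median bootstrap")
  rs <- ratio_stats(d)
  w <- 1 / rs$var
  point <- weighted_median_point(rs$ratio, w)
  boots <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(k, d$beta_exposure, d$se_exposure)
      by <- stats::rnorm(k, d$beta_outcome, d$se_outcome)
      ratio <- by / bx
      vr <- d$se_outcome^2 / bx^2 + by^2 * d$se_exposure^2 / bx^4
      weighted_median_point(ratio, 1 / vr)
    }, numeric(1))
  })
  mr_estimate("weighted_median", point, stats::sd(boots), k)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure effects *with* an intercept
#' (weights 1/se_outcome^2), after orienting all exposure effects to be
#' non-negative. A nonzero intercept indicates directional horizontal
#' pleiotropy; the slope is the pleiotropy-adjusted causal effect. SEs use
#' the multiplicative-overdispersion rule (residual scale floored at 1) and
#' p-values the t distribution with n_snp - 2 df.
#'
#' @param set `harmonized_set` with at least 3 SNPs.
#' @return list with `slope` and `intercept` (`mr_estimate`s) and
#'   `heterogeneity` (Q' on n_snp - 2 df).
#' @export
mr_egger <- function(set) {
  d <- unpack(set)
  k <- length(d$beta_exposure)
  if (k < 3) stop("insufficient instruments: MR-Egger needs >= 3 SNPs")
  flip <- sign(d$beta_exposure)
  flip[flip == 0] <- 1
  bx <- d$beta_exposure * flip
  by <- d$beta_outcome * flip
  w <- 1 / d$se_outcome^2
  fit <- stats::lm(by ~ bx, weights = w)
  cf <- summary(fit)$coefficients
  sigma <- summary(fit)$sigma
  resid_w <- stats::residuals(fit) * sqrt(w)
  q <- sum(resid_w^2)
  het <- heterogeneity_result(q, k - 2)
  # lm's SEs already carry the residual scale sigma; floor it at 1 so the
  # random-effects model never *shrinks* the fixed-effect SE
  infl <- max(1, sigma) / sigma
  slope <- mr_estimate("egger_slope", cf["bx", "Estimate"],
                       cf["bx", "Std. Error"] * infl, k, df = k - 2)
  intercept <- mr_estimate("egger_intercept", cf["(Intercept)", "Estimate"],
                           cf["(Intercept)", "Std. Error"] * infl, k,
                           df = k - 2)
  list(slope = slope, intercept = intercept, heterogeneity = het)
}

#' Leave-one-out IVW analysis
#'
#' Re-estimates the IVW effect omitting each SNP in turn; a single SNP whose
#' omission moves the estimate markedly flags an influential (possibly
#' pleiotropic) instrument.
#'
#' @param set `harmonized_set` with at least 3 SNPs.
#' @return data.frame with one row per omitted SNP: `snp_id`, `beta`, `se`,
#'   `ci_low`, `ci_high`, `pvalue`.
#' @export
mr_leave_one_out <- function(set) {
  k <- nrow(set$records)
  if (k < 3) stop("insufficient instruments: leave-one-out needs >= 3 SNPs")
  rows <- lapply(seq_len(k), function(i) {
    sub <- set
    sub$records <- set$records[-i, , drop = FALSE]
    est <- mr_ivw(sub)$estimate
    data.frame(snp_id = set$records$snp_id[i], beta = est$beta, se = est$se,
               ci_low = est$ci_low, ci_high = est$ci_high,
               pvalue = est$pvalue, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run all univariable estimators on one harmonized set
#'
#' @param set `harmonized_set`.
#' @param seed seed for the weighted-median bootstrap.
#' @return data.frame in the common estimator schema, one row per method
#'   (methods needing more SNPs than available are omitted).
#' @export
mr_all_methods <- function(set, seed = 1L) {
  k <- nrow(set$records)
  out <- list(as.data.frame(mr_ivw(set)$estimate))
  if (k >= 2)
    out <- c(out, list(as.data.frame(mr_max_likelihood(set))))
  if (k >= 3) {
    eg <- mr_egger(set)
    out <- c(out,
             list(as.data.frame(mr_weighted_median(set, seed = seed)),
                  as.data.frame(eg$slope), as.data.frame(eg$intercept)))
  }
  res <- do.call(rbind, out)
  res <- cbind(exposure = set$exposure_name, outcome = set$outcome_name, res,
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
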