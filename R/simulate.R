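# Summary-level GWAS simulator with known structural truth.
#
# Emulates the statistical structure of the study's inputs: per-SNP effects
# with SEs scaled by sample size and allele frequency, an
# exposure -> mediator -> outcome structural model, optional directional
# pleiotropy, and block-diagonal LD for clumping exercises. Betas are drawn
# directly with analytic SEs (summary-level, not individual-level), which is
# what every downstream estimator consumes.

#' Ground-truth structural parameters for a simulated triplet
#'
#' Defaults mirror the sample sizes of the motivating study design: a
#' microbial-trait exposure GWAS (n = 8956), a metabolite/cytokine mediator
#' GWAS (n = 7824) and a large binary-outcome GWAS (n = 463010) whose
#' effects live on a linear-probability scale (tiny betas, odds ratios near
#' 1). Structural effects follow the mediation diagram: theta1
#' (exposure to mediator), theta2 (mediator to outcome), theta3 (direct
#' exposure to outcome); the total exposure effect is theta3 + theta1*theta2.
#'
#' @param theta1,theta2,theta3 structural effects.
#' @param n_snp_exposure,n_snp_mediator,n_snp_outcome counts of exposure
#'   instruments, mediator-specific instruments, and outcome-specific
#'   instruments (SNPs acting on the outcome only — gives reverse MR a
#'   well-posed instrument set).
#' @param rsq_range range of per-SNP variance explained in the instrumented
#'   trait (uniform, random effect sign). Per-SNP instrument strength is
#'   then F ~= n * rsq regardless of allele frequency; the default 0.002 -
#'   0.01 gives F between roughly 20 and 90 at the default exposure sample
#'   size, the strength range typical of the motivating GWAS.
#' @param pleiotropy_frac fraction of exposure instruments given a direct
#'   outcome effect.
#' @param pleiotropy_sd SD of those pleiotropic effects.
#' @param pleiotropy_mean mean of pleiotropic effects, oriented to the
#'   exposure-raising allele (nonzero = directional pleiotropy of the kind
#'   the Egger intercept targets).
#' @param maf_range minor-allele-frequency range (uniform).
#' @param n_exp,n_med,n_out GWAS sample sizes.
#' @param ld_block_size,ld_rho LD structure: exchangeable blocks of this
#'   size with off-diagonal r^2 `ld_rho` (block size 1 = independent panel).
#' @param seed integer seed.
#' @return list of class `sim_truth`.
#' @export
sim_truth <- function(theta1 = 0.4, theta2 = 0.5, theta3 = 0.1,
                      n_snp_exposure = 50, n_snp_mediator = 30,
                      n_snp_outcome = 0,
                      rsq_range = c(0.002, 0.01),
                      pleiotropy_frac = 0, pleiotropy_sd = 0,
                      pleiotropy_mean = 0,
                      maf_range = c(0.05, 0.5),
                      n_exp = 8956, n_med = 7824, n_out = 463010,
                      ld_block_size = 1, ld_rho = 0,
                      seed = 1L) {
  stopifnot(n_snp_exposure > 0, n_snp_mediator >= 0, n_snp_outcome >= 0,
            pleiotropy_frac >= 0, pleiotropy_frac <= 1,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            rsq_range[1] > 0, rsq_range[2] < 1,
            ld_block_size >= 1, ld_rho >= 0, ld_rho < 1,
            n_exp > 0, n_med > 0, n_out > 0)
  structure(list(theta1 = theta1, theta2 = theta2, theta3 = theta3,
                 n_snp_exposure = as.integer(n_snp_exposure),
                 n_snp_mediator = as.integer(n_snp_mediator),
                 n_snp_outcome = as.integer(n_snp_outcome),
                 rsq_range = rsq_range,
                 pleiotropy_frac = pleiotropy_frac,
                 pleiotropy_sd = pleiotropy_sd,
                 pleiotropy_mean = pleiotropy_mean,
                 maf_range = maf_range,
                 n_exp = as.integer(n_exp), n_med = as.integer(n_med),
                 n_out = as.integer(n_out),
                 ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho,
                 seed = as.integer(seed)),
            class = "sim_truth")
}

# non-palindromic allele pairs only, so harmonization keeps every SNP
NONPAL_PAIRS <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                      c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))

#' Simulate a GWAS summary-statistic triplet with known truth
#'
#' Draws true instrument effects, propagates them through the structural
#' model, and adds sampling noise with analytic standard errors
#' se = 1/sqrt(2 maf (1-maf) n). Exposure instruments affect the mediator
#' through theta1 and the outcome through theta3 + theta1*theta2;
#' mediator-specific instruments affect the outcome through theta2 only.
#' A `pleiotropy_frac` fraction of exposure instruments additionally gets a
#' direct outcome effect drawn from N(pleiotropy_mean, pleiotropy_sd^2).
#' Fully reproducible from `truth$seed`.
#'
#' @param truth `sim_truth`.
#' @return list of class `sim_dataset`: `exposure`, `mediator`, `outcome`
#'   (`sumstats` over a shared panel), `ld` (`ld_matrix`), `truth` (with the
#'   drawn `gamma`, `alpha`, `delta` vectors attached).
#' @export
simulate_gwas <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  withr::with_seed(truth$seed, {
    m_e <- truth$n_snp_exposure
    m_m <- truth$n_snp_mediator
    m_o <- truth$n_snp_outcome
    m <- m_e + m_m + m_o
    snp_id <- sprintf("rs%05d", seq_len(m))
    # LD blocks are contiguous runs of `ld_block_size` SNPs; each block sits
    # on one chromosome with SNPs 10 kb apart, blocks 1 Mb apart (cross-block
    # r2 is 0, so block separation needs no relation to the clump window)
    bs <- truth$ld_block_size
    block <- (seq_len(m) - 1L) %/% bs
    chrom <- as.character((block %% 22L) + 1L)
    block_rank <- stats::ave(block, chrom, FUN = function(b)
      match(b, unique(b)))
    within <- (seq_len(m) - 1L) %% bs
    pos <- as.integer(1e6 + (block_rank - 1L) * 1e6 + within * 1e4)
    maf_v <- stats::runif(m, truth$maf_range[1], truth$maf_range[2])
    eaf <- ifelse(stats::runif(m) < 0.5, maf_v, 1 - maf_v)
    pair <- NONPAL_PAIRS[sample.int(nrow(NONPAL_PAIRS), m, replace = TRUE), ,
                         drop = FALSE]

    # effect magnitude from per-SNP variance explained:
    # rsq = 2 maf (1-maf) beta^2  =>  beta = sqrt(rsq / (2 maf (1-maf)))
    draw_effect <- function(idx)
      sample(c(-1, 1), length(idx), replace = TRUE) *
        sqrt(stats::runif(length(idx), truth$rsq_range[1],
                          truth$rsq_range[2]) /
               (2 * maf_v[idx] * (1 - maf_v[idx])))
    gamma <- alpha <- omega <- rep(0, m)
    gamma[seq_len(m_e)] <- draw_effect(seq_len(m_e))      # SNP -> exposure
    if (m_m > 0)                                          # mediator-specific
      alpha[m_e + seq_len(m_m)] <- draw_effect(m_e + seq_len(m_m))
    if (m_o > 0)                                          # outcome-specific
      omega[m_e + m_m + seq_len(m_o)] <-
        draw_effect(m_e + m_m + seq_len(m_o))

    delta <- rep(0, m)
    if (truth$pleiotropy_frac > 0 && m_e > 0) {
      n_pleio <- round(truth$pleiotropy_frac * m_e)
      idx <- sample.int(m_e, n_pleio)
      # oriented to the exposure-raising allele, so a nonzero mean is
      # directional in the frame Egger regression works in
      delta[idx] <- sign(gamma[idx]) *
        stats::rnorm(n_pleio, truth$pleiotropy_mean, truth$pleiotropy_sd)
    }

    true_exp <- gamma
    true_med <- truth$theta1 * gamma + alpha
    true_out <- (truth$theta3 + truth$theta1 * truth$theta2) * gamma +
      truth$theta2 * alpha + omega + delta

    make_trait <- function(true_beta, n) {
      se <- 1 / sqrt(2 * maf_v * (1 - maf_v) * n)
      beta <- stats::rnorm(m, true_beta, se)
      p <- 2 * stats::pnorm(-abs(beta / se))
      sumstats(data.frame(
        snp_id = snp_id, chrom = chrom, pos = pos,
        effect_allele = pair[, 1], other_allele = pair[, 2],
        eaf = eaf, beta = beta, se = se,
        pvalue = pmax(p, .Machine$double.xmin), n = n,
        stringsAsFactors = FALSE))
    }

    exposure <- make_trait(true_exp, truth$n_exp)
    mediator <- make_trait(true_med, truth$n_med)
    outcome <- make_trait(true_out, truth$n_out)

    r2 <- diag(m)
    if (bs > 1 && truth$ld_rho > 0) {
      same <- outer(block, block, "==")
      r2[same] <- truth$ld_rho
      diag(r2) <- 1
    }
    ld <- ld_matrix(r2, snp_ids = snp_id, positions = pos)

    truth_out <- truth
    truth_out$gamma <- gamma
    truth_out$alpha <- alpha
    truth_out$omega <- omega
    truth_out$delta <- delta
    structure(list(exposure = exposure, mediator = mediator,
                   outcome = outcome, ld = ld, truth = truth_out),
              class = "sim_dataset")
  })
}

#' Displace one SNP's outcome effect (outlier injection)
#'
#' Shifts the chosen SNP's outcome beta by `shift_in_se` outcome standard
#' errors (sign-preserving: negative shifts displace downward) and recomputes
#' its p-value; the truth is annotated with the injected index.
#'
#' @param ds `sim_dataset`.
#' @param snp_index row index into the shared panel.
#' @param shift_in_se displacement in units of that SNP's outcome SE.
#' @return modified `sim_dataset`.
#' @export
inject_outlier <- function(ds, snp_index, shift_in_se) {
  stopifnot(inherits(ds, "sim_dataset"),
            snp_index >= 1, snp_index <= nrow(ds$outcome))
  se <- ds$outcome$se[snp_index]
  ds$outcome$beta[snp_index] <- ds$outcome$beta[snp_index] + shift_in_se * se
  z <- ds$outcome$beta[snp_index] / se
  ds$outcome$pvalue[snp_index] <- max(2 * stats::pnorm(-abs(z)),
                                      .Machine$double.xmin)
  ds$truth$injected_outlier <- c(ds$truth$injected_outlier,
                                 stats::setNames(shift_in_se,
                                                 ds$outcome$snp_id[snp_index]))
  ds
}

#' Write a simulated dataset to a fixture directory
#'
#' Emits `exposure.tsv`, `mediator.tsv`, `outcome.tsv`, `ld.tsv` and a
#' machine-readable `truth.json` manifest.
#' @param ds `sim_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_sumstats(ds$exposure, file.path(dir, "exposure.tsv"))
  write_sumstats(ds$mediator, file.path(dir, "mediator.tsv"))
  write_sumstats(ds$outcome, file.path(dir, "outcome.tsv"))
  write_ld_matrix(ds$ld, file.path(dir, "ld.tsv"))
  truth <- ds$truth
  class(truth) <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
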