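---
title: "Methods: two-sample MR and mediation decomposition from GWAS summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR and mediation decomposition from GWAS summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
options(mrmediate.quiet = TRUE)
```

`mrmediate` implements a complete two-sample Mendelian randomization (MR)
workflow for asking whether an exposure (here, typically a gut microbial
trait) causally affects a disease outcome (a binary trait such as rheumatoid
arthritis), and how much of that effect flows through an intermediate
mediator (a blood metabolite or circulating cytokine). Everything operates
on GWAS summary statistics — one row per SNP with effect size, standard
error, allele coding, allele frequency, p-value and sample size — so no
individual-level data are needed.

## The causal model

Let $G$ index genetic variants used as instruments, $X$ the exposure, $M$
the mediator and $Y$ the outcome. The mediation diagram has three structural
coefficients:

* $\theta_1$: effect of $X$ on $M$,
* $\theta_2$: effect of $M$ on $Y$,
* $\theta_3$: direct effect of $X$ on $Y$ not through $M$.

The total causal effect of $X$ on $Y$ is $\theta_3 + \theta_1\theta_2$, the
indirect (mediated) effect is $\theta_1\theta_2$, and the proportion
mediated is $100 \cdot \theta_1\theta_2 / (\theta_3 + \theta_1\theta_2)$.

Instrumental-variable validity requires each instrument to (1) associate
with its exposure, (2) be independent of confounders of the
exposure–outcome relation, and (3) affect the outcome only through the
exposure. Assumption (1) is checked with F statistics; (3) is probed by the
sensitivity suite (Egger intercept, MR-PRESSO, leave-one-out); (2) is
untestable from summary data and remains an assumption.

## Instrument selection

* **Significance threshold.** Strict inequality `pvalue < threshold`.
  Defaults follow a dual-threshold policy: genome-wide $5\times10^{-8}$ for
  well-powered traits (metabolites, cytokines, the outcome) and a permissive
  $1\times10^{-5}$ for microbial traits, whose GWAS rarely yield genome-wide
  hits; both thresholds are per-trait-class configuration, not hard-coded.
* **LD clumping.** Greedy: visit SNPs by ascending p-value (ties broken
  lexicographically by SNP id for determinism); each accepted index SNP
  removes unaccepted SNPs on the same chromosome within a 10,000 kb window
  (center-to-center) with $r^2 \ge 0.01$. The $r^2$ semantics follow the
  PLINK clumping convention. SNPs missing from the LD matrix are retained
  with a warning (permissive clumping); cross-chromosome pairs are never
  clumped.
* **F statistic.** Default per-SNP strength is the summary-data
  approximation $F = (\beta/\mathrm{se})^2$; instruments with $F < 10$ are
  removed as weak. A variance-explained form
  $F = r^2(n-2)/(1-r^2)$ with $r^2 = 2\beta^2\,\mathrm{maf}(1-\mathrm{maf})$
  is available where allele frequencies are present, because published
  F ranges are sometimes computed that way and the two differ at small n.

## Harmonization

Outcome effects are aligned to the exposure's effect allele SNP by SNP.
Swapped allele labels flip the outcome beta's sign and complement its
frequency. Palindromic SNPs (A/T, C/G) carry no strand information in their
labels: those with minor-allele frequency above 0.3 are dropped as
unresolvable, the rest are aligned by comparing allele frequencies to 0.5.
The 0.3 cutoff is the conventional one for this rule. Duplicate rsIDs keep
the row with the smallest exposure p-value. Every removal is recorded in a
`dropped` audit table with a machine-readable reason
(`unmatched`, `allele-mismatch`, `palindromic-ambiguous`).

## Estimators

All estimators consume allele-aligned pairs
$(\hat\beta_{X,j}, \hat\beta_{Y,j})$ with standard errors
$(\sigma_{X,j}, \sigma_{Y,j})$.

* **Wald ratio** (1 SNP): $\hat\beta = \hat\beta_Y/\hat\beta_X$, first-order
  SE $\sigma_Y/|\hat\beta_X|$.
* **IVW, multiplicative random effects** (primary): weighted least squares
  of $\hat\beta_Y$ on $\hat\beta_X$ through the origin with weights
  $1/\sigma_Y^2$. Cochran's $Q$ is the weighted residual sum of squares on
  $k-1$ df; the fixed-effect SE is multiplied by
  $\max\{1, \sqrt{Q/(k-1)}\}$, so heterogeneity inflates but never deflates
  the SE. With one SNP, IVW *is* the Wald ratio.
* **Maximum likelihood**: bivariate-normal likelihood treating the true
  per-SNP exposure effects as nuisance parameters, profiled out
  analytically; the SE comes from the numerical observed information of the
  profile log-likelihood; IVW fallback (with a warning) on optimizer
  failure.
* **Weighted median**: weighted 50th percentile of per-SNP Wald ratios with
  first-order inverse-variance weights and cumulative-weight interpolation;
  consistent when valid instruments carry at least half the weight. The SE
  is a seeded parametric bootstrap (default 1000 replicates; the seed is a
  required argument so results are reproducible).
* **MR-Egger**: weighted regression *with* intercept after orienting all
  exposure effects non-negative; the intercept estimates directional
  pleiotropy, the slope is the bias-adjusted effect. SEs use the same
  overdispersion floor; p-values use the t distribution on $k-2$ df
  (small-sample convention). IVW/Wald/ML p-values use the normal.
* **Leave-one-out**: IVW re-estimated omitting each SNP in turn.

Odds-ratio columns are $\exp(\beta)$ per unit exposure, matching how a
0/1-coded binary-outcome GWAS is conventionally reported; no liability-scale
conversion is attempted.

## Sensitivity suite

* **MR-PRESSO.** The observed residual sum of squares uses leave-one-out
  IVW predictions, so no SNP's own (possibly pleiotropic) effect enters its
  prediction. The null distribution comes from parametric resampling:
  exposure effects around their observed values, outcome effects around the
  leave-one-out predictions, both with observed SEs; the global empirical
  p-value uses the $+1$ correction, $p = (1 + \#\{RSS^* \ge RSS\})/(n_{sim}+1)$,
  so it is never zero and is bounded below by $1/(n_{sim}+1)$. Per-SNP
  squared residuals are compared to their own simulated distributions and
  Bonferroni-adjusted over SNPs; SNPs with adjusted $p < 0.05$ are outliers.
  The distortion test compares the estimate shift after removing the flagged
  set with shifts from removing random subsets of the same size. Defaults:
  1000 simulations, mandatory seed, identical inputs and seed give an
  identical result.
* **Steiger directionality.** Per-SNP variance explained
  $r_j^2 = t_j^2/(t_j^2 + n - 2)$ with $t_j = \beta_j/\mathrm{se}_j$, summed
  over instruments per trait (clipped below 1 with a warning); $z$ is the
  difference of Fisher-transformed $\sqrt{r^2}$ scaled by
  $\sqrt{1/(n_X-3) + 1/(n_Y-3)}$. $r^2_X > r^2_Y$ supports the assumed
  ("forward") direction. An exact tie is reported as forward with $p = 1$
  and an `inconclusive` flag.
* **Colocalization.** Wakefield approximate Bayes factors per SNP from
  (beta, se) with a normal effect prior (SD 0.15 for quantitative traits,
  0.2 for a binary outcome — the method's conventional defaults), combined
  over the five single-causal-variant configurations with priors
  $p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$; computed in log space with
  log-sum-exp for numerical stability. PP.H4 $> 0.8$ is the usual gate for
  a shared causal variant. We report the posterior vector and the gate; we
  do not encode any further interpretation of low PP.H4 values.

## Mediation decomposition

`mediate()` runs both decompositions from three summary-statistic tables:

1. **Two-step (product of coefficients).** Step 1 estimates $\theta_1$ with
   the exposure's instruments against the mediator; step 2 estimates
   $\theta_2$ with the *mediator's* instruments against the outcome. The two
   instrument sets are made disjoint: SNPs instrumenting the exposure are
   excluded from the mediator set, because they act on the mediator through
   the exposure and would otherwise bias step 2 (in the mediation diagram
   the two instrument sets are distinct). The indirect effect is
   $\hat\theta_1\hat\theta_2$ with the first-order delta-method SE
   $\sqrt{\hat\theta_2^2 s_1^2 + \hat\theta_1^2 s_2^2}$; the exact-variance
   extra term $s_1^2 s_2^2$ is available via `exact = TRUE` and is
   negligible at these precisions.
2. **MVMR (difference in coefficients).** A multivariable weighted
   regression (no intercept, weights $1/\sigma_Y^2$) of outcome effects on
   the exposure- and mediator-effect columns over the union of both
   instrument sets gives the *direct* exposure effect; the indirect effect
   is total minus direct with SE $\sqrt{s_{total}^2 + s_{direct}^2}$
   (conservative, ignoring the positive covariance). Overdispersion is
   handled as in univariable IVW with $df = k - p$. Conditional instrument
   strength per exposure is the mean squared standardized residual of that
   exposure's instrument effects after regressing them on the other
   exposures' effects — an operational conditional F. The pipeline warns
   (rather than excludes) below the conventional threshold of 10, since
   mediation analyses in this design have been accepted at conditional
   F just above 9.

**Total effect.** The total is the direct exposure-to-outcome IVW estimate
using the exposure's instruments (the "total causal effect" arrow of the
diagram), not a reconstruction $\hat\theta_3 + \hat\theta_1\hat\theta_2$.

**Proportion mediated.** $100 \cdot$ indirect/total when the two share a
sign. When signs disagree the ratio is not interpretable as a proportion and
`NA` is returned with reason `"inconsistent-sign"` — this rule is inferred
from how published mediation tables leave such cells empty, and it exactly
reproduces the worked-example table shipped in
`inst/extdata/mediation_worked_example.tsv`. Proportions above 100% (possible
through estimation noise) are flagged, not truncated.

**Multiple testing.** Benjamini–Hochberg adjustment (via `stats::p.adjust`)
is applied within each exposure family, mirroring per-panel adjustment in
forest-plot reports.

## The synthetic-data generator

`simulate_gwas()` draws summary statistics directly at the summary level:
true instrument effects propagate through the structural model and observed
effects add noise with analytic SEs
$\mathrm{se} = 1/\sqrt{2\,\mathrm{maf}(1-\mathrm{maf})\,n}$ — the standard
error of a per-allele regression coefficient for a standardized trait.
Choices and what they emulate:

* **Sample sizes** default to the motivating study design: exposure GWAS
  n = 8956 (microbiome cohorts), mediator GWAS n = 7824 (metabolites),
  outcome GWAS n = 463,010 (biobank-scale binary trait). Outcome effects
  live on a linear-probability scale with tiny magnitudes, which is why
  odds ratios in such studies print as 0.999–1.001.
* **Instrument strength** is parameterized by per-SNP variance explained
  (default $r^2 \in [0.002, 0.01]$ uniform, random sign), so per-SNP
  $F \approx n r^2$ regardless of allele frequency — at the default
  exposure n this gives F roughly 20–90, the range reported for microbial
  GWAS instruments.
* **Pleiotropy**: a configurable fraction of exposure instruments receives
  a direct outcome effect oriented to the exposure-raising allele, so a
  nonzero mean is *directional* pleiotropy in the frame MR-Egger works in.
* **Outcome-specific instruments** (`n_snp_outcome`) give reverse MR a
  well-posed instrument set.
* **LD** is a block-diagonal exchangeable-$r^2$ matrix consumed by
  clumping, with blocks laid out contiguously on chromosomes, so clumping
  has known correct answers (one SNP per block at default thresholds).

What the generator does **not** emulate: correlation between observed
per-SNP estimates induced by LD (effects are drawn independently; the LD
matrix is structural input for clumping only), sample overlap between the
two GWAS, population stratification, winner's-curse from discovery-stage
selection, and allele-frequency differences between studies. Passing tests
therefore demonstrate correctness of the estimators and the pipeline logic
under a well-specified summary-level model, not robustness to those
real-data pathologies.

## Numerical and design choices

* Coordinates are 1-based; positions are only used for clumping windows.
* MAF is computed as $\min(\mathrm{eaf}, 1-\mathrm{eaf})$; strand ambiguity
  beyond palindromes is assumed pre-resolved.
* Ties in clumping order break lexicographically; ties in Steiger
  ($z = 0$) report forward/inconclusive.
* The reverse-MR stage applies per-SNP Steiger filtering (keep SNPs
  explaining more variance in the trait being instrumented), because under
  forward causation the outcome's significant SNPs include the exposure's
  instruments, which would otherwise masquerade as reverse evidence.
* Empirical p-values (PRESSO) carry the $+1$ correction; posterior vectors
  (coloc) are renormalized after log-sum-exp so they sum to 1 within 1e-9.
* Heterogeneity gate in the screen: exposures with Cochran-Q $p < 0.05$
  that remain heterogeneous after PRESSO outlier removal are excluded from
  mediation; the threshold is configurable.
* BH is applied before the diagnostic gates; diagnostics annotate rather
  than reorder the significance decision (gate ordering is configurable by
  running the stages separately).

## Calibration results the test suite computes

Problem sizes were chosen so the full suite runs in about two minutes: 300
replicates for coverage-style checks, 2000 for the type-I-error check,
parametric-bootstrap and resampling defaults of 1000.

* Under the structural truth $\theta_1 = 0.4$, $\theta_2 = 0.5$,
  $\theta_3 = 0.1$ with 50 instruments per instrumented trait and all GWAS
  at n = 50,000, the product-of-coefficients indirect CI covers
  $\theta_1\theta_2 = 0.2$ in at least 93% of 300 replicates, and the
  product and difference decompositions agree in mean within the
  Monte-Carlo error of the simulated means. A note on that tolerance: the
  two estimates correlate at ~0.99 across replicates, so a paired bound
  would resolve a real but tiny (under 0.5% relative) differential
  regression dilution — first-order IVW ignores exposure-side noise, and
  each step attenuates by roughly $1/(1+1/\bar F)$. That difference is a
  property of the estimators themselves; the claim under test is agreement
  in expectation at Monte-Carlo precision, and the difference method's
  reported SE is structurally the larger of the two (it combines the total
  and direct uncertainties).
* The IVW test's type-I error at $\alpha = 0.05$ under a complete null lies
  within [0.035, 0.065] over 2000 replicates.
* A single SNP displaced by 10 outcome SEs among 21 is flagged by
  MR-PRESSO (uniquely, at Bonferroni-adjusted $p < 0.05$) and its removal
  reduces the estimation error.
* A region with one shared causal variant at $|z| = 16$ gives
  PP.H4 $> 0.8$; posterior vectors sum to 1 within 1e-9.

## Known limitations

* Single-causal-variant colocalization only; no multi-signal (SuSiE-style)
  extension.
* One mediator at a time; no joint multi-mediator decomposition.
* No mode-based or robust-regression estimators beyond the implemented set;
  no SIMEX or $I^2_{GX}$ weak-instrument correction for Egger.
* No VCF ingestion, genome-build liftover, or proxy-SNP lookup; summary
  tables are assumed to share a reference and build.
* The conditional F reported for MVMR is the operational residual-strength
  form described above, not the full covariance-adjusted statistic.
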