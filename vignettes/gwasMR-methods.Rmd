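---
title: "Methods and design of gwasMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of gwasMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwasMR)
```

# The model

Two-sample MR works on the summary-level generative model

$$\hat\beta_{Xj} \sim N(\gamma_j,\ se_{Xj}^2), \qquad
  \hat\beta_{Yj} \sim N(\Gamma_j,\ se_{Yj}^2), \qquad
  \Gamma_j = \beta\,\gamma_j + \alpha_j,$$

where $\gamma_j$ is the true effect of SNP $j$ on the exposure,
$\beta$ the causal effect of interest, and $\alpha_j$ a horizontal
pleiotropic effect ($\alpha_j = 0$ for a valid instrument). A SNP is a
valid instrument when it is (i) associated with the exposure, (ii)
independent of confounders, and (iii) affects the outcome only through
the exposure. Binary outcomes are handled on the log-odds scale
throughout, so $\exp(\beta)$ is an odds ratio; 95% intervals use the
normal quantile 1.96 on the log scale.

# Instrument selection

`selectInstruments` composes the five standard screening steps in
order, with every exclusion logged (one provenance row per dropped
SNP). All thresholds are strict inequalities. Choices that the
procedure leaves open, and how this package resolves them:

* **F statistic.** The per-SNP instrument strength is
  $F_j = (\hat\beta_{Xj}/se_{Xj})^2$, the squared z-score, which needs
  neither sample size nor trait-variance assumptions; the
  variance-explained form $(n-2)R^2/(1-R^2)$ with
  $R^2 = 2f(1-f)\hat\beta^2$ is exposed via
  `fStatistic(..., method = "r2")` for users with standardized traits.
  Per-analysis summaries report the minimum, mean and maximum across
  retained instruments, since conventions differ on which is quoted.
  Note that under the default thresholds the F screen is dominated by
  the significance screen: any SNP passing $P < 10^{-5}$ already has
  $F > 19.5$.
* **Missing LD.** Pairs inside the clumping window that are absent
  from the LD table are treated as $r^2 = 0$ with a warning, so an
  incomplete reference panel can never silently shrink the instrument
  set.
* **Palindromes.** A/T and C/G SNPs are excluded outright; no
  frequency-based strand inference is attempted.
* **Step-4 ordering and proxies.** Outcome-associated SNPs are removed
  first; proxy search then runs only for instruments absent from the
  outcome GWAS. A proxy (best candidate with $r^2$ strictly above 0.8;
  ties broken by base-pair distance, then rsID) replaces the
  instrument wholesale and must be present in both datasets — with
  summary-level data there is no phase information with which to
  translate alleles between two different SNPs, so using the proxy's
  own exposure and outcome rows is the only coherent option. The
  substitution is recorded in the provenance log.
* **Harmonization.** Effects are aligned to the exposure's effect
  allele: matching order passes through, swapped alleles negate the
  outcome effect and complement its allele frequency, incompatible
  allele sets are dropped. The operation is idempotent, and all
  estimators are invariant to allele re-coding of the input datasets
  (exercised by `scrambleAlleles`).

# Estimators

* **IVW.** Closed-form weighted least squares of
  $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$ with zero intercept and weights
  $se_{Yj}^{-2}$. The default is multiplicative random effects: the SE
  is the fixed-effect SE inflated by $\max(1, \sqrt{Q/(J-1)})$, which
  matches mainstream two-sample MR software defaults and never
  undercuts the fixed-effect SE. Both modes are exposed and the mode
  is recorded in the estimate's auxiliary slot. A single-SNP set
  reduces to the Wald ratio with delta-method SE.
* **MR-Egger.** WLS with a free intercept. The model is not invariant
  to per-SNP sign flips, so instruments are re-oriented to
  $\hat\beta_{Xj} \ge 0$ before fitting (logged in `aux`); the
  residual variance scale is floored at 1; p-values use $t_{J-2}$.
  With the intercept constrained to zero the machinery reproduces IVW
  exactly — a useful internal consistency check that the acceptance
  tests exercise.
* **Weighted median.** Ratio weights are first-order,
  $w_j = (\hat\beta_{Xj}/se_{Yj})^2$, normalized; the estimate
  interpolates the sorted ratios at the cumulative midpoint percentile
  0.5. The SE is a parametric bootstrap (default 1000 resamples) with
  a mandatory seed; the caller's RNG state is saved and restored.
* **Maximum likelihood.** The profile of the joint normal likelihood
  in $\gamma$ has the closed form
  $-\tfrac12\sum_j (\hat\beta_{Yj}-\beta\hat\beta_{Xj})^2 /
  (se_{Yj}^2+\beta^2 se_{Xj}^2)$; it is maximized by 1-D golden-section
  search on an interval centred at the IVW estimate, with the SE from
  the numerical curvature at the optimum. When exposure error is
  negligible this coincides with fixed-effect IVW.
* **RAPS.** Solves $\sum_j \psi(t_j)\,\partial t_j/\partial\beta = 0$
  with standardized residuals
  $t_j = (\hat\beta_{Yj}-\beta\hat\beta_{Xj}) /
  \sqrt{se_{Yj}^2+\beta^2 se_{Xj}^2+\tau^2}$, $\psi$ the derivative of
  the loss (default Huber, $c = 1.345$). With overdispersion on
  (default), $\tau^2 \ge 0$ solves
  $\sum_j (\psi(t_j)t_j - \delta)/\sigma_j^2 = 0$ with the consistency
  constant $\delta = E[\psi(Z)Z] = 2\Phi(c)-1$; $\tau^2$ is pinned at 0
  (and flagged) when the data are underdispersed. Both equations are
  solved by alternating bracketed root finding from the IVW start;
  non-convergence after 100 sweeps is an error carrying diagnostics.
  The SE is the sandwich estimate.

`mrAll` runs the five in a fixed order and represents methods whose
preconditions fail (fewer than three instruments for Egger, weighted
median and RAPS) as explicit skipped estimates, never silent
omissions.

# Sensitivity diagnostics

Cochran's $Q = \sum_j w_j(\hat\theta_j - \hat\beta)^2$ with
$w_j = \hat\beta_{Xj}^2/se_{Yj}^2$ is referred to $\chi^2_{J-1}$ (an
Egger variant uses intercept-adjusted residuals on $J-2$ df). The
Egger intercept test flags directional pleiotropy at $p < 0.05$.

MR-PRESSO compares the observed weighted residual sum of squares
around leave-one-out IVW fits with its parametric-bootstrap null
distribution; p-values use add-one smoothing,
$p = (1+\#\{RSS^* \ge RSS\})/(n_{sim}+1)$, so they are never zero and
are exactly reproducible given (set, `nSim`, seed). Residuals are
inverse-variance weighted by default (matching the estimators'
variance model); the unweighted original is a flag. Outliers are
declared per SNP at the Bonferroni level $\alpha/J$. The downstream
distortion test is out of scope. Default `nSim = 1000`.

Leave-one-out re-estimates IVW $J$ times. A SNP is flagged influential
when its removal moves the estimate outside the full-set 95% interval;
the *fixed-effect* interval is used as the reference band, because a
gross outlier inflates the random-effects interval of the full set and
would otherwise mask its own influence.

# Multiple testing and classification

`qvalueStorey` implements the q-value procedure: $\hat\pi_0$ from the
smoother (natural cubic smoothing spline, df 3, over
$\lambda = 0.05, \dots, 0.95$, evaluated at the largest $\lambda$ and
clamped to $(0,1]$), then the step-up construction
$q_{(i)} = \min_{j \ge i} \hat\pi_0\, m\, p_{(j)}/j$. With $\hat\pi_0$
forced to 1 this is exactly Benjamini–Hochberg, which the tests assert
against `p.adjust`. Below 12 p-values the smoother is unstable, so
$\hat\pi_0$ is fixed at 1 with a warning. Labels follow the decision
rule: significant when $q < 0.1$; suggestive when $p < 0.05$ but
$q \ge 0.1$; none otherwise.

In `runPipeline`, q-value families are formed per outcome across
exposures within a direction — the natural family when a panel of
exposures (e.g. 119 genera) is screened against each outcome. The
family definition is recorded in the run metadata. Reverse analyses
default to a genome-wide exposure threshold (5e-8), appropriate for
well-powered disease GWAS; the forward locus-wide threshold is a flag
away. Method concordance is counted as the number of computed methods
with nominal $p < 0.05$ and direction agreeing with IVW, with the
denominator reported alongside.

In multivariable MR, instruments are the union of the per-exposure
locus-wide hits, jointly clumped by the minimum p-value across
exposures (a convention; recorded in metadata), harmonized everywhere,
and fitted by zero-intercept WLS on the $K$ exposure columns with
overdispersion scale floored at 1. Rank-deficient designs raise a
collinearity error naming the offending columns; an all-zero exposure
column is dropped (its estimate reported as skipped) so the remaining
coefficients equal the fit without it.

# The synthetic-data generator

`simulateSummaryStats` draws directly from the summary-level model
above: effects come with analytic standard errors
$se = (2f(1-f)n)^{-1/2}$ and observed values are truth plus normal
noise. The defaults emulate the scale of a genus-level microbiome
exposure GWAS ($n = 18{,}340$) against a case-control
pregnancy-outcome GWAS (7,686 cases / 115,893 controls; the outcome SE
uses the effective sample size $4/(1/n_{case}+1/n_{ctrl})$).
Instrument effects are positive half-normal
(`gammaScale` = 0.15) with the true $F$ confined by rejection to
[140, 245], the instrument-strength window reported for
selection-screened microbiome instruments; positivity fixes the
orientation convention under which the Egger intercept estimates mean
directional pleiotropy. Each locus carries LD satellites
($r^2 = 0.95$, entered into the emitted LD table) so clumping does
real work, plus null decoys for the significance filter; satellite
draws are rejection-sampled below their index SNP's observed z-score
so clump outcomes are deterministic, which exact bookkeeping tests
rely on. Fate injections (low MAF, palindromic, outcome-associated,
weak-F, missing-with-proxy, missing-without-proxy) create SNPs whose
selection fate is known a priori. Loci sit 15 Mb apart across 22
chromosomes, so 10 Mb clumping windows never straddle two loci.

What the generator deliberately does **not** emulate: genotype-level
sampling (effects are drawn, not computed from genotypes), realistic
LD beyond block-diagonal satellite structure, correlated noise between
SNPs sharing a block, sample overlap between the two GWAS, allele
frequency differences between datasets, and microbiome abundance
distributions (only their GWAS summary layer). Passing tests therefore
demonstrate correctness of the statistical machinery under the stated
model, not robustness to those real-data complications.

# Numerical choices

Two-sided normal p-values are floored at 1e-300 to stay inside
$(0,1]$. Results tables are serialized with `%.17g` so write-then-read
is exact. Weighted-median interpolation uses ordered ties; proxy ties
break by distance then rsID; clumping sorts by p-value with radix
order (stable and locale-independent). Sub-seeds for the pipeline's
per-analysis bootstraps and PRESSO simulations derive deterministically
from the master seed, and all seeded code paths restore the caller's
RNG state.

# Verification studies and their sizes

The acceptance suite runs: oracle equivalences (IVW vs normal
equations at 1e-10; weighted median vs brute-force percentile at
1e-12; zero-intercept Egger = IVW exactly); parameter recovery and
coverage at $J = 100$, $\beta = 0.25$, 500 replicates; type-I error
through the full selection pipeline at $\beta = 0$, 2000 replicates;
directional-pleiotropy behaviour (30% invalid instruments,
$\mu_\alpha = 0.05$) over 200 replicates; MR-PRESSO detection of a
10-SE outlier and null calibration over 200 replicates at
`nSim = 1000`; and exact selection bookkeeping on a universe with
injected fates. These sizes keep each study's Monte-Carlo error well
below the property being asserted.

# Known limitations

* The weighted median retains a finite bias under one-sided
  (directional) pleiotropy: with fraction $\rho$ of the weight
  displaced to one side, the estimate sits near the
  $0.5/(1-\rho)$ weighted quantile of the valid-ratio cluster, i.e. a
  bias of order that quantile's z-score times the per-SNP ratio SE. At
  the default study scale (instrument $F$ in the 140–245 window, 30%
  invalid weight) the acceptance study measures this at about +0.03 —
  smaller than the IVW bias in the same scenario but not negligible.
* MR-Egger is imprecise when instrument effects are homogeneous in
  magnitude (weak regression leverage), visible in its wide intervals.
* Proxy substitution cannot recover an instrument whose proxy is
  missing from either dataset; such SNPs are dropped with reason.
* The MR-PRESSO distortion test, mode-based estimators, Steiger
  filtering and genotype-level simulation are out of scope.
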