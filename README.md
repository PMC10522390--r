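# gwasMR

Bidirectional multivariable two-sample Mendelian randomization (MR)
from GWAS summary statistics, in Bioconductor-style S4.

## The problem

Observational associations between an exposure (for example, the
abundance of a gut microbial genus) and a disease outcome (for example,
hypertensive disorders in pregnancy) are confounded and subject to
reverse causation. Two-sample MR sidesteps both by using genetic
variants as instrumental variables: SNP–exposure effects
(β̂<sub>Xj</sub>, se<sub>Xj</sub>) come from one GWAS, SNP–outcome
effects (β̂<sub>Yj</sub>, se<sub>Yj</sub>) from another, and a causal
effect β is inferred from the per-SNP Wald ratios
θ̂<sub>j</sub> = β̂<sub>Yj</sub>/β̂<sub>Xj</sub>. Because instrument
validity is untestable SNP by SNP, credible MR reports several
estimators with different failure modes, plus diagnostics for
heterogeneity and horizontal pleiotropy. `gwasMR` implements that full
workflow for analysts working with summary-level GWAS data.

## What the package computes

**Instrument selection** (`selectInstruments`), the standard five-step
screen with a complete per-SNP provenance log:

1. exposure significance *P* < 1e-5 (locus-wide, for under-powered
   exposures such as genus-level microbiome GWAS);
2. greedy LD clumping, *r*² < 0.001 within 10,000 kb;
3. exclusion of SNPs with MAF < 0.01 and of all palindromic (A/T, C/G)
   SNPs;
4. removal of SNPs associated with the outcome (*P* < 5e-8), with proxy
   substitution (*r*² > 0.8) for instruments absent from the outcome
   GWAS;
5. exclusion of weak instruments, F = (β̂/se)² < 10;

followed by allele harmonization of every exposure/outcome pair to a
common effect allele.

**Five estimators** (`mrAll`, or individually):

- `mrIVW` — inverse-variance weighted:
  β̂ = Σ β̂<sub>Xj</sub>β̂<sub>Yj</sub>se<sub>Yj</sub>⁻² / Σ β̂<sub>Xj</sub>²se<sub>Yj</sub>⁻²,
  fixed-effect or multiplicative random-effects (default; SE never
  below the fixed-effect SE);
- `mrMaxLik` — profile maximum likelihood of the joint normal model;
- `mrWeightedMedian` — weighted-percentile median of the Wald ratios,
  consistent when valid instruments carry ≥ 50% of the weight;
  parametric-bootstrap SE;
- `mrEgger` — WLS with free intercept; the intercept estimates mean
  directional pleiotropy, the slope is consistent under InSiDE;
- `mrRAPS` — robust adjusted profile score with Huber loss and
  overdispersion τ².

**Sensitivity diagnostics** (`runSensitivity`): Cochran's Q,
MR-Egger intercept test, MR-PRESSO global and outlier tests
(simulation-based residual sums of squares), leave-one-out.

**Reverse and multivariable MR**: `runPipeline` swaps exposure and
outcome roles to check causal direction, and `selectMvInstruments` +
`mvmrIVW` estimate direct effects conditional on confounder GWAS (BMI,
smoking, and the like). Multiple testing uses Storey q-values
(`qvalueStorey`): *q* < 0.1 is significant; *P* < 0.05 with *q* ≥ 0.1
is suggestive.

**Synthetic data** (`simulateSummaryStats`, `simulateMv`,
`scrambleAlleles`): a summary-level generator with known ground truth —
configurable causal effect, instrument strength, balanced/directional
pleiotropy, LD satellites, decoy SNPs, allele-coding noise and
selection-fate injections — so that every stage of the pipeline is
verifiable without downloading any real GWAS.

## Worked example

```r
library(gwasMR)

## a synthetic universe: 40 instrument loci with true effect 0.25,
## LD satellites and null decoys included
tr  <- SimulationTruth(betaTrue = 0.25, J = 40, seed = 7)
sim <- simulateSummaryStats(tr)

set <- selectInstruments(sim$exposure, sim$outcome, sim$ld)
set
#> InstrumentSet: sim_exposure -> sim_outcome
#>   35 harmonized instruments; 285 SNPs dropped during selection
#>   F statistics: 119.72-283.83 (mean 198.80)

ests <- mrAll(set, seed = 42)
ests$ivw
#> MREstimate [ivw]: beta=0.2449 se=0.0096 OR=1.278 (95% CI 1.254-1.302)
#>   p=1.05e-144 (35 SNPs)
ests$egger
#> MREstimate [egger]: beta=0.2009 se=0.0496 OR=1.223 (95% CI 1.109-1.347)
#>   p=0.000288 (35 SNPs)

runSensitivity(set, nSim = 1000, seed = 42)
#> SensitivityReport
#>   Cochran's Q = 17.376 (df 34), p = 0.992
#>   Egger intercept = 0.0079 (se 0.0088), p = 0.372
#>   MR-PRESSO global p = 0.992; 0 outlier(s)
#>   Leave-one-out: 35 re-estimates, 0 influential
```

Reading the output: 35 of 40 simulated instruments survive selection
(satellites are clumped away; a few strong SNPs trip the
outcome-association screen). All five estimators bracket the true
log-odds effect 0.25 (OR ≈ 1.28 per unit exposure); Q and the PRESSO
global test find no heterogeneity, the Egger intercept is consistent
with no directional pleiotropy, and no single SNP drives the result.
`methodConcordance(ests)` reports 5/5 methods nominally significant in
the IVW direction.

Full tables are written with `writeResultsTable()` (TSV, exact
round-trip) and `writeSensitivityJSON()`; `runPipeline()` orchestrates
whole exposure × outcome grids bidirectionally with q-values and
classification labels.

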