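#' @import methods
NULL

## Standard internal column names for summary statistics. Mandatory fields
## must be present in every GwasDataset; optional ones may be NA.
.MANDATORY_COLS <- c("snp_id", "effect_allele", "other_allele",
                     "beta", "se", "pval")
.OPTIONAL_COLS <- c("chrom", "pos", "eaf", "n")
.STANDARD_COLS <- c("snp_id", "chrom", "pos", "effect_allele",
                    "other_allele", "eaf", "beta", "se", "pval", "n")

.isSingleBase <- function(x) {
  !is.na(x) & nchar(x) == 1L & x %in% c("A", "C", "G", "T")
}

.isPalindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' GwasDataset: validated GWAS summary statistics for one trait
#'
#' Container for per-SNP association statistics of a single trait together
#' with trait metadata. One row per SNP with the standard fields
#' \code{snp_id}, \code{chrom}, \code{pos}, \code{effect_allele},
#' \code{other_allele}, \code{eaf}, \code{beta}, \code{se}, \code{pval},
#' \code{n}. Effects on binary traits are log-odds per effect allele.
#' Positions are 1-based; strand is not modelled (it is resolved by allele
#' comparison during harmonization).
#'
#' @slot stats data.frame of validated per-SNP records.
#' @slot traitId character trait identifier.
#' @slot traitType "continuous" or "binary".
#' @slot nCase,nControl case/control counts for binary traits (NA otherwise).
#' @slot label free-text trait label.
#' @slot rejections data.frame (snp_id, reason) of input rows rejected
#'   during validation.
#'
#' @export
setClass("GwasDataset",
  slots = c(stats = "data.frame",
            traitId = "character",
            traitType = "character",
            nCase = "numeric",
            nControl = "numeric",
            label = "character",
            rejections = "data.frame"),
  prototype = prototype(traitType = "continuous", nCase = NA_real_,
                        nControl = NA_real_, label = "",
                        rejections = data.frame(snp_id = character(),
                                                reason = character())))

setValidity("GwasDataset", function(object) {
  st <- object@stats
  msgs <- character()
  missing <- setdiff(.MANDATORY_COLS, names(st))
  if (length(missing))
    return(paste("missing mandatory columns:", paste(missing, collapse = ", ")))
  if (nrow(st)) {
    if (any(!is.finite(st$se) | st$se <= 0))
      msgs <- c(msgs, "all se must be > 0")
    if (any(!is.finite(st$pval) | st$pval <= 0 | st$pval > 1))
      msgs <- c(msgs, "all pval must lie in (0, 1]")
    if (any(!.isSingleBase(st$effect_allele)) ||
        any(!.isSingleBase(st$other_allele)))
      msgs <- c(msgs, "alleles must be single bases from {A,C,G,T}")
    if (any(st$effect_allele == st$other_allele))
      msgs <- c(msgs, "effect and other allele must differ")
    if ("eaf" %in% names(st)) {
      bad <- !is.na(st$eaf) & (st$eaf < 0 | st$eaf > 1)
      if (any(bad)) msgs <- c(msgs, "eaf must lie in [0, 1] when present")
    }
    if (anyDuplicated(st$snp_id))
      msgs <- c(msgs, "duplicated snp_id")
  }
  if (!object@traitType %in% c("continuous", "binary"))
    msgs <- c(msgs, "traitType must be 'continuous' or 'binary'")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a GwasDataset from a data.frame
#'
#' Rows violating the record invariants (non-positive SE, p-value outside
#' (0,1], multi-character or identical alleles, allele frequency outside
#' [0,1]) are removed and logged in the \code{rejections} slot with a
#' machine-readable reason; alleles are upper-cased. Missing optional
#' columns (\code{chrom}, \code{pos}, \code{eaf}, \code{n}) are filled
#' with NA.
#'
#' @param stats data.frame with at least the mandatory columns
#'   \code{snp_id}, \code{effect_allele}, \code{other_allele}, \code{beta},
#'   \code{se}, \code{pval}.
#' @param traitId trait identifier string.
#' @param traitType "continuous" or "binary".
#' @param nCase,nControl optional case/control counts (binary traits).
#' @param label free-text label; defaults to \code{traitId}.
#' @return A \linkS4class{GwasDataset}.
#' @export
GwasDataset <- function(stats, traitId, traitType = "continuous",
                        nCase = NA_real_, nControl = NA_real_,
                        label = traitId) {
  stopifnot(is.data.frame(stats))
  missing <- setdiff(.MANDATORY_COLS, names(stats))
  if (length(missing))
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  for (col in .OPTIONAL_COLS)
    if (!col %in% names(stats)) stats[[col]] <- NA_real_
  stats$snp_id <- as.character(stats$snp_id)
  stats$chrom <- as.character(stats$chrom)
  stats$effect_allele <- toupper(as.character(stats$effect_allele))
  stats$other_allele <- toupper(as.character(stats$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n"))
    stats[[col]] <- as.numeric(stats[[col]])
  stats <- stats[, .STANDARD_COLS]

  reason <- rep(NA_character_, nrow(stats))
  mark <- function(bad, why) ifelse(is.na(reason) & bad, why, reason)
  reason <- mark(nchar(stats$effect_allele) != 1L |
                 nchar(stats$other_allele) != 1L, "multi-allelic")
  reason <- mark(!.isSingleBase(stats$effect_allele) |
                 !.isSingleBase(stats$other_allele), "invalid allele")
  reason <- mark(stats$effect_allele == stats$other_allele,
                 "identical alleles")
  reason <- mark(!is.finite(stats$beta), "missing beta")
  reason <- mark(!is.finite(stats$se) | stats$se <= 0, "non-positive se")
  reason <- mark(!is.finite(stats$pval) | stats$pval <= 0 | stats$pval > 1,
                 "invalid pval")
  reason <- mark(!is.na(stats$eaf) & (stats$eaf < 0 | stats$eaf > 1),
                 "invalid eaf")
  reason <- mark(duplicated(stats$snp_id), "duplicated snp_id")

  bad <- !is.na(reason)
  rejections <- data.frame(snp_id = stats$snp_id[bad],
                           reason = reason[bad],
                           stringsAsFactors = FALSE)
  stats <- stats[!bad, , drop = FALSE]
  rownames(stats) <- NULL
  if (nrow(stats) == 0L)
    stop("zero valid rows for trait '", traitId, "'")
  new("GwasDataset", stats = stats, traitId = traitId,
      traitType = traitType, nCase = as.numeric(nCase),
      nControl = as.numeric(nControl), label = label,
      rejections = rejections)
}

#' SelectionConfig: thresholds of the five-step instrument selection
#'
#' Defaults follow the standard microbiome-MR workflow: locus-wide
#' exposure significance P < 1e-5, PLINK-style clumping at r^2 < 0.001 in
#' a 10,000 kb window, minor-allele frequency >= 0.01 with palindromic
#' SNPs excluded, removal of instruments associated with the outcome at
#' genome-wide significance (P < 5e-8) with proxy substitution at
#' r^2 > 0.8, and exclusion of weak instruments with F < 10. All
#' comparisons use strict inequalities.
#'
#' @slot pThreshold exposure significance cutoff.
#' @slot clumpR2 LD r-squared cutoff for clumping.
#' @slot clumpKb clumping window in kilobases.
#' @slot mafMin minimum minor-allele frequency.
#' @slot proxyR2 minimum LD r-squared for a proxy SNP.
#' @slot outcomeP outcome-association exclusion cutoff.
#' @slot fMin minimum per-SNP F statistic.
#' @export
setClass("SelectionConfig",
  slots = c(pThreshold = "numeric", clumpR2 = "numeric", clumpKb = "numeric",
            mafMin = "numeric", proxyR2 = "numeric", outcomeP = "numeric",
            fMin = "numeric"),
  prototype = prototype(pThreshold = 1e-05, clumpR2 = 0.001, clumpKb = 10000,
                        mafMin = 0.01, proxyR2 = 0.8, outcomeP = 5e-08,
                        fMin = 10))

setValidity("SelectionConfig", function(object) {
  ok1 <- object@pThreshold > 0 && object@pThreshold < 1
  ok2 <- object@clumpR2 >= 0 && object@clumpR2 <= 1
  ok3 <- object@clumpKb > 0
  ok4 <- object@mafMin >= 0 && object@mafMin < 0.5
  ok5 <- object@proxyR2 >= 0 && object@proxyR2 <= 1
  ok6 <- object@outcomeP > 0 && object@outcomeP < 1
  ok7 <- object@fMin >= 0
  if (ok1 && ok2 && ok3 && ok4 && ok5 && ok6 && ok7) TRUE
  else "selection thresholds outside valid ranges"
})

#' @param pThreshold,clumpR2,clumpKb,mafMin,proxyR2,outcomeP,fMin see slots.
#' @return A \linkS4class{SelectionConfig}.
#' @rdname SelectionConfig-class
#' @export
SelectionConfig <- function(pThreshold = 1e-05, clumpR2 = 0.001,
                            clumpKb = 10000, mafMin = 0.01, proxyR2 = 0.8,
                            outcomeP = 5e-08, fMin = 10) {
  new("SelectionConfig", pThreshold = pThreshold, clumpR2 = clumpR2,
      clumpKb = clumpKb, mafMin = mafMin, proxyR2 = proxyR2,
      outcomeP = outcomeP, fMin = fMin)
}

#' LDSource: pairwise linkage-disequilibrium lookup
#'
#' Symmetric r-squared lookup between SNP pairs, typically loaded from a
#' pairwise LD table (columns SNP_A, SNP_B, R2) computed on a reference
#' panel. Self pairs have r^2 = 1; absent pairs are unknown (consumers
#' decide how to treat them; clumping treats them as 0 with a warning).
#'
#' @slot r2 named numeric; names are canonical "a|b" keys with a < b.
#' @slot pos named numeric of per-SNP base-pair positions (optional).
#' @slot panel character label of the reference panel.
#' @export
setClass("LDSource",
  slots = c(r2 = "numeric", pos = "numeric", panel = "character"),
  prototype = prototype(r2 = structure(numeric(0), names = character(0)),
                        pos = structure(numeric(0), names = character(0)),
                        panel = "unspecified"))

setValidity("LDSource", function(object) {
  if (length(object@r2) &&
      (any(object@r2 < 0) || any(object@r2 > 1)))
    return("r2 values must lie in [0, 1]")
  TRUE
})

.ldKey <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' @param table data.frame with columns SNP_A, SNP_B, R2 (extra columns
#'   ignored; a BP_A/BP_B pair, if present, populates positions).
#' @param pos optional named numeric of SNP positions.
#' @param panel reference-panel label.
#' @return An \linkS4class{LDSource}.
#' @rdname LDSource-class
#' @export
LDSource <- function(table = NULL, pos = NULL, panel = "unspecified") {
  r2 <- structure(numeric(0), names = character(0))
  pvec <- structure(numeric(0), names = character(0))
  if (!is.null(table) && nrow(table)) {
    need <- c("SNP_A", "SNP_B", "R2")
    if (!all(need %in% names(table)))
      stop("LD table needs columns SNP_A, SNP_B, R2")
    a <- as.character(table$SNP_A); b <- as.character(table$SNP_B)
    r2 <- as.numeric(table$R2)
    names(r2) <- .ldKey(a, b)
    r2 <- r2[!duplicated(names(r2))]
    if (all(c("BP_A", "BP_B") %in% names(table))) {
      pvec <- c(structure(as.numeric(table$BP_A), names = a),
                structure(as.numeric(table$BP_B), names = b))
      pvec <- pvec[!duplicated(names(pvec))]
    }
  }
  if (!is.null(pos)) {
    pvec <- c(structure(as.numeric(pos), names = names(pos)),
              pvec)
    pvec <- pvec[!duplicated(names(pvec))]
  }
  new("LDSource", r2 = r2, pos = pvec, panel = panel)
}

#' Look up pairwise r-squared values
#'
#' Vectorized symmetric lookup. Self pairs return 1; pairs absent from the
#' source return NA.
#'
#' @param ld an \linkS4class{LDSource}.
#' @param a,b character vectors of SNP ids (recycled to common length).
#' @return numeric vector of r-squared values (NA when unknown).
#' @export
ldR2 <- function(ld, a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n); b <- rep_len(as.character(b), n)
  out <- unname(ld@r2[.ldKey(a, b)])
  out[a == b] <- 1
  out
}

#' InstrumentSet: harmonized instruments for one exposure-outcome analysis
#'
#' Per-SNP exposure and outcome effects aligned to a common effect allele,
#' with instrument-strength F statistics and a provenance log recording
#' every SNP dropped during selection (one row per dropped SNP: step and
#' reason).
#'
#' @slot exposureId,outcomeId trait identifiers.
#' @slot snps data.frame with columns snp_id, chrom, pos, effect_allele,
#'   other_allele, eaf, beta_exp, se_exp, beta_out, se_out, f_stat,
#'   orientation ("same" or "flip").
#' @slot provenance data.frame (snp_id, step, reason) of dropped SNPs.
#' @export
setClass("InstrumentSet",
  slots = c(exposureId = "character", outcomeId = "character",
            snps = "data.frame", provenance = "data.frame"),
  prototype = prototype(
    provenance = data.frame(snp_id = character(), step = character(),
                            reason = character())))

setValidity("InstrumentSet", function(object) {
  sn <- object@snps
  need <- c("snp_id", "beta_exp", "se_exp", "beta_out", "se_out", "f_stat")
  missing <- setdiff(need, names(sn))
  if (length(missing))
    return(paste("snps lacks columns:", paste(missing, collapse = ", ")))
  msgs <- character()
  if (nrow(sn)) {
    if (any(sn$se_exp <= 0) || any(sn$se_out <= 0))
      msgs <- c(msgs, "standard errors must be > 0")
    if (anyDuplicated(sn$snp_id))
      msgs <- c(msgs, "duplicated snp_id")
    if (all(c("effect_allele", "other_allele") %in% names(sn)) &&
        any(.isPalindromic(sn$effect_allele, sn$other_allele)))
      msgs <- c(msgs, "palindromic SNPs are not allowed in an InstrumentSet")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

## Internal quick constructor used by selection and tests.
.InstrumentSet <- function(snps, exposureId = "exposure",
                           outcomeId = "outcome",
                           provenance = NULL) {
  if (is.null(provenance))
    provenance <- data.frame(snp_id = character(), step = character(),
                             reason = character())
  rownames(snps) <- NULL
  new("InstrumentSet", exposureId = exposureId, outcomeId = outcomeId,
      snps = snps, provenance = provenance)
}

#' Build an InstrumentSet directly from effect vectors
#'
#' Convenience constructor for already-harmonized per-SNP effects, mainly
#' used in simulations and examples. F statistics are computed as
#' (beta_exp / se_exp)^2.
#'
#' @param betaExp,seExp SNP-exposure effects and standard errors.
#' @param betaOut,seOut SNP-outcome effects and standard errors.
#' @param snpId SNP identifiers (default "snp1".."snpJ").
#' @param exposureId,outcomeId trait labels.
#' @param eaf optional effect-allele frequencies.
#' @return An \linkS4class{InstrumentSet}.
#' @export
makeInstrumentSet <- function(betaExp, seExp, betaOut, seOut,
                              snpId = paste0("snp", seq_along(betaExp)),
                              exposureId = "exposure",
                              outcomeId = "outcome", eaf = NA_real_) {
  snps <- data.frame(snp_id = snpId, chrom = NA_character_, pos = NA_real_,
                     effect_allele = "A", other_allele = "G",
                     eaf = eaf, beta_exp = betaExp, se_exp = seExp,
                     beta_out = betaOut, se_out = seOut,
                     f_stat = (betaExp / seExp)^2, orientation = "same",
                     stringsAsFactors = FALSE)
  .InstrumentSet(snps, exposureId, outcomeId)
}

#' MREstimate: one method's causal estimate
#'
#' Causal effect on the log-odds scale with normal-theory 95% confidence
#' interval on the odds-ratio scale and method-specific auxiliary results
#' (e.g. the Egger intercept, RAPS overdispersion, IVW heterogeneity Q).
#' A method skipped because its preconditions failed is represented with
#' NA numeric slots and \code{aux$skipped} giving the reason.
#'
#' @slot method one of "wald", "ivw", "egger", "weighted_median",
#'   "max_lik", "raps".
#' @slot beta,se causal log-odds estimate and its standard error.
#' @slot orValue exp(beta).
#' @slot ciLow,ciHigh 95% CI on the OR scale (1.96-normal on log scale).
#' @slot pval two-sided p-value.
#' @slot nSnp number of instruments used.
#' @slot aux list of method-specific terms.
#' @export
setClass("MREstimate",
  slots = c(method = "character", beta = "numeric", se = "numeric",
            orValue = "numeric", ciLow = "numeric", ciHigh = "numeric",
            pval = "numeric", nSnp = "integer", aux = "list"),
  prototype = prototype(aux = list()))

setValidity("MREstimate", function(object) {
  if (!is.finite(object@beta)) return(TRUE)  # skipped estimate
  msgs <- character()
  if (abs(object@orValue - exp(object@beta)) >
      1e-8 * max(1, exp(object@beta)))
    msgs <- c(msgs, "orValue must equal exp(beta)")
  if (is.finite(object@se) &&
      !(object@ciLow <= object@orValue && object@orValue <= object@ciHigh))
    msgs <- c(msgs, "CI must bracket the OR")
  if (is.finite(object@pval) && (object@pval <= 0 || object@pval > 1))
    msgs <- c(msgs, "pval must lie in (0, 1]")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

## Internal constructor computing OR/CI from (beta, se).
.MREstimate <- function(method, beta, se, pval, nSnp, aux = list()) {
  new("MREstimate", method = method, beta = beta, se = se,
      orValue = exp(beta), ciLow = exp(beta - 1.96 * se),
      ciHigh = exp(beta + 1.96 * se), pval = pval,
      nSnp = as.integer(nSnp), aux = aux)
}

.skippedEstimate <- function(method, reason) {
  new("MREstimate", method = method, beta = NA_real_, se = NA_real_,
      orValue = NA_real_, ciLow = NA_real_, ciHigh = NA_real_,
      pval = NA_real_, nSnp = 0L, aux = list(skipped = reason))
}

#' SensitivityReport: heterogeneity and pleiotropy diagnostics
#'
#' @slot qIvw,qDf,qPval Cochran's Q against the IVW slope, its degrees of
#'   freedom (J-1) and upper-tail chi-square p-value.
#' @slot eggerIntercept named numeric (estimate, se, pval) of the MR-Egger
#'   intercept test.
#' @slot pressoGlobalP MR-PRESSO global test p-value.
#' @slot pressoOutliers data.frame (snp_id, pval) of detected outliers.
#' @slot loo data.frame of leave-one-out IVW estimates with an
#'   \code{influential} flag.
#' @slot meta list of seeds and simulation counts used.
#' @export
setClass("SensitivityReport",
  slots = c(qIvw = "numeric", qDf = "numeric", qPval = "numeric",
            eggerIntercept = "numeric", pressoGlobalP = "numeric",
            pressoOutliers = "data.frame", loo = "data.frame",
            meta = "list"),
  prototype = prototype(meta = list()))

setValidity("SensitivityReport", function(object) {
  msgs <- character()
  if (is.finite(object@qIvw) && object@qIvw < 0)
    msgs <- c(msgs, "Q must be non-negative")
  if (is.finite(object@pressoGlobalP) &&
      (object@pressoGlobalP <= 0 || object@pressoGlobalP > 1))
    msgs <- c(msgs, "PRESSO global p must lie in (0, 1]")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' MvInstrumentMatrix: instruments for multivariable MR
#'
#' Joint instrument matrix for K >= 2 exposures against one outcome. All
#' rows are harmonized to a common effect allele (that of the first
#' exposure dataset).
#'
#' @slot outcomeId outcome trait id.
#' @slot exposureIds character vector of K exposure ids.
#' @slot snpId character vector of J instrument ids.
#' @slot betaExp,seExp J x K matrices of exposure effects and SEs.
#' @slot betaOut,seOut outcome effects and SEs.
#' @slot provenance data.frame (snp_id, step, reason) of dropped SNPs.
#' @export
setClass("MvInstrumentMatrix",
  slots = c(outcomeId = "character", exposureIds = "character",
            snpId = "character", betaExp = "matrix", seExp = "matrix",
            betaOut = "numeric", seOut = "numeric",
            provenance = "data.frame"),
  prototype = prototype(
    provenance = data.frame(snp_id = character(), step = character(),
                            reason = character())))

setValidity("MvInstrumentMatrix", function(object) {
  J <- length(object@snpId); K <- length(object@exposureIds)
  msgs <- character()
  if (!all(dim(object@betaExp) == c(J, K)) ||
      !all(dim(object@seExp) == c(J, K)))
    msgs <- c(msgs, "betaExp/seExp must be J x K")
  if (length(object@betaOut) != J || length(object@seOut) != J)
    msgs <- c(msgs, "betaOut/seOut must have length J")
  if (anyDuplicated(object@snpId))
    msgs <- c(msgs, "duplicated snp_id")
  if (J && J <= K)
    msgs <- c(msgs, "need more instruments than exposures (J > K)")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' SimulationTruth: generative parameters for synthetic GWAS data
#'
#' Parameters of the standard two-sample MR generative model. Defaults
#' emulate the study scale of a genus-level microbiome GWAS (n = 18,340)
#' against a binary pregnancy-outcome GWAS (7,686 cases / 115,893
#' controls): instrument effects are drawn on the allelic scale with
#' analytic standard errors from allele frequency and sample size, and a
#' fraction of instruments may carry horizontal-pleiotropy effects drawn
#' from N(muAlpha, sigmaAlpha^2).
#'
#' @slot betaTrue true causal effect (log-odds outcome per unit exposure).
#' @slot J number of instrument loci.
#' @slot mafRange range of effect-allele frequencies (uniform draw).
#' @slot nExp exposure GWAS sample size.
#' @slot nCase,nControl outcome case/control counts (effective sample size
#'   4/(1/nCase + 1/nControl)); set \code{nOut} instead for a continuous
#'   outcome.
#' @slot nOut continuous-outcome sample size (NA when case/control given).
#' @slot propInvalid fraction of pleiotropic (invalid) instruments.
#' @slot muAlpha,sigmaAlpha mean and SD of pleiotropic effects
#'   (directional when muAlpha != 0, balanced when muAlpha = 0).
#' @slot gammaScale scale of true SNP-exposure effects (half-normal).
#' @slot fFloor,fCeil bounds on the true instrument F, enforced by
#'   rejection. The defaults (140, 245) reproduce the instrument
#'   strength reported for genus-level microbiome instruments passing
#'   the selection pipeline (per-analysis F statistics of roughly
#'   140-240) and guarantee that clean simulations survive the F >= 10
#'   screen.
#' @slot reverseBeta causal effect of the outcome on the exposure.
#' @slot JOut number of outcome-specific instrument loci (reverse MR).
#' @slot nDecoy number of null decoy SNPs.
#' @slot nSatellite LD satellites per instrument locus.
#' @slot satelliteR2 within-block r-squared between index and satellite.
#' @slot seed mandatory RNG seed.
#' @export
setClass("SimulationTruth",
  slots = c(betaTrue = "numeric", J = "numeric", mafRange = "numeric",
            nExp = "numeric", nCase = "numeric", nControl = "numeric",
            nOut = "numeric", propInvalid = "numeric", muAlpha = "numeric",
            sigmaAlpha = "numeric", gammaScale = "numeric",
            fFloor = "numeric", fCeil = "numeric", reverseBeta = "numeric", JOut = "numeric",
            nDecoy = "numeric", nSatellite = "numeric",
            satelliteR2 = "numeric", seed = "numeric"))

setValidity("SimulationTruth", function(object) {
  msgs <- character()
  if (object@J < 1) msgs <- c(msgs, "J must be >= 1")
  if (object@propInvalid < 0 || object@propInvalid > 1)
    msgs <- c(msgs, "propInvalid must lie in [0, 1]")
  if (length(object@mafRange) != 2 || any(object@mafRange <= 0) ||
      any(object@mafRange >= 1))
    msgs <- c(msgs, "mafRange must be two frequencies in (0, 1)")
  if (!length(object@seed) || !is.finite(object@seed))
    msgs <- c(msgs, "seed is mandatory")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' @param betaTrue,J,mafRange,nExp,nCase,nControl,nOut,propInvalid see slots.
#' @param muAlpha,sigmaAlpha,gammaScale,fFloor,fCeil,reverseBeta,JOut see slots.
#' @param nDecoy,nSatellite,satelliteR2,seed see slots.
#' @return A \linkS4class{SimulationTruth}.
#' @rdname SimulationTruth-class
#' @export
SimulationTruth <- function(betaTrue = 0, J = 100, mafRange = c(0.05, 0.5),
                            nExp = 18340, nCase = 7686, nControl = 115893,
                            nOut = NA_real_, propInvalid = 0, muAlpha = 0,
                            sigmaAlpha = 0.02, gammaScale = 0.15,
                            fFloor = 140, fCeil = 245, reverseBeta = 0, JOut = 0,
                            nDecoy = 200, nSatellite = 2,
                            satelliteR2 = 0.95, seed) {
  if (missing(seed)) stop("seed is mandatory")
  new("SimulationTruth", betaTrue = betaTrue, J = J, mafRange = mafRange,
      nExp = nExp, nCase = nCase, nControl = nControl, nOut = nOut,
      propInvalid = propInvalid, muAlpha = muAlpha,
      sigmaAlpha = sigmaAlpha, gammaScale = gammaScale, fFloor = fFloor, fCeil = fCeil,
      reverseBeta = reverseBeta, JOut = JOut, nDecoy = nDecoy,
      nSatellite = nSatellite, satelliteR2 = satelliteR2, seed = seed)
}

#' PipelineResult: full bidirectional multivariable MR run
#'
#' @slot results data.frame with one row per (exposure, outcome,
#'   direction, method) holding estimates, q-values and classification
#'   labels in the standard results-table schema.
#' @slot sensitivity named list of \linkS4class{SensitivityReport}s keyed
#'   "direction:exposure:outcome".
#' @slot instruments named list of \linkS4class{InstrumentSet}s (same keys).
#' @slot meta list of configuration, seeds and package version.
#' @export
setClass("PipelineResult",
  slots = c(results = "data.frame", sensitivity = "list",
            instruments = "list", meta = "list"),
  prototype = prototype(sensitivity = list(), instruments = list(),
                        meta = list()))
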