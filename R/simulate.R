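## Analytic per-allele SE for a standardized trait: var(beta_hat) ~
## 1/(2 f (1-f) n). Binary outcomes use the effective sample size
## 4/(1/n_case + 1/n_control).
.gwasSE <- function(f, n) 1 / sqrt(2 * f * (1 - f) * n)

.effectiveN <- function(nCase, nControl) 4 / (1 / nCase + 1 / nControl)

## Non-palindromic ordered allele pairs.
.ALLELE_PAIRS <- rbind(c("A", "G"), c("A", "C"), c("G", "A"),
                       c("C", "A"), c("T", "G"), c("T", "C"),
                       c("G", "T"), c("C", "T"))

## Positive truncated-normal instrument effects with true F confined to
## [fFloor, fCeil], matching the instrument-strength window of a
## selection-screened microbiome GWAS.
.drawGamma <- function(J, scale, seX, fFloor, fCeil = Inf) {
  gamma <- abs(stats::rnorm(J, 0, scale))
  lo <- sqrt(fFloor) * seX
  hi <- sqrt(fCeil) * seX
  for (r in 1:200) {
    out <- gamma < lo | gamma > hi
    if (!any(out)) break
    gamma[out] <- abs(stats::rnorm(sum(out), 0, scale))
  }
  pmin(pmax(gamma, lo), hi)
}

## Genomic coordinates: loci spaced 15 Mb apart across 22 chromosomes so
## clumping windows (10 Mb) never span two loci.
.lociCoords <- function(nLoci) {
  chrom <- as.character(((seq_len(nLoci) - 1L) %% 22L) + 1L)
  island <- (seq_len(nLoci) - 1L) %/% 22L
  pos <- 1e6 + island * 15e6
  data.frame(chrom = chrom, pos = pos)
}

#' Simulate paired two-sample GWAS summary statistics
#'
#' Draws data from the standard two-sample MR generative model at
#' summary level: per instrument locus j an allele frequency f_j ~
#' Uniform(mafRange), a true SNP-exposure effect gamma_j (positive
#' half-normal with scale gammaScale, rejection-sampled so the true F =
#' (gamma_j / se_Xj)^2 clears fFloor), analytic standard errors se_Xj =
#' (2 f_j (1-f_j) n_exp)^(-1/2) (outcome analogous, using the effective
#' case-control sample size), a pleiotropic effect alpha_j ~ N(muAlpha,
#' sigmaAlpha^2) for the invalid fraction (0 otherwise), and true
#' SNP-outcome effect Gamma_j = betaTrue * gamma_j + alpha_j. Observed
#' effects are the true ones plus normal noise at the analytic SEs.
#'
#' Around each instrument locus, \code{nSatellite} SNPs in LD (r^2 =
#' satelliteR2 with the index, entered in the emitted LD table) carry the
#' attenuated signal r * gamma_j, so LD clumping does non-trivial work;
#' \code{nDecoy} null SNPs (gamma = Gamma = 0) exercise the significance
#' filter. Optional fate injections create SNPs destined to be removed
#' at a known selection step (see Details). With \code{JOut > 0} or
#' \code{reverseBeta != 0}, outcome-specific instrument loci are added
#' whose exposure effects are reverseBeta times their outcome effects
#' (reverse causation).
#'
#' @details Fate injections, each adding SNPs whose selection fate is
#' known in advance and recorded in the returned \code{perSnp} table:
#' \code{nLowMaf} (eaf = 0.005), \code{nPalindromic} (A/T alleles),
#' \code{nOutcomeAssoc} (genome-wide significant direct outcome
#' association), \code{nWeakF} (exposure z = 2.5, so F = 6.25; only
#' meaningful under a relaxed p threshold), \code{nMissingOutcome}
#' (absent from the outcome GWAS but with an in-LD satellite present in
#' both datasets, so a proxy is found), \code{nMissingNoProxy} (absent
#' from the outcome GWAS with no proxy).
#'
#' @param truth a \linkS4class{SimulationTruth}.
#' @param nLowMaf,nPalindromic,nOutcomeAssoc,nWeakF,nMissingOutcome,nMissingNoProxy
#'   fate-injection counts (default 0).
#' @return list with elements \code{exposure} and \code{outcome}
#'   (\linkS4class{GwasDataset}s), \code{ld} (\linkS4class{LDSource}),
#'   \code{truth} (the input parameters) and \code{perSnp} (data.frame
#'   of per-SNP ground truth: role, gamma, alpha, Gamma, expected fate).
#' @export
simulateSummaryStats <- function(truth, nLowMaf = 0, nPalindromic = 0,
                                 nOutcomeAssoc = 0, nWeakF = 0,
                                 nMissingOutcome = 0, nMissingNoProxy = 0) {
  stopifnot(is(truth, "SimulationTruth"))
  .withSeed(truth@seed, {
    J <- truth@J
    nEff <- if (is.finite(truth@nOut)) truth@nOut
    else .effectiveN(truth@nCase, truth@nControl)

    nInj <- c(low_maf = nLowMaf, palindrome = nPalindromic,
              outcome_assoc = nOutcomeAssoc, weak_f = nWeakF,
              missing_outcome = nMissingOutcome,
              no_proxy = nMissingNoProxy)
    JOut <- truth@JOut
    if (truth@reverseBeta != 0 && JOut == 0) JOut <- J
    nLoci <- J + sum(nInj) + JOut
    coords <- .lociCoords(nLoci)

    rows <- list()       # per-SNP records (both datasets share layout)
    ldA <- character(0); ldB <- character(0); ldR <- numeric(0)
    perSnp <- list()
    idx <- 0L

    addSnp <- function(id, chrom, pos, f, gamma, Gamma, role, fate,
                       alleles = NULL, alpha = 0, inOutcome = TRUE,
                       inExposure = TRUE, zMax = Inf, zMin = 0) {
      if (is.null(alleles))
        alleles <- .ALLELE_PAIRS[sample.int(nrow(.ALLELE_PAIRS), 1L), ]
      seX <- .gwasSE(f, truth@nExp)
      seY <- .gwasSE(f, nEff)
      bx <- stats::rnorm(1L, gamma, seX)
      ## observed exposure z-scores can be confined to a window: satellites
      ## never out-rank their index SNP (deterministic clump outcomes) and
      ## weak-F injections stay weak yet nominally significant
      tries <- 0L
      while ((abs(bx / seX) >= zMax || abs(bx / seX) <= zMin) &&
             tries < 200L) {
        bx <- stats::rnorm(1L, gamma, seX)
        tries <- tries + 1L
      }
      if (abs(bx / seX) >= zMax) bx <- 0.99 * zMax * seX * sign(bx)
      if (abs(bx / seX) <= zMin) bx <- 1.01 * zMin * seX * sign(bx + 1e-12)
      by <- stats::rnorm(1L, Gamma, seY)
      px <- max(2 * stats::pnorm(-abs(bx / seX)), 1e-300)
      py <- max(2 * stats::pnorm(-abs(by / seY)), 1e-300)
      rows[[length(rows) + 1L]] <<- list(
        snp_id = id, chrom = chrom, pos = pos,
        effect_allele = alleles[1L], other_allele = alleles[2L],
        eaf = f, beta_x = bx, se_x = seX, p_x = px,
        beta_y = by, se_y = seY, p_y = py,
        in_outcome = inOutcome, in_exposure = inExposure)
      perSnp[[length(perSnp) + 1L]] <<- list(
        snp_id = id, role = role, fate = fate, gamma = gamma,
        alpha = alpha, Gamma = Gamma)
    }

    addLocus <- function(id, chrom, pos, role, fate, gamma, alpha,
                         Gamma = NULL, f = NULL, alleles = NULL,
                         inOutcome = TRUE, satellites = truth@nSatellite,
                         satInOutcome = TRUE, zMax = Inf, zMin = 0) {
      if (is.null(f))
        f <- stats::runif(1L, truth@mafRange[1L], truth@mafRange[2L])
      if (is.null(Gamma)) Gamma <- truth@betaTrue * gamma + alpha
      addSnp(id, chrom, pos, f, gamma, Gamma, role, fate,
             alleles = alleles, alpha = alpha, inOutcome = inOutcome,
             zMax = zMax, zMin = zMin)
      zIndex <- abs(rows[[length(rows)]]$beta_x /
                      rows[[length(rows)]]$se_x)
      if (satellites > 0L) {
        r <- sqrt(truth@satelliteR2)
        for (s in seq_len(satellites)) {
          sid <- paste0(id, "_sat", s)
          addSnp(sid, chrom, pos + s * 2000, f, r * gamma, r * Gamma,
                 "satellite", "clumped", alpha = r * alpha,
                 inOutcome = satInOutcome, zMax = zIndex)
          ldA <<- c(ldA, id); ldB <<- c(ldB, sid)
          ldR <<- c(ldR, truth@satelliteR2)
          if (s > 1L) {
            prev <- paste0(id, "_sat", seq_len(s - 1L))
            ldA <<- c(ldA, prev); ldB <<- c(ldB, rep(sid, s - 1L))
            ldR <<- c(ldR, rep(truth@satelliteR2^2, s - 1L))
          }
        }
      }
    }

    ## main instrument loci
    invalid <- rep(FALSE, J)
    nInvalid <- round(truth@propInvalid * J)
    if (nInvalid > 0L) invalid[sample.int(J, nInvalid)] <- TRUE
    for (j in seq_len(J)) {
      idx <- idx + 1L
      f <- stats::runif(1L, truth@mafRange[1L], truth@mafRange[2L])
      gamma <- .drawGamma(1L, truth@gammaScale,
                          .gwasSE(f, truth@nExp), truth@fFloor, truth@fCeil)
      alpha <- if (invalid[j])
        stats::rnorm(1L, truth@muAlpha, truth@sigmaAlpha) else 0
      addLocus(paste0("rs", idx), coords$chrom[idx], coords$pos[idx],
               if (invalid[j]) "instrument_invalid" else "instrument",
               "retained", gamma, alpha, f = f)
    }

    ## fate injections
    inject <- function(kind, n) {
      for (k in seq_len(n)) {
        idx <<- idx + 1L
        id <- paste0("rs", idx)
        ch <- coords$chrom[idx]; po <- coords$pos[idx]
        f <- stats::runif(1L, truth@mafRange[1L], truth@mafRange[2L])
        seX <- .gwasSE(f, truth@nExp)
        gamma <- .drawGamma(1L, truth@gammaScale, seX, truth@fFloor, truth@fCeil)
        switch(kind,
          low_maf = {
            f2 <- 0.005
            g2 <- .drawGamma(1L, truth@gammaScale,
                             .gwasSE(f2, truth@nExp), truth@fFloor, truth@fCeil)
            addLocus(id, ch, po, "injected", "maf", g2, 0, f = f2,
                     satellites = 0L)
          },
          palindrome = addLocus(id, ch, po, "injected", "palindrome",
                                gamma, 0, f = f,
                                alleles = c("A", "T"), satellites = 0L),
          outcome_assoc = {
            seY <- .gwasSE(f, nEff)
            addLocus(id, ch, po, "injected", "outcome_assoc", gamma, 0,
                     Gamma = 8 * seY, f = f, satellites = 0L)
          },
          weak_f = addLocus(id, ch, po, "injected", "weak_f",
                            2.5 * seX, 0, f = f, satellites = 0L,
                            zMin = 2.1, zMax = 3.05),
          missing_outcome = addLocus(id, ch, po, "injected", "proxied",
                                     gamma, 0, f = f,
                                     inOutcome = FALSE,
                                     satellites = max(1L,
                                                      truth@nSatellite)),
          no_proxy = addLocus(id, ch, po, "injected", "no_proxy",
                              gamma, 0, f = f, inOutcome = FALSE,
                              satellites = 0L))
      }
    }
    for (kind in names(nInj)) inject(kind, nInj[[kind]])

    ## outcome-specific loci (reverse causation)
    for (j in seq_len(JOut)) {
      idx <- idx + 1L
      f <- stats::runif(1L, truth@mafRange[1L], truth@mafRange[2L])
      gammaY <- .drawGamma(1L, truth@gammaScale, .gwasSE(f, nEff),
                           truth@fFloor, truth@fCeil)
      addSnp(paste0("rs", idx), coords$chrom[idx], coords$pos[idx], f,
             truth@reverseBeta * gammaY, gammaY, "outcome_instrument",
             "outcome_locus")
    }

    ## null decoys, placed on their own spacing islands
    if (truth@nDecoy > 0L) {
      dcoords <- .lociCoords(nLoci + truth@nDecoy)[
        nLoci + seq_len(truth@nDecoy), , drop = FALSE]
      for (k in seq_len(truth@nDecoy)) {
        idx <- idx + 1L
        f <- stats::runif(1L, truth@mafRange[1L], truth@mafRange[2L])
        addSnp(paste0("rs", idx), dcoords$chrom[k], dcoords$pos[k], f,
               0, 0, "decoy", "not_significant")
      }
    }

    col <- function(lst, f, what) vapply(lst, `[[`, what, f)
    all <- data.frame(
      snp_id = col(rows, "snp_id", ""), chrom = col(rows, "chrom", ""),
      pos = col(rows, "pos", 0),
      effect_allele = col(rows, "effect_allele", ""),
      other_allele = col(rows, "other_allele", ""),
      eaf = col(rows, "eaf", 0), beta_x = col(rows, "beta_x", 0),
      se_x = col(rows, "se_x", 0), p_x = col(rows, "p_x", 0),
      beta_y = col(rows, "beta_y", 0), se_y = col(rows, "se_y", 0),
      p_y = col(rows, "p_y", 0),
      in_outcome = col(rows, "in_outcome", TRUE),
      in_exposure = col(rows, "in_exposure", TRUE),
      stringsAsFactors = FALSE)
    perSnp <- data.frame(
      snp_id = col(perSnp, "snp_id", ""), role = col(perSnp, "role", ""),
      fate = col(perSnp, "fate", ""), gamma = col(perSnp, "gamma", 0),
      alpha = col(perSnp, "alpha", 0), Gamma = col(perSnp, "Gamma", 0),
      stringsAsFactors = FALSE)
    exRows <- all[all$in_exposure, , drop = FALSE]
    outRows <- all[all$in_outcome, , drop = FALSE]
    exposure <- GwasDataset(
      data.frame(snp_id = exRows$snp_id, chrom = exRows$chrom,
                 pos = exRows$pos, effect_allele = exRows$effect_allele,
                 other_allele = exRows$other_allele, eaf = exRows$eaf,
                 beta = exRows$beta_x, se = exRows$se_x,
                 pval = exRows$p_x, n = truth@nExp,
                 stringsAsFactors = FALSE),
      traitId = "sim_exposure", traitType = "continuous")
    outcome <- GwasDataset(
      data.frame(snp_id = outRows$snp_id, chrom = outRows$chrom,
                 pos = outRows$pos, effect_allele = outRows$effect_allele,
                 other_allele = outRows$other_allele, eaf = outRows$eaf,
                 beta = outRows$beta_y, se = outRows$se_y,
                 pval = outRows$p_y,
                 n = if (is.finite(truth@nOut)) truth@nOut
                 else truth@nCase + truth@nControl,
                 stringsAsFactors = FALSE),
      traitId = "sim_outcome",
      traitType = if (is.finite(truth@nOut)) "continuous" else "binary",
      nCase = truth@nCase, nControl = truth@nControl)
    ld <- LDSource(
      if (length(ldA)) data.frame(SNP_A = ldA, SNP_B = ldB, R2 = ldR,
                                  stringsAsFactors = FALSE) else NULL,
      pos = structure(all$pos, names = all$snp_id))
    list(exposure = exposure, outcome = outcome, ld = ld, truth = truth,
         perSnp = perSnp)
  })
}

#' Scramble allele codings (harmonization stress test)
#'
#' Randomly swaps effect/other alleles (negating beta and complementing
#' eaf) for a fraction \code{pSwap} of SNPs, and converts a fraction
#' \code{pPalindrome} to palindromic codings (other allele set to the
#' complement of the effect allele). Since a swap is a pure re-coding of
#' the same association, downstream causal estimates are unchanged after
#' harmonization; palindromized SNPs are dropped at the
#' palindrome-exclusion step.
#'
#' @param dataset a \linkS4class{GwasDataset}.
#' @param pSwap,pPalindrome fractions in [0, 1].
#' @param seed mandatory RNG seed.
#' @return list with \code{dataset} (modified copy), \code{swapped} and
#'   \code{palindromized} (character vectors of affected snp_ids).
#' @export
scrambleAlleles <- function(dataset, pSwap = 0, pPalindrome = 0, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(is(dataset, "GwasDataset"))
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  .withSeed(seed, {
    st <- dataset@stats
    n <- nrow(st)
    doSwap <- stats::runif(n) < pSwap
    doPal <- stats::runif(n) < pPalindrome
    if (any(doSwap)) {
      ea <- st$effect_allele[doSwap]
      st$effect_allele[doSwap] <- st$other_allele[doSwap]
      st$other_allele[doSwap] <- ea
      st$beta[doSwap] <- -st$beta[doSwap]
      st$eaf[doSwap] <- 1 - st$eaf[doSwap]
    }
    if (any(doPal))
      st$other_allele[doPal] <- comp[st$effect_allele[doPal]]
    out <- dataset
    out@stats <- st
    validObject(out)
    list(dataset = out, swapped = st$snp_id[doSwap],
         palindromized = st$snp_id[doPal])
  })
}

#' Simulate data for multivariable MR
#'
#' Adds a second exposure (a confounder trait) with its own instrument
#' loci; the outcome combines both direct effects: Gamma_j = betaTrue *
#' gamma1_j + betaConf * gamma2_j. A fraction \code{overlap} of loci
#' affects both exposures. All three datasets cover the union of SNPs,
#' so joint selection can harmonize everywhere.
#'
#' @param truth a \linkS4class{SimulationTruth} (betaTrue is the direct
#'   effect of exposure 1; J is the instrument count per exposure).
#' @param betaConf direct causal effect of the second exposure.
#' @param overlap fraction of shared instrument loci in [0, 1].
#' @return list with \code{exposure}, \code{confounder}, \code{outcome}
#'   (\linkS4class{GwasDataset}s), \code{ld}, \code{truth},
#'   \code{perSnp}.
#' @export
simulateMv <- function(truth, betaConf = 0, overlap = 0) {
  stopifnot(is(truth, "SimulationTruth"), overlap >= 0, overlap <= 1)
  .withSeed(truth@seed, {
    J <- truth@J
    nEff <- if (is.finite(truth@nOut)) truth@nOut
    else .effectiveN(truth@nCase, truth@nControl)
    nShared <- round(overlap * J)
    nLoci <- 2L * J - nShared
    coords <- .lociCoords(nLoci)
    f <- stats::runif(nLoci, truth@mafRange[1L], truth@mafRange[2L])
    seX <- .gwasSE(f, truth@nExp)
    seY <- .gwasSE(f, nEff)

    ## locus roles: 1..J belong to exposure 1; the last nShared of those
    ## plus the remainder belong to exposure 2
    g1 <- numeric(nLoci)
    g2 <- numeric(nLoci)
    own1 <- seq_len(J)
    own2 <- c(if (nShared) (J - nShared + 1L):J,
              if (nLoci > J) (J + 1L):nLoci)
    g1[own1] <- .drawGamma(J, truth@gammaScale, seX[own1], truth@fFloor, truth@fCeil)
    g2[own2] <- .drawGamma(length(own2), truth@gammaScale, seX[own2],
                           truth@fFloor, truth@fCeil)
    Gamma <- truth@betaTrue * g1 + betaConf * g2

    ids <- paste0("rs", seq_len(nLoci))
    alleles <- .ALLELE_PAIRS[sample.int(nrow(.ALLELE_PAIRS), nLoci,
                                        replace = TRUE), , drop = FALSE]
    mk <- function(beta, se, traitId, type = "continuous",
                   nCase = NA_real_, nControl = NA_real_) {
      bhat <- stats::rnorm(nLoci, beta, se)
      GwasDataset(data.frame(
        snp_id = ids, chrom = coords$chrom, pos = coords$pos,
        effect_allele = alleles[, 1L], other_allele = alleles[, 2L],
        eaf = f, beta = bhat, se = se,
        pval = pmax(2 * stats::pnorm(-abs(bhat / se)), 1e-300),
        n = truth@nExp, stringsAsFactors = FALSE),
        traitId = traitId, traitType = type, nCase = nCase,
        nControl = nControl)
    }
    exposure <- mk(g1, seX, "sim_exposure")
    confounder <- mk(g2, seX, "sim_confounder")
    outcome <- mk(Gamma, seY, "sim_outcome",
                  type = if (is.finite(truth@nOut)) "continuous"
                  else "binary",
                  nCase = truth@nCase, nControl = truth@nControl)
    perSnp <- data.frame(snp_id = ids, gamma1 = g1, gamma2 = g2,
                         Gamma = Gamma,
                         shared = seq_len(nLoci) %in% intersect(own1, own2),
                         stringsAsFactors = FALSE)
    ld <- LDSource(pos = structure(coords$pos, names = ids))
    list(exposure = exposure, confounder = confounder,
         outcome = outcome, ld = ld, truth = truth, perSnp = perSnp)
  })
}

#' Harmonized instrument set straight from simulation truth
#'
#' Builds the \linkS4class{InstrumentSet} of the true instrument loci
#' (valid and invalid) from a \code{\link{simulateSummaryStats}} result,
#' bypassing the selection filters. This isolates estimator behaviour
#' from selection behaviour: under a strong true causal effect the
#' outcome-association filter preferentially removes the strongest
#' instruments (a property of the selection step), which would confound
#' calibration studies of the estimators themselves.
#'
#' @param sim result of \code{\link{simulateSummaryStats}}.
#' @return an \linkS4class{InstrumentSet} over the J instrument loci.
#' @export
simInstrumentSet <- function(sim) {
  ids <- sim$perSnp$snp_id[sim$perSnp$role %in%
                             c("instrument", "instrument_invalid")]
  ex <- sim$exposure@stats
  out <- sim$outcome@stats
  i <- match(ids, ex$snp_id)
  o <- match(ids, out$snp_id)
  snps <- data.frame(
    snp_id = ids, chrom = ex$chrom[i], pos = ex$pos[i],
    effect_allele = ex$effect_allele[i], other_allele = ex$other_allele[i],
    eaf = ex$eaf[i], beta_exp = ex$beta[i], se_exp = ex$se[i],
    beta_out = out$beta[o], se_out = out$se[o],
    f_stat = (ex$beta[i] / ex$se[i])^2, orientation = "same",
    stringsAsFactors = FALSE)
  .InstrumentSet(snps, sim$exposure@traitId, sim$outcome@traitId)
}
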