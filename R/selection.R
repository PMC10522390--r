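#' Step 1: filter SNPs by exposure p-value
#'
#' Keeps exactly the records with \code{pval < threshold} (strict
#' inequality), preserving input order. The default 1e-5 is the
#' locus-wide significance level used for under-powered exposure GWAS
#' such as genus-level microbiome traits.
#'
#' @param stats data.frame of summary statistics (or a
#'   \linkS4class{GwasDataset}, whose table is used).
#' @param threshold significance cutoff in (0, 1).
#' @return the filtered data.frame.
#' @export
filterByPvalue <- function(stats, threshold = 1e-05) {
  stats <- .asStats(stats)
  stopifnot(threshold > 0, threshold < 1)
  stats[stats$pval < threshold, , drop = FALSE]
}

.asStats <- function(x) {
  if (is(x, "GwasDataset")) x@stats else x
}

#' Step 2: greedy LD clumping
#'
#' PLINK-style clumping: SNPs are ranked by ascending p-value; the most
#' significant unclaimed SNP becomes an index, and every unclaimed SNP on
#' the same chromosome within \code{windowKb} of it with r-squared >=
#' \code{r2Max} against it is removed. The returned set is the index
#' SNPs, in the input row order. Pairs within the window but absent from
#' the LD source are treated as r^2 = 0 (with a warning), so incomplete
#' reference panels never silently shrink the instrument set.
#'
#' @param stats data.frame with chrom, pos and pval columns.
#' @param ld an \linkS4class{LDSource}.
#' @param r2Max r-squared cutoff (SNPs at or above it are clumped away).
#' @param windowKb window in kilobases around each index SNP.
#' @return the clumped data.frame (index SNPs only).
#' @export
clumpVariants <- function(stats, ld = LDSource(), r2Max = 0.001,
                          windowKb = 10000) {
  stats <- .asStats(stats)
  n <- nrow(stats)
  if (n <= 1L) return(stats)
  if (any(is.na(stats$chrom)) || any(is.na(stats$pos)))
    stop("clumping requires chrom and pos for every SNP")
  ord <- order(stats$pval, method = "radix")
  alive <- rep(TRUE, n)
  keep <- logical(n)
  nMissing <- 0L
  for (i in ord) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    cand <- which(alive & stats$chrom == stats$chrom[i] &
                    abs(stats$pos - stats$pos[i]) <= windowKb * 1000)
    if (!length(cand)) next
    r2 <- ldR2(ld, stats$snp_id[i], stats$snp_id[cand])
    nMissing <- nMissing + sum(is.na(r2))
    r2[is.na(r2)] <- 0
    alive[cand[r2 >= r2Max]] <- FALSE
  }
  if (nMissing > 0L)
    warning(nMissing, " within-window SNP pair(s) absent from the LD ",
            "source; treated as r2 = 0")
  stats[keep, , drop = FALSE]
}

#' Step 3: exclude rare and palindromic SNPs
#'
#' Drops SNPs whose minor-allele frequency \code{min(eaf, 1 - eaf)} is
#' below \code{mafMin} and all palindromic SNPs (allele pairs A/T or
#' C/G), whose strand cannot be resolved from alleles alone. SNPs with
#' missing frequency pass the MAF test but still face the palindrome
#' test.
#'
#' @param stats data.frame of summary statistics.
#' @param mafMin minimum minor-allele frequency.
#' @return the filtered data.frame.
#' @export
filterFreqAndPalindromes <- function(stats, mafMin = 0.01) {
  stats <- .asStats(stats)
  maf <- pmin(stats$eaf, 1 - stats$eaf)
  dropMaf <- !is.na(maf) & maf < mafMin
  dropPal <- .isPalindromic(stats$effect_allele, stats$other_allele)
  stats[!(dropMaf | dropPal), , drop = FALSE]
}

#' Step 4a: remove instruments associated with the outcome
#'
#' Drops exposure instruments whose p-value in the outcome GWAS is below
#' \code{outcomeP} (genome-wide significance by default): such SNPs
#' plausibly affect the outcome through pathways other than the exposure.
#' Instruments absent from the outcome dataset are passed through (they
#' go on to proxy lookup).
#'
#' @param stats data.frame of exposure instruments.
#' @param outcomeStats data.frame (or \linkS4class{GwasDataset}) of the
#'   outcome GWAS, indexable by snp_id.
#' @param outcomeP exclusion cutoff.
#' @return the filtered data.frame.
#' @export
filterOutcomeAssociated <- function(stats, outcomeStats, outcomeP = 5e-08) {
  stats <- .asStats(stats)
  outcomeStats <- .asStats(outcomeStats)
  op <- outcomeStats$pval[match(stats$snp_id, outcomeStats$snp_id)]
  drop <- !is.na(op) & op < outcomeP
  stats[!drop, , drop = FALSE]
}

#' Step 4b: find proxy SNPs for instruments missing from the outcome
#'
#' For each missing instrument, returns the candidate SNP with maximal
#' r-squared provided it strictly exceeds \code{proxyR2}; ties are broken
#' by smaller base-pair distance, then lexicographic rsID. Instruments
#' with no qualifying candidate are omitted from the mapping (callers log
#' them as dropped with reason "no proxy").
#'
#' @param missing character vector of instrument snp_ids absent from the
#'   outcome dataset.
#' @param ld an \linkS4class{LDSource}.
#' @param candidates data.frame of candidate SNPs (present in the outcome
#'   dataset) with snp_id and pos columns.
#' @param proxyR2 minimum r-squared (strict).
#' @param missingPos optional named numeric of positions for the missing
#'   SNPs (falls back to the LD source's positions).
#' @return named character vector: missing snp_id -> proxy snp_id.
#' @export
findProxies <- function(missing, ld, candidates, proxyR2 = 0.8,
                        missingPos = NULL) {
  candidates <- .asStats(candidates)
  out <- character(0)
  for (m in missing) {
    r2 <- ldR2(ld, m, candidates$snp_id)
    r2[is.na(r2)] <- 0
    ok <- which(r2 > proxyR2 & candidates$snp_id != m)
    if (!length(ok)) next
    mpos <- if (!is.null(missingPos) && m %in% names(missingPos))
      missingPos[[m]] else unname(ld@pos[m])
    dist <- abs(candidates$pos[ok] - mpos)
    dist[is.na(dist)] <- Inf
    o <- ok[order(-r2[ok], dist, candidates$snp_id[ok], method = "radix")]
    out[m] <- candidates$snp_id[o[1L]]
  }
  out
}

#' Step 5: per-SNP instrument-strength F statistic
#'
#' The default form is the squared z-score F = (beta/se)^2, which needs
#' neither sample size nor trait-variance assumptions. The variance-
#' explained form F = (n-2) R^2 / (1 - R^2) with R^2 = 2 f (1-f) beta^2
#' (standardized trait) is available when eaf and n are known.
#'
#' @param beta,se per-allele effect and its standard error.
#' @param eaf,n effect-allele frequency and sample size (r2 form only).
#' @param method "z2" (default) or "r2".
#' @return numeric vector of F statistics.
#' @export
fStatistic <- function(beta, se, eaf = NULL, n = NULL,
                       method = c("z2", "r2")) {
  method <- match.arg(method)
  if (method == "z2") return((beta / se)^2)
  if (is.null(eaf) || is.null(n))
    stop("the r2-based F statistic requires eaf and n")
  r2 <- 2 * eaf * (1 - eaf) * beta^2
  r2 <- pmin(r2, 1 - 1e-12)
  (n - 2) * r2 / (1 - r2)
}

#' Harmonize one exposure/outcome record pair to a common effect allele
#'
#' Aligns the outcome effect to the exposure's effect allele: identical
#' allele order passes through unchanged; swapped alleles (exposure A/G
#' vs outcome G/A) negate the outcome beta and complement the outcome
#' allele frequency; incompatible allele sets are dropped with reason
#' "allele mismatch". Palindromic pairs never reach this point in the
#' selection pipeline (excluded at step 3).
#'
#' @param exp,out single-row data.frames (or lists) with effect_allele,
#'   other_allele, beta, se, and optionally eaf fields.
#' @return list with \code{status} ("same", "flip" or "drop"), and for
#'   non-drops the harmonized \code{beta_out}, \code{se_out},
#'   \code{eaf_out}; for drops a \code{reason}.
#' @export
harmonizePair <- function(exp, out) {
  ea <- toupper(exp$effect_allele); oa <- toupper(exp$other_allele)
  ea2 <- toupper(out$effect_allele); oa2 <- toupper(out$other_allele)
  if (ea == ea2 && oa == oa2) {
    list(status = "same", beta_out = out$beta, se_out = out$se,
         eaf_out = out$eaf)
  } else if (ea == oa2 && oa == ea2) {
    list(status = "flip", beta_out = -out$beta, se_out = out$se,
         eaf_out = if (is.null(out$eaf)) NULL else 1 - out$eaf)
  } else {
    list(status = "drop", reason = "allele mismatch")
  }
}

#' Five-step instrument selection with harmonization
#'
#' Composes the full instrument-selection procedure in order:
#' \enumerate{
#'   \item exposure significance (\code{pval < pThreshold});
#'   \item greedy LD clumping (r^2 < clumpR2 within clumpKb);
#'   \item minor-allele-frequency and palindrome exclusion;
#'   \item removal of outcome-associated SNPs (\code{pval < outcomeP}),
#'     then proxy substitution (r^2 > proxyR2) for instruments absent
#'     from the outcome GWAS — a proxy replaces the instrument wholesale
#'     and must be present in both datasets;
#'   \item F-statistic screening (F >= fMin, F = (beta/se)^2);
#' } followed by per-SNP allele harmonization. Every dropped SNP appears
#' exactly once in the provenance log with the step and reason. Applying
#' the procedure to its own output reproduces the same set (idempotence),
#' and tightening any threshold can only shrink the set.
#'
#' @param exposure,outcome \linkS4class{GwasDataset}s (or plain
#'   data.frames in the standard schema).
#' @param ld an \linkS4class{LDSource} for clumping and proxy search.
#' @param config a \linkS4class{SelectionConfig}.
#' @return an \linkS4class{InstrumentSet}.
#' @export
selectInstruments <- function(exposure, outcome, ld = LDSource(),
                              config = SelectionConfig()) {
  exId <- if (is(exposure, "GwasDataset")) exposure@traitId else "exposure"
  outId <- if (is(outcome, "GwasDataset")) outcome@traitId else "outcome"
  ex <- .asStats(exposure)
  out <- .asStats(outcome)
  prov <- data.frame(snp_id = character(), step = character(),
                     reason = character(), stringsAsFactors = FALSE)
  logDrop <- function(ids, step, reason) {
    if (length(ids))
      prov <<- rbind(prov, data.frame(snp_id = ids, step = step,
                                      reason = rep_len(reason, length(ids)),
                                      stringsAsFactors = FALSE))
  }
  lastStep <- "input"
  checkEmpty <- function(df, step) {
    if (nrow(df) == 0L)
      stop("no instruments for ", exId, " -> ", outId,
           ": empty after step '", step, "' (last non-empty: '",
           lastStep, "')")
    lastStep <<- step
    df
  }

  ## step 1: exposure significance
  s1 <- filterByPvalue(ex, config@pThreshold)
  logDrop(setdiff(ex$snp_id, s1$snp_id), "pvalue", "p >= threshold")
  s1 <- checkEmpty(s1, "pvalue")

  ## step 2: LD clumping
  s2 <- clumpVariants(s1, ld, config@clumpR2, config@clumpKb)
  logDrop(setdiff(s1$snp_id, s2$snp_id), "clump", "in LD with index SNP")
  s2 <- checkEmpty(s2, "clump")

  ## step 3: MAF and palindromes
  s3 <- filterFreqAndPalindromes(s2, config@mafMin)
  droppedS3 <- s2[!s2$snp_id %in% s3$snp_id, , drop = FALSE]
  if (nrow(droppedS3)) {
    pal <- .isPalindromic(droppedS3$effect_allele, droppedS3$other_allele)
    logDrop(droppedS3$snp_id[pal], "maf_palindrome", "palindromic")
    logDrop(droppedS3$snp_id[!pal], "maf_palindrome", "MAF below minimum")
  }
  s3 <- checkEmpty(s3, "maf_palindrome")

  ## step 4: outcome association, then proxies for missing instruments
  s4 <- filterOutcomeAssociated(s3, out, config@outcomeP)
  logDrop(setdiff(s3$snp_id, s4$snp_id), "outcome_assoc",
          "associated with outcome")
  s4 <- checkEmpty(s4, "outcome_assoc")

  missing <- s4$snp_id[!s4$snp_id %in% out$snp_id]
  if (length(missing)) {
    ## candidates: present in both datasets, non-palindromic, not already
    ## instruments, and themselves clear of outcome association
    candIds <- intersect(out$snp_id, ex$snp_id)
    cand <- out[match(candIds, out$snp_id), , drop = FALSE]
    cand <- cand[!.isPalindromic(cand$effect_allele, cand$other_allele), ,
                 drop = FALSE]
    cand <- cand[cand$pval >= config@outcomeP, , drop = FALSE]
    cand <- cand[!cand$snp_id %in% s4$snp_id, , drop = FALSE]
    mpos <- structure(s4$pos[match(missing, s4$snp_id)], names = missing)
    prox <- findProxies(missing, ld, cand, config@proxyR2,
                        missingPos = mpos)
    noProxy <- setdiff(missing, names(prox))
    logDrop(noProxy, "proxy", "no proxy")
    s4 <- s4[!s4$snp_id %in% noProxy, , drop = FALSE]
    if (length(prox)) {
      logDrop(names(prox), "proxy",
              paste0("substituted by proxy ", unname(prox)))
      keepRows <- s4[!s4$snp_id %in% names(prox), , drop = FALSE]
      proxRows <- ex[match(unname(prox), ex$snp_id), , drop = FALSE]
      proxRows <- proxRows[!proxRows$snp_id %in% keepRows$snp_id, ,
                           drop = FALSE]
      s4 <- rbind(keepRows, proxRows)
    }
    s4 <- checkEmpty(s4, "proxy")
  }

  ## step 5: instrument strength
  f <- fStatistic(s4$beta, s4$se)
  weak <- f < config@fMin
  logDrop(s4$snp_id[weak], "f_stat", "F below minimum")
  s5 <- s4[!weak, , drop = FALSE]
  f <- f[!weak]
  s5 <- checkEmpty(s5, "f_stat")

  ## harmonization to the exposure's effect allele
  oidx <- match(s5$snp_id, out$snp_id)
  keep <- logical(nrow(s5))
  betaOut <- seOut <- eafOut <- rep(NA_real_, nrow(s5))
  orient <- rep(NA_character_, nrow(s5))
  for (i in seq_len(nrow(s5))) {
    h <- harmonizePair(s5[i, ], out[oidx[i], ])
    if (h$status == "drop") {
      logDrop(s5$snp_id[i], "harmonize", h$reason)
      next
    }
    keep[i] <- TRUE
    betaOut[i] <- h$beta_out
    seOut[i] <- h$se_out
    eafOut[i] <- if (is.null(h$eaf_out)) NA_real_ else h$eaf_out
    orient[i] <- h$status
  }
  snps <- data.frame(
    snp_id = s5$snp_id, chrom = s5$chrom, pos = s5$pos,
    effect_allele = s5$effect_allele, other_allele = s5$other_allele,
    eaf = s5$eaf, beta_exp = s5$beta, se_exp = s5$se,
    beta_out = betaOut, se_out = seOut, f_stat = f,
    orientation = orient, stringsAsFactors = FALSE)[keep, , drop = FALSE]
  snps <- checkEmpty(snps, "harmonize")
  .InstrumentSet(snps, exId, outId, prov)
}
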