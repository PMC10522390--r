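#' Select joint instruments for multivariable MR
#'
#' Instruments are the union of each exposure's locus-wide significant
#' SNPs, jointly clumped (greedy over the union ranked by the minimum
#' p-value across exposures), filtered for MAF/palindromes and outcome
#' association, and harmonized to the first exposure's effect allele
#' across all K exposures and the outcome. SNPs absent from any dataset
#' are dropped with the dataset named in the reason. Requires more
#' instruments than exposures (J > K).
#'
#' @param exposures list of K >= 2 \linkS4class{GwasDataset}s; the first
#'   is the exposure of interest, the rest the conditioning traits.
#' @param outcome the outcome \linkS4class{GwasDataset}.
#' @param ld an \linkS4class{LDSource}.
#' @param config a \linkS4class{SelectionConfig}.
#' @return an \linkS4class{MvInstrumentMatrix}.
#' @export
selectMvInstruments <- function(exposures, outcome, ld = LDSource(),
                                config = SelectionConfig()) {
  if (length(exposures) < 2L)
    stop("multivariable MR needs K >= 2 exposure datasets")
  K <- length(exposures)
  exIds <- vapply(exposures, function(d) d@traitId, "")
  exStats <- lapply(exposures, .asStats)
  out <- .asStats(outcome)
  outId <- if (is(outcome, "GwasDataset")) outcome@traitId else "outcome"
  prov <- data.frame(snp_id = character(), step = character(),
                     reason = character(), stringsAsFactors = FALSE)
  logDrop <- function(ids, step, reason) {
    if (length(ids))
      prov <<- rbind(prov, data.frame(snp_id = ids, step = step,
                                      reason = rep_len(reason, length(ids)),
                                      stringsAsFactors = FALSE))
  }

  ## union of step-1 hits, keyed by minimum p across exposures
  hits <- lapply(exStats, filterByPvalue, threshold = config@pThreshold)
  ids <- unique(unlist(lapply(hits, `[[`, "snp_id")))
  if (!length(ids)) stop("no instruments: no exposure reaches p threshold")
  ref <- exStats[[1L]]
  minP <- vapply(ids, function(s) {
    min(vapply(exStats, function(d) {
      i <- match(s, d$snp_id)
      if (is.na(i)) Inf else d$pval[i]
    }, 0))
  }, 0)
  ## coordinates from the first dataset carrying the SNP
  coord <- do.call(rbind, lapply(ids, function(s) {
    for (d in exStats) {
      i <- match(s, d$snp_id)
      if (!is.na(i))
        return(d[i, c("snp_id", "chrom", "pos", "effect_allele",
                      "other_allele", "eaf")])
    }
  }))
  un <- data.frame(coord, pval = minP, stringsAsFactors = FALSE)

  ## joint clumping by min-p
  cl <- clumpVariants(un, ld, config@clumpR2, config@clumpKb)
  logDrop(setdiff(un$snp_id, cl$snp_id), "clump", "in LD with index SNP")

  ## MAF / palindrome exclusion
  s3 <- filterFreqAndPalindromes(cl, config@mafMin)
  droppedS3 <- cl[!cl$snp_id %in% s3$snp_id, , drop = FALSE]
  if (nrow(droppedS3)) {
    pal <- .isPalindromic(droppedS3$effect_allele, droppedS3$other_allele)
    logDrop(droppedS3$snp_id[pal], "maf_palindrome", "palindromic")
    logDrop(droppedS3$snp_id[!pal], "maf_palindrome", "MAF below minimum")
  }

  ## presence in every dataset
  keep <- s3$snp_id
  for (k in seq_len(K)) {
    absent <- keep[!keep %in% exStats[[k]]$snp_id]
    logDrop(absent, "presence",
            paste0("absent in exposure ", k, " (", exIds[k], ")"))
    keep <- setdiff(keep, absent)
  }
  absentOut <- keep[!keep %in% out$snp_id]
  logDrop(absentOut, "presence", paste0("absent in outcome (", outId, ")"))
  keep <- setdiff(keep, absentOut)

  ## outcome-association removal
  op <- out$pval[match(keep, out$snp_id)]
  assoc <- keep[op < config@outcomeP]
  logDrop(assoc, "outcome_assoc", "associated with outcome")
  keep <- setdiff(keep, assoc)

  ## harmonize all datasets to the first exposure's effect allele
  refRows <- ref[match(keep, ref$snp_id), , drop = FALSE]
  betaExp <- seExp <- matrix(NA_real_, nrow = length(keep), ncol = K,
                             dimnames = list(keep, exIds))
  betaOut <- seOut <- rep(NA_real_, length(keep))
  ok <- rep(TRUE, length(keep))
  for (i in seq_along(keep)) {
    for (k in seq_len(K)) {
      d <- exStats[[k]]
      h <- harmonizePair(refRows[i, ], d[match(keep[i], d$snp_id), ])
      if (h$status == "drop") {
        logDrop(keep[i], "harmonize",
                paste0("allele mismatch in exposure ", k))
        ok[i] <- FALSE
        break
      }
      betaExp[i, k] <- h$beta_out
      seExp[i, k] <- h$se_out
    }
    if (!ok[i]) next
    h <- harmonizePair(refRows[i, ], out[match(keep[i], out$snp_id), ])
    if (h$status == "drop") {
      logDrop(keep[i], "harmonize", "allele mismatch in outcome")
      ok[i] <- FALSE
      next
    }
    betaOut[i] <- h$beta_out
    seOut[i] <- h$se_out
  }
  keep <- keep[ok]
  if (length(keep) <= K)
    stop("under-identified multivariable model: ", length(keep),
         " instruments for ", K, " exposures")
  new("MvInstrumentMatrix", outcomeId = outId, exposureIds = exIds,
      snpId = keep,
      betaExp = betaExp[ok, , drop = FALSE],
      seExp = seExp[ok, , drop = FALSE],
      betaOut = betaOut[ok], seOut = seOut[ok], provenance = prov)
}

#' Multivariable IVW estimator
#'
#' Weighted least squares of the outcome effects on the K exposure-effect
#' columns with no intercept and weights 1/se_out^2. Each coefficient is
#' the direct effect of that exposure conditional on the others.
#' Per-coefficient standard errors use the weighted covariance with a
#' multiplicative overdispersion scale floored at 1 (never below the
#' fixed-effect covariance). With K = 1 this reduces to the univariable
#' IVW estimator.
#'
#' @param matrix an \linkS4class{MvInstrumentMatrix} (or a plain list
#'   with betaExp/seExp matrices and betaOut/seOut vectors).
#' @return named list of \linkS4class{MREstimate}s, one per exposure
#'   (method "mvmr_ivw").
#' @export
mvmrIVW <- function(matrix) {
  if (is(matrix, "MvInstrumentMatrix")) {
    X <- matrix@betaExp
    y <- matrix@betaOut
    sy <- matrix@seOut
    ids <- matrix@exposureIds
  } else {
    X <- matrix$betaExp
    y <- matrix$betaOut
    sy <- matrix$seOut
    ids <- colnames(X)
    if (is.null(ids)) ids <- paste0("exposure", seq_len(ncol(X)))
  }
  X <- as.matrix(X)
  ## an all-zero exposure column carries no information: drop it from the
  ## fit (its estimate is reported as skipped), so the remaining
  ## coefficients equal the fit without it
  zero <- colSums(X != 0) == 0L
  skippedZero <- ids[zero]
  if (any(zero)) {
    X <- X[, !zero, drop = FALSE]
    ids <- ids[!zero]
  }
  if (!ncol(X)) stop("all exposure columns are zero")
  J <- nrow(X); K <- ncol(X)
  if (J <= K)
    stop("under-identified multivariable model: J = ", J, ", K = ", K)
  w <- 1 / sy^2
  qrX <- qr(X * sqrt(w))
  if (qrX$rank < K) {
    bad <- ids[qrX$pivot[(qrX$rank + 1):K]]
    stop("collinear exposure columns: ", paste(bad, collapse = ", "))
  }
  XtW <- t(X * w)
  XtWXinv <- solve(XtW %*% X)
  coefs <- unname(drop(XtWXinv %*% XtW %*% y))
  resid <- y - drop(X %*% coefs)
  scale <- max(1, sum(w * resid^2) / (J - K))
  covb <- scale * XtWXinv
  out <- lapply(seq_len(K), function(k) {
    se <- sqrt(covb[k, k])
    .MREstimate("mvmr_ivw", coefs[k], se, .normP(coefs[k] / se), J,
                aux = list(exposure = ids[k], scale = scale,
                           adjusted_for = ids[-k]))
  })
  names(out) <- ids
  for (id in skippedZero)
    out[[id]] <- .skippedEstimate("mvmr_ivw", "all-zero exposure column")
  out
}
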