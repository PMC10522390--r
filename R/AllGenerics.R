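#' Number of instruments
#' @param x an InstrumentSet, MvInstrumentMatrix or MREstimate.
#' @return integer count.
#' @export
setGeneric("nSnp", function(x) standardGeneric("nSnp"))

#' Per-SNP instrument table
#' @param x an InstrumentSet.
#' @return data.frame of harmonized per-SNP effects.
#' @export
setGeneric("instruments", function(x) standardGeneric("instruments"))

#' Provenance log of dropped SNPs
#' @param x an InstrumentSet, MvInstrumentMatrix or GwasDataset.
#' @return data.frame with one row per dropped/rejected SNP.
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' Trait identifiers
#' @param x an object carrying trait ids.
#' @return character id(s).
#' @export
setGeneric("exposureId", function(x) standardGeneric("exposureId"))

#' @rdname exposureId
#' @export
setGeneric("outcomeId", function(x) standardGeneric("outcomeId"))

#' Summary-statistics table of a GwasDataset
#' @param x a GwasDataset.
#' @return data.frame with the standard per-SNP columns.
#' @export
setGeneric("summaryStats", function(x) standardGeneric("summaryStats"))

#' @describeIn nSnp rows of the harmonized instrument table
#' @export
setMethod("nSnp", "InstrumentSet", function(x) nrow(x@snps))

#' @describeIn nSnp instruments used by an estimate
#' @export
setMethod("nSnp", "MREstimate", function(x) x@nSnp)

#' @describeIn nSnp rows of the multivariable instrument matrix
#' @export
setMethod("nSnp", "MvInstrumentMatrix", function(x) length(x@snpId))

#' @describeIn instruments harmonized per-SNP effect pairs
#' @export
setMethod("instruments", "InstrumentSet", function(x) x@snps)

#' @describeIn provenance dropped SNPs with step and reason
#' @export
setMethod("provenance", "InstrumentSet", function(x) x@provenance)

#' @describeIn provenance dropped SNPs with step and reason
#' @export
setMethod("provenance", "MvInstrumentMatrix", function(x) x@provenance)

#' @describeIn provenance rows rejected during validation
#' @export
setMethod("provenance", "GwasDataset", function(x) x@rejections)

#' @describeIn exposureId exposure id of an InstrumentSet
#' @export
setMethod("exposureId", "InstrumentSet", function(x) x@exposureId)

#' @describeIn outcomeId outcome id of an InstrumentSet
#' @export
setMethod("outcomeId", "InstrumentSet", function(x) x@outcomeId)

#' @describeIn exposureId exposure ids of an MvInstrumentMatrix
#' @export
setMethod("exposureId", "MvInstrumentMatrix", function(x) x@exposureIds)

#' @describeIn outcomeId outcome id of an MvInstrumentMatrix
#' @export
setMethod("outcomeId", "MvInstrumentMatrix", function(x) x@outcomeId)

#' @describeIn summaryStats validated per-SNP table
#' @export
setMethod("summaryStats", "GwasDataset", function(x) x@stats)

setMethod("show", "GwasDataset", function(object) {
  cat("GwasDataset '", object@traitId, "' (", object@traitType, ")\n",
      sep = "")
  cat("  ", nrow(object@stats), " SNPs; ", nrow(object@rejections),
      " rejected rows\n", sep = "")
  if (object@traitType == "binary" && is.finite(object@nCase))
    cat("  ", object@nCase, " cases / ", object@nControl, " controls\n",
        sep = "")
})

setMethod("show", "InstrumentSet", function(object) {
  cat("InstrumentSet: ", object@exposureId, " -> ", object@outcomeId,
      "\n  ", nrow(object@snps), " harmonized instruments; ",
      nrow(object@provenance), " SNPs dropped during selection\n",
      sep = "")
  if (nrow(object@snps))
    cat("  F statistics: ",
        sprintf("%.2f-%.2f (mean %.2f)", min(object@snps$f_stat),
                max(object@snps$f_stat), mean(object@snps$f_stat)),
        "\n", sep = "")
})

setMethod("show", "MREstimate", function(object) {
  if (!is.finite(object@beta)) {
    cat("MREstimate [", object@method, "]: skipped (",
        object@aux$skipped, ")\n", sep = "")
    return(invisible(NULL))
  }
  cat(sprintf(
    "MREstimate [%s]: beta=%.4f se=%.4f OR=%.3f (95%% CI %.3f-%.3f) p=%.3g (%d SNPs)\n",
    object@method, object@beta, object@se, object@orValue, object@ciLow,
    object@ciHigh, object@pval, object@nSnp))
})

setMethod("show", "SensitivityReport", function(object) {
  cat("SensitivityReport\n")
  cat(sprintf("  Cochran's Q = %.3f (df %d), p = %.3g\n", object@qIvw,
              as.integer(object@qDf), object@qPval))
  ei <- object@eggerIntercept
  cat(sprintf("  Egger intercept = %.4f (se %.4f), p = %.3g\n",
              ei[["estimate"]], ei[["se"]], ei[["pval"]]))
  cat(sprintf("  MR-PRESSO global p = %.3g; %d outlier(s)\n",
              object@pressoGlobalP, nrow(object@pressoOutliers)))
  cat(sprintf("  Leave-one-out: %d re-estimates, %d influential\n",
              nrow(object@loo), sum(object@loo$influential)))
})

setMethod("show", "SelectionConfig", function(object) {
  cat("SelectionConfig\n")
  cat(sprintf("  exposure P < %g; clump r2 < %g in %g kb; MAF >= %g\n",
              object@pThreshold, object@clumpR2, object@clumpKb,
              object@mafMin))
  cat(sprintf("  outcome P < %g (proxy r2 > %g); F >= %g\n",
              object@outcomeP, object@proxyR2, object@fMin))
})

setMethod("show", "PipelineResult", function(object) {
  res <- object@results
  cat("PipelineResult: ", length(unique(res$exposure)), " exposure(s) x ",
      length(unique(res$outcome)), " outcome(s)\n", sep = "")
  for (d in unique(res$direction))
    cat("  ", d, ": ", sum(res$direction == d & res$method == "ivw"),
        " analyses\n", sep = "")
})
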