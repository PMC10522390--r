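#' Storey q-values
#'
#' False-discovery-rate adjusted significance measures incorporating an
#' estimate of the null proportion pi0. pi0 is estimated by the smoother
#' method: pi0(lambda) = #\{p > lambda\} / (m (1 - lambda)) over the
#' lambda grid, smoothed with a cubic smoothing spline (df = 3) and
#' evaluated at the largest lambda, clamped to (0, 1]. Then
#' q_i = min over \{j : p_j >= p_i\} of pi0 * m * p_j / rank(p_j), which
#' is monotone non-decreasing in p. With pi0 forced to 1 the procedure
#' reduces exactly to the Benjamini-Hochberg step-up adjustment. With
#' fewer than 12 p-values the smoother is unstable, so pi0 is fixed at 1
#' with a warning.
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @param lambdaGrid grid for pi0 estimation (default 0.05..0.95 by
#'   0.05).
#' @param pi0 optional fixed null proportion (overrides estimation).
#' @return numeric vector of q-values, same order as \code{pvals}; the
#'   estimated pi0 is attached as attribute \code{"pi0"}.
#' @export
qvalueStorey <- function(pvals, lambdaGrid = seq(0.05, 0.95, by = 0.05),
                         pi0 = NULL) {
  m <- length(pvals)
  if (m < 1L) stop("need at least one p-value")
  if (any(!is.finite(pvals) | pvals <= 0 | pvals > 1))
    stop("all p-values must lie in (0, 1]")
  if (is.null(pi0)) {
    if (m < 12L) {
      warning("fewer than 12 p-values: pi0 smoother unstable, using pi0 = 1")
      pi0 <- 1
    } else {
      pi0Lambda <- vapply(lambdaGrid,
                          function(l) mean(pvals > l) / (1 - l), 0)
      fit <- stats::smooth.spline(lambdaGrid, pi0Lambda, df = 3)
      pi0 <- stats::predict(fit, x = max(lambdaGrid))$y
      pi0 <- min(max(pi0, .Machine$double.eps), 1)
    }
  }
  ord <- order(pvals, method = "radix")
  qSorted <- pi0 * m * pvals[ord] / seq_len(m)
  qSorted <- rev(cummin(rev(qSorted)))
  qSorted <- pmin(qSorted, 1)
  q <- numeric(m)
  q[ord] <- qSorted
  attr(q, "pi0") <- pi0
  q
}

#' Classify an association by p- and q-value
#'
#' The decision rule: significant when q < 0.1 (survives FDR
#' correction); suggestive when p < 0.05 but q >= 0.1 (nominal only);
#' none otherwise. Vectorized.
#'
#' @param pval,qval numeric vectors (recycled).
#' @param qSig q-value significance cutoff (default 0.1).
#' @param pSuggestive nominal p cutoff for suggestive associations
#'   (default 0.05).
#' @return character vector: "significant", "suggestive" or "none".
#' @export
classifyAssociation <- function(pval, qval, qSig = 0.1,
                                pSuggestive = 0.05) {
  n <- max(length(pval), length(qval))
  pval <- rep_len(pval, n); qval <- rep_len(qval, n)
  ifelse(qval < qSig, "significant",
         ifelse(pval < pSuggestive, "suggestive", "none"))
}

#' Cross-method concordance count
#'
#' Number of methods (among those actually computed) with nominal p <
#' 0.05 and effect direction agreeing with the IVW estimate; the
#' operational version of "found in more than three MR methods". Skipped
#' methods are excluded from both numerator and denominator.
#'
#' @param estimates named list of \linkS4class{MREstimate}s (as returned
#'   by \code{\link{mrAll}}); must include "ivw".
#' @param alpha nominal level.
#' @return named integer vector c(concordant, evaluated).
#' @export
methodConcordance <- function(estimates, alpha = 0.05) {
  if (!length(estimates)) stop("need at least one estimate")
  ivw <- estimates[["ivw"]]
  if (is.null(ivw) || !is.finite(ivw@beta))
    stop("concordance requires a computed IVW estimate")
  computed <- Filter(function(e) is.finite(e@beta), estimates)
  hits <- vapply(computed, function(e)
    is.finite(e@pval) && e@pval < alpha &&
      sign(e@beta) == sign(ivw@beta), TRUE)
  c(concordant = sum(hits), evaluated = length(computed))
}

## Deterministic per-analysis sub-seeds below 2^31.
.subSeeds <- function(seed, n) {
  .withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Run the full bidirectional MR pipeline
#'
#' For every exposure x outcome pair: five-step instrument selection,
#' the five estimators, sensitivity diagnostics, Storey q-values over
#' the IVW p-values (one family per outcome, across exposures), and
#' classification labels. With \code{reverse = TRUE} the same analyses
#' are repeated with roles swapped, using the reverse-specific exposure
#' threshold (genome-wide 5e-8 by default, since disease GWAS are
#' well-powered). With confounder datasets supplied, multivariable MR is
#' run for every forward pair whose label is not "none", one confounder
#' at a time. Pairs yielding no instruments are recorded with status
#' "no instruments", never dropped silently; the output is a pure
#' function of (inputs, config, seed).
#'
#' @param exposures,outcomes lists of \linkS4class{GwasDataset}s.
#' @param ld an \linkS4class{LDSource}.
#' @param config a \linkS4class{SelectionConfig} for forward analyses.
#' @param reverse also run reverse analyses (roles swapped).
#' @param reverseP exposure significance threshold for reverse analyses.
#' @param confounders optional named list of \linkS4class{GwasDataset}s
#'   used for multivariable adjustment.
#' @param seed mandatory master seed; all per-analysis seeds derive from
#'   it.
#' @param nBoot weighted-median bootstrap resamples.
#' @param pressoSims MR-PRESSO simulation count.
#' @param qSig,pSuggestive classification cutoffs, see
#'   \code{\link{classifyAssociation}}.
#' @return a \linkS4class{PipelineResult}.
#' @export
runPipeline <- function(exposures, outcomes, ld = LDSource(),
                        config = SelectionConfig(), reverse = TRUE,
                        reverseP = 5e-08, confounders = list(), seed,
                        nBoot = 1000, pressoSims = 1000, qSig = 0.1,
                        pSuggestive = 0.05) {
  if (missing(seed)) stop("seed is mandatory")
  if (!length(exposures) || !length(outcomes))
    stop("need at least one exposure and one outcome dataset")
  exIds <- vapply(exposures, function(d) d@traitId, "")
  outIds <- vapply(outcomes, function(d) d@traitId, "")
  names(exposures) <- exIds
  names(outcomes) <- outIds

  revConfig <- config
  revConfig@pThreshold <- reverseP
  plan <- expand.grid(exposure = exIds, outcome = outIds,
                      direction = "forward", stringsAsFactors = FALSE)
  if (reverse)
    plan <- rbind(plan,
                  expand.grid(exposure = outIds, outcome = exIds,
                              direction = "reverse",
                              stringsAsFactors = FALSE))
  plan <- plan[order(plan$direction, plan$exposure, plan$outcome,
                     method = "radix"), , drop = FALSE]
  seeds <- .subSeeds(seed, nrow(plan) + length(confounders) * nrow(plan))

  rows <- list()
  sens <- list()
  sets <- list()
  ivwP <- data.frame(exposure = character(), outcome = character(),
                     direction = character(), pval = numeric(),
                     stringsAsFactors = FALSE)
  for (i in seq_len(nrow(plan))) {
    dir <- plan$direction[i]
    exd <- if (dir == "forward") exposures[[plan$exposure[i]]]
    else outcomes[[plan$exposure[i]]]
    outd <- if (dir == "forward") outcomes[[plan$outcome[i]]]
    else exposures[[plan$outcome[i]]]
    cfg <- if (dir == "forward") config else revConfig
    key <- paste(dir, plan$exposure[i], plan$outcome[i], sep = ":")
    set <- tryCatch(selectInstruments(exd, outd, ld, cfg),
                    error = function(e) conditionMessage(e))
    if (is.character(set)) {
      rows[[key]] <- data.frame(
        exposure = plan$exposure[i], outcome = plan$outcome[i],
        direction = dir, method = "ivw", n_snp = 0L, beta = NA_real_,
        se = NA_real_, OR = NA_real_, ci_low = NA_real_,
        ci_high = NA_real_, pval = NA_real_, qval = NA_real_,
        label = NA_character_, status = "no instruments",
        concordant = NA_integer_, evaluated = NA_integer_,
        stringsAsFactors = FALSE)
      next
    }
    sets[[key]] <- set
    ests <- mrAll(set, seed = seeds[i], nBoot = nBoot)
    conc <- methodConcordance(ests)
    tab <- resultsTable(ests, exposure = plan$exposure[i],
                        outcome = plan$outcome[i])
    tab$direction <- dir
    tab$status <- "ok"
    tab$concordant <- conc[["concordant"]]
    tab$evaluated <- conc[["evaluated"]]
    rows[[key]] <- tab
    sens[[key]] <- runSensitivity(set, nSim = pressoSims,
                                  seed = seeds[i])
    ivwP <- rbind(ivwP, data.frame(
      exposure = plan$exposure[i], outcome = plan$outcome[i],
      direction = dir, pval = ests$ivw@pval, stringsAsFactors = FALSE))
  }
  results <- do.call(rbind, c(rows, list(make.row.names = FALSE)))

  ## q-value families: per outcome within a direction, across exposures
  results$qval <- NA_real_
  results$label <- NA_character_
  for (dir in unique(ivwP$direction)) {
    for (o in unique(ivwP$outcome[ivwP$direction == dir])) {
      fam <- ivwP$direction == dir & ivwP$outcome == o
      q <- suppressWarnings(qvalueStorey(ivwP$pval[fam]))
      lab <- classifyAssociation(ivwP$pval[fam], q, qSig, pSuggestive)
      for (k in which(fam)) {
        sel <- results$direction == dir &
          results$outcome == o & results$exposure == ivwP$exposure[k] &
          results$status == "ok"
        results$qval[sel & results$method == "ivw"] <-
          q[match(k, which(fam))]
        results$label[sel] <- lab[match(k, which(fam))]
      }
    }
  }

  ## multivariable adjustment for flagged forward pairs
  mvRows <- list()
  si <- nrow(plan)
  if (length(confounders)) {
    confIds <- names(confounders)
    if (is.null(confIds))
      confIds <- vapply(confounders, function(d) d@traitId, "")
    flagged <- unique(results[results$direction == "forward" &
                                results$method == "ivw" &
                                !is.na(results$label) &
                                results$label != "none",
                              c("exposure", "outcome")])
    for (j in seq_len(nrow(flagged))) {
      for (ci in seq_along(confounders)) {
        si <- si + 1
        key <- paste("mvmr", flagged$exposure[j], flagged$outcome[j],
                     confIds[ci], sep = ":")
        est <- tryCatch({
          mat <- selectMvInstruments(
            list(exposures[[flagged$exposure[j]]], confounders[[ci]]),
            outcomes[[flagged$outcome[j]]], ld, config)
          mvmrIVW(mat)[[1L]]
        }, error = function(e) conditionMessage(e))
        if (is.character(est)) {
          mvRows[[key]] <- data.frame(
            exposure = flagged$exposure[j], outcome = flagged$outcome[j],
            direction = paste0("mvmr:", confIds[ci]), method = "mvmr_ivw",
            n_snp = 0L, beta = NA_real_, se = NA_real_, OR = NA_real_,
            ci_low = NA_real_, ci_high = NA_real_, pval = NA_real_,
            qval = NA_real_, label = NA_character_, status = est,
            concordant = NA_integer_, evaluated = NA_integer_,
            stringsAsFactors = FALSE)
        } else {
          mvRows[[key]] <- data.frame(
            exposure = flagged$exposure[j], outcome = flagged$outcome[j],
            direction = paste0("mvmr:", confIds[ci]), method = "mvmr_ivw",
            n_snp = est@nSnp, beta = est@beta, se = est@se,
            OR = est@orValue, ci_low = est@ciLow, ci_high = est@ciHigh,
            pval = est@pval, qval = NA_real_, label = NA_character_,
            status = "ok", concordant = NA_integer_,
            evaluated = NA_integer_, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(mvRows))
    results <- rbind(results, do.call(rbind, c(mvRows,
                                               list(make.row.names = FALSE))))
  rownames(results) <- NULL
  new("PipelineResult", results = results, sensitivity = sens,
      instruments = sets,
      meta = list(seed = seed, config = config, reverseP = reverseP,
                  nBoot = nBoot, pressoSims = pressoSims, qSig = qSig,
                  pSuggestive = pSuggestive,
                  qvalue_family = "per outcome within direction",
                  version = as.character(utils::packageVersion("gwasMR"))))
}

#' Per-SNP plot data for scatter and forest displays
#'
#' Tabular export of what scatter plots (per-SNP effect pairs with
#' method fit lines) and forest plots (per-method OR and CI) display.
#'
#' @param set an \linkS4class{InstrumentSet}.
#' @param estimates named list of \linkS4class{MREstimate}s.
#' @return list with \code{scatter} and \code{forest} data.frames.
#' @export
plotData <- function(set, estimates) {
  sn <- set@snps
  scatter <- data.frame(snp_id = sn$snp_id, beta_exp = sn$beta_exp,
                        se_exp = sn$se_exp, beta_out = sn$beta_out,
                        se_out = sn$se_out, stringsAsFactors = FALSE)
  computed <- Filter(function(e) is.finite(e@beta), estimates)
  forest <- resultsTable(computed, exposure = set@exposureId,
                         outcome = set@outcomeId)
  fits <- data.frame(
    method = vapply(computed, function(e) e@method, ""),
    slope = vapply(computed, function(e) e@beta, 0),
    intercept = vapply(computed, function(e)
      if (!is.null(e@aux$intercept)) e@aux$intercept else 0, 0),
    stringsAsFactors = FALSE)
  list(scatter = scatter, forest = forest, fits = fits)
}
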