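#' Cochran's Q heterogeneity statistic
#'
#' Q = sum_j w_j (theta_j - beta_ref)^2 with Wald ratios theta_j and
#' weights w_j = beta_exp^2 / se_out^2; upper-tail chi-square p-value on
#' J - 1 degrees of freedom. Q is non-negative, zero exactly when all
#' ratios coincide, invariant to SNP ordering, and scales as 1/se_out^2.
#' The "egger" variant measures heterogeneity around the Egger fit
#' (intercept-adjusted residuals, J - 2 df).
#'
#' @param set an \linkS4class{InstrumentSet} with at least 2 instruments
#'   (3 for the Egger variant).
#' @param betaRef reference slope; defaults to the fixed-effect IVW
#'   estimate ("ivw" method) or the Egger slope ("egger").
#' @param method "ivw" or "egger".
#' @return list with Q, df and pval.
#' @export
cochranQ <- function(set, betaRef = NULL, method = c("ivw", "egger")) {
  method <- match.arg(method)
  e <- .effects(set)
  if (e$J < 2L) stop("insufficient instruments for Cochran's Q: need >= 2")
  w <- 1 / e$sy^2
  if (method == "ivw") {
    if (is.null(betaRef))
      betaRef <- sum(e$bx * e$by * w) / sum(e$bx^2 * w)
    Q <- sum(w * (e$by - betaRef * e$bx)^2)
    df <- e$J - 1
  } else {
    if (e$J < 3L) stop("the Egger Q variant needs >= 3 instruments")
    eg <- mrEgger(set)
    flip <- ifelse(e$bx < 0, -1, 1)
    resid <- e$by * flip - eg@aux$intercept - eg@beta * e$bx * flip
    Q <- sum(w * resid^2)
    df <- e$J - 2
  }
  list(Q = Q, df = df,
       pval = stats::pchisq(Q, df = df, lower.tail = FALSE))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' The intercept of the Egger regression estimates the mean directional
#' pleiotropic effect across instruments; its two-sided p-value (t with
#' J - 2 df) tests the no-directional-pleiotropy null. Flagged when
#' p < 0.05.
#'
#' @param set an \linkS4class{InstrumentSet} with at least 3 instruments.
#' @return list with estimate, se, pval and a logical
#'   \code{directional_pleiotropy} flag.
#' @export
eggerInterceptTest <- function(set) {
  eg <- mrEgger(set)
  list(estimate = eg@aux$intercept, se = eg@aux$intercept_se,
       pval = eg@aux$intercept_pval,
       directional_pleiotropy = eg@aux$intercept_pval < 0.05)
}

## Leave-one-out IVW slopes for all SNPs at once (zero-intercept WLS).
.looSlopes <- function(bx, by, w) {
  sxy <- sum(bx * by * w)
  sxx <- sum(bx^2 * w)
  (sxy - bx * by * w) / (sxx - bx^2 * w)
}

## Core of the PRESSO global and outlier tests: observed and simulated
## weighted residual sums of squares. Returns everything both wrappers
## need so the two tests share one simulation (same set, nSim, seed).
.pressoCore <- function(set, nSim, seed, weighted = TRUE) {
  e <- .effects(set)
  if (e$J < 4L)
    stop("insufficient instruments for MR-PRESSO: need >= 4, got ", e$J)
  w <- if (weighted) 1 / e$sy^2 else rep(1, e$J)
  slopes <- .looSlopes(e$bx, e$by, 1 / e$sy^2)
  resid <- e$by - slopes * e$bx
  rssObs <- sum(w * resid^2)
  sim <- .withSeed(seed, {
    bxs <- matrix(stats::rnorm(e$J * nSim, e$bx, e$sx), nrow = e$J)
    bys <- matrix(stats::rnorm(e$J * nSim, slopes * e$bx, e$sy),
                  nrow = e$J)
    wiv <- 1 / e$sy^2
    sxy <- colSums(bxs * bys * wiv)
    sxx <- colSums(bxs^2 * wiv)
    slopeStar <- (rep(sxy, each = e$J) - bxs * bys * wiv) /
      (rep(sxx, each = e$J) - bxs^2 * wiv)
    residStar <- bys - slopeStar * bxs
    list(rss = colSums(w * residStar^2), resid2 = residStar^2)
  })
  globalP <- (1 + sum(sim$rss >= rssObs)) / (nSim + 1)
  perSnpP <- (1 + rowSums(sim$resid2 >= resid^2)) / (nSim + 1)
  list(globalP = globalP, perSnpP = perSnpP, rssObs = rssObs,
       resid = resid, ids = e$id, J = e$J)
}

#' MR-PRESSO global test
#'
#' Simulation-based test of horizontal pleiotropy: the observed weighted
#' residual sum of squares around leave-one-out IVW fits is compared with
#' its distribution under a no-pleiotropy parametric null (effects
#' redrawn at their observed values and SEs). The p-value uses add-one
#' smoothing, p = (1 + #\{RSS* >= RSS_obs\}) / (nSim + 1), so it is
#' always in (0, 1] and deterministic given (set, nSim, seed).
#'
#' @param set an \linkS4class{InstrumentSet} with at least 4 instruments.
#' @param nSim number of simulated null datasets.
#' @param seed mandatory RNG seed.
#' @param weighted use inverse-variance weighted residuals (default);
#'   FALSE gives the unweighted original.
#' @return the global p-value.
#' @export
pressoGlobal <- function(set, nSim = 1000, seed, weighted = TRUE) {
  if (missing(seed)) stop("seed is mandatory for MR-PRESSO")
  .pressoCore(set, nSim, seed, weighted)$globalP
}

#' MR-PRESSO outlier test
#'
#' Per-SNP p-values are the (add-one smoothed) fraction of simulated
#' squared residuals at least as large as the observed one; SNPs with
#' p_j < alpha / J (Bonferroni) are declared pleiotropic outliers. Uses
#' the same simulation as the global test for the same (set, nSim,
#' seed).
#'
#' @inheritParams pressoGlobal
#' @param alpha family-wise significance level (default 0.05).
#' @return data.frame (snp_id, pval, outlier) for all SNPs; the subset
#'   with \code{outlier = TRUE} are the detected outliers.
#' @export
pressoOutlier <- function(set, nSim = 1000, seed, alpha = 0.05,
                          weighted = TRUE) {
  if (missing(seed)) stop("seed is mandatory for MR-PRESSO")
  core <- .pressoCore(set, nSim, seed, weighted)
  data.frame(snp_id = core$ids, pval = core$perSnpP,
             outlier = core$perSnpP < alpha / core$J,
             stringsAsFactors = FALSE)
}

#' Leave-one-out analysis
#'
#' Re-estimates the IVW causal effect J times, each time omitting one
#' instrument. A SNP is flagged influential when its removal moves the
#' estimate outside the full-set 95% confidence interval (the way
#' leave-one-out plots are read). The reference band uses the
#' fixed-effect interval: a gross outlier inflates the random-effects
#' interval of the full set and would otherwise mask its own influence.
#'
#' @param set an \linkS4class{InstrumentSet} with at least 3 instruments.
#' @param mode IVW mode used for the re-estimates.
#' @return data.frame (snp_id, beta, se, pval, influential) with the
#'   full-set estimate attached as attribute \code{"full"}.
#' @export
leaveOneOut <- function(set, mode = "multiplicative_random") {
  J <- nSnp(set)
  if (J < 3L) stop("insufficient instruments for leave-one-out: need >= 3")
  full <- mrIVW(set, mode = mode)
  seFE <- if (!is.null(full@aux$se_fixed)) full@aux$se_fixed else full@se
  lo <- full@beta - 1.96 * seFE
  hi <- full@beta + 1.96 * seFE
  rows <- lapply(seq_len(J), function(j) {
    sub <- .InstrumentSet(set@snps[-j, , drop = FALSE], set@exposureId,
                          set@outcomeId)
    est <- mrIVW(sub, mode = mode)
    data.frame(snp_id = set@snps$snp_id[j], beta = est@beta, se = est@se,
               pval = est@pval,
               influential = est@beta < lo || est@beta > hi,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "full") <- c(beta = full@beta, se = full@se,
                         pval = full@pval)
  out
}

#' Full sensitivity report
#'
#' Bundles Cochran's Q (IVW), the Egger intercept test, the MR-PRESSO
#' global and outlier tests, and the leave-one-out grid into a
#' \linkS4class{SensitivityReport}. Diagnostics whose preconditions fail
#' on small sets are recorded as NA with the reason in \code{meta}.
#'
#' @param set an \linkS4class{InstrumentSet}.
#' @param nSim MR-PRESSO simulation count.
#' @param seed mandatory RNG seed.
#' @param alpha outlier-test family-wise level.
#' @return a \linkS4class{SensitivityReport}.
#' @export
runSensitivity <- function(set, nSim = 1000, seed, alpha = 0.05) {
  if (missing(seed)) stop("seed is mandatory")
  skipped <- list()
  q <- tryCatch(cochranQ(set), error = function(e) {
    skipped$cochran_q <<- conditionMessage(e)
    list(Q = NA_real_, df = NA_real_, pval = NA_real_)
  })
  ei <- tryCatch(eggerInterceptTest(set), error = function(e) {
    skipped$egger_intercept <<- conditionMessage(e)
    list(estimate = NA_real_, se = NA_real_, pval = NA_real_)
  })
  pres <- tryCatch(pressoOutlier(set, nSim = nSim, seed = seed,
                                 alpha = alpha),
                   error = function(e) {
                     skipped$presso <<- conditionMessage(e)
                     NULL
                   })
  gp <- if (is.null(pres)) NA_real_
  else pressoGlobal(set, nSim = nSim, seed = seed)
  loo <- tryCatch(leaveOneOut(set), error = function(e) {
    skipped$leave_one_out <<- conditionMessage(e)
    data.frame(snp_id = character(), beta = numeric(), se = numeric(),
               pval = numeric(), influential = logical())
  })
  outliers <- if (is.null(pres))
    data.frame(snp_id = character(), pval = numeric())
  else pres[pres$outlier, c("snp_id", "pval"), drop = FALSE]
  rownames(outliers) <- NULL
  new("SensitivityReport", qIvw = q$Q, qDf = as.numeric(q$df),
      qPval = q$pval,
      eggerIntercept = c(estimate = ei$estimate, se = ei$se,
                         pval = ei$pval),
      pressoGlobalP = gp, pressoOutliers = outliers, loo = loo,
      meta = list(n_sim = nSim, seed = seed, alpha = alpha,
                  skipped = skipped))
}
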