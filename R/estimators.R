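## Pull aligned effect vectors out of an InstrumentSet.
.effects <- function(set) {
  sn <- set@snps
  list(bx = sn$beta_exp, sx = sn$se_exp, by = sn$beta_out, sy = sn$se_out,
       id = sn$snp_id, J = nrow(sn))
}

## Two-sided normal p, floored to stay inside (0, 1] at extreme z.
.normP <- function(z) pmax(2 * stats::pnorm(-abs(z)), 1e-300)

## Preserve the caller's RNG state while using a local seed.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Wald ratio: single-instrument causal estimate
#'
#' theta = beta_out / beta_exp with first-order (delta-method) standard
#' error se_out / |beta_exp|; two-sided normal p-value. Invariant to a
#' simultaneous sign flip of both effects (allele re-coding).
#'
#' @param betaExp,seExp SNP-exposure effect and SE.
#' @param betaOut,seOut SNP-outcome effect and SE.
#' @param snpId optional instrument id recorded in \code{aux}.
#' @return an \linkS4class{MREstimate} (method "wald").
#' @export
mrWald <- function(betaExp, seExp, betaOut, seOut, snpId = NULL) {
  if (betaExp == 0) stop("degenerate instrument: beta_exp = 0")
  theta <- betaOut / betaExp
  se <- seOut / abs(betaExp)
  .MREstimate("wald", theta, se, .normP(theta / se), 1L,
              aux = if (is.null(snpId)) list() else list(snp_id = snpId))
}

#' Inverse-variance weighted estimator
#'
#' Combines per-SNP Wald ratios with weights beta_exp^2 / se_out^2;
#' equivalently the zero-intercept weighted regression of outcome on
#' exposure effects. The fixed-effect standard error is
#' (sum beta_exp^2 / se_out^2)^(-1/2); in the default multiplicative
#' random-effects mode it is inflated by max(1, sqrt(Q/(J-1))) where Q is
#' Cochran's heterogeneity statistic, so the reported SE is never below
#' the fixed-effect one. A single-SNP set delegates to the Wald ratio.
#'
#' @param set an \linkS4class{InstrumentSet}.
#' @param mode "multiplicative_random" (default) or "fixed".
#' @return an \linkS4class{MREstimate} with Q, its p-value, the
#'   fixed-effect SE and the mode in \code{aux}.
#' @export
mrIVW <- function(set, mode = c("multiplicative_random", "fixed")) {
  mode <- match.arg(mode)
  e <- .effects(set)
  if (e$J < 1L) stop("empty instrument set")
  if (e$J == 1L)
    return(mrWald(e$bx, e$sx, e$by, e$sy, snpId = e$id))
  if (all(e$bx == 0)) stop("degenerate instrument set: all beta_exp = 0")
  w <- 1 / e$sy^2
  sxx <- sum(e$bx^2 * w)
  beta <- sum(e$bx * e$by * w) / sxx
  seFE <- 1 / sqrt(sxx)
  Q <- sum(w * (e$by - beta * e$bx)^2)
  qPval <- stats::pchisq(Q, df = e$J - 1, lower.tail = FALSE)
  infl <- if (mode == "multiplicative_random")
    max(1, sqrt(Q / (e$J - 1))) else 1
  se <- seFE * infl
  .MREstimate("ivw", beta, se, .normP(beta / se), e$J,
              aux = list(Q = Q, q_pval = qPval, se_fixed = seFE,
                         mode = mode))
}

## Shared weighted least squares for the Egger model (and its
## zero-intercept reduction). Residual scale is floored at 1 so the SE is
## never below the fixed-effect SE.
.eggerWLS <- function(bx, by, w, intercept = TRUE) {
  X <- if (intercept) cbind(`(Intercept)` = 1, bx = bx)
  else cbind(bx = bx)
  XtW <- t(X * w)
  XtWXinv <- solve(XtW %*% X)
  coefs <- drop(XtWXinv %*% XtW %*% by)
  resid <- by - drop(X %*% coefs)
  df <- length(by) - ncol(X)
  scale <- max(1, sum(w * resid^2) / df)
  list(coefs = coefs, cov = scale * XtWXinv, df = df,
       rss = sum(w * resid^2))
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome effects on exposure effects with an
#' unconstrained intercept (weights 1/se_out^2). The slope is the causal
#' estimate, consistent under the InSiDE assumption even when all
#' instruments are pleiotropic; the intercept estimates the mean
#' directional pleiotropic effect. Because the model is not invariant to
#' per-SNP sign flips, every SNP is first re-oriented so that
#' beta_exp >= 0. The residual variance scale is floored at 1. Slope and
#' intercept p-values use the t distribution with J-2 df.
#'
#' @param set an \linkS4class{InstrumentSet} with at least 3 instruments.
#' @param interceptZero fit with the intercept constrained to zero
#'   (diagnostic reduction; reproduces the IVW estimate).
#' @return an \linkS4class{MREstimate} (method "egger") with intercept
#'   estimate/se/pval in \code{aux}.
#' @export
mrEgger <- function(set, interceptZero = FALSE) {
  e <- .effects(set)
  minJ <- if (interceptZero) 2L else 3L
  if (e$J < minJ)
    stop("insufficient instruments for MR-Egger: need >= ", minJ,
         ", got ", e$J)
  flip <- ifelse(e$bx < 0, -1, 1)
  bx <- e$bx * flip
  by <- e$by * flip
  w <- 1 / e$sy^2
  fit <- .eggerWLS(bx, by, w, intercept = !interceptZero)
  if (interceptZero) {
    beta <- fit$coefs[["bx"]]
    se <- sqrt(fit$cov[1, 1])
    return(.MREstimate("egger", beta, se,
                       .normP(beta / se), e$J,
                       aux = list(intercept = 0, constrained = TRUE)))
  }
  beta <- fit$coefs[["bx"]]
  se <- sqrt(fit$cov["bx", "bx"])
  alpha <- fit$coefs[["(Intercept)"]]
  alphaSE <- sqrt(fit$cov["(Intercept)", "(Intercept)"])
  pSlope <- pmax(2 * stats::pt(-abs(beta / se), df = fit$df), 1e-300)
  pAlpha <- pmax(2 * stats::pt(-abs(alpha / alphaSE), df = fit$df), 1e-300)
  .MREstimate("egger", beta, se, pSlope, e$J,
              aux = list(intercept = alpha, intercept_se = alphaSE,
                         intercept_pval = pAlpha,
                         n_reoriented = sum(flip < 0)))
}

#' Weighted median estimator
#'
#' Consistent when instruments carrying at least half of the total weight
#' are valid. Per-SNP Wald ratios theta_j are weighted by the inverse
#' variance of the ratio (w_j = beta_exp^2 / se_out^2, normalized); after
#' sorting by theta the cumulative midpoint percentiles
#' p_j = (S_j - w_j/2) / S_total are linearly interpolated at 0.5. The
#' standard error is the SD of the estimate across \code{nBoot}
#' parametric resamples of the observed effects (seeded; the caller's RNG
#' state is untouched).
#'
#' @param set an \linkS4class{InstrumentSet} with at least 3 instruments.
#' @param nBoot bootstrap resamples for the SE.
#' @param seed mandatory RNG seed.
#' @return an \linkS4class{MREstimate} (method "weighted_median").
#' @export
mrWeightedMedian <- function(set, nBoot = 1000, seed) {
  if (missing(seed)) stop("seed is mandatory for the weighted median")
  e <- .effects(set)
  if (e$J < 3L)
    stop("insufficient instruments for the weighted median: need >= 3")
  est <- .weightedMedianPoint(e$bx, e$by, e$sy)
  boots <- .withSeed(seed, {
    vapply(seq_len(nBoot), function(b) {
      bxb <- stats::rnorm(e$J, e$bx, e$sx)
      byb <- stats::rnorm(e$J, e$by, e$sy)
      .weightedMedianPoint(bxb, byb, e$sy)
    }, 0)
  })
  se <- stats::sd(boots)
  .MREstimate("weighted_median", est, se, .normP(est / se), e$J,
              aux = list(n_boot = nBoot, seed = seed))
}

## Weighted-percentile point estimate of the median ratio.
.weightedMedianPoint <- function(bx, by, sy) {
  theta <- by / bx
  w <- (bx / sy)^2
  w <- w / sum(w)
  ord <- order(theta, method = "radix")
  theta <- theta[ord]
  w <- w[ord]
  pctl <- cumsum(w) - w / 2
  if (0.5 <= pctl[1L]) return(theta[1L])
  if (0.5 >= pctl[length(pctl)]) return(theta[length(theta)])
  stats::approx(pctl, theta, xout = 0.5, ties = "ordered")$y
}

#' Maximum-likelihood estimator
#'
#' Maximizes the joint normal likelihood in which the observed
#' SNP-exposure effects are noisy measurements of true effects gamma_j
#' and the SNP-outcome effects center on beta * gamma_j. Profiling out
#' gamma analytically reduces the problem to minimizing
#' sum (beta_out - beta * beta_exp)^2 / (se_out^2 + beta^2 se_exp^2) over
#' beta; the standard error comes from the observed information
#' (numerical curvature of the profile log-likelihood) at the optimum.
#' With exposure measurement error negligible this coincides with the
#' fixed-effect IVW estimate; its SE is smaller than IVW's when there is
#' no heterogeneity or pleiotropy.
#'
#' @param set an \linkS4class{InstrumentSet}.
#' @param interval search interval for the causal effect.
#' @return an \linkS4class{MREstimate} (method "max_lik").
#' @export
mrMaxLik <- function(set, interval = NULL) {
  e <- .effects(set)
  if (e$J < 1L) stop("empty instrument set")
  if (all(e$bx == 0)) stop("degenerate instrument set: all beta_exp = 0")
  negll <- function(beta)
    0.5 * sum((e$by - beta * e$bx)^2 / (e$sy^2 + beta^2 * e$sx^2))
  if (is.null(interval)) {
    center <- sum(e$bx * e$by / e$sy^2) / sum(e$bx^2 / e$sy^2)
    span <- 10 * (abs(center) + 1)
    interval <- c(center - span, center + span)
  }
  opt <- stats::optimize(negll, interval = interval, tol = 1e-12)
  beta <- opt$minimum
  h <- 1e-5 * (abs(beta) + 1)
  info <- (negll(beta + h) - 2 * negll(beta) + negll(beta - h)) / h^2
  if (!is.finite(info) || info <= 0)
    stop("maximum-likelihood estimation failed: non-positive curvature ",
         "at the optimum (beta = ", signif(beta, 6), ")")
  se <- 1 / sqrt(info)
  .MREstimate("max_lik", beta, se, .normP(beta / se), e$J,
              aux = list(objective = opt$objective))
}

#' Robust adjusted profile score (RAPS) estimator
#'
#' Solves the profile estimating equation
#' sum_j psi(t_j) * d t_j / d beta = 0 with standardized residuals
#' t_j = (beta_out - beta * beta_exp) / sqrt(se_out^2 + beta^2 se_exp^2
#' + tau^2), where psi is the derivative of the chosen loss (identity for
#' l2; Huber with tuning constant 1.345 by default). When
#' \code{overdispersion} is on, tau^2 >= 0 is estimated jointly from the
#' second estimating equation sum_j (psi(t_j) t_j - delta) / sigma_j^2 =
#' 0 with the consistency constant delta = E[psi(Z) Z] under N(0,1)
#' (2*Phi(c)-1 for Huber); tau^2 is pinned at 0 when the data are
#' underdispersed. The standard error is the sandwich estimate. This
#' accommodates systematic (overdispersed) and idiosyncratic (outlying)
#' pleiotropy and remains stable with many weak instruments.
#'
#' @param set an \linkS4class{InstrumentSet} with at least 3 instruments.
#' @param loss "huber" (default) or "l2".
#' @param overdispersion estimate tau^2 (default TRUE).
#' @param huberC Huber tuning constant.
#' @param maxIter,tol convergence controls.
#' @return an \linkS4class{MREstimate} (method "raps") with tau^2 and
#'   convergence diagnostics in \code{aux}.
#' @export
mrRAPS <- function(set, loss = c("huber", "l2"), overdispersion = TRUE,
                   huberC = 1.345, maxIter = 100, tol = 1e-10) {
  loss <- match.arg(loss)
  e <- .effects(set)
  if (e$J < 3L)
    stop("insufficient instruments for RAPS: need >= 3, got ", e$J)
  psi <- if (loss == "l2") function(t) t
  else function(t) pmin(huberC, pmax(-huberC, t))
  delta <- if (loss == "l2") 1 else 2 * stats::pnorm(huberC) - 1

  scoreBeta <- function(beta, tau2) {
    sig2 <- e$sy^2 + beta^2 * e$sx^2 + tau2
    sig <- sqrt(sig2)
    t <- (e$by - beta * e$bx) / sig
    dt <- -e$bx / sig - t * beta * e$sx^2 / sig2
    sum(psi(t) * dt)
  }
  scoreTau <- function(beta, tau2) {
    sig2 <- e$sy^2 + beta^2 * e$sx^2 + tau2
    t <- (e$by - beta * e$bx) / sqrt(sig2)
    sum((psi(t) * t - delta) / sig2)
  }
  solveBeta <- function(beta0, tau2) {
    span <- abs(beta0) + 1
    lo <- beta0 - span; hi <- beta0 + span
    flo <- scoreBeta(lo, tau2); fhi <- scoreBeta(hi, tau2)
    tries <- 0
    while (sign(flo) == sign(fhi) && tries < 40) {
      span <- span * 2
      lo <- beta0 - span; hi <- beta0 + span
      flo <- scoreBeta(lo, tau2); fhi <- scoreBeta(hi, tau2)
      tries <- tries + 1
    }
    if (sign(flo) == sign(fhi))
      stop("RAPS failed to bracket a root of the estimating equation ",
           "(loss = ", loss, ", tau2 = ", signif(tau2, 4), ")")
    stats::uniroot(scoreBeta, c(lo, hi), tau2 = tau2,
                   tol = 1e-12)$root
  }
  solveTau <- function(beta) {
    if (scoreTau(beta, 0) <= 0) return(0)
    hi <- stats::var(e$by - beta * e$bx) + max(e$sy^2)
    tries <- 0
    while (scoreTau(beta, hi) > 0 && tries < 40) {
      hi <- hi * 4; tries <- tries + 1
    }
    stats::uniroot(scoreTau, c(0, hi), beta = beta, tol = 1e-14)$root
  }

  beta <- sum(e$bx * e$by / e$sy^2) / sum(e$bx^2 / e$sy^2)
  tau2 <- 0
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    betaNew <- solveBeta(beta, tau2)
    tau2New <- if (overdispersion) solveTau(betaNew) else 0
    done <- abs(betaNew - beta) < tol && abs(tau2New - tau2) < tol
    beta <- betaNew; tau2 <- tau2New
    if (done) { converged <- TRUE; break }
  }
  if (!converged)
    stop("RAPS did not converge after ", maxIter,
         " iterations (beta = ", signif(beta, 6), ", tau2 = ",
         signif(tau2, 6), ")")

  ## sandwich variance: A^-1 B A^-T with A the score slope in beta
  sig2 <- e$sy^2 + beta^2 * e$sx^2 + tau2
  sig <- sqrt(sig2)
  t <- (e$by - beta * e$bx) / sig
  dt <- -e$bx / sig - t * beta * e$sx^2 / sig2
  B <- sum((psi(t) * dt)^2)
  h <- 1e-6 * (abs(beta) + 1)
  A <- (scoreBeta(beta + h, tau2) - scoreBeta(beta - h, tau2)) / (2 * h)
  if (!is.finite(A) || A == 0)
    stop("RAPS sandwich variance failed: flat estimating equation")
  se <- sqrt(B) / abs(A)
  .MREstimate("raps", beta, se, .normP(beta / se), e$J,
              aux = list(tau2 = tau2, tau2_pinned = (overdispersion &&
                                                       tau2 == 0),
                         loss = loss, overdispersion = overdispersion,
                         iterations = it))
}

#' Run all five estimators on one instrument set
#'
#' Applies, in fixed order, IVW, maximum likelihood, weighted median,
#' RAPS and MR-Egger. Methods whose preconditions fail (too few
#' instruments) are reported as skipped estimates carrying the reason in
#' \code{aux$skipped}, never silently omitted.
#'
#' @param set an \linkS4class{InstrumentSet}.
#' @param seed mandatory seed (weighted-median bootstrap).
#' @param nBoot weighted-median bootstrap resamples.
#' @param ivwMode IVW mode, see \code{\link{mrIVW}}.
#' @param rapsLoss,rapsOverdispersion RAPS options, see
#'   \code{\link{mrRAPS}}.
#' @return named list of \linkS4class{MREstimate}s:
#'   ivw, max_lik, weighted_median, raps, egger.
#' @export
mrAll <- function(set, seed, nBoot = 1000,
                  ivwMode = "multiplicative_random",
                  rapsLoss = "huber", rapsOverdispersion = TRUE) {
  if (missing(seed)) stop("seed is mandatory")
  J <- nSnp(set)
  tooFew <- paste0("n_snp < 3 (got ", J, ")")
  res <- list(
    ivw = mrIVW(set, mode = ivwMode),
    max_lik = mrMaxLik(set),
    weighted_median = if (J >= 3)
      mrWeightedMedian(set, nBoot = nBoot, seed = seed)
    else .skippedEstimate("weighted_median", tooFew),
    raps = if (J >= 3)
      tryCatch(mrRAPS(set, loss = rapsLoss,
                      overdispersion = rapsOverdispersion),
               error = function(e2)
                 .skippedEstimate("raps", conditionMessage(e2)))
    else .skippedEstimate("raps", tooFew),
    egger = if (J >= 3) mrEgger(set)
    else .skippedEstimate("egger", tooFew))
  res
}
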