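## Independent oracles and small fixture builders used across tests.
## These deliberately avoid the package's own code paths.

## Random harmonized instrument set on realistic scales.
randomSet <- function(J, seed, betaTrue = 0.2, sx = 0.012, sy = 0.01) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    bx <- rnorm(J, 0.15, 0.05) * sample(c(-1, 1), J, replace = TRUE)
    bx[abs(bx) < 0.02] <- 0.05
    sxv <- rep_len(sx, J) * runif(J, 0.8, 1.2)
    syv <- rep_len(sy, J) * runif(J, 0.8, 1.2)
    by <- betaTrue * bx + rnorm(J, 0, syv)
    makeInstrumentSet(bx, sxv, by, syv)
  })
}

## Zero-intercept weighted least squares via the stats::lm fitter.
oracleIVW <- function(set) {
  sn <- instruments(set)
  fit <- stats::lm(beta_out ~ 0 + beta_exp, data = sn,
                   weights = 1 / sn$se_out^2)
  unname(stats::coef(fit)[1])
}

## Egger WLS via stats::lm (intercept + slope), with the same
## residual-scale floor convention.
oracleEgger <- function(set) {
  sn <- instruments(set)
  flip <- ifelse(sn$beta_exp < 0, -1, 1)
  d <- data.frame(bx = sn$beta_exp * flip, by = sn$beta_out * flip,
                  w = 1 / sn$se_out^2)
  fit <- stats::lm(by ~ bx, data = d, weights = w)
  s2 <- max(1, sum(d$w * stats::resid(fit)^2) / (nrow(d) - 2))
  v <- s2 * chol2inv(chol(t(cbind(1, d$bx) * d$w) %*% cbind(1, d$bx)))
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       slope_se = sqrt(v[2, 2]), intercept_se = sqrt(v[1, 1]))
}

## Brute-force weighted-percentile median: walk the sorted ratios and
## interpolate at the 0.5 midpoint percentile by hand.
oracleWeightedMedian <- function(bx, by, sy) {
  theta <- by / bx
  w <- (bx / sy)^2
  w <- w / sum(w)
  o <- order(theta)
  theta <- theta[o]; w <- w[o]
  S <- 0
  p <- numeric(length(w))
  for (j in seq_along(w)) {
    p[j] <- S + w[j] / 2
    S <- S + w[j]
  }
  if (0.5 <= p[1]) return(theta[1])
  if (0.5 >= p[length(p)]) return(theta[length(theta)])
  j <- max(which(p < 0.5))
  theta[j] + (theta[j + 1] - theta[j]) * (0.5 - p[j]) / (p[j + 1] - p[j])
}

## Grid-search profile-likelihood oracle for the ML estimator.
oracleMaxLik <- function(set, lo, hi, n = 200001) {
  sn <- instruments(set)
  grid <- seq(lo, hi, length.out = n)
  obj <- vapply(grid, function(b)
    sum((sn$beta_out - b * sn$beta_exp)^2 /
          (sn$se_out^2 + b^2 * sn$se_exp^2)), 0)
  grid[which.min(obj)]
}

## Brute-force greedy clumping, written independently of the package.
oracleClump <- function(df, r2pairs, r2Max, windowKb) {
  keep <- character(0)
  claimed <- rep(FALSE, nrow(df))
  while (any(!claimed)) {
    i <- which(!claimed)[which.min(df$pval[!claimed])]
    keep <- c(keep, df$snp_id[i])
    claimed[i] <- TRUE
    for (j in which(!claimed)) {
      if (df$chrom[j] != df$chrom[i]) next
      if (abs(df$pos[j] - df$pos[i]) > windowKb * 1000) next
      key <- paste(sort(c(df$snp_id[i], df$snp_id[j])), collapse = "|")
      r2 <- if (key %in% names(r2pairs)) r2pairs[[key]] else 0
      if (r2 >= r2Max) claimed[j] <- TRUE
    }
  }
  df[df$snp_id %in% keep, , drop = FALSE]
}

## Plain data.frame of summary stats for I/O and selection tests.
statsFrame <- function(snp_id, beta, se, pval, chrom = "1",
                       pos = seq_along(snp_id) * 1e6,
                       effect_allele = "A", other_allele = "G",
                       eaf = 0.3, n = 10000) {
  data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
             effect_allele = effect_allele, other_allele = other_allele,
             eaf = eaf, beta = beta, se = se, pval = pval, n = n,
             stringsAsFactors = FALSE)
}
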