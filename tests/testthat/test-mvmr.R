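test_that("multivariable IVW recovers exact linear direct effects", {
  set.seed(1)
  J <- 20
  X <- cbind(e1 = runif(J, 0.05, 0.3), e2 = runif(J, 0.05, 0.3))
  y <- 0.5 * X[, 1] - 0.2 * X[, 2]
  fit <- mvmrIVW(list(betaExp = X, betaOut = y, seOut = rep(0.01, J)))
  expect_equal(fit$e1@beta, 0.5, tolerance = 1e-10)
  expect_equal(fit$e2@beta, -0.2, tolerance = 1e-10)
})

test_that("K = 1 multivariable IVW equals the univariable estimator", {
  s <- randomSet(15, seed = 33)
  sn <- instruments(s)
  fit <- mvmrIVW(list(betaExp = cbind(x = sn$beta_exp),
                      betaOut = sn$beta_out, seOut = sn$se_out))
  uni <- mrIVW(s)
  expect_equal(fit$x@beta, uni@beta, tolerance = 1e-12)
  expect_equal(fit$x@se, uni@se, tolerance = 1e-12)
})

test_that("collinear and zero exposure columns are handled distinctly", {
  set.seed(2)
  J <- 12
  x <- runif(J, 0.05, 0.3)
  y <- 0.4 * x + rnorm(J, 0, 0.01)
  ## duplicated column: collinearity error naming the column
  expect_error(mvmrIVW(list(betaExp = cbind(a = x, b = x),
                            betaOut = y, seOut = rep(0.01, J))),
               "collinear.*b")
  ## all-zero confounder column: adjusted estimate equals univariable
  fit <- mvmrIVW(list(betaExp = cbind(a = x, b = rep(0, J)),
                      betaOut = y, seOut = rep(0.01, J)))
  uni <- mrIVW(makeInstrumentSet(x, 0.01, y, rep(0.01, J)))
  expect_equal(fit$a@beta, uni@beta, tolerance = 1e-12)
  expect_false(is.finite(fit$b@beta))
  ## under-identification
  expect_error(mvmrIVW(list(betaExp = cbind(a = x[1:2], b = x[1:2] + 1),
                            betaOut = y[1:2], seOut = rep(0.01, 2))),
               "under-identified")
})

test_that("joint instrument selection unions, clumps and harmonizes", {
  ## two exposures with disjoint 20-SNP instrument sets, all present in
  ## every dataset: a 40-row matrix
  sig1 <- sprintf("rsA%02d", 1:20)
  sig2 <- sprintf("rsB%02d", 1:20)
  all40 <- c(sig1, sig2)
  pos40 <- seq(1e6, by = 15e6, length.out = 40)
  frame <- function(pvals) statsFrame(all40, beta = 0.15, se = 0.012,
                                      pval = pvals, chrom = "1",
                                      pos = pos40)
  ex1 <- GwasDataset(frame(c(rep(1e-8, 20), rep(0.5, 20))), "gm")
  ex2 <- GwasDataset(frame(c(rep(0.5, 20), rep(1e-8, 20))), "bmi")
  outd <- GwasDataset(frame(rep(0.5, 40)), "gh")
  mat <- selectMvInstruments(list(ex1, ex2), outd)
  expect_equal(nSnp(mat), 40L)
  expect_equal(exposureId(mat), c("gm", "bmi"))

  ## a SNP absent from the confounder dataset is dropped with the
  ## dataset named
  ex2b <- ex2
  ex2b@stats <- ex2b@stats[ex2b@stats$snp_id != "rsA01", , drop = FALSE]
  mat2 <- selectMvInstruments(list(ex1, ex2b), outd)
  expect_equal(nSnp(mat2), 39L)
  pr <- provenance(mat2)
  expect_match(pr$reason[pr$snp_id == "rsA01"], "absent in exposure 2")

  ## joint clumping of two SNPs in LD keeps the smaller min-p
  snp4 <- c("s1", "s2", "s3", "s4")
  pos4 <- c(1e6, 1.2e6, 30e6, 60e6)
  exA <- GwasDataset(statsFrame(snp4, beta = 0.15, se = 0.012,
                                pval = c(1e-8, 0.5, 1e-9, 1e-7),
                                chrom = "1", pos = pos4), "e1")
  exB <- GwasDataset(statsFrame(snp4, beta = 0.15, se = 0.012,
                                pval = c(0.5, 1e-6, 0.5, 0.5),
                                chrom = "1", pos = pos4), "e2")
  outAB <- GwasDataset(statsFrame(snp4, beta = 0, se = 0.012,
                                  pval = 0.5, chrom = "1", pos = pos4),
                       "o")
  ld <- LDSource(data.frame(SNP_A = "s1", SNP_B = "s2", R2 = 0.5))
  mat3 <- selectMvInstruments(list(exA, exB), outAB, ld)
  ## s1 (min p 1e-8) beats s2 (min p 1e-6); s3 and s4 independent
  expect_setequal(mat3@snpId, c("s1", "s3", "s4"))
})

test_that("simulated two-exposure data recover both direct effects", {
  nrep <- 100
  b1 <- b2 <- numeric(nrep)
  for (k in 1:nrep) {
    tr <- SimulationTruth(betaTrue = 0.3, J = 150, nDecoy = 0,
                          nSatellite = 0, seed = 8000 + k)
    sim <- simulateMv(tr, betaConf = -0.2, overlap = 0.2)
    ex <- summaryStats(sim$exposure)
    cf <- summaryStats(sim$confounder)
    out <- summaryStats(sim$outcome)
    fit <- mvmrIVW(list(betaExp = cbind(x1 = ex$beta, x2 = cf$beta),
                        betaOut = out$beta, seOut = out$se))
    b1[k] <- fit$x1@beta
    b2[k] <- fit$x2@beta
  }
  expect_lt(abs(mean(b1) - 0.3), 3 * sd(b1) / sqrt(nrep) + 0.005)
  expect_lt(abs(mean(b2) + 0.2), 3 * sd(b2) / sqrt(nrep) + 0.005)
  ## null confounder: adjusted and unadjusted estimates agree
  tr <- SimulationTruth(betaTrue = 0.3, J = 150, nDecoy = 0,
                        nSatellite = 0, seed = 8500)
  sim0 <- simulateMv(tr, betaConf = 0, overlap = 0)
  ex <- summaryStats(sim0$exposure)
  cf <- summaryStats(sim0$confounder)
  out <- summaryStats(sim0$outcome)
  adj <- mvmrIVW(list(betaExp = cbind(x1 = ex$beta, x2 = cf$beta),
                      betaOut = out$beta, seOut = out$se))$x1@beta
  unadj <- mvmrIVW(list(betaExp = cbind(x1 = ex$beta),
                        betaOut = out$beta, seOut = out$se))$x1@beta
  expect_lt(abs(adj - unadj), 0.02)
})
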