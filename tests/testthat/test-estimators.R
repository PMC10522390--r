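test_that("Wald ratio follows the delta method and is sign-invariant", {
  e <- mrWald(0.1, 0.02, 0.02, 0.01)
  expect_equal(e@beta, 0.2)
  expect_equal(e@se, 0.1)
  expect_equal(e@orValue, exp(0.2))
  neg <- mrWald(-0.1, 0.02, -0.02, 0.01)
  expect_equal(neg@beta, e@beta)
  expect_error(mrWald(0, 0.02, 0.02, 0.01), "degenerate")
})

test_that("IVW equals the weighted normal-equation solution", {
  set <- makeInstrumentSet(c(0.1, 0.2, 0.15), 0.01,
                           c(0.02, 0.05, 0.03), c(0.01, 0.01, 0.015))
  e <- mrIVW(set, mode = "fixed")
  ## weights bx^2/sy^2 = 100, 400, 100; beta = 140/600
  expect_equal(e@beta, 140 / 600, tolerance = 1e-12)
  expect_equal(e@se, 1 / sqrt(600))
  expect_equal(e@beta, oracleIVW(set), tolerance = 1e-10)
  ## random sets: oracle agreement to 1e-10, both modes share the slope
  for (seed in 1:8) {
    s <- randomSet(sample(3:30, 1), seed = seed)
    expect_equal(mrIVW(s)@beta, oracleIVW(s), tolerance = 1e-10)
    expect_equal(mrIVW(s, "fixed")@beta, mrIVW(s)@beta)
  }
})

test_that("IVW degenerates gracefully: identical ratios and single SNPs", {
  set <- makeInstrumentSet(c(0.1, 0.2, 0.4), 0.01,
                           0.3 * c(0.1, 0.2, 0.4), 0.01)
  e <- mrIVW(set)
  expect_equal(e@beta, 0.3)
  expect_equal(e@aux$Q, 0)
  expect_equal(e@se, e@aux$se_fixed)  # inflation floored at 1
  one <- makeInstrumentSet(0.1, 0.02, 0.02, 0.01)
  expect_equal(mrIVW(one)@beta, mrWald(0.1, 0.02, 0.02, 0.01)@beta)
  expect_equal(mrIVW(one)@method, "wald")
})

test_that("multiplicative random-effects SE inflates by sqrt(Q/(J-1))", {
  s <- randomSet(12, seed = 5, sy = 0.002)  # heterogeneous
  fe <- mrIVW(s, "fixed")
  mre <- mrIVW(s)
  expect_gte(mre@se, fe@se)
  expect_equal(mre@se, fe@se * max(1, sqrt(mre@aux$Q / (nSnp(s) - 1))))
})

test_that("Egger recovers exact affine data and matches the WLS oracle", {
  bx <- c(0.1, 0.2, 0.3, 0.4, 0.25)
  set <- makeInstrumentSet(bx, 0.01, 0.03 + 0.5 * bx, 0.01)
  e <- mrEgger(set)
  expect_equal(e@beta, 0.5, tolerance = 1e-10)
  expect_equal(e@aux$intercept, 0.03, tolerance = 1e-10)
  expect_error(mrEgger(makeInstrumentSet(c(0.1, 0.2), 0.01,
                                         c(0.02, 0.05), 0.01)),
               "insufficient")
  for (seed in 1:5) {
    s <- randomSet(sample(4:25, 1), seed = 100 + seed, sy = 0.002)
    got <- mrEgger(s)
    want <- oracleEgger(s)
    expect_equal(got@beta, want$slope, tolerance = 1e-10)
    expect_equal(got@aux$intercept, want$intercept, tolerance = 1e-10)
    expect_equal(got@se, want$slope_se, tolerance = 1e-10)
    expect_equal(got@aux$intercept_se, want$intercept_se,
                 tolerance = 1e-10)
  }
})

test_that("zero-intercept Egger reproduces IVW exactly", {
  for (seed in 1:5) {
    s <- randomSet(sample(3:20, 1), seed = 200 + seed)
    con <- mrEgger(s, interceptZero = TRUE)
    ivw <- mrIVW(s)
    expect_equal(con@beta, ivw@beta, tolerance = 1e-12)
    expect_equal(con@se, ivw@se, tolerance = 1e-12)
  }
})

test_that("weighted median matches the brute-force percentile definition", {
  ## equal weights, ratios {0.1, 0.2, 0.9}: midpoint percentile 0.5
  ## falls exactly on the middle ratio
  set <- makeInstrumentSet(c(1, 1, 1), 0.01, c(0.1, 0.2, 0.9), 0.01)
  wm <- mrWeightedMedian(set, nBoot = 50, seed = 1)
  expect_equal(wm@beta, 0.2, tolerance = 1e-12)
  ## all ratios equal
  setc <- makeInstrumentSet(c(0.1, 0.2, 0.3), 0.01,
                            0.4 * c(0.1, 0.2, 0.3), c(0.01, 0.02, 0.03))
  expect_equal(mrWeightedMedian(setc, nBoot = 20, seed = 1)@beta, 0.4,
               tolerance = 1e-12)
  for (seed in 1:10) {
    s <- randomSet(sample(3:40, 1), seed = 300 + seed)
    sn <- instruments(s)
    got <- mrWeightedMedian(s, nBoot = 2, seed = 1)@beta
    expect_equal(got,
                 oracleWeightedMedian(sn$beta_exp, sn$beta_out, sn$se_out),
                 tolerance = 1e-12)
    ## median boundedness
    theta <- sn$beta_out / sn$beta_exp
    expect_gte(got, min(theta))
    expect_lte(got, max(theta))
  }
  ## bootstrap SE is deterministic under a fixed seed
  s <- randomSet(10, seed = 9)
  expect_identical(mrWeightedMedian(s, nBoot = 200, seed = 42)@se,
                   mrWeightedMedian(s, nBoot = 200, seed = 42)@se)
  expect_error(mrWeightedMedian(s, nBoot = 10), "seed")
})

test_that("maximum likelihood profiles to the ratio and to IVW limits", {
  ## noiseless data with negligible exposure error recovers beta exactly
  bx <- c(0.1, 0.2, 0.3)
  set <- makeInstrumentSet(bx, 1e-9, 0.4 * bx, 0.01)
  expect_equal(mrMaxLik(set)@beta, 0.4, tolerance = 1e-8)
  ## negligible exposure error: agrees with fixed-effect IVW
  s <- randomSet(15, seed = 7)
  sn <- instruments(s)
  s2 <- makeInstrumentSet(sn$beta_exp, 1e-8 * sn$se_out, sn$beta_out,
                          sn$se_out)
  expect_equal(mrMaxLik(s2)@beta, mrIVW(s2, "fixed")@beta,
               tolerance = 1e-6)
  ## single SNP: profile reduces to the Wald ratio
  one <- makeInstrumentSet(0.12, 0.015, 0.03, 0.01)
  expect_equal(mrMaxLik(one)@beta, 0.03 / 0.12, tolerance = 1e-6)
  ## grid-search oracle on a moderate set
  s3 <- randomSet(10, seed = 8)
  got <- mrMaxLik(s3)@beta
  want <- oracleMaxLik(s3, got - 0.01, got + 0.01)
  expect_equal(got, want, tolerance = 1e-5)
})

test_that("RAPS handles overdispersion and resists gross outliers", {
  ## exact data: zero residuals pin tau2 at 0
  bx <- c(0.1, 0.2, 0.3, 0.15)
  set <- makeInstrumentSet(bx, 0.01, 0.3 * bx, 0.01)
  e <- mrRAPS(set)
  expect_equal(e@beta, 0.3, tolerance = 1e-6)
  expect_equal(e@aux$tau2, 0)
  expect_true(e@aux$tau2_pinned)
  ## clean simulation: close to truth and to IVW
  tr <- SimulationTruth(betaTrue = 0.25, J = 100, nDecoy = 0,
                        nSatellite = 0, seed = 31)
  s <- simInstrumentSet(simulateSummaryStats(tr))
  ivw <- mrIVW(s)
  rp <- mrRAPS(s)
  expect_lt(abs(rp@beta - 0.25), 4 * rp@se)
  expect_lt(abs(rp@beta - ivw@beta), 0.02)
  ## paired comparison: with one gross outlier, huber RAPS beats IVW
  wins <- 0L
  for (k in 1:20) {
    trk <- SimulationTruth(betaTrue = 0.25, J = 30, nDecoy = 0,
                           nSatellite = 0, seed = 600 + k)
    sk <- simInstrumentSet(simulateSummaryStats(trk))
    sn <- instruments(sk)
    sn$beta_out[1] <- sn$beta_out[1] + 10 * sn$se_out[1]
    sk2 <- makeInstrumentSet(sn$beta_exp, sn$se_exp, sn$beta_out,
                             sn$se_out)
    if (abs(mrRAPS(sk2, loss = "huber")@beta - 0.25) <
        abs(mrIVW(sk2)@beta - 0.25)) wins <- wins + 1L
  }
  expect_gte(wins, 16L)
})

test_that("estimators are invariant to per-SNP allele sign flips", {
  for (seed in 1:5) {
    s <- randomSet(12, seed = 400 + seed)
    sn <- instruments(s)
    set.seed(seed)
    flip <- sample(c(-1, 1), 12, replace = TRUE)
    s2 <- makeInstrumentSet(sn$beta_exp * flip, sn$se_exp,
                            sn$beta_out * flip, sn$se_out)
    expect_equal(mrIVW(s2)@beta, mrIVW(s)@beta, tolerance = 1e-12)
    expect_equal(mrWeightedMedian(s2, nBoot = 2, seed = 1)@beta,
                 mrWeightedMedian(s, nBoot = 2, seed = 1)@beta,
                 tolerance = 1e-12)
    expect_equal(mrMaxLik(s2)@beta, mrMaxLik(s)@beta, tolerance = 1e-8)
    expect_equal(mrRAPS(s2)@beta, mrRAPS(s)@beta, tolerance = 1e-8)
    expect_equal(mrEgger(s2)@beta, mrEgger(s)@beta, tolerance = 1e-12)
    expect_equal(mrEgger(s2)@aux$intercept, mrEgger(s)@aux$intercept,
                 tolerance = 1e-12)
  }
})

test_that("mrAll reports five methods with skip reasons, never omissions", {
  s <- randomSet(10, seed = 21)
  all5 <- mrAll(s, seed = 77)
  expect_named(all5, c("ivw", "max_lik", "weighted_median", "raps",
                       "egger"))
  expect_true(all(vapply(all5, function(e) is.finite(e@beta), TRUE)))
  ## two instruments: only ivw and max_lik computable
  s2 <- makeInstrumentSet(c(0.1, 0.2), 0.01, c(0.02, 0.05), 0.01)
  part <- mrAll(s2, seed = 77)
  expect_true(is.finite(part$ivw@beta))
  expect_true(is.finite(part$max_lik@beta))
  for (m in c("weighted_median", "raps", "egger")) {
    expect_false(is.finite(part[[m]]@beta))
    expect_match(part[[m]]@aux$skipped, "n_snp < 3")
  }
  ## weighted-median SE identical across runs under the same seed
  expect_identical(mrAll(s, seed = 5)$weighted_median@se,
                   mrAll(s, seed = 5)$weighted_median@se)
})
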