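test_that("the generator is deterministic and leaves the caller's RNG alone", {
  tr <- SimulationTruth(betaTrue = 0.2, J = 15, seed = 5)
  a <- simulateSummaryStats(tr)
  set.seed(999)
  probe1 <- rnorm(1)
  set.seed(999)
  b <- simulateSummaryStats(tr)
  probe2 <- rnorm(1)
  expect_identical(summaryStats(a$exposure), summaryStats(b$exposure))
  expect_identical(summaryStats(a$outcome), summaryStats(b$outcome))
  expect_identical(a$ld@r2, b$ld@r2)
  expect_identical(probe1, probe2)  # generator did not consume the stream
  expect_error(SimulationTruth(betaTrue = 0.2), "seed")
})

test_that("generated tables pass validation with zero rejections", {
  tr <- SimulationTruth(betaTrue = 0.1, J = 25, propInvalid = 0.2,
                        muAlpha = 0.03, seed = 6)
  sim <- simulateSummaryStats(tr, nLowMaf = 1, nPalindromic = 1)
  expect_equal(nrow(provenance(sim$exposure)), 0L)
  expect_equal(nrow(provenance(sim$outcome)), 0L)
  ## round trip through the text reader stays valid
  tf <- tempfile(fileext = ".tsv")
  utils::write.table(summaryStats(sim$exposure), tf, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  back <- readSummaryStats(tf, traitId = "rt")
  expect_equal(nrow(summaryStats(back)), nrow(summaryStats(sim$exposure)))
  expect_equal(nrow(provenance(back)), 0L)
})

test_that("analytic SEs and instrument strength match the design", {
  tr <- SimulationTruth(betaTrue = 0, J = 60, nDecoy = 0, nSatellite = 0,
                        seed = 8)
  sim <- simulateSummaryStats(tr)
  ex <- summaryStats(sim$exposure)
  out <- summaryStats(sim$outcome)
  expect_equal(ex$se, 1 / sqrt(2 * ex$eaf * (1 - ex$eaf) * 18340),
               tolerance = 1e-12)
  neff <- 4 / (1 / 7686 + 1 / 115893)
  expect_equal(out$se, 1 / sqrt(2 * out$eaf * (1 - out$eaf) * neff),
               tolerance = 1e-12)
  ## true F confined to the configured window
  fTrue <- (sim$perSnp$gamma / ex$se[match(sim$perSnp$snp_id,
                                           ex$snp_id)])^2
  expect_true(all(fTrue >= 140 - 1e-9 & fTrue <= 245 + 1e-9))
  ## observed F scatters around the window but clears the weak-IV screen
  fObs <- (ex$beta / ex$se)^2
  expect_true(all(fObs > 10))
})

test_that("allele scrambling is invisible after harmonization", {
  tr <- SimulationTruth(betaTrue = 0.25, J = 30, nDecoy = 50, seed = 14)
  sim <- simulateSummaryStats(tr)
  base <- mrIVW(selectInstruments(sim$exposure, sim$outcome, sim$ld))

  sc <- scrambleAlleles(sim$exposure, pSwap = 1, seed = 3)
  expect_setequal(sc$swapped, summaryStats(sim$exposure)$snp_id)
  expect_equal(summaryStats(sc$dataset)$beta,
               -summaryStats(sim$exposure)$beta)
  flipped <- mrIVW(selectInstruments(sc$dataset, sim$outcome, sim$ld))
  expect_equal(flipped@beta, base@beta, tolerance = 1e-12)
  expect_equal(flipped@se, base@se, tolerance = 1e-12)

  ## partial swaps too
  sc2 <- scrambleAlleles(sim$exposure, pSwap = 0.5, seed = 4)
  half <- mrIVW(selectInstruments(sc2$dataset, sim$outcome, sim$ld))
  expect_equal(half@beta, base@beta, tolerance = 1e-12)

  ## identity scramble
  sc0 <- scrambleAlleles(sim$exposure, 0, 0, seed = 5)
  expect_identical(summaryStats(sc0$dataset),
                   summaryStats(sim$exposure))
  expect_length(sc0$swapped, 0L)
})

test_that("palindromized SNPs are exactly the step-3 drops", {
  tr <- SimulationTruth(betaTrue = 0.05, J = 100, nDecoy = 0,
                        nSatellite = 0, seed = 22)
  sim <- simulateSummaryStats(tr)
  sc <- scrambleAlleles(sim$exposure, pPalindrome = 0.2, seed = 9)
  set <- selectInstruments(sc$dataset, sim$outcome, sim$ld)
  prov <- provenance(set)
  dropped <- prov$snp_id[prov$step == "maf_palindrome"]
  expect_setequal(dropped, sc$palindromized)
  expect_equal(nSnp(set), 100L - length(sc$palindromized))
})

test_that("reverse-causation universes give the outcome its own loci", {
  tr <- SimulationTruth(betaTrue = 0, J = 10, JOut = 12,
                        reverseBeta = 0.3, nDecoy = 20, nSatellite = 0,
                        seed = 33)
  sim <- simulateSummaryStats(tr)
  ## reverse analysis: outcome as exposure at genome-wide significance
  revSet <- selectInstruments(sim$outcome, sim$exposure, sim$ld,
                              SelectionConfig(pThreshold = 5e-8))
  outLoci <- sim$perSnp$snp_id[sim$perSnp$role == "outcome_instrument"]
  expect_setequal(instruments(revSet)$snp_id, outLoci)
  est <- mrIVW(revSet)
  expect_lt(abs(est@beta - 0.3), 4 * est@se)
})

test_that("two-exposure simulation recovers its own bookkeeping", {
  tr <- SimulationTruth(betaTrue = 0.3, J = 40, nDecoy = 0,
                        nSatellite = 0, seed = 44)
  sim <- simulateMv(tr, betaConf = -0.2, overlap = 0.5)
  ps <- sim$perSnp
  expect_equal(sum(ps$shared), 20L)
  expect_equal(nrow(ps), 60L)
  expect_identical(
    summaryStats(simulateMv(tr, betaConf = -0.2,
                            overlap = 0.5)$confounder),
    summaryStats(sim$confounder))
  ## truth reconstruction: Gamma = b1 * gamma1 + b2 * gamma2
  expect_equal(ps$Gamma, 0.3 * ps$gamma1 - 0.2 * ps$gamma2,
               tolerance = 1e-12)
})
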