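test_that("p-value filtering uses a strict threshold and preserves order", {
  df <- statsFrame(c("a", "b", "c"), beta = 0.1, se = 0.02,
                   pval = c(1e-6, 2e-5, 5e-6))
  expect_equal(filterByPvalue(df, 1e-5)$snp_id, c("a", "c"))
  ## boundary: p exactly equal to the threshold is excluded
  df2 <- statsFrame("d", beta = 0.1, se = 0.02, pval = 1e-5)
  expect_equal(nrow(filterByPvalue(df2, 1e-5)), 0L)
  expect_equal(formals(filterByPvalue)$threshold, 1e-5)
})

test_that("greedy clumping keeps index SNPs and matches a brute-force oracle", {
  df <- statsFrame(c("A", "B", "C"), beta = 0.1, se = 0.02,
                   pval = c(1e-8, 1e-6, 1e-7), chrom = "1",
                   pos = c(1e6, 1e6 + 5e4, 1e6 + 1e5))
  ld <- LDSource(data.frame(SNP_A = c("A", "A"), SNP_B = c("B", "C"),
                            R2 = c(0.5, 0.0005)))
  out <- clumpVariants(df, ld, r2Max = 0.001, windowKb = 10000)
  expect_setequal(out$snp_id, c("A", "C"))

  ## all pairwise r2 below the cutoff: everything retained
  ldLow <- LDSource(data.frame(SNP_A = c("A", "A", "B"),
                               SNP_B = c("B", "C", "C"), R2 = 1e-4))
  expect_equal(nrow(clumpVariants(df, ldLow, 0.001, 10000)), 3L)

  ## different chromosomes, no LD entry: both retained, no warning
  df2 <- statsFrame(c("x", "y"), beta = 0.1, se = 0.02,
                    pval = c(1e-8, 1e-7), chrom = c("1", "2"),
                    pos = c(1e6, 1e6))
  expect_silent(out2 <- clumpVariants(df2, LDSource(), 0.001, 10000))
  expect_equal(nrow(out2), 2L)

  ## property: agreement with an independent greedy implementation
  for (seed in 1:5) {
    set.seed(seed)
    n <- 12
    df3 <- statsFrame(paste0("s", 1:n), beta = 0.1, se = 0.02,
                      pval = runif(n, 1e-9, 1e-5),
                      chrom = sample(c("1", "2"), n, replace = TRUE),
                      pos = sample(seq(1e6, 9e6, by = 5e5), n))
    pairs <- t(combn(df3$snp_id, 2))
    r2 <- runif(nrow(pairs))^2
    ld3 <- LDSource(data.frame(SNP_A = pairs[, 1], SNP_B = pairs[, 2],
                               R2 = r2))
    r2named <- setNames(as.list(r2),
                        apply(pairs, 1, function(p)
                          paste(sort(p), collapse = "|")))
    got <- clumpVariants(df3, ld3, r2Max = 0.3, windowKb = 2000)
    want <- oracleClump(df3, r2named, r2Max = 0.3, windowKb = 2000)
    expect_setequal(got$snp_id, want$snp_id)
  }
})

test_that("rare and palindromic SNPs are excluded, missing eaf passes MAF", {
  df <- statsFrame(paste0("s", 1:4), beta = 0.1, se = 0.02, pval = 1e-6,
                   effect_allele = c("A", "A", "A", "C"),
                   other_allele = c("G", "T", "G", "G"),
                   eaf = c(0.005, 0.3, 0.5, NA))
  out <- filterFreqAndPalindromes(df, mafMin = 0.01)
  ## s1 rare, s2 palindromic (A/T), s4 palindromic (C/G) despite NA eaf
  expect_equal(out$snp_id, "s3")
})

test_that("outcome-associated instruments are removed at a strict cutoff", {
  ex <- statsFrame(c("a", "b", "c", "d"), beta = 0.1, se = 0.02,
                   pval = 1e-6)
  out <- statsFrame(c("a", "b", "c"), beta = 0.01, se = 0.01,
                    pval = c(1e-9, 1e-4, 5e-8))
  kept <- filterOutcomeAssociated(ex, out, outcomeP = 5e-8)
  ## a dropped; c exactly at the cutoff kept; d absent passes through
  expect_setequal(kept$snp_id, c("b", "c", "d"))
})

test_that("proxy search maximizes r2 with distance then rsID tie-breaks", {
  cand <- statsFrame(c("p1", "p2", "p3"), beta = 0.1, se = 0.02,
                     pval = 0.5, pos = c(1.01e6, 1.05e6, 2e6))
  ld <- LDSource(data.frame(SNP_A = c("m", "m", "m"),
                            SNP_B = c("p1", "p2", "p3"),
                            R2 = c(0.85, 0.85, 0.9)),
                 pos = c(m = 1e6))
  got <- findProxies("m", ld, cand, proxyR2 = 0.8)
  expect_equal(unname(got["m"]), "p3")  # max r2 wins
  ## drop the 0.9 candidate: equal r2, nearer SNP wins
  ld2 <- LDSource(data.frame(SNP_A = c("m", "m"), SNP_B = c("p1", "p2"),
                             R2 = c(0.85, 0.85)), pos = c(m = 1e6))
  expect_equal(unname(findProxies("m", ld2, cand, 0.8)["m"]), "p1")
  ## best candidate below the (strict) threshold: no mapping
  ld3 <- LDSource(data.frame(SNP_A = "m", SNP_B = "p1", R2 = 0.7))
  expect_length(findProxies("m", ld3, cand, 0.8), 0L)
  ld4 <- LDSource(data.frame(SNP_A = "m", SNP_B = "p1", R2 = 0.8))
  expect_length(findProxies("m", ld4, cand, 0.8), 0L)
})

test_that("F statistics follow the squared z-score with an r2 variant", {
  expect_equal(fStatistic(0.1, 0.02), 25)
  expect_equal(fStatistic(0.05, 0.02), 6.25)
  expect_equal(fStatistic(0, 0.02), 0)
  expect_error(fStatistic(0.1, 0.02, method = "r2"), "requires")
  f2 <- fStatistic(0.1, 0.02, eaf = 0.3, n = 10000, method = "r2")
  r2 <- 2 * 0.3 * 0.7 * 0.01
  expect_equal(f2, (10000 - 2) * r2 / (1 - r2))
})

test_that("harmonization aligns, flips or drops allele pairs", {
  ex <- list(effect_allele = "A", other_allele = "G", beta = 0.10,
             se = 0.02, eaf = 0.4)
  same <- harmonizePair(ex, list(effect_allele = "A", other_allele = "G",
                                 beta = 0.05, se = 0.01, eaf = 0.4))
  expect_equal(same$status, "same")
  expect_equal(same$beta_out, 0.05)
  flip <- harmonizePair(ex, list(effect_allele = "G", other_allele = "A",
                                 beta = 0.05, se = 0.01, eaf = 0.3))
  expect_equal(flip$status, "flip")
  expect_equal(flip$beta_out, -0.05)
  expect_equal(flip$eaf_out, 0.7)
  bad <- harmonizePair(ex, list(effect_allele = "A", other_allele = "C",
                                beta = 0.05, se = 0.01, eaf = 0.3))
  expect_equal(bad$status, "drop")
  expect_equal(bad$reason, "allele mismatch")
  ## harmonizing an already-harmonized pair changes nothing (involution)
  again <- harmonizePair(ex, list(effect_allele = "A", other_allele = "G",
                                  beta = same$beta_out, se = 0.01,
                                  eaf = 0.4))
  expect_equal(again$beta_out, same$beta_out)
})

test_that("full selection keeps clean instruments and is idempotent", {
  tr <- SimulationTruth(betaTrue = 0.1, J = 50, seed = 77)
  sim <- simulateSummaryStats(tr)
  set <- selectInstruments(sim$exposure, sim$outcome, sim$ld)
  expect_equal(nSnp(set), 50L)
  expect_true(all(instruments(set)$f_stat >= 10))
  ## provenance: every dropped SNP appears exactly once
  prov <- provenance(set)
  expect_false(anyDuplicated(prov$snp_id) > 0)
  expect_setequal(c(prov$snp_id, instruments(set)$snp_id),
                  summaryStats(sim$exposure)$snp_id)

  ## idempotence: selection restricted to its own output reproduces it
  keep <- instruments(set)$snp_id
  ex2 <- sim$exposure
  ex2@stats <- ex2@stats[ex2@stats$snp_id %in% keep, , drop = FALSE]
  set2 <- selectInstruments(ex2, sim$outcome, sim$ld)
  expect_equal(instruments(set2)$snp_id, instruments(set)$snp_id)
  expect_equal(instruments(set2)$beta_out, instruments(set)$beta_out)
})

test_that("selection is monotone under threshold tightening", {
  tr <- SimulationTruth(betaTrue = 0, J = 30, nDecoy = 100, seed = 91)
  sim <- simulateSummaryStats(tr)
  base <- SelectionConfig()
  loose <- selectInstruments(sim$exposure, sim$outcome, sim$ld, base)
  tighter <- list(
    SelectionConfig(pThreshold = 1e-8),
    SelectionConfig(mafMin = 0.2),
    SelectionConfig(fMin = 180))
  for (cfg in tighter) {
    got <- tryCatch(
      instruments(selectInstruments(sim$exposure, sim$outcome, sim$ld,
                                    cfg))$snp_id,
      error = function(e) character(0))
    expect_true(all(got %in% instruments(loose)$snp_id))
  }
})

test_that("an all-palindromic exposure fails with the step identified", {
  df <- statsFrame(paste0("s", 1:5), beta = 0.15, se = 0.012, pval = 1e-9,
                   effect_allele = "A", other_allele = "T",
                   pos = seq(1e6, 9e7, length.out = 5) )
  ex <- GwasDataset(df, traitId = "pal")
  out <- GwasDataset(statsFrame(paste0("s", 1:5), beta = 0, se = 0.01,
                                pval = 0.5), traitId = "o")
  expect_error(selectInstruments(ex, out),
               "maf_palindrome")
})

test_that("instruments missing from the outcome are proxied or dropped", {
  tr <- SimulationTruth(betaTrue = 0.1, J = 10, seed = 13)
  sim <- simulateSummaryStats(tr, nMissingOutcome = 2, nMissingNoProxy = 2)
  set <- selectInstruments(sim$exposure, sim$outcome, sim$ld)
  prov <- provenance(set)
  noProxy <- sim$perSnp$snp_id[sim$perSnp$fate == "no_proxy"]
  proxied <- sim$perSnp$snp_id[sim$perSnp$fate == "proxied"]
  expect_setequal(prov$snp_id[prov$reason == "no proxy"], noProxy)
  expect_setequal(prov$snp_id[grepl("^substituted by proxy", prov$reason)],
                  proxied)
  ## the substituted proxies are satellites of the missing instruments
  subs <- prov$reason[grepl("^substituted by proxy", prov$reason)]
  expect_true(all(grepl("_sat", subs)))
})
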