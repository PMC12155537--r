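test_that("site prevalence counts binary detection per group", {
  fx <- workedFixture()
  rec <- sitePrevalence(fx$cohort)
  expect_equal(nrow(rec), 8L)                        # every detected site
  expect_equal(rec$k_tumor, fx$kT)
  expect_equal(rec$k_adjacent, fx$kA)
  expect_equal(rec$n_tumor, rep(10L, 8))
  expect_equal(rec$prev_tumor, fx$kT / 10)
  ## a site detected nowhere never enters the roster
  detect <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  cohort <- cohortFromDetection(detect, c(10, 20),
                                c("tumor", "adjacent"))
  expect_equal(sitePrevalence(cohort)$pos, 10)
})

test_that("prevalence filter is inclusive at the 40% boundary, on either group", {
  fx <- workedFixture()
  rec <- prevalenceFilter(sitePrevalence(fx$cohort))
  expect_equal(rec$pos, fx$pos[-7])                  # only 0.3/0.3 removed
  expect_true(all(rec$passes_prevalence_filter))
  ## 0.40 exactly is retained (site 3: 4/10 in both groups)
  expect_true(3000 %in% rec$pos)
  expect_error(prevalenceFilter(rec, minPrevalence = 1.5), "\\[0, 1\\]")
})

test_that("ratios, zero-guard and Z-scores reproduce hand arithmetic to 1e-9", {
  fx <- workedFixture()
  rec <- zscoreRatios(prevalenceRatio(prevalenceFilter(
    sitePrevalence(fx$cohort))))
  ## expected values from the detection counts by direct arithmetic
  kT <- fx$kT[-7]; kA <- fx$kA[-7]
  num <- ifelse(kT == 0, 0.5 / 10, kT / 10)
  den <- ifelse(kA == 0, 0.5 / 10, kA / 10)
  ratio <- num / den
  expect_equal(rec$ratio, ratio, tolerance = 1e-12)
  expect_equal(rec$ratio[1], 18)                     # 0.9 / (0.5/10)
  v <- log2(ratio)
  m <- sum(v) / 7
  s <- sqrt(sum((v - m)^2) / 6)
  expect_lt(max(abs(rec$z - (v - m) / s)), 1e-9)
  expect_lt(abs(rec$z[1] - 2.251303), 1e-5)
  ## standardization identity
  expect_lt(abs(mean(rec$z)), 1e-9)
  expect_lt(abs(sd(rec$z) - 1), 1e-9)
})

test_that("candidate selection needs both |z| > threshold and NAT overlap", {
  fx <- workedFixture()
  rec <- zscoreRatios(prevalenceRatio(prevalenceFilter(
    sitePrevalence(fx$cohort))))
  nat <- makeAnn("nat", c(900, 3900), c(1100, 4100), strand = "-")
  cand <- selectCandidates(rec, nat, zThreshold = 1.96)
  expect_s4_class(cand, "CandidateList")
  expect_equal(candidateRecords(cand)$pos, 1000)     # only the guarded site
  ## same z but no NAT cover: rejected
  natFar <- makeAnn("nat", 5e5, 5e5 + 100)
  expect_equal(length(selectCandidates(rec, natFar)), 0L)
  ## at a permissive threshold both NAT-covered sites come out, |z| ordered
  both <- candidateRecords(selectCandidates(rec, nat, zThreshold = 0.3))
  expect_equal(both$pos, c(1000, 4000))
  expect_true(all(diff(abs(both$z)) <= 0))
  ## z exactly at the threshold is rejected (strict inequality)
  recEq <- rec; recEq$z[2] <- 1.96
  natAll <- makeAnn("nat", fx$pos - 10, fx$pos + 10)
  selEq <- candidateRecords(selectCandidates(recEq, natAll,
                                             zThreshold = 1.96))
  expect_false(2000 %in% selEq$pos)
  expect_error(selectCandidates(rec, makeAnn("alu", 1, 10)), "nat")
})

test_that("degenerate and small record sets are handled", {
  fx <- workedFixture()
  rec <- prevalenceRatio(prevalenceFilter(sitePrevalence(fx$cohort)))
  expect_error(zscoreRatios(rec[1:2, ]), ">= 3")
  flat <- rec; flat$ratio <- 2; flat$log2_ratio <- 1
  expect_warning(z <- zscoreRatios(flat), "equal")
  expect_equal(z$z, rep(0, nrow(z)))
})

test_that("swapping group labels inverts ratios, including the zero-guard", {
  fx <- workedFixture()
  swapped <- lapply(fx$cohort, function(x) {
    initialize(x, group = ifelse(sampleGroup(x) == "tumor",
                                 "adjacent", "tumor"))
  })
  a <- prevalenceRatio(prevalenceFilter(sitePrevalence(fx$cohort)))
  b <- prevalenceRatio(prevalenceFilter(sitePrevalence(swapped)))
  expect_equal(b$log2_ratio, -a$log2_ratio, tolerance = 1e-12)
})

test_that("candidate sets shrink as thresholds tighten", {
  fx <- workedFixture()
  nat <- makeAnn("nat", fx$pos - 10, fx$pos + 10)
  sizes <- vapply(c(0, 0.2, 0.5, 1, 2.3), function(zt) {
    length(prioritizeSites(fx$cohort, nat, zThreshold = zt))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
  prevSizes <- vapply(c(0, 0.3, 0.4, 0.55), function(mp) {
    rec <- prevalenceFilter(sitePrevalence(fx$cohort), mp)
    nrow(rec)
  }, numeric(1))
  expect_true(all(diff(prevSizes) <= 0))
})

test_that("strand-aware NAT mode requires antisense orientation", {
  fx <- workedFixture()
  rec <- zscoreRatios(prevalenceRatio(prevalenceFilter(
    sitePrevalence(fx$cohort))))
  ## calls are '+'; an antisense NAT is '-'
  natAnti <- makeAnn("nat", 900, 1100, strand = "-")
  natSense <- makeAnn("nat", 900, 1100, strand = "+")
  expect_equal(length(selectCandidates(rec, natAnti, strandAware = TRUE)),
               1L)
  expect_equal(length(selectCandidates(rec, natSense, strandAware = TRUE)),
               0L)
})

test_that("subtype intersection works on (chrom, pos)", {
  mk <- function(pos) new("CandidateList",
    records = data.frame(chrom = "chr7", pos = pos,
                         z = rep(3, length(pos))),
    subtype = "ER+", minPrevalence = 0.4, zThreshold = 1.96)
  shared <- intersectSubtypes(mk(c(77056248, 123)), mk(c(77056248, 456)))
  expect_equal(shared, data.frame(chrom = "chr7", pos = 77056248))
  expect_equal(nrow(intersectSubtypes(mk(1:3), mk(4:6))), 0L)
  expect_equal(nrow(intersectSubtypes(mk(1:3), mk(1:3))), 3L)
})

test_that("planted differential sites are recovered in a sparse-signal cohort", {
  ## 8 planted among 2000 sites: the standardization set is dominated by
  ## background, the regime where a global Z cutoff has discriminating power
  for (seed in c(1, 2)) {
    cfg <- cohortSimConfig(nTumor = 25, nAdjacent = 20, nSites = 2000,
                           nPlanted = 8, plantedPrevTumor = 0.9,
                           plantedPrevAdjacent = 0.05, seed = seed)
    sim <- simulateCohort(cfg)
    filt <- filterCohort(sim$cohort, sim$alu, sim$snps)$cohort
    rec <- candidateRecords(prioritizeSites(filt, sim$nat,
                                            subtype = "ER+"))
    truthP <- sim$truth$pos[sim$truth$planted]
    tp <- sum(rec$pos %in% truthP)
    expect_gte(tp / length(truthP), 0.85)
    expect_lte((nrow(rec) - tp) / max(1, nrow(rec)), 0.5)
    ## recovered planted sites all sit on the enrichment side
    expect_true(all(rec$z[rec$pos %in% truthP] > 0))
  }
})
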