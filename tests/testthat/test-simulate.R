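test_that("cohort simulation honors the cardinality contract and seeding", {
  cfg <- cohortSimConfig(nTumor = 20, nAdjacent = 15, nSites = 200,
                         nPlanted = 5, seed = 7)
  sim <- simulateCohort(cfg)
  expect_length(sim$cohort, 35L)
  expect_equal(nrow(sim$manifest), 35L)
  expect_equal(sum(sim$manifest$group == "tumor"), 20L)
  expect_equal(nrow(sim$truth), 200L)
  expect_equal(sum(sim$truth$planted), 5L)
  expect_error(cohortSimConfig(nSites = 10, nPlanted = 11), "nPlanted")
})

test_that("same config and seed give byte-identical output trees", {
  cfg <- cohortSimConfig(nTumor = 4, nAdjacent = 3, nSites = 60,
                         nPlanted = 2, seed = 12)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulateCohort(cfg, outDir = d1)
  simulateCohort(cfg, outDir = d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  ## and the emitted files reload into the same in-memory cohort
  sim <- simulateCohort(cfg)
  reread <- loadCohort(file.path(d1, "manifest.tsv"))
  expect_identical(as.data.frame(callRanges(sim$cohort[[1]])),
                   as.data.frame(callRanges(reread[[1]])))
})

test_that("degenerate planted prevalences give all-or-nothing detection", {
  cfg <- cohortSimConfig(nTumor = 12, nAdjacent = 9, nSites = 50,
                         nPlanted = 3, plantedPrevTumor = 1,
                         plantedPrevAdjacent = 0, seed = 3)
  sim <- simulateCohort(cfg)
  planted <- sim$truth$pos[sim$truth$planted]
  for (x in sim$cohort) {
    hit <- planted %in% GenomicRanges::start(callRanges(x))
    if (sampleGroup(x) == "tumor") expect_true(all(hit))
    else expect_false(any(hit))
  }
})

test_that("empirical detection frequency converges to configured prevalence", {
  cfg <- cohortSimConfig(nTumor = 500, nAdjacent = 500, nSites = 80,
                         nPlanted = 4, plantedPrevTumor = 0.7,
                         plantedPrevAdjacent = 0.25, seed = 17)
  sim <- simulateCohort(cfg)
  rec <- sitePrevalence(sim$cohort)
  m <- match(rec$pos, sim$truth$pos)
  tol <- 4 * sqrt(0.25 / 500) + 0.01        # binomial 4-sigma envelope
  expect_lt(max(abs(rec$prev_tumor - sim$truth$true_prev_tumor[m])), tol)
  expect_lt(max(abs(rec$prev_adjacent - sim$truth$true_prev_adjacent[m])),
            tol)
})

test_that("edited-site counts track sequencing depth under constant burden", {
  cfg <- cohortSimConfig(nTumor = 60, nAdjacent = 2, nSites = 600,
                         nPlanted = 0, burdenPerMillion = 2,
                         depthSdLog = 0.6, seed = 23)
  sim <- simulateCohort(cfg)
  b <- burdenCounts(sim$cohort)
  bt <- b[b$group == "tumor", ]
  expect_gt(cor(bt$mapped_reads, bt$raw_count), 0.5)
})

test_that("truth table and emitted annotations are mutually consistent", {
  cfg <- cohortSimConfig(nTumor = 3, nAdjacent = 3, nSites = 400,
                         nPlanted = 10, seed = 29)
  sim <- simulateCohort(cfg)
  sites <- GenomicRanges::GRanges(sim$truth$chrom,
                                  IRanges::IRanges(sim$truth$pos, width = 1))
  inAlu <- GenomicRanges::countOverlaps(
    sites, annotationRanges(sim$alu), ignore.strand = TRUE) > 0
  expect_identical(inAlu, sim$truth$in_alu)
  inNat <- GenomicRanges::countOverlaps(
    sites, annotationRanges(sim$nat), ignore.strand = TRUE) > 0
  expect_identical(inNat, sim$truth$in_nat)
  isSnp <- GenomicRanges::countOverlaps(
    sites, annotationRanges(sim$snps), ignore.strand = TRUE) > 0
  expect_identical(isSnp, sim$truth$is_snp)
  ## planted sites are always Alu-resident, SNP-free, NAT-overlapped
  expect_true(all(sim$truth$in_alu[sim$truth$planted]))
  expect_true(all(sim$truth$in_nat[sim$truth$planted]))
  expect_false(any(sim$truth$is_snp[sim$truth$planted]))
})

test_that("decay series encode exp(-lambda t) in Ct space", {
  ct <- simulateDecaySeries(tHalfHours = 4, noiseSd = 0)
  rel <- ddct(ct, "target", "reference", calibratorTimepoint = 0)
  expect_equal(rel$fold_change[rel$timepoint_hours == 0], 1)
  expect_equal(rel$fold_change[rel$timepoint_hours == 8], 0.25,
               tolerance = 1e-12)                    # two half-lives
  expect_equal(rel$fold_change,
               exp(-log(2) / 4 * rel$timepoint_hours),
               tolerance = 1e-12)
  ## replicate structure and determinism under seed
  ct3 <- simulateDecaySeries(2, noiseSd = 0.05, nReplicates = 3, seed = 1)
  expect_equal(nrow(ct3), 2 * 3 * 7)                 # 2 genes x 3 reps x 7 t
  expect_identical(ct3, simulateDecaySeries(2, noiseSd = 0.05,
                                            nReplicates = 3, seed = 1))
  expect_error(simulateDecaySeries(-1), "positive")
  expect_error(simulateDecaySeries(2, timepoints = c(1, 2)), "include 0")
})
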