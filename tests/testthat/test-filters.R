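test_that("editing-type filter enumerates the strand rule correctly", {
  pairs <- data.frame(
    ref = c("A", "T", "T", "A", "G"),
    alt = c("G", "C", "C", "G", "A"),
    strand = c("+", "-", "+", "-", "+"),
    keepStrict = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    keepLenient = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  cs <- makeCallSet(pos = (1:5) * 100, ref = pairs$ref, alt = pairs$alt,
                    strand = pairs$strand)
  strict <- filterEditingType(cs)
  expect_equal(length(strict), sum(pairs$keepStrict))
  expect_equal(GenomicRanges::start(callRanges(strict)),
               (1:5 * 100)[pairs$keepStrict])
  lenient <- filterEditingType(cs, lenient = TRUE)
  expect_equal(length(lenient), sum(pairs$keepLenient))
})

test_that("Alu overlap respects half-open BED boundaries", {
  ## call at 0-based [100, 101) = 1-based position 101
  cs <- makeCallSet(101)
  bedCases <- list(list(bed = "chrS\t50\t150", keep = TRUE),   # containment
                   list(bed = "chrS\t0\t100", keep = FALSE),   # half-open end
                   list(bed = "chrS\t100\t200", keep = TRUE))  # left-closed
  for (case in bedCases) {
    f <- withr::local_tempfile(fileext = ".bed")
    writeLines(case$bed, f)
    alu <- readIntervalBed(f, "alu")
    expect_equal(length(filterAluOverlap(cs, alu)), as.integer(case$keep))
  }
  expect_error(filterAluOverlap(cs, makeAnn("nat", 1, 10)), "alu")
})

test_that("SNP exclusion needs an allelic match by default, position-only as option", {
  cs <- makeCallSet(100)                       # A>G call at 100
  agSnp <- makeAnn("snp", 100, name = "A>G")
  ctSnp <- makeAnn("snp", 100, name = "C>T")
  expect_equal(length(filterSnpOverlap(cs, agSnp)$calls), 0L)
  expect_equal(length(filterSnpOverlap(cs, ctSnp)$calls), 1L)
  expect_equal(length(filterSnpOverlap(cs, ctSnp, allelic = FALSE)$calls),
               0L)
  expect_error(filterSnpOverlap(cs, makeAnn("alu", 1, 10)), "snp")
})

test_that("excluded fraction is exact arithmetic", {
  cs <- makeCallSet(seq_len(1000) * 10)
  snp <- makeAnn("snp", seq_len(10) * 10, name = "A>G")
  res <- filterSnpOverlap(cs, snp)
  expect_equal(res$report$input_count, 1000)
  expect_equal(res$report$excluded_count, 10)
  expect_equal(res$report$excluded_fraction, 0.010)
})

test_that("filter chain retains exactly the clean calls on the disjoint fixture", {
  ## 10 calls: 2 non-AG/TC, 3 outside Alu, 1 AG-SNP coincident, 4 clean
  pos <- (1:10) * 1000
  ref <- c("C", "G", rep("A", 8))
  alt <- c("T", "A", rep("G", 8))
  cs <- makeCallSet(pos, ref = ref, alt = alt)
  aluCovered <- c(1, 2, 6, 7, 8, 9, 10)       # 3,4,5 fall outside Alu
  alu <- makeAnn("alu", pos[aluCovered] - 50, pos[aluCovered] + 50)
  snp <- makeAnn("snp", pos[6], name = "A>G") # call 6 coincides with AG SNP
  res <- applyFilterChain(cs, alu, snp)
  expect_equal(length(res$calls), 4L)
  expect_equal(GenomicRanges::start(callRanges(res$calls)), pos[7:10])
  expect_equal(res$report$stage,
               c("editing_type", "alu_overlap", "snp_overlap"))
  ## count conservation at every stage
  expect_equal(res$report$input_count,
               res$report$retained_count + res$report$excluded_count)
  expect_equal(res$report$retained_count, c(8, 5, 4))
  ## stage ledger: each stage consumes the previous stage's output
  expect_equal(res$report$input_count[-1],
               res$report$retained_count[-3])
})

test_that("the chain is idempotent and monotone", {
  set.seed(5)
  pos <- sort(sample(1e5, 200))
  strand <- sample(c("+", "-"), 200, replace = TRUE)
  ref <- sample(c("A", "T", "C"), 200, replace = TRUE)
  alt <- ifelse(ref == "A", "G", ifelse(ref == "T", "C", "A"))
  cs <- makeCallSet(pos, ref = ref, alt = alt, strand = strand)
  aluStart <- sort(sample(1e5, 40))
  alu <- makeAnn("alu", start = aluStart,
                 end = aluStart + sample(50:500, 40, replace = TRUE))
  snp <- makeAnn("snp", sample(pos, 20), name = "A>G")
  r1 <- applyFilterChain(cs, alu, snp)
  r2 <- applyFilterChain(r1$calls, alu, snp)
  expect_identical(as.data.frame(callRanges(r1$calls)),
                   as.data.frame(callRanges(r2$calls)))
  expect_equal(r2$report$excluded_count, c(0, 0, 0))
  ## monotone: output positions are a subset of input positions
  expect_true(all(GenomicRanges::start(callRanges(r1$calls)) %in% pos))
})

test_that("interval overlap matches an all-pairs brute-force oracle", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(50:300, 1)
    pos <- sort(sample(1e5, n))
    chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
    ni <- sample(10:100, 1)
    ivStart <- sample(1e5, ni)
    ivEnd <- ivStart + sample(0:500, ni, replace = TRUE)
    ivChrom <- sample(c("chr1", "chr2"), ni, replace = TRUE)
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1),
      strand = "+", refBase = "A", altBase = "G",
      supportingReads = 1L, totalReads = 5L)
    gr <- BiocGenerics::sort(gr, ignore.strand = TRUE)
    cs <- EditingCallSet("S", gr)
    alu <- AnnotationSet(GenomicRanges::GRanges(
      ivChrom, IRanges::IRanges(ivStart, ivEnd)), "alu")
    kept <- filterAluOverlap(cs, alu)
    grs <- callRanges(cs)
    expected <- bruteOverlap(GenomicRanges::start(grs),
                             as.character(GenomicRanges::seqnames(grs)),
                             ivStart, ivEnd, ivChrom)
    expect_equal(length(kept), sum(expected))
    expect_equal(GenomicRanges::start(callRanges(kept)),
                 GenomicRanges::start(grs)[expected])
  }
})

test_that("Alu and SNP stages commute on disjoint criteria", {
  pos <- (1:20) * 500
  cs <- makeCallSet(pos)
  alu <- makeAnn("alu", pos[1:12] - 10, pos[1:12] + 10)
  snp <- makeAnn("snp", pos[15:17], name = "A>G")  # disjoint from non-Alu set
  a <- filterSnpOverlap(filterAluOverlap(cs, alu), snp)$calls
  b <- filterAluOverlap(filterSnpOverlap(cs, snp)$calls, alu)
  expect_identical(as.data.frame(callRanges(a)), as.data.frame(callRanges(b)))
})
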