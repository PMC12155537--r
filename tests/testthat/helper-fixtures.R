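## Fixture builders shared across the suite. Everything is generated in
## code; nothing is read from stored data files.

## A call set from parallel vectors; defaults give canonical A-to-I calls.
makeCallSet <- function(pos, ref = "A", alt = "G", strand = "+",
                        sup = 5L, tot = 10L, chrom = "chrS",
                        sampleId = "S1", group = NA_character_,
                        subtype = NA_character_, mappedReads = NA_real_) {
  n <- length(pos)
  gr <- GenomicRanges::GRanges(
    rep(chrom, length.out = n),
    IRanges::IRanges(pos, width = 1),
    strand = rep(strand, length.out = n),
    refBase = rep(ref, length.out = n),
    altBase = rep(alt, length.out = n),
    supportingReads = as.integer(rep(sup, length.out = n)),
    totalReads = as.integer(rep(tot, length.out = n)))
  EditingCallSet(sampleId, gr, group = group, subtype = subtype,
                 mappedReads = mappedReads)
}

## Annotation set from 1-based closed coordinates.
makeAnn <- function(kind, start, end = start, name = ".",
                    strand = "*", chrom = "chrS") {
  n <- length(start)
  gr <- GenomicRanges::GRanges(
    rep(chrom, length.out = n),
    IRanges::IRanges(start, end),
    strand = rep(strand, length.out = n),
    name = rep(name, length.out = n))
  AnnotationSet(gr, kind)
}

## Cohort whose per-site detection pattern is given explicitly:
## `detect` is a (site x sample) logical matrix; positions are 1-based.
cohortFromDetection <- function(detect, pos, groups,
                                subtype = "ER+", mappedReads = 1e7,
                                strand = "+") {
  stopifnot(nrow(detect) == length(pos), ncol(detect) == length(groups))
  ids <- sprintf("S%03d", seq_len(ncol(detect)))
  out <- lapply(seq_len(ncol(detect)), function(j) {
    makeCallSet(pos[detect[, j]], strand = strand, sampleId = ids[j],
                group = groups[j], subtype = subtype,
                mappedReads = mappedReads)
  })
  names(out) <- ids
  out
}

## Brute-force all-pairs single-base overlap oracle (1-based, closed).
bruteOverlap <- function(pos, chrom, ivStart, ivEnd, ivChrom) {
  vapply(seq_along(pos), function(i) {
    any(ivChrom == chrom[i] & ivStart <= pos[i] & ivEnd >= pos[i])
  }, logical(1))
}

## Exhaustive Mann-Whitney oracle: the exact two-sided p for the observed
## U, from full enumeration of rank subsets (tie-free inputs only).
mwuEnumOracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  stopifnot(!anyDuplicated(c(x, y)))
  U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- utils::combn(N, n1)
  us <- apply(splits, 2, function(s) sum(s) - n1 * (n1 + 1) / 2)
  pLo <- mean(us <= U1)
  pHi <- mean(us >= U1)
  list(U = U1, pValue = min(1, 2 * min(pLo, pHi)))
}

## Hand-built worked cohort: 8 sites, 10 tumor + 10 adjacent samples, with
## per-site detection counts chosen to exercise the prevalence boundary,
## the zero-guard and the Z-score arithmetic.
workedFixture <- function() {
  kT <- c(9, 5, 4, 5, 6, 5, 3, 4)
  kA <- c(0, 5, 4, 6, 5, 5, 3, 5)
  pos <- (1:8) * 1000
  detect <- matrix(FALSE, 8, 20)
  for (s in 1:8) {
    detect[s, seq_len(kT[s])] <- TRUE               # tumor samples 1..10
    detect[s, 10 + seq_len(kA[s])] <- TRUE          # adjacent samples 11..20
  }
  groups <- rep(c("tumor", "adjacent"), each = 10)
  list(cohort = cohortFromDetection(detect, pos, groups),
       pos = pos, kT = kT, kA = kA)
}
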