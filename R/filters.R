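## Per-sample editing-call filter chain: editing-type strand consistency,
## Alu-overlap retention, SNP-overlap exclusion. Each stage is monotone
## (output is a subset of input) and audited: input = retained + excluded.

stageRow <- function(stage, input, retained) {
  data.frame(stage = stage,
             input_count = input,
             retained_count = retained,
             excluded_count = input - retained,
             excluded_fraction = if (input > 0) (input - retained) / input
                                 else 0,
             stringsAsFactors = FALSE)
}

#' Retain A-to-I-consistent editing events
#'
#' A-to-I editing appears as A>G on the plus strand and T>C on the minus
#' strand. The strict rule retains exactly those two (base-change, strand)
#' pairs; \code{lenient = TRUE} retains any A>G or T>C call regardless of
#' strand.
#'
#' @param x an \linkS4class{EditingCallSet}.
#' @param lenient ignore strand when matching the base change.
#' @return A filtered \linkS4class{EditingCallSet} (order preserved).
#' @export
filterEditingType <- function(x, lenient = FALSE) {
  stopifnot(is(x, "EditingCallSet"))
  gr <- callRanges(x)
  ag <- mcols(gr)$refBase == "A" & mcols(gr)$altBase == "G"
  tc <- mcols(gr)$refBase == "T" & mcols(gr)$altBase == "C"
  keep <- if (lenient) ag | tc
          else (ag & as.character(strand(gr)) == "+") |
               (tc & as.character(strand(gr)) == "-")
  initialize(x, calls = gr[keep])
}

#' Retain calls overlapping Alu repeats
#'
#' Overlap is strand-agnostic: a single-base call either lies inside an Alu
#' interval or it does not, and repeat annotation strand is irrelevant to
#' that question.
#'
#' @param x an \linkS4class{EditingCallSet}.
#' @param alu an \linkS4class{AnnotationSet} of kind \code{"alu"}.
#' @return A filtered \linkS4class{EditingCallSet}.
#' @export
filterAluOverlap <- function(x, alu) {
  stopifnot(is(x, "EditingCallSet"), is(alu, "AnnotationSet"))
  if (annotationKind(alu) != "alu")
    stop("expected an AnnotationSet of kind 'alu', got '",
         annotationKind(alu), "'")
  gr <- callRanges(x)
  keep <- countOverlaps(gr, annotationRanges(alu), ignore.strand = TRUE) > 0
  initialize(x, calls = gr[keep])
}

#' Exclude calls coinciding with known SNPs
#'
#' By default a call is removed only when its position carries a SNP whose
#' allele pair is \code{A>G} or \code{T>C} (the pairs indistinguishable from
#' A-to-I edits in sequence data); SNPs of other types at the position do
#' not trigger removal. \code{allelic = FALSE} removes on position alone.
#'
#' @param x an \linkS4class{EditingCallSet}.
#' @param snps an \linkS4class{AnnotationSet} of kind \code{"snp"}.
#' @param allelic require the SNP allele pair to be A>G or T>C.
#' @return \code{list(calls = <filtered EditingCallSet>, report = <one-row
#'   stage data.frame>)} with the excluded fraction.
#' @export
filterSnpOverlap <- function(x, snps, allelic = TRUE) {
  stopifnot(is(x, "EditingCallSet"), is(snps, "AnnotationSet"))
  if (annotationKind(snps) != "snp")
    stop("expected an AnnotationSet of kind 'snp', got '",
         annotationKind(snps), "'")
  gr <- callRanges(x)
  sr <- annotationRanges(snps)
  if (allelic) sr <- sr[mcols(sr)$name %in% c("A>G", "T>C")]
  drop <- countOverlaps(gr, sr, ignore.strand = TRUE) > 0
  list(calls = initialize(x, calls = gr[!drop]),
       report = stageRow("snp_overlap", length(gr), sum(!drop)))
}

#' Apply the full per-sample filter chain
#'
#' Editing-type consistency, then Alu retention, then SNP exclusion, with a
#' per-stage audit report. The chain is idempotent and each stage's counts
#' are conserved (input = retained + excluded).
#'
#' @param x an \linkS4class{EditingCallSet}.
#' @param alu an \linkS4class{AnnotationSet} of kind \code{"alu"}.
#' @param snps an \linkS4class{AnnotationSet} of kind \code{"snp"}.
#' @param lenient passed to \code{\link{filterEditingType}}.
#' @param allelic passed to \code{\link{filterSnpOverlap}}.
#' @return \code{list(calls = <EditingCallSet>, report = <3-row
#'   data.frame>)}.
#' @examples
#' gr <- GenomicRanges::GRanges("chrS", IRanges::IRanges(c(100, 200), width = 1),
#'   strand = "+", refBase = c("A", "C"), altBase = c("G", "T"),
#'   supportingReads = c(5L, 5L), totalReads = c(10L, 10L))
#' cs <- EditingCallSet("S1", gr)
#' alu <- AnnotationSet(GenomicRanges::GRanges("chrS",
#'   IRanges::IRanges(50, 150)), "alu")
#' snp <- AnnotationSet(GenomicRanges::GRanges(character(0)), "snp")
#' applyFilterChain(cs, alu, snp)$report
#' @export
applyFilterChain <- function(x, alu, snps, lenient = FALSE, allelic = TRUE) {
  n0 <- length(x)
  s1 <- filterEditingType(x, lenient = lenient)
  r1 <- stageRow("editing_type", n0, length(s1))
  s2 <- filterAluOverlap(s1, alu)
  r2 <- stageRow("alu_overlap", length(s1), length(s2))
  s3 <- filterSnpOverlap(s2, snps, allelic = allelic)
  list(calls = s3$calls, report = rbind(r1, r2, s3$report))
}

#' Apply the filter chain to every sample of a cohort
#'
#' @param cohort named list of \linkS4class{EditingCallSet}.
#' @param alu,snps annotation sets as in \code{\link{applyFilterChain}}.
#' @param lenient,allelic stage options.
#' @return \code{list(cohort = <filtered list>, report = <3-row data.frame
#'   of pooled per-stage counts>)}.
#' @export
filterCohort <- function(cohort, alu, snps, lenient = FALSE,
                         allelic = TRUE) {
  res <- lapply(cohort, applyFilterChain, alu = alu, snps = snps,
                lenient = lenient, allelic = allelic)
  reports <- lapply(res, `[[`, "report")
  pooled <- reports[[1]]
  if (length(reports) > 1) {
    for (r in reports[-1]) {
      pooled$input_count    <- pooled$input_count    + r$input_count
      pooled$retained_count <- pooled$retained_count + r$retained_count
      pooled$excluded_count <- pooled$excluded_count + r$excluded_count
    }
    pooled$excluded_fraction <- ifelse(
      pooled$input_count > 0,
      pooled$excluded_count / pooled$input_count, 0)
  }
  list(cohort = lapply(res, `[[`, "calls"), report = pooled)
}
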