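## Central S4 containers. Coordinates are held in GRanges (1-based, closed),
## the native Bioconductor convention; BED/VCF readers and writers convert at
## the file boundary, and all rendered reports are 1-based.

VALID_GROUPS   <- c("tumor", "adjacent")
VALID_SUBTYPES <- c("ER+", "TNBC")
VALID_KINDS    <- c("alu", "nat", "snp")
BASES          <- c("A", "C", "G", "T")

#' EditingCallSet: RNA editing calls for one sample
#'
#' All candidate edited sites observed in one sample, as a width-1
#' \link[GenomicRanges]{GRanges} with metadata columns \code{refBase},
#' \code{altBase}, \code{supportingReads}, \code{totalReads}, together with
#' the sample's manifest metadata (group, subtype, mapped-read depth).
#'
#' @slot sampleId single sample identifier.
#' @slot group \code{"tumor"} or \code{"adjacent"} (may be \code{NA} before a
#'   manifest join).
#' @slot subtype \code{"ER+"} or \code{"TNBC"} (may be \code{NA}).
#' @slot mappedReads mapped-read count used for depth normalization
#'   (\code{NA} before a manifest join).
#' @slot calls width-1 \code{GRanges}, sorted, with the call metadata columns.
#'
#' @examples
#' gr <- GenomicRanges::GRanges("chr7", IRanges::IRanges(77056248, width = 1),
#'   strand = "+", refBase = "A", altBase = "G",
#'   supportingReads = 12L, totalReads = 40L)
#' EditingCallSet(sampleId = "S1", group = "tumor", subtype = "ER+",
#'   mappedReads = 5e7, calls = gr)
#' @export
setClass("EditingCallSet",
  slots = c(
    sampleId    = "character",
    group       = "character",
    subtype     = "character",
    mappedReads = "numeric",
    calls       = "GRanges"
  ),
  prototype = prototype(
    sampleId = NA_character_, group = NA_character_,
    subtype = NA_character_, mappedReads = NA_real_
  )
)

setValidity("EditingCallSet", function(object) {
  msg <- character()
  if (length(object@sampleId) != 1L)
    msg <- c(msg, "sampleId must be a single string")
  if (!is.na(object@group) && !object@group %in% VALID_GROUPS)
    msg <- c(msg, sprintf("group must be one of %s",
                          paste(VALID_GROUPS, collapse = "/")))
  if (!is.na(object@subtype) && !object@subtype %in% VALID_SUBTYPES)
    msg <- c(msg, sprintf("subtype must be one of %s",
                          paste(VALID_SUBTYPES, collapse = "/")))
  if (!is.na(object@mappedReads) && object@mappedReads <= 0)
    msg <- c(msg, "mappedReads must be positive")
  gr <- object@calls
  need <- c("refBase", "altBase", "supportingReads", "totalReads")
  if (!all(need %in% names(mcols(gr)))) {
    msg <- c(msg, paste("calls must carry metadata columns:",
                        paste(need, collapse = ", ")))
    return(if (length(msg)) msg else TRUE)
  }
  if (length(gr)) {
    if (any(width(gr) != 1L))
      msg <- c(msg, "all calls must be single-base (width 1)")
    if (!all(as.character(strand(gr)) %in% c("+", "-")))
      msg <- c(msg, "call strand must be '+' or '-'")
    if (!all(mcols(gr)$refBase %in% BASES) ||
        !all(mcols(gr)$altBase %in% BASES))
      msg <- c(msg, "refBase/altBase must be A, C, G or T")
    if (any(mcols(gr)$refBase == mcols(gr)$altBase))
      msg <- c(msg, "refBase must differ from altBase")
    sup <- mcols(gr)$supportingReads
    tot <- mcols(gr)$totalReads
    if (any(sup < 0) || any(tot <= 0) || any(sup > tot))
      msg <- c(msg, "need 0 <= supportingReads <= totalReads, totalReads > 0")
    key <- paste(seqnames(gr), start(gr), mcols(gr)$refBase,
                 mcols(gr)$altBase)
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate (chrom, position, ref, alt) call")
    o <- order(as.character(seqnames(gr)), start(gr))
    if (!identical(o, seq_along(gr)))
      msg <- c(msg, "calls must be sorted by (chrom, position)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an EditingCallSet
#'
#' @param sampleId,group,subtype,mappedReads sample metadata; see
#'   \linkS4class{EditingCallSet}.
#' @param calls width-1 \code{GRanges} with columns \code{refBase},
#'   \code{altBase}, \code{supportingReads}, \code{totalReads}. Calls are
#'   sorted by (chrom, position) on construction.
#' @return An \linkS4class{EditingCallSet}.
#' @export
EditingCallSet <- function(sampleId, calls,
                           group = NA_character_, subtype = NA_character_,
                           mappedReads = NA_real_) {
  if (length(calls)) {
    o <- order(as.character(seqnames(calls)), start(calls))
    calls <- calls[o]
  }
  new("EditingCallSet", sampleId = as.character(sampleId),
      group = as.character(group), subtype = as.character(subtype),
      mappedReads = as.numeric(mappedReads), calls = calls)
}

#' AnnotationSet: strand-aware genomic intervals of one annotation kind
#'
#' A \code{GRanges} of Alu repeats, natural antisense transcripts, or SNP
#' positions, tagged with its kind so filters can refuse mismatched inputs.
#' SNP-kind ranges are single-base and carry the allele pair in
#' \code{name} as \code{"REF>ALT"}.
#'
#' @slot ranges \code{GRanges} with a \code{name} metadata column.
#' @slot kind one of \code{"alu"}, \code{"nat"}, \code{"snp"}.
#' @export
setClass("AnnotationSet",
  slots = c(ranges = "GRanges", kind = "character")
)

setValidity("AnnotationSet", function(object) {
  msg <- character()
  if (length(object@kind) != 1L || !object@kind %in% VALID_KINDS)
    msg <- c(msg, sprintf("kind must be one of %s",
                          paste(VALID_KINDS, collapse = "/")))
  gr <- object@ranges
  if (!"name" %in% names(mcols(gr)))
    msg <- c(msg, "ranges must carry a 'name' metadata column")
  if (length(gr) && any(width(gr) < 1L))
    msg <- c(msg, "all intervals must have width >= 1")
  if (identical(object@kind, "snp") && length(gr)) {
    if (any(width(gr) != 1L))
      msg <- c(msg, "snp intervals must be single-base")
    if (!all(grepl("^[ACGT]>[ACGT]$", mcols(gr)$name)))
      msg <- c(msg, "snp names must have the form 'REF>ALT'")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AnnotationSet
#'
#' @param ranges a \code{GRanges}; a \code{name} column is added (from
#'   \code{names(ranges)} or empty strings) when absent.
#' @param kind \code{"alu"}, \code{"nat"} or \code{"snp"}.
#' @return An \linkS4class{AnnotationSet}.
#' @export
AnnotationSet <- function(ranges, kind) {
  if (!"name" %in% names(mcols(ranges))) {
    nm <- names(ranges)
    mcols(ranges)$name <- if (is.null(nm)) rep("", length(ranges)) else nm
  }
  new("AnnotationSet", ranges = ranges, kind = as.character(kind))
}

#' DecayFit: first-order decay fit of one transcript
#'
#' Result of regressing log expression on time after transcription shutoff:
#' decay rate \eqn{\lambda} (per hour), half-life \eqn{\ln 2 / \lambda},
#' log-scale intercept and goodness of fit.
#'
#' @slot gene,condition identifiers of the fitted series.
#' @slot lambda decay rate per hour (0 for no measurable decay).
#' @slot tHalfHours \eqn{\ln 2 / \lambda}; \code{Inf} when \code{lambda} = 0.
#' @slot intercept natural-log expression at t = 0.
#' @slot rSquared coefficient of determination (\code{NA} when the response
#'   is constant).
#' @slot nPoints number of (time, expression) points used.
#' @export
setClass("DecayFit",
  slots = c(gene = "character", condition = "character",
            lambda = "numeric", tHalfHours = "numeric",
            intercept = "numeric", rSquared = "numeric",
            nPoints = "integer")
)

setValidity("DecayFit", function(object) {
  msg <- character()
  if (object@lambda < 0) msg <- c(msg, "lambda must be >= 0")
  if (object@lambda > 0 &&
      abs(object@tHalfHours - log(2) / object@lambda) > 1e-8)
    msg <- c(msg, "tHalfHours must equal ln(2)/lambda")
  if (!is.na(object@rSquared) &&
      (object@rSquared < -1e-12 || object@rSquared > 1 + 1e-12))
    msg <- c(msg, "rSquared must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' CandidateList: prioritized editing sites for one subtype
#'
#' Sites passing the prevalence filter, the |Z| threshold and the NAT-overlap
#' restriction, ordered by |Z| descending (ties by chrom, position), together
#' with the selection parameters that produced them.
#'
#' @slot records data.frame of prevalence records (one site per row, 1-based
#'   positions) with all intermediate columns.
#' @slot subtype subtype the list was computed for (may be \code{NA}).
#' @slot minPrevalence prevalence filter threshold used.
#' @slot zThreshold |Z| threshold used (strict inequality).
#' @export
setClass("CandidateList",
  slots = c(records = "data.frame", subtype = "character",
            minPrevalence = "numeric", zThreshold = "numeric")
)

## ---- accessors ----

#' @describeIn EditingCallSet number of calls.
#' @param x,object an \code{EditingCallSet}.
#' @export
setMethod("length", "EditingCallSet", function(x) length(x@calls))

#' Accessors for natedit containers
#'
#' @param x an \linkS4class{EditingCallSet}, \linkS4class{AnnotationSet} or
#'   \linkS4class{CandidateList}.
#' @return \code{callRanges} and \code{annotationRanges} return the
#'   underlying \code{GRanges}; the scalar accessors return the
#'   corresponding slot.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("callRanges", function(x) standardGeneric("callRanges"))
#' @rdname accessors
#' @export
setMethod("callRanges", "EditingCallSet", function(x) x@calls)

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setMethod("sampleId", "EditingCallSet", function(x) x@sampleId)

#' @rdname accessors
#' @export
setGeneric("sampleGroup", function(x) standardGeneric("sampleGroup"))
#' @rdname accessors
#' @export
setMethod("sampleGroup", "EditingCallSet", function(x) x@group)

#' @rdname accessors
#' @export
setGeneric("sampleSubtype", function(x) standardGeneric("sampleSubtype"))
#' @rdname accessors
#' @export
setMethod("sampleSubtype", "EditingCallSet", function(x) x@subtype)

#' @rdname accessors
#' @export
setGeneric("mappedReads", function(x) standardGeneric("mappedReads"))
#' @rdname accessors
#' @export
setMethod("mappedReads", "EditingCallSet", function(x) x@mappedReads)

#' @rdname accessors
#' @export
setGeneric("annotationRanges", function(x) standardGeneric("annotationRanges"))
#' @rdname accessors
#' @export
setMethod("annotationRanges", "AnnotationSet", function(x) x@ranges)

#' @rdname accessors
#' @export
setGeneric("annotationKind", function(x) standardGeneric("annotationKind"))
#' @rdname accessors
#' @export
setMethod("annotationKind", "AnnotationSet", function(x) x@kind)

#' @rdname accessors
#' @export
setMethod("length", "AnnotationSet", function(x) length(x@ranges))

#' @rdname accessors
#' @export
setGeneric("candidateRecords", function(x) standardGeneric("candidateRecords"))
#' @rdname accessors
#' @export
setMethod("candidateRecords", "CandidateList", function(x) x@records)

#' @rdname accessors
#' @export
setMethod("length", "CandidateList", function(x) nrow(x@records))

#' @rdname accessors
#' @export
setGeneric("halfLife", function(x) standardGeneric("halfLife"))
#' @rdname accessors
#' @export
setMethod("halfLife", "DecayFit", function(x) x@tHalfHours)

#' @rdname accessors
#' @export
setGeneric("decayRate", function(x) standardGeneric("decayRate"))
#' @rdname accessors
#' @export
setMethod("decayRate", "DecayFit", function(x) x@lambda)

## ---- show ----

setMethod("show", "EditingCallSet", function(object) {
  cat(sprintf(
    "EditingCallSet '%s' (%s, %s): %d calls, %s mapped reads\n",
    object@sampleId, object@subtype, object@group, length(object@calls),
    format(object@mappedReads, big.mark = ",")))
})

setMethod("show", "AnnotationSet", function(object) {
  cat(sprintf("AnnotationSet kind='%s': %d intervals on %d sequence(s)\n",
              object@kind, length(object@ranges),
              length(unique(as.character(seqnames(object@ranges))))))
})

setMethod("show", "DecayFit", function(object) {
  th <- if (is.finite(object@tHalfHours))
    sprintf("%.3g h", object@tHalfHours) else "not reached"
  cat(sprintf(
    "DecayFit %s [%s]: lambda=%.4g /h, t1/2=%s, R2=%s (n=%d)\n",
    object@gene, object@condition, object@lambda, th,
    ifelse(is.na(object@rSquared), "NA", sprintf("%.3f", object@rSquared)),
    object@nPoints))
})

setMethod("show", "CandidateList", function(object) {
  cat(sprintf(
    "CandidateList (%s): %d candidate site(s) [prevalence >= %.2f, |Z| > %.2f, NAT-overlapped]\n",
    object@subtype, nrow(object@records), object@minPrevalence,
    object@zThreshold))
  if (nrow(object@records))
    print(utils::head(object@records[, c("chrom", "pos", "prev_tumor",
                                         "prev_adjacent", "ratio", "z")], 5))
})
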