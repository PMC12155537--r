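## Candidate-site prioritization: per-site detection prevalence in each
## group, >= 40% prevalence filter, tumor/adjacent prevalence ratio,
## Z-scores of the ratios, |Z| > 1.96 plus NAT-overlap selection, and the
## cross-subtype intersection. Detection is binary: a site either appears
## in a sample's filtered call file or it does not.

#' Per-site detection prevalence across a cohort
#'
#' For every site observed in any sample of the subtype, counts the tumor
#' and adjacent samples whose call set contains it. A site absent from a
#' sample counts 0 regardless of coverage. Positions are reported 1-based.
#'
#' @param cohort list of \linkS4class{EditingCallSet} with manifest metadata.
#' @param subtype restrict to one subtype (\code{NULL} uses all samples;
#'   normal use is per subtype, never pooled).
#' @return data.frame of prevalence records: \code{chrom, pos, strand,
#'   k_tumor, n_tumor, k_adjacent, n_adjacent, prev_tumor, prev_adjacent}.
#' @export
sitePrevalence <- function(cohort, subtype = NULL) {
  if (!is.null(subtype))
    cohort <- Filter(function(x) identical(sampleSubtype(x), subtype),
                     cohort)
  groups <- vapply(cohort, sampleGroup, character(1))
  if (any(is.na(groups)))
    stop("every sample needs a group label (join the manifest first)")
  nT <- sum(groups == "tumor"); nA <- sum(groups == "adjacent")
  if (nT < 1 || nA < 1)
    stop("need at least one tumor and one adjacent sample")
  perSample <- lapply(cohort, function(x) {
    gr <- callRanges(x)
    if (!length(gr))
      return(data.frame(chrom = character(), pos = integer(),
                        strand = character(), stringsAsFactors = FALSE))
    df <- data.frame(chrom = as.character(seqnames(gr)), pos = start(gr),
                     strand = as.character(strand(gr)),
                     stringsAsFactors = FALSE)
    unique(df)
  })
  all <- do.call(rbind, lapply(seq_along(cohort), function(i) {
    d <- perSample[[i]]
    if (nrow(d)) d$group <- groups[i]
    d
  }))
  if (is.null(all) || !nrow(all))
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(),
                      k_tumor = integer(), n_tumor = integer(),
                      k_adjacent = integer(), n_adjacent = integer(),
                      prev_tumor = numeric(), prev_adjacent = numeric(),
                      stringsAsFactors = FALSE))
  key <- paste(all$chrom, all$pos)
  kT <- tapply(all$group == "tumor", key, sum)
  kA <- tapply(all$group == "adjacent", key, sum)
  first <- !duplicated(key)
  ord <- order(all$chrom[first], all$pos[first])
  ukey <- key[first][ord]
  out <- data.frame(chrom = all$chrom[first][ord],
                    pos = all$pos[first][ord],
                    strand = all$strand[first][ord],
                    k_tumor = as.integer(kT[ukey]),
                    n_tumor = nT,
                    k_adjacent = as.integer(kA[ukey]),
                    n_adjacent = nA,
                    stringsAsFactors = FALSE)
  out$prev_tumor <- out$k_tumor / out$n_tumor
  out$prev_adjacent <- out$k_adjacent / out$n_adjacent
  rownames(out) <- NULL
  out
}

#' Prevalence filter
#'
#' Retains sites detected in at least \code{minPrevalence} of either the
#' tumor or the adjacent samples (boundary inclusive).
#'
#' @param records data.frame from \code{\link{sitePrevalence}}.
#' @param minPrevalence threshold in [0, 1]; default 0.40.
#' @return The retained records, with a \code{passes_prevalence_filter}
#'   column (all \code{TRUE}).
#' @export
prevalenceFilter <- function(records, minPrevalence = 0.40) {
  if (minPrevalence < 0 || minPrevalence > 1)
    stop("minPrevalence must lie in [0, 1]")
  keep <- records$prev_tumor >= minPrevalence |
          records$prev_adjacent >= minPrevalence
  out <- records[keep, , drop = FALSE]
  out$passes_prevalence_filter <- rep(TRUE, nrow(out))
  attr(out, "minPrevalence") <- minPrevalence
  rownames(out) <- NULL
  out
}

#' Tumor/adjacent prevalence ratio
#'
#' \code{ratio = prev_tumor / prev_adjacent}. A zero detection count on
#' either side is replaced, before division, by a Haldane-style half count
#' \code{0.5 / n} for that group (or by \code{zeroGuard} if supplied), so
#' the ratio is always positive and \code{log2_ratio} finite.
#'
#' @param records filtered prevalence records.
#' @param zeroGuard optional fixed replacement for a zero prevalence;
#'   default \code{NULL} uses \code{0.5 / n} of the zero group.
#' @return \code{records} with \code{ratio} and \code{log2_ratio} columns.
#' @export
prevalenceRatio <- function(records, zeroGuard = NULL) {
  gA <- if (is.null(zeroGuard)) 0.5 / records$n_adjacent else zeroGuard
  gT <- if (is.null(zeroGuard)) 0.5 / records$n_tumor else zeroGuard
  den <- ifelse(records$k_adjacent == 0, gA, records$prev_adjacent)
  num <- ifelse(records$k_tumor == 0, gT, records$prev_tumor)
  records$ratio <- num / den
  records$log2_ratio <- log2(records$ratio)
  records
}

#' Z-scores of prevalence ratios
#'
#' Standardizes the ratios over the record set: \code{z = (v - mean(v)) /
#' sd(v)} with the sample standard deviation (denominator n - 1) and
#' \code{v} the log2 ratio (default) or the raw ratio. If all ratios are
#' equal, every z is set to 0 with a warning.
#'
#' @param records records carrying \code{ratio} / \code{log2_ratio}.
#' @param scale \code{"log2"} (default; symmetric in enrichment and
#'   depletion) or \code{"raw"}.
#' @return \code{records} with a \code{z} column.
#' @export
zscoreRatios <- function(records, scale = c("log2", "raw")) {
  scale <- match.arg(scale)
  if (nrow(records) < 3)
    stop("need >= 3 records to standardize ratios")
  v <- if (scale == "log2") records$log2_ratio else records$ratio
  s <- sd(v)
  if (!is.finite(s) || s == 0) {
    warning("all ratios equal; Z-scores set to 0")
    records$z <- rep(0, nrow(records))
  } else {
    records$z <- (v - mean(v)) / s
  }
  attr(records, "ratioScale") <- scale
  records
}

#' Select NAT-overlapped candidates by |Z| threshold
#'
#' Retains records with \code{|z| > zThreshold} (strict) whose position
#' overlaps at least one natural antisense transcript interval, ordered by
#' |z| descending with ties broken by (chrom, position). NAT overlap is
#' positional and strand-agnostic by default; \code{strandAware = TRUE}
#' additionally requires the NAT interval's strand to be opposite the call
#' strand.
#'
#' @param records records carrying \code{z} (and \code{strand} for the
#'   strand-aware mode).
#' @param nat an \linkS4class{AnnotationSet} of kind \code{"nat"}.
#' @param zThreshold |Z| cutoff; default 1.96.
#' @param strandAware require antisense orientation of the NAT interval.
#' @param subtype label stored on the result.
#' @return A \linkS4class{CandidateList}.
#' @export
selectCandidates <- function(records, nat, zThreshold = 1.96,
                             strandAware = FALSE,
                             subtype = NA_character_) {
  stopifnot(is(nat, "AnnotationSet"))
  if (annotationKind(nat) != "nat")
    stop("expected an AnnotationSet of kind 'nat', got '",
         annotationKind(nat), "'")
  if (!"z" %in% names(records)) stop("records carry no z column")
  natGr <- annotationRanges(nat)
  if (nrow(records)) {
    siteGr <- GRanges(records$chrom, IRanges(records$pos, width = 1))
    if (strandAware) {
      hits <- findOverlaps(siteGr, natGr, ignore.strand = TRUE)
      opp <- as.character(strand(natGr))[subjectHits(hits)] !=
             records$strand[queryHits(hits)] &
             as.character(strand(natGr))[subjectHits(hits)] %in% c("+", "-")
      inNat <- tabulate(queryHits(hits)[opp], nbins = nrow(records)) > 0
    } else {
      inNat <- countOverlaps(siteGr, natGr, ignore.strand = TRUE) > 0
    }
  } else inNat <- logical(0)
  records$in_nat <- inNat
  records$passes_z <- abs(records$z) > zThreshold
  sel <- records[records$passes_z & records$in_nat, , drop = FALSE]
  if (nrow(sel)) {
    sel <- sel[order(-abs(sel$z), sel$chrom, sel$pos), , drop = FALSE]
    rownames(sel) <- NULL
  }
  mp <- attr(records, "minPrevalence")
  new("CandidateList", records = sel, subtype = as.character(subtype),
      minPrevalence = if (is.null(mp)) NA_real_ else mp,
      zThreshold = zThreshold)
}

#' Run the whole prioritization for one subtype
#'
#' Convenience wrapper: \code{\link{sitePrevalence}} then
#' \code{\link{prevalenceFilter}}, \code{\link{prevalenceRatio}},
#' \code{\link{zscoreRatios}} and \code{\link{selectCandidates}}.
#'
#' @param cohort list of filtered \linkS4class{EditingCallSet}.
#' @param nat NAT \linkS4class{AnnotationSet}.
#' @param subtype subtype to analyze.
#' @param minPrevalence,zThreshold,scale,strandAware parameters of the
#'   component stages.
#' @return A \linkS4class{CandidateList}.
#' @export
prioritizeSites <- function(cohort, nat, subtype = NULL,
                            minPrevalence = 0.40, zThreshold = 1.96,
                            scale = "log2", strandAware = FALSE) {
  rec <- sitePrevalence(cohort, subtype = subtype)
  rec <- prevalenceFilter(rec, minPrevalence = minPrevalence)
  if (nrow(rec) < 3)
    stop("fewer than 3 sites pass the prevalence filter; ",
         "Z-scores are undefined")
  rec <- prevalenceRatio(rec)
  rec <- zscoreRatios(rec, scale = scale)
  selectCandidates(rec, nat, zThreshold = zThreshold,
                   strandAware = strandAware,
                   subtype = if (is.null(subtype)) NA_character_
                             else subtype)
}

#' Intersect candidate lists from two subtypes
#'
#' Set intersection on (chrom, position); positions are 1-based throughout.
#'
#' @param a,b \linkS4class{CandidateList} objects from the same coordinate
#'   system.
#' @return data.frame \code{chrom, pos} of shared sites, coordinate-sorted.
#' @export
intersectSubtypes <- function(a, b) {
  stopifnot(is(a, "CandidateList"), is(b, "CandidateList"))
  ka <- paste(candidateRecords(a)$chrom, candidateRecords(a)$pos)
  kb <- paste(candidateRecords(b)$chrom, candidateRecords(b)$pos)
  ra <- candidateRecords(a)[ka %in% kb, c("chrom", "pos"), drop = FALSE]
  ra <- unique(ra)
  ra <- ra[order(ra$chrom, ra$pos), , drop = FALSE]
  rownames(ra) <- NULL
  ra
}
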