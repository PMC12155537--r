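## On-disk formats. Editing calls travel as a 7-column BED-like TSV
## (chrom, start0, end0, "REF>ALT", supporting, strand, total); annotations
## as BED3/BED6; SNPs as sites-only VCF; the manifest and Ct tables as
## headered TSV. Files are 0-based half-open where their format says so;
## everything in memory is GRanges (1-based).

#' Read a per-sample editing-call file
#'
#' Parses the 7-column BED-like dialect written by editing-site callers:
#' \code{chrom, start(0-based), end, "REF>ALT", supporting_reads, strand,
#' total_reads}. Lines beginning \code{#} are headers. Every malformed row
#' is reported with its line number; rows are never silently dropped.
#'
#' @param path path to the call file.
#' @param sampleId sample identifier (defaults to the file name without
#'   extension).
#' @param group,subtype,mappedReads sample metadata, normally joined from
#'   the manifest via \code{\link{loadCohort}}.
#' @param columnMap named integer vector remapping column positions for
#'   other dialects; names must be \code{chrom, start, end, edit, support,
#'   strand, total} (default \code{1:7} in that order).
#' @return An \linkS4class{EditingCallSet} sorted by coordinate.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr7\t77056247\t77056248\tA>G\t12\t+\t40", f)
#' readEditingCalls(f, sampleId = "S1")
#' @export
readEditingCalls <- function(path, sampleId = NULL,
                             group = NA_character_,
                             subtype = NA_character_,
                             mappedReads = NA_real_,
                             columnMap = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sampleId))
    sampleId <- sub("\\.[^.]*$", "", basename(path))
  cm <- c(chrom = 1L, start = 2L, end = 3L, edit = 4L,
          support = 5L, strand = 6L, total = 7L)
  if (!is.null(columnMap)) {
    if (!all(names(cm) %in% names(columnMap)))
      stop("columnMap must name all of: ", paste(names(cm), collapse = ", "))
    cm[names(columnMap)] <- as.integer(columnMap)
  }
  lines <- readLines(path)
  isData <- !grepl("^#", lines) & nzchar(trimws(lines))
  dataIdx <- which(isData)
  probs <- character()
  n <- length(dataIdx)
  chrom <- character(n); start0 <- numeric(n); end0 <- numeric(n)
  refB <- character(n); altB <- character(n)
  sup <- numeric(n); tot <- numeric(n); strd <- character(n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    ln <- dataIdx[i]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    bad <- function(why) probs <<- c(probs, sprintf("line %d: %s", ln, why))
    if (length(f) < max(cm)) { bad("too few columns"); next }
    s0 <- suppressWarnings(as.numeric(f[cm["start"]]))
    e0 <- suppressWarnings(as.numeric(f[cm["end"]]))
    if (is.na(s0) || is.na(e0)) { bad("non-numeric coordinates"); next }
    if (s0 < 0) { bad("negative start"); next }
    if (e0 != s0 + 1) { bad("end != start + 1"); next }
    ed <- f[cm["edit"]]
    if (!grepl("^[ACGT]>[ACGT]$", ed)) { bad("bad 'REF>ALT' field"); next }
    rb <- substr(ed, 1, 1); ab <- substr(ed, 3, 3)
    if (rb == ab) { bad("ref equals alt"); next }
    st <- f[cm["strand"]]
    if (!st %in% c("+", "-")) { bad("unknown strand"); next }
    sp <- suppressWarnings(as.numeric(f[cm["support"]]))
    tt <- suppressWarnings(as.numeric(f[cm["total"]]))
    if (is.na(sp) || is.na(tt)) { bad("non-numeric read counts"); next }
    if (sp < 0 || tt <= 0 || sp > tt) {
      bad("need 0 <= supporting <= total, total > 0"); next
    }
    chrom[i] <- f[cm["chrom"]]; start0[i] <- s0; end0[i] <- e0
    refB[i] <- rb; altB[i] <- ab; sup[i] <- sp; tot[i] <- tt; strd[i] <- st
    ok[i] <- TRUE
  }
  if (length(probs))
    stop("malformed rows in ", path, ":\n  ", paste(probs, collapse = "\n  "))
  gr <- GRanges(chrom[ok],
                IRanges(start = start0[ok] + 1, width = 1),
                strand = strd[ok],
                refBase = refB[ok], altBase = altB[ok],
                supportingReads = as.integer(sup[ok]),
                totalReads = as.integer(tot[ok]))
  EditingCallSet(sampleId = sampleId, calls = gr, group = group,
                 subtype = subtype, mappedReads = mappedReads)
}

#' Write a per-sample editing-call file
#'
#' Inverse of \code{\link{readEditingCalls}}: emits the 7-column BED-like
#' dialect with 0-based half-open coordinates, so a read/write round trip is
#' the identity.
#'
#' @param x an \linkS4class{EditingCallSet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeEditingCalls <- function(x, path) {
  stopifnot(is(x, "EditingCallSet"))
  validObject(x)
  gr <- callRanges(x)
  header <- "# chrom\tstart\tend\tedit\tsupporting_reads\tstrand\ttotal_reads"
  rows <- if (length(gr)) {
    sprintf("%s\t%d\t%d\t%s>%s\t%d\t%s\t%d",
            as.character(seqnames(gr)), start(gr) - 1L, start(gr),
            mcols(gr)$refBase, mcols(gr)$altBase,
            mcols(gr)$supportingReads, as.character(strand(gr)),
            mcols(gr)$totalReads)
  } else character()
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a BED annotation file as an AnnotationSet
#'
#' BED3 or BED6, via \code{rtracklayer}. BED6 strand is honored; BED3
#' intervals get strand \code{*} (rendered \code{.}). Zero-length intervals
#' are rejected.
#'
#' @param path BED file path.
#' @param kind \code{"alu"}, \code{"nat"} or \code{"snp"}.
#' @return An \linkS4class{AnnotationSet}.
#' @export
readIntervalBed <- function(path, kind = c("alu", "nat", "snp")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) && any(width(gr) < 1L))
    stop("zero-length interval(s) in ", path)
  if (!"name" %in% names(mcols(gr)))
    mcols(gr)$name <- rep("", length(gr))
  mcols(gr)$name[is.na(mcols(gr)$name)] <- ""
  mcols(gr) <- mcols(gr)["name"]
  AnnotationSet(gr, kind = kind)
}

#' Read a sites-only VCF of SNPs as a snp-kind AnnotationSet
#'
#' One single-base interval per (POS, REF, ALT) pair; multi-allelic ALT
#' fields are split. Rows with REF equal to ALT, or with non-single-base
#' alleles, are skipped with a warning.
#'
#' @param path VCF path (plain text, sites-only is enough).
#' @return An \linkS4class{AnnotationSet} of kind \code{"snp"} whose names
#'   are \code{"REF>ALT"}.
#' @export
readSnpVcf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altL <- rr$ALT
  nAlt <- lengths(altL)
  idx <- rep(seq_along(rr), nAlt)
  alt <- as.character(unlist(altL))
  chrom <- as.character(seqnames(rr))[idx]
  pos <- start(rr)[idx]
  refx <- ref[idx]
  keep <- nchar(refx) == 1L & nchar(alt) == 1L &
    refx %in% BASES & alt %in% BASES
  same <- keep & refx == alt
  if (any(same))
    warning(sum(same), " VCF record(s) with REF == ALT skipped")
  bad <- !keep
  if (any(bad))
    warning(sum(bad), " non-SNV VCF record(s) skipped")
  keep <- keep & !same
  gr <- GRanges(chrom[keep], IRanges(pos[keep], width = 1),
                name = paste0(refx[keep], ">", alt[keep]))
  AnnotationSet(gr, kind = "snp")
}

#' Write an AnnotationSet to BED6
#'
#' @param x an \linkS4class{AnnotationSet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeIntervalBed <- function(x, path) {
  stopifnot(is(x, "AnnotationSet"))
  gr <- annotationRanges(x)
  strd <- as.character(strand(gr))
  strd[strd == "*"] <- "."
  rows <- if (length(gr)) {
    sprintf("%s\t%d\t%d\t%s\t0\t%s",
            as.character(seqnames(gr)), start(gr) - 1L, end(gr),
            ifelse(nzchar(mcols(gr)$name), mcols(gr)$name, "."), strd)
  } else character()
  writeLines(rows, path)
  invisible(path)
}

#' Write a snp-kind AnnotationSet as a sites-only VCF
#'
#' @param x an \linkS4class{AnnotationSet} of kind \code{"snp"}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSnpVcf <- function(x, path) {
  stopifnot(is(x, "AnnotationSet"), annotationKind(x) == "snp")
  gr <- annotationRanges(x)
  ref <- substr(mcols(gr)$name, 1, 1)
  alt <- substr(mcols(gr)$name, 3, 3)
  header <- c("##fileformat=VCFv4.2",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- if (length(gr)) {
    sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.",
            as.character(seqnames(gr)), start(gr), ref, alt)
  } else character()
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read the cohort sample manifest
#'
#' The manifest is the single source of group labels and sequencing depth.
#' Required columns: \code{sample_id, subtype, group, mapped_reads,
#' calls_path}.
#'
#' @param path TSV path with a header.
#' @return A data.frame with validated columns; one row per sample.
#' @export
readSampleManifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c("sample_id", "subtype", "group", "mapped_reads", "calls_path")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("manifest missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in manifest: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]),
               collapse = ", "))
  if (!all(df$group %in% VALID_GROUPS))
    stop("unknown group token(s): ",
         paste(setdiff(df$group, VALID_GROUPS), collapse = ", "))
  if (!all(df$subtype %in% VALID_SUBTYPES))
    stop("unknown subtype token(s): ",
         paste(setdiff(df$subtype, VALID_SUBTYPES), collapse = ", "))
  if (any(!is.finite(df$mapped_reads)) || any(df$mapped_reads <= 0))
    stop("mapped_reads must be positive for every sample")
  df
}

#' Write a sample manifest
#' @param df a manifest data.frame (see \code{\link{readSampleManifest}}).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSampleManifest <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Load a full cohort from a manifest
#'
#' Reads every sample's call file named in the manifest, joining group,
#' subtype and depth metadata onto each \linkS4class{EditingCallSet}.
#' Relative \code{calls_path} entries are resolved against the manifest's
#' directory.
#'
#' @param manifest a manifest data.frame or a path to one.
#' @param baseDir directory against which relative call paths are resolved
#'   (default: the manifest's directory, or \code{"."} for a data.frame).
#' @return Named list of \linkS4class{EditingCallSet}, one per manifest row.
#' @export
loadCohort <- function(manifest, baseDir = NULL) {
  if (is.character(manifest)) {
    if (is.null(baseDir)) baseDir <- dirname(manifest)
    manifest <- readSampleManifest(manifest)
  }
  if (is.null(baseDir)) baseDir <- "."
  sets <- lapply(seq_len(nrow(manifest)), function(i) {
    p <- manifest$calls_path[i]
    if (!file.exists(p)) p <- file.path(baseDir, manifest$calls_path[i])
    readEditingCalls(p,
                     sampleId = manifest$sample_id[i],
                     group = manifest$group[i],
                     subtype = manifest$subtype[i],
                     mappedReads = manifest$mapped_reads[i])
  })
  names(sets) <- manifest$sample_id
  sets
}

#' Read a qPCR Ct table
#'
#' Required columns: \code{sample_label, condition, timepoint_hours, gene,
#' replicate, ct}; \code{ct} must be positive and \code{timepoint_hours}
#' non-negative.
#'
#' @param path TSV path with a header.
#' @return A validated data.frame.
#' @export
readCtTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validateCtTable(df)
}

validateCtTable <- function(df) {
  need <- c("sample_label", "condition", "timepoint_hours", "gene",
            "replicate", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("Ct table missing column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(df$ct)) || any(df$ct <= 0))
    stop("ct values must be positive")
  if (any(df$timepoint_hours < 0))
    stop("timepoint_hours must be non-negative")
  df
}

#' Write a Ct table
#' @param df a Ct table data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCtTable <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
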