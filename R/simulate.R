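## Synthetic-cohort generator. Emulates the statistical structure of a
## breast-cancer editing study: per-sample binary site detection with
## group-dependent prevalence, planted differential sites, depth-dependent
## burden, Alu/NAT membership and SNP decoys, all emitted in the same
## formats the readers consume, together with a ground-truth table.

## Deterministic child seed per named artifact stream, so adding one stream
## does not shift the others.
childSeed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483562) + 1L
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe a modest two-group cohort with a shared-background
#' prevalence model: background sites draw one detection prevalence per
#' site from Beta(\code{backgroundShape}) used in both groups; planted
#' sites use \code{plantedPrevTumor} / \code{plantedPrevAdjacent}. Planted
#' sites are always Alu-resident, SNP-free and NAT-overlapped (they model
#' NAT-mediated editing candidates); background sites get those memberships
#' with the configured probabilities. Per-sample depth is log-normal; when
#' \code{burdenPerMillion} is finite, per-sample detection probabilities
#' are thinned so the expected edited-site count tracks
#' \code{burdenPerMillion * mapped_reads / 1e6}.
#'
#' @param nTumor,nAdjacent group sizes.
#' @param nSites number of simulated sites.
#' @param nPlanted number of planted differential sites (<= \code{nSites}).
#' @param backgroundShape Beta shape parameters of the shared background
#'   prevalence distribution.
#' @param plantedPrevTumor,plantedPrevAdjacent planted detection
#'   prevalences per group.
#' @param depthMeanLog,depthSdLog log-normal parameters of mapped reads.
#' @param burdenPerMillion expected edited sites per million mapped reads
#'   (\code{NA}: no depth thinning; detection follows prevalence exactly).
#' @param fractionAlu,fractionSnpDecoy,fractionNat membership
#'   probabilities for background sites.
#' @param subtype subtype label stamped on every sample.
#' @param chrom name of the simulated pseudo-chromosome.
#' @param seed integer master seed; fixed seed gives byte-identical output.
#' @return A validated config list of class \code{CohortSimConfig}.
#' @export
cohortSimConfig <- function(nTumor = 20, nAdjacent = 15,
                            nSites = 1000, nPlanted = 20,
                            backgroundShape = c(2, 8),
                            plantedPrevTumor = 0.8,
                            plantedPrevAdjacent = 0.1,
                            depthMeanLog = log(4e7), depthSdLog = 0.4,
                            burdenPerMillion = NA_real_,
                            fractionAlu = 0.85,
                            fractionSnpDecoy = 0.02,
                            fractionNat = 0.30,
                            subtype = "ER+", chrom = "chrS",
                            seed = 1L) {
  cfg <- list(nTumor = as.integer(nTumor), nAdjacent = as.integer(nAdjacent),
              nSites = as.integer(nSites), nPlanted = as.integer(nPlanted),
              backgroundShape = as.numeric(backgroundShape),
              plantedPrevTumor = plantedPrevTumor,
              plantedPrevAdjacent = plantedPrevAdjacent,
              depthMeanLog = depthMeanLog, depthSdLog = depthSdLog,
              burdenPerMillion = burdenPerMillion,
              fractionAlu = fractionAlu,
              fractionSnpDecoy = fractionSnpDecoy,
              fractionNat = fractionNat,
              subtype = subtype, chrom = chrom, seed = as.integer(seed))
  probs <- c(cfg$plantedPrevTumor, cfg$plantedPrevAdjacent,
             cfg$fractionAlu, cfg$fractionSnpDecoy, cfg$fractionNat)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]")
  if (cfg$nPlanted > cfg$nSites) stop("nPlanted must be <= nSites")
  if (cfg$nTumor < 1 || cfg$nAdjacent < 1) stop("need >= 1 sample per group")
  if (length(cfg$backgroundShape) != 2 || any(cfg$backgroundShape <= 0))
    stop("backgroundShape must be two positive Beta parameters")
  class(cfg) <- "CohortSimConfig"
  cfg
}

#' Simulate a complete editing-call cohort
#'
#' Generates per-sample call sets (binary detection by group prevalence,
#' negative-binomial coverage, Beta-distributed editing fractions), a
#' manifest, Alu/NAT/SNP annotation sets consistent with the per-site
#' truth, and the truth table. Sites sit on a jittered grid (about one per
#' 500 bp) so annotation intervals never spill onto a neighboring site.
#' With \code{outDir} set, everything is also written in the package's file
#' formats (\code{calls/*.bed}, \code{manifest.tsv}, \code{alu.bed},
#' \code{nat.bed}, \code{snps.vcf}, \code{truth.tsv}).
#'
#' @param config a \code{\link{cohortSimConfig}}.
#' @param outDir optional output directory.
#' @return list with \code{cohort} (named list of
#'   \linkS4class{EditingCallSet}), \code{manifest}, \code{alu},
#'   \code{nat}, \code{snps}, \code{truth} and \code{dir}.
#' @export
simulateCohort <- function(config, outDir = NULL) {
  stopifnot(inherits(config, "CohortSimConfig"))
  cfg <- config
  nS <- cfg$nSites

  ## --- site roster ("sites" stream) ---
  set.seed(childSeed(cfg$seed, "sites"))
  pos <- 500L * seq_len(nS) - 250L +
    as.integer(round(runif(nS, -100, 100)))
  strandS <- sample(c("+", "-"), nS, replace = TRUE)
  refB <- ifelse(strandS == "+", "A", "T")
  altB <- ifelse(strandS == "+", "G", "C")
  planted <- logical(nS)
  planted[sample.int(nS, cfg$nPlanted)] <- TRUE
  pBg <- rbeta(nS, cfg$backgroundShape[1], cfg$backgroundShape[2])
  prevT <- ifelse(planted, cfg$plantedPrevTumor, pBg)
  prevA <- ifelse(planted, cfg$plantedPrevAdjacent, pBg)
  inAlu <- planted | runif(nS) < cfg$fractionAlu
  isSnp <- !planted & runif(nS) < cfg$fractionSnpDecoy
  inNat <- planted | runif(nS) < cfg$fractionNat

  ## --- depths ("depths" stream) ---
  set.seed(childSeed(cfg$seed, "depths"))
  nSamp <- cfg$nTumor + cfg$nAdjacent
  depth <- round(rlnorm(nSamp, cfg$depthMeanLog, cfg$depthSdLog))
  groups <- c(rep("tumor", cfg$nTumor), rep("adjacent", cfg$nAdjacent))
  ids <- c(sprintf("T%03d", seq_len(cfg$nTumor)),
           sprintf("A%03d", seq_len(cfg$nAdjacent)))

  ## --- detection and read counts ("calls" stream) ---
  set.seed(childSeed(cfg$seed, "calls"))
  cohort <- vector("list", nSamp)
  for (i in seq_len(nSamp)) {
    pv <- if (groups[i] == "tumor") prevT else prevA
    if (is.finite(cfg$burdenPerMillion)) {
      target <- cfg$burdenPerMillion * depth[i] / 1e6
      thin <- min(1, target / sum(pv))
      pv <- pv * thin
    }
    det <- which(runif(nS) < pv)
    tot <- rnbinom(length(det), mu = 28, size = 5) + 2L
    frac <- rbeta(length(det), 2, 5)
    sup <- 1L + rbinom(length(det), tot - 1L, frac)
    gr <- GRanges(rep(cfg$chrom, length(det)),
                  IRanges(pos[det], width = 1),
                  strand = strandS[det],
                  refBase = refB[det], altBase = altB[det],
                  supportingReads = as.integer(sup),
                  totalReads = as.integer(tot))
    cohort[[i]] <- EditingCallSet(ids[i], gr, group = groups[i],
                                  subtype = cfg$subtype,
                                  mappedReads = depth[i])
  }
  names(cohort) <- ids

  aluSet <- AnnotationSet(
    GRanges(rep(cfg$chrom, sum(inAlu)),
            IRanges(pos[inAlu] - 50, pos[inAlu] + 50),
            name = sprintf("AluSim%04d", which(inAlu))), "alu")
  natSet <- AnnotationSet(
    GRanges(rep(cfg$chrom, sum(inNat)),
            IRanges(pos[inNat] - 100, pos[inNat] + 100),
            strand = ifelse(strandS[inNat] == "+", "-", "+"),
            name = sprintf("NATSim%04d", which(inNat))), "nat")
  snpSet <- AnnotationSet(
    GRanges(rep(cfg$chrom, sum(isSnp)), IRanges(pos[isSnp], width = 1),
            name = paste0(refB[isSnp], ">", altB[isSnp])), "snp")

  manifest <- data.frame(
    sample_id = ids, subtype = cfg$subtype, group = groups,
    mapped_reads = depth,
    calls_path = file.path("calls", paste0(ids, ".bed")),
    stringsAsFactors = FALSE)

  truth <- data.frame(
    chrom = cfg$chrom, pos = pos, strand = strandS, planted = planted,
    true_prev_tumor = prevT, true_prev_adjacent = prevA,
    in_alu = inAlu, is_snp = isSnp, in_nat = inNat,
    stringsAsFactors = FALSE)

  if (!is.null(outDir)) {
    dir.create(file.path(outDir, "calls"), recursive = TRUE,
               showWarnings = FALSE)
    for (i in seq_len(nSamp))
      writeEditingCalls(cohort[[i]],
                        file.path(outDir, manifest$calls_path[i]))
    writeSampleManifest(manifest, file.path(outDir, "manifest.tsv"))
    writeIntervalBed(aluSet, file.path(outDir, "alu.bed"))
    writeIntervalBed(natSet, file.path(outDir, "nat.bed"))
    writeSnpVcf(snpSet, file.path(outDir, "snps.vcf"))
    utils::write.table(truth, file.path(outDir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(cohort = cohort, manifest = manifest, alu = aluSet, nat = natSet,
       snps = snpSet, truth = truth, dir = outDir)
}

#' Simulate a transcription-shutoff qPCR time course
#'
#' Relative abundance of the target follows \eqn{\exp(-\lambda t)} with
#' \eqn{\lambda = \ln 2 / t_{1/2}}, with multiplicative log-normal noise
#' (\code{noiseSd} on the natural-log scale). The series is encoded as
#' target/reference Ct pairs such that 2^-ddCt (calibrated at t = 0 within
#' each replicate) recovers the decay curve; the reference-gene Ct is
#' constant.
#'
#' @param tHalfHours true half-life in hours (> 0).
#' @param timepoints sampling times in hours; must include 0.
#' @param noiseSd log-scale noise standard deviation (>= 0).
#' @param nReplicates biological replicates (distinct noise draws).
#' @param seed integer seed.
#' @param gene,referenceGene,condition,sampleLabel identifiers written into
#'   the table.
#' @param ct0Target,ctReference baseline Ct of target at t = 0 and of the
#'   reference gene.
#' @return A Ct table data.frame (see \code{\link{readCtTable}}).
#' @examples
#' ct <- simulateDecaySeries(4, noiseSd = 0)
#' ddct(ct, "target", "reference", calibratorTimepoint = 0)
#' @export
simulateDecaySeries <- function(tHalfHours,
                                timepoints = c(0, 0.5, 1, 2, 4, 6, 8),
                                noiseSd = 0, nReplicates = 1, seed = 1L,
                                gene = "target",
                                referenceGene = "reference",
                                condition = "ActD", sampleLabel = "sim",
                                ct0Target = 22, ctReference = 18) {
  if (tHalfHours <= 0) stop("tHalfHours must be positive")
  if (!length(timepoints) || !any(timepoints == 0))
    stop("timepoints must be non-empty and include 0")
  if (noiseSd < 0) stop("noiseSd must be non-negative")
  lambda <- log(2) / tHalfHours
  set.seed(childSeed(seed, "decay"))
  rows <- list()
  for (r in seq_len(nReplicates)) {
    noise <- if (noiseSd > 0) rnorm(length(timepoints), 0, noiseSd)
             else numeric(length(timepoints))
    abundance <- exp(-lambda * timepoints + noise)
    ctT <- ct0Target - log2(abundance)
    rows[[length(rows) + 1L]] <- data.frame(
      sample_label = sampleLabel, condition = condition,
      timepoint_hours = timepoints, gene = gene, replicate = r,
      ct = ctT, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      sample_label = sampleLabel, condition = condition,
      timepoint_hours = timepoints, gene = referenceGene, replicate = r,
      ct = ctReference, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  validateCtTable(out)
}
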