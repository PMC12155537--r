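## One reproducible run: simulate (or load) -> filter -> burden ->
## prioritize -> intersect, with per-stage TSV outputs and a JSON summary.
## The summary carries versions, seed, parameters and stage counts, and no
## timestamps, so identical config + seed reruns are byte-identical.

defaultRunConfig <- function() {
  list(
    simulation = NULL,
    inputs = NULL,
    filters = list(lenient = FALSE, allelic = TRUE),
    prioritization = list(min_prevalence = 0.40, z_threshold = 1.96,
                          ratio_scale = "log2"),
    seed = 1L,
    out_dir = NULL
  )
}

mergeConfig <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- mergeConfig(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load-real-inputs), the per-sample filter
#' chain, burden comparison and candidate prioritization per subtype, and
#' the cross-subtype intersection. Exactly one of \code{config$simulation}
#' (arguments for \code{\link{cohortSimConfig}}, plus optional
#' \code{subtypes}) and \code{config$inputs} (paths: \code{manifest},
#' \code{alu}, \code{nat}, \code{snps}) must be provided.
#'
#' @param config a config list or the path to a YAML file with the same
#'   structure; unset fields take package defaults.
#' @param outDir output directory (overrides \code{config$out_dir};
#'   \code{NULL} writes nothing).
#' @param seed master seed (overrides \code{config$seed}).
#' @return (invisibly) list with \code{summary}, \code{cohorts},
#'   \code{filterReport}, \code{burden}, \code{comparisons},
#'   \code{candidates} and \code{intersection}.
#' @export
runPipeline <- function(config = list(), outDir = NULL, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- mergeConfig(defaultRunConfig(), config)
  if (!is.null(seed)) cfg$seed <- seed
  if (!is.null(outDir)) cfg$out_dir <- outDir
  hasSim <- !is.null(cfg$simulation)
  hasReal <- !is.null(cfg$inputs)
  if (hasSim == hasReal)
    stop("provide exactly one of config$simulation and config$inputs")

  stage <- "load_inputs"
  res <- tryCatch({
    cohorts <- list()       # per subtype: list(cohort, alu, nat, snps)
    if (hasSim) {
      sim <- cfg$simulation
      subtypes <- sim$subtypes
      if (is.null(subtypes)) subtypes <- sim$subtype
      if (is.null(subtypes)) subtypes <- "ER+"
      sim$subtypes <- NULL
      for (st in subtypes) {
        args <- sim
        args$subtype <- st
        args$seed <- childSeed(cfg$seed, paste0("cohort:", st))
        s <- simulateCohort(do.call(cohortSimConfig, args))
        cohorts[[st]] <- list(cohort = s$cohort, alu = s$alu,
                              nat = s$nat, snps = s$snps,
                              truth = s$truth)
      }
    } else {
      manifest <- readSampleManifest(cfg$inputs$manifest)
      full <- loadCohort(manifest, baseDir = dirname(cfg$inputs$manifest))
      alu <- readIntervalBed(cfg$inputs$alu, kind = "alu")
      nat <- readIntervalBed(cfg$inputs$nat, kind = "nat")
      snps <- if (grepl("\\.vcf$", cfg$inputs$snps))
        readSnpVcf(cfg$inputs$snps)
      else readIntervalBed(cfg$inputs$snps, kind = "snp")
      for (st in unique(manifest$subtype)) {
        sub <- full[manifest$subtype == st]
        cohorts[[st]] <- list(cohort = sub, alu = alu, nat = nat,
                              snps = snps)
      }
    }

    stage <- "filter"
    filterReports <- list()
    for (st in names(cohorts)) {
      f <- filterCohort(cohorts[[st]]$cohort, cohorts[[st]]$alu,
                        cohorts[[st]]$snps,
                        lenient = isTRUE(cfg$filters$lenient),
                        allelic = !isFALSE(cfg$filters$allelic))
      cohorts[[st]]$filtered <- f$cohort
      filterReports[[st]] <- f$report
    }
    pooled <- filterReports[[1]]
    if (length(filterReports) > 1) {
      for (r in filterReports[-1]) {
        pooled$input_count <- pooled$input_count + r$input_count
        pooled$retained_count <- pooled$retained_count + r$retained_count
        pooled$excluded_count <- pooled$excluded_count + r$excluded_count
      }
      pooled$excluded_fraction <- ifelse(
        pooled$input_count > 0,
        pooled$excluded_count / pooled$input_count, 0)
    }

    stage <- "burden"
    burden <- do.call(rbind, lapply(names(cohorts), function(st)
      burdenCounts(cohorts[[st]]$filtered)))
    comparisons <- lapply(names(cohorts), function(st)
      compareBurden(burden, st))
    names(comparisons) <- names(cohorts)

    stage <- "prioritize"
    pz <- cfg$prioritization
    candidates <- lapply(names(cohorts), function(st)
      prioritizeSites(cohorts[[st]]$filtered, cohorts[[st]]$nat,
                      subtype = st,
                      minPrevalence = pz$min_prevalence,
                      zThreshold = pz$z_threshold,
                      scale = pz$ratio_scale))
    names(candidates) <- names(cohorts)

    stage <- "intersect"
    intersection <- if (length(candidates) >= 2)
      intersectSubtypes(candidates[[1]], candidates[[2]])
    else data.frame(chrom = character(), pos = integer())

    stage <- "report"
    summary <- list(
      package = "natedit",
      version = as.character(utils::packageVersion("natedit")),
      seed = cfg$seed,
      parameters = list(filters = cfg$filters,
                        prioritization = cfg$prioritization,
                        simulation = cfg$simulation),
      stages = list(
        samples = sum(vapply(cohorts, function(x) length(x$cohort),
                             numeric(1))),
        filter = pooled,
        burden = lapply(comparisons, function(x)
          x[c("subtype", "nTumor", "nAdjacent", "medianTumor",
              "medianAdjacent", "U", "pValue", "method")]),
        candidates = lapply(candidates, length),
        intersection = nrow(intersection)
      ))

    if (!is.null(cfg$out_dir)) {
      dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
      w <- function(df, f) utils::write.table(
        df, file.path(cfg$out_dir, f), sep = "\t", quote = FALSE,
        row.names = FALSE)
      w(pooled, "filter_report.tsv")
      w(burden, "burden.tsv")
      for (st in names(candidates)) {
        safe <- gsub("\\+", "pos", st)
        w(candidateRecords(candidates[[st]]),
          sprintf("candidates_%s.tsv", safe))
      }
      w(intersection, "intersection.tsv")
      jsonlite::write_json(summary,
                           file.path(cfg$out_dir, "summary.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    list(summary = summary, cohorts = cohorts, filterReport = pooled,
         burden = burden, comparisons = comparisons,
         candidates = candidates, intersection = intersection)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(res)
}
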