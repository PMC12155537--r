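## qPCR relative quantification (2^-ddCt) and first-order decay fitting
## for actinomycin-D transcription-shutoff time courses.

#' Relative expression by the 2^-ddCt method
#'
#' Technical replicate rows (identical \code{sample_label, condition,
#' timepoint_hours, gene, replicate}) are averaged on the Ct scale first;
#' the \code{replicate} column itself denotes biological replicates, which
#' are kept separate. Per stratum, \code{dCt = Ct_target - Ct_reference};
#' \code{ddCt = dCt - dCt_calibrator}; \code{fold = 2^-ddCt}. The
#' calibrator stratum is chosen by \code{calibratorCondition} and/or
#' \code{calibratorTimepoint}, matched within the same
#' (\code{sample_label}, \code{replicate}) when possible, then within the
#' replicate, then as the mean over all calibrator strata.
#'
#' @param ct a Ct table (see \code{\link{readCtTable}}).
#' @param targetGene,referenceGene gene names in the table.
#' @param calibratorCondition condition whose dCt defines ddCt = 0.
#' @param calibratorTimepoint timepoint (hours) defining the calibrator,
#'   e.g. 0 for a decay series.
#' @return data.frame with one row per (sample, condition, timepoint,
#'   replicate): \code{delta_ct, delta_delta_ct, fold_change}.
#' @export
ddct <- function(ct, targetGene, referenceGene,
                 calibratorCondition = NULL, calibratorTimepoint = NULL) {
  ct <- validateCtTable(ct)
  if (is.null(calibratorCondition) && is.null(calibratorTimepoint))
    stop("give calibratorCondition and/or calibratorTimepoint")
  ct <- ct[ct$gene %in% c(targetGene, referenceGene), , drop = FALSE]
  if (!any(ct$gene == targetGene)) stop("no rows for target gene ",
                                        targetGene)
  if (!any(ct$gene == referenceGene)) stop("no rows for reference gene ",
                                           referenceGene)
  ## average technical replicates on the Ct scale
  agg <- stats::aggregate(
    ct ~ sample_label + condition + timepoint_hours + replicate + gene,
    data = ct, FUN = mean)
  tg <- agg[agg$gene == targetGene, , drop = FALSE]
  rf <- agg[agg$gene == referenceGene, , drop = FALSE]
  key <- function(d) paste(d$sample_label, d$condition, d$timepoint_hours,
                           d$replicate)
  m <- match(key(tg), key(rf))
  if (anyNA(m))
    stop("missing reference-gene rows for ",
         sum(is.na(m)), " (sample, condition, timepoint, replicate) strata")
  out <- tg[, c("sample_label", "condition", "timepoint_hours",
                "replicate")]
  out$gene <- targetGene
  out$delta_ct <- tg$ct - rf$ct[m]

  isCal <- rep(TRUE, nrow(out))
  if (!is.null(calibratorCondition))
    isCal <- isCal & out$condition == calibratorCondition
  if (!is.null(calibratorTimepoint))
    isCal <- isCal & out$timepoint_hours == calibratorTimepoint
  if (!any(isCal)) stop("no calibrator rows found")
  calDct <- numeric(nrow(out))
  for (i in seq_len(nrow(out))) {
    same <- isCal & out$sample_label == out$sample_label[i] &
      out$replicate == out$replicate[i]
    if (!any(same)) same <- isCal & out$replicate == out$replicate[i]
    if (!any(same)) same <- isCal
    calDct[i] <- mean(out$delta_ct[same])
  }
  out$delta_delta_ct <- out$delta_ct - calDct
  out$fold_change <- 2^(-out$delta_delta_ct)
  rownames(out) <- NULL
  out
}

#' Fit first-order decay to an expression time course
#'
#' Ordinary least squares of \code{log(expression)} on time:
#' \eqn{\lambda = -slope} (floored at 0), half-life \eqn{\ln 2 / \lambda}.
#' A deterministic closed-form fit is adequate for the short time courses
#' this models (7 points over 8 h).
#'
#' @param time timepoints in hours (>= 3 values, including 0).
#' @param expression positive relative expression values (normalized to
#'   t = 0).
#' @param gene,condition labels stored on the fit.
#' @return A \linkS4class{DecayFit}.
#' @examples
#' t <- c(0, 0.5, 1, 2, 4, 6, 8)
#' halfLife(fitDecay(t, 2^(-t / 4)))  # 4 h
#' @export
fitDecay <- function(time, expression, gene = "", condition = "") {
  if (length(time) != length(expression))
    stop("time and expression lengths differ")
  if (length(time) < 3) stop("need >= 3 points")
  if (!any(time == 0)) stop("timepoints must include 0")
  if (any(expression <= 0)) stop("expression values must be positive")
  y <- log(expression)
  fit <- lm(y ~ time)
  slope <- unname(coef(fit)[2])
  lambda <- max(0, -slope)
  ## suppressWarnings: summary.lm warns on numerically perfect fits
  r2 <- if (stats::var(y) == 0) NA_real_
        else suppressWarnings(summary(fit)$r.squared)
  new("DecayFit", gene = gene, condition = condition,
      lambda = lambda,
      tHalfHours = if (lambda > 0) log(2) / lambda else Inf,
      intercept = unname(coef(fit)[1]),
      rSquared = r2, nPoints = length(time))
}

#' Fit per-replicate decay curves from a Ct table
#'
#' For each (condition, replicate), computes 2^-ddCt relative expression
#' calibrated at t = 0 and fits \code{\link{fitDecay}}.
#'
#' @param ct a Ct table covering a decay time course.
#' @param targetGene,referenceGene gene names.
#' @return Named list of \linkS4class{DecayFit}, one per
#'   (condition, replicate).
#' @export
decayFits <- function(ct, targetGene, referenceGene) {
  rel <- ddct(ct, targetGene, referenceGene, calibratorTimepoint = 0)
  split <- split(rel, paste(rel$condition, rel$replicate, sep = "."))
  lapply(split, function(d) {
    d <- d[order(d$timepoint_hours), , drop = FALSE]
    fitDecay(d$timepoint_hours, d$fold_change, gene = targetGene,
             condition = d$condition[1])
  })
}

#' Compare half-lives between two conditions
#'
#' Welch two-sample t-test on replicate-level half-life estimates, so a
#' p-value is defined without pooling curves.
#'
#' @param fitsA,fitsB lists of \linkS4class{DecayFit} (>= 2 replicates
#'   each, finite half-lives).
#' @return list with \code{meanA}, \code{meanB}, \code{difference}
#'   (A - B, hours), \code{tStatistic}, \code{df} and \code{pValue}.
#' @export
compareDecay <- function(fitsA, fitsB) {
  th <- function(fits) vapply(fits, halfLife, numeric(1))
  a <- th(fitsA); b <- th(fitsB)
  if (length(a) < 2 || length(b) < 2)
    stop("need >= 2 replicate fits per condition")
  if (any(!is.finite(c(a, b))))
    stop("non-finite half-life among replicates (no measurable decay)")
  res <- tryCatch(t.test(a, b), error = function(e) NULL)
  if (is.null(res)) {
    ## both groups constant: degenerate Welch test
    d <- mean(a) - mean(b)
    return(list(meanA = mean(a), meanB = mean(b), difference = d,
                tStatistic = NA_real_, df = NA_real_,
                pValue = if (d == 0) 1 else 0))
  }
  list(meanA = mean(a), meanB = mean(b),
       difference = unname(mean(a) - mean(b)),
       tStatistic = unname(res$statistic), df = unname(res$parameter),
       pValue = res$p.value)
}
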