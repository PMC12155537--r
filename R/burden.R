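## Per-sample editing burden and the tumor-vs-adjacent Mann-Whitney
## comparison. "Depth-normalized" burden is edited sites per million mapped
## reads, using the manifest's mapped-read count.

#' Per-sample edited-site burden
#'
#' Raw burden is the number of distinct edited positions (chrom, position)
#' in a sample's filtered call set; normalized burden is
#' \code{raw * 1e6 / mapped_reads} (sites per million mapped reads).
#'
#' @param cohort list of \linkS4class{EditingCallSet} with metadata joined
#'   from the manifest.
#' @return data.frame with one row per sample: \code{sample_id, subtype,
#'   group, mapped_reads, raw_count, normalized_count}.
#' @export
burdenCounts <- function(cohort) {
  rows <- lapply(cohort, function(x) {
    stopifnot(is(x, "EditingCallSet"))
    if (is.na(mappedReads(x)))
      stop("sample '", sampleId(x), "' has no mapped_reads; ",
           "join manifest metadata first")
    gr <- callRanges(x)
    raw <- length(unique(paste(seqnames(gr), start(gr))))
    data.frame(sample_id = sampleId(x), subtype = sampleSubtype(x),
               group = sampleGroup(x), mapped_reads = mappedReads(x),
               raw_count = raw,
               normalized_count = raw * 1e6 / mappedReads(x),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## Exact null distribution of the Mann-Whitney U statistic: counts[u + 1]
## is the number of the C(n1+n2, n1) rank splits with U = u. Computed with
## the q-binomial recurrence N(u; k, m) = N(u - m; k - 1, m) + N(u; k, m - 1)
## (partitions of u into at most n1 parts, each at most n2).
exactUCounts <- function(n1, n2) {
  maxU <- n1 * n2
  prev <- matrix(0, n2 + 1, maxU + 1)   # k = 0 rows: only u = 0
  prev[, 1] <- 1
  if (n1 == 0L) return(prev[n2 + 1, ])
  for (k in seq_len(n1)) {
    cur <- matrix(0, n2 + 1, maxU + 1)
    cur[1, 1] <- 1
    for (j in seq_len(n2)) {
      shifted <- c(rep(0, j), prev[j + 1, seq_len(maxU + 1 - j)])
      cur[j + 1, ] <- shifted + cur[j, ]
    }
    prev <- cur
  }
  prev[n2 + 1, ]
}

#' Mann-Whitney U test
#'
#' U is computed from joint mid-ranks. For tie-free samples with
#' \code{n1 + n2 <= 16} the two-sided p-value is exact, from the full null
#' distribution of U over all rank splits; otherwise a normal approximation
#' with continuity correction is used. For tie-free data the approximation
#' carries an Edgeworth kurtosis term (the null U distribution is
#' platykurtic; the term removes most of the tail error of the plain
#' normal curve); with ties, the tie-corrected variance is used and the
#' kurtosis term is dropped.
#'
#' @param x,y numeric vectors, both non-empty.
#' @param alternative only \code{"two.sided"} is supported.
#' @param exact \code{NULL} (auto: exact when tie-free and
#'   \code{n1 + n2 <= 16}), or \code{TRUE}/\code{FALSE} to force a mode;
#'   \code{exact = TRUE} with ties is an error.
#' @return \code{list(U = <U statistic for x>, pValue, method)} with
#'   \code{method} one of \code{"exact"}, \code{"normal_approx"}.
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mannWhitneyU <- function(x, y, alternative = "two.sided", exact = NULL) {
  alternative <- match.arg(alternative, "two.sided")
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  if (any(!is.finite(c(x, y)))) stop("inputs must be finite")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(x, y))
  hasTies <- any(ties > 1)
  useExact <- if (is.null(exact)) !hasTies && N <= 16L else isTRUE(exact)
  if (useExact && hasTies)
    stop("exact p-value is not defined in the presence of ties")
  if (useExact) {
    counts <- exactUCounts(n1, n2)
    total <- sum(counts)
    u <- round(U1)
    pLo <- sum(counts[seq_len(u + 1)]) / total            # P(U <= u)
    pHi <- sum(counts[(u + 1):(n1 * n2 + 1)]) / total     # P(U >= u)
    p <- min(1, 2 * min(pLo, pHi))
    return(list(U = U1, pValue = p, method = "exact"))
  }
  mu <- n1 * n2 / 2
  tieTerm <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tieTerm / (N * (N - 1)))
  if (sigma2 <= 0)
    return(list(U = U1, pValue = 1, method = "normal_approx"))
  sigma <- sqrt(sigma2)
  ## excess kurtosis of the null U distribution (tie-free case); the
  ## Edgeworth term corrects the platykurtic tails of U
  g2 <- if (hasTies) 0
        else -6 * (n1^2 + n2^2 + n1 * n2 + n1 + n2) /
             (5 * n1 * n2 * (N + 1))
  cdf <- function(u) {
    z <- (u + 0.5 - mu) / sigma      # continuity-corrected lower tail
    pnorm(z) - dnorm(z) * (g2 / 24) * (z^3 - 3 * z)
  }
  pLo <- cdf(U1)
  pHi <- 1 - cdf(U1 - 1)
  p <- min(1, max(0, 2 * min(pLo, pHi)))
  list(U = U1, pValue = p, method = "normal_approx")
}

#' Tumor vs adjacent burden comparison within one subtype
#'
#' Applies the Mann-Whitney test to depth-normalized burden within a single
#' subtype; subtypes are never pooled.
#'
#' @param burden data.frame from \code{\link{burdenCounts}}.
#' @param subtype \code{"ER+"} or \code{"TNBC"}.
#' @param measure column to compare (default \code{"normalized_count"}).
#' @return list with \code{subtype}, group sizes, group medians, \code{U},
#'   \code{pValue} and \code{method}.
#' @export
compareBurden <- function(burden, subtype,
                          measure = "normalized_count") {
  stopifnot(measure %in% names(burden))
  b <- burden[burden$subtype == subtype, , drop = FALSE]
  xt <- b[[measure]][b$group == "tumor"]
  xa <- b[[measure]][b$group == "adjacent"]
  if (length(xt) < 2 || length(xa) < 2)
    stop("need >= 2 samples per group in subtype ", subtype)
  mw <- mannWhitneyU(xt, xa)
  list(subtype = subtype, nTumor = length(xt), nAdjacent = length(xa),
       medianTumor = median(xt), medianAdjacent = median(xa),
       U = mw$U, pValue = mw$pValue, method = mw$method,
       measure = measure)
}
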