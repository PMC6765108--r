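#' Group accepted mutations by inter-mutation distance
#'
#' Within each chromosome, consecutive accepted mutations (homozygous or
#' heterozygous) separated by no more than \code{dMax} bases (default
#' 100 kb) are collected into one group; groups never span chromosomes,
#' and the groups partition the accepted mutations.
#'
#' @param callset a filtered \code{\link{BirCallset}}.
#' @param dMax maximum gap in bases between consecutive group members.
#' @return GRanges with one range per group (first to last member
#'   position) and metadata columns \code{k} (mutation count),
#'   \code{span} (bases, \code{end - start + 1}) and \code{members}
#'   (IntegerList of member positions).
#' @examples
#' # three mutations, gaps 49.9 kb and 150 kb -> two groups
#' @export
groupByDistance <- function(callset, dMax = 100000L) {
  v <- acceptedVariants(callset)
  if (length(v) == 0L) {
    out <- GenomicRanges::GRanges()
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
      k = integer(), span = integer(),
      members = IRanges::IntegerList())
    return(out)
  }
  v <- BiocGenerics::sort(GenomeInfoDb::sortSeqlevels(v),
                           ignore.strand = TRUE)
  chrom <- as.character(GenomicRanges::seqnames(v))
  pos <- GenomicRanges::start(v)
  newGroup <- c(TRUE, diff(pos) > dMax | chrom[-1L] != chrom[-length(chrom)])
  gid <- cumsum(newGroup)
  posByGroup <- S4Vectors::splitAsList(pos, gid)
  chromByGroup <- vapply(split(chrom, gid), `[`, "", 1L)
  first <- vapply(split(pos, gid), min, 0)
  last <- vapply(split(pos, gid), max, 0)
  out <- GenomicRanges::GRanges(
    chromByGroup, IRanges::IRanges(first, last),
    seqinfo = GenomeInfoDb::seqinfo(v))
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    k = unname(lengths(posByGroup)),
    span = as.integer(last - first + 1),
    members = posByGroup)
  names(out) <- NULL
  out
}

#' Cluster p-value under the negative-binomial spacing null
#'
#' Under the null, each of the k-1 gaps between consecutive mutations of
#' a group is an independent geometric variable on {1, 2, ...} with
#' success probability \code{pi} (the per-base mutation probability).
#' The p-value is the probability that the k-1 gaps sum to at most the
#' observed span, i.e. the negative-binomial CDF at span-(k-1) failures
#' for k-1 required successes. Singletons carry no spacing evidence and
#' return 1.
#'
#' @param k mutation count(s) of the group(s).
#' @param span group span(s) in bases (last - first + 1).
#' @param null a \code{\link{ClusterNullModel}} or a bare probability
#'   \code{pi}.
#' @return p-value(s) in (0, 1].
#' @examples
#' clusterPvalue(2, 1, 0.5)       # single 1-base gap: exactly pi
#' clusterPvalue(3, 100, 1e-4)    # two tight gaps, very small p
#' @export
clusterPvalue <- function(k, span, null) {
  pi <- if (is(null, "ClusterNullModel")) null@pi else as.numeric(null)
  if (pi <= 0 || pi >= 1)
    stop("per-base mutation probability pi must lie strictly in (0,1)")
  stopifnot(all(k >= 1), all(span >= 1))
  n <- max(length(k), length(span))
  k <- rep_len(k, n); span <- rep_len(span, n)
  p <- rep(1, n)
  multi <- k >= 2
  p[multi] <- stats::pnbinom(span[multi] - (k[multi] - 1),
                             size = k[multi] - 1, prob = pi)
  p
}

#' Call mutation clusters from distance groups
#'
#' Evaluates every group against the negative-binomial spacing null and
#' labels groups with p-value strictly below \code{alpha} (default 0.01)
#' as mutation clusters. No multiplicity adjustment is applied.
#'
#' @param groups GRanges from \code{\link{groupByDistance}}.
#' @param null a \code{\link{ClusterNullModel}}.
#' @param alpha significance threshold; strict inequality.
#' @return The input GRanges with added columns \code{pValue},
#'   \code{isCluster}, \code{lengthKb} and \code{densityPerKb}.
#' @export
callClusters <- function(groups, null, alpha = 0.01) {
  mc <- S4Vectors::mcols(groups)
  p <- if (length(groups))
    clusterPvalue(mc$k, mc$span, null) else numeric()
  mc$pValue <- p
  mc$isCluster <- p < alpha
  mc$lengthKb <- mc$span / 1000
  mc$densityPerKb <- mc$k / (mc$span / 1000)
  S4Vectors::mcols(groups) <- mc
  groups
}

#' Summarize called clusters
#'
#' @param clusters output of \code{\link{callClusters}}.
#' @return data.frame over the called clusters only (isCluster TRUE)
#'   with columns chrom, start, end, k, length_kb, density_per_kb,
#'   p_value.
#' @export
clusterSummaries <- function(clusters) {
  mc <- S4Vectors::mcols(clusters)
  keep <- which(mc$isCluster)
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(clusters))[keep],
    start = GenomicRanges::start(clusters)[keep],
    end = GenomicRanges::end(clusters)[keep],
    k = mc$k[keep],
    length_kb = mc$lengthKb[keep],
    density_per_kb = mc$densityPerKb[keep],
    p_value = mc$pValue[keep],
    stringsAsFactors = FALSE)
}

#' Compare cluster metrics (or rates) between two conditions
#'
#' Two-sided Mann-Whitney U test with mid-rank handling of ties (exact
#' enumeration for small untied samples, normal approximation
#' otherwise), as used for per-cluster mutation counts, lengths,
#' densities and for median mutation rates.
#'
#' @param valuesA,valuesB non-empty numeric vectors.
#' @return list with \code{medianA}, \code{medianB}, \code{pValue}.
#' @export
compareClusterMetrics <- function(valuesA, valuesB) {
  if (!length(valuesA) || !length(valuesB))
    stop("both value sets must be non-empty")
  p <- suppressWarnings(
    stats::wilcox.test(valuesA, valuesB, exact = NULL,
                       correct = TRUE)$p.value)
  list(medianA = stats::median(valuesA),
       medianB = stats::median(valuesB),
       pValue = unname(p))
}

#' Mann-Whitney comparison of rate sets
#'
#' Same statistic as \code{\link{compareClusterMetrics}}; exported under
#' the name used in the rate workflow.
#' @inheritParams compareClusterMetrics
#' @return two-sided Mann-Whitney p-value.
#' @export
compareRateSets <- function(valuesA, valuesB) {
  compareClusterMetrics(valuesA, valuesB)$pValue
}

#' Co-localize clusters with rearrangement breakpoints
#'
#' For every cluster, finds the nearest breakpoint on the same
#' chromosome and reports its distance to the cluster interval (0 when
#' the breakpoint falls inside the cluster) and whether it lies within
#' \code{maxDist}.
#'
#' @param clusters GRanges of (called) clusters.
#' @param breakpoints data.frame with columns \code{chrom}, \code{pos},
#'   e.g. from \code{\link{detectCopySteps}}.
#' @param maxDist window in bases for \code{withinWindow}.
#' @return data.frame with one row per cluster: chrom, start, end,
#'   nearest_breakpoint (NA when the chromosome has none), distance,
#'   within_window.
#' @export
colocalizeClustersBreakpoints <- function(clusters, breakpoints,
                                          maxDist = 10000L) {
  n <- length(clusters)
  chrom <- as.character(GenomicRanges::seqnames(clusters))
  start <- GenomicRanges::start(clusters)
  end <- GenomicRanges::end(clusters)
  nearest <- rep(NA_real_, n); dist <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    bp <- breakpoints$pos[breakpoints$chrom == chrom[i]]
    if (!length(bp)) next
    d <- ifelse(bp < start[i], start[i] - bp,
                ifelse(bp > end[i], bp - end[i], 0))
    j <- which.min(d)
    nearest[i] <- bp[j]; dist[i] <- d[j]
  }
  data.frame(chrom = chrom, start = start, end = end,
             nearest_breakpoint = nearest, distance = dist,
             within_window = !is.na(dist) & dist <= maxDist,
             stringsAsFactors = FALSE)
}
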