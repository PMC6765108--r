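#' Filter a VCF and call mutation clusters in one pass
#'
#' Convenience wrapper running the standard chain on one isolate:
#' \code{\link{readVariants}} -> \code{\link{applySiteFilters}} ->
#' \code{\link{clusterNullModel}} -> \code{\link{groupByDistance}} ->
#' \code{\link{callClusters}}.
#'
#' @param vcfPath VCF file of the isolate.
#' @param disomicRegions GRanges of two-copy regions (chromosome III of
#'   the disome).
#' @param chromLengths named chromosome lengths; default from the VCF
#'   header.
#' @param mask optional GRanges mask.
#' @param recurrence optional recurrence table.
#' @param minAltReads minimum alt-supporting reads.
#' @param dMax grouping distance in bases.
#' @param alpha cluster significance threshold.
#' @param genomeSize analyzable genome size; default sum of chromosome
#'   lengths.
#' @return list with \code{callset}, \code{null}, \code{clusters}
#'   (clusters is NULL when no mutations are accepted).
#' @export
analyzeIsolateVcf <- function(vcfPath, disomicRegions,
                              chromLengths = NULL, mask = NULL,
                              recurrence = NULL, minAltReads = 10L,
                              dMax = 100000L, alpha = 0.01,
                              genomeSize = NULL) {
  cs <- readVariants(vcfPath, chromLengths = chromLengths,
                     disomicRegions = disomicRegions)
  if (is.list(cs) && !is(cs, "BirCallset"))
    stop("multi-sample VCF: run readVariants per sample instead")
  cs <- applySiteFilters(cs, minAltReads = minAltReads, mask = mask,
                         recurrence = recurrence)
  m <- length(acceptedVariants(cs))
  if (m == 0L)
    return(list(callset = cs, null = NULL, clusters = NULL))
  null <- clusterNullModel(cs, genomeSize = genomeSize)
  groups <- groupByDistance(cs, dMax = dMax)
  list(callset = cs, null = null,
       clusters = callClusters(groups, null, alpha = alpha))
}
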