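#' @import methods
#' @importFrom GenomicRanges GRanges
#' @importFrom S4Vectors DataFrame
NULL

ZYGOSITY_LEVELS <- c("homozygous", "heterozygous", "ambiguous", "rejected")

#' Callset of single-nucleotide variants for one isolate
#'
#' A \code{BirCallset} holds the SNV calls of one sequenced isolate as a
#' \link[GenomicRanges]{GRanges} (width-1 ranges, 1-based) with metadata
#' columns \code{ref}, \code{alt}, \code{depth}, \code{altReads},
#' \code{altFraction}, \code{zygosity} and \code{rejectReason}, together
#' with the regions of the genome known to be disomic (two copies; here
#' chromosome III of the disomic strain), where heterozygous calls at
#' allele fractions near 0.5 are biologically expected.
#'
#' Chromosome lengths travel as \code{seqlengths} of the variant ranges.
#'
#' @slot variants GRanges of width-1 SNV records.
#' @slot sampleId single character identifier of the isolate.
#' @slot disomicRegions GRanges of regions with copy number 2.
#' @slot droppedNonSnv number of non-SNV input records dropped at read time.
#'
#' @seealso \code{\link{readVariants}}, \code{\link{applySiteFilters}}
#' @export
setClass("BirCallset",
  representation(
    variants = "GRanges",
    sampleId = "character",
    disomicRegions = "GRanges",
    droppedNonSnv = "integer"
  ),
  prototype(
    variants = GenomicRanges::GRanges(),
    sampleId = NA_character_,
    disomicRegions = GenomicRanges::GRanges(),
    droppedNonSnv = 0L
  )
)

setValidity("BirCallset", function(object) {
  v <- object@variants
  msg <- character()
  need <- c("ref", "alt", "depth", "altReads", "altFraction",
            "zygosity", "rejectReason")
  missing <- setdiff(need, colnames(S4Vectors::mcols(v)))
  if (length(missing))
    msg <- c(msg, paste("missing variant columns:",
                        paste(missing, collapse = ", ")))
  if (length(v) && !length(missing)) {
    mc <- S4Vectors::mcols(v)
    if (any(GenomicRanges::width(v) != 1L))
      msg <- c(msg, "all variant ranges must have width 1")
    if (any(GenomicRanges::start(v) < 1L))
      msg <- c(msg, "positions must be >= 1")
    if (any(mc$ref == mc$alt))
      msg <- c(msg, "ref must differ from alt")
    if (any(mc$altReads > mc$depth | mc$altReads < 0L))
      msg <- c(msg, "altReads must lie in [0, depth]")
    ok <- is.na(mc$altFraction) |
      (mc$altFraction >= 0 & mc$altFraction <= 1)
    if (!all(ok))
      msg <- c(msg, "altFraction must be in [0,1] or NA")
    sl <- GenomeInfoDb::seqlengths(v)
    has <- !is.na(sl[as.character(GenomicRanges::seqnames(v))])
    over <- has & GenomicRanges::end(v) >
      sl[as.character(GenomicRanges::seqnames(v))]
    if (any(over))
      msg <- c(msg, "variant position beyond chromosome length")
    if (!all(mc$zygosity %in% ZYGOSITY_LEVELS))
      msg <- c(msg, "invalid zygosity level")
  }
  if (length(object@sampleId) != 1L)
    msg <- c(msg, "sampleId must be a single string")
  if (length(msg)) msg else TRUE
})

#' Negative-binomial null model for mutation clustering
#'
#' The null assumes the sample's \code{m} accepted mutations fall
#' independently and uniformly on the \code{G} analyzable (unmasked)
#' bases of the genome, so that successive inter-mutation distances are
#' geometric with per-base success probability \code{pi = m/G}, and the
#' total span of a group of k mutations is governed by a negative
#' binomial with k-1 required successes.
#'
#' @slot G analyzable genome size in bases (masked bases excluded).
#' @slot m total accepted mutations in the sample.
#' @slot pi per-base mutation probability, \code{m/G}.
#'
#' @seealso \code{\link{clusterPvalue}}, \code{\link{clusterNullModel}}
#' @export
setClass("ClusterNullModel",
  representation(G = "numeric", m = "numeric", pi = "numeric"))

setValidity("ClusterNullModel", function(object) {
  msg <- character()
  if (length(object@G) != 1L || object@G <= 0)
    msg <- c(msg, "G must be a positive scalar")
  if (length(object@m) != 1L || object@m < 0)
    msg <- c(msg, "m must be a non-negative scalar")
  if (length(object@pi) != 1L || object@pi <= 0 || object@pi >= 1)
    msg <- c(msg, "pi must lie strictly in (0,1)")
  if (length(msg)) msg else TRUE
})

#' Construct a cluster null model
#'
#' @param x either a \code{BirCallset} (the accepted mutations define m)
#'   or a numeric mutation count m.
#' @param genomeSize analyzable genome size in bases; for a callset this
#'   defaults to the sum of its chromosome lengths minus
#'   \code{maskedBases}.
#' @param maskedBases number of masked (excluded) bases to subtract when
#'   \code{genomeSize} is derived from the callset.
#' @return A \code{ClusterNullModel}.
#' @examples
#' null <- clusterNullModel(28, genomeSize = 12e6)
#' null@pi
#' @export
clusterNullModel <- function(x, genomeSize = NULL, maskedBases = 0) {
  if (is(x, "BirCallset")) {
    m <- length(acceptedVariants(x))
    if (is.null(genomeSize)) {
      sl <- GenomeInfoDb::seqlengths(variantRecords(x))
      if (anyNA(sl))
        stop("callset has chromosomes without lengths; supply genomeSize")
      genomeSize <- sum(as.numeric(sl)) - maskedBases
    }
  } else {
    m <- as.numeric(x)
    if (is.null(genomeSize))
      stop("genomeSize is required when m is given directly")
  }
  new("ClusterNullModel", G = as.numeric(genomeSize), m = m,
      pi = m / genomeSize)
}

setMethod("show", "BirCallset", function(object) {
  v <- object@variants
  z <- table(factor(S4Vectors::mcols(v)$zygosity, levels = ZYGOSITY_LEVELS))
  cat("BirCallset for sample", object@sampleId, "\n")
  cat(" ", length(v), "SNV records (", object@droppedNonSnv,
      "non-SNV input records dropped )\n")
  cat("  zygosity:", paste(names(z), z, sep = "=", collapse = " "), "\n")
  cat("  disomic regions:", length(object@disomicRegions), "\n")
})

setMethod("show", "ClusterNullModel", function(object) {
  cat("ClusterNullModel: m =", object@m, "mutations over G =", object@G,
      "bases (pi =", signif(object@pi, 4), ")\n")
})
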