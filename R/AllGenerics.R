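#' Accessors for BirCallset objects
#'
#' @param x a \code{BirCallset}.
#' @return \code{variantRecords} returns the full variant GRanges;
#'   \code{acceptedVariants} only the records whose zygosity is
#'   homozygous or heterozygous (the set used for clustering);
#'   \code{sampleId} the isolate identifier; \code{disomicRegions} the
#'   GRanges of two-copy regions.
#' @name BirCallset-accessors
NULL

#' @rdname BirCallset-accessors
#' @export
setGeneric("variantRecords", function(x) standardGeneric("variantRecords"))

#' @rdname BirCallset-accessors
#' @export
setGeneric("acceptedVariants", function(x) standardGeneric("acceptedVariants"))

#' @rdname BirCallset-accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname BirCallset-accessors
#' @export
setGeneric("disomicRegions", function(x) standardGeneric("disomicRegions"))

#' @rdname BirCallset-accessors
setMethod("variantRecords", "BirCallset", function(x) x@variants)

#' @rdname BirCallset-accessors
setMethod("acceptedVariants", "BirCallset", function(x) {
  v <- x@variants
  v[S4Vectors::mcols(v)$zygosity %in% c("homozygous", "heterozygous")]
})

#' @rdname BirCallset-accessors
setMethod("sampleId", "BirCallset", function(x) x@sampleId)

#' @rdname BirCallset-accessors
setMethod("disomicRegions", "BirCallset", function(x) x@disomicRegions)
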