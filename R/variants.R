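#' Read SNV calls for one (or every) sample of a VCF
#'
#' Parses a VCF v4.x file through \pkg{VariantAnnotation}, retains
#' single-nucleotide substitutions only (indels and MNVs are dropped
#' with a logged count), splits multi-allelic sites into one record per
#' alternative allele, and builds a \code{\link{BirCallset}} per sample.
#' Per-sample depth (\code{DP}) and allele depth (\code{AD}) are
#' required; their absence is a hard error naming the file.
#'
#' Records with zero depth are kept but immediately marked
#' \code{rejected} with reason \code{"zero depth"}, since their allele
#' fraction is undefined.
#'
#' @param path VCF file path.
#' @param sampleIds samples to extract; default all samples in the file.
#' @param chromLengths named vector of chromosome lengths; defaults to
#'   the contig lengths declared in the VCF header.
#' @param disomicRegions GRanges of regions carried at copy number 2
#'   (chromosome III of the disome); used later by zygosity
#'   classification.
#' @return A \code{BirCallset}, or a named list of them when the file
#'   holds several samples and \code{sampleIds} selects more than one.
#' @examples
#' vcf <- system.file("extdata", "toy.vcf", package = "kataegisBIR")
#' cs <- readVariants(vcf)
#' cs
#' @export
readVariants <- function(path, sampleIds = NULL, chromLengths = NULL,
                         disomicRegions = GenomicRanges::GRanges()) {
  vcf <- VariantAnnotation::readVcf(path)
  if (nrow(vcf) > 0L) vcf <- VariantAnnotation::expand(vcf)
  if (!all(c("DP", "AD") %in% rownames(VariantAnnotation::geno(
      VariantAnnotation::header(vcf)))))
    stop("VCF ", path, " lacks per-sample DP and/or AD FORMAT fields")

  rr <- SummarizedExperiment::rowRanges(vcf)
  refs <- if (nrow(vcf)) as.character(VariantAnnotation::ref(vcf)) else character(0)
  alts <- if (nrow(vcf)) as.character(VariantAnnotation::alt(vcf)) else character(0)
  isSnv <- nchar(refs) == 1L & nchar(alts) == 1L &
    refs %in% c("A", "C", "G", "T") & alts %in% c("A", "C", "G", "T") &
    refs != alts
  nDropped <- sum(!isSnv)
  if (nDropped > 0)
    message("readVariants: dropped ", nDropped, " non-SNV record(s)")

  dp <- VariantAnnotation::geno(vcf)$DP
  ad <- VariantAnnotation::geno(vcf)$AD
  samples <- colnames(vcf)
  if (is.null(sampleIds)) sampleIds <- samples
  unknown <- setdiff(sampleIds, samples)
  if (length(unknown))
    stop("sample(s) not present in ", path, ": ",
         paste(unknown, collapse = ", "))

  if (is.null(chromLengths)) {
    hdr <- VariantAnnotation::header(vcf)
    contigs <- tryCatch(VariantAnnotation::meta(hdr)$contig, error = function(e) NULL)
    if (!is.null(contigs) && "length" %in% colnames(contigs))
      chromLengths <- stats::setNames(as.numeric(contigs[, "length"]),
                                      rownames(contigs))
  }

  makeOne <- function(sid) {
    j <- match(sid, samples)
    depth <- as.integer(dp[, j])
    # AD after expand(): matrix when the field expands to (ref, alt)
    # pairs, list-matrix otherwise
    if (is.list(ad)) {
      altReads <- vapply(ad[, j], function(x) {
        if (length(x) >= 2L) as.integer(x[[2L]]) else NA_integer_
      }, integer(1))
    } else if (length(dim(ad)) == 3L) {
      altReads <- as.integer(ad[, j, 2L])
    } else {
      altReads <- as.integer(ad[, j])
    }
    if (anyNA(depth[isSnv]) || anyNA(altReads[isSnv])) {
      bad <- which(isSnv & (is.na(depth) | is.na(altReads)))[1L]
      stop("missing DP/AD for sample ", sid, " at ",
           as.character(GenomicRanges::seqnames(rr))[bad], ":",
           GenomicRanges::start(rr)[bad], " in ", path)
    }
    keep <- isSnv
    gr <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(rr)[keep],
      IRanges::IRanges(GenomicRanges::start(rr)[keep], width = 1L))
    d <- depth[keep]; a <- altReads[keep]
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      ref = refs[keep], alt = alts[keep],
      depth = d, altReads = a,
      altFraction = ifelse(d > 0L, a / d, NA_real_),
      zygosity = ifelse(d > 0L, "ambiguous", "rejected"),
      rejectReason = ifelse(d > 0L, NA_character_, "zero depth"))
    names(gr) <- NULL
    if (!is.null(chromLengths)) {
      lv <- union(GenomeInfoDb::seqlevels(gr), names(chromLengths))
      GenomeInfoDb::seqlevels(gr) <- lv
      GenomeInfoDb::seqlengths(gr)[names(chromLengths)] <- chromLengths
    }
    new("BirCallset", variants = gr, sampleId = sid,
        disomicRegions = disomicRegions, droppedNonSnv = as.integer(nDropped))
  }

  out <- lapply(sampleIds, makeOne)
  names(out) <- sampleIds
  if (length(out) == 1L) out[[1L]] else out
}

#' Read a genome mask from BED
#'
#' BED intervals are 0-based half-open on disk; \pkg{rtracklayer}
#' converts them to 1-based closed GRanges on import, which is the single
#' point of coordinate conversion in the package. Column 4 (name) is kept
#' as the mask \code{category} (e.g. "telomeric repeats", "LTR").
#'
#' @param path BED file path.
#' @return GRanges with a \code{category} metadata column.
#' @export
readGenomeMask <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  cat_ <- if (!is.null(gr$name)) gr$name else rep("masked", length(gr))
  if (any(!nzchar(cat_) | is.na(cat_)))
    stop("mask categories must be non-empty strings")
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(category = cat_)
  gr
}

#' Tabulate variant recurrence across a cohort
#'
#' Counts, for every chrom/pos/alt key, in how many of the supplied
#' callsets (isolates plus, typically, the sequenced parental strain) the
#' variant was called. Variants seen in two or more samples -- which
#' includes anything shared with the parent -- are treated as inherited
#' or systematic rather than BIR-induced and are excluded downstream.
#'
#' @param callsets list of \code{BirCallset} (include the parent's).
#' @return data.frame with columns chrom, pos, alt, count.
#' @seealso \code{\link{applySiteFilters}}
#' @export
buildRecurrenceTable <- function(callsets) {
  if (is(callsets, "BirCallset")) callsets <- list(callsets)
  keys <- unlist(lapply(callsets, function(cs) {
    v <- variantRecords(cs)
    unique(paste(as.character(GenomicRanges::seqnames(v)),
                 GenomicRanges::start(v),
                 S4Vectors::mcols(v)$alt, sep = ":"))
  }))
  tab <- table(keys)
  parts <- strsplit(names(tab), ":", fixed = TRUE)
  data.frame(
    chrom = vapply(parts, `[`, "", 1L),
    pos = as.integer(vapply(parts, `[`, "", 2L)),
    alt = vapply(parts, `[`, "", 3L),
    count = as.integer(tab),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify variant zygosity from allele fraction
#'
#' Homozygous calls require the alternative allele in at least
#' \code{homMin} (default 90\%) of the reads, on any chromosome.
#' Within disomic regions (two chromosome copies, so a heterozygous
#' variant sits near 50\% allele fraction) fractions inside
#' \code{hetWindow} (default 27--70\%) are heterozygous; the unclaimed
#' band between the windows is reported as \code{ambiguous} rather than
#' silently merged. Outside disomic regions anything below \code{homMin}
#' is rejected with reason \code{"fraction"}.
#'
#' @param altFraction numeric vector of alt-allele fractions.
#' @param inDisomicRegion logical vector, recycled.
#' @param homMin minimum fraction for a homozygous call.
#' @param hetWindow length-2 numeric, closed heterozygous window.
#' @return character vector of zygosity levels.
#' @examples
#' classifyZygosity(c(0.95, 0.5, 0.8, 0.5),
#'                  inDisomicRegion = c(FALSE, TRUE, TRUE, FALSE))
#' @export
classifyZygosity <- function(altFraction, inDisomicRegion,
                             homMin = 0.90, hetWindow = c(0.27, 0.70)) {
  n <- length(altFraction)
  inDisomicRegion <- rep_len(inDisomicRegion, n)
  out <- rep("rejected", n)
  out[!is.na(altFraction) & altFraction >= homMin] <- "homozygous"
  het <- !is.na(altFraction) & inDisomicRegion &
    altFraction >= hetWindow[1L] & altFraction <= hetWindow[2L]
  out[het] <- "heterozygous"
  amb <- !is.na(altFraction) & inDisomicRegion &
    altFraction > hetWindow[2L] & altFraction < homMin
  out[amb] <- "ambiguous"
  out
}

#' Apply site filters and zygosity classification
#'
#' Implements the callset filters: minimum alternative-read support
#' (default 10 reads), exclusion of masked regions (telomeric repeats,
#' LTRs), exclusion of recurrent variants seen in multiple isolates or
#' in the parental strain, and allele-fraction zygosity classification.
#' Failing records are retained with \code{zygosity = "rejected"} and a
#' \code{rejectReason}; the operation recomputes every label from the
#' raw fields, so it is idempotent and order-independent.
#'
#' @param callset a \code{BirCallset}.
#' @param minAltReads minimum alt-supporting reads (the "at least 10
#'   reads" rule, interpreted as alt support).
#' @param mask GRanges mask (e.g. from \code{\link{readGenomeMask}}), or
#'   NULL.
#' @param recurrence recurrence table from
#'   \code{\link{buildRecurrenceTable}}, or NULL to skip the filter.
#' @param recurrenceMin samples (isolate cohort plus parent) in which a
#'   variant must appear to be rejected as recurrent.
#' @param homMin,hetWindow passed to \code{\link{classifyZygosity}}.
#' @return The filtered \code{BirCallset}.
#' @export
applySiteFilters <- function(callset, minAltReads = 10L, mask = NULL,
                             recurrence = NULL, recurrenceMin = 2L,
                             homMin = 0.90, hetWindow = c(0.27, 0.70)) {
  stopifnot(is(callset, "BirCallset"))
  v <- variantRecords(callset)
  if (length(v) == 0L) return(callset)
  mc <- S4Vectors::mcols(v)
  n <- length(v)
  # hard-filter reasons from earlier passes stay sticky (so chained
  # single-filter calls accumulate); the allele-fraction classification
  # is always recomputed
  reason <- ifelse(mc$zygosity == "rejected" & !is.na(mc$rejectReason) &
                     mc$rejectReason != "fraction",
                   mc$rejectReason, NA_character_)

  zero <- is.na(mc$altFraction) | mc$depth == 0L
  reason[zero] <- "zero depth"

  low <- is.na(reason) & mc$altReads < minAltReads
  reason[low] <- "min_alt_reads"

  if (!is.null(mask) && length(mask)) {
    maskChroms <- unique(as.character(GenomicRanges::seqnames(mask)))
    absent <- setdiff(maskChroms, GenomeInfoDb::seqlevels(v))
    if (length(absent)) {
      warning("mask chromosome(s) absent from callset, skipped: ",
              paste(absent, collapse = ", "))
      mask <- mask[!(as.character(GenomicRanges::seqnames(mask)) %in% absent)]
    }
    if (length(mask)) {
      hit <- IRanges::overlapsAny(v, mask, ignore.strand = TRUE)
      reason[is.na(reason) & hit] <- "masked"
    }
  }

  if (!is.null(recurrence) && nrow(recurrence)) {
    key <- paste(as.character(GenomicRanges::seqnames(v)),
                 GenomicRanges::start(v), mc$alt, sep = ":")
    recKey <- paste(recurrence$chrom, recurrence$pos, recurrence$alt,
                    sep = ":")
    cnt <- recurrence$count[match(key, recKey)]
    rec <- !is.na(cnt) & cnt >= recurrenceMin
    reason[is.na(reason) & rec] <- "recurrent"
  }

  inDisomic <- IRanges::overlapsAny(v, callset@disomicRegions,
                                          ignore.strand = TRUE)
  zyg <- classifyZygosity(mc$altFraction, inDisomic,
                          homMin = homMin, hetWindow = hetWindow)
  pass <- is.na(reason)
  newZyg <- ifelse(pass, zyg, "rejected")
  reason[pass & zyg == "rejected"] <- "fraction"

  mc$zygosity <- newZyg
  mc$rejectReason <- reason
  S4Vectors::mcols(v) <- mc
  callset@variants <- v
  validObject(callset)
  callset
}

#' Write a callset to TSV
#'
#' @param callset a \code{BirCallset}.
#' @param path output path.
#' @return Invisibly, the data.frame written.
#' @export
writeCallsetTsv <- function(callset, path) {
  v <- variantRecords(callset)
  mc <- S4Vectors::mcols(v)
  df <- data.frame(
    sample = sampleId(callset),
    chrom = as.character(GenomicRanges::seqnames(v)),
    pos = GenomicRanges::start(v),
    ref = mc$ref, alt = mc$alt, depth = mc$depth,
    alt_reads = mc$altReads, alt_fraction = mc$altFraction,
    zygosity = mc$zygosity, reject_reason = mc$rejectReason,
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
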