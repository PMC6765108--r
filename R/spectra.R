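COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Pyrimidine-normalized substitution classes
#'
#' Substitutions are reported on the strand carrying the mutated
#' pyrimidine: when \code{ref} is C or T the change is read as-is on the
#' plus (Watson) strand; otherwise ref and alt are complemented and the
#' change is assigned to the minus strand. This is the standard
#' six-class convention (C>A, C>G, C>T, T>A, T>C, T>G).
#'
#' @param ref,alt single reference/alternative bases (vectorized).
#' @return data.frame with columns \code{pyrChange} (e.g. "C>T") and
#'   \code{pyrStrand} ("+" or "-").
#' @examples
#' normalizeSubstitution(c("G", "C", "A"), c("A", "G", "C"))
#' @export
normalizeSubstitution <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  ok <- ref %in% names(COMPLEMENT) & alt %in% names(COMPLEMENT) & ref != alt
  if (!all(ok))
    stop("ref/alt must be distinct unambiguous bases (A/C/G/T)")
  isPyr <- ref %in% c("C", "T")
  pyrChange <- ifelse(isPyr,
                      paste0(ref, ">", alt),
                      paste0(COMPLEMENT[ref], ">", COMPLEMENT[alt]))
  data.frame(pyrChange = unname(pyrChange),
             pyrStrand = ifelse(isPyr, "+", "-"),
             stringsAsFactors = FALSE)
}

#' Trinucleotide context of a mutated pyrimidine
#'
#' Returns the 3-mer centered on the mutated base, read 5'->3' on the
#' strand carrying the pyrimidine (i.e. reverse-complemented when
#' \code{pyrStrand} is "-"). Positions at a chromosome edge have no
#' full context; they are returned as NA with a logged count and are
#' excluded from motif statistics.
#'
#' @param genome a \link[Biostrings]{DNAStringSet} (or path to a FASTA
#'   file, read on the fly).
#' @param chrom,pos,pyrStrand parallel vectors locating each mutation.
#' @return character vector of uppercase 3-mers (NA at edges).
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "ATCAG"))
#' motifContext(g, "chr1", 3, "+")   # "TCA"
#' @export
motifContext <- function(genome, chrom, pos, pyrStrand) {
  if (is.character(genome) && length(genome) == 1L)
    genome <- Biostrings::readDNAStringSet(genome)
  if (is.null(names(genome)))
    stop("genome sequences must be named by chromosome")
  names(genome) <- sub("\\s.*$", "", names(genome))
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  pyrStrand <- rep_len(pyrStrand, n)
  out <- rep(NA_character_, n)
  for (ch in unique(chrom)) {
    if (!ch %in% names(genome)) stop("chromosome absent from genome: ", ch)
    sel <- which(chrom == ch)
    len <- Biostrings::nchar(genome[[ch]])
    inner <- sel[pos[sel] > 1L & pos[sel] < len]
    if (length(inner)) {
      tri <- as.character(Biostrings::extractAt(
        genome[[ch]],
        IRanges::IRanges(pos[inner] - 1L, width = 3L)))
      out[inner] <- toupper(tri)
    }
  }
  minus <- !is.na(out) & pyrStrand == "-"
  if (any(minus))
    out[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(out[minus])))
  nEdge <- sum(is.na(out))
  if (nEdge > 0)
    message("motifContext: ", nEdge,
            " mutation(s) at chromosome edges excluded from motif statistics")
  out
}

#' TC / TCW motif fractions of cytosine mutations
#'
#' Counts, among mutations whose pyrimidine-strand trinucleotide context
#' is centered on a C, how many sit in a TC dinucleotide (APOBEC target)
#' and, of those, how many sit in the A3A-favored TCW motif (W = A or
#' T). \code{fracTCWofTC} is conditional on TC.
#'
#' @param trinucleotides character vector of pyrimidine-strand 3-mers
#'   (NAs ignored).
#' @return list with nTotal, nAtC, nTC, nTCW, fracTC, fracTCWofTC
#'   (fractions NA when their denominator is zero).
#' @examples
#' motifFractions(c("TCA", "TCT", "TCC", "GCA"))
#' @export
motifFractions <- function(trinucleotides) {
  tri <- trinucleotides[!is.na(trinucleotides)]
  atC <- substr(tri, 2L, 2L) == "C"
  tc <- atC & substr(tri, 1L, 1L) == "T"
  tcw <- tc & substr(tri, 3L, 3L) %in% c("A", "T")
  nAtC <- sum(atC); nTC <- sum(tc); nTCW <- sum(tcw)
  list(nTotal = length(tri), nAtC = nAtC, nTC = nTC, nTCW = nTCW,
       fracTC = if (nAtC > 0) nTC / nAtC else NA_real_,
       fracTCWofTC = if (nTC > 0) nTCW / nTC else NA_real_)
}

#' Strand bias of pyrimidine-strand assignments
#'
#' Two-sided exact binomial test of the plus/minus pyrimidine-strand
#' counts against equal probability.
#'
#' @param pyrStrand character vector of "+"/"-" assignments.
#' @return list with nPlus, nMinus, pValue (NA when no mutations).
#' @export
strandBias <- function(pyrStrand) {
  nPlus <- sum(pyrStrand == "+"); nMinus <- sum(pyrStrand == "-")
  n <- nPlus + nMinus
  p <- if (n > 0) stats::binom.test(nPlus, n, 0.5)$p.value else NA_real_
  list(nPlus = nPlus, nMinus = nMinus, pValue = unname(p))
}

#' Strand coordination within a cluster
#'
#' Counts strand switches between consecutive (position-ordered) cluster
#' mutations. Under the null of independent fair-coin strands the number
#' of switches among k-1 adjacent pairs is Binomial(k-1, 1/2); the
#' p-value is the exact lower tail P(switches <= observed), so
#' strand-coordinated runs (few switches) give small p.
#'
#' @param pyrStrand "+"/"-" assignments of >= 2 mutations ordered by
#'   position.
#' @return list with nSwitches, longestRun, pValue.
#' @examples
#' strandCoordination(c("+", "+", "+", "+"))  # p = 1/8
#' @export
strandCoordination <- function(pyrStrand) {
  k <- length(pyrStrand)
  if (k < 2L)
    return(list(nSwitches = NA_integer_, longestRun = k,
                pValue = NA_real_))
  switches <- sum(pyrStrand[-1L] != pyrStrand[-k])
  runs <- rle(pyrStrand)
  list(nSwitches = switches,
       longestRun = max(runs$lengths),
       pValue = stats::pbinom(switches, k - 1L, 0.5))
}

#' Classify a reporter reversion
#'
#' The ura3-29 reporter carries a C at its revertible position and can
#' revert to Ura+ only via C>T, C>G or C>A at that base.
#'
#' @param observedBase base read at the reporter position in a Ura+
#'   revertant.
#' @return one of "C>T", "C>G", "C>A".
#' @export
classifyReporterReversion <- function(observedBase) {
  observedBase <- toupper(observedBase)
  if (any(observedBase == "C"))
    stop("observed base C is the reference: not a revertant")
  map <- c(T = "C>T", G = "C>G", A = "C>A")
  if (any(!observedBase %in% names(map)))
    stop("observed base must be one of T, G, A")
  unname(map[observedBase])
}

#' Per-class comparison of two mutation spectra
#'
#' For each substitution class, compares its count against the rest
#' between the two conditions with a two-sided Fisher exact test.
#'
#' @param countsA,countsB named non-negative integer vectors over the
#'   same classes.
#' @return named numeric vector of p-values (all NA if either total is
#'   zero).
#' @export
compareSpectra <- function(countsA, countsB) {
  if (!identical(names(countsA), names(countsB)))
    stop("the two spectra must cover the same classes, in order")
  tA <- sum(countsA); tB <- sum(countsB)
  if (tA == 0 || tB == 0)
    return(stats::setNames(rep(NA_real_, length(countsA)), names(countsA)))
  vapply(seq_along(countsA), function(i) {
    m <- matrix(c(countsA[i], tA - countsA[i],
                  countsB[i], tB - countsB[i]), nrow = 2)
    stats::fisher.test(m)$p.value
  }, numeric(1), USE.NAMES = FALSE) -> p
  stats::setNames(p, names(countsA))
}

#' Annotate a callset with substitution classes and motif context
#'
#' Convenience wrapper combining \code{\link{normalizeSubstitution}} and
#' \code{\link{motifContext}} over the accepted mutations of a callset.
#'
#' @param callset a filtered \code{\link{BirCallset}}.
#' @param genome DNAStringSet or FASTA path.
#' @return data.frame with chrom, pos, ref, alt, zygosity, pyrChange,
#'   pyrStrand, trinucleotide.
#' @export
annotateSpectra <- function(callset, genome) {
  v <- acceptedVariants(callset)
  mc <- S4Vectors::mcols(v)
  if (length(v) == 0L)
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      zygosity = character(), pyrChange = character(),
                      pyrStrand = character(),
                      trinucleotide = character()))
  ns <- normalizeSubstitution(mc$ref, mc$alt)
  chrom <- as.character(GenomicRanges::seqnames(v))
  pos <- GenomicRanges::start(v)
  tri <- motifContext(genome, chrom, pos, ns$pyrStrand)
  data.frame(chrom = chrom, pos = pos, ref = mc$ref, alt = mc$alt,
             zygosity = mc$zygosity, pyrChange = ns$pyrChange,
             pyrStrand = ns$pyrStrand, trinucleotide = tri,
             stringsAsFactors = FALSE)
}
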