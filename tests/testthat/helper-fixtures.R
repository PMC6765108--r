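# fixtures are built in code: a direct BirCallset constructor bypassing
# VCF I/O, a minimal VCF writer, and a small simulator configuration

makeCallset <- function(pos, chrom = "chrIII",
                        ref = "C", alt = "T",
                        depth = 100L, altReads = 50L,
                        chromLengths = c(chrIII = 340000, chrV = 560000),
                        disomic = GenomicRanges::GRanges(
                          "chrIII", IRanges::IRanges(1, 340000)),
                        sampleId = "s1") {
  n <- length(pos)
  rep_ <- function(x) rep_len(x, n)
  gr <- GenomicRanges::GRanges(rep_(chrom), IRanges::IRanges(pos, width = 1))
  d <- rep_(depth); a <- rep_(altReads)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    ref = rep_(ref), alt = rep_(alt), depth = d, altReads = a,
    altFraction = ifelse(d > 0, a / d, NA_real_),
    zygosity = rep("ambiguous", n),
    rejectReason = rep(NA_character_, n))
  GenomeInfoDb::seqlevels(gr) <- names(chromLengths)
  GenomeInfoDb::seqlengths(gr) <- chromLengths
  methods::new("BirCallset", variants = gr, sampleId = sampleId,
               disomicRegions = disomic, droppedNonSnv = 0L)
}

writeVcfFixture <- function(path, rows,
                            contigs = c(chrIII = 340000, chrV = 560000),
                            sample = "s1") {
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", names(contigs), ",length=",
                  format(contigs, scientific = FALSE, trim = TRUE), ">"),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", sample, sep = "\t"))
  writeLines(c(hdr, rows), path)
  path
}

vcfRow <- function(chrom, pos, ref, alt, depth, altReads,
                   gt = "0/1") {
  paste(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT:DP:AD",
        paste0(gt, ":", depth, ":", depth - altReads, ",", altReads),
        sep = "\t")
}

# small, fast simulator configuration used across tests
smallSimParams <- function(...) {
  args <- list(seed = 11,
               chromLengths = c(chrIII = 120000, chrV = 200000),
               dsbPos = 60000, resectionMax = 30000,
               repeatPairs = data.frame(start = 70000, end = 90000),
               markerSpacing = 5000)
  override <- list(...)
  args[names(override)] <- override
  do.call(birSimParams, args)
}

disomicChrIII <- function(len = 340000)
  GenomicRanges::GRanges("chrIII", IRanges::IRanges(1, len))
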