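#' Build the simulated reference genome and its annotation
#'
#' Generates a random genome at the configured GC fraction (independent
#' bases; A and T each at (1-GC)/2, C and G each at GC/2), or passes a
#' supplied genome through unchanged, and derives the DSB site, the
#' repeat pairs usable for deletion-forming GCRs, and a phased
#' donor/recipient marker table along the disomic chromosome.
#' Deterministic given \code{params@seed}.
#'
#' @param params a \code{\link{BirSimParams}}.
#' @param genome optional \link[Biostrings]{DNAStringSet} to use instead
#'   of a generated one (names must cover \code{chromLengths}).
#' @return list with \code{genome} (DNAStringSet), \code{dsb}
#'   (list chrom, pos), \code{repeatPairs} (data.frame) and
#'   \code{markers} (data.frame pos, donorAllele, recipientAllele).
#' @export
buildGenome <- function(params, genome = NULL) {
  stopifnot(is(params, "BirSimParams"))
  set.seed(params@seed)
  lens <- params@chromLengths
  if (is.null(genome)) {
    gc <- params@gcFraction
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    seqs <- vapply(lens, function(L) {
      paste(sample(names(probs), L, replace = TRUE, prob = probs),
            collapse = "")
    }, character(1))
    genome <- Biostrings::DNAStringSet(seqs)
    names(genome) <- names(lens)
  } else {
    missing <- setdiff(names(lens), names(genome))
    if (length(missing))
      stop("supplied genome lacks chromosome(s): ",
           paste(missing, collapse = ", "))
  }
  ch <- params@dsbChrom
  chromSeq <- genome[[ch]]
  mpos <- seq(params@markerSpacing,
              length(chromSeq) - 1, by = params@markerSpacing)
  donor <- as.character(Biostrings::extractAt(
    chromSeq, IRanges::IRanges(mpos, width = 1L)))
  recipient <- vapply(donor, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
  list(genome = genome,
       dsb = list(chrom = ch, pos = params@dsbPos),
       repeatPairs = params@repeatPairs,
       markers = data.frame(pos = mpos, donorAllele = unname(donor),
                            recipientAllele = unname(recipient),
                            stringsAsFactors = FALSE))
}

#' Draw the ssDNA-exposed tract of one isolate
#'
#' Resection exposes \code{[dsbPos - R, dsbPos]} with R uniform on
#' \code{[0, resectionMax]}; BIR synthesis exposes \code{[dsbPos,
#' chromosome end]}. The exposed strand is fixed by
#' \code{params@exposedStrand}.
#'
#' @param params a \code{\link{BirSimParams}}.
#' @return GRanges of the two exposed intervals with a \code{part}
#'   metadata column ("resection", "bir_tract").
#' @export
simulateExposedTract <- function(params) {
  ch <- params@dsbChrom
  len <- params@chromLengths[[ch]]
  R <- round(stats::runif(1, 0, params@resectionMax))
  gr <- GenomicRanges::GRanges(
    ch, IRanges::IRanges(c(params@dsbPos - R, params@dsbPos),
                         c(params@dsbPos, len)))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    part = c("resection", "bir_tract"))
  GenomeInfoDb::seqlevels(gr) <- names(params@chromLengths)
  GenomeInfoDb::seqlengths(gr) <- params@chromLengths
  gr
}

# trinucleotide contexts (exposed strand) of exposed-strand cytosines
# within [a, b]; returns absolute positions and a logical TCW flag
.exposedCytosines <- function(chromSeq, a, b, exposedStrand) {
  len <- length(chromSeq)
  a <- max(1L, a); b <- min(len, b)
  target <- if (exposedStrand == "+") "C" else "G"
  region <- as.character(Biostrings::subseq(chromSeq, a, b))
  rel <- which(strsplit(region, "", fixed = TRUE)[[1]] == target)
  if (!length(rel))
    return(data.frame(pos = integer(), tcw = logical()))
  pos <- a + rel - 1L
  inner <- pos > 1L & pos < len
  tri <- rep(NA_character_, length(pos))
  if (any(inner)) {
    plusTri <- as.character(Biostrings::extractAt(
      chromSeq, IRanges::IRanges(pos[inner] - 1L, width = 3L)))
    if (exposedStrand == "-")
      plusTri <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(plusTri)))
    tri[inner] <- plusTri
  }
  tcw <- !is.na(tri) & substr(tri, 1L, 2L) == "TC" &
    substr(tri, 3L, 3L) %in% c("A", "T")
  data.frame(pos = pos, tcw = tcw)
}

#' Place A3A deaminations along the exposed tract
#'
#' Every exposed-strand cytosine within the exposed intervals is
#' deaminated independently with probability \code{min(1, lambdaDeam *
#' fTCW)} when its exposed-strand trinucleotide is TCW and
#' \code{lambdaDeam} otherwise.
#'
#' @param genome DNAStringSet.
#' @param exposed GRanges of exposed intervals (one chromosome).
#' @param lambdaDeam base deamination probability.
#' @param fTCW TCW weight (>= 1).
#' @param exposedStrand "+" or "-".
#' @return sorted integer positions of deaminated cytosines (dU sites).
#' @export
placeDeaminations <- function(genome, exposed, lambdaDeam, fTCW,
                              exposedStrand = "+") {
  if (lambdaDeam == 0 || length(exposed) == 0L) return(integer())
  red <- GenomicRanges::reduce(exposed, ignore.strand = TRUE)
  ch <- unique(as.character(GenomicRanges::seqnames(red)))
  stopifnot(length(ch) == 1L)
  chromSeq <- genome[[ch]]
  sites <- do.call(rbind, lapply(seq_along(red), function(i)
    .exposedCytosines(chromSeq, GenomicRanges::start(red)[i],
                      GenomicRanges::end(red)[i], exposedStrand)))
  if (is.null(sites) || nrow(sites) == 0L) return(integer())
  p <- pmin(1, lambdaDeam * ifelse(sites$tcw, fTCW, 1))
  sort(sites$pos[stats::runif(nrow(sites)) < p])
}

#' Resolve uracil lesions into mutations and GCR events
#'
#' Without uracil glycosylase (\code{ung1D}) every dU templates adenine
#' incorporation and fixes a heterozygous C>T on the recipient copy.
#' With \code{UNG1}, each dU becomes an abasic site: with probability
#' \code{epsilonTLS} translesion synthesis fixes a heterozygous C>T or
#' C>G (split by \code{tlsCtCgRatio}); otherwise bypass is error-free,
#' and with probability \code{gammaGCR} it collapses into a GCR -- a
#' deletion between the innermost repeat pair spanning the site when one
#' exists, else a half-crossover truncation at the site.
#'
#' @param duPositions dU site positions from
#'   \code{\link{placeDeaminations}}.
#' @param params a \code{\link{BirSimParams}}.
#' @return list with \code{mutations} (data.frame chrom, pos, ref, alt,
#'   class, zygosity, copy) and \code{gcrEvents} (data.frame type,
#'   start, end).
#' @export
resolveLesions <- function(duPositions, params) {
  ch <- params@dsbChrom
  plusRef <- if (params@exposedStrand == "+") "C" else "G"
  altCT <- if (params@exposedStrand == "+") "T" else "A"
  altCG <- if (params@exposedStrand == "+") "G" else "C"
  emptyMut <- data.frame(chrom = character(), pos = integer(),
                         ref = character(), alt = character(),
                         class = character(), zygosity = character(),
                         copy = character(), stringsAsFactors = FALSE)
  emptyGcr <- data.frame(type = character(), start = numeric(),
                         end = numeric(), stringsAsFactors = FALSE)
  n <- length(duPositions)
  if (n == 0L) return(list(mutations = emptyMut, gcrEvents = emptyGcr))

  if (params@ung1Status == "ung1D") {
    mut <- data.frame(chrom = ch, pos = duPositions, ref = plusRef,
                      alt = altCT, class = "ung1_CT",
                      zygosity = "heterozygous", copy = "recipient",
                      stringsAsFactors = FALSE)
    return(list(mutations = mut, gcrEvents = emptyGcr))
  }

  isTls <- stats::runif(n) < params@epsilonTLS
  pCT <- params@tlsCtCgRatio / (1 + params@tlsCtCgRatio)
  tlsPos <- duPositions[isTls]
  isCT <- stats::runif(length(tlsPos)) < pCT
  mut <- if (length(tlsPos)) data.frame(
    chrom = ch, pos = tlsPos, ref = plusRef,
    alt = ifelse(isCT, altCT, altCG),
    class = ifelse(isCT, "TLS_CT", "TLS_CG"),
    zygosity = "heterozygous", copy = "recipient",
    stringsAsFactors = FALSE) else emptyMut

  apPos <- duPositions[!isTls]
  isGcr <- stats::runif(length(apPos)) < params@gammaGCR
  gcrPos <- apPos[isGcr]
  gcr <- emptyGcr
  if (length(gcrPos)) {
    rp <- params@repeatPairs
    rows <- lapply(gcrPos, function(p) {
      spanning <- which(rp$start <= p & rp$end >= p)
      if (length(spanning)) {
        j <- spanning[which.min(rp$end[spanning] - rp$start[spanning])]
        data.frame(type = "deletion_between_repeats",
                   start = rp$start[j], end = rp$end[j],
                   stringsAsFactors = FALSE)
      } else {
        data.frame(type = "half_crossover_truncation",
                   start = p, end = params@chromLengths[[ch]],
                   stringsAsFactors = FALSE)
      }
    })
    gcr <- do.call(rbind, rows)
  }
  list(mutations = mut[order(mut$pos), , drop = FALSE], gcrEvents = gcr)
}

# homozygous pre-BIR background mutations, uniform over the genome
.placeBackground <- function(params, genome) {
  lens <- params@chromLengths
  total <- sum(lens)
  nBg <- stats::rpois(1, total * params@backgroundHomRate)
  empty <- data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      class = character(), zygosity = character(),
                      copy = character(), stringsAsFactors = FALSE)
  if (nBg == 0L) return(empty)
  gpos <- sort(sample.int(total, nBg))
  bounds <- cumsum(lens)
  idx <- findInterval(gpos - 1, c(0, bounds), rightmost.closed = FALSE)
  chrom <- names(lens)[idx]
  pos <- gpos - c(0, bounds)[idx]
  ref <- vapply(seq_len(nBg), function(i)
    as.character(Biostrings::subseq(genome[[chrom[i]]], pos[i], pos[i])),
    character(1))
  alt <- vapply(ref, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref,
             alt = unname(alt), class = "background",
             zygosity = "homozygous", copy = "pre_BIR",
             stringsAsFactors = FALSE)
}

#' Simulate one BIR isolate
#'
#' Draws the exposed tract, places deaminations, resolves lesions
#' according to the UNG1 status, adds homozygous background mutations,
#' and returns the truth-labelled isolate. Deterministic given
#' \code{seed}.
#'
#' @param params a \code{\link{BirSimParams}}.
#' @param genomeData output of \code{\link{buildGenome}}.
#' @param sampleId isolate identifier.
#' @param seed integer seed for this isolate.
#' @return A \code{\link{SimulatedIsolate}}.
#' @export
simulateIsolate <- function(params, genomeData, sampleId = "isolate_1",
                            seed = params@seed) {
  set.seed(seed)
  exposed <- simulateExposedTract(params)
  du <- placeDeaminations(genomeData$genome, exposed, params@lambdaDeam,
                          params@fTCW, params@exposedStrand)
  res <- resolveLesions(du, params)
  bg <- .placeBackground(params, genomeData$genome)
  truth <- rbind(res$mutations, bg)
  # a background draw landing on a tract-mutation position is dropped
  truth <- truth[!duplicated(paste(truth$chrom, truth$pos)), , drop = FALSE]
  truth <- truth[order(truth$chrom, truth$pos), , drop = FALSE]
  rownames(truth) <- NULL
  new("SimulatedIsolate", sampleId = sampleId, truth = truth,
      gcrEvents = res$gcrEvents, exposedTract = exposed)
}

# per-window recipient+donor copy number of the DSB chromosome,
# relative to the parent profile (2 copies proximal, 1 distal)
.copyProfiles <- function(params, gcrEvents) {
  len <- params@chromLengths[[params@dsbChrom]]
  ws <- params@windowSize
  start <- as.integer(seq(1, len, by = ws))
  end <- as.integer(pmin(start + ws - 1, len))
  mid <- (start + end) / 2
  parent <- ifelse(mid <= params@dsbPos, 2, 1)
  isolate <- rep(2, length(mid))
  if (nrow(gcrEvents)) {
    for (i in seq_len(nrow(gcrEvents))) {
      ev <- gcrEvents[i, ]
      if (ev$type == "deletion_between_repeats") {
        isolate[mid >= ev$start & mid <= ev$end] <-
          pmin(isolate[mid >= ev$start & mid <= ev$end], 1)
      } else {
        isolate[mid >= ev$start] <- pmin(isolate[mid >= ev$start], 1)
      }
    }
  }
  data.frame(start = start, end = end, parentCopy = parent,
             isolateCopy = isolate)
}

#' Emit one isolate as VCF, coverage and truth files
#'
#' Writes a VCF v4.2 (FORMAT GT:DP:AD) with simulated depths
#' (Poisson with mean \code{depthMean}) and alt read counts (binomial
#' at 0.5 for heterozygous, 0.98 for homozygous truth sites), isolate
#' and parent coverage tracks over the DSB chromosome (Poisson per
#' window at \code{depthMean * copy/2}, reflecting GCR deletions and
#' truncations), a BED of the exposed tract (0-based half-open), and
#' the lossless truth table.
#'
#' @param isolate a \code{\link{SimulatedIsolate}}.
#' @param params a \code{\link{BirSimParams}}.
#' @param dir output directory (created if needed).
#' @param seed integer seed for read-count emulation.
#' @return named list of file paths (vcf, coverage, parentCoverage,
#'   truth, exposedBed).
#' @export
emitIsolate <- function(isolate, params, dir, seed = params@seed) {
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sid <- isolate@sampleId
  truth <- isolate@truth

  vcfPath <- file.path(dir, paste0(sid, ".vcf"))
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", names(params@chromLengths),
                  ",length=", format(params@chromLengths,
                                     scientific = FALSE, trim = TRUE), ">"),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
                  "Description=\"Allelic depths\">"),
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", sid, sep = "\t"))
  body <- character(0)
  if (nrow(truth)) {
    depth <- stats::rpois(nrow(truth), params@depthMean)
    pAlt <- ifelse(truth$zygosity == "heterozygous", 0.5, 0.98)
    altReads <- stats::rbinom(nrow(truth), depth, pAlt)
    gt <- ifelse(truth$zygosity == "heterozygous", "0/1", "1/1")
    body <- paste(truth$chrom, truth$pos, ".", truth$ref, truth$alt,
                  ".", "PASS", ".", "GT:DP:AD",
                  paste0(gt, ":", depth, ":", depth - altReads, ",",
                         altReads),
                  sep = "\t")
  }
  writeLines(c(hdr, body), vcfPath)

  prof <- .copyProfiles(params, isolate@gcrEvents)
  covPath <- file.path(dir, paste0(sid, "_coverage.tsv"))
  parPath <- file.path(dir, paste0(sid, "_parent_coverage.tsv"))
  isoDepth <- stats::rpois(nrow(prof), params@depthMean * prof$isolateCopy / 2)
  parDepth <- stats::rpois(nrow(prof), params@depthMean * prof$parentCopy / 2)
  utils::write.table(
    data.frame(chrom = params@dsbChrom, start = prof$start,
               end = prof$end, depth = isoDepth),
    covPath, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(chrom = params@dsbChrom, start = prof$start,
               end = prof$end, depth = parDepth),
    parPath, sep = "\t", quote = FALSE, row.names = FALSE)

  truthPath <- file.path(dir, paste0(sid, "_truth.tsv"))
  utils::write.table(truth, truthPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  bedPath <- file.path(dir, paste0(sid, "_exposed.bed"))
  ex <- isolate@exposedTract
  writeLines(paste(as.character(GenomicRanges::seqnames(ex)),
                   GenomicRanges::start(ex) - 1L,
                   GenomicRanges::end(ex),
                   S4Vectors::mcols(ex)$part, sep = "\t"), bedPath)

  list(vcf = vcfPath, coverage = covPath, parentCoverage = parPath,
       truth = truthPath, exposedBed = bedPath)
}

#' Simulate and emit a cohort of BIR isolates
#'
#' Builds the genome once, simulates \code{nIsolates} independent
#' isolates under distinct sub-seeds, writes each isolate's files plus
#' the reference FASTA, the marker table and a JSON manifest of truth
#' summaries. Byte-identical output under a fixed seed.
#'
#' @param params a \code{\link{BirSimParams}}.
#' @param dir output directory.
#' @param nIsolates cohort size (default \code{params@nIsolates}).
#' @param emit write per-isolate files (set FALSE to keep the cohort
#'   in memory only).
#' @return list with \code{isolates} (list of
#'   \code{\link{SimulatedIsolate}}), \code{genomeData},
#'   \code{manifest} (per-isolate truth summaries) and, when emitted,
#'   \code{files} and \code{referenceFasta}/\code{markerTable} paths.
#' @export
simulateCohort <- function(params, dir = NULL,
                           nIsolates = params@nIsolates, emit = !is.null(dir)) {
  genomeData <- buildGenome(params)
  isolates <- vector("list", nIsolates)
  files <- vector("list", nIsolates)
  manifest <- vector("list", nIsolates)
  for (i in seq_len(nIsolates)) {
    subSeed <- (params@seed + 7919L * i) %% .Machine$integer.max
    sid <- sprintf("RE_%02d", i)
    iso <- simulateIsolate(params, genomeData, sampleId = sid,
                           seed = subSeed)
    isolates[[i]] <- iso
    if (emit)
      files[[i]] <- emitIsolate(iso, params, dir, seed = subSeed + 1L)
    tract <- iso@truth$class %in% c("ung1_CT", "TLS_CT", "TLS_CG")
    manifest[[i]] <- list(
      sampleId = sid,
      nMutations = nrow(iso@truth),
      nTractMutations = sum(tract),
      exposedStart = min(GenomicRanges::start(iso@exposedTract)),
      exposedEnd = max(GenomicRanges::end(iso@exposedTract)),
      nGcr = nrow(iso@gcrEvents),
      gcrTypes = unique(iso@gcrEvents$type))
  }
  out <- list(isolates = isolates, genomeData = genomeData,
              manifest = manifest)
  if (emit) {
    fa <- file.path(dir, "reference.fa")
    Biostrings::writeXStringSet(genomeData$genome, fa)
    mk <- file.path(dir, "markers.tsv")
    utils::write.table(genomeData$markers, mk, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    out$files <- files
    out$referenceFasta <- fa
    out$markerTable <- mk
  }
  out
}

#' Simulate fluctuation-style rate experiments
#'
#' Each experiment plates \code{nCells} cells of which each reverts
#' independently with probability \code{rateTrue}; Ura+ colony counts
#' are binomial.
#'
#' @param rateTrue true per-cell reversion rate in [0, 1].
#' @param nCells viable cells per experiment.
#' @param nExperiments number of experiments.
#' @param seed optional seed.
#' @return data.frame (experiment, uraPlusColonies, viableCfu,
#'   dilutionFactor) matching the rates-module input schema.
#' @export
simulateFluctuation <- function(rateTrue, nCells, nExperiments,
                                seed = NULL) {
  stopifnot(rateTrue >= 0, rateTrue <= 1)
  if (!is.null(seed)) set.seed(seed)
  data.frame(experiment = seq_len(nExperiments),
             uraPlusColonies = stats::rbinom(nExperiments, nCells, rateTrue),
             viableCfu = nCells, dilutionFactor = 1)
}
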