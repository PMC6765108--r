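#' Parameters of the BIR/A3A mutagenesis simulator
#'
#' \code{BirSimParams} bundles the mechanistic parameters of the
#' simulator: a disomic chromosome with a double-strand break site,
#' ssDNA exposure from resection (uniform up to \code{resectionMax})
#' plus the BIR tract running from the break to the chromosome end,
#' per-cytosine deamination with TCW-motif weighting, UNG1-dependent
#' lesion processing (direct C>T fixation without uracil glycosylase;
#' with it, a small mutagenic translesion-synthesis fraction
#' \code{epsilonTLS} and otherwise error-free bypass that can collapse
#' into a gross chromosomal rearrangement with probability
#' \code{gammaGCR} per abasic site), homozygous background mutations,
#' and read-count emulation.
#'
#' @slot seed integer master seed.
#' @slot chromLengths named numeric chromosome lengths.
#' @slot gcFraction GC content of the generated random genome.
#' @slot dsbChrom,dsbPos chromosome and 1-based position of the DSB.
#' @slot resectionMax maximum resection length in bases.
#' @slot lambdaDeam per-exposed-cytosine deamination probability.
#' @slot fTCW multiplicative deamination weight for TCW-context
#'   cytosines (>= 1).
#' @slot ung1Status "UNG1" or "ung1D".
#' @slot epsilonTLS fraction of AP sites resolved mutagenically.
#' @slot tlsCtCgRatio C>T : C>G ratio among TLS outcomes.
#' @slot gammaGCR per-AP-site GCR probability on the error-free branch.
#' @slot repeatPairs data.frame (start, end) of repeat pairs on the DSB
#'   chromosome usable for deletion-forming GCRs.
#' @slot backgroundHomRate genome-wide per-base probability of a
#'   pre-BIR homozygous mutation.
#' @slot depthMean mean sequencing depth for read-count emulation.
#' @slot nIsolates default cohort size.
#' @slot exposedStrand reference strand exposed as ssDNA ("+" or "-").
#' @slot markerSpacing spacing of phased donor/recipient markers.
#' @slot windowSize coverage-window size in bases.
#'
#' @seealso \code{\link{birSimParams}}, \code{\link{simulateCohort}}
#' @export
setClass("BirSimParams",
  representation(
    seed = "integer", chromLengths = "numeric", gcFraction = "numeric",
    dsbChrom = "character", dsbPos = "numeric", resectionMax = "numeric",
    lambdaDeam = "numeric", fTCW = "numeric", ung1Status = "character",
    epsilonTLS = "numeric", tlsCtCgRatio = "numeric", gammaGCR = "numeric",
    repeatPairs = "data.frame", backgroundHomRate = "numeric",
    depthMean = "numeric", nIsolates = "integer", exposedStrand = "character",
    markerSpacing = "numeric", windowSize = "numeric"))

setValidity("BirSimParams", function(object) {
  msg <- character()
  pr <- c(lambdaDeam = object@lambdaDeam, epsilonTLS = object@epsilonTLS,
          gammaGCR = object@gammaGCR, gcFraction = object@gcFraction,
          backgroundHomRate = object@backgroundHomRate)
  bad <- pr < 0 | pr > 1
  if (any(bad))
    msg <- c(msg, paste("probabilities outside [0,1]:",
                        paste(names(pr)[bad], collapse = ", ")))
  if (object@fTCW < 1) msg <- c(msg, "fTCW must be >= 1")
  if (is.null(names(object@chromLengths)))
    msg <- c(msg, "chromLengths must be named")
  if (!object@dsbChrom %in% names(object@chromLengths))
    msg <- c(msg, "dsbChrom absent from chromLengths")
  else {
    if (object@dsbPos < 1 ||
        object@dsbPos > object@chromLengths[object@dsbChrom])
      msg <- c(msg, "dsbPos outside the DSB chromosome")
    if (object@resectionMax > object@dsbPos)
      msg <- c(msg, "resectionMax must not exceed dsbPos")
  }
  if (!object@ung1Status %in% c("UNG1", "ung1D"))
    msg <- c(msg, "ung1Status must be 'UNG1' or 'ung1D'")
  if (!object@exposedStrand %in% c("+", "-"))
    msg <- c(msg, "exposedStrand must be '+' or '-'")
  if (object@tlsCtCgRatio <= 0) msg <- c(msg, "tlsCtCgRatio must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct simulator parameters
#'
#' Defaults emulate the study conditions: a ~12 Mb yeast-like genome at
#' 38\% GC whose disomic chromosome III (340 kb) carries the DSB at
#' 190 kb; resection uniform up to 100 kb; deamination intensity preset
#' so an ung1-null isolate accrues on the order of twenty-odd tract
#' mutations; TCW weighting preset so the conditional TCW share of TC
#' mutations sits near 0.69; a 5\% mutagenic AP-site bypass fraction
#' split 1:1 between C>T and C>G; a per-AP-site GCR probability preset
#' so roughly half of UNG1 isolates acquire a rearrangement; 100x mean
#' depth; cohorts of 25 isolates.
#'
#' @param seed integer master seed.
#' @param chromLengths named numeric chromosome lengths.
#' @param gcFraction GC content of the generated genome.
#' @param dsbChrom,dsbPos DSB site.
#' @param resectionMax maximum resection length (bases).
#' @param lambdaDeam per-exposed-cytosine deamination probability.
#' @param fTCW TCW-context deamination weight (>= 1).
#' @param ung1Status "UNG1" or "ung1D".
#' @param epsilonTLS mutagenic AP-site bypass fraction.
#' @param tlsCtCgRatio C>T : C>G ratio among TLS outcomes.
#' @param gammaGCR per-AP-site GCR probability (error-free branch).
#' @param repeatPairs data.frame (start, end) of repeat pairs.
#' @param backgroundHomRate per-base homozygous background rate.
#' @param depthMean mean sequencing depth.
#' @param nIsolates default cohort size.
#' @param exposedStrand exposed reference strand.
#' @param markerSpacing marker spacing on the DSB chromosome.
#' @param windowSize coverage-window size.
#' @return A validated \code{BirSimParams} object.
#' @examples
#' p <- birSimParams(seed = 1, ung1Status = "ung1D")
#' p@dsbPos
#' @export
birSimParams <- function(seed = 1L,
                         chromLengths = c(chrIII = 340000,
                                          chrI = 2000000, chrII = 2400000,
                                          chrIV = 2500000, chrV = 2300000,
                                          chrVI = 2460000),
                         gcFraction = 0.38,
                         dsbChrom = "chrIII", dsbPos = 190000,
                         resectionMax = 100000,
                         lambdaDeam = 5.6e-4, fTCW = 1.4,
                         ung1Status = c("UNG1", "ung1D"),
                         epsilonTLS = 0.05, tlsCtCgRatio = 1,
                         gammaGCR = 0.028,
                         repeatPairs = data.frame(
                           start = c(205000, 255000),
                           end = c(245000, 295000)),
                         backgroundHomRate = 2.3e-6,
                         depthMean = 100, nIsolates = 25L,
                         exposedStrand = "+",
                         markerSpacing = 10000, windowSize = 500) {
  ung1Status <- match.arg(ung1Status)
  new("BirSimParams", seed = as.integer(seed),
      chromLengths = chromLengths, gcFraction = gcFraction,
      dsbChrom = dsbChrom, dsbPos = dsbPos, resectionMax = resectionMax,
      lambdaDeam = lambdaDeam, fTCW = fTCW, ung1Status = ung1Status,
      epsilonTLS = epsilonTLS, tlsCtCgRatio = tlsCtCgRatio,
      gammaGCR = gammaGCR, repeatPairs = repeatPairs,
      backgroundHomRate = backgroundHomRate, depthMean = depthMean,
      nIsolates = as.integer(nIsolates), exposedStrand = exposedStrand,
      markerSpacing = markerSpacing, windowSize = windowSize)
}

setMethod("show", "BirSimParams", function(object) {
  cat("BirSimParams:", object@ung1Status, "genome of",
      length(object@chromLengths), "chromosomes (",
      round(sum(object@chromLengths) / 1e6, 2), "Mb ), DSB at",
      object@dsbChrom, ":", object@dsbPos, "\n")
  cat("  lambdaDeam =", object@lambdaDeam, " fTCW =", object@fTCW,
      " epsilonTLS =", object@epsilonTLS, " gammaGCR =", object@gammaGCR,
      "\n")
})

#' One simulated BIR isolate with truth labels
#'
#' @slot sampleId isolate identifier.
#' @slot truth data.frame of truth mutations (chrom, pos, ref, alt,
#'   class, zygosity, copy).
#' @slot gcrEvents data.frame of GCR events (type, start, end).
#' @slot exposedTract GRanges of the ssDNA-exposed intervals.
#' @export
setClass("SimulatedIsolate",
  representation(sampleId = "character", truth = "data.frame",
                 gcrEvents = "data.frame", exposedTract = "GRanges"))

setMethod("show", "SimulatedIsolate", function(object) {
  cat("SimulatedIsolate", object@sampleId, ":", nrow(object@truth),
      "truth mutations,", nrow(object@gcrEvents), "GCR event(s)\n")
})
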