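#' Normalize isolate coverage against the parent
#'
#' Computes per-window log2((isolate + c)/(parent + c)) with pseudocount
#' \code{c}, optionally median-centering the ratios on a designated
#' reference chromosome known to be copy-number neutral between isolate
#' and parent.
#'
#' Tracks are data.frames with columns \code{chrom}, \code{start},
#' \code{end}, \code{depth}; isolate and parent must share the same
#' windows.
#'
#' @param isolate,parent coverage tracks.
#' @param pseudocount added to both depths to keep zero-depth windows
#'   finite.
#' @param centerChrom chromosome whose median log2 ratio is subtracted
#'   from all windows; NULL for no centering.
#' @return the isolate track with an added \code{log2Ratio} column.
#' @export
normalizeCoverage <- function(isolate, parent, pseudocount = 0.5,
                              centerChrom = NULL) {
  need <- c("chrom", "start", "end", "depth")
  stopifnot(all(need %in% names(isolate)), all(need %in% names(parent)))
  if (nrow(isolate) != nrow(parent) ||
      !all(isolate$chrom == parent$chrom) ||
      !all(isolate$start == parent$start))
    stop("isolate and parent tracks must share identical windows")
  lr <- log2((isolate$depth + pseudocount) / (parent$depth + pseudocount))
  if (!is.null(centerChrom)) {
    sel <- isolate$chrom == centerChrom
    if (!any(sel)) stop("centerChrom has no windows: ", centerChrom)
    lr <- lr - stats::median(lr[sel])
  }
  isolate$log2Ratio <- lr
  isolate
}

# Greedy binary segmentation of one chromosome's log2-ratio vector.
# A candidate boundary is scored by the local contrast between the
# minSegmentWindows windows on either side of it (so consecutive steps
# cannot dilute each other, as they would with whole-segment means);
# the best boundary is split when its contrast reaches minStep and the
# recursion continues on both sides.
.segmentOne <- function(x, minStep, minSegmentWindows) {
  w <- minSegmentWindows
  n <- length(x)
  segs <- list(c(1L, n))
  out <- list()
  while (length(segs)) {
    seg <- segs[[1L]]; segs <- segs[-1L]
    lo <- seg[1L]; hi <- seg[2L]
    len <- hi - lo + 1L
    if (len < 2L * w) { out[[length(out) + 1L]] <- seg; next }
    v <- x[lo:hi]
    cs <- c(0, cumsum(v))
    idx <- w:(len - w)   # last window index of the left side
    left <- (cs[idx + 1L] - cs[idx - w + 1L]) / w
    right <- (cs[idx + w + 1L] - cs[idx + 1L]) / w
    contrast <- abs(right - left)
    b <- which.max(contrast)
    if (contrast[b] >= minStep) {
      cut <- lo + idx[b] - 1L
      segs <- c(list(c(lo, cut), c(cut + 1L, hi)), segs)
    } else out[[length(out) + 1L]] <- seg
  }
  out <- out[order(vapply(out, `[`, 0L, 1L))]
  # merge adjacent segments whose levels ended up closer than minStep
  merged <- list(out[[1L]])
  for (s in out[-1L]) {
    prev <- merged[[length(merged)]]
    mPrev <- mean(x[prev[1L]:prev[2L]])
    mCur <- mean(x[s[1L]:s[2L]])
    if (abs(mCur - mPrev) < minStep)
      merged[[length(merged)]] <- c(prev[1L], s[2L])
    else merged[[length(merged) + 1L]] <- s
  }
  merged
}

#' Detect copy-number steps in a normalized coverage track
#'
#' Greedy binary segmentation of the per-window log2 ratios, per
#' chromosome; adjacent segments closer than \code{minStep} (default
#' 0.58 ~ log2(1.5), separating one from two copies) are merged.
#' Breakpoints are reported at the boundary between the flanking
#' windows.
#'
#' @param track normalized track from \code{\link{normalizeCoverage}}.
#' @param minStep minimum |log2| level difference between segments.
#' @param minSegmentWindows minimum windows per segment.
#' @return list with \code{segments} (data.frame chrom, start, end,
#'   nWindows, log2Level, copyRatio) and \code{breakpoints} (data.frame
#'   chrom, pos).
#' @export
detectCopySteps <- function(track, minStep = 0.58, minSegmentWindows = 5L) {
  stopifnot("log2Ratio" %in% names(track))
  segRows <- list(); bpRows <- list()
  for (ch in unique(track$chrom)) {
    t <- track[track$chrom == ch, , drop = FALSE]
    t <- t[order(t$start), , drop = FALSE]
    segs <- if (nrow(t) < 2L * minSegmentWindows)
      list(c(1L, nrow(t)))
    else .segmentOne(t$log2Ratio, minStep, minSegmentWindows)
    for (s in segs) {
      lvl <- mean(t$log2Ratio[s[1L]:s[2L]])
      segRows[[length(segRows) + 1L]] <- data.frame(
        chrom = ch, start = t$start[s[1L]], end = t$end[s[2L]],
        nWindows = s[2L] - s[1L] + 1L, log2Level = lvl,
        copyRatio = 2^lvl, stringsAsFactors = FALSE)
    }
    if (length(segs) > 1L)
      for (i in seq_len(length(segs) - 1L)) {
        cut <- segs[[i]][2L]
        bpRows[[length(bpRows) + 1L]] <- data.frame(
          chrom = ch, pos = t$end[cut], stringsAsFactors = FALSE)
      }
  }
  list(segments = do.call(rbind, c(segRows,
         list(data.frame(chrom = character(), start = numeric(),
                         end = numeric(), nWindows = integer(),
                         log2Level = numeric(), copyRatio = numeric())))),
       breakpoints = do.call(rbind, c(bpRows,
         list(data.frame(chrom = character(), pos = numeric())))))
}

#' Classify a BIR outcome from its copy-number segments
#'
#' The in-silico analog of sizing the two chromosome III copies on a
#' CHEF gel: a non-rearranged BIR outcome carries a two-copy region
#' running from the DSB-proximal boundary to the chromosome end. The
#' outcome is \code{rearranged} when the observed two-copy extent
#' deviates from that expectation by more than \code{tolerance}, when
#' the two-copy region is interrupted, or when a diagnostic marker
#' expected on one copy is absent; \code{incomplete} when no two-copy
#' region is seen at all.
#'
#' @param segments segment data.frame from \code{\link{detectCopySteps}}
#'   for the disomic chromosome.
#' @param expectedStart expected start of the two-copy region (the
#'   DSB-proximal boundary).
#' @param expectedEnd expected end (the chromosome end).
#' @param tolerance allowed deviation in bases (default 5 kb).
#' @param twoCopyMin log2 level above which a segment counts as
#'   two-copy (midpoint between one- and two-copy levels).
#' @param markerPresence optional named logical; any FALSE forces
#'   \code{rearranged}.
#' @return list with \code{label} in \{"BIR_non_rearranged",
#'   "rearranged", "incomplete"\} and \code{evidence} notes.
#' @export
classifyOutcome <- function(segments, expectedStart, expectedEnd,
                            tolerance = 5000, twoCopyMin = 0.5,
                            markerPresence = NULL) {
  two <- segments[segments$log2Level >= twoCopyMin, , drop = FALSE]
  if (nrow(two) == 0L)
    return(list(label = "incomplete", evidence = "no two-copy region"))
  notes <- character()
  if (!is.null(markerPresence) && any(!markerPresence))
    notes <- c(notes, paste("missing marker(s):",
                            paste(names(markerPresence)[!markerPresence],
                                  collapse = ", ")))
  if (nrow(two) > 1L) {
    gaps <- two$start[-1L] - two$end[-nrow(two)]
    if (any(gaps > tolerance))
      notes <- c(notes, "interrupted two-copy region")
  }
  if (abs(min(two$start) - expectedStart) > tolerance)
    notes <- c(notes, sprintf("two-copy start %d deviates from expected %d",
                              round(min(two$start)), round(expectedStart)))
  if (abs(max(two$end) - expectedEnd) > tolerance)
    notes <- c(notes, sprintf("two-copy end %d deviates from expected %d",
                              round(max(two$end)), round(expectedEnd)))
  if (length(notes))
    list(label = "rearranged", evidence = paste(notes, collapse = "; "))
  else
    list(label = "BIR_non_rearranged",
         evidence = "two-copy region at expected extent")
}

#' Assign heterozygous chromosome III mutations to donor or recipient copy
#'
#' Marker-based assignment with a zygosity fallback: a heterozygous
#' variant sitting at a phased marker position is assigned to the copy
#' whose allele it matches; otherwise heterozygous variants inside the
#' BIR tract default to the recipient copy (conservative inheritance of
#' newly synthesized DNA), homozygous variants are labelled pre-BIR
#' (plausibly S-phase events preceding BIR), and anything else is
#' unresolved.
#'
#' @param variants data.frame with columns chrom, pos, alt, zygosity.
#' @param markerHaplotypes optional data.frame with columns pos,
#'   donorAllele, recipientAllele.
#' @param birTract optional GRanges (or data.frame chrom/start/end) of
#'   the BIR tract.
#' @return character vector of labels: "donor", "recipient", "pre_BIR",
#'   "unresolved".
#' @export
assignToCopy <- function(variants, markerHaplotypes = NULL,
                         birTract = NULL) {
  n <- nrow(variants)
  out <- rep("unresolved", n)
  out[variants$zygosity == "homozygous"] <- "pre_BIR"
  het <- variants$zygosity == "heterozygous"
  if (!is.null(markerHaplotypes) && nrow(markerHaplotypes)) {
    i <- match(variants$pos, markerHaplotypes$pos)
    atMarker <- het & !is.na(i)
    don <- atMarker & variants$alt ==
      markerHaplotypes$donorAllele[ifelse(is.na(i), 1L, i)]
    rec <- atMarker & variants$alt ==
      markerHaplotypes$recipientAllele[ifelse(is.na(i), 1L, i)]
    out[don & !rec] <- "donor"
    out[rec & !don] <- "recipient"
    out[don & rec] <- "unresolved"
    het <- het & !atMarker
  }
  if (!is.null(birTract)) {
    if (is(birTract, "GRanges")) {
      tractChrom <- as.character(GenomicRanges::seqnames(birTract))
      tractStart <- GenomicRanges::start(birTract)
      tractEnd <- GenomicRanges::end(birTract)
    } else {
      tractChrom <- birTract$chrom
      tractStart <- birTract$start; tractEnd <- birTract$end
    }
    inTract <- rep(FALSE, n)
    for (j in seq_along(tractChrom))
      inTract <- inTract | (variants$chrom == tractChrom[j] &
                            variants$pos >= tractStart[j] &
                            variants$pos <= tractEnd[j])
    out[het & inTract] <- "recipient"
  }
  out
}
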