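makeTrack <- function(depth, chrom = "chrIII", windowSize = 1000) {
  n <- length(depth)
  start <- as.integer(seq(1, by = windowSize, length.out = n))
  data.frame(chrom = chrom, start = start,
             end = start + windowSize - 1L, depth = depth)
}

test_that("coverage normalization gives zero log-ratio for identical tracks", {
  t <- makeTrack(rep(100, 50))
  r <- normalizeCoverage(t, t)
  expect_true(all(r$log2Ratio == 0))
  # doubled suffix: ratio 1.0 there
  iso <- makeTrack(c(rep(100, 25), rep(200, 25)))
  r2 <- normalizeCoverage(iso, t)
  expect_equal(r2$log2Ratio[26:50], rep(1, 25), tolerance = 0.01)
  # zero-depth windows stay finite through the pseudocount
  z <- makeTrack(rep(0, 50))
  expect_true(all(is.finite(normalizeCoverage(z, t)$log2Ratio)))
  expect_error(normalizeCoverage(makeTrack(rep(1, 10)), t), "windows")
})

test_that("step detection recovers a single 1-vs-2 copy transition", {
  # geometry of the sequenced BIR event: step at 190,180 of a 340 kb
  # chromosome, 1 kb windows
  n <- 340
  lr <- c(rep(0, 190), rep(1, n - 190))
  t <- makeTrack(rep(100, n)); t$log2Ratio <- lr
  st <- detectCopySteps(t)
  expect_equal(nrow(st$segments), 2L)
  expect_equal(nrow(st$breakpoints), 1L)
  expect_lt(abs(st$breakpoints$pos - 190000), 1001)
  # constant track: a single segment, no breakpoints
  t2 <- makeTrack(rep(100, n)); t2$log2Ratio <- rep(0, n)
  st2 <- detectCopySteps(t2)
  expect_equal(nrow(st2$breakpoints), 0L)
  # up-down geometry: three segments, two breakpoints
  t3 <- makeTrack(rep(100, n))
  t3$log2Ratio <- c(rep(0, 100), rep(1, 120), rep(0, 120))
  st3 <- detectCopySteps(t3)
  expect_equal(nrow(st3$segments), 3L)
  expect_equal(nrow(st3$breakpoints), 2L)
})

test_that("parent-vs-itself stays breakpoint-free under Poisson noise", {
  set.seed(23)
  par <- makeTrack(stats::rpois(340, 100))
  r <- normalizeCoverage(par, par)
  expect_equal(nrow(detectCopySteps(r)$breakpoints), 0L)
})

test_that("noisy depth still localizes the breakpoint to within one window", {
  set.seed(29)
  n <- 340; hits <- 0L; reps <- 200L
  for (i in seq_len(reps)) {
    par <- makeTrack(stats::rpois(n, c(rep(60, 190), rep(30, n - 190))))
    iso <- makeTrack(stats::rpois(n, rep(60, n)))
    st <- detectCopySteps(normalizeCoverage(iso, par))
    hits <- hits + (nrow(st$breakpoints) >= 1 &&
                      any(abs(st$breakpoints$pos - 190000) <= 1000))
  }
  expect_gte(hits / reps, 0.95)
})

test_that("outcome classification follows the expected two-copy extent", {
  seg <- data.frame(chrom = "chrIII",
                    start = c(1, 190001), end = c(190000, 340000),
                    nWindows = c(190, 150),
                    log2Level = c(0, 1), copyRatio = c(1, 2))
  r <- classifyOutcome(seg, expectedStart = 190180, expectedEnd = 340000)
  expect_equal(r$label, "BIR_non_rearranged")
  # two-copy region stopping 40 kb short of the chromosome end
  seg2 <- seg; seg2$end[2] <- 300000
  r2 <- classifyOutcome(seg2, expectedStart = 190180, expectedEnd = 340000)
  expect_equal(r2$label, "rearranged")
  # no two-copy region at all
  seg3 <- seg[1, ]
  r3 <- classifyOutcome(seg3, expectedStart = 190180, expectedEnd = 340000)
  expect_equal(r3$label, "incomplete")
  # a missing diagnostic marker forces the rearranged label
  r4 <- classifyOutcome(seg, expectedStart = 190180, expectedEnd = 340000,
                        markerPresence = c(ade1 = FALSE))
  expect_equal(r4$label, "rearranged")
})

test_that("copy assignment uses markers first, then tract and zygosity logic", {
  v <- data.frame(chrom = "chrIII",
                  pos = c(195000, 210000, 50000, 220000),
                  alt = c("T", "G", "A", "T"),
                  zygosity = c("heterozygous", "heterozygous",
                               "heterozygous", "homozygous"))
  markers <- data.frame(pos = 210000, donorAllele = "G",
                        recipientAllele = "A")
  tract <- data.frame(chrom = "chrIII", start = 190000, end = 340000)
  lab <- assignToCopy(v, markerHaplotypes = markers, birTract = tract)
  expect_equal(lab, c("recipient", "donor", "unresolved", "pre_BIR"))
})

test_that("simulated GCR isolates classify as rearranged, plain BIR as not", {
  p <- smallSimParams(ung1Status = "UNG1", epsilonTLS = 0.05,
                      gammaGCR = 0, lambdaDeam = 1e-3)
  gd <- buildGenome(p)
  d <- withr::local_tempdir()
  iso <- simulateIsolate(p, gd, "plain", seed = 51)
  fp <- emitIsolate(iso, p, d, seed = 52)
  readTrack <- function(f) utils::read.table(f, header = TRUE, sep = "\t")
  st <- detectCopySteps(normalizeCoverage(readTrack(fp$coverage),
                                          readTrack(fp$parentCoverage)))
  r <- classifyOutcome(st$segments, expectedStart = p@dsbPos,
                       expectedEnd = p@chromLengths[["chrIII"]],
                       tolerance = 5000)
  expect_equal(r$label, "BIR_non_rearranged")
  # force a repeat-flanked deletion and re-emit
  gcr <- data.frame(type = "deletion_between_repeats",
                    start = 70000, end = 90000)
  isoG <- methods::new("SimulatedIsolate", sampleId = "gcr",
                       truth = iso@truth, gcrEvents = gcr,
                       exposedTract = iso@exposedTract)
  fpG <- emitIsolate(isoG, p, d, seed = 53)
  stG <- detectCopySteps(normalizeCoverage(readTrack(fpG$coverage),
                                           readTrack(fpG$parentCoverage)))
  rG <- classifyOutcome(stG$segments, expectedStart = p@dsbPos,
                        expectedEnd = p@chromLengths[["chrIII"]],
                        tolerance = 5000)
  expect_equal(rG$label, "rearranged")
})
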