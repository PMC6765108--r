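test_that("VCF reading keeps SNVs, drops indels, flags zero depth", {
  vcf <- writeVcfFixture(withr::local_tempfile(fileext = ".vcf"), c(
    vcfRow("chrIII", 1000, "C", "T", 100, 48),
    vcfRow("chrIII", 2000, "C", "G", 90, 44),
    vcfRow("chrIII", 3000, "CT", "C", 80, 40),   # deletion, dropped
    vcfRow("chrV", 5000, "G", "A", 95, 93, gt = "1/1"),
    vcfRow("chrV", 6000, "G", "A", 0, 0)))
  cs <- suppressMessages(readVariants(vcf))
  v <- variantRecords(cs)
  expect_equal(length(v), 4L)
  expect_equal(cs@droppedNonSnv, 1L)
  mc <- S4Vectors::mcols(v)
  zero <- which(mc$depth == 0L)
  expect_equal(mc$zygosity[zero], "rejected")
  expect_equal(mc$rejectReason[zero], "zero depth")
  expect_true(is.na(mc$altFraction[zero]))
  # chromosome lengths come from the header contigs
  expect_equal(unname(GenomeInfoDb::seqlengths(v)["chrIII"]), 340000)
})

test_that("empty VCF body yields an empty callset", {
  vcf <- writeVcfFixture(withr::local_tempfile(fileext = ".vcf"),
                         character(0))
  cs <- readVariants(vcf)
  expect_s4_class(cs, "BirCallset")
  expect_equal(length(variantRecords(cs)), 0L)
})

test_that("multi-allelic sites are split into one record per alt", {
  path <- withr::local_tempfile(fileext = ".vcf")
  rows <- paste("chrIII", 1500, ".", "C", "T,G", ".", "PASS", ".",
                "GT:DP:AD", "1/2:100:10,50,40", sep = "\t")
  writeVcfFixture(path, rows)
  cs <- readVariants(path)
  v <- variantRecords(cs)
  expect_equal(length(v), 2L)
  expect_setequal(S4Vectors::mcols(v)$alt, c("T", "G"))
  expect_equal(S4Vectors::mcols(v)$altReads,
               c(50L, 40L)[match(S4Vectors::mcols(v)$alt, c("T", "G"))])
})

test_that("site filters reject low alt support, masked and recurrent records", {
  cs <- makeCallset(pos = c(1000, 2000, 3000, 4000),
                    altReads = c(9L, 48L, 52L, 50L))
  mask <- GenomicRanges::GRanges("chrIII", IRanges::IRanges(2900, 3100))
  S4Vectors::mcols(mask)$category <- "LTR"
  # position 4000 also called in the parent
  parent <- makeCallset(pos = 4000, sampleId = "parent")
  rec <- buildRecurrenceTable(list(cs, parent))
  out <- applySiteFilters(cs, mask = mask, recurrence = rec)
  mc <- S4Vectors::mcols(variantRecords(out))
  expect_equal(mc$rejectReason[1], "min_alt_reads")
  expect_true(is.na(mc$rejectReason[2]))
  expect_equal(mc$zygosity[2], "heterozygous")
  expect_equal(mc$rejectReason[3], "masked")
  expect_equal(mc$rejectReason[4], "recurrent")
})

test_that("a mask chromosome absent from the callset is skipped with a warning", {
  cs <- makeCallset(pos = 1000)
  mask <- GenomicRanges::GRanges("chrXII", IRanges::IRanges(1, 100))
  expect_warning(out <- applySiteFilters(cs, mask = mask), "chrXII")
  expect_equal(S4Vectors::mcols(variantRecords(out))$zygosity, "heterozygous")
})

test_that("zygosity classification follows the allele-fraction windows", {
  # disomic: het window [0.27, 0.70], ambiguous band (0.70, 0.90)
  expect_equal(
    classifyZygosity(c(0.50, 0.27, 0.70, 0.80, 0.90, 0.95, 0.20),
                     inDisomicRegion = TRUE),
    c("heterozygous", "heterozygous", "heterozygous", "ambiguous",
      "homozygous", "homozygous", "rejected"))
  # outside disomic regions anything below 0.90 is rejected
  expect_equal(classifyZygosity(c(0.95, 0.50, 0.89),
                                inDisomicRegion = FALSE),
               c("homozygous", "rejected", "rejected"))
})

test_that("filtering is idempotent and reasons are recomputed from raw fields", {
  cs <- makeCallset(pos = c(1000, 2000, 3000),
                    altReads = c(5L, 48L, 95L))
  once <- applySiteFilters(cs)
  twice <- applySiteFilters(once)
  expect_identical(
    S4Vectors::mcols(variantRecords(once)),
    S4Vectors::mcols(variantRecords(twice)))
})

test_that("single-filter runs accept the same records as the combined run", {
  set.seed(42)
  pos <- sort(sample.int(250000, 60))
  cs <- makeCallset(pos = pos,
                    altReads = sample(c(5L, 30L, 60L), 60, replace = TRUE),
                    depth = 100L)
  mask <- GenomicRanges::GRanges(
    "chrIII", IRanges::IRanges(c(50000, 150000), c(80000, 160000)))
  parent <- makeCallset(pos = pos[c(3, 10)], sampleId = "parent")
  rec <- buildRecurrenceTable(list(cs, parent))
  acceptedOf <- function(x) GenomicRanges::start(acceptedVariants(x))
  combined <- acceptedOf(applySiteFilters(cs, mask = mask, recurrence = rec))
  # chaining the filters in either order gives the same accepted set
  ab <- acceptedOf(applySiteFilters(
    applySiteFilters(cs, mask = mask), recurrence = rec))
  ba <- acceptedOf(applySiteFilters(
    applySiteFilters(cs, recurrence = rec), mask = mask))
  expect_identical(combined, ab)
  expect_identical(combined, ba)
  # no accepted record lies in a masked interval
  acc <- acceptedVariants(applySiteFilters(cs, mask = mask))
  expect_false(any(IRanges::overlapsAny(acc, mask)))
})

test_that("well-supported heterozygous tract mutations survive the filters", {
  p <- smallSimParams(ung1Status = "ung1D")
  gd <- buildGenome(p)
  iso <- simulateIsolate(p, gd, "RE_t", seed = 21)
  d <- withr::local_tempdir()
  fp <- emitIsolate(iso, p, d, seed = 22)
  cs <- applySiteFilters(readVariants(
    fp$vcf, disomicRegions = disomicChrIII(120000)))
  mc <- S4Vectors::mcols(variantRecords(cs))
  truthHet <- iso@truth[iso@truth$zygosity == "heterozygous", ]
  emitted <- data.frame(pos = GenomicRanges::start(variantRecords(cs)),
                        altReads = mc$altReads,
                        altFraction = mc$altFraction,
                        zygosity = mc$zygosity)
  m <- merge(truthHet, emitted, by = "pos")
  good <- m$altReads >= 10 & m$altFraction >= 0.27 & m$altFraction <= 0.70
  expect_true(all(m$zygosity.y[good] == "heterozygous"))
  expect_gt(sum(good), 0)
})
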