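# Monte-Carlo oracle for the spacing null: draw k-1 geometric gaps on
# {1,2,...} and report the fraction of draws whose sum is <= span
mcGapOracle <- function(k, span, pi, nDraws = 3e5) {
  total <- rep(0L, nDraws)
  for (i in seq_len(k - 1))
    total <- total + stats::rgeom(nDraws, pi) + 1L
  mean(total <= span)
}

test_that("distance grouping follows the 100 kb rule and partitions mutations", {
  cs <- makeCallset(pos = c(100, 50000, 200000))
  cs <- applySiteFilters(cs)
  g <- groupByDistance(cs, dMax = 100000)
  expect_equal(length(g), 2L)
  expect_equal(S4Vectors::mcols(g)$k, c(2L, 1L))
  expect_equal(GenomicRanges::start(g), c(100, 200000))
  # singleton group: span 1, k 1
  g1 <- groupByDistance(applySiteFilters(makeCallset(pos = 7777)))
  expect_equal(S4Vectors::mcols(g1)$span, 1L)
  # empty callset
  g0 <- groupByDistance(applySiteFilters(makeCallset(pos = integer(0))))
  expect_equal(length(g0), 0L)
})

test_that("groups partition the accepted mutations and never span chromosomes", {
  set.seed(7)
  for (rep in 1:5) {
    pos <- sort(sample.int(300000, 40))
    chrom <- sample(c("chrIII", "chrV"), 40, replace = TRUE)
    cs <- applySiteFilters(makeCallset(pos = pos, chrom = chrom))
    g <- groupByDistance(cs, dMax = 20000)
    members <- S4Vectors::mcols(g)$members
    accepted <- acceptedVariants(cs)
    # every accepted mutation in exactly one group
    expect_equal(sum(lengths(members)), length(accepted))
    byChrom <- split(GenomicRanges::start(accepted),
                     as.character(GenomicRanges::seqnames(accepted)))
    got <- split(unlist(members),
                 rep(as.character(GenomicRanges::seqnames(g)),
                     lengths(members)))
    for (ch in names(byChrom))
      expect_setequal(got[[ch]], byChrom[[ch]])
  }
})

test_that("cluster p-value matches closed forms and the Monte-Carlo oracle", {
  expect_equal(clusterPvalue(1, 1, 0.5), 1.0)
  # k = 2, span 1: single geometric gap, P(gap <= 1) = pi
  expect_equal(clusterPvalue(2, 1, 0.5), 0.5)
  # k = 2 general closed form: P(gap <= s) = 1 - (1 - pi)^s
  expect_equal(clusterPvalue(2, 100, 1e-3), 1 - (1 - 1e-3)^100)
  # k = 3: two-gap sum against the sampling oracle
  set.seed(101)
  pHat <- mcGapOracle(3, 100, 1e-4, nDraws = 1e6)
  p <- clusterPvalue(3, 100, 1e-4)
  se <- sqrt(max(pHat * (1 - pHat), p * (1 - p)) / 1e6)
  expect_lt(abs(p - pHat), 3 * se + 2e-6)
  expect_error(clusterPvalue(2, 10, 1.5), "pi")
})

test_that("cluster p-value is monotone in span, pi and k", {
  spans <- c(100, 1000, 10000, 100000)
  p <- clusterPvalue(rep(5, 4), spans, 1e-4)
  expect_true(all(diff(p) >= 0))
  pis <- c(1e-5, 1e-4, 1e-3)
  p2 <- vapply(pis, function(x) clusterPvalue(5, 1000, x), 0)
  expect_true(all(diff(p2) >= 0))
  ks <- c(2, 3, 5, 10)
  p3 <- clusterPvalue(ks, rep(5000, 4), 1e-4)
  expect_true(all(diff(p3) <= 0))
})

test_that("pair p-values are uniform under the geometric null (exact size)", {
  # the two-mutation group p-value is the probability-integral
  # transform of the observed gap, so the per-group test has size
  # exactly alpha
  set.seed(31)
  pi <- 2e-5
  gaps <- stats::rgeom(4000, pi) + 1
  p <- clusterPvalue(rep(2, 4000), gaps + 1, pi)
  # discrete gaps collide occasionally at this pi; the tie warning is
  # expected and the continuous KS approximation remains adequate
  expect_gt(suppressWarnings(stats::ks.test(p, "punif")$p.value), 0.01)
  expect_lt(abs(mean(p < 0.01) - 0.01), 3 * sqrt(0.01 * 0.99 / 4000))
})

test_that("cluster calling uses strict inequality at alpha", {
  cs <- applySiteFilters(makeCallset(pos = c(1000, 1001)))
  g <- groupByDistance(cs)
  # k=2, span=2, pi=0.5: p = 1-(1-pi)^2 = 0.75
  cl <- callClusters(g, clusterNullModel(1000, genomeSize = 2000),
                     alpha = 0.75)
  expect_false(S4Vectors::mcols(cl)$isCluster[1])  # p == alpha
  cl2 <- callClusters(g, clusterNullModel(1000, genomeSize = 2000),
                      alpha = 0.7500001)
  expect_true(S4Vectors::mcols(cl2)$isCluster[1])
  # all-singleton input yields zero clusters
  s <- groupByDistance(applySiteFilters(
    makeCallset(pos = c(1000, 150000, 299000))), dMax = 10000)
  cls <- callClusters(s, clusterNullModel(3, genomeSize = 340000))
  expect_equal(sum(S4Vectors::mcols(cls)$isCluster), 0L)
})

test_that("cluster summaries report span-derived length and density", {
  # geometry echoing the largest observed cluster: 140 mutations / 235 kb
  cs <- applySiteFilters(makeCallset(
    pos = as.integer(seq(1, 235000, length.out = 140))))
  g <- groupByDistance(cs)
  cl <- callClusters(g, clusterNullModel(140, genomeSize = 12e6))
  s <- clusterSummaries(cl)
  expect_equal(nrow(s), 1L)
  expect_equal(s$length_kb, 235, tolerance = 1e-3)
  expect_equal(s$density_per_kb, 140 / 235, tolerance = 1e-3)
  # 23 mutations over ~147 kb gives ~0.156/kb (~1 per 6.4 kb)
  cs2 <- applySiteFilters(makeCallset(
    pos = as.integer(seq(50000, 196999, length.out = 23))))
  s2 <- clusterSummaries(callClusters(
    groupByDistance(cs2), clusterNullModel(23, genomeSize = 12e6)))
  expect_equal(s2$density_per_kb, 23 / 147, tolerance = 1e-3)
  # two mutations spanning 1000 bases: 1 kb, 2 per kb
  cs3 <- applySiteFilters(makeCallset(pos = c(5000, 5999)))
  s3 <- clusterSummaries(callClusters(
    groupByDistance(cs3), clusterNullModel(2, genomeSize = 340000),
    alpha = 1))
  expect_equal(s3$length_kb, 1.0)
  expect_equal(s3$density_per_kb, 2.0)
})

test_that("Mann-Whitney comparison agrees with exhaustive enumeration", {
  r <- compareClusterMetrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$pValue, 1.0, tolerance = 0.05)
  # disjoint samples: enumerate all choose(6,3) = 20 rank assignments
  a <- c(1, 2, 3); b <- c(10, 11, 12)
  obsU <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  vals <- c(a, b)
  us <- apply(utils::combn(6, 3), 2, function(idx) {
    x <- vals[idx]; y <- vals[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  })
  pEnum <- mean(abs(us - 4.5) >= abs(obsU - 4.5))
  expect_equal(compareClusterMetrics(a, b)$pValue, pEnum)
  # medians are reported as-is
  r2 <- compareClusterMetrics(rep(7, 25), rep(23, 25))
  expect_equal(r2$medianA, 7)
  expect_equal(r2$medianB, 23)
})

test_that("breakpoint co-localization measures interval distance", {
  cl <- GenomicRanges::GRanges("chrIII", IRanges::IRanges(10000, 50000))
  bp <- data.frame(chrom = "chrIII", pos = 30000)
  r <- colocalizeClustersBreakpoints(cl, bp, maxDist = 10000)
  expect_equal(r$distance, 0)
  expect_true(r$within_window)
  r2 <- colocalizeClustersBreakpoints(
    cl, data.frame(chrom = "chrIII", pos = 70000), maxDist = 10000)
  expect_equal(r2$distance, 20000)
  expect_false(r2$within_window)
  r3 <- colocalizeClustersBreakpoints(
    cl, data.frame(chrom = "chrV", pos = 70000), maxDist = 10000)
  expect_true(is.na(r3$distance))
  expect_false(r3$within_window)
})
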