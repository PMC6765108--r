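#' Per-experiment Ura+ reversion rate
#'
#' The rate of reporter reversion among all DSB repair outcomes of one
#' fluctuation-style experiment: Ura+ colonies divided by the effective
#' viable count. \code{dilutionFactor} scales the viable count when the
#' plated aliquot was diluted.
#'
#' @param uraPlusColonies non-negative Ura+ colony count.
#' @param viableCfu viable colony-forming units (post dilution
#'   correction if \code{dilutionFactor} is 1).
#' @param dilutionFactor multiplicative correction applied to
#'   \code{viableCfu}.
#' @return the rate, a non-negative number.
#' @examples
#' experimentRate(12, 1e7)   # 1.2e-6
#' @export
experimentRate <- function(uraPlusColonies, viableCfu, dilutionFactor = 1) {
  if (any(uraPlusColonies < 0)) stop("colony counts must be non-negative")
  if (any(viableCfu * dilutionFactor <= 0))
    stop("viable CFU must be positive")
  uraPlusColonies / (viableCfu * dilutionFactor)
}

#' Median rate with nonparametric confidence limits
#'
#' Rates are summarized by their median. For n >= 6 experiments the 95%
#' confidence limits for the median are the order statistics
#' (x_(j), x_(n+1-j)) with j the largest rank whose two-sided
#' Binomial(n, 1/2) coverage is at least 95% (conservative: coverage
#' never below the nominal level). For n < 6 no such ranks exist at a
#' useful level and the min-max range of the observations is reported
#' instead (\code{ciKind = "range"}).
#'
#' @param rates numeric vector of per-experiment rates, n >= 1.
#' @return list with n, median, ciLow, ciHigh, ciKind
#'   ("order-statistic 95%" or "range").
#' @examples
#' summarizeRates((1:7) * 1e-7)
#' @export
summarizeRates <- function(rates) {
  n <- length(rates)
  stopifnot(n >= 1)
  s <- sort(rates)
  med <- stats::median(rates)
  if (n >= 6) {
    cover <- function(j) 1 - 2 * stats::pbinom(j - 1, n, 0.5)
    js <- seq_len(floor(n / 2))
    ok <- js[vapply(js, cover, 0) >= 0.95]
    j <- if (length(ok)) max(ok) else 1L
    list(n = n, median = med, ciLow = s[j], ciHigh = s[n + 1 - j],
         ciKind = "order-statistic 95%")
  } else {
    list(n = n, median = med, ciLow = s[1], ciHigh = s[n],
         ciKind = "range")
  }
}

#' Fold change between two median rates
#'
#' @param medianA,medianB positive medians (or lists from
#'   \code{\link{summarizeRates}}).
#' @return medianA / medianB; NA with a warning when medianB is 0.
#' @export
foldChange <- function(medianA, medianB) {
  if (is.list(medianA)) medianA <- medianA$median
  if (is.list(medianB)) medianB <- medianB$median
  if (medianB == 0) {
    warning("fold change undefined: reference median is zero")
    return(NA_real_)
  }
  medianA / medianB
}

#' Error-free fraction implied by a mutagenesis fold change
#'
#' If losing uracil glycosylase raises the mutation frequency
#' \code{fold}-fold, then in its presence only 1/fold of the abasic
#' sites are resolved mutagenically: the error-free fraction is
#' 1 - 1/fold. The observed 19-fold difference corresponds to ~95%
#' error-free bypass of AP sites.
#'
#' @param fold fold change >= 1.
#' @return fraction in [0, 1).
#' @examples
#' errorFreeFraction(19)   # ~0.947
#' @export
errorFreeFraction <- function(fold) {
  if (any(fold < 1)) stop("fold must be >= 1")
  1 - 1 / fold
}

#' Cell viability
#'
#' Ratio of colony-forming units after to before DSB induction; may
#' exceed 1 when cells divided during the incubation.
#'
#' @param cfuAfter,cfuBefore CFU counts; \code{cfuBefore} must be > 0.
#' @return viability fraction.
#' @export
viability <- function(cfuAfter, cfuBefore) {
  if (any(cfuBefore <= 0)) stop("cfuBefore must be positive")
  cfuAfter / cfuBefore
}

#' Pool repair-outcome counts across experiments
#'
#' Sums per-experiment counts of DSB repair outcome classes (gene
#' conversion, BIR, chromosome loss, half-crossover), reports pooled
#' percentages, and tests experiment homogeneity with a chi-square test
#' over the experiments-by-classes table (classes with all-zero counts
#' dropped; no continuity correction, so the statistic is the classical
#' Pearson chi-square).
#'
#' @param counts matrix or data.frame, one row per experiment, one
#'   column per outcome class.
#' @return list with pooledCounts, pooledPercent, chisqStat, df, pValue
#'   (the latter NA for a single experiment).
#' @export
poolOutcomes <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  pooled <- colSums(counts)
  pct <- 100 * pooled / sum(pooled)
  if (nrow(counts) < 2) {
    return(list(pooledCounts = pooled, pooledPercent = pct,
                chisqStat = NA_real_, df = NA_integer_,
                pValue = NA_real_))
  }
  keep <- colSums(counts) > 0
  ct <- counts[, keep, drop = FALSE]
  ht <- suppressWarnings(stats::chisq.test(ct, correct = FALSE))
  list(pooledCounts = pooled, pooledPercent = pct,
       chisqStat = unname(ht$statistic), df = unname(ht$parameter),
       pValue = unname(ht$p.value))
}

#' Compare two proportions by Fisher's exact test
#'
#' Two-sided exact test (sum of 2x2 tables with point probability no
#' larger than the observed one), e.g. for rearranged-outcome fractions
#' between strains.
#'
#' @param aNum,aDen,bNum,bDen numerators and denominators of the two
#'   proportions.
#' @return two-sided p-value.
#' @examples
#' proportionCompare(27, 58, 2, 28)   # ~2e-4
#' @export
proportionCompare <- function(aNum, aDen, bNum, bDen) {
  stopifnot(aDen > 0, bDen > 0, aNum <= aDen, bNum <= bDen,
            aNum >= 0, bNum >= 0)
  m <- matrix(c(aNum, aDen - aNum, bNum, bDen - bNum), nrow = 2,
              byrow = TRUE)
  stats::fisher.test(m)$p.value
}
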