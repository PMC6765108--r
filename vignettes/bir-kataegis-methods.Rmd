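---
title: "Methods: detecting and simulating BIR-associated APOBEC mutation clusters"
author: "kataegisBIR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and simulating BIR-associated APOBEC mutation clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kataegisBIR)
```

## The biological setting

Break-induced replication (BIR) repairs one-ended DNA double-strand
breaks by invasion of a homologous chromosome and conservative copying
of the donor, often to the chromosome end. The migrating replication
bubble leaves long stretches of single-stranded DNA (ssDNA) behind it,
and 5'-to-3' resection ahead of strand invasion exposes further ssDNA —
up to ~100 kb — on the centromere-proximal side of the break. ssDNA is
hypermutable: the cytidine deaminase APOBEC3A (A3A) converts cytosines
in ssDNA to uracils, preferring TCA/TCT (collectively TCW)
trinucleotides. What happens next depends on uracil glycosylase
(Ung1):

* **without Ung1** (`ung1Δ`), the uracil persists and templates adenine,
  fixing a heterozygous C→T on the newly synthesized (recipient) strand;
* **with Ung1**, the uracil is excised to an abasic (AP) site. A small
  fraction of AP sites is bypassed mutagenically by translesion
  synthesis (C→T or C→G, in roughly equal parts); the large remainder is
  bypassed error-free by recombination, which can collapse into a gross
  chromosomal rearrangement (GCR) — a deletion between flanking repeats
  or a half-crossover-type truncation — visible in sequencing data as a
  copy-number step.

In a strain disomic for chromosome III, BIR-tract mutations are
heterozygous (allele fraction near 0.5) because only one of the two
chromosome copies is repaired. This package implements the analysis of
such experiments (variant filtering, cluster calling, motif and strand
statistics, reversion-rate summaries, copy-number classification) and a
mechanistic simulator of the whole process so that every stage can be
validated against known truth.

## Variant filtering and zygosity

Input is a standard VCF with per-sample `DP` and `AD`. Only
single-nucleotide substitutions are analyzed. The filters are:

* **alt support**: at least `minAltReads` (default 10) reads carrying
  the alternative allele. The threshold is interpreted as *alt* support
  rather than total depth, because it governs the evidence for the
  mutation itself; it is exposed as a parameter for users who prefer
  the total-depth reading.
* **masking**: variants in excluded regions (telomeric repeats, LTRs),
  supplied as a BED mask. BED is 0-based half-open on disk; conversion
  to 1-based coordinates happens exactly once, at import.
* **recurrence**: variants called in two or more samples of the cohort
  (the sequenced parent counts as a sample) are treated as inherited or
  systematic and excluded. The threshold (default 2) is a parameter.
* **allele fraction**: ≥ 90% of reads → homozygous, anywhere in the
  genome. Inside disomic regions, fractions within 27–70% →
  heterozygous. The band between 70% and 90% in a disomic region fits
  neither definition and is kept as a distinct *ambiguous* class —
  excluded from clustering but never silently merged. Below 90% outside
  a disomic region the record is rejected.

Rejected records are retained with a machine-readable reason, so
filtering is idempotent and chained single-filter passes accumulate to
the same accepted set as one combined pass.

## Cluster calling

Accepted (homozygous + heterozygous) mutations are grouped per
chromosome: consecutive mutations no more than 100 kb apart belong to
one group. Each group of $k$ mutations spanning $s$ bases is tested
against a null in which the sample's $m$ accepted mutations fall
uniformly on the $G$ analyzable bases, so inter-mutation gaps are
geometric with per-base success probability $\pi = m/G$. The p-value is

$$ P\!\left(\textstyle\sum_{i=1}^{k-1} g_i \le s\right)
   = F_{\mathrm{NB}(k-1,\,\pi)}\!\left(s - (k-1)\right), $$

the negative-binomial CDF at $s-(k-1)$ failures for $k-1$ required
successes. Singletons return 1. Groups with $p < 0.01$ (strict) are
clusters; no multiplicity adjustment is applied. Both the grouping
distance and the threshold are parameters with these defaults. The
implementation is validated against a Monte-Carlo oracle that draws
geometric gaps directly, across a grid of $k$, $s$ and $\pi$.

Whether clustered mutations should be excluded from $m$ when estimating
$\pi$ is ambiguous; they are included (simpler and conservative, since
it inflates $\pi$ and therefore the p-values). Chromosome III's two
copies are clustered in a single coordinate space, matching
per-chromosome cluster reporting.

**A type-I caveat worth stating plainly.** The two-mutation group
p-value is the probability-integral transform of the observed gap, so
the *per-group* test has size exactly $\alpha$ — the suite verifies
this by a uniformity test. But a genome with ~28 background mutations
contributes ~27 gaps, so at $\alpha = 0.01$ without adjustment the
*per-genome* probability of at least one false cluster is about
$1 - 0.99^{27} \approx 24\%$ (the suite measures 35–40% once groups
with $k \ge 3$ are included). Genome-wide cluster counts from this
procedure should therefore be read per test, not per genome; the
BIR-tract clusters themselves sit many orders of magnitude below the
threshold and are unaffected.

## Spectra, motifs and strand statistics

Substitutions are reported pyrimidine-normalized: the class is read on
the strand carrying the mutated pyrimidine (six classes, C>A/C>G/C>T/
T>A/T>C/T>G), and the trinucleotide context is the reference 3-mer
centered on the mutated base, reverse-complemented for minus-strand
pyrimidines. TC fraction is computed over mutated cytosines; the TCW
fraction is reported *conditional on TC*, matching how enrichment in
the A3A-favored motif is usually quoted. Positions at chromosome edges
have no full context and are excluded with a logged count.

Strand bias is a two-sided exact binomial test of plus versus minus
pyrimidine-strand counts. Strand coordination within a cluster counts
strand switches between consecutive mutations; under independent
fair-coin strands the switch count is Binomial($k-1$, ½), and the exact
lower-tail CDF is the p-value (few switches = coordinated). The
binomial form is exact at any $k$, so no simulation fallback is needed;
the suite cross-checks it against full $2^k$ enumeration. These two
statistics are declared normative for this package; no claim is made
that they reproduce any particular earlier pipeline bit-for-bit.

Reporter reversions (the *ura3-29* assay: a C that can revert via C→T,
C→G or C→A) are classified directly from the observed base, and spectra
are compared per class with two-sided Fisher tests of class-versus-rest.

## Rates and outcome frequencies

Each fluctuation-style experiment yields a rate = Ura+ colonies /
viable CFU (dilution-corrected). Conditions are summarized by the
median; for $n \ge 6$ experiments the 95% confidence limits are the
order statistics $(x_{(j)}, x_{(n+1-j)})$ with $j$ the largest rank
whose two-sided Binomial($n$, ½) coverage is at least 95% — chosen
conservatively (coverage never below nominal) because no interpolation
convention is prescribed anywhere. For $n < 6$ no useful ranks exist
and the min–max range is reported, labelled as such. Conditions are
compared with the two-sided Mann–Whitney U test (mid-ranks for ties,
exact for small untied samples).

Fold changes are ratios of medians. A fold change $f \ge 1$ between a
glycosylase-null and a wild-type condition implies that only $1/f$ of
AP sites resolve mutagenically, i.e. an error-free fraction of
$1 - 1/f$; a 19-fold difference corresponds to ~95% error-free bypass.

Repair-outcome tables (gene conversion, BIR, chromosome loss,
half-crossover) are pooled across experiments after a chi-square
homogeneity check (uncorrected Pearson statistic; all-zero classes
dropped). Proportions between conditions are compared with Fisher's
exact test; the test behind the published rearrangement comparison is
not named, so the exact-enumeration value is normative here and the
printed figure is treated as its rounding.

## Copy-number classification

Windowed read depth (default 500 bp windows) is normalized as
$\log_2((d_{iso}+c)/(d_{par}+c))$ with pseudocount $c = 0.5$, optionally
median-centered on a copy-neutral reference chromosome. Steps are found
by greedy binary segmentation: a candidate boundary is scored by the
contrast between the `minSegmentWindows` windows on either side of it
(local contrast, so consecutive steps cannot dilute each other), the
best boundary is split when the contrast reaches `minStep` (default
0.58 ≈ log2(1.5), the midpoint separating one from two copies), and
adjacent segments closer than `minStep` are re-merged. The procedure is
deterministic and dependency-light; it is designed for 1-vs-2-copy
steps, not for subclonal or noisy tumor-style profiles.

Outcome classification is the in-silico analog of sizing chromosomes on
a CHEF gel: a non-rearranged BIR outcome shows a two-copy region from
the DSB-proximal boundary to the chromosome end; deviation beyond a
tolerance (default 5 kb — a classification default, not a measured
value), an interrupted two-copy region, or a missing diagnostic marker
labels the outcome rearranged; no two-copy region at all is
*incomplete*. Heterozygous variants are assigned to the donor or
recipient copy by phased marker alleles where available, otherwise
heterozygous variants inside the BIR tract default to the recipient
copy (conservative inheritance of newly synthesized DNA) and homozygous
variants are labelled pre-BIR.

## The simulator

`birSimParams()` fixes the scenario; `simulateCohort()` generates
truth-labelled isolates. Default parameters are chosen once, as the
study conditions the analysis expects:

| parameter | default | why |
|---|---|---|
| genome | 12 Mb in 6 chromosomes, chrIII = 340 kb, GC 38% | yeast-scale genome; disomic chromosome III with the DSB at 190 kb and a ~150 kb BIR tract to the chromosome end |
| `resectionMax` | 100 kb | resection observed up to ~100 kb; the realized length is uniform on [0, max] since only the maximum is constrained |
| `lambdaDeam` | 5.6e-4 per exposed C | preset so an ung1-null isolate accrues ~23 tract mutations, the scale of the observed median cluster |
| `fTCW` | 1.4 | preset so the conditional TCW share of TC mutations sits near the observed ~69% for a 38% GC background |
| `epsilonTLS` | 0.05 | ~5% of AP sites resolve mutagenically |
| `tlsCtCgRatio` | 1 | C→T and C→G in approximately equal amounts |
| `gammaGCR` | 0.028 | per-AP-site GCR probability preset so roughly half of UNG1 isolates acquire a rearrangement (≈ 27/58) given ~22 AP sites per isolate |
| `backgroundHomRate` | 2.3e-6 per base | ~28 homozygous background mutations per 12 Mb genome |
| `depthMean` | 100× | all isolates were sequenced above 100× |
| `nIsolates` | 25 | cohort size per condition |

Deamination is a single-pass Bernoulli process over exposed-strand
cytosines — probability $\min(1, \lambda \cdot f_{TCW})$ in TCW context,
$\lambda$ otherwise — with no explicit bubble-migration kinetics, since
mutagenesis appears uniformly elevated along the tract. One reference
strand (Watson by default) is exposed; the alternative is a parameter.
Lesion resolution follows the branch structure above exactly, so
ung1-null isolates are *forced* to 100% heterozygous C→T in the tract.
Read counts are Poisson depths with binomial alt counts (0.5
heterozygous, 0.98 homozygous; overdispersion is out of scope).
Emission produces a VCF v4.2 (GT:DP:AD), isolate and parent coverage
tracks whose profiles reflect GCR deletions and truncations, a BED of
the exposed tract, a lossless truth table, and a JSON cohort manifest;
everything is byte-identical under a fixed seed.

**What passing the round trips does and does not show.** The simulator
reproduces the statistical structure the analysis assumes — cluster
geometry, zygosity, motif enrichment, coverage steps — not real
sequencing artifacts: no mapping errors, no GC-coverage bias, no
multi-round BIR cascades, no template switching, and background
mutations are uniform rather than weakly clustered. Green round trips
therefore validate the pipeline's logic and calibration, not its
robustness to alignment pathology.

## Problem sizes used by the test suite

Unit tests run on small constructed fixtures and a reduced genome
(chrIII 120 kb + one 200 kb background chromosome). The end-to-end
checks use the full default scenario: one emitted 25-isolate ung1-null
cohort, 60 in-memory isolate pairs for the fold-ratio recovery, two
emitted 25-isolate cohorts for the rearrangement asymmetry, 10,000
simulated cohorts per $n$ for the median-CI coverage, 1,000 uniform
genomes for the type-I measurement, and $10^5$–$10^6$ Monte-Carlo draws
per point for the cluster p-value oracle. These sizes were chosen so
the whole suite completes in a few minutes on one core while keeping
every binomial check at 3-standard-error resolution.

## Known limitations

* The negative-binomial null treats mutations as exchangeable across
  the unmasked genome; regional rate variation will inflate cluster
  calls outside the BIR tract (see the type-I caveat above).
* The segmentation detects clean 1↔2 copy steps; it is not a general
  CNV caller.
* Donor/recipient assignment without marker evidence relies on the
  conservative-inheritance default and cannot resolve variants outside
  the tract.
* The simulator's GCR classes are two stylized mechanisms chosen to
  exercise the coverage classifier, not a full rearrangement zoo.
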