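---
title: "Replicate-consensus detection of low-frequency somatic mutations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replicate-consensus detection of low-frequency somatic mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualseq)
library(dplyr)
```

## The problem

Cancer gene panel testing must detect somatic *mosaic* mutations — variants
present in only a fraction of the sampled cells, at variant allele
frequencies (VAF) well below the 50% of a heterozygous germline variant.
At these frequencies, calls made from a single deep-sequencing library are
dominated by artifacts: DNA-polymerase misincorporations in the first
cycles of pre-capture PCR amplification propagate through the library and
are indistinguishable, read by read, from real sub-clonal variants.
Tumor-only variant callers report thousands of such calls per run, of
which only a handful are real.

`dualseq` implements the replicate-consensus strategy for separating the
two: sequence the *same* DNA in independent libraries — amplified by
different DNA polymerases — and in duplicate experiments, call variants
with several somatic callers, and keep only variants that recur across
libraries and replicates. Because polymerase errors strike positions
essentially at random, an artifact is overwhelmingly unlikely to recur at
the same site in independently amplified libraries, while a real mosaic
variant is present in every library at roughly its true VAF.

## The consensus model

Variant identity is the normalized tuple (chromosome, position, ref, alt):
alleles are uppercased, shared suffixes then prefixes trimmed (position
advanced), and — when a reference sequence is available — indels are
left-aligned to their leftmost representation. Matching across callers is
exact on this key; genotype and annotation fields are ignored. Without a
reference, representation differences of indels inside repeats cannot be
unified; this is a documented limitation, and all synthetic data consists
of single-nucleotide variants where the trimmed form is already canonical.

For one caller, each variant's detections form a set of
(polymerase, replicate) libraries. With $P$ polymerases and $R$
replicates, let $c_r$ be the number of distinct polymerases detecting the
variant in replicate $r$. The variant's reproducibility category is

* **category 1** — $\min_r c_r = P$: all polymerases, every replicate;
* **category 2** — $\min_r c_r \ge 2$ (and not category 1): at least two
  polymerases in every replicate;
* **category 3** — exactly one replicate has $c_r \ge 2$;
* **category 4** — no replicate reaches two polymerases.

"Two of three polymerases" is deliberately read as a *threshold*
($\ge 2$), not an exact count. Under the exact-count reading, tuples such
as $(3,2)$ would be unclassifiable; the threshold reading makes the four
predicates a total partition of all nonzero support tuples, which the
tests verify by exhaustive enumeration (all 15 nonzero tuples for
$P=3, R=2$, and all 63 library-set patterns behind them). A consequence
worth noting: a variant detected by a *different* single polymerase in
each replicate (support $(1,1)$) is category 4 — it never reaches
two-polymerase support in any single experiment.

Categories are computed *per caller* and then intersected: the
category-1∪2 sets of the callers are combined in a three-set Venn
partition, and the all-caller intersection is the pipeline's headline
consensus output. Categories are never pooled across callers before
classification, because each caller's false-positive load and detection
behaviour differ.

Both filter modes are always computed. `mode = "all"` counts every call;
`mode = "passed"` recomputes support from filter-passing calls only.
Passing filters removes detections, so a variant's passed-mode support
tuple is pointwise $\le$ its all-mode tuple (property-tested), but its
*category* can move either way in principle, which is why both modes are
reported rather than one being derived from the other.

## VAF concordance

For consensus variants, `vaf_summary()` reports mean, sample SD
($n-1$ denominator; the estimator is a package choice, as "±" values in
the field rarely state one), min and max, overall or grouped by caller or
by library. `vaf_variance_decomposition()` contrasts, per variant, the SD
of VAF *across callers within one library* with the SD *across libraries
within one caller*. The first isolates algorithmic disagreement on
identical reads; the second isolates the PCR/library step. The ratio of
their means quantifies the claim that run-to-run variability (allele
amplification bias) dominates caller-to-caller variability. VAFs are
stored as fractions; outputs that quote percentages multiply by 100 at
the formatting stage only.

## Coverage and saturation

`coverage_metrics()` works on merged panels and `samtools depth`-style
tracks, with absent positions counted as depth 0. The depth threshold
behind "coverage rate" is not standardized; the default is
`min_depth = 1`, because the companion metrics — percentage of fully
covered and of completely uncovered target regions — are only meaningful
at ≥1×. `average_depth` always includes zero-depth bases.

Read downsampling is performed at the aligned-read-interval level rather
than from FASTQ: a single permutation of the reads is drawn under the
seed and each requested read count takes its prefix, so the samples are
nested and metrics move monotonically along the ladder. For simulated
experiments, where no reads exist, `saturation_curve()` thins each call's
alternate-read count binomially by `n / reads_total` and re-evaluates
detection: a true variant remains callable while it retains `alt_min`
supporting reads, an artifact call persists while at least one supporting
read remains. With this rule the `n = reads_total` row reproduces the
unthinned analysis exactly.

## The generative model behind the simulator

The error mechanism the consensus strategy exploits is hypothesized, not
formalized, in the literature; `sim_config()` encodes the minimal
generative structure that reproduces every qualitative observation the
strategy rests on, with every distributional choice exposed as a
configuration knob.

* **Panel.** `n_regions = 500` regions of `region_length = 2000` bp tiled
  on a synthetic chromosome — a 1 Mb panel, a realistic size for a
  several-hundred-gene capture design (the true size of the commercial
  panel that motivated the defaults is not published; collision rates
  scale with panel size, so it is a visible, reported parameter).
* **True variants.** `n_true = 6` mosaic variants at
  VAF ~ Uniform(0.15, 0.3), the range reported for validated mosaic
  mutations in tumor tissue of 30–40% purity.
* **Run bias.** Each (variant, library) pair draws a multiplicative
  lognormal amplification bias with mean 1 and coefficient of variation
  `run_bias_sd / mean(true_vaf_range)`, so the realized VAF SD across
  libraries is ≈ `run_bias_sd` (default 0.08) at mid-range VAF — and
  proportionally 0.05–0.11 across the VAF range, matching the dispersion
  observed for real mosaic variants. Depth is negative binomial
  (`mean_depth = 300`, dispersion 10); alternate reads are binomial.
* **False positives.** Each library owns one polymerase-error pool of
  Uniform(2000, 4000) sites placed uniformly over the panel (excluding
  planted sites). Each position of the synthetic genome has a fixed
  reference base and a fixed characteristic error substitution, so an
  error site struck in two libraries yields the *same* variant: recurrence
  across libraries is a pure positional birthday-collision process with
  expectation $m_1 m_2 / L$ per library pair, which the tests verify
  against that closed form. Error VAFs are sub-clonal — truncated
  Beta(1, 15) on (0, 0.1] — as first-cycle PCR errors enter only a
  fraction of the library.
* **Callers.** All callers see the same library pool but report subsets:
  per caller and replicate, a count is drawn from the calibrated ranges
  (strelka2-like 2000–4000 in both replicates, of which ~15% pass
  filters; mutect2-like 200–1000 then 1700–3000, ~35% passing;
  lofreq-like 150–600 then 50–120, all passing — that caller emits only
  filter-passing calls) and that many pool entries are sampled uniformly.
  Subset sampling from a shared pool reproduces the observed asymmetry:
  within one library, callers overlap heavily (the smaller call sets are
  near-subsets of the largest), while across libraries overlap is nearly
  nil. The tests assert the resulting caller-pairwise Jaccard exceeds the
  polymerase-pairwise Jaccard by an order of magnitude.
* **Caller noise.** Callers re-estimate the alternate-read count with
  Gaussian perturbation of SD `caller_vaf_noise_sd × depth`
  (default 0.005 on the VAF scale), keeping reported VAFs
  count-consistent — so they survive VCF round-trips exactly — while
  giving the variance decomposition a realistic, small between-caller
  component.
* **Detection.** A true variant is callable in a library when its
  alternate-read count reaches `alt_min = 3`; at depth 300 and VAF ≥ 0.15
  this is essentially always, so recall is governed by depth and VAF, not
  by the threshold.

What the simulator deliberately does *not* emulate: read-level artifacts
(alignment error, strand bias, FFPE deamination), non-uniform error
hotspots beyond the fixed per-position substitution, caller-specific
biases that correlate with sequence context, and UMI consensus
collapsing. Passing tests therefore demonstrate that the consensus
machinery is correct and that the strategy works *under this error
model*; they do not certify performance on real libraries, where error
processes are position-dependent and callers share systematic blind
spots.

## Numerical and design choices

* VCF dialects: the Strelka2-like reader derives SNV VAF from tier-1 base
  counts and falls back to allele depths for indels; the Mutect2-like
  reader uses the tumor sample's `AD`; the LoFreq-like reader uses
  `INFO/AF` with `INFO/DP` (no alternate count is recoverable). The
  choices follow each tool's documented conventions and sit behind the
  dialect object so they can be overridden. `FILTER` equal to `PASS` or
  `.` marks a passed call; failing records are carried with their flag,
  never dropped. Multi-allelic records are split into one call per
  alternate allele before normalization. Zero total depth yields a
  missing VAF, never zero.
* Venn region numbering (1–3 exclusive, 4–6 pairwise, 7 triple) follows
  input label order and is documented, since any figure's numbering is
  figure-specific.
* Ties and degenerate inputs: empty call sets produce header-only VCFs,
  zero-count reports and empty consensus with success status; an all-zero
  support tuple is rejected as "not a detected variant"; duplicate
  (variant, run) pairs are an error naming the offending key, because
  they indicate an upstream merge mistake rather than data.
* Determinism: every stochastic step runs under `withr::with_seed`;
  identical (config, seed) produce byte-identical simulated files, and
  pipeline reruns produce byte-identical reports (no timestamps in
  outputs). Outputs are staged in a temporary directory and moved into
  place only after all tables are written.
* Problem sizes: unit and property tests run on a 20 kb panel with
  ~100–200 errors per library, which preserves every structural feature
  of the full design; the calibrated acceptance simulations use the full
  1 Mb / 2000–4000-error defaults over 20 seeds each — the scale at which
  the headline percentages are meaningful.

## Limitations

Exact-key matching can split a real indel across caller representations
when no reference is supplied. The simulator's collision process makes
cross-library false-positive recurrence *rarer* than in real data, where
error hotspots exist; the consensus precision measured here is therefore
an upper bound with respect to that mechanism. The on-target-rate and
saturation analyses operate on aligned intervals, not raw reads, so
duplication and mapping quality are assumed already handled upstream.
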