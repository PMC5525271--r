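---
title: "Models and methods: small RNA and degradome analysis of de-etiolating seedlings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: small RNA and degradome analysis of de-etiolating seedlings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deetiolR)
```

# Scope

`deetiolR` analyses the small-RNA side of seedling photomorphogenesis: a
dark-grown seedling is exposed to continuous white light and sampled at
W0 (dark), W1, W3, W6, W12 and W24 hours in three biological replicates,
with degradome (PARE) libraries for the dark state and for a pool of the
five light time points. The package covers five analysis stages — I/O and
coordinate handling, expression quantification and classification,
PHAS/TAS locus detection, degradome cleavage calling, and comparative
statistics — plus a fully seeded synthetic-data generator so that every
stage can be exercised against known ground truth.

All in-memory intervals are 0-based half-open; everything written as GFF3
is 1-based inclusive. Sequences are handled DNA-style (`U` is normalized
to `T` on input).

# The phasing statistic

Phased siRNAs are produced by successive 21-nt dicing of a double-stranded
precursor, so their 5' ends recur in one of $L = 21$ residue classes
("registers") modulo the phase length. Within a window of $W = 251$ nt the
scan collapses reads to distinct (start, strand) alignment positions,
counts $n$ of them, finds the register holding the most positions, and
counts its occupancy $k$. Under the null that $n$ occupied positions are
drawn without replacement from $N$ candidate positions of which $K$ lie in
a register, the evidence for phasing is the upper hypergeometric tail

$$P(X \ge k) \;=\; \sum_{j \ge k} \frac{\binom{K}{j}\binom{N-K}{n-j}}{\binom{N}{n}},$$

optionally multiplied by a register-selection factor $m$ and capped at 1.

## Strand geometry

Both strands contribute positions. A plus-strand read phases by its 5'
(leftmost) coordinate. Dicing leaves 2-nt 3' overhangs, so the 5' end of a
phased minus-strand read sits 2 nt 3' of the plus-strand cut; the register
coordinate of a minus-strand read is therefore its 5' position minus 2,
taken modulo 21. The synthetic generator plants minus-strand phased reads
under the same geometry, so detector and simulator agree by construction
rather than by tuning.

## Calibrating the convention ($N$, $K$, $m$)

Published phasing analyses print $(n, k, p)$ per locus but rarely the
convention behind $N$ and $K$. `calibrate_phasing_convention()` sweeps the
candidate family $N \in \{W, 2W, L\lceil W/L\rceil, 2L\lceil W/L\rceil\}$,
$K \in \{\lceil W/L\rceil, 2\lceil W/L\rceil\}$, $m \in \{1, L\}$ against
the packaged twelve-locus table (`phas_locus_table()`) and ranks members by
the worst per-row $\log_{10}$ deviation. Members with $K = 12$ are
infeasible outright (the table prints $k$ up to 14, and $k \le K$), which
independently confirms that both strands were counted. The best member —
adopted as the `phasing_params()` default — is

* $N = 2W = 502$ candidate positions,
* $K = 2\lceil W/L\rceil = 24$ register positions,
* $m = 1$ (no register multiplier).

```{r calibration}
head(calibrate_phasing_convention(), 4)
```

**Residual.** No member of the family (indeed, no hypergeometric
convention at all — an exhaustive grid over $N$ and $K$ with a free
constant multiplier behaves identically) reproduces all twelve printed
p-values: eleven of twelve rows agree with the adopted convention within a
common factor of about 1.6 (one order of magnitude), but the TAS2 row
($n = 12$, $k = 9$) computes roughly 40-fold smaller than printed, and the
printed ordering contains inversions (a locus with $n=13$, $k=7$ printed
*above* one with $n=77$, $k=14$) that no tail probability monotone in
$k/n$ can reproduce. The package treats the convention above as normative,
reports the residual, and the acceptance suite asserts the published-table
agreement contract in full, so the two irreducible discrepancies are
visible as failing expectations rather than hidden.

## Window mechanics

`scan_phas()` slides full-width windows in steps of one phase cycle
(21 nt); a reference shorter than one window is scanned as a single
clipped window. Runs of overlapping significant windows are merged into
one locus call keeping the minimum p-value and its $(n, k)$. Windows with
fewer than `min_distinct_alignments = 10` distinct alignments are not
tested: with a fixed-$N$ convention, a sparsely covered window holding
two or three co-register reads would otherwise reach nominal
$p < 10^{-4}$ on evidence no practitioner would call phasing, and the
published calls all carry $n \ge 10$. The reporting threshold is
$p < 10^{-4}$.

# Degradome cleavage calling

## Complementarity score

Candidate sRNA:target duplexes are scored with the classic plant-miRNA
penalty scheme: mismatch 1, G:U wobble 0.5, bulge 1 (treated as a
single-position insertion), with every penalty doubled at sRNA positions
2–13 — the functionally critical region around the cleavage site. A
perfect duplex scores 0; candidate sites are all ungapped windows scoring
at most `max_score = 3` (the "expectation 3" style cutoff), overlapping
sites deduplicated keeping the best score (ties to the leftmost). The
target-site accessibility filter used by structure-aware predictors (a
folding-energy cutoff such as UPE 25) is **not** implemented: sites are
ranked by complementarity only, which over-predicts candidates in
structured regions; the degradome evidence downstream is what removes
them.

## Site localization and categories

Slicing occurs between sRNA positions 10 and 11, so the diagnostic
uncapped 5' end maps to the transcript coordinate opposite position 10.
Degradome reads are attributed to the expected site within
`site_tolerance = 1` nt (absorbing 5'-end heterogeneity); the attributed
position is the maximum-count position in that window. With $c$ the count
there and the comparison set the transcript's nonzero positions:

| category | rule |
|---|---|
| 0 | $c > 1$ and the unique maximum |
| 1 | $c > 1$, ties the maximum |
| 2 | $c > 1$, above the median of nonzero counts, below the maximum |
| 3 | $c > 1$, at or below the median |
| 4 | $c = 1$ |

A read-free site has no category and can never validate. Ties at the
median resolve downward (category 3): the rule is `> median` for
category 2, fixed and documented rather than guessed against external
tooling.

## Empirical p-value and validity

The null preserves sRNA composition: `n_shuffles = 100`
dinucleotide-preserving shuffles (Altschul–Erickson Eulerian-walk
sampling, exact dinucleotide counts, same first and last base) are scanned
against the whole transcriptome, and $b$ counts shuffles achieving — at
any site — a score at most the observed score *and* a category at most the
observed category. Then $p = (1+b)/(n_{\text{shuffles}}+1)$, bounded below
by $1/101$ and never invalidated by adding shuffles. A homopolymer
shuffles to itself, so its p-value is 1 by construction — the correct
degenerate answer. A call is **valid** when category $\le 2$, $p \le 0.05$
and at least 5 raw reads sit at the site; RPM-normalized site reads are
reported alongside but the filter deliberately uses raw counts.
`tplot_data()` exports the per-position series with called sites flagged
for T-plot rendering.

# Quantification and classification

RPM normalizes each library independently to its total mapped reads of
20–24 nt: $\mathrm{RPM} = 10^6 \, c/T$. Reads matching several members of
an sRNA family are split equally among the members hit, conserving total
mass. Two classification rules mirror common practice:

* **Expressed** — every replicate has some time point with raw count
  $\ge 5$. The phrase "in at least one time point for all replicates" is
  ambiguous; the default reads it per replicate (qualifying time points
  may differ), the stricter shared-time-point reading is available via
  `same_time_point = TRUE`. The default is the weaker, more inclusive
  reading; both are tested against hand-counted fixtures.
* **Light-regulated** — for each light time point a two-sided two-sample
  t-test of the three replicate RPM values against W0; regulated if any
  time point has $p < 0.05$. Welch's test is the default (safest for
  $n = 3$ library-normalized data); the pooled-variance variant sits
  behind `var_equal = TRUE`. If both groups are constant the test
  degenerates: equal means give $p = 1$, different means $p = 0$.

Log2 fold changes use replicate means with W0 as the anchor (the W0 entry
is 0 by construction). A feature with zero dark mean has undefined
(infinite) fold changes; it is reported with its detection time instead —
the behavior of dark-silent, light-induced miRNAs.

# Comparative statistics

* **K-S comparisons** (`ks_two_sample()`): exact permutation p-values when
  $n_1 n_2 \le 100$ (cheap and correct with ties), the asymptotic formula
  otherwise. $D$ is rank-invariant, so running the test on raw or
  log-scale abundances is equivalent; a log10 column is exported for
  plotting only.
* **Ratio determinant analysis** (`ratio_analysis()`): candidate pairs are
  partitioned by degradome support (`plus` = a valid cleavage call links
  the pair); sRNA abundance, target abundance and the pairwise
  sRNA-to-target ratio are each compared between strata. Ratios are
  defined only for expressed targets (RPKM > 0.01). The dark snapshot
  pairs W0 sRNA RPM with W0 mRNA RPKM; the light snapshot pairs W3 sRNA
  RPM with W4 mRNA RPKM — the 1-h offset comes from the companion mRNA
  dataset's sampling grid and is fixed, not configurable.
* **Fold-change comparison** (`fold_change_compare()`): two-sided t-test
  between strata on log2 light/dark ratios.
* **Fisher enrichment** (`fisher_2x2()`): exact two-sided p by
  point-probability summation — used for questions such as whether
  transposable-element transcripts are over-represented among
  siRNA-cleaved targets.
* **Clustering** (`cluster_profiles()`): k-means, Euclidean distance, on
  W0-anchored log2 fold-change profiles, 20 seeded restarts keeping the
  best inertia. The default $k = 3$ matches the three major
  light-response classes of the packaged 66-profile table
  (`light_response_profiles()`); the table's source figure was drawn with
  four clusters, so $k = 4$ is exposed as an option and the discrepancy
  recorded rather than resolved. Degenerate matrices (fewer distinct
  profiles than $k$) shrink $k$ to the distinct-profile count instead of
  erroring.

On the packaged table, $k = 3$ isolates the single induced-from-silence
profile (miR163) as cluster I and recovers the printed I/II/III partition
with adjusted Rand index 0.88:

```{r cluster}
lr <- light_response_profiles()
res <- cluster_profiles(lr$log2fc, k = 3, n_restarts = 20, seed = 1)
table(printed = lr$cluster, kmeans = res$cluster)
```

# The synthetic-data generator

`simulation_config()` fixes the study conditions: six time points, three
replicates, the three archetype trajectories (I induced from a zero dark
mean; II gradual up, ~0.9 log2 units by W24; III down ~1 log2 unit — a
two-fold decline — by W24) sized 1/15/50 like the published light-response
set, negative-binomial replicate noise (dispersion 0.2; the
dispersion-to-zero limit returns rounded means exactly, which anchors unit
tests), Poisson(10) degradome site signal over geometric(0.2) background
(sparse with heavy zero mass, so category medians are nontrivial), a 15%
transposable-element fraction, and library sizes around 20 M reads scaled
down by `desk_scale = 1e4` so a full pipeline run takes seconds. Planted
target sites are exact reverse complements (duplex score 0); PHAS loci
carry 15 distinct read positions at `phase_fraction` register fidelity on
both strands; `light_only` cleavage events are masked out of the dark
degradome, emulating cleavage signatures detectable only after
irradiation. Everything is generated under `seed` (stages use `seed`,
`seed + 1`, `seed + 2`), is byte-identical across runs, and is enumerated
in truth tables so recall and false-call rates are computed against
ground truth rather than re-simulation.

What the generator deliberately does **not** emulate — and hence what
passing tests cannot certify about field data: sequencing error and
adaptor artifacts, genome-scale multi-mapping ambiguity, RNA secondary
structure (both for target accessibility and for degradome background
shape), correlated replicate effects, and isomiR 5'/3' heterogeneity
beyond the ±1 nt site tolerance.

# Numerical choices and degenerate inputs

* Register ties break to the smallest register coordinate; overlapping
  candidate sites to the best score, then leftmost.
* `phasing_pvalue()` is clamped to $(0, 1]$ (double underflow maps to the
  smallest positive double rather than 0).
* Exact K-S enumeration threshold $n_1 n_2 \le 100$; Fisher follows the
  standard $1 + 10^{-7}$ tie tolerance of the exact test.
* Seeded functions snapshot and restore the caller's RNG state, so
  package calls never perturb user-level random streams.
* Problem sizes in the shipped tests and acceptance script: 20 planted
  PHAS loci against 100 decoy windows; 50 planted cleavage events on a
  50 x 500-nt transcriptome with 100-shuffle p-values; 10-seed ratio
  simulations with 50 pairs per stratum; enumeration oracles up to
  $N = 15$ (phasing), table total 40 (Fisher) and $n_1 n_2 = 100$ (K-S).

# Known limitations

Exact-match read placement only (a deliberate, minimal aligner for
synthetic references — not a replacement for genome-scale mapping); no
24-nt phasing; no trigger identification de novo (trigger annotation is
taken from degradome calls); no RNA-folding accessibility; the degradome
category and shuffle-null rules are this package's fixed reconstruction of
the cited tool family's behavior and may differ from any specific external
implementation in corner cases such as median ties.
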