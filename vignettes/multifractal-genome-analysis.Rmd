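---
title: "Estimating genome multifractality from chaos-game point clouds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating genome multifractality from chaos-game point clouds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgrmf)
```

## The model

The chaos game representation (CGR) maps a DNA sequence to a point cloud
in the unit square: starting at the center, each base moves the current
point halfway toward that base's corner, one emitted point per base.  The
point after base $i$ lands in the grid cell of side $2^{-k}$ determined
by the last $k$ bases, so the cloud's density at scale $2^{-k}$ encodes
the sequence's $k$-mer composition.  If bases were drawn i.i.d. with
corner probabilities $p = (p_A, p_C, p_G, p_T)$, the cloud samples the
self-similar measure with contraction $1/2$ and weights $p$, whose Rényi
dimension spectrum is exactly

$$D_q = -\frac{\log_2 \sum_{p_i > 0} p_i^{\,q}}{q - 1}, \qquad
  D_1 = -\sum p_i \log_2 p_i .$$

`analytic_dq()` implements this closed form; it is the package's
end-to-end oracle.  Real genome fragments are not i.i.d., and their
departure from a flat spectrum is exactly what the method measures.

The estimator is classical box counting.  At scale $k$ the unit square is
covered by disjoint half-open boxes of side $\varepsilon = 2^{-k}$; with
$M_i$ points in occupied box $i$ and $M_0$ points in total, the partition
sum is $S(q, \varepsilon) = \sum_i (M_i / M_0)^q$ over occupied boxes,
and $D_q$ is the least-squares slope of $\ln S(q, \varepsilon)$ against
$(q - 1)\ln\varepsilon$ across the scale range.  At $q = 1$ the partition
sum is singular and the entropy limit is used instead:
$D_1$ is the slope of $\sum_i (M_i/M_0)\ln(M_i/M_0)$ against
$\ln\varepsilon$.  From the spectrum follow the mass exponent
$\tau(q) = (q-1) D_q$ (exactly $0$ at $q = 1$ by construction; linear iff
the spectrum is flat) and the multifractality degree
$\Delta D_q = \max_q D_q - \min_q D_q \ge 0$, the per-fragment summary
statistic for all downstream analysis.

Assumptions worth stating: the method treats a fragment as a stationary
sample of one measure (fragments mixing two very different compositions
get an intermediate spectrum); N bases are skipped without resetting the
CGR position, so they neither emit points nor inject center-point
artifacts; and the estimate is a finite-scale regression, not the
$\varepsilon \to 0$ limit, which is why the per-$q$ fit $r^2$ is always
reported alongside $D_q$.

## Parameters and defaults

* **Fragment length** (`fragment_length`, default 300,000 bases).  The
  window at which spectra are computed; trailing partial windows are
  discarded.  300 kb gives $3 \times 10^5$ CGR points per fragment,
  enough to populate a $64 \times 64$ grid densely.
* **Ambiguity filter** (`max_n_fraction`, default 0.10).  Windows with
  more than 10% N are flagged `removed` rather than deleted, keeping the
  filter auditable; downstream functions skip them.  The threshold is a
  package choice: assembly gaps produce windows that are either nearly
  N-free or mostly N, so results are insensitive to values between
  roughly 0.05 and 0.5.
* **Moment orders** (`q`, default integers $-20..20$).  Positive $q$
  weights dense regions (repeats), negative $q$ sparse ones.  Beyond
  $|q| \approx 20$ the moments are dominated by single extreme boxes and
  add noise, not information.  Non-integer $q$ is accepted.
* **Scale range** (`k_range`, default $1..6$, i.e. grids from
  $2\times2$ to $64\times64$).  The finest scale must keep boxes
  populated: at $k = 6$ a 300-kb fragment averages $\approx 73$ points
  per box.  Pushing to $k = 7$ or $8$ (18 and 4.6 points per box)
  visibly corrupts the negative-$q$ moments — on uniform i.i.d. sequence,
  where every $D_q = 2$ exactly, the spurious spectrum spread grows from
  $\approx 0.07$ at $k \le 6$ to $\approx 0.39$ at $k \le 8$.  The
  working rule: choose the largest $k$ with $M_0 / 4^k \gtrsim 70$.
  All scales in `k_range` enter one ordinary least-squares fit; there is
  no adaptive scale selection, by design — reproducibility over
  adaptivity — and poor scaling regions remain visible through `fit_r2`.
* **Corner assignment** (`corners`).  The standard genomics convention
  A=(0,0), C=(0,1), G=(1,1), T=(1,0).  All $D_q$ statistics are invariant
  under corner permutation (a symmetry of the square), so this choice
  only affects rendered images.
* **Binning** (`rm_binning`, `bin_width` default 0.05).  Bins of the
  observed $\Delta D_q$ axis ("ranges of multifractality"); 0.05 resolves
  a typical genome-wide span of $\sim 0.8$ into $\sim 15$ bins.
* **Classification thresholds** (`threshold_classify`, defaults
  $\Delta D_q \ge 1.159$ and Alu count $\ge 217.9$, both inclusive).
  The published cut points separating the high-multifractality/high-Alu
  fragment group from the low-and-medium (LMM) remainder; both are plain
  arguments.
* **Interval counting rule** (`count_per_fragment`, default
  `"midpoint"`).  An annotation interval is counted once genome-wide, in
  the fragment containing its midpoint; `"any"` and `"within"` are
  available.  Midpoint containment avoids double counting across
  fragment boundaries while conserving totals (counted + skipped =
  input), which the tests assert.
* **Chromosome clustering** (`cluster_chromosomes`).  Rows
  (chromosome-averaged $D_q$ vectors) are min-max normalized (z-score
  alternative available), dissimilarity is $1 -$ Pearson correlation,
  agglomeration is complete linkage, and the tree is cut into three
  multifractality groups by default.  Merge similarities are reported as
  $1 - $ height.

## Numerical choices

* Partition sums are evaluated in log space
  ($\ln S = \mathrm{logsumexp}(q \ln(M_i/M_0))$), so $q = \pm 20$ on
  $3\times10^5$ points cannot overflow.
* Empty boxes are excluded from all sums; mandatory for $q < 0$, where
  $M_i = 0$ diverges, and standard practice elsewhere.
* Boxes are half-open, $[i\,2^{-k}, (i{+}1)\,2^{-k})$, with coordinate
  exactly 1.0 assigned to the last box — a deterministic tie-break.  CGR
  coordinates are dyadic rationals, so a handful of points fall exactly
  on box edges; consequently corner-permutation invariance holds to
  about $10^{-3}$ on $D_q$ rather than exactly (every non-identity
  symmetry of the square reverses the half-open direction of one axis).
* The CGR recursion $p_t = (p_{t-1} + c_t)/2$ is evaluated by
  `stats::filter(method = "recursive")`, which is exact (same arithmetic
  as the loop) and fast; the test suite checks bit-level agreement with
  a plain-loop implementation.
* Degenerate inputs error early: empty point sets, all-coincident
  points (a single occupied box at the finest scale), fewer than three
  scales, constant regression predictors.
* `simple_regression` reports $R^2$ as the squared Pearson correlation
  and the classical two-sided slope $t$-test; `multivariate_regression`
  min-max normalizes response and predictors to $[0,1]$ before fitting,
  errors on zero-variance or rank-deficient designs (naming the
  columns), warns on condition numbers above $10^8$, and reports the
  five largest-$|$coefficient$|$ predictors.  No multiple-testing
  correction is applied.

## What the synthetic generator emulates — and what it does not

`planted_repeat_genome()` produces i.i.d. background fragments carrying a
known number of copies of a single seed-derived 300-bp consensus,
placed uniformly at random without overlap (rejection sampling with a
retry cap) and mutated per base at rate 0.1 — the size and polymorphism
regime of Alu elements.  Copies overwrite the background, so fragment
lengths are exact and the annotation track matches the insertions
base-for-base; the tests recount the planted truth through the interval
layer exactly.  The consensus is generated from the seed rather than
taken from a repeat database, keeping the package free of external data.

This emulates the one mechanism under test — repeat density raising
$\Delta D_q$ — and deliberately nothing else: no subfamily phylogeny, no
insertion-site preference, no G+C heterogeneity, no tandem repeats, no
gene structure.  Passing the planted-gradient experiment therefore shows
the pipeline detects repeat-driven multifractality; it does not certify
the absolute $\Delta D_q$ scale of real chromosomes, where isochore
structure and tandem repeats also contribute.

`archetype_spectra()` generates labelled chromosome-averaged spectra for
cluster-recovery experiments.  Because the clustering metric
(row normalization + Pearson correlation) is invariant to scaling and
shifting a spectrum, groups that are mere scaled copies of one template
are indistinguishable *by construction*; the generator therefore plants
groups that differ in curve shape, using measures whose composition bias
is concentrated on one, two, or three corners.  With eight spectra per
group and Gaussian noise at 1% of the mean template range, the planted
partition is recovered exactly.

## Design notes

* Fragments are ordered by FASTA record order, then position; coordinates
  are 0-based half-open internally, with both BED and 1-based-inclusive
  interval dialects accepted at input.
* Ambiguous IUPAC codes collapse to N at read time: CGR corners exist
  only for A/C/G/T.
* The $q$ grid defaults to the integers $-20..20$ so that reported
  $\Delta D_q$ values refer to a fixed, comparable window of moment
  orders.
* Region averaging splits a chromosome's fragments into runs whose sizes
  differ by at most one, earlier runs taking the remainder — a stated,
  deterministic rule rather than quantile-based splitting.
* The fragment classification is a pure two-threshold conjunction; the
  three-group chromosome classification is realized only through the
  dendrogram cut, never by manual assignment.
* There is no command-line wrapper: the exported functions compose in a
  few lines (see the README example), and scripts are the natural
  interface for batch runs.

## Problem sizes used in the shipped experiments

The test suite and `scripts/acceptance.R` run entirely on synthetic
data: oracle spectra at $n = 3\times10^5$–$5\times10^5$ points per
sequence, the planted-repeat experiment at 60 fragments × 300 kb, the
exhaustive-grid oracle comparison at $\le 1000$ points
($q \in \{-5..5\}$, $k \le 3$, where full-grid enumeration is cheap), and
cluster recovery at 3 × 8 spectra.  These sizes reproduce the study
conditions at the fragment level while keeping a complete run in the
order of a minute.

## Known limitations

* Negative-$q$ dimensions are intrinsically the hardest to estimate
  (they amplify sparsely populated boxes); with the default scale range
  the uniform-sequence null shows a residual spurious spread of
  $\Delta D_q \approx 0.07$, which is the effective noise floor of the
  statistic at 300 kb.  Comparisons of $\Delta D_q$ are meaningful
  between fragments analyzed with identical $n$, $q$ and `k_range`.
* The estimator fixes one scale range for all $q$; a genuinely
  scale-dependent fragment will show depressed `fit_r2` rather than a
  corrected estimate.
* Whole-genome headline values depend on assembly version, annotation
  files, the N-filter threshold and the exact scale range, so external
  reproductions should be expected to agree approximately, not to the
  printed decimal.
* `markov_sequence` provides first-order Markov backgrounds, but no
  closed-form spectrum is provided for them; they are for qualitative
  contrasts only.
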