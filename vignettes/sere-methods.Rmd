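---
title: "Methods: the Simple Error Ratio Estimate and its simulation benchmarks"
author: "sere package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Simple Error Ratio Estimate and its simulation benchmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sere)
```

## The model

A bin-by-lane count table holds the number of reads $y_{ij}$ falling into
bin $i$ (an exon, gene, or any opaque counting unit) in lane $j$ (one
sequencing dataset). If the $M$ lanes are technical replicates of one
library, each count is well described as Poisson with a mean proportional
to the bin's abundance and the lane's depth. Estimating that mean from the
table margins gives
$$\hat y_{ij} = \frac{E_i\,L_j}{T},$$
with bin totals $E_i$, lane totals $L_j$ and grand total $T$. The per-bin
dispersion compares the observed squared deviation to the Poisson variance,
$$s_i^2 = \frac{1}{M-1}\sum_j \frac{(y_{ij}-\hat y_{ij})^2}{\hat y_{ij}},$$
the classical Pearson overdispersion measure for Poisson models; the
divisor is $M-1$ because the deviations sum to zero within each bin. The
aggregate statistic is the square root of the mean over the $N$ retained
bins,
$$\mathrm{SERE} = s = \sqrt{\tfrac1N\sum_i s_i^2}.$$

The scale is absolute: 1 for faithful replication, 0 for a dataset compared
with an exact copy of itself, above 1 in proportion to genuine global
differences. Because the expected Poisson variation is modelled per bin and
per lane, the statistic is insensitive to sequencing depth and to unequal
lane sizes — the properties the simulation benchmarks below verify. SERE is
a *global* diagnostic; for per-gene inference, methods that model
biological variance explicitly (DESeq2, edgeR) are the right tool.

### Filtering conventions

* **Uninformative bins.** A bin with zero counts in every compared lane
  carries no information and is dropped before any statistic (SERE,
  Pearson, Kappa alike). For more than two lanes the rule generalizes to
  "zero in all compared lanes".
* **Singletons.** A bin with exactly one read across the compared lanes has
  $s_i^2 = 1$ identically (for equal lane totals), whether or not the
  samples agree, so singletons pull the average towards 1. With
  `exclude_singletons = TRUE` (the default) the package removes singleton
  bins entirely before computing the margins $E_i, L_j, T$: the average,
  its divisor, *and* the expected counts then all refer to the same
  non-singleton bin set. This convention makes singleton exclusion an exact
  identity — appending singleton bins to a table leaves the statistic
  bit-identical — at a cost of order (singletons)/$T \sim 10^{-6}$ on
  realistic tables relative to only modifying the average. For multi-lane
  statistics the singleton definition uses the full lane set; pairwise
  values re-apply both filters within each pair.
* **Empty lanes** ($L_j = 0$) are rejected, not dropped: an empty lane is
  exactly the kind of upstream failure a QC statistic must not paper over.
* Counts must be raw non-negative integers. RPKM or otherwise normalized
  input is rejected by the container, because the Poisson variance model
  applies to raw counts only.

### Confidence intervals

Under the null, $\nu s^2$ with $\nu = N(M-1)$ follows a chi-square
distribution with $\nu$ degrees of freedom; under global differences it is
noncentral with parameter $\lambda = \sum L_j^2 (p_{ij}-\bar p_i)^2$
accumulated over bins, where $p_{ij}$ is the true fraction of bin $i$ in
lane $j$. (Strictly, estimating the lane proportions costs $M-1$ degrees of
freedom, making the exact asymptotic reference $(N-1)(M-1)$; at the
$N \sim 10^5$ scale of count tables the difference is far below the
interval width, and the package reports the conventional $N(M-1)$.)

Two interval constructions are provided:

* **`noncentral`** (default): test inversion on $\lambda \ge 0$ — find the
  $\lambda$ values placing the observed $\nu s^2$ at the outer quantiles of
  $\chi^2(\nu, \lambda)$ and map them to the SERE scale through
  $E[\chi^2(\nu,\lambda)] = \nu + \lambda$, i.e.
  $s_{\text{bound}} = \sqrt{(\nu+\lambda)/\nu}$. Since $\lambda$ is floored
  at 0 this interval never falls below 1: it quantifies the overdispersion
  component and is uninformative for underdispersed data (there it reports
  $[1, 1]$ while the point estimate is below 1 — by construction, not by
  error).
* **`null`**: the scaled chi-square interval treating $s^2$ as a dispersion
  factor $\phi$ with $\nu s^2/\phi \sim \chi^2_\nu$. It always brackets the
  point estimate and shrinks as $O(\nu^{-1/2})$; it is the mode to use when
  a two-sided statement about underdispersion is needed.

Numerically, the noncentral inversion uses `stats::pchisq` with a bracketed
`uniroot`; beyond $\lambda \approx 10^4$, where R's noncentral CDF loses
precision, it switches to the normal limit of $\chi^2(\nu,\lambda)$ (mean
$\nu+\lambda$, variance $2(\nu+2\lambda)$), whose error there is orders of
magnitude below the interval width.

## Comparator statistics

The two statistics most often used for the same task are implemented for
benchmarking:

* **Pearson's $r$** on log RPKM with a pseudo-count of one read (the
  pseudo-count keeps zero counts on the log scale). Alternative transforms
  — log counts and $\sqrt{\text{counts}}$, the Poisson
  variance-stabilizer — are available; $r$ is invariant to the log base.
* **Cohen's Kappa** on RPKM values cut into the customary 9 ordered
  categories (0, 1–10, 11–20, 21–40, 41–80, 80–160, 161–320, 321–1000,
  >1000). The printed category bounds touch at 80, so the package resolves
  the partition as half-open intervals
  $\{0\}, (0,10], (10,20], (20,40], (40,80], (80,160], (160,320],
  (320,1000], (1000,\infty)$ — exhaustive, disjoint, and preserving the
  customary labels. Kappa is computed **without** a pseudo-count (otherwise
  the zero category would be unreachable); Pearson keeps it. A linearly
  weighted Kappa ($w_{ab} = |a-b|/(K-1)$) is also provided.
* **Unit-length mode.** Simulated tables carry no bin lengths; the
  comparators then use unit length, making the "RPKM" scale
  reads-per-million × 10³, to which the same category edges are applied.
  At toy depths this scale can push every informative bin into the top
  category, in which case Kappa is reported as undefined — an inherent
  degeneracy of binned agreement, not a defect of the data.

Kappa's dependence on the binning is itself a reproducible phenomenon: on a
fixed replicate pair, coarsening the scheme can only raise observed
agreement and refining can only lower it (a property the test suite checks
exhaustively).

## The simulation framework

All benchmark experiments draw simulated lanes from a **finite read pool**.
Drawing $k$ reads without replacement from a pool whose per-bin totals are
known is exactly a multivariate hypergeometric draw on those totals, so the
simulation operates on counts alone; no read files are involved. The
sampler uses a binary-splitting recursion — the draw allocated to a group
of bins splits between its two halves as a univariate hypergeometric — with
every tree level evaluated as one vectorized `rhyper` call, giving exact
draws in $O(n_{\text{bins}})$ time regardless of depth.

* **Perfect replicates** are *sequential disjoint* draws from the shrinking
  pool, the analogue of randomly splitting a real lane's reads. Disjoint
  splitting matters: conditional on the pair's bin totals, the allocation
  between the two lanes is then a simple random split, which keeps SERE
  calibrated at 1. Independent (non-disjoint) draws from the same finite
  pool are available as a mode, but they are hypergeometrically
  *underdispersed* by a factor $\sqrt{1 - k/N_{\text{pool}}}$ (about 0.88
  for 5M-read lanes from a 22.9M-read pool) — a real finite-population
  effect worth knowing about when designing subsampling checks.
* **Contamination** builds the second lane from
  `round(fraction * n_reads)` contaminant-pool reads plus main-pool reads
  drawn disjointly from the first lane, preserving the total exactly.
  "Identical pools" in the calibration sense means pools with the same
  abundance profile but distinct reads (two multinomial realizations, via
  the `abundance` argument of `make_synthetic_pool()`); passing the same
  physical pool object as its own contaminant instead reproduces the
  finite-pool underdispersion above.
* **Seeding.** One master seed; realization $i$ uses the derived seed
  $(\text{master} \cdot 48271 + 16807\,i) \bmod 2147483587 + 1$, so
  reports are bit-reproducible and conditions can be regenerated
  independently.

### The synthetic pool

The default pool emulates a deeply right-skewed exon-level profile:
222,097 bins, 22.9 million reads, log-normal abundances with
$\sigma = 2.4$ on 40% of the bins, the rest unexpressed. The two calibration
diagnostics, fixed before any benchmarking and checked by the test suite,
are taken at a 5.5-million-read subsample: roughly 55% of observed bins at
a count of 10 or less, and a maximum bin count of order $10^5$. A pure
log-normal cannot satisfy both at once (both diagnostics rise with
$\sigma$); the unexpressed fraction — a standard feature of real exon
tables, where most annotated exons of a tissue are silent — decouples them.
What the generator does *not* emulate: positional/GC bias, length-coupled
abundance, and correlated exon structure within genes. Passing benchmarks
on this pool therefore demonstrates calibration and sensitivity of the
statistics under Poisson sampling from a realistic abundance *shape*, not
agreement with any particular real dataset's absolute comparator values,
which depend on the real profile.

## Benchmark sizes and what the tests assert

The packaged acceptance tests run, per condition, 200 realizations for the
5M-read calibration experiment (matching the standard design of such
benchmarks), 100 for the depth (0.5–10M reads) and split (1:9 … 9:1)
sweeps, 100 for the contamination sweep (fractions 0–1), and 60 for the
identical-profile control — sizes at which the Monte-Carlo error of a mean
SERE is below $10^{-3}$, comfortably inside the asserted $[0.99, 1.01]$
calibration band. The chi-square form of $\nu s^2$ is checked by
Kolmogorov–Smirnov against $\chi^2_{200}$ on 1,000 Poisson tables of 200
bins — large enough that the one-degree-of-freedom margin-estimation
correction noted above is invisible to the test, small enough to run in
seconds.

## Known limitations

* SERE aggregates dispersion globally; a strong difference confined to a
  handful of bins can hide in a near-1 score. The pairwise matrix and the
  per-bin dispersions (`per_bin_dispersion`) are the drill-down tools.
* The noncentral interval cannot express underdispersion (see above).
* The advisory labels printed by the CLI (underdispersion below 0.9,
  overdispersion above 1.1) are heuristics for triage, not tests.
* Unit-length "RPKM" changes the comparators' absolute values relative to
  true lengths; within the simulation framework only their qualitative
  behaviour (depth dependence, bin sensitivity) is meaningful.
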