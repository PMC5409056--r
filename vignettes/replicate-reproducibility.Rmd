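---
title: "Methods: technical-replicate reproducibility of amplicon OTU tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: technical-replicate reproducibility of amplicon OTU tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repamp)
```

## The problem

When the same DNA extract is amplified and sequenced several times under
distinct barcodes (technical replicates), the resulting OTU tables are not
identical. Two mechanisms drive the disagreement: *random sequence
sampling* — each library is a finite draw from the underlying community,
so rare taxa blink in and out — and *sequencing artifacts* — PCR and
base-calling errors that materialize as spurious low-abundance OTUs unique
to one replicate. repamp quantifies how much of the disagreement each
mechanism explains, how disagreement responds to sequencing depth and to
filtering, and whether it spills over into the diversity estimates an
ecological study actually interprets.

The package operates downstream of read processing: its currency is an OTU
count table (OTUs × libraries, non-negative integers) plus a replicate
design mapping each library into a nested hierarchy of location →
treatment → field (biological) replicate → technical replicate. Read
trimming, merging, chimera removal and OTU clustering are the business of
upstream tools; repamp only documents which table it was handed.

## The overlap statistics

For two replicate libraries $A$ and $B$ with $S_A$ and $S_B$ observed
OTUs, of which $S_{AB}$ occur in both:

$$\mathrm{overlap}(A,B) \;=\; \frac{2\,S_{AB}}{S_A + S_B},$$

which is exactly Sørensen similarity on presence/absence — the package
asserts `pairwise_overlap(a, b) == 1 - sorensen_dissimilarity(a, b)` as a
cross-module identity. Among three replicates the shared set is the OTUs
present in *all three* and the denominator is the summed richness, scaled
by 3. The abundance-weighted counterparts replace OTU counts with
sequence counts: the fraction of all sequences that sit in shared OTUs.
Unweighted overlap is harsh on rare taxa (an OTU seen once counts as much
as one seen 10,000 times); weighted overlap is dominated by abundant taxa
and is therefore much closer to 1 on the same data. Reporting both brackets
the reproducibility claim.

"Shared" and richness are always evaluated on the table as the pipeline
stage sees it — after whatever filtering and rarefaction precede the call
— never on raw pre-rarefaction counts.

Experiment-level summaries are reported under two reductions, because the
averaging structure is genuinely ambiguous when pairs nest in samples:
`per_sample_mean` (average the three pairs within each sample, then
mean ± sd across samples) and `pooled` (mean ± sd across all pairs). The
means coincide for balanced designs; the sds do not. `per_sample_mean` is
the primary reduction; both are emitted and labelled.

## Filtering rules

Two operational definitions are implemented, and nothing more:

* **Singleton**: an OTU with exactly one sequence in the whole table
  (which necessarily confines it to one library). Removed by
  `remove_singletons()` *before* rarefaction in the standard order.
  Because a singleton can never be shared, removing it can only shrink
  overlap denominators — unweighted overlap never decreases, a property
  the test suite checks on hundreds of random tables.
* **Unique OTU**: an OTU with nonzero counts in exactly one library,
  whatever its total. `remove_unique_otus(min_count = k)` removes unique
  OTUs with total ≤ k (`k = Inf` removes them all), *after* rarefaction,
  where resampling can strand newly unique OTUs.

The phrase "present in only one technical replicate across all samples"
admits a narrower reading in which the singleton test is scoped to each
sample's replicate group. Rather than silently picking one,
`remove_singletons()` exposes `scope = "table"` (default, the strict
whole-table reading) and `scope = "sample"` (zero the OTU within samples
where it has exactly one sequence); the pipeline log records which scope
ran. The filter order is likewise configurable (`filter_order` in
`analysis_config()`) and logged, because order changes results.

## Rarefaction and its oracle

`rarefy()` subsamples each library independently, **without
replacement**, to a common depth — a multivariate hypergeometric draw,
delegated to `vegan::rrarefy()`. The default depth is the shallowest
library's total (`min_depth()`), the conventional rarefaction level.
Libraries below the target fail loudly by default; silent dropping must be
asked for explicitly (`shallow = "drop"`), so a design cannot unbalance
itself unnoticed.

The analytic expectation

$$E[S_{\mathrm{obs}}(n)] \;=\; \sum_i \left[1 -
  \binom{N - N_i}{n} \Big/ \binom{N}{n}\right]$$

is implemented in `expected_richness()` with log-combinatorics
(`lchoose`), so depths in the 10^5 range do not overflow. It serves as an
independent oracle: the tests require the Monte-Carlo mean richness after
`rarefy()` to match it within three standard errors, and require exact
depth conservation and per-cell dominance on every draw.

## Depth profiling and the saturation convention

`depth_profile()` rarefies each library to every depth on a grid (default
100 → 160,000 reads, spanning typical shallow-to-deep amplicon runs),
recomputes the overlap statistics, and averages over `n_resamples`
independent draws (default 1, matching the single-draw practice common in
the field; the sd across resamples is reported when > 1).

A *saturation depth* is estimated per statistic as the smallest grid depth
beyond which every subsequent gain stays below 0.005 overlap per 10,000
additional reads. Both numbers are reporting conventions of this package —
a plateau-detection rule, not an inherited definition — and are
configurable (`saturation_threshold`, `saturation_window`) and stamped on
the result object.

Under artifact injection the unweighted curve rises, flattens below 1, and
can even dip slightly past its plateau: true richness saturates while
artifact OTUs keep accruing linearly with depth, inflating denominators.
That is precisely the mechanism that caps reproducibility regardless of
effort, and the reason the acceptance checks treat "non-decreasing" as
"non-decreasing up to the plateau-flatness allowance" rather than strict
monotonicity.

## Diversity summaries

Per library, `alpha_diversity()` reports observed richness, Shannon $H'$
(natural log, delegated to `vegan::diversity()`; nats make Pielou
$J = H'/\ln S$ base-free), $J$ (undefined and `NA` when $S_{obs} < 2$),
Chao1 and coverage. Chao1 defaults to the bias-corrected form
$S_{obs} + F_1(F_1-1)/(2(F_2+1))$, which cannot divide by zero when no
doubletons exist; the classic $S_{obs} + F_1^2/(2F_2)$ form is available
by flag and falls back to the corrected form at $F_2 = 0$. Coverage is
defined as $S_{obs}/\mathrm{Chao1}$ — the standard reading of "coverage
based on Chao1 estimation"; this is a definition adopted by this package
and documented as such.

Between libraries, the complements of Sørensen and Bray-Curtis similarity
are computed via `vegan::vegdist()`. `beta_level_summary()` partitions all
$\binom{L}{2}$ library pairs exhaustively and disjointly into: technical
(same sample), biological (same location and treatment), between
treatments within a location, same treatment across locations (one level
per treatment label), and "other" (different location *and* different
treatment). For the full 3 × 2 × 3 × 3 design this yields
54/162/243/243/243 pairs plus 486 "other". Level means are over pooled
pairs — consistent with reporting those pair counts as the data sizes —
with the per-sample-first reduction available for the overlap statistics.
Note the package does *not* assert Bray-Curtis < Sørensen as an
invariant; on real soil data the weighted metric tends to be smaller, but
that is an empirical observation, and only the reporting of both is built
in.

## The null-model dispersion test

The inferential core: are technical replicates more dispersed than random
sequence sampling of a single community can explain?

1. Estimate the sample's underlying community as the mean of its
   replicates' relative-abundance vectors, renormalized
   (`average_profile()`).
2. Compute the observed group dispersion $d_{obs}$: the mean distance of
   the replicates to their group centroid in a principal-coordinate
   embedding of the chosen dissimilarity matrix, with the standard
   negative-eigenvalue correction (the PERMDISP dispersion).
3. For each of `n_iter` iterations (default 1000), draw 3 null replicates
   multinomially from the averaged profile at the observed depths and
   record their dispersion $d_{null}$.
4. Report $p = (1 + \#\{d_{null} \ge d_{obs}\})/(1 + n_{iter})$,
   $\Delta d\% = 100\,(d_{obs} - \overline{d_{null}})/\overline{d_{null}}$,
   and a descriptive classic one-way ANOVA $F$ comparing
   distances-to-own-centroid of the observed group against one
   representative null group.

Design choices worth stating plainly:

* The permutation mechanics of published PERMDISP variants differ; the
  implemented test is the minimal Monte-Carlo comparison of observed
  against simulated null dispersions with the add-one correction (so $p$
  can never be exactly 0). Its operating characteristics are verified by
  simulation rather than assumed: under a pure-multinomial generator the
  rejection rate at $\alpha = 0.05$ stays within [0.01, 0.10] and the p
  distribution passes a Kolmogorov–Smirnov uniformity check; under strong
  Dirichlet-multinomial overdispersion ($\theta = 50$) power exceeds 0.8.
  $p$ is the primary output; $F$ is descriptive only.
* Null replicates match the observed replicates' depths one-for-one, so
  sampling effort is held constant; when post-rarefaction filtering has
  left depths slightly unequal, each null replicate matches its
  counterpart.
* The centroid distances need no eigendecomposition: for the
  Gower-centered matrix $G$ of the dissimilarities, the corrected squared
  distance of point $j$ to the centroid equals $G_{jj}$ (the positive- and
  negative-eigenvalue contributions sum to the diagonal), clamped at 0.
  This identity is exact, matches `vegan::betadisper(type = "centroid")`
  to machine precision in the tests, and makes the 200-iteration test
  loops cheap.

## What the simulator emulates — and what it does not

`simulate_experiment()` reconstructs the nested design: 3 locations × 2
treatments (planted/unplanted) × 3 field replicates × 3 technical
replicates = 54 libraries. Locations receive *independent* log-normal
abundance draws over a shared OTU pool (field sites hundreds to thousands
of kilometres apart with distinct soils are better modelled as distinct
communities than as perturbations of one); treatment and field-replicate
effects are independent log-normal perturbations nested under location,
with $\sigma_{treatment} > \sigma_{biological}$ by default (0.6 and 0.3)
so that the dissimilarity hierarchy technical < biological < treatment is
realizable. A location-level perturbation parameter would be redundant
with the independent draws and is deliberately absent.

Technical replicates are multinomial draws of `depth` reads from their
sample's profile; finite `theta` switches to Dirichlet-multinomial
overdispersion representing PCR/sequencing bias. Artifacts are injected as
$K \sim \mathrm{Poisson}(\varepsilon N)$ replicate-unique OTUs of count 1
(count ≥ 2 via `artifact_size`, to exercise the unique-OTU filter), each
*replacing* a true read so column sums stay exactly `depth` and
rarefaction bookkeeping stays exact. Artifact load therefore grows
linearly in depth — the mechanism behind the sub-complete overlap plateau.

Defaults (`simulation_recipe()`): richness 3,000 and log-abundance sd 2
(a typical steep microbial abundance distribution; observed richness and
Chao1 coverage then land in the range reported for soil libraries at
10^4 reads), 10,000 reads per library (the order of a multiplexed run's
per-library yield), $\varepsilon = 10^{-3}$ (a modest ~10 spurious OTUs
per 10,000 reads; the real error process is not quantitatively
characterized, so $\varepsilon$ and $\theta$ are free parameters, not
estimates), pure multinomial sampling ($\theta = \infty$).

The simulator does **not** emulate: read-level error (no FASTQ, qualities
or chimera sequences), clustering-induced OTU inflation or lumping,
between-run batch effects, primer or abundance bias, or taxonomic
structure. Passing tests therefore demonstrate that the *statistics* behave
correctly under the stated sampling model — multinomial noise plus
depth-proportional artifacts — not that real MiSeq data obey that model.

## Numerical choices and degenerate inputs

* Percentages live as fractions in [0, 1] internally and become percent
  only in rendered reports.
* Overlap of two empty libraries is undefined (error); one empty library
  gives 0 with a warning. Weighted statistics require nonzero depth.
* All randomized functions accept `seed` and are deterministic given it
  (`withr::with_seed`, caller RNG untouched); `run_analysis()` threads one
  seed through every stage and logs it, so identical config + seed means
  identical outputs.
* Ties in the Monte-Carlo p are handled by the add-one rule; the p grid is
  discrete with resolution $1/(n_{iter}+1)$.
* `expected_richness` treats OTUs with $N - N_i < n$ as certainly
  observed ($\log$-term $-\infty$).
* Saturation detection requires *all* subsequent slopes below threshold,
  not just the first crossing, so a noisy shoulder cannot fire it early.

## Problem sizes used by the test suite

The suite verifies operating characteristics at deliberately modest sizes:
null-model calibration at 200 simulated samples (richness 100, depth
2,000, 200 iterations) and power at 100 samples (richness 200, depth
5,000, $\theta = 50$); the depth criterion on one triplicate of 165,000
reads at richness 2,000 with $\varepsilon = 10^{-3}$ (165,000 rather than
160,000 so the default grid survives singleton removal); the β-hierarchy
over 20 independent 54-library experiments at depth 1,000. These sizes
were chosen to estimate each property with adequate Monte-Carlo precision;
the statistics themselves are size-agnostic.

## Known limitations

* The dispersion test conditions on a *fitted* null profile (the
  replicates' own average), which can make it slightly conservative; the
  calibration band [0.01, 0.10] accommodates this.
* The Monte-Carlo p is invariant to OTU relabeling in distribution, not
  realization: permuting table rows changes the RNG draw sequence, so two
  runs at the same seed differ within p's sampling error (the observed
  dispersion is exactly invariant).
* Exact numerical agreement with published PERMDISP F/P columns from
  unspecified software variants is not a target; direction and magnitude
  of $\Delta d\%$ are.
* `beta_level_summary()` assumes the five-level nested vocabulary; designs
  outside it land pairs in "other" rather than failing.

## A minimal session

```{r example, eval = FALSE}
library(repamp)

sim <- simulate_experiment(simulation_recipe(seed = 1))
filtered <- remove_singletons(sim$table)
rarefied <- rarefy(filtered, min_depth(filtered), seed = 2)

ov <- overlap_summary(rarefied, sim$design)
glance(ov) # experiment-level mean +/- sd, both weightings

beta_level_summary(dissimilarity_matrix(rarefied, "bray_curtis"), sim$design)

permdisp_summary(rarefied, sim$design, n_iter = 1000, seed = 3)
```
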