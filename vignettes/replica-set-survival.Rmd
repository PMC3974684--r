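---
title: "Replica-set survival analysis and promoter-target overlap: models and methods"
author: "replilife"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replica-set survival analysis and promoter-target overlap: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replilife)
```

## The replica-set design and its model

A traditional *C. elegans* lifespan assay tracks one cohort of animals
longitudinally, scoring each animal's death day. The replica-set design
instead cultures many parallel wells (24-well plates, roughly 25
animals per well), scores each well **once** — alive and dead counts at
its assigned timepoint — and discards it. The data are independent
cross-sectional binomial observations rather than a followed cohort,
which scales to RNAi screens but requires a parametric survival model
to summarise.

`replilife` models the probability that an animal is alive at time $t$
with the two-parameter logit survival curve

$$p(t) = \frac{1}{1 + e^{a t - b}},$$

with slope $a > 0$ (per day or per hour) controlling how sharply
survival declines and intercept $b$ (dimensionless) setting its
location. Alive counts per well are binomial, so this is a binomial
generalized linear model in time, and `fit_logit()` maximises its
likelihood by iteratively reweighted least squares (Newton scoring,
implemented in compiled code because the resampling procedures refit
the curve hundreds of thousands of times). Derived summaries:

* **LD50** (median survival time): $p(t) = 1/2$ at $t = b/a$.
* **Maximum lifespan**: read off the *fitted curve*, not the raw data,
  as the time where predicted survival drops to 5%:
  $t = (b + \ln 19)/a$ (`max_life()`, with the threshold a tunable
  parameter defaulting to 0.05).

Assumptions worth stating: wells are independent; all wells in one
dataset share a single underlying curve (trials can be fit separately
with `per_trial = TRUE`; the default pools, since whether pooling or
per-trial fitting was used in the original protocol is not
determinable — pooled fitting is the natural default for one condition
measured in interchangeable trials); time units are metadata (days for
lifespan, hours for acute stress survival) and are never mixed within
one dataset.

### Numerical choices

*Initialisation.* The iteration starts from the timepoint where pooled
observed survival first crosses one half (linear interpolation), with
the slope seeded from the empirical logits of the two bracketing pooled
timepoints. When the pooled curve never crosses 0.5 — common in
bootstrap replicates of sparse data — the start falls back to a
least-squares line through the empirical logits
$\log\{(n\hat p + 0.5)/(n(1-\hat p) + 0.5)\}$. Newton steps are
subjected to step-halving so only likelihood-increasing steps are
taken; convergence is a maximum absolute change in $(a, b)$ below
$10^{-8}$ within 100 iterations. Non-convergence sets a flag rather
than raising, because a resampling run must never abort on one awkward
replicate.

*Separation.* For a one-dimensional binomial logit, the MLE sits at
infinite slope exactly when the pooled survival fractions form a step
pattern in time: a block of fully-alive timepoints, at most one
fractional timepoint, then a block of fully-dead timepoints (or the
reverse ordering, which would mean survival rising with time). Two or
more fractional timepoints pin the optimum at finite parameters.
`fit_logit()` detects the step pattern exactly (integer count
comparisons, no tolerance) and raises a typed `SeparationError` at top
level. Inside resampling the same event is *flagged, not fatal*: the
replicate contributes the midpoint of its separating interval as a
stand-in LD50 (the fractional threshold time itself under
quasi-separation; the smallest/largest observed time when there are no
survivors/no deaths anywhere, where a true separating interval does not
exist). This keeps all $K$ replicates countable, which matters because
at $K = 10{,}000$ occasional separated resamples are expected.

*Orientation.* The curve is taken with $a > 0$ meaning declining
survival, which makes LD50 $= b/a$ positive; data implying $a \le 0$
fit fine but are flagged with a warning, since a rising survival curve
indicates a labelling or staging problem.

## Resampling inference on the LD50

All resampling treats the **well** as the exchangeable unit — wells are
the independent unit of the replica-set design; animals within a well
share a plate environment and a scoring event.

* `bootstrap_ld50()` resamples wells with replacement, refits, and
  reports percentile bounds (2.5/97.5% at the default level). The
  percentile method was chosen over BCa for transparency; with 24 wells
  its coverage, measured by simulation below, is slightly anticonservative
  but inside the 90–99% band.
* `permutation_ld50_test()` pools wells, reassigns condition labels
  preserving group sizes (optionally within trial), refits both groups
  and compares $|\Delta \text{LD50}|$ resampled versus observed. The
  p-value uses the add-one estimator $(c + 1)/(K + 1)$, so it is never
  zero and is valid at finite $K$.
* `ratio_ld50_test()` addresses a subtler question: is the
  *proportional* effect of a perturbation larger in one genetic
  background than another? The statistic is
  $(\text{LD50}^{A}_{\text{treat}}/\text{LD50}^{A}_{\text{ctrl}}) -
   (\text{LD50}^{B}_{\text{treat}}/\text{LD50}^{B}_{\text{ctrl}})$,
  with each of the four conditions bootstrapped independently. The
  two-sided p-value is the shifted-bootstrap form
  $(\#\{|d^* - d_{\text{obs}}| \ge |d_{\text{obs}}|\} + 1)/(K + 1)$:
  the resampled spread around the observed difference stands in for the
  null spread around zero. This form was chosen over the
  count-sign inversion because it is exact ($p = 1$) when the four
  inputs are identical and it agrees with deciding by whether the
  percentile interval of the difference covers zero.

Seeding: every top-level call takes one `seed`; per-replicate sub-seeds
are drawn up-front from that stream, so results are bit-reproducible
and each replicate is independently reconstructible (a layout that also
stays valid under future parallelisation).

```{r resample-demo}
wells <- simulate_replica_set(true_a = 0.4, true_b = 7.2,
                              n_wells = 24, seed = 11)
fit <- fit_logit(wells)
glance(fit)
bootstrap_ld50(wells, K = 500, seed = 1)
```

## Traditional assays: Kaplan–Meier and log-rank

For longitudinally tracked cohorts the package wraps the standard
product-limit estimator and the unweighted Mantel–Cox log-rank test (1
df, no continuity correction) from the `survival` package behind a
tibble-in/tibble-out surface (`kaplan_meier()`, `logrank_test()`). The
reported median is the first time the estimated survivor function drops
to one half or below. Effect sizes throughout are reported with
`percent_change()`: $100(c - r)/r$ rounded **half away from zero** at
the printed precision — base R's round-half-to-even would print a
21.95% reduction as $-22$ rather than $-22.0$ and disagree with
conventional reporting on exact halves.

## The promoter-target overlap pipeline

The regulatory module reproduces a ChIP-seq target-assignment analysis
working entirely from called peaks (peak calling itself is out of
scope):

1. **Midpoints** of 0-based half-open peaks are
   $\lfloor (start + end - 1)/2 \rfloor$, the middle base, left of
   centre for even lengths.
2. **TSS offsets** (`tss_offsets()`, `tss_offset_profile()`) are
   signed, strand-aware distances from each midpoint to the nearest
   transcription start site: upstream is negative on both strands.
3. **Target assignment** (`assign_targets()`): a gene is a target of a
   factor when some peak midpoint falls within $[-700, +100]$ bp of its
   TSS — the promoter-proximal band where binding is most enriched.
   Both window ends are inclusive (only the bounds, not their
   inclusivity, are conventionally stated; an inclusive closed interval
   is the least surprising reading). The default assigns *every* gene
   whose window contains the midpoint; a `nearest` mode restricts each
   peak to its closest TSS first, since which convention the original
   analysis used is not determinable from the description.
4. **E-boxes** (`scan_ebox()`, `ebox_fraction()`): the Myc-family
   enhancer-box consensus CANNTG, the standard consensus for
   Mad/Max-class bHLHZip binding. The pattern class is closed under
   reverse complement, so a single-strand scan suffices (verified as a
   property test). An `N` in the input satisfies only the wildcard
   positions.
5. **Three-way overlap** (`venn3()`) partitions a gene universe into
   the seven exclusive regions of three target sets plus the outside;
   conservation (regions summing to the universe) is asserted by tests.
6. **GO enrichment** (`chisq_enrichment()`): per term, a Pearson
   chi-squared (1 df, no continuity correction) on the 2×2 of target
   membership against term membership, with fold enrichment
   $(k_{in}/n_{in})/((k_{in}+k_{out})/(n_{in}+n_{out}))$. Degenerate
   margins yield a flagged row with $p = 1$ rather than an error. Raw
   p-values are the primary report, matching common practice for this
   analysis; a Benjamini–Hochberg column is available but off by
   default.
7. **Shared regulatory regions** (`peak_overlap_fraction()`): the
   fraction of a peak's bases covered by the union of another factor's
   peaks, used for rules like "75% or more overlapped".

Interval arithmetic goes through `GenomicRanges`/`IRanges`; sequence
handling through `Biostrings`.

## What the synthetic generators emulate

`simulate_replica_set()` draws deaths binomially under the logit curve,
one well per row, timepoints assigned round-robin over the scoring
schedule so coverage is even (the real protocol's allocation of plates
to days is not specified beyond every-other-day scoring). Defaults are
the study conditions used throughout the tests: 24 wells of 25 animals,
scored every 2 days, true LD50 18 days ($a = 0.4$, $b = 7.2$) — an
adult lifespan scale typical of wild-type worms at 20 °C. The
long-lived background in the ratio-test checks uses LD50 46 days with a
shallower slope ($a = 0.25$) and a 4-day scoring cadence out to 92
days, mirroring how much longer such experiments must run.

`simulate_traditional_lifespan()` inverts the logistic survival CDF
(death day $= (b + \mathrm{logit}(u))/a$, truncated at zero) with
independent uniform censoring times for a configurable censored
fraction.

`simulate_genome()` builds a coherent genes/peaks/sequences/annotations
quartet with planted ground truth: planted peaks get midpoints at
strand-aware offsets uniform in $[-700, 100]$; gene TSSs sit on a
spacing grid so promoter windows never overlap and planted targets are
exactly recoverable; peak sequences are i.i.d. uniform ACGT. Because a
uniform 200-bp sequence contains many chance CANNTG hexamers, the
default `ebox_background = "scrub"` removes background occurrences
before planting the motif in exactly the requested fraction of
sequences — that makes planted fractions exactly recoverable (0% gives
0.0%, 60% gives 60.0%); `"natural"` keeps the background for
realism-oriented use, where tests can only bound the recovered
fraction from below. Default genome scale (500 genes, 300 peaks, 40%
planted) keeps the planted target set near a quarter of the gene
universe, the order of magnitude of real genome-wide promoter-target
sets, and the default GO vocabulary (20 terms at a 10% base rate, one
term enriched 3-fold among targets) gives the enrichment test a
realistic signal-to-background ratio.

What these generators deliberately do **not** emulate: plate-to-plate
and trial-to-trial heterogeneity (wells are exchangeable draws from one
curve), age-dependent censoring mechanisms such as matricide or
crawl-off, ChIP-seq signal/noise (peaks are placed, not called), real
GO term dependency structure, and operon gene organisation. Passing
tests therefore certify the estimators under the design's own
assumptions, not robustness to those violations.

## Problem sizes and calibration results

The test suite and the acceptance script measure, at study scale
(24 wells × 25 animals, 200 simulated experiments per measure):

* median absolute LD50 recovery error (asserted below 5% of the true
  18 d);
* bootstrap 95% CI coverage at $K = 500$ (asserted within 90–99%);
* permutation type-I error at $\alpha = 0.05$, $K = 200$ (asserted
  within 1–10%);
* power of the ratio test to separate treatment ratios 0.61 vs 0.78
  across backgrounds at $K = 1000$ over 100 runs (asserted above 50%).

$K$ values in these calibration loops are smaller than the
$K = 10{,}000$ default a single real analysis would use; the defaults
are kept at 10,000 precisely because a one-off analysis can afford
them.

## Known limitations

* The logit curve forces symmetric survival decline on the logit
  scale; strongly right-skewed mortality (e.g. Gompertz-like late-life
  acceleration) will bias the 5% maximum-life extrapolation more than
  the LD50.
* Percentile bootstrap intervals with few wells (≤ 12) undercover;
  widths shrink and coverage improves as wells accumulate.
* `ratio_ld50_test()` assumes the four conditions are mutually
  independent experiments.
* GO enrichment tests each term marginally; terms are not independent
  and no hierarchy-aware correction is attempted.
* No Cox proportional-hazards or frailty modelling, and no
  multiple-testing correction across many pairwise lifespan
  comparisons (raw p-values are reported by design).
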