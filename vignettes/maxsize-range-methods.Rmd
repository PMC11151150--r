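---
title: "Quantifying disagreement in reported maximum body sizes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying disagreement in reported maximum body sizes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Large comparative studies of marine animals lean on one number per species:
its maximum reported body size, usually the largest linear dimension (length,
height, width or diameter). But the literature rarely agrees with itself.
Different sources measure different dimensions with different tools, copy
values through chains of databases, and occasionally slip a unit or record a
colony where an individual module was meant. `sizerange` quantifies that
disagreement, models what drives it, and asks whether it matters for the
rank-order comparisons macroecology actually performs.

The unit of analysis is a species with at least two independent reports of
maximum size. Every report is converted to centimetres and kept verbatim —
no quality control is applied at ingest, because gross errors are part of
what is being measured. For a species with smallest and largest reported
maxima $s$ and $l$, the range statistic is

$$\mathrm{range} = \log_{10} l - \log_{10} s,$$

the disagreement in orders of magnitude. It is zero exactly when all reports
agree, which makes its distribution a mixture of a point mass at zero
(roughly 38% of species) and a heavily right-skewed positive part.

# The hurdle model

That mixture motivates a zero-inflated gamma hurdle regression with two
components sharing one predictor set:

* a **binomial component with logit link**, fit to all species, for whether
  the range is non-zero;
* a **gamma component with log link**, fit to the positive-range species
  only, for how large a non-zero range is.

The likelihood factorizes, so the components are estimated independently and
the total log-likelihood is their sum. Predictors follow the study design:
the continuous $\log_{10}$ smallest maximum size, the report-count category
(2, 3, 4–5, ≥6 — counts are categorical because high counts are rare and a
continuous count destabilizes the fit), one or two grouping factors (phylum,
habitat, skeleton, or an invertebrate indicator), and the interactions of
the continuous term with each factor.

Internally the binomial component always models $P(\mathrm{range} > 0)$.
Published treatments of this model are ambiguous about orientation — prose
and captions sometimes describe the probability of *zero* variation while
figures plot the probability of *non-zero* variation — so the coefficient
reporter emits both orientations explicitly labelled, and the orientation is
never silently resolved.

## Estimation

Both components are fit by our own Newton / iteratively-reweighted
least-squares maximum likelihood: convergence requires the maximum absolute
score below $10^{-8}$ or a relative log-likelihood change below $10^{-10}$,
with step-halving on any likelihood decrease, a cap of 200 iterations, and
an explicit `converged` flag instead of exceptions. Logistic coefficients
larger than 30 in magnitude flag complete separation. The gamma shape is
estimated by full maximum likelihood — Newton steps on $\log \alpha$ using
digamma/trigamma — not by moment or deviance estimators, and it counts as
one parameter shared across the model. At the maximum the observed
information is block-diagonal between the mean coefficients and the shape
(the cross-derivative is the mean-model score, which is zero), which the
reported covariance exploits.

Model competition uses the small-sample corrected information criterion
$\mathrm{AICc} = -2\ell + 2k + 2k(k+1)/(n-k-1)$ with $n$ the number of
species entering the zero component; with both components and the shape, the
phylum + habitat model has $k = 2 \times 26 + 1 = 53$ parameters. Candidates
are only compared on identical species sets.

## Post hoc comparisons

Estimated marginal means are model predictions on the link scale over a
reference grid: requested factor levels are crossed, every non-requested
factor is averaged with equal weight over its levels, and continuous
covariates are fixed (observed mean by default). Standard errors follow from
the delta rule on the component covariance. All pairwise contrasts are
Tukey-adjusted through the studentized-range distribution with infinite
degrees of freedom, $p = P(Q_{m,\infty} \ge |z|\sqrt{2})$; with two means
this reduces exactly to the unadjusted normal test. Wald significance flags
default to the Bonferroni-style threshold $\alpha = 0.009$; the divisor
behind such thresholds is convention-dependent, so the value is a
configurable datum, not a derivation.

# Distribution-level analyses

Choosing the smallest, mean, or largest reported maximum per species yields
three across-species size distributions. The package compares each pair with
a two-sample Kolmogorov–Smirnov test (the supremum taken over every pooled
jump point, so ties are exact; asymptotic p at effective sample size
$n_a n_b/(n_a+n_b)$), a variance-ratio F test on mean-centered samples
(two-sided), and Spearman rank correlation (average-tie ranks, t
approximation). Right-skew is tested with the D'Agostino skewness
normalization of $g_1 = m_3/m_2^{3/2}$. The largest-versus-smallest
regression is ordinary least squares with a t test of the slope against 1:
a slope below one means small species carry proportionally more
disagreement. The per-species mean is the mean of $\log_{10}$ sizes (the
geometric mean) by default, since every analysis operates on the log scale;
an arithmetic-mean switch exists.

Interspecific context comes from the taxonomic hierarchy: for orders,
families and genera the range is the $\log_{10}$ ratio between the largest
and smallest member species, with each species represented by its largest
reported maximum (the natural reading of "largest and smallest species"; a
mean-size switch exists), and taxa with fewer than two species excluded.

# Rank stability

Whether report disagreement matters for comparative work is answered by a
randomization: draw one reported maximum per species (uniformly over all
reports, duplicates included — duplicated values encode report frequency; a
distinct-values switch exists), rank all species ascending with average
ties, and repeat in independent pairs. Each of the 1000 pairs records the
Spearman correlation between its two rankings, the median and maximum
absolute rank displacement, and the species attaining the maximum. The two
rankings of a pair are drawn independently rather than leave-one-out. On the
default cohort the mean correlation is ≈ 0.98 with a median displacement of
a few dozen places out of 27,271 — but single species with gross report
errors can fall tens of thousands of places, and the largest-mover tally
identifies them.

# The synthetic cohort

Because the deposited measurement compilation cannot be bundled, the package
generates cohorts with the statistical structure the analysis assumes, with
known truth. The default preset fixes, once:

* 27,271 species in eight phyla with relative frequencies matching the
  study cohort's published per-phylum totals, habitats 77/20/3%
  benthic/pelagic/unspecified, skeleton deterministic by phylum;
* report-count classes (60%, 25%, 12.2%, 2.8%) giving median count 2 and
  2.8% of species above five reports;
* $\log_{10}$ smallest size $\sim N(0.60, 0.89)$, matching the published
  moments of the minimum-size distribution;
* a logit-linear non-zero-probability model and a log-linear gamma mean
  (shape 0.5) over the same design as the fitted models. The coefficients
  are this package's own choices, made once for qualitative fidelity —
  published coefficient tables for this model family are orientation-
  ambiguous (see above) and internally inconsistent with the accompanying
  prose for a few terms, so they were not copied. The intercepts were
  calibrated so the marginal zero fraction is ≈ 0.38 and the positive tail
  crosses half / one / two orders of magnitude at ≈ 5%, ≈ 1%, ≈ 0.2% of
  species;
* rare gross errors: with probability 0.0008 each per species, one report
  multiplied or divided by 10–1000 (unit slip), or divided by ≥ 100
  (colony-versus-module), recorded in a truth ledger.

Measurement-level simulation anchors each species' largest and smallest
reports at the drawn range and places interior reports as exponential
decrements from the true maximum on the log scale, truncated to the realized
range — reports never exceed the true maximum, keeping the largest report an
order statistic, and summaries recomputed from error-free measurements equal
the species-level truth exactly.

What the generator does **not** emulate: phylogenetic correlation beyond
phylum membership (the fitted models are non-phylogenetic), correlation
between habitat and phylum, source-level structure (all reports are
exchangeable within a species), and real taxonomies (genus/family/order
nesting is synthetic and regular). Passing recovery tests therefore
certifies the estimators and the pipeline, not the biology of any real
dataset.

# Numerical choices and degenerate inputs

* Sizes are stored in centimetres; all logs are base 10.
* Exactly equal reports give a range of exactly 0 (computed by equality
  test, not subtraction), so the zero hurdle is numerically clean.
* Magnitude bins are disjoint with half-open interiors — zero; (0, 0.5);
  [0.5, 1); [1, 2]; above 2 strictly — and cumulative exceedance counts are
  always reported alongside, so either a disjoint or a cumulative reading of
  "varied by half an order" can be audited.
* Duplicated identical reports count toward the report count; nothing is
  de-duplicated.
* The unit-slip audit heuristic asks whether the species' log-range is
  within 5% (relative) of a whole number of decades; the colony heuristic
  requires a range above two orders with at least three reports, all but one
  within half an order of the smallest. Both are advisory tags; no record is
  ever dropped, and width-versus-length mixtures are left `unknown` because
  they have no within-species numeric signature.
* A cohort with no zero-range species degrades to a plain gamma fit with the
  binomial component flagged degenerate; constant responses drive the gamma
  shape into a guard and flag non-convergence; candidate models whose
  factors collapse to one level after filtering are dropped from the
  competition with a logged message, and a configured reference level that
  the phylum filter removed falls back to the first observed level.
* Every simulation and randomization takes an explicit seed, uses one local
  RNG stream, and restores the caller's RNG state.

# Problem sizes used in the tests

The test suite exercises the estimators against brute-force likelihood
optimizers on 50 small instances (≤ 60 rows), parameter recovery and AICc
competition on cohorts of 5,000 species (20 and 100 replicates), and the
full pipeline on cohorts of a few hundred species; the acceptance script
runs the complete analysis once at the study scale of 27,271 species. These
sizes keep every coefficient comfortably identified (the rarest phylum still
contributes ≈ 40 species at n = 5,000) while the whole suite stays fast.

# Known limitations

* The gamma hurdle cannot represent under-dispersed positive ranges
  (shape estimates simply grow large); none of the study's cohorts are in
  that regime.
* Tukey adjustment uses infinite degrees of freedom, appropriate at these
  sample sizes but anticonservative below a few dozen species.
* The KS p-value is asymptotic; exact small-sample enumeration is not
  implemented because the analysis operates on thousands of species.
* Audit tags are heuristics tuned for the two error signatures the truth
  ledger injects; real forensics (as for the published list of 44 extreme
  species) remain a human task.
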