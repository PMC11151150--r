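# sizerange

How much do published reports of a species' *maximum body size* disagree —
and does it matter? For tens of thousands of marine animal species the
literature carries two or more estimates of maximum linear dimension, and
they differ: by rounding, by measurement convention (arm versus disc, shell
versus siphon), by unit slips, and by colony-versus-zooid confusion.
`sizerange` is an R package plus a scripted analysis that quantifies this
intraspecific disagreement, models its drivers, and measures its consequence
for comparative macroecology.

For a species with smallest and largest reported maxima *s* and *l* (in cm),
the central statistic is the disagreement in orders of magnitude,

```
range = log10(l) − log10(s)
```

which is exactly 0 when all reports agree (~38% of species) and heavily
right-skewed otherwise. The package provides:

- **trait table** — CSV ingest (no quality control, by design), unit
  normalization to cm, per-species summaries, report-count categories
  (2 / 3 / 4–5 / ≥6), the ≥100-species phylum filter, and order-of-magnitude
  binning (disjoint and cumulative);
- **hurdle regression** — a zero-inflated gamma hurdle fit by its own
  Newton/IRLS maximum likelihood: binomial-logit component for zero vs
  non-zero range, gamma-log component for positive magnitudes, ML shape,
  AICc competition across seven candidate predictor sets, estimated
  marginal means, and Tukey-adjusted pairwise contrasts;
- **distribution tests** — largest-vs-smallest OLS with a slope-vs-1 test,
  D'Agostino skewness, ECDFs, two-sample Kolmogorov–Smirnov, centered
  variance-ratio F, Spearman correlation, and intra- vs interspecific range
  across genus/family/order;
- **rank stability** — 1000 paired randomizations drawing one reported
  maximum per species and measuring how far the across-species size ranking
  moves;
- **audit** — flags species whose reports disagree by more than half, one,
  or two orders of magnitude, with advisory unit-slip and colony-vs-module
  cause tags;
- **synthetic cohort** — a generator with known ground truth that emulates
  the study's statistical structure (zero inflation, skewed positive
  ranges, phylum/habitat/count/size effects, rare injected gross errors),
  so the entire analysis runs and is tested without any download.

## Worked example

The numbered drivers under `analysis/` run the full study on the synthetic
cohort (seed fixed; every run is bitwise reproducible):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_range_statistics.R
Rscript analysis/03_hurdle_models.R
Rscript analysis/04_distributions.R
Rscript analysis/05_rank_stability.R
Rscript analysis/06_audit.R
```

Stage 2 prints the cohort's headline statistics:

```
27271 species retained; 37.5% with zero range
exceedances: >0.5: 1491 (5.47%)  >1: 334 (1.22%)  >2: 51 (0.19%)
largest ~ smallest: slope 0.960 (t vs 1 = -25.2); range skew 5.96 (z = 148.0)
```

i.e. most species' reports agree well, a twentieth disagree by more than
half an order of magnitude, the positive ranges are strongly right-skewed,
and the slope below 1 means smaller species carry proportionally more
disagreement. Stage 3 runs the AICc competition and post hocs:

```
                 model df    loglik     aicc converged delta_aicc
1       phylum+habitat 53   83.6044 -60.9986      TRUE      0.000
2     skeleton+habitat 33  -71.7074 209.4971      TRUE    270.496
...
conditional-component marginal mean range by habitat:
      habitat emmean      se response
1     benthic -1.402 0.02894   0.2461
2     pelagic -1.836 0.03652   0.1595
3 unspecified -1.163 0.06103   0.3124
```

the phylum + habitat model (53 parameters across both components plus the
gamma shape) wins decisively, and the marginal means show pelagic species
with the most consistent reports and poorly-annotated (unspecified-habitat)
species with the least. Stage 5 answers the "does it matter" question:

```
rank stability: 1000 pairs over 27271 species (seed 2)
  mean rank correlation 0.9831; median displacement 21.0; max 25770
```

the size rank order is almost unaffected by which report you pick — the
typical species moves ~21 places out of 27,271 — but individual species with
gross errors can fall tens of thousands of places, and stage 6's audit
recovers exactly those (recall 1.00 against the generator's injected-error
ledger, 21 of 51 extreme species tagged as unit-slip candidates).

Equivalent programmatic entry points: `run_pipeline(pipeline_config(...))`
for the end-to-end run, or the individual functions (`summarize_species()`,
`fit_hurdle()`, `compare_models()`, `estimated_marginal_means()`,
`rank_stability()`, `flag_extreme_species()`, ...) for any one stage.

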