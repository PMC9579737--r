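# flordyn

Trait-based analysis of sown flower-strip plant communities followed over
several years: seed-mixture design, functional-diversity metrics, null
models, and AIC-based multimodel inference of temporal dynamics, together
with a mechanistic succession simulator that makes the whole pipeline
testable end to end.

## The scientific problem

Flower strips sown along crop fields support pollinators and natural
enemies of pests, but only through the plant community that actually
establishes and persists. Two properties of the seed mixture are thought to
govern those dynamics: sown species richness and sown functional diversity.
Richness at constant diversity creates *functional redundancy* — several
species occupying similar positions in trait space — which can buffer the
community's functional structure against the species losses that accompany
succession, while high functional dispersion may occupy niche space densely
enough to resist invasion by spontaneous (unsown) species.

flordyn packages the quantitative machinery to study these questions, for
community ecologists working with vegetation surveys (long-format percent
cover by plot, year and species) and mixed-type trait tables:

* **Assemblage design** — best-of-N subset search building mixtures that
  cross richness (default 9/14/29 species) with low/high functional
  dispersion over disjoint species lists, verified against the intended
  diversity gradient; sowing recipes via thousand-seed weights. The eight
  published reference mixtures ship as fixtures (`published_assemblages()`).
* **Metrics** — mixed-type Gower distances d_ij with pairwise
  missing-data renormalization; principal-coordinates embedding (Cailliez
  correction); Gini–Simpson diversity D = 1 − Σp²; Simpson's evenness
  E = (1/Σp²)/S; Rao's quadratic entropy Q = Σ d_ij p_i p_j; functional
  redundancy FR = D − Q; functional dispersion FDis = Σ p_j ‖x_j − c‖;
  community-weighted means; regeneration-strategy cover shares.
* **Null models** — name-shuffling nulls (trait vectors permuted over the
  species pool, 1000 iterations) and standardized effect sizes
  SES = (obs − null mean)/null sd, seeded and reproducible.
* **Inference** — all marginality-respecting candidate models over the
  predictors, time, and predictor×time interactions; maximum-likelihood
  mixed models (plot nested in transect); AIC ranking with ΔAIC < 4
  selection; full (zero-substitution) model averaging with 95% confidence
  intervals; marginal/conditional pseudo-R².
* **Simulation** — a succession generator with redundancy-moderated,
  functionally selective species loss, dominance shifts toward high-LDMC
  species, and invasion declining with sown dispersion.

Everything takes and returns tibbles and chains with the pipe; fitted
objects have `tidy()`, `glance()` and `autoplot()` methods.

## Worked example

Generate a full synthetic study at the reference layout (151-species pool,
8 assemblages × 6 replicate transects × 4 annual surveys), compute
per-plot-year metrics, and fit the temporal trend of functional dispersion:

```r
library(flordyn)

bench <- make_benchmark(sim_config(seed = 1))
attr(bench$designs, "verification")
#> # A tibble: 8 × 5  (columns shown: assemblage, n_species, fdis, redundancy)
#>   assemblage n_species  fdis redundancy
#> 1 LFMS1             14 0.648      0.653
#> 2 HFLS1              9 0.692      0.548
#> 3 HFMS1             14 0.721      0.554
#> 4 HFHS1             29 0.734      0.579
#> 5 LFMS2             14 0.668      0.627
#> 6 HFLS2              9 0.708      0.527
#> 7 HFMS2             14 0.729      0.544
#> 8 HFHS2             29 0.738      0.574

metrics <- community_metrics(bench$survey, bench$pool, cwm_traits = "ldmc") |>
  attach_design_factors(bench$designs)
fit <- fit_multimodel(metrics, "fdis", c("initial_richness", "initial_fd"))
fit
#> <full averaged model: fdis (gaussian), 2/13 candidates selected>
#>   term                        estimate std_error  abs_z conf_low conf_high
#> 1 (Intercept)                 0.761      0.0151   50.5     0.732    0.791
#> 4 initial_fdhigh              0.0292     0.0111    2.63    0.0074   0.0510
#> 5 time                       -0.0322     0.0038    8.39   -0.0397  -0.0247
#> 6 initial_richnessmedium:time 0.0085     0.0039    2.16    0.0008   0.0162
#> 7 initial_richnesshigh:time   0.0211     0.0043    4.87    0.0126   0.0296
#> ...
```

Read: the verification table confirms the designed gradient (low-FD mixes
disperse least; redundancy rises with richness within the high-FD series;
equal seed numbers force evenness 1 at sowing). The averaged model shows
functional dispersion declining over time (time = −0.032 per year), sown
high-FD mixes staying above low-FD ones (+0.029), and the decline
flattening with sown richness (richness × time interactions +0.008 and
+0.021 for medium and high richness) — the redundancy-buffering signal the
simulator encodes. `run_dynamics_analysis()`, `run_ses_analysis()` and
`run_invasion_analysis()` wrap the three full analyses including the
robustness subsets; `plot_metric_trajectories()`, `plot_ses()`,
`plot_strategy_proportions()` and `autoplot()` draw the standard figures.

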