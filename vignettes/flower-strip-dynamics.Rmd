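---
title: "Trait-based dynamics of sown flower-strip communities: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait-based dynamics of sown flower-strip communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flordyn)
```

# The problem

Flower strips are sown herbaceous habitats placed along or within crop
fields to support pollinators and natural enemies of pests. Whether a strip
actually delivers these functions depends on the plant community that
establishes and persists, not on the seed mixture alone. flordyn implements
the quantitative machinery needed to study this: designing seed mixtures
that cross species richness with functional diversity, measuring trait-based
community properties from annual vegetation surveys, separating dispersion
from richness with null models, and fitting the temporal trends with
AIC-based multimodel inference. A mechanistic succession simulator generates
complete synthetic studies so every stage can be validated end to end.

# Trait space

Communities are described by 16 traits spanning floral resources (nectar
amount, extrafloral nectar, flower diameter, nectar depth, colour, UV
pattern), phenology (flowering onset and duration), architecture (flowering
height, leaf distribution, Raunkiaer life form), resource strategy (SLA,
LDMC, Grime C and R scores) and a composite regeneration strategy. Three
presets matter in practice: the 11-trait plant-arthropod set used for the
headline dispersion analyses, the 9-trait competition set (phenology,
architecture, SLA, LDMC, Grime scores) used when the question is
plant-plant interaction, and the full 16-trait set. The arthropod preset is
also shipped as a 10-trait variant without the Raunkiaer life form, because
the two published descriptions of that trait list differ by exactly this
trait; `trait_subset` is an argument everywhere, so the choice is
configuration, not code.

Four size-like traits (flower diameter, flowering duration, nectar depth,
flowering height) are strongly skewed in field data and are log-transformed
before any distance computation. The natural logarithm is used; the base is
a documented constant, since any monotone log gives the same ranks and very
similar range-normalized distances.

Species dissimilarity is the mixed-type Gower distance: numeric and ordinal
traits contribute range-normalized absolute differences, categorical and
binary traits contribute 0/1 mismatches, and each pair is averaged over the
traits both species have, with weights renormalized per pair. This missing
data rule matters because field trait compilations are incomplete (nectar
depth typically the worst); dropping species or imputing values would bias
distances, while pairwise renormalization only widens their variance.
Ordinal traits (nectar amount scored 0/1/2) are treated as numeric after
range normalization - the simplest defensible reading, documented here
rather than hidden.

Functional dispersion needs a centroid, which a dissimilarity matrix does
not provide, so species are embedded by classical principal-coordinates
analysis. Mixed-type Gower matrices are generally non-Euclidean; the default
Cailliez correction adds the smallest constant making the matrix Euclidean,
matching the realization used by the standard functional-diversity tooling
this package is meant to interoperate with. The square-root correction and
no correction are available. Axes with eigenvalues above `1e-10` times the
largest are retained. One known artifact is documented and tested: under
the Cailliez correction, two functionally identical species end up a small
positive distance apart (the constant is added to their zero distance), so
the duplication invariance of FDis holds exactly only in the uncorrected
embedding; Rao's Q, computed on the raw matrix, is always exactly invariant.

# Community metrics

For a community with relative abundances $p_j$ and species dissimilarities
$d_{ij} \in [0,1]$:

* Gini-Simpson diversity $D = 1 - \sum_j p_j^2$;
* Simpson's evenness $E = (1/\sum_j p_j^2)/S$ with $S$ the richness;
* Rao's quadratic entropy $Q = \sum_{i,j} d_{ij} p_i p_j$;
* functional redundancy $FR = D - Q$;
* functional dispersion $FDis = \sum_j p_j \lVert x_j - c \rVert$ with
  $x_j$ the embedding coordinates and $c = \sum_j p_j x_j$;
* community-weighted mean $CWM = \sum_j p_j t_j$ for a numeric trait $t$.

The "Simpson index" entering redundancy is deliberately the Gini-Simpson
form: it is the unique choice for which $FR = D - Q$ is guaranteed
non-negative when $d_{ij} \le 1$, which is what makes redundancy
interpretable as diversity not expressed in trait space. Evenness is
inverse-Simpson over richness, the most common "Simpson's evenness"; the
published source never writes the formula and its index screening treats
the common variants as interchangeable, so the package keeps the choice in
one function that could be swapped.

Relative abundances are computed from raw percent cover without capping at
100: covers are independent eye estimates per species and overlap freely,
so totals above 100 are data, not errors. Redundancy and Q are computed on
the raw Gower matrix; FDis on the corrected embedding. CWM excludes species
with missing trait values and renormalizes the weights.

# Null models and standardized effect sizes

Realized FDis is confounded with realized richness. The name-shuffling null
breaks the trait-abundance link while keeping both the trait covariance
structure and the community structure: whole trait vectors are permuted
among the species labels of a pool, and FDis is recomputed for each of
`n_iter = 1000` shuffles. The standardized effect size is
$(FDis_{obs} - \bar{FDis}_{null})/sd(FDis_{null})$. When the null
distribution is degenerate (e.g. all pool species identical) the SES is
flagged undefined rather than forced to $\pm\infty$, and such plot-years
are excluded from downstream models with a count report.

The default shuffle pool is the full observed species list across all plots
and years, conditioning the null on the study-wide trait matrix at the
observed richness; a per-community pool is available via the `pool`
argument. An implementation contract worth stating: shuffling names is
realized by relabelling rows of the one precomputed embedding, which is
mathematically identical to rebuilding the Gower matrix and PCoA per
shuffle; a test verifies the equality against the naive recomputation.
Every SES records its seed, and a table-level seed deterministically
derives per-plot-year seeds.

# Designing assemblages

The experimental design crosses sown richness (9/14/29 species) with sown
functional dispersion (low/high) over two disjoint dicot lists, all
assemblages sharing three grasses and equal per-species seed numbers at
240 seeds per square metre. The original mixtures were hand-assembled and
then verified against the diversity gradient; since no algorithm exists to
reimplement, `design_assemblages()` reproduces the design *logic* as a
best-of-N random subset search (N = `n_search` draws per assemblage),
maximizing equal-abundance FDis for high-FD mixes and minimizing it for the
low-FD mixes, with the high-FD series nested across richness levels. The
returned set must pass the same verification the field design did - every
low-FD mix below every equal-richness high-FD mix in FDis, and redundancy
strictly increasing with richness within each high-FD series - otherwise
the search restarts from a derived seed and ultimately errors with the best
achieved margin. Sowing recipes divide the density equally by species and
convert to mass through thousand-seed weights; the original per-batch
weights were never published, so fixtures carry either none or an explicit
synthetic placeholder.

# Multimodel inference

Temporal trends are fitted by the information-theoretic recipe: enumerate
every marginality-respecting combination of the predictors, the time term
and predictor-by-time interactions (13 candidates for two predictors plus
time, including the intercept-only model); fit each by maximum likelihood
(`REML = FALSE`) as a mixed model with plot nested in transect as random
intercepts; rank by AIC; select the set with $\Delta AIC < 4$ (strict, so a
candidate at exactly 4 is out); and report the full averaged model, where
each coefficient is averaged over all selected models with zero substituted
where absent, and the averaged standard error combines within-model
variance with between-model spread. Confidence limits use the normal 1.96
multiplier; the reported `abs_z` column is $|\hat\beta/se|$, matching the
layout of the reference reporting tables. AIC (not AICc) is used because
that is the criterion named by the source methodology; the likelihood's
degrees of freedom count variance components, a convention ambiguity the
package resolves explicitly and consistently with `stats::AIC()`. AIC ties
break by ascending parameter count then model id, so ranking is
deterministic. Non-converged candidates are dropped with a message rather
than failing the run. Variance-partition pseudo-$R^2$ (marginal and
conditional) is computed for Gaussian fits; for Poisson it is reported as
not implemented rather than approximated silently.

Gaussian families serve the continuous responses (FDis, evenness, SES,
CWM, unsown cover) and Poisson the counts (richness, unsown richness). For
the SES response, time enters as a categorical year factor because the
standardized dispersion's temporal profile is not linear.

Model selection is known to make the averaged confidence intervals of
truly-zero coefficients somewhat optimistic; the simulation study below
quantifies this for the package's exact pipeline rather than assuming it
away.

# The succession simulator

`simulate_succession()` is mechanism-level, not distribution-matched: the
published study reports effects, not a generative model, so the generator
encodes the three mechanisms the analyses are meant to detect and leaves
everything else to simple noise models.

1. **Species loss moderated by redundancy.** Each established species
   persists each year with probability
   `plogis(survival_base + redundancy_effect * FR)`, with life-cycle
   penalties for annuals (from year 2) and biennials (from year 3), and a
   selectivity term: survival drops by `peripheral_loss` per standard
   deviation of the species' distance from its assemblage's trait-space
   centroid. The selectivity is what couples species loss to dispersion
   loss - competitive exclusion removes functionally extreme species first;
   random (non-selective) loss barely moves an abundance-weighted mean
   distance and would make redundancy undetectable through FDis.
2. **Dominance shift toward resource conservation.** Survivors' covers are
   multiplied yearly by `exp(ldmc_dominance * z(LDMC) + noise)`, producing
   the increase in community-weighted LDMC typical of mown grassland
   succession, plus strategy-specific factors: annuals flush in year 1
   (`annual_boost`) and fade after, biennials peak in years 1-2.
3. **Invasion resistance.** Unsown arrivals are Poisson with rate
   `invasion_rate * exp(-invasion_fd_effect * FDis_sown)` declining each
   year by `invasion_year_decay` (sward closure); invaders are drawn mostly
   from annual weeds (`invader_weight_annual`), start at lognormal cover,
   and survive with an extra `unsown_penalty` on the logit.

Covers live on a latent log scale: growth noise (`growth_noise`) is a
multiplicative random walk, observation error (`obs_noise`) is
non-accumulating per-survey noise, transect and plot random intercepts act
on log cover, and each plot-year is rescaled to a total-cover schedule with
its own lognormal error. Species below `extinction_cover` percent are
lost. The distinction between accumulating and non-accumulating noise is
not cosmetic: a multiplicative random walk erodes evenness faster in
species-poor plots, which by itself creates a richness-by-time interaction
in FDis; simulations that need a true null (below) therefore switch the
walk off and keep only observation noise.

The layout mirrors the reference experiment: a 151-species pool, eight
assemblages (two disjoint lists crossing low/high FD with 9/14/29 species),
six replicate transects in three blocks, four annual surveys, equal initial
proportions, and an optional partial mid-study campaign (only transects 4-6
surveyed in year 2). The design search down-weights annuals (seed mixtures
for perennial strips favour perennials) and invaders over-sample them
(arable colonists are mostly annual weeds).

Two calibration targets anchor the defaults: the across-assemblage mean of
year-4 sown-species persistence lies in the 0.60-0.75 band, and annual
species hold roughly half to two-thirds of total cover in the first survey
year. With the synthetic pool, functional redundancy spans about 0.50-0.60
(real floras cluster more tightly in trait space and reach 0.84-0.92), so
the survival logit parameters are scaled to that range rather than to the
field values. The total-cover trajectory over years is a free
configuration curve (the real one is unpublished); the default rises from
70 to 100 percent.

What passing tests on this generator do and do not show: they demonstrate
that the full pipeline - metrics, null models, enumeration, averaging -
recovers the mechanisms the generator encodes at the reference study size,
with honest coverage under the null. They do not show that real flower
strips behave like the generator: real succession has spatial structure,
seed banks, weather forcing, and trait-correlated colonization that the
generator deliberately omits.

# Numerical choices and degenerate inputs

* Gower distances are symmetrized after assembly to remove float noise;
  zero-range numeric traits contribute zero with a warning; a species pair
  with no shared non-missing trait is an error.
* Embeddings retain eigenvalues above `1e-10` of the maximum; a fully
  degenerate matrix (all species identical) embeds as a single zero axis,
  which propagates to FDis = 0 and an undefined SES rather than an error.
* Empty plot-years (all species lost) are retained as warnings and simply
  have no survey rows; the metric layer drops them.
* All stochastic stages restore the caller's RNG state and are fully
  determined by their seed arguments; derived seeds stay below $2^{31}$.

# Problem sizes used in validation

The test suite exercises the design search and pipeline shape on a reduced
benchmark (60-species pool, 5/8/12 richness targets) and the statistical
claims at the reference size: SES calibration uses 200 random communities
of 5-30 species with 500 shuffles each from the 151-species pool (mean SES
within 0.15 of 0, sd within 0.15 of 1); mechanism recovery uses 100
replicate benchmarks at the full layout (positive high-richness-by-time
FDis interaction in at least 90), and 100 null-dynamics replicates for CI
coverage of the truly-zero interaction (nominal 95 within 5 points). At
the frozen defaults the measured sign-recovery rate is close to the 90%
bound (replication noise of 48 plots over 4 years is the limit, as it is
for the field design itself), so occasional failures of that single check
reflect finite-sample noise around the bound rather than a missing effect.

# Known limitations

* Redundancy ordering and absolute FDis levels on synthetic pools are not
  comparable to field values; reproducing the published per-mixture values
  requires the study's own trait measurements, which are not
  redistributable with the package.
* The Cailliez correction's duplication artifact (above) means corrected
  FDis values should not be compared across embeddings built from
  different species sets.
* Poisson pseudo-$R^2$ is intentionally unimplemented.
* Full model averaging's confidence intervals are approximate under
  selection; the package reports them as the methodology prescribes and
  quantifies their null coverage by simulation instead of correcting them.
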