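---
title: "Land-use regression exposure modelling on synthetic geography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Land-use regression exposure modelling on synthetic geography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Epidemiological studies need outdoor NO~2~ concentrations at places where
nobody measured — typically the home addresses of study participants. Two
modelling traditions address this. *Land-use regression* (LUR) fits a linear
model for measured annual-mean concentrations at a modest number of
monitoring sites (tens of sites) on GIS-derived covariates: traffic intensity
around the site, distance to and flow on the nearest road, land-use
composition and population in circular buffers, and a regional background
level. *Screening dispersion models* of the CAR type instead add a physically
motivated local traffic term — emission times a dispersion factor that decays
with distance from the road — to a large-scale background map.

`lursim` implements both, together with everything needed to exercise them
end to end without access to real monitoring campaigns: a synthetic-geography
generator produces road networks, land-use and population rasters, and
simulated monitoring campaigns from a known ground-truth concentration
process, so that every stage — predictor extraction, imputation of lost
samplers, supervised model selection, internal and cross-campaign validation
— runs against a truth that is known by construction.

## The ground-truth process and what the generator emulates

The generator builds a planar region (coordinates in metres; at study extents
below ~100 km planar geometry is adequate and no map projections are used)
containing three road authorities: national freeways, provincial roads and a
dense municipal street network, each generated as random polylines to a
configurable length density. Each road carries a 24-hour traffic flow, a
heavy-duty fraction, and a flag saying whether a traffic count is actually
available. Count availability increases with flow: it is the quiet municipal
streets that lack counts, and those streets later receive a fixed minimal
flow of 1,225 vehicles/24 hr in the data product used for modelling. This
matters for the reduced-input experiments: replacing the counted municipal
flows with the minimal-flow default removes genuine information.

Land use is a Voronoi patchwork of seven categories (residential, industry,
port, transport, green space, water, agriculture) whose composition shifts
towards residential and industrial use near the regional core, on a fine grid
(25 m cells by default) from which a coarse 100 m product is derived by block
majority — emulating the two land-use resolutions (a high-resolution city map
versus a coarse continental class map) that the two model dialects consume.
Population counts live on a 100 m raster tied to residential land use.

True annual-mean concentration at a point decomposes additively:

* an intercept plus a smooth regional background field (west–east gradient
  with a low-frequency ripple, giving regional levels of roughly
  14–25 µg/m³);
* a local traffic term, `gain × Σ_roads flow × exp(−d/λ)` with an exponential
  decay length λ = 60 m — the same rationale that motivates entering log
  distances into the regression a priori;
* land-use terms proportional to category fractions within 300 m
  (residential positive, green/water/agriculture negative);
* per-period seasonal offsets (one Gaussian draw per period) and independent
  Gaussian sampler noise (2 µg/m³), truncated at zero.

Two campaign designs are emulated. The *large-area* campaign places 18
traffic, 34 urban-background and 8 rural sites (plus 8 external rural sites
outside the region, used only for background interpolation) at building
façades about 10 m from the road centreline, samples four periods, and loses
10.6% of samplers at random. The *city* campaign places 25 traffic and 37
non-traffic sites inside the central urban window at curbside (about 3 m,
lamppost-style), samples thirteen periods, and loses 3.7%. The purpose-built
campaign screens traffic sites away from multi-road situations (no second
busy road within 40 m); the routine-programme campaign applies only a minimal
12 m guard, so its sites can sit near complicated multi-road locations.

**What the generator does not emulate.** The truth is a deterministic, smooth
function of exactly the GIS layers that the predictors summarise, plus
i.i.d. noise. Real campaigns additionally face street-canyon microscale
gradients, congestion-dependent emissions, sampler micro-siting and geocoding
error — none of which are modelled here (and the dispersion comparator makes
no claim to calibrated chemistry). Consequently, passing tests demonstrate
that the algorithms are implemented correctly and behave as designed under a
known truth; they do not demonstrate that models fitted to real campaigns
transfer equally well. This distinction matters most for cross-campaign
validation: in our synthetic world a well-fitted large-area model transfers
to the curbside campaign with little loss — moving samplers from 10 m to 3 m
*enlarges* the local traffic signal (kernel 0.95 versus 0.85 of its at-road
value) and widens the concentration range, which, if anything, raises the
observed-versus-predicted correlation. The large external-validation drop
reported for real campaigns requires site-selection and microscale
heterogeneity mechanisms that are outside this generator's scope; the
package's validation reports therefore expose both the squared-Pearson R² and
the 1:1-line R² (`r2_1to1`), the latter being sensitive to the systematic
under/over-estimation that dominates real transfers.

## GIS predictors

For every site the predictor table contains: flow-weighted road length in
100 m and 250 m buffers (total and heavy-duty; the flow × intersected-length
integral is computed in closed form from segment–disc chords); log distance
to and flow at the nearest road of each class (all roads, busy ≥ 5,000,
main ≥ 10,000 vehicles/24 hr — thresholds applied as greater-or-equal — and
freeways, identified by national authority); distance-censored flow variables
at 25/50/100/250/500 m cutoffs; land-use fractions per category in
configurable buffer radii (300 m/1 km/5 km for the coarse dialect,
25–500 m for the fine dialect); and population counts in 100 m–5 km buffers.

Numerical conventions, each configurable: distances are clamped at 1 m before
the log (sites can sit at distance zero); a road class absent from the region
is censored at the region diagonal with flow 0 rather than producing missing
cells; raster buffers use the cell-centre membership rule, which agrees with
exact area integration to better than 0.02 once the radius spans at least
about six cells (at radius/cell-size = 3 the rule itself deviates by up to
~0.06 — use the fine raster for small buffers).

## Background, imputation, pooling

The large-area model enters the regional background a priori: for urban and
traffic sites the inverse-distance-weighted (power 1 by default, exponent
configurable) mean of rural-site annual means within 50 km; rural sites use
their own measured mean. Lost samplers are multiply imputed (m = 10) by
chained equations, each period column regressed on the other periods plus
site-type dummies with a Bayesian normal linear draw, ten sweeps per
imputation. Annual means are plain averages over periods per imputation;
model selection runs on the across-imputation mean, and the selected model is
then refitted within each imputation and pooled by Rubin's rules
(T = W + (1 + 1/m)·B, Barnard–Rubin degrees of freedom). With nothing
missing, all imputations coincide and B = 0 exactly.

## Supervised forward selection

Candidate predictors are organised in four ordered groups — traffic,
traffic-related land use, population-density-related land use, other land
use — and, within each group, into families of overlapping variants: the
buffer radii of one land-use category form a family, and the road-class
variants (all/busy/main/freeway, plus distance cutoffs) of one traffic
variable type form a family, because nested road classes overlap just as
nested buffers do. Only the best variant per family (highest univariate R²,
ties to the smaller radius/cutoff) is offered. Candidates are offered in
univariate-R² order and accepted only if the adjusted R² improves by at least
one percentage point (the threshold is absolute points, matching how
explained variance is reported in percent) *and* every coefficient in the
augmented model — including previously accepted ones and the a priori
background — keeps its declared sign (flows and built-up categories positive,
log distances and green/water/agriculture negative; fully configurable).
Rejected candidates are not revisited: a strict single-pass reading of
one-by-one addition, with an exhaustive-enumeration oracle in the test suite
confirming on small instances that the resulting set is always reachable
under the rules. After all groups, backward pruning repeatedly removes the
highest-p-value non-a-priori variable while the adjusted R² changes by less
than one point. Effects are reported per interquartile range (coefficient ×
empirical IQR, SE scaled identically).

Two behaviours of this procedure are worth knowing, and both are properties
of supervised selection on collinear menus rather than implementation
artefacts. First, near-duplicate families — the heavy-duty twin of a traffic
buffer, population versus residential fraction, compositional complements
among land-use categories — substitute freely for one another: on full GIS
menus the procedure reliably recovers the *predictive structure* but not
necessarily the generating columns, even when a direct regression on the true
columns is decisively significant. Second, the procedure is not monotone in
input information: refitting on a reduced-information table occasionally
yields a slightly *higher* adjusted R², because a family's univariately best
variant on the richer table can complement the already-accepted variables
poorly. Ranking candidates on the background-residualised response instead of
the raw response (`rank_on_residual = TRUE`) removes one source of such
confounding but is off by default.

## The dispersion comparator

The CAR-style comparator predicts background + emission × dispersion factor.
Emission is flow times a fleet-weighted, speed-class-dependent emission
factor (heavy vehicles roughly an order of magnitude above passenger cars).
The dispersion factor is a per-street-configuration quadratic in distance up
to 30 m continuing as c/d to the 60 m validity limit (continuous at 30 m,
strictly decreasing, canyon configurations above open roads), scaled by 1/wind
speed against a 5 m/s reference and multiplied by a tree factor ≥ 1. All
coefficients are configuration defaults chosen to satisfy these structural
contracts; they are not a certified parameterisation of any regulatory tool,
and no NOx→NO₂ chemistry is attempted — the module exists as a structurally
faithful comparator, and its rank agreement with the generator's exponential
kernel (Spearman > 0.9 on single-road batches) plus its correlation with the
LUR predictions are the claims the tests check.

## Validation

`loocv()` refits coefficients (not the selection path — selection-in-the-loop
would be a different, more expensive estimand) on each leave-one-out fold.
`external_validate()` scores a frozen model against the other campaign.
Reports carry both R² definitions, the observed-on-predicted slope and
intercept, and mean residuals overall, by site type, and in the top
concentration quartile — the diagnostic for hot-spot underestimation, which
appears in the synthetic world as a positive top-quartile residual whenever
the fitted linear distance response is shallower than the true kernel.

## Problem sizes and runtimes

The default study uses a 6 × 6 km region (240 × 240 fine land-use cells),
~60 + 8 and 62 sites, m = 10 imputations, and runs end to end in a few
seconds; the seeded 20-replicate experiments in the acceptance tests run in a
few minutes. Every stage derives its RNG stream from one master seed, so a
study is reproducible file-for-file.

## A worked run

```r
library(lursim)
study <- run_study(study_config(), seed = 1)
study$summary
per_iqr_effects(study$model_large)
red <- run_reduced_inputs(study)
c(traffic_penalty = red$delta_traffic, landuse_penalty = red$delta_landuse)
```

The summary juxtaposes in-sample, leave-one-out and cross-campaign R² for
both models plus the dispersion-model agreement; the reduced-input penalties
quantify how much more the complete municipal traffic data contribute to the
large-area fit than fine-resolution land use contributes to the city fit.
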