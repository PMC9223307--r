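---
title: "Supply, demand and balance of ecosystem services from land use"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supply, demand and balance of ecosystem services from land use}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esdbalance)
```

## The assessment model

`esdbalance` treats a region as a categorical land-use grid observed at a
small number of census years, partitioned into contiguous reporting zones
(counties, districts). Three quantities are computed per zone and year.

**Supply.** The equivalent-factor method assigns each land class a fixed
coefficient per service (yuan·hm⁻²·a⁻¹) and values supply as
`ESV = Σ_k A_k · VC_k`. Its assumptions are strong and worth stating: the
per-hectare value of a class is constant in space and time, services are
additive, and construction land supplies nothing. Its virtue is that it
needs only a classed raster and an agreed coefficient table, which makes
results comparable across studies using the same table. The packaged
table covers nine services by six classes; any replacement with the same
schema is accepted. The unit chain is fixed — areas in km², ×100 to hm²,
coefficients in yuan, reported in 10⁸ yuan — because that chain is what
regional summary tables print.

**Demand.** Demand per zone is the composite
`X = D · log(P) · log(NLCI·c)`, combining the built-up share `D` (%), the
population density `P` and a night-light composite `NLCI = 0.8·I + 0.2·S`,
where `I` is the mean intensity of lit pixels on the 0–63 DN scale and
`S` the lit-pixel share. The composite stands in for economic density:
lights track economic activity more directly than area-averaged GDP and
are observable everywhere, including where statistics are thin.

Three numerical choices are deliberate and exposed as arguments:

* *Log base.* The defining product does not fix a base; the package uses
  log₁₀ (`log_base`). The index is relative, so the base only rescales
  it, but it must be pinned for reproducibility.
* *NLCI rescaling.* `NLCI ∈ [0, 1]`, so its raw logarithm is negative.
  The index is computed on `NLCI · c` with `c = 100` (`nlci_scale`) — a
  percent-style index — so brighter zones contribute positively.
* *Floors.* Both log terms are floored via `max(·, 1)` (`p_floor`,
  `nlci_floor`), so an unlit or unpopulated zone contributes zero demand
  rather than negative demand, and `X ≥ 0` always. A zone with no lit
  pixels gets `I = S = 0` exactly (the 0/0 ratio is defined as zero):
  such data-gap zones are real in sparsely developed regions and must not
  poison the index.

The DN convention deserves a note: lit pixels are those with
`1 ≤ DN ≤ 63`. Continuous radiance products must be brought onto the
0–63 integer scale first; `rescale_dn()` clips at a saturation percentile
(default the 99th) and rescales linearly. `light_stats()` rejects
out-of-range input outright rather than guessing a calibration.

**Balance.** `BI = supply − demand` per zone. Supply is monetary and
demand dimensionless, so subtracting raw values mixes units; the default
`"normalized"` mode min–max scales both sides to `[0, 1]` within each
year before subtracting, giving `BI ∈ [−1, 1]`, antisymmetric under
swapping the two sides. `"raw"` mode is retained for literal fidelity to
the defining difference; every output records which mode produced it.

**Classification.** Supply, demand and balance maps conventionally use
natural-breaks legends. `jenks_breaks()` computes Fisher's optimal
partition (dynamic programming, globally optimal within-class sum of
squares, deterministic — unlike heuristic implementations). Ties at a
break go to the lower class; values outside the fitted range clamp to the
terminal classes with a warning. The balance typology fits `k = 7`
classes, names the class containing zero "balance", and grades classes
above/below as general/higher/high surplus/deficit. Breaks are refit per
year by default, matching year-by-year map legends; `per_year = FALSE`
fits one scheme across years when temporal comparability matters more.
With fewer distinct values than classes the scheme collapses gracefully
(all-equal values yield a single "balance" class).

**Attribution.** The association between balance and landscape
composition is estimated by quantile regression of `BI` on ten detailed
land-use proportions, `Q_θ(Y|X) = X′β(θ)`, at
θ ∈ {0.1, 0.3, 0.5, 0.7, 0.9} plus OLS. Quantile regression is the right
tool here because the interesting question is distributional: does
built-up expansion depress the balance more in already-deficit zones
than in surplus ones? A location-shift world gives flat `β(θ)`; scale
effects tilt it.

## The quantile-regression solver

The estimator minimises the check loss `ρ_θ(u) = u(θ − 1{u<0})`. The
contract is objective-value optimality, not a named algorithm: the solver
runs majorise–minimise iteratively reweighted least squares with epsilon
continuation (the smooth majoriser of `|u|` with weights
`1/max(|u|, ε)`, ε driven from 10⁻⁴ to 10⁻¹²), then polishes by
enumerating exact fits through observation subsets — every optimum of a
piecewise-linear objective interpolates `p` observations, so for small
problems all `C(n, p)` bases are enumerated and the solution is exactly
optimal; for large ones the enumeration is restricted to the
smallest-residual neighbourhood of the MM solution. Tests hold the
attained loss to within 10⁻⁸ of an independent brute-force enumeration.

Standard errors use a seeded x–y pair bootstrap (default 1000 resamples;
the polish step is skipped inside the bootstrap, where vertex-exact
solutions buy nothing). Pair bootstrap is distribution-free and valid
under heteroscedasticity, which the analysis explicitly cares about.
Significance stars follow the two-sided 10/5/1 % convention. Fitted
quantile planes may cross; the package does not rearrange them, but
`quantile_path()` counts crossings as a diagnostic.

## What the synthetic generator emulates

The generator exists so that every downstream stage has ground truth. Its
defaults describe the study conditions the package targets: a large
subtropical basin observed at 1 km over five census years.

* *Class mix* (cultivated 0.312, woodland 0.458, grassland 0.167, water
  0.028, construction 0.024, unused 0.011) matches the first-year
  composition of such a basin.
* *Transitions* are a per-interval Markov chain; the dominant pathway is
  cultivated → construction at 0.015 per interval, the signature of rapid
  urbanisation, with smaller conversions keeping other classes mildly
  dynamic. Cell count is conserved — transitions relabel, never create
  cells — and class shares converge to the chain's closed form as the
  grid grows (tested at three binomial standard deviations).
* *Population* is `base × multiplier(class) × lognormal noise`, with
  construction cells carrying a ×60 multiplier, so demand hot-spots
  co-locate with built-up land.
* *Night light* is a class-mean DN plus Gaussian noise, rounded and
  clipped to 0–63; construction averages DN 48, ecological classes sit
  near the noise floor.
* *Zones* are Voronoi cells of a seeded k-means on cell coordinates —
  convex, hence contiguous, county-like units.

What the generator does **not** emulate: spatial autocorrelation within
classes (cells are conditionally independent), sensor artefacts and
intercalibration drift between night-light products, migration dynamics
decoupled from land class, and real administrative geometry. Passing
tests therefore demonstrate the pipeline's arithmetic and statistical
machinery, not remote-sensing calibration.

The regression-data generator draws compositions from a flat Dirichlet
over the ten detailed classes plus a remainder (so covariates are not
collinear with the intercept) and supports heteroscedastic noise whose sd
grows with one covariate — the mechanism that produces quantile-dependent
slopes for recovery tests.

## Problem sizes and reproducibility

The test suite and the demonstration pipeline use desk-scale problems
chosen to exercise every code path at comfortable statistical power:
scenes of 30×30 to 100×100 cells, 2–9 zones, regression datasets of
60–800 zones, 20–1000 bootstrap resamples, and brute-force oracles up to
`n = 15` (classification) and `n = 10, p = 2` (quantile regression).
Every random quantity is a deterministic function of an explicit integer
seed; the pipeline writes byte-identical CSVs under identical
configuration, and `metadata.json` records every setting, seed and
fitted break so any table can be regenerated from the sidecar alone.

## Known limitations

* The equivalent-factor coefficients are taken as given; no regional
  recalibration, and no distinction between actual and potential supply.
* The demand index ignores demand-side preferences; it proxies intensity
  of use, not want.
* Balance is a per-zone difference; no service flows between surplus and
  deficit zones are modelled.
* The packaged area table is rounded to whole km², so values derived
  from it carry about ±0.02 × 10⁸ yuan of print-rounding uncertainty —
  the tolerance used throughout the tests.
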