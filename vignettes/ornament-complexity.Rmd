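---
title: "Quantifying ornament shape complexity and its developmental cost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ornament shape complexity and its developmental cost}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(ornametrics)
```

## The problem

Male sepsid flies (Diptera: Sepsidae) carry sexually dimorphic ornaments —
modified fore femora, fourth abdominal sternite brushes, and genital
claspers — that range from simple to highly elaborate across species.
Because all adult cuticular structures are built from a fixed energy budget
during pupal metamorphosis, a natural question is whether building a more
*complex* ornament (as opposed to merely a larger one) prolongs development.
Answering it needs three ingredients, which this package provides:

1. a **shape-complexity score** for a closed 2-D trait outline that does not
   depend on homologous landmarks (none exist across these genera);
2. **morphometric summaries** of a species-by-sex study panel — development
   times, body size, trait areas — with cross-species sex-difference tests;
3. a **phylogenetic regression** (PGLS with Pagel's λ) of development-time
   differences on complexity and size covariates, since species are not
   independent data points.

A synthetic-data generator emulates the whole study design so every stage
can be validated against known truth.

## The complexity score

An outline's coordinate functions are expanded in an elliptic Fourier
series: harmonic $n$ contributes a quadruple $(a_n, b_n, c_n, d_n)$ to

$$x(t) = A_0 + \sum_n a_n \cos nt + b_n \sin nt, \qquad
  y(t) = C_0 + \sum_n c_n \cos nt + d_n \sin nt .$$

A reconstruction truncated at 8 harmonics approximates a complex shape
poorly; one at 1000 harmonics is essentially exact. Overlaying the two
filled reconstructions splits the plane into a *congruent* region (covered
by both) and a *non-congruent* region (covered by exactly one), and

$$\text{complexity} \;=\; \frac{\text{non-congruent area}}
                               {\text{congruent area}} .$$

The score is dimensionless and size-free (both reconstructions scale
together), zero exactly when the outline carries no energy above the low
harmonic cutoff, and grows as high-frequency structure grows.

```{r score-demo}
sh <- make_shape(shape_spec(axes = c(120, 70),
                            perturb = data.frame(harmonic = 20, amplitude = 4)))
complexity_score(sh)
plot_reconstructions(sh, h_low = 8, h_high = 200)
```

### Numerical choices

* **Fourier parameter.** `efa()` treats the outline's vertices as equally
  spaced in the Fourier parameter and computes spectral (trapezoid/DFT)
  coefficients. For a digitized trace this means equal-arc-length
  resampling first (`resample_outline()`; applied automatically when the
  vertex count is below the Nyquist requirement `2 * n_harmonics`), which
  is the standard equal-arc elliptic Fourier fit. Shapes from the
  generator, and reconstructions, carry their own natural parameter and are
  used as given; on such band-limited curves the transform is exact to
  machine precision, which is what makes the zero law (`ellipse scores 0`)
  and the injected-energy accounting analytic rather than approximate.
  A consequence worth knowing: an *eccentric* ellipse re-parameterized by
  arc length is no longer a single Fourier harmonic, so a sparse hand
  trace of an ellipse that must be resampled scores not 0 but a small
  parameterization floor (about $3\times10^{-3}$ at 2:1 eccentricity).
* **"1000 harmonics"** is interpreted as `min(1000, Nyquist bound)` of the
  (possibly resampled) trace; the internal resampling default of 4096
  points makes 1000 harmonics representable.
* **Boolean areas.** Reconstructions are sampled at 4096 points and the
  intersection/union areas computed with the Clipper polygon engine under
  the even-odd fill rule, so self-intersecting low-harmonic reconstructions
  are repaired to valid regions exactly as a plotted closed curve looks.
  The integer snapping grid is set to ~1e-13 of the coordinate range. The
  non-congruent area is obtained as union minus intersection, so the
  congruent + non-congruent = union identity holds to rounding. An
  independent raster oracle (`raster_congruence_areas()`, point-in-polygon
  counting on a pixel-center grid) agrees with the vector areas to well
  under 0.5% and is exercised in the test suite.
* **Pixel conventions.** Mask tracing follows the pixel-center convention:
  the boundary polygon of a filled $n\times n$ block has area $(n-1)^2$
  while its pixel count is $n^2$. The pixel count is the paper-faithful
  trait-size measure; the polygon feeds the vector geometry. The polygon of
  a rasterized disc of radius $r$ therefore measures $\approx\pi(r-1/2)^2$,
  not $\pi r^2$ — a documented property of the convention, not an error.
* **Degenerate inputs.** Outlines need ≥ 3 distinct vertices; zero-perimeter
  and non-overlapping-reconstruction cases raise classed errors naming the
  failing harmonic level. Self-intersecting traces are accepted but flagged.

### Normalization against the female baseline

Male sternite and fore-femur scores are normalized by the female score of
the same species (`normalize_dimorphism()`, male/female), since females of
some species are ornamented too. Claspers occur only in males and are never
normalized. *Perochaeta dikowi* females lack a sclerotized fourth sternite;
their sternite score is fixed at 1 so the male score passes through.

## Morphometrics

`summarize_panel()` averages individual records into species-by-sex means,
then derives male − female differences and percent differences (female mean
as denominator, the baseline sex). Derived quantities: total development
time is larval + pupal duration; pupal volume uses the ellipsoid formula
$\frac{\pi}{6}\,w^2 \ell$; growth rate is scutum width divided by total
development time, **computed from the species-by-sex means** (the ratio of
means, not the mean of individual ratios — the definition is not uniquely
fixed by convention, and the mean-based form matches treating species means
as the unit of analysis). Cross-species inference treats species means as
replicates (n = number of species), unweighted by per-species sample size:
`sex_difference_tests()` runs one-sample t-tests of each mean difference
against zero, and `correlation_tests()` Pearson correlations between
species-mean columns. A deposited species-means table can be mapped into
the same schema with `read_species_means_csv()` and a column-name
configuration.

## Phylogenetic regression

`pgls()` fits $y = X\beta + \varepsilon$, $\varepsilon \sim \mathcal N(0,
\sigma^2 V(\lambda))$, with $V$ the Brownian-motion covariance of the tree
(shared root-to-MRCA path lengths) and $V(\lambda)$ Pagel's transform
(off-diagonals multiplied by $\lambda \in [0,1]$). Estimation is exact GLS
via the Cholesky-whitened regression; $\lambda$ is either fixed or
maximized over $[0,1]$ on the profile log-likelihood
($\sigma^2$ profiled out as RSS/n) with a bounded scalar optimizer at
1e-6 tolerance, ties broken toward smaller $\lambda$ by comparing the
boundary fits — so a flat likelihood reports "no signal" rather than an
arbitrary interior point. Standard errors use $\hat\sigma^2 =
\mathrm{RSS}/(n-p)$; the ANOVA table is sequential (type I) in the order
terms appear in the formula, which is the convention of the comparative
ecosystem this mirrors; marginal tests are available from the coefficient
t-values. Whether the original analyses used ML or REML and sequential or
marginal tables is not documented; both λ modes are exposed and sequential
is the default. Model fits are on raw scales (no predictor
standardization). Species absent from the tree are pruned with a warning —
the same behaviour as dropping a species missing from a published
phylogeny. At $\lambda = 0$, or on a star phylogeny, the fit reduces to
OLS exactly; the test suite verifies both, plus agreement of the ML fit
with an independent GLS implementation (`nlme::gls` with a Pagel
correlation structure) and slope recovery with nominal CI coverage on
simulated Brownian data.

## What the synthetic generator emulates — and what it does not

`make_shape()` builds outlines directly in Fourier space (ellipse plus
harmonic perturbations), so injected spectral energy is exact and the
score's zero law and amplitude monotonicity are analytic properties of the
fixtures. Amplitudes above `minor_axis / (2 * harmonic)` can self-intersect
and trigger a warning. These shapes are spectrally controlled abstractions;
no attempt is made to mimic actual clasper silhouettes.

`make_species_panel()` generates an 18-species, two-sex study panel whose
defaults *are* the study conditions: mean male − female scutum width
−0.134 mm, larval-duration difference −0.55 h, pupal-duration difference
+7.42 h, complexity differences 0.029 / 0.024 / 0.231 (sternite / femur /
clasper), sternite-area difference +0.62 mm². Between-species spreads are
derived from the corresponding 95% confidence intervals
($sd = CI\sqrt{n}/t_{0.975,17}$, e.g. 9.05 h for the pupal difference);
female baselines (scutum 1.2 mm, larval 210 h, pupal 158 h, pupal width
0.9 mm × length 2.3 mm) are plausible magnitudes for flies of this size
and are config values, not truth claims. Trait areas scale with body size,
and the ornament-area dimorphism carries a body-size-coupled component
(`size_coupling = 0.6`) so that trait-size means correlate positively
across species, as observed. Species means evolve on a unit-depth Yule
tree with Pagel's λ (`lambda_signal`, default 0 — most fitted models in
this clade show no phylogenetic signal); individuals are drawn around the
species-sex means with a 5% coefficient of variation. An optional
`complexity_pupal_slope` couples male pupal duration to sternite-complexity
dimorphism, providing the known-truth effect for power analyses.

What passing tests on these panels do **not** show about real data: the
generator's distributions are Gaussian with a single shared tree and
homogeneous within-species noise; real panels have unequal and small
per-species sample sizes (5–20 for trait measurements), measurement error
in tracing, non-Gaussian trait distributions, and a tree estimated with
uncertainty. Recovery of the built-in effects demonstrates correctness of
the estimators under their assumed model, not robustness to these
violations.

## Problem sizes and determinism

Every generator takes an explicit integer seed and is bit-reproducible.
The standing test suite uses reduced problem sizes chosen to keep the
statistical checks sharp: 50 replicates for the 100-tip slope-recovery
check, 20–25 replicates for λ-regime classification, 100 seeds for the
end-to-end power property, raster oracles at 768–1024 grid cells, and
20 random shapes for the vector/raster congruence comparison. The
acceptance script (`scripts/acceptance.R`) re-runs the same computations
from scratch at those sizes and averages the panel recoveries over 20
replicate panels so the reported values estimate the generator's means with
a few percent of Monte-Carlo error.

## Known limitations

* The score quantifies 3-D structures through 2-D outlines; the package is
  deliberately 2-D.
* Absolute score values depend on trace density and parameterization for
  sparse hand traces (see the eccentric-ellipse floor above); orderings are
  robust, which is why the clasper-ordering property, not the printed
  per-species values, is the portable check.
* Whether congruence areas were originally computed in raster or vector
  mode is unknown; both are provided, vector is canonical, and they agree
  to well under 0.5%.
* No Ornstein–Uhlenbeck or multi-rate evolutionary models, no tree
  inference, and no mixed-effects modelling of individual-level development
  times: species means are the unit of analysis throughout.
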