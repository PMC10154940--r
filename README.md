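# ornametrics

Outline shape complexity and comparative morphometrics of sexual ornaments.

Male sepsid flies (Diptera: Sepsidae) bear elaborate, rapidly evolving
sexual ornaments — armoured fore femora, fourth-sternite brushes, genital
claspers — whose structural complexity varies so much across genera that no
homologous landmarks can be defined. `ornametrics` is for comparative
morphologists and evolutionary biologists who want to (a) score the
complexity of any closed 2-D trait outline without landmarks and (b) ask
whether complexity or size of such traits carries a developmental cost
across species, while controlling for phylogeny.

## The score

An outline's coordinates are expanded as an elliptic Fourier series,
harmonic *n* contributing a quadruple (a_n, b_n, c_n, d_n):

    x(t) = A0 + Σ a_n cos(nt) + b_n sin(nt)
    y(t) = C0 + Σ c_n cos(nt) + d_n sin(nt)

The outline is reconstructed twice — truncated at 8 harmonics (coarse) and
at 1000 harmonics (essentially exact) — and the two filled curves are
overlaid. Complexity is the ratio

    complexity = non-congruent area / congruent area

i.e. symmetric-difference over intersection of the two reconstructions: 0
for shapes fully captured by 8 harmonics, growing with high-frequency
structure, invariant to translation, rotation and scale.

Downstream, the package summarizes species-by-sex panels (development
times, scutum width, ellipsoid pupal volume (π/6)·w²·l, trait areas),
tests cross-species male−female differences (one-sample t), correlates
trait sizes with development times (Pearson), and fits phylogenetic
generalized least squares regressions with Pagel's λ estimated by maximum
likelihood, including sequential ANOVA tables. A synthetic-data module
generates band-limited shapes with exactly known spectra and full study
panels with configurable effect sizes on simulated Yule trees.

## Worked example

Score a synthetic shape with known high-harmonic content:

```r
library(ornametrics)

sh <- make_shape(shape_spec(axes = c(120, 70),
                            perturb = data.frame(harmonic = 20, amplitude = 1.5)))
complexity_score(sh)
#> # A tibble: 1 × 6
#>   source_id       h_low h_high congruent_area noncongruent_area complexity
#>   <chr>           <int>  <int>          <dbl>             <dbl>      <dbl>
#> 1 synthetic_shape     8   1000         26170.              580.     0.0222
```

The ellipse alone scores 0 (it is one harmonic); the injected harmonic-20
ripple puts ~580 px² outside the 8-harmonic reconstruction against
~26,000 px² of shared area, a complexity of 0.022.

Generate a study-scale panel (18 species × 2 sexes, defaults at the
magnitudes reported for sepsids), summarize, test, and fit PGLS:

```r
panel <- make_species_panel(panel_spec(seed = 1))
summ  <- summarize_panel(panel$individuals)
sex_difference_tests(summ)
#> # A tibble: 10 × 8
#>   quantity     n  mean  ci95      t    df      p pct_mean
#>   <chr>    <int> <dbl> <dbl>  <dbl> <dbl>  <dbl>    <dbl>
#> 1 larval_h    18 -1.25  3.27 -0.803    17 0.433    -0.541
#> 2 pupal_h     18  6.30  5.93  2.24     17 0.0388    4.24
#> 3 total_h     18  5.05  7.68  1.39     17 0.183     1.62
#> # … 7 more rows

fit <- pgls(summ,
            pupal_h_diff ~ sternite_complexity_diff + scutum_mm_male + scutum_mm_diff,
            panel$tree, lambda = "ML")
fit
#> PGLS fit: pupal_h_diff ~ sternite_complexity_diff + scutum_mm_male + scutum_mm_diff
#> n = 18 species, lambda = 0.4490 (ML), logLik = -66.965
#>                       term estimate std.error statistic p.value
#> 1              (Intercept)    7.934    13.040    0.6084  0.5527
#> 2 sternite_complexity_diff   84.059    67.073    1.2533  0.2306
#> 3           scutum_mm_male   -5.589     9.106   -0.6137  0.5492
#> 4           scutum_mm_diff  -21.956    33.741   -0.6507  0.5258
```

Read across the rows: in this simulated panel males take ~6.3 h longer in
the pupal stage (4.2%, p = 0.039) while larval time does not differ — and
the PGLS finds no significant effect of sternite-complexity dimorphism on
that pupal-duration difference once body size and size dimorphism are in
the model (this panel was generated with no complexity cost, so that is
the correct answer). `tidy()`, `glance()`, and `anova()` give the fit as
tibbles; `autoplot()` and `plot_reconstructions()` draw results.

`run_full_analysis(run_config(...))` chains all stages — optional outline
scoring, panel summary, sex-difference tests, correlations, and a list of
PGLS models — and can write every table plus a JSON run log to a directory.

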