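#' Specification of a synthetic band-limited shape
#'
#' Shapes are built directly in Fourier space: harmonic 1 is an ellipse
#' with the given semi-axes, and each perturbation adds a quadruple of
#' amplitude `amplitude` at `harmonic` (with phase rotating energy between
#' the cosine and sine terms). Because the injected spectral energy is
#' exact, the zero law and amplitude monotonicity of the complexity score
#' are analytic properties of the generated shapes.
#'
#' Amplitudes above `minor_axis / (2 * harmonic)` can make the curve
#' self-intersect; generation then warns (or errors with
#' `on_unsafe = "error"`).
#'
#' @param axes Ellipse semi-axes (px), length 2.
#' @param perturb A data frame with columns `harmonic` (integer >= 2),
#'   `amplitude` (>= 0, same pixel units as `axes`) and optionally `phase`
#'   (radians, default 0).
#' @param n_points Vertices of the emitted outline (equal parameter steps).
#' @param rotation Rigid rotation of the whole shape, radians.
#' @param center Translation, length 2.
#' @return An object of class `shape_spec`.
#' @export
shape_spec <- function(axes = c(100, 60), perturb = NULL, n_points = 4096L,
                       rotation = 0, center = c(0, 0)) {
  stopifnot(length(axes) == 2, all(axes > 0), n_points >= 64)
  if (!is.null(perturb)) {
    stopifnot(is.data.frame(perturb),
              all(c("harmonic", "amplitude") %in% names(perturb)))
    if (any(perturb$harmonic < 2)) abort("perturbation harmonics must be >= 2")
    if (any(perturb$amplitude < 0)) abort("amplitudes must be >= 0")
    if (is.null(perturb$phase)) perturb$phase <- 0
  }
  structure(list(axes = as.double(axes), perturb = perturb,
                 n_points = as.integer(n_points), rotation = rotation,
                 center = as.double(center)),
            class = "shape_spec")
}

#' Generate a synthetic outline from a shape specification
#'
#' @param spec A [shape_spec()].
#' @param on_unsafe What to do when an amplitude exceeds the documented
#'   safe bound `minor_axis / (2 * harmonic)`: `"warn"` (default) or
#'   `"error"`.
#' @param source_id Provenance label.
#' @return An [outline] sampled at `spec$n_points` equal parameter steps.
#' @examples
#' sh <- make_shape(shape_spec(axes = c(2, 1),
#'                             perturb = data.frame(harmonic = 20, amplitude = 0.05)))
#' @export
make_shape <- function(spec, on_unsafe = c("warn", "error"),
                       source_id = "synthetic_shape") {
  stopifnot(inherits(spec, "shape_spec"))
  on_unsafe <- match.arg(on_unsafe)
  t <- seq(0, 2 * pi, length.out = spec$n_points + 1L)[-(spec$n_points + 1L)]
  x <- spec$center[1] + spec$axes[1] * cos(t)
  y <- spec$center[2] + spec$axes[2] * sin(t)
  if (!is.null(spec$perturb)) {
    safe <- min(spec$axes) / (2 * spec$perturb$harmonic)
    if (any(spec$perturb$amplitude > safe)) {
      msg <- "perturbation amplitude exceeds the self-intersection safe bound"
      if (on_unsafe == "error") abort(msg) else warn(msg)
    }
    for (i in seq_len(nrow(spec$perturb))) {
      n <- spec$perturb$harmonic[i]
      amp <- spec$perturb$amplitude[i]
      ph <- spec$perturb$phase[i]
      # quadruple (amp*cos(ph), amp*sin(ph)) on x and the quadrature pair on y
      x <- x + amp * cos(n * t + ph)
      y <- y + amp * sin(n * t + ph)
    }
  }
  if (spec$rotation != 0) {
    cs <- cos(spec$rotation); sn <- sin(spec$rotation)
    xr <- spec$center[1] + cs * (x - spec$center[1]) - sn * (y - spec$center[2])
    yr <- spec$center[2] + sn * (x - spec$center[1]) + cs * (y - spec$center[2])
    x <- xr; y <- yr
  }
  new_outline(x, y, source_id = source_id, simple = NA)
}

#' Simulate an ultrametric Yule tree
#'
#' Pure-birth tree with the total depth rescaled to 1; reproducible for a
#' fixed seed.
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed Integer seed.
#' @return A `phylo` tree with tips `t1..tn` and depth 1.
#' @export
make_tree <- function(n_tips, seed = 1L) {
  if (n_tips < 2) abort("n_tips must be >= 2")
  tr <- with_seed(seed, ape::rphylo(n_tips, birth = 1, death = 0))
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate tip values under lambda-scaled Brownian motion
#'
#' Draws y = beta * x + e with e ~ N(0, sigma2 * V_lambda), V_lambda the
#' Pagel-transformed Brownian covariance of the tree — exactly the
#' generative model PGLS assumes.
#'
#' @param tree A `phylo` tree.
#' @param beta Regression slope.
#' @param x Tip covariate (named by tip or in tip order); scalar 0 gives a
#'   pure Brownian draw.
#' @param sigma2 Residual rate (> 0).
#' @param lambda Pagel's lambda in \[0, 1\].
#' @param seed Integer seed.
#' @return Named numeric vector of tip values.
#' @export
simulate_brownian <- function(tree, beta = 0, x = 0, sigma2 = 1, lambda = 1,
                              seed = 1L) {
  if (sigma2 <= 0) abort("sigma2 must be positive")
  V <- pagel_transform(brownian_vcv(tree), lambda)
  n <- nrow(V)
  if (length(x) == 1) x <- rep(x, n)
  if (!is.null(names(x))) x <- x[rownames(V)]
  L <- chol(V)
  z <- with_seed(seed, rnorm(n))
  setNames(as.vector(beta * x + sqrt(sigma2) * crossprod(L, z)), rownames(V))
}

#' Default panel specification emulating the sepsid study design
#'
#' The defaults are the study conditions: 18 species, both sexes,
#' female-biased size dimorphism (mean male - female scutum width
#' -0.134 mm), no larval-duration difference (-0.55 h), a male-biased
#' pupal-duration difference (+7.42 h), male-biased trait complexity, and
#' trait areas scaling with body size. Between-species spreads of the sex
#' differences are derived from the corresponding 95% confidence intervals
#' (sd = CI * sqrt(n) / t(0.975, n-1)), e.g. 9.05 h for the pupal
#' difference. Species means evolve on a Yule tree with Pagel's lambda
#' `lambda_signal` (default 0: most fitted models in this clade show no
#' phylogenetic signal).
#'
#' @param n_species Species count.
#' @param n_per_sex Individuals measured per species and sex.
#' @param effects Named list of sex-difference means (male - female):
#'   `scutum_mm`, `larval_h`, `pupal_h`, `sternite_complexity`,
#'   `femur_complexity`, `clasper_complexity`, `sternite_area`,
#'   `femur_area`.
#' @param effect_sds Named list of between-species sds of those differences.
#' @param baselines Named list of female baseline means:
#'   `scutum_mm`, `larval_h`, `pupal_h`, `pupal_width_mm`,
#'   `pupal_length_mm`, complexities and areas.
#' @param baseline_sds Between-species sds of the baselines.
#' @param allometry Slope of trait area (mm^2) on scutum width (mm).
#' @param size_coupling Correlation between a species' ornament-area
#'   dimorphism and its body size: species with larger bodies carry
#'   disproportionately larger male trait areas, reproducing the positive
#'   across-species correlations among trait-size means.
#' @param complexity_pupal_slope Developmental-cost coupling: hours of extra
#'   male pupal duration per unit of male - female sternite-complexity
#'   difference (0 = no cost, the null structure).
#' @param individual_cv Within-species coefficient of variation of
#'   individual measurements around the species-sex mean.
#' @param lambda_signal Pagel's lambda of the Brownian component of the
#'   species means.
#' @param tree `"yule"` or a `phylo` tree with `n_species` tips.
#' @param seed Integer seed.
#' @return An object of class `panel_spec`.
#' @export
panel_spec <- function(n_species = 18L,
                       n_per_sex = 10L,
                       effects = list(scutum_mm = -0.134, larval_h = -0.55,
                                      pupal_h = 7.42,
                                      sternite_complexity = 0.029,
                                      femur_complexity = 0.024,
                                      clasper_complexity = 0.231,
                                      sternite_area = 0.62,
                                      femur_area = 0.002),
                       effect_sds = list(scutum_mm = 0.0845, larval_h = 4.59,
                                         pupal_h = 9.05,
                                         sternite_complexity = 0.032,
                                         femur_complexity = 0.016,
                                         clasper_complexity = 0.070,
                                         sternite_area = 1.17,
                                         femur_area = 0.012),
                       baselines = list(scutum_mm = 1.2, larval_h = 210,
                                        pupal_h = 158, pupal_width_mm = 0.9,
                                        pupal_length_mm = 2.3,
                                        sternite_complexity = 0.08,
                                        femur_complexity = 0.06,
                                        clasper_complexity = 0,
                                        sternite_area = 0.35,
                                        femur_area = 0.05),
                       baseline_sds = list(scutum_mm = 0.25, larval_h = 45,
                                           pupal_h = 35, pupal_width_mm = 0.12,
                                           pupal_length_mm = 0.3,
                                           sternite_complexity = 0.03,
                                           femur_complexity = 0.02,
                                           clasper_complexity = 0,
                                           sternite_area = 0.12,
                                           femur_area = 0.02),
                       allometry = 0.3,
                       size_coupling = 0.6,
                       complexity_pupal_slope = 0,
                       individual_cv = 0.05,
                       lambda_signal = 0,
                       tree = "yule",
                       seed = 1L) {
  stopifnot(n_species >= 2, n_per_sex >= 1,
            all(unlist(effect_sds) >= 0), all(unlist(baseline_sds) >= 0),
            individual_cv >= 0, lambda_signal >= 0, lambda_signal <= 1)
  structure(list(n_species = as.integer(n_species),
                 n_per_sex = as.integer(n_per_sex),
                 effects = effects, effect_sds = effect_sds,
                 baselines = baselines, baseline_sds = baseline_sds,
                 allometry = allometry, size_coupling = size_coupling,
                 complexity_pupal_slope = complexity_pupal_slope,
                 individual_cv = individual_cv,
                 lambda_signal = lambda_signal, tree = tree,
                 seed = as.integer(seed)),
            class = "panel_spec")
}

#' Simulate an individual-level study panel
#'
#' Generates species means with the configured sex effects and Brownian
#' phylogenetic structure on the tree, then draws individuals around each
#' species-by-sex mean. The individual table satisfies the morphometrics
#' input schema directly; clasper records exist only for males.
#'
#' @param spec A [panel_spec()].
#' @return A list with `individuals` (tibble of individual records),
#'   `species_means` (the generating species-by-sex means, wide tibble) and
#'   `tree` (`phylo`).
#' @export
make_species_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  with_seed(spec$seed, {
    n_sp <- spec$n_species
    tr <- if (identical(spec$tree, "yule")) {
      tr0 <- ape::rphylo(n_sp, birth = 1, death = 0)
      tr0$edge.length <- tr0$edge.length / max(ape::node.depth.edgelength(tr0))
      tr0
    } else spec$tree
    sp <- tr$tip.label
    V <- pagel_transform(brownian_vcv(tr), spec$lambda_signal)
    Lt <- chol(V)
    draw_species <- function(mu, sdev) {
      if (sdev == 0) return(setNames(rep(mu, n_sp), sp))
      setNames(mu + sdev * as.vector(crossprod(Lt, rnorm(n_sp))), sp)
    }

    quantities <- names(spec$baselines)
    female <- purrr::map(setNames(quantities, quantities), function(q) {
      draw_species(spec$baselines[[q]], spec$baseline_sds[[q]])
    })
    # trait areas scale with body size (allometry on the female baseline)
    for (q in c("sternite_area", "femur_area")) {
      female[[q]] <- female[[q]] +
        spec$allometry * (female$scutum_mm - spec$baselines$scutum_mm)
    }
    male <- female
    z_size <- if (spec$baseline_sds$scutum_mm > 0) {
      (female$scutum_mm - spec$baselines$scutum_mm) / spec$baseline_sds$scutum_mm
    } else rep(0, n_sp)
    rho <- spec$size_coupling
    for (q in names(spec$effects)) {
      eff <- draw_species(spec$effects[[q]], spec$effect_sds[[q]])
      if (q %in% c("sternite_area", "femur_area") && rho > 0) {
        # ornament-area dimorphism rides on body size: bigger species have
        # disproportionately bigger male trait areas
        eff <- spec$effects[[q]] + spec$effect_sds[[q]] *
          (rho * z_size + sqrt(1 - rho^2) * (eff - spec$effects[[q]]) /
             max(spec$effect_sds[[q]], 1e-12))
      }
      male[[q]] <- female[[q]] + eff
    }
    if (spec$complexity_pupal_slope != 0) {
      # developmental cost: complex male sternites prolong male metamorphosis
      male$pupal_h <- male$pupal_h + spec$complexity_pupal_slope *
        (male$sternite_complexity - female$sternite_complexity)
    }
    # durations and sizes stay non-negative
    for (q in quantities) {
      female[[q]] <- pmax(female[[q]], 0)
      male[[q]] <- pmax(male[[q]], 0)
    }
    male$clasper_area <- pmax(0.1 * male$scutum_mm +
                                0.02 * rnorm(n_sp), 0.001)
    male$clasper_complexity <- pmax(male$clasper_complexity, 0.01)

    means <- dplyr::bind_rows(
      tibble(species = sp, sex = "female", !!!female[quantities]),
      tibble(species = sp, sex = "male",
             !!!male[c(quantities, "clasper_area")]))
    means$clasper_complexity[means$sex == "female"] <- NA_real_

    draw_ind <- function(mu) {
      if (is.na(mu)) return(rep(NA_real_, spec$n_per_sex))
      s <- spec$individual_cv * abs(mu)
      pmax(mu + s * rnorm(spec$n_per_sex), 0)
    }
    ind_cols <- c("larval_h", "pupal_h", "pupal_width_mm", "pupal_length_mm",
                  "scutum_mm", "sternite_area", "femur_area", "clasper_area",
                  "sternite_complexity", "femur_complexity",
                  "clasper_complexity")
    male_only <- c("clasper_area", "clasper_complexity")
    individuals <- purrr::pmap_dfr(means, function(...) {
      row <- list(...)
      draws <- purrr::map(setNames(ind_cols, ind_cols), function(q) {
        if (row$sex == "female" && q %in% male_only) {
          rep(NA_real_, spec$n_per_sex)
        } else draw_ind(row[[q]])
      })
      tibble(species = row$species, sex = row$sex,
             individual = seq_len(spec$n_per_sex), !!!draws)
    }) |>
      dplyr::mutate(total_h = .data$larval_h + .data$pupal_h)

    list(individuals = individuals, species_means = means, tree = tr)
  })
}
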