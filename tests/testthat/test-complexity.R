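test_that("congruence areas do rectangle arithmetic and satisfy the union identity", {
  a <- outline(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(congruence_areas(a, a),
               c(congruent = 1, noncongruent = 0), tolerance = 1e-9)

  b <- outline(c(0.5, 1.5, 1.5, 0.5), c(0, 0, 1, 1))
  ab <- congruence_areas(a, b)
  expect_equal(ab[["congruent"]], 0.5, tolerance = 1e-9)
  expect_equal(ab[["noncongruent"]], 1.0, tolerance = 1e-9)
  uni <- ornametrics:::polyclip_area(list(x = a$x, y = a$y),
                                     list(x = b$x, y = b$y), "union")
  expect_equal(sum(ab), uni, tolerance = 1e-9 * uni)

  far <- outline(c(10, 11, 11, 10), c(0, 0, 1, 1))
  expect_error(congruence_areas(a, far),
               class = "ornametrics_degenerate_congruence")
})

test_that("vector and raster congruence agree on random convex polygons", {
  set.seed(21)
  for (k in 1:5) {
    # random convex polygon pair: convex hulls of point clouds
    p1 <- matrix(rnorm(40, sd = 30), ncol = 2)
    p2 <- matrix(rnorm(40, c(10, 5), sd = 25), ncol = 2)
    h1 <- p1[chull(p1), ]; h2 <- p2[chull(p2), ]
    a <- outline(h1[, 1], h1[, 2]); b <- outline(h2[, 1], h2[, 2])
    v <- congruence_areas(a, b)
    r <- raster_congruence_areas(a, b, resolution = 1024)
    expect_equal(r[["congruent"]], v[["congruent"]],
                 tolerance = 0.002 * v[["congruent"]])
    expect_equal(r[["noncongruent"]], v[["noncongruent"]],
                 tolerance = 0.002 * sum(v))
  }
})

test_that("band-limited shapes score zero: ellipse at any axes and rotation", {
  for (spec in list(shape_spec(axes = c(2, 1), rotation = 0.8),
                    shape_spec(axes = c(140, 35), rotation = 2.1,
                               center = c(300, -50)),
                    shape_spec(axes = c(60, 60)))) {
    cs <- complexity_score(make_shape(spec))
    expect_lt(cs$complexity, 1e-6)
  }
})

test_that("score increases strictly with injected high-harmonic amplitude and matches the raster oracle", {
  scores <- vapply(c(0.02, 0.05, 0.10), function(eps) {
    s <- suppressWarnings(
      make_shape(shape_spec(axes = c(2, 1),
                            perturb = data.frame(harmonic = 20,
                                                 amplitude = eps * 1))))
    complexity_score(s)$complexity
  }, numeric(1))
  expect_true(all(diff(scores) > 0))

  s <- make_shape(shape_spec(axes = c(200, 100),
                             perturb = data.frame(harmonic = 20, amplitude = 2)))
  cs <- complexity_score(s, n_points = 2048)
  ef <- efa(s, 1000)
  r <- raster_congruence_areas(reconstruct(ef, 8, 2048),
                               reconstruct(ef, 1000, 2048), resolution = 1024)
  expect_equal(cs$complexity, r[["noncongruent"]] / r[["congruent"]],
               tolerance = 0.01 * cs$complexity)
})

test_that("the score is invariant under similarity transforms of the outline", {
  base <- shape_spec(axes = c(2, 1),
                     perturb = data.frame(harmonic = c(11, 20),
                                          amplitude = c(0.03, 0.02),
                                          phase = c(0.4, 1.3)))
  s0 <- complexity_score(make_shape(base))$complexity
  moved <- shape_spec(axes = c(2 * 7, 1 * 7),
                      perturb = data.frame(harmonic = c(11, 20),
                                           amplitude = 7 * c(0.03, 0.02),
                                           phase = c(0.4, 1.3)),
                      rotation = 1.1, center = c(500, 900))
  s1 <- complexity_score(make_shape(moved))$complexity
  expect_equal(s1, s0, tolerance = 1e-6)
  expect_gt(s0, 0)
})

test_that("zero law: energy above h_low below 1e-12 of total scores ~0", {
  s <- make_shape(shape_spec(axes = c(2, 1),
                             perturb = data.frame(harmonic = 6, amplitude = 0.05)))
  ef <- efa(s, 1000)
  pw <- harmonic_power(ef)
  expect_lt(sum(pw[9:1000]) / sum(pw), 1e-12)
  expect_lt(complexity_score(s)$complexity, 1e-6)
})

test_that("score_outlines carries manifest ids through batch scoring", {
  manifest <- tibble::tibble(
    species = c("A", "B"), sex = "male", trait = "clasper",
    outline = list(
      make_shape(shape_spec(axes = c(2, 1)), source_id = "A"),
      make_shape(shape_spec(axes = c(2, 1),
                            perturb = data.frame(harmonic = 15, amplitude = 0.03)),
                 source_id = "B")))
  sc <- score_outlines(manifest, h_high = 500)
  expect_named(sc, c("species", "sex", "trait", "h_low", "h_high",
                     "congruent_area", "noncongruent_area", "complexity"))
  expect_lt(sc$complexity[1], 1e-6)
  expect_gt(sc$complexity[2], sc$complexity[1])
})

test_that("female-baseline normalization applies the P. dikowi sternite exception", {
  r <- normalize_dimorphism(0.30, 0.20, "Sepsis cynipsea", "sternite")
  expect_equal(r$normalized, 1.5)

  r2 <- normalize_dimorphism(0.27, NA, "Perochaeta dikowi", "sternite")
  expect_equal(r2$female_score, 1)
  expect_equal(r2$normalized, 0.27)

  expect_error(normalize_dimorphism(0.3, 0, "Sepsis fulgens", "sternite"),
               "female baseline")
  expect_error(normalize_dimorphism(0.3, NA, "Perochaeta dikowi", "fore_femur"),
               "female baseline")
  expect_error(normalize_dimorphism(0.3, 0.2, "Sepsis fulgens", "clasper"),
               "clasper")
})

test_that("per-species sex differences drop and report single-sex species", {
  panel <- tibble::tibble(
    species = c("A", "A", "B", "B", "C"),
    sex = c("male", "female", "male", "female", "male"),
    trait = "sternite",
    complexity = c(0.5, 0.3, 0.4, 0.4, 0.9))
  expect_message(d <- sex_complexity_difference(panel), "excluded.*C")
  expect_equal(d$difference[d$species == "A"], 0.2)
  expect_equal(d$difference[d$species == "B"], 0)
  expect_false("C" %in% d$species)
  expect_error(sex_complexity_difference(panel[0, ]), "empty")
})

test_that("a synthetic 18-species panel recovers its built-in mean complexity difference", {
  set.seed(77)
  truth <- 0.23
  diffs <- truth + rnorm(18, sd = 0.05)
  panel <- tibble::tibble(
    species = rep(sprintf("sp%02d", 1:18), each = 2),
    sex = rep(c("male", "female"), 18),
    trait = "clasper",
    complexity = as.vector(rbind(0.3 + diffs, 0.3)))
  d <- sex_complexity_difference(panel)
  t <- one_sample_t(d$difference)
  expect_lt(abs(t$mean - truth), 3 * 0.05 / sqrt(18))
})
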