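test_that("read_newick parses, validates, and round-trips path lengths", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  V <- brownian_vcv(tr)
  expect_equal(unname(diag(V)), rep(2, 3))  # root depth 2 for every tip

  expect_error(read_newick("(A:1,B:1"), "parse")
  expect_error(read_newick("(A:1,A:1);"), "unique")

  tr2 <- make_tree(17, seed = 4)
  f <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tr2, f)
  back <- read_newick(f)
  D1 <- ape::cophenetic.phylo(tr2)
  D2 <- ape::cophenetic.phylo(back)
  expect_equal(D2[rownames(D1), colnames(D1)], D1, tolerance = 1e-9)
})

test_that("Brownian VCV equals shared root-to-MRCA path lengths", {
  V <- brownian_vcv(read_newick("(A:1,B:1);"))
  expect_equal(unname(V), diag(2))

  V3 <- brownian_vcv(read_newick("((A:1,B:1):1,C:2);"))
  expect_equal(V3["A", "A"], 2)
  expect_equal(V3["A", "B"], 1)
  expect_equal(V3["A", "C"], 0)
  expect_equal(V3["C", "C"], 2)

  tr <- make_tree(20, seed = 8)
  V <- brownian_vcv(tr)
  Vb <- oracle_vcv(tr)
  expect_equal(V[rownames(Vb), colnames(Vb)], Vb, tolerance = 1e-12)
})

test_that("Pagel transform scales off-diagonals only", {
  V <- brownian_vcv(read_newick("((A:1,B:1):1,C:2);"))
  expect_equal(pagel_transform(V, 1), V)
  expect_equal(pagel_transform(V, 0), diag(diag(V)), ignore_attr = TRUE)
  expect_equal(pagel_transform(V, 0.5)["A", "B"], 0.5)
  expect_equal(pagel_transform(V, 0.5)["A", "A"], 2)
  expect_error(pagel_transform(V, 1.2), "\\[0, 1\\]")
})

test_that("GLS reduces to OLS on star trees and at lambda = 0", {
  set.seed(31)
  star <- ape::stree(12, "star")
  star$edge.length <- rep(1, nrow(star$edge))
  d <- data.frame(species = star$tip.label, x = rnorm(12))
  d$y <- 1 + 0.5 * d$x + rnorm(12, sd = 0.3)
  ols <- lm(y ~ x, d)
  for (lam in c(0, 0.6, 1)) {
    f <- pgls(d, y ~ x, star, lambda = lam)
    expect_equal(unname(f$coef), unname(coef(ols)), tolerance = 1e-8)
    expect_equal(unname(f$se), unname(sqrt(diag(vcov(ols)))), tolerance = 1e-8)
  }

  tr <- make_tree(15, seed = 2)  # ultrametric
  d2 <- data.frame(species = tr$tip.label, x = rnorm(15))
  d2$y <- 2 - 0.8 * d2$x + rnorm(15, sd = 0.5)
  f0 <- pgls(d2, y ~ x, tr, lambda = 0)
  ols2 <- lm(y ~ x, d2)
  expect_equal(unname(f0$coef), unname(coef(ols2)), tolerance = 1e-8)
  av <- anova(f0)
  av_lm <- stats::anova(ols2)
  expect_equal(av$ss[1:2], av_lm[["Sum Sq"]], tolerance = 1e-8)
  expect_equal(av$p[1], av_lm[["Pr(>F)"]][1], tolerance = 1e-8)
})

test_that("coefficients are invariant to rescaling all branch lengths", {
  tr <- make_tree(20, seed = 13)
  x <- rnorm(20)
  y <- simulate_brownian(tr, 0.7, setNames(x, tr$tip.label), 0.5, 1, seed = 5)
  d <- data.frame(species = tr$tip.label, x = x, y = as.vector(y[tr$tip.label]))
  f1 <- pgls(d, y ~ x, tr, lambda = 1)
  tr2 <- tr
  tr2$edge.length <- tr$edge.length * 37.5
  f2 <- pgls(d, y ~ x, tr2, lambda = 1)
  expect_equal(f2$coef, f1$coef, tolerance = 1e-8)
  expect_equal(f2$sigma2, f1$sigma2 / 37.5, tolerance = 1e-8)
})

test_that("ML lambda and the full fit match an independent GLS implementation", {
  skip_if_not_installed("nlme")
  tr <- make_tree(30, seed = 5)
  x <- simulate_brownian(tr, 0, 0, 1, 1, seed = 9)
  y <- simulate_brownian(tr, 0.5, x, 0.3, 1, seed = 10)
  d <- data.frame(species = names(x), x = as.vector(x), y = as.vector(y))
  f <- pgls(d, y ~ x, tr, lambda = "ML")
  g <- nlme::gls(y ~ x, data = d,
                 correlation = ape::corPagel(0.5, tr, form = ~species),
                 method = "ML")
  lam_nlme <- stats::coef(g$modelStruct$corStruct, unconstrained = FALSE)
  expect_equal(f$lambda, unname(lam_nlme), tolerance = 1e-4)
  expect_equal(unname(f$coef), unname(coef(g)), tolerance = 1e-6)
  expect_equal(f$logLik, as.numeric(stats::logLik(g)), tolerance = 1e-6)
})

test_that("species missing from the tree are pruned with a warning", {
  tr <- make_tree(10, seed = 1)
  d <- data.frame(species = c(tr$tip.label, "Meroplius_sauteri"),
                  x = rnorm(11), y = rnorm(11))
  expect_warning(f <- pgls(d, y ~ x, tr), "Meroplius_sauteri")
  expect_equal(f$n, 10)
  expect_error(pgls(d[11, ], y ~ x, tr), "too few species")
  d$x2 <- d$x
  expect_error(suppressWarnings(pgls(d, y ~ x + x2, tr)), "singular")
})

test_that("sequential ANOVA sums of squares add to the total generalized SS", {
  tr <- make_tree(18, seed = 23)
  set.seed(23)
  d <- data.frame(species = tr$tip.label, x1 = rnorm(18), x2 = rnorm(18))
  d$y <- 0.5 * d$x1 - 0.2 * d$x2 +
    as.vector(simulate_brownian(tr, 0, 0, 0.4, 1, seed = 3)[tr$tip.label])
  f <- pgls(d, y ~ x1 + x2, tr, lambda = 0.7)
  av <- anova(f)
  # total generalized SS about the GLS mean
  V <- pagel_transform(brownian_vcv(f$tree), 0.7)
  L <- chol(V)
  wy <- backsolve(L, d$y[match(f$tree$tip.label, d$species)], transpose = TRUE)
  w1 <- backsolve(L, rep(1, 18), transpose = TRUE)
  tot <- sum((wy - w1 * sum(w1 * wy) / sum(w1^2))^2)
  expect_equal(sum(av$ss), tot, tolerance = 1e-8)
})

test_that("lambda profile identifies simulated signal regimes", {
  tr <- make_tree(40, seed = 90)
  hits0 <- 0; hits1 <- 0
  n_rep <- 25
  for (k in seq_len(n_rep)) {
    y0 <- simulate_brownian(tr, 0, 0, 1, lambda = 0, seed = 1000 + k)
    y1 <- simulate_brownian(tr, 0, 0, 1, lambda = 1, seed = 2000 + k)
    d0 <- data.frame(species = names(y0), y = as.vector(y0))
    d1 <- data.frame(species = names(y1), y = as.vector(y1))
    l0 <- pgls(d0, y ~ 1, tr, lambda = "ML")$lambda
    l1 <- pgls(d1, y ~ 1, tr, lambda = "ML")$lambda
    hits0 <- hits0 + (l0 <= 0.2)
    hits1 <- hits1 + (l1 >= 0.8)
  }
  expect_gte(hits0 / n_rep, 0.9)
  expect_gte(hits1 / n_rep, 0.9)

  prof <- lambda_profile(d0, y ~ 1, tr, grid = c(0, 1))
  expect_equal(nrow(prof), 2)
  expect_true(attr(prof, "lambda_hat") %in% c(0, 1))
})

test_that("tidy and glance expose the fit in broom style", {
  tr <- make_tree(12, seed = 3)
  set.seed(3)
  d <- data.frame(species = tr$tip.label, x = rnorm(12))
  d$y <- d$x + rnorm(12)
  f <- pgls(d, y ~ x, tr, lambda = 0.5)
  td <- tidy(f)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_equal(nrow(td), 2)
  gl <- glance(f)
  expect_equal(gl$lambda, 0.5)
  expect_equal(gl$n, 12)
})
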