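test_that("a circle is a single-harmonic curve with a rotation-like quadruple", {
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  circ <- outline(cos(th), sin(th))
  ef <- efa(circ, 8)
  pw <- harmonic_power(ef)
  expect_gte(pw[1] / sum(pw), 0.999)
  # quadruple is a rotation/reflection of diag(1, 1): orthogonal with norm 1
  M <- matrix(ef$coef[1, ], 2, 2, byrow = TRUE)
  expect_equal(crossprod(M), diag(2), tolerance = 1e-4)
})

test_that("an ellipse sampled at its natural parameter is exactly harmonic 1", {
  ell <- make_shape(shape_spec(axes = c(2, 1), n_points = 1024))
  ef <- efa(ell, 8)
  pw <- harmonic_power(ef)
  expect_lt(sum(pw[-1]) / pw[1], 1e-24)
  r1 <- reconstruct(ef, 1, 1024)
  r8 <- reconstruct(ef, 8, 1024)
  expect_equal(r8$x, r1$x, tolerance = 1e-6)
  expect_equal(r8$y, r1$y, tolerance = 1e-6)
  expect_equal(polygon_area(r1), 2 * pi, tolerance = 5e-3)
})

test_that("square spectrum: odd harmonics only, ~n^-4 power decay, matches the exact integral oracle", {
  sq <- resample_outline(outline(c(0, 1, 1, 0), c(0, 0, 1, 1)), 4096)
  ef <- efa(sq, 20)
  pw <- harmonic_power(ef)
  even <- pw[seq(2, 20, by = 2)]
  odd_idx <- c(3, 5, 7)  # 4-fold symmetric square: energy at h = 4k +/- 1
  expect_lt(max(even) / pw[1], 1e-12)
  # power decay ~ n^-4 among the populated harmonics
  decay <- pw[odd_idx] * odd_idx^4
  expect_lt(max(decay) / min(decay), 3)

  oracle <- oracle_efa_uniform(sq$x, sq$y, 20)
  # the oracle integrates the piecewise-linear interpolant exactly; on a
  # 4096-point resampled square the two agree to the interpolation error
  expect_equal(ef$coef[pw > 1e-12, ], oracle[pw > 1e-12, ], tolerance = 1e-3)
})

test_that("coefficients agree with the exact integral oracle on random band-limited shapes", {
  for (seed in 1:5) {
    b <- random_blob(seed, n_points = 1024)
    n <- nrow(b)
    ef <- efa(b, 16)
    oracle <- oracle_efa_uniform(b$x, b$y, 16)
    # undo the exact sinc^2 attenuation of linear interpolation so the
    # oracle reports the band-limited curve's own coefficients
    h <- 1:16
    corr <- (sin(pi * h / n) / (pi * h / n))^2
    expect_equal(ef$coef, oracle / corr, tolerance = 1e-6)
  }
})

test_that("reconstruction is exact on band-limited sources and idempotent", {
  b <- random_blob(42, n_points = 2048)
  ef <- efa(b, 64)
  back <- reconstruct(ef, 64, nrow(b))
  expect_equal(back$x, b$x, tolerance = 1e-6 * max(abs(b$x)))
  expect_equal(back$y, b$y, tolerance = 1e-6 * max(abs(b$y)))

  p8 <- reconstruct(ef, 8, 512)
  ef2 <- efa(p8, 8)
  p8_again <- reconstruct(ef2, 8, 512)
  expect_equal(p8_again$x, p8$x, tolerance = 1e-9 * max(abs(p8$x)))
})

test_that("more harmonics never increase the squared deviation from the source", {
  sq <- resample_outline(outline(c(0, 1, 1, 0), c(0, 0, 1, 1)), 1024)
  ef <- efa(sq, 512)
  msd <- function(h) {
    r <- reconstruct(ef, h, 1024)
    mean((r$x - sq$x)^2 + (r$y - sq$y)^2)
  }
  errs <- vapply(c(1, 2, 4, 8, 16, 64, 256, 512), msd, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
  expect_lt(errs[length(errs)], errs[4])  # 1000-harmonic-style fit beats 8
})

test_that("similarity transforms act on coefficients as expected", {
  b <- random_blob(7, n_points = 512)
  ef <- efa(b, 16)
  th <- 0.9; sc <- 2.5; shift <- c(13, -4)
  xr <- sc * (cos(th) * b$x - sin(th) * b$y) + shift[1]
  yr <- sc * (sin(th) * b$x + cos(th) * b$y) + shift[2]
  ef2 <- efa(outline(xr, yr), 16)
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  for (h in c(1, 5, 16)) {
    M <- matrix(ef$coef[h, ], 2, 2, byrow = TRUE)   # rows: (a,b), (c,d)
    M2 <- matrix(ef2$coef[h, ], 2, 2, byrow = TRUE)
    expect_equal(M2, sc * R %*% M, tolerance = 1e-8)
  }
  expect_equal(c(ef2$A0, ef2$C0),
               as.vector(sc * R %*% c(ef$A0, ef$C0) + shift), tolerance = 1e-8)
})

test_that("harmonic energy injected by construction is reported exactly", {
  eps <- 0.35
  ph <- 0.6
  s <- make_shape(shape_spec(axes = c(100, 60),
                             perturb = data.frame(harmonic = 20, amplitude = eps,
                                                  phase = ph),
                             n_points = 1024))
  ef <- efa(s, 32)
  pw <- harmonic_power(ef)
  expect_equal(pw[20], eps^2, tolerance = 1e-9)  # two unit-quadrature terms: (e^2+e^2)/2
  expect_lt(max(pw[setdiff(2:32, 20)]), 1e-20)
})

test_that("Nyquist bound and degenerate inputs error", {
  th <- seq(0, 2 * pi, length.out = 65)[-65]
  circ <- outline(cos(th), sin(th))
  expect_error(efa(circ, 40, n_points = 64), "Nyquist")
  ef <- efa(circ, 8)
  expect_error(reconstruct(ef, 9), "1\\.\\.8")
  expect_error(reconstruct(ef, 8, n_points = 10), "too small")
})

test_that("EFA series round-trip through CSV", {
  b <- random_blob(3, n_points = 512)
  ef <- efa(b, 12)
  f <- withr::local_tempfile(fileext = ".csv")
  write_efa_csv(ef, f)
  ef2 <- read_efa_csv(f)
  expect_equal(ef2$coef, ef$coef, ignore_attr = TRUE)
  expect_equal(ef2$A0, ef$A0)
  td <- tidy(ef)
  expect_named(td, c("harmonic", "a", "b", "c", "d", "power"))
  expect_equal(td$power, harmonic_power(ef))
})
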