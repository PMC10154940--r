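#' Elliptic Fourier decomposition of a closed outline
#'
#' Expands the coordinate functions x(t), y(t) of a closed outline in a
#' Fourier series: harmonic n contributes a quadruple (a_n, b_n, c_n, d_n),
#'
#'   x(t) = A0 + sum_n a_n cos(nt) + b_n sin(nt)
#'   y(t) = C0 + sum_n c_n cos(nt) + d_n sin(nt),   t in [0, 2*pi).
#'
#' The Fourier parameter is the vertex sequence: vertices are treated as
#' equally spaced in t, and coefficients are the spectral (trapezoid-rule)
#' integrals, i.e. the DFT of the coordinate sequences. For a digitized
#' trace this means the outline should be (and, when its vertex count is
#' below the Nyquist requirement, automatically is) resampled to equal arc
#' length first — giving the standard equal-arc elliptic Fourier fit. For
#' band-limited curves sampled at their own parameter (e.g. shapes from
#' [make_shape()] or [reconstruct()]) the expansion is exact to machine
#' precision, so truncation-based complexity scores have an analytic zero
#' law.
#'
#' @param x An [outline].
#' @param n_harmonics Number of harmonics N to retain (>= 1). Must satisfy
#'   the Nyquist bound N <= floor(n_points / 2).
#' @param n_points If supplied (or if the outline has fewer than
#'   `2 * n_harmonics + 2` vertices), the outline is resampled to this many
#'   equal-arc points before fitting (default 4096 when resampling is
#'   triggered implicitly).
#' @return An object of class `efa`: list with `A0`, `C0`, `coef` (an
#'   N-by-4 matrix with columns a, b, c, d), `n_points_fit`, `perimeter`.
#' @examples
#' circ <- make_shape(shape_spec(axes = c(1, 1), n_points = 256))
#' ef <- efa(circ, 8)
#' harmonic_power(ef)[1] / sum(harmonic_power(ef))  # ~1: a circle is harmonic 1
#' @export
efa <- function(x, n_harmonics, n_points = NULL) {
  stopifnot(inherits(x, "outline"))
  if (n_harmonics < 1) abort("n_harmonics must be >= 1")
  n_harmonics <- as.integer(n_harmonics)
  if (!is.null(n_points)) {
    x <- resample_outline(x, n_points)
  } else if (nrow(x) < 2L * n_harmonics + 2L) {
    x <- resample_outline(x, max(4096L, 2L * n_harmonics + 2L))
  }
  n <- nrow(x)
  if (n_harmonics > floor(n / 2)) {
    abort(sprintf("n_harmonics = %d exceeds the Nyquist bound floor(%d/2)",
                  n_harmonics, n))
  }
  per <- outline_perimeter(x)
  if (per <= 0) abort("degenerate outline: zero perimeter")

  # DFT of the coordinate sequences (trapezoid rule on a uniform periodic grid)
  fx <- stats::fft(x$x) / n
  fy <- stats::fft(x$y) / n
  idx <- seq_len(n_harmonics) + 1L
  co <- cbind(a = 2 * Re(fx[idx]), b = -2 * Im(fx[idx]),
              c = 2 * Re(fy[idx]), d = -2 * Im(fy[idx]))
  structure(
    list(A0 = Re(fx[1]), C0 = Re(fy[1]), coef = co,
         n_points_fit = n, perimeter = per,
         source_id = attr(x, "source_id")),
    class = "efa")
}

#' @export
print.efa <- function(x, ...) {
  cat(sprintf("<efa '%s'> %d harmonics fit on %d points, perimeter %.6g px\n",
              x$source_id %||% "outline", nrow(x$coef), x$n_points_fit, x$perimeter))
  invisible(x)
}

#' Reconstruct an outline from a truncated Fourier series
#'
#' Evaluates the series at `n_points` equal steps of the Fourier parameter,
#' using the first `n_harmonics` harmonics. With all harmonics of a
#' band-limited source, the source points are reproduced exactly.
#'
#' @param x An `efa` object.
#' @param n_harmonics Harmonics to use (1..N_max of the series).
#' @param n_points Points to sample; at least `max(64, 2 * n_harmonics)`.
#' @return An [outline].
#' @export
reconstruct <- function(x, n_harmonics = nrow(x$coef),
                        n_points = max(512L, 4L * n_harmonics)) {
  stopifnot(inherits(x, "efa"))
  n_max <- nrow(x$coef)
  if (n_harmonics < 1 || n_harmonics > n_max) {
    abort(sprintf("n_harmonics must be in 1..%d (series N_max)", n_max))
  }
  if (n_points < max(64, 2 * n_harmonics)) {
    abort("n_points too small for requested harmonics")
  }
  # inverse DFT: pack quadruples back into a complex spectrum
  n <- as.integer(n_points)
  sx <- complex(length.out = n)
  sy <- complex(length.out = n)
  sx[1] <- x$A0
  sy[1] <- x$C0
  h <- seq_len(n_harmonics)
  co <- x$coef[h, , drop = FALSE]
  sx[h + 1L] <- (co[, "a"] - 1i * co[, "b"]) / 2
  sy[h + 1L] <- (co[, "c"] - 1i * co[, "d"]) / 2
  sx[n + 1L - h] <- Conj(sx[h + 1L])
  sy[n + 1L - h] <- Conj(sy[h + 1L])
  if (n %% 2L == 0L && n_harmonics == n %/% 2L) {
    # Nyquist bin is its own conjugate: only the cosine term is representable
    sx[n %/% 2L + 1L] <- co[n_harmonics, "a"]
    sy[n %/% 2L + 1L] <- co[n_harmonics, "c"]
  }
  xs <- Re(stats::fft(sx, inverse = TRUE))
  ys <- Re(stats::fft(sy, inverse = TRUE))
  new_outline(xs, ys,
              source_id = paste0(x$source_id %||% "efa", "_h", n_harmonics))
}

#' Per-harmonic power of a Fourier series
#'
#' Power of harmonic n is (a_n^2 + b_n^2 + c_n^2 + d_n^2) / 2; the sequence
#' is used to check band-limitedness and energy decay of outlines.
#'
#' @param x An `efa` object.
#' @return Numeric vector of length N_max.
#' @export
harmonic_power <- function(x) {
  stopifnot(inherits(x, "efa"))
  unname(rowSums(x$coef^2) / 2)
}

#' @describeIn efa Tidy the coefficient quadruples into a tibble with
#'   columns `harmonic`, `a`, `b`, `c`, `d`, `power`.
#' @param ... Unused.
#' @method tidy efa
#' @export
tidy.efa <- function(x, ...) {
  tibble(harmonic = seq_len(nrow(x$coef)),
         a = x$coef[, "a"], b = x$coef[, "b"],
         c = x$coef[, "c"], d = x$coef[, "d"],
         power = harmonic_power(x))
}

#' Serialize / read a Fourier series as CSV
#'
#' Rows are (harmonic, a, b, c, d); the offset is stored as harmonic 0 with
#' (A0, 0, C0, 0).
#'
#' @param x An `efa` object.
#' @param path File path.
#' @return `path` invisibly / an `efa` object.
#' @export
write_efa_csv <- function(x, path) {
  stopifnot(inherits(x, "efa"))
  d <- rbind(data.frame(harmonic = 0, a = x$A0, b = 0, c = x$C0, d = 0),
             data.frame(harmonic = seq_len(nrow(x$coef)),
                        a = x$coef[, "a"], b = x$coef[, "b"],
                        c = x$coef[, "c"], d = x$coef[, "d"]))
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_efa_csv
#' @export
read_efa_csv <- function(path) {
  d <- read.csv(path)
  off <- d[d$harmonic == 0, ]
  h <- d[d$harmonic > 0, ]
  h <- h[order(h$harmonic), ]
  structure(
    list(A0 = off$a[1], C0 = off$c[1],
         coef = cbind(a = h$a, b = h$b, c = h$c, d = h$d),
         n_points_fit = NA_integer_, perimeter = NA_real_,
         source_id = basename(path)),
    class = "efa")
}
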