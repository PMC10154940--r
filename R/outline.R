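#' Construct a closed trait outline
#'
#' An `outline` is an ordered, closed sequence of 2-D vertices in pixel
#' units: the raw trace of a trait (a sternite brush, fore femur, or genital
#' clasper). The last vertex connects implicitly back to the first.
#' Construction validates and normalizes the trace: consecutive duplicate
#' vertices are collapsed, orientation is normalized to counter-clockwise
#' (positive signed area in a y-up frame), and self-intersections are
#' detected and flagged (not rejected, since hand traces can contain
#' micro-crossings).
#'
#' Image coordinates are taken as 0-based and y-down; the signed area used
#' for the orientation contract is computed after flipping to y-up, so
#' counter-clockwise on screen is positive.
#'
#' @param x,y Numeric vertex coordinates (pixel units), or `x` may be a
#'   two-column matrix/data frame with columns `x` and `y`.
#' @param source_id Free-text provenance label carried through scoring.
#' @return A tibble of class `outline` with columns `x`, `y` and attributes
#'   `source_id`, `closed` (always `TRUE`) and `simple` (`FALSE` when
#'   self-intersections were detected).
#' @examples
#' sq <- outline(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' polygon_area(sq)
#' @export
outline <- function(x, y = NULL, source_id = "outline") {
  if (is.null(y)) {
    m <- as.data.frame(x)
    if (!all(c("x", "y") %in% names(m))) {
      if (ncol(m) < 2) abort("need two coordinate columns", class = "ornametrics_malformed_outline")
      names(m)[1:2] <- c("x", "y")
    }
    x <- m$x
    y <- m$y
  }
  if (!is.numeric(x) || !is.numeric(y) || anyNA(x) || anyNA(y)) {
    abort("outline coordinates must be numeric and non-missing",
          class = "ornametrics_parse_error")
  }
  if (length(x) != length(y)) abort("x and y lengths differ", class = "ornametrics_parse_error")

  # drop an explicit closing vertex and collapse consecutive duplicates
  n <- length(x)
  if (n >= 2 && x[1] == x[n] && y[1] == y[n]) {
    x <- x[-n]; y <- y[-n]
  }
  keep <- c(TRUE, diff(x) != 0 | diff(y) != 0)
  x <- x[keep]; y <- y[keep]
  if (length(unique(paste(x, y))) < 3 || length(x) < 3) {
    abort("an outline needs at least 3 distinct points",
          class = "ornametrics_malformed_outline")
  }

  if (signed_area(x, y) < 0) {  # normalize to counter-clockwise (y-up)
    x <- rev(x); y <- rev(y)
  }

  out <- tibble(x = as.double(x), y = as.double(y))
  class(out) <- c("outline", class(out))
  attr(out, "source_id") <- source_id
  attr(out, "closed") <- TRUE
  simple <- is_simple_polygon(out$x, out$y)
  attr(out, "simple") <- simple
  if (!simple) {
    warn(paste0("outline '", source_id, "' self-intersects; areas use even-odd fill"),
         class = "ornametrics_nonsimple_outline")
  }
  out
}

#' @export
print.outline <- function(x, ...) {
  cat(sprintf("<outline '%s'> %d vertices, area %.6g px^2%s\n",
              attr(x, "source_id"), nrow(x), polygon_area(x),
              if (isFALSE(attr(x, "simple"))) " (self-intersecting)" else ""))
  invisible(x)
}

# shoelace signed area in a y-up frame (image y-down traces flip sign on entry)
signed_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

# O(n^2) segment-crossing scan; adequate for trace-sized polygons.
# Shared endpoints between neighbouring edges are not crossings.
is_simple_polygon <- function(x, y, max_n = 2000L) {
  n <- length(x)
  if (n > max_n) {  # subsample long traces: detection only, not a certificate
    idx <- unique(round(seq(1, n, length.out = max_n)))
    x <- x[idx]; y <- y[idx]; n <- length(x)
  }
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    if (i == 1) js <- js[js != n]
    if (!length(js)) next
    d1 <- (x2[i] - x[i]) * (y[js] - y[i]) - (y2[i] - y[i]) * (x[js] - x[i])
    d2 <- (x2[i] - x[i]) * (y2[js] - y[i]) - (y2[i] - y[i]) * (x2[js] - x[i])
    d3 <- (x2[js] - x[js]) * (y[i] - y[js]) - (y2[js] - y[js]) * (x[i] - x[js])
    d4 <- (x2[js] - x[js]) * (y2[i] - y[js]) - (y2[js] - y[js]) * (x2[i] - x[js])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(FALSE)
  }
  TRUE
}

# fast internal constructor for programmatically generated curves:
# skips duplicate collapsing and the O(n^2) simplicity scan
new_outline <- function(x, y, source_id = "outline", simple = NA) {
  if (signed_area(x, y) < 0) {
    x <- rev(x); y <- rev(y)
  }
  out <- tibble(x = as.double(x), y = as.double(y))
  class(out) <- c("outline", class(out))
  attr(out, "source_id") <- source_id
  attr(out, "closed") <- TRUE
  attr(out, "simple") <- simple
  out
}

#' Read an outline from a coordinate CSV
#'
#' Expects one vertex per row with numeric columns `x` and `y` (pixel
#' units), no closing duplicate row required. Other column names can be
#' mapped in via `dialect`.
#'
#' @param path Path to a CSV file.
#' @param dialect Named character vector mapping the standard names to the
#'   file's column names, e.g. `c(x = "X_px", y = "Y_px")`.
#' @param source_id Provenance label; defaults to the file name.
#' @return An [outline].
#' @export
read_outline_csv <- function(path, dialect = c(x = "x", y = "y"),
                             source_id = basename(path)) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  d <- read.csv(path, check.names = FALSE)
  miss <- setdiff(unname(dialect[c("x", "y")]), names(d))
  if (length(miss)) {
    abort(paste("outline CSV lacks column(s):", paste(miss, collapse = ", ")),
          class = "ornametrics_parse_error")
  }
  xs <- d[[dialect[["x"]]]]
  ys <- d[[dialect[["y"]]]]
  if (!is.numeric(xs) || !is.numeric(ys)) {
    abort("outline CSV has non-numeric coordinate cells",
          class = "ornametrics_parse_error")
  }
  outline(xs, ys, source_id = source_id)
}

#' Write an outline to a coordinate CSV
#'
#' @param x An [outline].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_outline_csv <- function(x, path) {
  stopifnot(inherits(x, "outline"))
  write.csv(data.frame(x = x$x, y = x$y), path, row.names = FALSE)
  invisible(path)
}

#' Trace the outer boundary of the largest component in a binary mask
#'
#' Finds the largest 8-connected foreground component and returns its outer
#' boundary as a closed polygon through boundary pixel centers (so a filled
#' n-by-n block yields a polygon of area (n-1)^2, while its pixel count is
#' n^2). Holes are ignored.
#'
#' @param mask A logical or numeric matrix (or array; first channel used);
#'   foreground is nonzero.
#' @param source_id Provenance label.
#' @return An [outline] in 0-based pixel-center coordinates.
#' @export
trace_mask_boundary <- function(mask, source_id = "mask") {
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    abort("trace_mask_boundary requires the EBImage package")
  }
  m <- as_binary_mask(mask)
  if (!any(m)) abort("mask has no foreground pixels", class = "ornametrics_no_foreground")
  lab <- EBImage::bwlabel(EBImage::Image(m * 1))
  tab <- table(as.integer(lab)[as.integer(lab) > 0L])
  biggest <- as.integer(names(tab)[which.max(tab)])
  comp <- EBImage::Image((lab == biggest) * 1)
  ctr <- EBImage::ocontour(comp)[[1]]  # boundary pixel centers, 1-based
  outline(ctr[, 1] - 1, ctr[, 2] - 1, source_id = source_id)
}

as_binary_mask <- function(mask) {
  if (is.array(mask) && length(dim(mask)) > 2) {
    mask <- mask[, , 1]
  }
  if (!is.matrix(mask)) abort("mask must be a matrix")
  mask != 0
}

#' Count foreground pixels of a binary mask
#'
#' The paper-faithful trait-size measure: the total pixel count of the
#' filled trait image.
#'
#' @inheritParams trace_mask_boundary
#' @return Integer number of foreground pixels.
#' @export
pixel_count_area <- function(mask) {
  sum(as_binary_mask(mask))
}

#' Resample an outline to equal arc-length spacing
#'
#' Linearly interpolates `n_points` vertices equally spaced by cumulative
#' arc length along the closed contour. Equal-arc spacing is the standard
#' preparation of a digitized trace for Fourier fitting: after resampling,
#' the vertex index is an arc-length parameter.
#'
#' @param x An [outline].
#' @param n_points Number of output vertices (at least 8).
#' @return An [outline] with `n_points` vertices.
#' @export
resample_outline <- function(x, n_points) {
  stopifnot(inherits(x, "outline"))
  if (n_points < 8) abort("n_points must be at least 8")
  xs <- c(x$x, x$x[1]); ys <- c(x$y, x$y[1])
  seg <- sqrt(diff(xs)^2 + diff(ys)^2)
  per <- sum(seg)
  if (per <= 0) abort("degenerate outline: zero perimeter")
  s <- c(0, cumsum(seg))
  t_new <- seq(0, per, length.out = n_points + 1)[-(n_points + 1)]
  new_outline(approx(s, xs, xout = t_new)$y,
              approx(s, ys, xout = t_new)$y,
              source_id = attr(x, "source_id"),
              simple = attr(x, "simple"))
}

#' @importFrom stats approx
NULL

#' Polygon (shoelace) area of an outline
#'
#' The vector-geometry analogue of the pixel count: absolute shoelace area
#' of the closed polygon, in squared pixel units. Invariant under
#' translation and rotation of the trace.
#'
#' @param x An [outline], or anything `outline()` accepts.
#' @return Area in px^2.
#' @export
polygon_area <- function(x) {
  if (!inherits(x, "outline")) x <- outline(x)
  abs(signed_area(x$x, x$y))
}

#' Outline perimeter
#'
#' @param x An [outline].
#' @return Closed-contour perimeter in px.
#' @export
outline_perimeter <- function(x) {
  stopifnot(inherits(x, "outline"))
  sum(sqrt(diff(c(x$x, x$x[1]))^2 + diff(c(x$y, x$y[1]))^2))
}
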