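#' Congruent and non-congruent areas of two closed outlines
#'
#' The congruent area is the area of the intersection of the two filled
#' regions; the non-congruent area is the area covered by exactly one of
#' them (symmetric difference). Regions are filled with the even-odd rule,
#' so self-intersecting curves (as low-harmonic reconstructions can be) are
#' repaired to valid regions before the boolean operations. By construction
#' `congruent + noncongruent` equals the area of the union.
#'
#' @param outline_a,outline_b [outline]s over the same coordinate frame.
#' @return Named numeric vector `c(congruent =, noncongruent =)` in px^2.
#' @examples
#' a <- outline(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' b <- outline(c(0.5, 1.5, 1.5, 0.5), c(0, 0, 1, 1))
#' congruence_areas(a, b)  # congruent 0.5, noncongruent 1.0
#' @export
congruence_areas <- function(outline_a, outline_b) {
  A <- list(x = outline_a$x, y = outline_a$y)
  B <- list(x = outline_b$x, y = outline_b$y)
  inter <- polyclip_area(A, B, "intersection")
  uni <- polyclip_area(A, B, "union")
  if (inter <= 0) {
    abort("outlines do not overlap: congruent area is zero",
          class = "ornametrics_degenerate_congruence")
  }
  c(congruent = inter, noncongruent = uni - inter)
}

polyclip_area <- function(A, B, op) {
  # scale Clipper's integer grid to the data so rounding stays ~1e-13 relative
  eps <- max(1, abs(c(A$x, A$y, B$x, B$y))) * 1e-13
  ps <- polyclip::polyclip(A, B, op = op,
                           fillA = "evenodd", fillB = "evenodd",
                           eps = eps)
  if (!length(ps)) return(0)
  # Clipper returns hole rings with opposite orientation: signed sum is the area
  sum(vapply(ps, function(p) signed_area_evenodd(p$x, p$y), numeric(1)))
}

signed_area_evenodd <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

#' Raster oracle for congruence areas
#'
#' Independent check of [congruence_areas()]: fills both outlines on a
#' pixel-center grid (point-in-polygon via `mgcv::in.out`, even-odd rule)
#' and counts AND / XOR pixels.
#'
#' @inheritParams congruence_areas
#' @param resolution Grid cells along the longer side of the joint bounding
#'   box.
#' @return Named numeric vector `c(congruent =, noncongruent =)` in px^2.
#' @export
raster_congruence_areas <- function(outline_a, outline_b, resolution = 1024) {
  xs <- c(outline_a$x, outline_b$x)
  ys <- c(outline_a$y, outline_b$y)
  pad <- 1e-9 + 1e-6 * max(diff(range(xs)), diff(range(ys)))
  xr <- range(xs) + c(-pad, pad)
  yr <- range(ys) + c(-pad, pad)
  h <- max(diff(xr), diff(yr)) / resolution
  gx <- seq(xr[1] + h / 2, xr[2], by = h)
  gy <- seq(yr[1] + h / 2, yr[2], by = h)
  pts <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  ina <- in_polygon_evenodd(pts, outline_a)
  inb <- in_polygon_evenodd(pts, outline_b)
  c(congruent = sum(ina & inb) * h^2,
    noncongruent = sum(xor(ina, inb)) * h^2)
}

in_polygon_evenodd <- function(pts, o) {
  bnd <- rbind(cbind(o$x, o$y), c(o$x[1], o$y[1]))
  mgcv::in.out(bnd, pts)
}

#' Congruence-based shape complexity of an outline
#'
#' The core statistic: an outline is reconstructed from its elliptic
#' Fourier series at a low (`h_low`, default 8) and a high (`h_high`,
#' default 1000) harmonic count. A low-harmonic reconstruction of a complex
#' shape is a poor approximation, so the two reconstructions disagree; for
#' a simple shape they nearly coincide. Complexity is the ratio of the
#' non-congruent to the congruent area of the two reconstructions — a
#' dimensionless, size-free score that is 0 exactly when the outline is
#' band-limited below `h_low`.
#'
#' `h_high` is capped at the Nyquist bound of the (possibly resampled)
#' trace. Digitized traces with fewer vertices than the Nyquist requirement
#' are resampled internally to `resample_to` equal-arc points;
#' densely-sampled outlines (e.g. from [make_shape()]) are used as given so
#' that their native parameterization is respected.
#'
#' @param x An [outline].
#' @param h_low,h_high Harmonic counts of the two reconstructions
#'   (`h_low < h_high`).
#' @param resample_to Equal-arc points used when internal resampling is
#'   needed.
#' @param n_points Sampling density of each reconstruction used in the
#'   boolean-area step.
#' @return A tibble of class `complexity_score` with columns `source_id`,
#'   `h_low`, `h_high`, `congruent_area`, `noncongruent_area`, `complexity`.
#' @examples
#' sh <- make_shape(shape_spec(axes = c(2, 1),
#'                             perturb = data.frame(harmonic = 20, amplitude = 0.05)))
#' complexity_score(sh)
#' @export
complexity_score <- function(x, h_low = 8L, h_high = 1000L,
                             resample_to = 4096L, n_points = 4096L) {
  stopifnot(inherits(x, "outline"))
  if (h_low >= h_high) abort("h_low must be smaller than h_high")
  if (h_low < 1) abort("h_low must be >= 1")
  if (nrow(x) < 2L * h_high + 2L) {
    need <- max(resample_to, 2L * h_low + 2L)
    if (nrow(x) < need) x <- resample_outline(x, need)
    h_high <- min(h_high, (nrow(x) - 1L) %/% 2L)
    if (h_low >= h_high) abort("outline too sparse for the requested harmonic pair")
  }
  ef <- efa(x, n_harmonics = h_high)
  lo <- reconstruct(ef, h_low, n_points = n_points)
  hi <- reconstruct(ef, h_high, n_points = max(n_points, 2L * h_high + 2L))
  if (polygon_area(lo) <= 0) abort("low-harmonic reconstruction is degenerate")
  if (polygon_area(hi) <= 0) abort("high-harmonic reconstruction is degenerate")
  ar <- tryCatch(
    congruence_areas(lo, hi),
    ornametrics_degenerate_congruence = function(e) {
      abort(sprintf("reconstructions at %d and %d harmonics do not overlap",
                    h_low, h_high))
    })
  out <- tibble(source_id = attr(x, "source_id") %||% "outline",
                h_low = as.integer(h_low), h_high = as.integer(h_high),
                congruent_area = ar[["congruent"]],
                noncongruent_area = ar[["noncongruent"]],
                complexity = ar[["noncongruent"]] / ar[["congruent"]])
  class(out) <- c("complexity_score", class(out))
  out
}

#' Score a batch of outlines
#'
#' Data-frame-first wrapper around [complexity_score()]: takes a manifest
#' tibble with an `outline` list-column (plus any id columns such as
#' `species`, `sex`, `trait`) and returns it with the score columns bound
#' on.
#'
#' @param manifest A data frame with a list-column `outline` of [outline]s.
#' @inheritParams complexity_score
#' @return The manifest tibble plus `h_low`, `h_high`, `congruent_area`,
#'   `noncongruent_area`, `complexity`.
#' @export
score_outlines <- function(manifest, h_low = 8L, h_high = 1000L,
                           resample_to = 4096L, n_points = 4096L) {
  stopifnot(is.data.frame(manifest), "outline" %in% names(manifest))
  scores <- purrr::map(manifest$outline, complexity_score,
                       h_low = h_low, h_high = h_high,
                       resample_to = resample_to, n_points = n_points)
  dplyr::bind_cols(
    as_tibble(manifest[setdiff(names(manifest), "outline")]),
    dplyr::bind_rows(scores)[c("h_low", "h_high", "congruent_area",
                               "noncongruent_area", "complexity")])
}

#' Normalize male trait complexity against the female baseline
#'
#' Male sternite and fore-femur complexity scores are expressed relative to
#' the female structure of the same species (male / female), the stated
#' baseline for sexual dimorphism. Claspers occur only in males and are
#' never normalized. *Perochaeta dikowi* females lack a sclerotized fourth
#' sternite; their sternite score is fixed to 1 so the male score passes
#' through unchanged.
#'
#' @param male_score,female_score Non-negative scores; `female_score` may be
#'   `NA` only for the documented exception.
#' @param species,trait Labels; the exception triggers on
#'   `species = "Perochaeta dikowi"` (or acronym `"PDIK"`) with
#'   `trait = "sternite"`.
#' @return A tibble with `species`, `trait`, `male_score`, `female_score`
#'   (after any exception), `normalized`.
#' @export
normalize_dimorphism <- function(male_score, female_score, species, trait) {
  if (any(male_score < 0, na.rm = TRUE)) abort("male_score must be >= 0")
  if (any(trait == "clasper")) {
    abort("claspers occur only in males and are never female-normalized")
  }
  d <- tibble(species = species, trait = trait,
              male_score = male_score, female_score = female_score)
  exc <- d$species %in% c("Perochaeta dikowi", "PDIK") & d$trait == "sternite"
  d$female_score[exc] <- 1
  bad <- !exc & (is.na(d$female_score) | d$female_score <= 0)
  if (any(bad)) {
    abort(paste("non-positive or missing female baseline for:",
                paste(unique(d$species[bad]), collapse = ", ")))
  }
  d$normalized <- d$male_score / d$female_score
  d
}

#' Per-species male minus female complexity differences
#'
#' @param panel A data frame with columns `species`, `sex`
#'   (`"male"`/`"female"`), `trait`, and `complexity`. Species missing one
#'   sex for a trait are excluded and reported via a message.
#' @return A tibble `species`, `trait`, `male`, `female`,
#'   `difference = male - female`.
#' @export
sex_complexity_difference <- function(panel) {
  stopifnot(is.data.frame(panel))
  if (!nrow(panel)) abort("empty panel")
  wide <- panel |>
    dplyr::group_by(.data$species, .data$trait, .data$sex) |>
    dplyr::summarise(complexity = mean(.data$complexity), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "sex", values_from = "complexity")
  for (s in c("male", "female")) if (!s %in% names(wide)) wide[[s]] <- NA_real_
  dropped <- wide |> dplyr::filter(is.na(.data$male) | is.na(.data$female))
  if (nrow(dropped)) {
    message("excluded (missing one sex): ",
            paste(paste(dropped$species, dropped$trait, sep = "/"), collapse = ", "))
  }
  wide |>
    dplyr::filter(!is.na(.data$male) & !is.na(.data$female)) |>
    dplyr::mutate(difference = .data$male - .data$female) |>
    dplyr::select("species", "trait", "male", "female", "difference")
}
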