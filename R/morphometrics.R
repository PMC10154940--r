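#' Ellipsoid pupal volume
#'
#' Pupal volume proxies the resources available for metamorphosis and is
#' estimated from pupal width and length as a perfect ellipsoid:
#' (pi/6) * width^2 * length.
#'
#' @param width_mm,length_mm Pupal width and length in mm (>= 0), vectorized.
#' @return Volume in mm^3.
#' @examples
#' pupal_volume(0.8, 2.5)
#' @export
pupal_volume <- function(width_mm, length_mm) {
  if (any(width_mm < 0, na.rm = TRUE) || any(length_mm < 0, na.rm = TRUE)) {
    abort("pupal dimensions must be non-negative")
  }
  pi / 6 * width_mm^2 * length_mm
}

#' Growth rate from adult size and development time
#'
#' Adult scutum width divided by total (larval + pupal) development time,
#' in mm per hour.
#'
#' @param scutum_mm Adult scutum width, mm.
#' @param total_h Total development time, hours (> 0).
#' @return Growth rate, mm/h.
#' @export
growth_rate <- function(scutum_mm, total_h) {
  if (any(total_h <= 0, na.rm = TRUE)) abort("total_h must be positive")
  scutum_mm / total_h
}

panel_quantities <- c("larval_h", "pupal_h", "total_h", "scutum_mm",
                      "pupal_volume_mm3", "sternite_area", "femur_area",
                      "clasper_area", "sternite_complexity",
                      "femur_complexity", "clasper_complexity",
                      "growth_rate")

#' Species-by-sex means and sex differences of a study panel
#'
#' Averages individual records to sex-specific species means for every
#' quantity present, then derives per-species male minus female differences
#' and percent differences (relative to the female mean, the baseline sex).
#' Derived quantities are filled in first where their parts are present:
#' `total_h = larval_h + pupal_h`, `pupal_volume_mm3` from pupal width and
#' length, and `growth_rate = scutum_mm / total_h`.
#'
#' Species missing one sex entirely keep their one-sex means but carry `NA`
#' differences; they are reported via a message.
#'
#' @param records A data frame of individual records: `species`, `sex`
#'   (`"male"`/`"female"`) plus any of `larval_h`, `pupal_h`, `total_h`,
#'   `pupal_width_mm`, `pupal_length_mm`, `scutum_mm`, trait areas
#'   (`sternite_area`, `femur_area`, `clasper_area`) and complexities
#'   (`*_complexity`).
#' @return A tibble of class `species_summary`, one row per species:
#'   `n_male`, `n_female`, `<q>_male`, `<q>_female`, `<q>_diff`
#'   (male − female) and `<q>_pct` (100 * diff / female mean) for each
#'   quantity `<q>`.
#' @export
summarize_panel <- function(records) {
  stopifnot(is.data.frame(records))
  if (!nrow(records)) abort("empty panel")
  if (!all(c("species", "sex") %in% names(records))) {
    abort("records need 'species' and 'sex' columns")
  }
  if (!all(records$sex %in% c("male", "female"))) {
    abort("sex must be 'male' or 'female'")
  }
  rec <- as_tibble(records)
  if (!"total_h" %in% names(rec) && all(c("larval_h", "pupal_h") %in% names(rec))) {
    rec$total_h <- rec$larval_h + rec$pupal_h
  }
  if (!"pupal_volume_mm3" %in% names(rec) &&
      all(c("pupal_width_mm", "pupal_length_mm") %in% names(rec))) {
    rec$pupal_volume_mm3 <- pupal_volume(rec$pupal_width_mm, rec$pupal_length_mm)
  }
  qs <- intersect(panel_quantities, names(rec))
  if (!length(qs)) abort("no summarizable quantities found")

  means <- rec |>
    dplyr::group_by(.data$species, .data$sex) |>
    dplyr::summarise(n = dplyr::n(),
                     dplyr::across(dplyr::all_of(qs), ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "sex",
                       values_from = dplyr::all_of(c("n", qs)),
                       names_glue = "{.value}_{sex}")
  for (col in c("n_male", "n_female",
                paste0(qs, "_male"), paste0(qs, "_female"))) {
    if (!col %in% names(means)) means[[col]] <- NA_real_
  }
  # growth rate is defined on the species-by-sex means, not per individual
  if (all(c("scutum_mm", "total_h") %in% qs)) {
    for (sx in c("male", "female")) {
      means[[paste0("growth_rate_", sx)]] <-
        means[[paste0("scutum_mm_", sx)]] / means[[paste0("total_h_", sx)]]
    }
    qs <- c(qs, "growth_rate")
  }
  one_sexed <- means$species[is.na(means$n_male) | is.na(means$n_female)]
  if (length(one_sexed)) {
    message("species with a single sex (differences set NA): ",
            paste(one_sexed, collapse = ", "))
  }
  for (q in qs) {
    m <- means[[paste0(q, "_male")]]
    f <- means[[paste0(q, "_female")]]
    means[[paste0(q, "_diff")]] <- m - f
    means[[paste0(q, "_pct")]] <- 100 * (m - f) / f
  }
  means <- dplyr::arrange(means, .data$species)
  class(means) <- c("species_summary", class(means))
  attr(means, "quantities") <- qs
  means
}

#' One-sample t-test as a tidy row
#'
#' Two-sided one-sample t-test of the mean against `mu0`, with the 95%
#' confidence half-width t(0.975, n-1) * sd / sqrt(n). Used across species
#' means, so n is the number of species.
#'
#' @param values Numeric vector, n >= 2, positive variance; `NA`s dropped.
#' @param mu0 Null mean (default 0).
#' @return A one-row tibble: `n`, `mean`, `ci95`, `conf_low`, `conf_high`,
#'   `t`, `df`, `p`.
#' @export
one_sample_t <- function(values, mu0 = 0) {
  values <- values[!is.na(values)]
  if (length(values) < 2) abort("need at least 2 values")
  if (sd(values) == 0) abort("zero variance: t statistic undefined")
  ht <- t.test(values, mu = mu0)
  tibble(n = length(values), mean = unname(ht$estimate),
         ci95 = unname(diff(ht$conf.int)) / 2,
         conf_low = ht$conf.int[1], conf_high = ht$conf.int[2],
         t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value)
}

#' Pearson correlation as a tidy row
#'
#' Pearson's r with the two-sided p-value from the t transform
#' t = r * sqrt((n - 2) / (1 - r^2)).
#'
#' @param x,y Equal-length numeric vectors, n >= 3, positive variances;
#'   pairwise-complete observations are used.
#' @return A one-row tibble: `n`, `r`, `t`, `df`, `p`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("x and y lengths differ")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance: correlation undefined")
  ht <- cor.test(x, y, method = "pearson")
  tibble(n = length(x), r = unname(ht$estimate),
         t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value)
}

#' Sex-difference tests across species
#'
#' Runs the cross-species one-sample t-test (against 0) on the per-species
#' male minus female difference of every summarized quantity: the test of
#' whether a trait is sexually dimorphic with species means as the unit of
#' replication.
#'
#' @param summary A `species_summary` from [summarize_panel()].
#' @return A tibble, one row per quantity: `quantity`, `n`, `mean`, `ci95`,
#'   `t`, `df`, `p`, `pct_mean` (mean percent difference).
#' @export
sex_difference_tests <- function(summary) {
  qs <- attr(summary, "quantities") %||%
    sub("_diff$", "", grep("_diff$", names(summary), value = TRUE))
  purrr::map_dfr(qs, function(q) {
    d <- summary[[paste0(q, "_diff")]]
    d <- d[!is.na(d)]
    if (length(d) < 2 || sd(d) == 0) return(NULL)
    res <- one_sample_t(d)
    pct <- summary[[paste0(q, "_pct")]]
    dplyr::bind_cols(tibble(quantity = q),
                     res[c("n", "mean", "ci95", "t", "df", "p")],
                     tibble(pct_mean = mean(pct, na.rm = TRUE)))
  })
}

#' Trait-size / development-time correlations across species
#'
#' Pearson correlations between pairs of species-mean columns, e.g. male
#' sternite area against larval and pupal development times.
#'
#' @param summary A `species_summary` from [summarize_panel()].
#' @param pairs A data frame with character columns `x` and `y` naming
#'   columns of `summary`.
#' @return A tibble, one row per pair: `x`, `y`, `n`, `r`, `t`, `df`, `p`.
#' @export
correlation_tests <- function(summary, pairs) {
  stopifnot(is.data.frame(pairs), all(c("x", "y") %in% names(pairs)))
  purrr::pmap_dfr(pairs[c("x", "y")], function(x, y) {
    if (!x %in% names(summary) || !y %in% names(summary)) return(NULL)
    dplyr::bind_cols(tibble(x = x, y = y),
                     pearson_r(summary[[x]], summary[[y]]))
  })
}

#' Map a deposited species-means table into the panel schema
#'
#' Reads a one-row-per-species CSV of sex-specific means (the layout of the
#' study's archived species-means deposit) and renames columns to the
#' `species_summary` schema via a column-name configuration, recomputing
#' difference and percent columns.
#'
#' @param path CSV path.
#' @param mapping Named character vector: names are `species_summary`
#'   column names (`species`, `<q>_male`, `<q>_female`, ...), values the
#'   CSV's column names.
#' @return A `species_summary` tibble.
#' @export
read_species_means_csv <- function(path, mapping) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  d <- as_tibble(read.csv(path, check.names = FALSE))
  miss <- setdiff(unname(mapping), names(d))
  if (length(miss)) abort(paste("missing columns:", paste(miss, collapse = ", ")))
  out <- d[unname(mapping)]
  names(out) <- names(mapping)
  qs <- unique(sub("_(male|female)$", "",
                   grep("_(male|female)$", names(out), value = TRUE)))
  qs <- intersect(qs, panel_quantities)
  for (q in qs) {
    m <- out[[paste0(q, "_male")]]
    f <- out[[paste0(q, "_female")]]
    if (is.null(m) || is.null(f)) next
    out[[paste0(q, "_diff")]] <- m - f
    out[[paste0(q, "_pct")]] <- 100 * (m - f) / f
  }
  class(out) <- c("species_summary", class(out))
  attr(out, "quantities") <- qs
  out
}
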