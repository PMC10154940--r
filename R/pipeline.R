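#' Run configuration for the full analysis
#'
#' Bundles the inputs of an end-to-end run: either in-memory objects (an
#' individual-record table and a tree) or file paths (panel CSV, Newick),
#' the harmonic pair, the comparative model list, and a seed. Can also be
#' read from a YAML file with the same field names.
#'
#' @param panel Individual-record data frame, or path to its CSV.
#' @param tree A `phylo` tree, Newick string, or path to a Newick file.
#' @param manifest Optional outline manifest (data frame with an `outline`
#'   list-column plus `species`, `sex`, `trait`) to score; scored
#'   complexities are merged into the panel by species/sex.
#' @param h_low,h_high Harmonic pair for complexity scoring.
#' @param models List of model configs, each a list with `response`,
#'   `predictors` (ordered character vector) and optional `lambda`
#'   (`"ML"` or fixed value).
#' @param correlations Optional data frame of `x`, `y` species-mean column
#'   pairs for Pearson tests.
#' @param seed Integer seed recorded in the run log.
#' @param out_dir Optional directory; when set, all result tables are also
#'   written as CSVs.
#' @return An object of class `run_config`.
#' @export
run_config <- function(panel, tree = NULL, manifest = NULL,
                       h_low = 8L, h_high = 1000L,
                       models = list(list(
                         response = "pupal_h_diff",
                         predictors = c("sternite_complexity_diff",
                                        "scutum_mm_male", "scutum_mm_diff"),
                         lambda = "ML")),
                       correlations = NULL, seed = 1L, out_dir = NULL) {
  if (h_low >= h_high) abort("h_low must be smaller than h_high")
  if (is.character(panel) && !file.exists(panel)) {
    abort(paste("panel file does not exist:", panel))
  }
  if (is.character(tree) && length(tree) == 1 && !grepl("\\(", tree) &&
      !file.exists(tree)) {
    abort(paste("tree file does not exist:", tree))
  }
  structure(list(panel = panel, tree = tree, manifest = manifest,
                 h_low = as.integer(h_low), h_high = as.integer(h_high),
                 models = models, correlations = correlations,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with fields matching [run_config()] arguments
#'   (`panel` and `tree` as paths).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) abort("needs the yaml package")
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' Run the full ornament-cost analysis
#'
#' Orchestrates the pipeline: (optionally) score outline complexities and
#' merge them into the panel; summarize the panel into species-by-sex means
#' and male minus female differences; run the cross-species sex-difference
#' t-tests and trait-size correlations; and fit each configured PGLS model
#' of a development-time difference on complexity/size predictors. Every
#' stage is a pure function of (inputs, config, seed), so a rerun with the
#' same config reproduces the outputs exactly.
#'
#' @param config A [run_config()].
#' @return A list of class `ornament_run`: `scores` (or `NULL`),
#'   `species_summary`, `sex_tests`, `correlations`, `pgls` (named list of
#'   `pgls_fit`), `pgls_coefficients`, `pgls_anova` (stacked tidy tables)
#'   and `log` (stage-by-stage record with the config hash).
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- list(seed = config$seed,
              r_version = as.character(getRversion()),
              package_version = as.character(utils::packageVersion("ornametrics")),
              config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
              started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              stages = character())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  panel <- stage("load_panel", {
    if (is.character(config$panel)) {
      as_tibble(read.csv(config$panel))
    } else as_tibble(config$panel)
  })

  scores <- NULL
  if (!is.null(config$manifest)) {
    scores <- stage("score_outlines",
                    score_outlines(config$manifest,
                                   h_low = config$h_low, h_high = config$h_high))
    wide <- scores |>
      dplyr::select("species", "sex", "trait", "complexity") |>
      tidyr::pivot_wider(names_from = "trait", values_from = "complexity",
                         names_glue = "{trait}_complexity")
    panel <- panel |>
      dplyr::select(-dplyr::any_of(setdiff(names(wide), c("species", "sex")))) |>
      dplyr::left_join(wide, by = c("species", "sex"))
  }
  log$stages <- c(log$stages, "panel", if (!is.null(scores)) "scores")

  summary <- stage("summarize_panel", summarize_panel(panel))
  sex_tests <- stage("sex_difference_tests", sex_difference_tests(summary))

  cors <- NULL
  if (!is.null(config$correlations)) {
    cors <- stage("correlation_tests",
                  correlation_tests(summary, config$correlations))
  }

  fits <- list()
  if (length(config$models)) {
    tr <- stage("load_tree", {
      if (inherits(config$tree, "phylo")) config$tree else read_newick(config$tree)
    })
    fits <- stage("pgls", {
      purrr::map(config$models, function(m) {
        fml <- stats::reformulate(m$predictors, response = m$response)
        used <- c(m$response, m$predictors)
        n_missing <- sum(!stats::complete.cases(summary[used]))
        if (n_missing) {
          message(sprintf("model %s: dropped %d species with missing variables",
                          m$response, n_missing))
        }
        pgls(summary, fml, tr, lambda = m$lambda %||% "ML")
      }) |>
        setNames(vapply(config$models, function(m) m$response, character(1)))
    })
  }
  coefs <- purrr::imap_dfr(fits, ~ dplyr::mutate(tidy(.x), model = .y,
                                                 .before = 1))
  anovas <- purrr::imap_dfr(fits, ~ dplyr::mutate(anova(.x), model = .y,
                                                  .before = 1))
  log$stages <- c(log$stages, "summary", "tests", "pgls")
  log$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")

  res <- structure(list(scores = scores, species_summary = summary,
                        sex_tests = sex_tests, correlations = cors,
                        pgls = fits, pgls_coefficients = coefs,
                        pgls_anova = anovas, log = log),
                   class = "ornament_run")
  if (!is.null(config$out_dir)) write_run(res, config$out_dir)
  res
}

write_run <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, f) if (!is.null(x) && nrow(x)) {
    write.csv(as.data.frame(x), file.path(dir, f), row.names = FALSE)
  }
  wr(res$scores, "complexity_scores.csv")
  wr(res$species_summary, "species_summary.csv")
  wr(res$sex_tests, "sex_difference_tests.csv")
  wr(res$correlations, "correlations.csv")
  wr(res$pgls_coefficients, "pgls_coefficients.csv")
  wr(res$pgls_anova, "pgls_anova.csv")
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    writeLines(jsonlite::toJSON(res$log, auto_unbox = TRUE),
               file.path(dir, "run_log.json"))
  }
  invisible(dir)
}

#' @export
print.ornament_run <- function(x, ...) {
  cat("ornament-cost analysis run\n")
  cat(sprintf("  species: %d   models: %d   seed: %d\n",
              nrow(x$species_summary), length(x$pgls), x$log$seed))
  cat("sex-difference tests:\n")
  print(as.data.frame(x$sex_tests), digits = 3)
  if (length(x$pgls)) {
    cat("PGLS coefficients:\n")
    print(as.data.frame(x$pgls_coefficients), digits = 3)
  }
  invisible(x)
}
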