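#' Overlay low- and high-harmonic reconstructions of an outline
#'
#' Debugging aid mirroring the congruence construction: the two
#' reconstructions are drawn over each other, so the non-overlapping fringe
#' is the non-congruent region driving the complexity score.
#'
#' @param x An [outline].
#' @inheritParams complexity_score
#' @return A ggplot object.
#' @export
plot_reconstructions <- function(x, h_low = 8L, h_high = 1000L) {
  stopifnot(inherits(x, "outline"))
  if (nrow(x) < 2L * h_high + 2L) {
    x <- resample_outline(x, max(4096L, 2L * h_low + 2L))
    h_high <- min(h_high, (nrow(x) - 1L) %/% 2L)
  }
  ef <- efa(x, h_high)
  d <- dplyr::bind_rows(
    dplyr::mutate(as_tibble(reconstruct(ef, h_low, 2048L)),
                  which = sprintf("%d harmonics", h_low)),
    dplyr::mutate(as_tibble(reconstruct(ef, h_high, max(2048L, 2L * h_high + 2L))),
                  which = sprintf("%d harmonics", h_high)))
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, colour = .data$which)) +
    ggplot2::geom_path(linewidth = 0.4) +
    ggplot2::coord_equal() +
    ggplot2::labs(colour = NULL, title = attr(x, "source_id")) +
    ggplot2::theme_minimal()
}

#' Plot cross-species sex differences with their confidence intervals
#'
#' @param sex_tests Output of [sex_difference_tests()].
#' @return A ggplot object: mean male minus female difference per quantity
#'   with 95% CI bars.
#' @export
plot_sex_differences <- function(sex_tests) {
  ggplot2::ggplot(sex_tests,
                  ggplot2::aes(.data$mean, stats::reorder(.data$quantity, .data$mean))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$mean - .data$ci95,
                                          xmax = .data$mean + .data$ci95)) +
    ggplot2::labs(x = "male − female difference (mean ± 95% CI)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot complexity_score
#' @export
autoplot.complexity_score <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(stats::reorder(.data$source_id, .data$complexity),
                               .data$complexity)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "complexity (non-congruent / congruent area)") +
    ggplot2::theme_minimal()
}

#' @method autoplot pgls_fit
#' @export
autoplot.pgls_fit <- function(object, ...) {
  d <- tidy(object) |> dplyr::filter(.data$term != "(Intercept)")
  ggplot2::ggplot(d, ggplot2::aes(.data$estimate, .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$estimate - 1.96 * .data$std.error,
      xmax = .data$estimate + 1.96 * .data$std.error)) +
    ggplot2::labs(x = "PGLS estimate (± 1.96 SE)", y = NULL,
                  title = deparse(object$formula)) +
    ggplot2::theme_minimal()
}
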