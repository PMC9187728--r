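#' Plot an optimization trace
#'
#' Best-ever fitness (normalized-scale MSE) against generation; the
#' convergence-curve view of a spread search.
#'
#' @param object A `"qga_result"` or `"ga_result"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pn_opt_result
#' @export
autoplot.pn_opt_result <- function(object, ...) {
  ggplot(object$trace, aes(x = .data$generation, y = .data$best_fitness)) +
    geom_line(colour = "#2c7fb8") +
    geom_point(size = 1) +
    labs(x = "Generation", y = "Best fitness (MSE, normalized)",
         title = sprintf("%s convergence", toupper(object$method))) +
    theme_minimal()
}

#' @rdname autoplot.pn_opt_result
#' @method autoplot qga_result
#' @export
autoplot.qga_result <- function(object, ...) autoplot.pn_opt_result(object, ...)

#' @rdname autoplot.pn_opt_result
#' @method autoplot ga_result
#' @export
autoplot.ga_result <- function(object, ...) autoplot.pn_opt_result(object, ...)

#' Plot a spread sweep
#'
#' Verification-set MSE against the spread grid, on a log y scale.
#'
#' @param object A `"pn_sweep"` from [spread_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pn_sweep
#' @export
autoplot.pn_sweep <- function(object, ...) {
  ggplot(object, aes(x = .data$spread, y = .data$mse)) +
    geom_line() +
    geom_point() +
    scale_y_log10() +
    labs(x = "Spread", y = "Verification MSE",
         title = sprintf("Effect of the spread (%s)",
                         toupper(attr(object, "family") %||% "rbf"))) +
    theme_minimal()
}

#' Plot a model comparison
#'
#' Predicted-vs-measured scatter per model with the 1:1 line, the view used
#' to compare the six model/optimizer combinations.
#'
#' @param object A `"pn_comparison"` from [compare_models()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pn_comparison
#' @export
autoplot.pn_comparison <- function(object, ...) {
  ggplot(comparison_scatter(object),
         aes(x = .data$measured, y = .data$predicted)) +
    geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    geom_point(alpha = 0.4, size = 0.8, colour = "#2c7fb8") +
    facet_wrap(~model) +
    coord_equal() +
    labs(x = expression("Measured Pn (" * mu * "mol" ~ m^-2 ~ s^-1 * ")"),
         y = expression("Predicted Pn (" * mu * "mol" ~ m^-2 ~ s^-1 * ")")) +
    theme_minimal()
}

#' Plot synthetic light-response curves
#'
#' Noise-free net photosynthetic rate against PPFD for a set of temperatures
#' and blue-light ratios; a quick visual check of the generator's surface.
#'
#' @param params A [pn_truth_params()] object.
#' @param temperatures,blue_ratios Conditions to draw.
#' @param ppfd_max Upper PPFD limit of the curves.
#' @return A ggplot object.
#' @export
plot_light_response <- function(params = pn_truth_params(),
                                temperatures = c(18, 24, 30),
                                blue_ratios = c(0.1, 0.3, 0.6),
                                ppfd_max = 1600) {
  grid <- tidyr::expand_grid(
    temperature = temperatures, blue_ratio = blue_ratios,
    ppfd = seq(0, ppfd_max, length.out = 200)
  )
  grid$pn <- true_pn(grid$ppfd, grid$temperature, grid$blue_ratio, params)
  ggplot(grid, aes(x = .data$ppfd, y = .data$pn,
                   colour = factor(.data$blue_ratio))) +
    geom_line() +
    facet_wrap(~temperature, labeller = label_both) +
    labs(x = expression("PPFD (" * mu * "mol" ~ m^-2 ~ s^-1 * ")"),
         y = expression("Pn (" * mu * "mol" ~ m^-2 ~ s^-1 * ")"),
         colour = "Blue ratio") +
    theme_minimal()
}
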