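#' Stacked per-step NtC population plot
#'
#' Visualises the conformer make-up of each phosphate step as a
#' stacked bar of class weights, ordered 5' to 3' when the steps follow
#' the dodecamer naming.
#'
#' @param weights Population tibble from [population_weights()].
#' @return A ggplot object.
#' @export
plot_populations <- function(weights) {
  lv <- intersect(dodecamer_steps(), unique(weights$step_id))
  if (length(lv) == 0) lv <- unique(weights$step_id)
  weights %>%
    dplyr::mutate(step_id = factor(.data$step_id, levels = lv)) %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$step_id, y = .data$weight,
                                 fill = .data$class_id)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "dinucleotide step", y = "population weight w",
                  fill = "NtC class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Differential-weight plot for a population fit
#'
#' Shows, per step and class, the differential weight
#' `delta_w = w(original) - w(fitted)` produced by fitting the BI'/BII'
#' split to experiment: positive bars mean the fit reduced that class's
#' population.
#'
#' @param object An `ntc_fit` from [fit_equilibrium()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ntc_fit <- function(object, ...) {
  dw <- object$delta_w %>% dplyr::filter(.data$delta_w != 0)
  lv <- intersect(dodecamer_steps(), unique(dw$step_id))
  if (length(lv) == 0) lv <- unique(dw$step_id)
  dw %>%
    dplyr::mutate(step_id = factor(.data$step_id, levels = lv)) %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$class_id, y = .data$delta_w,
                                 fill = .data$class_id)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~step_id) +
    ggplot2::labs(x = "NtC class",
                  y = expression(Delta * italic(w) ==
                                   italic(w)[original] -
                                   italic(w)[fitted])) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Temperature-differential plot
#'
#' Plots shift differentials (and, when present, sectional population
#' differentials) against temperature, one panel per step, relative to
#' the series baseline.
#'
#' @param differentials Output of [differential_series()].
#' @return A ggplot object.
#' @export
plot_temperature_differentials <- function(differentials) {
  long <- differentials %>%
    tidyr::pivot_longer(dplyr::starts_with("d_"),
                        names_to = "quantity", values_to = "value")
  lv <- intersect(dodecamer_steps(), unique(long$step_id))
  if (length(lv) == 0) lv <- unique(long$step_id)
  long %>%
    dplyr::mutate(step_id = factor(.data$step_id, levels = lv)) %>%
    ggplot2::ggplot(ggplot2::aes(x = .data$temperature, y = .data$value,
                                 colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~step_id) +
    ggplot2::labs(x = "temperature (°C)",
                  y = "differential vs baseline") +
    ggplot2::theme_minimal()
}
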