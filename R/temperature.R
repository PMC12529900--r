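#' Temperature differentials of shifts and sectional populations
#'
#' For a temperature series of per-step observables (and optionally
#' per-step NtC populations), computes differentials relative to a
#' baseline temperature: `d_delta = delta(T) - delta(baseline)` per
#' step, and sectional population differentials
#' `d_w = w(T) - w(baseline)` for the groups BI (BB00 + BB01),
#' BII (BB04 + BB07) and "rest" (all remaining classes). Baseline rows
#' are exactly zero, and since populations sum to 1 at every
#' temperature the three sectional differentials sum to zero at every
#' (step, temperature).
#'
#' @param observables Tibble `step_id, temperature, delta_ppm` covering
#'   the same step set at every temperature.
#' @param weights Optional tibble `step_id, temperature, class_id,
#'   weight`; when supplied the sectional population differentials are
#'   included.
#' @param baseline Baseline temperature (default 20, degrees C); must
#'   be present in the series.
#' @param sections Named list of class-id vectors defining the
#'   sectional groups; classes in no section count as "rest".
#' @return A tibble `step_id, temperature, d_delta` plus one
#'   `d_w_<section>` column per section and `d_w_rest`.
#' @export
differential_series <- function(observables, weights = NULL,
                                baseline = 20,
                                sections = list(bi = c("BB00", "BB01"),
                                                bii = c("BB04", "BB07"))) {
  if (!baseline %in% observables$temperature) {
    abort(paste0("baseline temperature ", baseline,
                 " absent from the series"))
  }
  base <- observables %>%
    dplyr::filter(.data$temperature == baseline) %>%
    dplyr::select("step_id", delta_base = "delta_ppm")
  out <- observables %>%
    dplyr::inner_join(base, by = "step_id") %>%
    dplyr::mutate(d_delta = .data$delta_ppm - .data$delta_base) %>%
    dplyr::select("step_id", "temperature", "d_delta")
  if (!is.null(weights)) {
    sect <- sectional_weights(weights, sections)
    sect_base <- sect %>%
      dplyr::filter(.data$temperature == baseline) %>%
      dplyr::select("step_id", "section", w_base = "w")
    dws <- sect %>%
      dplyr::inner_join(sect_base, by = c("step_id", "section")) %>%
      dplyr::mutate(d_w = .data$w - .data$w_base) %>%
      dplyr::select("step_id", "temperature", "section", "d_w") %>%
      tidyr::pivot_wider(names_from = "section", values_from = "d_w",
                         names_prefix = "d_w_")
    out <- out %>%
      dplyr::inner_join(dws, by = c("step_id", "temperature"))
  }
  out %>% dplyr::arrange(.data$step_id, .data$temperature)
}

# Collapse class weights into sectional sums (missing sections get 0).
sectional_weights <- function(weights, sections) {
  lab <- rep("rest", nrow(weights))
  for (nm in names(sections)) {
    lab[weights$class_id %in% sections[[nm]]] <- nm
  }
  weights %>%
    dplyr::mutate(section = lab) %>%
    dplyr::group_by(.data$step_id, .data$temperature, .data$section) %>%
    dplyr::summarise(w = sum(.data$weight), .groups = "drop") %>%
    tidyr::complete(
      tidyr::nesting(!!rlang::sym("step_id"), !!rlang::sym("temperature")),
      section = c(names(sections), "rest"),
      fill = list(w = 0))
}

#' Total range of chemical shifts across steps
#'
#' The spread `max(delta) - min(delta)` of per-step 31P shifts at one
#' condition, a compact measure of how strongly the backbone
#' environments differentiate the phosphates (it narrows as
#' temperature rises and conformational averaging increases).
#'
#' @param delta Numeric vector of per-step shifts (ppm), or a tibble
#'   with a `delta_ppm` column.
#' @return The range in ppm.
#' @export
#' @examples
#' shift_range(c(0, 0.3, 0.5))
shift_range <- function(delta) {
  if (is.data.frame(delta)) delta <- delta$delta_ppm
  if (length(delta) < 2) {
    abort("shift_range needs at least 2 steps")
  }
  max(delta) - min(delta)
}
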