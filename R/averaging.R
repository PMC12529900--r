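#' Population-weighted NMR observables
#'
#' Dynamically averaged 31P shielding and 3J(P,H3') coupling per
#' dinucleotide step: the weighted sum of the class-specific scalar
#' parameters with the per-step NtC population weights,
#' `sigma = sum_i w_i sigma_i` and `J = sum_i w_i J_i`. The averages
#' are linear in the weights.
#'
#' @param weights Population tibble from [population_weights()]
#'   (columns `step_id, class_id, weight`).
#' @param classes A validated class table supplying `sigma_ppm` and
#'   `j_hz` for every class with nonzero weight.
#' @return A tibble `step_id, sigma_ppm, j_hz`, one row per step.
#' @export
#' @examples
#' classes <- synthetic_class_table(seed = 1)
#' w <- tibble::tibble(step_id = "A6pT7",
#'                     class_id = c("BB00", "BB07"),
#'                     weight = c(0.75, 0.25))
#' population_average(w, classes)
population_average <- function(weights, classes) {
  unknown <- setdiff(unique(weights$class_id[weights$weight > 0]),
                     classes$class_id)
  if (length(unknown) > 0) {
    abort(paste0("class(es) missing NMR parameters in the class table: ",
                 paste(unknown, collapse = ", ")))
  }
  weights %>%
    dplyr::inner_join(
      classes[c("class_id", "sigma_ppm", "j_hz")], by = "class_id") %>%
    dplyr::group_by(.data$step_id) %>%
    dplyr::summarise(
      sigma_ppm = sum(.data$weight * .data$sigma_ppm),
      j_hz = sum(.data$weight * .data$j_hz),
      .groups = "drop"
    )
}

# Expectation of a class's parameter surface/curve under its
# step-conditional torsion distribution.
surface_expectation <- function(traj, assignments, class_id, step_id,
                                surf, product_marginals = FALSE) {
  if (product_marginals) {
    pa <- torsion_histogram(traj, assignments, class_id, "alpha3", step_id)$p
    pz <- torsion_histogram(traj, assignments, class_id, "zeta", step_id)$p
    sum(outer(pa, pz) * surf)
  } else {
    jh <- joint_histogram(traj, assignments, class_id, step_id)
    sum(jh$p * surf[cbind(jh$alpha_bin, jh$zeta_bin)])
  }
}

curve_expectation <- function(traj, assignments, class_id, step_id, curve) {
  ph <- torsion_histogram(traj, assignments, class_id, "epsilon", step_id)
  sum(ph$p * curve)
}

#' Probability-averaged NMR observables
#'
#' Refines [population_average()] by replacing, for the BI-family and
#' BII-family classes, the scalar class parameters with expectations of
#' the class's geometric parameter dependences under the
#' class-conditional torsion distributions observed at each step: the
#' shielding surface over the (alpha3, zeta) grid and the coupling
#' curve over epsilon, both piecewise-constant on 10 degree bins.
#' Classes outside the two families contribute their scalars exactly as
#' in population weighting. When every surface and curve is constant at
#' the class scalar the result reduces to population averaging.
#'
#' @inheritParams population_average
#' @param traj,assignments The trajectory and its classification, used
#'   to build per-step class-conditional torsion distributions.
#' @param product_marginals If `TRUE`, approximate the joint
#'   (alpha3, zeta) distribution by the product of its marginals
#'   instead of the observed joint histogram (comparison mode).
#' @return A tibble `step_id, sigma_ppm, j_hz`.
#' @export
probability_average <- function(weights, classes, traj, assignments,
                                product_marginals = FALSE) {
  base <- classes[c("class_id", "family", "sigma_ppm", "j_hz")]
  w <- weights %>% dplyr::inner_join(base, by = "class_id")
  unknown <- setdiff(unique(weights$class_id[weights$weight > 0]),
                     classes$class_id)
  if (length(unknown) > 0) {
    abort(paste0("class(es) missing NMR parameters in the class table: ",
                 paste(unknown, collapse = ", ")))
  }
  fam <- w$family %in% c("BI_family", "BII_family") & w$weight > 0
  for (i in which(fam)) {
    id <- w$class_id[i]
    step <- w$step_id[i]
    surf <- class_surface(classes, id)
    curve <- class_curve(classes, id)
    if (is.null(surf)) {
      abort(paste0("family class ", id, " has no sigma_surface grid"))
    }
    if (is.null(curve)) {
      abort(paste0("family class ", id, " has no j_curve"))
    }
    jh_n <- class_frames(traj, assignments, id, step)
    if (nrow(jh_n) == 0) next  # zero-weight class cannot reach here
    w$sigma_ppm[i] <- surface_expectation(traj, assignments, id, step,
                                          surf, product_marginals)
    w$j_hz[i] <- curve_expectation(traj, assignments, id, step, curve)
  }
  w %>%
    dplyr::group_by(.data$step_id) %>%
    dplyr::summarise(
      sigma_ppm = sum(.data$weight * .data$sigma_ppm),
      j_hz = sum(.data$weight * .data$j_hz),
      .groups = "drop"
    )
}

#' Reference calculated shifts to an internal phosphate
#'
#' Converts averaged 31P shieldings to chemical shifts referenced to a
#' DNA-internal standard phosphate: `delta = sigma(ref) - sigma`, so a
#' larger shielding gives a smaller shift and the reference step's
#' shift is exactly zero. Internal referencing cancels any constant
#' offset in the shielding scale.
#'
#' @param observables Tibble with `step_id` and `sigma_ppm` (e.g. from
#'   [population_average()]). If a `temperature` column is present,
#'   referencing is applied within each temperature.
#' @param reference_step Step label of the internal standard
#'   (default `"A6pT7"`).
#' @return The input with a `delta_ppm` column added (reference row 0).
#' @export
reference_delta <- function(observables, reference_step = "A6pT7") {
  grp <- if ("temperature" %in% names(observables)) "temperature"
         else character()
  observables %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) %>%
    dplyr::group_modify(function(df, key) {
      i <- which(df$step_id == reference_step)
      if (length(i) != 1) {
        abort(paste0("reference step '", reference_step,
                     "' absent from observables"))
      }
      df$delta_ppm <- df$sigma_ppm[i] - df$sigma_ppm
      df
    }) %>%
    dplyr::ungroup()
}

#' Re-reference experimental shifts to an internal phosphate
#'
#' Experimental 31P shifts measured against an external standard
#' (delta', e.g. vs H3PO4) are re-expressed relative to the internal
#' reference phosphate: `delta = delta' - delta'(ref)`. This puts
#' experiment and calculation on the same internal scale and removes
#' any bias from the external-reference treatment. Idempotent: applying
#' it to already re-referenced data changes nothing.
#'
#' @param exp Tibble with `step_id` and `delta_prime` (ppm); an
#'   optional `temperature` column groups the referencing.
#' @param reference_step Internal reference step label.
#' @return The input with a `delta_ppm` column (reference row 0).
#' @export
rereference_experimental <- function(exp, reference_step = "A6pT7") {
  if (!"delta_prime" %in% names(exp)) {
    abort("experimental table needs a 'delta_prime' column (ppm)")
  }
  grp <- if ("temperature" %in% names(exp)) "temperature" else character()
  exp %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) %>%
    dplyr::group_modify(function(df, key) {
      i <- which(df$step_id == reference_step)
      if (length(i) != 1) {
        abort(paste0("reference step '", reference_step,
                     "' absent from experimental table"))
      }
      df$delta_ppm <- df$delta_prime - df$delta_prime[i]
      df
    }) %>%
    dplyr::ungroup()
}
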