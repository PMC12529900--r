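#' Dinucleotide step labels of the model B-DNA dodecamer
#'
#' The 11 internucleotide phosphate steps of the self-complementary
#' duplex 5'-CGCGAATTCGCG-3', labelled by their flanking bases
#' (`C1pG2` ... `C11pG12`). `A6pT7` is the internal chemical-shift
#' reference.
#'
#' @return Character vector of 11 step labels, 5' to 3'.
#' @export
dodecamer_steps <- function() {
  seq_chars <- strsplit("CGCGAATTCGCG", "")[[1]]
  paste0(seq_chars[1:11], 1:11, "p", seq_chars[2:12], 2:12)
}

#' Default synthetic duplex mixture specification
#'
#' Per-step NtC mixtures emulating the qualitative conformational
#' profile of a B-DNA dodecamer: BI-dominated central (stem) steps,
#' conformationally heterogeneous terminal (tail) steps with elevated
#' BII-family populations, and intermediate near-terminal steps.
#'
#' @param n_frames Frames per step (default 2000, i.e. 20 ns at a
#'   10 ps frame interval).
#' @param torsion_noise_sd Wrapped-Gaussian torsion fluctuation, in
#'   degrees (default 8).
#' @param temperature Metadata temperature in degrees C.
#' @return A tibble `step_id, class_id, target_weight, n_frames,
#'   torsion_noise_sd, temperature`; target weights sum to 1 per step.
#' @export
#' @examples
#' spec <- default_duplex_spec(n_frames = 100)
#' dplyr::count(spec, step_id)
default_duplex_spec <- function(n_frames = 2000, torsion_noise_sd = 8,
                                temperature = 20) {
  steps <- dodecamer_steps()
  tail_steps <- c("C1pG2", "G4pA5", "C9pG10", "G10pC11", "C11pG12")
  stem_steps <- c("A5pA6", "A6pT7", "T7pT8", "T8pC9")
  mixes <- list(
    stem = c(BB00 = 0.65, BB01 = 0.20, BB04 = 0.08, BB07 = 0.04,
             BA05 = 0.03),
    tail = c(BB00 = 0.35, BB01 = 0.10, BB04 = 0.20, BB07 = 0.25,
             AB01 = 0.10),
    mid = c(BB00 = 0.50, BB01 = 0.15, BB04 = 0.15, BB07 = 0.10,
            BA05 = 0.05, AB01 = 0.05)
  )
  purrr::map_dfr(steps, function(s) {
    mix <- if (s %in% stem_steps) mixes$stem
           else if (s %in% tail_steps) mixes$tail
           else mixes$mid
    tibble::tibble(step_id = s, class_id = names(mix),
                   target_weight = unname(mix), n_frames = n_frames,
                   torsion_noise_sd = torsion_noise_sd,
                   temperature = temperature)
  })
}

#' Sample a synthetic torsion trajectory with known mixture structure
#'
#' Draws, for every step and frame, an NtC class from the step's target
#' mixture and perturbs each of the nine class-defining torsions with
#' independent wrapped-Gaussian noise. The generating class labels are
#' returned alongside the trajectory, so classification and population
#' recovery can be validated against ground truth. Deterministic in
#' `seed`.
#'
#' @param spec Mixture specification as from [default_duplex_spec()].
#' @param classes A validated class table containing every class id
#'   referenced by `spec`.
#' @param seed Integer seed.
#' @return A list with `trajectory` (tibble `step_id, frame,
#'   <torsions>, temperature`) and `truth` (tibble
#'   `step_id, frame, class_id` of generating labels).
#' @export
sample_trajectory <- function(spec, classes, seed = 1L) {
  unknown <- setdiff(unique(spec$class_id), classes$class_id)
  if (length(unknown) > 0) {
    abort(paste0("mixture references unknown class(es): ",
                 paste(unknown, collapse = ", ")))
  }
  if (any(abs(tapply(spec$target_weight, spec$step_id, sum) - 1) > 1e-9)) {
    abort("target weights must sum to 1 within each step")
  }
  centers <- as.matrix(classes[torsion_names()])
  rownames(centers) <- classes$class_id
  with_seed(seed, {
    res <- spec %>%
      dplyr::distinct(.data$step_id, .data$n_frames,
                      .data$torsion_noise_sd, .data$temperature) %>%
      purrr::pmap(function(step_id, n_frames, torsion_noise_sd,
                           temperature) {
        mix <- spec[spec$step_id == step_id, ]
        lab <- sample(mix$class_id, n_frames, replace = TRUE,
                      prob = mix$target_weight)
        tors <- centers[lab, , drop = FALSE] +
          matrix(stats::rnorm(n_frames * 9, 0, torsion_noise_sd),
                 n_frames, 9)
        tors <- normalize_angle(tors)
        colnames(tors) <- torsion_names()
        list(
          trajectory = tibble::tibble(step_id = step_id,
                                      frame = seq_len(n_frames),
                                      tibble::as_tibble(tors),
                                      temperature = temperature),
          truth = tibble::tibble(step_id = step_id,
                                 frame = seq_len(n_frames),
                                 class_id = lab)
        )
      })
    list(
      trajectory = purrr::map_dfr(res, "trajectory"),
      truth = purrr::map_dfr(res, "truth")
    )
  })
}

#' Attach synthetic geometric parameter dependences to a class table
#'
#' Fills the per-class shielding surface over (alpha3, zeta) and the
#' coupling curve over epsilon. The coupling curve is a Karplus-type
#' relation `J(eps) = A cos^2(theta) + B cos(theta) + C` with
#' `theta = eps - 120 degrees`, evaluated at bin centers; the default
#' coefficients are the standard empirical 3J(H3'-P) parameterization
#' (A = 15.3, B = -6.2, C = 1.5 Hz). The shielding surface is a smooth
#' low-order periodic function of (alpha3, zeta) with seed-dependent
#' coefficients of roughly 1 ppm amplitude — a synthetic stand-in for
#' quantum-chemically computed surfaces. Each class's grid is shifted
#' so its value at the class-defining torsion bin equals the class
#' scalar exactly, keeping the two parameter representations
#' consistent.
#'
#' @param classes A class table (scalar columns only, or with grids to
#'   overwrite).
#' @param karplus Numeric length-3 Karplus coefficients `c(A, B, C)`
#'   in Hz.
#' @param seed Integer seed for the surface coefficients.
#' @return The class table with `sigma_surface` and `j_curve`
#'   list-columns populated.
#' @export
synthetic_dependences <- function(classes,
                                  karplus = c(15.3, -6.2, 1.5),
                                  seed = 1L) {
  stopifnot(length(karplus) == 3)
  centers_deg <- 10 * (1:36) - 5  # bin centers
  th <- (centers_deg - 120) * pi / 180
  j_raw <- karplus[1] * cos(th)^2 + karplus[2] * cos(th) + karplus[3]
  co <- with_seed(seed, stats::runif(4, -1, 1))
  a_rad <- centers_deg * pi / 180
  s_raw <- outer(a_rad, a_rad, function(a, z) {
    co[1] * cos(a) + co[2] * sin(z) + co[3] * cos(a - z) +
      0.5 * co[4] * sin(a + z)
  })
  out <- classes
  out$sigma_surface <- vector("list", nrow(out))
  out$j_curve <- vector("list", nrow(out))
  for (i in seq_len(nrow(out))) {
    ka <- torsion_bin(out$alpha3[i])
    kz <- torsion_bin(out$zeta[i])
    ke <- torsion_bin(out$epsilon[i])
    out$sigma_surface[[i]] <- s_raw + (out$sigma_ppm[i] - s_raw[ka, kz])
    out$j_curve[[i]] <- j_raw + (out$j_hz[i] - j_raw[ke])
  }
  tibble::as_tibble(out)
}

#' Generate a synthetic experimental observable table
#'
#' Forward-models per-step observables from known populations
#' (population weighting plus internal referencing), then adds
#' independent Gaussian measurement noise. The reference step's shift
#' is re-zeroed after adding noise, since internal referencing is exact
#' by definition. Used for parameter-recovery tests of the fitting
#' stage.
#'
#' @param true_weights Per-step population tibble.
#' @param classes A validated class table.
#' @param noise_delta,noise_j Gaussian noise standard deviations for
#'   the shift (ppm) and coupling (Hz); zero gives the exact forward
#'   model.
#' @param seed Integer seed.
#' @param reference_step Internal reference label.
#' @return An experimental tibble `step_id, delta_ppm, j_hz`.
#' @export
synthetic_experiment <- function(true_weights, classes, noise_delta = 0,
                                 noise_j = 0, seed = 1L,
                                 reference_step = "A6pT7") {
  obs <- population_average(true_weights, classes) %>%
    reference_delta(reference_step)
  with_seed(seed, {
    n <- nrow(obs)
    out <- tibble::tibble(
      step_id = obs$step_id,
      delta_ppm = obs$delta_ppm + stats::rnorm(n, 0, noise_delta),
      j_hz = obs$j_hz + stats::rnorm(n, 0, noise_j)
    )
    out$delta_ppm[out$step_id == reference_step] <- 0
    out
  })
}
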