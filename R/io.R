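#' Read a torsion trajectory table
#'
#' Reads a long-format CSV/TSV trajectory with one row per (step,
#' frame): columns `step_id, frame` plus the nine torsion columns of
#' [torsion_names()], in degrees. Files produced by MD dihedral
#' extraction tools often use different column names or orders; a
#' `column_map` (named character vector, canonical name -> file column
#' name) resolves them. Torsions are normalized to `[0, 360)` on input.
#'
#' @param path Path to the trajectory file.
#' @param column_map Optional named character vector mapping canonical
#'   column names to the names used in the file.
#' @return A trajectory tibble ordered by step then frame.
#' @export
read_trajectory <- function(path, column_map = NULL) {
  if (!file.exists(path)) abort(paste0("trajectory not found: ", path))
  tbl <- read_delim_auto(path)
  wanted <- c("step_id", "frame", torsion_names())
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(tbl)) {
        abort(paste0("mapped column '", src, "' (for ", canon,
                     ") not in file"))
      }
      names(tbl)[names(tbl) == src] <- canon
    }
  }
  missing_cols <- setdiff(wanted, names(tbl))
  if (length(missing_cols) > 0) {
    abort(paste0("cannot resolve trajectory column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  tbl <- tbl[c(wanted, intersect("temperature", names(tbl)))]
  for (tn in torsion_names()) tbl[[tn]] <- normalize_angle(tbl[[tn]])
  check_trajectory(tbl)
  tbl %>% dplyr::arrange(.data$step_id, .data$frame)
}

#' Write a torsion trajectory table
#'
#' @param traj Trajectory tibble.
#' @param path Output CSV/TSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  write_delim_auto(traj, path)
}

#' Read an experimental observable table
#'
#' CSV/TSV with `step_id` and any of `delta_prime` (shift vs an
#' external standard, ppm), `delta_ppm` (already internally
#' referenced), `j_hz`, and `temperature`.
#'
#' @param path Path to the table.
#' @return A tibble.
#' @export
read_experimental <- function(path) {
  if (!file.exists(path)) abort(paste0("experimental table not found: ",
                                       path))
  read_delim_auto(path)
}

#' Pipeline configuration
#'
#' Bundles the inputs of [run_pipeline()]. Either a trajectory file
#' (classified on the fly) or a synthetic run (when `trajectory` is
#' `NULL`, a trajectory is generated from [default_duplex_spec()]) can
#' drive the pipeline.
#'
#' @param classes_file Optional path to a class table; when `NULL` the
#'   synthetic table for `seed` is used.
#' @param trajectory_file Optional path to a trajectory table.
#' @param experimental_file Optional path to an experimental table;
#'   when present the BI'/BII' fit and agreement scores are produced.
#' @param mode Averaging mode, `"population"` or `"probability"`.
#' @param reference_step Internal reference phosphate.
#' @param seed Integer seed for synthetic stages.
#' @param n_frames Frames per step for the synthetic trajectory.
#' @return A list of class `ntc_config`.
#' @export
pipeline_config <- function(classes_file = NULL, trajectory_file = NULL,
                            experimental_file = NULL,
                            mode = c("population", "probability"),
                            reference_step = "A6pT7", seed = 1L,
                            n_frames = 2000) {
  mode <- match.arg(mode)
  for (f in c(classes_file, trajectory_file, experimental_file)) {
    if (!is.null(f) && !file.exists(f)) {
      abort(paste0("configured file does not exist: ", f))
    }
  }
  structure(list(classes_file = classes_file,
                 trajectory_file = trajectory_file,
                 experimental_file = experimental_file, mode = mode,
                 reference_step = reference_step, seed = as.integer(seed),
                 n_frames = n_frames),
            class = "ntc_config")
}

#' Run the full interpretation pipeline
#'
#' Chains the stages: classify every trajectory frame into NtC classes,
#' compute per-step population weights, average the 31P shielding and
#' 3J coupling (population or probability mode), reference shifts to
#' the internal standard, and — when experimental data are supplied —
#' score the agreement and fit the BI'/BII' populations in two stages.
#' Deterministic given the configuration and seed.
#'
#' @param config An [pipeline_config()] object.
#' @return A list with `classes`, `trajectory`, `assignments`,
#'   `weights`, `observables` (with `delta_ppm`), and, when
#'   experimental data are present, `experimental`, `scores_unfitted`
#'   and `fit` (an `ntc_fit`). A `summary` element carries the headline
#'   numbers as a flat named list suitable for JSON serialization.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "ntc_config"))
  classes <- if (is.null(config$classes_file)) {
    synthetic_class_table(seed = config$seed)
  } else {
    read_class_table(config$classes_file,
                     grid_dir = dirname(config$classes_file))
  }
  truth <- NULL
  traj <- if (is.null(config$trajectory_file)) {
    sim <- sample_trajectory(
      default_duplex_spec(n_frames = config$n_frames),
      classes, seed = config$seed)
    truth <- sim$truth
    sim$trajectory
  } else {
    read_trajectory(config$trajectory_file)
  }
  assignments <- classify_trajectory(traj, classes)
  weights <- population_weights(assignments)
  obs <- if (config$mode == "probability") {
    probability_average(weights, classes, traj, assignments)
  } else {
    population_average(weights, classes)
  }
  obs <- reference_delta(obs, config$reference_step)
  out <- list(classes = classes, trajectory = traj, truth = truth,
              assignments = assignments, weights = weights,
              observables = obs)
  summary <- list(mode = config$mode, seed = config$seed,
                  n_steps = nrow(obs),
                  shift_range_ppm = shift_range(obs))
  if (!is.null(config$experimental_file)) {
    exp <- read_experimental(config$experimental_file)
    if (!"delta_ppm" %in% names(exp) && "delta_prime" %in% names(exp)) {
      exp <- rereference_experimental(exp, config$reference_step)
    }
    out$experimental <- exp
    out$scores_unfitted <- list(
      delta = score_agreement(obs, exp, "delta_ppm", "delta"),
      j = score_agreement(obs, exp, "j_hz", "j"))
    out$fit <- fit_equilibrium(exp, weights, classes,
                               reference_step = config$reference_step)
    g <- glance(out$fit)
    summary$mad_delta_unfitted <- out$scores_unfitted$delta$mad
    summary$mad_j_unfitted <- out$scores_unfitted$j$mad
    summary$mad_delta_fitted <- g$mad_delta
    summary$mad_j_fitted <- g$mad_j
    summary$delta_w <- stats::setNames(
      as.list(out$fit$delta_w$delta_w),
      paste(out$fit$delta_w$step_id, out$fit$delta_w$class_id, sep = "."))
  }
  out$summary <- summary
  out
}
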