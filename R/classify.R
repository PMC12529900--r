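#' Assign one torsion vector to its nearest NtC class
#'
#' Computes the squared circular distance ([torsion_distance_sq()])
#' from the snapshot torsions to every class-defining torsion vector
#' and returns the argmin. Ties (measure zero, but possible with
#' constructed input) are broken by the lexicographically smallest
#' `class_id` so classification is deterministic.
#'
#' @param torsions Numeric vector of length 9 ordered as
#'   [torsion_names()], in degrees.
#' @param classes A validated class table.
#' @return A one-row tibble with `class_id` and `distance_sq` (deg^2).
#' @export
#' @examples
#' classes <- synthetic_class_table(seed = 1)
#' t0 <- as.numeric(classes[classes$class_id == "BB00", torsion_names()])
#' classify_frame(t0, classes)
classify_frame <- function(torsions, classes) {
  if (is.null(classes) || nrow(classes) == 0) {
    abort("class table is empty: nothing to classify against")
  }
  d <- apply_class_distances(matrix(torsions, nrow = 1), classes)
  pick <- nearest_class(d, classes$class_id)
  tibble::tibble(class_id = pick$class_id, distance_sq = pick$distance_sq)
}

# n x k matrix of squared circular distances, frames x classes.
apply_class_distances <- function(tors_mat, classes) {
  centers <- as.matrix(classes[torsion_names()])
  out <- matrix(0, nrow(tors_mat), nrow(centers))
  for (j in seq_len(nrow(centers))) {
    out[, j] <- torsion_distance_sq(tors_mat, centers[j, ])
  }
  out
}

# Argmin per row with lexicographic tie-break on class_id.
nearest_class <- function(d, class_ids) {
  ord <- order(class_ids)
  d <- d[, ord, drop = FALSE]
  ids <- class_ids[ord]
  j <- max.col(-d, ties.method = "first")
  list(class_id = ids[j], distance_sq = d[cbind(seq_len(nrow(d)), j)])
}

#' Classify every frame of a torsion trajectory
#'
#' Assigns each (step, frame) snapshot of a trajectory table to its
#' nearest NtC class by minimal squared circular distance in the
#' nine-dimensional torsion space. Optionally, frames farther than
#' `cutoff` (deg^2) from every class can be left unassigned
#' (`class_id = NA`); by default every frame is assigned to its nearest
#' class.
#'
#' @param traj Trajectory tibble in long format with columns `step_id`,
#'   `frame`, and the nine torsion columns of [torsion_names()]
#'   (degrees, any real values; normalized internally).
#' @param classes A validated class table.
#' @param cutoff Optional squared-distance cutoff in deg^2
#'   (default `Inf`, i.e. no cutoff).
#' @return A tibble `step_id, frame, class_id, distance_sq` with one row
#'   per input frame, in input order.
#' @export
#' @examples
#' classes <- synthetic_class_table(seed = 1)
#' traj <- sample_trajectory(default_duplex_spec(n_frames = 20),
#'                           classes, seed = 1)$trajectory
#' head(classify_trajectory(traj, classes))
classify_trajectory <- function(traj, classes, cutoff = Inf) {
  if (nrow(traj) == 0) abort("trajectory is empty")
  check_trajectory(traj)
  tors <- as.matrix(traj[torsion_names()])
  d <- apply_class_distances(tors, classes)
  pick <- nearest_class(d, classes$class_id)
  out <- tibble::tibble(
    step_id = traj$step_id,
    frame = traj$frame,
    class_id = pick$class_id,
    distance_sq = pick$distance_sq
  )
  if (is.finite(cutoff)) {
    out$class_id[out$distance_sq > cutoff] <- NA_character_
  }
  out
}

check_trajectory <- function(traj) {
  missing_cols <- setdiff(c("step_id", "frame", torsion_names()),
                          names(traj))
  if (length(missing_cols) > 0) {
    abort(paste0("trajectory is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  tors <- as.matrix(traj[torsion_names()])
  if (anyNA(tors)) {
    bad <- which(is.na(tors), arr.ind = TRUE)[1, ]
    abort(paste0("missing torsion '", torsion_names()[bad[2]],
                 "' at step ", traj$step_id[bad[1]],
                 ", frame ", traj$frame[bad[1]]))
  }
  invisible(traj)
}
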