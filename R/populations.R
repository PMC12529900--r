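#' Per-step NtC population weights
#'
#' Converts frame assignments into per-step conformer populations: for
#' each dinucleotide step, the weight of class i is the relative
#' occurrence `w_i = N_i / N` of frames assigned to that class among the
#' step's N frames. Classes never observed at a step are omitted (their
#' weight is zero). With the default classification (no distance
#' cutoff) the weights of each step sum to 1 exactly.
#'
#' @param assignments Tibble `step_id, frame, class_id, distance_sq` as
#'   returned by [classify_trajectory()]. Frames with `NA` class (from
#'   a distance cutoff) are excluded from the counts but still counted
#'   in N, so weights then sum to the assigned fraction.
#' @return A tibble `step_id, class_id, n_class, n_frames, weight`,
#'   one row per observed (step, class).
#' @export
#' @examples
#' a <- tibble::tibble(step_id = "A6pT7", frame = 1:10,
#'                     class_id = rep(c("BB00", "BB07"), c(6, 4)),
#'                     distance_sq = 0)
#' population_weights(a)
population_weights <- function(assignments) {
  if (nrow(assignments) == 0) abort("no frames: cannot compute populations")
  totals <- assignments %>%
    dplyr::count(.data$step_id, name = "n_frames")
  assignments %>%
    dplyr::filter(!is.na(.data$class_id)) %>%
    dplyr::count(.data$step_id, .data$class_id, name = "n_class") %>%
    dplyr::left_join(totals, by = "step_id") %>%
    dplyr::mutate(weight = .data$n_class / .data$n_frames) %>%
    dplyr::arrange(.data$step_id, .data$class_id)
}

# Frames of one class at one step (or pooled over steps when step_id NULL).
class_frames <- function(traj, assignments, class_id, step_id = NULL) {
  keep <- assignments$class_id == class_id & !is.na(assignments$class_id)
  if (!is.null(step_id)) keep <- keep & assignments$step_id == step_id
  key_a <- paste(assignments$step_id, assignments$frame)
  key_t <- paste(traj$step_id, traj$frame)
  traj[key_t %in% key_a[keep], , drop = FALSE]
}

#' Class-conditional torsion probability distribution
#'
#' Discretizes the values of one torsion over the frames assigned to
#' one NtC class into 36 bins of 10 degrees (bin k covers
#' `[10(k-1), 10k)`) and normalizes by the class frame count, giving
#' the class-conditional probability distribution P(t_k). When the
#' class has no assigned frames the histogram is returned with all
#' probabilities zero and `n_class = 0` (an empty-histogram signal, not
#' an error).
#'
#' @param traj Trajectory tibble (see [classify_trajectory()]).
#' @param assignments Assignments for `traj`.
#' @param class_id NtC class label.
#' @param torsion One of [torsion_names()].
#' @param step_id Optional step label; by default frames are pooled
#'   over all steps.
#' @return A 36-row tibble `class_id, torsion, bin, bin_lo, bin_hi, p,
#'   n_class`; `sum(p)` is 1 whenever `n_class >= 1`.
#' @export
torsion_histogram <- function(traj, assignments, class_id, torsion,
                              step_id = NULL) {
  stopifnot(torsion %in% torsion_names())
  sub <- class_frames(traj, assignments, class_id, step_id)
  n <- nrow(sub)
  counts <- tabulate(torsion_bin(sub[[torsion]]), nbins = 36L)
  tibble::tibble(
    class_id = class_id,
    torsion = torsion,
    bin = 1:36,
    bin_lo = 10 * (0:35),
    bin_hi = 10 * (1:36),
    p = if (n > 0) counts / n else rep(0, 36),
    n_class = n
  )
}

#' Class-conditional joint (alpha3, zeta) distribution
#'
#' The two-dimensional analogue of [torsion_histogram()] over the
#' (alpha3, zeta) torsion pair that parameterizes the 31P shielding
#' surface: a 36 x 36 grid of probabilities with the same half-open
#' 10 degree bin convention on both axes. Marginalizing the grid over
#' either axis reproduces the corresponding one-dimensional histogram
#' bin-by-bin.
#'
#' @inheritParams torsion_histogram
#' @return A 1296-row tibble `class_id, alpha_bin, zeta_bin, p,
#'   n_class`; `sum(p)` is 1 whenever `n_class >= 1`.
#' @export
joint_histogram <- function(traj, assignments, class_id, step_id = NULL) {
  sub <- class_frames(traj, assignments, class_id, step_id)
  n <- nrow(sub)
  grid <- matrix(0, 36, 36)
  if (n > 0) {
    ka <- torsion_bin(sub$alpha3)
    kz <- torsion_bin(sub$zeta)
    for (i in seq_len(n)) grid[ka[i], kz[i]] <- grid[ka[i], kz[i]] + 1
    grid <- grid / n
  }
  tibble::tibble(
    class_id = class_id,
    alpha_bin = rep(1:36, times = 36),
    zeta_bin = rep(1:36, each = 36),
    p = as.vector(grid),  # column-major: alpha varies fastest
    n_class = n
  )
}
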