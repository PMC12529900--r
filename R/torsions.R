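#' Backbone torsion roles of a dinucleotide step
#'
#' The nine torsions that define a dinucleotide-step conformation, in
#' fixed order: sugar pucker proxy and glycosidic torsion of the 5'
#' nucleotide (`delta5`, `chi5`), the inter-nucleotide backbone torsions
#' (`epsilon`, `zeta`, `alpha3`, `beta3`, `gamma3`), and the sugar and
#' glycosidic torsions of the 3' nucleotide (`delta3`, `chi3`). All
#' torsions are handled in degrees on `[0, 360)`.
#'
#' @return Character vector of the nine torsion column names, in order.
#' @export
#' @examples
#' torsion_names()
torsion_names <- function() {
  c("delta5", "chi5", "epsilon", "zeta", "alpha3", "beta3", "gamma3",
    "delta3", "chi3")
}

#' Normalize angles to the canonical torsion range
#'
#' Maps angles in degrees to `[0, 360)`. An input of exactly 360 (or any
#' multiple) maps to 0.
#'
#' @param x Numeric vector of angles in degrees.
#' @return Numeric vector in `[0, 360)`.
#' @export
#' @examples
#' normalize_angle(c(-90, 360, 370.5))
normalize_angle <- function(x) {
  x %% 360
}

#' Signed minimal-arc difference between two angles
#'
#' Computes `a - b` on the circle: the result lies in `(-180, 180]` and
#' its absolute value is the shortest arc between the two angles.
#' Torsions 359 and 1 degrees are 2 degrees apart, not 358; plain
#' subtraction would misjudge conformations near the branch cut.
#'
#' @param a,b Numeric vectors of angles in degrees (recycled).
#' @return Signed difference in degrees, in `(-180, 180]`.
#' @export
#' @examples
#' circular_diff(359, 1)   # -2
#' circular_diff(10, 350)  # 20
circular_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Squared circular distance between two torsion vectors
#'
#' Sum over the nine torsion components of the squared minimal-arc
#' difference, in squared degrees. This is the classification metric:
#' because the class assignment only ranks distances, the square root
#' and 1/n of an RMSD are omitted (monotone transforms preserve the
#' argmin).
#'
#' @param t_md Numeric vector (length 9) or matrix (n x 9) of torsions
#'   in degrees, ordered as [torsion_names()].
#' @param t_ntc Numeric vector of length 9: the class-defining torsions.
#' @return Non-negative squared distance(s) in deg^2; zero iff the
#'   vectors are identical modulo 360.
#' @export
#' @examples
#' torsion_distance_sq(rep(0, 9), rep(0, 9))
#' torsion_distance_sq(c(359, rep(0, 8)), c(1, rep(0, 8)))  # 4
#' Histogram bin index of a torsion angle
#'
#' Torsion distributions are discretized with a fixed 10 degree step:
#' bin `k` covers the half-open interval `[10(k-1), 10k)` degrees,
#' `k = 1..36`. Angles are normalized first, so exactly 360 falls in
#' bin 1.
#'
#' @param x Numeric vector of angles in degrees.
#' @return Integer bin indices in `1..36`.
#' @export
#' @examples
#' torsion_bin(c(0, 5, 359.99, 360))
torsion_bin <- function(x) {
  as.integer(floor(normalize_angle(x) / 10)) + 1L
}

torsion_distance_sq <- function(t_md, t_ntc) {
  if (is.matrix(t_md)) {
    stopifnot(ncol(t_md) == 9L, length(t_ntc) == 9L)
    d <- circular_diff(t_md, matrix(t_ntc, nrow(t_md), 9L, byrow = TRUE))
    rowSums(d * d)
  } else {
    stopifnot(length(t_md) == 9L, length(t_ntc) == 9L)
    d <- circular_diff(t_md, t_ntc)
    sum(d * d)
  }
}
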