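#' Benchmark 31P shifts for the Dickerson-Drew dodecamer
#'
#' Published per-step 31P chemical shifts (ppm) for the 11 phosphates
#' of the Dickerson-Drew duplex, internally referenced to the A6pT7
#' phosphate: values calculated from X-ray crystal structures
#' (`xray`), from NMR solution structures (`nmr`), and measured in
#' solution at 20 degrees C (`experiment`). Useful as a realistic
#' fixed input for the agreement metric and for examples.
#'
#' @return A tibble `step_id, xray, nmr, experiment` with 11 rows.
#' @seealso [dd_coupling_benchmark()], [score_agreement()]
#' @export
#' @examples
#' b <- dd_shift_benchmark()
#' rms_deviation(b$xray, b$experiment)
dd_shift_benchmark <- function() {
  tibble::tribble(
    ~step_id, ~xray, ~nmr, ~experiment,
    "C1pG2",    1.05,  0.10, 0.37,
    "G2pC3",    0.75,  0.02, 0.26,
    "C3pG4",    0.24,  0.10, 0.46,
    "G4pA5",    0.21,  0.10, 0.24,
    "A5pA6",   -0.03,  0.09, 0.12,
    "A6pT7",    0.00,  0.00, 0.00,
    "T7pT8",    0.06, -0.02, 0.02,
    "T8pC9",    0.00,  0.03, 0.12,
    "C9pG10",   0.11,  0.10, 0.52,
    "G10pC11",  4.10,  0.01, 0.37,
    "C11pG12",  0.49,  0.00, 0.52
  )
}

#' Benchmark 3J(P,H3') couplings for the Dickerson-Drew dodecamer
#'
#' Published per-step three-bond P-H3' scalar couplings (Hz) for the
#' Dickerson-Drew duplex: calculated from X-ray structures (`xray`),
#' from NMR solution structures (`nmr`), and the averaged experimental
#' couplings (`experiment`).
#'
#' @return A tibble `step_id, xray, nmr, experiment` with 11 rows.
#' @seealso [dd_shift_benchmark()]
#' @export
dd_coupling_benchmark <- function() {
  tibble::tribble(
    ~step_id, ~xray, ~nmr, ~experiment,
    "C1pG2",    4.49, 1.92, 6.27,
    "G2pC3",    3.43, 1.66, 3.64,
    "C3pG4",    2.52, 1.91, 5.58,
    "G4pA5",    2.70, 1.92, 4.00,
    "A5pA6",    1.59, 1.89, 2.95,
    "A6pT7",    1.85, 1.70, 2.53,
    "T7pT8",    2.00, 1.51, 2.69,
    "T8pC9",    1.70, 1.68, 3.07,
    "C9pG10",   2.04, 1.91, 5.07,
    "G10pC11", 10.06, 1.64, 4.04,
    "C11pG12",  3.64, 1.57, 5.21
  )
}
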