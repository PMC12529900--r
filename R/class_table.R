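#' @importFrom rlang .data abort warn
#' @importFrom dplyr %>%
NULL

class_table_cols <- function() {
  c("class_id", "family", torsion_names(), "sigma_ppm", "j_hz")
}

families <- function() c("BI_family", "BII_family", "other")

#' Validate an NtC class-definition table
#'
#' Checks the structural invariants of a class table: required columns,
#' unique class identifiers, at least two classes, torsions normalized
#' to `[0, 360)`, known family labels, and — when per-class dependence
#' grids are attached — consistency of each grid with the class scalar
#' at the class-defining torsion bin (the shielding surface evaluated at
#' the class's (alpha3, zeta) bin must equal `sigma_ppm`; the coupling
#' curve at the epsilon bin must equal `j_hz`).
#'
#' @param classes A class table as returned by [read_class_table()] or
#'   [synthetic_class_table()].
#' @param tol Tolerance for the grid-consistency checks.
#' @return The input, invisibly, if valid; otherwise an error.
#' @export
validate_class_table <- function(classes, tol = 1e-9) {
  missing_cols <- setdiff(class_table_cols(), names(classes))
  if (length(missing_cols) > 0) {
    abort(paste0("class table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(classes) < 2) {
    abort("class table must define at least 2 classes")
  }
  dup <- unique(classes$class_id[duplicated(classes$class_id)])
  if (length(dup) > 0) {
    abort(paste0("duplicate class_id: ", paste(dup, collapse = ", ")))
  }
  bad_family <- setdiff(unique(classes$family), families())
  if (length(bad_family) > 0) {
    abort(paste0("unknown family label(s): ",
                 paste(bad_family, collapse = ", "),
                 " (expected ", paste(families(), collapse = ", "), ")"))
  }
  tors <- as.matrix(classes[torsion_names()])
  if (!is.numeric(tors) || anyNA(tors)) {
    abort("class-defining torsions must be numeric and complete")
  }
  if (any(tors < 0 | tors >= 360)) {
    abort("class-defining torsions must be normalized to [0, 360)")
  }
  for (i in seq_len(nrow(classes))) {
    surf <- class_surface(classes, classes$class_id[i])
    if (!is.null(surf)) {
      ka <- torsion_bin(classes$alpha3[i])
      kz <- torsion_bin(classes$zeta[i])
      if (abs(surf[ka, kz] - classes$sigma_ppm[i]) > tol) {
        abort(paste0("sigma_surface of ", classes$class_id[i],
                     " disagrees with sigma_ppm at the class-defining bin"))
      }
    }
    curve <- class_curve(classes, classes$class_id[i])
    if (!is.null(curve)) {
      ke <- torsion_bin(classes$epsilon[i])
      if (abs(curve[ke] - classes$j_hz[i]) > tol) {
        abort(paste0("j_curve of ", classes$class_id[i],
                     " disagrees with j_hz at the class-defining bin"))
      }
    }
  }
  invisible(classes)
}

# Grid accessors: surfaces/curves live in list-columns that may be absent.
class_surface <- function(classes, class_id) {
  if (!"sigma_surface" %in% names(classes)) return(NULL)
  i <- match(class_id, classes$class_id)
  if (is.na(i)) return(NULL)
  classes$sigma_surface[[i]]
}

class_curve <- function(classes, class_id) {
  if (!"j_curve" %in% names(classes)) return(NULL)
  i <- match(class_id, classes$class_id)
  if (is.na(i)) return(NULL)
  classes$j_curve[[i]]
}

#' Read an NtC class-definition table
#'
#' Reads a CSV/TSV table with one row per NtC class, carrying the nine
#' class-defining backbone torsions (degrees), the class family
#' (`BI_family`, `BII_family` or `other`), and the per-class NMR
#' parameters `sigma_ppm` (31P shielding) and `j_hz` (3J(P,H3')
#' coupling). Torsions are normalized to `[0, 360)` on input.
#'
#' Optional per-class geometric dependence grids are read from sidecar
#' files in `grid_dir`: `<class_id>.sigma_grid.csv` (a headerless 36x36
#' grid of shielding over (alpha3, zeta) bins, rows indexing alpha3) and
#' `<class_id>.j_curve.csv` (36 rows of coupling over epsilon bins).
#'
#' @param path Path to the class table (CSV or TSV, autodetected by
#'   extension; one header row).
#' @param grid_dir Optional directory containing sidecar grid files.
#' @return A validated class table: a tibble with one row per class and
#'   list-columns `sigma_surface` / `j_curve` (entries `NULL` when no
#'   sidecar exists), plus a `source` attribute recording provenance.
#' @export
read_class_table <- function(path, grid_dir = NULL) {
  if (!file.exists(path)) abort(paste0("class table not found: ", path))
  tbl <- read_delim_auto(path)
  missing_cols <- setdiff(class_table_cols(), names(tbl))
  if (length(missing_cols) > 0) {
    abort(paste0("class table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  for (tn in torsion_names()) {
    bad <- which(is.na(suppressWarnings(as.numeric(tbl[[tn]]))))
    if (length(bad) > 0) {
      abort(paste0("non-numeric torsion '", tn, "' in row ", bad[1]))
    }
    tbl[[tn]] <- normalize_angle(as.numeric(tbl[[tn]]))
  }
  tbl$sigma_surface <- lapply(tbl$class_id, function(id) {
    f <- if (is.null(grid_dir)) "" else
      file.path(grid_dir, paste0(id, ".sigma_grid.csv"))
    if (nzchar(f) && file.exists(f)) {
      m <- as.matrix(utils::read.csv(f, header = FALSE))
      dimnames(m) <- NULL
      stopifnot(identical(dim(m), c(36L, 36L)))
      m
    } else NULL
  })
  tbl$j_curve <- lapply(tbl$class_id, function(id) {
    f <- if (is.null(grid_dir)) "" else
      file.path(grid_dir, paste0(id, ".j_curve.csv"))
    if (nzchar(f) && file.exists(f)) {
      v <- utils::read.csv(f, header = FALSE)[[1]]
      stopifnot(length(v) == 36L)
      as.numeric(v)
    } else NULL
  })
  out <- tibble::as_tibble(tbl[c(class_table_cols(),
                                 "sigma_surface", "j_curve")])
  attr(out, "source") <- path
  validate_class_table(out)
  out
}

#' Write an NtC class-definition table
#'
#' Inverse of [read_class_table()]: writes the scalar columns to `path`
#' and any attached dependence grids to sidecar files in `grid_dir`.
#'
#' @param classes A validated class table.
#' @param path Output CSV/TSV path.
#' @param grid_dir Directory for sidecar grid files (created if needed);
#'   defaults to the directory of `path`.
#' @return `path`, invisibly.
#' @export
write_class_table <- function(classes, path, grid_dir = dirname(path)) {
  scalar <- classes[class_table_cols()]
  write_delim_auto(scalar, path)
  if (!dir.exists(grid_dir)) dir.create(grid_dir, recursive = TRUE)
  for (i in seq_len(nrow(classes))) {
    id <- classes$class_id[i]
    surf <- class_surface(classes, id)
    if (!is.null(surf)) {
      utils::write.table(surf,
        file.path(grid_dir, paste0(id, ".sigma_grid.csv")),
        sep = ",", row.names = FALSE, col.names = FALSE)
    }
    curve <- class_curve(classes, id)
    if (!is.null(curve)) {
      utils::write.table(data.frame(j = curve),
        file.path(grid_dir, paste0(id, ".j_curve.csv")),
        sep = ",", row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(path)
}

# Domain-realistic B-form backbone torsion centers for the synthetic
# class inventory. BI classes have epsilon - zeta < 0, BII classes >= 0;
# every pair of classes is separated by >= 45 degrees in at least one
# torsion so a +/- 2 degree seed jitter preserves >= 40 separation.
synthetic_class_centers <- function() {
  tibble::tribble(
    ~class_id, ~family, ~delta5, ~chi5, ~epsilon, ~zeta, ~alpha3, ~beta3,
      ~gamma3, ~delta3, ~chi3, ~sigma_ppm, ~j_hz,
    "BB00", "BI_family",  135, 250, 185, 265, 300, 175, 55, 135, 250,
      280.00, 2.0,
    "BB01", "BI_family",   85, 200, 190, 260, 300, 175, 55, 135, 250,
      279.70, 1.8,
    "BB04", "BII_family", 140, 255, 200, 170, 300, 140, 55, 130, 255,
      279.36, 5.0,
    "BB07", "BII_family", 140, 260, 245, 175, 300, 140, 55, 140, 270,
      275.77, 6.5,
    "BA05", "other",       85, 205, 190, 265, 295, 170, 55,  85, 205,
      279.90, 1.9,
    "AB01", "other",       85, 200, 210, 310, 295, 175, 55, 140, 250,
      279.20, 5.5
  )
}

#' Generate a synthetic NtC class-definition table
#'
#' Builds a six-class inventory spanning the conformers that dominate
#' B-DNA phosphate equilibria: canonical BI (`BB00`), a BI variant
#' (`BB01`), the BI-BII bridging class (`BB04`), canonical BII
#' (`BB07`), and two further classes (`BA05`, `AB01`) outside the
#' BI/BII families. Torsion centers are realistic B-form values with a
#' small (+/- 2 degree) seed-dependent jitter; class centers stay
#' pairwise separated by at least 40 degrees in at least one torsion.
#' Per-class shielding surfaces over (alpha3, zeta) and coupling curves
#' over epsilon are attached via [synthetic_dependences()], so the grid
#' value at each class-defining bin equals the class scalar exactly.
#'
#' @param seed Integer seed; the same seed reproduces the table
#'   bit-identically.
#' @return A validated class table (see [read_class_table()]).
#' @export
#' @examples
#' classes <- synthetic_class_table(seed = 1)
#' classes$class_id
synthetic_class_table <- function(seed = 1L) {
  centers <- synthetic_class_centers()
  tors <- as.matrix(centers[torsion_names()])
  jitter <- with_seed(seed, {
    matrix(stats::runif(length(tors), -2, 2), nrow(tors), ncol(tors))
  })
  centers[torsion_names()] <- normalize_angle(tors + jitter)
  out <- synthetic_dependences(centers, seed = seed)
  attr(out, "source") <- paste0("synthetic_class_table(seed=", seed, ")")
  validate_class_table(out)
  out
}
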