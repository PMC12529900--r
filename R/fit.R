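#' Root-mean-square deviation between calculated and experimental values
#'
#' The accuracy metric used throughout: `sqrt(mean((calc - exp)^2))`
#' over the paired steps. (In the 31P literature this quantity is often
#' reported under the label "MAD"; the printed benchmark values match
#' the root-mean-square form, which is what is implemented here.)
#'
#' @param calc,exp Numeric vectors of equal length.
#' @return A non-negative scalar in the units of the inputs; zero iff
#'   all deviations are zero.
#' @export
#' @examples
#' rms_deviation(c(1, 3), c(0, 1))  # sqrt(2.5)
rms_deviation <- function(calc, exp) {
  stopifnot(length(calc) == length(exp), length(calc) >= 1)
  sqrt(mean((calc - exp)^2))
}

#' Score agreement between calculated and experimental observables
#'
#' Pairs calculated and experimental per-step values by `step_id`,
#' computes per-step deviations (calc - exp), and summarises them with
#' the root-mean-square metric [rms_deviation()].
#'
#' @param calc,exp Tibbles with `step_id` and the column named by
#'   `value`. The step sets must match exactly.
#' @param value Name of the observable column present in both tables
#'   (e.g. `"delta_ppm"` or `"j_hz"`).
#' @param observable Short label stored in the report (defaults to
#'   `value`).
#' @return An object of class `ntc_score`: a list with `observable`,
#'   `deviations` (tibble `step_id, calc, exp, dev`) and `mad` (the
#'   root-mean-square deviation). Has [generics::tidy()] and
#'   [generics::glance()] methods.
#' @export
#' @examples
#' calc <- tibble::tibble(step_id = c("a", "b"), delta_ppm = c(1, 3))
#' exp <- tibble::tibble(step_id = c("a", "b"), delta_ppm = c(0, 1))
#' glance(score_agreement(calc, exp, "delta_ppm"))
score_agreement <- function(calc, exp, value, observable = value) {
  only_calc <- setdiff(calc$step_id, exp$step_id)
  only_exp <- setdiff(exp$step_id, calc$step_id)
  if (length(only_calc) > 0 || length(only_exp) > 0) {
    abort(paste0(
      "step sets differ between calculation and experiment;",
      if (length(only_calc) > 0)
        paste0(" only in calc: ", paste(only_calc, collapse = ", ")),
      if (length(only_exp) > 0)
        paste0(" only in exp: ", paste(only_exp, collapse = ", "))))
  }
  calc_v <- calc[[value]]
  exp_v <- exp[[value]][match(calc$step_id, exp$step_id)]
  dev <- tibble::tibble(step_id = calc$step_id, calc = calc_v,
                        exp = exp_v, dev = calc_v - exp_v)
  structure(
    list(observable = observable, deviations = dev,
         mad = rms_deviation(dev$calc, dev$exp)),
    class = "ntc_score"
  )
}

#' @export
print.ntc_score <- function(x, ...) {
  cat("<ntc_score> ", x$observable, ": RMS deviation ",
      format(x$mad, digits = 4), " over ", nrow(x$deviations),
      " steps\n", sep = "")
  invisible(x)
}

#' @export
tidy.ntc_score <- function(x, ...) x$deviations

#' @export
glance.ntc_score <- function(x, ...) {
  tibble::tibble(observable = x$observable, mad = x$mad,
                 n_steps = nrow(x$deviations))
}

#' Define the BI'/BII' fitting groups
#'
#' The four NtC classes that dominate B-DNA phosphate equilibria are
#' grouped for population fitting: `BB00 + BB01` as BI' and
#' `BB04 + BB07` as BII'. Population ratios within each group stay
#' fixed at their input values during fitting; only the split of the
#' pooled group mass between BI' and BII' is adjusted. All classes
#' outside both groups retain their input populations unchanged.
#'
#' @param bi_prime,bii_prime Character vectors of class ids; must be
#'   disjoint.
#' @return An object of class `ntc_groups`.
#' @export
fit_groups <- function(bi_prime = c("BB00", "BB01"),
                       bii_prime = c("BB04", "BB07")) {
  if (length(intersect(bi_prime, bii_prime)) > 0) {
    abort("BI' and BII' groups must be disjoint")
  }
  structure(list(bi_prime = bi_prime, bii_prime = bii_prime),
            class = "ntc_groups")
}

# Split the pooled BI'+BII' mass of one step's weights at BII' fraction
# x_bii, preserving within-group ratios (equal split when a group had
# zero input mass). Non-pool classes are untouched.
regroup_weights <- function(x_bii, weights_step, groups) {
  stopifnot(x_bii >= 0, x_bii <= 1)
  pool_ids <- c(groups$bi_prime, groups$bii_prime)
  in_pool <- weights_step$class_id %in% pool_ids
  p <- sum(weights_step$weight[in_pool])
  if (p <= 0) abort("empty BI'/BII' pool: no mass to redistribute")
  out <- weights_step
  split_group <- function(ids, mass) {
    w <- out$weight[out$class_id %in% ids]
    present <- out$class_id %in% ids
    if (!any(present)) return(out)
    ratios <- if (sum(w) > 0) w / sum(w) else rep(1 / sum(present),
                                                  sum(present))
    out$weight[present] <<- mass * ratios
    invisible(NULL)
  }
  split_group(groups$bi_prime, p * (1 - x_bii))
  split_group(groups$bii_prime, p * x_bii)
  out
}

#' Forward-predict observables for a given BII' fraction
#'
#' Reassigns the pooled BI'+BII' population mass of one step according
#' to the BII' fraction `x_bii` (within-group ratios fixed, non-pool
#' classes untouched) and computes the population-weighted observables
#' of the resulting weights. The observables are affine in `x_bii`.
#'
#' @param x_bii BII' fraction of the pooled group mass, in `[0, 1]`.
#' @param weights_step One step's population tibble
#'   (`step_id, class_id, weight`).
#' @param groups An [fit_groups()] object.
#' @param classes A validated class table.
#' @return A one-row tibble `step_id, sigma_ppm, j_hz`, with the
#'   regrouped weights attached as attribute `"weights"`.
#' @export
forward_observables <- function(x_bii, weights_step, groups, classes) {
  w <- regroup_weights(x_bii, weights_step, groups)
  obs <- population_average(w, classes)
  attr(obs, "weights") <- w
  obs
}

#' Fit one step's BII' fraction to a single observable
#'
#' Solves the scalar affine equation `observable(x_bii) = target` for
#' the BII' fraction of the pooled BI'+BII' population mass. Solutions
#' outside `[0, 1]` (possible under experimental noise) are clamped to
#' the boundary and flagged.
#'
#' @param target Observed value (Hz for `"j_hz"`, ppm of shielding for
#'   `"sigma_ppm"`).
#' @param weights_step One step's population tibble.
#' @param groups An [fit_groups()] object.
#' @param classes A validated class table.
#' @param value Observable column to match: `"j_hz"` or `"sigma_ppm"`.
#' @param tol Degeneracy tolerance: if the BI'-pure and BII'-pure
#'   predictions differ by less than `tol` the data carry no
#'   information on the split and an error is raised.
#' @return A one-row tibble `step_id, x_bii, clamped` with the fitted
#'   weights attached as attribute `"weights"`.
#' @export
#' @examples
#' classes <- synthetic_class_table(seed = 1)
#' w <- tibble::tibble(step_id = "s", class_id = c("BB00", "BB07"),
#'                     weight = c(0.5, 0.5))
#' fit_step_population(4, w, fit_groups(), classes, "j_hz")
fit_step_population <- function(target, weights_step, groups, classes,
                                value = c("j_hz", "sigma_ppm"),
                                tol = 1e-9) {
  value <- match.arg(value)
  o0 <- forward_observables(0, weights_step, groups, classes)[[value]]
  o1 <- forward_observables(1, weights_step, groups, classes)[[value]]
  if (abs(o1 - o0) < tol) {
    abort(paste0("degenerate fit: BI' and BII' predict the same ",
                 value, " (", format(o0), "); no information on the split"))
  }
  x <- (target - o0) / (o1 - o0)
  clamped <- x < 0 || x > 1
  x <- min(max(x, 0), 1)
  fitted <- forward_observables(x, weights_step, groups, classes)
  tibble::tibble(step_id = weights_step$step_id[1], x_bii = x,
                 clamped = clamped) %>%
    structure(weights = attr(fitted, "weights"))
}

#' Fit BI'/BII' populations to experimental NMR data
#'
#' Two-stage, per-phosphate refinement of simulated NtC populations
#' against experiment. Stage `"j"` fits each step's BII' fraction to
#' its experimental 3J(P,H3') coupling; because this also refits the
#' internal reference phosphate, the reference shielding used for
#' chemical shifts is refreshed from the stage's result. Stage
#' `"delta"` then refits each step against its experimental 31P shift,
#' i.e. against the target shielding `sigma(ref) - delta_exp` under the
#' refreshed reference. Each stage overwrites the previous stage's
#' split; steps are fitted independently. Degenerate steps (no
#' observable contrast between BI' and BII') are reported and retain
#' their incoming weights.
#'
#' @param exp Experimental tibble with `step_id` and, per stage used,
#'   `j_hz` and/or `delta_ppm` (internally referenced shift; a
#'   `delta_prime` column is re-referenced automatically when
#'   `delta_ppm` is absent).
#' @param weights Per-step population tibble (e.g. from
#'   [population_weights()]) for the same steps.
#' @param classes A validated class table.
#' @param groups An [fit_groups()] object.
#' @param stages Character vector, ordered subset of
#'   `c("j", "delta")`.
#' @param reference_step Internal reference phosphate label.
#' @return An object of class `ntc_fit`: a list with per-step results
#'   (`steps`), fitted weights (`weights_fitted`), differential weights
#'   `delta_w` (original minus fitted), refitted observables
#'   (`observables`, with `delta_ppm` referenced to the fitted
#'   reference), and `scores` (an [score_agreement()] report per
#'   available observable). Has `tidy()`, `glance()` and `autoplot()`
#'   methods.
#' @export
fit_equilibrium <- function(exp, weights, classes, groups = fit_groups(),
                            stages = c("j", "delta"),
                            reference_step = "A6pT7") {
  stopifnot(all(stages %in% c("j", "delta")), length(stages) >= 1)
  if (!"delta_ppm" %in% names(exp) && "delta_prime" %in% names(exp)) {
    exp <- rereference_experimental(exp, reference_step)
  }
  steps <- unique(weights$step_id)
  current <- weights
  status <- tibble::tibble(step_id = steps, x_bii = NA_real_,
                           clamped = FALSE, degenerate = FALSE)
  ref_sigma <- function(w) {
    population_average(
      w %>% dplyr::filter(.data$step_id == reference_step), classes
    )$sigma_ppm
  }
  fit_stage <- function(value, targets) {
    for (s in steps) {
      tgt <- targets[match(s, exp$step_id)]
      if (is.na(tgt)) next
      ws <- current %>% dplyr::filter(.data$step_id == s)
      res <- tryCatch(
        fit_step_population(tgt, ws, groups, classes, value),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        warn(paste0("step ", s, " skipped in stage '", value, "': ",
                    conditionMessage(res)))
        status$degenerate[status$step_id == s] <<- TRUE
        next
      }
      status$x_bii[status$step_id == s] <<- res$x_bii
      status$clamped[status$step_id == s] <<- res$clamped
      current <<- dplyr::bind_rows(
        current %>% dplyr::filter(.data$step_id != s),
        attr(res, "weights")
      )
    }
  }
  for (stage in stages) {
    if (stage == "j") {
      if (!"j_hz" %in% names(exp)) {
        abort("stage 'j' requested but experimental table has no j_hz")
      }
      fit_stage("j_hz", exp$j_hz)
    } else {
      if (!"delta_ppm" %in% names(exp)) {
        abort(paste0("stage 'delta' requested but experimental table has",
                     " neither delta_ppm nor delta_prime"))
      }
      # shift targets become shielding targets under the refreshed
      # (possibly J-stage-fitted) internal reference
      sig_ref <- ref_sigma(current)
      fit_stage("sigma_ppm", sig_ref - exp$delta_ppm)
    }
  }
  current <- current %>% dplyr::arrange(.data$step_id, .data$class_id)
  obs <- population_average(current, classes) %>%
    reference_delta(reference_step)
  dw <- weights %>%
    dplyr::select("step_id", "class_id", w_original = "weight") %>%
    dplyr::full_join(
      current %>% dplyr::select("step_id", "class_id",
                                w_fitted = "weight"),
      by = c("step_id", "class_id")) %>%
    tidyr::replace_na(list(w_original = 0, w_fitted = 0)) %>%
    dplyr::mutate(delta_w = .data$w_original - .data$w_fitted)
  scores <- list()
  if ("j_hz" %in% names(exp)) {
    scores$j <- score_agreement(obs, exp, "j_hz", observable = "j")
  }
  if ("delta_ppm" %in% names(exp)) {
    scores$delta <- score_agreement(obs, exp, "delta_ppm",
                                    observable = "delta")
  }
  structure(
    list(steps = status, weights_fitted = current, delta_w = dw,
         observables = obs, scores = scores, groups = groups,
         stages = stages, reference_step = reference_step),
    class = "ntc_fit"
  )
}

#' @export
print.ntc_fit <- function(x, ...) {
  cat("<ntc_fit> BI'/BII' population fit over ", nrow(x$steps),
      " steps (stages: ", paste(x$stages, collapse = " -> "), ")\n",
      sep = "")
  for (sc in x$scores) {
    cat("  RMS deviation (", sc$observable, "): ",
        format(sc$mad, digits = 4), "\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.ntc_fit <- function(x, ...) {
  out <- x$steps %>% dplyr::left_join(x$observables, by = "step_id")
  for (sc in x$scores) {
    dev <- sc$deviations %>%
      dplyr::select("step_id", dev = "dev")
    names(dev)[2] <- paste0("dev_", sc$observable)
    out <- out %>% dplyr::left_join(dev, by = "step_id")
  }
  out
}

#' @export
glance.ntc_fit <- function(x, ...) {
  tibble::tibble(
    n_steps = nrow(x$steps),
    n_clamped = sum(x$steps$clamped, na.rm = TRUE),
    n_degenerate = sum(x$steps$degenerate),
    mad_delta = if (!is.null(x$scores$delta)) x$scores$delta$mad
                else NA_real_,
    mad_j = if (!is.null(x$scores$j)) x$scores$j$mad else NA_real_
  )
}
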