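test_that("the agreement metric is the root-mean-square deviation", {
  expect_identical(rms_deviation(c(1, 2), c(1, 2)), 0)
  expect_equal(rms_deviation(c(1, 3), c(0, 1)), sqrt(2.5))
  # permutation invariance and absolute homogeneity
  set.seed(31)
  x <- rnorm(8); y <- rnorm(8)
  p <- sample(8)
  expect_equal(rms_deviation(x[p], y[p]), rms_deviation(x, y))
  expect_equal(rms_deviation(3 * x, 3 * y), 3 * rms_deviation(x, y))
  expect_equal(rms_deviation(-x, -y), rms_deviation(x, y))
})

test_that("published dodecamer benchmarks reproduce the printed
           agreement values", {
  b <- dd_shift_benchmark()
  bj <- dd_coupling_benchmark()
  expect_equal(round(rms_deviation(b$xray, b$experiment), 2), 1.16)
  expect_equal(round(rms_deviation(bj$xray, bj$experiment), 2), 2.46)
  expect_equal(round(rms_deviation(bj$nmr, bj$experiment), 2), 2.61)
  # printed-input rounding leaves the NMR-structure shift value within
  # one hundredth of its published 0.27 ppm
  expect_equal(rms_deviation(b$nmr, b$experiment), 0.27,
               tolerance = 0.011 / 0.27)
  # the mean-absolute reading would give a very different number
  expect_equal(round(mean(abs(b$xray - b$experiment)), 2), 0.54)
})

test_that("score_agreement pairs steps and rejects mismatched sets", {
  calc <- tibble::tibble(step_id = c("a", "b"), delta_ppm = c(1, 3))
  exp <- tibble::tibble(step_id = c("b", "a"), delta_ppm = c(1, 0))
  sc <- score_agreement(calc, exp, "delta_ppm")
  expect_equal(sc$mad, sqrt(2.5))
  expect_equal(tidy(sc)$dev, c(1, 2))
  expect_equal(glance(sc)$n_steps, 2L)
  exp2 <- tibble::tibble(step_id = c("a", "zzz"), delta_ppm = 0)
  expect_error(score_agreement(calc, exp2, "delta_ppm"), "zzz")
})

# Two-class pool: A (BI') at 2 Hz, B (BII') at 6 Hz.
pool_setup <- function() {
  list(classes = toy_two_class_table(sigma = c(10, 20), j = c(2, 6)),
       weights = tibble::tibble(step_id = "s",
                                class_id = c("A", "B"),
                                weight = c(0.5, 0.5)),
       groups = fit_groups(bi_prime = "A", bii_prime = "B"))
}

test_that("forward observables are affine in the BII' fraction", {
  s <- pool_setup()
  o0 <- forward_observables(0, s$weights, s$groups, s$classes)
  o1 <- forward_observables(1, s$weights, s$groups, s$classes)
  expect_equal(o0$j_hz, 2)
  expect_equal(o1$j_hz, 6)
  for (x in c(0.25, 0.5, 0.9)) {
    ox <- forward_observables(x, s$weights, s$groups, s$classes)
    expect_equal(ox$j_hz, (1 - x) * o0$j_hz + x * o1$j_hz)
    expect_equal(ox$sigma_ppm, (1 - x) * o0$sigma_ppm + x * o1$sigma_ppm)
  }
  # the input's own BII' share is a fixed point
  own <- forward_observables(0.5, s$weights, s$groups, s$classes)
  expect_equal(own$j_hz,
               population_average(s$weights, s$classes)$j_hz)
})

test_that("non-pool classes are untouched by regrouping", {
  classes <- synthetic_class_table(seed = 1)
  w <- tibble::tibble(step_id = "s",
                      class_id = c("BB00", "BB01", "BB04", "BB07",
                                   "AB01", "BA05"),
                      weight = c(0.3, 0.2, 0.1, 0.2, 0.15, 0.05))
  obs <- forward_observables(0.8, w, fit_groups(), classes)
  w2 <- attr(obs, "weights")
  expect_identical(w2$weight[w2$class_id == "AB01"], 0.15)
  expect_identical(w2$weight[w2$class_id == "BA05"], 0.05)
  expect_equal(sum(w2$weight), 1)
  # within-group ratios preserved: BB00:BB01 stays 3:2
  wb <- setNames(w2$weight, w2$class_id)
  expect_equal(wb[["BB00"]] / wb[["BB01"]], 1.5)
})

test_that("single-step fits solve the affine equation and clamp", {
  s <- pool_setup()
  fit <- fit_step_population(3, s$weights, s$groups, s$classes, "j_hz")
  expect_equal(fit$x_bii, 0.25)
  expect_false(fit$clamped)
  # fit then forward reproduces the target exactly
  obs <- forward_observables(fit$x_bii, s$weights, s$groups, s$classes)
  expect_equal(obs$j_hz, 3)

  at0 <- fit_step_population(2, s$weights, s$groups, s$classes, "j_hz")
  expect_equal(at0$x_bii, 0)
  over <- fit_step_population(7, s$weights, s$groups, s$classes, "j_hz")
  expect_equal(over$x_bii, 1)
  expect_true(over$clamped)

  degen <- s$classes
  degen$j_hz <- c(4, 4)
  expect_error(
    fit_step_population(3, s$weights, s$groups, degen, "j_hz"),
    "degenerate")
})

test_that("self-consistent experiments leave populations unchanged", {
  run <- tiny_run()
  expd <- synthetic_experiment(run$weights, run$classes, 0, 0, seed = 1)
  fit <- fit_equilibrium(expd, run$weights, run$classes)
  expect_lt(max(abs(fit$delta_w$delta_w)), 1e-10)
  g <- glance(fit)
  expect_lt(g$mad_delta, 1e-10)
  expect_lt(g$mad_j, 1e-10)
  # non-pool populations bit-identical through the fit
  pool <- c(fit$groups$bi_prime, fit$groups$bii_prime)
  orig <- run$weights |> dplyr::filter(!class_id %in% pool) |>
    dplyr::arrange(step_id, class_id)
  fitted <- fit$weights_fitted |> dplyr::filter(!class_id %in% pool) |>
    dplyr::arrange(step_id, class_id)
  expect_identical(orig$weight, fitted$weight)
})

test_that("zero-noise experiments at known BII' fractions are recovered
           exactly", {
  run <- tiny_run()
  groups <- fit_groups()
  steps <- unique(run$weights$step_id)
  x_true <- setNames(seq(0.05, 0.95, length.out = length(steps)), steps)
  target_w <- purrr::map_dfr(steps, function(s) {
    ws <- run$weights |> dplyr::filter(step_id == s)
    attr(forward_observables(x_true[[s]], ws, groups, run$classes),
         "weights")
  })
  expd <- synthetic_experiment(target_w, run$classes, 0, 0, seed = 1)
  fit <- fit_equilibrium(expd, run$weights, run$classes, groups)
  expect_equal(setNames(fit$steps$x_bii, fit$steps$step_id)[steps],
               x_true, tolerance = 1e-10)
  expect_false(any(fit$steps$degenerate))
  # fitted observables reproduce the experiment
  g <- glance(fit)
  expect_lt(g$mad_j, 1e-10)
  expect_lt(g$mad_delta, 1e-10)
})

test_that("noisy couplings are recovered within the affine-slope bound", {
  s <- pool_setup()
  x_true <- 0.4
  slope <- 4  # J(1) - J(0) for the 2/6 Hz pool
  sd_j <- 0.4
  target0 <- 2 + slope * x_true
  set.seed(211)
  err <- replicate(200, {
    tgt <- target0 + rnorm(1, 0, sd_j)
    fit <- fit_step_population(tgt, s$weights, s$groups, s$classes,
                               "j_hz")
    abs(fit$x_bii - x_true)
  })
  # unclamped estimator error is noise/slope; its median is below
  # the noise sd over the slope
  expect_lt(stats::median(err), sd_j / slope)
})

test_that("degenerate steps are skipped with their weights retained", {
  classes <- toy_two_class_table(sigma = c(10, 20), j = c(4, 4))
  classes <- dplyr::bind_rows(
    classes,
    toy_two_class_table(sigma = c(12, 22), j = c(2, 6)) |>
      dplyr::mutate(class_id = c("A6", "B6"), delta5 = c(30, 75)))
  w <- tibble::tibble(
    step_id = rep(c("s1", "A6pT7"), each = 2),
    class_id = c("A", "B", "A6", "B6"),
    weight = rep(0.5, 4))
  groups <- fit_groups(bi_prime = c("A", "A6"),
                       bii_prime = c("B", "B6"))
  expd <- tibble::tibble(step_id = c("s1", "A6pT7"),
                         j_hz = c(5, 3), delta_ppm = c(0.5, 0))
  expect_warning(
    fit <- fit_equilibrium(expd, w, classes, groups, stages = "j"),
    "degenerate")
  st <- fit$steps
  expect_true(st$degenerate[st$step_id == "s1"])
  kept <- fit$weights_fitted |> dplyr::filter(step_id == "s1")
  expect_identical(kept$weight, c(0.5, 0.5))
})

test_that("fit tidiers expose per-step and whole-fit summaries", {
  run <- tiny_run()
  expd <- synthetic_experiment(run$weights, run$classes,
                               noise_delta = 0.05, noise_j = 0.2,
                               seed = 5)
  fit <- fit_equilibrium(expd, run$weights, run$classes)
  td <- tidy(fit)
  expect_true(all(c("step_id", "x_bii", "clamped", "delta_ppm", "j_hz",
                    "dev_delta", "dev_j") %in% names(td)))
  expect_identical(nrow(td), 11L)
  g <- glance(fit)
  expect_identical(g$n_steps, 11L)
  expect_true(is.finite(g$mad_delta) && is.finite(g$mad_j))
  # reference shift is exactly zero after fitting
  expect_identical(
    fit$observables$delta_ppm[fit$observables$step_id == "A6pT7"], 0)
})
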