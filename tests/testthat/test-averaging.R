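test_that("population averages are the weighted sums of class scalars", {
  classes <- toy_two_class_table(sigma = c(10, 20), j = c(2, 6))
  w <- tibble::tibble(step_id = "s", class_id = c("A", "B"),
                      weight = c(0.5, 0.5))
  got <- population_average(w, classes)
  expect_equal(got$sigma_ppm, 15)
  expect_equal(got$j_hz, 4)

  # point mass
  w1 <- tibble::tibble(step_id = "s", class_id = "B", weight = 1)
  got1 <- population_average(w1, classes)
  expect_equal(got1$sigma_ppm, 20)
  expect_equal(got1$j_hz, 6)

  # permutation invariance
  got_rev <- population_average(w[2:1, ], classes)
  expect_equal(got_rev, got)

  # unknown class is named in the error
  w_bad <- tibble::tibble(step_id = "s", class_id = "ZZ99", weight = 1)
  expect_error(population_average(w_bad, classes), "ZZ99")
})

test_that("averages are linear in the weights", {
  classes <- synthetic_class_table(seed = 1)
  w1 <- tibble::tibble(step_id = "s",
                       class_id = c("BB00", "BB07"),
                       weight = c(0.8, 0.2))
  w2 <- tibble::tibble(step_id = "s",
                       class_id = c("BB00", "BB04"),
                       weight = c(0.4, 0.6))
  blend <- dplyr::bind_rows(w1, w2) |>
    dplyr::group_by(step_id, class_id) |>
    dplyr::summarise(weight = sum(weight) / 2, .groups = "drop")
  o1 <- population_average(w1, classes)
  o2 <- population_average(w2, classes)
  ob <- population_average(blend, classes)
  expect_equal(ob$sigma_ppm, (o1$sigma_ppm + o2$sigma_ppm) / 2)
  expect_equal(ob$j_hz, (o1$j_hz + o2$j_hz) / 2)
})

test_that("probability averaging reduces to population averaging on
           constant grids", {
  run <- tiny_run()
  classes <- run$classes
  const <- classes
  const$sigma_surface <- lapply(seq_len(nrow(const)), function(i) {
    matrix(const$sigma_ppm[i], 36, 36)
  })
  const$j_curve <- lapply(seq_len(nrow(const)), function(i) {
    rep(const$j_hz[i], 36)
  })
  pop <- population_average(run$weights, classes)
  prob <- probability_average(run$weights, const, run$trajectory,
                              run$assignments)
  expect_equal(prob$sigma_ppm, pop$sigma_ppm, tolerance = 1e-12)
  expect_equal(prob$j_hz, pop$j_hz, tolerance = 1e-12)
})

test_that("probability averaging takes expectations over the torsion
           distributions", {
  # one BI-family class whose frames occupy two epsilon bins with
  # probabilities 1/4 and 3/4; curve values there are 2 and 6 Hz
  classes <- toy_two_class_table()
  classes$family <- c("BI_family", "other")
  ke1 <- torsion_bin(15); ke2 <- torsion_bin(25)
  curve <- rep(0, 36); curve[ke1] <- 2; curve[ke2] <- 6
  surf <- matrix(classes$sigma_ppm[1], 36, 36)
  classes$sigma_surface[[1]] <- surf
  classes$j_curve[[1]] <- curve
  # keep the table internally consistent at the class-defining bins
  classes$epsilon[1] <- 15
  classes$j_hz[1] <- 2
  t0 <- as.numeric(classes[1, torsion_names()])
  traj <- purrr::map_dfr(1:4, function(i) {
    tv <- t0
    tv[3] <- if (i == 1) 15 else 25
    tibble::as_tibble(as.list(setNames(tv, torsion_names()))) |>
      dplyr::mutate(step_id = "s", frame = i, .before = 1)
  })
  assign <- tibble::tibble(step_id = "s", frame = 1:4, class_id = "A",
                           distance_sq = 0)
  w <- tibble::tibble(step_id = "s", class_id = "A", weight = 1)
  got <- probability_average(w, classes, traj, assign)
  expect_equal(got$j_hz, 0.25 * 2 + 0.75 * 6)
  expect_equal(got$sigma_ppm, classes$sigma_ppm[1])

  # a family class without grids is an error
  classes2 <- classes
  classes2$j_curve[1] <- list(NULL)
  expect_error(probability_average(w, classes2, traj, assign), "j_curve")
})

test_that("point-mass torsion distributions pick single grid entries", {
  classes <- toy_two_class_table()
  classes$family[1] <- "BII_family"
  surf <- matrix(0, 36, 36)
  ka <- torsion_bin(classes$alpha3[1]); kz <- torsion_bin(classes$zeta[1])
  surf[ka, kz] <- classes$sigma_ppm[1]
  classes$sigma_surface[[1]] <- surf
  curve <- rep(0, 36); curve[torsion_bin(classes$epsilon[1])] <-
    classes$j_hz[1]
  classes$j_curve[[1]] <- curve
  t0 <- as.numeric(classes[1, torsion_names()])
  traj <- tibble::as_tibble(as.list(setNames(t0, torsion_names()))) |>
    dplyr::mutate(step_id = "s", frame = 1L, .before = 1)
  assign <- tibble::tibble(step_id = "s", frame = 1L, class_id = "A",
                           distance_sq = 0)
  w <- tibble::tibble(step_id = "s", class_id = "A", weight = 1)
  got <- probability_average(w, classes, traj, assign)
  expect_equal(got$sigma_ppm, classes$sigma_ppm[1])
  expect_equal(got$j_hz, classes$j_hz[1])
})

test_that("internal referencing zeroes the reference and is offset
           invariant", {
  obs <- tibble::tibble(step_id = c("A6pT7", "C1pG2", "G2pC3"),
                        sigma_ppm = c(280.0, 279.5, 281.2),
                        j_hz = 2)
  got <- reference_delta(obs)
  expect_identical(got$delta_ppm[got$step_id == "A6pT7"], 0)
  expect_equal(got$delta_ppm[got$step_id == "C1pG2"], 0.5)
  # adding a constant shielding offset changes no delta
  shifted <- obs |> dplyr::mutate(sigma_ppm = sigma_ppm + 3.7)
  expect_equal(reference_delta(shifted)$delta_ppm, got$delta_ppm)
  # equal shieldings give all-zero shifts
  flat <- obs |> dplyr::mutate(sigma_ppm = 280)
  expect_equal(reference_delta(flat)$delta_ppm, rep(0, 3))
  expect_error(reference_delta(obs[-1, ]), "A6pT7")
})

test_that("experimental re-referencing matches the internal convention", {
  exp <- tibble::tibble(step_id = c("A6pT7", "C1pG2"),
                        delta_prime = c(-4.21, -3.84))
  got <- rereference_experimental(exp)
  expect_equal(got$delta_ppm[got$step_id == "C1pG2"], 0.37)
  expect_identical(got$delta_ppm[got$step_id == "A6pT7"], 0)
  # all-equal shifts collapse to zero; re-referencing is idempotent
  flat <- tibble::tibble(step_id = c("A6pT7", "x"),
                         delta_prime = c(1.1, 1.1))
  expect_equal(rereference_experimental(flat)$delta_ppm, c(0, 0))
  twice <- rereference_experimental(got)
  expect_equal(twice$delta_ppm, got$delta_ppm)
  expect_error(rereference_experimental(exp[-1, ]), "A6pT7")
})
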