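# Shared fixtures, built in code.

# Minimal valid two-class table: classes "A" (BI-like) and "B"
# (BII-like) well separated in epsilon/zeta, with simple scalar
# parameters and no dependence grids.
toy_two_class_table <- function(sigma = c(10, 20), j = c(2, 6)) {
  tibble::tibble(
    class_id = c("A", "B"),
    family = c("other", "other"),
    delta5 = c(135, 140), chi5 = c(250, 260),
    epsilon = c(185, 245), zeta = c(265, 175),
    alpha3 = c(300, 300), beta3 = c(175, 140),
    gamma3 = c(55, 55), delta3 = c(135, 140), chi3 = c(250, 270),
    sigma_ppm = sigma, j_hz = j,
    sigma_surface = list(NULL, NULL), j_curve = list(NULL, NULL)
  )
}

# A small classified synthetic run shared across tests (cheap: 300
# frames per step). Memoised per test file load.
tiny_run <- local({
  cache <- NULL
  function(n_frames = 300, seed = 42) {
    if (!is.null(cache)) return(cache)
    classes <- synthetic_class_table(seed = 1)
    sim <- sample_trajectory(default_duplex_spec(n_frames = n_frames),
                             classes, seed = seed)
    assignments <- classify_trajectory(sim$trajectory, classes)
    cache <<- list(classes = classes, trajectory = sim$trajectory,
                   truth = sim$truth, assignments = assignments,
                   weights = population_weights(assignments))
    cache
  }
})

# Independent brute-force oracles, deliberately naive.

# Minimal-arc |difference| by enumerating 360-degree shifts.
oracle_abs_diff <- function(a, b) {
  min(abs(c(a - b, a - b + 360, a - b - 360)))
}

# Squared torsion distance by per-component shift enumeration.
oracle_distance_sq <- function(t1, t2) {
  s <- 0
  for (i in seq_along(t1)) s <- s + oracle_abs_diff(t1[i], t2[i])^2
  s
}

# Full linear scan over classes using the naive distance.
oracle_classify <- function(torsions, classes) {
  ids <- classes$class_id
  d <- vapply(seq_along(ids), function(j) {
    oracle_distance_sq(torsions,
                       as.numeric(classes[j, torsion_names()]))
  }, numeric(1))
  best <- min(d)
  sort(ids[d == best])[1]
}
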