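ion_with_oxygens <- function(dists) {
  n <- length(dists)
  tibble::tibble(
    atom_id = seq_len(n + 1),
    element = c(rep("O", n), "CA"),
    x = c(dists, 0), y = 0, z = 0,
    role = c(rep("atom", n), "ligand")
  )
}

test_that("contact counting uses a strict distance inequality", {
  expect_equal(count_contacts(ion_with_oxygens(3.99)), 1L)
  expect_equal(count_contacts(ion_with_oxygens(4.00)), 0L)
  expect_equal(count_contacts(ion_with_oxygens(c(1, 3.5, 3.999, 4, 7))), 3L)
})

test_that("contact counts match a brute-force distance scan", {
  set.seed(21)
  frame <- tibble::tibble(
    atom_id = 1:51,
    element = c(sample(c("O", "N", "C"), 50, replace = TRUE), "CA"),
    x = c(rnorm(50, 0, 3), 0), y = c(rnorm(50, 0, 3), 0),
    z = c(rnorm(50, 0, 3), 0),
    role = c(rep("atom", 50), "ligand")
  )
  d <- with(frame[1:50, ], sqrt(x^2 + y^2 + z^2))
  expect_equal(count_contacts(frame),
               sum(d < 4 & frame$element[1:50] == "O"))
  expect_equal(count_contacts(frame, partners = "all"), sum(d < 4))
  # monotone under uniform radial expansion about the ligand
  for (lambda in c(1.2, 1.6, 2.5)) {
    expanded <- frame
    expanded[1:50, c("x", "y", "z")] <- frame[1:50, c("x", "y", "z")] * lambda
    expect_lte(count_contacts(expanded), count_contacts(frame))
  }
})

test_that("isolated-ion SASA matches the analytic sphere area", {
  ion <- tibble::tibble(atom_id = 1, element = "CA", x = 0, y = 0, z = 0)
  area <- compute_sasa(ion, n_points = 960)
  expect_equal(area, 4 * pi * 2.9^2, tolerance = 1e-9) # every point exposed
  expect_equal(area, 105.7, tolerance = 0.005)
})

test_that("a tightly caged ion has zero accessible area", {
  cage_dirs <- fibrilmech:::fibonacci_sphere(30)
  cage <- tibble::tibble(
    atom_id = 1:31, element = c(rep("S", 30), "CA"),
    x = c(2.0 * cage_dirs[, 1], 0), y = c(2.0 * cage_dirs[, 2], 0),
    z = c(2.0 * cage_dirs[, 3], 0),
    role = c(rep("atom", 30), "ligand")
  )
  expect_equal(compute_sasa(cage), 0)
})

test_that("one neighbour reproduces the spherical-cap closed form", {
  # calcium + one oxygen at a range of separations
  for (d in c(2.5, 3.0, 3.5, 4.5)) {
    frame <- tibble::tibble(
      atom_id = 1:2, element = c("O", "CA"),
      x = c(d, 0), y = 0, z = 0, role = c("atom", "ligand")
    )
    got <- compute_sasa(frame, n_points = 4000)
    want <- oracle_two_sphere_sasa(R1 = 1.5 + 1.4, R2 = 1.52 + 1.4, d = d)
    expect_lt(abs(got - want) / want, 0.01)
  }
})

test_that("quadrature error decreases with lattice refinement", {
  # the isolated-atom case is exact at every level (all points exposed), so
  # convergence is probed on buried geometries; the lattice error oscillates
  # with the cap boundary, so it is averaged over a family of separations
  ds <- seq(2.2, 4.6, by = 0.2)
  err_at <- function(np) {
    vapply(ds, function(d) {
      frame <- tibble::tibble(atom_id = 1:2, element = c("O", "CA"),
                              x = c(d, 0), y = 0, z = 0,
                              role = c("atom", "ligand"))
      abs(compute_sasa(frame, n_points = np) -
            oracle_two_sphere_sasa(2.9, 2.92, d))
    }, numeric(1))
  }
  errs <- lapply(c(100, 1000, 10000), err_at)
  means <- vapply(errs, mean, numeric(1))
  maxes <- vapply(errs, max, numeric(1))
  expect_true(all(diff(means) < 0))
  expect_true(all(diff(maxes) < 0))
})

test_that("SASA normalisation maps the reference area to 100%", {
  expect_equal(normalize_sasa(105.7), 100)
  expect_equal(normalize_sasa(0), 0)
  expect_equal(normalize_sasa(52.85), 50)
  expect_warning(out <- normalize_sasa(110), "clip")
  expect_equal(out, 100)
  expect_error(normalize_sasa(-1), class = "fibrilmech_validation_error")
})

test_that("unknown elements require an explicit radius override", {
  frame <- tibble::tibble(atom_id = 1:2, element = c("XX", "CA"),
                          x = c(3, 0), y = 0, z = 0,
                          role = c("atom", "ligand"))
  expect_error(compute_sasa(frame), class = "fibrilmech_config_error")
  expect_silent(compute_sasa(frame, radii = c(XX = 1.6)))
})

test_that("work weighting follows the Boltzmann soft-max", {
  # equal works: plain arithmetic mean
  d <- tibble::tibble(strain = rep(c(0, 10), each = 3),
                      replicate = rep(1:3, 2),
                      value = c(1, 2, 3, 4, 5, 6),
                      work = rep(c(0.7, 1.3), each = 3))
  out <- jarzynski_weighted_average(d, temperature = 300)
  expect_equal(out$value, c(2, 5))

  # hand evaluation: works {0, kT ln 3} give weights {3/4, 1/4}
  d2 <- tibble::tibble(strain = 0, replicate = 1:2, value = c(1, 0),
                       work = c(0, kT300 * log(3)))
  expect_equal(jarzynski_weighted_average(d2, temperature = 300)$value, 0.75)

  # single replicate: identity
  d3 <- tibble::tibble(strain = c(0, 5), replicate = 1, value = c(2, 9),
                       work = c(0, 3))
  expect_equal(jarzynski_weighted_average(d3, temperature = 300)$value, c(2, 9))
})

test_that("weights are shift-invariant, normalised and range-preserving", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(2:12, 1)
    d <- tibble::tibble(strain = 0, replicate = seq_len(n),
                        value = rnorm(n), work = rnorm(n, 2, 1.5))
    out <- jarzynski_weighted_average(d, temperature = 300)$value
    shifted <- dplyr::mutate(d, work = work + 137)
    expect_equal(jarzynski_weighted_average(shifted, temperature = 300)$value,
                 out)
    expect_true(out >= min(d$value) - 1e-12 && out <= max(d$value) + 1e-12)
    # brute-force direct evaluation of the weighted mean
    w <- exp(-d$work / kT300)
    expect_equal(out, sum(w * d$value) / sum(w), tolerance = 1e-10)
  }
})

test_that("global weighting uses each replicate's endpoint work", {
  d <- tibble::tibble(strain = rep(c(0, 10), each = 2),
                      replicate = rep(1:2, 2),
                      value = c(1, 0, 1, 0),
                      work = c(0.3, 0.3, 0, kT300 * log(3)))
  out <- jarzynski_weighted_average(d, temperature = 300, global = TRUE)
  expect_equal(out$value, c(0.75, 0.75))
  expect_error(
    jarzynski_weighted_average(
      tibble::tibble(strain = c(0, 0, 1), replicate = c(1, 2, 1),
                     value = 1, work = 0), temperature = 300),
    class = "fibrilmech_validation_error")
})

test_that("strain binning partitions into half-open bins", {
  d <- tibble::tibble(strain = c(5, 15, 25), value = c(1, 2, 3))
  out <- bin_by_strain(d, edges = c(0, 10, 20, 30))
  expect_equal(out$value, c(1, 2, 3))

  d2 <- tibble::tibble(strain = c(5, 7), value = c(2, 4))
  expect_equal(bin_by_strain(d2, c(0, 10))$value, 3)

  # boundary values belong to the upper bin; empty bins are missing not zero
  d3 <- tibble::tibble(strain = c(10, 35), value = c(7, 9))
  out3 <- bin_by_strain(d3, c(0, 10, 20, 40))
  expect_equal(out3$value, c(NA, 7, 9))
  expect_equal(out3$n, c(0, 1, 1))

  set.seed(8)
  d4 <- tibble::tibble(strain = runif(60, 0, 50), value = rnorm(60))
  edges <- c(0, 12, 31, 50.0001)
  out4 <- bin_by_strain(d4, edges)
  for (k in 1:3) {
    sel <- d4$strain >= edges[k] & d4$strain < edges[k + 1]
    expect_equal(out4$value[k], mean(d4$value[sel]))
  }
  expect_warning(bin_by_strain(tibble::tibble(strain = 99, value = 1),
                               c(0, 10)), "No data")
})
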