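#' Simulate one steered-Langevin pulling trajectory
#'
#' Integrates an overdamped Langevin particle in a [potential_spec()] while a
#' harmonic steering spring of stiffness `k_s` moves at constant speed `v`
#' from the potential's reference position. The external work is accumulated
#' with the left-endpoint rule,
#' \eqn{dW = k_s\, v\, (z - x)\, dt}, where `z` is the spring centre and `x`
#' the particle position at the start of the step; analytic comparisons in the
#' package use the same convention.
#'
#' @param potential A [potential_spec()].
#' @param protocol A [steering_protocol()].
#' @param config A [langevin_config()].
#' @param seed Integer seed for this trajectory (defaults to `config$seed`).
#' @return A tibble with columns `extension` (A, the steering-coordinate
#'   grid starting at 0), `position` (A, particle position at each recorded
#'   sample) and `work` (kcal/mol, cumulative external work, exactly 0 at the
#'   first grid point).
#' @examples
#' pot <- potential_spec("harmonic", stiffness = 1)
#' pr <- steering_protocol(spring_constant = 50, pull_speed = 0.5,
#'                         total_distance = 3, output_interval = 1)
#' cfg <- langevin_config(temperature = 0, timestep = 0.002, seed = 7)
#' simulate_steered_trajectory(pot, pr, cfg)
#' @export
simulate_steered_trajectory <- function(potential, protocol, config,
                                        seed = config$seed) {
  stopifnot(inherits(potential, "potential_spec"),
            inherits(protocol, "steering_protocol"),
            inherits(config, "langevin_config"))
  dt <- config$timestep
  v  <- protocol$pull_speed
  ks <- protocol$spring_constant
  gam <- config$friction

  curv <- potential_curvature_bound(potential, protocol$total_distance) + ks
  if (dt * curv / gam > 1)
    abort(paste0("Unstable timestep: timestep * (k_s + max|V''|) / friction = ",
                 signif(dt * curv / gam, 3), " exceeds 1. Reduce `timestep`."),
          class = "fibrilmech_config_error")

  n_steps <- protocol$total_distance / (v * dt)
  if (abs(n_steps - round(n_steps)) > 1e-6)
    abort("total_distance / (pull_speed * timestep) must be an integer.",
          class = "fibrilmech_validation_error")
  n_steps <- round(n_steps)
  steps_per_out <- protocol$output_interval / dt
  if (abs(steps_per_out - round(steps_per_out)) > 1e-6)
    abort("output_interval must be an integer multiple of the timestep.",
          class = "fibrilmech_validation_error")
  steps_per_out <- round(steps_per_out)

  kT <- thermal_energy_or_zero(config$temperature)
  noise_sd <- sqrt(2 * kT * dt / gam)
  x0 <- potential$reference_position
  # spring centre at the start of each step
  z <- x0 + v * dt * (0:(n_steps - 1))

  xi <- if (noise_sd > 0) {
    withr::with_seed(seed, rnorm(n_steps, sd = noise_sd))
  } else rep(0, n_steps)

  x <- numeric(n_steps + 1)
  x[1] <- x0
  for (i in seq_len(n_steps)) {
    xc <- x[i]
    force <- -potential_gradient(potential, xc) + ks * (z[i] - xc)
    x[i + 1] <- xc + (force / gam) * dt + xi[i]
  }

  # cumulative work, left-endpoint rule, vectorised over the position series
  w <- c(0, cumsum(ks * v * (z - x[seq_len(n_steps)]) * dt))

  idx <- seq(1, n_steps + 1, by = steps_per_out)
  tibble::tibble(
    extension = (idx - 1) * v * dt,
    position  = x[idx],
    work      = w[idx]
  )
}

thermal_energy_or_zero <- function(temperature) {
  if (temperature == 0) 0 else thermal_energy(temperature)
}

#' Generate an ensemble of pulling work profiles
#'
#' Runs `config$n_replicates` independent trajectories of
#' [simulate_steered_trajectory()] on one shared extension grid. Replicate
#' seeds are derived deterministically as `config$seed + replicate`, so the
#' ensemble is bit-reproducible and each replicate can be regenerated in
#' isolation.
#'
#' @inheritParams simulate_steered_trajectory
#' @param l_ref Strain reference length (A); `strain = extension / l_ref`.
#'   Defaults to 60, the approximate calcium-bound equilibrium length of the
#'   study's domain pair, so a 30 A stretch spans 0-50% strain.
#' @return A `work_ensemble`: a tibble with columns `replicate`, `extension`,
#'   `work`, carrying the temperature, strain reference length and protocol as
#'   attributes.
#' @export
generate_work_ensemble <- function(potential, protocol, config, l_ref = 60) {
  stopifnot(inherits(config, "langevin_config"))
  profiles <- purrr::map(seq_len(config$n_replicates), function(i) {
    traj <- simulate_steered_trajectory(potential, protocol, config,
                                        seed = config$seed + i)
    tibble::tibble(replicate = i, extension = traj$extension, work = traj$work)
  })
  new_work_ensemble(
    dplyr::bind_rows(profiles),
    temperature = config$temperature, l_ref = l_ref,
    protocol = protocol
  )
}

new_work_ensemble <- function(data, temperature, l_ref, protocol = NULL) {
  stopifnot(all(c("replicate", "extension", "work") %in% names(data)))
  structure(
    tibble::as_tibble(data),
    temperature = temperature, l_ref = l_ref, protocol = protocol,
    class = c("work_ensemble", class(tibble::tibble()))
  )
}

#' Assemble a work ensemble from a wide work matrix
#'
#' Convenience constructor for analyses starting from externally produced
#' work-versus-extension curves rather than the synthetic generator.
#'
#' @param extension Shared strictly increasing extension grid (A), first
#'   point 0.
#' @param works Matrix of cumulative works (kcal/mol), one column per
#'   replicate, rows matching `extension`.
#' @param temperature Kelvin.
#' @param l_ref Strain reference length (A).
#' @return A `work_ensemble` tibble.
#' @export
work_ensemble <- function(extension, works, temperature = 300, l_ref = 60) {
  works <- as.matrix(works)
  if (length(extension) != nrow(works))
    abort("`works` must have one row per extension grid point.",
          class = "fibrilmech_validation_error")
  if (is.unsorted(extension, strictly = TRUE))
    abort("`extension` must be strictly increasing.",
          class = "fibrilmech_validation_error")
  if (any(abs(works[1, ]) > 1e-12))
    abort("Every work profile must start at exactly 0.",
          class = "fibrilmech_validation_error")
  data <- tibble::tibble(
    replicate = rep(seq_len(ncol(works)), each = length(extension)),
    extension = rep(extension, ncol(works)),
    work = as.vector(works)
  )
  new_work_ensemble(data, temperature = temperature, l_ref = l_ref)
}

# wide n_grid x n_replicates work matrix plus the shared grid; errors if the
# replicates do not share one grid
ensemble_matrix <- function(ensemble) {
  stopifnot(inherits(ensemble, "work_ensemble"))
  split_works <- split(ensemble, ensemble$replicate)
  grids <- purrr::map(split_works, "extension")
  ref <- grids[[1]]
  same <- purrr::map_lgl(grids, ~ length(.x) == length(ref) &&
                           all(abs(.x - ref) < 1e-9))
  if (!all(same))
    abort("All replicates must share one extension grid.",
          class = "fibrilmech_validation_error")
  list(extension = ref,
       works = vapply(split_works, function(d) d$work,
                      numeric(length(ref))))
}
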