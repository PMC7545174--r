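#' Parameterise a constant-velocity pulling protocol
#'
#' Describes the moving harmonic steering spring of a stiff-spring
#' constant-velocity pulling experiment. Defaults mirror the conditions of the
#' cbEGF12-cbEGF13 study system: a 7.4 kcal/mol/A^2 spring pulled at
#' 0.1 A/ns over 30 A with a 100 kcal/mol/A^2 terminal restraint.
#'
#' @param spring_constant Steering spring constant k_s, kcal/mol/A^2 (> 0).
#' @param pull_speed Constant pulling speed v, A/ns (> 0).
#' @param total_distance Total stretch distance, A (> 0).
#' @param restraint Terminal restraint constant, kcal/mol/A^2 (recorded in
#'   metadata; the one-bead toy has no second terminus to restrain).
#' @param output_interval Interval between recorded samples, ns; the output
#'   grid spacing is `pull_speed * output_interval`.
#' @return An object of class `steering_protocol`.
#' @export
steering_protocol <- function(spring_constant = 7.4, pull_speed = 0.1,
                              total_distance = 30, restraint = 100,
                              output_interval = pull_speed^-1) {
  if (spring_constant <= 0)
    abort("`spring_constant` must be > 0.", class = "fibrilmech_validation_error")
  if (pull_speed <= 0)
    abort("`pull_speed` must be > 0.", class = "fibrilmech_validation_error")
  if (total_distance <= 0)
    abort("`total_distance` must be > 0.", class = "fibrilmech_validation_error")
  if (output_interval <= 0)
    abort("`output_interval` must be > 0.", class = "fibrilmech_validation_error")
  structure(
    list(spring_constant = spring_constant, pull_speed = pull_speed,
         total_distance = total_distance, restraint = restraint,
         output_interval = output_interval),
    class = "steering_protocol"
  )
}

#' @export
print.steering_protocol <- function(x, ...) {
  cat("<steering_protocol>\n",
      " k_s =", x$spring_constant, "kcal/mol/A^2, v =", x$pull_speed,
      "A/ns,", x$total_distance, "A total\n",
      " restraint =", x$restraint, "kcal/mol/A^2, output every",
      x$output_interval, "ns\n")
  invisible(x)
}

# the shared extension grid a protocol records on, starting at 0
extension_grid <- function(protocol) {
  dz <- protocol$pull_speed * protocol$output_interval
  n <- round(protocol$total_distance / dz)
  if (abs(n * dz - protocol$total_distance) > 1e-8 * protocol$total_distance)
    abort("`total_distance` must be an integer multiple of the output grid spacing.",
          class = "fibrilmech_validation_error")
  seq(0, protocol$total_distance, by = dz)
}

#' Configure the overdamped Langevin integrator
#'
#' The synthetic generator integrates overdamped (Brownian) dynamics,
#' \eqn{dx = -V'(x)/\gamma\,dt + \sqrt{2kT\,dt/\gamma}\,\xi}, with
#' Euler-Maruyama steps. The inertial all-atom dynamics of the study system
#' are deliberately not modelled: the overdamped limit preserves the
#' nonequilibrium work statistics the estimators consume.
#'
#' The integrator is stable when `timestep * (k_s + max|V''|) / friction <= 1`;
#' this bound depends on the potential and spring and is therefore enforced at
#' simulation entry.
#'
#' @param temperature Kelvin (> 0, or 0 for deterministic dynamics).
#' @param friction Damping gamma, kcal*ns/mol/A^2 (> 0); mobility is
#'   `1/friction`.
#' @param timestep Integration step, ns (> 0).
#' @param seed Master integer seed; identical seeds give bit-identical
#'   trajectories.
#' @param n_replicates Number of independent pulling replicates.
#' @return An object of class `langevin_config`.
#' @export
langevin_config <- function(temperature = 300, friction = 1,
                            timestep = 0.002, seed = 1L,
                            n_replicates = 100L) {
  if (temperature < 0)
    abort("`temperature` must be >= 0.", class = "fibrilmech_validation_error")
  if (friction <= 0)
    abort("`friction` must be > 0.", class = "fibrilmech_validation_error")
  if (timestep <= 0)
    abort("`timestep` must be > 0.", class = "fibrilmech_validation_error")
  if (n_replicates < 1)
    abort("`n_replicates` must be >= 1.", class = "fibrilmech_validation_error")
  structure(
    list(temperature = temperature, friction = friction, timestep = timestep,
         seed = as.integer(seed), n_replicates = as.integer(n_replicates)),
    class = "langevin_config"
  )
}

#' @export
print.langevin_config <- function(x, ...) {
  cat("<langevin_config> T =", x$temperature, "K, gamma =", x$friction,
      ", dt =", x$timestep, "ns, seed =", x$seed,
      ", replicates =", x$n_replicates, "\n")
  invisible(x)
}
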