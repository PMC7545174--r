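#' Define an analytically tractable one-dimensional potential
#'
#' Desk-scale stand-in for the molecular free-energy surface that a pulling
#' experiment samples. Three closed-form families are supported:
#' \describe{
#'   \item{harmonic}{\eqn{V(z) = \kappa z^2 / 2} about the reference position.}
#'   \item{double_well}{a quartic with minima at extensions 0 and
#'     `well_separation` and a barrier of `barrier_height` at the midpoint:
#'     \eqn{V(z) = 16 h u^2 (1-u)^2}, \eqn{u = z / d}.}
#'   \item{flat}{\eqn{V(z) = 0} everywhere.}
#' }
#' Every family has an exact potential of mean force, so estimators downstream
#' can be validated against ground truth.
#'
#' @param kind One of `"harmonic"`, `"double_well"`, `"flat"`.
#' @param stiffness Harmonic stiffness kappa, kcal/mol/A^2 (harmonic only, > 0).
#' @param barrier_height Barrier height, kcal/mol (double_well only, >= 0).
#' @param well_separation Distance between the two minima, A (double_well, > 0).
#' @param reference_position Position of the unstrained minimum, A.
#' @return An object of class `potential_spec`.
#' @examples
#' pot <- potential_spec("harmonic", stiffness = 1)
#' analytic_pmf(pot, extensions = c(0, 3))$delta_g # 0, 4.5
#' @export
potential_spec <- function(kind = c("harmonic", "double_well", "flat"),
                           stiffness = NULL, barrier_height = NULL,
                           well_separation = NULL, reference_position = 0) {
  kind <- match.arg(kind)
  if (kind == "harmonic") {
    if (is.null(stiffness) || !is.numeric(stiffness) || stiffness <= 0)
      abort("`stiffness` must be a positive number for a harmonic potential.",
            class = "fibrilmech_validation_error")
  }
  if (kind == "double_well") {
    if (is.null(barrier_height) || barrier_height < 0)
      abort("`barrier_height` must be >= 0 for a double-well potential.",
            class = "fibrilmech_validation_error")
    if (is.null(well_separation) || well_separation <= 0)
      abort("`well_separation` must be > 0 for a double-well potential.",
            class = "fibrilmech_validation_error")
  }
  structure(
    list(kind = kind, stiffness = stiffness, barrier_height = barrier_height,
         well_separation = well_separation,
         reference_position = reference_position),
    class = "potential_spec"
  )
}

#' @export
print.potential_spec <- function(x, ...) {
  cat("<potential_spec>", x$kind, "\n")
  if (x$kind == "harmonic")
    cat("  stiffness:", x$stiffness, "kcal/mol/A^2\n")
  if (x$kind == "double_well")
    cat("  barrier:", x$barrier_height, "kcal/mol at",
        x$well_separation / 2, "A; wells 0 and", x$well_separation, "A\n")
  cat("  reference position:", x$reference_position, "A\n")
  invisible(x)
}

# potential energy at absolute position x (A), kcal/mol
potential_energy <- function(pot, x) {
  z <- x - pot$reference_position
  switch(pot$kind,
    harmonic    = 0.5 * pot$stiffness * z^2,
    flat        = rep(0, length(z)),
    double_well = {
      u <- z / pot$well_separation
      16 * pot$barrier_height * u^2 * (1 - u)^2
    }
  )
}

# dV/dx at absolute position x, kcal/mol/A
potential_gradient <- function(pot, x) {
  z <- x - pot$reference_position
  switch(pot$kind,
    harmonic    = pot$stiffness * z,
    flat        = rep(0, length(z)),
    double_well = {
      d <- pot$well_separation
      u <- z / d
      (32 * pot$barrier_height / d) * u * (1 - u) * (1 - 2 * u)
    }
  )
}

# an upper bound on |V''| over [reference, reference + span]; used for the
# Euler-Maruyama stability check
potential_curvature_bound <- function(pot, span) {
  switch(pot$kind,
    harmonic    = pot$stiffness,
    flat        = 0,
    double_well = {
      d <- pot$well_separation
      u <- seq(0, max(span / d, 1), length.out = 257)
      max(abs((32 * pot$barrier_height / d^2) * (1 - 6 * u + 6 * u^2)))
    }
  )
}

#' Exact potential of mean force of a toy potential
#'
#' Evaluates the closed-form free-energy profile of a [potential_spec()] along
#' the pulled coordinate, anchored to zero at zero extension. In the
#' stiff-spring regime this is the ground truth the Jarzynski estimator should
#' recover, which makes it the oracle for every estimator validation in the
#' package.
#'
#' @param potential A [potential_spec()].
#' @param extensions Numeric vector of extensions (A) measured from the
#'   reference position; alternatively pass a [steering_protocol()] via
#'   `protocol` to use its output grid.
#' @param protocol Optional [steering_protocol()] supplying the grid.
#' @param l_ref Strain reference length (A) used for the strain axis;
#'   default 60.
#' @return A `pmf_profile` tibble with columns `extension`, `strain`
#'   (percent), `delta_g` (kcal/mol).
#' @export
analytic_pmf <- function(potential, extensions = NULL, protocol = NULL,
                         l_ref = 60) {
  stopifnot(inherits(potential, "potential_spec"))
  if (is.null(extensions)) {
    if (is.null(protocol))
      abort("Supply `extensions` or a `protocol` to define the grid.",
            class = "fibrilmech_validation_error")
    extensions <- extension_grid(protocol)
  }
  x <- potential$reference_position + extensions
  dg <- potential_energy(potential, x) -
    potential_energy(potential, potential$reference_position)
  new_pmf_profile(
    tibble::tibble(extension = extensions,
                   strain = 100 * extensions / l_ref,
                   delta_g = dg),
    temperature = NA_real_, l_ref = l_ref, n_replicates = NA_integer_
  )
}
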