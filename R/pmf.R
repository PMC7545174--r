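new_pmf_profile <- function(data, temperature, l_ref, n_replicates) {
  structure(
    tibble::as_tibble(data),
    temperature = temperature, l_ref = l_ref, n_replicates = n_replicates,
    class = c("pmf_profile", class(tibble::tibble()))
  )
}

#' Jarzynski free-energy reconstruction from a work ensemble
#'
#' Estimates the equilibrium potential of mean force from nonequilibrium
#' pulling work via the Jarzynski equality,
#' \deqn{\Delta G(z) = -kT \log \frac{1}{n} \sum_i e^{-W_i(z)/kT},}
#' evaluated grid point by grid point with a max-shifted log-sum-exp so the
#' exponential average stays finite for works of thousands of kT. The
#' estimate is exactly 0 at zero extension, invariant under replicate
#' permutation, and bounded above by the mean work at every grid point
#' (Jensen's inequality).
#'
#' @param ensemble A `work_ensemble` (see [generate_work_ensemble()] or
#'   [work_ensemble()]).
#' @param temperature Kelvin; defaults to the ensemble's recorded temperature.
#' @return A `pmf_profile` tibble with columns `extension` (A), `strain`
#'   (percent of the ensemble's reference length) and `delta_g` (kcal/mol).
#' @export
jarzynski_pmf <- function(ensemble, temperature = attr(ensemble, "temperature")) {
  mat <- ensemble_matrix(ensemble)
  if (ncol(mat$works) < 1)
    abort("Empty ensemble.", class = "fibrilmech_validation_error")
  if (is.null(temperature) || is.na(temperature) || temperature <= 0)
    abort("`temperature` must be > 0 for the Jarzynski average.",
          class = "fibrilmech_validation_error")
  kT <- thermal_energy(temperature)
  dg <- -kT * apply(-mat$works / kT, 1, log_mean_exp)
  l_ref <- attr(ensemble, "l_ref") %||% 60
  new_pmf_profile(
    tibble::tibble(extension = mat$extension,
                   strain = 100 * mat$extension / l_ref,
                   delta_g = dg),
    temperature = temperature, l_ref = l_ref,
    n_replicates = ncol(mat$works)
  )
}

#' Free-energy change at a given strain
#'
#' Reads the accumulated free-energy change from 0% strain to the requested
#' strain off a PMF profile by linear interpolation on the strain axis. The
#' value at 50% strain is the `delta G_50` summary used to compare
#' calcium-bound, calcium-free and mutant domain pairs.
#'
#' @param pmf A `pmf_profile`.
#' @param strain Strain in percent, within the profile's range.
#' @return Free-energy change in kcal/mol.
#' @export
delta_g_at_strain <- function(pmf, strain) {
  stopifnot(inherits(pmf, "pmf_profile"))
  rng <- range(pmf$strain)
  if (any(strain < rng[1] - 1e-9 | strain > rng[2] + 1e-9))
    abort(paste0("Requested strain outside the profile range [",
                 signif(rng[1], 4), ", ", signif(rng[2], 4), "]%."),
          class = "fibrilmech_range_error")
  approx(pmf$strain, pmf$delta_g, xout = strain, rule = 1)$y
}

#' Per-replicate endpoint works with a normal moment fit
#'
#' Collects each replicate's cumulative work at the requested strain
#' (interpolated on the strain axis) and fits a normal distribution by
#' moments: location = sample mean, scale = sample standard deviation. These
#' are the per-trajectory endpoint works; they are not jackknifed Jarzynski
#' estimates.
#'
#' @param ensemble A `work_ensemble` with at least two replicates.
#' @param strain Strain in percent at which works are read off (default 50).
#' @return A `deltag_fit` object: list with `works` (per-replicate values,
#'   kcal/mol), `mean`, `sd`, `strain`, `n`.
#' @export
fit_deltag_histogram <- function(ensemble, strain = 50) {
  mat <- ensemble_matrix(ensemble)
  n <- ncol(mat$works)
  if (n < 2)
    abort("At least two replicates are required for a moment fit.",
          class = "fibrilmech_validation_error")
  l_ref <- attr(ensemble, "l_ref") %||% 60
  strain_axis <- 100 * mat$extension / l_ref
  rng <- range(strain_axis)
  if (strain < rng[1] - 1e-9 || strain > rng[2] + 1e-9)
    abort("Requested strain outside the ensemble range.",
          class = "fibrilmech_range_error")
  works <- apply(mat$works, 2, function(w)
    approx(strain_axis, w, xout = strain)$y)
  structure(
    list(works = unname(works), mean = mean(works), sd = sd(works),
         strain = strain, n = n),
    class = "deltag_fit"
  )
}

#' @export
print.deltag_fit <- function(x, ...) {
  cat("<deltag_fit> n =", x$n, "works at", x$strain, "% strain:",
      signif(x$mean, 4), "+/-", signif(x$sd, 4), "kcal/mol\n")
  invisible(x)
}

#' @rdname fit_deltag_histogram
#' @param x A `deltag_fit`.
#' @param ... Unused.
#' @export
tidy.deltag_fit <- function(x, ...) {
  tibble::tibble(
    term = c("mean", "sd"),
    estimate = c(x$mean, x$sd)
  )
}

#' @rdname fit_deltag_histogram
#' @export
glance.deltag_fit <- function(x, ...) {
  tibble::tibble(n = x$n, strain = x$strain, mean = x$mean, sd = x$sd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
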