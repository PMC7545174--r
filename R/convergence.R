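#' Pull-speed and sample-size convergence study
#'
#' Crosses a set of pull speeds with a set of sample sizes, estimates the
#' endpoint free energy from each sub-ensemble with [jarzynski_pmf()], and
#' reports the bias against the analytic profile. Dissipation grows with pull
#' speed, so the expected bias is non-increasing as speed decreases — a
#' statistical property over seed-averaged repeats, not a per-run guarantee.
#'
#' @param potential A [potential_spec()].
#' @param protocol A [steering_protocol()] used as template; its `pull_speed`
#'   is replaced by each entry of `speeds`.
#' @param speeds Numeric vector of pull speeds (A/ns).
#' @param sample_sizes Integer vector of replicate counts.
#' @param config A [langevin_config()]; `n_replicates` is replaced by each
#'   sample size, seeds are derived from `config$seed` per cell.
#' @return A `convergence_report` tibble with columns `pull_speed`,
#'   `n_samples`, `delta_g_end` (kcal/mol), `bias` (kcal/mol, estimate minus
#'   analytic endpoint).
#' @export
convergence_study <- function(potential, protocol, speeds, sample_sizes,
                              config) {
  if (length(speeds) < 1 || length(sample_sizes) < 1)
    abort("Provide at least one speed and one sample size.",
          class = "fibrilmech_validation_error")
  grid <- tidyr::expand_grid(pull_speed = speeds, n_samples = sample_sizes)
  rows <- purrr::pmap_dfr(grid, function(pull_speed, n_samples) {
    pr <- protocol
    pr$pull_speed <- pull_speed
    pr$output_interval <- protocol$output_interval *
      protocol$pull_speed / pull_speed  # keep the extension grid fixed
    cell_seed <- config$seed +
      1000L * match(pull_speed, speeds) + 100000L * match(n_samples, sample_sizes)
    cfg <- langevin_config(temperature = config$temperature,
                           friction = config$friction,
                           timestep = config$timestep,
                           seed = cell_seed, n_replicates = n_samples)
    ens <- generate_work_ensemble(potential, pr, cfg)
    pmf <- jarzynski_pmf(ens)
    ref <- analytic_pmf(potential, extensions = max(pmf$extension))$delta_g
    tibble::tibble(pull_speed = pull_speed, n_samples = n_samples,
                   delta_g_end = pmf$delta_g[nrow(pmf)],
                   bias = pmf$delta_g[nrow(pmf)] - ref)
  })
  structure(rows, class = c("convergence_report", class(tibble::tibble())))
}
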