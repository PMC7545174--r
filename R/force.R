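# centered moving average with shrinking windows at the edges; half_width in
# grid points
moving_average <- function(x, half_width) {
  if (half_width <= 0) return(x)
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half_width)
    hi <- min(n, i + half_width)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Derive a smoothed force profile from a PMF
#'
#' The force along the pulling coordinate is the distance derivative of the
#' potential of mean force. The PMF is first smoothed with a centered moving
#' average, differentiated by central finite differences (one-sided at the
#' edges), converted to piconewtons (1 kcal/mol/A = 69.48 pN) and smoothed
#' again with the same window. When the profile carries pulling-protocol
#' metadata the default window is `pull_speed * window_ns` — the study's
#' 10 ns moving average corresponds to 1 A at 0.1 A/ns.
#'
#' @param pmf A `pmf_profile`.
#' @param window Smoothing window in A; must be at least the grid spacing.
#'   Defaults to `pull_speed * window_ns` when protocol metadata is attached
#'   to the source ensemble, else exactly one grid spacing (no smoothing).
#' @param window_ns Time-domain window (ns) used to derive the default
#'   extension window; default 10.
#' @param protocol Optional [steering_protocol()] supplying `pull_speed`.
#' @return A `force_profile` tibble with columns `extension`, `strain`,
#'   `force_pn`; the window used (A and ns-equivalent where known) is stored
#'   in attributes.
#' @export
force_profile <- function(pmf, window = NULL, window_ns = 10, protocol = NULL) {
  stopifnot(inherits(pmf, "pmf_profile"))
  z <- pmf$extension
  if (length(z) < 3)
    abort("At least three grid points are needed to differentiate.",
          class = "fibrilmech_validation_error")
  dz <- z[2] - z[1]
  if (is.null(window)) {
    window <- if (!is.null(protocol)) protocol$pull_speed * window_ns else dz
  }
  if (window < dz - 1e-9)
    abort("`window` must be at least the grid spacing.",
          class = "fibrilmech_validation_error")
  half_width <- floor(window / (2 * dz))

  g <- moving_average(pmf$delta_g, half_width)
  n <- length(z)
  dgdz <- numeric(n)
  dgdz[1] <- (g[2] - g[1]) / dz
  dgdz[n] <- (g[n] - g[n - 1]) / dz
  if (n > 2) dgdz[2:(n - 1)] <- (g[3:n] - g[1:(n - 2)]) / (2 * dz)
  force_pn <- moving_average(dgdz, half_width) * mech_constants$pN_per_kcal_mol_A

  structure(
    tibble::tibble(extension = z, strain = pmf$strain, force_pn = force_pn),
    window = window, window_ns = if (!is.null(protocol)) window_ns else NA_real_,
    temperature = attr(pmf, "temperature"), l_ref = attr(pmf, "l_ref"),
    class = c("force_profile", class(tibble::tibble()))
  )
}

#' Windowed force summaries and global peak
#'
#' Computes the arithmetic mean and standard deviation of the smoothed force
#' inside half-open strain windows `[lo, hi)` — the study reports 0-20% and
#' 20-50% — and locates the global force peak.
#'
#' @param force A `force_profile`.
#' @param windows List of two-element numeric vectors `c(lo, hi)` in percent
#'   strain; default `list(c(0, 20), c(20, 50))`.
#' @return A list with `windows`, a tibble (`lo`, `hi`, `mean_pn`, `sd_pn`,
#'   `n`), and `peak`, a one-row tibble (`force_pn`, `strain`, `extension`).
#' @export
summarize_forces <- function(force, windows = list(c(0, 20), c(20, 50))) {
  stopifnot(inherits(force, "force_profile"))
  win_tbl <- purrr::map_dfr(windows, function(w) {
    if (length(w) != 2 || w[2] <= w[1])
      abort("Each window must be c(lo, hi) with hi > lo.",
            class = "fibrilmech_validation_error")
    sel <- force$strain >= w[1] & force$strain < w[2]
    if (!any(sel))
      abort(paste0("Window [", w[1], ", ", w[2], ")% contains no grid points."),
            class = "fibrilmech_validation_error")
    f <- force$force_pn[sel]
    tibble::tibble(lo = w[1], hi = w[2], mean_pn = mean(f),
                   sd_pn = if (length(f) > 1) sd(f) else 0,
                   n = length(f))
  })
  i <- which.max(force$force_pn)
  list(
    windows = win_tbl,
    peak = tibble::tibble(force_pn = force$force_pn[i],
                          strain = force$strain[i],
                          extension = force$extension[i])
  )
}

#' Percent change versus a reference value
#'
#' Reports `100 * (reference - comparison) / reference` rounded to the nearest
#' integer percent — the convention used for the study's headline summaries,
#' where a positive value is a decrease versus the reference (e.g. the
#' calcium-free `delta G_50` of 36 kcal/mol is 29% below the calcium-bound
#' 51 kcal/mol).
#'
#' @param reference Reference scalar (non-zero).
#' @param comparison Comparison scalar.
#' @param digits Rounding digits for the report (default 0, integer percent).
#' @return Percent change (positive = decrease versus reference).
#' @examples
#' report_relative_change(51, 36) # 29
#' report_relative_change(227, 169) # 26
#' @export
report_relative_change <- function(reference, comparison, digits = 0) {
  if (any(reference == 0))
    abort("`reference` must be non-zero.", class = "fibrilmech_domain_error")
  round(100 * (reference - comparison) / reference, digits = digits)
}
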