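#' Count ligand contacts within a distance cutoff
#'
#' Number of selected partner atoms strictly closer than `cutoff` to the
#' ligand. The default partner selection is oxygen atoms — calcium
#' coordination in cbEGF binding pockets is through oxygen — with
#' `partners = "all"` counting every non-ligand atom.
#'
#' @param frame A tibble of atoms with columns `x`, `y`, `z`, `element` and a
#'   way to identify the ligand (`role == "ligand"`, `element == "CA"`, or an
#'   explicit `ligand_id`).
#' @param cutoff Distance cutoff in A (default 4.0, strict `<`).
#' @param partners `"oxygen"` (default) or `"all"`.
#' @param ligand_id Optional atom id of the ligand.
#' @return Integer contact count.
#' @export
count_contacts <- function(frame, cutoff = mech_constants$default_contact_cutoff,
                           partners = c("oxygen", "all"), ligand_id = NULL) {
  partners <- match.arg(partners)
  if (cutoff <= 0)
    abort("`cutoff` must be > 0.", class = "fibrilmech_validation_error")
  lig <- locate_ligand(frame, ligand_id)
  others <- frame[-lig, , drop = FALSE]
  if (partners == "oxygen") others <- others[others$element == "O", , drop = FALSE]
  if (nrow(others) == 0) return(0L)
  d2 <- (others$x - frame$x[lig])^2 + (others$y - frame$y[lig])^2 +
    (others$z - frame$z[lig])^2
  sum(d2 < cutoff^2)
}

locate_ligand <- function(frame, ligand_id = NULL) {
  if (!is.null(ligand_id)) {
    i <- which(frame$atom_id == ligand_id)
  } else if ("role" %in% names(frame)) {
    i <- which(frame$role == "ligand")
  } else {
    i <- which(frame$element == "CA")
  }
  if (length(i) != 1)
    abort("Exactly one ligand atom must be identifiable in the frame.",
          class = "fibrilmech_validation_error")
  i
}

#' Shrake-Rupley solvent-accessible surface area of one atom
#'
#' Samples a deterministic Fibonacci lattice of points on the expanded sphere
#' of radius `r_atom + probe` around the target atom and reports the exposed
#' fraction times the analytic sphere area `4 pi (r + probe)^2`. An isolated
#' calcium ion (radius 1.5 A, probe 1.4 A) gives 105.7 A^2, the area that
#' defines the 100% normalisation of [normalize_sasa()].
#'
#' @param frame A tibble of atoms with `x`, `y`, `z`, `element`.
#' @param target_id Atom id of the target (default: the ligand, located as in
#'   [count_contacts()]).
#' @param probe Probe radius, A (default 1.4).
#' @param n_points Number of lattice points (>= 100; default 960).
#' @param radii Named vector of per-element radii overriding the built-in
#'   van der Waals table.
#' @return Accessible area in A^2.
#' @examples
#' ion <- tibble::tibble(atom_id = 1, element = "CA", x = 0, y = 0, z = 0)
#' compute_sasa(ion) # ~105.7
#' @export
compute_sasa <- function(frame, target_id = NULL,
                         probe = mech_constants$default_probe_radius,
                         n_points = 960, radii = NULL) {
  if (n_points < 100)
    abort("`n_points` must be at least 100.",
          class = "fibrilmech_validation_error")
  rad_tbl <- vdw_radii
  if (!is.null(radii)) rad_tbl[names(radii)] <- radii
  unknown <- setdiff(unique(frame$element), names(rad_tbl))
  if (length(unknown) > 0)
    abort(paste0("No radius for element(s): ", paste(unknown, collapse = ", "),
                 ". Supply overrides via `radii`."),
          class = "fibrilmech_config_error")

  ti <- locate_ligand(frame, target_id)
  r_t <- rad_tbl[[frame$element[ti]]] + probe
  center <- c(frame$x[ti], frame$y[ti], frame$z[ti])
  pts <- fibonacci_sphere(n_points) * r_t
  pts <- sweep(pts, 2, center, `+`)

  others <- frame[-ti, , drop = FALSE]
  if (nrow(others) > 0) {
    r_o <- rad_tbl[others$element] + probe
    # only neighbours whose expanded sphere can reach the target surface
    d_c <- sqrt((others$x - center[1])^2 + (others$y - center[2])^2 +
                  (others$z - center[3])^2)
    near <- d_c < (r_t + r_o)
    others <- others[near, , drop = FALSE]
    r_o <- r_o[near]
  }
  exposed <- rep(TRUE, n_points)
  if (nrow(others) > 0) {
    for (j in seq_len(nrow(others))) {
      d2 <- (pts[, 1] - others$x[j])^2 + (pts[, 2] - others$y[j])^2 +
        (pts[, 3] - others$z[j])^2
      exposed <- exposed & d2 > r_o[j]^2
    }
  }
  mean(exposed) * 4 * pi * r_t^2
}

#' Normalise a calcium SASA to the isolated-ion reference
#'
#' Expresses an absolute accessible area as a percentage of the isolated
#' calcium ion area (100% = 105.7 A^2), clipping at 100 with a warning when
#' quadrature overshoots.
#'
#' @param absolute Absolute SASA in A^2 (>= 0).
#' @return Percentage in \[0, 100\].
#' @export
normalize_sasa <- function(absolute) {
  if (any(absolute < 0))
    abort("SASA cannot be negative.", class = "fibrilmech_validation_error")
  pct <- 100 * absolute / mech_constants$calcium_reference_sasa
  if (any(pct > 100)) {
    warn("Normalised SASA exceeded 100%; clipping (quadrature overshoot).")
    pct <- pmin(pct, 100)
  }
  pct
}

#' Work-weighted ensemble average of a per-frame observable
#'
#' Averages an observable over pulling replicates with the Boltzmann weights
#' of the Jarzynski equality,
#' \deqn{\bar X = \sum_i w_i X_i, \qquad
#'   w_i = \frac{e^{-W_i/kT}}{\sum_j e^{-W_j/kT}},}
#' so low-work (near-equilibrium) trajectories dominate. Weights are computed
#' per strain point from that point's works via a max-shifted soft-max
#' (`global = TRUE` uses one weight per replicate from the endpoint works
#' instead). Weights sum to 1 and the result always lies within the range of
#' the replicate values.
#'
#' @param data A tibble with columns `strain`, `replicate`, `value`
#'   (observable) and `work` (kcal/mol).
#' @param temperature Kelvin.
#' @param global Use one weight per replicate from its final-strain work.
#' @return A tibble with columns `strain`, `value` (weighted mean), `n`.
#' @examples
#' d <- tibble::tibble(strain = 0, replicate = 1:2,
#'                     value = c(1, 0), work = c(0, 0.5962 * log(3)))
#' jarzynski_weighted_average(d, temperature = 300)$value # 0.75
#' @export
jarzynski_weighted_average <- function(data, temperature = 300,
                                       global = FALSE) {
  needed <- c("strain", "replicate", "value", "work")
  if (!all(needed %in% names(data)))
    abort(paste("`data` needs columns:", paste(needed, collapse = ", ")),
          class = "fibrilmech_validation_error")
  if (temperature <= 0)
    abort("`temperature` must be > 0.", class = "fibrilmech_validation_error")
  counts <- dplyr::count(data, .data$strain)
  if (length(unique(counts$n)) != 1)
    abort("Every strain point must carry the same replicate count.",
          class = "fibrilmech_validation_error")
  kT <- thermal_energy(temperature)
  if (global) {
    final_w <- data |>
      dplyr::filter(.data$strain == max(.data$strain)) |>
      dplyr::select("replicate", gw = "work")
    data <- dplyr::left_join(data, final_w, by = "replicate")
    data$work <- data$gw
  }
  data |>
    dplyr::group_by(.data$strain) |>
    dplyr::summarise(
      value = {
        lw <- -.data$work / kT
        w <- exp(lw - max(lw))
        sum(w * .data$value) / sum(w)
      },
      n = dplyr::n(), .groups = "drop"
    )
}

#' Bin a strain-indexed series into half-open strain bins
#'
#' @param data A tibble with columns `strain` and `value`.
#' @param edges Increasing vector of bin edges in percent strain; bins are
#'   `[lo, hi)`.
#' @return A tibble with `bin_lo`, `bin_hi`, `value` (bin mean, `NA` for
#'   empty bins) and `n`; warns when no data fall in any bin.
#' @export
bin_by_strain <- function(data, edges) {
  if (is.unsorted(edges, strictly = TRUE))
    abort("`edges` must be strictly increasing.",
          class = "fibrilmech_validation_error")
  bins <- tibble::tibble(bin_lo = head(edges, -1), bin_hi = tail(edges, -1))
  out <- purrr::pmap_dfr(bins, function(bin_lo, bin_hi) {
    sel <- data$strain >= bin_lo & data$strain < bin_hi
    tibble::tibble(bin_lo = bin_lo, bin_hi = bin_hi,
                   value = if (any(sel)) mean(data$value[sel]) else NA_real_,
                   n = sum(sel))
  })
  if (all(out$n == 0))
    warn("No data fall inside the requested strain bins.")
  out
}
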