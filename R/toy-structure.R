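#' Build a toy two-domain bead structure with a bound calcium ligand
#'
#' Constructs the schematic stand-in used to exercise the conformational and
#' calcium-binding observables without real coordinates: two bead "domains"
#' separated along the x axis, a calcium ligand at the origin, and a shell of
#' binding-pocket oxygen beads placed on fixed directions (a deterministic
#' Fibonacci lattice) around the ligand. Oxygens are split into an N-terminal
#' "loop" set and a C-terminal "beta-hairpin" set; under strain the hairpin
#' radii grow faster, mimicking the hairpin displacement that opens the
#' calcium-binding pocket in the study system.
#'
#' @param n_domain_atoms Beads per domain (default 10).
#' @param domain_separation Unstrained centre-to-centre separation, A
#'   (default 30, so the two-times-COM-distance length is 60 A).
#' @param n_contacts Number of pocket oxygens initially within the 4.0 A
#'   contact cutoff (default 8).
#' @param n_hairpin How many of the oxygens belong to the hairpin set
#'   (default 3, matching the three hairpin calcium ligands per domain).
#' @param contact_radii Range of unstrained ligand-oxygen distances, A;
#'   default `c(2.4, 3.8)`, all inside the cutoff.
#' @return A `toy_structure`: a tibble of atoms with columns `atom_id`,
#'   `element`, `mass`, `x`, `y`, `z`, `residue`, `domain`
#'   (`"domain_a"`, `"domain_b"` or `"ligand"`), `role`, plus attributes
#'   recording the build parameters.
#' @export
toy_structure <- function(n_domain_atoms = 10, domain_separation = 30,
                          n_contacts = 8, n_hairpin = 3,
                          contact_radii = c(2.4, 3.8)) {
  if (n_hairpin > n_contacts)
    abort("`n_hairpin` cannot exceed `n_contacts`.",
          class = "fibrilmech_validation_error")
  if (contact_radii[2] >= mech_constants$default_contact_cutoff)
    warn("Some unstrained oxygens start outside the 4.0 A cutoff.")

  # deterministic bead offsets inside each domain (no RNG)
  k <- seq_len(n_domain_atoms)
  offsets <- cbind(
    1.5 * cos(2 * pi * k / n_domain_atoms),
    1.5 * sin(2 * pi * k / n_domain_atoms),
    0.6 * (k - mean(k)) / n_domain_atoms
  )
  half <- domain_separation / 2
  dom_a <- sweep(offsets, 2, c(-half, 0, 0), `+`)
  dom_b <- sweep(offsets, 2, c(+half, 0, 0), `+`)

  dirs <- fibonacci_sphere(n_contacts)
  radii <- seq(contact_radii[1], contact_radii[2], length.out = n_contacts)
  oxy <- dirs * radii
  role_oxy <- c(rep("oxygen_hairpin", n_hairpin),
                rep("oxygen_loop", n_contacts - n_hairpin))

  atoms <- tibble::tibble(
    atom_id = seq_len(2 * n_domain_atoms + n_contacts + 1),
    element = c(rep("C", 2 * n_domain_atoms), rep("O", n_contacts), "CA"),
    mass    = c(rep(12.011, 2 * n_domain_atoms), rep(15.999, n_contacts), 40.078),
    x = c(dom_a[, 1], dom_b[, 1], oxy[, 1], 0),
    y = c(dom_a[, 2], dom_b[, 2], oxy[, 2], 0),
    z = c(dom_a[, 3], dom_b[, 3], oxy[, 3], 0),
    residue = c(seq_len(n_domain_atoms),
                n_domain_atoms + seq_len(n_domain_atoms),
                rep(1L, n_contacts), 2L * n_domain_atoms + 1L),
    domain = c(rep("domain_a", n_domain_atoms), rep("domain_b", n_domain_atoms),
               rep("domain_a", n_contacts), "ligand"),
    role = c(rep("backbone", 2 * n_domain_atoms), role_oxy, "ligand")
  )
  structure(atoms,
            n_contacts = n_contacts, n_hairpin = n_hairpin,
            domain_separation = domain_separation,
            base_radii = radii, directions = dirs,
            class = c("toy_structure", class(tibble::tibble())))
}

# deterministic Fibonacci lattice on the unit sphere (no RNG)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  cz <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - cz^2))
  cbind(r * cos(phi), r * sin(phi), cz)
}

#' Generate strained snapshots of a toy structure
#'
#' Produces one coordinate frame per strain value. Strain `s` moves the two
#' domains apart (centre separation scales as `1 + s`) and inflates the
#' ligand-oxygen distances: loop oxygens as `r0 * (1 + s)`, hairpin oxygens as
#' `r0 * (1 + hairpin_factor * s)`, so contact counts are non-increasing and
#' calcium exposure non-decreasing along a monotone strain grid before any
#' noise is added.
#'
#' @param base A [toy_structure()].
#' @param strain_grid Non-decreasing numeric vector of dimensionless strains
#'   starting at 0 (0.5 = 50% strain).
#' @param noise Gaussian positional jitter, A (standard deviation; default 0).
#' @param seed Integer seed for the jitter.
#' @param hairpin_factor Strain multiplier for hairpin oxygens (default 3).
#' @return A tibble of frames: columns `frame`, `strain` plus the atom
#'   columns of the base structure.
#' @export
generate_toy_conformations <- function(base, strain_grid, noise = 0, seed = 1L,
                                       hairpin_factor = 3) {
  stopifnot(inherits(base, "toy_structure"))
  if (any(strain_grid < 0))
    abort("Strains must be non-negative.", class = "fibrilmech_validation_error")
  if (is.unsorted(strain_grid))
    abort("`strain_grid` must be non-decreasing.",
          class = "fibrilmech_validation_error")
  if (abs(strain_grid[1]) > 1e-12)
    abort("`strain_grid` must start at 0.", class = "fibrilmech_validation_error")

  radii <- attr(base, "base_radii")
  dirs <- attr(base, "directions")
  is_oxy <- grepl("^oxygen", base$role)
  is_backbone <- base$role == "backbone"
  mult <- ifelse(base$role[is_oxy] == "oxygen_hairpin", hairpin_factor, 1)

  frames <- purrr::imap_dfr(strain_grid, function(s, i) {
    at <- base
    # domains move apart
    at$x[is_backbone] <- at$x[is_backbone] * (1 + s)
    # pocket oxygens inflate radially about the ligand
    r_s <- radii * (1 + mult * s)
    at[is_oxy, c("x", "y", "z")] <- dirs * r_s
    tibble::tibble(frame = i, strain = s, tibble::as_tibble(at))
  })
  if (noise > 0) {
    jitter <- withr::with_seed(seed, rnorm(3 * nrow(frames), sd = noise))
    frames$x <- frames$x + jitter[seq_len(nrow(frames))]
    frames$y <- frames$y + jitter[nrow(frames) + seq_len(nrow(frames))]
    frames$z <- frames$z + jitter[2 * nrow(frames) + seq_len(nrow(frames))]
  }
  frames
}
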