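# shared fixtures and independent oracles used across the suite

kT300 <- fibrilmech::thermal_energy(300)

# a small harmonic test system: stiff spring, slow pulling, coarse grid
toy_harmonic <- function() {
  list(
    potential = potential_spec("harmonic", stiffness = 1),
    protocol = steering_protocol(spring_constant = 100, pull_speed = 0.1,
                                 total_distance = 5, output_interval = 2.5),
    config = langevin_config(temperature = 300, timestep = 0.005,
                             friction = 1, seed = 42, n_replicates = 20)
  )
}

# endpoint free energy of the combined trap + harmonic system in the
# quasi-static limit (exact; the spring holds the bead at ks z/(k+ks))
combined_harmonic_dg <- function(kappa, ks, z) {
  0.5 * (kappa * ks / (kappa + ks)) * z^2
}

# brute-force mass-weighted center of mass, written independently of the
# package implementation
oracle_com <- function(df) {
  m <- sum(df$mass)
  c(sum(df$x * df$mass), sum(df$y * df$mass), sum(df$z * df$mass)) / m
}

# analytic accessible area of sphere 1 (radius R1) partially buried by
# sphere 2 (radius R2) at center distance d: full area minus the hidden cap
oracle_two_sphere_sasa <- function(R1, R2, d) {
  if (d >= R1 + R2) return(4 * pi * R1^2)
  cos_theta <- (d^2 + R1^2 - R2^2) / (2 * d * R1)
  4 * pi * R1^2 - 2 * pi * R1^2 * (1 - cos_theta)
}

# closed-form Pearson chi-squared for a 2x2 table, no continuity correction
oracle_chisq_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# rotate coordinates of a frame rigidly (independent of package code)
rotate_frame <- function(frame, angle = 0.7, shift = c(3, -2, 5)) {
  R <- matrix(c(cos(angle), -sin(angle), 0,
                sin(angle),  cos(angle), 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  xyz <- as.matrix(frame[, c("x", "y", "z")]) %*% t(R)
  frame$x <- xyz[, 1] + shift[1]
  frame$y <- xyz[, 2] + shift[2]
  frame$z <- xyz[, 3] + shift[3]
  frame
}

# a synthetic replica of the mutation database marginals: 93 neonatal,
# 1718 classical, 1420 non-qualifying labels
replica_mutation_table <- function(seed = 7) {
  map <- fbn1_domain_map()
  n_mfs <- generate_mutation_cohort(
    93, c(calcium_binding = 0.4, cysteine_bond1 = 0.25, cysteine_bond2 = 0.05,
          cysteine_bond3 = 0.15, other = 0.15),
    disease = "neonatal MFS", map = map, seed = seed)
  c_mfs <- generate_mutation_cohort(
    1718, c(calcium_binding = 0.25, cysteine_bond1 = 0.13, cysteine_bond2 = 0.13,
            cysteine_bond3 = 0.13, other = 0.36),
    disease = c("Classical MFS", "MFS"), map = map, seed = seed + 1)
  excluded <- generate_mutation_cohort(
    1420, c(calcium_binding = 0.2, other = 0.8),
    disease = c("unknown", "isolated ectopia lentis", "TAA"),
    map = map, seed = seed + 2)
  dplyr::bind_rows(n_mfs, c_mfs, excluded) |>
    dplyr::mutate(id = dplyr::row_number())
}
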