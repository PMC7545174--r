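# resolve the atoms of one named domain inside a frame: either via an explicit
# `domain` column or via residue ranges from a domain map
domain_atoms <- function(frame, domain, map = NULL) {
  if (!is.null(map)) {
    row <- map$domains[map$domains$name == domain, ]
    if (nrow(row) != 1)
      abort(paste0("Domain '", domain, "' not found in the map."),
            class = "fibrilmech_validation_error")
    sel <- frame$residue >= row$start & frame$residue <= row$end
  } else {
    if (!"domain" %in% names(frame))
      abort("Frame has no `domain` column; supply a domain map.",
            class = "fibrilmech_validation_error")
    sel <- frame$domain == domain
  }
  out <- frame[sel, , drop = FALSE]
  if (nrow(out) == 0 || sum(out$mass) <= 0)
    abort(paste0("Domain '", domain, "' selects no atoms with positive mass."),
          class = "fibrilmech_validation_error")
  out
}

center_of_mass <- function(atoms) {
  w <- atoms$mass / sum(atoms$mass)
  c(sum(w * atoms$x), sum(w * atoms$y), sum(w * atoms$z))
}

#' Two-domain length of a coordinate frame
#'
#' The length of a tandem domain pair is defined as two times the Euclidean
#' distance between the mass-weighted centers of mass of the two domains (the
#' free chain termini are deliberately not used, as they do not reflect the
#' native protein context).
#'
#' @param frame A tibble of atoms with columns `x`, `y`, `z`, `mass` and
#'   either a `domain` column or `residue` numbers resolvable through `map`.
#' @param domain_a,domain_b Domain names.
#' @param map Optional [domain_map()] giving residue ranges.
#' @return Length in A.
#' @export
domain_length <- function(frame, domain_a = "domain_a", domain_b = "domain_b",
                          map = NULL) {
  ca <- center_of_mass(domain_atoms(frame, domain_a, map))
  cb <- center_of_mass(domain_atoms(frame, domain_b, map))
  2 * sqrt(sum((ca - cb)^2))
}

#' Straightness of a two-domain arrangement
#'
#' The negative dot product of the normalised vectors drawn from the combined
#' center of mass to the centers of mass of each domain:
#' +1 for a perfectly straight (antiparallel) arrangement, 0 at right angles,
#' -1 when both domain centers lie on the same side. The combined center of
#' mass is taken over the whole frame: for a construct consisting of exactly
#' the two domains it coincides with their union's center of mass (in which
#' case the metric is identically +1 by construction), while bound ions and
#' other particles shift it off the inter-domain axis and make the metric
#' informative.
#'
#' @inheritParams domain_length
#' @return Dimensionless value in \[-1, 1\].
#' @export
straightness <- function(frame, domain_a = "domain_a", domain_b = "domain_b",
                         map = NULL) {
  at_a <- domain_atoms(frame, domain_a, map)
  at_b <- domain_atoms(frame, domain_b, map)
  ca <- center_of_mass(at_a)
  cb <- center_of_mass(at_b)
  cc <- center_of_mass(frame)
  u <- ca - cc
  v <- cb - cc
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-12 || nv < 1e-12)
    abort("Degenerate geometry: a domain center coincides with the combined center of mass.",
          class = "fibrilmech_degenerate_error")
  -sum(u * v) / (nu * nv)
}

#' Apparent stiffness modulus from equilibrium length fluctuations
#'
#' Estimates the effective stiffness of a domain pair from the thermal
#' fluctuations of its instantaneous length,
#' \deqn{K = \frac{kT}{\langle (L_0 - L)^2 \rangle} L,}
#' where `L` is the mean length and the denominator is the population
#' (divide-by-n) variance of the instantaneous lengths, reflecting the
#' ensemble-average brackets; set `population = FALSE` for the n-1
#' convention. The result is converted to piconewtons.
#'
#' @param lengths Numeric vector of instantaneous lengths L0 (A), n >= 2.
#' @param temperature Kelvin.
#' @param population Use the population (1/n) variance (default TRUE).
#' @return A `stiffness_estimate`: list with `K_pn`, `K_kcal_mol_A`,
#'   `mean_length`, `variance`, `temperature`, `n`.
#' @examples
#' apparent_stiffness(rep(c(59.5, 60.5), 50), temperature = 300)
#' @export
apparent_stiffness <- function(lengths, temperature = 300, population = TRUE) {
  n <- length(lengths)
  if (n < 2)
    abort("At least two length samples are required.",
          class = "fibrilmech_validation_error")
  L <- mean(lengths)
  v <- if (population) mean((lengths - L)^2) else var(lengths)
  if (v <= 0)
    abort("Zero length variance: apparent stiffness is infinite.",
          class = "fibrilmech_degenerate_error")
  kT <- thermal_energy(temperature)
  K <- kT * L / v
  structure(
    list(K_pn = K * mech_constants$pN_per_kcal_mol_A, K_kcal_mol_A = K,
         mean_length = L, variance = v, temperature = temperature, n = n,
         population = population),
    class = "stiffness_estimate"
  )
}

#' @export
print.stiffness_estimate <- function(x, ...) {
  cat("<stiffness_estimate> K =", signif(x$K_pn, 4), "pN  (L =",
      signif(x$mean_length, 4), "A, var =", signif(x$variance, 4),
      "A^2, T =", x$temperature, "K, n =", x$n, ")\n")
  invisible(x)
}

#' @rdname apparent_stiffness
#' @param x A `stiffness_estimate`.
#' @param ... Unused.
#' @export
tidy.stiffness_estimate <- function(x, ...) {
  tibble::tibble(
    term = c("K_pn", "mean_length", "variance"),
    estimate = c(x$K_pn, x$mean_length, x$variance)
  )
}

#' @rdname apparent_stiffness
#' @export
glance.stiffness_estimate <- function(x, ...) {
  tibble::tibble(K_pn = x$K_pn, mean_length = x$mean_length,
                 variance = x$variance, temperature = x$temperature, n = x$n)
}

#' Two-sample comparison of means
#'
#' Two-tailed two-sample t-test on equilibrium metric samples. The default is
#' Welch's unequal-variance form; `pooled = TRUE` gives the classical
#' equal-variance test.
#'
#' @param sample_a,sample_b Numeric vectors, each n >= 2.
#' @param pooled Assume equal variances (default FALSE, Welch).
#' @return A one-row tibble: `estimate_a`, `estimate_b`, `statistic`,
#'   `parameter` (df), `p_value`, `method`.
#' @export
compare_means <- function(sample_a, sample_b, pooled = FALSE) {
  if (length(sample_a) < 2 || length(sample_b) < 2)
    abort("Each sample needs at least two observations.",
          class = "fibrilmech_validation_error")
  ht <- t.test(sample_a, sample_b, var.equal = pooled)
  tibble::tibble(
    estimate_a = mean(sample_a), estimate_b = mean(sample_b),
    statistic = unname(ht$statistic), parameter = unname(ht$parameter),
    p_value = ht$p.value, method = if (pooled) "pooled t" else "Welch t"
  )
}

#' Two-sample comparison of variances
#'
#' Two-sided F-test on the ratio of sample variances, with the larger
#' variance in the numerator so the result is invariant to sample order:
#' `F = max(s_a^2, s_b^2) / min(s_a^2, s_b^2)` with `(n1 - 1, n2 - 1)`
#' degrees of freedom and `p = min(1, 2 * P(F_{df1,df2} > F))`.
#'
#' @param sample_a,sample_b Numeric vectors, each n >= 2, non-zero variance.
#' @return A one-row tibble: `statistic`, `df1`, `df2`, `p_value`,
#'   `var_a`, `var_b`.
#' @export
compare_variances <- function(sample_a, sample_b) {
  if (length(sample_a) < 2 || length(sample_b) < 2)
    abort("Each sample needs at least two observations.",
          class = "fibrilmech_validation_error")
  va <- var(sample_a); vb <- var(sample_b)
  if (va <= 0 || vb <= 0)
    abort("Zero variance in a sample.", class = "fibrilmech_validation_error")
  if (va >= vb) {
    f <- va / vb; df1 <- length(sample_a) - 1; df2 <- length(sample_b) - 1
  } else {
    f <- vb / va; df1 <- length(sample_b) - 1; df2 <- length(sample_a) - 1
  }
  p <- min(1, 2 * pf(f, df1, df2, lower.tail = FALSE))
  tibble::tibble(statistic = f, df1 = df1, df2 = df2, p_value = p,
                 var_a = va, var_b = vb)
}
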