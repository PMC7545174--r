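two_atom_frame <- function(d = 30) {
  tibble::tibble(
    atom_id = 1:2, element = "C", mass = 12,
    x = c(0, d), y = 0, z = 0,
    residue = 1:2, domain = c("domain_a", "domain_b")
  )
}

test_that("two-domain length doubles the COM distance", {
  expect_equal(domain_length(two_atom_frame(30)), 60)
  expect_equal(domain_length(two_atom_frame(0)), 0)
})

test_that("length matches a brute-force COM oracle on random beads", {
  set.seed(5)
  frame <- tibble::tibble(
    atom_id = 1:20, element = "C", mass = runif(20, 1, 20),
    x = rnorm(20, rep(c(-10, 10), each = 10), 3),
    y = rnorm(20), z = rnorm(20),
    residue = 1:20, domain = rep(c("domain_a", "domain_b"), each = 10)
  )
  ca <- oracle_com(frame[frame$domain == "domain_a", ])
  cb <- oracle_com(frame[frame$domain == "domain_b", ])
  expect_equal(domain_length(frame), 2 * sqrt(sum((ca - cb)^2)))
})

test_that("length and straightness are rigid-motion invariant", {
  set.seed(6)
  frame <- tibble::tibble(
    atom_id = 1:12, element = "C", mass = runif(12, 5, 15),
    x = rnorm(12, rep(c(-8, 8), each = 6)), y = rnorm(12), z = rnorm(12),
    residue = 1:12, domain = rep(c("domain_a", "domain_b"), each = 6)
  )
  moved <- rotate_frame(frame)
  expect_equal(domain_length(moved), domain_length(frame))
  expect_equal(straightness(moved), straightness(frame))
  # linear scaling scales the length linearly
  scaled <- dplyr::mutate(frame, x = 2.5 * x, y = 2.5 * y, z = 2.5 * z)
  expect_equal(domain_length(scaled), 2.5 * domain_length(frame))
})

test_that("straightness is +1 collinear, 0 at right angles, within [-1, 1]", {
  expect_equal(straightness(two_atom_frame(30)), 1)

  # domain COMs at (1,0) and (0,1); the anchor pulls the frame COM to the
  # origin, so the two arms are orthogonal
  right <- tibble::tibble(
    atom_id = 1:3, element = "C", mass = c(1, 1, 2),
    x = c(1, 0, -0.5), y = c(0, 1, -0.5), z = 0,
    residue = 1:3, domain = c("domain_a", "domain_b", "anchor")
  )
  expect_equal(straightness(right), 0, tolerance = 1e-12)

  set.seed(7)
  for (i in 1:10) {
    frame <- tibble::tibble(
      atom_id = 1:9, element = "C", mass = runif(9, 1, 10),
      x = rnorm(9), y = rnorm(9), z = rnorm(9),
      residue = 1:9, domain = c(rep(c("domain_a", "domain_b"), each = 4),
                                "ligand")
    )
    s <- straightness(frame)
    expect_true(s >= -1 - 1e-12 && s <= 1 + 1e-12)
    # hand-rolled oracle
    at_a <- frame[frame$domain == "domain_a", ]
    at_b <- frame[frame$domain == "domain_b", ]
    ca <- oracle_com(at_a); cb <- oracle_com(at_b)
    cc <- oracle_com(frame)
    u <- (ca - cc) / sqrt(sum((ca - cc)^2))
    v <- (cb - cc) / sqrt(sum((cb - cc)^2))
    expect_equal(s, -sum(u * v))
  }
})

test_that("apparent stiffness follows the fluctuation formula exactly", {
  # kT L / var = 0.5962 * 60 / 0.5 kcal/mol/A = 4971 pN
  lengths <- 60 + c(-1, 1) * sqrt(0.5) # population variance exactly 0.5
  est <- apparent_stiffness(lengths, temperature = 300)
  expect_equal(est$K_kcal_mol_A, 0.5962 * 60 / 0.5, tolerance = 1e-12)
  expect_equal(est$K_pn, 0.5962 * 60 / 0.5 * 69.48, tolerance = 1e-12)
  expect_equal(round(est$K_pn), 4971)

  est2 <- apparent_stiffness(lengths, temperature = 600)
  expect_equal(est2$K_pn, 2 * est$K_pn)

  # doubling the variance halves K
  wider <- 60 + c(-1, 1) * sqrt(1.0)
  expect_equal(apparent_stiffness(wider, 300)$K_pn, est$K_pn / 2)

  expect_error(apparent_stiffness(rep(60, 5), 300),
               class = "fibrilmech_degenerate_error")
  expect_error(apparent_stiffness(60, 300),
               class = "fibrilmech_validation_error")
  expect_equal(tidy(est)$term, c("K_pn", "mean_length", "variance"))
  expect_equal(glance(est)$n, 2)
})

test_that("stiffness is recovered from large Gaussian length samples", {
  set.seed(123)
  sigma2 <- 1.7
  lengths <- rnorm(1e5, mean = 60, sd = sqrt(sigma2))
  est <- apparent_stiffness(lengths, temperature = 300)
  closed <- 0.5962 * 60 / sigma2 * 69.48
  expect_lt(abs(est$K_pn - closed) / closed, 0.05)
})

test_that("mean comparison reproduces the Welch formula", {
  same <- compare_means(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  out <- compare_means(c(1, 2, 3), c(2, 3, 4))
  # hand-computed: means 2 vs 3, var 1 each, se = sqrt(2/3), df = 4
  t_hand <- (2 - 3) / sqrt(1 / 3 + 1 / 3)
  expect_equal(out$statistic, t_hand)
  expect_equal(out$parameter, 4)
  expect_equal(out$p_value, 2 * pt(t_hand, 4))
  pooled <- compare_means(c(1, 2, 3), c(2, 3, 4), pooled = TRUE)
  expect_equal(pooled$method, "pooled t")
  expect_error(compare_means(1, c(1, 2)),
               class = "fibrilmech_validation_error")
})

test_that("mean comparison detects the calcium length shift at n = 10", {
  # the holo/apo regime: tight 59.60 +/- 2.06 vs broad 56.19 +/- 11.86;
  # power check by simulation, not a reproduction of the study p-value
  set.seed(42)
  detected <- replicate(40, {
    holo <- rnorm(10, 59.60, 2.06)
    apo <- rnorm(10, 56.19, 11.86)
    res <- compare_means(holo, apo)
    res$estimate_a > res$estimate_b
  })
  expect_gt(mean(detected), 0.7)
})

test_that("variance comparison is a symmetric two-sided F-test", {
  set.seed(9)
  a <- rnorm(10, sd = 1)
  b <- rnorm(10, sd = 2)
  out <- compare_variances(a, b)
  f_hand <- max(var(a), var(b)) / min(var(a), var(b))
  expect_equal(out$statistic, f_hand)
  expect_equal(out$p_value, min(1, 2 * (1 - pf(f_hand, 9, 9))))
  swapped <- compare_variances(b, a)
  expect_equal(swapped$p_value, out$p_value)
  expect_equal(swapped$statistic, out$statistic)

  eq <- compare_variances(c(1, 2, 3, 4), c(5, 6, 7, 8))
  expect_equal(eq$statistic, 1)
  expect_equal(eq$p_value, 1)
  expect_error(compare_variances(c(1, 1), c(1, 2)),
               class = "fibrilmech_validation_error")
})
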