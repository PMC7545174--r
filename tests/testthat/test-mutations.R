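map <- fbn1_domain_map()

test_that("disease keyword filtering assigns each record exactly once", {
  rec <- tibble::tibble(
    id = 1:6,
    disease = c("neonatal MFS", "intantil MFS", "Classical MFS", "MFS",
                "isolated ectopia lentis", "mfs")
  )
  out <- filter_records(rec)
  expect_equal(out$cohort, c("nMFS", "nMFS", "cMFS", "cMFS",
                             "excluded", "excluded")) # exact, case-sensitive
  expect_equal(sum(table(out$cohort)), nrow(rec))
})

test_that("the replica database partitions to the recorded marginals", {
  records <- replica_mutation_table()
  expect_equal(nrow(records), 3231)
  out <- filter_records(records)
  counts <- cohort_counts(out)
  expect_equal(counts$n[counts$cohort == "nMFS"], 93)
  expect_equal(counts$n[counts$cohort == "cMFS"], 1718)
  expect_equal(counts$n[counts$cohort == "excluded"], 1420)
  expect_equal(attr(counts, "included"), 1811)
})

test_that("positions resolve to the expected domains", {
  out <- assign_domain(c(1086, 1138, 1070, 1112, 1113, 1154), map)
  expect_equal(out$domain,
               c("cbEGF12", "cbEGF13", "cbEGF12", "cbEGF12",
                 "cbEGF13", "cbEGF13"))
  # the proline-rich linker is typed "other"
  pr <- map$domains[map$domains$name == "proline_rich", ]
  out2 <- assign_domain(pr$start + 5, map)
  expect_equal(out2$type, "other")
  expect_error(assign_domain(99999, map),
               class = "fibrilmech_validation_error")
})

test_that("named study mutations classify to their residue classes", {
  rec <- tibble::tibble(
    id = 1:5,
    position = c(1086, 1111, 1117, 1138, 1088),
    wt_aa = c("C", "C", "C", "C", "N"),
    mut_aa = c("R", "R", "R", "R", "S")
  )
  out <- classify_residue(rec, map)
  expect_equal(out$residue_class,
               c("cysteine", "cysteine", "cysteine", "cysteine",
                 "calcium_binding"))
  expect_equal(out$bond, c(1, 3, 1, 2, NA))       # C1086R/C1117R bond 1,
  expect_equal(out$domain,                        # C1111R bond 3, C1138R bond 2
               c("cbEGF12", "cbEGF12", "cbEGF13", "cbEGF13", "cbEGF12"))
  # wild-type C at an unmapped position is a data inconsistency
  bad <- tibble::tibble(id = 1, position = 1090, wt_aa = "C", mut_aa = "R")
  expect_error(classify_residue(bad, map), class = "fibrilmech_data_error")
})

test_that("every cbEGF domain maps its six cysteines onto three bonds", {
  cb <- map$domains[map$domains$type == "cbEGF", ]
  for (i in seq_len(nrow(cb))) {
    positions <- unlist(cb[i, paste0("C", 1:6)], use.names = FALSE)
    rec <- tibble::tibble(id = 1:6, position = positions,
                          wt_aa = "C", mut_aa = "Y")
    out <- classify_residue(rec, map)
    expect_equal(out$residue_class, rep("cysteine", 6))
    expect_equal(out$bond, c(1, 2, 1, 2, 3, 3)) # C1-C3, C2-C4, C5-C6
    expect_equal(as.integer(table(out$bond)), rep(2L, 3))
  }
})

test_that("synthetic cohorts apportion counts exactly and round-trip", {
  half <- generate_mutation_cohort(
    100, c(calcium_binding = 0.5, other = 0.5), seed = 3)
  expect_equal(sum(half$class == "calcium_binding"), 50)
  expect_equal(sum(half$class == "other"), 50)

  # largest-remainder apportionment: exact total at awkward proportions
  odd <- generate_mutation_cohort(
    93, c(calcium_binding = 0.4, cysteine_bond1 = 0.25, cysteine_bond2 = 0.05,
          cysteine_bond3 = 0.15, other = 0.15), seed = 4)
  expect_equal(nrow(odd), 93)
  expect_equal(unname(fibrilmech:::largest_remainder(
    c(a = 1 / 3, b = 1 / 3, c = 1 / 3), 10)), c(4L, 3L, 3L))

  # classification recovers the generating class for every record
  cohort <- generate_mutation_cohort(
    400, c(calcium_binding = 0.3, cysteine_bond1 = 0.2, cysteine_bond2 = 0.2,
           cysteine_bond3 = 0.1, other = 0.2), seed = 5)
  out <- classify_residue(cohort, map)
  got <- ifelse(out$residue_class == "cysteine",
                paste0("cysteine_bond", out$bond), out$residue_class)
  expect_equal(got, cohort$class)

  expect_error(generate_mutation_cohort(10, c(calcium_binding = 0.7)),
               class = "fibrilmech_validation_error")
})

test_that("cohort summaries report percentages with binomial SE", {
  records <- filter_records(replica_mutation_table()) |>
    dplyr::filter(cohort != "excluded") |>
    classify_residue(map)
  s <- summarize_cohort(records, by = "residue_class")
  for (co in unique(s$cohort)) {
    sub <- s[s$cohort == co, ]
    expect_equal(sum(sub$n), sub$total[1])
    expect_equal(sum(sub$pct), 100)
    p <- sub$pct / 100
    expect_equal(sub$se, 100 * sqrt(p * (1 - p) / sub$total))
  }
})

test_that("chi-squared comparisons match the closed form", {
  out <- chisq_2x2(matrix(c(10, 90, 30, 70), 2, 2, byrow = TRUE))
  expect_equal(out$statistic, 12.5)
  expect_equal(out$df, 1)
  expect_equal(out$p_value, 1 - pchisq(12.5, 1))

  same <- chisq_2x2(matrix(c(20, 80, 10, 40), 2, 2, byrow = TRUE))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  swapped <- chisq_2x2(matrix(c(30, 70, 10, 90), 2, 2, byrow = TRUE))
  expect_equal(swapped$statistic, 12.5)

  expect_error(chisq_2x2(matrix(c(0, 0, 3, 4), 2, 2)),
               class = "fibrilmech_degenerate_error")
  expect_equal(tidy(out)$p.value, out$p_value)
})

test_that("cohort comparison builds the right 2x2 table", {
  records <- tibble::tibble(
    cohort = rep(c("cMFS", "nMFS"), times = c(100, 100)),
    residue_class = c(rep("cysteine", 10), rep("other", 90),
                      rep("cysteine", 30), rep("other", 70))
  )
  out <- compare_cohorts(records, class = "cysteine")
  expect_equal(out$statistic, 12.5)
  expect_equal(out$prop_a, 0.10)
  expect_equal(out$prop_b, 0.30)
  yates <- compare_cohorts(records, class = "cysteine", yates = TRUE)
  expect_lt(yates$statistic, out$statistic)
})

test_that("the uniform baseline reproduces residue shares", {
  one <- domain_map(tibble::tibble(name = "all", type = "cbEGF",
                                   start = 1, end = 100,
                                   C1 = 5, C2 = 12, C3 = 17, C4 = 26,
                                   C5 = 34, C6 = 42))
  expect_equal(uniform_random_baseline(one)$expected_pct, 100)

  two <- domain_map(tibble::tibble(
    name = c("a", "b"), type = c("EGF", "TB"),
    start = c(1, 51), end = c(50, 100)))
  out <- uniform_random_baseline(two)
  expect_equal(out$expected_pct, c(50, 50))

  # Monte-Carlo within 3 binomial SE of the analytic expectation
  mc <- uniform_random_baseline(map, n_draws = 1e5, seed = 2)
  p <- mc$expected_pct / 100
  se <- 100 * sqrt(p * (1 - p) / 1e5)
  expect_true(all(abs(mc$mc_pct - mc$expected_pct) <= 3 * se + 1e-9))
})
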