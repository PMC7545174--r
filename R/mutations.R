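#' Partition mutation records into disease cohorts
#'
#' Assigns every record to exactly one of the neonatal cohort (nMFS), the
#' classical cohort (cMFS) or the excluded pool by exact, case-sensitive
#' disease-label matching. The neonatal keywords are matched first: the
#' database's generic "MFS" label is a substring-free but exact member of the
#' classical set, so precedence is the only consistent reading of the
#' overlapping keyword lists. The database's "intantil MFS" spelling is
#' accepted verbatim alongside "infantile MFS".
#'
#' @param records A tibble with at least a `disease` column.
#' @param nmfs_keywords Labels defining the neonatal cohort.
#' @param cmfs_keywords Labels defining the classical cohort.
#' @return The records with a new `cohort` column
#'   (`"nMFS"`, `"cMFS"` or `"excluded"`).
#' @export
filter_records <- function(records,
                           nmfs_keywords = c("neonatal MFS", "intantil MFS",
                                             "infantile MFS"),
                           cmfs_keywords = c("Classical MFS", "MFS")) {
  stopifnot("disease" %in% names(records))
  records |>
    dplyr::mutate(cohort = dplyr::case_when(
      .data$disease %in% nmfs_keywords ~ "nMFS",
      .data$disease %in% cmfs_keywords ~ "cMFS",
      TRUE ~ "excluded"
    ))
}

#' Cohort counts after filtering
#'
#' @param records Output of [filter_records()].
#' @return A tibble with columns `cohort` and `n`, plus an `included` total
#'   attribute.
#' @export
cohort_counts <- function(records) {
  out <- dplyr::count(records, .data$cohort)
  structure(out, included = sum(out$n[out$cohort != "excluded"]))
}

# bond membership of the six cysteine ordinals: C1-C3, C2-C4, C5-C6
cysteine_bond_of_ordinal <- c(1L, 2L, 1L, 2L, 3L, 3L)

#' Classify mutated residues by functional class
#'
#' Classifies each record as a calcium-binding residue mutation, a disulfide
#' cysteine mutation (attributed to bond 1, 2 or 3 via the ordinal of the
#' mutated cysteine: C1/C3 form bond 1, C2/C4 bond 2, C5/C6 bond 3 — either
#' partner counts toward its bond), or "other". A record whose wild-type
#' residue is C at a position the map does not list as a cysteine is a data
#' inconsistency and raises an error.
#'
#' @param records A tibble with columns `position` and `wt_aa`.
#' @param map A [domain_map()].
#' @return The records with new columns `domain`, `domain_type`,
#'   `residue_class` (`"calcium_binding"`, `"cysteine"`, `"other"`) and
#'   `bond` (1, 2, 3 or `NA`).
#' @export
classify_residue <- function(records, map) {
  stopifnot(inherits(map, "domain_map"),
            all(c("position", "wt_aa") %in% names(records)))
  dom <- assign_domain(records$position, map)

  cys_long <- map$domains |>
    dplyr::filter(.data$type == "cbEGF") |>
    tidyr::pivot_longer(dplyr::all_of(paste0("C", 1:6)),
                        names_to = "ordinal", values_to = "position") |>
    dplyr::mutate(ordinal = as.integer(sub("^C", "", .data$ordinal)),
                  bond = cysteine_bond_of_ordinal[.data$ordinal]) |>
    dplyr::select("position", "bond")

  bond <- cys_long$bond[match(records$position, cys_long$position)]
  is_cys <- !is.na(bond)
  is_ca <- records$position %in% map$calcium_sites$position & !is_cys

  bad <- records$wt_aa == "C" & !is_cys
  if (any(bad))
    abort(paste0("Record(s) claim wild-type cysteine at non-cysteine position(s): ",
                 paste(unique(records$position[bad]), collapse = ", ")),
          class = "fibrilmech_data_error")

  records |>
    dplyr::mutate(
      domain = dom$domain, domain_type = dom$type,
      residue_class = dplyr::case_when(is_cys ~ "cysteine",
                                       is_ca ~ "calcium_binding",
                                       TRUE ~ "other"),
      bond = bond
    )
}

#' Generate a synthetic mutation cohort with known class structure
#'
#' Draws missense mutation records whose functional classes are fixed by
#' construction, so classification round-trips exactly. Counts per class
#' follow largest-remainder apportionment of the requested proportions
#' (floors first, then the largest fractional remainders), giving exact
#' totals.
#'
#' @param n Number of records.
#' @param proportions Named numeric vector summing to 1 over the classes
#'   `calcium_binding`, `cysteine_bond1`, `cysteine_bond2`, `cysteine_bond3`,
#'   `other` (omit classes at 0).
#' @param disease Disease label applied to every record (vectorised labels
#'   are recycled).
#' @param map A [domain_map()]; default [fbn1_domain_map()].
#' @param neonatal_only Restrict cbEGF draws to the neonatal region
#'   (cbEGF11-cbEGF18).
#' @param seed Integer seed.
#' @return A tibble with columns `id`, `position`, `wt_aa`, `mut_aa`,
#'   `disease`, `class` (the generating class).
#' @export
generate_mutation_cohort <- function(n, proportions, disease = "MFS",
                                     map = fbn1_domain_map(),
                                     neonatal_only = FALSE, seed = 1L) {
  classes <- c("calcium_binding", "cysteine_bond1", "cysteine_bond2",
               "cysteine_bond3", "other")
  if (!all(names(proportions) %in% classes))
    abort(paste("Proportion names must be among:",
                paste(classes, collapse = ", ")),
          class = "fibrilmech_validation_error")
  if (abs(sum(proportions) - 1) > 1e-9)
    abort("Proportions must sum to 1.", class = "fibrilmech_validation_error")
  counts <- largest_remainder(proportions, n)

  cb <- map$domains[map$domains$type == "cbEGF", ]
  if (neonatal_only) cb <- cb[cb$name %in% paste0("cbEGF", 11:18), ]
  cys_pos <- list(
    cysteine_bond1 = c(cb$C1, cb$C3),
    cysteine_bond2 = c(cb$C2, cb$C4),
    cysteine_bond3 = c(cb$C5, cb$C6)
  )
  ca_sites <- map$calcium_sites
  if (neonatal_only)
    ca_sites <- ca_sites[ca_sites$domain %in% paste0("cbEGF", 11:18), ]
  special <- sort(unique(c(unlist(cys_pos, use.names = FALSE),
                           map$calcium_sites$position,
                           unlist(map$domains[paste0("C", 1:6)],
                                  use.names = FALSE))))
  other_pool <- setdiff(seq_len(map$length), special)

  withr::with_seed(seed, {
    rows <- purrr::imap(counts, function(k, class) {
      if (k == 0) return(NULL)
      if (class == "calcium_binding") {
        i <- sample.int(nrow(ca_sites), k, replace = TRUE)
        pos <- ca_sites$position[i]
        wt <- ca_sites$residue[i]
      } else if (class == "other") {
        pos <- sample(other_pool, k, replace = TRUE)
        wt <- sample(setdiff(amino_acids, "C"), k, replace = TRUE)
      } else {
        pos <- sample(cys_pos[[class]], k, replace = TRUE)
        wt <- rep("C", k)
      }
      mut <- purrr::map_chr(wt, ~ sample(setdiff(amino_acids, c(.x, "C")), 1))
      tibble::tibble(position = pos, wt_aa = wt, mut_aa = mut, class = class)
    })
    out <- dplyr::bind_rows(rows)
    out <- out[sample.int(nrow(out)), ]
  })
  out$id <- seq_len(nrow(out))
  out$disease <- rep_len(disease, nrow(out))
  dplyr::select(out, "id", "position", "wt_aa", "mut_aa", "disease", "class")
}

# largest-remainder apportionment: exact total, floors plus the largest
# fractional remainders (ties broken by class order)
largest_remainder <- function(proportions, n) {
  raw <- proportions * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- raw - base
    extra <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(proportions))
}

#' Summarise a classified cohort
#'
#' Counts, percentages and binomial standard errors
#' (`SE = sqrt(p (1 - p) / n)`) of a classified record table, grouped by any
#' classification column.
#'
#' @param records Output of [classify_residue()] (optionally already carrying
#'   a `cohort` column from [filter_records()]).
#' @param by Grouping column: `"residue_class"`, `"domain_type"`, `"domain"`
#'   or `"bond"`.
#' @param cohort_col Optional name of a cohort column to stratify by.
#' @return A tibble with columns (`cohort`,) `category`, `n`, `total`, `pct`,
#'   `se`.
#' @export
summarize_cohort <- function(records, by = "residue_class",
                             cohort_col = if ("cohort" %in% names(records))
                               "cohort" else NULL) {
  stopifnot(by %in% names(records))
  grp <- if (is.null(cohort_col)) by else c(cohort_col, by)
  out <- records |>
    dplyr::filter(!is.na(.data[[by]])) |>
    dplyr::count(dplyr::across(dplyr::all_of(grp)), name = "n")
  denom_grp <- if (is.null(cohort_col)) character() else cohort_col
  out <- out |>
    dplyr::group_by(dplyr::across(dplyr::all_of(denom_grp))) |>
    dplyr::mutate(total = sum(.data$n),
                  pct = 100 * .data$n / .data$total,
                  se = 100 * sqrt((.data$pct / 100) * (1 - .data$pct / 100) /
                                    .data$total)) |>
    dplyr::ungroup() |>
    dplyr::rename(category = dplyr::all_of(by))
  structure(out, class = c("cohort_summary", class(out)))
}

#' Chi-squared comparison of a class between two cohorts
#'
#' Builds the 2x2 table (in class / not in class) x (cohort A / cohort B) and
#' tests equality of proportions with Pearson's chi-squared on one degree of
#' freedom. Continuity correction is off by default (`yates = TRUE` enables
#' it).
#'
#' @param records Classified records with a `cohort` column.
#' @param class Value of `column` defining membership (e.g. `"cysteine"`).
#' @param column Classification column (default `"residue_class"`).
#' @param cohorts Two cohort labels to compare (default `c("cMFS", "nMFS")`).
#' @param yates Apply the continuity correction.
#' @return A `cohort_comparison`: one-row tibble with `statistic`, `df`,
#'   `p_value`, `prop_a`, `prop_b`, `n_a`, `n_b` and the table as an
#'   attribute.
#' @export
compare_cohorts <- function(records, class, column = "residue_class",
                            cohorts = c("cMFS", "nMFS"), yates = FALSE) {
  stopifnot(all(c(column, "cohort") %in% names(records)))
  sub <- records[records$cohort %in% cohorts & !is.na(records[[column]]), ]
  tbl <- vapply(cohorts, function(co) {
    x <- sub[[column]][sub$cohort == co]
    c(sum(x == class), sum(x != class))
  }, numeric(2))
  chisq_2x2(t(tbl), yates = yates)
}

#' Chi-squared test on a 2x2 contingency table
#'
#' @param tbl A 2x2 matrix of non-negative counts: rows = groups,
#'   columns = in/out of class.
#' @param yates Apply the continuity correction (default FALSE).
#' @return A `cohort_comparison` one-row tibble (see [compare_cohorts()]).
#' @examples
#' chisq_2x2(matrix(c(10, 90, 30, 70), nrow = 2, byrow = TRUE)) # X^2 = 12.5
#' @export
chisq_2x2 <- function(tbl, yates = FALSE) {
  tbl <- as.matrix(tbl)
  if (!all(dim(tbl) == c(2, 2)) || any(tbl < 0))
    abort("`tbl` must be a 2x2 matrix of non-negative counts.",
          class = "fibrilmech_validation_error")
  expected <- outer(rowSums(tbl), colSums(tbl)) / sum(tbl)
  if (any(expected == 0))
    abort("Degenerate table: an expected count is zero.",
          class = "fibrilmech_degenerate_error")
  ht <- suppressWarnings(chisq.test(tbl, correct = yates))
  out <- tibble::tibble(
    statistic = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value,
    prop_a = unname(tbl[1, 1] / sum(tbl[1, ])),
    prop_b = unname(tbl[2, 1] / sum(tbl[2, ])),
    n_a = unname(sum(tbl[1, ])), n_b = unname(sum(tbl[2, ]))
  )
  structure(out, table = tbl,
            class = c("cohort_comparison", class(out)))
}

#' @rdname chisq_2x2
#' @param x A `cohort_comparison`.
#' @param ... Unused.
#' @export
tidy.cohort_comparison <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, parameter = x$df,
                 p.value = x$p_value,
                 method = "Pearson chi-squared (2x2)")
}

#' Expected mutation distribution under a uniform positional model
#'
#' The null used for the "random" bars of the domain-type figure: mutations
#' land uniformly on the protein sequence, so the expected percentage per
#' domain type is its share of residues. An optional Monte-Carlo draw
#' provides an empirical percentage and binomial standard error per type.
#'
#' @param map A [domain_map()].
#' @param n_draws Monte-Carlo sample size (0 = analytic only).
#' @param seed Integer seed for the draw.
#' @return A tibble with columns `type`, `expected_pct` and, when draws are
#'   requested, `mc_pct` and `mc_se`.
#' @export
uniform_random_baseline <- function(map, n_draws = 0, seed = 1L) {
  stopifnot(inherits(map, "domain_map"))
  res <- assign_domain(seq_len(map$length), map)
  expected <- res |>
    dplyr::count(.data$type, name = "residues") |>
    dplyr::mutate(expected_pct = 100 * .data$residues / map$length) |>
    dplyr::select("type", "expected_pct")
  if (n_draws > 0) {
    pos <- withr::with_seed(seed, sample.int(map$length, n_draws, replace = TRUE))
    mc <- assign_domain(pos, map) |>
      dplyr::count(.data$type, name = "k") |>
      dplyr::mutate(mc_pct = 100 * .data$k / n_draws,
                    mc_se = 100 * sqrt((.data$k / n_draws) *
                                         (1 - .data$k / n_draws) / n_draws)) |>
      dplyr::select("type", "mc_pct", "mc_se")
    expected <- dplyr::left_join(expected, mc, by = "type") |>
      dplyr::mutate(mc_pct = dplyr::coalesce(.data$mc_pct, 0),
                    mc_se = dplyr::coalesce(.data$mc_se, 0))
  }
  expected
}
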