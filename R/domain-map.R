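#' Construct a protein domain map
#'
#' A domain map is the lookup table the mutation and conformational analyses
#' share: ordered, non-overlapping inclusive residue ranges with a type for
#' each domain, the six cysteine ordinals (C1..C6) of every cbEGF domain, and
#' the calcium-binding residue set per cbEGF domain.
#'
#' @param domains A tibble with columns `name`, `type` (one of `"EGF"`,
#'   `"cbEGF"`, `"TB"`, `"hybrid"`, `"other"`), `start`, `end` and, for
#'   cbEGF rows, `C1`..`C6` residue numbers.
#' @param calcium_sites A tibble with columns `domain`, `position`,
#'   `residue` (one-letter code) listing calcium-binding residues.
#' @return An object of class `domain_map`.
#' @export
domain_map <- function(domains, calcium_sites = NULL) {
  domains <- tibble::as_tibble(domains)
  stopifnot(all(c("name", "type", "start", "end") %in% names(domains)))
  domains <- dplyr::arrange(domains, .data$start)
  if (any(domains$end < domains$start))
    abort("Domain ranges must satisfy start <= end.",
          class = "fibrilmech_validation_error")
  if (nrow(domains) > 1 &&
      any(domains$start[-1] <= domains$end[-nrow(domains)]))
    abort("Domain ranges must be non-overlapping.",
          class = "fibrilmech_validation_error")
  cb <- domains[domains$type == "cbEGF", ]
  cys_cols <- paste0("C", 1:6)
  if (nrow(cb) > 0) {
    if (!all(cys_cols %in% names(domains)))
      abort("cbEGF domains require cysteine ordinal columns C1..C6.",
            class = "fibrilmech_validation_error")
    if (anyNA(cb[cys_cols]))
      abort("Every cbEGF domain must map all six cysteine ordinals.",
            class = "fibrilmech_validation_error")
  }
  if (is.null(calcium_sites))
    calcium_sites <- tibble::tibble(domain = character(), position = integer(),
                                    residue = character())
  structure(
    list(domains = domains, calcium_sites = tibble::as_tibble(calcium_sites),
         length = max(domains$end)),
    class = "domain_map"
  )
}

#' @export
print.domain_map <- function(x, ...) {
  cat("<domain_map>", nrow(x$domains), "domains over residues 1..",
      x$length, "\n")
  print(dplyr::count(x$domains, .data$type))
  invisible(x)
}

#' Schematic fibrillin-1 domain map
#'
#' Builds a synthetic full-length fibrillin-1 domain map: 43 cbEGF domains,
#' 7 TB domains, 2 hybrid domains and 4 EGF domains over 2871 residues, with
#' the cbEGF12 (D1070-M1112) and cbEGF13 (D1113-I1154) ranges placed exactly.
#' Cysteine ordinals sit at offsets +4, +11, +16, +25, +33, +41 from each
#' cbEGF start — reproducing every cysteine the study names (C1074, C1081,
#' C1086 and C1111 in cbEGF12; C1117, C1124 and C1138 in cbEGF13) — and
#' calcium-binding residues at offsets +0 (D), +18 (N), +19 (T), +22 (D/S),
#' reproducing the named binding residues N1088/T1089/D1092 and
#' N1131/T1132/S1135. Ranges outside cbEGF12/13 are schematic stand-ins, not
#' database coordinates; the map is for synthetic cohorts and baselines.
#'
#' @return A [domain_map()].
#' @export
fbn1_domain_map <- function() {
  lay <- list(
    c("Nterm", "other", 45),
    c("EGF1", "EGF", 36), c("EGF2", "EGF", 36), c("EGF3", "EGF", 36),
    c("hybrid1", "hybrid", 60),
    c("cbEGF1", "cbEGF", 42),
    c("TB1", "TB", 70),
    c("proline_rich", "other", 88),
    c("EGF4", "EGF", 36),
    c("hybrid2", "hybrid", 60)
  )
  for (i in 2:11) lay <- c(lay, list(c(paste0("cbEGF", i), "cbEGF", 42)))
  lay <- c(lay, list(c("TB2", "TB", 70), c("TB3", "TB", 70)))
  lay <- c(lay, list(c("cbEGF12", "cbEGF", 43), c("cbEGF13", "cbEGF", 42)))
  lay <- c(lay, list(c("TB4", "TB", 70)))
  for (i in 14:22) lay <- c(lay, list(c(paste0("cbEGF", i), "cbEGF", 42)))
  lay <- c(lay, list(c("TB5", "TB", 70)))
  for (i in 23:32) lay <- c(lay, list(c(paste0("cbEGF", i), "cbEGF", 42)))
  lay <- c(lay, list(c("TB6", "TB", 70)))
  for (i in 33:42) lay <- c(lay, list(c(paste0("cbEGF", i), "cbEGF", 42)))
  lay <- c(lay, list(c("TB7", "TB", 70), c("cbEGF43", "cbEGF", 42),
                     c("Cterm", "other", 177)))

  len <- as.integer(purrr::map_chr(lay, 3))
  end <- cumsum(len)
  start <- end - len + 1L
  domains <- tibble::tibble(
    name = purrr::map_chr(lay, 1),
    type = purrr::map_chr(lay, 2),
    start = start, end = end
  )
  stopifnot(domains$start[domains$name == "cbEGF12"] == 1070,
            domains$end[domains$name == "cbEGF13"] == 1154)

  cys_off <- c(4, 11, 16, 25, 33, 41)
  cb <- domains$type == "cbEGF"
  for (k in 1:6) {
    domains[[paste0("C", k)]] <- ifelse(cb, domains$start + cys_off[k],
                                        NA_integer_)
  }

  ca_off <- c(0, 18, 19, 22)
  ca_res <- c("D", "N", "T", "D")
  cb_rows <- domains[cb, ]
  calcium_sites <- purrr::pmap_dfr(
    list(cb_rows$name, cb_rows$start),
    function(name, start) {
      res <- ca_res
      if (name == "cbEGF13") res[4] <- "S"  # S1135
      tibble::tibble(domain = name, position = start + ca_off, residue = res)
    }
  )
  domain_map(domains, calcium_sites)
}

#' Assign protein positions to domains
#'
#' @param positions Integer vector of residue positions (1-based).
#' @param map A [domain_map()].
#' @return A tibble with columns `position`, `domain` (`"other"` for
#'   inter-domain linkers covered by an `other` range), `type`.
#' @export
assign_domain <- function(positions, map) {
  stopifnot(inherits(map, "domain_map"))
  if (any(positions < 1 | positions > map$length))
    abort(paste0("Positions must lie in 1..", map$length, "."),
          class = "fibrilmech_validation_error")
  idx <- findInterval(positions, map$domains$start)
  inside <- idx >= 1 & positions <= map$domains$end[pmax(idx, 1)]
  tibble::tibble(
    position = positions,
    domain = ifelse(inside, map$domains$name[pmax(idx, 1)], "other"),
    type = ifelse(inside, map$domains$type[pmax(idx, 1)], "other")
  )
}
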