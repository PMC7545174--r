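# --- TSV with '#key=value' metadata headers ---------------------------------

write_metadata_tsv <- function(data, path, metadata = list()) {
  metadata <- c(metadata, list(package = "fibrilmech",
                               version = as.character(utils::packageVersion("fibrilmech"))))
  header <- paste0("#", names(metadata), "=", unname(unlist(metadata)))
  writeLines(header, path)
  suppressMessages(
    readr::write_tsv(data, path, append = TRUE, col_names = TRUE)
  )
  invisible(path)
}

read_metadata_tsv <- function(path, assume_units = FALSE) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines)
  kv <- sub("^#", "", lines[meta_lines])
  meta <- as.list(setNames(sub("^[^=]*=", "", kv), sub("=.*$", "", kv)))
  if (is.null(meta$units) && !assume_units)
    abort(paste0("File '", path, "' carries no `units` metadata; ",
                 "pass assume_units = TRUE to read it anyway."),
          class = "fibrilmech_validation_error")
  data <- suppressMessages(
    readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  )
  list(data = data, metadata = meta)
}

#' Write / read a work ensemble as TSV
#'
#' The on-disk format is one `extension` column plus one column per replicate
#' (`W1`, `W2`, ...), preceded by `#key=value` metadata lines recording the
#' units, temperature, strain reference length and pulling protocol.
#'
#' @param ensemble A `work_ensemble`.
#' @param path Output file.
#' @return `path`, invisibly (writer); a `work_ensemble` (reader).
#' @export
write_work_ensemble <- function(ensemble, path) {
  mat <- ensemble_matrix(ensemble)
  wide <- tibble::as_tibble(as.data.frame(mat$works))
  names(wide) <- paste0("W", seq_len(ncol(wide)))
  wide <- dplyr::bind_cols(tibble::tibble(extension = mat$extension), wide)
  pr <- attr(ensemble, "protocol")
  meta <- list(units = "extension=A;work=kcal/mol",
               temperature_K = attr(ensemble, "temperature"),
               l_ref_A = attr(ensemble, "l_ref"))
  if (!is.null(pr))
    meta <- c(meta, list(spring_constant = pr$spring_constant,
                         pull_speed = pr$pull_speed,
                         total_distance = pr$total_distance,
                         restraint = pr$restraint,
                         output_interval = pr$output_interval))
  write_metadata_tsv(wide, path, meta)
}

#' @rdname write_work_ensemble
#' @param assume_units Accept files lacking a `units` metadata line.
#' @export
read_work_ensemble <- function(path, assume_units = FALSE) {
  parsed <- read_metadata_tsv(path, assume_units = assume_units)
  wide <- parsed$data
  works <- as.matrix(wide[grep("^W[0-9]+$", names(wide))])
  ens <- work_ensemble(
    extension = wide$extension, works = works,
    temperature = as.numeric(parsed$metadata$temperature_K %||% 300),
    l_ref = as.numeric(parsed$metadata$l_ref_A %||% 60)
  )
  if (!is.null(parsed$metadata$spring_constant)) {
    attr(ens, "protocol") <- steering_protocol(
      spring_constant = as.numeric(parsed$metadata$spring_constant),
      pull_speed = as.numeric(parsed$metadata$pull_speed),
      total_distance = as.numeric(parsed$metadata$total_distance),
      restraint = as.numeric(parsed$metadata$restraint),
      output_interval = as.numeric(parsed$metadata$output_interval)
    )
  }
  ens
}

#' Write a PMF or force profile as TSV
#'
#' @param profile A `pmf_profile` or `force_profile`.
#' @param path Output file.
#' @export
write_profile_tsv <- function(profile, path) {
  units <- if (inherits(profile, "force_profile"))
    "extension=A;strain=%;force_pn=pN" else "extension=A;strain=%;delta_g=kcal/mol"
  write_metadata_tsv(tibble::as_tibble(profile), path, list(units = units))
}

# --- PDB ---------------------------------------------------------------------

#' Write toy-structure frames to a PDB file
#'
#' One MODEL per frame; the calcium ligand is written as a HETATM with
#' residue name `CA`, the convention by which readers rediscover it.
#'
#' @param frames Output of [generate_toy_conformations()] (or a single
#'   [toy_structure()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_frames_pdb <- function(frames, path) {
  if (!"frame" %in% names(frames)) frames <- dplyr::mutate(frames, frame = 1L)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in unique(frames$frame)) {
    at <- frames[frames$frame == f, ]
    writeLines(sprintf("MODEL     %4d", f), con)
    for (i in seq_len(nrow(at))) {
      is_lig <- !is.na(at$role[i]) && at$role[i] == "ligand"
      rec <- if (is_lig) "HETATM" else "ATOM  "
      resname <- if (is_lig) "CA " else "TOY"
      elety <- if (is_lig) "CA" else substr(at$element[i], 1, 2)
      writeLines(sprintf(
        "%-6s%5d %-4s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        rec, at$atom_id[i], elety, resname, at$residue[i],
        at$x[i], at$y[i], at$z[i], 1.0, 0.0, toupper(at$element[i])), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read coordinate frames from a PDB file
#'
#' Parses single- or multi-model PDB files through `bio3d::read.pdb()` and
#' returns one tibble row per atom per frame. Elements are taken from the
#' element column when present and inferred from atom names (with a warning)
#' otherwise; a HETATM with residue name `CA` is flagged as the calcium
#' ligand.
#'
#' @param path PDB file.
#' @return A tibble with columns `frame`, `atom_id`, `element`, `mass`, `x`,
#'   `y`, `z`, `residue`, `role`.
#' @export
read_pdb_frames <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  elements <- toupper(trimws(at$elesy))
  if (any(is.na(elements) | elements == "")) {
    warn("PDB file lacks element entries for some atoms; inferring from atom names.")
    guess <- toupper(substr(trimws(at$elety), 1, 1))
    elements <- ifelse(is.na(elements) | elements == "", guess, elements)
  }
  is_lig <- at$type == "HETATM" & trimws(at$resid) == "CA"
  masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
              CA = 40.078)
  n_atoms <- nrow(at)
  xyz <- pdb$xyz
  n_frames <- nrow(xyz)
  purrr::map_dfr(seq_len(n_frames), function(f) {
    coords <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    tibble::tibble(
      frame = f, atom_id = at$eleno, element = elements,
      mass = unname(masses[elements]),
      x = coords[, 1], y = coords[, 2], z = coords[, 3],
      residue = at$resno,
      role = ifelse(is_lig, "ligand", "atom")
    )
  })
}

# --- YAML configuration ------------------------------------------------------

#' Read a pipeline configuration from YAML
#'
#' The YAML blocks mirror the constructor arguments of [potential_spec()],
#' [steering_protocol()] and [langevin_config()], plus top-level `seed`,
#' `l_ref` and optional `mutations` (path to a record CSV).
#'
#' @param path YAML file.
#' @return A named list ready for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}
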