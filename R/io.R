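# Sniff the field delimiter of a header-free numeric text file.
sniff_delim <- function(path) {
  line1 <- readLines(path, n = 1)
  if (grepl(",", line1, fixed = TRUE)) "," else "white"
}

read_numeric_matrix <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  delim <- sniff_delim(path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sep <- if (delim == ",") "," else "[ \t]+"
  rows <- strsplit(trimws(lines), sep)
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1) {
    abort(paste0("Ragged rows in ", path), class = "longconn_invalid_matrix")
  }
  vals <- suppressWarnings(as.numeric(unlist(rows)))  # strtod: exact parse
  if (anyNA(vals)) {
    abort(paste0("Non-numeric or NaN entries in ", path),
          class = "longconn_invalid_matrix")
  }
  matrix(vals, nrow = length(rows), ncol = ncols[1], byrow = TRUE)
}

#' Read a connectivity matrix from delimited text
#'
#' Expects `N` header-free rows of `N` numeric fields (tab, space or comma
#' separated). The matrix must be square and symmetric (relative tolerance
#' 1e-8); a nonzero diagonal is forced to zero with a warning; NaN entries
#' are an error.
#'
#' @param path File path.
#' @param modality `"functional"` or `"structural"`.
#' @param subject_id,group,timepoint Identifiers attached to the result.
#' @return A [connectivity_matrix()].
#' @export
read_connectivity_matrix <- function(path, modality,
                                     subject_id = NA_character_,
                                     group = NA_character_,
                                     timepoint = NA_character_) {
  m <- read_numeric_matrix(path)
  if (nrow(m) != ncol(m)) {
    abort(sprintf("Matrix in %s is %d x %d, not square.", path, nrow(m), ncol(m)),
          class = "longconn_invalid_matrix")
  }
  connectivity_matrix(m, modality, subject_id, group, timepoint)
}

#' Write a connectivity matrix (or bare matrix) to tab-delimited text
#'
#' Values are written with 17 significant digits, so a read/write round trip
#' reproduces the numeric content exactly.
#'
#' @param x A [connectivity_matrix()], [weighted_network()], or matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_connectivity_matrix <- function(x, path) {
  w <- if (inherits(x, c("connectivity_matrix", "weighted_network"))) x$weights else x
  lines <- apply(w, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read an ROI time-series file (volumes x ROIs)
#'
#' @param path Delimited text, one row per volume, one column per ROI.
#' @return Numeric matrix.
#' @export
read_roi_timeseries <- function(path) {
  m <- read_numeric_matrix(path)
  if (nrow(m) < 3) abort("Need at least 3 volumes.")
  m
}

#' Read a study manifest
#'
#' A delimited table with columns `subject_id`, `group`, `timepoint`,
#' `modality` and `path` (matrix files, or ROI time-series files for rows
#' with modality `"timeseries"`). Paths are resolved relative to the
#' manifest's directory.
#'
#' @param path Manifest file path (CSV or TSV).
#' @return Tibble.
#' @export
read_manifest <- function(path) {
  delim <- sniff_delim(path)
  mf <- if (delim == ",") readr::read_csv(path, show_col_types = FALSE)
        else readr::read_tsv(path, show_col_types = FALSE)
  need <- c("subject_id", "group", "timepoint", "modality", "path")
  miss <- setdiff(need, names(mf))
  if (length(miss) > 0) {
    abort(paste0("Manifest lacks columns: ", paste(miss, collapse = ", ")))
  }
  mf$path <- ifelse(grepl("^/", mf$path), mf$path,
                    file.path(dirname(path), mf$path))
  tibble::as_tibble(mf)
}

#' Load a full study from a manifest
#'
#' Reads every matrix (building functional matrices from ROI time series
#' where the manifest says `timeseries`), and verifies completeness: every
#' subject must have both modalities at every timepoint. Incomplete
#' subjects are an error, never silently dropped.
#'
#' @param manifest_path Path to the manifest file.
#' @param subjects_path Optional covariate table (CSV/TSV) with
#'   `subject_id` plus covariate columns.
#' @return An `lc_study`-like list with `manifest`, `matrices`, `subjects`.
#' @export
read_study <- function(manifest_path, subjects_path = NULL) {
  mf <- read_manifest(manifest_path)
  tps <- unique(mf$timepoint)
  complete <- mf |>
    dplyr::mutate(modality = ifelse(.data$modality == "timeseries",
                                    "functional", .data$modality)) |>
    dplyr::distinct(.data$subject_id, .data$timepoint, .data$modality) |>
    dplyr::count(.data$subject_id)
  bad <- complete$subject_id[complete$n < 2 * length(tps)]
  if (length(bad) > 0) {
    abort(paste0("Incomplete subjects (missing scans): ",
                 paste(bad, collapse = ", ")),
          class = "longconn_incomplete")
  }
  matrices <- purrr::pmap(mf, function(subject_id, group, timepoint, modality,
                                       path, ...) {
    if (modality == "timeseries") {
      functional_matrix_from_timeseries(read_roi_timeseries(path),
                                        subject_id, group, timepoint)
    } else {
      read_connectivity_matrix(path, modality, subject_id, group, timepoint)
    }
  })
  modality_out <- ifelse(mf$modality == "timeseries", "functional", mf$modality)
  names(matrices) <- paste(mf$subject_id, mf$timepoint, modality_out, sep = "_")
  manifest <- dplyr::mutate(mf, modality = modality_out,
                            key = names(matrices))
  subjects <- if (!is.null(subjects_path)) {
    d <- sniff_delim(subjects_path)
    if (d == ",") readr::read_csv(subjects_path, show_col_types = FALSE)
    else readr::read_tsv(subjects_path, show_col_types = FALSE)
  } else NULL
  structure(list(manifest = manifest, matrices = matrices, subjects = subjects),
            class = "lc_study")
}

#' Write a synthetic study to disk in the package's file formats
#'
#' Writes one tab-delimited matrix file per subject x timepoint x modality,
#' a manifest, a covariate table and the clinical table — the same formats
#' [read_study()] consumes, so the pipeline can be exercised end-to-end
#' through files.
#'
#' @param study An `lc_study` from [generate_study()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "lc_study"))
  dir.create(file.path(dir, "matrices"), recursive = TRUE, showWarnings = FALSE)
  mf <- study$manifest
  mf$path <- file.path("matrices", paste0(mf$key, ".tsv"))
  purrr::walk2(study$matrices[mf$key], file.path(dir, mf$path),
               write_connectivity_matrix)
  readr::write_csv(mf[, c("subject_id", "group", "timepoint", "modality", "path")],
                   file.path(dir, "manifest.csv"))
  if (!is.null(study$subjects)) {
    readr::write_csv(study$subjects, file.path(dir, "subjects.csv"))
  }
  if (!is.null(study$clinical)) {
    readr::write_csv(study$clinical, file.path(dir, "clinical.csv"))
  }
  invisible(file.path(dir, "manifest.csv"))
}
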