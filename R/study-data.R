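#' Required columns of a study table
#'
#' A study table holds one row per case-control study: identifying metadata
#' plus the CC/CT/TT genotype counts of cases and controls.
#'
#' @return Character vector of the twelve required column names.
#' @export
study_columns <- function() {
  c("study_id", "year", "country", "ethnicity", "method", "control_source",
    "case_cc", "case_ct", "case_tt", "ctrl_cc", "ctrl_ct", "ctrl_tt")
}

count_columns <- function() study_columns()[7:12]

#' Read a study table from a delimited text file
#'
#' Reads a UTF-8 comma- or tab-delimited file (the delimiter is detected from
#' the header line) with one row per study and the columns named by
#' [study_columns()], and validates it.
#'
#' @param file Path to a CSV or TSV file.
#' @return A validated tibble of studies.
#' @seealso [mthfr_mm_studies()] for the packaged dataset, [write_studies()]
#'   for the inverse operation.
#' @export
read_studies <- function(file) {
  if (!file.exists(file)) {
    abort(paste0("file not found: ", file), class = "mmtsa_io_error")
  }
  header <- readLines(file, n = 1L, encoding = "UTF-8")
  delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- readr::read_delim(
    file, delim = delim, progress = FALSE, show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  missing <- setdiff(study_columns(), names(raw))
  if (length(missing) > 0) {
    abort(paste0("missing required column(s): ", paste(missing, collapse = ", ")),
          class = "mmtsa_schema_error")
  }
  if (nrow(raw) == 0) {
    abort("no studies: file contains a header but no data rows",
          class = "mmtsa_validation_error")
  }
  studies <- dplyr::mutate(
    raw,
    year = parse_count(.data$year, .data$study_id, "year"),
    dplyr::across(dplyr::all_of(count_columns()),
                  ~ parse_count(.x, raw$study_id, dplyr::cur_column()))
  )
  validate_studies(studies)
}

# strict non-negative integer parser; names the offending study and field
parse_count <- function(x, study_id, field) {
  v <- suppressWarnings(as.numeric(x))
  bad <- is.na(v) | v < 0 | v != trunc(v)
  if (any(bad)) {
    abort(sprintf("invalid %s for study '%s': got '%s' (need a non-negative integer)",
                  field, study_id[bad][1], x[bad][1]),
          class = "mmtsa_validation_error")
  }
  as.integer(v)
}

#' Validate a study table
#'
#' Checks the schema and invariants: all required columns present, counts
#' non-negative integers, at least one study, positive case and control
#' totals per study, and unique study identifiers.
#'
#' @param studies A data frame of studies (see [study_columns()]).
#' @return The input as a tibble, invisibly unchanged, for piping.
#' @export
validate_studies <- function(studies) {
  missing <- setdiff(study_columns(), names(studies))
  if (length(missing) > 0) {
    abort(paste0("missing required column(s): ", paste(missing, collapse = ", ")),
          class = "mmtsa_schema_error")
  }
  studies <- tibble::as_tibble(studies)
  if (nrow(studies) == 0) {
    abort("no studies: a study set needs at least one study",
          class = "mmtsa_validation_error")
  }
  for (col in count_columns()) {
    v <- studies[[col]]
    bad <- is.na(v) | v < 0 | v != trunc(v)
    if (any(bad)) {
      abort(sprintf("invalid %s for study '%s': need a non-negative integer",
                    col, studies$study_id[bad][1]),
            class = "mmtsa_validation_error")
    }
  }
  n_case <- studies$case_cc + studies$case_ct + studies$case_tt
  n_ctrl <- studies$ctrl_cc + studies$ctrl_ct + studies$ctrl_tt
  if (any(n_case == 0) || any(n_ctrl == 0)) {
    who <- studies$study_id[n_case == 0 | n_ctrl == 0][1]
    abort(sprintf("study '%s' has an empty case or control arm", who),
          class = "mmtsa_validation_error")
  }
  if (anyDuplicated(studies$study_id)) {
    dup <- studies$study_id[duplicated(studies$study_id)][1]
    abort(sprintf("duplicated study_id '%s'", dup),
          class = "mmtsa_validation_error")
  }
  studies
}

#' Write a study table to CSV
#'
#' @param studies A validated study table.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_studies <- function(studies, file) {
  studies <- validate_studies(studies)
  readr::write_csv(studies[, study_columns()], file, progress = FALSE)
  invisible(file)
}

#' The packaged MTHFR C677T / multiple myeloma study table
#'
#' Genotype distributions and metadata of the nine case-control studies of
#' the MTHFR C677T polymorphism and multiple myeloma (2,092 cases and 4,954
#' controls) on which the whole pipeline operates.
#'
#' @return A tibble with nine rows and the columns of [study_columns()].
#' @examples
#' mthfr_mm_studies() |> study_totals()
#' @export
mthfr_mm_studies <- function() {
  read_studies(system.file("extdata", "table1_mthfr_mm.csv",
                           package = "mmtsa", mustWork = TRUE))
}

#' Case/control totals of a study table
#'
#' @param studies A study table.
#' @return One-row tibble with `n_studies`, `n_cases`, `n_controls`,
#'   `n_total`.
#' @export
study_totals <- function(studies) {
  studies <- validate_studies(studies)
  tibble::tibble(
    n_studies  = nrow(studies),
    n_cases    = sum(studies$case_cc + studies$case_ct + studies$case_tt),
    n_controls = sum(studies$ctrl_cc + studies$ctrl_ct + studies$ctrl_tt),
    n_total    = n_cases + n_controls
  )
}

#' Sort studies chronologically
#'
#' Orders studies by ascending publication year, breaking ties by
#' lexicographic `study_id`. This is the accrual order used by the
#' cumulative meta-analysis inside [tsa()].
#'
#' @param studies A study table.
#' @return The study table, reordered.
#' @export
sort_chronological <- function(studies) {
  studies <- validate_studies(studies)
  if (any(is.na(studies$year))) {
    abort("sort_chronological needs a year for every study",
          class = "mmtsa_validation_error")
  }
  dplyr::arrange(studies, .data$year, .data$study_id)
}
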