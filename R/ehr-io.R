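ehr_schemas <- list(
  patients = c(patient_id = "c", birth_date = "D", sex = "c", vital_status = "c"),
  problem_list = c(patient_id = "c", code = "c", onset_date = "D"),
  treatment_episodes = c(patient_id = "c", drug_name = "c", drug_class = "c",
                         start_date = "D"),
  imaging_studies = c(patient_id = "c", modality = "c", study_date = "D",
                      lvef = "d"),
  medication_orders = c(patient_id = "c", drug_name = "c",
                        pharmaceutical_class = "c", pharmaceutical_subclass = "c",
                        active = "l", as_of_date = "D"),
  referrals = c(patient_id = "c", specialty = "c", referral_date = "D")
)

#' Write an EHR dataset to a directory of CSV files
#'
#' One CSV per entity table (`patients.csv`, `problem_list.csv`, ...). Dates
#' are written in ISO-8601, so the files are diffable plain text and
#' round-trip exactly through [read_ehr_dataset()].
#'
#' @param dataset An [ehr_dataset()].
#' @param dir Output directory (created if absent).
#' @param truth Optional ground-truth tibble; written as `truth.csv`.
#' @return `dir`, invisibly.
#' @export
write_ehr_dataset <- function(dataset, dir, truth = NULL) {
  stopifnot(inherits(dataset, "ehr_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(ehr_schemas)) {
    readr::write_csv(dataset[[nm]], file.path(dir, paste0(nm, ".csv")), na = "")
  }
  if (!is.null(truth)) {
    readr::write_csv(truth, file.path(dir, "truth.csv"), na = "")
  }
  invisible(dir)
}

#' Read an EHR dataset from a directory of CSV files
#'
#' Inverse of [write_ehr_dataset()]. Each file is validated against its
#' expected schema; a missing or extra situation on a required column is an
#' error naming the file and column.
#'
#' @param dir Directory containing the entity CSVs.
#' @return An [ehr_dataset()].
#' @export
read_ehr_dataset <- function(dir) {
  tables <- lapply(names(ehr_schemas), function(nm) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(path)) stop("missing table file: ", path, call. = FALSE)
    schema <- ehr_schemas[[nm]]
    hdr <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                                 show_col_types = FALSE))
    missing <- setdiff(names(schema), hdr)
    if (length(missing) > 0) {
      stop("file '", basename(path), "': missing column(s) ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    spec <- do.call(readr::cols, as.list(schema))
    readr::read_csv(path, col_types = spec, na = c("", "NA"),
                    show_col_types = FALSE)[, names(schema)]
  })
  names(tables) <- names(ehr_schemas)
  do.call(ehr_dataset, tables)
}

#' Read the ground-truth table written next to a synthetic dataset
#'
#' @param dir Directory containing `truth.csv`.
#' @return A tibble, one row per generated patient.
#' @export
read_cohort_truth <- function(dir) {
  readr::read_csv(file.path(dir, "truth.csv"),
                  col_types = readr::cols(patient_id = "c",
                                          exposure_class = "c",
                                          .default = "l"),
                  na = c("", "NA"), show_col_types = FALSE)
}
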