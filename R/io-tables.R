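#' Read a clinical table
#'
#' Reads the per-patient clinical CSV with columns `patient_id`, `age`,
#' `sex`, `smoking`, `survival_months` (optional) and `response`.  The
#' response label encodes the four RECIST outcome classes: 0 complete
#' response, 1 partial response, 2 stable disease, 3 progressive disease.
#' Sex and smoking history are pre-encoded integer codes in `{0, 1, 2}`
#' (sex code 2 is accepted and treated as "unrecorded").
#'
#' @param path path to the CSV file.
#' @return tibble with columns `patient_id`, `age_years`, `sex_code`,
#'   `smoking_code`, `survival_months`, `response_label`.
#' @export
read_clinical_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("patient_id", "age", "sex", "smoking", "response")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0)
    abort(paste0("clinical table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  out <- tibble(
    patient_id = as.character(df$patient_id),
    age_years = as.integer(df$age),
    sex_code = as.integer(df$sex),
    smoking_code = as.integer(df$smoking),
    survival_months = if ("survival_months" %in% names(df))
      as.double(df$survival_months) else NA_real_,
    response_label = as.integer(df$response)
  )
  bad <- which(!out$response_label %in% 0:3)
  if (length(bad) > 0)
    abort(paste0("row ", bad[1], " (", out$patient_id[bad[1]],
                 "): response label ", out$response_label[bad[1]],
                 " outside {0, 1, 2, 3}"))
  bad_age <- which(is.na(out$age_years) | out$age_years < 0)
  if (length(bad_age) > 0)
    abort(paste0("row ", bad_age[1], ": invalid age"))
  for (col in c("sex_code", "smoking_code")) {
    bad_c <- which(!out[[col]] %in% 0:2)
    if (length(bad_c) > 0)
      abort(paste0("row ", bad_c[1], ": ", col, " outside {0, 1, 2}"))
  }
  out
}

#' Read an MM-GBSA energy-components table
#'
#' Reads the per-patient energy CSV with columns `patient_id`, `VDW`
#' (van der Waals), `EEL` (electrostatic), `ESURF` (nonpolar solvation) and
#' `EPB` (polar solvation), all in kcal/mol, plus optional thermodynamic-cycle
#' terms `DG_BIND_VACUUM`, `DG_SOLV_COMPLEX`, `DG_SOLV_LIGAND`,
#' `DG_SOLV_RECEPTOR` used by [binding_free_energy()].
#'
#' @param path path to the CSV file.
#' @return tibble with one row per patient; column names lower-cased.
#' @export
read_energy_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  names(df) <- tolower(names(df))
  req <- c("patient_id", "vdw", "eel", "esurf", "epb")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0)
    abort(paste0("energy table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  if (anyDuplicated(df$patient_id)) {
    dup <- df$patient_id[duplicated(df$patient_id)][1]
    abort(paste0("duplicate patient_id in energy table: ", dup))
  }
  numcols <- setdiff(names(df), "patient_id")
  for (col in numcols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) | !is.finite(v) & !is.na(df[[col]]))
    if (length(bad) > 0)
      abort(paste0("non-numeric ", toupper(col), " value '", df[[col]][bad[1]],
                   "' in row ", bad[1]))
    df[[col]] <- v
  }
  as_tibble(df)
}
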