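# CSV contracts: validated readers for the patient and plan tables,
# decision report writer with round-trip-stable formatting.

read_csv_checked <- function(path, required, max_dose = 80) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("missing column(s) in ", basename(path), ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(tab), required)
  if (length(extra) > 0) {
    warning("ignoring unknown column(s) in ", basename(path), ": ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  tab
}

# data line numbers: row i sits on file line i + 1 (header on line 1)
row_errors <- function(bad, path, what) {
  if (any(bad)) {
    stop(what, " in ", basename(path), " at line(s) ",
         paste(which(bad) + 1, collapse = ", "), call. = FALSE)
  }
}

#' Read a patient table (clinical factors + eligibility columns)
#'
#' Columns: `patient_id`, `tumor_site`, `distant_metastases`,
#' `curative_intent`, `xer_baseline`, `dysphagia_baseline_ge2`,
#' `advanced_t_stage`, `weight_loss`, `treatment` (UTF-8 CSV, fixed
#' header names; unknown extra columns are accepted with a warning).
#' Enum levels are validated with the offending line numbers reported.
#'
#' @param path CSV file path.
#' @return Validated data.frame.
#' @export
read_patient_table <- function(path) {
  req <- c("patient_id", "tumor_site", "distant_metastases",
           "curative_intent", "xer_baseline", "dysphagia_baseline_ge2",
           "advanced_t_stage", "weight_loss", "treatment")
  tab <- read_csv_checked(path, req)
  row_errors(!(tab$tumor_site %in% c("pharynx", "larynx", "oral_cavity",
                                     "other")), path, "unknown tumor_site")
  for (nm in c("xer_baseline", "weight_loss", "treatment")) {
    row_errors(!(tab[[nm]] %in% clinical_levels[[nm]]), path,
               paste0("unknown ", nm, " level"))
  }
  for (nm in c("distant_metastases", "curative_intent",
               "dysphagia_baseline_ge2", "advanced_t_stage")) {
    v <- tab[[nm]]
    if (!is.logical(v)) {
      lv <- tolower(as.character(v))
      row_errors(!(lv %in% c("true", "false", "0", "1")), path,
                 paste0("non-boolean ", nm))
      tab[[nm]] <- lv %in% c("true", "1")
    }
  }
  row_errors(duplicated(tab$patient_id), path, "duplicate patient_id")
  tab[req]
}

#' Read a plan table (per-plan OAR mean doses)
#'
#' Columns: `patient_id`, `plan_id`, and the five dose columns of
#' [oar_fields()] in Gy. Doses must be numeric within
#' \[0, max_dose\]; violations are reported with line numbers.
#'
#' @param path CSV file path.
#' @param max_dose Sanity upper bound in Gy.
#' @return Validated data.frame.
#' @export
read_plan_table <- function(path, max_dose = 80) {
  req <- c("patient_id", "plan_id", oar_fields())
  tab <- read_csv_checked(path, req)
  for (nm in oar_fields()) {
    v <- suppressWarnings(as.numeric(tab[[nm]]))
    row_errors(is.na(v) & !is.na(tab[[nm]]), path,
               paste0("non-numeric ", nm))
    row_errors(!is.na(v) & (v < 0 | v > max_dose), path,
               paste0(nm, " outside [0, ", max_dose, "] Gy"))
    tab[[nm]] <- v
  }
  row_errors(duplicated(tab$patient_id), path, "duplicate patient_id")
  tab[req]
}

#' Write a decision report as CSV plus a JSON summary
#'
#' Percentages (delta columns) are serialized to one decimal place and
#' probabilities to four; decisions were computed before rounding.
#' Logical columns are written lowercase `true`/`false`. The JSON
#' summary holds the screened / compared / qualified counts.
#'
#' @param decisions Output of [screen_cohort()].
#' @param csv_path Output CSV path.
#' @param json_path Optional JSON summary path.
#' @return Invisibly, the formatted data.frame written.
#' @export
write_decision_report <- function(decisions, csv_path, json_path = NULL) {
  out <- decisions
  for (nm in names(out)) {
    if (grepl("^ntcp_", nm)) out[[nm]] <- round(out[[nm]], 4)
    if (grepl("^delta_", nm)) out[[nm]] <- round(out[[nm]], 1)
    if (is.logical(out[[nm]])) out[[nm]] <- ifelse(out[[nm]], "true", "false")
  }
  utils::write.csv(out, csv_path, row.names = FALSE, quote = FALSE,
                   na = "")
  if (!is.null(json_path)) {
    s <- attr(decisions, "summary")
    if (is.null(s)) {
      s <- list(screened = nrow(decisions),
                compared = sum(decisions$plan_comparison_indicated %in% TRUE),
                qualified = sum(decisions$qualifies %in% TRUE))
    }
    jsonlite::write_json(c(list(schema = "ntcpselect/decisions-summary/v1"), s),
                         json_path, auto_unbox = TRUE)
  }
  invisible(out)
}

#' Write a simulated cohort to the engine's CSV dialects
#'
#' @param cohort A `simulated_cohort`.
#' @param dir Output directory (created if needed); writes
#'   `patients.csv`, `photon_plans.csv`, `proton_plans.csv`,
#'   `outcomes.csv`.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(patients = file.path(dir, "patients.csv"),
             photon_plans = file.path(dir, "photon_plans.csv"),
             proton_plans = file.path(dir, "proton_plans.csv"),
             outcomes = file.path(dir, "outcomes.csv"))
  for (nm in names(paths)) {
    tab <- cohort[[nm]]
    for (cn in names(tab)) {
      if (is.logical(tab[[cn]])) tab[[cn]] <- ifelse(tab[[cn]], "true", "false")
      if (is.numeric(tab[[cn]])) tab[[cn]] <- round(tab[[cn]], 6)
    }
    utils::write.csv(tab, paths[[nm]], row.names = FALSE, quote = FALSE)
  }
  invisible(paths)
}

#' Write a set of models to a JSON coefficient file
#'
#' @param models Named list of `ntcp_model`s.
#' @param path Output path.
#' @param version Version string recorded in the file.
#' @return Invisibly, `path`.
#' @export
write_models <- function(models, path, version = "custom") {
  body <- list(version = version, models = lapply(unname(models), function(m) {
    list(name = m$name, endpoint_label = m$endpoint_label,
         ctcae_grade = m$ctcae_grade, intercept = m$intercept,
         dose_coefficients = as.list(m$dose_coefficients),
         clinical_coefficients = as.list(m$clinical_coefficients))
  }))
  jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
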