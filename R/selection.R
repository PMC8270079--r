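# Selection engine: eligibility gate, delta-NTCP_max pre-screen,
# plan-pair delta-NTCP profile, threshold-based qualification.

#' National threshold policy for delta-NTCP qualification
#'
#' Thresholds in percentage points by CTCAE grade. A patient qualifies if
#' a single endpoint's delta-NTCP meets the single threshold for its
#' grade, or if two endpoints of the same grade sum to the summed
#' threshold. Comparisons are inclusive (>=) and performed at full
#' floating precision; no summation across different grades.
#'
#' @param single Named numeric, percentage points per grade
#'   (default `c("2" = 10, "3" = 5, "4" = 2)`).
#' @param summed Named numeric, summed-pair thresholds per grade
#'   (default 1.5 x single: `c("2" = 15, "3" = 7.5, "4" = 3)`).
#' @return Object of class `threshold_policy`.
#' @examples
#' default_policy()
#' @export
threshold_policy <- function(single = c("2" = 10, "3" = 5, "4" = 2),
                             summed = NULL) {
  if (is.null(summed)) summed <- 1.5 * single
  stopifnot(length(single) == length(summed),
            all(names(single) == names(summed)),
            all(single > 0), all(summed > 0))
  g <- as.integer(names(single))
  if (length(g) > 1 && any(diff(single[order(g)]) > 0)) {
    stop("single thresholds must decrease with grade", call. = FALSE)
  }
  structure(list(single = single, summed = summed),
            class = "threshold_policy")
}

#' @rdname threshold_policy
#' @export
default_policy <- function() threshold_policy()

#' Load a threshold policy from a JSON file
#'
#' @param path JSON file with `single` and `summed` maps from grade to
#'   percentage points.
#' @return A `threshold_policy`.
#' @export
load_policy <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  threshold_policy(single = unlist(raw$single), summed = unlist(raw$summed))
}

#' General eligibility gate of the indication protocol
#'
#' A patient may enter model-based selection only if the primary tumor
#' originates in the pharynx, larynx, or oral cavity, there are no
#' distant metastases, and treatment is with curative intent.
#'
#' @param tumor_site One of `"pharynx"`, `"larynx"`, `"oral_cavity"`,
#'   `"other"` (vectorised).
#' @param distant_metastases Logical.
#' @param curative_intent Logical.
#' @return Logical: gate passed.
#' @export
eligibility_gate <- function(tumor_site, distant_metastases, curative_intent) {
  ok_site <- tumor_site %in% c("pharynx", "larynx", "oral_cavity")
  ok_site & !as.logical(distant_metastases) & as.logical(curative_intent)
}

#' Maximum achievable delta-NTCP for one model
#'
#' The pre-screen bound: the delta-NTCP obtained if protons could reduce
#' every dose term of the model to 0 Gy while the clinical factors stay
#' fixed, `100 * (NTCP(photon doses) - NTCP(all model doses = 0))` in
#' percentage points.
#'
#' @param photon_doses [oar_doses()] of the photon plan.
#' @param clinical [clinical_factors()].
#' @param model An `ntcp_model`.
#' @return delta-NTCP_max in percentage points.
#' @examples
#' m <- default_models()$xerostomia
#' delta_ntcp_max(oar_doses(parotid_contralateral_mean = 25),
#'                clinical_factors(xer_baseline = "minor"), m)  # 30.6 pp
#' @export
delta_ntcp_max <- function(photon_doses, clinical, model) {
  zero <- as.list(photon_doses)
  zero[names(model$dose_coefficients)] <- 0
  100 * (ntcp(model, photon_doses, clinical) - ntcp(model, zero, clinical))
}

# Core rule engine. delta_pp: named numeric (endpoint names), grades:
# integer vector aligned with delta_pp. Applies the single rule per
# endpoint and the summed rule over every unordered same-grade pair,
# with signed values and inclusive comparison at full precision.
apply_threshold_rules <- function(delta_pp, grades, policy) {
  stopifnot(length(delta_pp) == length(grades))
  eps <- 0  # exact inclusive comparison
  rules <- list()
  nm <- names(delta_pp)
  if (is.null(nm)) nm <- paste0("endpoint", seq_along(delta_pp))
  for (i in seq_along(delta_pp)) {
    g <- as.character(grades[i])
    thr <- policy$single[[g]]
    if (is.null(thr)) next
    if (delta_pp[i] >= thr - eps) {
      rules[[length(rules) + 1]] <- list(rule = "single", grade = grades[i],
                                         endpoints = nm[i],
                                         value_pp = unname(delta_pp[i]),
                                         threshold_pp = unname(thr))
    }
  }
  if (length(delta_pp) >= 2) {
    pairs <- utils::combn(seq_along(delta_pp), 2, simplify = FALSE)
    for (p in pairs) {
      if (grades[p[1]] != grades[p[2]]) next
      g <- as.character(grades[p[1]])
      thr <- policy$summed[[g]]
      if (is.null(thr)) next
      s <- delta_pp[p[1]] + delta_pp[p[2]]
      if (s >= thr - eps) {
        rules[[length(rules) + 1]] <- list(rule = "summed", grade = grades[p[1]],
                                           endpoints = paste(nm[p], collapse = "+"),
                                           value_pp = unname(s),
                                           threshold_pp = unname(thr))
      }
    }
  }
  list(qualifies = length(rules) > 0, triggered_rules = rules)
}

#' Apply the qualification rules to a delta-NTCP profile
#'
#' @param delta_pp Named numeric vector of delta-NTCP values in
#'   percentage points, one per endpoint (positive favors protons;
#'   negative values are allowed and never trigger, but they do enter
#'   summed pairs with their sign).
#' @param grades Integer CTCAE grades aligned with `delta_pp`.
#' @param policy A [threshold_policy()].
#' @return List with `qualifies` (logical) and `triggered_rules` (list of
#'   rule records: rule, grade, endpoints, value_pp, threshold_pp).
#' @examples
#' qualifies(c(xerostomia = 10, dysphagia = 0, tube_feeding = 0),
#'           grades = c(2L, 2L, 3L), default_policy())
#' @export
qualifies <- function(delta_pp, grades, policy = default_policy()) {
  apply_threshold_rules(delta_pp, grades, policy)
}

format_rules <- function(rules) {
  if (length(rules) == 0) return("")
  paste(vapply(rules, function(r) {
    sprintf("%s[grade%d:%s %.1f>=%g]", r$rule, r$grade, r$endpoints,
            r$value_pp, r$threshold_pp)
  }, ""), collapse = ";")
}

#' Run the full selection flowchart for one patient
#'
#' Traverses the national flowchart: eligibility gate, delta-NTCP_max
#' pre-screen (a plan comparison is only indicated if the thresholds can
#' potentially be reached with all model doses at 0 Gy), then — when a
#' proton plan is supplied — the plan-pair delta-NTCP profile and the
#' threshold qualification. Without a proton plan the decision stops
#' after the pre-screen.
#'
#' @param tumor_site,distant_metastases,curative_intent Eligibility gate
#'   inputs (see [eligibility_gate()]).
#' @param photon_doses [oar_doses()] of the photon plan.
#' @param proton_doses [oar_doses()] of the proton plan, or `NULL` if no
#'   plan comparison has been made yet.
#' @param clinical [clinical_factors()].
#' @param models Named list of `ntcp_model`s.
#' @param policy [threshold_policy()].
#' @return Object of class `selection_decision`: `gate_passed`,
#'   `plan_comparison_indicated`, `qualifies`, `triggered_rules`, and the
#'   per-endpoint `ntcp_photon`, `ntcp_proton`, `delta_pp`,
#'   `delta_max_pp` (percentage points). The implication chain
#'   qualifies => plan_comparison_indicated => gate_passed always holds.
#' @export
select_patient <- function(tumor_site, distant_metastases, curative_intent,
                           photon_doses, proton_doses = NULL, clinical,
                           models = default_models(),
                           policy = default_policy()) {
  gate <- eligibility_gate(tumor_site, distant_metastases, curative_intent)
  grades <- vapply(models, `[[`, 0L, "ctcae_grade")
  empty <- stats::setNames(rep(NA_real_, length(models)), names(models))
  out <- list(gate_passed = gate, plan_comparison_indicated = FALSE,
              qualifies = FALSE, triggered_rules = list(),
              ntcp_photon = empty, ntcp_proton = empty,
              delta_pp = empty, delta_max_pp = empty, grades = grades)
  class(out) <- "selection_decision"
  if (!gate) return(out)

  out$ntcp_photon <- vapply(models, ntcp, 0, doses = photon_doses,
                            clinical = clinical)
  out$delta_max_pp <- vapply(models, function(m)
    delta_ntcp_max(photon_doses, clinical, m), 0)
  screen <- apply_threshold_rules(out$delta_max_pp, grades, policy)
  out$plan_comparison_indicated <- screen$qualifies
  if (!screen$qualifies || is.null(proton_doses)) return(out)

  out$ntcp_proton <- vapply(models, ntcp, 0, doses = proton_doses,
                            clinical = clinical)
  out$delta_pp <- 100 * (out$ntcp_photon - out$ntcp_proton)
  res <- apply_threshold_rules(out$delta_pp, grades, policy)
  out$qualifies <- res$qualifies
  out$triggered_rules <- res$triggered_rules
  out
}

#' @export
print.selection_decision <- function(x, ...) {
  cat("<selection_decision>\n")
  cat("  gate passed:              ", x$gate_passed, "\n")
  cat("  plan comparison indicated:", x$plan_comparison_indicated, "\n")
  cat("  qualifies for protons:    ", x$qualifies, "\n")
  if (x$gate_passed) {
    for (nm in names(x$delta_max_pp)) {
      cat(sprintf("  %-14s NTCP_photon %s  delta %s pp  delta_max %5.1f pp\n", nm,
                  ifelse(is.na(x$ntcp_photon[nm]), "   NA",
                         sprintf("%5.1f%%", 100 * x$ntcp_photon[nm])),
                  ifelse(is.na(x$delta_pp[nm]), "   NA",
                         sprintf("%5.1f", x$delta_pp[nm])),
                  x$delta_max_pp[nm]))
    }
  }
  if (length(x$triggered_rules) > 0) {
    cat("  triggered:", format_rules(x$triggered_rules), "\n")
  }
  invisible(x)
}

#' Screen a cohort of patients and plan pairs
#'
#' Row-wise [select_patient()] over joined patient and plan tables.
#'
#' @param patients data.frame with `patient_id`, the eligibility columns
#'   (`tumor_site`, `distant_metastases`, `curative_intent`) and the five
#'   clinical factor columns.
#' @param photon_plans data.frame with `patient_id`, `plan_id` and the
#'   five dose columns in Gy ([oar_fields()]).
#' @param proton_plans Optional data.frame like `photon_plans`; when
#'   `NULL` the screen stops at the delta-NTCP_max stage.
#' @param models,policy As in [select_patient()].
#' @param strict If `TRUE`, a row-level error aborts the screen;
#'   otherwise failing rows are skipped and reported in the `errors`
#'   attribute.
#' @return data.frame with one row per patient: decision columns plus
#'   per-endpoint NTCP and delta columns; attributes `summary` (screened,
#'   compared, qualified counts) and `errors`.
#' @export
screen_cohort <- function(patients, photon_plans, proton_plans = NULL,
                          models = default_models(),
                          policy = default_policy(), strict = FALSE) {
  stopifnot(is.data.frame(patients), is.data.frame(photon_plans))
  if (anyDuplicated(photon_plans$patient_id)) {
    stop("duplicate patient_id in photon plan table", call. = FALSE)
  }
  if (!is.null(proton_plans) && anyDuplicated(proton_plans$patient_id)) {
    stop("duplicate patient_id in proton plan table", call. = FALSE)
  }
  ph_idx <- match(patients$patient_id, photon_plans$patient_id)
  pr_idx <- if (is.null(proton_plans)) rep(NA_integer_, nrow(patients)) else
    match(patients$patient_id, proton_plans$patient_id)
  rows <- list()
  errors <- list()
  for (i in seq_len(nrow(patients))) {
    pid <- patients$patient_id[i]
    res <- tryCatch({
      if (is.na(ph_idx[i])) stop("no photon plan for this patient")
      ph <- photon_plans[ph_idx[i], , drop = FALSE]
      pr <- NULL
      if (!is.na(pr_idx[i])) {
        pr <- do.call(oar_doses, as.list(proton_plans[pr_idx[i], oar_fields()]))
      }
      cl <- clinical_factors(
        xer_baseline = patients$xer_baseline[i],
        dysphagia_baseline_ge2 = as.logical(patients$dysphagia_baseline_ge2[i]),
        advanced_t_stage = as.logical(patients$advanced_t_stage[i]),
        weight_loss = patients$weight_loss[i],
        treatment = patients$treatment[i])
      d <- select_patient(patients$tumor_site[i],
                          as.logical(patients$distant_metastases[i]),
                          as.logical(patients$curative_intent[i]),
                          photon_doses = do.call(oar_doses, as.list(ph[1, oar_fields()])),
                          proton_doses = pr, clinical = cl,
                          models = models, policy = policy)
      row <- data.frame(patient_id = pid, gate_passed = d$gate_passed,
                        stringsAsFactors = FALSE)
      for (nm in names(models)) {
        row[[paste0("ntcp_photon_", nm)]] <- d$ntcp_photon[[nm]]
        row[[paste0("ntcp_proton_", nm)]] <- d$ntcp_proton[[nm]]
        row[[paste0("delta_pp_", nm)]] <- d$delta_pp[[nm]]
        row[[paste0("delta_max_pp_", nm)]] <- d$delta_max_pp[[nm]]
      }
      row$plan_comparison_indicated <- d$plan_comparison_indicated
      row$qualifies <- d$qualifies
      row$triggered_rules <- format_rules(d$triggered_rules)
      row
    }, error = function(e) e)
    if (inherits(res, "error")) {
      msg <- sprintf("patient %s: %s", pid, conditionMessage(res))
      if (strict) stop(msg, call. = FALSE)
      errors[[length(errors) + 1]] <- msg
    } else {
      rows[[length(rows) + 1]] <- res
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else {
    cols <- c("patient_id", "gate_passed",
              as.vector(t(outer(c("ntcp_photon_", "ntcp_proton_", "delta_pp_",
                                  "delta_max_pp_"), names(models), paste0))),
              "plan_comparison_indicated", "qualifies", "triggered_rules")
    as.data.frame(stats::setNames(rep(list(logical(0)), length(cols)), cols))
  }
  rownames(out) <- NULL
  attr(out, "summary") <- list(
    screened = nrow(out),
    compared = sum(out$plan_comparison_indicated %in% TRUE &
                     !is.na(out[[paste0("ntcp_proton_", names(models)[1])]])),
    qualified = sum(out$qualifies %in% TRUE))
  attr(out, "errors") <- unlist(errors)
  out
}
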