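# NTCP models: coefficient containers, linear predictors, probabilities.

#' Organ-at-risk dose fields recognised by the engine
#'
#' Mean physical doses in Gy read from a treatment plan's dose-volume
#' histogram: contralateral parotid gland, oral cavity, superior and
#' inferior pharyngeal constrictor muscles (PCM), and cricopharyngeal
#' muscle.
#'
#' @return Character vector of the five dose column names.
#' @export
oar_fields <- function() {
  c("parotid_contralateral_mean", "oral_cavity_mean",
    "pcm_superior_mean", "pcm_inferior_mean", "cricopharyngeal_mean")
}

# Enumerated levels of the clinical predictors; the first level of each
# enum is the reference level (implicit coefficient 0).
clinical_levels <- list(
  xer_baseline = c("none", "minor", "moderate_severe"),
  weight_loss  = c("none", "moderate_1_10pct", "severe_gt10pct"),
  treatment    = c("conventional_rt_alone", "accelerated_rt",
                   "chemoradiation", "rt_plus_cetuximab")
)

#' Clinical predictor indicator names
#'
#' Every non-reference level of the categorical clinical predictors plus
#' the two binary predictors, in the dummy coding the coefficient files
#' use (`factor.level` for enums, bare name for binaries).
#'
#' @return Character vector of indicator names.
#' @export
clinical_indicator_names <- function() {
  c("xer_baseline.minor", "xer_baseline.moderate_severe",
    "dysphagia_baseline_ge2", "advanced_t_stage",
    "weight_loss.moderate_1_10pct", "weight_loss.severe_gt10pct",
    "treatment.accelerated_rt", "treatment.chemoradiation",
    "treatment.rt_plus_cetuximab")
}

#' Per-plan organ-at-risk mean doses
#'
#' @param parotid_contralateral_mean,oral_cavity_mean,pcm_superior_mean,pcm_inferior_mean,cricopharyngeal_mean
#'   Mean dose in Gy to the respective organ-at-risk. Fields a model does
#'   not use may be left `NA`; evaluating a model whose coefficients need
#'   an `NA` field is an error.
#' @param max_dose Sanity upper bound in Gy (default 80).
#' @return A named numeric vector of class `oar_doses`.
#' @examples
#' oar_doses(parotid_contralateral_mean = 25, oral_cavity_mean = 40,
#'           pcm_superior_mean = 50, pcm_inferior_mean = 30,
#'           cricopharyngeal_mean = 25)
#' @export
oar_doses <- function(parotid_contralateral_mean = NA_real_,
                      oral_cavity_mean = NA_real_,
                      pcm_superior_mean = NA_real_,
                      pcm_inferior_mean = NA_real_,
                      cricopharyngeal_mean = NA_real_,
                      max_dose = 80) {
  d <- c(parotid_contralateral_mean = as.numeric(parotid_contralateral_mean),
         oral_cavity_mean = as.numeric(oral_cavity_mean),
         pcm_superior_mean = as.numeric(pcm_superior_mean),
         pcm_inferior_mean = as.numeric(pcm_inferior_mean),
         cricopharyngeal_mean = as.numeric(cricopharyngeal_mean))
  bad <- !is.na(d) & (d < 0 | d > max_dose)
  if (any(bad)) {
    stop("dose out of [0, ", max_dose, "] Gy: ",
         paste0(names(d)[bad], "=", d[bad], collapse = ", "), call. = FALSE)
  }
  structure(d, class = "oar_doses")
}

#' Non-dosimetric clinical predictors of the NTCP models
#'
#' @param xer_baseline Baseline xerostomia: `"none"`, `"minor"` or
#'   `"moderate_severe"`.
#' @param dysphagia_baseline_ge2 Logical; baseline dysphagia grade >= 2.
#' @param advanced_t_stage Logical; T3 or T4 primary tumor.
#' @param weight_loss Pre-treatment weight loss: `"none"`,
#'   `"moderate_1_10pct"` (1-10 percent) or `"severe_gt10pct"` (over 10
#'   percent of body weight).
#' @param treatment One of `"conventional_rt_alone"`, `"accelerated_rt"`,
#'   `"chemoradiation"`, `"rt_plus_cetuximab"` (mutually exclusive).
#' @return A list of class `clinical_factors`.
#' @examples
#' clinical_factors(xer_baseline = "minor", treatment = "chemoradiation")
#' @export
clinical_factors <- function(xer_baseline = "none",
                             dysphagia_baseline_ge2 = FALSE,
                             advanced_t_stage = FALSE,
                             weight_loss = "none",
                             treatment = "conventional_rt_alone") {
  xer_baseline <- match.arg(xer_baseline, clinical_levels$xer_baseline)
  weight_loss <- match.arg(weight_loss, clinical_levels$weight_loss)
  treatment <- match.arg(treatment, clinical_levels$treatment)
  stopifnot(is.logical(dysphagia_baseline_ge2), length(dysphagia_baseline_ge2) == 1,
            is.logical(advanced_t_stage), length(advanced_t_stage) == 1)
  structure(list(xer_baseline = xer_baseline,
                 dysphagia_baseline_ge2 = dysphagia_baseline_ge2,
                 advanced_t_stage = advanced_t_stage,
                 weight_loss = weight_loss,
                 treatment = treatment),
            class = "clinical_factors")
}

#' Expand clinical factors to 0/1 indicator variables
#'
#' Dummy-codes the enum levels (reference level dropped) and the binary
#' predictors into the indicator names coefficient files use.
#'
#' @param clinical A [clinical_factors()] object or a data.frame with the
#'   five clinical columns (one row per patient).
#' @return Named numeric vector (single patient) or matrix with one row
#'   per patient and one column per indicator.
#' @export
clinical_indicators <- function(clinical) {
  if (inherits(clinical, "clinical_factors")) {
    clinical <- as.data.frame(unclass(clinical), stringsAsFactors = FALSE)
    single <- TRUE
  } else {
    single <- FALSE
  }
  need <- c("xer_baseline", "dysphagia_baseline_ge2", "advanced_t_stage",
            "weight_loss", "treatment")
  missing_cols <- setdiff(need, names(clinical))
  if (length(missing_cols) > 0) {
    stop("missing clinical column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  check_level <- function(col, levels) {
    bad <- !is.na(clinical[[col]]) & !(clinical[[col]] %in% levels)
    if (any(bad)) {
      stop("unknown level(s) for ", col, ": ",
           paste(unique(clinical[[col]][bad]), collapse = ", "), call. = FALSE)
    }
  }
  check_level("xer_baseline", clinical_levels$xer_baseline)
  check_level("weight_loss", clinical_levels$weight_loss)
  check_level("treatment", clinical_levels$treatment)
  ind <- cbind(
    xer_baseline.minor = as.numeric(clinical$xer_baseline == "minor"),
    xer_baseline.moderate_severe = as.numeric(clinical$xer_baseline == "moderate_severe"),
    dysphagia_baseline_ge2 = as.numeric(as.logical(clinical$dysphagia_baseline_ge2)),
    advanced_t_stage = as.numeric(as.logical(clinical$advanced_t_stage)),
    weight_loss.moderate_1_10pct = as.numeric(clinical$weight_loss == "moderate_1_10pct"),
    weight_loss.severe_gt10pct = as.numeric(clinical$weight_loss == "severe_gt10pct"),
    treatment.accelerated_rt = as.numeric(clinical$treatment == "accelerated_rt"),
    treatment.chemoradiation = as.numeric(clinical$treatment == "chemoradiation"),
    treatment.rt_plus_cetuximab = as.numeric(clinical$treatment == "rt_plus_cetuximab")
  )
  if (single) ind[1, ] else ind
}

#' Construct an NTCP model specification
#'
#' A named logistic model: NTCP = 1 / (1 + exp(-LP)) with
#' LP = intercept + sum(dose coefficients x mean doses in Gy) +
#' sum(clinical coefficients x 0/1 indicators). Reference levels carry an
#' implicit coefficient of 0.
#'
#' @param name Model identifier.
#' @param endpoint_label Human-readable toxicity endpoint.
#' @param ctcae_grade CTCAE grade the endpoint maps to (2 or 3 for the
#'   shipped models; 4 allowed for future models).
#' @param intercept Intercept of the linear predictor.
#' @param dose_coefficients Named numeric; names must be [oar_fields()]
#'   entries; units are per Gy.
#' @param clinical_coefficients Named numeric; names must be
#'   [clinical_indicator_names()] entries.
#' @return An object of class `ntcp_model`.
#' @export
model_spec <- function(name, endpoint_label, ctcae_grade, intercept,
                       dose_coefficients = numeric(),
                       clinical_coefficients = numeric()) {
  dose_coefficients <- unlist(dose_coefficients)
  clinical_coefficients <- unlist(clinical_coefficients)
  if (length(dose_coefficients) == 0) dose_coefficients <- numeric()
  if (length(clinical_coefficients) == 0) clinical_coefficients <- numeric()
  bad_d <- setdiff(names(dose_coefficients), oar_fields())
  if (length(bad_d) > 0) {
    stop("unknown dose coefficient field(s) in model '", name, "': ",
         paste(bad_d, collapse = ", "), call. = FALSE)
  }
  bad_c <- setdiff(names(clinical_coefficients), clinical_indicator_names())
  if (length(bad_c) > 0) {
    stop("unknown clinical coefficient key(s) in model '", name, "': ",
         paste(bad_c, collapse = ", "), call. = FALSE)
  }
  stopifnot(is.numeric(intercept), length(intercept) == 1, is.finite(intercept),
            ctcae_grade %in% 2:4)
  structure(list(name = name,
                 endpoint_label = endpoint_label,
                 ctcae_grade = as.integer(ctcae_grade),
                 intercept = as.numeric(intercept),
                 dose_coefficients = dose_coefficients,
                 clinical_coefficients = clinical_coefficients),
            class = "ntcp_model")
}

#' @export
print.ntcp_model <- function(x, ...) {
  cat(sprintf("<ntcp_model> %s (%s, CTCAE grade %d)\n",
              x$name, x$endpoint_label, x$ctcae_grade))
  cat(sprintf("  LP = %.3f", x$intercept))
  for (nm in names(x$dose_coefficients)) {
    cat(sprintf(" + %.3f x %s", x$dose_coefficients[[nm]], nm))
  }
  for (nm in names(x$clinical_coefficients)) {
    cat(sprintf(" + %.3f x [%s]", x$clinical_coefficients[[nm]], nm))
  }
  cat("\n")
  invisible(x)
}

#' Load NTCP model specifications from a JSON coefficient file
#'
#' The file holds a `version` string and a `models` array; each model
#' carries name, endpoint, CTCAE grade, intercept, and dose/clinical
#' coefficient maps. The shipped default file reproduces the three
#' national-protocol models exactly.
#'
#' @param path Path to the JSON coefficient file.
#' @return Named list of [model_spec()] objects with attributes `version`
#'   and `source` (the file path).
#' @export
load_models <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(raw$models)) stop("model file has no 'models' entry: ", path, call. = FALSE)
  models <- lapply(raw$models, function(m) {
    model_spec(name = m$name, endpoint_label = m$endpoint_label,
               ctcae_grade = m$ctcae_grade, intercept = m$intercept,
               dose_coefficients = m$dose_coefficients,
               clinical_coefficients = m$clinical_coefficients)
  })
  names(models) <- vapply(models, `[[`, "", "name")
  attr(models, "version") <- if (is.null(raw$version)) "unversioned" else raw$version
  attr(models, "source") <- normalizePath(path)
  models
}

#' The three default NTCP models of the national indication protocol
#'
#' Loads the shipped coefficient file: moderate-to-severe xerostomia
#' (grade 2), grade II-IV dysphagia (grade 2), and tube feeding
#' dependence (grade 3), all at 6 months after radiotherapy. A
#' transcription guard asserts that all dose coefficients are positive
#' and all clinical coefficients nonnegative.
#'
#' @return Named list of three `ntcp_model` objects.
#' @examples
#' default_models()
#' @export
default_models <- function() {
  path <- system.file("extdata", "models.json", package = "ntcpselect")
  models <- load_models(path)
  for (m in models) {
    if (any(m$dose_coefficients <= 0) || any(m$clinical_coefficients < 0)) {
      stop("transcription guard: default model '", m$name,
           "' has a non-positive dose or negative clinical coefficient",
           call. = FALSE)
    }
  }
  models
}

#' Logistic function
#'
#' The standard NTCP link: maps a linear predictor to a probability,
#' 1 / (1 + exp(-lp)).
#'
#' @param lp Finite numeric vector of linear predictor values.
#' @return Probabilities in (0, 1).
#' @examples
#' logistic(0)       # 0.5
#' logistic(-1.507)  # 0.1814
#' @export
logistic <- function(lp) {
  if (!is.numeric(lp) || any(!is.finite(lp))) {
    stop("linear predictor must be finite numeric", call. = FALSE)
  }
  stats::plogis(lp)
}

# Vectorised linear predictor over a cohort. doses: data.frame/list with
# the dose columns the model needs; clinical: data.frame of clinical
# columns (or precomputed indicator matrix via `indicators`).
model_lp <- function(model, doses, clinical = NULL, indicators = NULL) {
  dn <- names(model$dose_coefficients)
  miss <- setdiff(dn, names(doses))
  if (length(miss) > 0) {
    stop("model '", model$name, "': missing dose predictor(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  lp <- model$intercept
  for (nm in dn) {
    d <- as.numeric(doses[[nm]])
    if (any(is.na(d))) {
      stop("model '", model$name, "': dose predictor '", nm, "' is NA",
           call. = FALSE)
    }
    lp <- lp + model$dose_coefficients[[nm]] * d
  }
  cn <- names(model$clinical_coefficients)
  if (length(cn) > 0) {
    if (is.null(indicators)) {
      if (is.null(clinical)) {
        stop("model '", model$name, "': clinical factors required", call. = FALSE)
      }
      indicators <- clinical_indicators(clinical)
      if (is.null(dim(indicators))) indicators <- matrix(indicators, nrow = 1,
                                                         dimnames = list(NULL, names(indicators)))
    }
    for (nm in cn) {
      v <- indicators[, nm]
      if (any(is.na(v))) {
        stop("model '", model$name, "': clinical predictor '", nm, "' is NA",
             call. = FALSE)
      }
      lp <- lp + model$clinical_coefficients[[nm]] * v
    }
  }
  as.numeric(lp)
}

#' Evaluate a model's linear predictor for one patient/plan
#'
#' LP = intercept + sum over organs of (coefficient x mean dose) + sum
#' over clinical indicator levels of (coefficient x indicator). Missing
#' required predictors raise an explicit error naming the model and the
#' field; there is no silent default.
#'
#' @param model An `ntcp_model`.
#' @param doses An [oar_doses()] vector (or named list of doses in Gy).
#' @param clinical A [clinical_factors()] object.
#' @return The linear predictor (numeric scalar).
#' @examples
#' m <- default_models()$xerostomia
#' linear_predictor(m, oar_doses(parotid_contralateral_mean = 25),
#'                  clinical_factors())   # -0.207
#' @export
linear_predictor <- function(model, doses, clinical) {
  stopifnot(inherits(model, "ntcp_model"))
  model_lp(model, as.list(doses), clinical = clinical)
}

#' Evaluate an NTCP value for one patient/plan
#'
#' @inheritParams linear_predictor
#' @return NTCP as a probability in (0, 1).
#' @export
ntcp <- function(model, doses, clinical) {
  logistic(linear_predictor(model, doses, clinical))
}

#' NTCP profile across a set of models
#'
#' Evaluates every model for one patient/plan combination, the
#' "NTCP profile" of expected toxicity rates.
#'
#' @inheritParams linear_predictor
#' @param models Named list of `ntcp_model` objects; defaults to the
#'   three national-protocol models.
#' @return data.frame with one row per model: `endpoint`, `ctcae_grade`,
#'   `linear_predictor`, `ntcp`.
#' @examples
#' ntcp_profile(oar_doses(25, 40, 50, 30, 25), clinical_factors())
#' @export
ntcp_profile <- function(doses, clinical, models = default_models()) {
  rows <- lapply(models, function(m) {
    lp <- linear_predictor(m, doses, clinical)
    data.frame(endpoint = m$name, ctcae_grade = m$ctcae_grade,
               linear_predictor = lp, ntcp = logistic(lp),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
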