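# Synthetic referral cohorts: correlated OAR mean doses, categorical
# clinical factors, Bernoulli outcomes drawn from the NTCP models, and
# proton plans as dose-reduced variants of the photon plans.

default_dose_means <- c(parotid_contralateral_mean = 26, oral_cavity_mean = 36,
                        pcm_superior_mean = 46, pcm_inferior_mean = 34,
                        cricopharyngeal_mean = 30)
default_dose_sds <- c(parotid_contralateral_mean = 11, oral_cavity_mean = 13,
                      pcm_superior_mean = 12, pcm_inferior_mean = 15,
                      cricopharyngeal_mean = 15)

# Dose correlation: strong oral cavity <-> superior PCM coupling (the
# two sit in one anatomical dose bath), moderate elsewhere.
default_dose_correlation <- function() {
  oars <- names(default_dose_means)
  R <- matrix(0.45, 5, 5, dimnames = list(oars, oars))
  diag(R) <- 1
  R["oral_cavity_mean", "pcm_superior_mean"] <- 0.85
  R["pcm_superior_mean", "oral_cavity_mean"] <- 0.85
  R["pcm_superior_mean", "pcm_inferior_mean"] <- 0.60
  R["pcm_inferior_mean", "pcm_superior_mean"] <- 0.60
  R["pcm_inferior_mean", "cricopharyngeal_mean"] <- 0.60
  R["cricopharyngeal_mean", "pcm_inferior_mean"] <- 0.60
  R
}

default_clinical_prevalences <- function() {
  list(
    xer_baseline = c(none = 0.55, minor = 0.30, moderate_severe = 0.15),
    dysphagia_baseline_ge2 = 0.20,
    advanced_t_stage = 0.45,
    weight_loss = c(none = 0.60, moderate_1_10pct = 0.30, severe_gt10pct = 0.10),
    treatment = c(conventional_rt_alone = 0.30, accelerated_rt = 0.20,
                  chemoradiation = 0.40, rt_plus_cetuximab = 0.10),
    tumor_site = c(pharynx = 0.55, larynx = 0.30, oral_cavity = 0.15)
  )
}

#' Configuration of the synthetic referral cohort
#'
#' Defines the statistical structure the selection protocol assumes:
#' correlated truncated-normal OAR mean doses, categorical clinical
#' factors, proton plans as multiplicatively dose-reduced photon plans,
#' and binary toxicity outcomes drawn from the true NTCP models.
#'
#' @param n Number of patients.
#' @param dose_means,dose_sds Named numeric per OAR, Gy.
#' @param dose_correlation 5x5 positive semi-definite correlation matrix
#'   over [oar_fields()] (default: high oral-cavity/superior-PCM
#'   correlation, moderate elsewhere).
#' @param clinical_prevalences List of level probabilities per clinical
#'   factor (each categorical entry sums to 1) plus `tumor_site`.
#' @param proton_reduction_mean,proton_reduction_sd Mean and spread of
#'   the per-patient, per-OAR multiplicative dose-reduction factor in
#'   \[0, 1\] (proton dose = photon dose x factor); draws are truncated
#'   to \[0, 1\].
#' @param true_models Models generating the latent NTCPs and outcomes.
#' @param max_dose Truncation upper bound in Gy.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n = 500,
                       dose_means = default_dose_means,
                       dose_sds = default_dose_sds,
                       dose_correlation = default_dose_correlation(),
                       clinical_prevalences = default_clinical_prevalences(),
                       proton_reduction_mean = 0.6,
                       proton_reduction_sd = 0.15,
                       true_models = default_models(),
                       max_dose = 80) {
  stopifnot(n >= 1, all(dose_sds > 0), all(dose_means >= 0))
  ev <- eigen(dose_correlation, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8)) {
    stop("dose_correlation is not positive semi-definite", call. = FALSE)
  }
  stopifnot(proton_reduction_mean >= 0, proton_reduction_mean <= 1,
            proton_reduction_sd >= 0)
  for (nm in c("xer_baseline", "weight_loss", "treatment", "tumor_site")) {
    p <- clinical_prevalences[[nm]]
    if (abs(sum(p) - 1) > 1e-8) {
      stop("prevalences for ", nm, " must sum to 1", call. = FALSE)
    }
  }
  structure(list(n = n, dose_means = dose_means, dose_sds = dose_sds,
                 dose_correlation = dose_correlation,
                 clinical_prevalences = clinical_prevalences,
                 proton_reduction_mean = proton_reduction_mean,
                 proton_reduction_sd = proton_reduction_sd,
                 true_models = true_models, max_dose = max_dose),
            class = "sim_config")
}

rtrunc01 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  pmin(1, pmax(0, stats::rnorm(n, mean, sd)))
}

#' Generate a synthetic referral cohort
#'
#' Draws, deterministically from `(config, seed)`: correlated
#' multivariate-normal photon doses truncated to \[0, max_dose\] Gy;
#' clinical factors from the configured prevalences; proton doses as
#' photon doses times per-patient/per-OAR reduction factors; latent true
#' NTCPs from the photon plan under the true models; and Bernoulli
#' realized outcomes. A single seed governs all draws through fixed
#' per-table substreams, so each table is stable under partial
#' regeneration.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List of class `simulated_cohort`: `patients`, `photon_plans`,
#'   `proton_plans` (data.frames in the engine's CSV dialects),
#'   `true_ntcp` and `outcomes` (one column per model).
#' @examples
#' cohort <- generate_cohort(sim_config(n = 50), seed = 1)
#' head(cohort$patients)
#' @export
generate_cohort <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n
  oars <- oar_fields()
  prev <- config$clinical_prevalences

  # substream 1: photon doses
  set.seed(seed)
  Sigma <- diag(config$dose_sds[oars]) %*% config$dose_correlation %*%
    diag(config$dose_sds[oars])
  Z <- MASS::mvrnorm(n, mu = config$dose_means[oars], Sigma = Sigma)
  Z <- pmin(pmax(Z, 0), config$max_dose)
  colnames(Z) <- oars
  photon <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                       plan_id = sprintf("P%04d_photon", seq_len(n)),
                       Z, stringsAsFactors = FALSE)

  # substream 2: clinical factors
  set.seed(seed + 1L)
  draw_cat <- function(p) sample(names(p), n, replace = TRUE, prob = p)
  patients <- data.frame(
    patient_id = photon$patient_id,
    tumor_site = draw_cat(prev$tumor_site),
    distant_metastases = FALSE,
    curative_intent = TRUE,
    xer_baseline = draw_cat(prev$xer_baseline),
    dysphagia_baseline_ge2 = stats::runif(n) < prev$dysphagia_baseline_ge2,
    advanced_t_stage = stats::runif(n) < prev$advanced_t_stage,
    weight_loss = draw_cat(prev$weight_loss),
    treatment = draw_cat(prev$treatment),
    stringsAsFactors = FALSE)

  # substream 3: proton reduction factors
  set.seed(seed + 2L)
  red <- matrix(rtrunc01(n * length(oars), config$proton_reduction_mean,
                         config$proton_reduction_sd),
                nrow = n, dimnames = list(NULL, oars))
  proton <- photon
  proton$plan_id <- sprintf("P%04d_proton", seq_len(n))
  proton[, oars] <- photon[, oars] * red

  # substream 4: latent NTCPs (photon plan) and realized outcomes
  set.seed(seed + 3L)
  ind <- clinical_indicators(patients)
  true_ntcp <- data.frame(patient_id = patients$patient_id,
                          stringsAsFactors = FALSE)
  outcomes <- true_ntcp
  for (m in config$true_models) {
    p <- stats::plogis(model_lp(m, photon, indicators = ind))
    true_ntcp[[m$name]] <- p
    outcomes[[m$name]] <- stats::rbinom(n, 1, p)
  }

  structure(list(patients = patients, photon_plans = photon,
                 proton_plans = proton, true_ntcp = true_ntcp,
                 outcomes = outcomes, config = config, seed = seed),
            class = "simulated_cohort")
}

#' Assemble a validation cohort table for one endpoint
#'
#' Binds the photon-plan doses, the clinical factors and the realized
#' outcome of one endpoint into the flat table the validation and
#' updating functions consume.
#'
#' @param cohort A `simulated_cohort`.
#' @param endpoint Model/endpoint name (e.g. `"xerostomia"`).
#' @return data.frame with dose columns, clinical columns and `outcome`.
#' @export
cohort_table <- function(cohort, endpoint) {
  stopifnot(inherits(cohort, "simulated_cohort"),
            endpoint %in% names(cohort$outcomes))
  out <- merge(cohort$patients, cohort$photon_plans, by = "patient_id")
  out <- merge(out, cohort$outcomes[, c("patient_id", endpoint)],
               by = "patient_id")
  names(out)[names(out) == endpoint] <- "outcome"
  out[order(out$patient_id), , drop = FALSE]
}

#' Fraction of a cohort qualifying for proton therapy
#'
#' Screens the cohort through the full flowchart and returns the
#' fraction of patients with a qualifying plan comparison. Monotone
#' non-increasing as the proton dose-reduction factor approaches 1
#' (proton plan equal to photon plan).
#'
#' @param cohort A `simulated_cohort` (or list with `patients`,
#'   `photon_plans`, `proton_plans`).
#' @param models,policy As in [screen_cohort()].
#' @return Fraction in \[0, 1\].
#' @export
qualification_rate <- function(cohort, models = default_models(),
                               policy = default_policy()) {
  dec <- screen_cohort(cohort$patients, cohort$photon_plans,
                       cohort$proton_plans, models = models, policy = policy)
  if (nrow(dec) == 0) return(0)
  mean(dec$qualifies)
}
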