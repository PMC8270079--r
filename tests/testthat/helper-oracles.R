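# Independent brute-force oracles and fixture builders used across the
# suite. These deliberately avoid the package's own code paths.

# Pairwise concordance by explicit enumeration of event/non-event pairs.
bf_auc <- function(scores, outcomes) {
  s1 <- scores[outcomes == 1]
  s0 <- scores[outcomes == 0]
  tot <- 0
  for (a in s1) for (b in s0) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(s1) * length(s0))
}

# Qualification by explicit enumeration of every single rule and every
# unordered same-grade pair, inclusive comparison.
bf_qualifies <- function(delta_pp, grades, single, summed) {
  for (i in seq_along(delta_pp)) {
    thr <- single[[as.character(grades[i])]]
    if (!is.null(thr) && delta_pp[i] >= thr) return(TRUE)
  }
  n <- length(delta_pp)
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (grades[i] != grades[j]) next
      thr <- summed[[as.character(grades[i])]]
      if (!is.null(thr) && delta_pp[i] + delta_pp[j] >= thr) return(TRUE)
    }
  }
  FALSE
}

# Linear predictor by explicit term-by-term accumulation from a flat
# value map (doses in Gy and 0/1 indicators), independent of model_lp().
bf_linear_predictor <- function(model, values) {
  lp <- model$intercept
  for (nm in names(model$dose_coefficients)) {
    lp <- lp + model$dose_coefficients[[nm]] * values[[nm]]
  }
  for (nm in names(model$clinical_coefficients)) {
    lp <- lp + model$clinical_coefficients[[nm]] * values[[nm]]
  }
  lp
}

# Random full dose profile within the sanity bounds.
rand_doses <- function() {
  d <- stats::runif(5, 0, 80)
  oar_doses(d[1], d[2], d[3], d[4], d[5])
}

# Random clinical factor draw.
rand_clinical <- function() {
  clinical_factors(
    xer_baseline = sample(c("none", "minor", "moderate_severe"), 1),
    dysphagia_baseline_ge2 = sample(c(TRUE, FALSE), 1),
    advanced_t_stage = sample(c(TRUE, FALSE), 1),
    weight_loss = sample(c("none", "moderate_1_10pct", "severe_gt10pct"), 1),
    treatment = sample(c("conventional_rt_alone", "accelerated_rt",
                         "chemoradiation", "rt_plus_cetuximab"), 1))
}

# Small eligible patient table + matching plan tables for IO/CLI tests.
make_tiny_cohort <- function(n = 3, seed = 99) {
  co <- generate_cohort(sim_config(n = n), seed = seed)
  co
}
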