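test_that("default threshold policy encodes the national rules", {
  p <- default_policy()
  expect_equal(p$single, c("2" = 10, "3" = 5, "4" = 2))
  expect_equal(p$summed, c("2" = 15, "3" = 7.5, "4" = 3))
  expect_equal(unname(p$summed), unname(1.5 * p$single))
  expect_error(threshold_policy(single = c("2" = 5, "3" = 10)), "decrease")
  expect_error(threshold_policy(single = c("2" = -1, "3" = -2)))
})

test_that("eligibility gate requires site, M0 and curative intent", {
  expect_true(eligibility_gate("pharynx", FALSE, TRUE))
  expect_true(eligibility_gate("larynx", FALSE, TRUE))
  expect_true(eligibility_gate("oral_cavity", FALSE, TRUE))
  expect_false(eligibility_gate("other", FALSE, TRUE))
  expect_false(eligibility_gate("pharynx", TRUE, TRUE))
  expect_false(eligibility_gate("pharynx", FALSE, FALSE))
})

test_that("delta_ntcp_max matches hand-computed bounds", {
  m <- default_models()
  # logistic(-1.507+1.3+0.525) - logistic(-1.507+0.525), in pp
  expect_equal(delta_ntcp_max(oar_doses(parotid_contralateral_mean = 25),
                              clinical_factors(xer_baseline = "minor"),
                              m$xerostomia),
               30.634, tolerance = 1e-4)
  # logistic(-1.143) - logistic(-3.303)
  expect_equal(delta_ntcp_max(oar_doses(oral_cavity_mean = 40,
                                        pcm_superior_mean = 50),
                              clinical_factors(), m$dysphagia),
               20.630, tolerance = 1e-4)
  # photon doses already zero: bound is exactly 0
  expect_equal(delta_ntcp_max(oar_doses(0, 0, 0, 0, 0),
                              rand_clinical(), m$tube_feeding), 0)
})

test_that("qualification rules apply singles and same-grade pairs inclusively", {
  pol <- default_policy()
  g223 <- c(2L, 2L, 3L)
  run <- function(d) qualifies(setNames(d, c("a", "b", "c")), g223, pol)

  expect_true(run(c(12, 3, 1))$qualifies)          # single grade-2
  expect_true(run(c(8, 7.5, 0))$qualifies)         # 15.5 >= 15 summed
  expect_false(run(c(9.9, 4.9, 4.9))$qualifies)    # all rules short
  expect_true(run(c(10, 0, 0))$qualifies)          # inclusive boundary
  expect_true(run(c(0, 0, 5))$qualifies)           # grade-3 single boundary
  expect_false(run(c(7, 7, 4))$qualifies)          # 14 < 15, no cross-grade sum
  expect_false(run(c(0, 0, 0))$qualifies)          # self-comparison
  expect_false(run(c(7.5, 7.4999, 0))$qualifies)   # 14.9999 < 15, exact compare

  r <- run(c(12, 4, 6))
  expect_true(r$qualifies)
  kinds <- vapply(r$triggered_rules, `[[`, "", "rule")
  expect_true("single" %in% kinds)  # grade-2 single and grade-3 single
  expect_true(any(vapply(r$triggered_rules, `[[`, 0, "grade") == 3))
  # negative deltas never trigger but do enter signed sums
  expect_true(run(c(16, -2, 0))$qualifies)    # single still fires
  expect_false(run(c(9.5, -2, 0))$qualifies)  # 7.5 < 15 signed sum, no single
})

test_that("select_patient walks the flowchart with the implication chain", {
  m <- default_models()
  cl <- clinical_factors(treatment = "chemoradiation")
  photon <- oar_doses(35, 45, 55, 30, 25)
  proton <- oar_doses(20, 25, 35, 20, 15)

  d <- select_patient("other", FALSE, TRUE, photon, proton, cl)
  expect_false(d$gate_passed)
  expect_false(d$qualifies)
  expect_true(all(is.na(d$ntcp_photon)))

  # independent spreadsheet-style evaluation of the worked pair
  pl <- function(x) 1 / (1 + exp(-x))
  lp_ph <- c(-1.507 + 0.052 * 35,
             -3.303 + 0.024 * 45 + 0.024 * 55,
             -6.849 + 1.101 + 0.030 * 55 + 0.013 * 30 + 0.022 * 35 + 0.008 * 25)
  lp_pr <- c(-1.507 + 0.052 * 20,
             -3.303 + 0.024 * 25 + 0.024 * 35,
             -6.849 + 1.101 + 0.030 * 35 + 0.013 * 20 + 0.022 * 20 + 0.008 * 15)
  d2 <- select_patient("pharynx", FALSE, TRUE, photon, proton, cl)
  expect_true(d2$gate_passed)
  expect_true(d2$plan_comparison_indicated)
  expect_equal(unname(d2$ntcp_photon), pl(lp_ph), tolerance = 1e-12)
  expect_equal(unname(d2$delta_pp), 100 * (pl(lp_ph) - pl(lp_pr)),
               tolerance = 1e-12)
  expect_true(d2$qualifies)  # xerostomia delta 19.2 pp >= 10
  expect_gt(length(d2$triggered_rules), 0)

  # no proton plan: decision stops after the pre-screen
  d3 <- select_patient("pharynx", FALSE, TRUE, photon, NULL, cl)
  expect_true(d3$plan_comparison_indicated)
  expect_false(d3$qualifies)
  expect_true(all(is.na(d3$ntcp_proton)))
})

test_that("delta-NTCP_max dominates the plan-pair delta and the chain holds", {
  set.seed(21)
  models <- default_models()
  for (rep in 1:1000) {
    photon <- rand_doses()
    frac <- runif(5)
    proton <- do.call(oar_doses, as.list(unclass(photon) * frac))
    cl <- rand_clinical()
    d <- select_patient(sample(c("pharynx", "larynx", "oral_cavity", "other"), 1),
                        FALSE, TRUE, photon, proton, cl)
    expect_true(!d$qualifies || d$plan_comparison_indicated)
    expect_true(!d$plan_comparison_indicated || d$gate_passed)
    if (d$gate_passed && !any(is.na(d$delta_pp))) {
      expect_true(all(d$delta_pp <= d$delta_max_pp + 1e-9))
    }
  }
})

test_that("rule engine agrees with the brute-force enumerator", {
  set.seed(22)
  pol <- default_policy()
  for (rep in 1:1000) {
    k <- sample(2:5, 1)
    delta <- round(runif(k, -5, 20), 2)
    grades <- sample(2:4, k, replace = TRUE)
    expect_identical(qualifies(delta, grades, pol)$qualifies,
                     bf_qualifies(delta, grades, pol$single, pol$summed))
  }
})

test_that("raising a single threshold never increases the qualified count", {
  co <- generate_cohort(sim_config(n = 300), seed = 31)
  base <- default_policy()
  n_base <- sum(screen_cohort(co$patients, co$photon_plans, co$proton_plans,
                              policy = base)$qualifies)
  for (g in c("2", "3")) {
    single <- base$single
    single[[g]] <- single[[g]] + 5
    stricter <- threshold_policy(single = single, summed = base$summed)
    n_strict <- sum(screen_cohort(co$patients, co$photon_plans,
                                  co$proton_plans, policy = stricter)$qualifies)
    expect_lte(n_strict, n_base)
  }
})

test_that("screen_cohort handles empty, identical-plan and failing rows", {
  co <- make_tiny_cohort(n = 5)
  empty <- co$patients[0, ]
  out <- screen_cohort(empty, co$photon_plans)
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "summary")$qualified, 0)

  # proton plan identical to photon plan: nobody qualifies
  same <- screen_cohort(co$patients, co$photon_plans, co$photon_plans)
  expect_equal(sum(same$qualifies), 0)
  expect_true(all(abs(na.omit(unlist(same[grepl("^delta_pp", names(same))]))) < 1e-12))

  # a corrupted row is skipped (reported) in lax mode, fatal in strict mode
  bad <- co$patients
  bad$xer_baseline[2] <- "impossible"
  lax <- screen_cohort(bad, co$photon_plans, co$proton_plans)
  expect_equal(nrow(lax), 4)
  expect_match(attr(lax, "errors"), "P0002")
  expect_error(screen_cohort(bad, co$photon_plans, co$proton_plans,
                             strict = TRUE), "P0002")
})
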