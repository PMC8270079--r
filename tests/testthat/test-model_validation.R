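test_that("AUC equals pairwise concordance with ties counted one half", {
  # brute force over the 4 event/non-event pairs: 3 concordant of 4
  expect_equal(auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(bf_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)          # separated
  expect_equal(auc(c(5, 5, 5, 5), c(0, 1, 0, 1)), 0.5)        # all tied
  expect_error(auc(1:4, c(0, 0, 0, 0)), "event")
  set.seed(41)
  scores <- sample(seq(0, 1, 0.1), 40, replace = TRUE)  # ties likely
  y <- rbinom(40, 1, 0.4)
  expect_equal(auc(scores, y), bf_auc(scores, y))
  # invariant under strictly monotone transforms
  expect_equal(auc(qlogis(pmin(pmax(scores, 0.01), 0.99)), y), auc(scores, y))
  expect_equal(auc(scores * 7 - 2, y), auc(scores, y))
})

test_that("AUC matches an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(42)
  scores <- rnorm(150)
  y <- rbinom(150, 1, plogis(scores))
  ref <- as.numeric(pROC::auc(pROC::roc(y, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auc(scores, y), ref, tolerance = 1e-12)
})

test_that("logistic refit recovers closed forms and flags pathologies", {
  set.seed(43)
  n <- 400
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.5 + x))
  dat <- data.frame(x = x, outcome = y)

  # intercept-only fit: log(events / non-events)
  f0 <- refit_logistic(dat, design = character(0))
  expect_equal(unname(f0$coefficients["(Intercept)"]),
               log(sum(y) / (n - sum(y))), tolerance = 1e-8)

  # duplicating the dataset leaves the MLE unchanged
  f1 <- refit_logistic(dat, "x")
  f2 <- refit_logistic(rbind(dat, dat), "x")
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-8)
  expect_equal(f2$log_likelihood, 2 * f1$log_likelihood, tolerance = 1e-6)

  # aliased design errors; separated data warns
  dat$x2 <- 2 * dat$x
  expect_error(refit_logistic(dat, c("x", "x2")), "rank-deficient")
  sep <- data.frame(x = c(1:5, 11:15), outcome = rep(0:1, each = 5))
  w <- capture_warnings(res <- refit_logistic(sep, "x"))
  expect_true(any(grepl("separation", w)))  # glm also warns about 0/1 fits
  expect_true(res$separation)
})

test_that("refit on model-generated data recovers the coefficients", {
  set.seed(44)
  n <- 20000
  x1 <- runif(n, 0, 60); x2 <- runif(n, 0, 60)
  lp <- -3 + 0.03 * x1 + 0.05 * x2
  dat <- data.frame(x1 = x1, x2 = x2, outcome = rbinom(n, 1, plogis(lp)))
  fit <- refit_logistic(dat, c("x1", "x2"))
  truth <- c("(Intercept)" = -3, x1 = 0.03, x2 = 0.05)
  z <- abs(fit$coefficients[names(truth)] - truth) / fit$se[names(truth)]
  expect_true(all(z < 3))

  # merged-predictor option: one common per-Gy coefficient for both doses
  fit_m <- refit_logistic(dat, c("x1", "x2"), merge = list(xsum = c("x1", "x2")))
  expect_named(fit_m$coefficients, c("(Intercept)", "xsum"))
  expect_gt(fit_m$coefficients[["xsum"]], 0.02)
  expect_lt(fit_m$coefficients[["xsum"]], 0.06)
})

test_that("calibration recovers slope 1 / intercept 0 in self-consistency", {
  m <- default_models()$dysphagia
  co <- generate_cohort(sim_config(n = 20000), seed = 45)
  ct <- cohort_table(co, "dysphagia")
  cal <- calibration(ct, m)
  expect_equal(cal$calibration_slope, 1, tolerance = 0.1)
  expect_equal(cal$calibration_intercept, 0, tolerance = 0.1)

  # outcomes from a +0.5-shifted truth: intercept-in-the-large picks up
  # the shift (observed minus predicted log-odds, so +0.5 here)
  set.seed(46)
  lp <- -1 + rnorm(10000)
  y2 <- rbinom(10000, 1, plogis(lp + 0.5))
  cal2 <- calibration(data.frame(outcome = y2), lp = lp)
  expect_equal(cal2$calibration_intercept, 0.5, tolerance = 0.1)

  expect_error(calibration(data.frame(outcome = c(0, 1, 0, 1)),
                           lp = rep(0.3, 4)), "constant")
})

test_that("validate_model reports discrimination and calibration", {
  m <- default_models()$xerostomia
  co <- generate_cohort(sim_config(n = 5000), seed = 47)
  rep <- validate_model(cohort_table(co, "xerostomia"), m, tripod_level = "1b")
  expect_s3_class(rep, "validation_report")
  expect_gt(rep$auc, 0.5)
  expect_lt(rep$auc, 1)
  expect_equal(rep$calibration_slope, 1, tolerance = 0.2)
  expect_equal(rep$n, 5000)
  expect_identical(rep$tripod_level, "1b")
})

test_that("closed testing selects sensible levels across the hierarchy", {
  m <- default_models()$xerostomia
  co <- generate_cohort(sim_config(n = 2000), seed = 48)
  ct <- cohort_table(co, "xerostomia")

  # log-likelihood non-decreasing along the nested sequence
  res <- closed_testing_update(ct, m)
  ll <- res$params$log_likelihoods
  expect_true(all(diff(ll[c("original", "intercept_update",
                            "recalibration", "revision")]) > -1e-8))

  # limiting behavior in alpha
  expect_identical(closed_testing_update(ct, m, alpha = 1)$selected_update,
                   "revision")
  expect_identical(closed_testing_update(ct, m, alpha = 1e-12)$selected_update,
                   "original")

  # monotone in alpha: a larger alpha never selects a simpler level
  levels <- c(original = 1, intercept_update = 2, recalibration = 3,
              revision = 4)
  picks <- vapply(c(0.001, 0.05, 0.5, 0.999), function(a)
    levels[[closed_testing_update(ct, m, alpha = a)$selected_update]], 0)
  expect_true(all(diff(picks) >= 0))

  # a true +1 intercept shift is detected as an update
  shifted <- m
  shifted$intercept <- m$intercept + 1
  co2 <- generate_cohort(sim_config(n = 2000, true_models = list(
    xerostomia = shifted, dysphagia = default_models()$dysphagia,
    tube_feeding = default_models()$tube_feeding)), seed = 49)
  res2 <- closed_testing_update(cohort_table(co2, "xerostomia"), m)
  expect_true(res2$selected_update != "original")
})

test_that("apply_update materialises each update level correctly", {
  m <- default_models()$dysphagia
  co <- generate_cohort(sim_config(n = 3000), seed = 50)
  ct <- cohort_table(co, "dysphagia")
  res <- closed_testing_update(ct, m)

  expect_identical(apply_update(res, "original"), m)

  up <- apply_update(res, "intercept_update")
  expect_equal(up$intercept, m$intercept + res$params$intercept_shift)
  expect_identical(up$dose_coefficients, m$dose_coefficients)
  expect_identical(up$clinical_coefficients, m$clinical_coefficients)

  rc <- apply_update(res, "recalibration")
  b <- res$params$recalibration[["slope"]]
  expect_equal(unname(rc$dose_coefficients / m$dose_coefficients),
               rep(b, length(m$dose_coefficients)))

  rv <- apply_update(res, "revision")
  ref <- refit_logistic(ct, m)
  expect_equal(rv$intercept, unname(ref$coefficients[["(Intercept)"]]))
  expect_equal(unname(rv$dose_coefficients["oral_cavity_mean"]),
               unname(ref$coefficients[["oral_cavity_mean"]]))
  # the revised model reproduces the refit linear predictor
  lp_rv <- plogis(drop(as.matrix(cbind(1, ct[, names(ref$coefficients)[-1]])) %*%
                         ref$coefficients))
  expect_equal(vapply(seq_len(5), function(i)
    ntcp(rv, as.list(ct[i, oar_fields()]),
         clinical_factors(dysphagia_baseline_ge2 = as.logical(ct$dysphagia_baseline_ge2[i]))),
    0), unname(lp_rv[1:5]), tolerance = 1e-10)
})
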