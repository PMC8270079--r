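# External validation and model updating: discrimination, calibration,
# logistic refitting, and the closed-testing update hierarchy.

#' Area under the ROC curve (concordance)
#'
#' Probability that a randomly chosen event outscores a randomly chosen
#' non-event, ties counted one half — identical to brute-force pairwise
#' concordance, computed here via the Wilcoxon rank statistic.
#'
#' @param scores Numeric risk scores (any strictly monotone transform of
#'   predicted probability gives the same AUC).
#' @param outcomes Binary outcomes (0/1 or logical).
#' @return AUC in \[0, 1\].
#' @examples
#' auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.875
#' @export
auc <- function(scores, outcomes) {
  outcomes <- as.integer(as.logical(outcomes))
  stopifnot(length(scores) == length(outcomes),
            all(outcomes %in% c(0L, 1L)), all(is.finite(scores)))
  n1 <- sum(outcomes == 1L)
  n0 <- sum(outcomes == 0L)
  if (n1 == 0 || n0 == 0) {
    stop("AUC undefined: need at least one event and one non-event",
         call. = FALSE)
  }
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[outcomes == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Build the design data.frame a model implies from a cohort table:
# one column per dose coefficient and per clinical indicator. The cohort
# carries the raw dose and clinical factor columns (or precomputed
# indicator columns).
model_design <- function(model, cohort) {
  X <- list()
  for (nm in names(model$dose_coefficients)) {
    if (is.null(cohort[[nm]])) {
      stop("cohort lacks dose column '", nm, "' required by model '",
           model$name, "'", call. = FALSE)
    }
    X[[nm]] <- as.numeric(cohort[[nm]])
  }
  cn <- names(model$clinical_coefficients)
  if (length(cn) > 0) {
    have <- cn %in% names(cohort)
    ind <- NULL
    if (!all(have)) ind <- clinical_indicators(cohort)
    for (nm in cn) {
      X[[nm]] <- if (nm %in% names(cohort)) as.numeric(cohort[[nm]]) else ind[, nm]
    }
  }
  as.data.frame(X, check.names = FALSE)
}

# Linear predictor of a model over a cohort table.
cohort_lp <- function(model, cohort) {
  X <- model_design(model, cohort)
  cf <- c(model$dose_coefficients, model$clinical_coefficients)
  drop(model$intercept + as.matrix(X)[, names(cf), drop = FALSE] %*% cf)
}

check_outcome <- function(y) {
  y <- as.integer(as.logical(y))
  if (any(is.na(y))) stop("outcome contains NA", call. = FALSE)
  if (sum(y) == 0 || sum(y) == length(y)) {
    stop("need at least one event and one non-event", call. = FALSE)
  }
  y
}

#' Maximum-likelihood logistic refit on a cohort
#'
#' Fits outcome ~ design by iteratively reweighted least squares (via
#' `glm`, convergence at relative deviance change < 1e-10 or 100
#' iterations). Flags likely separation (any |coefficient| > 15) with a
#' warning; aliased (rank-deficient) designs are an error.
#'
#' @param cohort data.frame holding the predictor columns and a binary
#'   `outcome` column (override with `outcome_col`).
#' @param design Character vector of predictor column names, or an
#'   `ntcp_model` whose dose/clinical coefficient keys name the design.
#' @param outcome_col Name of the outcome column.
#' @param merge Optional named list; each entry `name = c(cols)` replaces
#'   the listed dose columns by their sum under a single coefficient
#'   (the remedy for collinear organ doses when a model is meant to steer
#'   plan optimisation).
#' @return List with `coefficients` (intercept first), `se`,
#'   `log_likelihood`, `converged`, `separation` flag, `n`, `events`.
#' @export
refit_logistic <- function(cohort, design, outcome_col = "outcome",
                           merge = NULL) {
  y <- check_outcome(cohort[[outcome_col]])
  X <- if (inherits(design, "ntcp_model")) {
    model_design(design, cohort)
  } else {
    missing_cols <- setdiff(design, names(cohort))
    if (length(missing_cols) > 0) {
      stop("cohort lacks design column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    cohort[, design, drop = FALSE]
  }
  if (!is.null(merge)) {
    for (nm in names(merge)) {
      cols <- merge[[nm]]
      X[[nm]] <- rowSums(X[, cols, drop = FALSE])
      X <- X[, setdiff(names(X), cols), drop = FALSE]
    }
  }
  dat <- cbind(data.frame(.y = y), X)
  form <- if (ncol(X) == 0) stats::as.formula(".y ~ 1") else
    stats::as.formula(paste(".y ~", paste(sprintf("`%s`", names(X)),
                                          collapse = " + ")))
  fit <- stats::glm(form, family = stats::binomial(), data = dat,
                    control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  cf <- stats::coef(fit)
  if (any(is.na(cf))) {
    stop("rank-deficient design: aliased predictor(s) ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  names(cf) <- sub("^`|`$", "", gsub("`", "", names(cf)))
  separation <- any(abs(cf) > 15)
  if (separation) {
    warning("possible separation: |coefficient| > 15", call. = FALSE)
  }
  se <- sqrt(diag(stats::vcov(fit)))
  names(se) <- names(cf)
  list(coefficients = cf, se = se,
       log_likelihood = as.numeric(stats::logLik(fit)),
       converged = fit$converged, separation = separation,
       n = length(y), events = sum(y))
}

#' Calibration intercept and slope of a model on a cohort
#'
#' Calibration slope: coefficient of the model's linear predictor (LP)
#' in a logistic refit of the outcome on LP. Calibration-in-the-large
#' intercept: intercept of a logistic refit with LP as a fixed offset.
#' Slope 1 and intercept 0 indicate perfect calibration; a positive
#' intercept means the model under-predicts on this cohort (sign
#' convention: observed log-odds minus predicted).
#'
#' @param cohort data.frame with the model's predictor columns and a
#'   binary `outcome` column.
#' @param model An `ntcp_model`, or use `lp` to supply linear predictors
#'   directly.
#' @param lp Optional numeric linear predictors (bypasses `model`).
#' @param outcome_col Name of the outcome column.
#' @return List with `calibration_intercept` and `calibration_slope`.
#' @export
calibration <- function(cohort, model = NULL, lp = NULL,
                        outcome_col = "outcome") {
  y <- check_outcome(cohort[[outcome_col]])
  if (is.null(lp)) {
    stopifnot(inherits(model, "ntcp_model"))
    lp <- cohort_lp(model, cohort)
  }
  if (stats::sd(lp) == 0) {
    stop("constant linear predictor: calibration slope not identifiable",
         call. = FALSE)
  }
  ctl <- stats::glm.control(epsilon = 1e-10, maxit = 100)
  slope_fit <- stats::glm(y ~ lp, family = stats::binomial(), control = ctl)
  itl_fit <- stats::glm(y ~ 1 + offset(lp), family = stats::binomial(),
                        control = ctl)
  list(calibration_intercept = unname(stats::coef(itl_fit)[1]),
       calibration_slope = unname(stats::coef(slope_fit)["lp"]))
}

#' External validation report for a model on a cohort
#'
#' Discrimination (AUC) and calibration (intercept-in-the-large, slope)
#' of an NTCP model evaluated on an external cohort with observed
#' outcomes. Validation operates on complete cases.
#'
#' @inheritParams calibration
#' @param tripod_level Optional user-declared stage-of-evaluation label
#'   (e.g. `"1b"`, `"2a"`); it is recorded, not computed.
#' @return List of class `validation_report`: `model`, `auc`,
#'   `calibration_intercept`, `calibration_slope`, `n`, `events`,
#'   `tripod_level`.
#' @export
validate_model <- function(cohort, model, outcome_col = "outcome",
                           tripod_level = NA_character_) {
  cc <- stats::complete.cases(model_design(model, cohort)) &
    !is.na(cohort[[outcome_col]])
  cohort <- cohort[cc, , drop = FALSE]
  y <- check_outcome(cohort[[outcome_col]])
  lp <- cohort_lp(model, cohort)
  cal <- calibration(cohort, lp = lp, outcome_col = outcome_col)
  structure(list(model = model$name,
                 auc = auc(lp, y),
                 calibration_intercept = cal$calibration_intercept,
                 calibration_slope = cal$calibration_slope,
                 n = length(y), events = sum(y),
                 tripod_level = tripod_level),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> model '%s' (n=%d, events=%d)\n",
              x$model, x$n, x$events))
  cat(sprintf("  AUC %.3f | calibration intercept %+0.3f, slope %.3f\n",
              x$auc, x$calibration_intercept, x$calibration_slope))
  if (!is.na(x$tripod_level)) cat("  declared evaluation level:", x$tripod_level, "\n")
  invisible(x)
}

# Log-likelihood of outcomes under fixed probabilities.
bernoulli_ll <- function(y, p) {
  p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  sum(y * log(p) + (1 - y) * log(1 - p))
}

#' Closed-testing model update on a validation cohort
#'
#' Decides among keeping the original model, updating its intercept,
#' recalibrating (intercept + common slope), or full revision (refit of
#' all coefficients), while controlling the overall type-I error at
#' `alpha`. The step-down traversal tests the full revision against the
#' nested alternatives by likelihood-ratio tests: revision vs original
#' first (no update if not rejected), then revision vs intercept update,
#' then revision vs recalibration; the selected level is the simplest
#' one the revision does not significantly improve upon.
#'
#' @param cohort data.frame with the model's predictor columns and a
#'   binary `outcome` column.
#' @param model The original `ntcp_model`.
#' @param alpha Significance level per test (default 0.05).
#' @param outcome_col Name of the outcome column.
#' @return List of class `closed_test_result`: `selected_update` (one of
#'   `"original"`, `"intercept_update"`, `"recalibration"`,
#'   `"revision"`), `test_statistics` (data.frame of each traversed LR
#'   test: step, chisq, df, p, rejected), `updated_model` (an
#'   `ntcp_model`), and the fitted update parameters.
#' @export
closed_testing_update <- function(cohort, model, alpha = 0.05,
                                  outcome_col = "outcome") {
  stopifnot(alpha >= 0, alpha <= 1)
  y <- check_outcome(cohort[[outcome_col]])
  lp <- cohort_lp(model, cohort)
  X <- model_design(model, cohort)
  k <- ncol(X)
  ctl <- stats::glm.control(epsilon = 1e-10, maxit = 100)

  ll_orig <- bernoulli_ll(y, stats::plogis(lp))
  fit_int <- stats::glm(y ~ 1 + offset(lp), family = stats::binomial(),
                        control = ctl)
  ll_int <- as.numeric(stats::logLik(fit_int))
  have_slope <- stats::sd(lp) > 0
  fit_recal <- if (have_slope) {
    stats::glm(y ~ lp, family = stats::binomial(), control = ctl)
  } else NULL
  ll_recal <- if (have_slope) as.numeric(stats::logLik(fit_recal)) else ll_int
  rev_fit <- tryCatch(
    refit_logistic(cohort, model, outcome_col = outcome_col),
    error = function(e) stop("revision refit failed: ", conditionMessage(e),
                             call. = FALSE))
  ll_rev <- rev_fit$log_likelihood

  lr_test <- function(step, ll1, ll0, df) {
    chisq <- max(0, 2 * (ll1 - ll0))
    p <- if (df > 0) stats::pchisq(chisq, df, lower.tail = FALSE) else 1
    data.frame(step = step, chisq = chisq, df = df, p = p,
               rejected = df > 0 && p < alpha, stringsAsFactors = FALSE)
  }
  tests <- lr_test("revision_vs_original", ll_rev, ll_orig, k + 1)
  selected <- "original"
  if (tests$rejected[1]) {
    tests <- rbind(tests, lr_test("revision_vs_intercept_update",
                                  ll_rev, ll_int, k))
    if (!tests$rejected[2]) {
      selected <- "intercept_update"
    } else {
      tests <- rbind(tests, lr_test("revision_vs_recalibration",
                                    ll_rev, ll_recal, k - 1))
      selected <- if (!tests$rejected[3]) "recalibration" else "revision"
    }
  }

  params <- list(
    intercept_shift = unname(stats::coef(fit_int)[1]),
    recalibration = if (have_slope) {
      c(intercept = unname(stats::coef(fit_recal)[1]),
        slope = unname(stats::coef(fit_recal)["lp"]))
    } else c(intercept = unname(stats::coef(fit_int)[1]), slope = 1),
    revision = rev_fit$coefficients,
    revision_se = rev_fit$se,
    log_likelihoods = c(original = ll_orig, intercept_update = ll_int,
                        recalibration = ll_recal, revision = ll_rev))
  res <- structure(list(selected_update = selected, test_statistics = tests,
                        original_model = model, params = params,
                        alpha = alpha, n = length(y), events = sum(y)),
                   class = "closed_test_result")
  res$updated_model <- apply_update(res)
  res
}

#' @export
print.closed_test_result <- function(x, ...) {
  cat(sprintf("<closed_test_result> model '%s' (n=%d, events=%d, alpha=%g)\n",
              x$original_model$name, x$n, x$events, x$alpha))
  print(x$test_statistics, row.names = FALSE)
  cat("  selected update:", x$selected_update, "\n")
  invisible(x)
}

#' Materialise the model implied by a closed-testing result
#'
#' `"original"` returns the input model unchanged; `"intercept_update"`
#' shifts the intercept only; `"recalibration"` maps LP to a + b x LP
#' (so the intercept becomes a + b x intercept and every coefficient is
#' scaled by b); `"revision"` takes the refitted coefficients.
#'
#' @param result A `closed_test_result`.
#' @param level Override the selected level (one of the four names).
#' @return An `ntcp_model`.
#' @export
apply_update <- function(result, level = result$selected_update) {
  m <- result$original_model
  level <- match.arg(level, c("original", "intercept_update",
                              "recalibration", "revision"))
  if (level == "original") return(m)
  if (level == "intercept_update") {
    m$intercept <- m$intercept + result$params$intercept_shift
    m$name <- paste0(m$name, "_intercept_update")
    return(m)
  }
  if (level == "recalibration") {
    a <- result$params$recalibration[["intercept"]]
    b <- result$params$recalibration[["slope"]]
    m$intercept <- a + b * m$intercept
    m$dose_coefficients <- b * m$dose_coefficients
    m$clinical_coefficients <- b * m$clinical_coefficients
    m$name <- paste0(m$name, "_recalibrated")
    return(m)
  }
  cf <- result$params$revision
  m$intercept <- unname(cf[["(Intercept)"]])
  for (nm in names(m$dose_coefficients)) m$dose_coefficients[[nm]] <- unname(cf[[nm]])
  for (nm in names(m$clinical_coefficients)) m$clinical_coefficients[[nm]] <- unname(cf[[nm]])
  m$name <- paste0(m$name, "_revised")
  m
}
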