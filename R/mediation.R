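#' Attenuation of an exposure coefficient after mediator adjustment
#'
#' Percent change of a standardized exposure coefficient when mediators
#' are added to the model: `100 * (beta_full - beta_prior) / beta_prior`.
#' Negative values indicate attenuation (partial mediation).
#'
#' @param beta_full coefficient(s) from the mediator-adjusted model.
#' @param beta_prior coefficient(s) from the total-effect model.
#' @return numeric vector of percentages; `NA` where `beta_prior` is 0
#'   (attenuation undefined), with a warning.
#' @examples
#' attenuation_pct(0.1377, 0.1686)  # -18.3
#' @export
attenuation_pct <- function(beta_full, beta_prior) {
  out <- 100 * (beta_full - beta_prior) / beta_prior
  undef <- beta_prior == 0
  if (any(undef, na.rm = TRUE)) {
    warning("attenuation undefined where the prior coefficient is 0",
            call. = FALSE)
    out[undef] <- NA_real_
  }
  out
}

task_formula <- function(task, rhs) {
  stats::as.formula(paste0(task, "_fu ~ ", paste(rhs, collapse = " + ")))
}

#' Step 1: total-effect models of activity on lower-extremity function
#'
#' For each of the four LEF tasks, fits
#' `followup ~ pa + age + sex + bmi + same-task baseline` and applies
#' Holm-Bonferroni control across the family of four activity p-values.
#'
#' @param cohort a cohort data frame (see [cohort_columns()]).
#' @param alpha familywise error level.
#' @return list with `models` (named list of [fit_ols] results), `hb`
#'   (Holm-Bonferroni table for the activity coefficients) and
#'   `significant` (task names whose activity coefficient survives).
#' @export
mediation_step1 <- function(cohort, alpha = 0.05) {
  validate_cohort(cohort)
  models <- lapply(LEF_TASKS, function(t)
    fit_ols(task_formula(t, c("pa", "age", "sex", "bmi",
                              paste0(t, "_base"))), cohort))
  names(models) <- LEF_TASKS
  p <- vapply(models, ols_coef, numeric(1), term = "pa", col = "p_value")
  hb <- holm_bonferroni(p, alpha)
  hb$task <- LEF_TASKS
  list(models = models, hb = hb, significant = LEF_TASKS[hb$reject])
}

#' Step 2: exposure-to-mediator models and mediator screening
#'
#' Models each of the eleven trimodal radiodensity parameters on the
#' activity score adjusted for age, sex and BMI, and screens mediators by
#' Holm-Bonferroni across the family of eleven activity p-values. The
#' connective skewness is structurally zero and is not among the eleven.
#'
#' @inheritParams mediation_step1
#' @return list with `models`, `hb` and `selected` (parameter names whose
#'   activity coefficient survives the familywise screen).
#' @export
mediation_step2 <- function(cohort, alpha = 0.05) {
  validate_cohort(cohort)
  models <- lapply(NTRA_PARAM_NAMES, function(j)
    fit_ols(stats::as.formula(paste(j, "~ pa + age + sex + bmi")), cohort))
  names(models) <- NTRA_PARAM_NAMES
  p <- vapply(models, ols_coef, numeric(1), term = "pa", col = "p_value")
  hb <- holm_bonferroni(p, alpha)
  hb$parameter <- NTRA_PARAM_NAMES
  list(models = models, hb = hb, selected = NTRA_PARAM_NAMES[hb$reject])
}

#' Step 3: mediator-to-outcome models (no exposure)
#'
#' For each LEF task, fits `followup ~ mediators + age + sex + bmi +
#' baseline`, Holm-Bonferroni corrected across the mediators-by-tasks
#' family of mediator coefficients.
#'
#' @inheritParams mediation_step1
#' @param mediators character vector of selected mediator names (subset of
#'   the 11 trimodal parameter names).
#' @return list with `models`, `hb` (one row per mediator-task pair) or,
#'   for an empty mediator set, a structured no-op with
#'   `message = "no mediation testable"`.
#' @export
mediation_step3 <- function(cohort, mediators, alpha = 0.05) {
  validate_cohort(cohort)
  if (length(mediators) == 0L) {
    return(list(models = NULL, hb = NULL,
                message = "no mediation testable"))
  }
  stopifnot(all(mediators %in% NTRA_PARAM_NAMES))
  models <- lapply(LEF_TASKS, function(t)
    fit_ols(task_formula(t, c(mediators, "age", "sex", "bmi",
                              paste0(t, "_base"))), cohort))
  names(models) <- LEF_TASKS
  fam <- expand.grid(mediator = mediators, task = LEF_TASKS,
                     stringsAsFactors = FALSE)
  fam_p <- mapply(function(m, t) ols_coef(models[[t]], m, "p_value"),
                  fam$mediator, fam$task)
  hb <- cbind(fam, holm_bonferroni(fam_p, alpha))
  list(models = models, hb = hb)
}

#' Step 4: full models with exposure and mediators, and attenuation
#'
#' Adds the selected mediators to the step-1 total-effect models
#' (`followup ~ pa + mediators + age + sex + bmi + baseline`) and computes
#' per-task attenuation of the standardized activity coefficient relative
#' to step 1. Holm-Bonferroni is applied across the
#' `(1 + mediators) x tasks` family of activity and mediator coefficients.
#'
#' @inheritParams mediation_step3
#' @param step1 result of [mediation_step1()] on the same cohort.
#' @return list with `models`, `hb`, and `attenuation` (data frame with
#'   the standardized activity coefficients before/after and `% change`).
#' @export
mediation_step4 <- function(cohort, mediators, step1, alpha = 0.05) {
  validate_cohort(cohort)
  if (length(mediators) == 0L) {
    return(list(models = NULL, hb = NULL, attenuation = NULL,
                message = "no mediation testable"))
  }
  models <- lapply(LEF_TASKS, function(t)
    fit_ols(task_formula(t, c("pa", mediators, "age", "sex", "bmi",
                              paste0(t, "_base"))), cohort))
  names(models) <- LEF_TASKS
  fam <- expand.grid(term = c("pa", mediators), task = LEF_TASKS,
                     stringsAsFactors = FALSE)
  fam_p <- mapply(function(m, t) ols_coef(models[[t]], m, "p_value"),
                  fam$term, fam$task)
  hb <- cbind(fam, holm_bonferroni(fam_p, alpha))

  beta_prior <- vapply(step1$models, ols_coef, numeric(1),
                       term = "pa", col = "beta")
  beta_full <- vapply(models, ols_coef, numeric(1),
                      term = "pa", col = "beta")
  att <- suppressWarnings(attenuation_pct(beta_full, beta_prior))
  attenuation <- data.frame(
    task = LEF_TASKS,
    beta_prior = beta_prior,
    beta_full = beta_full,
    pct_change = att,
    defined = beta_prior != 0
  )
  list(models = models, hb = hb, attenuation = attenuation)
}

#' Bootstrap indirect and direct mediation effects for one task
#'
#' Point estimates come from full-sample fits: each specific indirect
#' effect is the product `a_j * b_j` of the activity coefficient in
#' mediator j's exposure model (`mediator ~ pa + age + sex + bmi`) and the
#' mediator coefficient in the full outcome model (`followup ~ pa +
#' mediators + age + sex + bmi + baseline`); the total indirect effect is
#' their sum and the direct effect is the activity coefficient in the full
#' model. Confidence intervals are percentile intervals over `B` resamples
#' of subjects with replacement; resamples producing a rank-deficient
#' design are discarded and redrawn (capped at 1% of `B`). All effects are
#' on the raw (unstandardized) scale.
#'
#' @param cohort a cohort data frame.
#' @param mediators non-empty character vector of mediator names.
#' @param task one of `"gsf", "gsn", "str", "tug"`.
#' @param B number of bootstrap replicates (>= 200; default 5000).
#' @param ci_level confidence level (default 0.95, percentile).
#' @param seed integer seed.
#' @param bias_corrected use bias-corrected (BC) rather than plain
#'   percentile intervals.
#' @return an object of class `"boot_effects"`: list with `effects`
#'   (data frame: `effect`, `estimate`, `ci_lower`, `ci_upper`,
#'   `significant`), `replicates` (B x effects matrix), `B`, `n`,
#'   `n_discarded`, `ci_level`, `seed`, `task`.
#' @export
bootstrap_effects <- function(cohort, mediators, task, B = 5000,
                              ci_level = 0.95, seed = 1L,
                              bias_corrected = FALSE) {
  validate_cohort(cohort)
  if (length(mediators) == 0L) {
    stop("'mediators' must be non-empty", call. = FALSE)
  }
  if (B < 200) stop("'B' must be at least 200", call. = FALSE)
  stopifnot(task %in% LEF_TASKS)

  cols <- c("pa", "age", "sex", "bmi", mediators,
            paste0(task, "_base"), paste0(task, "_fu"))
  cc <- stats::complete.cases(cohort[cols])
  d <- cohort[cc, cols]
  n <- nrow(d)
  X2 <- cbind(`(Intercept)` = 1, pa = d$pa, age = d$age, sex = d$sex,
              bmi = d$bmi)
  Y2 <- as.matrix(d[mediators])
  X4 <- cbind(`(Intercept)` = 1, pa = d$pa, as.matrix(d[mediators]),
              age = d$age, sex = d$sex, bmi = d$bmi,
              base = d[[paste0(task, "_base")]])
  y4 <- d[[paste0(task, "_fu")]]

  est_fun <- function(idx) {
    q4 <- qr(X4[idx, , drop = FALSE])
    if (q4$rank < ncol(X4)) return(NULL)
    cf4 <- qr.coef(q4, y4[idx])
    q2 <- qr(X2[idx, , drop = FALSE])
    if (q2$rank < ncol(X2)) return(NULL)
    cf2 <- qr.coef(q2, Y2[idx, , drop = FALSE])
    a <- cf2["pa", mediators]
    b <- cf4[mediators]
    spec <- a * b
    c(spec, indirect_total = sum(spec), direct = unname(cf4["pa"]))
  }

  point <- est_fun(seq_len(n))
  if (is.null(point)) stop("full-sample design is rank deficient",
                           call. = FALSE)
  eff_names <- c(paste0("indirect_", mediators), "indirect_total", "direct")
  names(point) <- eff_names

  max_discard <- ceiling(0.01 * B)
  reps <- matrix(NA_real_, B, length(point),
                 dimnames = list(NULL, eff_names))
  n_discarded <- with_seed(seed, {
    discarded <- 0L
    i <- 1L
    while (i <= B) {
      idx <- sample.int(n, n, replace = TRUE)
      est <- est_fun(idx)
      if (is.null(est)) {
        discarded <- discarded + 1L
        if (discarded > max_discard) {
          stop("more than 1% of bootstrap resamples were rank deficient",
               call. = FALSE)
        }
        next
      }
      reps[i, ] <- est
      i <- i + 1L
    }
    discarded
  })

  probs <- c((1 - ci_level) / 2, 1 - (1 - ci_level) / 2)
  ci <- t(vapply(eff_names, function(e) {
    if (bias_corrected) {
      z0 <- stats::qnorm(mean(reps[, e] < point[[e]]))
      p_adj <- stats::pnorm(2 * z0 + stats::qnorm(probs))
      stats::quantile(reps[, e], p_adj, names = FALSE)
    } else {
      stats::quantile(reps[, e], probs, names = FALSE)
    }
  }, numeric(2)))

  effects <- data.frame(
    effect = eff_names,
    estimate = unname(point),
    ci_lower = ci[, 1L],
    ci_upper = ci[, 2L],
    row.names = NULL
  )
  effects$significant <- effects$ci_lower > 0 | effects$ci_upper < 0

  structure(list(effects = effects, replicates = reps, B = B, n = n,
                 n_discarded = n_discarded, ci_level = ci_level,
                 seed = seed, task = task, mediators = mediators),
            class = "boot_effects")
}

#' @export
print.boot_effects <- function(x, digits = 4, ...) {
  cat(sprintf("Bootstrap mediation effects: %s (B = %d, n = %d, %g%% CI)\n",
              LEF_LABELS[[x$task]], x$B, x$n, 100 * x$ci_level))
  ef <- x$effects
  ef[2:4] <- lapply(ef[2:4], signif, digits = digits)
  print(ef, row.names = FALSE)
  if (x$n_discarded > 0) {
    cat(sprintf("(%d rank-deficient resamples discarded)\n", x$n_discarded))
  }
  invisible(x)
}

#' Four-step multiple-mediator analysis of activity on physical function
#'
#' Runs the full pipeline on a longitudinal cohort: (1) covariate-adjusted
#' total-effect models of the activity score on each of the four
#' lower-extremity-function tasks; (2) activity-to-mediator models for the
#' eleven trimodal radiodensity parameters with Holm-Bonferroni mediator
#' screening; (3) mediator-to-outcome models; (4) full models giving
#' attenuation of the activity coefficient; then subject-resampling
#' bootstrap of specific/total indirect and direct effects per task. Each
#' step applies familywise correction within its own family of tests
#' (4, 11, mediators x 4, and (1 + mediators) x 4 hypotheses).
#'
#' @param cohort a cohort data frame with the columns of
#'   [cohort_columns()].
#' @param alpha familywise error level for every Holm-Bonferroni family.
#' @param B bootstrap replicates per task (default 5000).
#' @param ci_level bootstrap confidence level.
#' @param seed integer seed driving the bootstrap.
#' @param mediators optional override of the screened mediator set.
#' @param bootstrap set `FALSE` to skip the bootstrap stage.
#' @return an object of class `"ntra_mediation"` with elements `step1`,
#'   `step2`, `selected`, `step3`, `step4`, `attenuation`, `bootstrap`
#'   (named list per task, `NULL` when no mediator survives) and
#'   `settings`.
#' @export
ntra_mediation <- function(cohort, alpha = 0.05, B = 5000, ci_level = 0.95,
                           seed = 1L, mediators = NULL, bootstrap = TRUE) {
  validate_cohort(cohort)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
  }
  s1 <- run_stage("step1", mediation_step1(cohort, alpha))
  s2 <- run_stage("step2", mediation_step2(cohort, alpha))
  selected <- mediators %||% s2$selected
  s3 <- run_stage("step3", mediation_step3(cohort, selected, alpha))
  s4 <- run_stage("step4", mediation_step4(cohort, selected, s1, alpha))
  boot <- NULL
  if (bootstrap && length(selected) > 0L) {
    boot <- lapply(seq_along(LEF_TASKS), function(k)
      run_stage("bootstrap",
                bootstrap_effects(cohort, selected, LEF_TASKS[k], B = B,
                                  ci_level = ci_level, seed = seed + k)))
    names(boot) <- LEF_TASKS
  }
  structure(list(
    step1 = s1, step2 = s2, selected = selected, step3 = s3, step4 = s4,
    attenuation = s4$attenuation, bootstrap = boot,
    settings = list(alpha = alpha, B = B, ci_level = ci_level, seed = seed,
                    mediator_override = !is.null(mediators),
                    n = nrow(cohort))
  ), class = "ntra_mediation")
}

#' @export
print.ntra_mediation <- function(x, ...) {
  cat("Multiple-mediator analysis of physical activity on LEF\n")
  cat(sprintf("  n = %d subjects, alpha = %g, B = %d\n",
              x$settings$n, x$settings$alpha, x$settings$B))
  cat("  Step 1 activity effect significant for:",
      if (length(x$step1$significant)) paste(x$step1$significant,
                                             collapse = ", ") else "none",
      "\n")
  cat("  Selected mediators:",
      if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "none (no mediation testable)", "\n")
  if (!is.null(x$attenuation)) {
    cat("  Attenuation of the activity coefficient (% change):\n")
    a <- x$attenuation
    for (i in seq_len(nrow(a))) {
      cat(sprintf("    %-4s %8.4f -> %8.4f  (%+.1f%%)\n", a$task[i],
                  a$beta_prior[i], a$beta_full[i], a$pct_change[i]))
    }
  }
  invisible(x)
}

#' @export
summary.ntra_mediation <- function(object, ...) {
  print(object)
  if (!is.null(object$bootstrap)) {
    cat("\nBootstrap effects:\n")
    for (t in names(object$bootstrap)) print(object$bootstrap[[t]])
  }
  invisible(object)
}

#' Render a mediation analysis as a set of report tables
#'
#' @param x an `"ntra_mediation"` object.
#' @return named list of data frames: `table2_total_effect`,
#'   `table3_mediator_models`, `table4_outcome_models`,
#'   `table5_attenuation`, `table6_bootstrap`. Tables for skipped stages
#'   are present but empty.
#' @export
mediation_tables <- function(x) {
  stopifnot(inherits(x, "ntra_mediation"))
  flat <- function(models, extra_hb = NULL) {
    if (is.null(models)) {
      return(data.frame(outcome = character(0), term = character(0),
                        estimate = numeric(0), beta = numeric(0),
                        se = numeric(0), p_value = numeric(0)))
    }
    do.call(rbind, lapply(names(models), function(nm) {
      cf <- models[[nm]]$coefficients
      cbind(outcome = nm, cf)
    }))
  }
  t6 <- if (is.null(x$bootstrap)) {
    data.frame(task = character(0), effect = character(0),
               estimate = numeric(0), ci_lower = numeric(0),
               ci_upper = numeric(0), significant = logical(0))
  } else {
    do.call(rbind, lapply(names(x$bootstrap), function(t)
      cbind(task = t, x$bootstrap[[t]]$effects)))
  }
  t5 <- if (is.null(x$attenuation)) {
    data.frame(task = character(0), beta_prior = numeric(0),
               beta_full = numeric(0), pct_change = numeric(0))
  } else x$attenuation
  list(
    table2_total_effect = flat(x$step1$models),
    table3_mediator_models = flat(x$step2$models),
    table4_outcome_models = flat(x$step3$models),
    table5_attenuation = t5,
    table6_bootstrap = t6
  )
}
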