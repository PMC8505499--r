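LEF_TASKS <- c("gsf", "gsn", "str", "tug")

LEF_LABELS <- c(
  gsf = "Fast gait speed (GSF, m/s)",
  gsn = "Normal gait speed (GSN, m/s)",
  str = "Isometric leg strength (STR, N)",
  tug = "Timed up-and-go (TUG, s)"
)

#' Published cohort marginals used as simulation defaults
#'
#' Summary statistics (means, SDs, category frequencies) of a large
#' longitudinal study of healthy elderly volunteers (the AGES-Reykjavik
#' cohort), at the baseline visit and a follow-up roughly five years
#' later. The individual-level data are access-restricted, so the
#' synthetic generator reproduces these marginals as its default study
#' conditions.
#'
#' @return a list with elements `age` (mean, sd), `female_prop`, `bmi`
#'   (mean, sd), `pa_probs` (five-level activity score frequencies),
#'   `lef_baseline` / `lef_followup` (per-task mean and sd) and
#'   `ntra_followup` (per-parameter mean and sd).
#' @export
cohort_reference_marginals <- function() {
  list(
    age = c(mean = 74.9, sd = 4.8),
    female_prop = 0.580,
    bmi = c(mean = 27.3, sd = 4.2),
    pa_probs = c(0.398, 0.167, 0.077, 0.183, 0.175),
    lef_baseline = list(
      mean = c(gsf = 1.34, gsn = 0.99, str = 337.9, tug = 11.5),
      sd   = c(gsf = 0.25, gsn = 0.19, str = 115.9, tug = 2.7)
    ),
    lef_followup = list(
      mean = c(gsf = 1.26, gsn = 0.92, str = 279.5, tug = 12.7),
      sd   = c(gsf = 0.26, gsn = 0.20, str = 101.4, tug = 3.8)
    ),
    ntra_followup = list(
      mean = stats::setNames(
        c(62.3, -117.2, 8.1, -2.5, 41.8, -25.9, 24.6, 72.6, 60.9, 9.2, 3.0),
        NTRA_PARAM_NAMES),
      sd = stats::setNames(
        c(33.2, 4.7, 5.7, 2.0, 9.3, 28.2, 5.6, 17.4, 2.9, 2.6, 0.8),
        NTRA_PARAM_NAMES)
    )
  )
}

#' Published physical-activity coefficients for the attenuation worked
#' example
#'
#' Standardized physical-activity coefficients on the four
#' lower-extremity-function tasks from the reference cohort analysis:
#' `beta_total` is the coefficient before mediator adjustment and
#' `beta_adjusted` after adding the muscle amplitude and location
#' mediators. [attenuation_pct()] applied to these pairs reproduces the
#' published attenuation percentages (GSF -18.3, GSN -18.5, STR -32.1; the
#' TUG pair gives -20.5 from the rounded coefficients versus a published
#' -20.3 computed from unrounded values).
#'
#' @return data frame with columns `task`, `beta_total`, `beta_adjusted`.
#' @export
published_pa_coefficients <- function() {
  data.frame(
    task = LEF_TASKS,
    beta_total = c(0.1686, 0.1755, 0.1060, -0.1406),
    beta_adjusted = c(0.1377, 0.1431, 0.0720, -0.1118)
  )
}

mean_sd_pa <- function(probs) {
  v <- 1:5
  m <- sum(probs * v)
  c(mean = m, sd = sqrt(sum(probs * v^2) - m^2))
}

zero_named <- function(nms) stats::setNames(numeric(length(nms)), nms)

#' Configuration for the synthetic longitudinal cohort generator
#'
#' Collects the marginal distributions and planted standardized path
#' coefficients that define a simulated cohort. All path coefficients are
#' given on the standardized scale (per-SD effects) and converted
#' internally to raw units using the nominal marginal SDs; with all paths
#' zero (the default) the generator produces a null cohort.
#'
#' @param n_subjects number of subjects.
#' @param marginals list in the shape of [cohort_reference_marginals()].
#' @param a named length-11 vector of standardized activity-to-mediator
#'   path coefficients (names = the 11 trimodal parameters).
#' @param b 11 x 4 matrix of standardized mediator-to-outcome paths
#'   (rows = trimodal parameters, columns = `gsf, gsn, str, tug`).
#' @param c_direct named length-4 vector of standardized direct
#'   activity-to-outcome paths.
#' @param cov_mediator list with elements `age`, `sex`, `bmi`, each a
#'   named length-11 vector of standardized covariate effects on the
#'   mediators.
#' @param cov_outcome list with elements `age`, `sex`, `bmi`, each a named
#'   length-4 vector of standardized covariate effects on the outcomes.
#' @param gamma_base named length-4 vector of standardized baseline-LEF
#'   effects on follow-up LEF.
#' @param noise_scale multiplier on all residual SDs; 0 gives a
#'   deterministic structural cohort whose regressions recover the planted
#'   raw coefficients exactly (note that with zero mediator noise the
#'   mediators are exact linear functions of the exposure and covariates,
#'   so models containing both are rank deficient by construction).
#' @param mediator_noise_scale,outcome_noise_scale optional per-equation
#'   overrides of `noise_scale`.
#' @param seed integer seed.
#' @return a list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_subjects = 3000,
                          marginals = cohort_reference_marginals(),
                          a = zero_named(NTRA_PARAM_NAMES),
                          b = matrix(0, 11, 4,
                                     dimnames = list(NTRA_PARAM_NAMES,
                                                     LEF_TASKS)),
                          c_direct = zero_named(LEF_TASKS),
                          cov_mediator = default_mediator_covariates(),
                          cov_outcome = default_outcome_covariates(),
                          gamma_base = stats::setNames(rep(0.02, 4),
                                                       LEF_TASKS),
                          noise_scale = 1,
                          mediator_noise_scale = noise_scale,
                          outcome_noise_scale = noise_scale,
                          seed = 1L) {
  if (abs(sum(marginals$pa_probs) - 1) > 1e-8) {
    stop("physical-activity category probabilities must sum to 1",
         call. = FALSE)
  }
  if (n_subjects < 1) stop("'n_subjects' must be positive", call. = FALSE)
  stopifnot(all(marginals$lef_baseline$sd > 0),
            all(marginals$lef_followup$sd > 0),
            all(marginals$ntra_followup$sd > 0),
            noise_scale >= 0, mediator_noise_scale >= 0,
            outcome_noise_scale >= 0)
  a <- a[NTRA_PARAM_NAMES]; a[is.na(a)] <- 0; names(a) <- NTRA_PARAM_NAMES
  structure(list(
    n_subjects = n_subjects, marginals = marginals, a = a,
    b = b[NTRA_PARAM_NAMES, LEF_TASKS, drop = FALSE],
    c_direct = c_direct[LEF_TASKS],
    cov_mediator = cov_mediator, cov_outcome = cov_outcome,
    gamma_base = gamma_base[LEF_TASKS],
    noise_scale = noise_scale,
    mediator_noise_scale = mediator_noise_scale,
    outcome_noise_scale = outcome_noise_scale, seed = seed
  ), class = "cohort_config")
}

# illustrative covariate effect sizes (standardized), signs matching the
# reference cohort's fitted models: older age degrades gait and strength
# and slows up-and-go, male sex and higher BMI raise fat and connective
# amplitudes, etc. Magnitudes are round numbers, not estimates.
default_mediator_covariates <- function() {
  mk <- function(fat, conn, muscle) {
    stats::setNames(c(fat, conn, muscle), NTRA_PARAM_NAMES)
  }
  list(
    age = mk(c(-0.02, 0.03, 0.035, -0.07), c(-0.04, -0.04, -0.14),
             c(-0.22, -0.24, 0.14, 0.18)),
    sex = mk(c(0.55, 0.05, -0.42, 0.28), c(-0.35, -0.64, 0.19),
             c(-0.51, -0.07, 0.22, 0.19)),
    bmi = mk(c(0.59, 0.08, -0.20, 0.26), c(0.67, -0.31, -0.06),
             c(0.51, 0.12, 0.47, 0.17))
  )
}

default_outcome_covariates <- function() {
  list(
    age = stats::setNames(c(-0.30, -0.35, -0.20, 0.30), LEF_TASKS),
    sex = stats::setNames(c(-0.30, -0.16, -0.50, 0.05), LEF_TASKS),
    bmi = stats::setNames(c(-0.13, -0.15, 0.09, 0.15), LEF_TASKS)
  )
}

#' Scenario with planted muscle-parameter mediation
#'
#' Returns a [cohort_config] whose only nonzero activity-to-mediator paths
#' run through the muscle amplitude (`muscle_N`) and muscle location
#' (`muscle_mu`), with nonzero direct effects on all four tasks — partial
#' (not full) mediation, the qualitative pattern reported for the
#' reference cohort. Timed up-and-go paths are sign-flipped (higher is
#' worse). Standardized magnitudes are chosen so that at the default
#' `n = 3000` the pipeline's mediator screen selects exactly these two
#' parameters and all bootstrap indirect and direct intervals exclude
#' zero.
#'
#' @param n_subjects number of subjects (default 3000).
#' @param seed integer seed.
#' @return a `"cohort_config"`.
#' @export
muscle_mediation_scenario <- function(n_subjects = 3000, seed = 1L) {
  a <- zero_named(NTRA_PARAM_NAMES)
  a["muscle_N"] <- 0.10
  a["muscle_mu"] <- 0.12
  b <- matrix(0, 11, 4, dimnames = list(NTRA_PARAM_NAMES, LEF_TASKS))
  b["muscle_N", ]  <- c(0.30, 0.27, 0.33, -0.08)
  b["muscle_mu", ] <- c(0.10, 0.12, 0.10, -0.16)
  c_direct <- stats::setNames(c(0.14, 0.14, 0.07, -0.11), LEF_TASKS)
  cohort_config(n_subjects = n_subjects, a = a, b = b, c_direct = c_direct,
                seed = seed)
}

#' Sample voxel HU values from trimodal parameters
#'
#' Draws each voxel's tissue component with probability `N_i / sum(N)` and
#' then from the component's skew-normal distribution (location `mu`,
#' scale `sigma`, shape `-alpha`, matching the erfc convention of
#' [component_density()], so `alpha > 0` gives a tail toward lower HU).
#' Values outside `[-200, 200)` are replaced by rejection so the sample
#' stays inside the soft-tissue range.
#'
#' @param params a [trimodal_params] object.
#' @param n number of voxels.
#' @param seed integer seed (NULL uses the current RNG stream).
#' @return numeric vector of `n` HU values.
#' @export
sample_voxels <- function(params, n, seed = NULL) {
  m <- param_matrix(params)
  if (sum(m[, 1L]) <= 0) {
    stop("all amplitudes are zero; nothing to sample", call. = FALSE)
  }
  if (n < 1) stop("'n' must be at least 1", call. = FALSE)
  with_seed(seed, {
    comp <- sample.int(3L, n, replace = TRUE, prob = m[, 1L] / sum(m[, 1L]))
    x <- numeric(n)
    for (i in 1:3) {
      idx <- which(comp == i)
      if (!length(idx)) next
      x[idx] <- rskewnorm(length(idx), m[i, 2L], m[i, 3L], -m[i, 4L])
    }
    out <- x < -200 | x >= 200
    guard <- 0L
    while (any(out) && guard < 1000L) {
      idx <- which(out)
      x[idx] <- vapply(comp[idx], function(i)
        rskewnorm(1L, m[i, 2L], m[i, 3L], -m[i, 4L]), numeric(1))
      out <- x < -200 | x >= 200
      guard <- guard + 1L
    }
    x[out] <- pmin(pmax(x[out], -200), 200 - 1e-9)
    x
  })
}

# skew-normal draws via the additive two-normal representation
rskewnorm <- function(n, location, scale, shape) {
  delta <- shape / sqrt(1 + shape^2)
  z0 <- stats::rnorm(n)
  z1 <- stats::rnorm(n)
  location + scale * (delta * abs(z0) + sqrt(1 - delta^2) * z1)
}

#' Generate a synthetic longitudinal cohort with known mediation structure
#'
#' Simulates one row per subject: exposure (five-level physical-activity
#' score), covariates (age, sex coded 0 = female / 1 = male, BMI), four
#' baseline lower-extremity-function measures, the eleven follow-up
#' trimodal radiodensity parameters as mediators, and four follow-up LEF
#' outcomes. Mediators are linear in the exposure and covariates; outcomes
#' are linear in exposure, mediators, covariates and the same-task
#' baseline. Residual SDs are set so marginal SDs approximate the
#' configured nominal values.
#'
#' @param config a [cohort_config].
#' @return list with `cohort` (data frame) and `truth` (list per task:
#'   raw-scale specific indirect effects `a_j * b_j`, their sum
#'   `total_indirect`, the raw `direct` effect, and the standardized
#'   planted paths), plus `raw_a` and `raw_b` conversion results.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  mg <- config$marginals
  n <- config$n_subjects
  pa_stats <- mean_sd_pa(mg$pa_probs)
  med_mean <- mg$ntra_followup$mean
  med_sd <- mg$ntra_followup$sd
  out_mean <- mg$lef_followup$mean
  out_sd <- mg$lef_followup$sd
  base_mean <- mg$lef_baseline$mean
  base_sd <- mg$lef_baseline$sd
  sex_mean <- 1 - mg$female_prop
  sex_sd <- sqrt(mg$female_prop * (1 - mg$female_prop))
  cov_sd <- c(age = unname(mg$age["sd"]), sex = sex_sd,
              bmi = unname(mg$bmi["sd"]))
  cov_mean <- c(age = unname(mg$age["mean"]), sex = sex_mean,
                bmi = unname(mg$bmi["mean"]))

  raw_a <- config$a * med_sd / pa_stats[["sd"]]
  raw_b <- config$b * outer(1 / med_sd, out_sd)
  raw_c <- config$c_direct * out_sd / pa_stats[["sd"]]
  raw_gamma <- config$gamma_base * out_sd / base_sd

  med_noise <- med_sd * sqrt(pmax(0, 1 - config$a^2 -
    Reduce(`+`, lapply(config$cov_mediator, function(v) v[NTRA_PARAM_NAMES]^2)))) *
    config$mediator_noise_scale
  out_noise <- out_sd * sqrt(pmax(0, 1 - config$c_direct^2 -
    colSums(config$b^2) -
    Reduce(`+`, lapply(config$cov_outcome, function(v) v[LEF_TASKS]^2)) -
    config$gamma_base^2)) * config$outcome_noise_scale

  cohort <- with_seed(config$seed, {
    pa <- sample.int(5L, n, replace = TRUE, prob = mg$pa_probs)
    age <- stats::rnorm(n, mg$age["mean"], mg$age["sd"])
    sex <- stats::rbinom(n, 1L, 1 - mg$female_prop)  # 1 = male
    bmi <- stats::rnorm(n, mg$bmi["mean"], mg$bmi["sd"])
    covs <- cbind(age = age, sex = sex, bmi = bmi)

    med <- matrix(NA_real_, n, 11,
                  dimnames = list(NULL, NTRA_PARAM_NAMES))
    for (j in NTRA_PARAM_NAMES) {
      lin <- med_mean[[j]] + raw_a[[j]] * (pa - pa_stats[["mean"]])
      for (cv in c("age", "sex", "bmi")) {
        raw_cov <- config$cov_mediator[[cv]][[j]] * med_sd[[j]] / cov_sd[[cv]]
        lin <- lin + raw_cov * (covs[, cv] - cov_mean[[cv]])
      }
      med[, j] <- lin + stats::rnorm(n, 0, med_noise[[j]])
    }

    base <- sapply(LEF_TASKS, function(t)
      stats::rnorm(n, base_mean[[t]], base_sd[[t]]))
    fu <- matrix(NA_real_, n, 4, dimnames = list(NULL, LEF_TASKS))
    for (t in LEF_TASKS) {
      lin <- out_mean[[t]] + raw_c[[t]] * (pa - pa_stats[["mean"]]) +
        as.numeric((med - matrix(med_mean, n, 11, byrow = TRUE)) %*%
                     raw_b[, t]) +
        raw_gamma[[t]] * (base[, t] - base_mean[[t]])
      for (cv in c("age", "sex", "bmi")) {
        raw_cov <- config$cov_outcome[[cv]][[t]] * out_sd[[t]] / cov_sd[[cv]]
        lin <- lin + raw_cov * (covs[, cv] - cov_mean[[cv]])
      }
      fu[, t] <- lin + stats::rnorm(n, 0, out_noise[[t]])
    }

    df <- data.frame(id = sprintf("S%05d", seq_len(n)),
                     age = age, sex = sex, bmi = bmi, pa = pa)
    for (t in LEF_TASKS) df[[paste0(t, "_base")]] <- base[, t]
    for (t in LEF_TASKS) df[[paste0(t, "_fu")]] <- fu[, t]
    for (j in NTRA_PARAM_NAMES) df[[j]] <- med[, j]
    df
  })

  truth <- lapply(LEF_TASKS, function(t) {
    spec <- raw_a * raw_b[, t]
    list(specific_indirect = spec,
         total_indirect = sum(spec),
         direct = unname(raw_c[[t]]),
         std_specific = config$a * config$b[, t],
         std_direct = unname(config$c_direct[[t]]))
  })
  names(truth) <- LEF_TASKS

  list(cohort = cohort, truth = truth, raw_a = raw_a, raw_b = raw_b,
       raw_c = raw_c)
}

#' Column schema of a longitudinal cohort table
#' @return character vector of required column names.
#' @export
cohort_columns <- function() {
  c("id", "age", "sex", "bmi", "pa",
    paste0(LEF_TASKS, "_base"), paste0(LEF_TASKS, "_fu"),
    NTRA_PARAM_NAMES)
}

validate_cohort <- function(cohort) {
  missing_cols <- setdiff(cohort_columns(), names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  pa <- cohort$pa[!is.na(cohort$pa)]
  if (any(!pa %in% 1:5)) {
    stop("column 'pa' must contain integer scores 1..5", call. = FALSE)
  }
  invisible(cohort)
}
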