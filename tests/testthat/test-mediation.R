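test_that("attenuation percentages reproduce the published worked example", {
  pub <- published_pa_coefficients()
  att <- attenuation_pct(pub$beta_adjusted, pub$beta_total)
  names(att) <- pub$task
  expect_equal(round(att[["gsf"]], 1), -18.3)
  expect_equal(round(att[["gsn"]], 1), -18.5)
  expect_equal(round(att[["str"]], 1), -32.1)
  # TUG from rounded coefficients: -20.5 (published -20.3 used unrounded)
  expect_equal(round(att[["tug"]], 1), -20.5)

  expect_equal(attenuation_pct(0.1, 0.1), 0)
  expect_warning(res <- attenuation_pct(0.1, 0), "undefined")
  expect_true(is.na(res))
})

test_that("zero-noise cohorts are recovered exactly by steps 1, 2 and 4", {
  cfg <- muscle_mediation_scenario(n_subjects = 400, seed = 5)
  cfg$noise_scale <- 0
  cfg$mediator_noise_scale <- 0
  cfg$outcome_noise_scale <- 0
  gen <- generate_cohort(cfg)
  # step 1: the PA coefficient is exactly direct + total indirect
  s1 <- suppressWarnings(mediation_step1(gen$cohort))
  for (t in names(s1$models)) {
    expect_equal(ols_coef(s1$models[[t]], "pa"),
                 gen$truth[[t]]$direct + gen$truth[[t]]$total_indirect,
                 tolerance = 1e-8)
  }
  # step 2: the PA coefficient on each mediator is exactly the raw a-path
  s2 <- suppressWarnings(mediation_step2(gen$cohort))
  for (j in c("muscle_N", "muscle_mu")) {
    expect_equal(ols_coef(s2$models[[j]], "pa"), unname(gen$raw_a[[j]]),
                 tolerance = 1e-8)
  }

  # step 4 (needs mediator noise to break exact collinearity): exact raw
  # b-paths and direct effect when only the outcome is noise-free
  cfg2 <- muscle_mediation_scenario(n_subjects = 400, seed = 5)
  cfg2$outcome_noise_scale <- 0
  gen2 <- generate_cohort(cfg2)
  s1b <- mediation_step1(gen2$cohort)
  s4 <- suppressWarnings(
    mediation_step4(gen2$cohort, c("muscle_N", "muscle_mu"), s1b))
  for (t in c("gsf", "tug")) {
    expect_equal(ols_coef(s4$models[[t]], "muscle_N"),
                 unname(gen2$raw_b["muscle_N", t]), tolerance = 1e-6)
    expect_equal(ols_coef(s4$models[[t]], "pa"),
                 gen2$truth[[t]]$direct, tolerance = 1e-6)
  }
})

test_that("the mediator screen selects exactly the planted parameters", {
  gen <- generate_cohort(muscle_mediation_scenario(3000, seed = 1))
  s2 <- mediation_step2(gen$cohort)
  expect_setequal(s2$selected, c("muscle_N", "muscle_mu"))
  expect_equal(nrow(s2$hb), 11)
  # connective skewness is structurally zero and never modelled
  expect_false("conn_alpha" %in% names(s2$models))
})

test_that("a null cohort yields no step-1 signal but a complete report", {
  gen <- generate_cohort(cohort_config(n_subjects = 500, seed = 2))
  rep <- ntra_mediation(gen$cohort, B = 200, seed = 2)
  expect_length(rep$step1$significant, 0)
  tabs <- mediation_tables(rep)
  expect_named(tabs, c("table2_total_effect", "table3_mediator_models",
                       "table4_outcome_models", "table5_attenuation",
                       "table6_bootstrap"))
  expect_gt(nrow(tabs$table2_total_effect), 0)
})

test_that("an empty mediator set short-circuits into a structured no-op", {
  gen <- generate_cohort(cohort_config(n_subjects = 200, seed = 3))
  s3 <- mediation_step3(gen$cohort, character(0))
  expect_identical(s3$message, "no mediation testable")
  s4 <- mediation_step4(gen$cohort, character(0), NULL)
  expect_null(s4$models)
})

test_that("structural failures carry the stage label", {
  gen <- generate_cohort(cohort_config(n_subjects = 100, seed = 4))
  gen$cohort$pa <- 3L
  expect_error(ntra_mediation(gen$cohort, bootstrap = FALSE),
               "\\[step1\\].*pa")
})

test_that("the full pipeline on the planted scenario finds partial mediation", {
  gen <- generate_cohort(muscle_mediation_scenario(3000, seed = 1))
  rep <- ntra_mediation(gen$cohort, B = 300, seed = 1)
  expect_setequal(rep$selected, c("muscle_N", "muscle_mu"))
  expect_true(all(rep$attenuation$pct_change < 0))
  expect_true(all(abs(rep$attenuation$pct_change) < 100))
  expect_setequal(rep$step1$significant, c("gsf", "gsn", "str", "tug"))
})

test_that("identical seeds give byte-identical reports", {
  gen <- generate_cohort(muscle_mediation_scenario(400, seed = 6))
  r1 <- ntra_mediation(gen$cohort, B = 200, seed = 9)
  r2 <- ntra_mediation(gen$cohort, B = 200, seed = 9)
  expect_identical(mediation_tables(r1), mediation_tables(r2))
})
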