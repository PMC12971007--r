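test_that("the generator is deterministic under a fixed seed", {
  cfg <- simulation_config(n_subjects = 50, seed = 314)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  b1 <- generate_bundle(simulation_config(n_subjects = 8, seed = 99))
  b2 <- generate_bundle(simulation_config(n_subjects = 8, seed = 99))
  expect_identical(b1$cohort, b2$cohort)
  expect_identical(b1$trust_series, b2$trust_series)
  expect_identical(b1$velocity_scenes, b2$velocity_scenes)
  expect_identical(b1$truth, simulation_config(n_subjects = 8, seed = 99))
})

test_that("configured moments and prevalences are recovered at n = 10000", {
  n <- 10000
  cfg <- simulation_config(n_subjects = n, seed = 2024)
  co <- generate_cohort(cfg)
  se_mean <- function(sd) sd / sqrt(n)
  expect_lt(abs(mean(co$oef) - 39.7), 3 * se_mean(4.45))
  expect_lt(abs(sd(co$oef) - 4.45), 3 * 4.45 / sqrt(2 * n))
  expect_lt(abs(mean(co$cbf) - 58.2), 3 * se_mean(8.95))
  expect_lt(abs(sd(co$cbf) - 8.95), 3 * 8.95 / sqrt(2 * n))
  expect_lt(abs(cor(co$oef, co$cbf)), 3 / sqrt(n))  # independence case
  expect_lt(abs(mean(co$age) - 67.8), 3 * se_mean(8.76))
  expect_lt(abs(mean(co$bmi) - 24.2), 3 * se_mean(3.21))
  p_se <- function(p) sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(co$sex == "male") - 92 / 296), 3 * p_se(92 / 296))
  expect_lt(abs(mean(co$hypertension) - 0.453), 3 * p_se(0.453))
  expect_lt(abs(mean(co$diabetes) - 0.203), 3 * p_se(0.203))
  expect_lt(abs(mean(co$hyperlipidaemia) - 0.348), 3 * p_se(0.348))
  expect_lt(abs(mean(co$smoking_ever) - 0.206), 3 * p_se(0.206))
  expect_lt(abs(mean(co$infarct) - 42 / 296), 3 * p_se(42 / 296))
  expect_lt(abs(mean(!is.na(co$apoe4)) - 140 / 296), 3 * p_se(140 / 296))
  expect_lt(abs(mean(log(co$wmh_volume)) - 0.486), 3 * se_mean(1.21))
  # default obesity prevalence matches the BMI tail probability
  p_ob <- pnorm(28, 24.2, 3.21, lower.tail = FALSE)
  expect_lt(abs(mean(co$bmi > 28) - p_ob), 3 * p_se(p_ob))
})

test_that("a nonzero configured OEF-CBF correlation is recovered", {
  cfg <- simulation_config(n_subjects = 10000, seed = 5, oef_cbf_corr = 0.4)
  co <- generate_cohort(cfg)
  expect_lt(abs(cor(co$oef, co$cbf) - 0.4), 3 * (1 - 0.4^2) / sqrt(10000))
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(n_subjects = 3),
               class = "hemosurf_config_error")
  expect_error(simulation_config(oef_sd = 0),
               class = "hemosurf_config_error")
  expect_error(simulation_config(oef_cbf_corr = 1.2),
               class = "hemosurf_config_error")
  expect_error(simulation_config(oef_cbf_corr = 1),
               class = "hemosurf_config_error")
  expect_error(simulation_config(sex_male_prob = -0.1),
               class = "hemosurf_config_error")
  expect_error(simulation_config(education_probs = c(0.5, 0.5, 0.5, 0, 0)),
               class = "hemosurf_config_error")
})

test_that("noiseless TRUST series follow the closed-form decay", {
  s <- generate_trust_series(80, 1000, etes = c(0.44, 40, 80, 160),
                             noise_sd = 0)
  expect_equal(s$signals[3], 1000 * exp(-1), tolerance = 1e-12)
  s0 <- generate_trust_series(80, 1000, etes = c(0, 40, 80), noise_sd = 0)
  expect_equal(s0$signals[1], 1000)
  expect_error(generate_trust_series(80, 1000, etes = c(0, 40)),
               class = "hemosurf_input_error")
  expect_error(generate_trust_series(-5, 1000),
               class = "hemosurf_input_error")
})

test_that("noisy TRUST series refit to the truth over replicates", {
  set.seed(777)
  est <- replicate(1000, {
    s <- generate_trust_series(80, 1000, noise_sd = 0.01)
    fit_blood_t2(s)$t2
  })
  expect_lt(abs(mean(est) - 80), 1)
})

test_that("velocity scenes integrate to the requested flow", {
  sc <- generate_velocity_scene(600, noise_sd = 0)
  expect_equal(integrate_flow(sc, "ROI1"), 600, tolerance = 1e-9)
  sc0 <- generate_velocity_scene(0, noise_sd = 0)
  expect_equal(integrate_flow(sc0, "ROI1"), 0)
  sc4 <- generate_velocity_scene(c(LICA = 280, RICA = 280, LVA = 90,
                                   RVA = 90), noise_sd = 0)
  flows <- vapply(c("LICA", "RICA", "LVA", "RVA"),
                  function(r) integrate_flow(sc4, r), numeric(1))
  expect_equal(unname(flows), c(280, 280, 90, 90), tolerance = 1e-9)
  expect_error(generate_velocity_scene(-10),
               class = "hemosurf_input_error")
  # a flow whose peak velocity would alias past the venc is refused
  expect_error(generate_velocity_scene(5000),
               class = "hemosurf_input_error")
})

test_that("mean recovered flow is within 1% of truth under noise", {
  set.seed(55)
  rec <- replicate(1000, {
    sc <- generate_velocity_scene(600, noise_sd = 0.5)
    integrate_flow(sc, "ROI1")
  })
  expect_lt(abs(mean(rec) - 600) / 600, 0.01)
})

test_that("the embedded response surface is recovered exactly without noise", {
  b_true <- c(0.3, -0.4, 0.12, 0.008, -0.004, 0.002)
  cfg <- simulation_config(
    n_subjects = 120, seed = 61,
    surface_coeffs = stats::setNames(rep(list(b_true), 6),
                                     names(simulation_config()$surface_coeffs)),
    cognitive_noise_sd = 1e-12,
    covariate_effects = c(age = 0, sex_male = 0, education = 0))
  co <- generate_cohort(cfg)
  fit <- fit_rsa(co$oef, co$cbf, co$latent_memory,
                 center = c(cfg$oef_mean, cfg$cbf_mean))
  expect_lt(max(abs(unname(fit$b) - b_true)), 1e-9)
})

test_that("bundle components share consistent subject identifiers", {
  b <- generate_bundle(simulation_config(n_subjects = 6, seed = 12))
  ids <- b$cohort$subject_id
  expect_false(any(duplicated(ids)))
  expect_identical(names(b$trust_series), ids)
  expect_identical(names(b$velocity_scenes), ids)
  expect_identical(b$truth$n_subjects, 6L)
})

test_that("quantification recovers the generator's truth on noiseless signals", {
  cfg <- simulation_config(n_subjects = 12, seed = 17, trust_noise_sd = 0,
                           velocity_noise_sd = 0)
  b <- generate_bundle(cfg)
  q <- quantify_bundle(b)
  expect_lt(max(abs(q$oef_pct - b$cohort$oef)), 1e-5)
  expect_lt(max(abs(q$cbf - b$cohort$cbf)), 1e-5)
})

test_that("write_bundle produces the documented plain-text files", {
  dir <- file.path(tempdir(), "bundle_out")
  b <- generate_bundle(simulation_config(n_subjects = 5, seed = 3))
  paths <- write_bundle(b, dir)
  expect_true(all(file.exists(paths)))
  trust <- read.csv(paths["trust"])
  expect_identical(names(trust), c("subject_id", "ete_ms", "signal"))
  expect_equal(nrow(trust), 5 * 4)
  geom <- jsonlite::read_json(paths["geometry"])
  expect_equal(geom$rois, list("LICA", "RICA", "LVA", "RVA"))
  unlink(dir, recursive = TRUE)
})
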