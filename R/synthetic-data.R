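#' Simulation configuration for the synthetic cohort
#'
#' Bundles every knob of the synthetic-data generator: cohort size, the
#' joint OEF/CBF law (bivariate normal with configurable correlation),
#' log-normal WMH volumes, demographics and risk-factor prevalences
#' matching a community ageing cohort, the prescribed second-order response
#' surface linking centred OEF/CBF to each cognitive domain, and the
#' signal-level noise of the TRUST and phase-contrast acquisitions.
#'
#' Default moments reproduce the cohort the analysis targets: OEF
#' 39.7 +/- 4.45 %, CBF 58.2 +/- 8.95 ml/100g/min, age 67.8 +/- 8.76 y,
#' 31.08% male, BMI 24.2 +/- 3.21 kg/m^2, prevalences of hypertension /
#' diabetes / hyperlipidaemia / smoking of 45.3 / 20.3 / 34.8 / 20.6 %,
#' 47.3% genotyped for APOE with 17.1% carriers, 14.2% infarct flags, and
#' education category frequencies of 16.2 / 34.8 / 22.0 / 14.9 / 12.2 %.
#'
#' @param n_subjects Cohort size (>= 4).
#' @param seed Master seed; per-component child streams are derived from it
#'   so adding a component never perturbs the others.
#' @param oef_mean,oef_sd OEF moments in percent.
#' @param cbf_mean,cbf_sd CBF moments in ml/100g/min.
#' @param oef_cbf_corr Correlation of the bivariate normal OEF/CBF law.
#' @param age_mean,age_sd Age moments in years.
#' @param sex_male_prob Probability of male sex.
#' @param education_probs Probabilities of the five ordinal education
#'   levels 0-4 (none, primary, middle, high/technical, college+).
#' @param bmi_mean,bmi_sd BMI moments (kg/m^2).
#' @param risk_prevalences Named probabilities for `hypertension`,
#'   `diabetes`, `hyperlipidaemia`, `smoking_ever`, `obesity`. The obesity
#'   entry may be `NA`, in which case it defaults to
#'   `P(N(bmi_mean, bmi_sd) > 28)` so BMI remains exactly normal.
#' @param wmh_logmean,wmh_logsd Log-normal WMH volume parameters (log-cm^3).
#' @param wmh_quadrant_shift Named log-scale WMH shifts for quadrants Q1,
#'   Q3, Q4 relative to Q2, applied at the sample-median quadrant split.
#' @param surface_coeffs Named list (one entry per cognitive domain) of
#'   six-vectors `c(b0, b1, b2, b3, b4, b5)` acting on OEF/CBF centred at
#'   the configured means.
#' @param cognitive_noise_sd Residual SD of each domain latent (Z-units).
#' @param covariate_effects Named slopes `age` (per year, age centred at
#'   `age_mean`), `sex_male`, `education` (per ordinal level) added to each
#'   domain latent.
#' @param apoe_fraction_genotyped Fraction of the cohort with APOE data.
#' @param apoe_carrier_prob Carrier probability among the genotyped.
#' @param infarct_fraction Fraction flagged with infarcts.
#' @param brain_volume_mean,brain_volume_sd Brain volume moments (ml).
#' @param trust_noise_sd TRUST signal noise as a fraction of S0.
#' @param velocity_noise_sd Velocity map noise in cm/s.
#' @param s0 TRUST signal amplitude at eTE = 0.
#' @param etes TRUST effective echo times (ms).
#' @param venc Velocity encoding limit (cm/s).
#' @param grid_size,pixel_area Velocity map geometry (pixels, cm^2).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 296,
                              seed = 1L,
                              oef_mean = 39.7, oef_sd = 4.45,
                              cbf_mean = 58.2, cbf_sd = 8.95,
                              oef_cbf_corr = 0,
                              age_mean = 67.8, age_sd = 8.76,
                              sex_male_prob = 92 / 296,
                              education_probs = c(48, 103, 65, 44, 36) / 296,
                              bmi_mean = 24.2, bmi_sd = 3.21,
                              risk_prevalences = c(hypertension = 0.453,
                                                   diabetes = 0.203,
                                                   hyperlipidaemia = 0.348,
                                                   smoking_ever = 0.206,
                                                   obesity = NA),
                              wmh_logmean = 0.486, wmh_logsd = 1.21,
                              wmh_quadrant_shift = c(Q1 = 0, Q3 = 0, Q4 = 0),
                              surface_coeffs = NULL,
                              cognitive_noise_sd = 1,
                              covariate_effects = c(age = -0.02,
                                                    sex_male = 0,
                                                    education = 0.15),
                              apoe_fraction_genotyped = 140 / 296,
                              apoe_carrier_prob = 24 / 140,
                              infarct_fraction = 42 / 296,
                              brain_volume_mean = 1200,
                              brain_volume_sd = 100,
                              trust_noise_sd = 0.01,
                              velocity_noise_sd = 0.5,
                              s0 = 1000,
                              etes = default_etes(),
                              venc = 40,
                              grid_size = 32, pixel_area = 0.0025) {
  if (!is_scalar_number(n_subjects) || n_subjects < 4)
    hs_config_error("n_subjects must be at least 4")
  sds <- c(oef_sd, cbf_sd, age_sd, bmi_sd, wmh_logsd, brain_volume_sd)
  if (any(!is.finite(sds)) || any(sds <= 0))
    hs_config_error("all standard deviations must be positive")
  if (!is_scalar_number(oef_cbf_corr) || abs(oef_cbf_corr) > 1)
    hs_config_error("oef_cbf_corr must lie in [-1, 1]")
  if (abs(oef_cbf_corr) >= 1)
    hs_config_error("implied OEF/CBF covariance is not positive definite (|corr| >= 1)")
  if (is.na(risk_prevalences[["obesity"]]))
    risk_prevalences[["obesity"]] <-
      stats::pnorm(28, bmi_mean, bmi_sd, lower.tail = FALSE)
  probs <- c(sex_male_prob, education_probs, risk_prevalences,
             apoe_fraction_genotyped, apoe_carrier_prob, infarct_fraction)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    hs_config_error("all probabilities must lie in [0, 1]")
  if (abs(sum(education_probs) - 1) > 1e-8)
    hs_config_error("education_probs must sum to 1")
  req <- c("hypertension", "diabetes", "hyperlipidaemia", "smoking_ever",
           "obesity")
  if (!all(req %in% names(risk_prevalences)))
    hs_config_error("risk_prevalences must name the five vascular risk factors")
  if (is.null(surface_coeffs)) {
    # default prescribed surface: the global-cognition response-surface
    # coefficients (b0, b1, b2, b3, b4, b5), shared by all six domains
    b <- c(0, -0.49, -0.03, 0.01, 0, 0)
    surface_coeffs <- stats::setNames(
      rep(list(b), 6),
      c("executive", "attention", "language", "visuomotor",
        "visuospatial", "memory"))
  }
  if (any(vapply(surface_coeffs, length, 1L) != 6L))
    hs_config_error("each surface_coeffs entry must have six coefficients b0..b5")
  structure(
    list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
         oef_mean = oef_mean, oef_sd = oef_sd,
         cbf_mean = cbf_mean, cbf_sd = cbf_sd,
         oef_cbf_corr = oef_cbf_corr,
         age_mean = age_mean, age_sd = age_sd,
         sex_male_prob = sex_male_prob,
         education_probs = education_probs,
         bmi_mean = bmi_mean, bmi_sd = bmi_sd,
         risk_prevalences = risk_prevalences,
         wmh_logmean = wmh_logmean, wmh_logsd = wmh_logsd,
         wmh_quadrant_shift = wmh_quadrant_shift,
         surface_coeffs = surface_coeffs,
         cognitive_noise_sd = cognitive_noise_sd,
         covariate_effects = covariate_effects,
         apoe_fraction_genotyped = apoe_fraction_genotyped,
         apoe_carrier_prob = apoe_carrier_prob,
         infarct_fraction = infarct_fraction,
         brain_volume_mean = brain_volume_mean,
         brain_volume_sd = brain_volume_sd,
         trust_noise_sd = trust_noise_sd,
         velocity_noise_sd = velocity_noise_sd,
         s0 = s0, etes = etes, venc = venc,
         grid_size = as.integer(grid_size), pixel_area = pixel_area),
    class = "simulation_config")
}

# truncated-normal draws via inverse CDF, given uniforms
rtruncnorm_u <- function(u, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + u * (phi - plo), mean, sd)
}

#' Generate a synthetic cohort table
#'
#' Draws one cohort from the configured generative model: OEF/CBF from a
#' bivariate normal, WMH volumes log-normal (optionally shifted by
#' median-split quadrant), demographics and risk factors Bernoulli /
#' normal / ordinal at the configured rates, and six cognitive domain
#' latents equal to covariate effects plus the prescribed second-order
#' surface in centred OEF/CBF plus Gaussian noise. Raw test scores for the
#' standard neuropsychological battery are derived from the domain latents.
#' Deterministic under a fixed seed.
#'
#' @param config A [simulation_config()].
#' @param battery Test battery (see [default_battery()]).
#' @return A tibble with one row per subject; domain latents are in
#'   `latent_<domain>` columns, raw test scores in per-test columns.
#' @export
generate_cohort <- function(config, battery = default_battery()) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_subjects
  set.seed(child_seed(config$seed, "cohort"))

  age <- stats::rnorm(n, config$age_mean, config$age_sd)
  sex <- ifelse(stats::runif(n) < config$sex_male_prob, "male", "female")
  education <- sample(0:4, n, replace = TRUE, prob = config$education_probs)
  rp <- config$risk_prevalences
  hypertension <- stats::rbinom(n, 1, rp[["hypertension"]])
  diabetes <- stats::rbinom(n, 1, rp[["diabetes"]])
  hyperlipidaemia <- stats::rbinom(n, 1, rp[["hyperlipidaemia"]])
  smoking_ever <- stats::rbinom(n, 1, rp[["smoking_ever"]])
  # obesity flag drawn first; BMI then drawn from the matching side of the
  # 28 kg/m^2 threshold. At the default prevalence the mixture is exactly
  # the configured normal.
  obese <- stats::rbinom(n, 1, rp[["obesity"]])
  u <- stats::runif(n)
  bmi <- ifelse(obese == 1,
                rtruncnorm_u(u, config$bmi_mean, config$bmi_sd, lower = 28),
                rtruncnorm_u(u, config$bmi_mean, config$bmi_sd, upper = 28))

  rho <- config$oef_cbf_corr
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  oef <- config$oef_mean + config$oef_sd * z1
  cbf <- config$cbf_mean + config$cbf_sd * (rho * z1 + sqrt(1 - rho^2) * z2)

  wmh_log <- stats::rnorm(n, config$wmh_logmean, config$wmh_logsd)
  if (any(config$wmh_quadrant_shift != 0)) {
    q <- assign_quadrants(oef, cbf)$labels
    shift <- c(Q1 = 0, Q2 = 0, Q3 = 0, Q4 = 0)
    shift[names(config$wmh_quadrant_shift)] <- config$wmh_quadrant_shift
    wmh_log <- wmh_log + shift[as.character(q)]
  }
  wmh_volume <- pmax(exp(wmh_log), 0.01)

  infarct <- stats::rbinom(n, 1, config$infarct_fraction)
  genotyped <- stats::rbinom(n, 1, config$apoe_fraction_genotyped)
  apoe4 <- ifelse(genotyped == 1,
                  stats::rbinom(n, 1, config$apoe_carrier_prob), NA_integer_)
  brain_volume <- stats::rnorm(n, config$brain_volume_mean,
                               config$brain_volume_sd)

  X <- oef - config$oef_mean
  Y <- cbf - config$cbf_mean
  eff <- config$covariate_effects
  covar_part <- eff[["age"]] * (age - config$age_mean) +
    eff[["sex_male"]] * (sex == "male") +
    eff[["education"]] * education

  out <- tibble::tibble(
    subject_id = sprintf("S%04d", seq_len(n)),
    age = age, sex = sex, education = education,
    hypertension = hypertension, diabetes = diabetes,
    hyperlipidaemia = hyperlipidaemia, smoking_ever = smoking_ever,
    bmi = bmi, apoe4 = apoe4, infarct = infarct,
    oef = oef, cbf = cbf, wmh_volume = wmh_volume,
    brain_volume = brain_volume)

  for (d in names(config$surface_coeffs)) {
    b <- config$surface_coeffs[[d]]
    latent <- b[1] + b[2] * X + b[3] * Y + b[4] * X^2 + b[5] * X * Y +
      b[6] * Y^2 + covar_part +
      stats::rnorm(n, 0, config$cognitive_noise_sd)
    out[[paste0("latent_", d)]] <- latent
  }
  for (i in seq_len(nrow(battery))) {
    latent <- out[[paste0("latent_", battery$domain[i])]]
    signal <- 0.5 * latent + 0.866 * stats::rnorm(n)
    if (!battery$higher_better[i]) signal <- -signal
    out[[battery$test[i]]] <- battery$mean[i] + battery$sd[i] * signal
  }
  out
}

#' Generate one noisy TRUST decay series
#'
#' `signal[i] = s0 * exp(-eTE[i] / t2_true) + e`, with Gaussian noise of SD
#' `noise_sd * s0`.
#'
#' @param t2_true True blood T2 in ms (> 0).
#' @param s0 Amplitude at eTE = 0 (> 0).
#' @param etes Effective echo times (ms); at least 3, default the standard
#'   protocol `c(0.44, 40, 80, 160)`.
#' @param noise_sd Noise SD as a fraction of `s0`.
#' @param seed Optional seed; if `NULL` the current RNG stream is used.
#' @param subject_id Optional identifier.
#' @return A [trust_series()].
#' @export
generate_trust_series <- function(t2_true, s0, etes = default_etes(),
                                  noise_sd = 0, seed = NULL,
                                  subject_id = NA_character_) {
  if (!is_scalar_number(t2_true) || t2_true <= 0)
    hs_input_error("t2_true must be positive (ms)")
  if (!is_scalar_number(s0) || s0 <= 0)
    hs_input_error("s0 must be positive")
  if (length(unique(etes)) < 3L)
    hs_input_error("at least 3 distinct effective echo times are required")
  if (!is.null(seed)) set.seed(seed)
  sig <- s0 * exp(-etes / t2_true) +
    stats::rnorm(length(etes), 0, noise_sd * s0)
  trust_series(etes, sig, subject_id = subject_id)
}

# Blunted ("plug") velocity profile on a disc: flat core, linear taper over
# the outer 30% of the radius. Peak/mean ~ 1.34, keeping peak velocities
# well inside the venc for physiological flows.
disc_profile <- function(grid_size, centre, radius) {
  ij <- expand.grid(row = seq_len(grid_size), col = seq_len(grid_size))
  r <- sqrt((ij$row - centre[1])^2 + (ij$col - centre[2])^2)
  p <- pmin(1, pmax(0, (1 - r / radius) / 0.3))
  matrix(p, grid_size, grid_size)
}

#' Generate a synthetic phase-contrast velocity scene
#'
#' Builds a velocity map whose noiseless ROI integral equals the requested
#' flow exactly; background pixels are zero apart from noise. `true_flow`
#' may be a named vector, producing one disc ROI per artery laid out on a
#' 2x2 grid (the four-artery geometry), or a single unnamed value for one
#' central ROI.
#'
#' @param true_flow Flow(s) in ml/min (>= 0).
#' @param grid_size Map side length in pixels.
#' @param pixel_area Pixel area in cm^2.
#' @param noise_sd Gaussian velocity noise SD (cm/s), added to every pixel.
#' @param venc Velocity encoding limit (cm/s); noisy values are clamped.
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @param subject_id Optional identifier.
#' @return A [velocity_scene()].
#' @export
generate_velocity_scene <- function(true_flow, grid_size = 32,
                                    pixel_area = 0.0025, noise_sd = 0,
                                    venc = 40, seed = NULL,
                                    subject_id = NA_character_) {
  if (!is.numeric(true_flow) || any(!is.finite(true_flow)) ||
      any(true_flow < 0))
    hs_input_error("true_flow must be non-negative and finite (ml/min)")
  if (!is_scalar_number(pixel_area) || pixel_area <= 0)
    hs_input_error("pixel_area must be positive (cm^2)")
  if (!is.null(seed)) set.seed(seed)
  multi <- !is.null(names(true_flow)) && length(true_flow) > 1L
  if (multi) {
    qc <- round(grid_size / 4); qc3 <- grid_size - qc
    centres <- list(c(qc, qc), c(qc, qc3), c(qc3, qc), c(qc3, qc3))
    radius <- max(2, round(grid_size * 0.22))
    roi_names <- names(true_flow)
  } else {
    centres <- list(c((grid_size + 1) / 2, (grid_size + 1) / 2))
    radius <- max(2, round(grid_size * 0.3))
    roi_names <- names(true_flow) %||% "ROI1"
  }
  v <- matrix(0, grid_size, grid_size)
  masks <- list()
  for (k in seq_along(true_flow)) {
    prof <- disc_profile(grid_size, centres[[k]], radius)
    mask <- prof > 0
    if (!any(mask)) hs_input_error("ROI is empty: grid too small for the ROI radius")
    # scale so the discrete noiseless integral equals true_flow exactly
    scale <- true_flow[k] / (sum(prof) * pixel_area * 60)
    vmax <- max(prof) * scale
    if (vmax > venc)
      hs_input_error(sprintf(
        "implied peak velocity %.1f cm/s exceeds venc = %g cm/s", vmax, venc))
    v <- v + prof * scale
    masks[[roi_names[k]]] <- mask
  }
  if (noise_sd > 0) {
    v <- v + matrix(stats::rnorm(grid_size^2, 0, noise_sd),
                    grid_size, grid_size)
    v <- pmin(pmax(v, -venc), venc)
  }
  velocity_scene(v, masks, pixel_area = pixel_area, venc = venc,
                 subject_id = subject_id)
}

#' Generate the full synthetic bundle
#'
#' Produces the cohort table plus per-subject TRUST decay series and
#' phase-contrast velocity scenes consistent with each subject's OEF and
#' CBF: the true blood T2 is obtained by inverting the calibration at the
#' sex-specific haematocrit, and the total arterial inflow is
#' `CBF * brain_volume * density / 100` split over the four feeding
#' arteries (38/38/12/12% for LICA/RICA/LVA/RVA).
#'
#' @param config A [simulation_config()].
#' @param density Brain density (g/ml) used to map CBF to flow.
#' @param ya Arterial oxygenation percent used to map OEF to venous
#'   oxygenation.
#' @return An object of class `synthetic_bundle`: a list with `cohort`,
#'   `trust_series`, `velocity_scenes` and `truth` (the config echoed
#'   back).
#' @export
generate_bundle <- function(config, density = 1.06, ya = 98) {
  stopifnot(inherits(config, "simulation_config"))
  cohort <- generate_cohort(config)
  cal <- list(male = trust_calibration(0.42),
              female = trust_calibration(0.40))
  shares <- c(LICA = 0.38, RICA = 0.38, LVA = 0.12, RVA = 0.12)

  set.seed(child_seed(config$seed, "trust"))
  trust <- lapply(seq_len(nrow(cohort)), function(i) {
    yv <- (1 - cohort$oef[i] / 100) * ya / 100
    m <- cal[[cohort$sex[i]]]
    yv <- pmin(pmax(yv, m$valid_y_range[1] + 0.01),
               m$valid_y_range[2] - 0.01)
    generate_trust_series(yv_to_t2(yv, m), config$s0, etes = config$etes,
                          noise_sd = config$trust_noise_sd,
                          subject_id = cohort$subject_id[i])
  })
  names(trust) <- cohort$subject_id

  set.seed(child_seed(config$seed, "velocity"))
  scenes <- lapply(seq_len(nrow(cohort)), function(i) {
    total <- cohort$cbf[i] * cohort$brain_volume[i] * density / 100
    generate_velocity_scene(total * shares, grid_size = config$grid_size,
                            pixel_area = config$pixel_area,
                            noise_sd = config$velocity_noise_sd,
                            venc = config$venc,
                            subject_id = cohort$subject_id[i])
  })
  names(scenes) <- cohort$subject_id

  structure(list(cohort = cohort, trust_series = trust,
                 velocity_scenes = scenes, truth = config),
            class = "synthetic_bundle")
}

#' Write a synthetic bundle to plain-text files
#'
#' Writes `cohort.csv` (one row per subject), `trust_long.csv`
#' (subject_id, ete_ms, signal), `velocity_long.csv` (subject_id, row, col,
#' velocity_cm_s, roi), `geometry.json` (pixel area, venc, grid size) and
#' `config.json`.
#'
#' @param bundle A [generate_bundle()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(cohort = file.path(dir, "cohort.csv"),
             trust = file.path(dir, "trust_long.csv"),
             velocity = file.path(dir, "velocity_long.csv"),
             geometry = file.path(dir, "geometry.json"),
             config = file.path(dir, "config.json"))
  utils::write.csv(bundle$cohort, paths["cohort"], row.names = FALSE)

  trust_long <- do.call(rbind, lapply(bundle$trust_series, function(ts)
    data.frame(subject_id = ts$subject_id, ete_ms = ts$etes,
               signal = ts$signals)))
  utils::write.csv(trust_long, paths["trust"], row.names = FALSE)

  vel_long <- do.call(rbind, lapply(bundle$velocity_scenes, function(sc) {
    g <- nrow(sc$velocity_map)
    roi <- matrix("", g, g)
    for (nm in names(sc$roi_masks)) roi[sc$roi_masks[[nm]]] <- nm
    data.frame(subject_id = sc$subject_id,
               row = rep(seq_len(g), g), col = rep(seq_len(g), each = g),
               velocity_cm_s = as.vector(sc$velocity_map),
               roi = as.vector(roi))
  }))
  utils::write.csv(vel_long, paths["velocity"], row.names = FALSE)

  sc1 <- bundle$velocity_scenes[[1]]
  jsonlite::write_json(list(grid_size = nrow(sc1$velocity_map),
                            pixel_area_cm2 = sc1$pixel_area,
                            venc_cm_s = sc1$venc,
                            rois = names(sc1$roi_masks)),
                       paths["geometry"], auto_unbox = TRUE, digits = NA)
  cfg <- bundle$truth
  jsonlite::write_json(unclass(cfg), paths["config"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
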