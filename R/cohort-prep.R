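#' Standard neuropsychological test battery
#'
#' The six-domain battery used throughout: executive function (colour
#' trails A and B, timed so higher raw scores are worse), attention (digit
#' span forward/backward), language (modified Boston Naming), visuomotor
#' speed (Symbol Digit Modalities), visuospatial function (Rey Complex
#' Figure copy) and memory (Rey Complex Figure and Hopkins Verbal Learning
#' immediate/delayed recall). Means and SDs are the synthetic generator's
#' raw-score anchors; `higher_better` drives the direction alignment
#' applied before Z-scoring.
#'
#' @return A tibble with columns `test`, `domain`, `mean`, `sd`,
#'   `higher_better`.
#' @export
default_battery <- function() {
  tibble::tibble(
    test = c("ctt_a", "ctt_b", "digit_span_forward", "digit_span_backward",
             "boston_naming", "sdmt", "rcft_copy", "rcft_immediate",
             "rcft_delayed", "hvlt_immediate", "hvlt_delayed"),
    domain = c("executive", "executive", "attention", "attention",
               "language", "visuomotor", "visuospatial", "memory",
               "memory", "memory", "memory"),
    mean = c(60, 140, 8, 5, 12, 30, 32, 15, 14, 20, 7),
    sd = c(20, 45, 2, 2, 2, 10, 4, 6, 6, 5, 3),
    higher_better = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                      TRUE, TRUE, TRUE))
}

z_score <- function(x) {
  s <- stats::sd(x)  # n - 1 denominator throughout
  (x - mean(x)) / s
}

#' Cognitive Z-score standardization: tests, domains, global composite
#'
#' Raw test scores are converted to Z-scores against the sample mean and SD
#' (n - 1 denominator). Timed tests where a higher raw value means worse
#' performance are negated first, so higher Z is always better. Each
#' domain score is the mean of its tests' Z-scores, re-standardized against
#' the sample; the global composite is the mean of the domain Z-scores,
#' again re-standardized, so it has sample mean 0 and SD 1 by construction.
#' All battery tests must be present and non-constant; there is no
#' missing-test averaging.
#'
#' @param scores Data frame with one column per battery test.
#' @param battery Battery definition, see [default_battery()].
#' @return A list with tibbles `test_z` and `domain_z`, and numeric
#'   `global` (the global cognition Z-score).
#' @export
standardize_cognition <- function(scores, battery = default_battery()) {
  missing_tests <- setdiff(battery$test, names(scores))
  if (length(missing_tests))
    hs_input_error(sprintf("missing test column(s): %s",
                           paste(missing_tests, collapse = ", ")))
  if (nrow(scores) < 2L)
    hs_input_error("standardization needs at least 2 subjects")
  test_z <- tibble::as_tibble(lapply(stats::setNames(nm = battery$test),
    function(t) {
      raw <- scores[[t]]
      if (any(!is.finite(raw)))
        hs_input_error(sprintf("non-finite raw scores in test '%s'", t))
      if (stats::sd(raw) == 0)
        hs_input_error(sprintf("test '%s' has zero variance", t))
      if (!battery$higher_better[battery$test == t]) raw <- -raw
      z_score(raw)
    }))
  domains <- unique(battery$domain)
  domain_z <- tibble::as_tibble(lapply(stats::setNames(nm = domains),
    function(d) {
      tests <- battery$test[battery$domain == d]
      z_score(rowMeans(test_z[tests]))
    }))
  global <- z_score(rowMeans(domain_z))
  list(test_z = test_z, domain_z = domain_z, global = global)
}

#' Log-transformed WMH volume
#'
#' Natural log of volume plus a 0.01 cm^3 floor offset, so zero volumes map
#' to `log(0.01)` rather than `-Inf`.
#'
#' @param volume WMH volume(s) in cm^3, non-negative.
#' @param floor Offset in cm^3 (default 0.01).
#' @return Log-volume.
#' @export
log_wmh <- function(volume, floor = 0.01) {
  if (any(!is.finite(volume)) || any(volume < 0))
    hs_input_error("WMH volume must be non-negative and finite")
  log(volume + floor)
}

#' Composite vascular risk score (0-5) and stratum
#'
#' Counts the presence of hypertension, diabetes, hyperlipidaemia, ever
#' smoking and obesity (BMI strictly above 28 kg/m^2). Scores of 0-2 form
#' the low-risk stratum, 3-5 the high-risk stratum. Missing components are
#' an error; no imputation is performed.
#'
#' @param data Data frame (or list) with columns `hypertension`,
#'   `diabetes`, `hyperlipidaemia`, `smoking_ever` (0/1) and `bmi`.
#' @return A tibble with integer `vrs` and factor `vrs_stratum`
#'   (`low`/`high`).
#' @export
vascular_risk_score <- function(data) {
  req <- c("hypertension", "diabetes", "hyperlipidaemia", "smoking_ever",
           "bmi")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols))
    hs_input_error(sprintf("missing risk component(s): %s",
                           paste(missing_cols, collapse = ", ")))
  comp <- cbind(data[["hypertension"]], data[["diabetes"]],
                data[["hyperlipidaemia"]], data[["smoking_ever"]],
                as.numeric(data[["bmi"]] > 28))
  if (any(is.na(comp)))
    hs_input_error("missing values in risk components; no imputation is performed")
  vrs <- as.integer(rowSums(comp))
  tibble::tibble(
    vrs = vrs,
    vrs_stratum = factor(ifelse(vrs <= 2, "low", "high"),
                         levels = c("low", "high")))
}

#' Median-split OEF/CBF quadrant assignment
#'
#' Classifies each subject by the joint position of OEF and CBF relative to
#' their sample medians: Q1 = high OEF + high CBF, Q2 = high OEF + low CBF
#' (the misery-perfusion pattern), Q3 = low OEF + low CBF, Q4 = low OEF +
#' high CBF. "High" means strictly above the median; values equal to the
#' median are assigned low, which makes the split deterministic.
#'
#' @param oef,cbf Numeric vectors (same length, n >= 4, finite).
#' @return A list with `labels` (factor Q1-Q4), `oef_median` and
#'   `cbf_median`.
#' @export
assign_quadrants <- function(oef, cbf) {
  if (length(oef) != length(cbf) || length(oef) < 4L)
    hs_input_error("oef and cbf must have equal length >= 4")
  if (any(!is.finite(oef)) || any(!is.finite(cbf)))
    hs_input_error("oef and cbf must be finite")
  if (length(unique(oef)) == 1L || length(unique(cbf)) == 1L)
    hs_input_error("degenerate split: all OEF or all CBF values are identical")
  om <- stats::median(oef); cm <- stats::median(cbf)
  high_oef <- oef > om; high_cbf <- cbf > cm
  lab <- ifelse(high_oef & high_cbf, "Q1",
         ifelse(high_oef & !high_cbf, "Q2",
         ifelse(!high_oef & !high_cbf, "Q3", "Q4")))
  list(labels = factor(lab, levels = c("Q1", "Q2", "Q3", "Q4")),
       oef_median = om, cbf_median = cm)
}

#' Build all derived analysis variables
#'
#' Adds to a cohort table: per-domain cognitive Z-scores (`z_<domain>`),
#' the global composite (`global_cognition`), `log_wmh`, the vascular risk
#' score and stratum, the obesity flag, a 0/1 male indicator, and the
#' median-split OEF/CBF quadrant (factor Q1-Q4; the quadrant medians are
#' attached as attributes `oef_median` / `cbf_median`).
#'
#' @param cohort Cohort tibble (see [generate_cohort()] for the column
#'   contract).
#' @param battery Test battery, see [default_battery()].
#' @return The cohort tibble with derived columns appended.
#' @export
derive_variables <- function(cohort, battery = default_battery()) {
  cog <- standardize_cognition(cohort, battery)
  out <- cohort
  for (d in names(cog$domain_z)) out[[paste0("z_", d)]] <- cog$domain_z[[d]]
  out$global_cognition <- cog$global
  out$log_wmh <- log_wmh(cohort$wmh_volume)
  vr <- vascular_risk_score(cohort)
  out$vrs <- vr$vrs
  out$vrs_stratum <- vr$vrs_stratum
  out$obese <- as.integer(cohort$bmi > 28)
  out$sex_male <- as.integer(cohort$sex == "male")
  q <- assign_quadrants(cohort$oef, cohort$cbf)
  out$quadrant <- q$labels
  attr(out, "oef_median") <- q$oef_median
  attr(out, "cbf_median") <- q$cbf_median
  out
}
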