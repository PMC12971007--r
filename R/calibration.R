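#' Blood T2 -- venous oxygenation calibration model
#'
#' The TRUST calibration literature relates the transverse relaxation rate of
#' blood to its oxygenation `Y` (fraction of oxyhaemoglobin) through a
#' quadratic relaxivity law at a given haematocrit:
#' \deqn{1/T_2 = a + b(1 - Y) + c(1 - Y)^2}
#' with `1/T2` in s\eqn{^{-1}}. Over the physiological range the map
#' `Y -> T2` is strictly increasing, so the law can be inverted to read
#' venous oxygenation off a fitted blood T2.
#'
#' @param hct Haematocrit as a fraction (e.g. 0.42).
#' @param coeffs Numeric length-3 vector `c(a, b, c)` in s^-1.
#' @param valid_y_range Oxygenation interval (fractions) over which the model
#'   is trusted and guaranteed monotone.
#' @return An object of class `calibration_model`.
#' @seealso [trust_calibration()] for haematocrit-interpolated coefficients,
#'   [t2_to_yv()], [yv_to_t2()].
#' @export
calibration_model <- function(hct, coeffs, valid_y_range = c(0.4, 0.95)) {
  if (!is_scalar_number(hct) || hct <= 0 || hct >= 1)
    hs_config_error("haematocrit must be a fraction in (0, 1)")
  if (!is.numeric(coeffs) || length(coeffs) != 3L || any(!is.finite(coeffs)))
    hs_config_error("coeffs must be three finite numbers (a, b, c) in s^-1")
  if (!is.numeric(valid_y_range) || length(valid_y_range) != 2L ||
      valid_y_range[1] >= valid_y_range[2] ||
      valid_y_range[1] < 0 || valid_y_range[2] > 1)
    hs_config_error("valid_y_range must be an increasing interval within [0, 1]")
  # d(1/T2)/dY = -(b + 2c(1-Y)); strict monotonicity of T2 in Y requires
  # b + 2c(1-Y) > 0 across the valid range (check both endpoints: linear in Y).
  u <- 1 - valid_y_range
  if (any(coeffs[2] + 2 * coeffs[3] * u <= 0))
    hs_config_error("calibration is not strictly monotone over valid_y_range")
  structure(
    list(hct = hct, coeffs = as.numeric(coeffs),
         valid_y_range = as.numeric(valid_y_range)),
    class = "calibration_model"
  )
}

#' Haematocrit-interpolated TRUST calibration coefficients
#'
#' Evaluates the quadratic relaxivity coefficients at a given haematocrit
#' from the haematocrit polynomials of the published TRUST calibration
#' (CPMG inter-echo spacing 10 ms, 3 T):
#' `a = a1 + a2*hct + a3*hct^2`, `b = b1*hct + b2*hct^2`,
#' `c = c1*hct*(1 - hct)`, all in s^-1. The polynomial coefficients ship in
#' `inst/extdata/trust_calibration.json` so an alternative calibration can be
#' swapped in without touching code.
#'
#' @param hct Haematocrit fraction; see [hct_default()] for the sex defaults.
#' @param file Optional path to a JSON coefficient file with fields
#'   `a`, `b`, `c` and `valid_y_range`.
#' @return A [calibration_model()].
#' @export
trust_calibration <- function(hct, file = NULL) {
  file <- file %||% system.file("extdata", "trust_calibration.json",
                                package = "hemosurf", mustWork = TRUE)
  cal <- jsonlite::read_json(file, simplifyVector = TRUE)
  a <- sum(cal$a * hct^(seq_along(cal$a) - 1))
  b <- sum(cal$b * hct^(seq_along(cal$b)))
  cc <- cal$c[1] * hct * (1 - hct)
  calibration_model(hct, c(a, b, cc),
                    valid_y_range = cal$valid_y_range %||% c(0.4, 0.95))
}

#' Map venous oxygenation to blood T2
#'
#' @param yv Oxygenation fraction(s) within the model's valid range.
#' @param model A [calibration_model()].
#' @return Blood T2 in ms.
#' @export
yv_to_t2 <- function(yv, model) {
  stopifnot(inherits(model, "calibration_model"))
  if (any(yv < model$valid_y_range[1] - 1e-12) ||
      any(yv > model$valid_y_range[2] + 1e-12))
    hs_range_error(sprintf(
      "oxygenation outside the calibrated range [%.2f, %.2f]",
      model$valid_y_range[1], model$valid_y_range[2]))
  u <- 1 - yv
  r2 <- model$coeffs[1] + model$coeffs[2] * u + model$coeffs[3] * u^2  # s^-1
  1000 / r2
}

#' Invert the calibration: blood T2 to venous oxygenation
#'
#' Solves the quadratic relaxivity law for `Y` and returns the root that
#' falls inside the model's valid oxygenation range.
#'
#' @param t2 Blood T2 in ms.
#' @param model A [calibration_model()].
#' @return Venous oxygenation as a fraction.
#' @export
t2_to_yv <- function(t2, model) {
  stopifnot(inherits(model, "calibration_model"))
  if (!is.numeric(t2) || any(!is.finite(t2)) || any(t2 <= 0))
    hs_input_error("t2 must be positive and finite (ms)")
  t2_lo <- yv_to_t2(model$valid_y_range[1], model)
  t2_hi <- yv_to_t2(model$valid_y_range[2], model)
  if (any(t2 < t2_lo - 1e-9) || any(t2 > t2_hi + 1e-9))
    hs_range_error(sprintf(
      "t2 = %.3g ms maps outside the calibrated oxygenation range; admissible T2 interval is [%.2f, %.2f] ms",
      t2[which(t2 < t2_lo - 1e-9 | t2 > t2_hi + 1e-9)[1]], t2_lo, t2_hi))
  a <- model$coeffs[1]; b <- model$coeffs[2]; cc <- model$coeffs[3]
  r2 <- 1000 / t2
  # c u^2 + b u + (a - r2) = 0, u = 1 - Y; the monotone branch is the root
  # with the positive discriminant sign reversed (smaller u for larger T2).
  disc <- b^2 - 4 * cc * (a - r2)
  disc <- pmax(disc, 0)
  u <- (-b + sqrt(disc)) / (2 * cc)
  y <- 1 - u
  pmin(pmax(y, model$valid_y_range[1]), model$valid_y_range[2])
}
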