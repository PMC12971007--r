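#' Second-order response surface fit of an outcome on OEF and CBF
#'
#' Fits the polynomial
#' \deqn{Z = b_0 + b_1 X + b_2 Y + b_3 X^2 + b_4 XY + b_5 Y^2 (+ covariates)}
#' by ordinary least squares, where `X` is centred OEF and `Y` centred CBF.
#' Covariates can be adjusted for inside the polynomial regression (the
#' primary mode) or removed beforehand by residualizing the outcome on the
#' covariates (a sensitivity mode); the mode used is recorded in the fit.
#' The coefficient covariance restricted to `b0..b5` is stored for
#' delta-method axis inference.
#'
#' @param x OEF values (percent).
#' @param y CBF values (ml/100g/min).
#' @param z Outcome (WMH log-volume or a cognition Z-score).
#' @param covariates Optional data frame of covariates.
#' @param center `TRUE` to centre at the sample means, `FALSE` for no
#'   centring, or a numeric length-2 vector `c(mu_x, mu_y)` of known
#'   centring constants.
#' @param mode `"adjust"` (covariates inside the regression, primary) or
#'   `"residualize"` (outcome pre-residualized on covariates).
#' @return An object of class `rsa_fit`: coefficients `b` (b0..b5), their
#'   covariance `vcov_b`, covariate coefficients, centring constants
#'   `mu`, residual ranges of centred X/Y, `n_used`, `sigma` and `mode`.
#' @export
fit_rsa <- function(x, y, z, covariates = NULL, center = TRUE,
                    mode = c("adjust", "residualize")) {
  mode <- match.arg(mode)
  if (length(x) != length(y) || length(x) != length(z))
    hs_input_error("x, y and z must have equal length")
  keep <- stats::complete.cases(x, y, z,
                                if (!is.null(covariates)) covariates)
  x <- x[keep]; y <- y[keep]; z <- z[keep]
  if (!is.null(covariates))
    covariates <- as.data.frame(covariates)[keep, , drop = FALSE]
  n <- length(x)
  p_cov <- if (is.null(covariates)) 0L else ncol(covariates)
  if (n <= 6L + p_cov)
    hs_input_error("need more observations than parameters (6 + covariates)")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    hs_input_error("X and Y must be non-degenerate")
  mu <- if (isTRUE(center)) c(mean(x), mean(y))
        else if (identical(center, FALSE)) c(0, 0)
        else if (is.numeric(center) && length(center) == 2L) center
        else hs_input_error("center must be TRUE, FALSE or a numeric length-2 vector")
  X <- x - mu[1]; Y <- y - mu[2]
  if (mode == "residualize" && p_cov > 0) {
    z <- stats::resid(stats::lm(z ~ ., data = covariates))
    covariates <- NULL; p_cov <- 0L
  }
  df <- data.frame(z = z, X = X, Y = Y, X2 = X^2, XY = X * Y, Y2 = Y^2)
  poly_terms <- c("X", "Y", "X2", "XY", "Y2")
  if (p_cov > 0) df <- cbind(df, covariates)
  mm <- stats::model.matrix(~ ., df[-1])
  qrx <- qr(mm)
  if (qrx$rank < ncol(mm)) {
    bad <- colnames(mm)[qrx$pivot[(qrx$rank + 1):ncol(mm)]]
    hs_fit_error(sprintf(
      "response-surface design is rank deficient (collinear: %s); is X identical to Y?",
      paste(bad, collapse = ", ")))
  }
  fit <- stats::lm(z ~ ., data = df)
  cf <- stats::coef(fit)
  V <- quiet_perfect(stats::vcov(fit))
  bnames <- c("(Intercept)", poly_terms)
  b <- stats::setNames(cf[bnames], c("b0", "b1", "b2", "b3", "b4", "b5"))
  vb <- V[bnames, bnames]
  dimnames(vb) <- list(names(b), names(b))
  structure(
    list(b = b, vcov_b = vb,
         covariate_coef = cf[setdiff(names(cf), bnames)],
         mu = stats::setNames(mu, c("mu_x", "mu_y")),
         x_range = range(X), y_range = range(Y),
         x_sd = stats::sd(X), y_sd = stats::sd(Y),
         n_used = n, sigma = quiet_perfect(summary(fit)$sigma),
         mode = mode),
    class = "rsa_fit")
}

#' @export
print.rsa_fit <- function(x, ...) {
  cat(sprintf(
    "Response surface fit (n = %d, mode = %s, centred at mu_x = %.3f, mu_y = %.3f)\n",
    x$n_used, x$mode, x$mu[1], x$mu[2]))
  print(round(x$b, 4))
  invisible(x)
}

axis_combinations <- function() {
  list(balance_slope     = c(1, 1, 0, 0, 0),
       balance_curvature = c(0, 0, 1, 1, 1),
       bias_slope        = c(1, -1, 0, 0, 0),
       bias_curvature    = c(0, 0, 1, -1, 1))
}

#' Balance-axis and bias-axis statistics of a response surface
#'
#' Along the balance axis (CBF = OEF in centred units, i.e. coordinated
#' OEF--CBF states) the surface slope is `b1 + b2` and the curvature
#' `b3 + b4 + b5`; along the bias (mismatch) axis (CBF = -OEF + 2 mu) they
#' are `b1 - b2` and `b3 - b4 + b5`. Standard errors come from the delta
#' method, `SE^2 = c' Sigma c` for each combination vector `c`, with Wald
#' 95% intervals.
#'
#' @param fit An [fit_rsa()] object, or a numeric vector of surface
#'   coefficients: either `c(b1, b2, b3, b4, b5)` or `c(b0, ..., b5)`.
#' @param vcov Optional 5x5 covariance of `(b1..b5)` when `fit` is a plain
#'   coefficient vector; defaults to a zero matrix (point estimates only,
#'   intervals collapse to the estimate).
#' @return A tibble with columns `quantity` (`balance_slope`,
#'   `balance_curvature`, `bias_slope`, `bias_curvature`), `estimate`,
#'   `se`, `lo`, `hi`.
#' @export
axis_tests <- function(fit, vcov = NULL) {
  if (inherits(fit, "rsa_fit")) {
    if (is.null(fit$vcov_b)) hs_input_error("fit carries no coefficient covariance")
    b <- fit$b[2:6]
    S <- fit$vcov_b[2:6, 2:6]
  } else if (is.numeric(fit)) {
    b <- if (length(fit) == 6L) fit[2:6]
         else if (length(fit) == 5L) fit
         else hs_input_error("coefficient vector must have length 5 (b1..b5) or 6 (b0..b5)")
    S <- vcov %||% matrix(0, 5, 5)
    if (!identical(dim(S), c(5L, 5L)))
      hs_input_error("vcov must be a 5x5 matrix for (b1..b5)")
  } else {
    hs_input_error("fit must be an rsa_fit or a numeric coefficient vector")
  }
  combos <- axis_combinations()
  est <- vapply(combos, function(cc) sum(cc * b), numeric(1))
  se <- vapply(combos, function(cc) sqrt(drop(t(cc) %*% S %*% cc)),
               numeric(1))
  tibble::tibble(quantity = names(combos), estimate = unname(est),
                 se = unname(se),
                 lo = unname(est - 1.96 * se),
                 hi = unname(est + 1.96 * se))
}

#' Evaluate the fitted surface on a grid and along the two axes
#'
#' Evaluates the polynomial part of the fit (the predicted outcome
#' residual, excluding covariates) on an `n_grid` x `n_grid` lattice over
#' the observed ranges of centred X and Y (clipped to +/- `k` SD), and
#' along the balance line (Y = X) and bias line (Y = -X) in centred units.
#'
#' @param fit An [fit_rsa()] object.
#' @param n_grid Grid resolution per axis (default 50).
#' @param k Range clip in SD units (default 2.5).
#' @return An object of class `surface_grid`: list with tibbles `grid`
#'   (`x`, `y` centred; `x_raw`, `y_raw`; `z_pred`) and `axes` (`axis`,
#'   `t`, `x`, `y`, `z_pred`).
#' @export
predict_surface <- function(fit, n_grid = 50, k = 2.5) {
  stopifnot(inherits(fit, "rsa_fit"))
  if (!is_scalar_number(n_grid) || n_grid < 2)
    hs_input_error("n_grid must be at least 2 (empty or degenerate grid)")
  xr <- c(max(fit$x_range[1], -k * fit$x_sd),
          min(fit$x_range[2], k * fit$x_sd))
  yr <- c(max(fit$y_range[1], -k * fit$y_sd),
          min(fit$y_range[2], k * fit$y_sd))
  xs <- seq(xr[1], xr[2], length.out = n_grid)
  ys <- seq(yr[1], yr[2], length.out = n_grid)
  b <- fit$b
  surf <- function(X, Y) b[1] + b[2] * X + b[3] * Y + b[4] * X^2 +
    b[5] * X * Y + b[6] * Y^2
  grid <- expand.grid(x = xs, y = ys)
  grid_tb <- tibble::tibble(x = grid$x, y = grid$y,
                            x_raw = grid$x + fit$mu[1],
                            y_raw = grid$y + fit$mu[2],
                            z_pred = unname(surf(grid$x, grid$y)))
  tr <- c(max(xr[1], yr[1]), min(xr[2], yr[2]))
  t_bal <- seq(tr[1], tr[2], length.out = n_grid)
  tr2 <- c(max(xr[1], -yr[2]), min(xr[2], -yr[1]))
  t_bias <- seq(tr2[1], tr2[2], length.out = n_grid)
  axes <- rbind(
    tibble::tibble(axis = "balance", t = t_bal, x = t_bal, y = t_bal,
                   z_pred = unname(surf(t_bal, t_bal))),
    tibble::tibble(axis = "bias", t = t_bias, x = t_bias, y = -t_bias,
                   z_pred = unname(surf(t_bias, -t_bias))))
  structure(list(grid = grid_tb, axes = axes, mu = fit$mu),
            class = "surface_grid")
}
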