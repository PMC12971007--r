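#' Covariate-adjusted linear model with tidy output
#'
#' Ordinary least squares (identity-link Gaussian GLM) of one outcome on an
#' exposure plus covariates. A factor exposure named `quadrant` is
#' re-levelled to the misery-perfusion quadrant Q2 as reference, and the
#' reference level is emitted as an explicit zero row. Confidence intervals
#' are Wald normal-approximation intervals, `estimate +/- 1.96 * SE`.
#'
#' @param data Data frame holding outcome, exposure and covariates.
#' @param outcome Outcome column name.
#' @param exposure Exposure column name (factor or continuous).
#' @param covariates Character vector of covariate column names.
#' @param subset Optional logical vector selecting rows.
#' @param ref Reference level used when the exposure is a factor
#'   (default `"Q2"`).
#' @return A tibble with columns `outcome`, `term`, `estimate`, `se`,
#'   `lo`, `hi`, `n`.
#' @export
fit_linear <- function(data, outcome, exposure, covariates = character(),
                       subset = NULL, ref = "Q2") {
  cols <- c(outcome, exposure, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols))
    hs_input_error(sprintf("column(s) not in data: %s",
                           paste(missing_cols, collapse = ", ")))
  df <- as.data.frame(data[cols])
  if (!is.null(subset)) df <- df[which(subset), , drop = FALSE]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nrow(df) == 0L) hs_input_error("empty subset: no rows to fit")
  is_factor_exposure <- is.factor(df[[exposure]]) ||
    is.character(df[[exposure]])
  if (is_factor_exposure) {
    df[[exposure]] <- stats::relevel(factor(df[[exposure]]), ref = ref)
    df[[exposure]] <- droplevels(df[[exposure]])
  }
  fml <- stats::reformulate(c(exposure, covariates), response = outcome)
  mm <- stats::model.matrix(fml, df)
  if (nrow(mm) <= ncol(mm))
    hs_input_error("fewer observations than parameters")
  qrx <- qr(mm)
  if (qrx$rank < ncol(mm)) {
    bad <- colnames(mm)[qrx$pivot[(qrx$rank + 1):ncol(mm)]]
    hs_input_error(sprintf("design is rank deficient; collinear column(s): %s",
                           paste(bad, collapse = ", ")))
  }
  fit <- stats::lm(fml, data = df)
  est <- stats::coef(fit)
  se <- sqrt(diag(quiet_perfect(stats::vcov(fit))))
  out <- tibble::tibble(outcome = outcome, term = names(est),
                        estimate = unname(est), se = unname(se),
                        lo = unname(est - 1.96 * se),
                        hi = unname(est + 1.96 * se),
                        n = nrow(df))
  if (is_factor_exposure) {
    ref_row <- tibble::tibble(outcome = outcome,
                              term = paste0(exposure, ref),
                              estimate = 0, se = 0, lo = 0, hi = 0,
                              n = nrow(df))
    out <- rbind(out[1, ], ref_row, out[-1, ])
  }
  out
}

#' Quadrant contrast battery for WMH and cognition
#'
#' Fits the full set of quadrant-contrast models against the
#' misery-perfusion reference (Q2): log-WMH volume on the infarct-free
#' subset with covariates age + sex (Model 1) and additionally the vascular
#' risk score (Model 2); and the global composite plus the six domain
#' Z-scores with covariates age + sex + education (Model 1) and
#' additionally the vascular risk score (Model 2). Only the non-reference
#' quadrant contrasts are returned: 8 outcomes x 3 contrasts x 2 models.
#'
#' @param data A cohort with derived variables (see [derive_variables()]).
#' @return A tibble with columns `outcome`, `model`, `term`, `estimate`,
#'   `se`, `lo`, `hi`, `n`.
#' @export
run_quadrant_battery <- function(data) {
  req <- c("quadrant", "log_wmh", "global_cognition", "age", "sex_male",
           "education", "vrs", "infarct")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols))
    hs_input_error(sprintf("derived variable(s) missing: %s",
                           paste(missing_cols, collapse = ", ")))
  cog_outcomes <- c("global_cognition", "z_executive", "z_attention",
                    "z_language", "z_visuomotor", "z_visuospatial",
                    "z_memory")
  specs <- rbind(
    data.frame(outcome = "log_wmh", model = c("M1", "M2"), wmh = TRUE),
    expand.grid(outcome = cog_outcomes, model = c("M1", "M2"),
                wmh = FALSE, stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(specs)), function(i) {
    sp <- specs[i, ]
    covars <- if (sp$wmh) c("age", "sex_male")
              else c("age", "sex_male", "education")
    if (sp$model == "M2") covars <- c(covars, "vrs")
    subset <- if (sp$wmh) data$infarct == 0 else NULL
    res <- fit_linear(data, sp$outcome, "quadrant", covars, subset = subset)
    res <- res[grepl("^quadrant", res$term) & res$term != "quadrantQ2", ]
    res$model <- sp$model
    res
  })
  out <- do.call(rbind, rows)
  out[, c("outcome", "model", "term", "estimate", "se", "lo", "hi", "n")]
}

#' Stratified continuous-exposure models
#'
#' Refits the continuous OEF and CBF slope models within strata of vascular
#' risk (score 0-2 versus 3-5) or APOE4 carriage, with the same covariates
#' as the corresponding main model. Strata with too few complete rows for
#' the parameter count are skipped with a warning.
#'
#' @param data A cohort with derived variables.
#' @param stratifier `"vrs"` (vascular risk stratum) or `"apoe"` (APOE4
#'   carrier status; ungenotyped subjects are dropped).
#' @param outcome Outcome column (default `"global_cognition"`).
#' @param exposures Continuous exposure columns (default OEF and CBF).
#' @return A tibble of slope rows with columns `stratum`, `outcome`,
#'   `term`, `estimate`, `se`, `lo`, `hi`, `n`.
#' @export
run_stratified <- function(data, stratifier = c("vrs", "apoe"),
                           outcome = "global_cognition",
                           exposures = c("oef", "cbf")) {
  stratifier <- match.arg(stratifier)
  strata_var <- if (stratifier == "vrs") data$vrs_stratum
                else factor(ifelse(data$apoe4 == 1, "carrier",
                                   "non-carrier"),
                            levels = c("non-carrier", "carrier"))
  covars <- if (outcome == "log_wmh") c("age", "sex_male")
            else c("age", "sex_male", "education")
  if (stratifier == "apoe") covars <- c(covars, "vrs")
  present <- levels(droplevels(strata_var[!is.na(strata_var)]))
  if (length(present) == 0L) hs_input_error("no non-empty strata")
  if (length(present) < 2L)
    warning("only one non-empty stratum; returning a single result set")
  rows <- list()
  for (s in present) {
    idx <- !is.na(strata_var) & strata_var == s
    for (e in exposures) {
      res <- tryCatch(
        fit_linear(data, outcome, e, covars, subset = idx),
        hemosurf_input_error = function(err) {
          warning(sprintf("stratum '%s': %s; skipped", s,
                          conditionMessage(err)))
          NULL
        })
      if (is.null(res)) next
      res <- res[res$term == e, ]
      res$stratum <- s
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  out[, c("stratum", "outcome", "term", "estimate", "se", "lo", "hi", "n")]
}

#' MANCOVA with Pillai's trace and follow-up ANCOVAs
#'
#' Multivariate analysis of covariance over a set of outcomes. Covariates
#' enter first; each listed term is then added sequentially, and its
#' hypothesis cross-product matrix is `H = Y'(P_j - P_(j-1))Y`, with error
#' matrix `E = Y'(I - P_full)Y`. Pillai's trace is
#' `V = tr(H (H + E)^-1)`, converted to an F statistic with the standard
#' degrees-of-freedom approximation. Follow-up univariate ANCOVA F tests
#' are reported per outcome for each term.
#'
#' @param data Data frame.
#' @param outcomes Character vector of outcome columns (the multivariate
#'   response).
#' @param terms Character vector of model terms tested sequentially after
#'   the covariates; interaction syntax such as `"oef:cbf"` is allowed.
#' @param covariates Character vector of covariate columns (nuisance
#'   block).
#' @return An object of class `mancova_result`: list with tibbles
#'   `multivariate` (term, df, pillai, f, df1, df2, p) and `followup`
#'   (term, outcome, f, df1, df2, p), plus `error_df`.
#' @export
mancova <- function(data, outcomes, terms, covariates = character()) {
  cols <- unique(c(outcomes, all.vars(stats::reformulate(c(terms, if (length(covariates)) covariates else "1")))))
  df <- as.data.frame(data[intersect(cols, names(data))])
  df <- df[stats::complete.cases(df), , drop = FALSE]
  Y <- as.matrix(df[outcomes])
  n <- nrow(Y); p <- ncol(Y)
  rhs_blocks <- c(if (length(covariates)) covariates, terms)
  mats <- vector("list", length(terms) + 1L)
  base_terms <- if (length(covariates)) covariates else NULL
  fml0 <- if (is.null(base_terms)) ~1 else stats::reformulate(base_terms)
  mats[[1L]] <- stats::model.matrix(fml0, df)
  for (j in seq_along(terms))
    mats[[j + 1L]] <- stats::model.matrix(
      stats::reformulate(c(base_terms, terms[seq_len(j)])), df)
  ranks <- integer(length(mats))
  fits <- vector("list", length(mats))
  for (k in seq_along(mats)) {
    qx <- qr(mats[[k]])
    ranks[k] <- qx$rank
    fits[[k]] <- qr.fitted(qx, Y)
  }
  rank_full <- ranks[length(ranks)]
  if (n <= rank_full + p)
    hs_input_error("too few rows: n must exceed the parameter count plus the number of outcomes")
  E <- crossprod(Y - fits[[length(fits)]])
  ve <- n - rank_full
  if (rcond(E) < 1e-12)
    hs_fit_error("error cross-product matrix is singular")
  multi <- list(); fu <- list()
  for (j in seq_along(terms)) {
    H <- crossprod(fits[[j + 1L]]) - crossprod(fits[[j]])
    H <- (H + t(H)) / 2
    q <- ranks[j + 1L] - ranks[j]
    V <- sum(diag(H %*% solve(H + E)))
    s <- min(p, q)
    m <- (abs(p - q) - 1) / 2
    nn <- (ve - p - 1) / 2
    df1 <- s * (2 * m + s + 1)
    df2 <- s * (2 * nn + s + 1)
    f <- (df2 / df1) * V / (s - V)
    multi[[j]] <- tibble::tibble(term = terms[j], df = q, pillai = V,
                                 f = f, df1 = df1, df2 = df2,
                                 p = stats::pf(f, df1, df2,
                                               lower.tail = FALSE))
    fu[[j]] <- tibble::tibble(
      term = terms[j], outcome = outcomes,
      f = (diag(H)[outcomes] / q) / (diag(E)[outcomes] / ve),
      df1 = q, df2 = ve)
    fu[[j]]$p <- stats::pf(fu[[j]]$f, q, ve, lower.tail = FALSE)
  }
  structure(list(multivariate = do.call(rbind, multi),
                 followup = do.call(rbind, fu),
                 error_df = ve, n_used = n),
            class = "mancova_result")
}

#' @export
print.mancova_result <- function(x, ...) {
  cat("MANCOVA (Pillai's trace), n =", x$n_used,
      ", error df =", x$error_df, "\n")
  print(x$multivariate)
  cat("\nFollow-up ANCOVAs:\n")
  print(x$followup)
  invisible(x)
}
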