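test_that("OLS recovers a closed-form toy effect exactly", {
  toy <- data.frame(x = c(0, 0, 1, 1), y = c(0, 0, 2, 2))
  res <- fit_linear(toy, "y", "x")
  expect_equal(res$estimate[res$term == "x"], 2, tolerance = 1e-12)
})

test_that("coefficients equal an independent normal-equations oracle", {
  set.seed(21)
  df <- data.frame(y = rnorm(40), x = rnorm(40), a = rnorm(40),
                   b = rnorm(40))
  res <- fit_linear(df, "y", "x", covariates = c("a", "b"))
  X <- cbind(1, df$x, df$a, df$b)
  beta <- solve(t(X) %*% X, t(X) %*% df$y)
  expect_equal(res$estimate, as.vector(beta), tolerance = 1e-10)
  r <- df$y - X %*% beta
  s2 <- sum(r^2) / (40 - 4)
  se <- sqrt(diag(s2 * solve(t(X) %*% X)))
  expect_equal(res$se, unname(se), tolerance = 1e-10)
  expect_equal(res$lo, res$estimate - 1.96 * res$se)
})

test_that("the misery-perfusion reference contrast is identically zero", {
  d <- derive_variables(small_cohort(n = 80, seed = 30))
  res <- fit_linear(d, "global_cognition", "quadrant",
                    covariates = c("age", "sex_male", "education"))
  expect_equal(res$estimate[res$term == "quadrantQ2"], 0)
  expect_true(all(c("quadrantQ1", "quadrantQ3", "quadrantQ4") %in%
                    res$term))
})

test_that("rank-deficient designs raise an error listing collinear columns", {
  df <- data.frame(y = rnorm(20), x = rnorm(20))
  df$x2 <- 2 * df$x
  err <- expect_error(fit_linear(df, "y", "x", covariates = "x2"),
                      class = "hemosurf_input_error")
  expect_match(conditionMessage(err), "x2")
  expect_error(fit_linear(df[0, ], "y", "x"),
               class = "hemosurf_input_error")
})

test_that("OLS contrasts are invariant to covariate order and affine rescaling", {
  d <- derive_variables(small_cohort(n = 90, seed = 31))
  r1 <- fit_linear(d, "log_wmh", "quadrant",
                   covariates = c("age", "sex_male"))
  r2 <- fit_linear(d, "log_wmh", "quadrant",
                   covariates = c("sex_male", "age"))
  q_terms <- grepl("^quadrant", r1$term)
  expect_equal(r1$estimate[q_terms],
               r2$estimate[match(r1$term[q_terms], r2$term)],
               tolerance = 1e-10)
  d2 <- d; d2$age <- (d$age - 60) / 10
  r3 <- fit_linear(d2, "log_wmh", "quadrant",
                   covariates = c("age", "sex_male"))
  expect_equal(r1$estimate[q_terms],
               r3$estimate[match(r1$term[q_terms], r3$term)],
               tolerance = 1e-10)
})

test_that("the quadrant battery emits 8 outcomes x 3 contrasts x 2 models", {
  d <- derive_variables(small_cohort(n = 100, seed = 32))
  res <- run_quadrant_battery(d)
  expect_equal(nrow(res), (1 + 7) * 3 * 2)
  expect_true(all(res$term %in% c("quadrantQ1", "quadrantQ3",
                                  "quadrantQ4")))
  # WMH rows exclude subjects with infarcts
  n_wmh <- unique(res$n[res$outcome == "log_wmh"])
  expect_equal(n_wmh, sum(d$infarct == 0))
  n_cog <- unique(res$n[res$outcome == "global_cognition"])
  expect_equal(n_cog, nrow(d))
})

test_that("a generated quadrant WMH contrast is recovered by the battery", {
  # generator embeds a Q4-vs-Q2 log-WMH difference of -0.55
  reps <- 120
  est <- vapply(seq_len(reps), function(r) {
    cfg <- simulation_config(n_subjects = 296, seed = 5000 + r,
                             wmh_quadrant_shift = c(Q1 = 0, Q3 = 0,
                                                    Q4 = -0.55),
                             infarct_fraction = 42 / 296)
    d <- derive_variables(generate_cohort(cfg))
    res <- fit_linear(d, "log_wmh", "quadrant",
                      covariates = c("age", "sex_male"),
                      subset = d$infarct == 0)
    res$estimate[res$term == "quadrantQ4"]
  }, numeric(1))
  se <- sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - (-0.55)), 3 * se)
})

test_that("quadrant contrasts are unbiased under the null generator", {
  reps <- 300
  est <- vapply(seq_len(reps), function(r) {
    d <- derive_variables(generate_cohort(
      simulation_config(n_subjects = 150, seed = 9000 + r)))
    res <- fit_linear(d, "log_wmh", "quadrant",
                      covariates = c("age", "sex_male"))
    res$estimate[res$term == "quadrantQ4"]
  }, numeric(1))
  expect_lt(abs(mean(est)), 2 * sd(est) / sqrt(reps))
})

test_that("stratified analysis splits vascular risk at score 2 vs 3", {
  d <- derive_variables(small_cohort(n = 200, seed = 33))
  res <- run_stratified(d, "vrs")
  expect_setequal(unique(res$stratum), c("low", "high"))
  n_low <- unique(res$n[res$stratum == "low"])
  expect_equal(n_low, sum(d$vrs <= 2))
  expect_equal(unique(res$n[res$stratum == "high"]), sum(d$vrs >= 3))
  expect_setequal(unique(res$term), c("oef", "cbf"))
  # APOE stratification drops ungenotyped subjects
  res_apoe <- run_stratified(d, "apoe")
  expect_equal(sum(unique(res_apoe$n[res_apoe$term == "oef"])),
               sum(!is.na(d$apoe4)))
})

test_that("degenerate single-stratum data yield a warning and one result set", {
  d <- derive_variables(small_cohort(n = 60, seed = 34))
  d$vrs_stratum <- factor(rep("low", nrow(d)), levels = c("low", "high"))
  expect_warning(res <- run_stratified(d, "vrs"), "one non-empty stratum")
  expect_equal(unique(res$stratum), "low")
})

test_that("stratum slopes match the pooled slope when strata are homogeneous", {
  d <- derive_variables(generate_cohort(
    simulation_config(n_subjects = 400, seed = 35)))
  pooled <- fit_linear(d, "global_cognition", "oef",
                       covariates = c("age", "sex_male", "education"))
  slope_pooled <- pooled$estimate[pooled$term == "oef"]
  se_pooled <- pooled$se[pooled$term == "oef"]
  res <- run_stratified(d, "vrs")
  strat <- res[res$term == "oef", ]
  # each stratum slope within ~3 stratum SEs of the pooled slope
  expect_true(all(abs(strat$estimate - slope_pooled) <
                    3 * pmax(strat$se, se_pooled)))
})

test_that("Pillai trace reduces to the univariate ANCOVA F for one outcome", {
  d <- derive_variables(small_cohort(n = 70, seed = 36))
  mv <- mancova(d, outcomes = "z_memory", terms = "oef",
                covariates = c("age", "sex_male"))
  uni <- anova(lm(z_memory ~ age + sex_male + oef, data = d))
  expect_equal(mv$multivariate$f, uni["oef", "F value"], tolerance = 1e-10)
  expect_equal(mv$multivariate$p, uni["oef", "Pr(>F)"], tolerance = 1e-10)
})

test_that("Pillai trace equals an eigenvalue-sum oracle on hand-sized matrices", {
  d <- derive_variables(small_cohort(n = 50, seed = 37))
  outs <- c("z_executive", "z_attention", "z_memory")
  mv <- mancova(d, outcomes = outs, terms = c("oef", "cbf"),
                covariates = "age")
  # independent oracle: eigenvalues of H(H+E)^-1 from explicit projections
  df <- as.data.frame(d[c(outs, "oef", "cbf", "age")])
  Y <- as.matrix(df[outs])
  P <- function(X) X %*% solve(t(X) %*% X) %*% t(X)
  X0 <- cbind(1, df$age)
  X1 <- cbind(X0, df$oef)
  X2 <- cbind(X1, df$cbf)
  E <- t(Y) %*% (diag(nrow(Y)) - P(X2)) %*% Y
  for (j in 1:2) {
    Xa <- list(X0, X1)[[j]]; Xb <- list(X1, X2)[[j]]
    H <- t(Y) %*% (P(Xb) - P(Xa)) %*% Y
    V <- sum(Re(eigen(H %*% solve(H + E))$values))
    expect_equal(mv$multivariate$pillai[j], V, tolerance = 1e-10)
  }
})

test_that("Pillai trace and F match the reference sequential MANOVA", {
  d <- derive_variables(small_cohort(n = 90, seed = 38))
  outs <- c("z_executive", "z_attention", "z_visuospatial", "z_memory")
  mv <- mancova(d, outcomes = outs, terms = c("oef", "cbf", "oef:cbf"),
                covariates = c("age", "sex_male", "education"))
  ref <- summary(stats::manova(
    as.matrix(as.data.frame(d[outs])) ~ age + sex_male + education +
      oef + cbf + oef:cbf, data = d), test = "Pillai")$stats
  expect_equal(mv$multivariate$pillai,
               unname(ref[c("oef", "cbf", "oef:cbf"), "Pillai"]),
               tolerance = 1e-10)
  expect_equal(mv$multivariate$f,
               unname(ref[c("oef", "cbf", "oef:cbf"), "approx F"]),
               tolerance = 1e-8)
})

test_that("MANCOVA p-values are uniform under row permutation of the outcomes", {
  set.seed(39)
  n <- 40
  base <- data.frame(y1 = rnorm(n), y2 = rnorm(n), y3 = rnorm(n),
                     x = rnorm(n))
  ps <- vapply(seq_len(1000), function(i) {
    d <- base
    idx <- sample.int(n)
    d[c("y1", "y2", "y3")] <- base[idx, c("y1", "y2", "y3")]
    mancova(d, outcomes = c("y1", "y2", "y3"), terms = "x")$multivariate$p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("singular error matrices and undersized samples are rejected", {
  d <- derive_variables(small_cohort(n = 40, seed = 40))
  d$dup <- d$z_memory  # duplicate outcome makes E singular
  expect_error(mancova(d, outcomes = c("z_memory", "dup"), terms = "oef"),
               class = "hemosurf_fit_error")
  expect_error(mancova(d[1:5, ],
                       outcomes = c("z_memory", "z_executive",
                                    "z_attention"),
                       terms = "oef", covariates = c("age", "sex_male")),
               class = "hemosurf_input_error")
})
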