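test_that("ML fit matches a profile-likelihood grid search on a 12-row toy", {
  set.seed(7)
  subj <- rep(1:4, each = 3)
  x <- c(0.2, -1, 0.5, 1.2, 0.3, -0.7, 0.9, -0.2, 0.1, -1.1, 0.6, 0.4)
  u <- c(1.5, -0.8, 0.3, -1)[subj]
  y <- 1 + 0.8 * x + u + rnorm(12, sd = 0.3)
  X <- cbind(1, x)
  oracle <- lme_grid_oracle(X, y, subj,
                            lambda_grid = exp(seq(log(1e-4), log(500),
                                                  length.out = 4000)))
  fit <- fit_lme(y, cbind(x = x), subj)
  expect_equal(unname(coef(fit)), oracle$beta, tolerance = 1e-3)
  expect_equal(fit$sigma2_e, oracle$sigma2_e, tolerance = 1e-2)
  expect_equal(fit$sigma2_u, oracle$sigma2_u, tolerance = 1e-2)
  expect_gte(fit$logLik, oracle$ll - 1e-6)
})

test_that("ML fit agrees with an independent mixed-model implementation", {
  skip_if_not_installed("lme4")
  set.seed(42)
  subj <- rep(1:8, each = 4)
  x <- rnorm(32)
  y <- 2 + 0.7 * x + rnorm(8, sd = 1.5)[subj] + rnorm(32, sd = 0.5)
  fit <- fit_lme(y, cbind(x = x), subj)
  ref <- lme4::lmer(y ~ x + (1 | subj), REML = FALSE)
  expect_equal(unname(coef(fit)), unname(lme4::fixef(ref)), tolerance = 1e-5)
  vc <- as.data.frame(lme4::VarCorr(ref))
  expect_equal(fit$sigma2_u, vc$vcov[1], tolerance = 1e-4)
  expect_equal(fit$sigma2_e, vc$vcov[2], tolerance = 1e-4)
  expect_equal(fit$logLik, as.numeric(stats::logLik(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$ranef),
               unname(lme4::ranef(ref)$subj[, 1]), tolerance = 1e-4)
})

test_that("constant-within-subject outcome is reproduced exactly", {
  subj <- rep(1:5, each = 3)
  y <- c(2, 2, 2, -1, -1, -1, 0.5, 0.5, 0.5, 3, 3, 3, 1, 1, 1)
  fit <- fit_lme(y, X = NULL, subject = subj, intercept = TRUE)
  expect_equal(unname(fitted(fit)), y, tolerance = 1e-6)
})

test_that("zero between-subject variance degenerates to OLS", {
  # residual pattern identical across subjects -> zero between-group
  # variance -> lambda-hat = 0 and predictions equal the OLS closed form
  x <- rep(c(0, 1, 2), 4)
  subj <- rep(1:4, each = 3)
  y <- 1 + 2 * x + rep(c(0.1, -0.1, 0), 4)
  fit <- fit_lme(y, cbind(x = x), subj)
  ols <- lm(y ~ x)
  expect_equal(unname(fitted(fit)), unname(fitted(ols)), tolerance = 1e-6)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-6)
  expect_equal(fit$sigma2_u, 0)

  # explicit fixed-only mode matches OLS on arbitrary data
  set.seed(3)
  y2 <- rnorm(12)
  f2 <- fit_lme(y2, cbind(x = x), subj, random = FALSE)
  expect_equal(unname(coef(f2)), unname(coef(lm(y2 ~ x))), tolerance = 1e-9)
})

test_that("prediction uses the subject BLUP when available", {
  set.seed(9)
  subj <- rep(letters[1:6], each = 4)
  x <- rnorm(24)
  y <- 0.5 * x + rnorm(6, sd = 2)[match(subj, letters)] + rnorm(24, 0.2)
  fit <- fit_lme(y, cbind(x = x), subj)
  p_known <- predict(fit, matrix(1, 1, 1), newsubject = "c")
  p_pop <- predict(fit, matrix(1, 1, 1), newsubject = "zz")
  expect_equal(p_known - p_pop, unname(fit$ranef["c"]))
  expect_equal(p_pop, unname(coef(fit)[1] + coef(fit)[2]))
  expect_equal(residuals(fit), y - fitted(fit))
})

test_that("degenerate designs error clearly", {
  subj <- rep(1:3, each = 4)
  x <- rnorm(12)
  expect_error(fit_lme(rnorm(12), cbind(x, x), subj), "singular")
  expect_error(fit_lme(rnorm(12), NULL, subj, intercept = FALSE), "empty")
  expect_error(fit_lme(rnorm(4), cbind(rnorm(4)), rep(1, 4)), "2 subjects")
  expect_error(fit_lme(c(1, NA, 3, 4), cbind(rnorm(4)), rep(1:2, 2)),
               "missing")
})

test_that("simulate() reproduces the fitted variance structure", {
  set.seed(11)
  subj <- rep(1:10, each = 4)
  y <- rnorm(10, sd = 2)[subj] + rnorm(40, sd = 0.5)
  fit <- fit_lme(y, NULL, subj, intercept = TRUE)
  sims <- simulate(fit, nsim = 200, seed = 5)
  # between-subject spread of simulated data matches sigma2_u + sigma2_e
  v <- mean(apply(sims, 2, var))
  expect_equal(v, fit$sigma2_u + fit$sigma2_e, tolerance = 0.25)
  sims2 <- simulate(fit, nsim = 2, seed = 5)
  expect_identical(sims[, 1], sims2[, 1])  # seeded reproducibility
})
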