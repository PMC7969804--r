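# small realizable problem: outcome is a linear function of a latent factor
# that dominates the feature covariance, plus subject intercepts
make_realizable <- function(n_subj = 12, n_sess = 4, noise = 0, seed = 1) {
  set.seed(seed)
  n <- n_subj * n_sess
  subject <- rep(sprintf("P%02d", seq_len(n_subj)), each = n_sess)
  session <- rep(seq_len(n_sess), n_subj)
  z <- rnorm(n, sd = 2)
  X <- cbind(f1 = z + rnorm(n, sd = 0.01), f2 = z + rnorm(n, sd = 0.01),
             f3 = rnorm(n, sd = 0.1), f4 = rnorm(n, sd = 0.1))
  u <- rnorm(n_subj, sd = 1.5)[rep(seq_len(n_subj), each = n_sess)]
  y <- 3 + 2 * z + u + rnorm(n, sd = noise)
  list(X = X, y = y, subject = subject, session = session)
}

test_that("prediction metrics match hand arithmetic", {
  m <- evaluate_predictions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(m$corr, 1)
  expect_equal(m$rmse, 0)
  expect_equal(m$bias, 0)

  m2 <- evaluate_predictions(c(1, 2, 3) + 0.5, c(1, 2, 3))
  expect_equal(m2$corr, 1)
  expect_equal(m2$bias, 0.5)
  expect_equal(m2$rmse, 0.5)

  m3 <- evaluate_predictions(c(1, 2, 3), c(3, 2, 1))
  expect_equal(m3$corr, -1)
  expect_equal(m3$bias, 0)
  expect_equal(m3$rmse, sqrt(8 / 3), tolerance = 1e-12)
  expect_equal(m3$r2, 1)

  expect_error(evaluate_predictions(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(evaluate_predictions(1:2, 1:2), "at least 3")
})

test_that("a realizable linear model is recovered almost perfectly", {
  d <- make_realizable(noise = 0)
  res <- loso_predict(d$X, d$y, d$subject, d$session, variant = "raw",
                      pc_grid = 1:3)
  expect_gte(res$metrics$corr, 0.99)
  expect_lt(res$metrics$rmse, 0.5)
  # every session held out exactly once
  expect_equal(nrow(res$predictions), length(d$y))
  expect_false(any(is.na(res$predictions$predicted)))
})

test_that("fold predictions are invariant to row order", {
  d <- make_realizable(n_subj = 8, noise = 0.3, seed = 4)
  res <- loso_predict(d$X, d$y, d$subject, d$session, pc_grid = 1:2,
                      baseline = FALSE)
  set.seed(2)
  perm <- sample(length(d$y))
  res_p <- loso_predict(d$X[perm, ], d$y[perm], d$subject[perm],
                        d$session[perm], pc_grid = 1:2, baseline = FALSE)
  key <- paste(res$predictions$subject, res$predictions$session)
  key_p <- paste(res_p$predictions$subject, res_p$predictions$session)
  expect_equal(res_p$predictions$predicted[match(key, key_p)],
               res$predictions$predicted, tolerance = 1e-6)
})

test_that("held-out outcomes cannot leak into their own predictions", {
  d <- make_realizable(n_subj = 8, noise = 0.3, seed = 6)
  res <- loso_predict(d$X, d$y, d$subject, d$session, pc_grid = 1:3,
                      baseline = FALSE)
  for (i in c(3, 17)) {
    y_mut <- d$y
    y_mut[i] <- y_mut[i] + 50
    res_mut <- loso_predict(d$X, y_mut, d$subject, d$session, pc_grid = 1:3,
                            baseline = FALSE)
    expect_equal(res_mut$predictions$predicted[i],
                 res$predictions$predicted[i], tolerance = 1e-9)
    expect_equal(res_mut$predictions$n_pcs[i], res$predictions$n_pcs[i])
  }
})

test_that("missing features are imputed from the training fold only", {
  d <- make_realizable(n_subj = 8, noise = 0.2, seed = 8)
  X <- d$X
  X[5, 2] <- NA
  X[10, ] <- NA
  res <- loso_predict(X, d$y, d$subject, d$session, pc_grid = 1:2,
                      baseline = FALSE)
  expect_false(any(is.na(res$predictions$predicted)))
})

test_that("feature importance normalizes to 1 and matches hand sums", {
  # single dominant loading: that feature gets weight 1, others 0
  res1 <- structure(list(folds = list(list(
    loadings = matrix(c(1, 0, 0), dimnames = list(c("a", "b", "c"), NULL)),
    coef = c(2), feature_names = c("a", "b", "c")))),
    class = "loso_result")
  imp1 <- feature_importance(res1)
  expect_equal(imp1$weight[imp1$feature == "a"], 1)
  expect_equal(sum(imp1$weight[imp1$feature != "a"]), 0)

  # two PCs, two folds, hand-computed weights
  L1 <- matrix(c(0.8, 0.6, 0.6, -0.8), 2, 2,
               dimnames = list(c("a", "b"), NULL))
  L2 <- matrix(c(0.6, 0.8, -0.8, 0.6), 2, 2,
               dimnames = list(c("a", "b"), NULL))
  res2 <- structure(list(folds = list(
    list(loadings = L1, coef = c(1, 2), feature_names = c("a", "b")),
    list(loadings = L2, coef = c(2, 1), feature_names = c("a", "b")))),
    class = "loso_result")
  imp2 <- feature_importance(res2, top_k = 2)
  # fold 1: a = .8*1 + .6*2 = 2.0 ; b = .6*1 + .8*2 = 2.2
  # fold 2: a = .6*2 + .8*1 = 2.0 ; b = .8*2 + .6*1 = 2.2
  w_hand <- c(a = 2.0, b = 2.2) / 2.2
  expect_equal(imp2$weight[match(c("a", "b"), imp2$feature)],
               unname(w_hand), tolerance = 1e-12)
  expect_equal(max(imp2$weight), 1)

  # no folds: empty table
  res0 <- structure(list(folds = list()), class = "loso_result")
  expect_equal(nrow(feature_importance(res0)), 0)
})

test_that("top-k selection keeps only the largest loadings per component", {
  L <- matrix(c(0.9, 0.3, 0.1), dimnames = list(c("a", "b", "c"), NULL))
  res <- structure(list(folds = list(list(loadings = L, coef = 1,
                                          feature_names = c("a", "b", "c")))),
                   class = "loso_result")
  imp <- feature_importance(res, top_k = 2)
  expect_equal(imp$weight[imp$feature == "c"], 0)
  expect_gt(imp$weight[imp$feature == "b"], 0)
})
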