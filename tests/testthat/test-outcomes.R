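toy_composites <- function(n = 20, seed = 2) {
  set.seed(seed)
  z <- rnorm(n)
  data.frame(verbal = 80 + 5 * z + rnorm(n), visual = 70 + 4 * z + rnorm(n),
             visual_motor = 40 + 2 * z + rnorm(n, sd = 0.5),
             reaction_time = 0.55 - 0.03 * z + 0.2 + 0.01 * rnorm(n),
             impulse_control = 8 - z + 0.5 * rnorm(n),
             symptom = 9 - z + 0.5 * rnorm(n))
}

test_that("rank-1 composites give a first PC explaining all variance", {
  z <- seq(-2, 2, length.out = 10)
  tbl <- data.frame(verbal = 80 + 5 * z, visual = 70 + 4 * z,
                    visual_motor = 40 + 2 * z,
                    reaction_time = 1 / (2 + z), impulse_control = 1 / (3 + z),
                    symptom = 1 / (4 + z))
  pc <- impact_pc(tbl)
  expect_equal(pc$var_explained[1], 1, tolerance = 1e-9)
  expect_true(all(pc$loadings[c("verbal", "visual", "visual_motor"), 1] > 0))
})

test_that("reciprocal transform and validation behave as specified", {
  tbl <- toy_composites()
  tbl$reaction_time <- c(0.5, rep(0.75, nrow(tbl) - 1))
  pcm <- impact_pc(tbl)
  # reciprocal scale: 0.5 s enters as 2.0, so the training mean matches
  expect_equal(unname(pcm$center["reaction_time"]),
               mean(1 / tbl$reaction_time))
  tbl$reaction_time[3] <- 0
  expect_error(impact_pc(tbl), "> 0")
  expect_error(impact_pc(toy_composites()[1, ]), "2 rows")
  expect_error(impact_pc(toy_composites()[-3]), "missing composite")
})

test_that("loadings match a brute-force eigendecomposition oracle", {
  tbl <- toy_composites(n = 6, seed = 5)
  pc <- impact_pc(tbl)
  # independent route: reciprocal, z-score, covariance eigenvectors
  x <- as.matrix(tbl)
  x[, 4:6] <- 1 / x[, 4:6]
  z <- scale(x)
  eig <- eigen(stats::cov(z))
  v1 <- eig$vectors[, 1]
  if (sum(v1[1:3]) < 0) v1 <- -v1
  expect_equal(unname(pc$loadings[, 1]), unname(v1), tolerance = 1e-8)
  expect_equal(pc$var_explained[1], eig$values[1] / sum(eig$values),
               tolerance = 1e-8)
  # orthonormal loadings, non-increasing variance fractions
  expect_equal(crossprod(pc$loadings), diag(ncol(x)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(pc$var_explained) <= 1e-12))
  # scores centred on training rows
  expect_equal(mean(pc$scores), 0, tolerance = 1e-10)
})

test_that("PC-ImPACT orientation and scaling invariance", {
  tbl <- toy_composites(n = 30, seed = 8)
  pc <- impact_pc(tbl)
  # a common worsening of the cognitive composites lowers PC-ImPACT
  worse <- tbl
  worse$verbal <- worse$verbal - 5
  worse$visual <- worse$visual - 5
  worse$visual_motor <- worse$visual_motor - 5
  worse$reaction_time <- worse$reaction_time + 0.1
  expect_true(all(predict(pc, worse) < predict(pc, tbl)))
  # invariance to positive rescaling of an input column
  tbl2 <- tbl
  tbl2$verbal <- tbl2$verbal * 7
  pc2 <- impact_pc(tbl2)
  expect_equal(pc2$scores, pc$scores, tolerance = 1e-6)
  # drop_symptom switch removes the symptom column
  pc3 <- impact_pc(tbl, drop_symptom = TRUE)
  expect_equal(nrow(pc3$loadings), 5)
})

test_that("subtractive normalization computes per-subject deltas", {
  tbl <- data.frame(subject_id = rep(c("a", "b"), each = 4),
                    session = rep(1:4, 2),
                    onsd_mm = c(4.0, 4.3, 4.5, 4.2, 3.8, 3.9, 4.4, 4.0))
  d <- subtractive_normalize(tbl)
  expect_equal(d$onsd_mm[1:4], c(0, 0.3, 0.5, 0.2))
  expect_equal(d$baseline, rep(c(TRUE, FALSE, FALSE, FALSE), 2))
  expect_true(all(d$onsd_mm[d$baseline] == 0))
  # idempotent on delta tables
  d2 <- subtractive_normalize(d[names(tbl)])
  expect_equal(d2$onsd_mm, d$onsd_mm)
  # eligible row count for SN fitting is rows - subjects
  expect_equal(sum(!d$baseline), nrow(tbl) - 2)
  # missing baseline errors and names the subject
  expect_error(subtractive_normalize(tbl[tbl$session > 1 |
                                           tbl$subject_id == "a", ]), "b")
})

test_that("changes summary recovers injected shifts and the null", {
  cfg0 <- cohort_config(impairment = c(0, 0, 0, 0), seed = 3)
  co0 <- simulate_cohort(cfg0)
  d0 <- subtractive_normalize(co0$outcomes[c("subject_id", "session",
                                             "onsd_mm")])
  cs0 <- changes_summary(d0)
  late <- cs0[!is.na(cs0$se) & cs0$session > 1, ]
  expect_true(all(abs(late$mean) < 3 * late$se))

  # single subject: means equal that subject's deltas
  one <- d0[d0$subject_id == "S01", ]
  cs1 <- changes_summary(one)
  expect_equal(cs1$mean[match(1:4, cs1$session)], one$onsd_mm)

  # injected +0.3 mm shift at session 4
  cfg <- cohort_config(impairment = c(0, 0, 0, 1), onsd_impairment = 0.3,
                       onsd_resid_sd = 0.2, seed = 3)
  co <- simulate_cohort(cfg)
  d <- subtractive_normalize(co$outcomes[c("subject_id", "session",
                                           "onsd_mm")])
  m4 <- mean(d$onsd_mm[d$session == 4])
  # delta noise is eps_s4 - eps_s1, hence sd sqrt(2) * 0.2
  expect_lt(abs(m4 - 0.3), 3 * sqrt(2) * 0.2 / sqrt(30))
})
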