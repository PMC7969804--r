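test_that("Q-ratio definition: rectangular profile gives 1, triangular 2", {
  # definitional identity on constructed velocity pulses
  dt <- 0.001
  rect <- rep(300, 50)                      # deg/s for 50 ms
  amp_rect <- sum(rect) * dt
  expect_equal(max(rect) * (50 / 1000) / amp_rect, 1)
  tri <- c(seq(0, 300, length.out = 26), seq(288, 12, length.out = 25))
  amp_tri <- sum(tri) * dt
  expect_equal(max(tri) * (51 / 1000) / amp_tri, 2, tolerance = 0.01)
  # and the simulator's profile family hits the same endpoints analytically
  expect_equal(q_ratio_of_shape(0), 1)
  expect_equal(q_ratio_of_shape(1), 2)
  expect_equal(q_ratio_of_shape(0.5), pi / 2)
})

test_that("ideal responder recovers its programmed latency and accuracy", {
  sched <- make_visually_guided_schedule(n_jumps = 30, seed = 11)
  p <- subject_params(latency_mean_ms = 200, latency_sd_ms = 0,
                      landing_noise_deg = 0, gaze_noise_deg = 0,
                      premature_rate = 0)
  sim <- simulate_trace(sched, p, seed = 3)
  pr <- preprocess_gaze(sim$trace)
  ev <- detect_saccades(pr)
  m <- compute_saccade_task_metrics(pr, sched, ev)
  expect_equal(median(m$steps$reaction_time_ms, na.rm = TRUE), 200,
               tolerance = 5 / 200)
  expect_lt(median(m$steps$landing_error_deg, na.rm = TRUE), 0.05)
  expect_true(all(m$steps$premature_count == 0))
  expect_true(all(m$steps$time_to_fixate_ms >= m$steps$reaction_time_ms,
                  na.rm = TRUE))
})

test_that("perfect tracking gives gain 1 with no catch-up saccades", {
  sched <- make_pursuit_schedule(n_cycles = 8)
  tms <- 0:(schedule_duration_ms(sched) - 1)
  tp <- schedule_target_position(sched, tms)
  x <- tp$x_deg
  y <- tp$y_deg
  for (i in which(is.na(x))) {
    x[i] <- x[i - 1]
    y[i] <- y[i - 1]
  }
  trace <- data.frame(time_ms = tms, x_deg = x, y_deg = y, valid = TRUE)
  attr(trace, "task") <- "pursuit"
  pr <- preprocess_gaze(trace)
  ev <- detect_saccades(pr)
  m <- compute_pursuit_metrics(pr, sched, ev)
  expect_equal(median(m$cycles$gain, na.rm = TRUE), 1, tolerance = 0.02)
  expect_equal(sum(m$cycles$catch_up_count), 0)

  # stationary eye: gain 0
  still <- data.frame(time_ms = tms, x_deg = 8, y_deg = 0, valid = TRUE)
  attr(still, "task") <- "pursuit"
  prs <- preprocess_gaze(still)
  ms <- compute_pursuit_metrics(prs, sched, detect_saccades(prs))
  expect_equal(median(ms$cycles$gain, na.rm = TRUE), 0, tolerance = 1e-6)
})

test_that("programmed pursuit gain and catch-up counts are recovered", {
  p <- subject_params(pursuit_gain = 0.8)
  sched <- make_pursuit_schedule()
  sim <- simulate_trace(sched, p, seed = 5)
  pr <- preprocess_gaze(sim$trace)
  ev <- detect_saccades(pr)
  m <- compute_pursuit_metrics(pr, sched, ev)
  expect_equal(median(m$cycles$gain, na.rm = TRUE), 0.8, tolerance = 0.05)
  expect_equal(sum(m$cycles$catch_up_count), nrow(sim$log))
})

test_that("anti-saccade error flags match the injected error log exactly", {
  sched <- make_antisaccade_schedule(seed = 1)
  for (ep in c(0, 0.3, 1)) {
    p <- subject_params(antisaccade_error_p = ep)
    sim <- simulate_trace(sched, p, seed = 9)
    pr <- preprocess_gaze(sim$trace)
    m <- compute_antisaccade_metrics(pr, sched, detect_saccades(pr))
    truth <- sim$log$direction_error[sim$log$kind == "antisaccade"]
    expect_equal(as.logical(m$cues$error), as.logical(truth))
    if (ep %in% c(0, 1)) {
      expect_equal(mean(m$cues$error), ep,
                   info = sprintf("error_p = %g", ep))
    }
  }
})

test_that("premature fixation breaks are counted from the ground truth", {
  sched <- make_antisaccade_schedule(seed = 2)
  p <- subject_params(premature_rate = 0.6, antisaccade_error_p = 0)
  sim <- simulate_trace(sched, p, seed = 12)
  pr <- preprocess_gaze(sim$trace)
  m <- compute_antisaccade_metrics(pr, sched, detect_saccades(pr))
  injected <- sum(sim$log$kind == "premature")
  expect_gt(injected, 0)
  expect_equal(sum(m$premature), injected)
})

test_that("aggregation follows the registry with median/count and SD channels", {
  expect_equal(median(c(180, 200, 240)), 200)
  p <- subject_params()
  sims <- simulate_session(p, seed = 30, n_cycles = 6, n_jumps = 12,
                           n_cues = 4)
  fv <- session_features(sims)
  reg <- feature_registry()
  expect_identical(names(fv), reg$name)
  expect_equal(length(fv), 2 * 12 + 2 + 2)  # 12 two-channel metrics + slopes
  expect_true(all(fv[reg$name[reg$channel == "dispersion"]] >= 0,
                  na.rm = TRUE))
  # deterministic: same traces, same features
  expect_identical(fv, session_features(sims))

  # constant per-trial metric -> zero dispersion channel
  cues <- data.frame(cue = 1:4, error = c(TRUE, TRUE, TRUE, TRUE),
                     reaction_time_ms = NA_real_)
  anti <- list(cues = cues, premature = c(0L, 0L, 0L, 0L), ms_slope = NA,
               fixation_dispersion = numeric(0))
  vgs <- list(steps = data.frame(step = 1:2, reaction_time_ms = c(200, 200),
                                 landing_error_deg = c(0.1, 0.1),
                                 time_to_fixate_ms = c(250, 250),
                                 q_ratio = c(1.5, 1.5),
                                 pm_vel_ratio = c(1.4, 1.4),
                                 premature_count = c(1L, 1L)),
              ms_slope = 2.5, fixation_dispersion = c(0.1, 0.1))
  pur <- list(cycles = data.frame(cycle = 1:2, gain = c(0.9, 0.9),
                                  catch_up_count = c(2L, 2L)),
              ms_slope = 2.4)
  out <- aggregate_feature_vector(vgs, pur, anti)
  expect_equal(unname(out["vgs_rt_sd"]), 0)
  expect_equal(unname(out["anti_error_sd"]), 0)
  expect_equal(unname(out["vgs_rt_med"]), 200)
  expect_equal(unname(out["vgs_premature_count"]), 2)
  expect_true(is.na(out["anti_rt_med"]))  # all-missing metric stays flagged
})

test_that("main-sequence slope is recovered from the ground-truth log", {
  p <- subject_params(ms_slope_ms_per_deg = 2.5, gaze_noise_deg = 0)
  sched <- make_visually_guided_schedule(n_jumps = 200, seed = 21)
  sim <- simulate_trace(sched, p, seed = 22)
  lg <- sim$log
  expect_gte(nrow(lg), 200)
  dur <- lg$offset_ms - lg$onset_ms
  sl <- unname(coef(lm(dur ~ lg$amplitude_deg))[2])
  expect_equal(sl, 2.5, tolerance = 0.05)
})
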