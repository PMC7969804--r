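#' Subject-level oculomotor parameters
#'
#' Bundles the behavioural quantities the trace simulator programs into a
#' gaze recording: saccade latency distribution, main-sequence coefficients
#' (duration = intercept + slope * amplitude), velocity-profile shape,
#' pursuit gain, anti-saccade error probability, premature-saccade rate,
#' landing noise and sensor noise.
#'
#' The velocity profile family is `v(t) ~ (0.5 * (1 - cos(2*pi*t/T)))^s`
#' with shape `s = vel_shape`; its Q-ratio (peak velocity x duration /
#' amplitude) is `sqrt(pi) * gamma(s + 1) / gamma(s + 1/2)`, i.e. 1 for the
#' rectangular profile (s = 0), 2 for the raised cosine (s = 1), and ~1.61
#' at the default s = 0.55, a physiological value.
#'
#' @param latency_mean_ms,latency_sd_ms saccade reaction-time distribution.
#' @param ms_slope_ms_per_deg,ms_intercept_ms main-sequence coefficients.
#' @param vel_shape velocity-profile shape (>= 0).
#' @param pursuit_gain eye/target speed ratio during pursuit (>= 0).
#' @param antisaccade_error_p probability of a prosaccade error in [0, 1].
#' @param premature_rate expected premature saccades per fixation period.
#' @param landing_noise_deg saccade endpoint SD (degrees).
#' @param gaze_noise_deg additive position noise SD (degrees).
#' @param subject_id identifier.
#' @return object of class `subject_params` (a validated list).
#' @export
subject_params <- function(latency_mean_ms = 200, latency_sd_ms = 30,
                           ms_slope_ms_per_deg = 2.5, ms_intercept_ms = 30,
                           vel_shape = 0.55, pursuit_gain = 0.95,
                           antisaccade_error_p = 0.2, premature_rate = 0.05,
                           landing_noise_deg = 0.3, gaze_noise_deg = 0.02,
                           subject_id = "s1") {
  p <- list(latency_mean_ms = latency_mean_ms, latency_sd_ms = latency_sd_ms,
            ms_slope_ms_per_deg = ms_slope_ms_per_deg,
            ms_intercept_ms = ms_intercept_ms, vel_shape = vel_shape,
            pursuit_gain = pursuit_gain,
            antisaccade_error_p = antisaccade_error_p,
            premature_rate = premature_rate,
            landing_noise_deg = landing_noise_deg,
            gaze_noise_deg = gaze_noise_deg,
            subject_id = as.character(subject_id))
  stop_if_not_scalar_num(p$latency_mean_ms, "latency_mean_ms", min = 60)
  stop_if_not_scalar_num(p$latency_sd_ms, "latency_sd_ms", min = 0)
  stop_if_not_scalar_num(p$ms_slope_ms_per_deg, "ms_slope_ms_per_deg",
                         min = 1e-9)
  stop_if_not_scalar_num(p$ms_intercept_ms, "ms_intercept_ms", min = 0)
  stop_if_not_scalar_num(p$vel_shape, "vel_shape", min = 0)
  stop_if_not_scalar_num(p$pursuit_gain, "pursuit_gain", min = 0)
  stop_if_not_scalar_num(p$antisaccade_error_p, "antisaccade_error_p",
                         min = 0, max = 1)
  stop_if_not_scalar_num(p$premature_rate, "premature_rate", min = 0)
  stop_if_not_scalar_num(p$landing_noise_deg, "landing_noise_deg", min = 0)
  stop_if_not_scalar_num(p$gaze_noise_deg, "gaze_noise_deg", min = 0)
  structure(p, class = "subject_params")
}

#' Q-ratio implied by a velocity-profile shape parameter
#' @param shape shape parameter (>= 0) of the `(0.5*(1-cos))^shape` family.
#' @return the profile's peak-to-mean velocity ratio.
#' @export
q_ratio_of_shape <- function(shape) {
  sqrt(pi) * gamma(shape + 1) / gamma(shape + 0.5)
}

# normalized displacement profile of one saccade: returns the per-ms
# cumulative fraction travelled and the peak velocity scale (1/ms units)
.sacc_profile <- function(dur_ms, shape) {
  t <- (seq_len(dur_ms) - 0.5) / dur_ms
  w <- (0.5 * (1 - cos(2 * pi * t)))^shape
  if (all(w == 0)) w <- rep(1, dur_ms)
  list(cum = cumsum(w) / sum(w), peak_frac = max(w) / sum(w))
}

# internal builder: accumulates saccade displacements onto a base position
# array and appends to the ground-truth log
.sacc_dur <- function(amp, params) {
  max(4L, as.integer(round(params$ms_intercept_ms +
                             params$ms_slope_ms_per_deg * amp)))
}

#' Simulate a gaze trace for a task schedule
#'
#' Generates a 1 kHz monocular gaze recording that performs the given task
#' with the programmed subject parameters, together with a ground-truth log
#' of every injected event (the oracle for detector and feature tests).
#' Saccades follow the main-sequence duration law with a unimodal velocity
#' profile; pursuit tracks the target at `pursuit_gain` with catch-up
#' saccades triggered when positional error exceeds a threshold;
#' anti-saccade trials err toward the cue with the programmed probability;
#' premature saccades are injected during fixation periods; one 150 ms
#' blink (invalid samples) is inserted per ~30 s, never overlapping a
#' logged event; Gaussian position noise is added throughout.
#'
#' @param schedule a `task_schedule`.
#' @param params a `subject_params`.
#' @param seed integer seed; the simulation is deterministic given it.
#' @param catchup_threshold_deg positional error triggering a catch-up
#'   saccade during pursuit (default 1.5).
#' @param catchup_delay_ms latency from trigger to catch-up onset
#'   (default 125).
#' @param blink_every_s expected blink spacing (default 30; `Inf` disables).
#' @param blink_duration_ms blink length (default 150).
#' @return object of class `gaze_sim`: list with `trace` (data frame
#'   `time_ms`, `x_deg`, `y_deg`, `valid`), `log` (ground-truth events:
#'   `kind`, `onset_ms`, `offset_ms`, `amplitude_deg`,
#'   `peak_velocity_deg_s`, `x0`, `y0`, `x1`, `y1`, `segment`,
#'   `direction_error`), `schedule`, `params`.
#' @export
simulate_trace <- function(schedule, params, seed = 1,
                           catchup_threshold_deg = 1.5,
                           catchup_delay_ms = 125,
                           blink_every_s = 30, blink_duration_ms = 150) {
  stopifnot(inherits(schedule, "task_schedule"),
            inherits(params, "subject_params"))
  n <- as.integer(round(schedule_duration_ms(schedule)))
  log0 <- data.frame(kind = character(0), onset_ms = numeric(0),
                     offset_ms = numeric(0), amplitude_deg = numeric(0),
                     peak_velocity_deg_s = numeric(0), x0 = numeric(0),
                     y0 = numeric(0), x1 = numeric(0), y1 = numeric(0),
                     segment = integer(0), direction_error = logical(0))
  if (n == 0) {
    trace <- data.frame(time_ms = numeric(0), x_deg = numeric(0),
                        y_deg = numeric(0), valid = logical(0))
    attr(trace, "task") <- schedule$task
    return(structure(list(trace = trace, log = log0, schedule = schedule,
                          params = params), class = "gaze_sim"))
  }
  sim <- with_seed(seed, {
    switch(schedule$task,
           pursuit = .sim_pursuit(schedule, params, n, catchup_threshold_deg,
                                  catchup_delay_ms),
           visually_guided = .sim_step_task(schedule, params, n,
                                            antisaccade = FALSE),
           antisaccade = .sim_step_task(schedule, params, n,
                                        antisaccade = TRUE))
  })
  x <- sim$x
  y <- sim$y
  log <- sim$log
  if (nrow(log) > 0) log <- log[order(log$onset_ms), , drop = FALSE]
  rownames(log) <- NULL
  valid <- rep(TRUE, n)
  # blinks: one per ~blink_every_s window, avoiding logged events
  if (is.finite(blink_every_s) && n > blink_every_s * 1000) {
    blinks <- with_seed(child_seed(seed, 777), {
      .place_blinks(n, log, blink_every_s * 1000, blink_duration_ms,
                    pad = 60)
    })
    for (b in blinks) {
      idx <- b:(b + blink_duration_ms - 1L)
      valid[idx] <- FALSE
      x[idx] <- NA_real_
      y[idx] <- NA_real_
    }
  }
  if (params$gaze_noise_deg > 0) {
    noise <- with_seed(child_seed(seed, 888), {
      cbind(rnorm(n, sd = params$gaze_noise_deg),
            rnorm(n, sd = params$gaze_noise_deg))
    })
    x <- x + noise[, 1]
    y <- y + noise[, 2]
  }
  trace <- data.frame(time_ms = 0:(n - 1L), x_deg = x, y_deg = y,
                      valid = valid)
  attr(trace, "task") <- schedule$task
  structure(list(trace = trace, log = log, schedule = schedule,
                 params = params), class = "gaze_sim")
}

#' @export
print.gaze_sim <- function(x, ...) {
  cat(sprintf("<gaze_sim: %s task, %.1f s, %d logged events>\n",
              x$schedule$task, nrow(x$trace) / 1000, nrow(x$log)))
  invisible(x)
}

# choose blink starts, one per window, not overlapping logged events
.place_blinks <- function(n, log, window_ms, dur_ms, pad) {
  starts <- integer(0)
  n_win <- floor(n / window_ms)
  for (wdx in seq_len(n_win)) {
    lo <- (wdx - 1) * window_ms + 1
    hi <- wdx * window_ms - dur_ms
    if (hi <= lo) next
    for (try in 1:50) {
      cand <- as.integer(runif(1, lo, hi))
      bad <- FALSE
      if (nrow(log) > 0) {
        bad <- any(log$onset_ms - pad < cand + dur_ms &
                     log$offset_ms + pad > cand)
      }
      if (!bad) {
        starts <- c(starts, cand)
        break
      }
    }
  }
  starts
}

# render one saccade onto position arrays (in place via returned arrays)
.add_saccade <- function(x, y, onset, dx, dy, params) {
  n <- length(x)
  amp <- sqrt(dx^2 + dy^2)
  dur <- .sacc_dur(amp, params)
  if (onset + dur > n) dur <- n - onset
  if (dur < 2) return(NULL)
  pr <- .sacc_profile(dur, params$vel_shape)
  idx <- onset:(onset + dur - 1L)
  x[idx] <- x[idx] + dx * pr$cum
  y[idx] <- y[idx] + dy * pr$cum
  if (onset + dur <= n) {
    tail_idx <- (onset + dur):n
    x[tail_idx] <- x[tail_idx] + dx
    y[tail_idx] <- y[tail_idx] + dy
  }
  list(x = x, y = y, dur = dur,
       peak_velocity = amp * pr$peak_frac * 1000)
}

# step-target tasks (visually guided and anti-saccade): the eye is
# stationary between saccades; all movement is saccadic
.sim_step_task <- function(schedule, params, n, antisaccade) {
  seg <- schedule$segments
  x <- rep(0, n)
  y <- rep(0, n)
  log <- list()
  add_event <- function(kind, onset, dur, amp, peak, x0, y0, x1, y1, sgm,
                        err = NA) {
    log[[length(log) + 1L]] <<- data.frame(
      kind = kind, onset_ms = onset - 1, offset_ms = onset - 1 + dur,
      amplitude_deg = amp, peak_velocity_deg_s = peak,
      x0 = x0, y0 = y0, x1 = x1, y1 = y1, segment = sgm,
      direction_error = err)
  }
  # current eye position tracked analytically
  if (!antisaccade) {
    cur_x <- seg$x_deg[1]
    x <- rep(cur_x, n)
  } else {
    cur_x <- 0
  }
  cur_y <- 0
  pending_offset <- 1L  # earliest sample index the next saccade may start at
  do_saccade <- function(kind, onset_idx, target_x, noise_sd, sgm, err = NA) {
    land <- target_x + if (noise_sd > 0) rnorm(1, sd = noise_sd) else 0
    dx <- land - cur_x
    if (abs(dx) < 1e-9) return(invisible(NULL))
    res <- .add_saccade(x, y, onset_idx, dx, 0, params)
    if (is.null(res)) return(invisible(NULL))
    add_event(kind, onset_idx, res$dur, abs(dx), res$peak_velocity,
              cur_x, cur_y, cur_x + dx, cur_y, sgm, err)
    x <<- res$x; y <<- res$y
    cur_x <<- cur_x + dx
    pending_offset <<- onset_idx + res$dur
    invisible(res)
  }
  for (j in seq_len(nrow(seg))) {
    onset <- seg$onset_ms[j] + 1L  # 1-based sample index
    offset <- seg$offset_ms[j]
    kind <- seg$kind[j]
    if (kind == "step_target" && j > 1L) {
      # premature (anticipatory) saccades right after the jump
      n_pre <- rpois(1, params$premature_rate)
      t_pre <- onset
      for (q in seq_len(min(n_pre, 1L))) {
        amp_pre <- runif(1, 1.2, 3) * sample(c(-1, 1), 1)
        t_pre <- onset + as.integer(runif(1, 5, 40))
        do_saccade("premature", t_pre, cur_x + amp_pre, 0, j)
      }
      lat <- max(90, rnorm(1, params$latency_mean_ms, params$latency_sd_ms))
      t_resp <- max(onset + as.integer(round(lat)), pending_offset + 10L)
      do_saccade("visually_guided", t_resp, seg$x_deg[j],
                 params$landing_noise_deg, j)
    } else if (kind == "central_fixation") {
      # return to centre after the previous cue
      if (abs(cur_x) > 0.5) {
        lat <- max(90, rnorm(1, params$latency_mean_ms, params$latency_sd_ms))
        t_ret <- max(onset + as.integer(round(lat)), pending_offset + 10L)
        do_saccade("return", t_ret, 0, params$landing_noise_deg, j)
      }
      # premature fixation breaks: out and back, completed before the cue
      n_pre <- rpois(1, params$premature_rate)
      win_lo <- max(onset + 150L, pending_offset + 200L)
      win_hi <- offset - 500L
      for (q in seq_len(min(n_pre, 1L))) {
        if (win_hi <= win_lo) break
        t_out <- as.integer(runif(1, win_lo, win_hi))
        amp_pre <- runif(1, 2.5, 4) * sample(c(-1, 1), 1)
        do_saccade("premature", t_out, amp_pre, 0, j)
        t_back <- pending_offset + as.integer(runif(1, 120, 200))
        do_saccade("return", t_back, 0, 0, j)
      }
    } else if (kind == "peripheral_cue") {
      err <- runif(1) < params$antisaccade_error_p
      goal <- if (err) seg$x_deg[j] else -seg$x_deg[j]
      lat <- max(90, rnorm(1, params$latency_mean_ms, params$latency_sd_ms))
      t_resp <- max(onset + as.integer(round(lat)), pending_offset + 10L)
      do_saccade("antisaccade", t_resp, goal, params$landing_noise_deg, j,
                 err = err)
    }
  }
  log <- if (length(log)) do.call(rbind, log) else
    data.frame(kind = character(0), onset_ms = numeric(0),
               offset_ms = numeric(0), amplitude_deg = numeric(0),
               peak_velocity_deg_s = numeric(0), x0 = numeric(0),
               y0 = numeric(0), x1 = numeric(0), y1 = numeric(0),
               segment = integer(0), direction_error = logical(0))
  list(x = x, y = y, log = log)
}

# smooth pursuit: gain-tracking between catch-up saccades
.sim_pursuit <- function(schedule, params, n, thresh, delay_ms) {
  seg <- schedule$segments
  tt <- schedule_target_position(schedule, 0:(n - 1L))
  x <- numeric(n)
  y <- numeric(n)
  log <- list()
  on_seg <- which(seg$kind == "pursuit_on")
  # eye starts on the target
  first_on <- seg$onset_ms[on_seg[1]] + 1L
  e_x <- tt$x_deg[first_on]
  e_y <- tt$y_deg[first_on]
  if (first_on > 1L) {
    x[1:(first_on - 1L)] <- e_x
    y[1:(first_on - 1L)] <- e_y
  }
  g <- params$pursuit_gain
  for (j in on_seg) {
    a <- seg$onset_ms[j] + 1L
    b <- seg$offset_ms[j]
    lat <- max(60, rnorm(1, params$latency_mean_ms, params$latency_sd_ms))
    t0 <- min(b, a + as.integer(round(lat)))
    # hold during the pursuit latency
    if (t0 > a) {
      x[a:(t0 - 1L)] <- e_x
      y[a:(t0 - 1L)] <- e_y
    }
    anchor <- t0
    ax <- e_x
    ay <- e_y
    while (anchor <= b) {
      idx <- anchor:b
      px <- ax + g * (tt$x_deg[idx] - tt$x_deg[anchor])
      py <- ay + g * (tt$y_deg[idx] - tt$y_deg[anchor])
      err <- sqrt((tt$x_deg[idx] - px)^2 + (tt$y_deg[idx] - py)^2)
      trig <- which(err >= thresh)[1]
      if (is.na(trig)) {
        x[idx] <- px
        y[idx] <- py
        e_x <- px[length(px)]
        e_y <- py[length(py)]
        break
      }
      s_on <- anchor + trig - 1L + as.integer(delay_ms)
      if (s_on >= b - 8L) {
        x[idx] <- px
        y[idx] <- py
        e_x <- px[length(px)]
        e_y <- py[length(py)]
        break
      }
      # pursue up to saccade onset
      pre <- anchor:(s_on - 1L)
      x[pre] <- px[seq_along(pre)]
      y[pre] <- py[seq_along(pre)]
      sx <- px[s_on - anchor + 1L]
      sy <- py[s_on - anchor + 1L]
      dx <- tt$x_deg[s_on] - sx
      dy <- tt$y_deg[s_on] - sy
      amp <- sqrt(dx^2 + dy^2)
      dur <- .sacc_dur(amp, params)
      if (s_on + dur > b) dur <- max(2L, b - s_on)
      pr <- .sacc_profile(dur, params$vel_shape)
      sidx <- s_on:(s_on + dur - 1L)
      # pursuit continues under the saccade
      base_x <- sx + g * (tt$x_deg[sidx] - tt$x_deg[s_on])
      base_y <- sy + g * (tt$y_deg[sidx] - tt$y_deg[s_on])
      x[sidx] <- base_x + dx * pr$cum
      y[sidx] <- base_y + dy * pr$cum
      log[[length(log) + 1L]] <- data.frame(
        kind = "catch_up", onset_ms = s_on - 1,
        offset_ms = s_on - 1 + dur, amplitude_deg = amp,
        peak_velocity_deg_s = amp * pr$peak_frac * 1000,
        x0 = sx, y0 = sy, x1 = sx + dx, y1 = sy + dy, segment = j,
        direction_error = NA)
      anchor <- s_on + dur
      ax <- x[anchor - 1L]
      ay <- y[anchor - 1L]
      e_x <- ax
      e_y <- ay
      if (anchor > b) break
    }
    # hold through the following gap
    if (j < nrow(seg)) {
      gap_a <- b + 1L
      gap_b <- if (j + 1L <= nrow(seg)) seg$offset_ms[j + 1L] else n
      gap_b <- min(gap_b, n)
      if (seg$kind[min(j + 1L, nrow(seg))] == "gap" && gap_a <= gap_b) {
        x[gap_a:gap_b] <- e_x
        y[gap_a:gap_b] <- e_y
      }
    }
  }
  log <- if (length(log)) do.call(rbind, log) else
    data.frame(kind = character(0), onset_ms = numeric(0),
               offset_ms = numeric(0), amplitude_deg = numeric(0),
               peak_velocity_deg_s = numeric(0), x0 = numeric(0),
               y0 = numeric(0), x1 = numeric(0), y1 = numeric(0),
               segment = integer(0), direction_error = logical(0))
  list(x = x, y = y, log = log)
}
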