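#' Oculomotor feature registry
#'
#' The fixed, documented ordering of the per-session feature vector. Each
#' base metric contributes a central channel (median for continuous
#' metrics, total count for event metrics) and a dispersion channel
#' (standard deviation across trials); per-task main-sequence slopes are
#' single central-channel features.
#'
#' @return data frame with columns `name`, `task`, `metric`, `channel`.
#' @export
feature_registry <- function() {
  reg <- rbind(
    c("vgs_rt_med", "visually_guided", "reaction_time", "central"),
    c("vgs_rt_sd", "visually_guided", "reaction_time", "dispersion"),
    c("vgs_landing_err_med", "visually_guided", "landing_error", "central"),
    c("vgs_landing_err_sd", "visually_guided", "landing_error", "dispersion"),
    c("vgs_ttf_med", "visually_guided", "time_to_fixate", "central"),
    c("vgs_ttf_sd", "visually_guided", "time_to_fixate", "dispersion"),
    c("vgs_q_ratio_med", "visually_guided", "q_ratio", "central"),
    c("vgs_q_ratio_sd", "visually_guided", "q_ratio", "dispersion"),
    c("vgs_pm_vel_ratio_med", "visually_guided", "peak_mean_velocity_ratio", "central"),
    c("vgs_pm_vel_ratio_sd", "visually_guided", "peak_mean_velocity_ratio", "dispersion"),
    c("vgs_premature_count", "visually_guided", "premature_saccades", "central"),
    c("vgs_premature_sd", "visually_guided", "premature_saccades", "dispersion"),
    c("vgs_ms_slope", "visually_guided", "main_sequence_slope", "central"),
    c("vgs_fixdisp_med", "visually_guided", "fixation_dispersion", "central"),
    c("vgs_fixdisp_sd", "visually_guided", "fixation_dispersion", "dispersion"),
    c("pur_gain_med", "pursuit", "pursuit_gain", "central"),
    c("pur_gain_sd", "pursuit", "pursuit_gain", "dispersion"),
    c("pur_catchup_count", "pursuit", "catch_up_saccades", "central"),
    c("pur_catchup_sd", "pursuit", "catch_up_saccades", "dispersion"),
    c("pur_ms_slope", "pursuit", "main_sequence_slope", "central"),
    c("anti_error_count", "antisaccade", "direction_errors", "central"),
    c("anti_error_sd", "antisaccade", "direction_errors", "dispersion"),
    c("anti_rt_med", "antisaccade", "reaction_time", "central"),
    c("anti_rt_sd", "antisaccade", "reaction_time", "dispersion"),
    c("anti_premature_count", "antisaccade", "premature_breaks", "central"),
    c("anti_premature_sd", "antisaccade", "premature_breaks", "dispersion"),
    c("anti_fixdisp_med", "antisaccade", "fixation_dispersion", "central"),
    c("anti_fixdisp_sd", "antisaccade", "fixation_dispersion", "dispersion"))
  out <- as.data.frame(reg, stringsAsFactors = FALSE)
  names(out) <- c("name", "task", "metric", "channel")
  out
}

# main-sequence slope: least squares of duration on amplitude
.ms_slope <- function(sac, min_amp = 1) {
  s <- sac[sac$amplitude_deg >= min_amp, , drop = FALSE]
  if (nrow(s) < 3 || sd(s$amplitude_deg) == 0) return(NA_real_)
  unname(coef(lm(duration_ms ~ amplitude_deg, data = s))[2])
}

#' Per-step metrics for the visually guided saccade task
#'
#' For each target jump: the first saccade with amplitude >= 1 deg starting
#' at least 80 ms after the jump is the response (reaction time, landing
#' error, Q-ratio, peak/mean velocity ratio); saccades starting within
#' 80 ms are counted premature; time-to-fixate is the latency until gaze
#' stays within 2 deg of the target for >= 100 ms. Steps without a
#' response are marked missing.
#'
#' @param prep `gaze_prep` for the trial.
#' @param schedule the `visually_guided` `task_schedule`.
#' @param events output of [detect_saccades()].
#' @param anticipatory_ms responsive/premature cutoff (default 80).
#' @return list with `steps` (one row per jump), `ms_slope`, and
#'   `fixation_dispersion` values.
#' @export
compute_saccade_task_metrics <- function(prep, schedule, events,
                                         anticipatory_ms = 80) {
  stopifnot(inherits(prep, "gaze_prep"), schedule$task == "visually_guided")
  seg <- schedule$segments
  sac <- events$saccades
  d <- prep$data
  steps <- list()
  if (nrow(seg) >= 2) {
    for (j in 2:nrow(seg)) {
      t0 <- seg$onset_ms[j]
      t1 <- seg$offset_ms[j]
      tx <- seg$x_deg[j]
      ty <- seg$y_deg[j]
      in_win <- sac$onset_ms >= t0 & sac$onset_ms < t1
      prem <- sum(in_win & sac$onset_ms < t0 + anticipatory_ms &
                    sac$amplitude_deg >= 1)
      resp_i <- which(in_win & sac$onset_ms >= t0 + anticipatory_ms &
                        sac$amplitude_deg >= 1)[1]
      if (is.na(resp_i)) {
        steps[[j - 1]] <- data.frame(step = j - 1, reaction_time_ms = NA_real_,
                                     landing_error_deg = NA_real_,
                                     time_to_fixate_ms = NA_real_,
                                     q_ratio = NA_real_,
                                     pm_vel_ratio = NA_real_,
                                     premature_count = prem)
        next
      }
      rs <- sac[resp_i, ]
      # time to fixate: gaze within 2 deg of target sustained >= 100 ms
      idx <- which(d$time_ms >= t0 & d$time_ms < t1)
      near <- !is.na(d$x_f[idx]) &
        sqrt((d$x_f[idx] - tx)^2 + (d$y_f[idx] - ty)^2) <= 2
      ttf <- NA_real_
      if (any(near)) {
        rr <- rle(near)
        re <- cumsum(rr$lengths)
        rsrt <- re - rr$lengths + 1L
        ok <- which(rr$values & rr$lengths >= 100)
        if (length(ok)) ttf <- d$time_ms[idx[rsrt[ok[1]]]] - t0
      }
      steps[[j - 1]] <- data.frame(
        step = j - 1, reaction_time_ms = rs$onset_ms - t0,
        landing_error_deg = sqrt((rs$x1 - tx)^2 + (rs$y1 - ty)^2),
        time_to_fixate_ms = ttf, q_ratio = rs$q_ratio,
        pm_vel_ratio = rs$peak_velocity_deg_s / rs$mean_velocity_deg_s,
        premature_count = prem)
    }
  }
  steps <- if (length(steps)) do.call(rbind, steps) else
    data.frame(step = integer(0), reaction_time_ms = numeric(0),
               landing_error_deg = numeric(0), time_to_fixate_ms = numeric(0),
               q_ratio = numeric(0), pm_vel_ratio = numeric(0),
               premature_count = integer(0))
  list(steps = steps, ms_slope = .ms_slope(sac),
       fixation_dispersion = events$fixations$dispersion_deg)
}

#' Per-cycle metrics for the smooth pursuit task
#'
#' Pursuit velocity gain is the median, over visible-target samples
#' excluding detected saccades and the first 100 ms of each cycle, of eye
#' speed divided by target speed; catch-up saccades are the detected
#' saccades inside pursuit-on epochs.
#'
#' @param prep `gaze_prep`.
#' @param schedule the `pursuit` `task_schedule`.
#' @param events output of [detect_saccades()].
#' @param settle_ms samples skipped at each cycle start (default 100).
#' @return list with `cycles` (per-cycle gain and catch-up count) and
#'   `ms_slope`.
#' @export
compute_pursuit_metrics <- function(prep, schedule, events, settle_ms = 100) {
  stopifnot(inherits(prep, "gaze_prep"), schedule$task == "pursuit")
  seg <- schedule$segments
  sac <- events$saccades
  d <- prep$data
  target_speed <- schedule$circle$radius_deg *
    schedule$circle$angular_speed_deg_s * pi / 180
  in_sacc <- rep(FALSE, nrow(d))
  if (nrow(sac) > 0) {
    for (k in seq_len(nrow(sac))) {
      in_sacc[d$time_ms >= sac$onset_ms[k] - 5 &
                d$time_ms < sac$offset_ms[k] + 5] <- TRUE
    }
  }
  on_idx <- which(seg$kind == "pursuit_on")
  cycles <- list()
  for (ci in seq_along(on_idx)) {
    j <- on_idx[ci]
    t0 <- seg$onset_ms[j]
    t1 <- seg$offset_ms[j]
    sel <- d$time_ms >= t0 + settle_ms & d$time_ms < t1 & !d$masked &
      !in_sacc & !is.na(d$speed)
    gain <- if (any(sel)) median(d$speed[sel] / target_speed) else NA_real_
    cu <- sum(sac$onset_ms >= t0 & sac$onset_ms < t1)
    cycles[[ci]] <- data.frame(cycle = ci, gain = gain,
                               catch_up_count = cu)
  }
  cycles <- if (length(cycles)) do.call(rbind, cycles) else
    data.frame(cycle = integer(0), gain = numeric(0),
               catch_up_count = integer(0))
  list(cycles = cycles, ms_slope = .ms_slope(sac))
}

#' Per-cue metrics for the anti-saccade task
#'
#' A cue is an error when the first saccade (amplitude >= 1 deg) after cue
#' onset moves horizontally toward the cue; reaction time is recorded for
#' correct anti-saccades. Premature fixation breaks are saccades leaving a
#' 2 deg central window during central fixation.
#'
#' @param prep `gaze_prep`.
#' @param schedule the `antisaccade` `task_schedule`.
#' @param events output of [detect_saccades()].
#' @return list with `cues` (per-cue error flag and RT), `premature` (per
#'   fixation-period break counts), `ms_slope`, `fixation_dispersion`.
#' @export
compute_antisaccade_metrics <- function(prep, schedule, events) {
  stopifnot(inherits(prep, "gaze_prep"), schedule$task == "antisaccade")
  seg <- schedule$segments
  sac <- events$saccades
  cues <- list()
  cue_idx <- which(seg$kind == "peripheral_cue")
  for (ci in seq_along(cue_idx)) {
    j <- cue_idx[ci]
    t0 <- seg$onset_ms[j]
    t1 <- seg$offset_ms[j]
    cue_x <- seg$x_deg[j]
    k <- which(sac$onset_ms >= t0 & sac$onset_ms < t1 &
                 sac$amplitude_deg >= 1)[1]
    if (is.na(k)) {
      cues[[ci]] <- data.frame(cue = ci, error = NA,
                               reaction_time_ms = NA_real_)
      next
    }
    err <- sign(sac$x1[k] - sac$x0[k]) == sign(cue_x)
    cues[[ci]] <- data.frame(
      cue = ci, error = err,
      reaction_time_ms = if (!err) sac$onset_ms[k] - t0 else NA_real_)
  }
  cues <- if (length(cues)) do.call(rbind, cues) else
    data.frame(cue = integer(0), error = logical(0),
               reaction_time_ms = numeric(0))
  fix_idx <- which(seg$kind == "central_fixation")
  prem <- integer(length(fix_idx))
  for (fi in seq_along(fix_idx)) {
    j <- fix_idx[fi]
    prem[fi] <- sum(sac$onset_ms >= seg$onset_ms[j] &
                      sac$onset_ms < seg$offset_ms[j] &
                      abs(sac$x0) < 2 & abs(sac$x1) >= 2)
  }
  list(cues = cues, premature = prem, ms_slope = .ms_slope(sac),
       fixation_dispersion = events$fixations$dispersion_deg)
}

#' Aggregate trial metrics into the per-session feature vector
#'
#' Continuous metrics contribute their median (central channel) and SD
#' (dispersion channel) across trials; event metrics their total count and
#' per-trial SD. Missing metrics stay `NA` (downstream models impute with
#' training-fold means). Ordering follows [feature_registry()].
#'
#' @param vgs output of [compute_saccade_task_metrics()].
#' @param pursuit output of [compute_pursuit_metrics()].
#' @param anti output of [compute_antisaccade_metrics()].
#' @return named numeric vector in registry order.
#' @export
aggregate_feature_vector <- function(vgs, pursuit, anti) {
  med <- function(x) if (sum(!is.na(x)) >= 1) median(x, na.rm = TRUE) else NA_real_
  dsd <- function(x) if (sum(!is.na(x)) >= 2) sd(x, na.rm = TRUE) else NA_real_
  st <- vgs$steps
  cy <- pursuit$cycles
  cu <- anti$cues
  out <- c(
    vgs_rt_med = med(st$reaction_time_ms),
    vgs_rt_sd = dsd(st$reaction_time_ms),
    vgs_landing_err_med = med(st$landing_error_deg),
    vgs_landing_err_sd = dsd(st$landing_error_deg),
    vgs_ttf_med = med(st$time_to_fixate_ms),
    vgs_ttf_sd = dsd(st$time_to_fixate_ms),
    vgs_q_ratio_med = med(st$q_ratio),
    vgs_q_ratio_sd = dsd(st$q_ratio),
    vgs_pm_vel_ratio_med = med(st$pm_vel_ratio),
    vgs_pm_vel_ratio_sd = dsd(st$pm_vel_ratio),
    vgs_premature_count = if (nrow(st)) sum(st$premature_count) else NA_real_,
    vgs_premature_sd = dsd(st$premature_count),
    vgs_ms_slope = vgs$ms_slope,
    vgs_fixdisp_med = med(vgs$fixation_dispersion),
    vgs_fixdisp_sd = dsd(vgs$fixation_dispersion),
    pur_gain_med = med(cy$gain),
    pur_gain_sd = dsd(cy$gain),
    pur_catchup_count = if (nrow(cy)) sum(cy$catch_up_count) else NA_real_,
    pur_catchup_sd = dsd(cy$catch_up_count),
    pur_ms_slope = pursuit$ms_slope,
    anti_error_count = if (sum(!is.na(cu$error))) sum(cu$error, na.rm = TRUE)
                       else NA_real_,
    anti_error_sd = dsd(as.numeric(cu$error)),
    anti_rt_med = med(cu$reaction_time_ms),
    anti_rt_sd = dsd(cu$reaction_time_ms),
    anti_premature_count = if (length(anti$premature)) sum(anti$premature)
                           else NA_real_,
    anti_premature_sd = dsd(anti$premature),
    anti_fixdisp_med = med(anti$fixation_dispersion),
    anti_fixdisp_sd = dsd(anti$fixation_dispersion))
  stopifnot(identical(names(out), feature_registry()$name))
  out
}

#' Full per-session feature extraction from simulated traces
#'
#' Convenience wrapper running preprocessing, detection, the three task
#' metric computations, and aggregation for one session's three trials.
#'
#' @param sims named list with elements `pursuit`, `visually_guided`,
#'   `antisaccade`, each a `gaze_sim` (or a list with `trace` and
#'   `schedule`).
#' @return named feature vector (see [feature_registry()]).
#' @export
session_features <- function(sims) {
  stopifnot(all(c("pursuit", "visually_guided", "antisaccade") %in%
                  names(sims)))
  one <- function(sim) {
    prep <- preprocess_gaze(sim$trace)
    prep$task <- sim$schedule$task
    list(prep = prep, events = detect_saccades(prep), sched = sim$schedule)
  }
  v <- one(sims$visually_guided)
  p <- one(sims$pursuit)
  a <- one(sims$antisaccade)
  aggregate_feature_vector(
    vgs = compute_saccade_task_metrics(v$prep, v$sched, v$events),
    pursuit = compute_pursuit_metrics(p$prep, p$sched, p$events),
    anti = compute_antisaccade_metrics(a$prep, a$sched, a$events))
}
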