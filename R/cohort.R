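#' Configuration of the synthetic longitudinal cohort
#'
#' Describes the study design the generator emulates: `n_subjects` athletes
#' followed over up to four sessions (pre-, early-, late-, post-season),
#' with a session-linked latent impairment that jointly shifts the
#' oculomotor parameters, ONSD and the ImPACT composites, subject random
#' intercepts in every outcome, and within-subject residual noise.
#'
#' @param n_subjects number of subjects (>= 2; default 30).
#' @param sessions_per_subject sessions per subject (1--4; >= 2 needed for
#'   subtractive-normalized analyses; default 4).
#' @param seed root seed; per-subject/per-session substreams are derived by
#'   counter so the cohort is invariant to evaluation order.
#' @param impairment latent impairment level per session (default
#'   `c(0, 0.25, 1, 0.5)`: none at baseline, peak late season, partial
#'   post-season recovery).
#' @param onsd_mean population baseline ONSD in mm (default 4.0).
#' @param onsd_subject_sd between-subject ONSD intercept SD (default 0.35).
#' @param onsd_resid_sd within-subject residual SD (default 0.15).
#' @param onsd_impairment ONSD shift in mm per unit impairment
#'   (default 0.30, i.e. +0.30 mm late season).
#' @param impact_mean,impact_subject_sd,impact_resid_sd,impact_impairment
#'   named numeric vectors over the six composites (defaults are typical
#'   raw-score scales; reaction time in seconds).
#' @param impact_cog_loading loadings of a standard-normal shared subject
#'   cognition factor onto the composites, reproducing the moderate
#'   inter-composite correlations (~0.3--0.5) that make the first
#'   principal component dominant; signs follow score direction (higher
#'   cognitive scores, lower reaction time / error counts are better).
#' @param param_impairment,param_subject_sd named lists of per-unit
#'   impairment shifts and between-subject SDs for [subject_params()]
#'   entries.
#' @param output `"features"` (default; analytic feature vectors with
#'   sampling noise, fast) or `"traces"` (full 1 kHz trace simulation per
#'   subject-session-task).
#' @return validated `cohort_config` object.
#' @export
cohort_config <- function(n_subjects = 30, sessions_per_subject = 4,
                          seed = 1,
                          impairment = c(0, 0.25, 1, 0.5),
                          onsd_mean = 4.0, onsd_subject_sd = 0.35,
                          onsd_resid_sd = 0.15, onsd_impairment = 0.30,
                          impact_mean = c(verbal = 85, visual = 75,
                                          visual_motor = 40,
                                          reaction_time = 0.55,
                                          impulse_control = 7, symptom = 8),
                          impact_subject_sd = c(verbal = 5, visual = 5,
                                                visual_motor = 3,
                                                reaction_time = 0.035,
                                                impulse_control = 1.2,
                                                symptom = 1.6),
                          impact_cog_loading = c(verbal = 5.5, visual = 5.5,
                                                 visual_motor = 3.5,
                                                 reaction_time = -0.035,
                                                 impulse_control = -0.25,
                                                 symptom = -0.3),
                          impact_resid_sd = c(verbal = 3, visual = 4,
                                              visual_motor = 2,
                                              reaction_time = 0.02,
                                              impulse_control = 1,
                                              symptom = 1.2),
                          impact_impairment = c(verbal = -3, visual = -4,
                                                visual_motor = -2,
                                                reaction_time = 0.04,
                                                impulse_control = 1.5,
                                                symptom = 2),
                          param_impairment = list(latency_mean_ms = 15,
                                                  pursuit_gain = -0.08,
                                                  antisaccade_error_p = 0.08,
                                                  premature_rate = 0.05,
                                                  landing_noise_deg = 0.15,
                                                  ms_slope_ms_per_deg = 0.2),
                          param_subject_sd = list(latency_mean_ms = 20,
                                                  pursuit_gain = 0.05,
                                                  antisaccade_error_p = 0.08,
                                                  premature_rate = 0.03,
                                                  landing_noise_deg = 0.1,
                                                  ms_slope_ms_per_deg = 0.3),
                          output = c("features", "traces")) {
  output <- match.arg(output)
  stop_if_not_scalar_num(n_subjects, "n_subjects", min = 2)
  stop_if_not_scalar_num(sessions_per_subject, "sessions_per_subject",
                         min = 1, max = 4)
  stopifnot(is.numeric(impairment), length(impairment) >= sessions_per_subject,
            all(names(impact_mean) == .IMPACT_COLS))
  cfg <- list(n_subjects = as.integer(n_subjects),
              sessions_per_subject = as.integer(sessions_per_subject),
              seed = seed, impairment = impairment,
              onsd_mean = onsd_mean, onsd_subject_sd = onsd_subject_sd,
              onsd_resid_sd = onsd_resid_sd,
              onsd_impairment = onsd_impairment,
              impact_mean = impact_mean,
              impact_subject_sd = impact_subject_sd,
              impact_cog_loading = impact_cog_loading,
              impact_resid_sd = impact_resid_sd,
              impact_impairment = impact_impairment,
              param_impairment = param_impairment,
              param_subject_sd = param_subject_sd,
              output = output)
  class(cfg) <- "cohort_config"
  cfg
}

# session-level subject parameters: population defaults + subject offsets +
# impairment shifts, clipped into their valid ranges
.session_params <- function(base_offsets, impair, cfg, subject_id) {
  p <- subject_params(subject_id = subject_id)
  for (nm in names(cfg$param_impairment)) {
    p[[nm]] <- p[[nm]] + base_offsets[[nm]] +
      impair * cfg$param_impairment[[nm]]
  }
  p$latency_mean_ms <- max(100, p$latency_mean_ms)
  p$pursuit_gain <- min(1.05, max(0.3, p$pursuit_gain))
  p$antisaccade_error_p <- min(1, max(0, p$antisaccade_error_p))
  p$premature_rate <- max(0, p$premature_rate)
  p$landing_noise_deg <- max(0.05, p$landing_noise_deg)
  p$ms_slope_ms_per_deg <- max(1, p$ms_slope_ms_per_deg)
  class(p) <- "subject_params"
  p
}

# analytic feature expectations implied by a parameter set, plus sampling
# noise emulating finite-trial estimation (counts drawn from their event
# distributions)
.analytic_features <- function(p, n_jumps = 78, n_cycles = 35,
                               n_cues = 18) {
  q <- q_ratio_of_shape(p$vel_shape)
  drift <- max(0, 1 - p$pursuit_gain) * 16.76
  catchup_mean <- n_cycles * (1 + drift * 1.4 / 1.5)
  expected <- c(
    vgs_rt_med = p$latency_mean_ms,
    vgs_rt_sd = p$latency_sd_ms,
    vgs_landing_err_med = 0.674 * p$landing_noise_deg,
    vgs_landing_err_sd = 0.6 * p$landing_noise_deg,
    vgs_ttf_med = p$latency_mean_ms + 45,
    vgs_ttf_sd = 1.2 * p$latency_sd_ms,
    vgs_q_ratio_med = q,
    vgs_q_ratio_sd = 0.03 + 0.02 * p$vel_shape,
    vgs_pm_vel_ratio_med = 0.97 * q,
    vgs_pm_vel_ratio_sd = 0.03 + 0.02 * p$vel_shape,
    vgs_premature_count = NA,  # drawn below
    vgs_premature_sd = NA,
    vgs_ms_slope = p$ms_slope_ms_per_deg,
    vgs_fixdisp_med = 1.5 * p$gaze_noise_deg + 0.02,
    vgs_fixdisp_sd = 0.5 * p$gaze_noise_deg + 0.01,
    pur_gain_med = p$pursuit_gain,
    pur_gain_sd = 0.02 + 0.5 * p$gaze_noise_deg,
    pur_catchup_count = NA,
    pur_catchup_sd = NA,
    pur_ms_slope = p$ms_slope_ms_per_deg,
    anti_error_count = NA,
    anti_error_sd = NA,
    anti_rt_med = p$latency_mean_ms + 25,
    anti_rt_sd = 1.1 * p$latency_sd_ms,
    anti_premature_count = NA,
    anti_premature_sd = NA,
    anti_fixdisp_med = 1.5 * p$gaze_noise_deg + 0.02,
    anti_fixdisp_sd = 0.5 * p$gaze_noise_deg + 0.01)
  se <- c(vgs_rt_med = p$latency_sd_ms / sqrt(n_jumps),
          vgs_rt_sd = p$latency_sd_ms / sqrt(2 * n_jumps),
          vgs_landing_err_med = 0.08 * p$landing_noise_deg + 0.01,
          vgs_landing_err_sd = 0.08 * p$landing_noise_deg + 0.01,
          vgs_ttf_med = 1.5 * p$latency_sd_ms / sqrt(n_jumps),
          vgs_ttf_sd = 2 * p$latency_sd_ms / sqrt(2 * n_jumps),
          vgs_q_ratio_med = 0.01, vgs_q_ratio_sd = 0.005,
          vgs_pm_vel_ratio_med = 0.01, vgs_pm_vel_ratio_sd = 0.005,
          vgs_premature_count = 0, vgs_premature_sd = 0.02,
          vgs_ms_slope = 0.06, vgs_fixdisp_med = 0.005,
          vgs_fixdisp_sd = 0.003,
          pur_gain_med = 0.012, pur_gain_sd = 0.006,
          pur_catchup_count = 0, pur_catchup_sd = 0.3,
          pur_ms_slope = 0.12,
          anti_error_count = 0, anti_error_sd = 0.04,
          anti_rt_med = 1.8 * p$latency_sd_ms / sqrt(n_cues),
          anti_rt_sd = 2 * p$latency_sd_ms / sqrt(2 * n_cues),
          anti_premature_count = 0, anti_premature_sd = 0.05,
          anti_fixdisp_med = 0.006, anti_fixdisp_sd = 0.004)
  f <- expected + rnorm(length(expected), sd = se)
  f["vgs_premature_count"] <- rpois(1, n_jumps * p$premature_rate)
  f["vgs_premature_sd"] <- abs(f["vgs_premature_sd"]) +
    sqrt(max(p$premature_rate, 1e-4))
  f["pur_catchup_count"] <- rpois(1, catchup_mean)
  f["pur_catchup_sd"] <- abs(f["pur_catchup_sd"]) +
    sqrt(catchup_mean / n_cycles)
  pe <- p$antisaccade_error_p
  f["anti_error_count"] <- rbinom(1, n_cues, pe)
  f["anti_error_sd"] <- abs(f["anti_error_sd"]) + sqrt(pe * (1 - pe))
  f["anti_premature_count"] <- rpois(1, n_cues * p$premature_rate)
  f["anti_premature_sd"] <- abs(f["anti_premature_sd"]) +
    sqrt(max(p$premature_rate, 1e-4))
  f
}

#' Simulate a synthetic longitudinal cohort
#'
#' For each subject a random outcome intercept and subject-specific
#' oculomotor parameters are drawn; per session, the latent impairment
#' shifts both the parameters and the outcomes, so that
#' `ONSD[i,s] = mu + subject_i + effect_s + noise` (and analogously for the
#' ImPACT composites), while the oculomotor feature vector reflects the
#' same impairment through the parameter shifts. Deterministic given the
#' config seed.
#'
#' @param config a [cohort_config()].
#' @return object of class `cohort_sim`: list with `outcomes` (data frame
#'   `subject_id`, `session`, `onsd_mm`, the six composites), `features`
#'   (numeric matrix, rows aligned with `outcomes`, columns per
#'   [feature_registry()]; `NULL` in trace mode), `params_true` (per-row
#'   true parameter values and impairment), and in trace mode `sims`
#'   (nested list `sims[[subject]][[session]]` of the three `gaze_sim`
#'   objects).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  ns <- config$n_subjects
  sessions <- seq_len(config$sessions_per_subject)
  rows <- list()
  feats <- list()
  ptrue <- list()
  sims <- if (config$output == "traces") vector("list", ns) else NULL
  for (i in seq_len(ns)) {
    sid <- sprintf("S%02d", i)
    sub <- with_seed(child_seed(config$seed, i * 101), {
      cog <- rnorm(1)  # shared cognition factor across composites
      list(onsd_int = rnorm(1, sd = config$onsd_subject_sd),
           impact_int = rnorm(length(.IMPACT_COLS)) *
             config$impact_subject_sd + cog * config$impact_cog_loading,
           par_off = lapply(config$param_subject_sd,
                            function(s) rnorm(1, sd = s)))
    })
    if (config$output == "traces") sims[[i]] <- vector("list",
                                                       length(sessions))
    for (s in sessions) {
      impair <- config$impairment[s]
      p <- .session_params(sub$par_off, impair, config, sid)
      drawn <- with_seed(child_seed(config$seed, i * 101 + s), {
        onsd <- config$onsd_mean + sub$onsd_int +
          impair * config$onsd_impairment +
          rnorm(1, sd = config$onsd_resid_sd)
        comp <- config$impact_mean + sub$impact_int +
          impair * config$impact_impairment +
          rnorm(length(.IMPACT_COLS)) * config$impact_resid_sd
        comp <- pmax(comp, c(1, 1, 1, 0.2, 0.5, 0.5))
        fv <- if (config$output == "features") .analytic_features(p) else NULL
        list(onsd = onsd, comp = comp, fv = fv)
      })
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sid, session = s, onsd_mm = drawn$onsd,
        verbal = drawn$comp[["verbal"]], visual = drawn$comp[["visual"]],
        visual_motor = drawn$comp[["visual_motor"]],
        reaction_time = drawn$comp[["reaction_time"]],
        impulse_control = drawn$comp[["impulse_control"]],
        symptom = drawn$comp[["symptom"]])
      ptrue[[length(ptrue) + 1L]] <- data.frame(
        subject_id = sid, session = s, impairment = impair,
        latency_mean_ms = p$latency_mean_ms,
        pursuit_gain = p$pursuit_gain,
        antisaccade_error_p = p$antisaccade_error_p,
        premature_rate = p$premature_rate,
        landing_noise_deg = p$landing_noise_deg,
        ms_slope_ms_per_deg = p$ms_slope_ms_per_deg)
      if (config$output == "features") {
        feats[[length(feats) + 1L]] <- drawn$fv
      } else {
        trial_seed <- child_seed(config$seed, i * 101 + s)
        sims[[i]][[s]] <- list(
          pursuit = simulate_trace(make_pursuit_schedule(), p,
                                   seed = child_seed(trial_seed, 1)),
          visually_guided = simulate_trace(
            make_visually_guided_schedule(seed = 11), p,
            seed = child_seed(trial_seed, 2)),
          antisaccade = simulate_trace(make_antisaccade_schedule(seed = 13),
                                       p, seed = child_seed(trial_seed, 3)))
      }
    }
  }
  outcomes <- do.call(rbind, rows)
  features <- if (config$output == "features") do.call(rbind, feats) else NULL
  if (!is.null(features)) {
    rownames(features) <- paste0(outcomes$subject_id, "_", outcomes$session)
  }
  structure(list(outcomes = outcomes, features = features,
                 params_true = do.call(rbind, ptrue),
                 sims = sims, config = config),
            class = "cohort_sim")
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf("<cohort_sim: %d subjects x %d sessions (%s mode)>\n",
              x$config$n_subjects, x$config$sessions_per_subject,
              x$config$output))
  invisible(x)
}

#' Write the cohort outcome table as CSV
#'
#' Schema: `subject_id,session,onsd_mm,verbal,visual,visual_motor,`
#' `reaction_time,impulse_control,symptom`.
#'
#' @param cohort a `cohort_sim`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort$outcomes, path, row.names = FALSE)
  invisible(path)
}
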