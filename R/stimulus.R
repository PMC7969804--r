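#' @useDynLib oculoseason, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median sd coef lm rnorm runif rpois rbinom prcomp
#'   cor cor.test t.test cooks.distance pf predict
NULL

# screen extent (degrees of visual angle) used to validate target positions
.SCREEN_X_DEG <- 24
.SCREEN_Y_DEG <- 16

#' Task schedule objects
#'
#' A `task_schedule` describes one eye-tracking trial as an ordered set of
#' contiguous target segments on a screen viewed from 60 cm, sampled at
#' 1000 Hz. Positions are degrees of visual angle, origin at screen centre,
#' +x right, +y up; times are ms from trial start.
#'
#' @param task one of `"pursuit"`, `"visually_guided"`, `"antisaccade"`.
#' @param segments data frame with columns `onset_ms`, `offset_ms`, `x_deg`,
#'   `y_deg`, `kind` (one of `pursuit_on`, `gap`, `step_target`,
#'   `central_fixation`, `peripheral_cue`). Segments must be contiguous and
#'   non-overlapping.
#' @param circle for pursuit schedules, a list with `radius_deg`,
#'   `angular_speed_deg_s` and per-segment onset phases (degrees).
#' @return an object of class `task_schedule`.
#' @keywords internal
new_task_schedule <- function(task, segments, circle = NULL) {
  task <- match.arg(task, c("pursuit", "visually_guided", "antisaccade"))
  stopifnot(is.data.frame(segments),
            all(c("onset_ms", "offset_ms", "x_deg", "y_deg", "kind") %in%
                  names(segments)))
  if (nrow(segments) > 0) {
    if (any(segments$offset_ms <= segments$onset_ms)) {
      stop("every segment must have offset_ms > onset_ms", call. = FALSE)
    }
    if (nrow(segments) > 1) {
      gaps <- segments$onset_ms[-1] - segments$offset_ms[-nrow(segments)]
      if (any(abs(gaps) > 1e-9)) {
        stop("segments must be contiguous (offset k == onset k+1)",
             call. = FALSE)
      }
    }
    pos <- segments[segments$kind != "gap", c("x_deg", "y_deg")]
    if (any(!is.finite(as.matrix(pos)))) {
      stop("target positions must be finite", call. = FALSE)
    }
    if (any(abs(pos$x_deg) > .SCREEN_X_DEG) || any(abs(pos$y_deg) > .SCREEN_Y_DEG)) {
      stop("target positions exceed screen bounds", call. = FALSE)
    }
  }
  structure(list(task = task,
                 segments = segments,
                 viewing_distance_cm = 60,
                 sample_rate_hz = 1000,
                 circle = circle),
            class = "task_schedule")
}

#' @export
print.task_schedule <- function(x, ...) {
  cat(sprintf("<task_schedule: %s>\n", x$task))
  cat(sprintf("  segments: %d, duration: %.1f s, %d Hz, %g cm viewing\n",
              nrow(x$segments), schedule_duration_ms(x) / 1000,
              x$sample_rate_hz, x$viewing_distance_cm))
  invisible(x)
}

#' Total duration of a schedule in ms
#' @param schedule a `task_schedule`.
#' @return scalar duration (0 for an empty schedule).
#' @export
schedule_duration_ms <- function(schedule) {
  stopifnot(inherits(schedule, "task_schedule"))
  if (nrow(schedule$segments) == 0) 0 else max(schedule$segments$offset_ms)
}

#' Smooth-pursuit task schedule
#'
#' The target travels at constant speed around a circle, visible for
#' `on_duration_s` then blanked for `gap_s`, repeated `n_cycles` times. The
#' circle phase is frozen during gaps, so the target reappears where it
#' vanished and the trajectory is continuous across cycles.
#'
#' @param n_cycles number of on/gap cycles (default 35).
#' @param on_duration_s visible duration per cycle in seconds (default 1.5).
#' @param gap_s blank duration per cycle in seconds (default 0.5).
#' @param radius_deg circle radius in degrees (default 8).
#' @param angular_speed_deg_s angular phase speed in deg/s (default 120,
#'   i.e. tangential target speed `radius * speed * pi/180` ~ 16.8 deg/s).
#' @return a `task_schedule` with `n_cycles` `pursuit_on` segments
#'   alternating with `gap` segments.
#' @examples
#' sched <- make_pursuit_schedule()
#' sum(sched$segments$kind == "pursuit_on")  # 35
#' @export
make_pursuit_schedule <- function(n_cycles = 35, on_duration_s = 1.5,
                                  gap_s = 0.5, radius_deg = 8,
                                  angular_speed_deg_s = 120) {
  stop_if_not_scalar_num(n_cycles, "n_cycles", min = 0)
  if (n_cycles > 0) {
    stop_if_not_scalar_num(on_duration_s, "on_duration_s", min = 1e-9)
    stop_if_not_scalar_num(gap_s, "gap_s", min = 1e-9)
  }
  stop_if_not_scalar_num(radius_deg, "radius_deg", min = 0.1,
                         max = .SCREEN_Y_DEG)
  stop_if_not_scalar_num(angular_speed_deg_s, "angular_speed_deg_s",
                         min = 1e-9)
  n_cycles <- as.integer(n_cycles)
  if (n_cycles == 0) {
    seg <- data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                      x_deg = numeric(0), y_deg = numeric(0),
                      kind = character(0))
    return(new_task_schedule("pursuit", seg,
                             circle = list(radius_deg = radius_deg,
                                           angular_speed_deg_s = angular_speed_deg_s,
                                           phase_onset_deg = numeric(0))))
  }
  on_ms <- on_duration_s * 1000
  gap_ms <- gap_s * 1000
  cyc_ms <- on_ms + gap_ms
  onset <- rep((seq_len(n_cycles) - 1) * cyc_ms, each = 2) +
    rep(c(0, on_ms), n_cycles)
  offset <- onset + rep(c(on_ms, gap_ms), n_cycles)
  kind <- rep(c("pursuit_on", "gap"), n_cycles)
  # phase advances only while the target is visible
  phase_on <- (seq_len(n_cycles) - 1) * angular_speed_deg_s * on_duration_s
  phase <- rep(phase_on, each = 2)
  phase[seq(2, 2 * n_cycles, by = 2)] <- phase_on + angular_speed_deg_s * on_duration_s
  x <- radius_deg * cospi(phase / 180)
  y <- radius_deg * sinpi(phase / 180)
  x[kind == "gap"] <- NA_real_
  y[kind == "gap"] <- NA_real_
  seg <- data.frame(onset_ms = onset, offset_ms = offset,
                    x_deg = x, y_deg = y, kind = kind)
  new_task_schedule("pursuit", seg,
                    circle = list(radius_deg = radius_deg,
                                  angular_speed_deg_s = angular_speed_deg_s,
                                  phase_onset_deg = phase))
}

#' Default target positions for the visually guided saccade task
#'
#' Ten unique horizontal eccentricities: centre (0, treated as the central
#' target with a longer dwell), +/-2.5, +/-5, +/-7.5, +/-10, and +12.5 deg.
#' @return numeric vector of length 10.
#' @export
vgs_default_positions <- function() {
  c(0, -2.5, 2.5, -5, 5, -7.5, 7.5, -10, 10, 12.5)
}

#' Visually guided saccade task schedule
#'
#' The target jumps instantaneously between unique horizontal positions;
#' peripheral targets dwell 1.5 s, the central (0 deg) target 2 s. The jump
#' sequence is a seeded random walk whose first `length(positions_deg)`
#' entries are a permutation of all positions, so every position is used at
#' least once whenever `n_jumps + 1 >= length(positions_deg)`.
#'
#' @param positions_deg unique horizontal target positions in degrees
#'   (default [vgs_default_positions()]).
#' @param n_jumps number of target jumps (default 78; segments = jumps + 1).
#' @param peripheral_dwell_s dwell for non-central targets (default 1.5 s).
#' @param central_dwell_s dwell for the 0-deg target (default 2 s).
#' @param seed integer seed fixing the jump sequence.
#' @return a `task_schedule` with `n_jumps + 1` `step_target` segments in
#'   which consecutive segments always differ in position and `y = 0`
#'   throughout.
#' @examples
#' sched <- make_visually_guided_schedule(seed = 1)
#' nrow(sched$segments) - 1L  # 78 jumps
#' @export
make_visually_guided_schedule <- function(positions_deg = vgs_default_positions(),
                                          n_jumps = 78,
                                          peripheral_dwell_s = 1.5,
                                          central_dwell_s = 2,
                                          seed = 1) {
  positions_deg <- unique(as.numeric(positions_deg))
  stop_if_not_scalar_num(n_jumps, "n_jumps", min = 0)
  stop_if_not_scalar_num(peripheral_dwell_s, "peripheral_dwell_s", min = 1e-9)
  stop_if_not_scalar_num(central_dwell_s, "central_dwell_s", min = 1e-9)
  n_jumps <- as.integer(n_jumps)
  if (length(positions_deg) < 2 && n_jumps > 0) {
    stop("need at least 2 unique positions to jump between", call. = FALSE)
  }
  n_seg <- n_jumps + 1L
  seq_pos <- with_seed(seed, {
    npos <- length(positions_deg)
    if (n_seg <= npos) {
      sample(positions_deg, n_seg)
    } else {
      out <- numeric(n_seg)
      out[1:npos] <- sample(positions_deg)
      for (k in (npos + 1L):n_seg) {
        out[k] <- sample(positions_deg[positions_deg != out[k - 1L]], 1L)
      }
      out
    }
  })
  dwell <- ifelse(seq_pos == 0, central_dwell_s, peripheral_dwell_s) * 1000
  offset <- cumsum(dwell)
  seg <- data.frame(onset_ms = c(0, offset[-n_seg]), offset_ms = offset,
                    x_deg = seq_pos, y_deg = 0,
                    kind = "step_target")
  new_task_schedule("visually_guided", seg)
}

#' Anti-saccade task schedule
#'
#' Central fixation periods of 1--4 s (drawn uniformly, seeded) alternate
#' with 1 s peripheral cues at +/-`cue_eccentricity_deg`, balanced left and
#' right. The correct response is a saccade to the mirror position of the
#' cue; the cue side sequence is seeded and balanced.
#'
#' @param n_peripheral number of peripheral cues, must be even (default 18).
#' @param cue_duration_s cue dwell in seconds (default 1).
#' @param fixation_choices_s candidate central fixation durations in seconds
#'   (default `c(1, 2, 3, 4)`).
#' @param cue_eccentricity_deg absolute cue position (default 10 deg).
#' @param seed integer seed fixing sides and fixation durations.
#' @return a `task_schedule` alternating `central_fixation` and
#'   `peripheral_cue` segments with exactly `n_peripheral / 2` cues per side.
#' @examples
#' sched <- make_antisaccade_schedule(seed = 1)
#' table(sign(sched$segments$x_deg[sched$segments$kind == "peripheral_cue"]))
#' @export
make_antisaccade_schedule <- function(n_peripheral = 18, cue_duration_s = 1,
                                      fixation_choices_s = c(1, 2, 3, 4),
                                      cue_eccentricity_deg = 10, seed = 1) {
  stop_if_not_scalar_num(n_peripheral, "n_peripheral", min = 0)
  n_peripheral <- as.integer(n_peripheral)
  if (n_peripheral %% 2L != 0L) {
    stop("`n_peripheral` must be even (equal left/right cue counts)",
         call. = FALSE)
  }
  stop_if_not_scalar_num(cue_duration_s, "cue_duration_s", min = 1e-9)
  stopifnot(is.numeric(fixation_choices_s), length(fixation_choices_s) >= 1,
            all(fixation_choices_s > 0))
  stop_if_not_scalar_num(cue_eccentricity_deg, "cue_eccentricity_deg",
                         min = 0.1, max = .SCREEN_X_DEG)
  if (n_peripheral == 0L) {
    seg <- data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                      x_deg = numeric(0), y_deg = numeric(0),
                      kind = character(0))
    return(new_task_schedule("antisaccade", seg))
  }
  draws <- with_seed(seed, list(
    sides = sample(rep(c(-1, 1), n_peripheral / 2L)),
    fix_s = sample(fixation_choices_s, n_peripheral, replace = TRUE)
  ))
  dur <- as.vector(rbind(draws$fix_s * 1000, rep(cue_duration_s * 1000,
                                                 n_peripheral)))
  x <- as.vector(rbind(rep(0, n_peripheral),
                       draws$sides * cue_eccentricity_deg))
  kind <- rep(c("central_fixation", "peripheral_cue"), n_peripheral)
  offset <- cumsum(dur)
  seg <- data.frame(onset_ms = c(0, offset[-length(offset)]),
                    offset_ms = offset, x_deg = x, y_deg = 0, kind = kind)
  new_task_schedule("antisaccade", seg)
}

#' Target position at arbitrary times
#'
#' Evaluates the target trajectory of a schedule at the requested times.
#' During pursuit gaps the target is off and `NA` is returned.
#'
#' @param schedule a `task_schedule`.
#' @param time_ms numeric vector of times (ms from trial start).
#' @return data frame with `time_ms`, `x_deg`, `y_deg`.
#' @export
schedule_target_position <- function(schedule, time_ms) {
  stopifnot(inherits(schedule, "task_schedule"), is.numeric(time_ms))
  seg <- schedule$segments
  x <- rep(NA_real_, length(time_ms))
  y <- rep(NA_real_, length(time_ms))
  if (nrow(seg) > 0) {
    idx <- findInterval(time_ms, seg$onset_ms)
    ok <- idx >= 1 & time_ms < max(seg$offset_ms) & time_ms >= 0
    okn <- which(ok)
    si <- idx[okn]
    kind <- seg$kind[si]
    stat <- kind %in% c("step_target", "central_fixation", "peripheral_cue")
    x[okn[stat]] <- seg$x_deg[si[stat]]
    y[okn[stat]] <- seg$y_deg[si[stat]]
    purs <- which(kind == "pursuit_on")
    if (length(purs)) {
      cc <- schedule$circle
      ph <- cc$phase_onset_deg[si[purs]] +
        cc$angular_speed_deg_s * (time_ms[okn[purs]] - seg$onset_ms[si[purs]]) / 1000
      x[okn[purs]] <- cc$radius_deg * cospi(ph / 180)
      y[okn[purs]] <- cc$radius_deg * sinpi(ph / 180)
    }
  }
  data.frame(time_ms = time_ms, x_deg = x, y_deg = y)
}

#' Read/write a schedule as CSV
#'
#' The on-disk format is the segment table
#' (`onset_ms,offset_ms,x_deg,y_deg,kind`); pursuit circle parameters are
#' carried in commented header lines.
#'
#' @param schedule a `task_schedule`.
#' @param path file path.
#' @return `write_schedule_csv` returns `path` invisibly;
#'   `read_schedule_csv` a `task_schedule`.
#' @export
write_schedule_csv <- function(schedule, path) {
  stopifnot(inherits(schedule, "task_schedule"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# task=%s", schedule$task), con)
  if (!is.null(schedule$circle)) {
    writeLines(sprintf("# radius_deg=%.10g angular_speed_deg_s=%.10g",
                       schedule$circle$radius_deg,
                       schedule$circle$angular_speed_deg_s), con)
  }
  utils::write.csv(schedule$segments, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) {
  hdr <- readLines(path, n = 2)
  task <- sub("^# task=", "", hdr[1])
  seg <- utils::read.csv(path, comment.char = "#",
                         colClasses = c(kind = "character"))
  circle <- NULL
  if (task == "pursuit") {
    m <- regmatches(hdr[2], regexec(
      "radius_deg=([0-9.eE+-]+) angular_speed_deg_s=([0-9.eE+-]+)", hdr[2]))[[1]]
    radius <- as.numeric(m[2]); omega <- as.numeric(m[3])
    on <- seg$kind == "pursuit_on"
    phase <- rep(NA_real_, nrow(seg))
    phase[on] <- (atan2(seg$y_deg[on], seg$x_deg[on]) * 180 / pi) %% 360
    # recover cumulative (unwrapped) phase from the on-durations
    if (any(on)) {
      dur_s <- (seg$offset_ms[on] - seg$onset_ms[on]) / 1000
      phase[on] <- c(0, cumsum(dur_s[-length(dur_s)])) * omega +
        phase[on][1]
    }
    circle <- list(radius_deg = radius, angular_speed_deg_s = omega,
                   phase_onset_deg = phase)
  }
  new_task_schedule(task, seg, circle = circle)
}
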