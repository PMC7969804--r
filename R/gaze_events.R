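#' Preprocess a raw gaze trace
#'
#' Masks invalid (blink) samples plus a guard band on either side, low-pass
#' filters position with a centred moving average, and differentiates the
#' filtered position (centred difference) into a 2-D velocity and speed
#' series. Masked samples and the filter edges carry no velocity.
#'
#' @param trace data frame with columns `time_ms` (strictly increasing 1 ms
#'   steps), `x_deg`, `y_deg`, `valid` (logical).
#' @param blink_pad_ms guard band masked around invalid samples (default 50).
#' @param smooth_window_ms moving-average window (default 20; rounded to an
#'   odd sample count).
#' @return object of class `gaze_prep`: a list with `data` (columns
#'   `time_ms`, `x_deg`, `y_deg`, `x_f`, `y_f`, `vx`, `vy`, `speed`,
#'   `masked`) and the filter settings.
#' @export
preprocess_gaze <- function(trace, blink_pad_ms = 50, smooth_window_ms = 20) {
  stopifnot(is.data.frame(trace),
            all(c("time_ms", "x_deg", "y_deg", "valid") %in% names(trace)))
  n <- nrow(trace)
  w <- max(3L, as.integer(round(smooth_window_ms)))
  if (w %% 2L == 0L) w <- w + 1L
  if (n < w) stop("trace shorter than the smoothing window", call. = FALSE)
  if (any(abs(diff(trace$time_ms) - 1) > 1e-9)) {
    stop("trace must be uniformly sampled at 1 ms steps", call. = FALSE)
  }
  valid <- as.logical(trace$valid) & is.finite(trace$x_deg) &
    is.finite(trace$y_deg)
  pad <- as.integer(round(blink_pad_ms))
  masked <- !valid
  if (any(masked) && pad > 0) {
    r <- rle(masked)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      masked[max(1L, starts[k] - pad):min(n, ends[k] + pad)] <- TRUE
    }
  }
  half <- (w - 1L) %/% 2L
  x <- trace$x_deg
  y <- trace$y_deg
  x[!valid] <- NA_real_
  y[!valid] <- NA_real_
  kern <- rep(1 / w, w)
  x_f <- as.numeric(stats::filter(x, kern, sides = 2))
  y_f <- as.numeric(stats::filter(y, kern, sides = 2))
  # centred difference, deg/s at 1 kHz
  vx <- c(NA, (x_f[-(1:2)] - x_f[seq_len(n - 2)]) / 2, NA) * 1000
  vy <- c(NA, (y_f[-(1:2)] - y_f[seq_len(n - 2)]) / 2, NA) * 1000
  edge <- c(seq_len(half + 1L), seq(n - half, n))
  masked[edge] <- TRUE
  vx[masked] <- NA_real_
  vy[masked] <- NA_real_
  speed <- sqrt(vx^2 + vy^2)
  structure(list(data = data.frame(time_ms = trace$time_ms,
                                   x_deg = trace$x_deg, y_deg = trace$y_deg,
                                   x_f = x_f, y_f = y_f, vx = vx, vy = vy,
                                   speed = speed, masked = masked),
                 blink_pad_ms = blink_pad_ms, smooth_window_ms = w,
                 task = attr(trace, "task")),
            class = "gaze_prep")
}

#' Detect saccades and fixations in a preprocessed trace
#'
#' Two-threshold velocity detection: a saccade seed is a maximal run of
#' samples with speed above `onset_thresh_deg_s` lasting at least
#' `min_duration_ms`; each seed's boundaries are then refined outward while
#' speed stays above `offset_thresh_deg_s`, so the reported duration covers
#' the whole velocity pulse rather than only its suprathreshold core.
#' Events separated by less than `merge_gap_ms` are merged; events smaller
#' than `min_amplitude_deg` or overlapping the blink mask are discarded.
#' Inter-saccade spans of at least 40 ms become fixations (labelled pursuit
#' epochs for the pursuit task).
#'
#' @param prep a `gaze_prep` from [preprocess_gaze()].
#' @param onset_thresh_deg_s detection speed threshold in deg/s (default 30).
#' @param offset_thresh_deg_s boundary-refinement threshold (default 15).
#' @param min_duration_ms minimum event duration (default 4).
#' @param min_amplitude_deg minimum displacement (default 0.5).
#' @param merge_gap_ms events closer than this are merged (default 20).
#' @param fixation_min_ms minimum fixation duration (default 40).
#' @return list with data frames `saccades` (`onset_ms`, `offset_ms`,
#'   `duration_ms`, `amplitude_deg`, `peak_velocity_deg_s`,
#'   `mean_velocity_deg_s`, `q_ratio`, `x0`, `y0`, `x1`, `y1`) and
#'   `fixations` (`onset_ms`, `offset_ms`, `duration_ms`, `x`, `y`,
#'   `dispersion_deg`, `kind`).
#' @export
detect_saccades <- function(prep, onset_thresh_deg_s = 30,
                            offset_thresh_deg_s = 15,
                            min_duration_ms = 4, min_amplitude_deg = 0.5,
                            merge_gap_ms = 20, fixation_min_ms = 40) {
  stopifnot(inherits(prep, "gaze_prep"))
  d <- prep$data
  n <- nrow(d)
  empty_sac <- data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                          duration_ms = numeric(0), amplitude_deg = numeric(0),
                          peak_velocity_deg_s = numeric(0),
                          mean_velocity_deg_s = numeric(0),
                          q_ratio = numeric(0), x0 = numeric(0),
                          y0 = numeric(0), x1 = numeric(0), y1 = numeric(0))
  empty_fix <- data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                          duration_ms = numeric(0), x = numeric(0),
                          y = numeric(0), dispersion_deg = numeric(0),
                          kind = character(0))
  if (n == 0) return(list(saccades = empty_sac, fixations = empty_fix))
  above <- !is.na(d$speed) & d$speed > onset_thresh_deg_s
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- starts[r$values]
  off <- ends[r$values]
  keep <- (off - on + 1L) >= min_duration_ms
  on <- on[keep]; off <- off[keep]
  # refine boundaries outward to the lower offset threshold
  low <- !is.na(d$speed) & d$speed > offset_thresh_deg_s
  for (k in seq_along(on)) {
    while (on[k] > 1L && low[on[k] - 1L]) on[k] <- on[k] - 1L
    while (off[k] < n && low[off[k] + 1L]) off[k] <- off[k] + 1L
  }
  # merge events separated by short gaps (refinement may make them touch)
  if (length(on) > 1) {
    merged_on <- on[1]; merged_off <- off[1]
    for (k in 2:length(on)) {
      if (on[k] - merged_off[length(merged_off)] - 1L < merge_gap_ms) {
        merged_off[length(merged_off)] <- off[k]
      } else {
        merged_on <- c(merged_on, on[k])
        merged_off <- c(merged_off, off[k])
      }
    }
    on <- merged_on; off <- merged_off
  }
  if (length(on) == 0) {
    sac <- empty_sac
  } else {
    # kinematics from the filtered trace; endpoints just outside the run
    i0 <- pmax(1L, on - 1L)
    i1 <- pmin(n, off + 1L)
    x0 <- d$x_f[i0]; y0 <- d$y_f[i0]
    x1 <- d$x_f[i1]; y1 <- d$y_f[i1]
    amp <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
    dur <- off - on + 1L
    peak <- mean_v <- numeric(length(on))
    has_mask <- logical(length(on))
    for (k in seq_along(on)) {
      sp <- d$speed[on[k]:off[k]]
      has_mask[k] <- any(d$masked[on[k]:off[k]]) || any(is.na(sp))
      peak[k] <- if (all(is.na(sp))) NA_real_ else max(sp, na.rm = TRUE)
      mean_v[k] <- mean(sp)
    }
    keep <- !has_mask & !is.na(amp) & amp >= min_amplitude_deg
    sac <- data.frame(onset_ms = d$time_ms[on], offset_ms = d$time_ms[off] + 1,
                      duration_ms = dur, amplitude_deg = amp,
                      peak_velocity_deg_s = peak, mean_velocity_deg_s = mean_v,
                      q_ratio = peak * (dur / 1000) / amp,
                      x0 = x0, y0 = y0, x1 = x1, y1 = y1)[keep, , drop = FALSE]
    rownames(sac) <- NULL
    on <- on[keep]; off <- off[keep]
  }
  # fixations: unmasked spans between saccades
  in_sac <- logical(n)
  if (nrow(sac) > 0) {
    for (k in seq_along(on)) in_sac[on[k]:off[k]] <- TRUE
  }
  free <- !in_sac & !d$masked
  rf <- rle(free)
  fe <- cumsum(rf$lengths)
  fs <- fe - rf$lengths + 1L
  fon <- fs[rf$values]
  foff <- fe[rf$values]
  keepf <- (foff - fon + 1L) >= fixation_min_ms
  fon <- fon[keepf]; foff <- foff[keepf]
  kind <- if (identical(prep$task, "pursuit")) "pursuit_epoch" else "fixation"
  if (length(fon) == 0) {
    fix <- empty_fix
  } else {
    cx <- cy <- disp <- numeric(length(fon))
    for (k in seq_along(fon)) {
      xs <- d$x_f[fon[k]:foff[k]]; ys <- d$y_f[fon[k]:foff[k]]
      cx[k] <- mean(xs, na.rm = TRUE); cy[k] <- mean(ys, na.rm = TRUE)
      disp[k] <- sqrt(mean((xs - cx[k])^2 + (ys - cy[k])^2, na.rm = TRUE))
    }
    fix <- data.frame(onset_ms = d$time_ms[fon], offset_ms = d$time_ms[foff] + 1,
                      duration_ms = foff - fon + 1L, x = cx, y = cy,
                      dispersion_deg = disp, kind = kind)
  }
  list(saccades = sac, fixations = fix)
}
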