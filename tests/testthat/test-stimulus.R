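test_that("pursuit schedule honours cycle count, durations and continuity", {
  s <- make_pursuit_schedule()
  expect_equal(sum(s$segments$kind == "pursuit_on"), 35)
  expect_equal(schedule_duration_ms(s), 35 * 2000)

  s0 <- make_pursuit_schedule(n_cycles = 0)
  expect_equal(nrow(s0$segments), 0)
  expect_equal(schedule_duration_ms(s0), 0)

  s2 <- make_pursuit_schedule(n_cycles = 2, on_duration_s = 1.5, gap_s = 0.5)
  expect_equal(schedule_duration_ms(s2), 4000)

  # target reappears where it vanished: phase frozen across gaps
  pos_end <- schedule_target_position(s, s$segments$offset_ms[1] - 1)
  pos_next <- schedule_target_position(s, s$segments$onset_ms[3])
  expect_lt(abs(pos_end$x_deg - pos_next$x_deg), 0.1)
  expect_lt(abs(pos_end$y_deg - pos_next$y_deg), 0.1)

  # constant speed on the circle
  t <- seq(100, 1400, by = 1)
  p <- schedule_target_position(s, t)
  v <- sqrt(diff(p$x_deg)^2 + diff(p$y_deg)^2) * 1000
  expect_equal(unname(v),
               rep(8 * 120 * pi / 180, length(v)), tolerance = 1e-6)

  expect_error(make_pursuit_schedule(n_cycles = -1), "n_cycles")
  expect_error(make_pursuit_schedule(on_duration_s = -2), "on_duration_s")
})

test_that("visually guided schedule has the right jump structure", {
  s <- make_visually_guided_schedule(seed = 1)
  seg <- s$segments
  expect_equal(nrow(seg), 79)            # 78 jumps
  expect_equal(length(unique(seg$x_deg)), 10)
  expect_true(all(diff(seg$x_deg) != 0))  # every jump changes x
  expect_true(all(seg$y_deg == 0))
  expect_true(all(vgs_default_positions() %in% seg$x_deg))
  # central target dwells 2 s, peripheral 1.5 s
  dwell <- seg$offset_ms - seg$onset_ms
  expect_true(all(dwell[seg$x_deg == 0] == 2000))
  expect_true(all(dwell[seg$x_deg != 0] == 1500))

  s2 <- make_visually_guided_schedule(seed = 1)
  expect_identical(s$segments, s2$segments)  # deterministic given seed

  tiny <- make_visually_guided_schedule(positions_deg = c(-5, 5),
                                        n_jumps = 1, seed = 3)
  expect_equal(nrow(tiny$segments), 2)
  expect_error(make_visually_guided_schedule(positions_deg = 3, n_jumps = 2),
               "unique positions")
})

test_that("anti-saccade schedule balances sides and draws allowed fixations", {
  s <- make_antisaccade_schedule(seed = 1)
  seg <- s$segments
  cues <- seg[seg$kind == "peripheral_cue", ]
  expect_equal(nrow(cues), 18)
  expect_equal(sum(cues$x_deg < 0), 9)
  expect_equal(sum(cues$x_deg > 0), 9)
  fix <- seg[seg$kind == "central_fixation", ]
  expect_true(all((fix$offset_ms - fix$onset_ms) %in% c(1000, 2000, 3000,
                                                        4000)))
  expect_true(all(cues$offset_ms - cues$onset_ms == 1000))

  expect_equal(nrow(make_antisaccade_schedule(n_peripheral = 0)$segments), 0)
  expect_error(make_antisaccade_schedule(n_peripheral = 17), "even")
})

test_that("segments are contiguous for every schedule type", {
  for (s in list(make_pursuit_schedule(5), make_visually_guided_schedule(
    n_jumps = 12, seed = 2), make_antisaccade_schedule(n_peripheral = 6,
                                                       seed = 2))) {
    seg <- s$segments
    expect_equal(seg$onset_ms[-1], seg$offset_ms[-nrow(seg)])
  }
  # left/right balance holds for any even cue count
  for (np in c(2, 6, 12)) {
    cues <- make_antisaccade_schedule(n_peripheral = np, seed = 5)$segments
    cues <- cues[cues$kind == "peripheral_cue", ]
    expect_equal(sum(cues$x_deg < 0), np / 2)
  }
})

test_that("schedule CSV round-trips", {
  path <- tempfile(fileext = ".csv")
  for (s in list(make_pursuit_schedule(4), make_visually_guided_schedule(
    n_jumps = 10, seed = 4), make_antisaccade_schedule(n_peripheral = 4,
                                                       seed = 4))) {
    write_schedule_csv(s, path)
    s2 <- read_schedule_csv(path)
    expect_equal(s2$task, s$task)
    expect_equal(s2$segments$onset_ms, s$segments$onset_ms)
    expect_equal(s2$segments$x_deg, s$segments$x_deg)
    if (s$task == "pursuit") {
      t <- seq(0, schedule_duration_ms(s) - 1)
      expect_equal(schedule_target_position(s2, t)$x_deg,
                   schedule_target_position(s, t)$x_deg, tolerance = 1e-8)
    }
  }
  unlink(path)
})
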