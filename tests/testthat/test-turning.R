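test_that("yaw segmentation cuts at direction reversals and tiles the trace", {
  pw <- piecewise_yaw(c(0, 120, 30, 200))
  seg <- segment_yaw(pw$yaw, t = pw$t)
  expect_identical(nrow(seg), 3L)
  expect_equal(seg$magnitude, c(120, -90, 170), tolerance = 1e-9)
  expect_equal(seg$t_start[-1L], seg$t_end[-3L])
  # strictly monotone trace: one segment; constant trace: none
  expect_identical(nrow(segment_yaw(1:50, t = (0:49) / 10)), 1L)
  expect_identical(nrow(segment_yaw(rep(5, 50), t = (0:49) / 10)), 0L)
})

test_that("segment boundaries match a brute-force extrema scan", {
  set.seed(21)
  for (rep in 1:5) {
    knots <- cumsum(c(0, stats::runif(8, -120, 120)))
    pw <- piecewise_yaw(knots)
    yaw <- pw$yaw
    seg <- segment_yaw(yaw, t = pw$t)
    # oracle: interior boundaries are exactly the strict local extrema of
    # the trace after collapsing plateaus to their last sample
    d <- diff(yaw)
    s <- sign(d)
    runs <- rle(s)
    oracle_bounds <- cumsum(runs$lengths) + 1L
    expect_equal(seg$end_idx, oracle_bounds)
    expect_equal(seg$start_idx, c(1L, oracle_bounds[-length(oracle_bounds)]))
    # monotone (non-strict) within every segment
    for (k in seq_len(nrow(seg))) {
      dk <- diff(yaw[seg$start_idx[k]:seg$end_idx[k]])
      expect_true(all(dk >= 0) || all(dk <= 0))
    }
  }
})

test_that("a qualifying hesitation merges its neighbours into one net turn", {
  seg <- make_segments(c(100, -5, 100), c(2, 0.3, 2))
  out <- merge_hesitations(seg)
  expect_identical(nrow(out), 1L)
  expect_equal(out$magnitude, 195)
  expect_equal(out$duration, 4.3)
  expect_equal(out$t_start, 0)
  expect_equal(out$t_end, 4.3)
})

test_that("every hesitation conjunct flips the merge at its boundary", {
  base <- list(mags = c(100, -5, 100), durs = c(2, 0.3, 2))
  merges <- function(mags, durs)
    nrow(merge_hesitations(make_segments(mags, durs))) == 1L
  expect_true(merges(base$mags, base$durs))
  # duration: strictly less than 0.5 s
  expect_true(merges(c(100, -5, 100), c(2, 0.499, 2)))
  expect_false(merges(c(100, -5, 100), c(2, 0.5, 2)))
  expect_false(merges(c(100, -5, 100), c(2, 0.6, 2)))
  # magnitude: strictly less than 10% of BOTH neighbours
  expect_true(merges(c(100, -9.99, 100), base$durs))
  expect_false(merges(c(100, -10, 100), base$durs))
  expect_false(merges(c(100, -15, 100), base$durs))
  expect_false(merges(c(100, -5, 40), base$durs))   # 5 >= 10% of 40
  expect_true(merges(c(100, -5, 50.1), base$durs))
  # neighbours: each strictly greater than 10 degrees
  expect_false(merges(c(10, -0.5, 100), base$durs))
  expect_true(merges(c(10.01, -0.5, 100), base$durs))
  expect_false(merges(c(100, -0.5, 10), base$durs))
  # neighbours: identical direction
  expect_false(merges(c(100, 5, -100), base$durs))
  expect_true(merges(c(-100, 5, -100), base$durs))
})

test_that("hesitation chains collapse to a fixed point, left to right", {
  seg <- make_segments(c(80, -4, 80, -4, 80), c(1.5, 0.2, 1.5, 0.2, 1.5))
  out <- merge_hesitations(seg)
  expect_identical(nrow(out), 1L)
  expect_equal(out$magnitude, 80 * 3 - 8)
  # a noise-split hesitation (several minute reversals) still merges
  seg2 <- make_segments(c(100, -0.02, 0.03, -5, 0.02, 100),
                        c(2, 0.02, 0.02, 0.3, 0.02, 2))
  out2 <- merge_hesitations(seg2)
  expect_identical(nrow(out2), 1L)
  expect_equal(out2$magnitude, 195.03)
})

test_that("tiling is preserved by every merge pass", {
  set.seed(31)
  for (rep in 1:10) {
    m <- 15L
    mags <- stats::runif(m, -120, 120)
    durs <- stats::runif(m, 0.05, 2)
    seg <- make_segments(mags, durs)
    out <- merge_hesitations(seg)
    if (nrow(out) > 1L) {
      expect_equal(out$t_start[-1L], out$t_end[-nrow(out)])
      expect_equal(out$start_idx[-1L], out$end_idx[-nrow(out)])
    }
    expect_equal(sum(out$magnitude), sum(mags), tolerance = 1e-9)
    expect_equal(out$t_end[nrow(out)], seg$t_end[m])
  }
})

test_that("turn filtering applies inclusive magnitude and duration bounds", {
  cfg <- detection_config()
  seg <- make_segments(c(90, -89.9, 95, 120), c(2, 2, 12, 0.09))
  ev <- filter_turns(seg, cfg)
  expect_identical(nrow(ev), 1L)
  expect_equal(ev$magnitude, 90)          # >= 90 is accepted
  expect_equal(ev$direction, "right")     # positive yaw change, default map
  # duration bounds inclusive at both ends
  seg2 <- make_segments(c(100, -100), c(10, 0.1))
  expect_identical(nrow(filter_turns(seg2, cfg)), 2L)
})

test_that("turn direction follows the vertical gyro integral and flips under mirroring", {
  script <- turn_script(list(quiet_phase(2), turn_phase(-180, 2),
                             quiet_phase(2)),
                        gyro_noise_sd_dps = 0, accel_noise_sd = 0)
  sim <- render_script(script, seed = 5)
  fit <- detect_turns(sim$recording)
  expect_identical(fit$events$direction, "left")
  d <- turn_direction(fit$track, fit$events$t_start, fit$events$t_end)
  expect_identical(as.character(d), "left")
  expect_equal(attr(d, "integral_deg"), -180, tolerance = 0.5)
  # mirror the gyro: every direction flips
  rec2 <- sim$recording
  rec2$gyro <- -rec2$gyro
  fit2 <- detect_turns(rec2)
  expect_identical(fit2$events$direction, "right")
})

test_that("gyro-integral direction equals yaw-segment direction for all accepted turns", {
  sim <- render_script(random_turn_script(25, seed = 13))
  fit <- detect_turns(sim$recording)
  expect_gt(nrow(fit$events), 0L)
  cfg <- fit$config
  for (i in seq_len(nrow(fit$events))) {
    gy <- turn_direction(fit$track, fit$events$t_start[i],
                         fit$events$t_end[i], cfg)
    expect_identical(as.character(gy), fit$events$direction[i])
  }
})

test_that("the full pipeline recovers scripted turns and ignores stillness", {
  mags <- c(90.5, -120, 150, -180, 95, -110)
  phases <- list(quiet_phase(3))
  for (m in mags)
    phases <- c(phases, list(turn_phase(m, 2)), list(quiet_phase(2.5)))
  sim <- render_script(turn_script(phases), seed = 17)
  fit <- detect_turns(sim$recording)
  expect_identical(nrow(fit$events), length(mags))
  expect_identical(fit$events$direction,
                   ifelse(mags > 0, "right", "left"))
  expect_lt(max(abs(fit$events$magnitude - abs(mags))), 2)
  # a stationary recording yields no turns
  still <- render_script(turn_script(list(quiet_phase(30))), seed = 2)
  expect_identical(nrow(detect_turns(still$recording)$events), 0L)
})

test_that("detected-turn count is monotone non-increasing in the threshold", {
  sim <- render_script(random_turn_script(40, seed = 19,
                                          magnitude_range = c(50, 180)))
  fit <- detect_turns(sim$recording)
  counts <- vapply(c(45, 60, 70, 80, 90, 100, 110), function(th) {
    cfg <- detection_config(magnitude_threshold = th)
    nrow(filter_turns(fit$merged, cfg))
  }, integer(1L))
  expect_true(all(diff(counts) <= 0))
  expect_gt(counts[1L], counts[7L])  # the sweep actually discriminates
})
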