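test_that("periods_for_code maps bits to periods in descending order", {
  sc <- barcode_scheme()
  expect_equal(periods_for_code(0x8, sc), 857)            # 1000b
  expect_equal(periods_for_code(0x4, sc), 1000)           # 0100b
  expect_equal(periods_for_code(0x3, sc), c(1200, 1500))  # 0011b
  expect_equal(periods_for_code(0, sc), numeric(0))
  expect_equal(periods_for_code(15, sc), sc$periods)
  expect_error(periods_for_code(16, sc), "0..15")
  expect_error(periods_for_code(-1, sc), "0..15")
})

test_that("code_for_detections quantizes into tolerance bins", {
  sc <- barcode_scheme()
  expect_equal(as.integer(code_for_detections(1450, sc)), 1L)
  expect_equal(as.integer(code_for_detections(c(935, 1190), sc)), 6L)
  oob <- code_for_detections(700, sc)
  expect_equal(as.integer(oob), 0L)
  expect_equal(attr(oob, "out_of_band"), 700)
  # duplicates in one bin count once
  expect_equal(as.integer(code_for_detections(c(990, 1000), sc)), 4L)
  # upper-edge slack admits quantization overshoot without joining bins
  expect_equal(as.integer(code_for_detections(1006, sc, slack = 10)), 4L)
  expect_equal(as.integer(code_for_detections(1006, sc, slack = 0)), 0L)
})

test_that("codec round-trips every code under both bit orders", {
  for (bo in c("msb_shortest", "lsb_shortest")) {
    sc <- barcode_scheme(bit_order = bo)
    for (cd in 0:15)
      expect_equal(as.integer(code_for_detections(periods_for_code(cd, sc), sc)),
                   cd)
  }
})

test_that("flipping bit_order reverses the 4-bit word", {
  msb <- barcode_scheme(bit_order = "msb_shortest")
  lsb <- barcode_scheme(bit_order = "lsb_shortest")
  rev4 <- function(c) sum(2^(3:0)[as.logical(bitwAnd(c, 2^(0:3)))])
  for (cd in 0:15)
    expect_equal(as.integer(code_for_detections(periods_for_code(cd, msb), lsb)),
                 rev4(cd))
})

test_that("scheme invariants are enforced", {
  expect_error(barcode_scheme(c(1000, 1020),
                              tolerance_bins = rbind(c(930, 1005), c(950, 1020))),
               "overlap")
  expect_error(barcode_scheme(c(1000, 1200),
                              tolerance_bins = rbind(c(930, 990), c(1120, 1200))),
               "inside its own")
  expect_error(barcode_scheme(c(1000, 1000)), "distinct")
  # auto bins are disjoint even for near-colliding periods
  sc <- barcode_scheme(c(1000, 1020))
  expect_true(sc$bins[1, 2] < sc$bins[2, 1])
})

test_that("make_schedule reproduces the printed pulse intervals", {
  s <- make_schedule(857, v_x = 1000)
  expect_equal(unname(s$intervals), 0.857)
  s4 <- make_schedule(c(857, 1000, 1200, 1500), v_x = 1000)
  expect_equal(unname(s4$intervals), c(0.857, 1, 1.2, 1.5))
})

test_that("single-period schedules enumerate k x_b <= region_length", {
  s <- make_schedule(1500, v_x = 1000, region_length = 12000)
  expect_equal(s$event_times, seq(0, 12, by = 1.5))      # 9 events
  expect_equal(s$event_weights, rep(1L, 9))
})

test_that("union schedules merge coincident events with summed weight", {
  s <- make_schedule(c(1000, 1500), v_x = 1000, region_length = 12000)
  # 13 + 9 events with coincidences at 0, 3, 6, 9, 12 s
  expect_equal(length(s$event_times), 17L)
  expect_equal(sum(s$event_weights), 22L)
  expect_equal(s$event_times[s$event_weights == 2L], c(0, 3, 6, 9, 12))
  # brute-force union oracle
  oracle <- sort(unique(c(seq(0, 12, 1), seq(0, 12, 1.5))))
  expect_equal(s$event_times, oracle)
})

test_that("per-period trains are arithmetic progressions at x_b / v_x", {
  s <- make_schedule(c(857, 1200), v_x = 1100, region_length = 12000)
  for (p in names(s$period_events)) {
    d <- diff(s$period_events[[p]])
    expect_true(all(abs(d - as.numeric(p) / 1100) < 1e-9))
  }
})

test_that("scheduling a duplicated period equals scheduling it once", {
  a <- make_schedule(c(1200, 1200), v_x = 1000)
  b <- make_schedule(1200, v_x = 1000)
  expect_equal(a$event_times, b$event_times)
  expect_equal(a$event_weights, b$event_weights)
})

test_that("schedule argument errors are raised", {
  expect_error(make_schedule(numeric(0), 1000), "non-empty")
  expect_error(make_schedule(1000, 0), "positive velocity")
  expect_error(make_schedule(1500, 1000, region_length = 1000), "longest period")
})

test_that("spot irradiance matches the worked example", {
  expect_equal(round(spot_irradiance(12.7)), 35)
  expect_equal(round(spot_irradiance(9.5)), 26)
})

test_that("design_sweep returns an empty table for n_reps = 0", {
  out <- design_sweep(list(c(1000, 1500)), n_reps = 0)
  expect_equal(nrow(out), 0L)
  expect_named(out, c("set", "periods", "accuracy", "false_bit_rate",
                      "out_of_band_rate"))
})

test_that("overlapping tolerance bins are rejected naming the pair", {
  expect_error(
    barcode_scheme(c(1000, 1020),
                   tolerance_bins = rbind(c(930, 1010), c(1005, 1020))),
    "1000 and 1020")
})

test_that("unresolvable period pairs decode worse than the chosen set", {
  sweep <- design_sweep(
    list(c(1200, 1500), c(1000, 1020)),
    sim_params = list(noise = FALSE,
                      motion = motion_params(jitter_fraction = 0.07)),
    n_reps = 2, seed = 5, codes = 3)
  expect_equal(sweep$accuracy[1], 1.0)
  expect_lt(sweep$accuracy[2], sweep$accuracy[1])
})
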