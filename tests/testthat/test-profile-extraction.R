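test_that("a uniform image yields a flat profile on the 3x grid", {
  frame <- matrix(7.5, nrow = 15, ncol = 60)
  pl <- data.frame(x_nm = c(1000, 8000), y_nm = 1120)
  pr <- extract_profile(frame, pl, pixel_size = 160)
  expect_equal(diff(pr$positions[1:2]), 160 / 3)
  expect_true(all(abs(pr$intensities - 7.5) < 1e-9))
})

test_that("profiles sample a stripe image to sub-percent accuracy", {
  px <- 160
  nx <- 80; ny <- 15
  period_nm <- 12 * px
  stripe <- function(x_nm) 100 + 40 * sin(2 * pi * x_nm / period_nm)
  frame <- matrix(stripe((col(matrix(0, ny, nx)) - 1) * px), ny, nx)
  pl <- data.frame(x_nm = c(500, 12000), y_nm = (ny - 1) / 2 * px)
  pr <- extract_profile(frame, pl, pixel_size = px)
  expect_lt(max(abs(pr$intensities - stripe(500 + pr$positions))), 0.4)
})

test_that("polylines touching the frame edge raise a boundary error", {
  frame <- matrix(1, 15, 40)
  expect_error(extract_profile(frame, data.frame(x_nm = c(0, 3000), y_nm = 1120),
                               pixel_size = 160), "edge")
  expect_error(extract_profile(frame, data.frame(x_nm = c(1000, 3000), y_nm = 0),
                               pixel_size = 160), "edge")
})

test_that("alignment recovers on-grid shifts exactly and averages cleanly", {
  h <- 160 / 3
  pos <- seq(0, 8000, by = h)
  f <- function(x) 100 + 30 * exp(-(x - 3000)^2 / 1e5) +
    20 * sin(2 * pi * x / 1100)
  shifts_true <- c(0, 3, -2, 5) * h
  profs <- lapply(seq_along(shifts_true), function(i)
    intensity_profile(pos, f(pos - shifts_true[i]), frame_id = i))
  al <- align_and_average(profs)
  expect_equal(al$shifts_nm, shifts_true)
  # average equals the template on the overlap
  expect_equal(al$average$intensities, f(al$average$positions),
               tolerance = 1e-9)
  expect_equal(al$average$n_frames_averaged, 4L)
})

test_that("a single profile is returned unchanged with zero shift", {
  pos <- seq(0, 2000, by = 160 / 3)
  pr <- intensity_profile(pos, sin(pos / 300))
  al <- align_and_average(list(pr))
  expect_equal(al$shifts_nm, 0)
  expect_equal(al$average$intensities, pr$intensities)
  expect_error(align_and_average(list()), "at least one")
})

test_that("averaging is order-invariant and flat-field equivariant", {
  h <- 160 / 3
  pos <- seq(0, 6000, by = h)
  f <- function(x) 50 + 10 * cos(2 * pi * x / 1300) +
    8 * exp(-(x - 2500)^2 / 4e5)
  shifts <- c(0, 2, -3, 1, 4, -2) * h
  profs <- lapply(seq_along(shifts), function(i)
    intensity_profile(pos, f(pos - shifts[i]), frame_id = i))
  a1 <- align_and_average(profs)
  a2 <- align_and_average(profs[c(1, 4, 2, 6, 3, 5)])
  expect_lt(max(abs(a1$average$intensities - a2$average$intensities)) /
              mean(a1$average$intensities), 1e-9)
  profs_c <- lapply(profs, function(p)
    intensity_profile(p$positions, p$intensities + 17, frame_id = p$frame_id))
  a3 <- align_and_average(profs_c)
  expect_equal(a3$average$intensities, a1$average$intensities + 17,
               tolerance = 1e-9)
})

test_that("frame averaging reduces white noise like 1/sqrt(N)", {
  set.seed(77)
  h <- 160 / 3
  pos <- seq(0, 8000, by = h)
  template <- 200 + 40 * sin(2 * pi * pos / 1200)
  sigma <- 12; N <- 25
  res_sd <- replicate(8, {
    profs <- lapply(1:N, function(i)
      intensity_profile(pos, template + rnorm(length(pos), 0, sigma),
                        frame_id = i))
    al <- align_and_average(profs)
    idx <- match(round(al$average$positions, 6), round(pos, 6))
    sd(al$average$intensities - template[idx])
  })
  expect_lt(abs(mean(res_sd) - sigma / sqrt(N)) / (sigma / sqrt(N)), 0.2)
})

test_that("extract_profiles puts stack frames on one common grid", {
  sim <- quiet_sim(5, seed = 21, n_frames = 4)
  profs <- extract_profiles(sim$stack, sim$track)
  lens <- vapply(profs, function(p) length(p$positions), integer(1))
  expect_true(all(lens == lens[1]))
  expect_equal(profs[[1]]$positions, profs[[4]]$positions)
})
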