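test_that("filament labeling is Poisson with uniform positions", {
  expect_length(generate_filament(20000, 0, seed = 1)$positions, 0L)
  f1 <- generate_filament(20000, 2, seed = 42)
  f2 <- generate_filament(20000, 2, seed = 42)
  expect_identical(f1$positions, f2$positions)
  expect_true(all(f1$positions >= 0 & f1$positions <= 20000))
  expect_length(f1$survival, length(f1$positions))
  # Poisson mean over 100 seeds: 20000 nm at 10 dyes/nm -> mean 2e5,
  # SE of the mean sqrt(2e5 / 100) ~ 45
  counts <- vapply(1:100, function(s)
    length(generate_filament(20000, 10, seed = s)$positions), numeric(1))
  expect_lt(abs(mean(counts) - 2e5), 3 * sqrt(2e5 / 100))
})

test_that("motion is exact without jitter and matches the increment model", {
  mo <- motion_params(v_x = 1000, jitter_fraction = 0)
  tr <- simulate_motion(mo, 2, seed = 1)
  expect_equal(tr$x, 1000 * tr$t)
  tr0 <- simulate_motion(mo, 0, seed = 1)
  expect_equal(tr0$x, 0)
  # Monte Carlo: 1 s at dt = 0.01, jitter 3% -> displacement N(1000, 3^2)
  mo2 <- motion_params(v_x = 1000, jitter_fraction = 0.03, dt = 0.01)
  disp <- vapply(1:1000, function(s) {
    tr <- simulate_motion(mo2, 1, seed = s)
    tr$x[length(tr$x)]
  }, numeric(1))
  sd_theory <- 0.03 * 1000 * 0.01 * sqrt(100)
  expect_lt(abs(mean(disp) - 1000), 3 * sd_theory / sqrt(1000))
  expect_lt(abs(sd(disp) - sd_theory), 0.1 * sd_theory)
  # monotone non-decreasing even at large jitter (negative steps clamp)
  trj <- simulate_motion(motion_params(jitter_fraction = 2), 1, seed = 7)
  expect_true(all(diff(trj$x) >= 0))
})

test_that("bleaching multiplies survival by the Gaussian dose profile", {
  fil <- generate_filament(20000, 1, seed = 3)
  mo <- motion_params(jitter_fraction = 0)
  tr <- simulate_motion(mo, 13, seed = 1)
  sch <- make_schedule(1500, 1000, 12000)
  f0 <- apply_bleaching(fil, tr, sch, dose = 0, seed = 5)
  expect_identical(f0$survival, fil$survival)
  expect_identical(f0$survival_prob, fil$survival_prob)
  fb <- apply_bleaching(fil, tr, sch, beam_sigma = 180, dose = 5, lead_in = 4000,
                        seed = 5)
  # analytic oracle for the survival probability of each dye
  centers <- 4000 + 1000 * (sch$event_times + sch$event_duration / 2)
  dose_o <- rowSums(vapply(centers, function(c0)
    5 * exp(-(fil$positions - c0)^2 / (2 * 180^2)),
    numeric(length(fil$positions))))
  expect_equal(fb$survival_prob, exp(-dose_o), tolerance = 1e-12)
  # dyes at line centers are almost surely bleached at this dose
  at_lines <- vapply(fil$positions, function(p) min(abs(p - centers)), 1) < 90
  expect_lt(mean(fb$survival[at_lines]), exp(-1))
  # events after the motion ends are reported with their time
  expect_error(apply_bleaching(fil, simulate_motion(mo, 5, seed = 1), sch),
               "6.000 s is after the motion ends")
})

test_that("summed-dose minima reproduce the coded spacing", {
  sch <- make_schedule(1500, 1000, 12000)
  arc <- seq(-500, 12500, by = 5)
  prof <- expected_bleach_profile(sch, arc, beam_sigma = 180, dose = 0.7)
  n <- length(prof)
  mins <- arc[which(prof[2:(n - 1)] < prof[1:(n - 2)] &
                      prof[2:(n - 1)] <= prof[3:n]) + 1L]
  mins <- mins[mins > -100 & mins < 12100]
  expect_length(mins, 9L)
  expect_true(all(abs(diff(mins) - 1500) <= 10))
})

test_that("rendering a single dye gives a PSF-sized Gaussian spot", {
  fil <- structure(list(length = 4000, positions = 2000, survival_prob = 1,
                        survival = TRUE, labeling_density = 0),
                   class = "filament")
  mo <- motion_params(v_x = 1, jitter_fraction = 0)
  tr <- simulate_motion(mo, 1, seed = 1)
  op <- optics_params()
  cam <- camera_params(exposure = 0.001)
  rf <- render_frames(fil, tr, op, cam, frame_times = 0.1, lead_in = 0,
                      noise = FALSE, seed = 1)
  fr <- rf$stack$frames[[1]] - cam$offset
  # x marginal: weighted SD of a pixel-integrated Gaussian is
  # sqrt(sigma^2 + px^2 / 12) (+ negligible motion blur / fine-grid terms)
  colx <- colSums(fr)
  x_nm <- (seq_along(colx) - 1) * op$pixel_size
  mu <- sum(colx * x_nm) / sum(colx)
  sdx <- sqrt(sum(colx * (x_nm - mu)^2) / sum(colx))
  expect_equal(sdx, sqrt(op$psf_sigma^2 + op$pixel_size^2 / 12),
               tolerance = 0.01)
  rowy <- rowSums(fr)
  y_nm <- (seq_along(rowy) - 1) * op$pixel_size
  muy <- sum(rowy * y_nm) / sum(rowy)
  sdy <- sqrt(sum(rowy * (y_nm - muy)^2) / sum(rowy))
  expect_equal(sdy, sqrt(op$psf_sigma^2 + op$pixel_size^2 / 12),
               tolerance = 0.01)
})

test_that("noiseless rendering is linear in the surviving dye count", {
  mo <- motion_params(jitter_fraction = 0)
  tr <- simulate_motion(mo, 1, seed = 1)
  mk <- function(n) structure(
    list(length = 4000, positions = seq(500, 3500, length.out = n),
         survival_prob = rep(1, n), survival = rep(TRUE, n),
         labeling_density = 0), class = "filament")
  cam <- camera_params(offset = 0)
  s1 <- render_frames(mk(40), tr, optics_params(), cam, 0.1, lead_in = 0,
                      noise = FALSE, seed = 1)$stack$frames[[1]]
  s2 <- render_frames(mk(80), tr, optics_params(), cam, 0.1, lead_in = 0,
                      noise = FALSE, seed = 1)$stack$frames[[1]]
  expect_equal(sum(s2) / sum(s1), 2, tolerance = 1e-6)
})

test_that("with dose 0 and noise off the stack conserves intensity", {
  sim <- quiet_sim(0, seed = 11, noise = FALSE, jitter = 0, n_frames = 6)
  sums <- vapply(sim$stack$frames, sum, numeric(1))
  expect_lt(diff(range(sums)) / mean(sums), 1e-6)
})

test_that("simulation is bit-identical under a fixed seed", {
  a <- quiet_sim(9, seed = 123, n_frames = 3)
  b <- quiet_sim(9, seed = 123, n_frames = 3)
  expect_identical(a$stack$frames, b$stack$frames)
  expect_identical(a$track, b$track)
  expect_identical(a$truth$filament$survival, b$truth$filament$survival)
})

test_that("track polylines span the filament, leading end first", {
  sim <- quiet_sim(5, seed = 4, n_frames = 3)
  t1 <- sim$track[sim$track$frame == 1, ]
  arc <- sum(sqrt(diff(t1$x_nm)^2 + diff(t1$y_nm)^2))
  expect_lt(abs(arc - 20000), 160)
  expect_gt(t1$x_nm[1], t1$x_nm[nrow(t1)])   # leading end has largest x
})

test_that("long-period patterns are less sinusoidal than short ones", {
  h <- 160 / 3
  arc <- seq(0, 12000 - 1, by = h)
  ratio <- vapply(c(857, 1500), function(p) {
    prof <- expected_bleach_profile(make_schedule(p, 1000, 12000), arc)
    sp <- amplitude_spectrum(prof, pad_factor = 8, spacing = h)
    fund <- sp$amplitude[which.min(abs(sp$period - p))]
    harm <- sp$amplitude[which.min(abs(sp$period - p / 2))]
    harm / fund
  }, numeric(1))
  expect_gt(ratio[2], ratio[1])   # 1500 nm richer in 2nd harmonic than 857 nm
})

test_that("realized spatial period spread grows with velocity jitter", {
  spread <- vapply(c(0.01, 0.05, 0.15), function(j) {
    mo <- motion_params(jitter_fraction = j, dt = 0.005)
    sp <- vapply(1:40, function(s) {
      tr <- simulate_motion(mo, 2, seed = 700 + s)
      diff(mtbarcode:::motion_offset_at(tr, c(0, 1.5)))  # one 1500 nm interval
    }, numeric(1))
    sd(sp)
  }, numeric(1))
  expect_true(all(diff(spread) > 0))
})
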