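test_that("amplitude spectrum matches a brute-force DFT sum", {
  set.seed(5)
  for (n in c(64, 225, 512)) {
    h <- 160 / 3
    y <- rnorm(n, 100, 20)
    sp <- amplitude_spectrum(y, pad_factor = 4, spacing = h)
    yc <- y - mean(y)
    j <- seq_len(n) - 1
    oracle <- vapply(sp$freq, function(f)
      2 * Mod(sum(yc * exp(-2i * pi * f * j * h))) / n, numeric(1))
    expect_lt(max(abs(sp$amplitude - oracle)) / max(oracle), 1e-9)
  }
})

test_that("pure tones are located and normalized correctly", {
  h <- 160 / 3
  pos <- seq(0, 12000 - 1, by = h)
  y <- sin(2 * pi * pos / 1200)
  sp <- amplitude_spectrum(y, pad_factor = 8, spacing = h)
  pk <- which.max(sp$amplitude)
  step <- sp$period[pk]^2 * (sp$freq[2] - sp$freq[1])
  expect_lt(abs(sp$period[pk] - 1200), step + 1e-9)
  expect_equal(sp$amplitude[pk], 1, tolerance = 0.05)
  # constant input: DC is removed entirely
  spc <- amplitude_spectrum(rep(3, 100), spacing = h)
  expect_true(all(spc$amplitude < 1e-12))
  # two tones resolve to their own natural bins
  y2 <- sin(2 * pi * pos / 857.142857) + sin(2 * pi * pos / 1500)
  sp2 <- amplitude_spectrum(y2, pad_factor = 8, spacing = h)
  nat <- seq(8, length(sp2$amplitude), by = 8)
  for (p in c(857.14, 1500)) {
    at <- nat[which.min(abs(sp2$period[nat] - p))]
    expect_lt(abs(sp2$period[at] - p), 10)
    expect_equal(sp2$amplitude[at], 1, tolerance = 0.05)
  }
})

test_that("reversing the region profile leaves amplitudes unchanged", {
  set.seed(9)
  y <- rnorm(200, 50, 8)
  a <- amplitude_spectrum(y, spacing = 160 / 3)$amplitude
  b <- amplitude_spectrum(rev(y), spacing = 160 / 3)$amplitude
  expect_lt(max(abs(a - b)) / max(a), 1e-9)
})

test_that("baseline is homogeneous and blind to in-ROI peaks", {
  set.seed(12)
  h <- 160 / 3
  y <- rnorm(225, 0, 1)
  sp <- amplitude_spectrum(y, spacing = h)
  bl <- fit_baseline(sp, k = 3)
  expect_equal(bl$threshold, 3 * bl$baseline)
  # homogeneity: scaling the profile scales baseline and threshold
  sp_c <- amplitude_spectrum(y * 40, spacing = h)
  bl_c <- fit_baseline(sp_c, k = 3)
  expect_equal(bl_c$baseline, 40 * bl$baseline, tolerance = 1e-6)
  # an added in-ROI tone does not move the baseline (ROI is excluded
  # from the fitting support)
  pos <- seq(0, by = h, length.out = 225)
  sp_p <- amplitude_spectrum(y + 25 * sin(2 * pi * pos / 1200), spacing = h)
  bl_p <- fit_baseline(sp_p, k = 3)
  expect_lt(max(abs(bl_p$baseline - bl$baseline) / bl$baseline), 0.05)
  # no support on one side -> argument error
  expect_error(fit_baseline(sp, fit_range = c(900, 4000)), "both sides")
})

test_that("white-noise false-positive rate stays within the 1% target", {
  set.seed(1)
  h <- 160 / 3
  k <- default_threshold_factor()
  hits <- 0L; total <- 0L
  for (i in 1:400) {
    sp <- amplitude_spectrum(rnorm(225), spacing = h)
    bl <- fit_baseline(sp, k = k)
    nat <- seq(8, length(sp$amplitude), by = 8)
    pn <- sp$period[nat]
    in_roi <- pn >= 850 & pn <= 1500
    r <- sp$amplitude[nat][in_roi] > mtbarcode:::threshold_at(bl, pn[in_roi])
    hits <- hits + sum(r); total <- total + length(r)
  }
  # target 1% per bin; allow 3 binomial SD
  expect_lt(hits / total, 0.01 + 3 * sqrt(0.01 * 0.99 / total))
})

test_that("bootstrap CIs collapse for identical frames and demand >= 2 frames", {
  pr <- well_profile(c(1000, 1500))
  Y <- rbind(pr$intensities, pr$intensities, pr$intensities)
  al <- make_aligned(Y, pr$positions)
  reg <- find_bleached_region(al$average, min_length = 1500)
  det <- bootstrap_detections(al, reg, n_boot = 50, seed = 3)
  expect_true(all(det$ci_low == det$amplitude & det$ci_high == det$amplitude))
  expect_true(all(det$significant))
  al1 <- make_aligned(Y[1, , drop = FALSE], pr$positions)
  expect_error(bootstrap_detections(al1, reg), class = "InsufficientFrames")
})

test_that("a noiseless single-period stack gives exactly one significant hit", {
  sim <- quiet_sim(4, seed = 2, noise = FALSE, jitter = 0)
  ro <- fast_decode(sim, n_boot = 50)
  sig <- ro$detections[ro$detections$significant, ]
  expect_equal(nrow(sig), 1L)
  sc <- barcode_scheme()
  expect_true(sig$period >= sc$bins[2, 1] - 1 & sig$period <= sc$bins[2, 2] + 50)
  expect_equal(ro$code, 4L)
})

test_that("bootstrap 95% CIs cover the true amplitude at the nominal rate", {
  h <- 160 / 3
  pos <- seq(0, 12000 - 1, by = h)
  template <- 1000 + 80 * cos(2 * pi * pos / 1200)
  a_true <- {
    sp0 <- amplitude_spectrum(template, pad_factor = 8, spacing = h)
    sp0$amplitude[which.min(abs(sp0$period - 1200))]
  }
  reg <- override_region(intensity_profile(pos, template), pos[1],
                         pos[length(pos)])
  set.seed(99)
  n_rep <- 200
  cover <- replicate(n_rep, {
    Y <- t(replicate(25, template + rnorm(length(pos), 0, 60)))
    det <- bootstrap_detections(make_aligned(Y, pos), reg, n_boot = 150,
                                seed = sample.int(1e6, 1), candidates = 1200)
    det$ci_low[1] <= a_true && a_true <= det$ci_high[1]
  })
  # binomial 3 SD band around 0.95 with 200 outer replications
  expect_gt(mean(cover), 0.95 - 3 * sqrt(0.95 * 0.05 / n_rep))
  expect_lte(mean(cover), 1)
})

test_that("decoding is deterministic given the config seed", {
  sim <- quiet_sim(11, seed = 33, n_frames = 12)
  r1 <- fast_decode(sim, n_boot = 80, seed = 5)
  r2 <- fast_decode(sim, n_boot = 80, seed = 5)
  expect_identical(r1$code, r2$code)
  expect_equal(as.data.frame(r1$detections), as.data.frame(r2$detections))
})

test_that("the 1500 nm line is no stronger than the 1000 nm line in 4-bit codes", {
  # deterministic expectation of the bleached pattern
  h <- 160 / 3
  arc <- seq(0, 12000 - 1, by = h)
  sch <- make_schedule(c(857, 1000, 1200, 1500), 1000, 12000)
  sp <- amplitude_spectrum(expected_bleach_profile(sch, arc),
                           pad_factor = 8, spacing = h)
  nat <- seq(8, length(sp$amplitude), by = 8)
  amp_at <- function(p) sp$amplitude[nat[which.min(abs(sp$period[nat] - p))]]
  expect_lte(amp_at(1500), amp_at(1000))
  # and in a simulated readout, up to measurement noise
  for (s in c(3, 11)) {
    sim <- quiet_sim(15, seed = s, n_frames = 15)
    ro <- fast_decode(sim, n_boot = 60)
    d <- ro$detections
    a1500 <- d$amplitude[abs(d$period - 1500) < 60]
    a1000 <- d$amplitude[abs(d$period - 1000) < 60]
    expect_true(length(a1500) == 1L && length(a1000) == 1L)
    expect_lte(a1500, a1000 * 1.05)
  }
})

test_that("an unbleached stack has no bleached region to decode", {
  sim <- suppressWarnings(quiet_sim(0, seed = 6, n_frames = 8))
  expect_error(fast_decode(sim), class = "NoBleachedRegion")
})
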