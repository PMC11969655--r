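# Fourier readout of the bleached region: amplitude spectrum, dynamic
# baseline and threshold, bootstrap confidence intervals, significance
# calls and code assembly.

#' Amplitude spectrum of a region profile
#'
#' Mean-subtracted, windowed, zero-padded discrete Fourier transform.
#' Amplitudes are normalized by the window sum so that a unit-amplitude
#' pure sinusoid whose period lies on the frequency grid yields amplitude
#' 1 (up to the window's scalloping, a few percent at most with the
#' default 8-fold padding).
#'
#' @param region_profile An [intensity_profile()] (the averaged profile
#'   cropped to the bleached region) or a numeric vector with `spacing`.
#' @param pad_factor Zero-padding factor (default 8; the period grid near
#'   1 um is then ~15 nm fine for a 12 um region).
#' @param window `"rect"` (default) or `"hann"`. The coded periods are
#'   consecutive harmonics of half the region length, so with the region
#'   cropped to the bleached well they fall on (near-)orthogonal
#'   rectangular-window bins; a Hann window would widen the mainlobe past
#'   the comb spacing and merge adjacent coded peaks.
#' @param spacing Sample spacing in nm (taken from the profile when one
#'   is supplied).
#' @return A list of class `mt_spectrum`: `period` (nm, decreasing
#'   follows increasing `freq`), `freq` (cycles/nm), `amplitude`,
#'   `pad_factor`, `window`, `spacing`, `n`.
#' @export
amplitude_spectrum <- function(region_profile, pad_factor = 8,
                               window = c("rect", "hann"), spacing = NULL) {
  window <- match.arg(window)
  if (inherits(region_profile, "intensity_profile")) {
    y <- region_profile$intensities
    spacing <- region_profile$positions[2] - region_profile$positions[1]
  } else {
    y <- as.numeric(region_profile)
    if (is.null(spacing)) stop_arg("'spacing' is required for a bare vector")
  }
  n <- length(y)
  if (n < 2L) stop_arg("region profile needs at least 2 samples")
  w <- if (window == "hann") hann_window(n) else rep(1, n)
  yw <- (y - mean(y)) * w
  n_pad <- as.integer(ceiling(pad_factor) * n)
  z <- stats::fft(c(yw, rep(0, n_pad - n)))
  half <- seq_len(n_pad %/% 2L)
  amp <- 2 * Mod(z[half + 1L]) / sum(w)
  freq <- half / (n_pad * spacing)
  structure(list(period = 1 / freq, freq = freq, amplitude = amp,
                 pad_factor = pad_factor, window = window,
                 spacing = spacing, n = n),
            class = "mt_spectrum")
}

#' @export
print.mt_spectrum <- function(x, ...) {
  cat(sprintf("<mt_spectrum> %d bins (n = %d, pad x%g, %s window), periods %.0f..%.0f nm\n",
              length(x$amplitude), x$n, x$pad_factor, x$window,
              max(x$period), min(x$period)))
  invisible(x)
}

#' Dynamic baseline and detection threshold for a spectrum
#'
#' Fits a robust smooth baseline (low-order polynomial in log-period via
#' an M-estimator, so isolated peaks in the fitting support are
#' down-weighted) to the amplitudes *outside* the decoding region of
#' interest, and evaluates it across the ROI. The detection threshold is
#' the baseline scaled by the factor `k`, calibrated once against
#' white-noise profiles so that at most ~1% of ROI bins exceed it in the
#' absence of signal (see [calibrate_threshold_factor()]).
#'
#' @param spectrum An [amplitude_spectrum()].
#' @param roi Closed period interval (nm) being decoded
#'   (default `c(850, 1500)`).
#' @param k Threshold factor (default [default_threshold_factor()]).
#' @param fit_range Period range (nm) supplying baseline support
#'   (default `c(500, 4000)`); the ROI is excluded from the fit.
#' @param degree Polynomial degree in log-period (default 2).
#' @param exclude_freq Optional frequencies (cycles/nm) of known lines
#'   (harmonics and mixing products of detected peaks); support bins
#'   within 3/4 of a natural bin of any of them are masked out of the
#'   fit, unless that would empty one side of the support.
#' @return A list of class `mt_baseline`: `period`, `baseline`,
#'   `threshold` (all on the spectrum's grid restricted to `fit_range`),
#'   `k`, `roi`.
#' @export
fit_baseline <- function(spectrum, roi = c(850, 1500),
                         k = default_threshold_factor(),
                         fit_range = c(500, 4000), degree = 2,
                         exclude_freq = NULL) {
  stopifnot(inherits(spectrum, "mt_spectrum"))
  # fit on the natural (unpadded) bins only: between the coded lines the
  # padded grid carries the lines' sinc sidelobes, which are not noise
  # and would drag the baseline up; at natural bins on-bin lines leak
  # nothing, so natural bins measure the true noise floor
  pad <- as.integer(ceiling(spectrum$pad_factor))
  nat <- seq(pad, length(spectrum$amplitude), by = pad)
  p <- spectrum$period[nat]; a <- spectrum$amplitude[nat]
  in_range <- p >= fit_range[1] & p <= fit_range[2]
  in_roi <- p >= roi[1] & p <= roi[2]
  support <- in_range & !in_roi
  if (!any(support & p < roi[1]) || !any(support & p > roi[2]))
    stop_arg("spectrum must cover periods on both sides of the ROI")
  # mask bins occupied by known lines (harmonics / mixing products of
  # the detected peaks) so they never enter the noise-floor estimate
  if (length(exclude_freq) > 0L) {
    dfn <- 1 / (spectrum$n * spectrum$spacing)
    f_nat <- 1 / p
    masked <- vapply(f_nat, function(f)
      any(abs(f - exclude_freq) < 0.75 * dfn), logical(1))
    if (any(support & !masked & p < roi[1]) &&
        any(support & !masked & p > roi[2]))
      support <- support & !masked
  }
  # MM-estimation: the support bins also carry the pattern's harmonic and
  # difference-frequency lines (up to about half the bins), which must be
  # rejected as outliers, not averaged in -- hence a 50%-breakdown fit
  # the S-estimation initial step subsamples randomly; a fixed internal
  # seed keeps the whole readout deterministic (caller RNG is restored)
  lp <- log(p[support])
  eval_p <- p[in_range]
  if (sum(support) >= max(8L, 3L * (degree + 1L))) {
    fit <- with_seed(285713L,
                     MASS::rlm(a[support] ~ stats::poly(lp, degree),
                               method = "MM", maxit = 100))
    X <- stats::predict(fit, newdata = data.frame(lp = log(eval_p)))
  } else {
    # short windows leave too few support bins for a polynomial fit
    X <- rep(stats::median(a[support]), length(eval_p))
  }
  floor_amp <- 0.05 * stats::median(a[support])
  base <- pmax(X, floor_amp)
  structure(list(period = eval_p, baseline = base, threshold = k * base,
                 k = k, roi = roi),
            class = "mt_baseline")
}

baseline_at <- function(bl, period) {
  stats::approx(bl$period, bl$baseline, xout = period, rule = 2)$y
}
threshold_at <- function(bl, period) {
  stats::approx(bl$period, bl$threshold, xout = period, rule = 2)$y
}

#' Default spectral detection threshold factor
#'
#' Frozen result of [calibrate_threshold_factor()] at its defaults: the
#' multiple of the dynamic baseline that white-noise profiles exceed in
#' at most ~1% of ROI bins.
#'
#' @return A single number.
#' @export
default_threshold_factor <- function() 3.8

#' Calibrate the threshold factor against white noise
#'
#' Simulates pure white-noise profiles (no spatial signal), computes
#' their amplitude spectra and dynamic baselines, and returns the factor
#' `k` such that the per-bin false-positive rate inside the ROI (fraction
#' of ROI bins with amplitude above `k` times the baseline) equals
#' `target_fpr`.
#'
#' @param n_sim Number of simulated profiles (default 1000).
#' @param n_samples Profile length (default 225, a 12 um region on the
#'   3x-interpolated 160 nm pixel grid).
#' @param spacing Sample spacing nm (default 160/3).
#' @param roi,fit_range,pad_factor As in [fit_baseline()].
#' @param target_fpr Target per-bin false-positive rate (default 0.01).
#' @param seed Integer seed.
#' @return The calibrated factor `k`.
#' @export
calibrate_threshold_factor <- function(n_sim = 1000, n_samples = 225,
                                       spacing = 160 / 3,
                                       roi = c(850, 1500),
                                       fit_range = c(500, 4000),
                                       pad_factor = 8,
                                       target_fpr = 0.01, seed = 1) {
  ratios <- with_seed(seed, {
    unlist(lapply(seq_len(n_sim), function(i) {
      y <- stats::rnorm(n_samples)
      sp <- amplitude_spectrum(y, pad_factor = pad_factor, spacing = spacing)
      bl <- fit_baseline(sp, roi = roi, k = 1, fit_range = fit_range)
      pad <- as.integer(ceiling(sp$pad_factor))
      nat <- seq(pad, length(sp$amplitude), by = pad)  # bins used in detection
      pn <- sp$period[nat]
      in_roi <- pn >= roi[1] & pn <= roi[2]
      sp$amplitude[nat][in_roi] / baseline_at(bl, pn[in_roi])
    }))
  })
  as.numeric(stats::quantile(ratios, 1 - target_fpr, names = FALSE))
}

# Candidate periods: local maxima of the spectrum sampled at its NATURAL
# (unpadded) frequency bins inside the ROI that exceed the baseline.
# The bleached region spans an integer number of cycles of every coded
# period (the borders are the first and last bleached line), so the
# coded lines fall exactly on natural bins, where the Dirichlet
# sidelobes and |.|-interference tilt of all other on-bin lines vanish;
# detecting on the padded grid instead would let slowly decaying
# rectangular-window sidelobes displace peaks and spawn spurious maxima
# between the lines. Candidates closer than `merge_width` merge to the
# larger one.
find_candidates <- function(spectrum, bl, roi, merge_width = 60) {
  a <- spectrum$amplitude; p <- spectrum$period
  pad <- as.integer(ceiling(spectrum$pad_factor))
  nat <- seq(pad, length(a), by = pad)     # padded indices of natural bins
  an <- a[nat]; pn <- p[nat]
  m <- length(nat)
  # extend the search window by one natural-bin step at each edge so a
  # line sitting exactly on an ROI boundary is not lost to quantization
  dfn <- 1 / (spectrum$n * spectrum$spacing)
  lo <- roi[1] - roi[1]^2 * dfn
  hi <- roi[2] + roi[2]^2 * dfn
  sel <- which(pn >= lo & pn <= hi)
  sel <- sel[sel > 1L & sel < m]
  if (length(sel) == 0L) return(NULL)
  lmax <- sel[an[sel] > an[sel - 1L] & an[sel] >= an[sel + 1L]]
  lmax <- lmax[an[lmax] > baseline_at(bl, pn[lmax])]
  if (length(lmax) == 0L) return(NULL)
  ord <- order(an[lmax], decreasing = TRUE)
  keep <- logical(length(lmax))
  taken <- numeric(0)
  for (i in ord) {
    if (all(abs(pn[lmax[i]] - taken) >= merge_width)) {
      keep[i] <- TRUE
      taken <- c(taken, pn[lmax[i]])
    }
  }
  data.frame(idx = nat[lmax[keep]], period = pn[lmax[keep]],
             amplitude = an[lmax[keep]])
}

#' Bootstrap confidence intervals and significance of spectral peaks
#'
#' Candidate periods are the local maxima of the full-stack spectrum
#' inside the ROI that exceed the dynamic baseline. Frames are resampled
#' with replacement `n_boot` times (whole frames, preserving within-frame
#' correlation; the stored alignment shifts are reused); each resample is
#' re-averaged and re-transformed, and the percentile interval of each
#' candidate's amplitude across resamples forms its confidence interval.
#' A candidate is significant when the lower CI bound exceeds the
#' threshold at its period. The interval is widened, if necessary, to
#' contain the full-stack point amplitude.
#'
#' @param aligned An [align_and_average()] result (>= 2 frames).
#' @param region A `bleached_region`.
#' @param roi Decoding period interval (nm).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param level CI level (default 0.95).
#' @param k Threshold factor.
#' @param pad_factor,window As in [amplitude_spectrum()].
#' @param merge_width Candidates closer than this (nm) merge (default
#'   60, about one tolerance-bin width).
#' @param rel_min Relative-amplitude floor of the threshold (default
#'   0.1): the threshold at each candidate is at least `rel_min` times
#'   the largest candidate amplitude, rejecting the phase-noise
#'   sidebands that velocity jitter spreads around a dominant line
#'   (a few percent of its amplitude) while keeping genuine bits, which
#'   are written at comparable dose and stay above ~30% relative
#'   amplitude. `0` disables the floor.
#' @param seed Integer seed for the resampling.
#' @param candidates Optional numeric vector of periods (nm) to evaluate
#'   instead of auto-detected peaks (each is mapped to its nearest grid
#'   bin).
#' @return A data frame of class `period_detections`: `period`,
#'   `amplitude`, `ci_low`, `ci_high`, `baseline`, `threshold`, `snr`
#'   (amplitude / threshold), `significant`.
#' @export
bootstrap_detections <- function(aligned, region, roi = c(850, 1500),
                                 n_boot = 1000, level = 0.95,
                                 k = default_threshold_factor(),
                                 pad_factor = 8, window = "rect",
                                 merge_width = 60, rel_min = 0.1,
                                 seed = NULL, candidates = NULL) {
  stopifnot(inherits(aligned, "aligned_profiles"),
            inherits(region, "bleached_region"))
  Yl <- aligned$aligned
  pos <- aligned$positions
  if (nrow(Yl) < 2L)
    stop(errorCondition("bootstrap needs at least 2 frames",
                        class = c("InsufficientFrames", "mtbarcode_error")))
  # right-exclusive crop: the DFT treats n samples as one period of
  # length n * spacing, so [left, right) makes the transform length equal
  # the border-to-border distance (an integer number of coded cycles).
  # The detected border minima can sit one sample inside the true bleach
  # line centers (the dips have asymmetric shoulders), so the crop is
  # refined over +/- 1 sample at each border, keeping the crop whose ROI
  # energy concentrates best onto the natural bins.
  spacing <- pos[2] - pos[1]
  i0 <- region$left_idx
  i1 <- region$right_idx      # inclusive index of the right border sample
  if (i1 - i0 < 8L) stop_arg("bleached region covers too few samples")
  best <- NULL; best_e <- -Inf
  for (dl in c(0L, -1L, 1L)) for (dr in c(0L, -1L, 1L)) {
    a0 <- i0 + dl; a1 <- i1 + dr
    if (a0 < 1L || a1 > length(pos) || a1 - a0 < 8L) next
    avg <- colMeans(Yl[, a0:(a1 - 1L), drop = FALSE])
    sp0 <- amplitude_spectrum(avg, pad_factor = 1, window = window,
                              spacing = spacing)
    e <- sum(sp0$amplitude[sp0$period >= roi[1] & sp0$period <= roi[2]]^2)
    if (e > best_e) { best_e <- e; best <- c(a0, a1) }
  }
  Yr <- Yl[, best[1]:(best[2] - 1L), drop = FALSE]

  full_avg <- colMeans(Yr)
  spec <- amplitude_spectrum(full_avg, pad_factor = pad_factor,
                             window = window, spacing = spacing)
  bl <- fit_baseline(spec, roi = roi, k = k)
  cand <- if (is.null(candidates)) {
    find_candidates(spec, bl, roi, merge_width)
  } else {
    idx <- vapply(candidates, function(pp) which.min(abs(spec$period - pp)),
                  integer(1))
    data.frame(idx = idx, period = candidates, amplitude = spec$amplitude[idx])
  }
  if (!is.null(cand) && nrow(cand) > 0L) {
    # second pass: the candidates' harmonics and intermodulation products
    # (2f, 3f, f_i +/- f_j, 2f_i +/- f_j) are real lines that sit in the
    # baseline support and would inflate the noise-floor estimate; mask
    # them and refit
    f <- 1 / cand$period
    pairs <- expand.grid(i = seq_along(f), j = seq_along(f))
    fex <- unique(abs(c(2 * f, 3 * f,
                        f[pairs$i] + f[pairs$j], f[pairs$i] - f[pairs$j],
                        2 * f[pairs$i] + f[pairs$j],
                        2 * f[pairs$i] - f[pairs$j])))
    fex <- fex[fex > 0]
    bl <- fit_baseline(spec, roi = roi, k = k, exclude_freq = fex)
    cand <- if (is.null(candidates)) find_candidates(spec, bl, roi, merge_width)
            else cand
  }
  empty <- data.frame(period = numeric(0), amplitude = numeric(0),
                      ci_low = numeric(0), ci_high = numeric(0),
                      baseline = numeric(0), threshold = numeric(0),
                      snr = numeric(0), significant = logical(0))
  if (is.null(cand) || nrow(cand) == 0L)
    return(structure(empty, class = c("period_detections", "data.frame"),
                     spectrum = spec, baseline_fit = bl))

  nf <- nrow(Yr)
  w <- if (window == "hann") hann_window(ncol(Yr)) else rep(1, ncol(Yr))
  n_pad <- as.integer(ceiling(pad_factor) * ncol(Yr))
  boot_amp <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      avg <- colMeans(Yr[sample.int(nf, nf, replace = TRUE), , drop = FALSE])
      z <- stats::fft(c((avg - mean(avg)) * w, rep(0, n_pad - ncol(Yr))))
      2 * Mod(z[cand$idx + 1L]) / sum(w)
    }, numeric(nrow(cand)))
  })
  boot_amp <- matrix(boot_amp, nrow = nrow(cand))
  alpha <- (1 - level) / 2
  ci <- t(apply(boot_amp, 1L, stats::quantile,
                probs = c(alpha, 1 - alpha), names = FALSE))
  out <- data.frame(
    period = cand$period,
    amplitude = cand$amplitude,
    ci_low = pmin(ci[, 1], cand$amplitude),
    ci_high = pmax(ci[, 2], cand$amplitude),
    baseline = baseline_at(bl, cand$period),
    threshold = threshold_at(bl, cand$period))
  # second threshold component: velocity jitter phase-modulates every
  # written line, spreading a few percent of a strong line's amplitude
  # into neighbouring bins as sidebands. Real bits are all written with
  # comparable dose (relative amplitudes >~ 0.3 of the largest line), so
  # a floor at rel_min of the largest candidate rejects sidebands (and
  # speckle flukes riding on a dominant line) without touching real bits.
  if (rel_min > 0 && nrow(out) > 0L)
    out$threshold <- pmax(out$threshold, rel_min * max(out$amplitude))
  out$snr <- out$amplitude / out$threshold
  out$significant <- out$ci_low > out$threshold
  out <- out[order(out$period), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("period_detections", "data.frame"),
            spectrum = spec, baseline_fit = bl)
}

#' Decode configuration
#'
#' Bundles the tunable readout parameters with their defaults: the
#' 850--1500 nm decoding ROI, 8-fold zero padding, the white-noise
#' calibrated threshold factor, 1000 bootstrap resamples at the 95% CI
#' level, the 3-fold sub-pixel interpolation with 3 transverse samples,
#' and an optional manual region override `c(left, right)` in nm.
#'
#' @param roi,pad_factor,k,n_boot,level,interp_factor,transverse_px,
#'   merge_width,smoothing,region,seed See the respective operations.
#' @return A list of class `decode_config`.
#' @export
decode_config <- function(roi = c(850, 1500), pad_factor = 8,
                          k = default_threshold_factor(), n_boot = 1000,
                          level = 0.95, interp_factor = 3L,
                          transverse_px = 3L, merge_width = 60,
                          rel_min = 0.1, window = "rect", smoothing = NULL,
                          region = NULL, seed = NULL) {
  structure(list(roi = roi, pad_factor = pad_factor, k = k, n_boot = n_boot,
                 level = level, interp_factor = interp_factor,
                 transverse_px = transverse_px, merge_width = merge_width,
                 rel_min = rel_min, window = window, smoothing = smoothing,
                 region = region, seed = seed),
            class = "decode_config")
}

#' Read a barcode from a frame stack and track
#'
#' Runs the full readout pipeline: per-frame profile extraction along the
#' track, cross-correlation alignment and averaging, bleached-region
#' detection (or manual override), Fourier analysis with dynamic baseline
#' and bootstrap significance, and code assembly from the significant
#' detections.
#'
#' @param stack A `frame_stack` (see [read_stack()] /
#'   [simulate_barcode_stack()]).
#' @param track Track table (`frame`, `index`, `x_nm`, `y_nm`).
#' @param scheme A [barcode_scheme()].
#' @param config A [decode_config()].
#' @return A list of class `barcode_readout`: `code`, `detections`,
#'   `region`, `diagnostics` (out-of-band detections, frame count,
#'   alignment shifts, config echo), `profile` (the averaged profile).
#' @export
read_barcode <- function(stack, track, scheme = barcode_scheme(),
                         config = decode_config()) {
  stopifnot(inherits(scheme, "barcode_scheme"),
            inherits(config, "decode_config"))
  profiles <- extract_profiles(stack, track,
                               interp_factor = config$interp_factor,
                               transverse_px = config$transverse_px)
  aligned <- align_and_average(profiles)
  region <- if (is.null(config$region)) {
    find_bleached_region(aligned$average, smoothing = config$smoothing,
                         min_length = max(scheme$periods))
  } else {
    override_region(aligned$average, config$region[1], config$region[2])
  }
  det <- bootstrap_detections(aligned, region, roi = config$roi,
                              n_boot = config$n_boot, level = config$level,
                              k = config$k, pad_factor = config$pad_factor,
                              window = config$window,
                              merge_width = config$merge_width,
                              rel_min = config$rel_min,
                              seed = config$seed)
  sig <- det$period[det$significant]
  # Bin matching with a quantization allowance: detected periods are
  # quantized to the natural bins T/k of the cropped window, a grid
  # coarser than the tolerance bins themselves, so a detection matches a
  # bin when the bin lies within half a natural-bin step (the
  # quantization cell) above its upper edge. The bins' own downward
  # extent absorbs the other half.
  spec <- attr(det, "spectrum")
  dfn <- 1 / (spec$n * spec$spacing)
  code <- code_for_detections(sig, scheme, slack = 0.5 * sig^2 * dfn)
  structure(
    list(code = as.integer(code),
         detections = det,
         region = region,
         profile = aligned$average,
         diagnostics = list(out_of_band = attr(code, "out_of_band"),
                            n_frames = nrow(aligned$aligned),
                            shifts_nm = aligned$shifts_nm,
                            config = config)),
    class = "barcode_readout")
}

#' @export
print.barcode_readout <- function(x, ...) {
  cat(sprintf("<barcode_readout> code %d (binary %s)\n", x$code,
              paste(rev(as.integer(intToBits(x$code))[1:4]), collapse = "")))
  print(x$region)
  if (nrow(x$detections) > 0L) {
    df <- x$detections
    df$period <- round(df$period)
    print(df, digits = 3)
  } else cat("no candidate periods in ROI\n")
  if (length(x$diagnostics$out_of_band) > 0L)
    cat("out-of-band detections at",
        paste(round(x$diagnostics$out_of_band), collapse = ", "), "nm\n")
  invisible(x)
}
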