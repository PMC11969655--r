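# Synthetic-data generator: a dye-speckled filament gliding through a
# pulsed Gaussian bleaching beam, rendered as EMCCD-like frames.
#
# Coordinate conventions: arc-length a runs from the leading tip (a = 0)
# towards the trailing end, in nm. Lab x is the gliding axis; the bleach
# line sits at lab x = 0 and the filament moves towards +x. At schedule
# time t = 0 the leading tip has already passed the line by `lead_in`
# (the operator waits until ~4 um of filament has crossed before encoding
# starts), so a fluorophore at arc a sits at lab x = lead_in + x(t) - a
# and the bleach line illuminates arc position a* = lead_in + x(t).

#' Motion parameters of a gliding filament
#'
#' @param v_x Mean gliding velocity (nm/s, default 1000).
#' @param jitter_fraction SD of the per-step velocity relative to `v_x`
#'   (default 0.03); kinesin stepping noise largely averages out over many
#'   motors, leaving a small white velocity jitter.
#' @param dt Integration step (s, default 0.005, one bleach-pulse duration).
#' @param lead_in Filament length already past the bleach line when the
#'   schedule starts (nm, default 4000).
#' @return A list of class `motion_params`.
#' @export
motion_params <- function(v_x = 1000, jitter_fraction = 0.03, dt = 0.005,
                          lead_in = 4000) {
  if (v_x <= 0 || jitter_fraction < 0 || dt <= 0 || lead_in < 0)
    stop_arg("invalid motion parameters")
  structure(list(v_x = v_x, jitter_fraction = jitter_fraction, dt = dt,
                 lead_in = lead_in), class = "motion_params")
}

#' Optics parameters
#'
#' Defaults reflect a 1.49 NA / 100x TIRF objective with 488 nm
#' excitation: an imaging PSF of sigma ~ 90 nm (~0.21 lambda / NA at the
#' ~520 nm emission), a 160 nm camera pixel (16 um EMCCD pixel / 100x),
#' and a bleaching-beam sigma of 180 nm, consistent with a ~0.6 um focused
#' spot (FWHM ~0.42 um, 99% of the dose within ~0.9 um) and an effective
#' bleaching resolution of ~500 nm (the shortest period with usable
#' modulation transfer).
#'
#' @param psf_sigma Imaging PSF sigma (nm).
#' @param beam_sigma Bleaching-beam sigma along the gliding axis (nm).
#' @param excitation_wavelength nm (record-keeping only).
#' @param pixel_size Camera pixel size in sample space (nm).
#' @export
optics_params <- function(psf_sigma = 90, beam_sigma = 180,
                          excitation_wavelength = 488, pixel_size = 160) {
  if (any(c(psf_sigma, beam_sigma, excitation_wavelength, pixel_size) <= 0))
    stop_arg("optics parameters must all be positive")
  structure(list(psf_sigma = psf_sigma, beam_sigma = beam_sigma,
                 excitation_wavelength = excitation_wavelength,
                 pixel_size = pixel_size), class = "optics_params")
}

#' EMCCD camera parameters
#'
#' The electron-multiplying register is modelled as a Gamma-distributed
#' amplification of the Poisson photo-electron count (shape = n electrons,
#' scale = EM gain), which reproduces the EMCCD excess-noise factor of
#' sqrt(2). Output counts are electrons / `e_per_adu` plus Gaussian read
#' noise and a fixed offset, clamped to the 16-bit range.
#'
#' @param exposure Exposure time (s, default 0.05).
#' @param em_gain EM gain (default 300).
#' @param read_noise Read noise SD in output counts (ADU).
#' @param offset Camera bias offset (ADU).
#' @param photons_per_fluorophore Expected detected photons per surviving
#'   fluorophore per exposure (default 5, typical of low-power TIRF
#'   imaging at 1% laser power).
#' @param e_per_adu Electrons per output count after the EM register
#'   (default 16).
#' @export
camera_params <- function(exposure = 0.05, em_gain = 300, read_noise = 2,
                          offset = 100, photons_per_fluorophore = 5,
                          e_per_adu = 16) {
  if (exposure <= 0 || em_gain < 1 || read_noise < 0 || offset < 0 ||
      photons_per_fluorophore < 0 || e_per_adu <= 0)
    stop_arg("invalid camera parameters")
  structure(list(exposure = exposure, em_gain = em_gain,
                 read_noise = read_noise, offset = offset,
                 photons_per_fluorophore = photons_per_fluorophore,
                 e_per_adu = e_per_adu), class = "camera_params")
}

#' Generate a randomly labeled filament
#'
#' Fluorophore positions model the speckling caused by the stochastic
#' labeling and assembly of the filament: the number of dyes is Poisson
#' with mean `labeling_density * length` and positions are uniform along
#' the filament.
#'
#' @param length Filament length (nm), > 0.
#' @param labeling_density Expected dyes per nm (default 1); 0 gives an
#'   unlabeled filament.
#' @param seed Integer seed (optional).
#' @return A list of class `filament`: `length`, `positions` (arc-length
#'   nm from the leading tip), `survival_prob`, `survival` (all `TRUE`
#'   before bleaching), `labeling_density`.
#' @export
generate_filament <- function(length, labeling_density = 1, seed = NULL) {
  if (!is_scalar_number(length) || length <= 0)
    stop_arg("'length' must be a positive filament length in nm")
  if (!is_scalar_number(labeling_density) || labeling_density < 0)
    stop_arg("'labeling_density' must be >= 0")
  with_seed(seed, {
    n <- stats::rpois(1L, labeling_density * length)
    pos <- sort(stats::runif(n, 0, length))
    structure(list(length = length, positions = pos,
                   survival_prob = rep(1, n), survival = rep(TRUE, n),
                   labeling_density = labeling_density),
              class = "filament")
  })
}

#' Simulate gliding motion with white velocity jitter
#'
#' Arc-length offset x(t) with x(0) = 0 and independent Gaussian
#' increments of mean `v_x * dt` and SD `jitter_fraction * v_x * dt`;
#' negative increments are clamped to zero (the gliding filament does not
#' move backwards).
#'
#' @param motion A [motion_params()].
#' @param duration Total time (s); `0` returns the single sample x = 0.
#' @param seed Integer seed (optional).
#' @return A list of class `motion_trace` with `t` and `x` (nm).
#' @export
simulate_motion <- function(motion, duration, seed = NULL) {
  stopifnot(inherits(motion, "motion_params"))
  if (!is_scalar_number(duration) || duration < 0)
    stop_arg("'duration' must be >= 0")
  n <- ceiling(duration / motion$dt)
  x <- with_seed(seed, {
    if (n == 0L) 0
    else {
      inc <- stats::rnorm(n, motion$v_x * motion$dt,
                          motion$jitter_fraction * motion$v_x * motion$dt)
      c(0, cumsum(pmax(inc, 0)))
    }
  })
  structure(list(t = seq(0, by = motion$dt, length.out = n + 1L), x = x),
            class = "motion_trace")
}

motion_offset_at <- function(trace, t) {
  if (any(t < trace$t[1] - 1e-9 | t > trace$t[length(trace$t)] + 1e-9))
    stop_arg(sprintf("time %.3f s is outside the simulated motion (0..%.3f s)",
                     max(t), trace$t[length(trace$t)]))
  stats::approx(trace$t, trace$x, xout = t, rule = 2)$y
}

#' Apply a pulsed-beam bleaching schedule to a filament
#'
#' Each laser event deposits a Gaussian dose profile across the filament,
#' centred on the bleach line. A fluorophore at distance d from the line
#' during an event keeps its fluorophore with probability
#' `exp(-dose * exp(-d^2 / (2 beam_sigma^2)))`; doses from all events
#' multiply. Survival is then sampled once per fluorophore from the
#' accumulated probability.
#'
#' @param filament A [generate_filament()] result.
#' @param trace A [simulate_motion()] result covering all event times.
#' @param schedule A [make_schedule()] result.
#' @param beam_sigma Bleaching-beam sigma (nm).
#' @param dose Peak e-folding exposures per event; the default 0.7
#'   bleaches ~50% of the dyes at the line centre in a single 5 ms event,
#'   deep enough for clear line contrast while keeping the superposed
#'   4-bit dose in the quasi-linear regime (strong nonlinearity mixes the
#'   coded combs into intermodulation lines on other code positions).
#' @param lead_in Filament length already past the line at schedule t = 0
#'   (nm).
#' @param seed Integer seed for the per-fluorophore survival draws.
#' @return The filament with updated `survival_prob` and `survival`.
#' @export
apply_bleaching <- function(filament, trace, schedule, beam_sigma = 180,
                            dose = 0.7, lead_in = 4000, seed = NULL) {
  stopifnot(inherits(filament, "filament"), inherits(trace, "motion_trace"),
            inherits(schedule, "bleach_schedule"))
  if (dose < 0) stop_arg("'dose' must be >= 0")
  t_max <- trace$t[length(trace$t)]
  late <- schedule$event_times[schedule$event_times > t_max + 1e-9]
  if (length(late) > 0L)
    stop_arg(sprintf("bleach event at t = %.3f s is after the motion ends (%.3f s)",
                     late[1], t_max))
  if (length(filament$positions) == 0L || dose == 0) return(filament)
  # event midpoints; over 5 ms the filament moves ~5 nm, negligible smear
  t_ev <- schedule$event_times + schedule$event_duration / 2
  t_ev <- pmin(t_ev, t_max)
  wts <- schedule$event_weights
  if (is.null(wts)) wts <- rep(1, length(t_ev))
  line_arc <- lead_in + motion_offset_at(trace, t_ev)
  total_dose <- rep(0, length(filament$positions))
  for (i in seq_along(line_arc)) {
    d <- filament$positions - line_arc[i]
    total_dose <- total_dose + wts[i] * dose * exp(-d^2 / (2 * beam_sigma^2))
  }
  p_surv <- filament$survival_prob * exp(-total_dose)
  surv <- with_seed(seed, stats::runif(length(p_surv)) < p_surv)
  filament$survival_prob <- p_surv
  filament$survival <- surv
  filament
}

#' Render EMCCD frames and the ground-truth track
#'
#' Each surviving fluorophore contributes a 2-D Gaussian (the imaging PSF,
#' broadened along x by motion blur over the exposure) of
#' `photons_per_fluorophore` expected photons. With `noise = TRUE`, photon
#' shot noise, Gamma EM amplification, Gaussian read noise and the camera
#' offset are applied and frames are quantized to the 16-bit range; with
#' `noise = FALSE` the expected-value image is returned un-quantized.
#'
#' @param filament Filament (after bleaching).
#' @param trace Motion trace covering all frame exposures.
#' @param optics,camera [optics_params()] / [camera_params()].
#' @param frame_times Exposure start times (s), strictly increasing.
#' @param lead_in As in [apply_bleaching()].
#' @param noise Apply the stochastic camera model?
#' @param seed Integer seed.
#' @return List with `stack` (class `frame_stack`: `frames`, `timestamps`,
#'   `pixel_size`, `origin_nm`) and `track` (data frame `frame`, `index`,
#'   `x_nm`, `y_nm`; leading end first, image coordinates where pixel
#'   column/row 1 is at 0 nm).
#' @export
render_frames <- function(filament, trace, optics = optics_params(),
                          camera = camera_params(), frame_times,
                          lead_in = 4000, noise = TRUE, seed = NULL) {
  stopifnot(inherits(filament, "filament"), inherits(trace, "motion_trace"),
            inherits(optics, "optics_params"), inherits(camera, "camera_params"))
  if (length(frame_times) == 0L || is.unsorted(frame_times, strictly = TRUE))
    stop_arg("'frame_times' must be non-empty and strictly increasing")
  px <- optics$pixel_size
  t_mid <- frame_times + camera$exposure / 2
  tip <- lead_in + motion_offset_at(trace, t_mid)

  # motion blur over the exposure adds variance (v * exposure)^2 / 12
  v_eff <- if (length(t_mid) > 1L) diff(range(tip)) / diff(range(t_mid)) else
    trace$x[length(trace$x)] / max(trace$t[length(trace$t)], 1e-9)
  sigma_x <- sqrt(optics$psf_sigma^2 + (v_eff * camera$exposure)^2 / 12)

  fine <- px / 8
  margin <- 6 * sigma_x + 2 * px
  x_lo <- min(tip) - filament$length - margin
  x_hi <- max(tip) + margin
  x_origin <- floor(x_lo / px) * px           # pixel column 1 centred here
  nx <- ceiling((x_hi - x_origin) / px) + 1L
  ny <- 15L
  y0_row <- (ny + 1L) / 2
  y0_nm <- (y0_row - 1) * px

  # transverse PSF weight per pixel row (pixel-integrated Gaussian)
  row_edges <- ((0:ny) - 0.5) * px
  yw <- diff(stats::pnorm(row_edges, mean = y0_nm, sd = optics$psf_sigma))

  # x kernel on the fine grid, normalized so each fluorophore deposits
  # exactly one unit across the grid (photon conservation)
  kh <- ceiling(5 * sigma_x / fine)
  kern <- exp(-((-kh:kh) * fine)^2 / (2 * sigma_x^2))
  kern <- kern / sum(kern)
  n_fine <- nx * 8L

  surv_pos <- filament$positions[filament$survival]
  frames <- vector("list", length(frame_times))
  track_rows <- vector("list", length(frame_times))
  arc_s <- seq(0, filament$length, by = px)

  with_seed(seed, {
    for (f in seq_along(frame_times)) {
      lab_x <- tip[f] - surv_pos
      idx <- round((lab_x - x_origin) / fine) + 1L
      if (length(idx) > 0L && (min(idx) <= kh || max(idx) > n_fine - kh))
        stop_arg("filament leaves the rendered frame; enlarge the margin")
      dep <- numeric(n_fine)
      if (length(idx) > 0L) {
        tb <- tabulate(idx, nbins = n_fine)
        dep <- stats::convolve(tb, rev(kern), type = "open")
        dep <- dep[(kh + 1L):(kh + n_fine)]
      }
      dep <- pmax(dep, 0)   # FFT convolution can leave ~1e-12 negatives
      colx <- camera$photons_per_fluorophore *
        colSums(matrix(dep, nrow = 8L))     # aggregate 8 fine cells / pixel
      expected <- outer(yw, colx)           # [row, col] expected photons
      if (noise) {
        n_ph <- stats::rpois(length(expected), expected)
        elec <- numeric(length(n_ph))
        pos <- n_ph > 0L
        elec[pos] <- stats::rgamma(sum(pos), shape = n_ph[pos],
                                   scale = camera$em_gain)
        adu <- elec / camera$e_per_adu +
          stats::rnorm(length(elec), 0, camera$read_noise) + camera$offset
        fr <- matrix(pmin(pmax(round(adu), 0), 65535), nrow = ny)
      } else {
        fr <- matrix(expected * camera$em_gain / camera$e_per_adu +
                       camera$offset, nrow = ny)
      }
      frames[[f]] <- fr
      track_rows[[f]] <- data.frame(
        frame = f, index = seq_along(arc_s),
        x_nm = (tip[f] - arc_s) - x_origin, y_nm = y0_nm)
    }
  })
  stack <- structure(list(frames = frames, timestamps = frame_times,
                          pixel_size = px, origin_nm = x_origin),
                     class = "frame_stack")
  list(stack = stack, track = do.call(rbind, track_rows))
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_stack> %d frames of %d x %d px (%g nm/px), t = %.2f..%.2f s\n",
              length(x$frames), d[1], d[2], x$pixel_size,
              min(x$timestamps), max(x$timestamps)))
  invisible(x)
}

#' Simulate a complete barcode experiment
#'
#' End-to-end synthetic data: builds the bleach schedule for `code`,
#' simulates the gliding filament through the pulsed beam, then images it
#' for `n_frames` exposures after the last bleach event. Code 0 produces
#' an unbleached stack (no schedule), which the decoder rejects because it
#' has no bleached region.
#'
#' @param code Integer code, `0 .. 2^n_bits - 1`.
#' @param scheme A [barcode_scheme()].
#' @param motion,optics,camera Parameter objects.
#' @param dose Peak bleach dose per event (see [apply_bleaching()]).
#' @param filament_length nm (default 20000; long filaments are selected
#'   so the encoded region plus lead-in fits with unbleached plateaus).
#' @param labeling_density Dyes per nm (default 6.5, fully labeled
#'   tubulin: ~1.6 dimers per nm of lattice, up to 4 amine-reactive dye
#'   sites per dimer).
#' @param region_length Length of the encoded region (nm).
#' @param n_frames,frame_interval,imaging_delay Imaging protocol: frames
#'   start `imaging_delay` s after the last bleach event, spaced
#'   `frame_interval` s.
#' @param noise Apply the stochastic camera model?
#' @param seed Integer seed controlling every random draw.
#' @return List `stack`, `track`, `truth` (code, schedule, filament with
#'   survival map, motion trace, parameter echo).
#' @export
simulate_barcode_stack <- function(code, scheme = barcode_scheme(),
                                   motion = motion_params(),
                                   optics = optics_params(),
                                   camera = camera_params(),
                                   dose = 0.7,
                                   filament_length = 20000,
                                   labeling_density = 6.5,
                                   region_length = 12000,
                                   n_frames = 20, frame_interval = 0.2,
                                   imaging_delay = 0.5,
                                   noise = TRUE, seed = NULL) {
  periods <- periods_for_code(code, scheme)
  schedule <- if (length(periods) > 0L)
    make_schedule(periods, motion$v_x, region_length) else NULL
  t_bleach_end <- if (is.null(schedule)) 0 else
    max(schedule$event_times) + schedule$event_duration
  frame_times <- t_bleach_end + imaging_delay +
    (seq_len(n_frames) - 1L) * frame_interval
  duration <- max(frame_times) + camera$exposure + motion$dt

  trace <- simulate_motion(motion, duration, seed = child_seed(seed, 1L))
  fil <- generate_filament(filament_length, labeling_density,
                           seed = child_seed(seed, 2L))
  if (!is.null(schedule))
    fil <- apply_bleaching(fil, trace, schedule,
                           beam_sigma = optics$beam_sigma, dose = dose,
                           lead_in = motion$lead_in,
                           seed = child_seed(seed, 3L))
  rf <- render_frames(fil, trace, optics, camera, frame_times,
                      lead_in = motion$lead_in, noise = noise,
                      seed = child_seed(seed, 4L))
  list(stack = rf$stack, track = rf$track,
       truth = list(code = as.integer(code), schedule = schedule,
                    filament = fil, trace = trace,
                    params = list(motion = motion, optics = optics,
                                  camera = camera, dose = dose,
                                  region_length = region_length,
                                  noise = noise, seed = seed)))
}

#' Expected bleached-intensity profile (no sampling)
#'
#' Analytic expectation of the fluorescence-vs-arc-length profile after a
#' schedule: labeling density times the survival probability of the summed
#' Gaussian dose, convolved with the imaging PSF. Useful as ground truth
#' for the shape of the bleached pattern (e.g. harmonic content of long
#' spatial periods).
#'
#' @param schedule A [make_schedule()] (constant velocity assumed).
#' @param arc Grid of arc positions (nm) relative to the start of the
#'   encoded region.
#' @param beam_sigma,psf_sigma nm.
#' @param dose Peak dose per event.
#' @return Numeric vector, relative intensity on `arc` (1 = unbleached).
#' @export
expected_bleach_profile <- function(schedule, arc, beam_sigma = 180,
                                    psf_sigma = 90, dose = 0.7) {
  stopifnot(inherits(schedule, "bleach_schedule"))
  centers <- schedule$event_times * schedule$v_x
  wts <- schedule$event_weights
  if (is.null(wts)) wts <- rep(1, length(centers))
  total <- rep(0, length(arc))
  for (i in seq_along(centers))
    total <- total + wts[i] * dose * exp(-(arc - centers[i])^2 / (2 * beam_sigma^2))
  surv <- exp(-total)
  # PSF blur on the arc grid
  h <- arc[2] - arc[1]
  kh <- ceiling(5 * psf_sigma / h)
  kern <- exp(-((-kh:kh) * h)^2 / (2 * psf_sigma^2))
  kern <- kern / sum(kern)
  n <- length(surv)
  padded <- c(rep(surv[1], kh), surv, rep(surv[n], kh))
  out <- stats::convolve(padded, rev(kern), type = "open")
  out[(2 * kh + 1L):(2 * kh + n)]
}
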