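# Readers/writers tying the pipeline together: 16-bit multi-page TIFF
# stacks, tab-separated track tables, JSON sidecars (scheme, schedule,
# ground truth, readout) and the YAML run configuration.
#
# Unit convention throughout files and APIs: lengths in nm, times in s.
#
# Track table layout (tab-separated, header line):
#   frame  index  x_nm  y_nm
# One row per centerline point, ordered from the leading end (index 1).
# External tracker output can be converted by resampling each frame's
# centerline to roughly one point per pixel and expressing coordinates in
# nm with pixel column/row 1 at 0 nm.

#' Write a frame stack as 16-bit multi-page TIFF
#'
#' @param stack A `frame_stack`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  imgs <- lapply(stack$frames, function(f)
    pmin(pmax(round(f), 0), 65535) / 65535)
  tiff::writeTIFF(imgs, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a multi-page TIFF as a frame stack
#'
#' @param path TIFF file.
#' @param pixel_size nm per pixel (default 160).
#' @param frame_interval Nominal frame spacing in s for the timestamps.
#' @return A `frame_stack` with counts in 0..65535.
#' @export
read_stack <- function(path, pixel_size = 160, frame_interval = 0.2) {
  if (!file.exists(path)) stop_arg(sprintf("no such file: %s", path))
  imgs <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                   error = function(e)
                     stop_arg(sprintf("cannot read TIFF '%s': %s", path,
                                      conditionMessage(e))))
  if (!is.list(imgs)) imgs <- list(imgs)
  imgs <- lapply(imgs, function(m) {
    if (length(dim(m)) == 3L) m <- m[, , 1]
    matrix(as.numeric(m), nrow = nrow(m))
  })
  structure(list(frames = imgs,
                 timestamps = (seq_along(imgs) - 1L) * frame_interval,
                 pixel_size = pixel_size, origin_nm = 0),
            class = "frame_stack")
}

#' Write / read a track table
#'
#' Plain-text, tab-separated, with a header line and columns
#' `frame`, `index`, `x_nm`, `y_nm` (see the format notes in this file's
#' documentation source).
#'
#' @param track Data frame with those columns.
#' @param path File path.
#' @return `write_track`: `path` invisibly; `read_track`: the data frame.
#' @export
write_track <- function(track, path) {
  track <- as.data.frame(track)
  stopifnot(all(c("frame", "index", "x_nm", "y_nm") %in% names(track)))
  utils::write.table(track[, c("frame", "index", "x_nm", "y_nm")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  if (!file.exists(path)) stop_arg(sprintf("no such file: %s", path))
  lines <- readLines(path)
  if (length(lines) < 2L) stop_arg("track table has no data rows")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  need <- c("frame", "index", "x_nm", "y_nm")
  if (!all(need %in% header))
    stop_arg("track table header must contain: frame, index, x_nm, y_nm")
  fields <- strsplit(lines[-1], "\t", fixed = TRUE)
  for (i in seq_along(fields)) {
    v <- suppressWarnings(as.numeric(fields[[i]][match(need, header)]))
    if (length(fields[[i]]) != length(header) || anyNA(v))
      stop_arg(sprintf("malformed track table row at line %d of '%s'",
                       i + 1L, path))
  }
  df <- utils::read.delim(path)
  df[, need]
}

#' Serialize a barcode scheme to / from JSON
#'
#' @param scheme A [barcode_scheme()].
#' @param path JSON file.
#' @return `write_scheme`: `path` invisibly; `read_scheme`: the scheme.
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "barcode_scheme"))
  jsonlite::write_json(
    list(periods_nm = scheme$periods,
         tolerance_bins_nm = unname(apply(scheme$bins, 1L, c, simplify = FALSE)),
         bit_order = scheme$bit_order),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scheme
#' @export
read_scheme <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  bins <- j$tolerance_bins_nm
  if (is.list(bins)) bins <- do.call(rbind, bins)
  barcode_scheme(periods = j$periods_nm, tolerance_bins = bins,
                 bit_order = j$bit_order)
}

#' Serialize a bleach schedule to JSON
#'
#' @param schedule A [make_schedule()] result.
#' @param path JSON file.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "bleach_schedule"))
  jsonlite::write_json(
    list(event_times_s = schedule$event_times,
         event_duration_s = schedule$event_duration,
         intervals_s = as.list(schedule$intervals),
         region_length_nm = schedule$region_length,
         v_x_nm_per_s = schedule$v_x,
         periods_nm = schedule$periods),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialize a barcode readout to JSON
#'
#' @param readout A [read_barcode()] result.
#' @param path JSON file.
#' @export
write_readout <- function(readout, path) {
  stopifnot(inherits(readout, "barcode_readout"))
  cfg <- readout$diagnostics$config
  jsonlite::write_json(
    list(code = readout$code,
         detections = as.data.frame(readout$detections),
         region = list(left_nm = readout$region$left,
                       right_nm = readout$region$right,
                       method = readout$region$method),
         out_of_band_nm = readout$diagnostics$out_of_band,
         n_frames = readout$diagnostics$n_frames,
         shifts_nm = readout$diagnostics$shifts_nm,
         config = list(roi_nm = cfg$roi, pad_factor = cfg$pad_factor,
                       k = cfg$k, n_boot = cfg$n_boot, level = cfg$level,
                       interp_factor = cfg$interp_factor,
                       transverse_px = cfg$transverse_px,
                       seed = cfg$seed)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Default run configuration
#'
#' The full pipeline configuration as a nested list matching the YAML
#' layout: `scheme` (periods, bit order), `motion`, `optics`, `camera`,
#' `sim` (dose, filament and region geometry, imaging protocol, noise
#' switch) and `decode` (ROI, padding, threshold factor, bootstrap
#' settings), plus a run `seed`. All defaults are the parameter-object
#' defaults.
#'
#' @return A nested list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    scheme = list(periods = c(857, 1000, 1200, 1500),
                  bit_order = "msb_shortest"),
    motion = list(v_x = 1000, jitter_fraction = 0.03, dt = 0.005,
                  lead_in = 4000),
    optics = list(psf_sigma = 90, beam_sigma = 180,
                  excitation_wavelength = 488, pixel_size = 160),
    camera = list(exposure = 0.05, em_gain = 300, read_noise = 2,
                  offset = 100, photons_per_fluorophore = 5, e_per_adu = 16),
    sim = list(dose = 0.7, filament_length = 20000, labeling_density = 6.5,
               region_length = 12000, n_frames = 20, frame_interval = 0.2,
               imaging_delay = 0.5, noise = TRUE),
    decode = list(roi = c(850, 1500), pad_factor = 8,
                  k = default_threshold_factor(), n_boot = 1000,
                  level = 0.95, interp_factor = 3, transverse_px = 3,
                  merge_width = 60, rel_min = 0.1),
    seed = 1), class = "run_config")
}

check_config_keys <- function(cfg, ref, path = "") {
  extra <- setdiff(names(cfg), names(ref))
  if (length(extra) > 0L)
    stop_arg(sprintf("unknown configuration key%s: %s",
                     if (length(extra) > 1L) "s" else "",
                     paste0(path, extra, collapse = ", ")))
  for (nm in names(cfg)) {
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])))
      check_config_keys(cfg[[nm]], ref[[nm]], paste0(path, nm, "."))
  }
  invisible(TRUE)
}

#' Load / save a run configuration (YAML)
#'
#' Unknown keys are rejected; keys absent from the file keep their
#' defaults.
#'
#' @param path YAML file.
#' @param config A `run_config` list.
#' @return `load_run_config`: a validated `run_config`;
#'   `save_run_config`: `path` invisibly.
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  ref <- default_run_config()
  check_config_keys(raw, ref)
  cfg <- utils::modifyList(unclass(ref), raw)
  for (nm in c("roi")) cfg$decode[[nm]] <- as.numeric(cfg$decode[[nm]])
  structure(cfg, class = "run_config")
}

#' @rdname load_run_config
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_objects <- function(cfg) {
  list(
    scheme = barcode_scheme(periods = cfg$scheme$periods,
                            bit_order = cfg$scheme$bit_order),
    motion = motion_params(v_x = cfg$motion$v_x,
                           jitter_fraction = cfg$motion$jitter_fraction,
                           dt = cfg$motion$dt, lead_in = cfg$motion$lead_in),
    optics = optics_params(psf_sigma = cfg$optics$psf_sigma,
                           beam_sigma = cfg$optics$beam_sigma,
                           excitation_wavelength = cfg$optics$excitation_wavelength,
                           pixel_size = cfg$optics$pixel_size),
    camera = camera_params(exposure = cfg$camera$exposure,
                           em_gain = cfg$camera$em_gain,
                           read_noise = cfg$camera$read_noise,
                           offset = cfg$camera$offset,
                           photons_per_fluorophore = cfg$camera$photons_per_fluorophore,
                           e_per_adu = cfg$camera$e_per_adu))
}

decode_config_from <- function(cfg, seed = NULL, region = NULL) {
  d <- cfg$decode
  decode_config(roi = d$roi, pad_factor = d$pad_factor, k = d$k,
                n_boot = d$n_boot, level = d$level,
                interp_factor = d$interp_factor,
                transverse_px = d$transverse_px,
                merge_width = d$merge_width,
                rel_min = if (is.null(d$rel_min)) 0.1 else d$rel_min,
                region = region, seed = seed)
}

#' Simulate a barcode experiment and write its artifacts
#'
#' Writes `<out_prefix>.tif` (16-bit stack), `<out_prefix>_track.tsv`
#' and `<out_prefix>_truth.json` (code, schedule, per-fluorophore
#' survival, realized velocity statistics).
#'
#' @param code Integer code (0 is allowed but produces an unbleached,
#'   undecodable stack; a warning is issued).
#' @param out_prefix Output path prefix.
#' @param config A `run_config` (default [default_run_config()]).
#' @param seed Integer seed (overrides `config$seed` when given).
#' @return Named character vector of the written paths, invisibly.
#' @export
cmd_simulate <- function(code, out_prefix, config = default_run_config(),
                         seed = NULL) {
  obj <- config_objects(config)
  if (!is_scalar_number(code) || code != round(code) ||
      code < 0 || code > 2^obj$scheme$n_bits - 1)
    stop_arg(sprintf("'code' must be an integer in 0..%d",
                     2^obj$scheme$n_bits - 1))
  if (code == 0) warning("code 0 has no bleached region and cannot be decoded",
                         call. = FALSE)
  seed <- if (is.null(seed)) config$seed else seed
  s <- config$sim
  sim <- simulate_barcode_stack(code, obj$scheme, obj$motion, obj$optics,
                                obj$camera, dose = s$dose,
                                filament_length = s$filament_length,
                                labeling_density = s$labeling_density,
                                region_length = s$region_length,
                                n_frames = s$n_frames,
                                frame_interval = s$frame_interval,
                                imaging_delay = s$imaging_delay,
                                noise = s$noise, seed = seed)
  paths <- c(stack = paste0(out_prefix, ".tif"),
             track = paste0(out_prefix, "_track.tsv"),
             truth = paste0(out_prefix, "_truth.json"))
  write_stack(sim$stack, paths["stack"])
  write_track(sim$track, paths["track"])
  tr <- sim$truth$trace
  realized_v <- diff(range(tr$x)) / diff(range(tr$t))
  jsonlite::write_json(
    list(code = sim$truth$code,
         schedule = if (is.null(sim$truth$schedule)) NULL else
           list(event_times_s = sim$truth$schedule$event_times,
                intervals_s = as.list(sim$truth$schedule$intervals)),
         n_fluorophores = length(sim$truth$filament$positions),
         survival = sim$truth$filament$survival,
         realized_velocity_nm_s = realized_v,
         seed = seed),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  message(sprintf("simulated code %d: %d events, realized velocity %.0f nm/s (seed %s)",
                  code,
                  if (is.null(sim$truth$schedule)) 0L else
                    length(sim$truth$schedule$event_times),
                  realized_v, as.character(seed)))
  invisible(paths)
}

#' Decode a stack + track from disk
#'
#' @param stack_path 16-bit multi-page TIFF.
#' @param track_path Track table (see [write_track()]).
#' @param out Optional path for the readout JSON.
#' @param config A `run_config`.
#' @param region Optional `c(left, right)` nm manual region override.
#' @param seed Integer seed for the bootstrap.
#' @return The [read_barcode()] readout, with attribute `status`: 0 on
#'   success, 2 on `NoBleachedRegion`, 3 on `InsufficientFrames` (in the
#'   failure cases the readout is `NULL`).
#' @export
cmd_decode <- function(stack_path, track_path, out = NULL,
                       config = default_run_config(), region = NULL,
                       seed = NULL) {
  obj <- config_objects(config)
  stack <- read_stack(stack_path, pixel_size = config$optics$pixel_size,
                      frame_interval = config$sim$frame_interval)
  track <- read_track(track_path)
  dc <- decode_config_from(config, seed = if (is.null(seed)) config$seed
                           else seed, region = region)
  readout <- tryCatch(
    read_barcode(stack, track, obj$scheme, dc),
    NoBleachedRegion = function(e) structure(list(error = conditionMessage(e)),
                                             status = 2L),
    InsufficientFrames = function(e) structure(list(error = conditionMessage(e)),
                                               status = 3L))
  status <- attr(readout, "status")
  if (is.null(status)) {
    status <- 0L
    if (!is.null(out)) write_readout(readout, out)
    structure(readout, status = status)
  } else {
    message("decode failed: ", readout$error)
    structure(list(), status = status)
  }
}

#' Simulate-and-decode validation across all codes
#'
#' Runs the full simulate-then-decode loop for each code, `n_reps` times,
#' and summarizes per-code accuracy and the SNR range of the significant
#' detections.
#'
#' @param config A `run_config`.
#' @param n_reps Replicates per code (>= 1).
#' @param seed Integer seed.
#' @param codes Codes tested (default 1..15).
#' @return Data frame: `code`, `n_reps`, `accuracy`, `min_snr`,
#'   `max_snr` (SNRs over significant detections of correct bits; NA if
#'   none).
#' @export
cmd_validate <- function(config = default_run_config(), n_reps = 1,
                         seed = NULL, codes = NULL) {
  if (n_reps < 1) stop_arg("'n_reps' must be >= 1")
  obj <- config_objects(config)
  seed <- if (is.null(seed)) config$seed else seed
  if (is.null(codes)) codes <- seq_len(2L^obj$scheme$n_bits - 1L)
  s <- config$sim
  rows <- lapply(codes, function(cd) {
    correct <- 0L; snrs <- numeric(0)
    for (r in seq_len(n_reps)) {
      sd_r <- child_seed(seed, cd * 101L + r)
      sim <- simulate_barcode_stack(cd, obj$scheme, obj$motion, obj$optics,
                                    obj$camera, dose = s$dose,
                                    filament_length = s$filament_length,
                                    labeling_density = s$labeling_density,
                                    region_length = s$region_length,
                                    n_frames = s$n_frames,
                                    frame_interval = s$frame_interval,
                                    imaging_delay = s$imaging_delay,
                                    noise = s$noise, seed = sd_r)
      ro <- tryCatch(read_barcode(sim$stack, sim$track, obj$scheme,
                                  decode_config_from(config,
                                                     seed = child_seed(sd_r, 9L))),
                     mtbarcode_error = function(e) NULL)
      if (!is.null(ro)) {
        correct <- correct + as.integer(ro$code == cd)
        snrs <- c(snrs, ro$detections$snr[ro$detections$significant])
      }
    }
    data.frame(code = cd, n_reps = n_reps, accuracy = correct / n_reps,
               min_snr = if (length(snrs)) min(snrs) else NA_real_,
               max_snr = if (length(snrs)) max(snrs) else NA_real_)
  })
  do.call(rbind, rows)
}
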