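#' Barcode scheme: spatial periods, bit assignment and tolerance bins
#'
#' A barcode scheme maps the bits of a small binary number onto a set of
#' spatial periods bleached into a gliding filament. Each period carries one
#' bit: the bit is 1 when that period is present in the bleached pattern.
#' At decode time a detected period is accepted for a bit when it falls
#' inside that bit's closed tolerance bin, which absorbs the downward
#' excursions of the realized period caused by velocity jitter.
#'
#' The default scheme uses periods 857, 1000, 1200 and 1500 nm with
#' tolerance bins 800--857, 930--1000, 1120--1200 and 1400--1500 nm.
#' With `bit_order = "msb_shortest"` (the default) periods are assigned to
#' bits in descending order: the shortest period is the most significant
#' bit (857 nm encodes 1000b, 1500 nm encodes 0001b). The alternative
#' `"lsb_shortest"` reverses the assignment.
#'
#' @param periods Numeric vector of spatial periods in nm, all distinct.
#' @param tolerance_bins Optional n x 2 matrix of closed bin bounds
#'   `[lo, hi]` in nm, one row per period (rows in the order of `periods`).
#'   When `NULL`, each period `p` receives the bin
#'   `[max(p * (1 - bin_frac), midpoint to the next-shorter period), p]`,
#'   which is always pairwise disjoint.
#' @param bit_order `"msb_shortest"` or `"lsb_shortest"`.
#' @param bin_frac Fractional downward width of auto-generated bins
#'   (default 0.07, accommodating roughly 7% downward velocity excursions).
#' @return An object of class `barcode_scheme` with elements `periods`
#'   (sorted ascending), `bins` (matrix aligned to `periods`), `weights`
#'   (bit weight per period), `bit_order` and `n_bits`.
#' @examples
#' sc <- barcode_scheme()
#' periods_for_code(0x8, sc)  # 857 nm
#' @export
barcode_scheme <- function(periods = c(857, 1000, 1200, 1500),
                           tolerance_bins = NULL,
                           bit_order = c("msb_shortest", "lsb_shortest"),
                           bin_frac = 0.07) {
  bit_order <- match.arg(bit_order)
  if (!is.numeric(periods) || length(periods) < 1L || anyNA(periods) ||
      any(periods <= 0))
    stop_arg("'periods' must be positive numbers")
  if (anyDuplicated(periods))
    stop_arg("'periods' must be distinct")
  ord <- order(periods)
  p <- periods[ord]
  n <- length(p)

  if (is.null(tolerance_bins)) {
    if (identical(sort(periods), c(857, 1000, 1200, 1500))) {
      bins <- cbind(c(800, 930, 1120, 1400), c(857, 1000, 1200, 1500))
    } else {
      lo <- p * (1 - bin_frac)
      if (n > 1L) {
        mid <- (p[-n] + p[-1L]) / 2
        lo[-1L] <- pmax(lo[-1L], mid + .Machine$double.eps * p[-1L])
      }
      bins <- cbind(lo, p)
    }
  } else {
    bins <- as.matrix(tolerance_bins)
    if (!is.numeric(bins) || ncol(bins) != 2L || nrow(bins) != n)
      stop_arg("'tolerance_bins' must be an n x 2 numeric matrix")
    bins <- bins[ord, , drop = FALSE]
  }
  colnames(bins) <- c("lo", "hi")
  rownames(bins) <- NULL
  if (any(bins[, 1] > bins[, 2]))
    stop_arg("each tolerance bin must satisfy lo <= hi")
  if (any(p < bins[, 1] | p > bins[, 2]))
    stop_arg("every period must lie inside its own tolerance bin")
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      if (bins[i, 2] >= bins[i + 1L, 1])
        stop_arg(sprintf(
          "tolerance bins for periods %g and %g nm overlap ([%g, %g] vs [%g, %g])",
          p[i], p[i + 1L], bins[i, 1], bins[i, 2], bins[i + 1L, 1], bins[i + 1L, 2]))
    }
  }
  weights <- if (bit_order == "msb_shortest") 2^(n - seq_len(n)) else 2^(seq_len(n) - 1L)
  structure(
    list(periods = p, bins = bins, weights = weights,
         bit_order = bit_order, n_bits = n),
    class = "barcode_scheme")
}

#' @export
print.barcode_scheme <- function(x, ...) {
  cat(sprintf("<barcode_scheme> %d bits, bit order: %s\n", x$n_bits, x$bit_order))
  df <- data.frame(period_nm = x$periods, bin_lo = x$bins[, 1],
                   bin_hi = x$bins[, 2], bit_weight = x$weights)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Spatial periods encoding a given code
#'
#' Returns the set of spatial periods whose bit is set in `code` under the
#' scheme's bit assignment.
#'
#' @param code Integer in `0 .. 2^n_bits - 1`.
#' @param scheme A [barcode_scheme()].
#' @return Numeric vector of periods (nm), sorted ascending; empty for
#'   `code = 0`.
#' @export
periods_for_code <- function(code, scheme = barcode_scheme()) {
  stopifnot(inherits(scheme, "barcode_scheme"))
  if (!is_scalar_number(code) || code != round(code))
    stop_arg("'code' must be a single integer")
  code <- as.integer(code)
  if (code < 0L || code > 2L^scheme$n_bits - 1L)
    stop_arg(sprintf("'code' must be in 0..%d", 2L^scheme$n_bits - 1L))
  scheme$periods[bitwAnd(code, as.integer(scheme$weights)) != 0L]
}

#' Assemble a code from detected spatial periods
#'
#' Quantizes each detected period into the scheme's tolerance bins and sets
#' the corresponding bits. Detections falling outside every bin do not
#' contribute to the code; they are returned in the `out_of_band`
#' attribute so downstream diagnostics can flag them.
#'
#' @param detected_periods Numeric vector of detected periods (nm); may be
#'   empty.
#' @param scheme A [barcode_scheme()].
#' @param slack Non-negative allowance (nm) added to each bin's upper
#'   edge when matching; scalar or one value per detection. A bin's upper
#'   edge is the nominal period itself, so a spectral estimate of an
#'   exactly-nominal peak scatters half above it; callers pass the local
#'   period-grid step of their spectrum (default 0: strict bins).
#' @return The decoded integer, with attribute `out_of_band` holding any
#'   detections that fell outside every bin.
#' @export
code_for_detections <- function(detected_periods, scheme = barcode_scheme(),
                                slack = 0) {
  stopifnot(inherits(scheme, "barcode_scheme"))
  if (length(detected_periods) == 0L)
    return(structure(0L, out_of_band = numeric(0)))
  if (!is.numeric(detected_periods) || anyNA(detected_periods))
    stop_arg("'detected_periods' must be numeric and non-missing")
  if (any(slack < 0)) stop_arg("'slack' must be >= 0")
  slack <- rep_len(slack, length(detected_periods))
  bin_of <- vapply(seq_along(detected_periods), function(i) {
    p <- detected_periods[i]
    hit <- which(p >= scheme$bins[, 1] & p <= scheme$bins[, 2] + slack[i])
    if (length(hit) == 0L) NA_integer_ else hit[1L]
  }, integer(1))
  out_of_band <- detected_periods[is.na(bin_of)]
  hit_bins <- unique(bin_of[!is.na(bin_of)])
  code <- as.integer(sum(scheme$weights[hit_bins]))
  structure(code, out_of_band = out_of_band)
}

#' Bleach-pulse schedule realizing a set of spatial periods
#'
#' For a filament gliding at velocity `v_x`, a spatial period `x_b` along
#' the filament is written by firing the bleaching laser at time intervals
#' `t_x = x_b / v_x`. The schedule is the merged union of one pulse train
#' per requested period, all trains sharing the event at t = 0 (the moment
#' the leading edge of the encoded region crosses the bleach line). Events
#' from different trains that fall within one pulse duration of each other
#' are coalesced into a single schedule entry whose weight is the number
#' of coalesced pulses (the laser sweeps the line once per pulse, back to
#' back, delivering the summed dose).
#'
#' @param periods Numeric vector of spatial periods (nm), non-empty.
#' @param v_x Assumed gliding velocity (nm/s), > 0.
#' @param region_length Length of the encoded region (nm, default 12000).
#' @param event_duration Laser-on duration per event (s, default 0.005).
#' @return An object of class `bleach_schedule`: `event_times` (s, sorted,
#'   merged), `event_weights` (pulses per merged event), `event_duration`,
#'   `intervals` (named per-period `t_x`), `period_events` (per-period
#'   un-merged pulse trains), `region_length`, `v_x`.
#' @examples
#' make_schedule(857, v_x = 1000)$intervals  # 0.857 s
#' @export
make_schedule <- function(periods, v_x, region_length = 12000,
                          event_duration = 0.005) {
  if (!is.numeric(periods) || length(periods) == 0L || any(periods <= 0))
    stop_arg("'periods' must be a non-empty vector of positive periods (nm)")
  if (!is_scalar_number(v_x) || v_x <= 0)
    stop_arg("'v_x' must be a positive velocity (nm/s)")
  if (!is_scalar_number(region_length) || region_length < max(periods))
    stop_arg("'region_length' must be at least the longest period")
  periods <- sort(unique(as.numeric(periods)))
  trains <- lapply(periods, function(p) {
    t_x <- p / v_x
    k <- 0:floor(region_length / p + 1e-9)
    k * t_x
  })
  names(trains) <- as.character(periods)
  all_t <- sort(unlist(trains))
  # coalesce events separated by less than one pulse duration; a merged
  # event keeps the pulse count as its weight (back-to-back line sweeps
  # deliver their summed dose), so coincidences between trains do not
  # carve a periodic missing-dose pattern into the code
  if (length(all_t) > 1L) {
    grp <- cumsum(c(TRUE, diff(all_t) >= event_duration))
    wts <- as.integer(table(grp))
    all_t <- as.numeric(tapply(all_t, grp, function(tt) tt[1L]))
  } else {
    wts <- rep(1L, length(all_t))
  }
  structure(
    list(event_times = all_t,
         event_weights = wts,
         event_duration = event_duration,
         intervals = stats::setNames(periods / v_x, names(trains)),
         period_events = trains,
         region_length = region_length,
         v_x = v_x,
         periods = periods),
    class = "bleach_schedule")
}

#' @export
print.bleach_schedule <- function(x, ...) {
  cat(sprintf("<bleach_schedule> %d events over %.3f s (v_x = %g nm/s, region %g nm)\n",
              length(x$event_times), max(x$event_times), x$v_x, x$region_length))
  cat("intervals t_x (s):", paste(sprintf("%s nm -> %.4g", names(x$intervals),
                                          x$intervals), collapse = ", "), "\n")
  invisible(x)
}

#' Peak irradiance of the bleaching spot
#'
#' Laser power focused into a rectangular spot, expressed as irradiance.
#' With the 0.6 um x 0.6 um bleaching spot, 12.7 mW gives 35 mW/um^2
#' (rounded).
#'
#' @param power_mW Laser power delivered to the spot (mW).
#' @param spot_x_um,spot_y_um Spot extent (um), default 0.6 x 0.6.
#' @return Irradiance in mW/um^2.
#' @export
spot_irradiance <- function(power_mW, spot_x_um = 0.6, spot_y_um = 0.6) {
  if (any(c(spot_x_um, spot_y_um) <= 0)) stop_arg("spot dimensions must be > 0")
  power_mW / (spot_x_um * spot_y_um)
}

#' Monte Carlo comparison of candidate period sets
#'
#' For each candidate set of spatial periods, runs the full
#' simulate-then-decode loop `n_reps` times per code and reports the
#' fraction of codes decoded exactly, the mean per-bit error rate and the
#' mean number of out-of-band detections. Used to choose period sets whose
#' tolerance bins remain separable under velocity jitter and imaging noise.
#'
#' @param candidate_period_sets List of numeric period vectors (nm).
#' @param sim_params Named list of overrides forwarded to
#'   [simulate_barcode_stack()] (e.g. `motion`, `camera`, `n_frames`).
#' @param n_reps Replicates per code; `0` returns an empty table.
#' @param seed Integer seed; the same per-rep child seeds are used for
#'   every candidate set, so sets are compared on identical noise draws.
#' @param codes Codes to test (default all nonzero codes of the set).
#' @param bin_frac Tolerance-bin fraction for auto-generated bins.
#' @return A data frame with one row per candidate set: `set`, `periods`,
#'   `accuracy`, `false_bit_rate`, `out_of_band_rate`.
#' @export
design_sweep <- function(candidate_period_sets, sim_params = list(),
                         n_reps = 10, seed = 1, codes = NULL,
                         bin_frac = 0.07) {
  stopifnot(is.list(candidate_period_sets))
  schemes <- lapply(candidate_period_sets, barcode_scheme, bin_frac = bin_frac)
  empty <- data.frame(set = integer(0), periods = character(0),
                      accuracy = numeric(0), false_bit_rate = numeric(0),
                      out_of_band_rate = numeric(0))
  if (n_reps == 0) return(empty)
  rows <- lapply(seq_along(schemes), function(si) {
    sc <- schemes[[si]]
    cds <- if (is.null(codes)) seq_len(2L^sc$n_bits - 1L) else codes
    correct <- 0L; bit_err <- 0; oob <- 0; total <- 0L
    for (cd in cds) {
      for (r in seq_len(n_reps)) {
        sd <- child_seed(seed, cd * 1000L + r)
        sim <- do.call(simulate_barcode_stack,
                       c(list(code = cd, scheme = sc, seed = sd), sim_params))
        ro <- tryCatch(
          read_barcode(sim$stack, sim$track, sc,
                       config = decode_config(n_boot = 50,
                                              seed = child_seed(sd, 1L))),
          error = function(e) NULL)
        got <- if (is.null(ro)) 0L else ro$code
        n_oob <- if (is.null(ro)) 0L else length(ro$diagnostics$out_of_band)
        correct <- correct + as.integer(got == cd)
        bit_err <- bit_err +
          sum(bitwAnd(bitwXor(got, cd), 2L^(seq_len(sc$n_bits) - 1L)) != 0L) /
          sc$n_bits
        oob <- oob + n_oob
        total <- total + 1L
      }
    }
    data.frame(set = si,
               periods = paste(sc$periods, collapse = ","),
               accuracy = correct / total,
               false_bit_rate = bit_err / total,
               out_of_band_rate = oob / total)
  })
  do.call(rbind, rows)
}
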