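# Detection of the bleached segment within an averaged intensity profile.

#' Construct a bleached-region object
#' @keywords internal
new_bleached_region <- function(left, right, left_idx, right_idx,
                                method = c("automatic", "manual")) {
  method <- match.arg(method)
  structure(list(left = left, right = right, left_idx = left_idx,
                 right_idx = right_idx, method = method),
            class = "bleached_region")
}

#' @export
print.bleached_region <- function(x, ...) {
  cat(sprintf("<bleached_region> %.0f..%.0f nm (%.1f um, %s)\n",
              x$left, x$right, (x$right - x$left) / 1000, x$method))
  invisible(x)
}

region_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "mtbarcode_error")))
}

# Smoothing parameter chosen so the spline's residual SD approximates the
# profile's high-frequency noise (robust successive-difference estimate).
fit_profile_spline <- function(x, y, smoothing = NULL) {
  sigma <- stats::median(abs(diff(y))) / (sqrt(2) * 0.6745)
  if (!is.null(smoothing))
    return(list(fit = stats::smooth.spline(x, y, spar = smoothing),
                sigma = sigma))
  spars <- seq(0.1, 1.0, by = 0.1)
  fits <- lapply(spars, function(sp)
    tryCatch(stats::smooth.spline(x, y, spar = sp), error = function(e) NULL))
  ok <- !vapply(fits, is.null, logical(1))
  fits <- fits[ok]; spars <- spars[ok]
  if (length(fits) == 0L) region_error("spline fit failed", "NoBleachedRegion")
  res_sd <- vapply(fits, function(f)
    stats::sd(y - stats::predict(f, x)$y), numeric(1))
  list(fit = fits[[which.min(abs(res_sd - sigma))]], sigma = sigma)
}

#' Locate the bleached region of an averaged profile
#'
#' Two-scale search mirroring the semi-automated border identification.
#' First the well *envelope* is located: the profile is averaged over a
#' window of `envelope_window` nm (wide enough to null every coded
#' period), and the envelope's steepest descent / subsequent steepest
#' ascent mark the entry and exit of the bleached well. Then a smoothing
#' spline (its parameter chosen so the residual SD matches the
#' high-frequency noise estimate, so the spline tracks the coded
#' oscillations) supplies the *bleached minima*: its local minima that
#' dip below the plateau by at least a quarter of the well depth. The
#' region borders are the first and last bleached minimum, automating
#' the usual manual verification.
#'
#' A region is only accepted when the envelope has a genuine
#' falling/rising edge pair and the well is deeper than both 3x the
#' high-frequency noise and 5% of the surrounding plateau level; flat or
#' monotone profiles raise a `NoBleachedRegion` condition.
#'
#' @param profile An [intensity_profile()] (typically the aligned
#'   average).
#' @param smoothing Optional `spar` for [stats::smooth.spline()]; by
#'   default chosen so the spline residual SD matches the noise estimate.
#' @param min_length Minimum acceptable region length (nm); regions
#'   shorter than the longest coded period cannot carry the code
#'   (default 1500). Raises `RegionTooShort` when violated.
#' @param envelope_window Averaging window (nm) for the coarse envelope
#'   (default 3000, twice the longest default period, which nulls a
#'   1500 nm modulation exactly).
#' @return A `bleached_region`.
#' @export
find_bleached_region <- function(profile, smoothing = NULL,
                                 min_length = 1500,
                                 envelope_window = 3000) {
  stopifnot(inherits(profile, "intensity_profile"))
  x <- profile$positions; y <- profile$intensities
  n <- length(x)
  if (n < 16L) region_error("profile too short", "NoBleachedRegion")
  h <- x[2] - x[1]
  sigma <- stats::median(abs(diff(y))) / (sqrt(2) * 0.6745)

  # coarse envelope: moving average wide enough to null the coded periods
  w <- min(max(3L, round(envelope_window / h)), n %/% 4L)
  if (w %% 2L == 0L) w <- w + 1L
  half <- (w - 1L) %/% 2L
  env <- y
  for (pass in 1:2) {   # two passes: residual period ripple is squared away
    env <- as.numeric(stats::filter(env, rep(1 / w, w)))
    env[seq_len(half)] <- env[half + 1L]
    env[(n - half + 1L):n] <- env[n - half]
  }
  d1e <- c(env[2] - env[1], (env[-(1:2)] - env[1:(n - 2)]) / 2,
           env[n] - env[n - 1]) / h

  trim <- max(1L, floor(0.05 * n))
  interior <- (trim + 1L):(n - trim)
  li0 <- interior[which.min(d1e[interior])]
  if (!(d1e[li0] < 0))
    region_error("no falling edge in the profile envelope", "NoBleachedRegion")
  right_of <- interior[interior > li0]
  if (length(right_of) == 0L)
    region_error("no rising edge right of the falling edge", "NoBleachedRegion")
  ri0 <- right_of[which.max(d1e[right_of])]
  if (!(d1e[ri0] > 0))
    region_error("no rising edge right of the falling edge", "NoBleachedRegion")

  inside_min <- min(env[li0:ri0])
  outside_level <- stats::median(env[-(li0:ri0)])
  depth <- outside_level - inside_min
  if (!(depth > 3 * sigma) || !(depth > 0.05 * abs(outside_level)))
    region_error("no bleached well deeper than the noise", "NoBleachedRegion")

  # fine scale: local minima of the noise-matched spline that dip below
  # the plateau by at least a quarter of the well depth
  fs <- fit_profile_spline(x, y, smoothing)
  s <- stats::predict(fs$fit, x)$y
  level <- outside_level - 0.25 * depth
  is_lmin <- c(FALSE, s[2:(n - 1)] <= s[1:(n - 2)] & s[2:(n - 1)] <= s[3:n],
               FALSE)
  pad <- round(1000 / h)
  cand <- which(is_lmin & s < level &
                  seq_len(n) >= li0 - pad & seq_len(n) <= ri0 + pad)
  if (length(cand) == 0L)
    region_error("no bleached minima below the well level", "NoBleachedRegion")
  li <- cand[1]; ri <- cand[length(cand)]
  if (ri <= li)
    region_error("bleached region collapsed to a single minimum",
                 "NoBleachedRegion")
  if (x[ri] - x[li] < min_length)
    region_error(sprintf("bleached region (%.0f nm) shorter than %g nm",
                         x[ri] - x[li], min_length), "RegionTooShort")
  new_bleached_region(x[li], x[ri], li, ri, "automatic")
}

#' Manually override the bleached region
#'
#' The manual path of the semi-automated border verification: supply the
#' region bounds directly; downstream readout is identical to an
#' automatically detected region.
#'
#' @param profile An [intensity_profile()].
#' @param left,right Region bounds (nm), `left < right`, inside the
#'   profile support.
#' @return A `bleached_region` flagged `manual`.
#' @export
override_region <- function(profile, left, right) {
  stopifnot(inherits(profile, "intensity_profile"))
  x <- profile$positions
  if (!is_scalar_number(left) || !is_scalar_number(right) || left >= right)
    stop_arg("'left' must be < 'right'")
  if (left < x[1] || right > x[length(x)])
    stop_arg("region bounds outside the profile support")
  li <- which.min(abs(x - left)); ri <- which.min(abs(x - right))
  if (ri <= li) stop_arg("region collapses to fewer than 2 samples")
  new_bleached_region(x[li], x[ri], li, ri, "manual")
}
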