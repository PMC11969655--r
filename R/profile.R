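# Intensity-profile extraction along a tracked filament, cross-correlation
# alignment of per-frame profiles, and averaging.

#' Construct an intensity profile
#'
#' @param positions Uniform, strictly increasing arc-length grid (nm).
#' @param intensities Fluorescence counts, same length as `positions`.
#' @param frame_id Frame number or `"averaged"`.
#' @param n_frames_averaged Number of frames contributing.
#' @return A list of class `intensity_profile`.
#' @export
intensity_profile <- function(positions, intensities, frame_id = 1L,
                              n_frames_averaged = 1L) {
  if (length(positions) != length(intensities))
    stop_arg("'positions' and 'intensities' must have the same length")
  if (length(positions) >= 2L) {
    d <- diff(positions)
    if (any(d <= 0) || diff(range(d)) > 1e-6 * mean(d))
      stop_arg("'positions' must be a uniform, strictly increasing grid")
  }
  structure(list(positions = as.numeric(positions),
                 intensities = as.numeric(intensities),
                 frame_id = frame_id,
                 n_frames_averaged = as.integer(n_frames_averaged)),
            class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  h <- if (length(x$positions) > 1L) diff(x$positions[1:2]) else NA_real_
  cat(sprintf("<intensity_profile> %d samples, spacing %.2f nm, frame %s (%d averaged)\n",
              length(x$positions), h, as.character(x$frame_id),
              x$n_frames_averaged))
  invisible(x)
}

# Separable cubic-convolution (Keys, a = -0.5) interpolation of image M
# [row, col] at fractional pixel coordinates (qy = row, qx = col).
# Border pixels are replicated; callers enforce an interior margin.
interp_bicubic <- function(M, qx, qy) {
  ny <- nrow(M); nx <- ncol(M)
  cub_w <- function(s) {
    s <- abs(s)
    ifelse(s <= 1, 1.5 * s^3 - 2.5 * s^2 + 1,
           ifelse(s < 2, -0.5 * s^3 + 2.5 * s^2 - 4 * s + 2, 0))
  }
  fx <- floor(qx); tx <- qx - fx
  fy <- floor(qy); ty <- qy - fy
  out <- numeric(length(qx))
  for (i in -1:2) {
    wx <- cub_w(tx - i)
    ci <- pmin(pmax(fx + i, 1L), nx)
    for (j in -1:2) {
      wy <- cub_w(ty - j)
      rj <- pmin(pmax(fy + j, 1L), ny)
      out <- out + wx * wy * M[cbind(rj, ci)]
    }
  }
  out
}

#' Extract the intensity profile along a tracked centerline
#'
#' Samples the frame by separable cubic interpolation at stations spaced
#' `pixel_size / interp_factor` along the polyline (the 3-fold
#' interpolation of the pixel grid), averaging `transverse_px` samples
#' perpendicular to the filament axis at each station. Transverse samples
#' are taken on the interpolated grid, spanning about one original pixel.
#'
#' @param frame Numeric matrix `[row, col]`.
#' @param track_polyline Data frame or matrix with columns `x_nm`, `y_nm`
#'   (image coordinates; pixel column/row 1 sits at 0 nm), ordered from
#'   the leading end.
#' @param pixel_size nm per pixel.
#' @param interp_factor Sub-pixel interpolation factor (default 3).
#' @param transverse_px Number of perpendicular samples averaged
#'   (default 3).
#' @param frame_id Label stored in the profile.
#' @return An [intensity_profile()] with arc-length 0 at the leading end.
#' @export
extract_profile <- function(frame, track_polyline, pixel_size,
                            interp_factor = 3L, transverse_px = 3L,
                            frame_id = 1L) {
  pl <- as.data.frame(track_polyline)
  if (!all(c("x_nm", "y_nm") %in% names(pl))) {
    if (ncol(pl) >= 2L) names(pl)[1:2] <- c("x_nm", "y_nm")
    else stop_arg("'track_polyline' needs columns x_nm, y_nm")
  }
  if (nrow(pl) < 2L) stop_arg("polyline needs at least 2 points")
  h <- pixel_size / interp_factor
  seg <- sqrt(diff(pl$x_nm)^2 + diff(pl$y_nm)^2)
  arc <- c(0, cumsum(seg))
  stations <- seq(0, arc[length(arc)], by = h)
  sx <- stats::approx(arc, pl$x_nm, xout = stations)$y
  sy <- stats::approx(arc, pl$y_nm, xout = stations)$y
  # unit tangent by central differences, then the perpendicular
  n_st <- length(stations)
  txv <- c(sx[2] - sx[1], (sx[-(1:2)] - sx[1:(n_st - 2)]) / 2,
           sx[n_st] - sx[n_st - 1])
  tyv <- c(sy[2] - sy[1], (sy[-(1:2)] - sy[1:(n_st - 2)]) / 2,
           sy[n_st] - sy[n_st - 1])
  tl <- sqrt(txv^2 + tyv^2)
  nxv <- -tyv / tl; nyv <- txv / tl
  offs <- (seq_len(transverse_px) - (transverse_px + 1) / 2) * h
  vals <- matrix(0, nrow = n_st, ncol = transverse_px)
  for (k in seq_along(offs)) {
    qx_nm <- sx + offs[k] * nxv
    qy_nm <- sy + offs[k] * nyv
    qx <- qx_nm / pixel_size + 1
    qy <- qy_nm / pixel_size + 1
    if (any(qx < 2 | qx > ncol(frame) - 1 | qy < 2 | qy > nrow(frame) - 1))
      stop_arg("polyline (with its transverse margin) touches the frame edge")
    vals[, k] <- interp_bicubic(frame, qx, qy)
  }
  intensity_profile(stations, rowMeans(vals), frame_id = frame_id)
}

#' Extract per-frame profiles from a stack and its track table
#'
#' @param stack A `frame_stack`.
#' @param track Track table (`frame`, `index`, `x_nm`, `y_nm`).
#' @inheritParams extract_profile
#' @return List of [intensity_profile()], truncated to a common grid.
#' @export
extract_profiles <- function(stack, track, interp_factor = 3L,
                             transverse_px = 3L) {
  stopifnot(inherits(stack, "frame_stack"))
  track <- as.data.frame(track)
  frames <- sort(unique(track$frame))
  if (!all(frames %in% seq_along(stack$frames)))
    stop_arg("track refers to frames missing from the stack")
  profs <- lapply(frames, function(f) {
    pl <- track[track$frame == f, , drop = FALSE]
    pl <- pl[order(pl$index), , drop = FALSE]
    extract_profile(stack$frames[[f]], pl, stack$pixel_size,
                    interp_factor, transverse_px, frame_id = f)
  })
  n_min <- min(vapply(profs, function(p) length(p$positions), integer(1)))
  lapply(profs, function(p)
    intensity_profile(p$positions[seq_len(n_min)],
                      p$intensities[seq_len(n_min)], frame_id = p$frame_id))
}

# Pearson cross-correlation of two equal-grid profiles over integer lags.
xcorr_lag <- function(ref, prof, max_lag) {
  n <- length(ref)
  lags <- -max_lag:max_lag
  vapply(lags, function(l) {
    if (l >= 0) { a <- ref[1:(n - l)]; b <- prof[(1 + l):n] }
    else        { a <- ref[(1 - l):n]; b <- prof[1:(n + l)] }
    if (length(a) < 8L || stats::sd(a) == 0 || stats::sd(b) == 0) return(-Inf)
    stats::cor(a, b)
  }, numeric(1))
}

#' Align per-frame profiles by cross-correlation and average them
#'
#' Each profile is aligned to the first frame by the argmax of its
#' cross-correlation, with sub-grid refinement by parabolic interpolation
#' of the correlation peak; the alignment is then iterated once against
#' the running mean. Profiles are resampled at the shifted positions
#' (linear interpolation; integer-grid shifts are exact), the
#' non-overlapping edges are trimmed, and the overlap is averaged.
#'
#' When the discrete correlation peak is already a perfect match
#' (correlation > 1 - 1e-9), the sub-grid refinement is skipped so that
#' noiseless on-grid shifts are recovered exactly.
#'
#' @param profiles List of [intensity_profile()] on a common grid.
#' @param max_shift_nm Largest lateral shift searched (default 500 nm,
#'   a few pixels). It must stay below the shortest coded period: the
#'   bleached pattern is periodic, so wider searches can lock onto a
#'   whole-period offset.
#' @return A list of class `aligned_profiles`: `average` (an
#'   [intensity_profile()] on the trimmed overlap), `shifts_nm` (per
#'   frame), `aligned` (frames x positions matrix on the overlap),
#'   `positions`.
#' @export
align_and_average <- function(profiles, max_shift_nm = 500) {
  if (length(profiles) == 0L) stop_arg("'profiles' must contain at least one profile")
  stopifnot(all(vapply(profiles, inherits, logical(1), "intensity_profile")))
  pos <- profiles[[1]]$positions
  n <- length(pos)
  h <- pos[2] - pos[1]
  Y <- do.call(rbind, lapply(profiles, function(p) {
    if (length(p$positions) != n) stop_arg("profiles must share one grid")
    p$intensities
  }))
  nf <- nrow(Y)
  if (nf == 1L) {
    avg <- intensity_profile(pos, Y[1, ], frame_id = "averaged",
                             n_frames_averaged = 1L)
    return(structure(list(average = avg, shifts_nm = 0,
                          aligned = Y, positions = pos),
                     class = "aligned_profiles"))
  }
  max_lag <- max(1L, min(round(max_shift_nm / h), n %/% 3L))
  pick_peak <- function(cc, ml) {
    best <- max(cc)
    near <- which(cc >= best - 1e-9)
    near[which.min(abs(near - (ml + 1L)))]   # ties: smallest |lag|
  }
  est_shifts <- function(ref) {
    vapply(seq_len(nf), function(i) {
      cc <- xcorr_lag(ref, Y[i, ], max_lag)
      j <- pick_peak(cc, max_lag)
      lag <- j - (max_lag + 1L)
      off <- 0
      if (cc[j] < 1 - 1e-9 && j > 1L && j < length(cc) &&
          is.finite(cc[j - 1]) && is.finite(cc[j + 1]))
        off <- parabolic_offset(cc[j - 1], cc[j], cc[j + 1])
      (lag + off) * h
    }, numeric(1))
  }
  apply_shifts <- function(shifts) {
    t(vapply(seq_len(nf), function(i)
      stats::approx(pos, Y[i, ], xout = pos + shifts[i])$y, numeric(n)))
  }
  shifts <- est_shifts(Y[1, ])
  al <- apply_shifts(shifts)
  ok <- colSums(is.na(al)) == 0L
  if (sum(ok) >= 16L) {
    # one pass against the running mean to avoid reference bias
    ref2 <- colMeans(al[, ok, drop = FALSE])
    ml2 <- max(1L, min(max_lag, sum(ok) %/% 3L))
    extra <- vapply(seq_len(nf), function(i) {
      cc <- xcorr_lag(ref2, al[i, ok], ml2)
      j <- pick_peak(cc, ml2)
      lag <- j - (ml2 + 1L)
      off <- 0
      if (cc[j] < 1 - 1e-9 && j > 1L && j < length(cc) &&
          is.finite(cc[j - 1]) && is.finite(cc[j + 1]))
        off <- parabolic_offset(cc[j - 1], cc[j], cc[j + 1])
      (lag + off) * h
    }, numeric(1))
    shifts <- shifts + extra - mean(extra)   # keep the common frame
    al <- apply_shifts(shifts)
  }
  keep <- colSums(is.na(al)) == 0L
  if (!any(keep)) stop_arg("no overlap remains after alignment")
  first <- which(keep)[1]; last <- rev(which(keep))[1]
  idx <- first:last
  al <- al[, idx, drop = FALSE]
  avg <- intensity_profile(pos[idx], colMeans(al), frame_id = "averaged",
                           n_frames_averaged = nf)
  structure(list(average = avg, shifts_nm = shifts, aligned = al,
                 positions = pos[idx]),
            class = "aligned_profiles")
}
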