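# AFM fiber morphometry: cross-section extraction on height maps, fiber
# height / half-height width / equivalent circular radius, and axial
# periodicity by spectral analysis.
#
# The equivalent radius treats the fiber cross-section as a (half-)ellipse
# with the half-height width w and height h as its axes: the circle of
# equal area has r = (1/2) sqrt(h * w).

#' Extract a 1-D height profile along a line on a height map
#'
#' Bilinear interpolation along the segment from `(row0, col0)` to
#' `(row1, col1)` (0-based grid indices), sampled at `pixel_size` spacing;
#' the returned distances start at 0 nm.
#'
#' @param map a [height_map()].
#' @param line numeric `c(row0, col0, row1, col1)`, 0-based grid
#'   coordinates, endpoints inside the grid.
#' @return data.frame with columns `distance` (nm) and `height` (nm).
#' @export
extract_cross_section <- function(map, line) {
  stopifnot(inherits(map, "height_map"))
  if (length(line) != 4L || any(!is.finite(line)))
    stop_input("line must be c(row0, col0, row1, col1)")
  H <- map$heights
  r0 <- line[1]; c0 <- line[2]; r1 <- line[3]; c1 <- line[4]
  if (any(c(r0, r1) < 0) || any(c(r0, r1) > nrow(H) - 1) ||
      any(c(c0, c1) < 0) || any(c(c0, c1) > ncol(H) - 1))
    stop_input("line endpoints fall outside the grid")
  len_px <- sqrt((r1 - r0)^2 + (c1 - c0)^2)
  if (len_px == 0) stop_input("zero-length line")
  s <- seq(0, len_px, by = 1)
  if (s[length(s)] < len_px) s <- c(s, len_px)
  rr <- r0 + s / len_px * (r1 - r0)
  cc <- c0 + s / len_px * (c1 - c0)
  i0 <- pmin(floor(rr), nrow(H) - 2); i0 <- pmax(i0, 0)
  j0 <- pmin(floor(cc), ncol(H) - 2); j0 <- pmax(j0, 0)
  fr <- rr - i0; fc <- cc - j0
  idx <- function(i, j) H[cbind(i + 1, j + 1)]
  h <- (1 - fr) * (1 - fc) * idx(i0, j0) +
       (1 - fr) * fc       * idx(i0, j0 + 1) +
       fr       * (1 - fc) * idx(i0 + 1, j0) +
       fr       * fc       * idx(i0 + 1, j0 + 1)
  data.frame(distance = s * map$pixel_size, height = h)
}

#' Measure a fiber cross-section on a 1-D height profile
#'
#' The baseline is the median of the lowest quartile of heights (robust
#' when the fiber occupies less than half of the profile). The fiber
#' height is `h = peak - baseline`; the width `w` is the
#' linearly-interpolated extent of the contiguous region around the peak
#' that lies above `baseline + h/2`. The equivalent circular radius is
#' `r = (1/2) sqrt(h w)` and the flattening ratio `w/h`.
#'
#' @param profile data.frame with columns `distance` and `height` (as from
#'   [extract_cross_section()]), or a numeric vector of heights with an
#'   implied unit spacing.
#' @param noise_factor multiple of the baseline-region MAD used as the
#'   detection floor; a profile with no peak above
#'   `baseline + noise_factor * mad` raises a no-fiber error.
#' @return An object of class `fiber_section`: `h`, `w`, `r`,
#'   `width_height_ratio` (all nm except the ratio).
#' @export
measure_fiber_section <- function(profile, noise_factor = 5) {
  if (is.numeric(profile))
    profile <- data.frame(distance = seq_along(profile) - 1, height = profile)
  stopifnot(all(c("distance", "height") %in% names(profile)))
  x <- profile$distance; y <- profile$height
  qcut <- stats::quantile(y, 0.25)
  low <- y <= qcut
  baseline <- stats::median(y[low])
  floor_mad <- stats::mad(y[low])
  h <- max(y) - baseline
  if (h <= noise_factor * floor_mad + 1e-9)
    stop(errorCondition("no fiber peak above baseline + noise floor",
                        class = c("pepgel_no_fiber_error",
                                  "pepgel_input_error", "error")))
  peaks <- which(y == max(y))
  if (length(peaks) > 1L)
    warning("multiple equal peaks; taking the leftmost", call. = FALSE)
  ipk <- peaks[1]
  half <- baseline + h / 2
  above <- y > half
  # contiguous region containing the peak
  i_lo <- ipk
  while (i_lo > 1L && above[i_lo - 1L]) i_lo <- i_lo - 1L
  i_hi <- ipk
  while (i_hi < length(y) && above[i_hi + 1L]) i_hi <- i_hi + 1L
  x_lo <- if (i_lo == 1L) x[1] else {
    x[i_lo - 1] + (x[i_lo] - x[i_lo - 1]) *
      (half - y[i_lo - 1]) / (y[i_lo] - y[i_lo - 1])
  }
  x_hi <- if (i_hi == length(y)) x[length(x)] else {
    x[i_hi] + (x[i_hi + 1] - x[i_hi]) *
      (y[i_hi] - half) / (y[i_hi] - y[i_hi + 1])
  }
  w <- x_hi - x_lo
  if (w <= 0) stop_input("degenerate half-height width")
  structure(list(h = h, w = w, r = equivalent_radius(h, w),
                 width_height_ratio = w / h),
            class = "fiber_section")
}

#' @export
print.fiber_section <- function(x, ...) {
  cat(sprintf(
    "<fiber_section> h = %.3g nm, w = %.3g nm, r = %.3g nm, w/h = %.3g\n",
    x$h, x$w, x$r, x$width_height_ratio))
  invisible(x)
}

#' Equivalent circular fiber radius
#'
#' `r = (1/2) sqrt(h w)`: radius of the circle with the same area as the
#' ellipse of axes h and w. For `h = w` it reduces to `h/2`.
#'
#' @param h fiber height, nm; > 0.
#' @param w half-height width, nm; > 0.
#' @return equivalent radius, nm.
#' @export
equivalent_radius <- function(h, w) {
  if (any(!is.finite(h)) || any(h <= 0) || any(!is.finite(w)) || any(w <= 0))
    stop_input("h and w must be > 0")
  0.5 * sqrt(h * w)
}

#' Dominant axial period of a fiber profile
#'
#' Subtracts the best linear trend, computes the periodogram, and reports
#' the period `1/f` of the strongest non-DC spectral peak. The peak is
#' flagged significant when its power exceeds the spectral median by
#' `significance_factor`. The peak frequency is refined on a Hann-windowed,
#' zero-padded transform (`pad_factor` times the record length) so the
#' period is resolved below the raw bin width. A constant profile returns
#' an absent period (`NA`) with `significant = FALSE`.
#'
#' @param values 1-D signal sampled at `pixel_size` spacing; >= 64 samples.
#' @param pixel_size sample spacing, nm.
#' @param significance_factor power-over-median threshold (default 10).
#' @param pad_factor zero-padding multiple for peak refinement (default 8).
#' @return list with `period` (nm or `NA`), `frequency` (nm^-1),
#'   `significant` (logical), `power_ratio` (peak/median).
#' @export
axial_periodicity <- function(values, pixel_size,
                              significance_factor = 10, pad_factor = 8) {
  values <- as.numeric(values)
  if (length(values) < 64L) stop_input("need at least 64 samples")
  if (!is.finite(pixel_size) || pixel_size <= 0)
    stop_input("pixel_size must be > 0")
  n <- length(values)
  x <- seq_len(n)
  detr <- stats::lm.fit(cbind(1, x), values)$residuals
  if (stats::sd(detr) < 1e-12 * (1 + max(abs(values))))
    return(list(period = NA_real_, frequency = NA_real_,
                significant = FALSE, power_ratio = NA_real_))
  pw <- Mod(stats::fft(detr))^2
  half <- 2:(n %/% 2)            # non-DC, up to Nyquist
  kpk <- half[which.max(pw[half])]
  ratio <- pw[kpk] / stats::median(pw[half])
  # refine on a Hann-windowed zero-padded transform near the raw peak
  hann <- 0.5 * (1 - cos(2 * pi * (x - 1) / (n - 1)))
  np <- pad_factor * n
  pwz <- Mod(stats::fft(c(detr * hann, rep(0, np - n))))^2
  k_lo <- max(2L, (kpk - 2L - 1L) * pad_factor + 1L)
  k_hi <- min(np %/% 2, (kpk + 2L - 1L) * pad_factor + 1L)
  kz <- (k_lo:k_hi)[which.max(pwz[k_lo:k_hi])]
  freq <- (kz - 1) / (np * pixel_size)
  list(period = 1 / freq, frequency = freq,
       significant = ratio > significance_factor, power_ratio = ratio)
}
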