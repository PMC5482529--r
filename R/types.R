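# Domain containers for the five measurement modalities. All are light S3
# lists with validating constructors; downstream code assumes the invariants
# enforced here.

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("pepgel_input_error", "error")))
}

#' Reduced SANS profile
#'
#' Container for a reduced small-angle neutron scattering curve: scattering
#' wave vector `q` (nm^-1), absolute intensity and its one-sigma uncertainty,
#' plus sample metadata. If `sigma` is missing, a counting-statistics
#' surrogate `sigma = max(eps, sqrt(I) * sigma_scale)` is synthesized and the
#' profile is flagged with `attr(, "sigma_synthesized")`.
#'
#' @param q scattering wave vector, nm^-1; strictly increasing, all > 0,
#'   length >= 8.
#' @param intensity absolute intensity, arbitrary consistent units; finite.
#' @param sigma one-sigma intensity uncertainty, same units; all > 0, or
#'   `NULL` to synthesize.
#' @param temperature sample temperature, degrees C (metadata).
#' @param concentration gelator concentration, mass percent (metadata).
#' @param wavelength neutron wavelength, nm (optional metadata).
#' @param sigma_scale scale of the sqrt(I) surrogate used when `sigma` is
#'   absent.
#' @return An object of class `scattering_profile`.
#' @examples
#' q <- exp(seq(log(0.04), log(4), length.out = 50))
#' p <- scattering_profile(q, 1 / (1 + q^2 * 4), sigma = rep(0.01, 50))
#' @export
scattering_profile <- function(q, intensity, sigma = NULL,
                               temperature = NA_real_,
                               concentration = NA_real_,
                               wavelength = NA_real_,
                               sigma_scale = 0.01) {
  q <- as.numeric(q); intensity <- as.numeric(intensity)
  if (length(q) < 8L) stop_input("a scattering profile needs at least 8 points")
  if (length(intensity) != length(q))
    stop_input("q and intensity lengths differ")
  if (any(!is.finite(q)) || any(q <= 0)) stop_input("all q must be finite and > 0")
  if (any(diff(q) <= 0)) stop_input("q must be strictly increasing")
  if (any(!is.finite(intensity))) stop_input("intensity must be finite")
  synthesized <- is.null(sigma)
  if (synthesized) {
    sigma <- pmax(1e-12, sqrt(pmax(intensity, 0)) * sigma_scale)
  } else {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q)) stop_input("sigma length differs from q")
    if (any(!is.finite(sigma)) || any(sigma <= 0))
      stop_input("all sigma must be finite and > 0")
  }
  out <- structure(
    list(q = q, intensity = intensity, sigma = sigma,
         temperature = temperature, concentration = concentration,
         wavelength = wavelength),
    class = "scattering_profile")
  attr(out, "sigma_synthesized") <- synthesized
  out
}

#' @export
print.scattering_profile <- function(x, ...) {
  cat(sprintf("<scattering_profile> %d points, q in [%.3g, %.3g] nm^-1\n",
              length(x$q), min(x$q), max(x$q)))
  cat(sprintf("  T = %s degC, c = %s mass%%\n", format(x$temperature),
              format(x$concentration)))
  invisible(x)
}

#' SANS model parameter set
#'
#' Parameters of the one- and two-length-scale correlation models
#' `I(q) = B/(1+q^2 R^2) + C q^-n` and
#' `I(q) = B/[(1+q^2 R^2) sqrt(1+(qL)^2)] + C q^-n`.
#'
#' @param model_id `"one_level"` or `"two_level"`.
#' @param B Lorentzian amplitude (intensity units), >= 0.
#' @param R cross-sectional fiber radius, nm, > 0.
#' @param C power-law prefactor, >= 0.
#' @param n power-law exponent, in (0, 6).
#' @param L second characteristic length (inter-fibrillar spacing / mesh
#'   size), nm; required > 0 for `"two_level"`, ignored otherwise.
#' @return An object of class `sans_params`.
#' @export
sans_params <- function(model_id = c("one_level", "two_level"),
                        B, R, C, n, L = NULL) {
  model_id <- match.arg(model_id)
  for (v in c("B", "R", "C", "n")) {
    val <- get(v)
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val))
      stop_input(v, " must be a finite scalar")
  }
  if (B < 0) stop_input("B must be >= 0")
  if (R <= 0) stop_input("R must be > 0")
  if (C < 0) stop_input("C must be >= 0")
  if (n <= 0 || n >= 6) stop_input("n must lie in (0, 6)")
  if (model_id == "two_level") {
    if (is.null(L) || !is.finite(L) || L <= 0)
      stop_input("two_level model requires L > 0")
  } else L <- NULL
  structure(list(model_id = model_id, B = B, R = R, L = L, C = C, n = n),
            class = "sans_params")
}

#' @export
print.sans_params <- function(x, ...) {
  cat(sprintf("<sans_params> %s: B=%.4g R=%.4g nm%s C=%.4g n=%.4g\n",
              x$model_id, x$B, x$R,
              if (!is.null(x$L)) sprintf(" L=%.4g nm", x$L) else "",
              x$C, x$n))
  invisible(x)
}

#' DLS autocorrelation trace
#'
#' @param lag lag times, seconds; strictly increasing, > 0, length >= 10.
#' @param g autocorrelation values; finite. The first value should be the
#'   maximum up to noise (a warning is issued otherwise).
#' @param sigma optional per-point uncertainties (> 0).
#' @param temperature degrees C (metadata).
#' @param concentration mass percent (metadata).
#' @return An object of class `correlation_trace`.
#' @export
correlation_trace <- function(lag, g, sigma = NULL,
                              temperature = NA_real_,
                              concentration = NA_real_) {
  lag <- as.numeric(lag); g <- as.numeric(g)
  if (length(lag) < 10L) stop_input("a correlation trace needs >= 10 points")
  if (length(g) != length(lag)) stop_input("lag and g lengths differ")
  if (any(!is.finite(lag)) || any(lag <= 0)) stop_input("lag times must be > 0")
  if (any(diff(lag) <= 0)) stop_input("lag must be strictly increasing")
  if (any(!is.finite(g))) stop_input("g must be finite")
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(lag) || any(sigma <= 0))
      stop_input("sigma must match lag and be > 0")
  }
  # tolerate noise at the plateau: compare against an early-lag summary
  head_level <- stats::median(g[seq_len(min(5L, length(g)))])
  if (max(g) > head_level + 0.2 * abs(head_level) + 1e-12)
    warning("first correlation values are not the maximum of the trace",
            call. = FALSE)
  structure(list(lag = lag, g = g, sigma = sigma,
                 temperature = temperature, concentration = concentration),
            class = "correlation_trace")
}

#' 1-D NMR spectrum with internal standard metadata
#'
#' @param shift chemical shift axis, ppm; strictly monotone (either
#'   direction).
#' @param intensity real spectrum values, finite.
#' @param temperature degrees C (metadata).
#' @param c_total total gelator concentration, mass percent.
#' @param std_conc internal standard (DSS) concentration, in the same unit
#'   the derived free concentration is reported in; > 0.
#' @param std_protons proton count of the standard's reference peak
#'   (9 for the DSS trimethylsilyl singlet).
#' @param gelator_protons proton count of the integrated gelator peak set.
#' @return An object of class `nmr_spectrum`.
#' @export
nmr_spectrum <- function(shift, intensity, temperature = NA_real_,
                         c_total = NA_real_, std_conc, std_protons = 9L,
                         gelator_protons = 5L) {
  shift <- as.numeric(shift); intensity <- as.numeric(intensity)
  if (length(shift) != length(intensity)) stop_input("shift/intensity lengths differ")
  if (length(shift) < 16L) stop_input("spectrum too short")
  d <- diff(shift)
  if (!(all(d > 0) || all(d < 0))) stop_input("shift axis must be strictly monotone")
  if (any(!is.finite(intensity))) stop_input("intensity must be finite")
  if (!is.finite(std_conc) || std_conc <= 0) stop_input("std_conc must be > 0")
  if (std_protons < 1 || gelator_protons < 1) stop_input("proton counts must be >= 1")
  structure(list(shift = shift, intensity = intensity,
                 temperature = temperature, c_total = c_total,
                 std_conc = std_conc, std_protons = std_protons,
                 gelator_protons = gelator_protons),
            class = "nmr_spectrum")
}

#' AFM height map
#'
#' @param heights numeric matrix of heights, nm; at least 16 x 16, finite.
#'   Rows index the slow (axial) scan direction, columns the fast direction.
#' @param pixel_size nm per pixel, equal in both axes; > 0.
#' @return An object of class `height_map`.
#' @export
height_map <- function(heights, pixel_size) {
  if (!is.matrix(heights) || !is.numeric(heights))
    stop_input("heights must be a numeric matrix")
  if (nrow(heights) < 16L || ncol(heights) < 16L)
    stop_input("height map must be at least 16 x 16")
  if (any(!is.finite(heights))) stop_input("heights must be finite")
  if (!is.finite(pixel_size) || pixel_size <= 0) stop_input("pixel_size must be > 0")
  structure(list(heights = heights, pixel_size = pixel_size),
            class = "height_map")
}

#' Oscillatory rheology frequency sweep
#'
#' Points are stored sorted by angular frequency, so classification is
#' invariant to input order.
#'
#' @param omega angular frequencies, rad/s; > 0, length >= 5.
#' @param g_prime storage modulus G', Pa; > 0.
#' @param g_double_prime loss modulus G'', Pa; > 0.
#' @param temperature degrees C (metadata).
#' @param concentration mass percent (metadata).
#' @param strain strain amplitude, percent (metadata).
#' @return An object of class `rheo_sweep`.
#' @export
rheo_sweep <- function(omega, g_prime, g_double_prime,
                       temperature = NA_real_, concentration = NA_real_,
                       strain = NA_real_) {
  omega <- as.numeric(omega)
  g_prime <- as.numeric(g_prime); g_double_prime <- as.numeric(g_double_prime)
  n <- length(omega)
  if (n < 5L) stop_input("a frequency sweep needs >= 5 points")
  if (length(g_prime) != n || length(g_double_prime) != n)
    stop_input("omega and moduli lengths differ")
  if (any(!is.finite(omega)) || any(omega <= 0)) stop_input("omega must be > 0")
  if (any(!is.finite(g_prime)) || any(g_prime <= 0) ||
      any(!is.finite(g_double_prime)) || any(g_double_prime <= 0))
    stop_input("moduli must be finite and > 0")
  ord <- order(omega)
  structure(list(omega = omega[ord], g_prime = g_prime[ord],
                 g_double_prime = g_double_prime[ord],
                 temperature = temperature, concentration = concentration,
                 strain = strain),
            class = "rheo_sweep")
}
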