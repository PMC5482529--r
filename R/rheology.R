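# Sol / viscoelastic-fluid / gel classification of oscillatory frequency
# sweeps and assembly of the concentration-temperature state diagram.
#
# Gel criterion: tan(delta) = G''/G' < 1 across the whole frequency window
# AND a nearly frequency-independent G' (log-log slope below a threshold),
# the latter guarding against labelling a terminal-zone crossover as a gel.

#' Loss tangent
#'
#' `tan(delta) = G''/G'`, the ratio of loss to storage modulus.
#' Homogeneous of degree 0: scaling both moduli leaves it unchanged.
#'
#' @param g_prime storage modulus G', Pa; > 0 (vectorized).
#' @param g_double_prime loss modulus G'', Pa.
#' @return dimensionless ratio.
#' @export
tan_delta <- function(g_prime, g_double_prime) {
  if (any(!is.finite(g_prime)) || any(g_prime <= 0))
    stop_input("G' must be > 0")
  g_double_prime / g_prime
}

#' Classify a frequency sweep as sol, viscoelastic fluid, or gel
#'
#' Rules (thresholds configurable): *gel* when `max(tan delta) <
#' tan_delta_threshold` over the window and the log-log slope of G' versus
#' omega is below `slope_threshold`; *sol* when `tan delta >=
#' tan_delta_threshold` over the entire window; *viscoelastic* otherwise.
#'
#' @param sweep a [rheo_sweep()].
#' @param tan_delta_threshold gel/sol loss-tangent threshold (default 1).
#' @param slope_threshold maximum `d log G' / d log omega` for a gel
#'   (default 0.2).
#' @return An object of class `regime_label`: `regime`, `max_tan_delta`,
#'   `gprime_slope`.
#' @export
classify_regime <- function(sweep, tan_delta_threshold = 1,
                            slope_threshold = 0.2) {
  stopifnot(inherits(sweep, "rheo_sweep"))
  if (tan_delta_threshold <= 0 || slope_threshold <= 0)
    stop_input("thresholds must be positive")
  td <- tan_delta(sweep$g_prime, sweep$g_double_prime)
  slope <- stats::coef(stats::lm(log(sweep$g_prime) ~ log(sweep$omega)))[[2]]
  regime <- if (max(td) < tan_delta_threshold && slope < slope_threshold)
    "gel"
  else if (min(td) >= tan_delta_threshold)
    "sol"
  else "viscoelastic"
  structure(list(regime = regime, max_tan_delta = max(td),
                 gprime_slope = slope),
            class = "regime_label")
}

#' @export
print.regime_label <- function(x, ...) {
  cat(sprintf("<regime_label> %s (max tan delta = %.3g, G' slope = %.3g)\n",
              x$regime, x$max_tan_delta, x$gprime_slope))
  invisible(x)
}

#' Assemble a concentration-temperature state diagram
#'
#' For each concentration with at least one gel and one warmer non-gel
#' point, the sol-gel transition temperature is the midpoint between the
#' warmest gel point and the coolest non-gel point above it (gels melt on
#' heating). Concentrations with all-gel or all-non-gel points get an
#' undefined boundary, not an error.
#'
#' @param labels data.frame with columns `concentration`, `temperature`
#'   and `regime` (character: `"sol"`, `"viscoelastic"`, `"gel"`), or a
#'   list of `(c, T, regime_label)` triples.
#' @return An object of class `state_diagram`: `points` (the input table),
#'   `boundary` (data.frame `concentration`, `t_gel`), and
#'   `boundary_monotone_fraction` (fraction of adjacent concentration
#'   pairs with non-decreasing transition temperature).
#' @export
build_state_diagram <- function(labels) {
  if (is.list(labels) && !is.data.frame(labels)) {
    labels <- do.call(rbind, lapply(labels, function(p)
      data.frame(concentration = p[[1]], temperature = p[[2]],
                 regime = if (inherits(p[[3]], "regime_label"))
                   p[[3]]$regime else as.character(p[[3]]))))
  }
  stopifnot(all(c("concentration", "temperature", "regime") %in% names(labels)))
  cs <- sort(unique(labels$concentration))
  if (length(cs) < 2L) stop_input("need at least 2 distinct concentrations")
  bnd <- lapply(cs, function(cc) {
    sub <- labels[labels$concentration == cc, , drop = FALSE]
    gel_t <- sub$temperature[sub$regime == "gel"]
    non_t <- sub$temperature[sub$regime != "gel"]
    if (!length(gel_t) || !length(non_t))
      return(data.frame(concentration = cc, t_gel = NA_real_))
    warm_gel <- max(gel_t)
    above <- non_t[non_t > warm_gel]
    if (!length(above))
      return(data.frame(concentration = cc, t_gel = NA_real_))
    data.frame(concentration = cc, t_gel = (warm_gel + min(above)) / 2)
  })
  boundary <- do.call(rbind, bnd)
  tg <- boundary$t_gel[!is.na(boundary$t_gel)]
  frac <- if (length(tg) >= 2L) mean(diff(tg) >= 0) else NA_real_
  structure(list(points = labels, boundary = boundary,
                 boundary_monotone_fraction = frac),
            class = "state_diagram")
}

#' @export
print.state_diagram <- function(x, ...) {
  cat("<state_diagram>\n")
  print(x$boundary)
  invisible(x)
}

#' @export
plot.state_diagram <- function(x, ...) {
  pts <- x$points
  col <- c(sol = 3, viscoelastic = 4, gel = 2)[pts$regime]
  graphics::plot(pts$concentration, pts$temperature, col = col, pch = 19,
                 xlab = "concentration (mass %)",
                 ylab = "temperature (degC)", ...)
  ok <- !is.na(x$boundary$t_gel)
  if (any(ok))
    graphics::lines(x$boundary$concentration[ok], x$boundary$t_gel[ok],
                    lwd = 2)
  graphics::legend("topleft", legend = c("sol", "viscoelastic", "gel"),
                   col = c(3, 4, 2), pch = 19, bty = "n")
  invisible(x)
}
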