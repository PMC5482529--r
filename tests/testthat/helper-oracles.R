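# Independent oracle implementations used to cross-check the package's
# model evaluations. Deliberately written as a separate code path
# (different algebraic arrangement) from the implementations in R/.

oracle_one_level <- function(q, B, R, C, n) {
  lorentz <- B * (1 + (q * R)^2)^(-1)
  power <- if (C > 0) C * exp(-n * log(q)) else rep(0, length(q))
  lorentz + power
}

oracle_two_level <- function(q, B, R, L, C, n) {
  lorentz <- B * (1 + (q * R)^2)^(-1) * (1 + (q * L)^2)^(-0.5)
  power <- if (C > 0) C * exp(-n * log(q)) else rep(0, length(q))
  lorentz + power
}

# Closed-form integral of a Lorentzian area * (gamma/pi) / ((x-x0)^2 +
# gamma^2) over [lo, hi], minus the straight-line baseline through its own
# values at the window edges (what edge-anchored baseline subtraction
# removes in the limit of fine sampling).
oracle_lorentz_window_area <- function(area, x0, gamma, lo, hi) {
  cdf <- function(x) atan((x - x0) / gamma) / pi
  raw <- area * (cdf(hi) - cdf(lo))
  height <- function(x) area * (gamma / pi) / ((x - x0)^2 + gamma^2)
  raw - (height(lo) + height(hi)) / 2 * (hi - lo)
}

# Plain-exponential fit by log-linear regression (oracle for
# fit_dls(alpha_mode = 1) on noise-free data).
oracle_exp_fit <- function(t, g) {
  co <- stats::coef(stats::lm(log(g) ~ t))
  list(g0 = exp(co[[1]]), tau = -1 / co[[2]])
}

# Half-height chord of a semi-ellipse of base width b: the height profile
# is H sqrt(1 - (2x/b)^2), equal to H/2 at |x| = (b/2) sqrt(3)/2.
oracle_half_height_width <- function(base_width) base_width * sqrt(3) / 2
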