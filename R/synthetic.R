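# Synthetic-data generators for all five modalities, with known ground
# truth, controlled noise, and deterministic seeding. These emulate the
# study conditions of the hydrogelator characterisation (SANS correlation
# curves, stretched-exponential DLS decays, internally referenced NMR
# spectra, semi-elliptical AFM fiber ridges with axial modulation, and
# sol / viscoelastic / gel frequency sweeps) so every analysis stage is
# verifiable by parameter recovery.
#
# Noise models: multiplicative Gaussian for SANS (a proxy for counting
# statistics after reduction), additive Gaussian for DLS, NMR and AFM,
# multiplicative Gaussian for rheology moduli. Every generator is a
# bit-exact function of its arguments and the seed.

#' Named fixture presets mirroring the reported experimental values
#'
#' - `"gel25C"`: two-length-scale SANS parameters of a fully developed gel
#'   at 25 degC (R = 2.9 nm, L = 20 nm, B = 1, C = 0.02, n = 3).
#' - `"sol"`: one-level SANS parameters of the dilute fiber-precursor
#'   regime (R = 2.0 nm, B = 1, C = 0.05, n = 1).
#' - `"dls"`: stretched-exponential truth (tau = 1e-3 s, alpha = 0.6,
#'   g0 = 1).
#' - `"paper_fiber"`: AFM ridge geometry solved so the measured height and
#'   half-height width give w/h = 3.5 and r = 3.6 nm, with an axial
#'   modulation period of 14.5 nm.
#'
#' @param name preset name.
#' @return a named list of generating parameters.
#' @export
pepgel_preset <- function(name = c("gel25C", "sol", "dls", "paper_fiber")) {
  name <- match.arg(name)
  switch(name,
    gel25C = list(params = sans_params("two_level", B = 1, R = 2.9,
                                       C = 0.02, n = 3, L = 20),
                  temperature = 25, concentration = 5),
    sol = list(params = sans_params("one_level", B = 1, R = 2.0,
                                    C = 0.05, n = 1),
               temperature = 70, concentration = 0.5),
    dls = list(tau = 1e-3, alpha = 0.6, g0 = 1,
               temperature = 25, concentration = 2),
    paper_fiber = local({
      r <- 3.6; ratio <- 3.5
      h <- 2 * r / sqrt(ratio)        # from r = (1/2) sqrt(h w), w = ratio h
      w <- ratio * h
      list(height = h, half_width = w,
           base_width = 2 * w / sqrt(3),  # semi-ellipse: half-height chord
           period = 14.5, pixel_size = 0.5)
    }))
}

#' Generate a synthetic SANS profile
#'
#' `I = model(q) * (1 + eps)`, `eps ~ N(0, noise)`, on a log-spaced q grid;
#' the uncertainty column is `noise * model(q)` (floored at a relative
#' 1e-6 so noise-free profiles remain weightable). Positivity is enforced
#' by redrawing `eps` at violating points.
#'
#' @param params a [sans_params()] truth set.
#' @param n_points number of q points (default 200).
#' @param q_min,q_max q range, nm^-1 (default 0.04-4, the instrument
#'   window).
#' @param noise relative noise level (>= 0).
#' @param temperature,concentration metadata carried on the profile.
#' @param seed integer RNG seed; same seed, same profile.
#' @return a [scattering_profile()].
#' @export
gen_sans <- function(params, n_points = 200L, q_min = 0.04, q_max = 4,
                     noise = 0.01, temperature = NA_real_,
                     concentration = NA_real_, seed = 1L) {
  stopifnot(inherits(params, "sans_params"))
  if (noise < 0) stop_input("noise must be >= 0")
  q <- exp(seq(log(q_min), log(q_max), length.out = n_points))
  m <- if (params$model_id == "one_level") eval_one_level(q, params)
       else eval_two_level(q, params)
  I <- withr::with_seed(as.integer(seed), {
    eps <- stats::rnorm(n_points, 0, noise)
    out <- m * (1 + eps)
    for (it in seq_len(100L)) {
      bad <- out <= 0
      if (!any(bad)) break
      out[bad] <- m[bad] * (1 + stats::rnorm(sum(bad), 0, noise))
    }
    out
  })
  scattering_profile(q, I, sigma = pmax(noise, 1e-6) * m,
                     temperature = temperature,
                     concentration = concentration)
}

#' Generate a synthetic DLS correlation trace
#'
#' `g = g0 exp[-(t/tau)^alpha] + N(0, noise)` on a log-spaced lag grid.
#'
#' @param tau relaxation time, s; > 0.
#' @param alpha stretching exponent in (0, 1].
#' @param g0 amplitude.
#' @param n_points number of lags (default 100).
#' @param t_min,t_max lag range, s (default 1e-6 to 1).
#' @param noise additive noise sd.
#' @param temperature,concentration metadata.
#' @param seed integer RNG seed.
#' @return a [correlation_trace()].
#' @export
gen_dls <- function(tau, alpha, g0 = 1, n_points = 100L,
                    t_min = 1e-6, t_max = 1, noise = 0.01,
                    temperature = NA_real_, concentration = NA_real_,
                    seed = 1L) {
  if (noise < 0) stop_input("noise must be >= 0")
  t <- exp(seq(log(t_min), log(t_max), length.out = n_points))
  m <- g0 * eval_stretched_exp(t, tau, alpha)
  g <- m + withr::with_seed(as.integer(seed),
                            stats::rnorm(n_points, 0, noise))
  correlation_trace(t, g, temperature = temperature,
                    concentration = concentration)
}

#' Generate a temperature series of DLS traces
#'
#' Maps a `(temperature, tau)` table (tau strictly decreasing with
#' increasing temperature emulates network rigidification on cooling) to a
#' list of traces with per-row derived seeds.
#'
#' @param tau_table data.frame with columns `temperature` and `tau`.
#' @inheritParams gen_dls
#' @return list of [correlation_trace()] objects.
#' @export
gen_dls_series <- function(tau_table, alpha = 0.6, g0 = 1, n_points = 100L,
                           t_min = 1e-6, t_max = 1, noise = 0.01,
                           seed = 1L) {
  stopifnot(all(c("temperature", "tau") %in% names(tau_table)))
  lapply(seq_len(nrow(tau_table)), function(i)
    gen_dls(tau_table$tau[i], alpha, g0, n_points, t_min, t_max, noise,
            temperature = tau_table$temperature[i],
            seed = as.integer(seed) * 131L + i))
}

#' Generate a synthetic NMR spectrum with internal standard
#'
#' Lorentzian peaks for the free gelator fraction (aromatic peak set, total
#' per-proton area proportional to `(1 - phi) * c_total`), a DSS reference
#' singlet at 0 ppm of area proportional to `std_conc * std_protons`, an
#' optional very broad low-amplitude hump standing in for the NMR-invisible
#' aggregate, and additive Gaussian noise scaled to the tallest model peak.
#'
#' @param c_total total gelator concentration (mass percent).
#' @param phi extent of assembly in `[0, 1]`; the visible fraction is
#'   `1 - phi`.
#' @param std_conc internal standard concentration; > 0.
#' @param n_points points on the shift axis (default 8192).
#' @param shift_range ppm axis limits (default -1 to 10).
#' @param linewidth Lorentzian half width at half maximum, ppm.
#' @param gelator_shifts,gelator_weights positions (ppm) and proton
#'   weights of the gelator peak set; weights sum to the gelator proton
#'   count.
#' @param std_protons protons in the standard reference peak.
#' @param aggregate_hump if `TRUE`, add a broad (2 ppm HWHM) hump with
#'   area proportional to the aggregated fraction.
#' @param noise additive noise sd relative to the tallest peak.
#' @param temperature metadata.
#' @param seed integer RNG seed.
#' @return an [nmr_spectrum()].
#' @export
gen_nmr <- function(c_total, phi, std_conc = 0.05, n_points = 8192L,
                    shift_range = c(-1, 10), linewidth = 0.005,
                    gelator_shifts = c(7.2, 7.45, 8.1),
                    gelator_weights = c(2, 2, 1), std_protons = 9L,
                    aggregate_hump = FALSE, noise = 0.002,
                    temperature = NA_real_, seed = 1L) {
  if (phi < 0 || phi > 1) stop_input("phi must lie in [0, 1]")
  if (c_total <= 0) stop_input("c_total must be > 0")
  if (noise < 0) stop_input("noise must be >= 0")
  x <- seq(shift_range[1], shift_range[2], length.out = n_points)
  lorentz <- function(x0, area)
    area * (linewidth / pi) / ((x - x0)^2 + linewidth^2)
  c_free <- (1 - phi) * c_total
  y <- lorentz(0, std_protons * std_conc)
  for (i in seq_along(gelator_shifts))
    y <- y + lorentz(gelator_shifts[i], gelator_weights[i] * c_free)
  if (aggregate_hump)
    y <- y + (phi * c_total * 0.5) * (2 / pi) / ((x - 4)^2 + 2^2)
  # noise floor scaled to the reference singlet: noise = 0.002 puts the
  # internal standard at SNR 500, typical of quantitative 1H work
  std_height <- std_protons * std_conc * (linewidth / pi) / linewidth^2
  y <- y + withr::with_seed(as.integer(seed),
                            stats::rnorm(n_points, 0, noise * std_height))
  nmr_spectrum(x, y, temperature = temperature, c_total = c_total,
               std_conc = std_conc, std_protons = std_protons,
               gelator_protons = sum(gelator_weights))
}

#' Generate a synthetic AFM height map with one fiber
#'
#' A flat substrate at 0 with optional Gaussian roughness carries one
#' straight fiber running along the row (axial) direction with a
#' semi-elliptical cross-section of the given height and base width,
#' optionally modulated sinusoidally along its axis. The `"paper_fiber"`
#' preset reproduces the reported morphometry: measured height and
#' half-height width satisfying w/h = 3.5 and r = 3.6 nm, axial period
#' 14.5 nm.
#'
#' @param preset `"paper_fiber"` to load the reported-geometry preset
#'   (overrides `height`, `base_width`, `period`, `pixel_size`), or `NULL`.
#' @param height fiber apex height, nm.
#' @param base_width semi-ellipse base width, nm; must fit inside the map.
#' @param n_rows,n_cols grid size (rows = axial direction).
#' @param pixel_size nm per pixel.
#' @param roughness substrate Gaussian roughness sd, nm.
#' @param modulate if `TRUE`, modulate the fiber height along its axis.
#' @param period axial modulation period, nm.
#' @param mod_amplitude relative modulation amplitude.
#' @param seed integer RNG seed.
#' @return a [height_map()]; the fiber centre column (0-based) is stored
#'   in `attr(, "center_col")` and the truth parameters in
#'   `attr(, "truth")`.
#' @export
gen_afm <- function(preset = NULL, height = 4, base_width = 10,
                    n_rows = 512L, n_cols = 64L, pixel_size = 0.5,
                    roughness = 0, modulate = FALSE, period = 14.5,
                    mod_amplitude = 0.08, seed = 1L) {
  if (!is.null(preset)) {
    p <- pepgel_preset(preset)
    height <- p$height; base_width <- p$base_width
    period <- p$period; pixel_size <- p$pixel_size
  }
  if (height <= 0 || base_width <= 0) stop_input("fiber dimensions must be > 0")
  a <- base_width / 2
  width_nm <- (n_cols - 1) * pixel_size
  if (base_width >= width_nm) stop_input("fiber wider than the map")
  center_col <- (n_cols - 1L) %/% 2L      # 0-based, on-grid apex
  col_nm <- (seq_len(n_cols) - 1) * pixel_size
  row_nm <- (seq_len(n_rows) - 1) * pixel_size
  cross <- sqrt(pmax(0, 1 - ((col_nm - center_col * pixel_size) / a)^2))
  axial <- if (modulate) 1 + mod_amplitude * sin(2 * pi * row_nm / period)
           else rep(1, n_rows)
  H <- outer(axial * height, cross)
  if (roughness > 0)
    H <- H + withr::with_seed(as.integer(seed),
           matrix(stats::rnorm(n_rows * n_cols, 0, roughness),
                  n_rows, n_cols))
  out <- height_map(H, pixel_size)
  attr(out, "center_col") <- center_col
  attr(out, "truth") <- list(height = height, base_width = base_width,
                             period = if (modulate) period else NA_real_,
                             mod_amplitude = if (modulate) mod_amplitude
                                             else 0)
  out
}

#' Generate a synthetic rheology frequency sweep
#'
#' - `"gel"`: nearly flat `G' = g0 omega^0.03` with `G'' = 0.1 G'`.
#' - `"sol"`: terminal-zone Maxwell scaling `G' = 0.5 omega^2`,
#'   `G'' = 5 omega` on a default window of 0.1-1 rad/s (tan delta >= 1
#'   throughout).
#' - `"viscoelastic"`: a single-mode Maxwell element with relaxation time
#'   1 s, so the `G'`/`G''` crossover sits inside the default 0.1-10 rad/s
#'   window.
#'
#' Moduli get multiplicative Gaussian noise (positivity enforced by
#' redrawing).
#'
#' @param regime `"gel"`, `"sol"` or `"viscoelastic"`.
#' @param n_points sweep length (default 20).
#' @param omega_range angular frequency window, rad/s; regime-specific
#'   default.
#' @param g0 modulus scale, Pa.
#' @param noise relative noise level.
#' @param temperature,concentration metadata.
#' @param seed integer RNG seed.
#' @return a [rheo_sweep()].
#' @export
gen_rheo <- function(regime = c("gel", "sol", "viscoelastic"),
                     n_points = 20L, omega_range = NULL, g0 = NULL,
                     noise = 0.02, temperature = NA_real_,
                     concentration = NA_real_, seed = 1L) {
  regime <- match.arg(regime)
  if (is.null(omega_range))
    omega_range <- switch(regime, sol = c(0.1, 1), c(0.1, 10))
  w <- exp(seq(log(omega_range[1]), log(omega_range[2]),
               length.out = n_points))
  moduli <- switch(regime,
    gel = {
      g0 <- if (is.null(g0)) 200 else g0
      list(gp = g0 * w^0.03, gpp = 0.1 * g0 * w^0.03)
    },
    sol = list(gp = 0.5 * w^2, gpp = 5 * w),
    viscoelastic = {
      g0 <- if (is.null(g0)) 100 else g0
      list(gp = g0 * w^2 / (1 + w^2), gpp = g0 * w / (1 + w^2))
    })
  noisy <- withr::with_seed(as.integer(seed), {
    perturb <- function(m) {
      out <- m * (1 + stats::rnorm(length(m), 0, noise))
      for (it in seq_len(100L)) {
        bad <- out <= 0
        if (!any(bad)) break
        out[bad] <- m[bad] * (1 + stats::rnorm(sum(bad), 0, noise))
      }
      out
    }
    list(gp = perturb(moduli$gp), gpp = perturb(moduli$gpp))
  })
  rheo_sweep(w, noisy$gp, noisy$gpp, temperature = temperature,
             concentration = concentration)
}

#' Generate a synthetic concentration-temperature rheology grid
#'
#' Emulates the tilt-test state diagram: sol below 2 mass %; gel at
#' >= 3 mass % below a linear melting line `T_melt(c) = melt_intercept +
#' melt_slope * c` (passing through ~50 degC at 5 mass % with the
#' defaults); viscoelastic fluid in the intermediate band below the melt
#' line; sol above it everywhere.
#'
#' @param concentrations mass percent grid.
#' @param temperatures degC grid.
#' @param melt_intercept,melt_slope parameters of the linear melting line.
#' @param noise relative modulus noise.
#' @param seed integer RNG seed.
#' @return list with `grid` (data.frame `concentration`, `temperature`,
#'   `true_regime`), `sweeps` (list of [rheo_sweep()]), and `melt_line`
#'   (function of concentration).
#' @export
gen_state_grid <- function(concentrations = c(0.5, 1, 2, 3, 4, 5),
                           temperatures = c(25, 35, 45, 55, 65),
                           melt_intercept = 20, melt_slope = 6,
                           noise = 0.02, seed = 1L) {
  grid <- expand.grid(concentration = concentrations,
                      temperature = temperatures)
  melt <- function(c) melt_intercept + melt_slope * c
  grid$true_regime <- with(grid, ifelse(
    concentration < 2, "sol",
    ifelse(temperature >= melt(concentration), "sol",
           ifelse(concentration >= 3, "gel", "viscoelastic"))))
  sweeps <- lapply(seq_len(nrow(grid)), function(i)
    gen_rheo(grid$true_regime[i], noise = noise,
             temperature = grid$temperature[i],
             concentration = grid$concentration[i],
             seed = as.integer(seed) * 211L + i))
  list(grid = grid, sweeps = sweeps, melt_line = melt)
}
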