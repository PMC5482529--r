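mk_spec <- function(y, x = seq(-1, 10, length.out = 4096), ...) {
  nmr_spectrum(x, y, std_conc = 0.05, ...)
}

test_that("peak integration matches the closed-form Lorentzian oracle", {
  x <- seq(-1, 10, length.out = 2^15)
  gamma <- 0.01; area <- 2.5; x0 <- 5
  y <- area * (gamma / pi) / ((x - x0)^2 + gamma^2)
  sp <- mk_spec(y, x)
  # window of +/- 20 linewidths (FWHM = 2 gamma)
  w <- c(x0 - 40 * gamma, x0 + 40 * gamma)
  got <- integrate_peak(sp, w)
  want <- oracle_lorentz_window_area(area, x0, gamma, w[1], w[2])
  expect_equal(got, want, tolerance = 2e-3)
  # the window captures the bulk of the analytic area
  expect_gt(got / area, 0.95)
  # all-zero spectrum integrates to zero over any window
  expect_identical(integrate_peak(mk_spec(rep(0, length(x)), x), c(2, 3)), 0)
  expect_error(integrate_peak(sp, c(20, 30)), class = "pepgel_input_error")
  expect_error(integrate_peak(sp, c(3, 2)), class = "pepgel_input_error")
})

test_that("free concentration follows the per-proton internal-standard ratio", {
  sp <- gen_nmr(c_total = 0.9, phi = 0, std_conc = 0.05, noise = 0)
  cfg <- pepgel_config()
  cf <- free_concentration(sp, cfg$nmr_gelator_window, cfg$nmr_std_window)
  expect_equal(cf, 0.9, tolerance = 0.02)
  # scale invariance: multiplying the spectrum by k leaves c_free unchanged
  sp_k <- nmr_spectrum(sp$shift, sp$intensity * 7.3, std_conc = sp$std_conc,
                       std_protons = sp$std_protons,
                       gelator_protons = sp$gelator_protons)
  expect_equal(free_concentration(sp_k, cfg$nmr_gelator_window,
                                  cfg$nmr_std_window), cf,
               tolerance = 1e-10)
  # fully assembled: gelator window integrates to ~0
  sp1 <- gen_nmr(c_total = 0.9, phi = 1, std_conc = 0.05, noise = 0)
  # an empty gelator window may clip a tiny negative net area, with warning
  expect_lt(suppressWarnings(
    free_concentration(sp1, cfg$nmr_gelator_window, cfg$nmr_std_window)),
    0.9 * 0.01)
  # molar-mass rescaling multiplies by M_gel / M_std
  cf_mass <- free_concentration(sp, cfg$nmr_gelator_window,
                                cfg$nmr_std_window,
                                molar_mass = c(gelator = 700,
                                               standard = 218.32))
  expect_equal(cf_mass / cf, 700 / 218.32, tolerance = 1e-10)
  expect_error(free_concentration(sp, c(6.8, 8.6), c(7, 9)),
               class = "pepgel_input_error")
})

test_that("extent of assembly is the clipped complement of the free fraction", {
  expect_identical(extent_of_assembly(0.3, 0.3), 0)
  expect_identical(extent_of_assembly(0, 0.5), 1)
  expect_equal(extent_of_assembly(0.3, 0.9), 2 / 3)
  expect_warning(phi <- extent_of_assembly(1.2, 1.0), "exceeds c_total")
  expect_identical(phi, 0)
  expect_error(extent_of_assembly(0.1, 0), class = "pepgel_input_error")
  expect_error(extent_of_assembly(-0.1, 1), class = "pepgel_input_error")
  # mass balance: c_free + phi * c_total = c_total when no clipping occurs
  set.seed(3)
  for (i in 1:25) {
    ct <- stats::runif(1, 0.1, 5)
    cf <- stats::runif(1, 0, ct)
    expect_equal(cf + extent_of_assembly(cf, ct) * ct, ct, tolerance = 1e-12)
  }
})

test_that("generator/analyzer round trip recovers phi within 0.03", {
  cfg <- pepgel_config()
  for (phi_true in c(0.1, 0.45, 0.8)) {
    sp <- gen_nmr(c_total = 0.9, phi = phi_true, std_conc = 0.05,
                  noise = 0.002, aggregate_hump = TRUE, seed = 17)
    cf <- free_concentration(sp, cfg$nmr_gelator_window, cfg$nmr_std_window)
    expect_lt(abs(extent_of_assembly(cf, 0.9) - phi_true), 0.03)
  }
})

test_that("phi_series sorts by temperature and reports monotonicity", {
  cfg <- pepgel_config()
  temps <- c(50, 45, 40, 35, 30)
  phis <- 1 / (1 + exp((temps - 40) / 3))   # sigmoidal, decreasing in T
  spectra <- lapply(seq_along(temps), function(i)
    gen_nmr(c_total = 0.9, phi = phis[i], noise = 0.001,
            temperature = temps[i], seed = 50 + i))
  out <- phi_series(spectra, cfg$nmr_gelator_window, cfg$nmr_std_window)
  expect_identical(out$temperature, sort(temps))
  expect_equal(attr(out, "monotone_fraction"), 1.0)
  # shuffled input: same sorted output
  out_sh <- phi_series(spectra[c(3, 1, 5, 2, 4)], cfg$nmr_gelator_window,
                       cfg$nmr_std_window)
  expect_equal(out_sh$phi, out$phi)
  expect_error(phi_series(spectra[1], cfg$nmr_gelator_window,
                          cfg$nmr_std_window),
               class = "pepgel_input_error")
})
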