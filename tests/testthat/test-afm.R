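test_that("cross-section extraction interpolates the grid bilinearly", {
  flat <- height_map(matrix(5, 32, 32), pixel_size = 0.5)
  pr <- extract_cross_section(flat, c(0, 0, 0, 31))
  expect_true(all(abs(pr$height - 5) < 1e-12))
  expect_identical(pr$distance[1], 0)
  # axis-aligned line across a synthetic ridge matches the analytic profile
  m <- gen_afm(height = 4, base_width = 10, n_rows = 64, n_cols = 64,
               pixel_size = 0.5)
  cc <- attr(m, "center_col")
  pr2 <- extract_cross_section(m, c(10, 0, 10, 63))
  analytic <- 4 * sqrt(pmax(0, 1 - ((pr2$distance - cc * 0.5) / 5)^2))
  expect_lt(max(abs(pr2$height - analytic)) / 4, 0.01)
  expect_error(extract_cross_section(flat, c(0, 0, 0, 0)),
               class = "pepgel_input_error")
  expect_error(extract_cross_section(flat, c(0, 0, 40, 0)),
               class = "pepgel_input_error")
})

test_that("fiber sections report height, half-height width and radius", {
  # fine sampling so the discrete profile is near-analytic
  m <- gen_afm(height = 4, base_width = 10, n_rows = 64, n_cols = 512,
               pixel_size = 0.1)
  pr <- extract_cross_section(m, c(5, 0, 5, 511))
  sec <- measure_fiber_section(pr)
  expect_equal(sec$h, 4, tolerance = 0.01)
  expect_equal(sec$w, oracle_half_height_width(10), tolerance = 0.01)
  expect_equal(sec$r, equivalent_radius(sec$h, sec$w))
  # baseline shift invariance
  pr_shift <- pr; pr_shift$height <- pr$height + 7
  sec2 <- measure_fiber_section(pr_shift)
  expect_equal(sec2$h, sec$h, tolerance = 1e-10)
  expect_equal(sec2$w, sec$w, tolerance = 1e-10)
  # flat profile: no fiber
  expect_error(measure_fiber_section(data.frame(distance = 0:63,
                                                height = rep(1, 64))),
               class = "pepgel_no_fiber_error")
  # area conservation is definitional: pi r^2 = pi (h/2) (w/2)
  expect_equal(pi * sec$r^2, pi * (sec$h / 2) * (sec$w / 2))
})

test_that("equivalent radius follows r = half sqrt(h w)", {
  expect_identical(equivalent_radius(2, 2), 1.0)
  expect_identical(equivalent_radius(1, 4), 1.0)
  expect_equal(equivalent_radius(3.85, 13.47), 3.60, tolerance = 1e-2)
  expect_error(equivalent_radius(0, 1), class = "pepgel_input_error")
  expect_error(equivalent_radius(1, -1), class = "pepgel_input_error")
})

test_that("scaling a height map scales every morphometric output", {
  k <- 2.5
  m1 <- gen_afm(height = 4, base_width = 10, n_rows = 128, n_cols = 64,
                pixel_size = 0.5)
  m2 <- height_map(m1$heights * k, m1$pixel_size * k)
  p1 <- extract_cross_section(m1, c(3, 0, 3, 63))
  p2 <- extract_cross_section(m2, c(3, 0, 3, 63))
  s1 <- measure_fiber_section(p1); s2 <- measure_fiber_section(p2)
  expect_equal(s2$h, k * s1$h, tolerance = 1e-10)
  expect_equal(s2$w, k * s1$w, tolerance = 1e-10)
  expect_equal(s2$r, k * s1$r, tolerance = 1e-10)
})

test_that("axial periodicity finds the dominant period", {
  x <- (0:511) * 0.5
  sig <- sin(2 * pi * x / 14.5)
  out <- axial_periodicity(sig, 0.5)
  expect_true(out$significant)
  expect_lt(abs(out$period - 14.5), 0.5)
  # constant profile: absent period, not significant
  out0 <- axial_periodicity(rep(3, 128), 0.5)
  expect_false(out0$significant)
  expect_true(is.na(out0$period))
  # 10% noise on a 20 nm period: still within one raw spectral bin
  noisy <- withr::with_seed(4, sin(2 * pi * x / 20) + rnorm(512, 0, 0.1))
  outn <- axial_periodicity(noisy, 0.5)
  expect_true(outn$significant)
  expect_lt(abs(outn$period - 20), 20^2 / (512 * 0.5))
  expect_error(axial_periodicity(sig[1:32], 0.5),
               class = "pepgel_input_error")
})

test_that("the paper_fiber preset reproduces the reported morphometry", {
  m <- gen_afm(preset = "paper_fiber")
  cc <- attr(m, "center_col")
  pr <- extract_cross_section(m, c(100, 0, 100, ncol(m$heights) - 1))
  sec <- measure_fiber_section(pr)
  expect_equal(sec$r, 3.6, tolerance = 0.03)
  expect_equal(sec$width_height_ratio, 3.5, tolerance = 0.03)
  mm <- gen_afm(preset = "paper_fiber", modulate = TRUE)
  ridge <- extract_cross_section(mm, c(0, cc, nrow(mm$heights) - 1, cc))
  per <- axial_periodicity(ridge$height, mm$pixel_size)
  expect_true(per$significant)
  expect_lt(abs(per$period - 14.5), 0.5)
})
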