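one_truth <- sans_params("one_level", B = 1, R = 2.9, C = 0.05, n = 1)
two_truth <- sans_params("two_level", B = 1, R = 2.9, C = 0.002, n = 1,
                         L = 10)

test_that("noise-free curves are recovered to 1e-4 relative", {
  f1 <- fit_sans(gen_sans(one_truth, n_points = 64L, noise = 0), "one_level")
  expect_true(f1$converged)
  for (k in c("B", "R", "C", "n"))
    expect_equal(f1$params[[k]], one_truth[[k]], tolerance = 1e-4)
  f2 <- fit_sans(gen_sans(two_truth, n_points = 64L, noise = 0), "two_level")
  for (k in c("B", "R", "L", "C", "n"))
    expect_equal(f2$params[[k]], two_truth[[k]], tolerance = 1e-4)
  expect_equal(f2$fractal_dimension, 6 - f2$params$n)
  expect_true(all(f2$fitted_curve > 0))
  expect_gt(f2$chi2_reduced, 0)
})

test_that("1% noise leaves parameter bias below 5% on identifiable curves", {
  res <- sapply(1:20, function(i) {
    f <- fit_sans(gen_sans(two_truth, seed = i), "two_level")
    c(f$params$R, f$params$L, f$params$n)
  })
  expect_lt(abs(mean(res[1, ]) / two_truth$R - 1), 0.05)
  expect_lt(abs(mean(res[2, ]) / two_truth$L - 1), 0.05)
  expect_lt(abs(mean(res[3, ]) / two_truth$n - 1), 0.05)
})

test_that("initial guesses are deterministic and land near the truth scale", {
  prof <- gen_sans(sans_params("one_level", B = 1, R = 2, C = 0.05, n = 1),
                   noise = 0)
  g1 <- initial_guess(prof, "one_level")
  g2 <- initial_guess(prof, "one_level")
  expect_identical(g1, g2)
  expect_gt(g1$R / 2, 0.5)
  expect_lt(g1$R / 2, 2)
  # flat profile: zero log-log slope clips n at the lower bound
  flat <- scattering_profile(seq(0.01, 0.02, length.out = 20), rep(5, 20),
                             sigma = rep(0.05, 20))
  expect_equal(initial_guess(flat, "one_level")$n, 0.2)
  g3 <- initial_guess(prof, "two_level")
  expect_equal(g3$L, 5 * g3$R)
})

test_that("model selection prefers parsimony and detects the second scale", {
  prof1 <- gen_sans(sans_params("one_level", B = 1, R = 2, C = 0.05, n = 1),
                    seed = 7)
  sel1 <- select_model(prof1)
  expect_identical(sel1$selected, "one_level")
  # nested models with no signal for L: one_level never loses on AICc
  expect_lte(sel1$one_level$aicc, sel1$two_level$aicc)
  prof2 <- gen_sans(sans_params("two_level", B = 1, R = 3, C = 0.01, n = 1,
                                L = 30), seed = 7)
  expect_identical(select_model(prof2)$selected, "two_level")
  # determinism: same profile, same selection
  expect_identical(select_model(prof2)$selected,
                   select_model(prof2)$selected)
})

test_that("fitted R preserves a temperature-decreasing ordering", {
  r_true <- c(3.0, 2.6, 2.3, 2.0)
  fitted <- vapply(seq_along(r_true), function(i) {
    p <- sans_params("one_level", B = 1, R = r_true[i], C = 0.05, n = 1)
    fit_sans(gen_sans(p, seed = 40 + i), "one_level")$params$R
  }, numeric(1))
  expect_true(all(diff(fitted) < 0))
})

test_that("fit guards reject bad windows and mismatched inits", {
  prof <- gen_sans(one_truth, seed = 1)
  expect_error(fit_sans(prof, "one_level", q_range = c(10, 20)),
               class = "pepgel_input_error")
  expect_error(fit_sans(prof, "one_level", q_range = c(2, 1)),
               class = "pepgel_input_error")
  wrong <- sans_params("two_level", B = 1, R = 1, C = 0.1, n = 1, L = 5)
  expect_error(fit_sans(prof, "one_level", init = wrong),
               class = "pepgel_input_error")
  # restricted window still fits
  f <- fit_sans(prof, "one_level", q_range = c(0.1, 4))
  expect_gte(min(f$q_range_used), 0.1)
})

test_that("uncertainties are finite one-sigma values at the optimum", {
  f <- fit_sans(gen_sans(one_truth, seed = 3), "one_level")
  expect_true(all(is.finite(f$uncertainties)))
  expect_true(all(f$uncertainties > 0))
  # R is determined to a few percent at 1% noise on this curve
  expect_lt(f$uncertainties[["R"]] / f$params$R, 0.2)
})
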