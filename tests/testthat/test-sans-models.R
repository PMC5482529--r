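test_that("q_from_angle implements the momentum-transfer definition", {
  expect_identical(q_from_angle(0.6, 0), 0)
  expect_equal(q_from_angle(0.6, 2 * asin(0.1)), 4 * pi * 0.1 / 0.6,
               tolerance = 1e-12)
  expect_equal(q_from_angle(0.6, 2 * asin(0.1)), 2.0944, tolerance = 1e-4)
  # monotone increasing in the angle on [0, pi)
  th <- seq(0, 3, length.out = 50)
  expect_true(all(diff(q_from_angle(0.6, th)) > 0))
  # a 0.6 nm beam can reach both ends of the 0.04-4 nm^-1 window
  expect_lt(q_from_angle(0.6, 0.001), 0.04)
  expect_gt(q_from_angle(0.6, 3), 4)
  expect_error(q_from_angle(-1, 0.1), class = "pepgel_input_error")
  expect_error(q_from_angle(0.6, pi), class = "pepgel_input_error")
})

test_that("model evaluation matches hand-computed values", {
  expect_equal(eval_one_level(0, B = 2, R = 5, C = 0, n = 1), 2.0)
  expect_equal(eval_one_level(1, B = 0, R = 1, C = 3, n = 2), 3.0)
  expect_equal(eval_one_level(0.5, B = 10, R = 2, C = 0.1, n = 1), 5.2)
  expect_equal(eval_two_level(1, B = 6, R = 1, L = sqrt(3), C = 0, n = 1), 1.5)
  expect_equal(eval_two_level(1, B = 0, R = 1, L = 5, C = 5, n = 3), 5.0)
  expect_error(eval_one_level(0, B = 1, R = 1, C = 1, n = 2),
               class = "pepgel_input_error")
  expect_error(eval_two_level(0, B = 1, R = 1, L = 2, C = 1, n = 2),
               class = "pepgel_input_error")
})

test_that("two-level model reduces exactly to one-level at L = 0", {
  set.seed(11)
  for (i in 1:50) {
    q <- sort(stats::runif(20, 0.01, 10))
    B <- stats::runif(1, 0, 5); R <- stats::runif(1, 0.2, 20)
    C <- stats::runif(1, 0, 1); n <- stats::runif(1, 0.3, 5.5)
    expect_identical(eval_two_level(q, B = B, R = R, L = 0, C = C, n = n),
                     eval_one_level(q, B = B, R = R, C = C, n = n))
  }
})

test_that("model evaluation agrees with the independent oracle", {
  set.seed(7)
  worst <- 0
  for (i in 1:1000) {
    q <- stats::runif(1, 0.01, 10)
    B <- stats::runif(1, 0, 10); R <- stats::runif(1, 0.1, 50)
    L <- stats::runif(1, 0.1, 500)
    C <- stats::runif(1, 0, 2); n <- stats::runif(1, 0.25, 5.7)
    a <- eval_one_level(q, B = B, R = R, C = C, n = n)
    b <- oracle_one_level(q, B, R, C, n)
    a2 <- eval_two_level(q, B = B, R = R, L = L, C = C, n = n)
    b2 <- oracle_two_level(q, B, R, L, C, n)
    worst <- max(worst, abs(a - b) / b, abs(a2 - b2) / b2)
  }
  expect_lt(worst, 1e-12)
})

test_that("fractal dimension is 6 - n with domain checks", {
  expect_identical(fractal_dimension(3), 3)
  expect_identical(fractal_dimension(2), 4)
  eps <- 1e-9
  expect_equal(fractal_dimension(6 - eps), eps, tolerance = 1e-3)
  # involution: D -> 6 - D -> D
  for (D in c(0.5, 1.7, 2.9, 4.2))
    expect_equal(fractal_dimension(6 - D), D)
  expect_error(fractal_dimension(0), class = "pepgel_input_error")
  expect_error(fractal_dimension(6), class = "pepgel_input_error")
  expect_error(fractal_dimension(-1), class = "pepgel_input_error")
})

test_that("scattering_profile enforces its invariants", {
  q <- exp(seq(log(0.04), log(4), length.out = 20))
  expect_error(scattering_profile(q[1:5], rep(1, 5)),
               class = "pepgel_input_error")
  expect_error(scattering_profile(rev(q), rep(1, 20)),
               class = "pepgel_input_error")
  expect_error(scattering_profile(q, rep(1, 20), sigma = rep(0, 20)),
               class = "pepgel_input_error")
  p <- scattering_profile(q, rep(1, 20))
  expect_true(attr(p, "sigma_synthesized"))
  expect_true(all(p$sigma > 0))
})
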