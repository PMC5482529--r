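test_that("tan delta is the loss/storage ratio, scale-free", {
  expect_identical(tan_delta(100, 100), 1.0)
  expect_identical(tan_delta(200, 20), 0.1)
  expect_identical(tan_delta(10, 100), 10.0)
  expect_error(tan_delta(0, 1), class = "pepgel_input_error")
  set.seed(9)
  for (i in 1:20) {
    gp <- stats::runif(1, 1, 1e4); gpp <- stats::runif(1, 1, 1e4)
    k <- stats::runif(1, 0.01, 100)
    expect_equal(tan_delta(k * gp, k * gpp), tan_delta(gp, gpp),
                 tolerance = 1e-12)
  }
})

test_that("sweeps classify as gel, sol or viscoelastic by construction", {
  w <- 10^seq(-1, 1, length.out = 10)
  gel <- rheo_sweep(w, rep(200, 10), rep(20, 10))
  lab_gel <- classify_regime(gel)
  expect_identical(lab_gel$regime, "gel")
  expect_equal(lab_gel$max_tan_delta, 0.1)
  expect_lt(abs(lab_gel$gprime_slope), 1e-10)
  # Maxwell terminal zone on 0.1-1 rad/s: tan delta = 10/omega >= 10
  ws <- seq(0.1, 1, length.out = 10)
  sol <- rheo_sweep(ws, 0.5 * ws^2, 5 * ws)
  expect_identical(classify_regime(sol)$regime, "sol")
  # crossover inside the window
  wv <- 10^seq(-1, 1, length.out = 12)
  ve <- rheo_sweep(wv, 100 * wv^2 / (1 + wv^2), 100 * wv / (1 + wv^2))
  expect_identical(classify_regime(ve)$regime, "viscoelastic")
  # classification is invariant to point order (constructor sorts)
  perm <- sample(seq_along(wv))
  ve2 <- rheo_sweep(wv[perm], (100 * wv^2 / (1 + wv^2))[perm],
                    (100 * wv / (1 + wv^2))[perm])
  expect_identical(classify_regime(ve2)$regime, "viscoelastic")
  expect_error(rheo_sweep(wv[1:3], rep(1, 3), rep(1, 3)),
               class = "pepgel_input_error")
})

test_that("generated sweeps classify as their generating regime", {
  for (reg in c("gel", "sol", "viscoelastic"))
    for (s in 1:5)
      expect_identical(classify_regime(gen_rheo(reg, seed = s))$regime, reg)
})

test_that("the state diagram recovers its constructed sol-gel boundary", {
  grid <- gen_state_grid(seed = 5)
  labels <- grid$grid
  labels$regime <- vapply(grid$sweeps,
                          function(s) classify_regime(s)$regime,
                          character(1))
  # every grid point classifies exactly as constructed
  expect_identical(labels$regime, grid$grid$true_regime)
  sd <- build_state_diagram(labels[c("concentration", "temperature",
                                     "regime")])
  step <- 10   # temperature grid spacing
  for (cc in c(3, 4, 5)) {
    b <- sd$boundary$t_gel[sd$boundary$concentration == cc]
    expect_false(is.na(b))
    expect_lt(abs(b - grid$melt_line(cc)), step)
    # boundary lies between the warmest gel and coolest non-gel point
    sub <- labels[labels$concentration == cc, ]
    expect_gte(b, max(sub$temperature[sub$regime == "gel"]))
    expect_lte(b, min(sub$temperature[sub$regime != "gel" &
                        sub$temperature >
                          max(sub$temperature[sub$regime == "gel"])]))
  }
  # no gel at low concentrations: boundary undefined there
  expect_true(all(is.na(sd$boundary$t_gel[sd$boundary$concentration < 2])))
  expect_gte(sd$boundary_monotone_fraction, 1)
  expect_error(build_state_diagram(labels[labels$concentration == 3, ]),
               class = "pepgel_input_error")
})
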