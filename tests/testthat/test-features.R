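test_that("derived curves match hand trigonometry", {
  c1 <- derive_curves(complex(real = 1, imaginary = -1))
  expect_equal(c1$magnitude, sqrt(2))
  expect_equal(c1$phase, -45)
  expect_equal(c1$tan_delta, 1)

  # phase -30 deg -> tan delta = tan(60 deg)
  z <- complex(modulus = 2, argument = -30 * pi / 180)
  expect_equal(derive_curves(z)$tan_delta, tan(60 * pi / 180),
               tolerance = 1e-12)

  # purely real impedance: capped with a warning
  expect_warning(c2 <- derive_curves(complex(real = 5, imaginary = 0)),
                 "capped")
  expect_equal(c2$tan_delta, 1e6)
  expect_equal(c2$phase, 0)
})

test_that("loss tangent is the cotangent of |phase|", {
  withr::with_seed(2, {
    z <- complex(modulus = runif(200, 1, 100),
                 argument = runif(200, -89, -1) * pi / 180)
    cur <- derive_curves(z)
    expect_equal(cur$tan_delta * tan(abs(cur$phase) * pi / 180),
                 rep(1, 200), tolerance = 1e-9)
  })
})

test_that("Py measures the relative magnitude drop and ignores scaling", {
  grid <- make_frequency_grid(300, 20, 3e5)
  p <- cole_params(100, 20, 1e-4, 1)   # tau centered in band
  cur <- derive_curves(cole_impedance(grid, p))
  expect_equal(compute_py(cur), 0.8, tolerance = 0.01)

  flat <- derive_curves(complex(modulus = rep(7, 10),
                                argument = rep(-10, 10) * pi / 180))
  expect_equal(compute_py(flat), 0)

  withr::with_seed(4, {
    for (g in runif(5, 0.1, 10)) {
      scaled <- derive_curves(cole_impedance(grid, p, scale = g))
      expect_equal(compute_py(scaled), compute_py(cur), tolerance = 1e-12)
    }
  })
  # any monotone-decreasing magnitude gives Py in (0, 1)
  dec <- derive_curves(complex(modulus = seq(50, 10, length.out = 20),
                               argument = rep(-5, 20) * pi / 180))
  expect_gt(compute_py(dec), 0)
  expect_lt(compute_py(dec), 1)
})

test_that("minimum phase matches a dense-grid numerical oracle", {
  ph <- c(-5, -40, -12)
  cur <- structure(list(magnitude = rep(1, 3), phase = ph,
                        tan_delta = rep(1, 3)), class = "derived_curves")
  expect_equal(compute_min_phase(cur), -40)
  cur$phase <- rep(-10, 3)
  expect_equal(compute_min_phase(cur), -10)

  # alpha = 1 Cole: analytic minimum at omega = sqrt(R0/Rinf)/tau
  p <- cole_params(100, 20, 1e-4, 1)
  dense <- make_frequency_grid(20000, 20, 3e5)
  cur <- derive_curves(cole_impedance(dense, p))
  f_min <- dense[which.min(cur$phase)]
  f_star <- sqrt(p$R0 / p$Rinf) / p$tau / (2 * pi)
  expect_equal(log(f_min), log(f_star), tolerance = 1e-3)
  # coarse-grid minimum within one grid step of the dense one
  coarse <- make_frequency_grid(300, 20, 3e5)
  curc <- derive_curves(cole_impedance(coarse, p))
  i <- which.min(curc$phase)
  expect_lt(abs(log10(coarse[i]) - log10(f_min)),
            1.5 * diff(log10(coarse[1:2])))
})

test_that("feature assembly has the documented shape and strictness", {
  d <- small_dataset(8, n_freq = 40)
  sel <- fixed_selection(d$train$grid)
  ft <- assemble_features(d$train, sel)
  expect_equal(nrow(ft), 90)
  expect_true(all(feature_names() %in% names(ft)))
  expect_length(feature_names(with_size = FALSE), 17)
  expect_false(anyNA(ft[, feature_names()]))
  expect_identical(ft$fruit_id, d$train$fruit_id)  # order preserved

  bad <- sel
  bad$magnitude[3] <- bad$magnitude[3] * 1.01
  expect_error(assemble_features(d$train, bad), "not on the acquisition grid")
  expect_error(assemble_features(d$train, list(magnitude = sel$magnitude[1:4],
                                               phase = sel$phase,
                                               tan_delta = sel$tan_delta)),
               "exactly 5")

  empty <- generate_dataset(generator_config(0, 0, 0, 0, n_freq = 40))
  sel0 <- lapply(sel, function(x) empty$train$grid[c(1, 5, 10, 20, 30)])
  ft0 <- assemble_features(empty$train, sel0)
  expect_equal(nrow(ft0), 0)
  expect_true(all(feature_names() %in% names(ft0)))
})
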