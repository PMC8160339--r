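# Hand-built dataset whose magnitude equals an arbitrary per-frequency
# monotone transform of a chosen driver (a* or size or noise).
driver_dataset <- function(n = 200, n_freq = 30, driver = "a_star",
                           seed = 1) {
  withr::with_seed(seed, {
    grid <- make_frequency_grid(n_freq, 20, 3e5)
    a <- runif(n, 10, 60)
    s <- runif(n, 15, 35)
    base <- switch(driver, a_star = a, size = s, noise = NULL)
    z <- matrix(complex(real = NA_real_), n, n_freq)
    for (j in seq_len(n_freq)) {
      v <- if (is.null(base)) rnorm(n) else base
      z[, j] <- complex(modulus = exp(v / 20) + j,  # increasing transform
                        argument = -runif(n, 5, 80) * pi / 180)
    }
    ds <- list(fruit_id = sprintf("d%03d", 1:n), size = s, a_star = a,
               label = as.integer(a > 35), grid = grid, z = z)
    class(ds) <- "fruit_dataset"
    ds
  })
}

test_that("perfect monotone association gives rank correlation 1", {
  ds <- driver_dataset(driver = "a_star")
  cc <- correlation_curves(ds, "magnitude", n_boot = 1, seed = 1)
  expect_equal(unname(cc$r_color), rep(1, 30))
  expect_true(all(abs(cc$r_size) <= 1))
})

test_that("pure-noise features stay inside the null correlation band", {
  ds <- driver_dataset(driver = "noise", seed = 5)
  cc <- correlation_curves(ds, "magnitude", n_boot = 1, seed = 2)
  expect_gte(mean(abs(cc$r_color) < 0.2), 0.95)
  expect_gte(mean(abs(cc$r_size) < 0.2), 0.95)
})

test_that("rank correlation is invariant under increasing transforms", {
  ds <- driver_dataset(driver = "a_star", seed = 3)
  cc1 <- correlation_curves(ds, "magnitude", n_boot = 4, seed = 9)
  ds2 <- ds
  ds2$z <- complex(modulus = Mod(ds$z)^3 + 1, argument = Arg(ds$z))
  dim(ds2$z) <- dim(ds$z)
  cc2 <- correlation_curves(ds2, "magnitude", n_boot = 4, seed = 9)
  expect_equal(cc1$r_color, cc2$r_color, tolerance = 1e-12)
})

# Build synthetic correlation curves directly.
fake_curves <- function(r_color, r_size, grid) {
  structure(list(parameter = "magnitude", freq_hz = grid,
                 r_color = r_color, r_size = r_size),
            class = "correlation_curves")
}

test_that("selection finds crossings and maxima of the correlation gap", {
  grid <- make_frequency_grid(41, 10, 1e5)
  lf <- log10(grid)
  # D(f): rises from -0.4, crosses zero at index ~15, peaks at index 30
  D <- c(seq(-0.4, 0.3, length.out = 31), seq(0.28, 0.05, length.out = 10))
  cv <- fake_curves(r_color = pmax(D, 0) + 0.1, r_size = 0.1 - pmin(D, 0),
                    grid = grid)
  # by construction |r_color| - |r_size| == D
  expect_equal(abs(cv$r_color) - abs(cv$r_size), D, tolerance = 1e-12)
  sel <- select_frequency_points(cv, k = 5, min_sep = 0.3)
  expect_length(sel, 5)
  expect_true(all(diff(sel) > 0))
  cross <- grid[which.min(abs(D[1:25]))]
  peak <- grid[which.max(D)]
  expect_true(cross %in% sel)
  expect_true(peak %in% sel)
})

test_that("degenerate flat curves fall back to even log-spacing", {
  grid <- make_frequency_grid(100, 20, 3e5)
  cv <- fake_curves(rep(0.3, 100), rep(0.3, 100), grid)
  sel <- select_frequency_points(cv, k = 5, min_sep = 0.3)
  expect_equal(sel, grid[round(seq(1, 100, length.out = 5))],
               ignore_attr = TRUE)
})

test_that("larger min_sep never increases the non-fallback pick count", {
  grid <- make_frequency_grid(60, 20, 3e5)
  withr::with_seed(11, {
    D <- stats::filter(rnorm(60, sd = 0.3), rep(1 / 5, 5), circular = TRUE)
    cv <- fake_curves(as.numeric(pmax(D, 0) + 0.05),
                      as.numeric(0.05 - pmin(D, 0)), grid)
  })
  non_fallback <- function(min_sep)
    attr(select_frequency_points(cv, k = 5, min_sep = min_sep),
         "n_candidates")
  counts <- vapply(c(0.1, 0.3, 0.6, 1.0), non_fallback, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("selection is deterministic and covers all three parameters", {
  d <- small_dataset(6, n_freq = 50)
  s1 <- screen_frequencies(d$train, n_boot = 10, seed = 4)
  s2 <- screen_frequencies(d$train, n_boot = 10, seed = 4)
  expect_identical(s1[c("magnitude", "phase", "tan_delta")],
                   s2[c("magnitude", "phase", "tan_delta")])
  for (par in c("magnitude", "phase", "tan_delta")) {
    expect_length(s1[[par]], 5)
    expect_true(all(s1[[par]] %in% d$train$grid))
    expect_true(all(diff(s1[[par]]) > 0))
  }
})
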