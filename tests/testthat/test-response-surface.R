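test_that("published surrogate evaluates to its hand-computed values", {
  m <- published_model()
  expect_equal(suppressWarnings(evaluate_strain(m, 0, 0)), 4.09e-3)
  expect_equal(evaluate_strain(m, 0.15, 2.5), 7.599825e-3)
  expect_equal(evaluate_strain(m, 0.3375, 2.38), 4.4078034375e-3)
  # vectorised
  expect_equal(evaluate_strain(m, c(0.15, 0.3375), c(2.5, 2.38)),
               c(7.599825e-3, 4.4078034375e-3))
})

test_that("evaluation warns outside the training envelope, errors on negatives", {
  m <- published_model()
  expect_warning(evaluate_strain(m, 0.3375, 3.5), "envelope")
  expect_warning(evaluate_strain(m, 1.5, 2.0), "envelope")
  expect_silent(evaluate_strain(m, 0.3375, 2.38))
  expect_error(evaluate_strain(m, -0.1, 2), "non-negative")
  expect_error(evaluate_strain(m, 0.3, -2), "non-negative")
})

test_that("surrogate has a positive load slope and negative BMD slope", {
  m <- published_model()
  a <- m$coefficients
  grid <- expand.grid(bmd = seq(0, 0.9, 0.05), bw = seq(0, 3.5, 0.1))
  d_bw <- a[["a2"]] + a[["a3"]] * grid$bmd + 2 * a[["a5"]] * grid$bw
  expect_true(all(d_bw > 0))
  low <- grid[grid$bmd <= 0.56 & grid$bw >= 1.5, ]
  d_bmd <- a[["a1"]] + a[["a3"]] * low$bw + 2 * a[["a4"]] * low$bmd
  expect_true(all(d_bmd < 0))
})

test_that("least squares recovers its own function class exactly", {
  d <- noise_free_data()
  f <- fit_response_surface(d)
  expect_equal(f$model$coefficients, published_model()$coefficients,
               tolerance = 1e-10)
  expect_equal(f$stats$r_squared, 1, tolerance = 1e-10)
  expect_equal(f$stats$sse, 0, tolerance = 1e-18)
  # fitting the fitted model's own predictions is idempotent
  d2 <- d
  d2$strain <- predict(f$model, d2)
  f2 <- fit_response_surface(d2)
  expect_equal(f2$model$coefficients, f$model$coefficients,
               tolerance = 1e-10)
})

test_that("six noise-free points are interpolated exactly", {
  d <- noise_free_data(n = 6, seed = 21)
  f <- fit_response_surface(d)
  expect_equal(unname(residuals(f$fit)), rep(0, 6), tolerance = 1e-12)
})

test_that("fit statistics follow their definitions on noisy data", {
  set.seed(42)
  d <- noise_free_data(seed = 13)
  d$strain <- d$strain + rnorm(nrow(d), 0, 6.57e-4)
  f <- fit_response_surface(d)
  sse <- sum(residuals(f$fit)^2)
  sst <- sum((d$strain - mean(d$strain))^2)
  expect_equal(f$stats$sse, sse)
  expect_equal(f$stats$r_squared, 1 - sse / sst)
  expect_equal(f$stats$adjusted_r_squared,
               1 - (1 - f$stats$r_squared) * (100 - 1) / (100 - 6))
  expect_equal(f$stats$rmse, sqrt(sse / 94))
})

test_that("degenerate fits are handled: constant response and collinearity", {
  d <- noise_free_data(n = 30, seed = 2)
  d$strain <- 0.005
  expect_warning(f <- fit_response_surface(d), "SST = 0")
  expect_equal(f$stats$r_squared, 0)
  expect_equal(unname(f$model$coefficients[2:6]), rep(0, 5),
               tolerance = 1e-9)
  # bmd == bw makes the quadratic regressors collinear
  dc <- data.frame(bmd = seq(0.1, 0.9, length.out = 20))
  dc$bw <- dc$bmd
  dc$strain <- 0.001 * dc$bmd
  expect_error(fit_response_surface(dc), "collinear")
  expect_error(fit_response_surface(d[1:5, ]), "at least 6")
})

test_that("failure boundary roots lie exactly on the yield contour", {
  m <- published_model()
  roots <- failure_boundary_bmd(m, 0.0085, bw = 2.5)
  expect_equal(roots[1], 0.103967780858, tolerance = 1e-9)
  for (r in roots) {
    expect_equal(evaluate_strain(m, r, 2.5, warn_envelope = FALSE), 0.0085,
                 tolerance = 1e-10)
  }
  # at modest load the physical BMD range is entirely safe: S(0, 1) sits
  # below yield and the only crossing is far outside the training envelope
  # (the quadratic opens upward in BMD, so it re-crosses the yield level at
  # a nonphysical density)
  r1 <- failure_boundary_bmd(m, 0.0085, bw = 1.0)
  expect_lt(evaluate_strain(m, 0, 1, warn_envelope = FALSE), 0.0085)
  expect_true(all(r1 > 0.9))
  expect_equal(r1, 1.355135, tolerance = 1e-6)
  # a yield far above any strain in the physical range: no root below
  # 0.9 g/cm^3 either
  expect_true(all(failure_boundary_bmd(m, 0.05, bw = 2.5) > 0.9))
  expect_error(failure_boundary_bmd(m, 0, bw = 2), "positive")
})

test_that("a vanishing quadratic coefficient degrades to the linear solve", {
  m <- quadratic_response_model(4.09, -17.66, 2.80, 0, 0, 0)
  r <- failure_boundary_bmd(m, 0.0085, bw = 2.5)
  expect_equal(r, (4.09 + 2.80 * 2.5 - 8.5) / 17.66)
  expect_equal(evaluate_strain(m, r, 2.5, warn_envelope = FALSE), 0.0085)
})

test_that("region classification matches pointwise evaluation and the boundary", {
  m <- published_model()
  expect_true(classify_region(m, 0.0085, 0.10, 3.0)[1, 1])
  expect_false(classify_region(m, 0.0085, 0.5, 2.0)[1, 1])
  # strain is strictly positive inside the training envelope, so a zero
  # yield classifies everything there as failure (outside it the
  # extrapolated surrogate can go negative)
  expect_true(all(classify_region(m, 0, seq(0, 0.9, 0.1),
                                  seq(0.8, 3.2, 0.2))))
  # sign changes down each BW column coincide with the solver's roots
  bmd_grid <- seq(0, 0.9, length.out = 181)
  bw_grid <- seq(0.5, 3.2, length.out = 28)
  mask <- classify_region(m, 0.0085, bmd_grid, bw_grid)
  h <- diff(bmd_grid[1:2])
  for (j in seq_along(bw_grid)) {
    roots <- failure_boundary_bmd(m, 0.0085, bw_grid[j])
    roots <- roots[roots <= max(bmd_grid)]
    flips <- which(diff(mask[, j]) != 0)
    expect_length(flips, length(roots))
    for (k in seq_along(roots)) {
      expect_lt(abs(bmd_grid[flips[k]] - roots[k]), h)
    }
  }
})

test_that("region table exports long-format CSV", {
  f <- withr::local_tempfile(fileext = ".csv")
  g <- region_table(published_model(), 0.0085, c(0.1, 0.5), c(2, 2.5),
                    path = f)
  expect_named(g, c("bmd", "bw", "strain", "failure"))
  expect_equal(nrow(g), 4)
  expect_equal(read.csv(f)$failure,
               c(FALSE, FALSE, TRUE, FALSE)) # only (0.1, 2.5) fails
})

test_that("model configs round-trip through YAML", {
  f <- withr::local_tempfile(fileext = ".yaml")
  m <- quadratic_response_model(1.1, -2.2, 3.3, -4.4, 5.5, -6.6,
                                scale = 1e-2)
  write_model_config(m, f)
  m2 <- read_model_config(f)
  expect_equal(m2$coefficients, m$coefficients)
  expect_equal(m2$scale, m$scale)
  bad <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(a0 = 1), bad)
  expect_error(read_model_config(bad), "must contain")
})
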