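test_that("polynomial evaluation follows the coefficient definition", {
  expect_equal(predict_feature(poly_model(c(1, 2)), 3), 7)
  expect_equal(predict_feature(poly_model(c(0, 0, 0)), 5), 0)
  expect_equal(predict_feature(poly_model(c(1, 0, 0, 0, 1)), 2), 17)
  expect_equal(predict_feature(poly_model(c(1, 2)), c(0, 1, 2)), c(1, 3, 5))
  expect_error(poly_model(c(1, NA)), "finite")
})

test_that("penalized cost combines data misfit and the intercept-free penalty", {
  s <- line_series(c(8, 10, 12))
  exact <- poly_model(c(60, 8))
  cfg0 <- penalty_config(order = 1, c = 0, lambda = 0, alpha = 1)
  expect_equal(cost(exact, s, cfg0), 0)
  one <- prepare_series(1, 2)
  expect_equal(cost(poly_model(c(0, 0)), one,
                    penalty_config(order = 1, c = 0, lambda = 0, alpha = 1)),
               4)
  # Penalty term only (no data): E = lambda * c_1 * a_1^2 = 1 * 2 * 9.
  expect_equal(cost(poly_model(c(0, 3)), NULL,
                    penalty_config(order = 1, c = 2, lambda = 1, alpha = 1)),
               18)
  # The intercept is never penalized.
  expect_equal(cost(poly_model(c(1e6, 0)), NULL,
                    penalty_config(order = 1, c = 2, lambda = 1, alpha = 1)),
               0)
})

test_that("analytic gradient matches central finite differences", {
  for (seed in 1:5) {
    s <- noisy_series(15, c(100, 3, -0.5), noise_sd = 2, seed = seed)
    cfg <- penalty_config(order = 3, c = c(1, 10, 20), lambda = 0.5,
                          alpha = 0.7)
    a <- withr::with_seed(seed + 100, runif(4, -2, 2))
    g <- cost_gradient(poly_model(a), s, cfg)
    delta <- 1e-6
    g_num <- vapply(seq_along(a), function(i) {
      ap <- a; am <- a
      ap[i] <- a[i] + delta; am[i] <- a[i] - delta
      (cost(poly_model(ap), s, cfg) - cost(poly_model(am), s, cfg)) /
        (2 * delta)
    }, numeric(1))
    expect_equal(g, g_num, tolerance = 1e-6)
  }
})

test_that("unpenalized gradient descent matches the normal-equation solution", {
  for (seed in 1:5) {
    s1 <- noisy_series(30, c(3, -0.2), noise_sd = 0.1, seed = seed)
    m1 <- fit_penalty_regression(s1, toy_penalty_config(order = 1,
                                                        init_seed = seed))
    ols1 <- as.numeric(coef(lm(z ~ hb, data = s1)))
    expect_equal(m1$coeffs, ols1, tolerance = 1e-3)

    s2 <- noisy_series(30, c(1, 0.5, -0.03), noise_sd = 0.05, seed = seed)
    m2 <- fit_penalty_regression(s2, toy_penalty_config(order = 2,
                                                        init_seed = seed))
    ols2 <- as.numeric(coef(lm(z ~ hb + I(hb^2), data = s2)))
    expect_equal(m2$coeffs, ols2, tolerance = 1e-3)
  }
})

test_that("the fitted cost never increases across accepted iterations", {
  s <- noisy_series(40, c(150, -4, 0.1), noise_sd = 3, seed = 2)
  m <- fit_penalty_regression(
    s, toy_penalty_config(order = 4, c = c(1, 10, 20, 30), lambda = 1e-3),
    trace = TRUE)
  tr <- m$fit_report$cost_trace
  expect_true(all(diff(tr) <= 0))
})

test_that("a heavy ridge penalty shrinks the slope terms toward a constant fit", {
  s <- noisy_series(30, c(2, 0.4), noise_sd = 0.05, seed = 3)
  m <- fit_penalty_regression(
    s, toy_penalty_config(order = 2, c = c(1, 10), lambda = 1e6,
                          max_iter = 2e5))
  expect_lt(max(abs(m$coeffs[-1])), 1e-3)
})

test_that("penalty strength is monotone: larger lambda, smaller penalty term", {
  # The penalty acts on the coefficients in the fitting space, so this is
  # checked on an unstandardized problem with Hb near 1 where gradient
  # descent converges to the ridge minimizer.
  s <- noisy_series(40, c(1, 0.8, -0.2, 0.05, -0.01), noise_sd = 0.05,
                    seed = 9, hb_range = c(0.5, 1.5))
  cpen <- c(1, 10, 20, 30)
  pen_term <- vapply(c(1e-3, 1e-1, 10), function(lam) {
    m <- fit_penalty_regression(
      s, penalty_config(order = 4, c = cpen, lambda = lam, alpha = 2e-3,
                        tol = 1e-13, tol_type = "absolute", max_iter = 2e5,
                        standardize = FALSE))
    sum(cpen * m$coeffs[-1]^2)
  }, numeric(1))
  expect_true(all(diff(pen_term) < 0))
})

test_that("the raw update diverges for an oversized step and reports it", {
  s <- noisy_series(30, c(100, 5), noise_sd = 1, seed = 1,
                    hb_range = c(6, 16))
  cfg <- penalty_config(order = 4, c = c(1, 10, 20, 30), lambda = 1e-12,
                        alpha = 1e-6, tol = 1e-10, max_iter = 1e4,
                        adapt_step = FALSE)
  expect_error(fit_penalty_regression(s, cfg),
               class = "hbscreen_numerical_error")
})

test_that("config validation enforces the penalty assignment principle", {
  expect_error(penalty_config(order = 0), "order")
  expect_error(penalty_config(order = 4, c = c(1, 2)), "penalty coefficients")
  expect_error(penalty_config(alpha = 0), "alpha")
  expect_warning(penalty_config(order = 2, c = c(10, 1)), "nondecreasing")
})

test_that("the closed-form linear baseline is exact on simple cases", {
  s <- prepare_series(c(1, 2), c(1, 2))
  expect_equal(fit_linear_regression(s)$coeffs, c(0, 1))
  flat <- prepare_series(c(2, 4, 6), c(5, 5, 5))
  expect_equal(fit_linear_regression(flat)$coeffs, c(5, 0))
  col <- prepare_series(c(1, 2, 3), c(10, 12, 14))
  m <- fit_linear_regression(col)
  expect_equal(m$coeffs, c(8, 2))
  expect_equal(m$fit_report$final_cost, 0, tolerance = 1e-20)
  expect_error(fit_linear_regression(prepare_series(rep(3, 2), c(1, 2))),
               "distinct")
})

test_that("curve inversion recovers Hb, clamps, and flags matching issues", {
  line <- poly_model(c(200, -10))
  expect_equal(invert_model(line, 90, c(5, 16)), 11, tolerance = 1e-6)
  # Feature above the curve's maximum on a decreasing line: clamp to h_lo.
  expect_equal(invert_model(line, 500, c(5, 16)), 5)
  expect_equal(invert_model(line, -500, c(5, 16)), 16)
  # Non-monotone curve: ties resolve to the lowest Hb with a warning.
  quad <- poly_model(c(0, 0, 1))
  expect_warning(est <- invert_model(quad, 1, c(-2, 2)), "matching issue")
  expect_equal(est, -1, tolerance = 1e-6)
  expect_error(invert_model(line, 90, c(16, 5)), "h_range")
  # Round trip within grid resolution for a strictly monotone model.
  mono <- poly_model(c(60, 8, 0.1))
  for (h_true in c(6.3, 9.7, 12.2, 15.8)) {
    f <- predict_feature(mono, h_true)
    expect_equal(invert_model(mono, f, c(6, 16)), h_true, tolerance = 1e-3)
  }
})

test_that("standardized fits report coefficients in raw units", {
  s <- noisy_series(25, c(60, 8), noise_sd = 0.2, seed = 6)
  m <- fit_penalty_regression(s, toy_penalty_config(order = 1))
  expect_equal(predict_feature(m, 10),
               as.numeric(predict(lm(z ~ hb, data = s),
                                  data.frame(hb = 10))),
               tolerance = 1e-3)
  expect_equal(m$coeffs[1], 60, tolerance = 0.5)
})

test_that("models serialize to JSON and back", {
  s <- noisy_series(20, c(2, 1), noise_sd = 0.1, seed = 4)
  cfg <- toy_penalty_config(order = 1)
  m <- fit_penalty_regression(s, cfg)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, path, cfg = cfg)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$coeffs, m$coeffs)
  expect_identical(back$order, m$order)
})
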