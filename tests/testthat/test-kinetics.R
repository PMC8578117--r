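# Forward simulation and per-pixel fitting of the DCE signal models.

test_that("cumulative trapezoid integral matches closed forms", {
  # constant input: trapezoid is exact, ramp 0, 1, 2, ...
  expect_equal(cumulative_integral(rep(1, 6), dt = 1), 0:5)
  # linear input: trapezoid is exact for degree-1 polynomials
  t <- seq(0, 5, by = 0.5)
  expect_equal(cumulative_integral(2 * t, dt = 0.5), t^2, tolerance = 1e-12)
  # all-zero input, both orders
  expect_equal(cumulative_integral(rep(0, 9), dt = 0.3), rep(0, 9))
  expect_equal(cumulative_integral(rep(0, 9), dt = 0.3, order = 2), rep(0, 9))
  # sin(t) against the analytic antiderivative 1 - cos(t)
  t <- seq(0, 10, by = 0.01)
  err <- cumulative_integral(sin(t), dt = 0.01) - (1 - cos(t))
  expect_lt(max(abs(err)), 1e-3)
  # first output sample is zero, and matrices integrate columnwise
  m <- cbind(sin(t), cos(t))
  im <- cumulative_integral(m, dt = 0.01)
  expect_equal(im[1, ], c(0, 0))
  expect_equal(im[, 2], cumulative_integral(cos(t), dt = 0.01))
})

test_that("cumulative integral rejects invalid sampling", {
  expect_error(cumulative_integral(1:5, dt = -1), "invalid sampling")
  expect_error(cumulative_integral(1:5, times = c(0, 1, 2, 4, 5)),
               "invalid sampling")
  expect_error(cumulative_integral(1:5, dt = 1, order = 3), "order")
})

test_that("2CFM forward simulation obeys limiting cases", {
  # zero input concentration gives zero tissue concentration
  ca0 <- aif(seq(0, 50, 0.1), rep(0, 501), baseline = 50)
  p <- kinetic_params(FP = 150, TP = 10, FT = 50, TT = 120)
  expect_equal(simulate_concentration_2cfm(p, ca0, dt = 0.1),
               rep(0, 501))
  # FT = 0 with a narrow unit-area bolus: single-compartment exponential
  dt <- 0.005
  t <- seq(0, 30, by = dt)
  w <- 1  # short bolus of unit area
  ca <- aif(t, ifelse(t < w, 1 / w, 0), baseline = 0)
  p1 <- suppressWarnings(kinetic_params(FP = 150, TP = 10, FT = 0, TT = 120))
  C <- simulate_concentration_2cfm(p1, ca, dt = dt)
  late <- t > 2
  # analytic single-compartment response to the finite-width bolus
  ref <- (150 / 6000) * 10 / w * (exp(-(t[late] - w) / 10) - exp(-t[late] / 10))
  expect_lt(max(abs(C[late] - ref)), 1e-2 * 150 / 6000)
  # parameter-domain errors
  expect_error(kinetic_params(FP = 150, TP = -1, FT = 50, TT = 120))
})

test_that("biexponential convolution agrees with an ODE solver", {
  skip_if_not_installed("deSolve")
  ca <- aif(seq(0, 60, 0.01),
            ifelse(seq(0, 60, 0.01) >= 5 & seq(0, 60, 0.01) < 15, 1, 0),
            baseline = 5)
  p <- kinetic_params(FP = 150, TP = 10, FT = 50, TT = 120)
  C <- simulate_concentration_2cfm(p, ca, dt = 0.01)
  caf <- stats::approxfun(ca$times, ca$values, rule = 2)
  fp <- 150 / 6000; ft <- 50 / 6000
  rhs <- function(t, y, parms) {
    list(c(fp * caf(t) - y[1] / 10,
           (ft / (fp * 10)) * y[1] - y[2] / 120))
  }
  sol <- deSolve::lsoda(c(0, 0), ca$times, rhs, NULL,
                        rtol = 1e-10, atol = 1e-12)
  Code <- sol[, 2] + sol[, 3]
  expect_lt(max(abs(C - Code)) / max(Code), 1e-3)
})

test_that("signal conversion is elementwise and invertible", {
  C <- array(runif(2 * 3 * 4), dim = c(2, 3, 4))
  S0 <- matrix(1:6 / 6, 2, 3)
  S <- concentration_to_signal(S0, C)
  expect_equal(S[, , 2], S0 + C[, , 2])
  expect_equal(signal_to_concentration(S0, S), C)
  # zero concentration returns S0; DRO convention S0 = 1
  expect_equal(concentration_to_signal(1, C * 0), C * 0 + 1)
  expect_error(concentration_to_signal(matrix(1, 3, 3), C), "shape")
})

test_that("linearised 2CFM fit reproduces noise-free data and parameters", {
  ca <- population_aif(180, dt = 0.1, baseline = 15)
  t <- seq(0, 180, by = 0.1)
  p <- kinetic_params(FP = 150, TP = 10, FT = 50, TT = 120)
  C <- simulate_concentration_2cfm(p, ca, dt = 0.1)
  ser <- pixel_series(1 + C, t, n0 = 120)
  fit <- fit_linear_2cfm(ser, ca)
  # relative RMS residual well below 1e-3
  num <- sqrt(mean((ser$data - fit$fitted)^2))
  den <- sqrt(mean((ser$data - 1)^2))
  expect_lt(num / den, 1e-3)
  # inversion recovers the parameters within 1%
  pp <- coeffs_to_params(fit)
  expect_equal(pp$FP[1], 150, tolerance = 0.01)
  expect_equal(pp$TP[1], 10, tolerance = 0.01)
  expect_equal(pp$FT[1], 50, tolerance = 0.01)
  expect_equal(pp$TT[1], 120, tolerance = 0.01)
  expect_true(all(pp$ok))
  # discretisation quantities are small at dt << TP, TT
  eps <- attr(coeffs_to_params(fit, dt = 0.1), "epsilons")
  expect_lt(max(eps$eps1), 0.05)
  expect_lt(max(eps$eps2), 0.05)
})

test_that("flat pixels degrade gracefully to a constant target", {
  ca <- population_aif(40, dt = 1, baseline = 10)
  ser <- pixel_series(rep(2, 41), seq(0, 40), n0 = 5)
  fit <- fit_linear_2cfm(ser, ca)
  expect_false(any(fit$ok))
  expect_equal(unname(fit$coefficients), matrix(0, 4, 4))
  expect_equal(fit$fitted, ser$data * 0 + 2)
})

test_that("fit is equivariant under affine signal rescaling", {
  ca <- population_aif(120, dt = 0.5, baseline = 15)
  t <- seq(0, 120, by = 0.5)
  p <- kinetic_params(FP = 250, TP = 8, FT = 45, TT = 100)
  C <- simulate_concentration_2cfm(p, ca, dt = 0.5)
  set.seed(11)
  noisy <- 1 + C + rnorm(length(C), sd = 0.01)
  ser <- pixel_series(noisy, t, n0 = 25)
  fit1 <- fit_linear_2cfm(ser, ca)
  ser2 <- ser
  ser2$data <- 3.5 * ser$data + 0.7
  fit2 <- fit_linear_2cfm(ser2, ca)
  expect_equal(fit2$fitted, 3.5 * fit1$fitted + 0.7, tolerance = 1e-8)
})

test_that("fitted target is the least-squares optimum", {
  ca <- population_aif(120, dt = 0.5, baseline = 15)
  t <- seq(0, 120, by = 0.5)
  p <- kinetic_params(FP = 100, TP = 12, FT = 55, TT = 200)
  C <- simulate_concentration_2cfm(p, ca, dt = 0.5)
  set.seed(4)
  ser <- pixel_series(1 + C + rnorm(length(C), sd = 0.02), t, n0 = 25)
  fit <- fit_linear_2cfm(ser, ca)
  rss0 <- sum((ser$data[1, 1, ] - fit$fitted[1, 1, ])^2)
  # random coefficient perturbations never reduce the residual
  y <- ser$data[1, 1, ] - fit$S0[1, 1]
  X <- cbind(cumulative_integral(y, dt = 0.5),
             cumulative_integral(y, dt = 0.5, order = 2),
             cumulative_integral(sample_aif(ca, t), dt = 0.5),
             cumulative_integral(sample_aif(ca, t), dt = 0.5, order = 2))
  for (i in 1:25) {
    cpert <- fit$coefficients[, 1] + rnorm(4, sd = 1e-3 *
                                             (abs(fit$coefficients[, 1]) + 1e-6))
    rss <- sum((y - X %*% cpert)^2)
    expect_gte(rss, rss0 - 1e-12)
  }
})

test_that("coefficient inversion handles degenerate branches", {
  # one-compartment limit: alpha2 = beta2 = 0
  pp <- coeffs_to_params(c(-0.1, 0, 0.02, 0))
  expect_equal(pp$TP[1], 10)
  expect_equal(pp$FP[1], 120)
  expect_true(is.na(pp$TT[1]) && is.na(pp$FT[1]))
  expect_true(pp$ok[1])
  # complex roots are flagged, not an error
  pp2 <- coeffs_to_params(c(0.01, -5, 0.02, 0.001))
  expect_false(pp2$ok[1])
  expect_true(all(is.na(unlist(pp2[1, 1:4]))))
  # forward and inverse mappings are mutually consistent
  p <- kinetic_params(FP = 80, TP = 15, FT = 40, TT = 250)
  back <- coeffs_to_params(params_to_coeffs(p))
  expect_equal(back$FP[1], 80, tolerance = 1e-10)
  expect_equal(back$TT[1], 250, tolerance = 1e-10)
})

test_that("modified Tofts fit recovers its own simulations", {
  dt <- 1.1
  t <- seq(0.55, 120, by = dt)
  ca_obj <- population_aif(130, dt = 0.1, baseline = 15)
  ca <- sample_aif(ca_obj, t)
  kep_grid <- 10^seq(-4, 0, length.out = 30)
  kep_true <- kep_grid[17]  # on the search grid: recovery can be exact
  b <- exp(-kep_true * (t - t[1]))
  conv <- stats::convolve(b, rev(ca), type = "open")[seq_along(t)]
  B <- dt * (conv - 0.5 * b[1] * ca - 0.5 * b * ca[1]); B[1] <- 0
  C <- 0.05 * ca + 0.002 * B
  ser <- pixel_series(1 + C, t, n0 = 13)
  fit <- fit_modified_tofts(ser, ca_obj)
  expect_equal(unname(fit$coefficients["vp", 1]), 0.05, tolerance = 0.01)
  expect_equal(unname(fit$coefficients["ktrans", 1]), 0.002, tolerance = 0.01)
  expect_equal(unname(fit$coefficients["kep", 1]), kep_true, tolerance = 1e-12)
  # zero input: fit returns zeros regardless of the data shape
  ca0 <- aif(seq(0, 120, dt), rep(0, length(seq(0, 120, dt))), baseline = 120)
  fit0 <- fit_modified_tofts(pixel_series(1 + C, t, n0 = 13), ca0)
  expect_equal(unname(fit0$coefficients["vp", ]), rep(0, 4))
  expect_equal(unname(fit0$coefficients["ktrans", ]), rep(0, 4))
})

test_that("Tofts misfits the first pass of 2CFM data more than the 2CFM", {
  ca <- population_aif(130, dt = 0.1, baseline = 15)
  t <- seq(0.55, 130, by = 1.1)
  p <- kinetic_params(FP = 300, TP = 6, FT = 60, TT = 90)
  Cf <- simulate_concentration_2cfm(p, ca, dt = 0.1)
  C <- stats::approx(seq(0, 130, 0.1), Cf, xout = t)$y
  ser <- pixel_series(1 + C, t, n0 = 13)
  f2 <- fit_linear_2cfm(ser, ca)
  ft <- fit_modified_tofts(ser, ca)
  first_pass <- t > 15 & t < 40
  r2 <- mean((ser$data[1, 1, first_pass] - f2$fitted[1, 1, first_pass])^2)
  rt <- mean((ser$data[1, 1, first_pass] - ft$fitted[1, 1, first_pass])^2)
  expect_gt(rt, r2)
})

test_that("parameter recovery works across the phantom parameter ranges", {
  ca <- population_aif(180, dt = 0.1, baseline = 15)
  t <- seq(0, 180, by = 0.1)
  combos <- expand.grid(FP = c(30, 300), TP = c(6, 20),
                        FT = c(40, 60), TT = c(90, 300))
  for (i in seq_len(nrow(combos))) {
    p <- kinetic_params(combos$FP[i], combos$TP[i], combos$FT[i],
                        combos$TT[i])
    C <- simulate_concentration_2cfm(p, ca, dt = 0.1)
    fit <- fit_linear_2cfm(pixel_series(1 + C, t, n0 = 120), ca)
    expect_true(all(fit$ok))
    pp <- coeffs_to_params(fit)
    expect_equal(pp$FP[1], combos$FP[i], tolerance = 0.01)
    expect_equal(pp$TT[1], combos$TT[i], tolerance = 0.01)
  }
})
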