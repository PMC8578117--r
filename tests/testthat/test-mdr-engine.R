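# The registration engine: cost, analytical gradient, generalised
# residual, per-frame deformation fitting and the full alternating scheme.

test_that("the joint cost matches its definition", {
  expect_equal(mdr_cost(matrix(1, 2, 2), matrix(1, 2, 2)), 0)
  expect_equal(mdr_cost(3, 1), 2)  # single residual of 2 -> 0.5 * 4
  set.seed(8)
  a <- array(rnorm(60), dim = c(3, 4, 5))
  b <- array(rnorm(60), dim = c(3, 4, 5))
  brute <- 0
  for (i in 1:3) for (j in 1:4) for (t in 1:5)
    brute <- brute + 0.5 * (a[i, j, t] - b[i, j, t])^2
  expect_equal(mdr_cost(a, b), brute)
})

test_that("analytical control-point gradient matches finite differences", {
  set.seed(9)
  img <- blob_image(16)
  nt <- 5
  targets <- lapply(1:nt, function(t) img * (0.85 + 0.05 * t) + 0.02 * t)
  g <- control_grid(c(16, 16), spacing = 5, n_frames = nt)
  # generic non-integer displacement state: at the exact identity every
  # voxel sits on an interpolation-cell boundary where the piecewise-linear
  # interpolant is not differentiable
  g$disp[] <- array(runif(length(g$disp), 0.25, 0.45), dim = dim(g$disp))
  h <- 1e-3
  worst <- 0
  for (t in 1:nt) {
    G <- gradient_control_points(g, img, targets[[t]], t)
    fd <- G * 0
    for (j in seq_len(nrow(G))) for (a in 1:2) {
      gp <- g; gp$disp[j, a, t] <- gp$disp[j, a, t] + h
      gm <- g; gm$disp[j, a, t] <- gm$disp[j, a, t] - h
      fd[j, a] <- (mdr_cost(deform_image(img, gp, t), targets[[t]]) -
                     mdr_cost(deform_image(img, gm, t), targets[[t]])) / (2 * h)
    }
    worst <- max(worst, max(abs(G - fd)) / max(abs(fd)))
  }
  expect_lt(worst, 1e-3)
  # trivial cases: zero residual or spatially constant image
  gi <- control_grid(c(16, 16), spacing = 5)
  expect_equal(max(abs(gradient_control_points(gi, img, img))), 0)
  expect_equal(max(abs(gradient_control_points(gi, matrix(2, 16, 16),
                                               matrix(1, 16, 16)))), 0)
})

test_that("generalised residual matches the perturbation oracle", {
  set.seed(10)
  Tn <- 12; n0 <- 3; dt <- 1.1
  a1 <- -0.11; a2 <- -9e-4; b1 <- 0.02; b2 <- 1e-3
  ca1 <- cumsum(runif(Tn)); ca2 <- cumulative_integral(ca1, dt = dt)
  S <- 1 + cumsum(runif(Tn, 0, 0.1))
  resid_of <- function(S) {
    S0 <- mean(S[1:n0]); y <- S - S0
    S - (S0 + a1 * cumulative_integral(y, dt = dt) +
           a2 * cumulative_integral(y, dt = dt, order = 2) +
           b1 * ca1 + b2 * ca2)
  }
  dR_fd <- matrix(0, Tn, Tn)
  h <- 1e-6
  for (s in 1:Tn) {
    Sp <- S; Sp[s] <- Sp[s] + h
    Sm <- S; Sm[s] <- Sm[s] - h
    dR_fd[, s] <- (resid_of(Sp) - resid_of(Sm)) / (2 * h)
  }
  dR <- residual_derivative_matrix(a1, a2, dt, n0, Tn)
  expect_lt(max(abs(dR - dR_fd)), 1e-6)
  # forcing the identity returns the plain residual exactly
  R <- matrix(resid_of(S), ncol = 1)
  cf <- matrix(c(a1, a2, b1, b2), ncol = 1)
  expect_identical(generalized_residual(R, cf, dt, n0, identity = TRUE), R)
  # alpha -> 0 leaves only the baseline-averaging term
  dR0 <- residual_derivative_matrix(0, 0, dt, n0, Tn)
  M0 <- matrix(0, Tn, Tn); M0[, 1:n0] <- 1 / n0
  expect_equal(dR0, diag(Tn) - M0)
})

test_that("single-frame deformation fitting recovers a known shift", {
  img <- blob_image(32)
  f <- matrix(0, 32 * 32, 2); f[, 2] <- -3  # target: img shifted by 3 px
  target <- warp_image(img, f)
  g <- control_grid(c(32, 32), spacing = 32)
  res <- fit_deformation_frame(img, target, g,
                               config = mdr_config(tolerance = 0.1,
                                                   grid_spacing_min = 16))
  mean_dy <- mean(dense_displacement_field(res$grid)[, 2])
  expect_lt(abs(mean_dy - (-3)), 0.5)
  # a frame already equal to its target does not move
  res0 <- fit_deformation_frame(img, img, control_grid(c(32, 32), 32),
                                config = mdr_config(tolerance = 0.1))
  expect_equal(res0$max_change, 0)
  expect_equal(max(abs(dense_displacement_field(res0$grid))), 0)
})

test_that("full MDR is deterministic and initialises at the identity", {
  d <- build_dro(small_dro_spec(motion = "rigid", amplitude = 3,
                                period = 4, cnr = 500, seed = 21))
  f1 <- mdr(d$series, d$aif_frames, grid_spacing_min = 16, tolerance = 0.3)
  f2 <- mdr(d$series, d$aif_frames, grid_spacing_min = 16, tolerance = 0.3)
  expect_identical(f1$fields, f2$fields)
  expect_identical(f1$corrected$data, f2$corrected$data)
  expect_identical(f1$trace$chi2, f2$trace$chi2)
  # corrected series has the input's shape; result object is complete
  expect_equal(dim(f1$corrected$data), dim(d$series$data))
  expect_s3_class(f1, "mdr")
  expect_true(all(c("FP", "TP", "FT", "TT") %in% names(f1$params)))
})

test_that("chi-squared never increases within a resolution level", {
  d <- build_dro(small_dro_spec(motion = "rigid", amplitude = 3,
                                period = 4, cnr = 500, seed = 22))
  fit <- mdr(d$series, d$aif_frames, grid_spacing_min = 16, tolerance = 0.3)
  tr <- fit$trace
  for (lev in unique(tr$level)) {
    ch <- tr$chi2[tr$level == lev]
    expect_true(all(diff(ch) <= 1e-9 * pmax(ch[-length(ch)], 1)))
  }
})

test_that("motion-free data stays at the identity", {
  d <- build_dro(small_dro_spec(motion = "none", cnr = NULL))
  fit <- mdr(d$series, d$aif_frames, grid_spacing_min = 16, tolerance = 0.3)
  dn <- sqrt(rowSums(matrix(aperm(fit$fields, c(1, 3, 2)), ncol = 2)^2))
  expect_lt(mean(dn), 0.1)
})

test_that("S3 methods expose the fit components", {
  d <- build_dro(small_dro_spec(motion = "none", cnr = 200, seed = 23))
  fit <- mdr(d$series, d$aif_frames, grid_spacing_min = 16, tolerance = 0.5)
  expect_output(print(fit), "Model-driven registration")
  s <- summary(fit)
  expect_s3_class(s, "summary.mdr")
  expect_output(print(s), "chi2")
  expect_equal(dim(coef(fit, type = "model")),
               c(4L, prod(dim(d$series$data)[1:2])))
  expect_equal(names(coef(fit)), c("FP", "TP", "FT", "TT"))
  expect_equal(fitted(fit), fit$fitted)
  expect_equal(residuals(fit), fit$corrected$data - fit$fitted)
  tf <- tempfile(fileext = ".png")
  grDevices::png(tf)
  plot(fit, which = "cost")
  plot(fit, which = "timecut")
  grDevices::dev.off()
  expect_true(file.exists(tf))
  unlink(tf)
})

test_that("configuration validation catches bad settings", {
  expect_error(mdr_config(grid_spacing_min = 0), "grid_spacing_min")
  expect_error(mdr_config(tolerance = 0), "tolerance")
  expect_error(mdr_config(model = "nonsense"))
})
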