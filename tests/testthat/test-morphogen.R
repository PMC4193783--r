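test_that("closed-form gradient has the defining exponential properties", {
  g <- grid_spec()
  gp <- gradient_params(c0 = 5, lambda_d = 70)
  f <- closed_form_gradient(g, gp)
  expect_equal(f$conc[142, 20], 5)                  # source column
  expect_equal(f$conc[142 - 70, 5], 5 / exp(1))     # one decay length in
  ratios <- f$conc[2:141, 10] / f$conc[1:140, 10]
  expect_equal(ratios, rep(exp(1 / 70), 140))       # constant log-slope
  expect_true(all(f$conc[, 1] == f$conc[, 37]))     # uniform in y
})

test_that("diffusion and degradation satisfy the decay-length relation", {
  gp <- gradient_params()
  expect_equal(gp$D / gp$k, gp$lambda_d^2, tolerance = 1e-4)
})

test_that("the noiseless field is a fixed point and a contraction", {
  g <- grid_spec(6, 3)
  gp <- gradient_params(c0 = 5, lambda_d = 20, eta = 0)
  ref <- closed_form_gradient(g, gp)$conc
  f <- noisy_gradient(g, gp)
  f <- evolve_noisy(f, 500)
  expect_lt(sqrt(sum((f$conc - ref)^2) / sum(ref^2)), 1e-9)

  # perturbed start: L2 distance to the profile never increases
  set.seed(8)
  f2 <- noisy_gradient(g, gp)
  f2$conc[2:20, ] <- f2$conc[2:20, ] * runif(19, 0.5, 1.5)
  d <- vapply(1:50, function(i) {
    f2 <<- evolve_noisy(f2, 1)
    sqrt(sum((f2$conc - ref)^2))
  }, numeric(1))
  expect_true(all(diff(d) <= 1e-12))
})

test_that("the field relaxes from zero to the exponential profile", {
  g <- grid_spec(6, 3)
  gp <- gradient_params(c0 = 5, lambda_d = 20, eta = 0)
  ref <- closed_form_gradient(g, gp)$conc
  f <- noisy_gradient(g, gp, init = "zero")
  f <- evolve_noisy(f, 20000)
  expect_lt(sqrt(sum((f$conc - ref)^2) / sum(ref^2)), 0.01)
})

test_that("noisy snapshots average back to the deterministic profile", {
  set.seed(12)
  g <- grid_spec(6, 3)
  gp <- gradient_params(c0 = 5, lambda_d = 20, k = 0.05, eta = 0.5)
  ref <- closed_form_gradient(g, gp)
  f <- evolve_noisy(noisy_gradient(g, gp), 500)
  acc <- matrix(0, g$width, g$height)
  for (i in 1:100) {
    f <- evolve_noisy(f, 100)
    acc <- acc + f$conc
  }
  mean_dev <- fractional_noise(acc / 100, ref)
  snap_dev <- fractional_noise(f, ref)
  expect_lt(mean_dev, snap_dev / 2) # averaging cancels the fluctuations
  expect_lt(mean_dev, 0.05)
})

test_that("fractional deviation measures relative distance from reference", {
  g <- grid_spec(6, 3)
  ref <- closed_form_gradient(g)
  expect_equal(fractional_noise(ref, ref), 0)
  scaled <- ref; scaled$conc <- 1.1 * ref$conc
  expect_equal(fractional_noise(scaled, ref), 0.1, tolerance = 1e-12)
  zr <- ref$conc; zr[3, 3] <- 0
  expect_warning(fractional_noise(ref$conc, zr), "zero reference")
})

test_that("fractional noise rises monotonically with the noise magnitude", {
  set.seed(23)
  g <- grid_spec(6, 3)
  tab <- calibrate_noise(c(0.2, 1, 4), grid = g,
                         params = gradient_params(c0 = 5, lambda_d = 20,
                                                  k = 0.02),
                         n_snapshots = 10, spacing = 100, burn_in = 500)
  expect_true(all(diff(tab$fractional_deviation) > 0))
})

test_that("noisy fields advance one integration step per MCS during runs", {
  set.seed(33)
  g <- grid_spec(2, 2)
  gp <- gradient_params(c0 = 5, lambda_d = 20, eta = 0.3)
  f <- evolve_noisy(noisy_gradient(g, gp), 50) # short burn-in
  sys <- init_cells(g, potts_params(mu0 = 0.75), r = 1, field = f)
  tr <- run_mcs(sys, 30, cadence = 10)
  expect_equal(tr$system$field$step, 50 + 30)
  expect_equal(tr$summary$mcs, c(0, 10, 20, 30))
  # the field actually fluctuates around the reference
  ref <- closed_form_gradient(g, gp)
  expect_gt(fractional_noise(tr$system$field, ref), 0)
})
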