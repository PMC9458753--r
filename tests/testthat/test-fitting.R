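test_that("sse sums squared residuals over non-censored points", {
  expect_equal(sse(c(1, 2), c(1, 2)), 0)
  expect_equal(sse(c(0, 0), c(1, 2)), 5)
  tc <- tumor_timecourse("m", "treatment", c(0, 3, 6), c(1, 9, 2),
                         censored = c(FALSE, TRUE, FALSE))
  expect_equal(sse(c(1, 2), tc), 0)
  expect_error(sse(c(1, 2, 3), tc), "length mismatch")
})

test_that("Sobol sequence reproduces the canonical direction numbers", {
  # frozen from an independent reference implementation (unscrambled,
  # Joe-Kuo direction numbers), first 8 points in 7 dimensions
  expected <- matrix(c(
    0, 0, 0, 0, 0, 0, 0,
    0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5,
    0.75, 0.25, 0.25, 0.25, 0.75, 0.75, 0.25,
    0.25, 0.75, 0.75, 0.75, 0.25, 0.25, 0.75,
    0.375, 0.375, 0.625, 0.875, 0.375, 0.125, 0.375,
    0.875, 0.875, 0.125, 0.375, 0.875, 0.625, 0.875,
    0.625, 0.125, 0.875, 0.625, 0.625, 0.875, 0.125,
    0.125, 0.625, 0.375, 0.125, 0.125, 0.375, 0.625),
    nrow = 8, byrow = TRUE)
  expect_equal(sobol_sequence(8, 7), expected)
  # skip advances the same sequence
  expect_equal(sobol_sequence(4, 7, skip = 4), expected[5:8, ])
})

test_that("scale_sobol_point maps the unit cube affinely onto the bounds", {
  spec <- resistance_spec("1.1")
  b <- sampling_bounds(spec, V0 = 200)
  expect_equal(unname(scale_sobol_point(rep(0, 3), b)), unname(b[, "lo"]))
  expect_equal(unname(scale_sobol_point(rep(1, 3), b)), unname(b[, "hi"]))
  mid <- scale_sobol_point(rep(0.5, 3), b)
  expect_equal(unname(mid["r_S"]), 0.1)   # midpoint of [0, 0.2]
  expect_equal(unname(mid["S0"]), 200)    # midpoint of [0, 2 V0]
  expect_error(scale_sobol_point(c(0.5, 1.2, 0), b), "\\[0, 1\\]")
})

test_that("perturbation ranges scale with the parameter's order of magnitude", {
  expect_equal(perturbation_range(0.2), c(-1e-2, 1e-2))
  expect_equal(perturbation_range(200), c(-10, 10))
  expect_equal(perturbation_range(0), c(-1e-4, 1e-4))
  expect_equal(perturbation_range(0.009), c(-1e-4, 1e-4))
})

test_that("qmc_search returns the single scaled Sobol point when asked for one", {
  tc <- exp_tc(r = 0.09, V0 = 200, group = "treatment", id = "t1")
  spec <- resistance_spec("1.1")
  b <- sampling_bounds(spec, initial_volume(tc))
  # point 0 of the sequence is the origin (S0 = 0, non-viable)
  expect_error(qmc_search(spec, tc, n_points = 1), "viable")
  res <- qmc_search(spec, tc, n_points = 1, skip = 1)
  expect_equal(unname(res$best_params), unname(scale_sobol_point(rep(0.5, 3), b)))
  expect_equal(res$n_viable, 1)
})

test_that("qmc_search beats a random-search oracle on noiseless data", {
  tc <- exp_tc(r = 0.05, V0 = 200)
  spec <- growth_spec("exponential")
  b <- sampling_bounds(spec, 200)
  res <- qmc_search(spec, tc, n_points = 2000)
  set.seed(5)
  rand_sse <- replicate(1000, {
    p <- scale_sobol_point(runif(2), b)
    sse(solve_growth(spec, p, tc$times), tc)
  })
  expect_lte(res$sse, min(rand_sse))
})

test_that("gradient descent is a no-op at zero iterations and never moves uphill", {
  tc <- exp_tc(r = 0.05, V0 = 200)
  spec <- growth_spec("exponential")
  start <- c(r = 0.06, V0 = 210)
  g0 <- gradient_descent(spec, tc, start, n_iter = 0)
  expect_equal(g0$params, start)
  set.seed(7)
  g <- gradient_descent(spec, tc, start, n_iter = 2000, trace_every = 1)
  expect_true(all(diff(g$sse_trace) <= 0))
  expect_lt(g$sse, sse(solve_growth(spec, start, tc$times), tc))
  expect_error(gradient_descent(spec, tc, c(r = -1, V0 = 200), n_iter = 10),
               "not viable")
})

test_that("gradient descent solves a convex 1-parameter problem (golden-section oracle)", {
  r_true <- 0.05
  tc <- exp_tc(r = r_true, V0 = 200)
  spec <- growth_spec("exponential")
  set.seed(9)
  g <- gradient_descent(spec, tc, c(r = r_true + 0.01, V0 = 200),
                        n_iter = 1e4, trace_every = 0)
  expect_lt(abs(g$params[["r"]] - r_true), 1e-3)
  # golden-section oracle on r alone confirms the optimum location
  f <- function(r) sse(solve_growth(spec, c(r = r, V0 = 200), tc$times), tc)
  opt <- optimize(f, c(0, 0.2), tol = 1e-10)
  expect_lt(abs(opt$minimum - r_true), 1e-6)
  expect_lte(abs(g$params[["r"]] - opt$minimum), 1e-3)
})

test_that("the acceptance loop matches the normal equations on a linear toy", {
  # same perturb/accept machinery applied to a linear least-squares problem;
  # the optimum is available in closed form from the normal equations
  set.seed(13)
  t <- seq(0, 10, by = 1)
  y <- 3 + 0.7 * t + rnorm(length(t), 0, 0.2)
  beta_hat <- solve(crossprod(cbind(1, t)), crossprod(cbind(1, t), y))
  obj <- function(p) sum((y - p[1] - p[2] * t)^2)
  cur <- c(1, 1); cur_sse <- obj(cur)
  for (i in 1:20000) {
    prop <- cur + vapply(cur, function(p) {
      rng <- perturbation_range(p)
      runif(1, rng[1], rng[2])
    }, numeric(1))
    s <- obj(prop)
    if (s <= cur_sse) { cur <- prop; cur_sse <- s }
  }
  sse_opt <- obj(beta_hat)
  expect_lt((cur_sse - sse_opt) / sse_opt, 0.01)
})

test_that("multistart fit is deterministic, viable, and returns the per-start minimum", {
  set.seed(17)
  sched <- dose_schedule(5, 7, 7)
  spec <- resistance_spec("1.1")
  sim <- simulate_treatment(spec, c(r_S = 0.09, lambda_S = 0.03, S0 = 200),
                            sched, seq(0, 42, by = 3.5))
  tc <- tumor_timecourse("t1", "treatment", sim$time,
                         sim$V * exp(rnorm(length(sim$V), 0, 0.05)))
  fit1 <- multistart_fit(spec, tc, n_starts = 4, n_qmc = 2000, n_iter = 2000,
                         seed = 99)
  fit2 <- multistart_fit(spec, tc, n_starts = 4, n_qmc = 2000, n_iter = 2000,
                         seed = 99)
  expect_identical(fit1, fit2)
  expect_equal(fit1$sse, min(fit1$per_start$final_sse))
  expect_true(is_viable(spec, fit1$best_params))
  expect_equal(nrow(fit1$per_start), 4)
  # refinement never worsens the QMC stage
  expect_true(all(fit1$per_start$final_sse <= fit1$per_start$qmc_sse))
})

test_that("QMC stage scales exactly with the data (rates invariant, volumes doubled)", {
  tc1 <- exp_tc(r = 0.09, V0 = 200, group = "treatment")
  tc2 <- tumor_timecourse("m1", "treatment", tc1$times, 2 * tc1$volumes)
  spec <- resistance_spec("1.1")
  r1 <- qmc_search(spec, tc1, n_points = 4000)
  r2 <- qmc_search(spec, tc2, n_points = 4000)
  expect_equal(r2$best_params[["r_S"]], r1$best_params[["r_S"]])
  expect_equal(r2$best_params[["lambda_S"]], r1$best_params[["lambda_S"]])
  expect_equal(r2$best_params[["S0"]], 2 * r1$best_params[["S0"]])
})
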