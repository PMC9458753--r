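test_that("resistance_spec encodes the six family members", {
  ks <- c("1.1" = 3, "1.2" = 6, "2.1" = 6, "2.2" = 7, "3.1" = 6, "3.2" = 7)
  for (m in names(ks)) {
    spec <- resistance_spec(m)
    expect_equal(spec$k, unname(ks[m]), info = m)
    expect_equal(spec$pre_existing, substr(m, 3, 3) == "2", info = m)
  }
  expect_equal(resistance_spec("1.1")$transition, "none")
  expect_equal(resistance_spec("2.2")$transition, "random")
  expect_equal(resistance_spec("3.1")$transition, "drug_induced")
  expect_equal(resistance_spec("1.1")$free_params, c("r_S", "lambda_S", "S0"))
})

test_that("default_gamma reflects the 4.75-day half-life", {
  g <- default_gamma()
  expect_equal(round(g, 4), 0.1459)
  expect_equal(exp(-g * 4.75), 0.5)
})

test_that("treatment_rhs implements the compartment equations", {
  # no drug: pure exponential growth of S
  d <- treatment_rhs(resistance_spec("1.1"), c(100, 0, 0),
                     c(r_S = 0.1, lambda_S = 0.05, S0 = 100))
  expect_equal(unname(d), c(10, 0, 0))
  # drug-induced transition flux g*S*D
  spec31 <- resistance_spec("3.1")
  p31 <- c(r_S = 0, r_R = 0, lambda_S = 0.05, lambda_R = 0, g = 0.01,
           S0 = 100)
  d31 <- treatment_rhs(spec31, c(100, 0, 5), p31)
  expect_equal(unname(d31[1]), -5 - 0.05 * 5 * 100)  # outflux includes kill
  expect_equal(unname(d31[2]), 5)                    # flux arrives in R
  # the transition conserves total volume when rates are zero
  for (m in c("2.1", "3.2")) {
    spec <- resistance_spec(m)
    p <- c(r_S = 0, r_R = 0, lambda_S = 0, lambda_R = 0, g = 0.02,
           S0 = 80, R0 = 20)
    d <- treatment_rhs(spec, c(80, 20, 5), p)
    expect_equal(unname(d[1] + d[2]), 0)
  }
  expect_error(treatment_rhs(resistance_spec("1.1"), c(-1, 0, 0),
                             c(r_S = 0.1, lambda_S = 0.05, S0 = 1)),
               "non-negative")
})

test_that("drug concentration follows piecewise exponential decay with jumps", {
  g <- default_gamma()
  sched <- dose_schedule(dose = 5, interval = 7, n_doses = 3)
  sim <- simulate_treatment(resistance_spec("1.1"),
                            c(r_S = 0.05, lambda_S = 0.01, S0 = 200), sched,
                            c(0, 3, 7, 10))
  expect_equal(sim$D[1], 5)                       # D(0) = dose
  expect_equal(sim$D[2], 5 * exp(-g * 3), tolerance = 1e-7)
  expect_equal(sim$D[3], 5 * exp(-g * 7) + 5, tolerance = 1e-7)  # post-jump
  # pre-dose reporting at a dose time
  sim_pre <- simulate_treatment(resistance_spec("1.1"),
                                c(r_S = 0.05, lambda_S = 0.01, S0 = 200),
                                sched, c(0, 7), pre_dose = TRUE)
  expect_equal(sim_pre$D[1], 0)
  expect_equal(sim_pre$D[2], 5 * exp(-g * 7), tolerance = 1e-7)
})

test_that("model 1.1 matches its piecewise closed form below 1e-6", {
  g <- default_gamma()
  sched <- dose_schedule(dose = 5, interval = 7, n_doses = 7)
  times <- sort(c(seq(0, 42, by = 3.5), 7, 14) + 0)
  times <- unique(times)
  sim <- simulate_treatment(resistance_spec("1.1"),
                            c(r_S = 0.09, lambda_S = 0.03, S0 = 200), sched,
                            times)
  cf <- model11_closed_form(0.09, 0.03, 200, g, sched$dose_times, 5, times)
  expect_lt(max(abs(sim$V - cf) / cf), 1e-6)
})

test_that("decoupled limit reduces to a two-clone exponential mixture", {
  sched <- dose_schedule(dose = 5, interval = 7, n_doses = 5)
  times <- seq(0, 28, by = 2)
  p <- c(r_S = 0.08, r_R = 0.03, lambda_S = 0, lambda_R = 0, g = 0,
         S0 = 150, R0 = 50)
  sim <- simulate_treatment(resistance_spec("2.2"), p, sched, times)
  mix <- 150 * exp(0.08 * times) + 50 * exp(0.03 * times)
  expect_equal(sim$V, mix, tolerance = 1e-7)
})

test_that("simulation agrees with a fixed-step RK4 oracle across the family", {
  g <- default_gamma()
  sched <- dose_schedule(dose = 5, interval = 7, n_doses = 5)
  times <- c(0, 3, 7, 9.5, 14, 20, 28)
  pars <- list(r_S = 0.09, r_R = 0.04, lambda_S = 0.03, lambda_R = 0.004,
               g = 0.01, S0 = 150, R0 = 50)
  for (m in c("1.2", "2.2", "3.2")) {
    spec <- resistance_spec(m)
    sim <- simulate_treatment(spec, pars, sched, times)
    oracle <- rk4_treatment(spec$transition_code, pars, g, sched$dose_times,
                            5, times)
    expect_equal(sim$S, oracle[, 1], tolerance = 1e-5, info = m)
    expect_equal(sim$R, oracle[, 2], tolerance = 1e-5, info = m)
  }
})

test_that("states stay non-negative along viable trajectories", {
  set.seed(33)
  sched <- dose_schedule(dose = 5, interval = 7, n_doses = 9)
  times <- seq(0, 60, by = 1.5)
  for (rep in 1:15) {
    m <- sample(c("1.1", "1.2", "2.1", "2.2", "3.1", "3.2"), 1)
    spec <- resistance_spec(m)
    p <- list(r_S = runif(1, 0, 0.2), r_R = runif(1, 0, 0.1),
              lambda_S = runif(1, 0, 0.1), lambda_R = runif(1, 0, 0.1),
              g = runif(1, 0, 0.1), S0 = runif(1, 10, 400),
              R0 = if (spec$pre_existing) runif(1, 0, 200) else 0)
    p$r_R <- min(p$r_R, p$r_S)
    p$lambda_R <- min(p$lambda_R, p$lambda_S * 0.9)
    sim <- simulate_treatment(spec, p, sched, times)
    expect_true(all(sim$S > -1e-8 & sim$R > -1e-8 & sim$D > -1e-8), info = m)
  }
})

test_that("stronger sensitive kill lowers S pointwise", {
  sched <- dose_schedule(dose = 5, interval = 7, n_doses = 5)
  times <- seq(1, 28, by = 3)
  base <- list(r_S = 0.09, r_R = 0.04, lambda_S = 0.02, lambda_R = 0.002,
               g = 0.01, S0 = 150, R0 = 50)
  for (m in c("1.2", "3.2")) {
    spec <- resistance_spec(m)
    s_lo <- simulate_treatment(spec, base, sched, times)$S
    hi <- base; hi$lambda_S <- 0.05
    s_hi <- simulate_treatment(spec, hi, sched, times)$S
    expect_true(all(s_hi < s_lo), info = m)
  }
})

test_that("is_viable enforces the fitness cost of resistance", {
  expect_false(is_viable(resistance_spec("2.2"),
                         c(r_S = 0.1, r_R = 0.12, lambda_S = 0.05,
                           lambda_R = 0.01, g = 0.01, S0 = 100, R0 = 10)))
  expect_true(is_viable(resistance_spec("1.1"),
                        c(r_S = 0.1, lambda_S = 0.05, S0 = 200)))
  expect_false(is_viable(resistance_spec("1.2"),
                         c(r_S = 0.1, r_R = 0.05, lambda_S = 0.05,
                           lambda_R = 0.05, S0 = 100, R0 = 10)))
  expect_false(is_viable(resistance_spec("1.1"),
                         c(r_S = -0.1, lambda_S = 0.05, S0 = 200)))
  expect_false(is_viable(resistance_spec("2.1"),
                         c(r_S = 0.1, r_R = 0.05, lambda_S = 0.05,
                           lambda_R = 0.01, g = 0.01, S0 = 100, R0 = 5)))
})

test_that("initial_resistance_fraction is R0 over the total", {
  expect_equal(initial_resistance_fraction(c(S0 = 100)), 0)
  expect_equal(initial_resistance_fraction(c(S0 = 50, R0 = 50)), 0.5)
  expect_equal(initial_resistance_fraction(c(S0 = 90, R0 = 10)), 0.1)
  expect_error(initial_resistance_fraction(c(S0 = 0, R0 = 0)), "positive")
})
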