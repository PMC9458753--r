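# Shared fixtures and independent oracles for the test suite.
# Oracles are deliberately naive (closed forms, enumeration, fixed-step RK4)
# and never call the code paths they check.

# noiseless exponential time course
exp_tc <- function(r = 0.05, V0 = 200, times = seq(0, 42, by = 3),
                   group = "control", id = "m1") {
  tumor_timecourse(id, group, times, V0 * exp(r * times))
}

# two-sided Fisher exact p by direct hypergeometric enumeration
fisher_oracle <- function(a, b, c, d) {
  # table rows (a, b), (c, d); margins fixed
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  kk <- a + c         # column 1 total
  x_range <- max(0, kk - n):min(kk, m)
  probs <- stats::dhyper(x_range, m, n, kk)
  p_obs <- stats::dhyper(a, m, n, kk)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# fixed-step RK4 for the treatment system with manual dose jumps
rk4_treatment <- function(transition, pars, gamma, dose_times, dose, times,
                          h = 0.005) {
  # pars: named list r_S, r_R, lambda_S, lambda_R, g, S0, R0
  rhs <- function(y) {
    f <- switch(transition + 1, 0, pars$g * y[1], pars$g * y[1] * y[3])
    c(pars$r_S * y[1] - f - pars$lambda_S * y[3] * y[1],
      pars$r_R * y[2] + f - pars$lambda_R * y[3] * y[2],
      -gamma * y[3])
  }
  stops <- sort(unique(c(dose_times, times)))
  y <- c(pars$S0, pars$R0, 0)
  t <- 0
  out <- matrix(NA_real_, length(times), 3)
  for (s in stops) {
    if (s > t) {
      nstep <- ceiling((s - t) / h)
      hh <- (s - t) / nstep
      for (i in seq_len(nstep)) {
        k1 <- rhs(y); k2 <- rhs(y + hh / 2 * k1)
        k3 <- rhs(y + hh / 2 * k2); k4 <- rhs(y + hh * k3)
        y <- y + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      }
      t <- s
    }
    if (s %in% dose_times) y[3] <- y[3] + dose
    hit <- which(abs(times - s) < 1e-12)
    if (length(hit)) out[hit, ] <- matrix(y, length(hit), 3, byrow = TRUE)
  }
  out
}

# fixed-step RK4 for a growth model
rk4_growth <- function(spec, params, times, h = 0.001) {
  y <- params[["V0"]]
  out <- numeric(length(times))
  out[1] <- y
  for (i in seq_along(times)[-1]) {
    t0 <- times[i - 1]; t1 <- times[i]
    nstep <- ceiling((t1 - t0) / h)
    hh <- (t1 - t0) / nstep
    for (s in seq_len(nstep)) {
      k1 <- growth_rhs(spec, y, params)
      k2 <- growth_rhs(spec, y + hh / 2 * k1, params)
      k3 <- growth_rhs(spec, y + hh / 2 * k2, params)
      k4 <- growth_rhs(spec, y + hh * k3, params)
      y <- y + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    out[i] <- y
  }
  out
}

# integral of the piecewise-exponential drug concentration on [0, t],
# doses of `dose` at dose_times (applied post-jump)
drug_integral <- function(t, gamma, dose_times, dose) {
  total <- 0
  D <- 0
  tcur <- 0
  for (td in dose_times[dose_times < t]) {
    if (td > tcur) {
      total <- total + D / gamma * (1 - exp(-gamma * (td - tcur)))
      D <- D * exp(-gamma * (td - tcur))
      tcur <- td
    }
    D <- D + dose
  }
  total + D / gamma * (1 - exp(-gamma * (t - tcur)))
}

# closed-form model 1.1 volume: S(t) = S0 exp(r_S t - lambda_S int_0^t D)
model11_closed_form <- function(r_S, lambda_S, S0, gamma, dose_times, dose,
                                times) {
  vapply(times, function(t)
    S0 * exp(r_S * t - lambda_S * drug_integral(t, gamma, dose_times, dose)),
    numeric(1))
}
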