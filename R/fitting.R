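#' Per-parameter sampling bounds for the global search
#'
#' Rate-like parameters (`r_R`, `lambda_S`, `lambda_R`, `g`) are searched over
#' `[0, 0.1]` and the sensitive growth rate `r_S` (or the control growth rate
#' `r`) over `[0, 0.2]`; beyond these ranges model predictions leave the
#' magnitude of the data entirely. Initial conditions are mouse-dependent:
#' `S0`, `R0`, `V0` (and the profiled total `T0`) lie in `[0, 2 V0]` where V0
#' is the observed initial volume, the logistic carrying capacity `K` in
#' `[V0, 1e5]` and the Allee threshold `m` in `[0, 10 V0]`. For the two
#' surface-motivated growth laws the proliferation coefficient `a` spans
#' `[0, 2]` (its effective per-day rate is `a` divided by a length scale of
#' order `V^(1/3)`), the surface offset `b` spans `[0, 10 V0]` mm^3 and the
#' von Bertalanffy loss rate `b` is rate-like.
#'
#' @param spec A [growth_spec()] or [resistance_spec()].
#' @param V0 Observed initial tumor volume of the mouse (mm^3).
#' @return Matrix with one row per free parameter and columns `lo`, `hi`.
#' @export
sampling_bounds <- function(spec, V0) {
  if (!(V0 > 0)) stop("V0 must be positive")
  one <- function(nm) {
    if (inherits(spec, "growth_spec")) {
      switch(nm,
        r = c(0, 0.2),
        K = c(V0, 1e5),
        m = c(0, 10 * V0),
        a = c(0, 2),
        b = if (spec$name == "surface") c(0, 10 * V0) else c(0, 0.1),
        V0 = c(0, 2 * V0))
    } else {
      switch(nm,
        r_S = c(0, 0.2),
        r_R = c(0, 0.1),
        lambda_S = c(0, 0.1),
        lambda_R = c(0, 0.1),
        g = c(0, 0.1),
        S0 = c(0, 2 * V0),
        R0 = c(0, 2 * V0),
        T0 = c(0, 2 * V0))
    }
  }
  b <- t(vapply(spec$free_params, one, numeric(2)))
  colnames(b) <- c("lo", "hi")
  b
}

#' Sum of squared errors of a prediction against a time course
#'
#' The fitting objective: squared differences between observed and predicted
#' volumes summed over the non-censored points.
#'
#' @param predicted Predicted volumes aligned to the non-censored observation
#'   times (or to all points of a plain numeric `observed`).
#' @param observed A [tumor_timecourse()] or a numeric vector.
#' @return The SSE (mm^6).
#' @export
sse <- function(predicted, observed) {
  if (inherits(observed, "tumor_timecourse")) {
    y <- observed$volumes[!observed$censored]
  } else {
    y <- as.numeric(observed)
  }
  if (length(predicted) != length(y)) {
    stop(sprintf("length mismatch: %d predicted vs %d observed points",
                 length(predicted), length(y)))
  }
  sum((y - predicted)^2)
}

#' Generate points of the Sobol low-discrepancy sequence
#'
#' Unscrambled, Gray-code construction with Joe-Kuo direction numbers;
#' point 0 is the origin. Used to cover parameter space uniformly in the
#' quasi-Monte Carlo search stage.
#'
#' @param n Number of points.
#' @param k Dimension (1..10).
#' @param skip Number of initial points of the sequence to skip (used to give
#'   each multistart repetition a fresh stretch of the sequence).
#' @return An `n x k` matrix with entries in `[0, 1)`.
#' @export
sobol_sequence <- function(n, k, skip = 0) {
  .sobol_points_cpp(as.integer(n), as.integer(k), as.numeric(skip))
}

#' Scale a unit hypercube point to parameter bounds
#'
#' @param unit_point Numeric vector in `[0, 1]^k`.
#' @param bounds Bounds matrix from [sampling_bounds()].
#' @return Named parameter vector `lo + p * (hi - lo)`.
#' @export
scale_sobol_point <- function(unit_point, bounds) {
  if (length(unit_point) != nrow(bounds)) stop("dimension mismatch with bounds")
  if (any(unit_point < 0 | unit_point > 1)) {
    stop("unit_point coordinates must lie in [0, 1]")
  }
  out <- bounds[, "lo"] + unit_point * (bounds[, "hi"] - bounds[, "lo"])
  names(out) <- rownames(bounds)
  out
}

#' Perturbation range of the gradient-descent stage
#'
#' A parameter of order of magnitude `alpha = floor(log10(|p|))` is perturbed
#' by a uniform draw from `[-10^(alpha - 1), 10^(alpha - 1)]`, i.e. one decade
#' below its own scale. At `p = 0` the order of magnitude is taken as -3 (the
#' smallest scale among the sampled parameter ranges), giving `[-1e-4, 1e-4]`.
#'
#' @param p_j Parameter value.
#' @return Length-2 vector `c(lo, hi)`.
#' @examples
#' perturbation_range(0.2) # c(-0.01, 0.01)
#' @export
perturbation_range <- function(p_j) {
  if (!is.finite(p_j)) stop("p_j must be finite")
  alpha <- if (p_j == 0) -3 else floor(log10(abs(p_j)))
  w <- 10^(alpha - 1)
  c(-w, w)
}

# build the C++ fit descriptor for one mouse x model problem
.fit_descriptor <- function(spec, tc, bounds = NULL, schedule = NULL,
                            gamma = default_gamma(), rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(tc, "tumor_timecourse"))
  keep <- !tc$censored
  if (sum(keep) < 2) stop("need at least two non-censored points to fit")
  obs_t <- tc$times[keep]
  obs_y <- tc$volumes[keep]
  V0 <- obs_y[1]
  if (is.null(bounds)) bounds <- sampling_bounds(spec, V0)
  if (!identical(rownames(bounds), spec$free_params)) {
    stop("bounds rows must match the spec's free parameters in order")
  }
  if (inherits(spec, "growth_spec")) {
    slot <- match(spec$free_params, c("r", "K", "m", "a", "b", "V0"))
    list(kind = 1L, model = spec$code, slot = as.integer(slot),
         profile_frac = -1, gamma = 0, V0 = V0,
         dose_times = numeric(0), dose_amts = numeric(0),
         obs_times = obs_t, obs_vols = obs_y,
         lo = unname(bounds[, "lo"]), hi = unname(bounds[, "hi"]),
         rtol = rtol, atol = atol, pre_existing = FALSE)
  } else if (inherits(spec, "resistance_spec")) {
    if (is.null(schedule)) {
      schedule <- dose_schedule(n_doses = floor(max(obs_t) / 7) + 1)
    }
    slot <- match(spec$free_params,
                  c("r_S", "r_R", "lambda_S", "lambda_R", "g", "S0", "R0", "T0"))
    list(kind = 2L, model = spec$transition_code, slot = as.integer(slot),
         profile_frac = spec$profile_frac, gamma = gamma, V0 = V0,
         dose_times = schedule$dose_times,
         dose_amts = rep(schedule$dose, schedule$n_doses),
         obs_times = obs_t, obs_vols = obs_y,
         lo = unname(bounds[, "lo"]), hi = unname(bounds[, "hi"]),
         rtol = rtol, atol = atol, pre_existing = spec$pre_existing)
  } else {
    stop("spec must be a growth_spec or resistance_spec")
  }
}

.named_free <- function(spec, x) {
  names(x) <- spec$free_params
  x
}

#' Quasi-Monte Carlo global parameter search
#'
#' Stage one of the two-stage fitter: scans `n_points` consecutive Sobol
#' points scaled into the biological sampling bounds, discards non-viable
#' parameter sets (fitness-cost constraints, initial volume outside
#' `(0, 2 V0]`), simulates the model at the remaining sets and returns the
#' SSE-minimizing one. Deterministic given `(skip, n_points, bounds)`.
#'
#' @param spec A [growth_spec()] or [resistance_spec()].
#' @param tc A [tumor_timecourse()].
#' @param n_points Number of Sobol points (default 1.5e6 as in the headline
#'   analysis; reduce for exploratory work).
#' @param bounds Optional bounds matrix; defaults to [sampling_bounds()] at
#'   the mouse's V0.
#' @param skip Sobol points to skip before sampling.
#' @param schedule Dosing schedule for resistance models; defaults to 5 mg/kg
#'   every 7 days covering the observation window.
#' @param gamma Drug decay rate.
#' @param rtol,atol Solver tolerances.
#' @return List with `best_params` (named), `sse` and `n_viable`.
#' @export
qmc_search <- function(spec, tc, n_points = 1.5e6, bounds = NULL, skip = 0,
                       schedule = NULL, gamma = default_gamma(),
                       rtol = 1e-8, atol = 1e-10) {
  if (n_points < 1) stop("n_points must be at least 1")
  desc <- .fit_descriptor(spec, tc, bounds, schedule, gamma, rtol, atol)
  res <- .qmc_search_cpp(desc, n_points, skip)
  if (is.null(res$best)) {
    stop("no viable parameter set among the Sobol points; increase n_points")
  }
  list(best_params = .named_free(spec, res$best), sse = res$sse,
       n_viable = res$n_viable)
}

#' Stochastic gradient descent refinement
#'
#' Stage two of the fitter: starting from a viable parameter set, every
#' parameter is perturbed at each iteration by an independent uniform draw
#' from its [perturbation_range()]; the move is rejected if the perturbed set
#' is non-viable (including any negative parameter) or if the SSE increases.
#' With no uphill acceptance the accepted-SSE trace is non-increasing. Uses
#' R's RNG, so results are reproducible under `set.seed()`.
#'
#' @inheritParams qmc_search
#' @param start Named (or spec-ordered) viable starting parameter vector.
#' @param n_iter Number of perturbation iterations (default 5e5 as in the
#'   headline analysis).
#' @param trace_every Record the accepted SSE every this many iterations
#'   (0 disables the trace).
#' @return List with `params`, `sse`, `sse_trace` and `accepted` (move count).
#' @export
gradient_descent <- function(spec, tc, start, n_iter = 5e5, trace_every = 1,
                             bounds = NULL, schedule = NULL,
                             gamma = default_gamma(), rtol = 1e-8,
                             atol = 1e-10) {
  desc <- .fit_descriptor(spec, tc, bounds, schedule, gamma, rtol, atol)
  if (!is.null(names(start))) {
    if (!setequal(names(start), spec$free_params)) {
      stop("start names must match the spec's free parameters")
    }
    start <- start[spec$free_params]
  }
  if (!.viable_eval_cpp(desc, as.numeric(start))) {
    stop("starting parameter set is not viable")
  }
  res <- .grad_descent_cpp(desc, as.numeric(start), n_iter,
                           as.integer(trace_every))
  list(params = .named_free(spec, res$params), sse = res$sse,
       sse_trace = res$trace, accepted = res$accepted)
}

#' Two-stage multistart fit of one model to one mouse
#'
#' Repeats (QMC search then gradient descent) `n_starts` times — each start
#' consuming a fresh stretch of the Sobol sequence and an independent
#' sub-seeded RNG stream — and returns the overall SSE minimum with a
#' per-start audit trail. Fully reproducible from `(seed, budgets)`.
#'
#' @inheritParams qmc_search
#' @param n_starts Number of independent repetitions (default 15).
#' @param n_qmc Sobol points per start.
#' @param n_iter Gradient-descent iterations per start.
#' @param seed Integer master seed; per-start sub-seeds are derived from it.
#' @return An object of class `fit_result` with fields `mouse_id`, `model_id`,
#'   `best_params`, `sse`, `n_points` (non-censored count), `k`, `per_start`
#'   (data frame audit trail) and `seed`.
#' @export
multistart_fit <- function(spec, tc, n_starts = 15, n_qmc = 1.5e6,
                           n_iter = 5e5, seed = 1L, bounds = NULL,
                           schedule = NULL, gamma = default_gamma(),
                           rtol = 1e-8, atol = 1e-10) {
  if (n_starts < 1) stop("n_starts must be at least 1")
  desc <- .fit_descriptor(spec, tc, bounds, schedule, gamma, rtol, atol)
  k <- length(spec$free_params)
  per_start <- vector("list", n_starts)
  best <- NULL
  n_fail <- 0
  for (i in seq_len(n_starts)) {
    skip <- (i - 1) * n_qmc
    q <- .qmc_search_cpp(desc, n_qmc, skip)
    if (is.null(q$best)) {
      n_fail <- n_fail + 1
      per_start[[i]] <- data.frame(start = i, qmc_sse = NA_real_,
                                   final_sse = NA_real_)
      per_start[[i]]$final_params <- list(NULL)
      next
    }
    sub_seed <- (as.numeric(seed) * 1009 + i) %% 2147483647
    set.seed(as.integer(sub_seed))
    g <- .grad_descent_cpp(desc, q$best, n_iter, 0L)
    per_start[[i]] <- data.frame(start = i, qmc_sse = q$sse,
                                 final_sse = g$sse)
    per_start[[i]]$final_params <- list(.named_free(spec, g$params))
    if (is.null(best) || g$sse < best$sse) {
      best <- list(params = .named_free(spec, g$params), sse = g$sse)
    }
  }
  if (n_fail == n_starts) {
    stop("no viable parameter set in any start; increase n_qmc")
  }
  structure(
    list(mouse_id = tc$mouse_id,
         model_id = if (inherits(spec, "growth_spec")) spec$name else spec$model_id,
         best_params = best$params, sse = best$sse,
         n_points = sum(!tc$censored), k = k,
         per_start = do.call(rbind, per_start), seed = seed),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> mouse %s, model %s: sse = %.4g (n = %d, k = %d)\n",
              x$mouse_id, x$model_id, x$sse, x$n_points, x$k))
  cat("  best parameters:\n")
  print(signif(x$best_params, 4))
  invisible(x)
}

#' Predicted volumes of a fitted model at the non-censored observation times
#'
#' @param fit A `fit_result`.
#' @param spec The spec the fit was produced with.
#' @param tc The fitted time course.
#' @inheritParams qmc_search
#' @return Numeric vector of predicted volumes.
#' @export
predict_fit <- function(fit, spec, tc, schedule = NULL,
                        gamma = default_gamma(), rtol = 1e-8, atol = 1e-10) {
  keep <- !tc$censored
  obs_t <- tc$times[keep]
  if (inherits(spec, "growth_spec")) {
    solve_growth(spec, fit$best_params, obs_t, rtol, atol)
  } else {
    if (is.null(schedule)) {
      schedule <- dose_schedule(n_doses = floor(max(obs_t) / 7) + 1)
    }
    params <- .profile_expand(spec, fit$best_params)
    sim <- simulate_treatment(spec0_of(spec), params, schedule, obs_t, gamma,
                              rtol, atol)
    sim$V
  }
}

# expand a profiled parameter vector (with T0) into S0/R0 at the fixed fraction
.profile_expand <- function(spec, params) {
  if (inherits(spec, "resistance_spec") && spec$profile_frac >= 0) {
    p <- as.list(params)
    p$S0 <- (1 - spec$profile_frac) * p$T0
    p$R0 <- spec$profile_frac * p$T0
    p$T0 <- NULL
    p
  } else {
    params
  }
}

# underlying unprofiled spec (simulate_treatment needs the plain family member)
spec0_of <- function(spec) {
  if (inherits(spec, "resistance_spec") && spec$profile_frac >= 0) {
    resistance_spec(spec$model_id)
  } else {
    spec
  }
}
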