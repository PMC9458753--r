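#' Default inter-mouse parameter distributions for synthetic cohorts
#'
#' Each entry is `c(mean, cv)` of a lognormal distribution across mice. The
#' defaults are chosen once to emulate the experimental setting: control
#' growth rates capped so the fastest doubling time is about two weeks, and
#' treatment effect sizes such that a 5 mg/kg weekly schedule yields a
#' majority of increasing trajectories with a minority decreasing or
#' stabilizing. `rfrac` is the initial resistance fraction for models with
#' pre-existing resistance (draws of 1 or more are rejected).
#'
#' @param spec A [growth_spec()] or [resistance_spec()].
#' @return Named list of `c(mean, cv)` pairs.
#' @export
default_param_distribution <- function(spec) {
  if (inherits(spec, "growth_spec")) {
    switch(spec$name,
      exponential = list(r = c(0.035, 0.4)),
      logistic = list(r = c(0.05, 0.4), K = c(5000, 0.3)),
      allee = list(r = c(0.05, 0.4), K = c(5000, 0.3), m = c(50, 0.5)),
      surface = list(a = c(0.3, 0.3), b = c(100, 0.5)),
      von_bertalanffy = list(a = c(0.25, 0.3), b = c(0.02, 0.5)))
  } else {
    out <- list(r_S = c(0.09, 0.3))
    if ("r_R" %in% spec$free_params) out$r_R <- c(0.05, 0.3)
    out$lambda_S <- c(0.025, 0.3)
    if ("lambda_R" %in% spec$free_params) out$lambda_R <- c(0.003, 0.5)
    if ("g" %in% spec$free_params) out$g <- c(0.01, 0.5)
    if (spec$pre_existing) out$rfrac <- c(0.25, 0.3)
    out
  }
}

#' Recipe for a synthetic xenograft cohort
#'
#' Describes a cohort with known ground truth: which model generates the
#' trajectories, how parameters vary across mice, the dosing schedule, the
#' sparse irregular sampling grid, the multiplicative measurement noise and
#' the rate of implausible outlier spikes (injected so the censoring rule has
#' true positives to find).
#'
#' @param model A [growth_spec()] (control cohort) or [resistance_spec()]
#'   (treatment cohort).
#' @param n_mice Cohort size (default 28, matching the experimental cohorts
#'   of 25-29 mice).
#' @param param_distribution Named list of `c(mean, cv)` lognormal specs;
#'   defaults to [default_param_distribution()]. Entries override defaults
#'   individually; `cv = 0` fixes a parameter across mice.
#' @param v0_mean,v0_cv Initial-volume distribution (default mean 200 mm^3,
#'   the volume at which treatment starts, cv 0.2).
#' @param schedule A [dose_schedule()]; default 5 mg/kg every 7 days.
#' @param t_max Last sampling day (default 42).
#' @param gap_range Uniform range of gaps between measurements in days
#'   (default `c(3, 4)`, giving 11-15 points per mouse).
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   measurement noise (default 0.1; caliper error scales with size).
#' @param outlier_rate Per-interior-point probability of an injected spike
#'   (default 0.05).
#' @param outlier_fold Range of spike magnitudes (default `c(2.5, 8)`).
#' @param seed Integer seed; the cohort is deterministic given the recipe.
#' @return An object of class `cohort_recipe`.
#' @export
cohort_recipe <- function(model, n_mice = 28, param_distribution = NULL,
                          v0_mean = 200, v0_cv = 0.2,
                          schedule = dose_schedule(dose = 5, interval = 7,
                                                   n_doses = 7),
                          t_max = 42, gap_range = c(3, 4), noise_cv = 0.1,
                          outlier_rate = 0.05, outlier_fold = c(2.5, 8),
                          seed = 1L) {
  stopifnot(inherits(model, "growth_spec") || inherits(model, "resistance_spec"))
  if (n_mice < 1) stop("n_mice must be at least 1")
  if (noise_cv < 0 || v0_cv < 0) stop("coefficients of variation must be non-negative")
  if (outlier_rate < 0 || outlier_rate > 1) stop("outlier_rate must be in [0, 1]")
  dist <- default_param_distribution(model)
  for (nm in names(param_distribution)) dist[[nm]] <- param_distribution[[nm]]
  structure(list(model = model, n_mice = n_mice, param_distribution = dist,
                 v0_mean = v0_mean, v0_cv = v0_cv, schedule = schedule,
                 t_max = t_max, gap_range = gap_range, noise_cv = noise_cv,
                 outlier_rate = outlier_rate, outlier_fold = outlier_fold,
                 seed = seed),
            class = "cohort_recipe")
}

# lognormal draw parameterized by (mean, cv); cv = 0 returns the mean
.rlnorm_mc <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sigma <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sigma^2 / 2, sdlog = sigma)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Per mouse: draws an initial volume and model parameters (re-drawing until
#' the set is biologically viable), simulates the generating model on a
#' jittered sparse time grid, applies multiplicative lognormal measurement
#' noise `V * exp(eps)` with `sd(eps) = sqrt(log(1 + cv^2))`, and injects
#' isolated outlier spikes at interior points. Deterministic given the
#' recipe's seed.
#'
#' @param recipe A [cohort_recipe()].
#' @return List with `cohort` (named list of [tumor_timecourse()]) and
#'   `truth` (per mouse: the drawn parameters and injected outlier indices).
#' @export
generate_cohort <- function(recipe) {
  stopifnot(inherits(recipe, "cohort_recipe"))
  if (!is.null(recipe$seed)) set.seed(as.integer(recipe$seed))
  spec <- recipe$model
  is_growth <- inherits(spec, "growth_spec")
  group <- if (is_growth) "control" else "treatment"
  cohort <- list()
  truth <- list()
  for (i in seq_len(recipe$n_mice)) {
    id <- sprintf("mouse_%02d", i)
    V0 <- .rlnorm_mc(1, recipe$v0_mean, recipe$v0_cv)
    params <- NULL
    for (try in 1:1000) {
      draw <- lapply(recipe$param_distribution,
                     function(mc) .rlnorm_mc(1, mc[1], mc[2]))
      if (!is.null(draw$rfrac) && draw$rfrac >= 1) next
      if (is_growth) {
        cand <- c(draw, V0 = V0)
        if (spec$name == "logistic" && cand$K < V0) next
        if (spec$name == "allee" && cand$K < V0) next
        params <- cand
        break
      } else {
        cand <- draw
        frac <- if (spec$pre_existing) draw$rfrac else 0
        cand$rfrac <- NULL
        cand$S0 <- (1 - frac) * V0
        cand$R0 <- frac * V0
        if (is_viable(spec, cand)) {
          params <- cand
          break
        }
      }
    }
    if (is.null(params)) {
      stop("could not draw a viable parameter set in 1000 tries; check param_distribution")
    }
    # sparse, jittered sampling grid starting at treatment start
    times <- 0
    while (TRUE) {
      nxt <- times[length(times)] +
        stats::runif(1, recipe$gap_range[1], recipe$gap_range[2])
      if (nxt > recipe$t_max) break
      times <- c(times, nxt)
    }
    clean <- if (is_growth) {
      solve_growth(spec, params, times)
    } else {
      simulate_treatment(spec, params, recipe$schedule, times)$V
    }
    vols <- clean
    if (recipe$noise_cv > 0) {
      sigma <- sqrt(log(1 + recipe$noise_cv^2))
      vols <- vols * exp(stats::rnorm(length(vols), 0, sigma))
    }
    outlier_idx <- integer(0)
    n <- length(times)
    if (recipe$outlier_rate > 0 && n >= 3) {
      for (j in 2:(n - 1)) {
        if (stats::runif(1) < recipe$outlier_rate) {
          vols[j] <- vols[j] *
            stats::runif(1, recipe$outlier_fold[1], recipe$outlier_fold[2])
          outlier_idx <- c(outlier_idx, j)
        }
      }
    }
    cohort[[id]] <- tumor_timecourse(id, group, times, vols)
    truth[[id]] <- list(params = params, outlier_idx = outlier_idx,
                        clean_volumes = clean)
  }
  list(cohort = cohort, truth = truth)
}

#' Parameter- and selection-recovery experiment on a synthetic cohort
#'
#' The acceptance surface of the whole pipeline: generates a cohort from the
#' recipe, censors it, fits the requested models to every mouse with the
#' two-stage multistart fitter, ranks them, and tabulates (a) the recovery
#' error of the generating model's parameters under the generating model and
#' (b) how often each candidate model is selected.
#'
#' @param recipe A [cohort_recipe()] whose model is a [resistance_spec()].
#' @param models Character vector of model ids to fit (default all six).
#' @param n_starts,n_qmc,n_iter Fit budgets (defaults are desk-scale; the
#'   headline budgets are 15 starts, 1.5e6 Sobol points and 5e5 iterations).
#' @param seed Master seed for the fits.
#' @return List with `param_recovery` (long data frame of true/fitted values
#'   and relative errors for the generating model), `selection` (the four
#'   cohort tally matrices from [cohort_selection_summary()]), `ic_tables`,
#'   `fits` (mouse -> model -> `fit_result`), `cohort` and `truth`.
#' @export
recovery_experiment <- function(recipe,
                                models = c("1.1", "1.2", "2.1", "2.2", "3.1", "3.2"),
                                n_starts = 5, n_qmc = 1e4, n_iter = 1e4,
                                seed = 1L) {
  stopifnot(inherits(recipe$model, "resistance_spec"))
  gen <- generate_cohort(recipe)
  cohort <- lapply(gen$cohort, censor_timecourse)
  gen_id <- recipe$model$model_id
  fits <- list()
  ic_tables <- list()
  rec_rows <- list()
  for (id in names(cohort)) {
    tc <- cohort[[id]]
    mouse_fits <- list()
    for (m in models) {
      spec <- resistance_spec(m)
      mouse_fits[[m]] <- multistart_fit(
        spec, tc, n_starts = n_starts, n_qmc = n_qmc, n_iter = n_iter,
        seed = (as.numeric(seed) * 7919 +
                  match(id, names(cohort)) * 97 + match(m, models)) %% 2147483647,
        schedule = recipe$schedule)
    }
    fits[[id]] <- mouse_fits
    ic_tables[[id]] <- rank_models(mouse_fits)
    if (gen_id %in% models) {
      true_p <- gen$truth[[id]]$params
      fit_p <- mouse_fits[[gen_id]]$best_params
      for (nm in names(fit_p)) {
        tv <- true_p[[nm]]
        if (is.null(tv)) next
        rec_rows[[length(rec_rows) + 1]] <- data.frame(
          mouse_id = id, param = nm, true = tv, fitted = unname(fit_p[[nm]]),
          rel_error = if (tv != 0) (unname(fit_p[[nm]]) - tv) / tv else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(param_recovery = if (length(rec_rows)) do.call(rbind, rec_rows) else NULL,
       selection = cohort_selection_summary(ic_tables),
       ic_tables = ic_tables, fits = fits, cohort = cohort, truth = gen$truth)
}
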