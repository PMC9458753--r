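#' Fold reduction in tumor volume after two weeks of treatment
#'
#' Simulates a mouse at its (fitted) parameters under weekly dosing at the
#' given dose and returns `V(0) / V(duration)`: a fold reduction of 4 means
#' the tumor is four times smaller after treatment than before, so larger is
#' a stronger response; values below 1 mean the tumor grew despite treatment.
#' The initial volume is the model-predicted `S0 + R0`, not the observed first
#' data point — the quantity is purely in silico.
#'
#' @param spec A [resistance_spec()].
#' @param params Named viable parameters for the model.
#' @param dose Dose per administration (mg/kg).
#' @param duration Days simulated (default 14).
#' @param interval Days between doses (default 7, so doses at days 0 and 7).
#' @param gamma,rtol,atol Passed to [simulate_treatment()].
#' @return The fold reduction (positive ratio).
#' @export
fold_reduction <- function(spec, params, dose, duration = 14, interval = 7,
                           gamma = default_gamma(), rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(spec, "resistance_spec"))
  if (dose < 0) stop("dose must be non-negative")
  params <- .profile_expand(spec, params)
  if (!is_viable(spec0_of(spec), params)) stop("params are not viable for this model")
  n_doses <- floor((duration - 1e-9) / interval) + 1
  sched <- dose_schedule(dose = dose, interval = interval, n_doses = n_doses)
  sim <- simulate_treatment(spec0_of(spec), params, sched, c(0, duration),
                            gamma, rtol, atol)
  v0 <- sim$V[1]
  v_end <- sim$V[2]
  if (v_end <= 0) stop("simulated volume collapsed to zero; fold reduction undefined")
  v0 / v_end
}

#' Simulated dose-escalation study over a fitted cohort
#'
#' Replays each mouse's best-fit parameters under escalated weekly doses and
#' summarises the cohort by the median fold reduction per dose, plus the
#' average rate of change of that median across the dose range
#' (`(median at max dose - median at min dose) / (max - min)`, in fold per
#' mg/kg). Random-acquisition models respond more steeply to escalation than
#' drug-induced models, because in the latter a higher dose also drives more
#' resistance formation.
#'
#' @param fits List of `fit_result` objects, all for the same model.
#' @param spec The [resistance_spec()] those fits used.
#' @param doses Increasing dose grid (default `16:20` mg/kg).
#' @param duration,interval,gamma,rtol,atol Passed to [fold_reduction()].
#' @return An object of class `escalation_result`: `model_id`, `doses`,
#'   `per_mouse_fold` (mouse x dose matrix), `median_fold` (per dose) and
#'   `avg_rate_of_change`.
#' @export
escalation_study <- function(fits, spec, doses = 16:20, duration = 14,
                             interval = 7, gamma = default_gamma(),
                             rtol = 1e-8, atol = 1e-10) {
  if (length(fits) < 1) stop("need at least one fit")
  ids <- vapply(fits, function(f) f$model_id, character(1))
  if (length(unique(ids)) != 1) stop("all fits must be for the same model")
  if (is.unsorted(doses, strictly = TRUE)) stop("doses must be increasing")
  mice <- vapply(fits, function(f) f$mouse_id, character(1))
  fold <- matrix(NA_real_, length(fits), length(doses),
                 dimnames = list(mice, paste0("dose_", doses)))
  for (i in seq_along(fits)) {
    for (j in seq_along(doses)) {
      fold[i, j] <- fold_reduction(spec, fits[[i]]$best_params, doses[j],
                                   duration, interval, gamma, rtol, atol)
    }
  }
  med <- apply(fold, 2, stats::median)
  rate <- if (length(doses) > 1) {
    (med[length(doses)] - med[1]) / (doses[length(doses)] - doses[1])
  } else {
    NA_real_
  }
  structure(list(model_id = ids[1], doses = doses, per_mouse_fold = fold,
                 median_fold = unname(med), avg_rate_of_change = unname(rate)),
            class = "escalation_result")
}

#' @export
print.escalation_result <- function(x, ...) {
  cat(sprintf("<escalation_result> model %s over %g-%g mg/kg\n", x$model_id,
              min(x$doses), max(x$doses)))
  print(data.frame(dose = x$doses, median_fold = signif(x$median_fold, 4)))
  cat(sprintf("  average rate of change: %.4g fold per mg/kg\n",
              x$avg_rate_of_change))
  invisible(x)
}
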