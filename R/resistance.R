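#' Specify a member of the treatment (resistance) model family
#'
#' The family describes a tumor as sensitive volume S and resistant volume R
#' under an exponentially decaying drug concentration D, with weekly bolus
#' dosing:
#'
#' \deqn{dS/dt = r_S S - f(S, D) - \lambda_S D S}
#' \deqn{dR/dt = r_R R + f(S, D) - \lambda_R D R}
#' \deqn{dD/dt = -\gamma D}
#'
#' The six members differ in the timing and mechanism of resistance:
#'
#' | model | pre-existing R(0) > 0 | transition f(S, D) |
#' |-------|-----------------------|--------------------|
#' | 1.1   | no                    | 0 (none)           |
#' | 1.2   | yes                   | 0 (none)           |
#' | 2.1   | no                    | g S (random)       |
#' | 2.2   | yes                   | g S (random)       |
#' | 3.1   | no                    | g S D (drug-induced) |
#' | 3.2   | yes                   | g S D (drug-induced) |
#'
#' For model 1.1 the R compartment is identically zero and its parameters are
#' absent; the free-parameter counts are k = 3, 6, 6, 7, 6, 7 for models
#' 1.1, 1.2, 2.1, 2.2, 3.1, 3.2.
#'
#' @param model_id One of `"1.1"`, `"1.2"`, `"2.1"`, `"2.2"`, `"3.1"`, `"3.2"`.
#' @return An object of class `resistance_spec`.
#' @export
resistance_spec <- function(model_id = c("1.1", "1.2", "2.1", "2.2", "3.1", "3.2")) {
  model_id <- match.arg(model_id)
  major <- substr(model_id, 1, 1)
  pre_existing <- substr(model_id, 3, 3) == "2"
  transition <- switch(major, "1" = "none", "2" = "random", "3" = "drug_induced")
  free <- "r_S"
  if (major != "1" || pre_existing) free <- c(free, "r_R")
  free <- c(free, "lambda_S")
  if (major != "1" || pre_existing) free <- c(free, "lambda_R")
  if (major != "1") free <- c(free, "g")
  free <- c(free, "S0")
  if (pre_existing) free <- c(free, "R0")
  structure(list(model_id = model_id, pre_existing = pre_existing,
                 transition = transition,
                 transition_code = match(transition,
                                         c("none", "random", "drug_induced")) - 1L,
                 free_params = free, k = length(free), profile_frac = -1),
            class = "resistance_spec")
}

#' @export
print.resistance_spec <- function(x, ...) {
  cat(sprintf("<resistance_spec> model %s: transition %s, pre-existing %s, k = %d\n",
              x$model_id, x$transition, x$pre_existing, x$k))
  if (x$profile_frac >= 0) {
    cat(sprintf("  profiled at initial resistance fraction %.3f (free total T0)\n",
                x$profile_frac))
  }
  invisible(x)
}

#' Cetuximab elimination rate constant
#'
#' First-order decay rate corresponding to the mean serum half-life of
#' 4.75 days: `log(2)/4.75` which is approximately 0.1459 per day.
#'
#' @return Decay rate in 1/day.
#' @export
default_gamma <- function() log(2) / 4.75

#' Weekly bolus dosing schedule
#'
#' @param dose Dose added to the drug compartment at each administration
#'   (mg/kg); default 5, the experimental cetuximab dose.
#' @param interval Days between doses (default 7).
#' @param n_doses Number of administrations.
#' @param start Day of the first dose (default 0, treatment start).
#' @return An object of class `dose_schedule` with the vector of dose times.
#' @export
dose_schedule <- function(dose = 5, interval = 7, n_doses = 10, start = 0) {
  if (dose < 0) stop("dose must be non-negative")
  if (interval <= 0) stop("interval must be positive")
  if (n_doses < 0 || n_doses != round(n_doses)) stop("n_doses must be a non-negative integer")
  structure(list(dose = dose, interval = interval, n_doses = n_doses,
                 start = start,
                 dose_times = start + interval * seq_len(n_doses) - interval),
            class = "dose_schedule")
}

# full parameter list with absent entries zeroed; errors on missing required
.treat_par_list <- function(spec, params) {
  params <- as.list(params)
  for (nm in setdiff(spec$free_params, "T0")) {
    if (is.null(params[[nm]]) || !is.finite(params[[nm]])) {
      stop(sprintf("missing or non-finite parameter '%s' for model %s",
                   nm, spec$model_id))
    }
  }
  get0p <- function(nm) if (is.null(params[[nm]])) 0 else params[[nm]]
  list(r_S = get0p("r_S"), r_R = get0p("r_R"), lambda_S = get0p("lambda_S"),
       lambda_R = get0p("lambda_R"), g = get0p("g"), S0 = get0p("S0"),
       R0 = get0p("R0"))
}

#' Right-hand side of a resistance model
#'
#' @param spec A [resistance_spec()].
#' @param state Named or positional numeric vector `(S, R, D)`, non-negative.
#' @param params Named parameters for the model.
#' @param gamma Drug decay rate (default [default_gamma()]).
#' @return Numeric vector `(dS/dt, dR/dt, dD/dt)`.
#' @export
treatment_rhs <- function(spec, state, params, gamma = default_gamma()) {
  stopifnot(inherits(spec, "resistance_spec"))
  if (any(state < 0)) stop("state must be non-negative")
  S <- state[[1]]; R <- state[[2]]; D <- state[[3]]
  p <- .treat_par_list(spec, params)
  f <- switch(spec$transition, none = 0, random = p$g * S,
              drug_induced = p$g * S * D)
  dS <- p$r_S * S - f - p$lambda_S * D * S
  dR <- if (spec$model_id == "1.1") 0 else p$r_R * R + f - p$lambda_R * D * R
  c(dS = dS, dR = dR, dD = -gamma * D)
}

#' Simulate a resistance model under impulsive dosing
#'
#' Integrates the model piecewise between dose times with hard restarts at
#' each bolus: at a dose time `D` jumps by `schedule$dose`. When an
#' observation time coincides with a dose, the post-jump value is reported
#' unless `pre_dose = TRUE`. `D(0) = dose` when the schedule starts at day 0.
#'
#' @param spec A [resistance_spec()].
#' @param params Named parameters; `R0` defaults to 0 for models without
#'   pre-existing resistance.
#' @param schedule A [dose_schedule()].
#' @param times Increasing non-negative observation days.
#' @param gamma Drug decay rate.
#' @param rtol,atol Solver tolerances.
#' @param pre_dose Report pre-jump drug values at dose times (default FALSE).
#' @return Data frame with columns `time`, `S`, `R`, `D`, `V` (= S + R).
#' @export
simulate_treatment <- function(spec, params, schedule, times,
                               gamma = default_gamma(), rtol = 1e-8,
                               atol = 1e-10, pre_dose = FALSE) {
  stopifnot(inherits(spec, "resistance_spec"), inherits(schedule, "dose_schedule"))
  times <- as.numeric(times)
  if (any(times < 0) || is.unsorted(times, strictly = TRUE)) {
    stop("times must be non-negative and strictly increasing")
  }
  p <- .treat_par_list(spec, params)
  if (!spec$pre_existing && p$R0 != 0) {
    stop(sprintf("model %s has no pre-existing resistance; R0 must be 0",
                 spec$model_id))
  }
  pars <- c(p$r_S, p$r_R, p$lambda_S, p$lambda_R, p$g, gamma, p$S0, p$R0)
  m <- tryCatch(
    .treat_solve_cpp(spec$transition_code, pars, schedule$dose_times,
                     rep(schedule$dose, schedule$n_doses), times, rtol, atol,
                     pre_dose),
    error = function(e) stop(sprintf(
      "integration of model %s failed: %s", spec$model_id,
      conditionMessage(e))))
  data.frame(time = times, S = m[, 1], R = m[, 2], D = m[, 3],
             V = m[, 1] + m[, 2])
}

#' Biological viability of a parameter set
#'
#' A parameter set is viable when all parameters are non-negative and
#' resistance carries a fitness cost: `r_S >= r_R` and `lambda_S > lambda_R`
#' whenever both members of a pair are present in the model. For models
#' without pre-existing resistance, `R0` must be zero.
#'
#' @param spec A [resistance_spec()].
#' @param params Named parameter values.
#' @return Logical scalar.
#' @export
is_viable <- function(spec, params) {
  stopifnot(inherits(spec, "resistance_spec"))
  params <- as.list(params)
  vals <- unlist(params[intersect(names(params),
                                  c("r_S", "r_R", "lambda_S", "lambda_R", "g",
                                    "S0", "R0", "T0"))])
  if (any(!is.finite(vals)) || any(vals < 0)) return(FALSE)
  has <- function(nm) !is.null(params[[nm]])
  if (has("r_S") && has("r_R") && "r_R" %in% spec$free_params) {
    if (params$r_S < params$r_R) return(FALSE)
  }
  if (has("lambda_S") && has("lambda_R") && "lambda_R" %in% spec$free_params) {
    if (!(params$lambda_S > params$lambda_R)) return(FALSE)
  }
  if (!spec$pre_existing && has("R0") && params$R0 != 0) return(FALSE)
  TRUE
}

#' Initial resistance fraction
#'
#' The profiled quantity of the identifiability analysis:
#' `R(0) / (S(0) + R(0))`.
#'
#' @param params Named parameters with `S0` and optionally `R0` (default 0).
#' @return Fraction in `[0, 1]`.
#' @export
initial_resistance_fraction <- function(params) {
  params <- as.list(params)
  S0 <- params$S0
  R0 <- if (is.null(params$R0)) 0 else params$R0
  if (is.null(S0)) stop("params must contain S0")
  if (S0 + R0 <= 0) stop("S0 + R0 must be positive")
  R0 / (S0 + R0)
}
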