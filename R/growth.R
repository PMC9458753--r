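#' Specify an untreated tumor-growth model
#'
#' Five single-compartment growth laws are supported, forming a hierarchy of
#' complexity used to describe control (placebo) mice:
#'
#' * `exponential`: dV/dt = r V
#' * `logistic`: dV/dt = r V (1 - V/K)
#' * `allee`: dV/dt = r V (1 - V/K)(V/m - 1), growth suppressed below the
#'   Allee threshold m
#' * `surface`: dV/dt = a V (V + b)^(-1/3), only a thin proliferating rim
#' * `von_bertalanffy`: dV/dt = a V^(2/3) - b V, surface-area-driven growth
#'   with volumetric loss
#'
#' @param name One of `"exponential"`, `"logistic"`, `"allee"`, `"surface"`,
#'   `"von_bertalanffy"`.
#' @return An object of class `growth_spec` with fields `name`, `free_params`
#'   (ordered, including the initial volume `V0`), `k` (parameter count) and
#'   an internal model code.
#' @export
growth_spec <- function(name = c("exponential", "logistic", "allee", "surface",
                                 "von_bertalanffy")) {
  name <- match.arg(name)
  free <- switch(name,
    exponential = c("r", "V0"),
    logistic = c("r", "K", "V0"),
    allee = c("r", "K", "m", "V0"),
    surface = c("a", "b", "V0"),
    von_bertalanffy = c("a", "b", "V0"))
  code <- match(name, c("exponential", "logistic", "allee", "surface",
                        "von_bertalanffy"))
  structure(list(name = name, free_params = free, k = length(free),
                 code = code),
            class = "growth_spec")
}

#' @export
print.growth_spec <- function(x, ...) {
  cat(sprintf("<growth_spec> %s: k = %d (%s)\n", x$name, x$k,
              paste(x$free_params, collapse = ", ")))
  invisible(x)
}

# named parameter list/vector -> internal [r, K, m, a, b, V0] layout
.growth_par_vec <- function(spec, params) {
  params <- as.list(params)
  needed <- spec$free_params
  for (nm in needed) {
    if (is.null(params[[nm]]) || !is.finite(params[[nm]])) {
      stop(sprintf("missing or non-finite parameter '%s' for %s model",
                   nm, spec$name))
    }
  }
  get0p <- function(nm) if (is.null(params[[nm]])) 0 else params[[nm]]
  c(get0p("r"), get0p("K"), get0p("m"), get0p("a"), get0p("b"), get0p("V0"))
}

#' Right-hand side of a growth model
#'
#' @param spec A [growth_spec()].
#' @param V Tumor volume (mm^3), non-negative.
#' @param params Named list/vector with the model's parameters.
#' @return dV/dt in mm^3 per day.
#' @export
growth_rhs <- function(spec, V, params) {
  stopifnot(inherits(spec, "growth_spec"))
  if (any(V < 0)) stop("volume must be non-negative")
  p <- .growth_par_vec(spec, c(as.list(params), V0 = 1))  # V0 unused in RHS
  switch(spec$name,
    exponential = p[1] * V,
    logistic = p[1] * V * (1 - V / p[2]),
    allee = p[1] * V * (1 - V / p[2]) * (V / p[3] - 1),
    surface = p[4] * V * (V + p[5])^(-1 / 3),
    von_bertalanffy = p[4] * V^(2 / 3) - p[5] * V)
}

#' Solve a growth model at requested times
#'
#' Integrates the initial-value problem with an adaptive explicit
#' Dormand-Prince Runge-Kutta scheme; the solution starts at `times[1]` with
#' `V = V0`.
#'
#' @param spec A [growth_spec()].
#' @param params Named parameters including `V0`.
#' @param times Increasing, non-negative observation days.
#' @param rtol,atol Solver tolerances.
#' @return Numeric vector of volumes, `volumes[1] == V0`.
#' @examples
#' solve_growth(growth_spec("exponential"), c(r = 0.1, V0 = 200), c(0, 7))
#' @export
solve_growth <- function(spec, params, times, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(spec, "growth_spec"))
  times <- as.numeric(times)
  if (length(times) < 1 || any(times < 0) || is.unsorted(times, strictly = TRUE)) {
    stop("times must be non-negative and strictly increasing")
  }
  p <- .growth_par_vec(spec, params)
  tryCatch(
    .growth_solve_cpp(spec$code, p, times, rtol, atol),
    error = function(e) stop(sprintf(
      "integration of %s model failed (stiffness or blow-up): %s",
      spec$name, conditionMessage(e)))
  )
}

#' Analytic exponential fit to a time course
#'
#' Ordinary least squares of log-volume on time over the non-censored points:
#' the slope is the growth rate r and the exponentiated intercept is V0. The
#' returned SSE is nevertheless evaluated on the original volume scale so that
#' information criteria are comparable with numerically fitted models.
#'
#' @param tc A [tumor_timecourse()] with at least two non-censored points.
#' @return List with `r`, `V0` and `sse`.
#' @export
fit_exponential_analytic <- function(tc) {
  stopifnot(inherits(tc, "tumor_timecourse"))
  keep <- !tc$censored
  if (sum(keep) < 2) stop("need at least two non-censored points")
  t <- tc$times[keep]
  y <- tc$volumes[keep]
  fit <- stats::lm.fit(cbind(1, t), log(y))
  r <- unname(fit$coefficients[2])
  V0 <- exp(unname(fit$coefficients[1]))
  pred <- V0 * exp(r * t)
  list(r = r, V0 = V0, sse = sum((y - pred)^2))
}

#' Tumor doubling time of an exponential growth rate
#'
#' @param r Growth rate per day, positive.
#' @return `log(2)/r` in days.
#' @export
doubling_time <- function(r) {
  if (any(r <= 0)) stop("doubling time is defined for positive growth rates")
  log(2) / r
}
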