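#' Construct a tumor-volume time course for one mouse
#'
#' The elementary data unit of the package: an ordered series of caliper-derived
#' tumor volumes for a single xenograft-bearing mouse, together with per-point
#' censor flags and a group label. Time is measured in days with `t = 0` at
#' treatment start; volumes are in cubic millimetres.
#'
#' @param mouse_id Character scalar identifying the mouse.
#' @param group Either `"control"` or `"treatment"`.
#' @param times Numeric vector of measurement days, non-negative and strictly
#'   increasing.
#' @param volumes Numeric vector of tumor volumes (mm^3), positive, same length
#'   as `times`.
#' @param censored Logical vector of censor flags (same length); censored points
#'   are retained in the object but excluded from all fitting, SSE evaluation
#'   and trajectory classification.
#'
#' @return An object of class `tumor_timecourse`.
#' @seealso [censor_timecourse()], [classify_trajectory()], [read_cohort()]
#' @export
tumor_timecourse <- function(mouse_id, group, times, volumes,
                             censored = rep(FALSE, length(times))) {
  group <- match.arg(group, c("control", "treatment"))
  times <- as.numeric(times)
  volumes <- as.numeric(volumes)
  censored <- as.logical(censored)
  if (length(times) != length(volumes) || length(times) != length(censored)) {
    stop("times, volumes and censored must have equal length")
  }
  if (length(times) == 0) stop("a time course needs at least one point")
  if (any(!is.finite(times)) || any(times < 0)) {
    stop("times must be finite and non-negative")
  }
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(!is.finite(volumes)) || any(volumes <= 0)) {
    stop("volumes must be finite and positive")
  }
  structure(
    list(mouse_id = as.character(mouse_id), group = group, times = times,
         volumes = volumes, censored = censored),
    class = "tumor_timecourse"
  )
}

#' @export
print.tumor_timecourse <- function(x, ...) {
  cat(sprintf("<tumor_timecourse> mouse %s (%s): %d points over days %g-%g, %d censored\n",
              x$mouse_id, x$group, length(x$times), min(x$times), max(x$times),
              sum(x$censored)))
  invisible(x)
}

#' Initial tumor volume of a time course
#'
#' Returns the first non-censored volume, the quantity written V0 throughout:
#' it anchors the per-mouse parameter sampling ranges (initial conditions are
#' searched over `[0, 2 V0]`).
#'
#' @param tc A [tumor_timecourse()].
#' @return Numeric scalar (mm^3).
#' @export
initial_volume <- function(tc) {
  stopifnot(inherits(tc, "tumor_timecourse"))
  keep <- !tc$censored
  if (!any(keep)) stop("all points are censored; V0 is undefined")
  tc$volumes[which(keep)[1]]
}

#' Tumor volume from caliper length and width
#'
#' Ellipsoid approximation `V = l w^2 pi / 6` used to convert two-axis caliper
#' measurements to a volume.
#'
#' @param l Tumor length (mm), non-negative.
#' @param w Tumor width (mm), non-negative.
#' @return Volume in mm^3 (vectorized).
#' @examples
#' compute_volume(2, 1) # pi/3
#' @export
compute_volume <- function(l, w) {
  if (any(l < 0) || any(w < 0)) stop("caliper measurements must be non-negative")
  l * w^2 * pi / 6
}

#' Censor biologically implausible volume spikes
#'
#' Flags any interior point whose volume more than doubles (by default) relative
#' to the previous point within a short window, when the jump is not sustained
#' by the following point. The rationale: the fastest doubling time observed in
#' untreated control mice is on the order of two weeks, so a doubling within
#' 3-4 days that immediately reverses is a measurement artifact, not growth.
#' Only flags are changed; times and volumes are kept for audit. The first and
#' last points are never censored (no neighbouring point to judge by).
#'
#' @param tc A [tumor_timecourse()].
#' @param max_fold Ratio above which a jump is suspect (default 2, i.e. more
#'   than doubling).
#' @param window Maximum time gap in days for the jump to count (default 4).
#' @param sustain_tol The jump is "sustained" (and kept) when the next volume is
#'   at least `sustain_tol` times the spiked volume; default 1, i.e. the next
#'   point must not fall back below the spike.
#' @return The time course with updated censor flags.
#' @examples
#' tc <- tumor_timecourse("m1", "control", c(0, 3, 6), c(100, 600, 110))
#' censor_timecourse(tc)$censored # middle point flagged
#' @export
censor_timecourse <- function(tc, max_fold = 2, window = 4, sustain_tol = 1) {
  stopifnot(inherits(tc, "tumor_timecourse"))
  if (!(max_fold > 1)) stop("max_fold must exceed 1")
  if (!(window > 0)) stop("window must be positive")
  n <- length(tc$times)
  if (n < 3) {
    warning("fewer than 3 points; censoring rule needs both neighbours, returning input unchanged")
    return(tc)
  }
  for (j in 2:(n - 1)) {
    jump <- tc$volumes[j] / tc$volumes[j - 1] > max_fold
    fast <- (tc$times[j] - tc$times[j - 1]) <= window
    unsustained <- tc$volumes[j + 1] < sustain_tol * tc$volumes[j]
    if (jump && fast && unsustained) tc$censored[j] <- TRUE
  }
  tc
}

#' Classify a trajectory as increasing, decreasing or stable
#'
#' Compares the last non-censored volume with the initial volume V0; a ratio
#' within `1 +/- stable_band` is "stable", above is "increasing", below is
#' "decreasing". In the treatment group, "decreasing" is the signature of
#' therapeutic response.
#'
#' @param tc A [tumor_timecourse()].
#' @param stable_band Half-width of the stability band as a ratio
#'   (default 0.2, i.e. +/- 20 percent).
#' @return One of `"increasing"`, `"decreasing"`, `"stable"`.
#' @export
classify_trajectory <- function(tc, stable_band = 0.2) {
  stopifnot(inherits(tc, "tumor_timecourse"))
  keep <- which(!tc$censored)
  if (length(keep) < 2) stop("need at least 2 non-censored points to classify")
  ratio <- tc$volumes[keep[length(keep)]] / tc$volumes[keep[1]]
  if (ratio > 1 + stable_band) "increasing"
  else if (ratio < 1 - stable_band) "decreasing"
  else "stable"
}

#' Tally trajectory classes for one experimental group
#'
#' @param n_increasing,n_decreasing,n_stable Non-negative integer counts.
#' @return An object of class `response_counts`.
#' @export
response_counts <- function(n_increasing, n_decreasing, n_stable) {
  counts <- c(increasing = n_increasing, decreasing = n_decreasing,
              stable = n_stable)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  structure(as.list(counts), class = "response_counts")
}

#' Count trajectory classes across a cohort
#'
#' @param cohort List of [tumor_timecourse()] objects (one group).
#' @param stable_band Passed to [classify_trajectory()].
#' @return A `response_counts` object.
#' @export
count_responses <- function(cohort, stable_band = 0.2) {
  cls <- vapply(cohort, classify_trajectory, character(1),
                stable_band = stable_band)
  response_counts(sum(cls == "increasing"), sum(cls == "decreasing"),
                  sum(cls == "stable"))
}

#' Fisher exact test of tumor-volume response by group
#'
#' Builds the 2x2 table (decreasing vs not-decreasing) x (control vs treatment)
#' and returns the two-sided Fisher exact p-value: the sum of probabilities of
#' all tables with the same margins whose hypergeometric probability does not
#' exceed that of the observed table. A small p-value indicates that volume
#' decreases are associated with treatment.
#'
#' @param control,treatment [response_counts()] for each group.
#' @return Two-sided p-value.
#' @examples
#' ctrl <- response_counts(19, 1, 5)
#' trt <- response_counts(19, 7, 3)
#' fisher_exact_response(ctrl, trt) # ~0.056
#' @export
fisher_exact_response <- function(control, treatment) {
  stopifnot(inherits(control, "response_counts"),
            inherits(treatment, "response_counts"))
  n_ctrl <- control$increasing + control$decreasing + control$stable
  n_trt <- treatment$increasing + treatment$decreasing + treatment$stable
  if (n_ctrl == 0 || n_trt == 0) stop("both groups must be non-empty")
  tab <- matrix(c(control$decreasing, n_ctrl - control$decreasing,
                  treatment$decreasing, n_trt - treatment$decreasing),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("control", "treatment"),
                                c("decreasing", "not_decreasing")))
  stats::fisher.test(tab)$p.value
}

#' Read a cohort of tumor time courses from CSV
#'
#' The canonical interchange format is a tidy CSV with one row per observation
#' and columns `mouse_id`, `group`, `time_days`, `volume_mm3`, `censored`.
#'
#' @param path Path to a CSV file.
#' @return A named list of [tumor_timecourse()] objects.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("mouse_id", "group", "time_days", "volume_mm3", "censored")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("cohort CSV is missing column(s): ", paste(missing, collapse = ", "))
  }
  ids <- unique(df$mouse_id)
  cohort <- vector("list", length(ids))
  names(cohort) <- ids
  for (id in ids) {
    rows <- which(df$mouse_id == id)
    sub <- df[rows, ]
    if (any(sub$volume_mm3 <= 0 | !is.finite(sub$volume_mm3))) {
      bad <- rows[which(sub$volume_mm3 <= 0 | !is.finite(sub$volume_mm3))[1]]
      stop(sprintf("non-positive volume for mouse %s at row %d", id, bad))
    }
    if (any(duplicated(sub$time_days)) || is.unsorted(sub$time_days, strictly = TRUE)) {
      stop(sprintf("times for mouse %s are not strictly increasing (rows %s)",
                   id, paste(range(rows), collapse = "-")))
    }
    if (length(unique(sub$group)) != 1) {
      stop(sprintf("mouse %s has inconsistent group labels", id))
    }
    cohort[[id]] <- tumor_timecourse(id, sub$group[1], sub$time_days,
                                     sub$volume_mm3, as.logical(sub$censored))
  }
  cohort
}

#' Write a cohort of tumor time courses to CSV
#'
#' @param cohort List of [tumor_timecourse()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  rows <- lapply(cohort, function(tc) {
    data.frame(mouse_id = tc$mouse_id, group = tc$group, time_days = tc$times,
               volume_mm3 = tc$volumes, censored = tc$censored,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
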