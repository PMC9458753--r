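#' Akaike information criterion from an SSE fit
#'
#' For least-squares fits with Gaussian errors the criterion reduces (up to an
#' additive constant shared across models for the same data) to
#' `n * log(sse / n) + 2 k`. The penalty `2k` does not grow with the number of
#' data points.
#'
#' @param sse Sum of squared errors at the optimum.
#' @param n Number of (non-censored) data points.
#' @param k Number of fitted parameters.
#' @return The AIC value; `-Inf` with a warning for a perfect fit (`sse = 0`).
#' @export
aic <- function(sse, n, k) {
  .ic_check(sse, n, k)
  if (sse == 0) {
    warning("sse is 0 (perfect fit); returning -Inf")
    return(-Inf)
  }
  n * log(sse / n) + 2 * k
}

#' Bayesian information criterion from an SSE fit
#'
#' As [aic()] but with penalty `k * log(n)`: the weight of the parameter
#' penalty grows with the number of data points, so for `n >= 8` BIC penalizes
#' complexity harder than AIC.
#'
#' @inheritParams aic
#' @return The BIC value.
#' @export
bic <- function(sse, n, k) {
  .ic_check(sse, n, k)
  if (sse == 0) {
    warning("sse is 0 (perfect fit); returning -Inf")
    return(-Inf)
  }
  n * log(sse / n) + k * log(n)
}

.ic_check <- function(sse, n, k) {
  if (sse < 0) stop("sse must be non-negative")
  if (n < 1) stop("n must be at least 1")
  if (k < 1) stop("k must be at least 1")
}

#' Confidence tier of a model-selection call
#'
#' How much better is the top-ranked model's information criterion than the
#' runner-up's? The relative gap `|IC2 - IC1| / max(|IC1|, 1)` is mapped to a
#' tier: at or below the first threshold is `"low"` confidence, between the
#' two is `"medium"`, above the second is `"high"`. The default thresholds
#' (5% and 10%) follow the reported figure annotations; set
#' `thresholds = c(0.05, 0.15)` for the stricter prose variant in which high
#' confidence requires a 15% gap. The denominator is floored at 1 because ICs
#' computed from SSE can legitimately be near or below zero.
#'
#' @param ic_sorted Numeric vector of IC values sorted ascending (best first);
#'   at least 2 values.
#' @param thresholds Length-2 increasing vector of relative-gap cut points.
#' @return `"low"`, `"medium"` or `"high"`; `NA_character_` for a single model.
#' @export
confidence_tier <- function(ic_sorted, thresholds = c(0.05, 0.10)) {
  if (length(ic_sorted) < 2) return(NA_character_)
  if (is.unsorted(ic_sorted)) stop("ic_sorted must be sorted ascending")
  .tier_gap(ic_sorted[1], ic_sorted[2], thresholds)
}

.tier_gap <- function(top, runner_up, thresholds = c(0.05, 0.10)) {
  stopifnot(length(thresholds) == 2, thresholds[1] < thresholds[2])
  g <- abs(runner_up - top) / max(abs(top), 1)
  if (g <= thresholds[1]) "low" else if (g <= thresholds[2]) "medium" else "high"
}

#' Rank models fitted to one mouse by information criterion
#'
#' Computes AIC and BIC for each fit, identifies the most and least
#' parsimonious models by each criterion and attaches confidence tiers. Ties
#' are broken by smaller `k`, then lexicographic model id.
#'
#' @param fits List of `fit_result` objects for the same mouse (hence the
#'   same non-censored point count).
#' @param thresholds Passed to [confidence_tier()].
#' @return An object of class `ic_table`: a list with the per-model data frame
#'   `table` and fields `best_by_aic`, `best_by_bic`, `worst_by_aic`,
#'   `worst_by_bic`, `confidence_aic`, `confidence_bic`,
#'   `confidence_worst_aic`, `confidence_worst_bic`.
#' @export
rank_models <- function(fits, thresholds = c(0.05, 0.10)) {
  if (length(fits) < 1) stop("need at least one fit")
  ids <- vapply(fits, function(f) f$mouse_id, character(1))
  if (length(unique(ids)) != 1) stop("fits must all be for the same mouse")
  ns <- vapply(fits, function(f) f$n_points, numeric(1))
  if (length(unique(ns)) != 1) {
    stop("fits disagree on the number of non-censored points")
  }
  tab <- data.frame(
    model_id = vapply(fits, function(f) f$model_id, character(1)),
    k = vapply(fits, function(f) f$k, numeric(1)),
    n = ns,
    sse = vapply(fits, function(f) f$sse, numeric(1)),
    stringsAsFactors = FALSE)
  tab$aic <- suppressWarnings(mapply(aic, tab$sse, tab$n, tab$k))
  tab$bic <- suppressWarnings(mapply(bic, tab$sse, tab$n, tab$k))
  tab <- tab[order(tab$model_id), , drop = FALSE]
  rownames(tab) <- NULL

  pick <- function(ic, decreasing = FALSE) {
    o <- order(if (decreasing) -ic else ic, tab$k, tab$model_id)
    tab$model_id[o[1]]
  }
  tier_of <- function(ic, decreasing = FALSE) {
    if (nrow(tab) < 2) return(NA_character_)
    s <- sort(ic, decreasing = decreasing)
    .tier_gap(s[1], s[2], thresholds)
  }
  structure(
    list(mouse_id = ids[1], table = tab,
         best_by_aic = pick(tab$aic), best_by_bic = pick(tab$bic),
         worst_by_aic = pick(tab$aic, TRUE), worst_by_bic = pick(tab$bic, TRUE),
         confidence_aic = tier_of(tab$aic),
         confidence_bic = tier_of(tab$bic),
         confidence_worst_aic = tier_of(tab$aic, TRUE),
         confidence_worst_bic = tier_of(tab$bic, TRUE)),
    class = "ic_table")
}

#' @export
print.ic_table <- function(x, ...) {
  cat(sprintf("<ic_table> mouse %s\n", x$mouse_id))
  print(x$table)
  cat(sprintf("  best AIC: %s (%s confidence), best BIC: %s (%s confidence)\n",
              x$best_by_aic, x$confidence_aic, x$best_by_bic, x$confidence_bic))
  invisible(x)
}

#' Cohort-level model-selection tallies
#'
#' Counts, over a cohort of per-mouse [rank_models()] tables, how often each
#' model is the most parsimonious (lowest IC) and the least parsimonious
#' (highest IC), by AIC and by BIC, stratified by confidence tier.
#'
#' @param tables List of `ic_table` objects.
#' @return List of four `model x tier` count matrices: `lowest_aic`,
#'   `lowest_bic`, `highest_aic`, `highest_bic`. Each matrix's counts sum to
#'   the cohort size.
#' @export
cohort_selection_summary <- function(tables) {
  if (length(tables) < 1) stop("need at least one ic_table")
  models <- sort(unique(unlist(lapply(tables, function(t) t$table$model_id))))
  tiers <- c("low", "medium", "high")
  count <- function(model_field, tier_field) {
    m <- matrix(0L, length(models), length(tiers),
                dimnames = list(models, tiers))
    for (t in tables) {
      tier <- t[[tier_field]]
      if (is.na(tier)) tier <- "low"  # single-model tables carry no gap
      m[t[[model_field]], tier] <- m[t[[model_field]], tier] + 1L
    }
    m
  }
  list(lowest_aic = count("best_by_aic", "confidence_aic"),
       lowest_bic = count("best_by_bic", "confidence_bic"),
       highest_aic = count("worst_by_aic", "confidence_worst_aic"),
       highest_bic = count("worst_by_bic", "confidence_worst_bic"))
}
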