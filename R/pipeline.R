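#' Configuration for a full analysis run
#'
#' Exactly one of `cohort_path` (a cohort CSV) or `recipe` (a
#' [cohort_recipe()] to synthesize one) must be given.
#'
#' @param cohort_path Path to a cohort CSV, or `NULL`.
#' @param recipe A [cohort_recipe()], or `NULL`.
#' @param out_dir Output directory for all artifacts.
#' @param n_starts,n_qmc,n_iter Fit budgets for the headline fits.
#' @param profile_n_starts,profile_n_qmc,profile_n_iter Reduced budgets for
#'   the 21-point profile refits.
#' @param treatment_models Model ids fitted to treatment mice.
#' @param profile_models Pre-existing-resistance models to profile.
#' @param escalation_models Models replayed in the dose-escalation study.
#' @param doses Escalation dose grid (mg/kg).
#' @param grid_step Profile grid step for the resistance fraction.
#' @param rel_rise Identifiability threshold, see [classify_identifiability()].
#' @param thresholds Confidence-tier cut points, see [confidence_tier()].
#' @param seed Master seed; per-mouse/model sub-seeds derive from it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort_path = NULL, recipe = NULL, out_dir = "resistfam_run",
                       n_starts = 15, n_qmc = 1.5e6, n_iter = 5e5,
                       profile_n_starts = 5, profile_n_qmc = 2000,
                       profile_n_iter = 2000,
                       treatment_models = c("1.1", "1.2", "2.1", "2.2", "3.1", "3.2"),
                       profile_models = c("1.2", "3.2"),
                       escalation_models = c("2.1", "3.1", "1.2", "3.2"),
                       doses = 16:20, grid_step = 0.05, rel_rise = 0.10,
                       thresholds = c(0.05, 0.10), seed = 1L) {
  if (is.null(cohort_path) == is.null(recipe)) {
    stop("exactly one of cohort_path or recipe must be given")
  }
  if (any(c(n_starts, n_qmc, n_iter, profile_n_starts, profile_n_qmc,
            profile_n_iter) < 1)) {
    stop("fit budgets must be at least 1")
  }
  structure(as.list(environment()), class = "run_config")
}

.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

.fits_to_df <- function(fits) {
  do.call(rbind, lapply(fits, function(f) data.frame(
    mouse_id = f$mouse_id, model_id = f$model_id, k = f$k, n = f$n_points,
    sse = f$sse, stringsAsFactors = FALSE)))
}

#' Run the full analysis pipeline
#'
#' Orchestrates preprocess (censoring, trajectory classification, Fisher
#' test), growth-model fits to control mice, six-member resistance-model fits
#' to treatment mice, AIC/BIC selection at both stages, resistance-fraction
#' profiles for the pre-existing-resistance models, and the dose-escalation
#' study, writing CSV/JSON artifacts plus a manifest with checksums.
#' Idempotent for a fixed config and seed.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return The output directory, invisibly; artifacts on disk.
#' @export
run_full_analysis <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  outputs <- character(0)
  manifest <- list(seed = config$seed,
                   budgets = list(n_starts = config$n_starts,
                                  n_qmc = config$n_qmc, n_iter = config$n_iter),
                   package_version = as.character(utils::packageVersion("resistfam")),
                   stages = list())
  record <- function(stage, files) {
    outputs <<- c(outputs, files)
    manifest$stages[[stage]] <<- basename(files)
  }
  fail_at <- NULL
  result <- tryCatch({
    # --- stage: input -----------------------------------------------------
    fail_at <- "input"
    if (!is.null(config$recipe)) {
      gen <- generate_cohort(config$recipe)
      cohort <- gen$cohort
      truth_path <- file.path(config$out_dir, "truth.json")
      jsonlite::write_json(lapply(gen$truth, function(t)
        list(params = t$params, outlier_idx = t$outlier_idx)),
        truth_path, auto_unbox = TRUE, digits = NA)
      record("input", truth_path)
    } else {
      cohort <- read_cohort(config$cohort_path)
    }

    # --- stage: preprocess ------------------------------------------------
    fail_at <- "preprocess"
    say("preprocess: censoring and classifying %d mice", length(cohort))
    cohort <- lapply(cohort, censor_timecourse)
    cens_path <- file.path(config$out_dir, "cohort_censored.csv")
    write_cohort(cohort, cens_path)
    groups <- vapply(cohort, function(tc) tc$group, character(1))
    summary <- list()
    for (grp in intersect(c("control", "treatment"), unique(groups))) {
      summary[[grp]] <- unclass(count_responses(cohort[groups == grp]))
    }
    if (all(c("control", "treatment") %in% names(summary))) {
      summary$fisher_p <- fisher_exact_response(
        do.call(response_counts, unname(summary$control)),
        do.call(response_counts, unname(summary$treatment)))
    }
    resp_path <- file.path(config$out_dir, "response_summary.json")
    jsonlite::write_json(summary, resp_path, auto_unbox = TRUE, digits = NA)
    record("preprocess", c(cens_path, resp_path))

    control <- cohort[groups == "control"]
    treated <- cohort[groups == "treatment"]

    # --- stage: control growth fits ---------------------------------------
    if (length(control) > 0) {
      fail_at <- "fit_control"
      say("fit-control: 5 growth laws x %d control mice", length(control))
      growth_names <- c("exponential", "logistic", "allee", "surface",
                        "von_bertalanffy")
      ctrl_tables <- list()
      ctrl_fits <- list()
      for (id in names(control)) {
        fits <- list()
        for (gname in growth_names) {
          spec <- growth_spec(gname)
          fits[[gname]] <- multistart_fit(
            spec, control[[id]], n_starts = config$n_starts,
            n_qmc = config$n_qmc, n_iter = config$n_iter,
            seed = (as.numeric(config$seed) * 331 +
                      match(id, names(control)) * 17 +
                      match(gname, growth_names)) %% 2147483647)
        }
        ctrl_fits[[id]] <- fits
        ctrl_tables[[id]] <- rank_models(fits, config$thresholds)
      }
      f1 <- .write_csv(.fits_to_df(unlist(ctrl_fits, recursive = FALSE)),
                       file.path(config$out_dir, "control_fits.csv"))
      ctrl_sum <- cohort_selection_summary(ctrl_tables)
      f2 <- file.path(config$out_dir, "control_selection.json")
      jsonlite::write_json(lapply(ctrl_sum, as.data.frame), f2, digits = NA)
      record("fit_control", c(f1, f2))
    }

    # --- stage: treatment fits + selection --------------------------------
    trt_fits <- list()
    if (length(treated) > 0) {
      fail_at <- "fit_treatment"
      say("fit: %d resistance models x %d treated mice",
          length(config$treatment_models), length(treated))
      trt_tables <- list()
      for (id in names(treated)) {
        fits <- list()
        for (m in config$treatment_models) {
          spec <- resistance_spec(m)
          fits[[m]] <- multistart_fit(
            spec, treated[[id]], n_starts = config$n_starts,
            n_qmc = config$n_qmc, n_iter = config$n_iter,
            seed = (as.numeric(config$seed) * 7919 +
                      match(id, names(treated)) * 97 +
                      match(m, config$treatment_models)) %% 2147483647)
        }
        trt_fits[[id]] <- fits
        trt_tables[[id]] <- rank_models(fits, config$thresholds)
      }
      f1 <- .write_csv(.fits_to_df(unlist(trt_fits, recursive = FALSE)),
                       file.path(config$out_dir, "treatment_fits.csv"))
      trt_sum <- cohort_selection_summary(trt_tables)
      f2 <- file.path(config$out_dir, "treatment_selection.json")
      jsonlite::write_json(lapply(trt_sum, as.data.frame), f2, digits = NA)
      record("fit_treatment", c(f1, f2))

      # --- stage: profiles -------------------------------------------------
      fail_at <- "profile"
      prof_rows <- list()
      for (m in intersect(config$profile_models, config$treatment_models)) {
        say("profile: resistance fraction scan, model %s", m)
        for (id in names(treated)) {
          curve <- profile_rfrac(
            resistance_spec(m), treated[[id]],
            grid = seq(0, 1, by = config$grid_step),
            n_starts = config$profile_n_starts,
            n_qmc = config$profile_n_qmc, n_iter = config$profile_n_iter,
            seed = (as.numeric(config$seed) * 4409 +
                      match(id, names(treated))) %% 2147483647,
            rel_rise = config$rel_rise)
          prof_rows[[paste(m, id)]] <- data.frame(
            mouse_id = id, model_id = m, frac = curve$grid,
            sse = curve$sse_profile, argmin = curve$argmin,
            verdict = curve$verdict, stringsAsFactors = FALSE)
        }
      }
      if (length(prof_rows) > 0) {
        f3 <- .write_csv(do.call(rbind, prof_rows),
                         file.path(config$out_dir, "profiles.csv"))
        record("profile", f3)
      }

      # --- stage: dose escalation -----------------------------------------
      fail_at <- "escalate"
      esc_rows <- list()
      for (m in intersect(config$escalation_models, config$treatment_models)) {
        say("escalate: model %s over %g-%g mg/kg", m, min(config$doses),
            max(config$doses))
        fits_m <- lapply(trt_fits, function(f) f[[m]])
        esc <- escalation_study(fits_m, resistance_spec(m),
                                doses = config$doses)
        esc_rows[[m]] <- data.frame(
          model_id = m, dose = esc$doses, median_fold = esc$median_fold,
          avg_rate_of_change = esc$avg_rate_of_change,
          stringsAsFactors = FALSE)
      }
      if (length(esc_rows) > 0) {
        f4 <- .write_csv(do.call(rbind, esc_rows),
                         file.path(config$out_dir, "escalation.csv"))
        record("escalate", f4)
      }
    }
    fail_at <- NULL
    TRUE
  }, error = function(e) e)

  manifest$failed_at <- fail_at
  if (inherits(result, "error")) {
    manifest$error <- conditionMessage(result)
  }
  manifest$files <- lapply(outputs, function(f)
    list(path = basename(f), md5 = unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (inherits(result, "error")) {
    stop(sprintf("pipeline failed at stage '%s': %s (partial outputs retained in %s)",
                 fail_at, conditionMessage(result), config$out_dir))
  }
  invisible(config$out_dir)
}
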