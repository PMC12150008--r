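# File formats: trial data and results as comma-separated text (header row,
# '.' decimal, UTF-8; arm 0 = control), configuration as JSON, manifest as
# JSON.

#' Write patient-level trial data as CSV
#'
#' @param data Trial data frame from [simulate_trial()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_trial_data <- function(data, path) {
  req <- c("j", "t", "arm", "y")
  if (!all(req %in% names(data)))
    stop("trial data must contain columns j, t, arm, y", call. = FALSE)
  out <- data
  # %.17g round-trips doubles exactly through read.csv
  for (cc in names(out))
    if (is.double(out[[cc]])) out[[cc]] <- sprintf("%.17g", out[[cc]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read patient-level trial data from CSV
#'
#' Columns `period` and `calendar` are optional; when a `plan` is supplied
#' and `period` is missing it is recomputed from the plan.
#'
#' @param path Input path.
#' @param plan Optional `ncct_plan` used to recompute period labels.
#' @return A trial data frame.
#' @export
read_trial_data <- function(path, plan = NULL) {
  dat <- utils::read.csv(path)
  req <- c("j", "t", "arm", "y")
  miss <- setdiff(req, names(dat))
  if (length(miss))
    stop("trial data file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(dat$period) && !is.null(plan)) {
    pm <- assign_periods(plan)
    dat$period <- pm$s[dat$t]
  }
  dat
}

#' Flatten fit results to a one-row-per-fit data frame
#'
#' @param fits An `ncct_fit` or list of them.
#' @return Data frame with model, adjustment, estimate, SE, one-sided p,
#'   rejection, variance components, convergence, and n.
#' @export
fit_results_table <- function(fits) {
  if (inherits(fits, "ncct_fit")) fits <- list(fits)
  vcn <- unique(unlist(lapply(fits, function(f)
    names(f$variance_components))))
  rows <- lapply(fits, function(f) {
    vc <- setNames(rep(NA_real_, length(vcn)), vcn)
    vc[names(f$variance_components)] <- f$variance_components
    cbind(data.frame(model = f$model, adjustment = f$adjustment,
                     theta_hat = f$theta_hat, se = f$se,
                     p_one_sided = f$p_one_sided, reject = f$reject,
                     converged = f$converged, n_used = f$n_used),
          as.data.frame(as.list(vc)))
  })
  do.call(rbind, rows)
}

#' Write fit results as CSV
#'
#' @param fits An `ncct_fit` or list of them.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fit_results <- function(fits, path) {
  utils::write.csv(fit_results_table(fits), path, row.names = FALSE)
  invisible(path)
}

config_defaults <- list(
  n_arm = 250, clength = 100, eta0 = 0, sigma = 1, alpha = 0.025,
  n_reps = 10000, psi = 1, pattern = "none", lambda = 0, M = NULL,
  Np = NULL, theta = NULL, models = c("fixed_period", "ttest_separate"))

config_known <- c("K", "d", "schedule", names(config_defaults))

#' Load and validate a scenario/design configuration (JSON)
#'
#' Unknown keys, type mismatches and range violations are all collected and
#' reported together.  Defaults: `alpha = 0.025`, `sigma = 1`,
#' `n_reps = 10000`, `psi = 1`, `clength = 100`, `eta0 = 0`.
#'
#' @param path Path to a JSON file, or a named list.
#' @return A validated configuration list (class `ncct_config`).
#' @export
load_config <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else if (is.list(path)) path
  else stop("path must be a file path or a list", call. = FALSE)

  errs <- character(0)
  unknown <- setdiff(names(cfg), config_known)
  if (length(unknown))
    errs <- c(errs, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  for (key in names(config_defaults))
    if (is.null(cfg[[key]])) cfg[[key]] <- config_defaults[[key]]

  if (is.null(cfg$K) || !is.numeric(cfg$K) || cfg$K < 1)
    errs <- c(errs, "K: required integer >= 1")
  if (is.null(cfg$d) && is.null(cfg$schedule))
    errs <- c(errs, "d or schedule: one is required")
  if (!is.null(cfg$pattern) &&
      !cfg$pattern %in% c("none", "linear", "stepwise", "inverted_u",
                          "seasonal"))
    errs <- c(errs, paste0("pattern: unknown trend pattern '", cfg$pattern,
                           "'"))
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1)
    errs <- c(errs, "alpha: must lie in (0, 1)")
  if (!is.numeric(cfg$sigma) || cfg$sigma <= 0)
    errs <- c(errs, "sigma: must be > 0")
  if (!is.numeric(cfg$n_reps) || cfg$n_reps < 1)
    errs <- c(errs, "n_reps: must be >= 1")
  if (!is.numeric(cfg$psi) || cfg$psi <= 0)
    errs <- c(errs, "psi: must be > 0")
  if (!is.null(cfg$lambda) && !is.numeric(cfg$lambda))
    errs <- c(errs, "lambda: must be numeric")
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  if (is.null(cfg$M)) cfg$M <- cfg$K
  structure(cfg, class = "ncct_config")
}

config_design <- function(cfg) {
  platform_design(K = cfg$K, d = cfg$d, schedule = cfg$schedule,
                  n_arm = cfg$n_arm, clength = cfg$clength)
}

#' Parse a model label into a model specification
#'
#' Accepts the labels used throughout the package, e.g. `"fixed_period"`,
#' `"fixed_calendar"`, `"spline_period_q3"`, `"mixed_ar1_calendar"`,
#' `"interaction_period"`, `"ttest_pooled"`.
#'
#' @param label Model label string.
#' @param clength,alpha Passed to [model_spec()].
#' @return An `ncct_model_spec`.
#' @export
parse_model_label <- function(label, clength = NULL, alpha = 0.025) {
  parts <- strsplit(label, "_", fixed = TRUE)[[1L]]
  bad <- function() stop("unknown model label: ", label, call. = FALSE)
  if (parts[1L] == "fixed" && length(parts) == 2L &&
      parts[2L] %in% c("period", "calendar"))
    return(model_spec("fixed", parts[2L], clength = clength, alpha = alpha))
  if (parts[1L] == "spline" && length(parts) == 3L &&
      parts[2L] %in% c("period", "calendar") && grepl("^q[123]$", parts[3L]))
    return(model_spec("spline",
                      knot_strategy = if (parts[2L] == "period")
                        "period_starts" else "equidistant_calendar",
                      degree = as.integer(sub("q", "", parts[3L])),
                      clength = clength, alpha = alpha))
  if (parts[1L] == "mixed" && length(parts) == 3L &&
      parts[2L] %in% c("iid", "ar1") &&
      parts[3L] %in% c("period", "calendar"))
    return(model_spec("mixed", parts[3L], covariance = parts[2L],
                      clength = clength, alpha = alpha))
  if (parts[1L] == "interaction" && length(parts) == 2L &&
      parts[2L] %in% c("period", "calendar"))
    return(model_spec("mixed_interaction", parts[2L], clength = clength,
                      alpha = alpha))
  if (parts[1L] == "ttest" && length(parts) == 2L &&
      parts[2L] %in% c("pooled", "separate"))
    return(model_spec(paste0("ttest_", parts[2L]), alpha = alpha))
  bad()
}

#' Run a configured scenario grid and write summary plus manifest
#'
#' Expands the configuration's `d` and `lambda` entries into a scenario
#' grid, runs every cell with [run_scenario()], and (optionally) writes a
#' long-format summary CSV and a JSON run manifest sufficient to replay the
#' study exactly.
#'
#' @param config Path to a JSON configuration or an `ncct_config` list.
#' @param master_seed Master seed for the whole study.
#' @param n_reps Optional override of the configured replicate count.
#' @param out_dir Optional output directory for `summary.csv` and
#'   `manifest.json`.
#' @return List with `summary` (data frame) and `manifest` (list),
#'   invisibly when `out_dir` is given.
#' @export
run_study <- function(config, master_seed = 1, n_reps = NULL,
                      out_dir = NULL) {
  cfg <- if (inherits(config, "ncct_config")) config else load_config(config)
  if (is.null(n_reps)) n_reps <- cfg$n_reps
  d_grid <- if (is.null(cfg$d)) NA else cfg$d
  lam_grid <- if (is.list(cfg$lambda)) cfg$lambda else
    as.list(cfg$lambda)
  grid <- expand.grid(d_i = seq_along(d_grid), l_i = seq_along(lam_grid))

  results <- vector("list", nrow(grid))
  scen_seeds <- integer(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    d <- d_grid[grid$d_i[i]]
    lambda <- lam_grid[[grid$l_i[i]]]
    design <- if (is.na(d)) config_design(cfg) else
      platform_design(cfg$K, d = d, n_arm = cfg$n_arm,
                      clength = cfg$clength)
    specs <- lapply(cfg$models, parse_model_label, clength = cfg$clength,
                    alpha = cfg$alpha)
    names(specs) <- cfg$models
    scen_seeds[i] <- derive_seed(master_seed, i, offset = 1500000)
    res <- run_scenario(design, M = cfg$M, models = specs,
                        eta0 = cfg$eta0, theta = cfg$theta,
                        sigma = cfg$sigma, pattern = cfg$pattern,
                        lambda = lambda, Np = cfg$Np, psi = cfg$psi,
                        n_reps = n_reps, master_seed = scen_seeds[i],
                        scenario = sprintf("scen%03d", i))
    res$d <- d
    res$lambda <- paste(lambda, collapse = ";")
    res$pattern <- cfg$pattern
    res$clength <- cfg$clength
    results[[i]] <- res
  }
  summary <- summarize_study(results)
  manifest <- list(
    package = "ncctrend",
    version = as.character(utils::packageVersion("ncctrend")),
    timestamp = format(Sys.time(), tz = "UTC"),
    master_seed = master_seed, n_reps = n_reps,
    scenario_seeds = scen_seeds,
    config = unclass(cfg))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    return(invisible(list(summary = summary, manifest = manifest)))
  }
  list(summary = summary, manifest = manifest)
}

#' Replay a study from its manifest
#'
#' @param manifest_path Path to a `manifest.json` written by [run_study()].
#' @param out_dir Optional output directory.
#' @return As [run_study()]; the summary is byte-identical to the original
#'   run.
#' @export
replay_manifest <- function(manifest_path, out_dir = NULL) {
  man <- jsonlite::fromJSON(manifest_path, simplifyVector = TRUE)
  cfg <- load_config(man$config)
  run_study(cfg, master_seed = man$master_seed, n_reps = man$n_reps,
            out_dir = out_dir)
}
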