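# Monte-Carlo operating-characteristics harness: replicate loop over
# simulate -> analysis window -> model fits, with per-replicate derived
# seeds so any single replicate is reproducible in isolation.

#' Derive a replicate seed from a master seed
#'
#' Deterministic, collision-free for `offset + r < 2^31 - (master %% 1e5) *
#' 20011`, and always below 2^31 for the offsets used internally.
#'
#' @param master Master integer seed.
#' @param r Replicate counter (>= 1).
#' @param offset Stream offset separating independent uses.
#' @return An integer seed.
#' @export
derive_seed <- function(master, r, offset = 0) {
  as.integer((as.double(master) %% 100000) * 20011 + offset + r)
}

#' Run one simulation scenario
#'
#' Simulates `n_reps` platform trials, fits every requested model to the
#' evaluated arm's analysis window, and aggregates rejection rate (type I
#' error when `theta[M] == 0`, power otherwise), Monte-Carlo standard
#' error, bias of the effect estimate, empirical and mean model standard
#' errors, and the convergence rate.  Replicates failing to fit are counted
#' against convergence and excluded from both numerator and denominator of
#' the rejection rate.
#'
#' @param design An `ncct_design`.
#' @param M Evaluated experimental arm.
#' @param models Named list of `ncct_model_spec` objects (names become model
#'   labels; unnamed lists are labelled automatically).
#' @param eta0,theta,sigma Generative parameters (see [simulate_trial()]).
#' @param pattern,lambda,Np,psi Time-trend parameters (see [trend_spec()]);
#'   `pattern = "none"` disables the trend.
#' @param n_reps Number of replicates (reference-study scale, default 10000).
#' @param master_seed Master seed; replicate `r` uses
#'   `derive_seed(master_seed, r)`.
#' @param scenario Optional scenario id attached to the output.
#' @return A data frame with one row per model: rejection rate, `mc_se`,
#'   `bias`, `emp_se`, `mean_se`, `conv_rate`, `n_used`.
#' @export
run_scenario <- function(design, M, models, eta0 = 0, theta = NULL,
                         sigma = 1, pattern = "none", lambda = 0,
                         Np = NULL, psi = 1, n_reps = 10000,
                         master_seed = 1, scenario = NA_character_) {
  stopifnot(inherits(design, "ncct_design"), n_reps >= 1)
  if (is.null(theta)) theta <- rep(0, design$K)
  plan <- plan_recruitment(design)
  trend <- if (identical(pattern, "none")) NULL else
    trend_spec(pattern, lambda, plan$N, Np = Np, psi = psi)
  if (is.null(names(models)) || any(!nzchar(names(models))))
    names(models) <- vapply(models, model_label, "")

  nm <- length(models)
  rejects <- matrix(NA, n_reps, nm)
  ests <- matrix(NA_real_, n_reps, nm)
  ses <- matrix(NA_real_, n_reps, nm)
  conv <- matrix(FALSE, n_reps, nm)

  for (r in seq_len(n_reps)) {
    dat <- simulate_trial(design, eta0, theta, sigma, trend,
                          seed = derive_seed(master_seed, r), plan = plan)
    w <- analysis_window(dat, plan, M)
    for (i in seq_len(nm)) {
      f <- tryCatch(suppressMessages(fit_model(w, models[[i]])),
                    error = function(e) NULL)
      if (is.null(f)) next
      conv[r, i] <- isTRUE(f$converged)
      if (conv[r, i]) {
        rejects[r, i] <- f$reject
        ests[r, i] <- f$theta_hat
        ses[r, i] <- f$se
      }
    }
  }

  out <- data.frame(
    scenario = scenario, model = names(models), M = M,
    n_reps = n_reps,
    n_used = colSums(!is.na(rejects)),
    reject_rate = colMeans(rejects, na.rm = TRUE),
    bias = colMeans(ests, na.rm = TRUE) - theta[M],
    emp_se = apply(ests, 2, stats::sd, na.rm = TRUE),
    mean_se = colMeans(ses, na.rm = TRUE),
    conv_rate = colMeans(conv),
    row.names = NULL)
  out$mc_se <- sqrt(out$reject_rate * (1 - out$reject_rate) / out$n_used)
  out
}

#' Combine scenario results into one long-format study table
#'
#' @param results A list of data frames from [run_scenario()] (extra
#'   scenario columns such as `lambda`, `d` or `pattern` are kept).
#' @return A single data frame, rows in input order.
#' @export
summarize_study <- function(results) {
  if (!length(results)) stop("no scenario results supplied", call. = FALSE)
  cols <- unique(unlist(lapply(results, names)))
  results <- lapply(results, function(df) {
    for (cc in setdiff(cols, names(df))) df[[cc]] <- NA
    df[, cols, drop = FALSE]
  })
  do.call(rbind, results)
}

#' Pooled Monte-Carlo standard error for a difference of two rejection rates
#'
#' @param p1,p2 Rejection rates.
#' @param n1,n2 Replicate counts.
#' @return Standard error of `p1 - p2` for independent estimates.
#' @export
pooled_mc_se <- function(p1, n1, p2, n2) {
  sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
}
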