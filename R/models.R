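#' Specify an analysis model
#'
#' @param family One of `"fixed"` (categorical time adjustment),
#'   `"spline"` (B-spline on entry time), `"mixed"` (random time-interval
#'   intercepts), `"mixed_interaction"` (fixed time effects plus random
#'   treatment-by-time interaction), `"ttest_pooled"`, `"ttest_separate"`.
#' @param adjustment `"period"` or `"calendar"` (ignored by t-tests).
#' @param covariance Random-effect covariance for `family = "mixed"`:
#'   `"iid"` or `"ar1"`.
#' @param degree Spline degree `q` in 1, 2, 3 (spline only; default 3).
#' @param knot_strategy `"period_starts"` or `"equidistant_calendar"`
#'   (spline only).
#' @param clength Calendar interval length; `NULL` uses the design default.
#' @param alpha One-sided significance level (default 0.025).
#' @param welch Use Welch instead of pooled-variance t-test (default FALSE).
#' @return An object of class `ncct_model_spec`.
#' @export
model_spec <- function(family = c("fixed", "spline", "mixed",
                                  "mixed_interaction", "ttest_pooled",
                                  "ttest_separate"),
                       adjustment = c("period", "calendar"),
                       covariance = c("iid", "ar1"),
                       degree = 3L, knot_strategy = c("period_starts",
                                                      "equidistant_calendar"),
                       clength = NULL, alpha = 0.025, welch = FALSE) {
  family <- match.arg(family)
  adjustment <- match.arg(adjustment)
  covariance <- match.arg(covariance)
  knot_strategy <- match.arg(knot_strategy)
  if (!degree %in% 1:3) stop("degree must be 1, 2 or 3", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)", call. = FALSE)
  structure(list(family = family, adjustment = adjustment,
                 covariance = covariance, degree = as.integer(degree),
                 knot_strategy = knot_strategy, clength = clength,
                 alpha = alpha, welch = isTRUE(welch)),
            class = "ncct_model_spec")
}

model_label <- function(spec) {
  switch(spec$family,
    fixed = paste0("fixed_", spec$adjustment),
    spline = paste0("spline_", if (spec$knot_strategy == "period_starts")
      "period" else "calendar", "_q", spec$degree),
    mixed = paste0("mixed_", spec$covariance, "_", spec$adjustment),
    mixed_interaction = paste0("interaction_", spec$adjustment),
    ttest_pooled = "ttest_pooled",
    ttest_separate = "ttest_separate")
}

new_fit_result <- function(model, adjustment, theta_hat, se, p, alpha,
                           coefficients, variance_components, converged,
                           n_used, df = NA_real_, dropped = character(0)) {
  structure(list(model = model, adjustment = adjustment,
                 theta_hat = theta_hat, se = se, p_one_sided = p,
                 reject = isTRUE(p <= alpha), alpha = alpha,
                 coefficients = coefficients,
                 variance_components = variance_components,
                 converged = converged, n_used = n_used, df = df,
                 dropped = dropped),
            class = "ncct_fit")
}

#' @export
print.ncct_fit <- function(x, ...) {
  cat(x$model, ": theta_hat = ", format(x$theta_hat, digits = 4),
      ", se = ", format(x$se, digits = 4),
      ", one-sided p = ", format(x$p_one_sided, digits = 4),
      if (x$reject) " [reject]" else " [do not reject]", "\n", sep = "")
  if (!x$converged) cat("  (fit did not converge)\n")
  if (length(x$dropped))
    cat("  dropped aliased columns:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

# time levels (period or calendar) for the window under a given adjustment;
# always truncated at t_M^exit
window_time_levels <- function(window, adjustment, clength) {
  if (adjustment == "period") return(window$data$period)
  if (is.null(clength)) clength <- window$clength
  grid <- assign_calendar(window$t_exit, clength)
  grid$c[window$data$t]
}

#' Fixed-effect regression with categorical time adjustment
#'
#' Ordinary least squares of the response on indicators for every
#' experimental arm with data in the window and for every time level
#' (period or calendar interval) beyond the first.  One-sided inference on
#' the evaluated arm's effect uses the t distribution with residual degrees
#' of freedom.  A time level perfectly aliased with an arm indicator is
#' dropped and flagged.
#'
#' @param window An `ncct_window` from [analysis_window()].
#' @param adjustment `"period"` or `"calendar"`.
#' @param clength Calendar interval length (calendar adjustment only;
#'   `NULL` uses the design default).
#' @param alpha One-sided significance level.
#' @return An `ncct_fit`.
#' @export
fit_fixed <- function(window, adjustment = c("period", "calendar"),
                      clength = NULL, alpha = 0.025) {
  stopifnot(inherits(window, "ncct_window"))
  adjustment <- match.arg(adjustment)
  dat <- window$data
  lev <- window_time_levels(window, adjustment, clength)
  pre <- if (adjustment == "period") "tau_s" else "tau_c"
  X <- cbind(`(Intercept)` = 1, arm_columns(dat$arm, window$K_M),
             time_columns(lev, pre))
  fit <- ols_engine(X, dat$y)
  tcol <- paste0("theta_", window$M)
  if (is.na(fit$coef[tcol]))
    stop("evaluated arm effect is not estimable in this window",
         call. = FALSE)
  if (length(fit$dropped)) {
    if (any(grepl("^theta_", fit$dropped)))
      stop("an arm indicator is aliased; model cannot be fit", call. = FALSE)
    message("fit_fixed: dropped aliased time column(s): ",
            paste(fit$dropped, collapse = ", "))
  }
  p <- one_sided_p_t(fit$coef[[tcol]], fit$se[[tcol]], fit$df)
  new_fit_result(paste0("fixed_", adjustment), adjustment,
                 fit$coef[[tcol]], fit$se[[tcol]], p, alpha,
                 fit$coef, c(sigma2 = fit$sigma2), TRUE, nrow(dat),
                 df = fit$df, dropped = fit$dropped)
}

#' Build a B-spline basis over entry times
#'
#' Inner knots sit at the beginning of each period after the first
#' (`"period_starts"`) or at the beginning of each calendar interval after
#' the first (`"equidistant_calendar"`); boundary knots at the range of the
#' supplied times.  Knots outside the open range are dropped with a message.
#' The fitting basis omits the first column of the full
#' (partition-of-unity) basis so that an explicit intercept can be kept.
#'
#' @param t_values Patient entry times in the window.
#' @param knot_strategy `"period_starts"` or `"equidistant_calendar"`.
#' @param q Spline degree (1, 2 or 3).
#' @param clength Calendar interval length (equidistant strategy).
#' @param period_starts Start times of periods 2..S in the window
#'   (period strategy); an `ncct_period_map` is also accepted.
#' @return An object of class `ncct_spline_basis`: list with `degree`,
#'   `knots`, `boundary`, `basis` (fitting basis), `basis_full`
#'   (partition-of-unity basis including the first column).
#' @export
build_spline_basis <- function(t_values,
                               knot_strategy = c("period_starts",
                                                 "equidistant_calendar"),
                               q = 3L, clength = NULL, period_starts = NULL) {
  knot_strategy <- match.arg(knot_strategy)
  if (!q %in% 1:3) stop("q must be 1, 2 or 3", call. = FALSE)
  if (length(unique(t_values)) < q + 1L)
    stop("need at least q + 1 distinct time values", call. = FALSE)
  rng <- range(t_values)
  if (knot_strategy == "period_starts") {
    if (inherits(period_starts, "ncct_period_map"))
      period_starts <- period_starts$boundaries + 1L
    knots <- as.numeric(period_starts)
  } else {
    if (is.null(clength))
      stop("clength is required for equidistant knots", call. = FALSE)
    kmax <- floor((rng[2L] - 1) / clength)
    knots <- if (kmax >= 1L) seq_len(kmax) * clength + 1 else numeric(0)
  }
  inside <- knots > rng[1L] & knots < rng[2L]
  if (any(!inside)) {
    message("build_spline_basis: dropped ", sum(!inside),
            " knot(s) outside the data range")
    knots <- knots[inside]
  }
  knots <- sort(unique(knots))
  full <- splines::bs(t_values, knots = knots, degree = q,
                      Boundary.knots = rng, intercept = TRUE)
  basis <- full[, -1L, drop = FALSE]
  colnames(basis) <- paste0("spl", seq_len(ncol(basis)))
  structure(list(degree = as.integer(q), knots = knots, boundary = rng,
                 basis = basis, basis_full = unclass(full)),
            class = "ncct_spline_basis")
}

#' Spline regression on patient entry time
#'
#' Least squares of the response on arm indicators plus a B-spline in entry
#' time (explicit intercept; the first basis column is dropped for
#' identifiability).  Inference as in [fit_fixed()].
#'
#' @inheritParams fit_fixed
#' @param knot_strategy `"period_starts"` or `"equidistant_calendar"`.
#' @param q Spline degree (1, 2 or 3; default 3).
#' @return An `ncct_fit`.
#' @export
fit_spline <- function(window, knot_strategy = c("period_starts",
                                                 "equidistant_calendar"),
                       q = 3L, clength = NULL, alpha = 0.025) {
  stopifnot(inherits(window, "ncct_window"))
  knot_strategy <- match.arg(knot_strategy)
  dat <- window$data
  if (is.null(clength)) clength <- window$clength
  starts <- NULL
  if (knot_strategy == "period_starts") {
    per <- window$plan$periods
    starts <- per$start[per$start > 1 & per$start <= window$t_exit]
  }
  sb <- build_spline_basis(dat$t, knot_strategy, q, clength, starts)
  X <- cbind(`(Intercept)` = 1, arm_columns(dat$arm, window$K_M), sb$basis)
  fit <- ols_engine(X, dat$y)
  tcol <- paste0("theta_", window$M)
  if (is.na(fit$coef[tcol]))
    stop("evaluated arm effect is not estimable in this window",
         call. = FALSE)
  if (length(fit$dropped)) {
    if (any(grepl("^theta_", fit$dropped)))
      stop("an arm indicator is aliased; model cannot be fit", call. = FALSE)
    message("fit_spline: dropped aliased basis column(s): ",
            paste(fit$dropped, collapse = ", "))
  }
  p <- one_sided_p_t(fit$coef[[tcol]], fit$se[[tcol]], fit$df)
  lab <- paste0("spline_", if (knot_strategy == "period_starts") "period"
                else "calendar", "_q", q)
  adj <- if (knot_strategy == "period_starts") "period" else "calendar"
  new_fit_result(lab, adj, fit$coef[[tcol]], fit$se[[tcol]], p, alpha,
                 fit$coef, c(sigma2 = fit$sigma2), TRUE, nrow(dat),
                 df = fit$df, dropped = fit$dropped)
}

#' Mixed model with random time-interval intercepts
#'
#' Fixed arm effects plus a random intercept for every period or calendar
#' interval, fit by REML.  The random effects are independent
#' (`covariance = "iid"`) or share an AR(1) correlation `rho^|s - s'|`
#' (`covariance = "ar1"`).  Inference on the evaluated arm uses a Wald z
#' (normal approximation).
#'
#' @inheritParams fit_fixed
#' @param covariance `"iid"` or `"ar1"`.
#' @return An `ncct_fit` with variance components `sigma2`,
#'   `sigma2_period`/`sigma2_calendar`, and `rho` (AR(1) only).
#' @export
fit_mixed <- function(window, adjustment = c("period", "calendar"),
                      covariance = c("iid", "ar1"), clength = NULL,
                      alpha = 0.025) {
  stopifnot(inherits(window, "ncct_window"))
  adjustment <- match.arg(adjustment)
  covariance <- match.arg(covariance)
  dat <- window$data
  lev <- window_time_levels(window, adjustment, clength)
  ulev <- sort(unique(lev))
  if (length(ulev) < 2L)
    stop("only one time level in the window; use fit_fixed", call. = FALSE)
  cell <- match(lev, ulev)
  X <- cbind(`(Intercept)` = 1, arm_columns(dat$arm, window$K_M))
  fit <- reml_fit(dat$y, X, cell, length(ulev), covariance)
  tcol <- paste0("theta_", window$M)
  th <- fit$beta[[tcol]]; se <- fit$se[[which(names(fit$beta) == tcol)]]
  p <- stats::pnorm(th / se, lower.tail = FALSE)
  vc <- c(sigma2 = fit$sigma2, fit$sigma2_u)
  names(vc)[2L] <- paste0("sigma2_", adjustment)
  if (covariance == "ar1") vc <- c(vc, rho = fit$rho)
  if (!fit$converged)
    message("fit_mixed: REML optimisation did not converge")
  res <- new_fit_result(paste0("mixed_", covariance, "_", adjustment),
                        adjustment, th, se, p, alpha, fit$beta, vc,
                        fit$converged, nrow(dat))
  res$loglik <- fit$loglik
  res
}

#' Mixed model with a random treatment-by-time interaction
#'
#' Fixed arm and time-level effects exactly as in [fit_fixed()], plus
#' independent random effects for every combination of a non-evaluated
#' experimental arm with a time level beyond the first (the evaluated arm
#' and the control are excluded from the interaction, as their trends are
#' assumed equal).  REML; Wald z inference.
#'
#' @inheritParams fit_fixed
#' @return An `ncct_fit` with variance components `sigma2` and
#'   `sigma2_arm_period`/`sigma2_arm_calendar`.
#' @export
fit_mixed_interaction <- function(window,
                                  adjustment = c("period", "calendar"),
                                  clength = NULL, alpha = 0.025) {
  stopifnot(inherits(window, "ncct_window"))
  adjustment <- match.arg(adjustment)
  dat <- window$data
  lev <- window_time_levels(window, adjustment, clength)
  ulev <- sort(unique(lev))
  if (length(ulev) < 2L)
    stop("only one time level in the window; use fit_fixed", call. = FALSE)
  other <- setdiff(window$K_M, window$M)
  if (!length(other)) {
    message("fit_mixed_interaction: no non-evaluated experimental arm; ",
            "falling back to fit_fixed")
    return(fit_fixed(window, adjustment, clength, alpha))
  }
  pre <- if (adjustment == "period") "tau_s" else "tau_c"
  X <- cbind(`(Intercept)` = 1, arm_columns(dat$arm, window$K_M),
             time_columns(lev, pre))
  # interaction cells: non-M experimental arms crossed with time levels >= 2
  lev_idx <- match(lev, ulev)
  in_int <- dat$arm %in% other & lev_idx >= 2L
  key <- ifelse(in_int, paste(dat$arm, lev_idx, sep = ":"), NA)
  cells_present <- sort(unique(key[in_int]))
  cell <- match(key, cells_present)
  fit <- reml_fit(dat$y, X, cell, length(cells_present), "iid")
  tcol <- paste0("theta_", window$M)
  th <- fit$beta[[tcol]]; se <- fit$se[[which(names(fit$beta) == tcol)]]
  p <- stats::pnorm(th / se, lower.tail = FALSE)
  vc <- c(sigma2 = fit$sigma2, fit$sigma2_u)
  names(vc)[2L] <- paste0("sigma2_arm_", adjustment)
  if (!fit$converged)
    message("fit_mixed_interaction: REML optimisation did not converge")
  res <- new_fit_result(paste0("interaction_", adjustment), adjustment,
                        th, se, p, alpha, fit$beta, vc, fit$converged,
                        nrow(dat))
  res$loglik <- fit$loglik
  res
}

#' One-sided two-sample t-test comparators
#'
#' The pooled analysis compares the evaluated arm to *all* control patients
#' in the window (concurrent plus non-concurrent); the separate analysis
#' uses concurrent controls only (those recruited while the evaluated arm
#' was open).  Pooled-variance test by default.
#'
#' @inheritParams fit_fixed
#' @param mode `"pooled"` or `"separate"`.
#' @param welch Use Welch's test instead of pooled variance.
#' @return An `ncct_fit`.
#' @export
t_test <- function(window, mode = c("pooled", "separate"), alpha = 0.025,
                   welch = FALSE) {
  stopifnot(inherits(window, "ncct_window"))
  mode <- match.arg(mode)
  dat <- window$data
  yM <- dat$y[dat$arm == window$M]
  yC <- if (mode == "pooled") dat$y[dat$arm == 0L]
        else dat$y[dat$arm == 0L & dat$t >= window$t_entry]
  if (length(yM) < 2L || length(yC) < 2L)
    stop("each group needs at least 2 observations", call. = FALSE)
  tt <- stats::t.test(yM, yC, alternative = "greater",
                      var.equal = !isTRUE(welch))
  th <- unname(tt$estimate[1L] - tt$estimate[2L])
  se <- unname(tt$stderr)
  new_fit_result(paste0("ttest_", mode), "none", th, se, tt$p.value, alpha,
                 c(theta = th), c(sigma2 = NA_real_), TRUE,
                 length(yM) + length(yC), df = unname(tt$parameter))
}

#' Fit any model specification to an analysis window
#'
#' @param window An `ncct_window`.
#' @param spec An `ncct_model_spec`.
#' @return An `ncct_fit`.
#' @export
fit_model <- function(window, spec) {
  stopifnot(inherits(spec, "ncct_model_spec"))
  switch(spec$family,
    fixed = fit_fixed(window, spec$adjustment, spec$clength, spec$alpha),
    spline = fit_spline(window, spec$knot_strategy, spec$degree,
                        spec$clength, spec$alpha),
    mixed = fit_mixed(window, spec$adjustment, spec$covariance,
                      spec$clength, spec$alpha),
    mixed_interaction = fit_mixed_interaction(window, spec$adjustment,
                                              spec$clength, spec$alpha),
    ttest_pooled = t_test(window, "pooled", spec$alpha, spec$welch),
    ttest_separate = t_test(window, "separate", spec$alpha, spec$welch))
}
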