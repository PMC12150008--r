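test_that("fixed-effect fits match the normal-equations oracle to 1e-8", {
  des <- design_k4()
  plan <- plan_recruitment(des)
  tr <- trend_spec("linear", 0.4, plan$N)
  dat <- simulate_trial(des, theta = c(0.1, 0, 0.25, 0), trend = tr,
                        seed = 11, plan = plan)
  w <- analysis_window(dat, plan, 3)

  f <- fit_fixed(w, "period")
  X <- cbind(1,
             sapply(1:4, function(k) as.numeric(w$data$arm == k)),
             sapply(2:6, function(s) as.numeric(w$data$period == s)))
  expect_equal(unname(f$coefficients), as.numeric(ne_oracle(X, w$data$y)),
               tolerance = 1e-8)

  # calendar adjustment against lm() as a second, construction-independent
  # oracle
  fc <- fit_fixed(w, "calendar", clength = 100)
  cal <- ceiling(w$data$t / 100)
  lmfit <- lm(w$data$y ~ factor(w$data$arm) + factor(cal))
  expect_equal(unname(f$df), unname(df.residual(
    lm(w$data$y ~ factor(w$data$arm) + factor(w$data$period)))))
  expect_equal(unname(fc$theta_hat),
               unname(coef(lmfit)[["factor(w$data$arm)3"]]),
               tolerance = 1e-8)
})

test_that("single-period window collapses to a difference of raw means", {
  des <- platform_design(K = 2, d = 0, n_arm = 80)
  plan <- plan_recruitment(des)
  dat <- simulate_trial(des, theta = c(0.3, 0.1), seed = 4, plan = plan)
  w <- analysis_window(dat, plan, 2)
  f <- fit_fixed(w, "period")
  raw <- mean(dat$y[dat$arm == 2]) - mean(dat$y[dat$arm == 0])
  expect_equal(unname(f$theta_hat), raw, tolerance = 1e-10)
})

test_that("period and calendar fits coincide when the grids align", {
  des <- design_k10(500)
  plan <- plan_recruitment(des)
  dat <- simulate_trial(des, theta = rep(0.2, 10), seed = 6, plan = plan)
  w <- analysis_window(dat, plan, 10)   # window = whole trial, periods of 500
  fp <- fit_fixed(w, "period")
  fc <- fit_fixed(w, "calendar", clength = 500)
  expect_equal(fp$theta_hat, fc$theta_hat, tolerance = 1e-10)
  expect_equal(fp$se, fc$se, tolerance = 1e-10)
})

test_that("one-sided inference points in the stated direction", {
  des <- platform_design(K = 1, d = 0, n_arm = 150)
  plan <- plan_recruitment(des)
  up <- simulate_trial(des, theta = 1.5, seed = 8, plan = plan)
  dn <- simulate_trial(des, theta = -1.5, seed = 8, plan = plan)
  wu <- analysis_window(up, plan, 1)
  wd <- analysis_window(dn, plan, 1)
  expect_lt(fit_fixed(wu, "period")$p_one_sided, 0.001)
  expect_gt(fit_fixed(wd, "period")$p_one_sided, 0.999)
  expect_true(fit_fixed(wu, "period")$reject)
  expect_false(fit_fixed(wd, "period")$reject)
})

test_that("spline basis is a partition of unity with correct knots", {
  des <- design_k10(500)
  plan <- plan_recruitment(des)
  pm <- assign_periods(plan)
  tvals <- seq_len(plan$N)
  sb <- build_spline_basis(tvals, "period_starts", q = 3,
                           period_starts = pm)
  expect_length(sb$knots, 9L)                      # 9 inner knots
  expect_equal(sb$knots, 500 * (1:9) + 1)
  expect_equal(rowSums(sb$basis_full), rep(1, length(tvals)),
               tolerance = 1e-12)

  # knots outside the data range are dropped with a message
  expect_message(
    sb2 <- build_spline_basis(1:400, "period_starts", q = 2,
                              period_starts = c(101, 999)),
    "dropped")
  expect_equal(sb2$knots, 101)
  expect_error(build_spline_basis(c(1, 2), "period_starts", q = 3,
                                  period_starts = numeric(0)), "distinct")
})

test_that("degree-1 spline with no inner knots is the linear-time model", {
  des <- platform_design(K = 2, d = 0, n_arm = 100)   # single period
  plan <- plan_recruitment(des)
  dat <- simulate_trial(des, theta = c(0.2, 0.4), seed = 12, plan = plan)
  w <- analysis_window(dat, plan, 2)
  f <- fit_spline(w, "period_starts", q = 1)
  lmfit <- lm(y ~ factor(arm) + t, data = w$data)
  expect_equal(unname(f$theta_hat), unname(coef(lmfit)[["factor(arm)2"]]),
               tolerance = 1e-8)
})

test_that("q = 1 period-knot spline recovers a period-breakpoint trend", {
  des <- design_k4()
  plan <- plan_recruitment(des)
  base <- simulate_trial(des, theta = c(0, 0, 0.25, 0), sigma = 1e-8,
                         seed = 13, plan = plan)
  # continuous piecewise-linear drift with kinks exactly at period starts
  starts <- c(1L, plan$periods$start[-1L])
  slopes <- c(0.002, -0.001, 0.0015, 0, -0.002, 0.001, 0.0005)
  f <- c(0, cumsum(slopes[findInterval(seq_len(plan$N)[-1L] - 1L, starts)]))
  base$y <- base$y + f[base$t]
  w <- analysis_window(base, plan, 3)
  fit <- fit_spline(w, "period_starts", q = 1)
  expect_equal(unname(fit$theta_hat), 0.25, tolerance = 1e-6)
})

test_that("an aliased time level is dropped and flagged, not fatal", {
  # period 3 contains only arm-9 data and arm 9 appears only there:
  # the tau_3 column equals the theta_9 column
  set.seed(30)
  dat <- data.frame(
    t = 1:60,
    arm = c(rep(c(0L, 1L), 15), rep(c(0L, 1L), 10), rep(9L, 10)),
    y = rnorm(60),
    period = rep(1:3, c(30, 20, 10)))
  dat$j <- dat$t
  w <- fake_window(dat, M = 1)
  expect_message(f <- fit_fixed(w, "period"), "aliased")
  expect_true(length(f$dropped) == 1L)
  expect_false(is.na(f$theta_hat))
})

test_that("mixed iid fit agrees with lme4 REML", {
  skip_if_not_installed("lme4")
  des <- design_k4()
  plan <- plan_recruitment(des)
  dat <- simulate_trial(des, theta = c(0, 0.1, 0.25, 0), seed = 14,
                        plan = plan)
  # genuine random period effects so the optimum is interior
  set.seed(15)
  u <- rnorm(nrow(plan$periods), 0, 0.4)
  dat$y <- dat$y + u[dat$period]
  w <- analysis_window(dat, plan, 3)
  f <- fit_mixed(w, "period", "iid")
  df <- w$data
  df$perf <- factor(df$period)
  lf <- lme4::lmer(y ~ factor(arm) + (1 | perf), data = df, REML = TRUE)
  expect_equal(unname(f$theta_hat),
               unname(lme4::fixef(lf)[["factor(arm)3"]]), tolerance = 1e-5)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(unname(f$variance_components[["sigma2_period"]]),
               vc$vcov[1L], tolerance = 1e-4)
  expect_equal(unname(f$variance_components[["sigma2"]]),
               vc$vcov[2L], tolerance = 1e-4)
  se_lme4 <- sqrt(diag(as.matrix(vcov(lf))))[[4L]]
  expect_equal(unname(f$se), se_lme4, tolerance = 1e-4)
})

test_that("AR(1) constrained to rho = 0 reproduces the iid fit", {
  des <- design_small()
  plan <- plan_recruitment(des)
  dat <- simulate_trial(des, theta = c(0.1, 0.3), seed = 16, plan = plan)
  set.seed(17)
  dat$y <- dat$y + rnorm(3, 0, 0.5)[dat$period]
  w <- analysis_window(dat, plan, 2)
  lev <- w$data$period
  X <- cbind(1, sapply(1:2, function(k) as.numeric(w$data$arm == k)))
  colnames(X) <- c("(Intercept)", "theta_1", "theta_2")
  iid <- ncctrend:::reml_fit(w$data$y, X, lev, 3, "iid")
  ar0 <- ncctrend:::reml_fit(w$data$y, X, lev, 3, "ar1", rho_fixed = 0)
  expect_equal(iid$loglik, ar0$loglik, tolerance = 1e-6)
  expect_equal(iid$beta, ar0$beta, tolerance = 1e-6)
})

test_that("REML engine matches the dense-matrix oracle", {
  des <- design_small()
  plan <- plan_recruitment(des)
  dat <- simulate_trial(des, theta = c(0.2, 0.4), seed = 18, plan = plan)
  set.seed(19)
  dat$y <- dat$y + rnorm(3, 0, 0.6)[dat$period]
  w <- analysis_window(dat, plan, 2)
  X <- cbind(1, sapply(1:2, function(k) as.numeric(w$data$arm == k)))
  colnames(X) <- c("(Intercept)", "theta_1", "theta_2")
  cell <- w$data$period
  ss <- ncctrend:::reml_suffstat(w$data$y, X, cell, 3)
  for (gamma in c(0.05, 0.5, 2)) {
    for (rho in c(-0.5, 0, 0.7)) {
      expect_equal(ncctrend:::reml_eval(ss, gamma, rho, "ar1"),
                   as.numeric(dense_reml_obj(w$data$y, X, cell, 3,
                                             gamma, rho, "ar1")),
                   tolerance = 1e-7)
    }
  }
})

test_that("zero time-structure collapses the mixed model to pooling", {
  des <- design_k4()
  plan <- plan_recruitment(des)
  dat <- simulate_trial(des, theta = c(0, 0, 0.25, 0), seed = 20,
                        plan = plan)   # no trend, no period effects
  w <- analysis_window(dat, plan, 3)
  f <- fit_mixed(w, "period", "iid")
  pooled <- t_test(w, "pooled")
  expect_lt(f$variance_components[["sigma2_period"]], 1e-4)
  # with sigma2_period ~ 0 the estimate equals the no-time-adjustment OLS,
  # whose arm-vs-control contrast is the pooled difference in means
  expect_equal(unname(f$theta_hat), unname(pooled$theta_hat),
               tolerance = 1e-3)
})

test_that("interaction model excludes arm M and shrinks to the fixed fit", {
  des <- design_k4()
  plan <- plan_recruitment(des)
  dat <- simulate_trial(des, theta = c(0, 0, 0.25, 0), seed = 21,
                        plan = plan)
  w <- analysis_window(dat, plan, 3)
  f <- fit_mixed_interaction(w, "period")
  ff <- fit_fixed(w, "period")
  # no interaction structure in truth: variance ~ 0 and theta matches fixed
  expect_lt(f$variance_components[["sigma2_arm_period"]], 1e-3)
  expect_equal(f$theta_hat, ff$theta_hat, tolerance = 1e-4)

  # with only arm M in the window the model falls back to fit_fixed
  sub <- w$data[w$data$arm %in% c(0L, 3L), ]
  wsub <- fake_window(sub, M = 3, plan = plan)
  expect_message(fb <- fit_mixed_interaction(wsub, "period"), "falling back")
  expect_identical(fb$model, "fixed_period")
})

test_that("t-test comparators use the stated control sets", {
  des <- design_k4()
  plan <- plan_recruitment(des)
  dat <- simulate_trial(des, seed = 22, plan = plan)
  w <- analysis_window(dat, plan, 3)
  tp <- t_test(w, "pooled")
  ts <- t_test(w, "separate")
  n_ctrl_all <- sum(w$data$arm == 0L)
  n_ctrl_cc <- sum(w$data$arm == 0L & w$data$t >= w$t_entry)
  n_m <- sum(w$data$arm == 3L)
  expect_identical(tp$n_used, n_ctrl_all + n_m)
  expect_identical(ts$n_used, n_ctrl_cc + n_m)
  expect_lt(ts$n_used, tp$n_used)

  # identical groups give t = 0, one-sided p = 0.5
  eq <- data.frame(t = 1:20, arm = rep(c(0L, 1L), 10),
                   y = rep(c(1, 1, 2, 2), 5), period = 1L)
  eq$y <- ave(eq$y, eq$arm, FUN = function(v) v - mean(v) + 1)
  weq <- fake_window(eq, M = 1)
  feq <- t_test(weq, "pooled")
  expect_equal(feq$p_one_sided, 0.5, tolerance = 1e-12)

  few <- fake_window(data.frame(t = 1:3, arm = c(0L, 0L, 1L),
                                y = rnorm(3), period = 1L), M = 1)
  expect_error(t_test(few, "separate"), "2 observations")
})

test_that("fit_model dispatches every family", {
  des <- design_small()
  plan <- plan_recruitment(des)
  dat <- simulate_trial(des, seed = 23, plan = plan)
  w <- analysis_window(dat, plan, 2)
  labels <- c("fixed_period", "fixed_calendar", "spline_period_q2",
              "spline_calendar_q1", "mixed_iid_period",
              "mixed_ar1_calendar", "interaction_period", "ttest_pooled",
              "ttest_separate")
  for (lab in labels) {
    f <- suppressMessages(fit_model(w, parse_model_label(lab, clength = 50)))
    expect_s3_class(f, "ncct_fit")
    expect_true(is.finite(f$p_one_sided))
    expect_identical(f$reject, f$p_one_sided <= 0.025)
  }
})
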