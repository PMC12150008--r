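#' Specify a time-trend pattern
#'
#' The drift `f(j)` acting on the mean response of patients in arm `k`
#' (control = 0) as a function of the patient index `j`:
#' \describe{
#'   \item{linear}{`lambda_k * (j - 1) / (N - 1)`; slope `lambda_k` over the
#'     whole trial.}
#'   \item{stepwise}{`lambda_k * (i_j - 1)` where `i_j` is the number of
#'     experimental arms that had entered the trial when patient `j` was
#'     enrolled; the response jumps by `lambda_k` at every arm entry.}
#'   \item{inverted_u}{rises with slope `lambda_k` until patient `Np`, then
#'     falls with the same slope.}
#'   \item{seasonal}{`lambda_k * sin(psi * 2 * pi * (j - 1) / (N - 1))`;
#'     `psi` full cycles over the trial.}
#' }
#'
#' @param pattern One of `"linear"`, `"stepwise"`, `"inverted_u"`,
#'   `"seasonal"`.
#' @param lambda Per-arm trend strengths, length `K + 1` with the control
#'   first (`lambda[1]` = control), or a single value recycled to all arms.
#' @param N Total trial size the trend is scaled over.
#' @param Np Turning point for the inverted-U pattern (patient index,
#'   default the middle of the trial).
#' @param psi Number of seasonal cycles (default 1).
#' @return An object of class `ncct_trend`.
#' @export
trend_spec <- function(pattern = c("linear", "stepwise", "inverted_u",
                                   "seasonal"),
                       lambda, N, Np = NULL, psi = 1) {
  pattern <- match.arg(pattern)
  if (!is.numeric(lambda) || any(!is.finite(lambda)))
    stop("lambda must be finite numeric", call. = FALSE)
  if (!is.numeric(N) || length(N) != 1L || N < 2)
    stop("N must be a single value >= 2", call. = FALSE)
  if (is.null(Np)) Np <- round(N / 2)
  if (Np < 1 || Np > N)
    stop("Np must lie in 1..N", call. = FALSE)
  if (!is.numeric(psi) || length(psi) != 1L || psi <= 0)
    stop("psi must be > 0", call. = FALSE)
  structure(list(pattern = pattern, lambda = as.numeric(lambda),
                 N = as.integer(N), Np = as.integer(Np), psi = psi),
            class = "ncct_trend")
}

lambda_for_arm <- function(trend, arm) {
  lam <- trend$lambda
  if (length(lam) == 1L) return(rep(lam, length(arm)))
  lam[arm + 1L]
}

#' Evaluate the time-trend drift for given patients
#'
#' @param trend An `ncct_trend`.
#' @param j Patient indices (vectorised).
#' @param arm Arm index per patient (0 = control; recycled if scalar).
#' @param i_j Number of experimental arms entered when patient `j` enrolled;
#'   required for the stepwise pattern.
#' @return Drift values `f(j)`.
#' @export
trend_value <- function(trend, j, arm = 0L, i_j = NULL) {
  stopifnot(inherits(trend, "ncct_trend"))
  if (any(j < 1 | j > trend$N))
    stop("patient index outside 1..N", call. = FALSE)
  if (length(arm) == 1L) arm <- rep(arm, length(j))
  lam <- lambda_for_arm(trend, arm)
  N <- trend$N
  switch(trend$pattern,
    linear = lam * (j - 1) / (N - 1),
    seasonal = lam * sin(trend$psi * 2 * pi * (j - 1) / (N - 1)),
    inverted_u = {
      Np <- trend$Np
      up <- lam * (j - 1) / (N - 1)
      down <- -lam * (j - Np) / (N - 1) + lam * (Np - 1) / (N - 1)
      ifelse(j <= Np, up, down)
    },
    stepwise = {
      if (is.null(i_j))
        stop("i_j is required for the stepwise pattern", call. = FALSE)
      if (length(i_j) != length(j))
        stop("i_j must match j in length", call. = FALSE)
      lam * (i_j - 1)
    },
    stop("unknown trend pattern", call. = FALSE))
}

#' Permuted-block randomisation among active arms
#'
#' Block size is `2 * (number of active arms including control)`.  Every
#' complete block is a uniform random permutation of two copies of each
#' active arm; a trailing incomplete block takes the first entries of one
#' fresh permuted block (a without-replacement draw).
#'
#' @param active_arms Arm labels including the control (0).
#' @param n_patients Number of assignments to generate.
#' @return Integer vector of arm labels, length `n_patients`.
#' @export
block_randomize <- function(active_arms, n_patients) {
  active_arms <- as.integer(active_arms)
  if (!length(active_arms))
    stop("active_arms must be nonempty", call. = FALSE)
  if (n_patients < 1) return(integer(0))
  bsize <- 2L * length(active_arms)
  template <- rep(active_arms, each = 2L)
  n_full <- n_patients %/% bsize
  rem <- n_patients %% bsize
  out <- integer(0)
  if (n_full > 0L) {
    x <- rep(template, n_full)
    blk <- rep(seq_len(n_full), each = bsize)
    out <- x[order(blk, stats::runif(length(x)))]
  }
  if (rem > 0L)
    out <- c(out, template[order(stats::runif(bsize))][seq_len(rem)])
  out
}

#' Simulate one platform trial
#'
#' One patient per time unit (`t_j = j`), assigned by permuted-block
#' randomisation within each period of the deterministic recruitment plan.
#' The response is `y_j = eta0 + theta_k * I(k >= 1) + f(j) + eps_j` with
#' `eps_j ~ N(0, sigma^2)`; responses are observed at recruitment time.
#'
#' @param design An `ncct_design`.
#' @param eta0 Control mean response (default 0).
#' @param theta Treatment effects, length `K` (default all 0).
#' @param sigma Residual standard deviation (default 1).
#' @param trend Optional `ncct_trend`; its `N` must equal the planned total
#'   size.  `NULL` means no drift.
#' @param seed Optional integer seed; a fixed seed gives a byte-identical
#'   table on rerun.
#' @param plan Optional precomputed `ncct_plan` (avoids replanning in
#'   replicate loops).
#' @return A data frame with columns `j`, `t`, `arm`, `y`, `period`,
#'   `calendar` (one row per patient).
#' @export
simulate_trial <- function(design, eta0 = 0, theta = NULL, sigma = 1,
                           trend = NULL, seed = NULL, plan = NULL) {
  stopifnot(inherits(design, "ncct_design"))
  if (is.null(plan)) plan <- plan_recruitment(design)
  if (is.null(theta)) theta <- rep(0, design$K)
  if (length(theta) != design$K)
    stop("theta must have length K", call. = FALSE)
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (!is.null(trend) && trend$N != plan$N)
    stop("trend N (", trend$N, ") does not match planned N (", plan$N, ")",
         call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))

  N <- plan$N
  arm <- integer(N)
  for (s in seq_len(nrow(plan$periods))) {
    idx <- plan$periods$start[s]:plan$periods$end[s]
    arm[idx] <- block_randomize(c(0L, plan$period_active[[s]]), length(idx))
  }

  j <- seq_len(N)
  mu <- rep(eta0, N)
  trt <- arm > 0L
  mu[trt] <- mu[trt] + theta[arm[trt]]
  if (!is.null(trend)) {
    i_j <- NULL
    if (trend$pattern == "stepwise")
      i_j <- entered_count(design$schedule, j)
    mu <- mu + trend_value(trend, j, arm, i_j)
  }
  y <- mu + stats::rnorm(N, 0, sigma)

  pm <- assign_periods(plan)
  cal <- assign_calendar(N, design$clength)
  data.frame(j = j, t = j, arm = arm, y = y, period = pm$s, calendar = cal$c)
}

# number of experimental arms entered by the time patient j enrols
# (entries only: arms with d_k < j, i.e. d_k <= j - 1)
entered_count <- function(schedule, j) {
  findInterval(j - 1, schedule)
}
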