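#' Define a staggered-entry platform-trial design
#'
#' A platform trial recruits one patient per time unit into the currently
#' active arms (experimental arms plus the shared control).  Arm `k` opens
#' once `schedule[k]` patients have been recruited overall and closes as soon
#' as it has accumulated `n_arm` patients.  In the equidistant case the entry
#' schedule is `d * (k - 1)`.
#'
#' @param K Number of experimental arms (>= 1).
#' @param d Entry spacing: arm `k` enters after `d * (k - 1)` patients.
#'   Ignored when `schedule` is given.  `d = 0` gives a standard multi-arm
#'   trial in which all arms open at patient 1.
#' @param schedule Optional explicit cumulative entry counts `d_1..d_K`
#'   (first element must be 0, nondecreasing).
#' @param n_arm Patients required per experimental arm (default 250).
#' @param clength Calendar-time interval length in patients (default 100).
#' @return An object of class `ncct_design` with elements `K`, `schedule`,
#'   `n_arm`, `clength`.
#' @examples
#' platform_design(K = 4, d = 250, n_arm = 250)
#' @export
platform_design <- function(K, d = NULL, schedule = NULL, n_arm = 250,
                            clength = 100) {
  if (!is.numeric(K) || length(K) != 1L || K < 1 || K != round(K))
    stop("K must be a single integer >= 1", call. = FALSE)
  K <- as.integer(K)
  if (is.null(schedule)) {
    if (is.null(d))
      stop("either d or schedule must be supplied", call. = FALSE)
    if (!is.numeric(d) || length(d) != 1L || d < 0)
      stop("d must be a single nonnegative spacing", call. = FALSE)
    schedule <- d * (seq_len(K) - 1)
  }
  schedule <- as.numeric(schedule)
  if (length(schedule) != K)
    stop("schedule must have length K", call. = FALSE)
  if (schedule[1L] != 0)
    stop("schedule: d_1 must be 0", call. = FALSE)
  if (is.unsorted(schedule))
    stop("schedule must be nondecreasing", call. = FALSE)
  if (any(schedule != round(schedule)) || any(schedule < 0))
    stop("schedule entries must be nonnegative integers", call. = FALSE)
  if (!is.numeric(n_arm) || length(n_arm) != 1L || n_arm < 1 ||
      n_arm != round(n_arm))
    stop("n_arm must be a single integer >= 1", call. = FALSE)
  if (!is.numeric(clength) || length(clength) != 1L || clength < 1 ||
      clength != round(clength))
    stop("clength must be a single integer >= 1", call. = FALSE)
  structure(
    list(K = K, schedule = as.integer(round(schedule)),
         n_arm = as.integer(n_arm), clength = as.integer(clength)),
    class = "ncct_design")
}

#' @export
print.ncct_design <- function(x, ...) {
  cat("Platform-trial design:", x$K, "experimental arms + shared control\n")
  cat("  entry schedule (cumulative patients):",
      paste(x$schedule, collapse = ", "), "\n")
  cat("  patients per experimental arm:", x$n_arm, "\n")
  cat("  calendar interval length:", x$clength, "patients\n")
  invisible(x)
}

#' Deterministic recruitment plan for a platform design
#'
#' Runs the continuous equal-allocation flow: within each period every active
#' arm (including control) receives an equal share of the one-patient-per-time
#' unit recruitment; an arm exits once its continuous count reaches `n_arm`,
#' and every entry or exit starts a new period.  Exit times are computed
#' exactly on the continuous scale; the integer period boundary of an exit is
#' its ceiling and the total trial size `N` is the ceiling of the last exit.
#' Simultaneous events produce a single boundary.  The plan is seed-free.
#'
#' @param design An `ncct_design`.
#' @return An object of class `ncct_plan` with elements:
#'   `design`; `N` (total integer trial size); `arms` (data frame with entry
#'   time `d_k`, integer exit boundary, and continuous exit time per arm);
#'   `periods` (data frame: period, start/end patient index, active
#'   experimental arms as comma string, number of active experimental arms,
#'   continuous per-arm share); `counts_cont` (matrix of exact continuous
#'   per-arm counts per continuous-time segment, rows summing the trial flow;
#'   columns control + arms 1..K).
#' @examples
#' plan_recruitment(platform_design(K = 4, d = 250))$N  # 1528
#' @export
plan_recruitment <- function(design) {
  stopifnot(inherits(design, "ncct_design"))
  K <- design$K
  n_arm <- design$n_arm
  entry <- as.numeric(design$schedule)

  tol <- 1e-9
  t_now <- 0
  counts <- numeric(K)                 # continuous per-arm counts
  entered <- rep(FALSE, K)
  exited <- rep(FALSE, K)
  exit_cont <- rep(NA_real_, K)

  seg_start <- numeric(0)
  seg_end <- numeric(0)
  seg_counts <- NULL                   # rows: per-segment per-arm continuous counts
  seg_active <- list()

  events <- numeric(0)                 # continuous event times (boundaries)

  # open arms with entry 0 at t = 0
  entered[entry <= tol] <- TRUE

  guard <- 0L
  while (any(!exited) && guard < 10L * K + 100L) {
    guard <- guard + 1L
    active <- which(entered & !exited)
    n_act <- length(active)
    rate <- 1 / (n_act + 1)            # share per active arm (control same)

    next_entry <- suppressWarnings(min(entry[!entered]))
    if (n_act > 0L) {
      t_exit <- t_now + (n_arm - counts[active]) / rate
      next_exit <- min(t_exit)
    } else {
      next_exit <- Inf
    }
    t_next <- min(next_entry, next_exit)
    if (!is.finite(t_next))
      stop("infeasible design: recruitment can never complete", call. = FALSE)

    # record segment
    seg_start <- c(seg_start, t_now)
    seg_end <- c(seg_end, t_next)
    inc <- numeric(K + 1)
    inc[1L] <- (t_next - t_now) * rate          # control share
    if (n_act > 0L) inc[active + 1L] <- (t_next - t_now) * rate
    if (n_act == 0L) inc[1L] <- t_next - t_now  # control-only gap
    seg_counts <- rbind(seg_counts, inc)
    seg_active[[length(seg_active) + 1L]] <- active
    counts[active] <- counts[active] + (t_next - t_now) * rate

    # process all events at t_next (simultaneous events -> one boundary)
    newly_exited <- which(entered & !exited & counts >= n_arm - tol)
    exited[newly_exited] <- TRUE
    exit_cont[newly_exited] <- t_next
    entered[!entered & entry <= t_next + tol] <- TRUE
    events <- c(events, t_next)
    t_now <- t_next
  }
  if (any(!exited))
    stop("infeasible design: recruitment plan did not terminate", call. = FALSE)

  exit_int <- as.integer(ceiling(exit_cont - tol))
  N <- max(exit_int)

  # integer period boundaries: ceilings of all interior event times
  b <- sort(unique(as.integer(ceiling(events - tol))))
  b <- b[b > 0L & b < N]
  bounds <- c(0L, b, N)
  S <- length(bounds) - 1L

  period_active <- vector("list", S)
  for (s in seq_len(S)) {
    lo <- bounds[s]; hi <- bounds[s + 1L]
    period_active[[s]] <- which(entry <= lo & exit_int >= hi)
  }
  periods <- data.frame(
    period = seq_len(S),
    start = bounds[-length(bounds)] + 1L,
    end = bounds[-1L],
    active_arms = vapply(period_active, paste, "", collapse = ","),
    n_active = vapply(period_active, length, 0L)
  )
  periods$share <- (periods$end - periods$start + 1L) / (periods$n_active + 1L)

  counts_cont <- seg_counts
  dimnames(counts_cont) <- list(NULL, c("control", paste0("arm", seq_len(K))))

  structure(
    list(design = design, N = N,
         arms = data.frame(arm = seq_len(K), entry = as.integer(entry),
                           exit = exit_int, exit_cont = exit_cont),
         periods = periods, period_active = period_active,
         counts_cont = counts_cont,
         segments = data.frame(start = seg_start, end = seg_end)),
    class = "ncct_plan")
}

#' @export
print.ncct_plan <- function(x, ...) {
  cat("Recruitment plan: N =", x$N, "patients,",
      nrow(x$periods), "periods\n")
  print(x$periods[, c("period", "start", "end", "active_arms", "n_active")],
        row.names = FALSE)
  invisible(x)
}

#' Period labels for every patient in the plan
#'
#' @param plan An `ncct_plan`.
#' @return An object of class `ncct_period_map`: list with `boundaries`
#'   (interior integer boundaries), `s` (period index per patient 1..N), `S`.
#' @export
assign_periods <- function(plan) {
  stopifnot(inherits(plan, "ncct_plan"))
  bounds <- c(plan$periods$start[1L] - 1L, plan$periods$end)
  s <- findInterval(seq_len(plan$N), bounds, left.open = TRUE,
                    rightmost.closed = TRUE)
  structure(list(boundaries = plan$periods$end[-nrow(plan$periods)],
                 s = as.integer(s), S = nrow(plan$periods)),
            class = "ncct_period_map")
}

#' Calendar-time interval labels up to a cutoff
#'
#' Interval `c` covers patients `((c-1) * clength, c * clength]`; the last
#' interval is truncated at `cutoff`.
#'
#' @param cutoff Last patient index covered (>= 1).
#' @param clength Interval length in patients (>= 1).
#' @return An object of class `ncct_calendar_grid`: list with `clength`,
#'   `cutoff`, `c` (interval index per patient 1..cutoff), `C`.
#' @export
assign_calendar <- function(cutoff, clength) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff < 1 ||
      cutoff != round(cutoff))
    stop("cutoff must be a single integer >= 1", call. = FALSE)
  if (!is.numeric(clength) || length(clength) != 1L || clength < 1 ||
      clength != round(clength))
    stop("clength must be a single integer >= 1", call. = FALSE)
  cutoff <- as.integer(cutoff); clength <- as.integer(clength)
  cidx <- as.integer(ceiling(seq_len(cutoff) / clength))
  structure(list(clength = clength, cutoff = cutoff, c = cidx,
                 C = as.integer(ceiling(cutoff / clength))),
            class = "ncct_calendar_grid")
}

#' Analysis window for an evaluated arm
#'
#' Selects all data observed up to the evaluated arm's exit time
#' `t_M^exit` (inclusive), i.e. the set `D_M`.  Data from arms still
#' recruiting at that time are included.
#'
#' @param data A trial data frame as produced by [simulate_trial()] (columns
#'   `j`, `t`, `arm`, `y`; `period` recomputed if missing).
#' @param plan The `ncct_plan` the data were generated under.
#' @param M Evaluated experimental arm index.
#' @return An object of class `ncct_window`: list with `data` (the subset,
#'   with period labels), `M`, `t_entry`, `t_exit`, `K_M` (experimental arms
#'   with data in the window), `S_M`, `clength` (design default), `plan`.
#' @export
analysis_window <- function(data, plan, M) {
  stopifnot(inherits(plan, "ncct_plan"))
  if (!is.numeric(M) || length(M) != 1L || !(M %in% plan$arms$arm))
    stop("M must be an experimental arm present in the plan", call. = FALSE)
  M <- as.integer(M)
  req <- c("t", "arm", "y")
  if (!all(req %in% names(data)))
    stop("data must contain columns t, arm, y", call. = FALSE)
  t_exit <- plan$arms$exit[plan$arms$arm == M]
  t_entry <- plan$arms$entry[plan$arms$arm == M] + 1L
  sel <- data$t <= t_exit
  dat <- data[sel, , drop = FALSE]
  if (!nrow(dat))
    stop("analysis window is empty", call. = FALSE)
  if (is.null(dat$period)) {
    pm <- assign_periods(plan)
    dat$period <- pm$s[dat$t]
  }
  if (!any(dat$arm == 0L))
    stop("analysis window contains no control patients", call. = FALSE)
  if (!any(dat$arm == M))
    stop("analysis window contains no patients in arm M", call. = FALSE)
  K_M <- sort(unique(dat$arm[dat$arm > 0L]))
  structure(
    list(data = dat, M = M, t_entry = as.integer(t_entry),
         t_exit = as.integer(t_exit), K_M = as.integer(K_M),
         S_M = max(dat$period), clength = plan$design$clength, plan = plan),
    class = "ncct_window")
}

#' @export
print.ncct_window <- function(x, ...) {
  cat("Analysis window for arm", x$M, ": patients 1..", x$t_exit,
      " (", nrow(x$data), " obs)\n", sep = "")
  cat("  arms with data:", paste(x$K_M, collapse = ", "),
      "| periods:", x$S_M, "\n")
  invisible(x)
}

#' Export a recruitment plan as delimited text
#'
#' @param plan An `ncct_plan`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_plan <- function(plan, path) {
  stopifnot(inherits(plan, "ncct_plan"))
  utils::write.csv(plan$periods, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
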