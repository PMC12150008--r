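# Profiled-REML engine for linear mixed models with a single grouped random
# effect: y = X beta + Z u + eps, cov(u) = sigma2_u * R(rho), with R either
# the identity ("iid") or AR(1) (rho^|s - s'|) across ordered levels.
# Z is an indicator matrix built from an integer cell index per observation
# (NA = observation carries no random effect, its Z row is zero).
#
# With gamma = sigma2_u / sigma2 and A = gamma * R:
#   Sigma = I + Z A Z',  Sigma^{-1} = I - Z (I + A W)^{-1} A Z'  (W = Z'Z)
#   log|Sigma| = log|I_m + A W|
# so after the sufficient statistics X'X, X'y, y'y, Z'X, Z'y, W are formed,
# each objective evaluation costs O(m^3 + m^2 p) independent of n.

reml_suffstat <- function(y, X, cell, m) {
  ok <- !is.na(cell)
  ZtX <- matrix(0, m, ncol(X))
  Zty <- numeric(m)
  W <- numeric(m)
  if (any(ok)) {
    ZtX[sort(unique(cell[ok])), ] <-
      rowsum(X[ok, , drop = FALSE], cell[ok])
    Zty[sort(unique(cell[ok]))] <- rowsum(y[ok], cell[ok])
    tab <- tabulate(cell[ok], nbins = m)
    W <- as.numeric(tab)
  }
  list(n = length(y), p = ncol(X), XtX = crossprod(X), Xty = crossprod(X, y),
       yty = sum(y * y), ZtX = ZtX, Zty = Zty, W = W, m = m,
       xnames = colnames(X))
}

ar1_cor <- function(m, rho) rho^abs(outer(seq_len(m), seq_len(m), "-"))

# profiled negative REML objective and, on request, the full solution
reml_eval <- function(ss, gamma, rho, cov_type, full = FALSE) {
  m <- ss$m
  R <- if (cov_type == "ar1") ar1_cor(m, rho) else diag(m)
  A <- gamma * R
  Mmat <- diag(m) + A * rep(ss$W, each = m)      # I + A W  (W diagonal)
  if (rcond(Mmat) < 1e-12) return(if (full) NULL else Inf)
  ld <- determinant(Mmat, logarithm = TRUE)
  if (ld$sign <= 0) return(if (full) NULL else Inf)
  B <- solve(Mmat, A)                             # (I + A W)^{-1} A, symmetric
  B <- (B + t(B)) / 2
  XtSiX <- ss$XtX - crossprod(ss$ZtX, B %*% ss$ZtX)
  XtSiy <- ss$Xty - crossprod(ss$ZtX, B %*% ss$Zty)
  ytSiy <- ss$yty - as.numeric(crossprod(ss$Zty, B %*% ss$Zty))
  ch <- tryCatch(chol(XtSiX), error = function(e) NULL)
  if (is.null(ch)) return(if (full) NULL else Inf)
  beta <- backsolve(ch, forwardsolve(t(ch), XtSiy))
  rss <- ytSiy - as.numeric(crossprod(XtSiy, beta))
  dfres <- ss$n - ss$p
  if (rss <= 0) return(if (full) NULL else Inf)
  obj <- 0.5 * (dfres * log(rss) + as.numeric(ld$modulus) +
                  2 * sum(log(diag(ch))))
  if (!full) return(obj)
  sigma2 <- rss / dfres
  vcov <- chol2inv(ch) * sigma2
  loglik <- -0.5 * (dfres * (log(2 * pi * sigma2) + 1) +
                      as.numeric(ld$modulus) + 2 * sum(log(diag(ch))))
  beta <- as.numeric(beta)
  names(beta) <- ss$xnames
  list(beta = beta, se = sqrt(pmax(diag(vcov), 0)), sigma2 = sigma2,
       sigma2_u = gamma * sigma2, gamma = gamma, rho = rho,
       loglik = loglik, objective = obj, vcov = vcov)
}

# Fit by REML.  cov_type "iid" optimises over log(gamma) only (Brent with
# restarts); "ar1" optimises (log gamma, atanh rho) by Nelder-Mead from
# several starts.  rho is mapped to (-1, 1) by tanh.
reml_fit <- function(y, X, cell, m, cov_type = c("iid", "ar1"),
                     rho_fixed = NULL) {
  cov_type <- match.arg(cov_type)
  ss <- reml_suffstat(y, X, cell, m)
  converged <- TRUE

  if (cov_type == "iid" || !is.null(rho_fixed)) {
    rho <- if (is.null(rho_fixed)) 0 else rho_fixed
    f <- function(lg) reml_eval(ss, exp(lg), rho, cov_type)
    opts <- lapply(c(-4, 0, 4), function(st)
      stats::optim(st, f, method = "Brent", lower = -25, upper = 12,
                   control = list(reltol = 1e-12)))
    best <- opts[[which.min(vapply(opts, `[[`, 0, "value"))]]
    # compare against the gamma -> 0 boundary (plain OLS)
    if (f(-25) <= best$value + 1e-10) best$par <- -25
    gamma <- exp(best$par)
    sol <- reml_eval(ss, gamma, rho, cov_type, full = TRUE)
  } else {
    # The REML surface has a flat ridge as rho -> 1 with gamma -> Inf (the
    # AR(1) effect degenerates into the intercept direction, to which REML
    # is invariant); estimates are stable along the ridge but numerics are
    # not, so the search is confined to log(gamma) <= 8, |rho| <= 0.9999.
    f <- function(par) {
      if (par[1L] > 8 || abs(tanh(par[2L])) > 0.9999) return(Inf)
      reml_eval(ss, exp(par[1L]), tanh(par[2L]), "ar1")
    }
    starts <- list(c(0, 0), c(-3, 1), c(3, -1), c(-6, 0.5))
    opts <- lapply(starts, function(st)
      tryCatch(stats::optim(st, f, method = "Nelder-Mead",
                            control = list(reltol = 1e-10, maxit = 2000)),
               error = function(e) NULL))
    opts <- Filter(Negate(is.null), opts)
    if (!length(opts)) {
      converged <- FALSE
      sol <- reml_eval(ss, 1e-8, 0, "ar1", full = TRUE)
    } else {
      vals <- vapply(opts, `[[`, 0, "value")
      best <- opts[[which.min(vals)]]
      if (best$convergence != 0) converged <- FALSE
      sol <- reml_eval(ss, exp(best$par[1L]), tanh(best$par[2L]), "ar1",
                       full = TRUE)
    }
  }
  if (is.null(sol)) {
    converged <- FALSE
    sol <- reml_eval(ss, 1e-10, 0, cov_type, full = TRUE)
    if (is.null(sol))
      stop("mixed-model fixed-effect design is rank deficient; cannot fit",
           call. = FALSE)
  }
  sol$converged <- converged
  sol$n <- ss$n
  sol
}
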