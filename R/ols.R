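# Internal ordinary-least-squares engine with pivoted QR and explicit
# aliasing bookkeeping.  All fixed-effect and spline fits go through here;
# the test suite checks it against a normal-equations oracle.

ols_engine <- function(X, y) {
  n <- nrow(X)
  p <- ncol(X)
  fit <- stats::lm.fit(X, y)
  r <- fit$rank
  piv <- fit$qr$pivot
  used <- piv[seq_len(r)]
  dropped <- if (r < p) colnames(X)[piv[seq.int(r + 1L, p)]] else character(0)

  rss <- sum(fit$residuals^2)
  df <- n - r
  if (df <= 0) stop("no residual degrees of freedom", call. = FALSE)
  sigma2 <- rss / df

  R <- fit$qr$qr[seq_len(r), seq_len(r), drop = FALSE]
  R[lower.tri(R)] <- 0
  XtXinv <- chol2inv(R)

  coef <- fit$coefficients            # NA for aliased columns
  se <- rep(NA_real_, p)
  names(se) <- colnames(X)
  se[used] <- sqrt(pmax(diag(XtXinv), 0) * sigma2)

  list(coef = coef, se = se, sigma2 = sigma2, df = df, rank = r,
       dropped = dropped, rss = rss, fitted = fit$fitted.values)
}

# one-sided upper-tail p for H0: theta <= 0 using the t distribution
one_sided_p_t <- function(est, se, df) stats::pt(est / se, df, lower.tail = FALSE)

# arm indicator columns for experimental arms in K_M
arm_columns <- function(arm, K_M) {
  X <- vapply(K_M, function(k) as.numeric(arm == k), numeric(length(arm)))
  colnames(X) <- paste0("theta_", K_M)
  X
}

# indicator columns for time levels 2..max (levels relabelled consecutively)
time_columns <- function(lev, prefix) {
  ulev <- sort(unique(lev))
  if (length(ulev) < 2L) return(NULL)
  ulev <- ulev[-1L]
  X <- vapply(ulev, function(l) as.numeric(lev == l), numeric(length(lev)))
  colnames(X) <- paste0(prefix, ulev)
  X
}
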