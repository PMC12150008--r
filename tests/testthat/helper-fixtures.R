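# Shared fixtures: small designs and a hand-built window constructor used
# by the aliasing tests.

design_k4 <- function() platform_design(K = 4, d = 250, n_arm = 250,
                                        clength = 100)
design_k10 <- function(d = 500) platform_design(K = 10, d = d, n_arm = 250,
                                                clength = 450)
design_small <- function() platform_design(K = 2, d = 100, n_arm = 100,
                                           clength = 50)

# normal-equations least-squares oracle (independent of ols_engine's QR path)
ne_oracle <- function(X, y) solve(crossprod(X), crossprod(X, y))

# window object built directly from a data frame (unit tests of degenerate
# layouts that the planner cannot produce)
fake_window <- function(data, M, plan = NULL) {
  structure(list(data = data, M = M, t_entry = 1L, t_exit = max(data$t),
                 K_M = sort(unique(data$arm[data$arm > 0L])),
                 S_M = max(data$period), clength = 100L, plan = plan),
            class = "ncct_window")
}

# dense-matrix REML objective: the independent oracle for the Woodbury
# engine.  Builds Sigma explicitly and evaluates the profiled criterion.
dense_reml_obj <- function(y, X, cell, m, gamma, rho, cov_type) {
  R <- if (cov_type == "ar1") rho^abs(outer(seq_len(m), seq_len(m), "-"))
       else diag(m)
  Z <- matrix(0, length(y), m)
  ok <- !is.na(cell)
  Z[cbind(which(ok), cell[ok])] <- 1
  Sigma <- diag(length(y)) + Z %*% (gamma * R) %*% t(Z)
  Si <- solve(Sigma)
  XtSiX <- t(X) %*% Si %*% X
  beta <- solve(XtSiX, t(X) %*% Si %*% y)
  r <- y - X %*% beta
  rss <- as.numeric(t(r) %*% Si %*% r)
  0.5 * ((length(y) - ncol(X)) * log(rss) +
           determinant(Sigma)$modulus +
           determinant(XtSiX)$modulus)
}
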