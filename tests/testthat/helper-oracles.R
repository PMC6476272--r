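# Independent oracles used across tests. These deliberately share no code
# with the package implementation: brute-force grids, closed forms and
# hand-rolled linear algebra only.

# Brute-force profile restricted-likelihood grid search for tau^2 in the
# random-effects meta-regression model.
oracle_reml_grid <- function(y, se, X, grid = seq(0, 0.5, by = 1e-4)) {
  v <- se^2
  ll <- vapply(grid, function(t2) {
    W <- diag(1 / (v + t2))
    XtWX <- t(X) %*% W %*% X
    gam <- solve(XtWX, t(X) %*% W %*% y)
    r <- y - X %*% gam
    as.numeric(-0.5 * (sum(log(v + t2)) + log(det(XtWX)) + t(r) %*% W %*% r))
  }, numeric(1))
  best <- grid[which.max(ll)]
  W <- diag(1 / (v + best))
  gam <- solve(t(X) %*% W %*% X, t(X) %*% W %*% y)
  list(tau2 = best, gamma = as.numeric(gam))
}

# Normal-equations solution for OLS with analytic Wald SEs.
oracle_ols <- function(y, X) {
  XtX <- t(X) %*% X
  b <- solve(XtX, t(X) %*% y)
  r <- y - X %*% b
  df <- length(y) - ncol(X)
  s2 <- sum(r^2) / df
  se <- unname(sqrt(diag(s2 * solve(XtX))))
  list(coef = as.numeric(b), se = se, df = df)
}

# Closed-form 2x2 log odds ratio and SE.
oracle_logor_2x2 <- function(a, b, c, d) {
  # a = exposed cases, b = exposed controls, c = unexposed cases,
  # d = unexposed controls
  list(log_or = log((a * d) / (b * c)),
       se = sqrt(1 / a + 1 / b + 1 / c + 1 / d))
}

# Hand trapezoid over a sampled grid.
oracle_trapezoid <- function(t, y) {
  sum(diff(t) * (y[-length(y)] + y[-1]) / 2)
}

# Closed-form AUC of the saturating exponential baseline + A(1 - e^{-kt})
# integrated over [0, T] after baseline subtraction (continuous form; the
# sampled trapezoid converges to this as the grid refines).
oracle_sat_exp_auc <- function(A, k, T) {
  A * (T - (1 - exp(-k * T)) / k)
}

# Noiseless trace builder used by several assay tests.
make_trace <- function(time_s, signal, variant_id = "V1", pathway = "cAMP",
                       condition = "variant", replicate = 1) {
  data.frame(variant_id = variant_id, pathway = pathway, condition = condition,
             replicate = replicate, time_s = time_s, signal = signal,
             stringsAsFactors = FALSE)
}
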