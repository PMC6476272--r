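#' Fixed-effect inverse-variance meta-analysis
#'
#' Pools per-variant association estimates with weights `1/se^2`, and reports
#' Cochran's Q heterogeneity statistic, its chi-square p-value on k-1 degrees
#' of freedom, and I^2.
#'
#' @param beta effect estimates.
#' @param se standard errors (> 0).
#' @return list: `pooled_effect`, `se`, `p`, `q_statistic`, `q_df`,
#'   `p_heterogeneity`, `i2_pct`, `k`.
#' @export
fixed_effect_meta <- function(beta, se) {
  if (length(beta) < 1) stop("at least one estimate is required")
  if (length(beta) != length(se) || any(se <= 0)) stop("invalid standard errors")
  w <- 1 / se^2
  pooled <- sum(w * beta) / sum(w)
  se_pooled <- 1 / sqrt(sum(w))
  p <- floor_p(2 * stats::pnorm(-abs(pooled / se_pooled)))
  k <- length(beta)
  if (k == 1) {
    return(list(pooled_effect = pooled, se = se_pooled, p = p,
                q_statistic = 0, q_df = 0, p_heterogeneity = NA_real_,
                i2_pct = 0, k = 1L))
  }
  q <- sum(w * (beta - pooled)^2)
  df <- k - 1
  p_het <- stats::pchisq(q, df, lower.tail = FALSE)
  i2 <- 100 * max(0, (q - df) / q)
  list(pooled_effect = pooled, se = se_pooled, p = p, q_statistic = q,
       q_df = df, p_heterogeneity = p_het, i2_pct = i2, k = as.integer(k))
}

#' Heterogeneity p-value between two estimates
#'
#' Two-estimate Cochran Q, equivalently a z test on the difference:
#' `z = (a - b) / sqrt(se_a^2 + se_b^2)`, two-sided.
#'
#' @param effect_a,se_a first estimate and SE.
#' @param effect_b,se_b second estimate and SE.
#' @return two-sided p-value.
#' @export
compare_two_estimates <- function(effect_a, se_a, effect_b, se_b) {
  if (se_a <= 0 || se_b <= 0) stop("standard errors must be positive")
  z <- (effect_a - effect_b) / sqrt(se_a^2 + se_b^2)
  2 * stats::pnorm(-abs(z))
}

# Restricted log-likelihood of tau2 for the meta-regression model
# y = X gamma + u + e, u ~ N(0, tau2 I), e ~ N(0, diag(v)).
reml_loglik <- function(tau2, y, X, v) {
  w <- 1 / (v + tau2)
  XtWX <- crossprod(X * w, X)
  cf <- solve(XtWX, crossprod(X * w, y))
  r <- y - X %*% cf
  -0.5 * (sum(log(v + tau2)) + determinant(XtWX, logarithm = TRUE)$modulus[1] +
            sum(w * r^2))
}

# REML estimate of tau2 by Fisher scoring with step-halving; tau2 truncated
# at zero every iteration.
reml_tau2 <- function(y, X, v, tol = 1e-10, maxit = 100) {
  k <- length(y)
  p <- ncol(X)
  # method-of-moments start
  w0 <- 1 / v
  XtWX0 <- crossprod(X * w0, X)
  cf0 <- solve(XtWX0, crossprod(X * w0, y))
  qe <- sum(w0 * (y - X %*% cf0)^2)
  denom <- sum(w0) - sum(diag(solve(XtWX0, crossprod(X * w0^2, X))))
  tau2 <- max(0, (qe - (k - p)) / denom)

  ll <- reml_loglik(tau2, y, X, v)
  for (it in seq_len(maxit)) {
    w <- 1 / (v + tau2)
    WX <- X * w
    XtWX_inv <- solve(crossprod(WX, X))
    # P y and diagonal pieces of P = W - WX (X'WX)^{-1} X'W
    H <- WX %*% XtWX_inv %*% t(WX)
    Pm <- diag(w) - H
    Py <- Pm %*% y
    score <- -0.5 * (sum(diag(Pm)) - sum(Py^2))
    info <- 0.5 * sum(Pm * Pm)
    step <- as.numeric(score) / info
    new_tau2 <- max(0, tau2 + step)
    # step-halving if the restricted likelihood does not improve
    new_ll <- reml_loglik(new_tau2, y, X, v)
    halvings <- 0
    while (new_ll < ll - 1e-12 && halvings < 30) {
      step <- step / 2
      new_tau2 <- max(0, tau2 + step)
      new_ll <- reml_loglik(new_tau2, y, X, v)
      halvings <- halvings + 1
    }
    delta <- abs(new_tau2 - tau2)
    tau2 <- new_tau2
    ll <- new_ll
    if (delta < tol) return(list(tau2 = tau2, iterations = it, converged = TRUE))
  }
  stop(sprintf("REML for tau^2 did not converge after %d iterations", maxit))
}

# DerSimonian-Laird method-of-moments tau2 (meta-regression generalization)
dl_tau2 <- function(y, X, v) {
  k <- length(y)
  p <- ncol(X)
  w0 <- 1 / v
  XtWX0 <- crossprod(X * w0, X)
  cf0 <- solve(XtWX0, crossprod(X * w0, y))
  qe <- sum(w0 * (y - X %*% cf0)^2)
  denom <- sum(w0) - sum(diag(solve(XtWX0, crossprod(X * w0^2, X))))
  list(tau2 = max(0, (qe - (k - p)) / denom), iterations = 1L, converged = TRUE)
}

#' Random-effects meta-regression of association estimates on functional
#' moderators
#'
#' Fits `beta_v = gamma0 + gamma' x_v + u_v + e_v` with known sampling
#' variances `e_v ~ N(0, se_v^2)` and between-variant heterogeneity
#' `u_v ~ N(0, tau^2)` estimated by REML (Fisher scoring, converged when the
#' change in tau^2 falls below 1e-10; DerSimonian-Laird available as an
#' alternative). Coefficients are weighted least squares with weights
#' `1/(se_v^2 + tau2)` and Wald z inference (Knapp-Hartung t inference
#' optional). The percent of between-variant variance explained is the
#' reduction in tau^2 relative to the intercept-only model on the same rows,
#' truncated to [0, 100].
#'
#' @param beta per-variant effect estimates (kg/m^2 per allele, or log OR).
#' @param se per-variant standard errors (> 0).
#' @param moderators numeric vector, matrix or data frame of moderator
#'   columns; NULL for an intercept-only random-effects model.
#' @param method `"reml"` (default) or `"dl"`.
#' @param knapp_hartung use Knapp-Hartung t inference for the coefficients.
#' @return object of class `metareg_fit`: `gamma` (named coefficients),
#'   `se_gamma`, `p_gamma`, `ci_gamma` (matrix), `tau2`, `tau2_null`,
#'   `r2_pct`, `k`, `method`, `iterations`.
#' @export
random_effects_metareg <- function(beta, se, moderators = NULL,
                                   method = c("reml", "dl"),
                                   knapp_hartung = FALSE) {
  method <- match.arg(method)
  if (any(se <= 0)) stop("standard errors must be positive")
  if (any(!is.finite(beta))) stop("effect estimates must be finite")
  y <- as.numeric(beta)
  k <- length(y)
  if (is.null(moderators)) {
    X <- matrix(1, nrow = k, ncol = 1, dimnames = list(NULL, "intercept"))
  } else {
    M <- as.matrix(as.data.frame(moderators))
    if (any(!is.finite(M))) stop("moderators must be finite")
    if (is.null(colnames(M)) || any(colnames(M) == "")) {
      colnames(M) <- paste0("x", seq_len(ncol(M)))
    }
    X <- cbind(intercept = 1, M)
  }
  p <- ncol(X)
  if (k < p + 1) stop("too few rows: need at least number of moderators + 2 variants")
  v <- se^2

  est <- if (method == "reml") reml_tau2(y, X, v) else dl_tau2(y, X, v)
  tau2 <- est$tau2
  w <- 1 / (v + tau2)
  XtWX_inv <- solve(crossprod(X * w, X))
  gamma <- as.numeric(XtWX_inv %*% crossprod(X * w, y))
  names(gamma) <- colnames(X)
  vg <- XtWX_inv
  if (knapp_hartung) {
    r <- y - X %*% gamma
    s2 <- sum(w * r^2) / (k - p)
    vg <- vg * max(s2, .Machine$double.eps)
    se_g <- sqrt(diag(vg))
    p_g <- floor_p(2 * stats::pt(-abs(gamma / se_g), df = k - p))
    crit <- stats::qt(0.975, df = k - p)
  } else {
    se_g <- sqrt(diag(vg))
    p_g <- floor_p(2 * stats::pnorm(-abs(gamma / se_g)))
    crit <- stats::qnorm(0.975)
  }
  ci <- cbind(lo = gamma - crit * se_g, hi = gamma + crit * se_g)

  if (p > 1) {
    X0 <- X[, 1, drop = FALSE]
    est0 <- if (method == "reml") reml_tau2(y, X0, v) else dl_tau2(y, X0, v)
    tau2_null <- est0$tau2
    r2 <- if (tau2_null > 0) {
      min(100, 100 * max(0, (tau2_null - tau2) / tau2_null))
    } else {
      0
    }
  } else {
    tau2_null <- tau2
    r2 <- NA_real_
  }

  structure(list(gamma = gamma, se_gamma = se_g, p_gamma = p_g,
                 ci_gamma = ci, tau2 = tau2, tau2_null = tau2_null,
                 r2_pct = r2, k = as.integer(k), method = method,
                 iterations = est$iterations,
                 knapp_hartung = knapp_hartung),
            class = "metareg_fit")
}

#' @export
print.metareg_fit <- function(x, ...) {
  cat(sprintf("Random-effects meta-regression (%s), k = %d\n",
              toupper(x$method), x$k))
  tab <- data.frame(estimate = x$gamma, se = x$se_gamma, p = x$p_gamma,
                    ci_lo = x$ci_gamma[, "lo"], ci_hi = x$ci_gamma[, "hi"])
  print(tab, digits = 4)
  cat(sprintf("tau^2 = %.5f (intercept-only tau^2 = %.5f)\n",
              x$tau2, x$tau2_null))
  if (!is.na(x$r2_pct)) {
    cat(sprintf("between-variant variance explained: %.1f%%\n", x$r2_pct))
  }
  invisible(x)
}

#' Moderator value from a functional profile
#'
#' The continuous moderator is the natural log of relative E_max (fraction of
#' wild type). Truncating variants, which are not assayed, are substituted at
#' a fixed fraction of wild type (default 1%). Categorical mode returns the
#' pathway's functional class instead, for the sensitivity analysis using
#' category rather than the experimental value.
#'
#' @param emax_pct measured E_max as % WT (NA for truncating variants).
#' @param is_truncating logical flag.
#' @param truncating_substitution fraction of wild type assumed for
#'   truncating variants (default 0.01).
#' @param pathway_class the LoF/WT-like/GoF call, used in categorical mode.
#' @param categorical return the class label instead of ln E_max.
#' @return `ln(E_max fraction)` or, in categorical mode, the class label.
#' @export
moderator_from_profile <- function(emax_pct, is_truncating = FALSE,
                                   truncating_substitution = 0.01,
                                   pathway_class = NULL,
                                   categorical = FALSE) {
  if (categorical) {
    if (is.null(pathway_class)) stop("categorical mode needs the pathway class")
    return(pathway_class)
  }
  n <- max(length(emax_pct), length(is_truncating))
  emax_pct <- rep_len(emax_pct, n)
  is_truncating <- rep_len(is_truncating, n)
  x <- numeric(n)
  for (i in seq_len(n)) {
    if (is_truncating[i]) {
      x[i] <- log(truncating_substitution)
    } else {
      if (is.na(emax_pct[i]) || emax_pct[i] <= 0) {
        stop("non-positive or missing E_max for a non-truncating variant")
      }
      x[i] <- log(emax_pct[i] / 100)
    }
  }
  x
}

#' Leave-one-out meta-regression
#'
#' Refits the meta-regression excluding one variant at a time.
#'
#' @inheritParams random_effects_metareg
#' @param labels variant labels for the rows.
#' @return data frame with one row per excluded variant: `excluded`,
#'   the moderator coefficient (`gamma1`), its `se` and `p`, `tau2`,
#'   `r2_pct`.
#' @export
leave_one_out_metareg <- function(beta, se, moderators, labels = NULL,
                                  method = "reml") {
  k <- length(beta)
  if (is.null(labels)) labels <- paste0("row", seq_len(k))
  M <- as.matrix(as.data.frame(moderators))
  rows <- lapply(seq_len(k), function(i) {
    f <- random_effects_metareg(beta[-i], se[-i], M[-i, , drop = FALSE],
                                method = method)
    data.frame(excluded = labels[i], gamma1 = unname(f$gamma[2]),
               se = unname(f$se_gamma[2]), p = unname(f$p_gamma[2]),
               tau2 = f$tau2, r2_pct = f$r2_pct, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Monte-Carlo recovery of between-variant variance explained
#'
#' Simulates replicate panels of per-variant association rows directly from
#' the meta-regression generating model — moderator `x_v ~ N(0, 1)`, true
#' effects `beta_v = gamma0 + gamma1 x_v + u_v` with `u_v ~ N(0, tau2)`,
#' observed estimates `beta_v + e_v` with `e_v ~ N(0, se_v^2)` and `se_v ~
#' U(se_range)` — and fits the random-effects meta-regression to each,
#' recording the percent reduction in tau^2 versus the intercept-only model.
#' Under the defaults the moderator-attributable share of between-variant
#' variance is `gamma1^2 / (gamma1^2 + tau2)` = 88%.
#'
#' @param n_replicates number of replicate panels.
#' @param k variants per panel.
#' @param gamma0,gamma1,tau2 generating parameters.
#' @param se_range range of the uniform sampling-SE draw.
#' @param seed seed for the whole experiment.
#' @param method tau^2 estimator passed to [random_effects_metareg()].
#' @return numeric vector of per-replicate R^2 percentages.
#' @export
recover_variance_explained <- function(n_replicates = 500, k = 49,
                                       gamma0 = 0, gamma1 = -0.55,
                                       tau2 = 0.04125,
                                       se_range = c(0.05, 0.15),
                                       seed = 1, method = "reml") {
  set.seed(as.integer(seed %% 2147483647))
  vapply(seq_len(n_replicates), function(r) {
    x <- stats::rnorm(k)
    u <- stats::rnorm(k, 0, sqrt(tau2))
    se_v <- stats::runif(k, se_range[1], se_range[2])
    y <- gamma0 + gamma1 * x + u + stats::rnorm(k, 0, se_v)
    fit <- random_effects_metareg(y, se_v, data.frame(x = x), method = method)
    fit$r2_pct
  }, numeric(1))
}

#' Filter meta-regression input rows
#'
#' Applies the sensitivity-analysis row filters: minimum allele frequency,
#' minimum cluster-plot quality score, functional-category subset, rare-only
#' (frequency below 0.5%), and inclusion/exclusion of truncating variants.
#' One message per rule reports how many rows it removed.
#'
#' @param rows data frame with (as needed per rule) columns `allele_freq`,
#'   `quality_score`, `category`, `is_truncating`.
#' @param min_freq drop rows with allele frequency below this fraction (the
#'   ultra-rare exclusion uses 1e-5, i.e. 0.001%).
#' @param min_quality drop rows with quality score below this (0-4 scale).
#' @param categories keep only these functional categories.
#' @param rare_only keep only rows with allele frequency below 0.5%.
#' @param include_truncating if FALSE, drop truncating rows.
#' @return the filtered data frame; an empty result is an error.
#' @export
filter_rows <- function(rows, min_freq = NULL, min_quality = NULL,
                        categories = NULL, rare_only = FALSE,
                        include_truncating = TRUE) {
  apply_rule <- function(d, keep, what) {
    removed <- sum(!keep)
    message(sprintf("filter %s: removed %d of %d rows", what, removed, nrow(d)))
    d[keep, , drop = FALSE]
  }
  if (!is.null(min_freq)) {
    rows <- apply_rule(rows, rows$allele_freq >= min_freq,
                       sprintf("allele frequency >= %g", min_freq))
  }
  if (!is.null(min_quality)) {
    rows <- apply_rule(rows, rows$quality_score >= min_quality,
                       sprintf("quality score >= %d", min_quality))
  }
  if (!is.null(categories)) {
    rows <- apply_rule(rows, rows$category %in% categories,
                       paste("category in", paste(categories, collapse = "/")))
  }
  if (rare_only) {
    rows <- apply_rule(rows, rows$allele_freq < 0.005, "rare only (< 0.5%)")
  }
  if (!include_truncating) {
    rows <- apply_rule(rows, !rows$is_truncating, "exclude truncating")
  }
  if (nrow(rows) == 0) stop("all rows removed by filters")
  rows
}
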