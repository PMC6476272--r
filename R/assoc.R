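#' Derive case/control status for BMI-threshold obesity phenotypes
#'
#' Obesity is BMI >= 30 kg/m^2 and severe obesity BMI >= 40 kg/m^2; for both,
#' controls are individuals with BMI < 25 kg/m^2 and individuals in between
#' are excluded from that case-control analysis.
#'
#' @param bmi numeric vector of BMI values (kg/m^2), all positive.
#' @return data frame with columns `obesity` and `severe_obesity`, each a
#'   factor with levels `case`, `control`, `excluded`.
#' @export
derive_obesity_phenotypes <- function(bmi) {
  if (any(bmi <= 0)) stop("BMI must be positive")
  lv <- c("case", "control", "excluded")
  flag <- function(threshold) {
    factor(ifelse(bmi >= threshold, "case",
                  ifelse(bmi < 25, "control", "excluded")), levels = lv)
  }
  data.frame(obesity = flag(30), severe_obesity = flag(40))
}

check_design <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("collinear design: column(s) ", paste(bad, collapse = ", "),
         " are linearly dependent")
  }
}

#' Linear association of an outcome with genotype dose
#'
#' Ordinary least squares of `y` on allele count with an intercept and the
#' supplied covariates. Inference is Wald, on residual degrees of freedom.
#'
#' @param y continuous outcome.
#' @param dose per-sample allele count (0/1/2) or other exposure.
#' @param covariates data frame (or NULL) of adjustment covariates.
#' @param unit_id,outcome labels carried into the result row.
#' @return one-row data frame: `unit_id`, `outcome`, `effect`, `se`, `p`, `n`,
#'   `n_cases` (NA for continuous outcomes).
#' @export
fit_linear_assoc <- function(y, dose, covariates = NULL, unit_id = "exposure",
                             outcome = "y") {
  X <- cbind(`(Intercept)` = 1, dose = dose)
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0) {
    X <- cbind(X, as.matrix(as.data.frame(covariates)))
  }
  n <- length(y)
  if (n <= ncol(X) + 1) stop("too few observations for the design")
  check_design(X)
  fit <- stats::lm.fit(X, y)
  df <- n - ncol(X)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / df
  XtX_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * XtX_inv[2, 2])
  eff <- unname(fit$coefficients["dose"])
  p <- if (se == 0) {
    if (eff == 0) 1 else .Machine$double.xmin
  } else {
    floor_p(2 * stats::pt(-abs(eff / se), df))
  }
  data.frame(unit_id = unit_id, outcome = outcome, effect = eff, se = se,
             p = p, n = n, n_cases = NA_integer_, stringsAsFactors = FALSE)
}

#' Logistic association of a binary outcome with genotype dose
#'
#' Maximum likelihood via iteratively reweighted least squares
#' (`stats::glm`, binomial logit), effect reported as log odds ratio per
#' allele with Wald SE from the inverse observed information. Complete or
#' quasi-complete separation is detected and reported as an explicit failure.
#'
#' @inheritParams fit_linear_assoc
#' @param y binary outcome (0/1); both classes must be present.
#' @return one-row data frame as in [fit_linear_assoc()], with `n_cases`.
#' @export
fit_logistic_assoc <- function(y, dose, covariates = NULL,
                               unit_id = "exposure", outcome = "y") {
  if (length(unique(y)) < 2) stop("both outcome classes must be present")
  dat <- data.frame(y = y, dose = dose)
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0) {
    dat <- cbind(dat, as.data.frame(covariates))
  }
  check_design(stats::model.matrix(~ ., dat[, -1, drop = FALSE]))
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-12, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warn <<- TRUE
      }
      invokeRestart("muffleWarning")
    })
  eff <- unname(stats::coef(fit)["dose"])
  se <- unname(sqrt(diag(stats::vcov(fit)))["dose"])
  if (!fit$converged || (sep_warn && (abs(eff) > 10 || se > 100))) {
    stop("complete or quasi-complete separation: log OR for dose diverges")
  }
  p <- floor_p(2 * stats::pnorm(-abs(eff / se)))
  data.frame(unit_id = unit_id, outcome = outcome, effect = eff, se = se,
             p = p, n = length(y), n_cases = sum(y == 1),
             stringsAsFactors = FALSE)
}

#' Carrier-group association over a variant set
#'
#' Sums allele counts across the variant set per sample (a compound
#' heterozygote counts as two copies), classifies individuals as noncarriers,
#' 1-copy or >=2-copy carriers, and regresses the outcome on the two carrier
#' indicators (noncarriers as reference) with covariates. Additive (dose)
#' coding is also supported.
#'
#' @param genotypes allele-count matrix (samples x variants).
#' @param variant_set column names of the variants forming the carrier set.
#' @param y outcome vector.
#' @param covariates data frame or NULL.
#' @param model `"linear"` or `"logistic"`.
#' @param coding `"indicator"` (1-copy and >=2-copy contrasts) or
#'   `"additive"` (single dose term).
#' @param outcome label for the result rows.
#' @return data frame of association rows, one per contrast; an empty carrier
#'   class yields a row with NA effect rather than an error.
#' @export
carrier_group_assoc <- function(genotypes, variant_set, y, covariates = NULL,
                                model = c("linear", "logistic"),
                                coding = c("indicator", "additive"),
                                outcome = "y") {
  model <- match.arg(model)
  coding <- match.arg(coding)
  if (length(variant_set) == 0) stop("variant set is empty")
  total <- rowSums(genotypes[, variant_set, drop = FALSE])
  fitter <- if (model == "linear") fit_linear_assoc else fit_logistic_assoc

  if (coding == "additive") {
    return(fitter(y, total, covariates, unit_id = "carriers_additive",
                  outcome = outcome))
  }

  cg1 <- as.numeric(total == 1)
  cg2 <- as.numeric(total >= 2)
  one_row <- function(label) {
    data.frame(unit_id = label, outcome = outcome, effect = NA_real_,
               se = NA_real_, p = NA_real_, n = length(y),
               n_cases = NA_integer_, stringsAsFactors = FALSE)
  }
  # joint model with both indicators where both classes are populated
  if (sum(cg1) > 0 && sum(cg2) > 0) {
    covs1 <- data.frame(cg2 = cg2)
    covs2 <- data.frame(cg1 = cg1)
    if (!is.null(covariates)) {
      covs1 <- cbind(covs1, as.data.frame(covariates))
      covs2 <- cbind(covs2, as.data.frame(covariates))
    }
    r1 <- fitter(y, cg1, covs1, unit_id = "carriers_1copy", outcome = outcome)
    r2 <- fitter(y, cg2, covs2, unit_id = "carriers_2copy", outcome = outcome)
    return(rbind(r1, r2))
  }
  r1 <- if (sum(cg1) > 0) {
    fitter(y, cg1, covariates, unit_id = "carriers_1copy", outcome = outcome)
  } else one_row("carriers_1copy")
  r2 <- if (sum(cg2) > 0) {
    fitter(y, cg2, covariates, unit_id = "carriers_2copy", outcome = outcome)
  } else one_row("carriers_2copy")
  rbind(r1, r2)
}

#' Rescale a per-allele odds ratio to a per-kg/m^2-lower-BMI exposure
#'
#' Wald-ratio rescaling: the log OR per allele is divided by the absolute
#' per-allele BMI effect, giving the OR per 1 kg/m^2 genetically lower BMI.
#' The SE is scaled by the same factor (first order, BMI effect treated as
#' fixed).
#'
#' @param log_or_per_allele log odds ratio per allele.
#' @param beta_bmi_per_allele BMI effect (kg/m^2 per allele), non-zero.
#' @param se_log_or optional SE of the log OR; scaled alongside.
#' @return list: `or_per_kgm2`, `log_or_per_kgm2`, `se` (NA if not supplied).
#' @export
scale_or_per_unit <- function(log_or_per_allele, beta_bmi_per_allele,
                              se_log_or = NA_real_) {
  if (beta_bmi_per_allele == 0) stop("BMI effect per allele must be non-zero")
  f <- abs(beta_bmi_per_allele)
  list(or_per_kgm2 = exp(log_or_per_allele / f),
       log_or_per_kgm2 = log_or_per_allele / f,
       se = se_log_or / f)
}

#' Phenome-wide association scan
#'
#' Tests a genotype dose against every binary outcome with more than
#' `min_cases` cases using [fit_logistic_assoc()]; the significance threshold
#' is Bonferroni-corrected for the number of outcomes actually tested.
#'
#' @param outcomes data frame or matrix of binary outcomes (one column per
#'   diagnosis).
#' @param dose genotype dose vector.
#' @param covariates data frame or NULL.
#' @param min_cases outcomes with case counts at or below this are excluded.
#' @param alpha family-wise level.
#' @return list: `table` (association rows plus `significant` flag),
#'   `threshold` (`alpha / m`; NA when nothing passes the filter),
#'   `n_tested`.
#' @export
phewas_scan <- function(outcomes, dose, covariates = NULL, min_cases = 500,
                        alpha = 0.05) {
  if (min_cases < 1) stop("min_cases must be >= 1")
  outcomes <- as.data.frame(outcomes)
  cases <- vapply(outcomes, function(v) sum(v == 1), numeric(1))
  keep <- names(outcomes)[cases > min_cases]
  if (length(keep) == 0) {
    return(list(table = data.frame(), threshold = NA_real_, n_tested = 0L))
  }
  threshold <- alpha / length(keep)
  rows <- lapply(keep, function(nm) {
    fit_logistic_assoc(outcomes[[nm]], dose, covariates,
                       unit_id = "dose", outcome = nm)
  })
  tab <- do.call(rbind, rows)
  tab$significant <- tab$p < threshold
  list(table = tab, threshold = threshold, n_tested = length(keep))
}

#' Per-variant association table for a cohort
#'
#' Runs [fit_linear_assoc()] (BMI) for every variant with at least
#' `min_carriers` carriers; variants below the floor are reported with NA
#' effect and flagged, since a regression on (near-)empty carrier classes is
#' uninformative.
#'
#' @param genotypes allele-count matrix.
#' @param phenotypes phenotype/covariate data frame with columns `bmi`,
#'   `age`, `sex`, `array`.
#' @param min_carriers minimum carrier count for estimation (default 2).
#' @return data frame of association rows with an `estimable` flag.
#' @export
per_variant_bmi_assoc <- function(genotypes, phenotypes, min_carriers = 2) {
  covs <- phenotypes[, c("age", "sex", "array")]
  rows <- lapply(colnames(genotypes), function(v) {
    dose <- genotypes[, v]
    if (sum(dose > 0) < min_carriers) {
      return(data.frame(unit_id = v, outcome = "bmi", effect = NA_real_,
                        se = NA_real_, p = NA_real_, n = nrow(genotypes),
                        n_cases = NA_integer_, estimable = FALSE,
                        stringsAsFactors = FALSE))
    }
    r <- fit_linear_assoc(phenotypes$bmi, dose, covs, unit_id = v,
                          outcome = "bmi")
    r$estimable <- TRUE
    r
  })
  do.call(rbind, rows)
}
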