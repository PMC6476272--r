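#' Signaling-bias ratio of geometric means
#'
#' Quantifies bias between the two pathways as the ratio of geometric means of
#' per-experiment maximal activity: `exp(mean(ln barr) - mean(ln cAMP))`. The
#' null hypothesis of no bias (ratio = 1) is tested with an unpaired
#' two-sample t test on the log-transformed samples (pooled variance by
#' default; Welch available), and the 95% CI is the exponentiated t interval
#' for the difference of log-means.
#'
#' @param barr_pct per-experiment beta-arrestin maximal activities (% WT),
#'   strictly positive, length >= 2.
#' @param camp_pct per-experiment cAMP maximal activities (% WT), strictly
#'   positive, length >= 2.
#' @param welch use Welch's unequal-variance test instead of the pooled test.
#' @return list: `ratio`, `ci95` (length-2), `p`, `df`.
#' @export
compute_bias <- function(barr_pct, camp_pct, welch = FALSE) {
  if (length(barr_pct) < 2 || length(camp_pct) < 2) {
    stop("each sample needs at least 2 values")
  }
  if (any(barr_pct <= 0) || any(camp_pct <= 0)) {
    stop("maximal activities must be strictly positive for a geometric-mean ratio")
  }
  lb <- log(barr_pct)
  lc <- log(camp_pct)
  ratio <- exp(mean(lb) - mean(lc))
  if (stats::sd(lb) == 0 && stats::sd(lc) == 0) {
    # no within-sample variability: CI collapses to the point estimate
    p <- if (isTRUE(all.equal(ratio, 1))) 1 else .Machine$double.xmin
    return(list(ratio = ratio, ci95 = c(ratio, ratio), p = p,
                df = length(lb) + length(lc) - 2))
  }
  tt <- stats::t.test(lb, lc, var.equal = !welch)
  list(ratio = ratio, ci95 = exp(as.numeric(tt$conf.int)),
       p = floor_p(tt$p.value), df = unname(tt$parameter))
}

#' Classify bias direction
#'
#' @param ratio geometric-mean ratio (beta-arrestin over cAMP).
#' @param p two-sided p against ratio = 1.
#' @param alpha significance level; a tie at exactly `p == alpha` is
#'   non-significant.
#' @return `"barr-biased"`, `"cAMP-biased"` or `"unbiased"`.
#' @export
classify_bias <- function(ratio, p, alpha = 0.05) {
  if (p < alpha && ratio > 1) return("barr-biased")
  if (p < alpha && ratio < 1) return("cAMP-biased")
  "unbiased"
}

#' Variants entering the bias analysis
#'
#' The bias analysis covers variants with a gain of function in at least one
#' pathway: overall GoF variants plus opposing variants whose GoF arm is one
#' of the two pathways.
#'
#' @param profiles profile table from [quantify_traces()].
#' @return character vector of variant IDs.
#' @export
select_bias_analysis_set <- function(profiles) {
  keep <- profiles$class_camp == "GoF" | profiles$class_barr == "GoF"
  profiles$variant_id[keep & !profiles$is_truncating]
}

#' Per-variant bias table
#'
#' Runs [compute_bias()] and [classify_bias()] for every variant in the bias
#' analysis set, using the per-experiment normalized activities.
#'
#' @param norm_values data frame of per-experiment normalized activities with
#'   columns `variant_id`, `pathway` (`"cAMP"`/`"barr"`), `pct_wt`.
#' @param variant_ids variants to analyse (from
#'   [select_bias_analysis_set()]).
#' @param alpha significance level.
#' @param welch passed to [compute_bias()].
#' @return data frame: `variant_id`, `ratio`, `ci_lo`, `ci_hi`, `p`,
#'   `bias_class`.
#' @export
bias_table <- function(norm_values, variant_ids, alpha = 0.05, welch = FALSE) {
  rows <- lapply(variant_ids, function(id) {
    b <- norm_values$pct_wt[norm_values$variant_id == id &
                              norm_values$pathway == "barr"]
    c_ <- norm_values$pct_wt[norm_values$variant_id == id &
                               norm_values$pathway == "cAMP"]
    r <- compute_bias(b, c_, welch = welch)
    data.frame(variant_id = id, ratio = r$ratio, ci_lo = r$ci95[1],
               ci_hi = r$ci95[2], p = r$p,
               bias_class = classify_bias(r$ratio, r$p, alpha),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
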