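#' Baseline-corrected area under a time-resolved trace
#'
#' The baseline is the arithmetic mean of the signal within the
#' pre-stimulation window; the AUC is the trapezoidal integral of
#' `signal - baseline` over all timepoints after the window. Negative areas
#' are allowed (a response below baseline).
#'
#' @param time_s strictly increasing numeric vector of times (seconds).
#' @param signal numeric vector, same length as `time_s`.
#' @param baseline_window length-2 numeric, the closed time interval treated
#'   as pre-stimulation; must cover at least 2 points.
#' @return area in signal-seconds.
#' @export
compute_auc <- function(time_s, signal, baseline_window) {
  if (length(time_s) != length(signal)) stop("time and signal lengths differ")
  if (any(diff(time_s) <= 0)) stop("time must be strictly increasing")
  in_base <- time_s >= baseline_window[1] & time_s <= baseline_window[2]
  if (sum(in_base) < 2) stop("baseline window must cover at least 2 points")
  baseline <- mean(signal[in_base])
  post <- time_s > baseline_window[2]
  if (sum(post) < 2) return(0)
  t <- time_s[post]
  y <- signal[post] - baseline
  sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Two-point (0%/100%) normalization
#'
#' Expresses a readout as a percentage of the span between a zero reference
#' and a full reference, the convention used both for assay AUCs (mock
#' transfection = 0%, wild-type receptor = 100%) and for ERK band intensities
#' (unstimulated wild type = 0%, maximally stimulated wild type = 100%).
#'
#' @param value numeric readout(s).
#' @param zero_ref readout defining 0%.
#' @param full_ref readout defining 100%.
#' @param label context used in the error message for degenerate references
#'   (e.g. a plate identifier).
#' @return percent value(s).
#' @export
normalize_two_point <- function(value, zero_ref, full_ref, label = "plate") {
  if (isTRUE(all.equal(full_ref, zero_ref, tolerance = 0)) ||
      full_ref == zero_ref) {
    stop(sprintf("degenerate normalization references on %s: 0%% and 100%% anchors are equal", label))
  }
  100 * (value - zero_ref) / (full_ref - zero_ref)
}

#' Single-sample t test of normalized activity against wild type (100%)
#'
#' Per-experiment normalized values for one variant and pathway are compared
#' to the wild-type level of 100% with a two-sided single-sample t test. A
#' variant is called LoF if significantly below 100%, GoF if significantly
#' above, otherwise WT-like.
#'
#' @param values numeric vector of per-experiment normalized activities (% WT),
#'   length >= 2.
#' @param alpha two-sided significance level (default 0.05).
#' @return list: `mean`, `sd`, `n`, `ci95` (length-2), `p`, `pathway_class`,
#'   `degenerate` (TRUE when the sample has zero variance away from 100, in
#'   which case the class is assigned by sign and `p` is the machine floor).
#' @export
test_vs_wt <- function(values, alpha = 0.05) {
  if (length(values) < 2) stop("at least 2 replicate values are required")
  if (any(!is.finite(values))) stop("non-finite normalized values")
  m <- mean(values)
  s <- stats::sd(values)
  n <- length(values)
  degenerate <- FALSE
  if (s == 0) {
    if (m == 100) {
      p <- 1
      ci <- c(m, m)
      cls <- "WT-like"
    } else {
      degenerate <- TRUE
      p <- .Machine$double.xmin
      ci <- c(m, m)
      cls <- if (m < 100) "LoF" else "GoF"
      warning("zero-variance sample away from 100%: class assigned by sign")
    }
  } else {
    tt <- stats::t.test(values, mu = 100)
    p <- floor_p(tt$p.value)
    ci <- as.numeric(tt$conf.int)
    cls <- if (p < alpha) (if (m < 100) "LoF" else "GoF") else "WT-like"
  }
  list(mean = m, sd = s, n = n, ci95 = ci, p = p, pathway_class = cls,
       degenerate = degenerate)
}

#' Combine per-pathway calls into an overall functional category
#'
#' A variant is LoF if significantly reduced in either pathway, GoF if
#' significantly enhanced in either pathway, WT-like if unchanged in both, and
#' "opposing" when the two pathways disagree in direction (GoF in one, LoF in
#' the other). Truncating (nonsense/frameshift) variants bypass the table and
#' are always LoF.
#'
#' @param camp_class,barr_class per-pathway class, each one of `"LoF"`,
#'   `"WT-like"`, `"GoF"`.
#' @param is_truncating logical flag.
#' @return one of `"LoF"`, `"WT-like"`, `"GoF"`, `"opposing"`.
#' @export
classify_variant <- function(camp_class, barr_class, is_truncating = FALSE) {
  if (is_truncating) return("LoF")
  valid <- c("LoF", "WT-like", "GoF")
  if (!(camp_class %in% valid) || !(barr_class %in% valid)) {
    stop("unknown pathway class label")
  }
  if (camp_class == "GoF" && barr_class == "LoF") return("opposing")
  if (camp_class == "LoF" && barr_class == "GoF") return("opposing")
  if (camp_class == "LoF" || barr_class == "LoF") return("LoF")
  if (camp_class == "GoF" || barr_class == "GoF") return("GoF")
  "WT-like"
}

#' Per-experiment normalized maximal activities
#'
#' Computes the baseline-corrected AUC of every well and normalizes each
#' variant well against the mock (0%) and wild-type (100%) anchor wells of its
#' own replicate plate and pathway. These per-experiment values are the raw
#' samples behind both the E_max summaries and the bias ratios.
#'
#' @inheritParams quantify_traces
#' @return data frame: `variant_id`, `pathway`, `condition`, `replicate`,
#'   `auc`, `pct_wt`.
#' @export
normalized_activities <- function(traces, baseline_end = 600) {
  req <- c("variant_id", "pathway", "condition", "replicate", "time_s", "signal")
  if (!all(req %in% names(traces))) {
    stop("trace table must have columns: ", paste(req, collapse = ", "))
  }
  bw <- c(0, baseline_end)

  key <- interaction(traces$variant_id, traces$pathway, traces$replicate,
                     drop = TRUE)
  wells <- lapply(split(traces, key), function(d) {
    d <- d[order(d$time_s), ]
    data.frame(variant_id = d$variant_id[1], pathway = d$pathway[1],
               condition = d$condition[1], replicate = d$replicate[1],
               auc = compute_auc(d$time_s, d$signal, bw),
               stringsAsFactors = FALSE)
  })
  wells <- do.call(rbind, wells)

  # normalize within replicate plate x pathway against its own mock/WT wells
  norm <- lapply(split(wells, interaction(wells$pathway, wells$replicate,
                                          drop = TRUE)), function(d) {
    mock <- d$auc[d$condition == "mock"]
    wt <- d$auc[d$condition == "WT"]
    lab <- sprintf("pathway %s replicate %s", d$pathway[1], d$replicate[1])
    if (length(mock) != 1 || length(wt) != 1) {
      stop("missing mock or WT anchor well on ", lab)
    }
    v <- d[d$condition == "variant", , drop = FALSE]
    v$pct_wt <- normalize_two_point(v$auc, mock, wt, label = lab)
    v
  })
  norm <- do.call(rbind, norm)
  rownames(norm) <- NULL
  norm
}

#' Quantify a plate of traces into per-variant functional profiles
#'
#' For each replicate experiment and pathway, the AUC of every well is
#' baseline-corrected ([compute_auc()]) and normalized against the mock (0%)
#' and wild-type (100%) wells of the same replicate plate
#' ([normalize_two_point()]). Per-experiment normalized values are then
#' averaged per variant and tested against 100% ([test_vs_wt()]), and the two
#' pathway calls are combined ([classify_variant()]). Variants listed in
#' `truncating_ids` are appended as LoF with no assay summary.
#'
#' @param traces long-format trace data frame (`variant_id`, `pathway`,
#'   `condition`, `replicate`, `time_s`, `signal`).
#' @param baseline_end end of the pre-stimulation window (seconds); the
#'   window is `[0, baseline_end]`.
#' @param alpha significance level for the per-pathway calls.
#' @param truncating_ids character vector of variant IDs classified LoF by
#'   rule (not assayed).
#' @return data frame with one row per variant: `variant_id`,
#'   `emax_camp_pct`, `emax_camp_ci_lo`, `emax_camp_ci_hi`, `p_camp`,
#'   `class_camp`, the same four `barr` columns, `is_truncating`,
#'   `overall_category`.
#' @export
quantify_traces <- function(traces, baseline_end = 600, alpha = 0.05,
                            truncating_ids = character()) {
  norm <- normalized_activities(traces, baseline_end = baseline_end)

  summarize_pathway <- function(d) {
    tw <- test_vs_wt(d$pct_wt, alpha = alpha)
    data.frame(emax_pct = tw$mean, ci_lo = tw$ci95[1], ci_hi = tw$ci95[2],
               p = tw$p, class = tw$pathway_class, n_experiments = tw$n,
               stringsAsFactors = FALSE)
  }

  ids <- unique(norm$variant_id)
  rows <- lapply(ids, function(id) {
    dc <- norm[norm$variant_id == id & norm$pathway == "cAMP", ]
    db <- norm[norm$variant_id == id & norm$pathway == "barr", ]
    sc <- summarize_pathway(dc)
    sb <- summarize_pathway(db)
    data.frame(variant_id = id,
               emax_camp_pct = sc$emax_pct, emax_camp_ci_lo = sc$ci_lo,
               emax_camp_ci_hi = sc$ci_hi, p_camp = sc$p, class_camp = sc$class,
               emax_barr_pct = sb$emax_pct, emax_barr_ci_lo = sb$ci_lo,
               emax_barr_ci_hi = sb$ci_hi, p_barr = sb$p, class_barr = sb$class,
               n_experiments = min(sc$n_experiments, sb$n_experiments),
               is_truncating = FALSE,
               overall_category = classify_variant(sc$class, sb$class),
               stringsAsFactors = FALSE)
  })
  profiles <- do.call(rbind, rows)

  if (length(truncating_ids) > 0) {
    tr <- data.frame(variant_id = truncating_ids,
                     emax_camp_pct = NA_real_, emax_camp_ci_lo = NA_real_,
                     emax_camp_ci_hi = NA_real_, p_camp = NA_real_,
                     class_camp = "LoF",
                     emax_barr_pct = NA_real_, emax_barr_ci_lo = NA_real_,
                     emax_barr_ci_hi = NA_real_, p_barr = NA_real_,
                     class_barr = "LoF",
                     n_experiments = 0L, is_truncating = TRUE,
                     overall_category = "LoF", stringsAsFactors = FALSE)
    profiles <- rbind(profiles, tr)
  }
  rownames(profiles) <- NULL
  profiles
}

#' Fit a three-parameter logistic dose-response curve
#'
#' Least-squares fit of `response = top / (1 + 10^(hill * (log10_ec50 -
#' log10(conc))))` — a sigmoidal curve with variable slope and the bottom
#' fixed at 0. Initialization is multi-start from data-derived guesses.
#'
#' @param conc ligand concentrations (molar), at least 4 distinct values.
#' @param response responses (% of wild-type maximum).
#' @param max_restarts number of perturbed restarts after the data-derived
#'   starts fail or stall.
#' @return list: `top`, `log10_ec50`, `hill`, `rss`, `converged`,
#'   `degenerate` (all-zero response).
#' @export
fit_dose_response <- function(conc, response, max_restarts = 10) {
  if (length(unique(conc)) < 4) stop("need at least 4 distinct concentrations")
  if (length(conc) != length(response)) stop("length mismatch")
  if (all(response == 0)) {
    return(list(top = 0, log10_ec50 = NA_real_, hill = NA_real_, rss = 0,
                converged = TRUE, degenerate = TRUE))
  }
  lc <- log10(conc)
  model <- function(p) p[1] / (1 + 10^(p[3] * (p[2] - lc)))
  rss_fun <- function(p) sum((response - model(p))^2)

  top0 <- max(response)
  half <- top0 / 2
  ec50_0 <- lc[which.min(abs(response - half))]
  starts <- list(c(top0, ec50_0, 1), c(top0, ec50_0, 0.5),
                 c(top0, ec50_0, 2), c(top0, stats::median(lc), 1))
  # deterministic perturbed restarts spanning the concentration range
  grid_ec <- stats::quantile(lc, c(0.25, 0.5, 0.75), names = FALSE)
  grid_hill <- c(0.3, 0.7, 1.5, 3)
  extra <- expand.grid(ec = grid_ec, hill = grid_hill)
  for (i in seq_len(min(max_restarts, nrow(extra)))) {
    starts[[length(starts) + 1]] <- c(top0, extra$ec[i], extra$hill[i])
  }

  best <- NULL
  df <- data.frame(lc = lc, response = response)
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(response ~ top / (1 + 10^(hill * (ec50 - lc))),
                        data = df,
                        start = list(top = st[1], ec50 = st[2], hill = st[3]),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      p <- stats::coef(fit)
      r <- rss_fun(c(p["top"], p["ec50"], p["hill"]))
      if (is.null(best) || r < best$rss) {
        best <- list(top = unname(p["top"]), log10_ec50 = unname(p["ec50"]),
                     hill = unname(p["hill"]), rss = r, converged = TRUE,
                     degenerate = FALSE)
      }
    }
  }
  if (is.null(best)) {
    return(list(top = NA_real_, log10_ec50 = NA_real_, hill = NA_real_,
                rss = NA_real_, converged = FALSE, degenerate = FALSE))
  }
  best
}

#' Percent receptor internalization from flow-cytometry MFI
#'
#' `% internalization = (1 - MFI_stimulated / MFI_unstimulated) * 100`.
#' Negative values indicate a gain of receptor at the cell surface.
#'
#' @param mfi_unstim mean fluorescence intensity of unstimulated cells (> 0).
#' @param mfi_stim mean fluorescence intensity after agonist stimulation.
#' @return percent internalization.
#' @export
pct_internalization <- function(mfi_unstim, mfi_stim) {
  if (any(mfi_unstim <= 0)) stop("unstimulated MFI must be positive")
  (1 - mfi_stim / mfi_unstim) * 100
}
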