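#' Classify a TE family's integration strategy
#'
#' Heuristic three-way call from the evidence the comparative analysis
#' produces. The peak-fold statistic is the maximum profile value (genic +
#' intergenic) within `peak_window` bp of the anchor divided by the profile
#' median: a family with a TSS peak but no TTS peak is type A
#' (single-peak precision targeting), peaks at both anchors give type B
#' (double-peak), and anything else is type C (Pol II-independent). The
#' peak-fold threshold of 3 is a package default chosen for the simulation
#' scale — the underlying taxonomy is qualitative — and all evidence values
#' are carried in the report so users can re-threshold.
#'
#' @param tss_profile,tts_profile `te_metaprofile` objects computed on the
#'   same annotation.
#' @param bin_curve Optional `te_bin_curve`; its Spearman correlation between
#'   bin index and percentage is reported as `expr_rho` (not used in the call).
#' @param peak_threshold Minimum peak fold counting as a peak (default 3).
#' @param peak_window Distance from the anchor searched for the peak
#'   (default 500 bp).
#' @return A `te_strategy` object: list with `call` (`"A"`, `"B"` or `"C"`),
#'   `tss_peak_fold`, `tts_peak_fold`, `expr_rho`, `peak_threshold`.
#' @export
classify_strategy <- function(tss_profile, tts_profile, bin_curve = NULL,
                              peak_threshold = 3, peak_window = 500) {
  tss_fold <- peak_fold(tss_profile, peak_window)
  tts_fold <- peak_fold(tts_profile, peak_window)
  expr_rho <- NA_real_
  if (!is.null(bin_curve)) {
    expr_rho <- suppressWarnings(
      stats::cor(bin_curve$bin, bin_curve$mean_pct, method = "spearman")
    )
  }
  degenerate <- is.na(tss_fold) && is.na(tts_fold)
  if (degenerate) {
    warn("degenerate (all-zero) profiles: calling type C")
    call <- "C"
  } else {
    tssp <- isTRUE(tss_fold >= peak_threshold)
    ttsp <- isTRUE(tts_fold >= peak_threshold)
    call <- if (tssp && !ttsp) "A" else if (tssp && ttsp) "B" else "C"
  }
  structure(list(call = call,
                 tss_peak_fold = tss_fold,
                 tts_peak_fold = tts_fold,
                 expr_rho = expr_rho,
                 peak_threshold = peak_threshold,
                 peak_window = peak_window),
            class = "te_strategy")
}

# mean profile value near the anchor over the median of positions carrying
# signal. The mean (not the max) keeps the null expectation near 1: a max
# over ~1000 noisy positions is extreme-value biased upward at small n.
# The denominator uses only positions with signal because a one-sided
# profile (e.g. gene-body targeting) would otherwise have median 0.
# NA for an all-zero profile.
peak_fold <- function(profile, peak_window) {
  vals <- profile_total(profile)
  if (all(vals == 0)) return(NA_real_)
  near <- abs(profile$position) <= peak_window
  peak <- mean(vals[near])
  med <- stats::median(vals[vals > 0])
  peak / med
}

profile_total <- function(profile) {
  if ("value" %in% names(profile)) profile$value
  else profile$genic + profile$intergenic
}

#' @export
print.te_strategy <- function(x, ...) {
  cat("<te_strategy> type ", x$call,
      sprintf(" (TSS peak fold %.2f, TTS peak fold %.2f",
              x$tss_peak_fold, x$tts_peak_fold),
      if (!is.na(x$expr_rho)) sprintf(", expression rho %.2f)", x$expr_rho)
      else ")", "\n", sep = "")
  invisible(x)
}

#' @rdname classify_strategy
#' @param x A `te_strategy` object.
#' @param ... Unused.
#' @method tidy te_strategy
#' @export
tidy.te_strategy <- function(x, ...) {
  tibble(
    statistic = c("tss_peak_fold", "tts_peak_fold", "expr_rho"),
    value = c(x$tss_peak_fold, x$tts_peak_fold, x$expr_rho)
  )
}

#' @rdname classify_strategy
#' @method glance te_strategy
#' @export
glance.te_strategy <- function(x, ...) {
  tibble(call = x$call, tss_peak_fold = x$tss_peak_fold,
         tts_peak_fold = x$tts_peak_fold, expr_rho = x$expr_rho,
         peak_threshold = x$peak_threshold)
}

#' End-to-end strategy report for an insertion set
#'
#' Runs the whole evidence pipeline — TSS and TTS metaprofiles, TSS-associated
#' pairs, per-dataset expression bins and the bin curve — and classifies the
#' strategy.
#'
#' @param insertions A `te_insertions` tibble.
#' @param annotation A `te_annotation`.
#' @param expr Long expression tibble `dataset_id`, `gene_id`, `fpkm`.
#' @inheritParams classify_strategy
#' @param halfwidth,window_bp Metaprofile parameters.
#' @return A `te_strategy` object.
#' @export
strategy_report <- function(insertions, annotation, expr,
                            peak_threshold = 3, peak_window = 500,
                            halfwidth = 4000, window_bp = 30) {
  genes <- annotation$genes
  tssp <- profile_insertions(insertions, genes, "TSS", halfwidth, window_bp)
  ttsp <- profile_insertions(insertions, genes, "TTS", halfwidth, window_bp)
  curve <- NULL
  pairs <- tss_associated(insertions, genes)
  if (nrow(pairs) > 0L) {
    assignments <- bin_genes_all(expr)
    curve <- bin_curve(pairs, assignments)
  }
  classify_strategy(tssp, ttsp, curve,
                    peak_threshold = peak_threshold,
                    peak_window = peak_window)
}
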