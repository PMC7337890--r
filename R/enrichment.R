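#' Sub-genic feature membership of insertions
#'
#' Flags, for every insertion, membership in each of the (deliberately
#' overlapping) categories used in genic enrichment summaries: `genic` (inside
#' any gene span), `up500`/`up200` (within 500/200 bp upstream of any TSS,
#' strand-aware, boundary inclusive), `utr5`, `cds`, `utr3` (inside the
#' corresponding annotated interval of any gene), `intron` (genic but in no
#' annotated UTR/CDS interval), and `down200`/`down500` (within 200/500 bp
#' downstream of any TTS). An insertion upstream of one gene and inside
#' another sets both flags; `up200` is a subset of `up500` and `down200` of
#' `down500` by construction.
#'
#' @param insertions A `te_insertions` tibble.
#' @param annotation A `te_annotation` (genes + sub-genic features).
#' @return The insertion tibble with nine logical flag columns appended.
#' @export
classify_features <- function(insertions, annotation) {
  genes <- annotation$genes
  features <- annotation$features
  ins <- as_tibble(insertions)[, c("chrom", "pos")]
  ins_gr <- GenomicRanges::GRanges(ins$chrom, IRanges::IRanges(ins$pos, width = 1L))
  in_any <- function(chrom, lo, hi) {
    keep <- lo <= hi
    if (!any(keep)) return(rep(FALSE, nrow(ins)))
    gr <- GenomicRanges::GRanges(chrom[keep],
                                 IRanges::IRanges(pmax(lo[keep], 1L), hi[keep]))
    GenomicRanges::countOverlaps(ins_gr, gr, ignore.strand = TRUE) > 0L
  }
  up_window <- function(d) {
    lo <- ifelse(genes$strand == "+", genes$tss - d, genes$tss + 1L)
    hi <- ifelse(genes$strand == "+", genes$tss - 1L, genes$tss + d)
    in_any(genes$chrom, lo, hi)
  }
  down_window <- function(d) {
    lo <- ifelse(genes$strand == "+", genes$tts + 1L, genes$tts - d)
    hi <- ifelse(genes$strand == "+", genes$tts + d, genes$tts - 1L)
    in_any(genes$chrom, lo, hi)
  }
  feat_flag <- function(type) {
    f <- features[features$type == type, , drop = FALSE]
    if (nrow(f) == 0L) return(rep(FALSE, nrow(ins)))
    fc <- genes$chrom[match(f$gene_id, genes$gene_id)]
    in_any(fc, f$start, f$end)
  }
  out <- ins
  out$genic <- in_any(genes$chrom, genes$start, genes$end)
  out$up500 <- up_window(500L)
  out$up200 <- up_window(200L)
  out$utr5 <- feat_flag("five_prime_UTR")
  out$cds <- feat_flag("CDS")
  out$utr3 <- feat_flag("three_prime_UTR")
  out$intron <- out$genic & !(out$utr5 | out$cds | out$utr3)
  out$down200 <- down_window(200L)
  out$down500 <- down_window(500L)
  out
}

#' Insertion enrichment fold over the random background
#'
#' Ratio of category proportions: `(te_count / te_total) /
#' (rand_count / rand_total)`. The random background has fold 1 by
#' definition; values above 1 mean enrichment of TE insertions, below 1
#' depletion.
#'
#' @param te_count,te_total In-category and total counts for the TE set.
#' @param rand_count,rand_total The same for the random background.
#' @return Numeric fold (vectorized); `Inf` with a warning when
#'   `rand_count` is 0.
#' @examples
#' enrichment_fold(25142, 92702, 1268, 421280) # ~90.1
#' @export
enrichment_fold <- function(te_count, te_total, rand_count, rand_total) {
  if (any(te_total < 1) || any(rand_total < 1)) abort("totals must be >= 1")
  if (any(rand_count == 0)) warn("rand_count of 0: fold reported as Inf")
  (te_count / te_total) / (rand_count / rand_total)
}

#' Chi-square test for one enrichment category
#'
#' Pearson chi-square (1 df, no continuity correction by default) on the 2x2
#' table crossing in-category vs not with TE vs random.
#'
#' @inheritParams enrichment_fold
#' @param correct Apply Yates continuity correction (default `FALSE`).
#' @return List with `statistic`, `p_value`, and `expected_warning` (`TRUE`
#'   when any expected cell is below 1).
#' @export
category_chi2 <- function(te_count, te_total, rand_count, rand_total,
                          correct = FALSE) {
  tab <- matrix(c(te_count, te_total - te_count,
                  rand_count, rand_total - rand_count), nrow = 2)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  low <- any(expected < 1)
  if (all(tab[1, ] == 0) || all(tab[2, ] == 0)) {
    return(list(statistic = 0, p_value = 1, expected_warning = low))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value),
       expected_warning = low)
}

te_feature_categories <- c("genic", "up500", "up200", "utr5",
                           "cds", "utr3", "down200", "down500")

#' Category enrichment table
#'
#' The full per-category summary for a TE insertion set against the random
#' background: count, percent of total, enrichment fold and chi-square
#' p-value per category, in the order genic, 500/200 bp upstream of TSS,
#' 5' UTR, CDS, 3' UTR, 200/500 bp downstream of TTS.
#'
#' @param te_set,random_set `te_insertions` tibbles classified on the same
#'   annotation.
#' @param annotation A `te_annotation`.
#' @param correct Continuity correction for the chi-square tests.
#' @return Tibble `category`, `count`, `pct_of_total`, `fold`, `p_value`,
#'   `expected_warning`.
#' @export
enrichment_table <- function(te_set, random_set, annotation, correct = FALSE) {
  if (nrow(te_set) == 0L) abort("empty TE insertion set")
  te_flags <- classify_features(te_set, annotation)
  rand_flags <- classify_features(random_set, annotation)
  enrichment_from_counts(
    te_counts = colSums(te_flags[, te_feature_categories]),
    te_total = nrow(te_set),
    rand_counts = colSums(rand_flags[, te_feature_categories]),
    rand_total = nrow(random_set),
    correct = correct
  )
}

#' Enrichment table from pre-tabulated counts
#'
#' Same statistics as [enrichment_table()] but starting from per-category
#' counts (e.g. a published summary table) instead of coordinates.
#'
#' @param te_counts,rand_counts Named numeric vectors of per-category counts.
#' @param te_total,rand_total Set totals.
#' @param correct Continuity correction for the chi-square tests.
#' @return Tibble `category`, `count`, `pct_of_total`, `fold`, `p_value`,
#'   `expected_warning`.
#' @export
enrichment_from_counts <- function(te_counts, te_total, rand_counts,
                                   rand_total, correct = FALSE) {
  cats <- names(te_counts)
  stopifnot(identical(cats, names(rand_counts)))
  rows <- lapply(cats, function(cat) {
    chi <- category_chi2(te_counts[[cat]], te_total,
                         rand_counts[[cat]], rand_total, correct = correct)
    tibble(
      category = cat,
      count = as.numeric(te_counts[[cat]]),
      pct_of_total = 100 * te_counts[[cat]] / te_total,
      fold = enrichment_fold(te_counts[[cat]], te_total,
                             rand_counts[[cat]], rand_total),
      p_value = chi$p_value,
      expected_warning = chi$expected_warning
    )
  })
  dplyr::bind_rows(rows)
}
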