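#' Knockdown index from allele-specific counts
#'
#' In a hybrid where every new insertion is on the B73 allele, the insertion's
#' effect on transcription is the ratio of non-insertion-allele (Mo17) to
#' insertion-allele (B73) transcript counts in insertion carriers, normalized
#' by the same ratio in siblings without the insertion:
#' `(mo17_ins / b73_ins) / (mo17_noins / b73_noins)`. An index of 1 means no
#' allelic effect; larger values mean the insertion allele is knocked down;
#' `Inf` (when `b73_ins` is 0) means complete silencing.
#'
#' @param b73_ins,mo17_ins Read counts of the two alleles in
#'   insertion-carrying individuals.
#' @param b73_noins,mo17_noins Read counts of the two alleles in individuals
#'   without the insertion; both must be at least 1.
#' @return Numeric vector of indices (vectorized over all four arguments);
#'   `Inf` where `b73_ins` is 0.
#' @examples
#' knockdown_index(39, 960, 553, 480) # ~28.4
#' @export
knockdown_index <- function(b73_ins, mo17_ins, b73_noins, mo17_noins) {
  counts <- cbind(b73_ins, mo17_ins, b73_noins, mo17_noins)
  if (any(counts < 0) || anyNA(counts)) abort("allele counts must be non-negative")
  if (any(b73_noins < 1) || any(mo17_noins < 1)) {
    abort("undefined index: zero count in a no-insertion denominator")
  }
  ifelse(b73_ins == 0, Inf,
         (mo17_ins / b73_ins) / (mo17_noins / b73_noins))
}

#' Classify the consequence of an insertion from its knockdown index
#'
#' Maps an index to a consequence label. The default cut-offs (knockout at
#' 100 or an infinite index, knockdown at 10, weak knockdown at 2, weak
#' activation at or below 0.5, otherwise unchanged) are this package's
#' reconstruction — the original survey printed labels, not thresholds — and
#' are fully configurable.
#'
#' @param index Numeric vector of knockdown indices (may contain `Inf`).
#' @param thresholds Named list with elements `knockout`, `knockdown`, `weak`,
#'   `activation`.
#' @return Factor with levels `knockout`, `knockdown`, `weak_knockdown`,
#'   `unchanged`, `weak_activation`.
#' @export
classify_consequence <- function(index,
                                 thresholds = list(knockout = 100,
                                                   knockdown = 10,
                                                   weak = 2,
                                                   activation = 0.5)) {
  if (any(index < 0, na.rm = TRUE)) abort("index must be non-negative")
  lab <- ifelse(is.infinite(index) | index >= thresholds$knockout, "knockout",
         ifelse(index >= thresholds$knockdown, "knockdown",
         ifelse(index >= thresholds$weak, "weak_knockdown",
         ifelse(index <= thresholds$activation, "weak_activation",
                "unchanged"))))
  factor(lab, levels = c("knockout", "knockdown", "weak_knockdown",
                         "unchanged", "weak_activation"))
}

#' Score an allele-count table
#'
#' Adds `index` and `consequence` columns to a table of allele-specific
#' counts (columns `gene_id`, `site_class`, `b73_ins`, `mo17_ins`,
#' `b73_noins`, `mo17_noins`).
#'
#' @param records Allele-count tibble.
#' @param thresholds Passed to [classify_consequence()].
#' @param pseudocount Added to all four counts before computing the index
#'   (default 0; guards against zero no-insertion denominators in new data).
#' @return The input tibble with `index` and `consequence` appended.
#' @export
score_allele_counts <- function(records,
                                thresholds = list(knockout = 100,
                                                  knockdown = 10,
                                                  weak = 2,
                                                  activation = 0.5),
                                pseudocount = 0) {
  rec <- as_tibble(records)
  rec$index <- knockdown_index(rec$b73_ins + pseudocount,
                               rec$mo17_ins + pseudocount,
                               rec$b73_noins + pseudocount,
                               rec$mo17_noins + pseudocount)
  rec$consequence <- classify_consequence(rec$index, thresholds)
  rec
}

#' Summarize insertion consequences by site class
#'
#' Cross-tabulates scored allele-count records by insertion site class and
#' consequence, with the aggregate counts used in the survey's headline
#' claims: `n_reduced` (index of at least 2, i.e. weak knockdown or stronger)
#' and `n_knockout` (complete knockouts, index infinite or at least the
#' knockout threshold).
#'
#' @param records Allele-count tibble; scored with [score_allele_counts()]
#'   first if `index` is absent.
#' @param strong_cut Index bound counting as a strong effect per site class
#'   (default 10).
#' @return List with `by_class` (tibble `site_class`, `n`, `n_strong`),
#'   `crosstab` (tibble `site_class` x `consequence` counts), `n_records`,
#'   `n_reduced`, `n_knockout`.
#' @export
consequence_summary <- function(records, strong_cut = 10) {
  rec <- as_tibble(records)
  if (nrow(rec) == 0L) {
    return(list(by_class = tibble(site_class = character(), n = integer(),
                                  n_strong = integer()),
                crosstab = tibble(site_class = character(),
                                  consequence = character(), n = integer()),
                n_records = 0L, n_reduced = 0L, n_knockout = 0L))
  }
  if (!"index" %in% names(rec)) rec <- score_allele_counts(rec)
  rec$.strong <- is.infinite(rec$index) | rec$index >= strong_cut
  by_class <- rec |>
    dplyr::group_by(.data$site_class) |>
    dplyr::summarise(n = dplyr::n(), n_strong = sum(.data$.strong),
                     .groups = "drop")
  rec$.strong <- NULL
  crosstab <- dplyr::count(rec, .data$site_class, .data$consequence,
                           name = "n")
  list(by_class = by_class,
       crosstab = crosstab,
       n_records = nrow(rec),
       n_reduced = sum(rec$index >= 2 | is.infinite(rec$index)),
       n_knockout = sum(rec$consequence == "knockout"))
}

#' Read an allele-count table
#'
#' Reads a TSV with columns `gene_id`, `site_class`, `b73_ins`, `mo17_ins`,
#' `b73_noins`, `mo17_noins`.
#'
#' @param path Path to the TSV.
#' @return Tibble of allele-count records.
#' @export
read_allele_counts <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    site_class = readr::col_character(),
    b73_ins = readr::col_integer(),
    mo17_ins = readr::col_integer(),
    b73_noins = readr::col_integer(),
    mo17_noins = readr::col_integer()
  ))
}
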