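#' Published per-category insertion counts for Mu and P elements
#'
#' Per-category insertion counts for the maize Mu collections (germinal
#' UniformMu, SomaticMu), maize Pack-MULEs, the Drosophila P element, and the
#' matched in-silico random backgrounds, as printed in the published survey
#' of insertion enrichment in and near genes. Categories overlap by
#' construction (e.g. the 200-bp upstream window lies within the 500-bp one).
#'
#' @return Tibble with columns `dataset`, `total`, `category`, `count`.
#' @examples
#' counts <- mu_p_feature_counts()
#' subset(counts, dataset == "UniformMu_Zm" & category == "utr5")
#' @export
mu_p_feature_counts <- function() {
  path <- system.file("extdata", "mu_p_feature_counts.tsv",
                      package = "tetarget", mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    dataset = readr::col_character(),
    total = readr::col_integer(),
    category = readr::col_character(),
    count = readr::col_integer()
  ))
}

#' Published allele-specific counts for segregating Mu insertions
#'
#' Allele-specific transcript read counts for segregating Mu insertions in
#' B73/Mo17 hybrid maize seedlings, as printed in the published survey: for
#' each affected gene, the B73 (insertion) and Mo17 allele counts in
#' insertion-carrying individuals and in individuals without the insertion,
#' plus the annotated insertion site class.
#'
#' @return Tibble with columns `gene_id`, `site_class`, `b73_ins`,
#'   `mo17_ins`, `b73_noins`, `mo17_noins`.
#' @examples
#' rec <- score_allele_counts(mu_allele_counts())
#' head(rec[, c("gene_id", "index", "consequence")])
#' @export
mu_allele_counts <- function() {
  read_allele_counts(system.file("extdata", "mu_allele_counts.tsv",
                                 package = "tetarget", mustWork = TRUE))
}
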