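#' Generate random background loci
#'
#' Draws the in-silico random insertion set used as the background control in
#' every comparison. Per chromosome, `floor(length / spacing_bp)` loci are
#' placed: in `uniform_random` mode they are drawn uniformly without
#' replacement from `[1, length]`; in `regular_grid` mode they sit at
#' `spacing_bp, 2*spacing_bp, ...`. A density of one locus per 5 kb matches a
#' large maize-scale insertion collection; one per 400 bp suits small,
#' gene-dense genomes.
#'
#' @param chroms Chromosome tibble (`name`, `length`) or a `te_annotation`.
#' @param spacing_bp Mean spacing between loci in bp (default 5000).
#' @param seed Integer RNG seed; required in `uniform_random` mode so the
#'   background is reproducible.
#' @param mode `"uniform_random"` (default) or `"regular_grid"`.
#' @return A `te_insertions` tibble labeled `"random"`.
#' @examples
#' chroms <- tibble::tibble(name = "chr1", length = 1e6)
#' nrow(generate_random_loci(chroms, spacing_bp = 5000, seed = 1))
#' @export
generate_random_loci <- function(chroms, spacing_bp = 5000, seed = NULL,
                                 mode = c("uniform_random", "regular_grid")) {
  mode <- match.arg(mode)
  if (inherits(chroms, "te_annotation")) chroms <- chroms$chroms
  if (spacing_bp < 1) abort("spacing_bp must be >= 1")
  n_per <- floor(chroms$length / spacing_bp)
  if (all(n_per == 0L)) {
    warn("spacing larger than every chromosome: empty locus set")
  }
  if (mode == "uniform_random") {
    if (is.null(seed)) abort("uniform_random mode requires an explicit seed")
    pieces <- withr::with_seed(as.integer(seed), {
      purrr::map2(chroms$name, seq_len(nrow(chroms)), function(nm, i) {
        n <- n_per[i]
        if (n == 0L) return(NULL)
        tibble(chrom = nm,
               pos = sort(sample.int(chroms$length[i], n, replace = FALSE)))
      })
    })
  } else {
    pieces <- purrr::map2(chroms$name, seq_len(nrow(chroms)), function(nm, i) {
      n <- n_per[i]
      if (n == 0L) return(NULL)
      tibble(chrom = nm, pos = as.integer(spacing_bp) * seq_len(n))
    })
  }
  out <- dplyr::bind_rows(pieces)
  if (nrow(out) == 0L) out <- tibble(chrom = character(), pos = integer())
  insertion_set(out, label = "random", chroms = chroms)
}
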