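#' Rank genes into expression bins
#'
#' Per RNA-seq dataset, genes are sorted by ascending FPKM (ties broken
#' deterministically by `gene_id`, or randomly with `tie_shuffle_seed`) and
#' partitioned into `n_bins` contiguous, equal-sized groups — bin 1 holds the
#' lowest-expressed genes, bin `n_bins` the highest. When the gene count is
#' not divisible, the extra genes go to the low-expression bins. Binning is
#' per dataset: a bin is a categorical expression level, not a fixed gene set.
#'
#' @param expr Tibble with columns `gene_id`, `fpkm` (and optionally
#'   `dataset_id`, ignored here — see [bin_genes_all()]).
#' @param n_bins Number of bins (default 20).
#' @param tie_shuffle_seed Optional seed; when given, FPKM ties are broken by
#'   a seeded shuffle instead of `gene_id` order.
#' @return Tibble `gene_id`, `bin` (integer 1..`n_bins`).
#' @export
bin_genes <- function(expr, n_bins = 20, tie_shuffle_seed = NULL) {
  expr <- as_tibble(expr)
  if (anyNA(expr$fpkm) || any(!is.finite(expr$fpkm)) || any(expr$fpkm < 0)) {
    abort("fpkm values must be finite and non-negative")
  }
  n <- nrow(expr)
  if (n < n_bins) abort("fewer genes than bins")
  if (is.null(tie_shuffle_seed)) {
    ord <- order(expr$fpkm, expr$gene_id)
  } else {
    ord <- withr::with_seed(as.integer(tie_shuffle_seed), {
      order(expr$fpkm, sample.int(n))
    })
  }
  base <- n %/% n_bins
  extra <- n %% n_bins
  sizes <- rep(base, n_bins)
  if (extra > 0L) sizes[seq_len(extra)] <- base + 1L  # larger bins at the low end
  bin <- rep.int(seq_len(n_bins), sizes)
  tibble(gene_id = expr$gene_id[ord], bin = bin)
}

#' Bin every dataset of a long expression table
#'
#' @param expr Long tibble `dataset_id`, `gene_id`, `fpkm`.
#' @inheritParams bin_genes
#' @return Tibble `dataset_id`, `gene_id`, `bin`.
#' @export
bin_genes_all <- function(expr, n_bins = 20, tie_shuffle_seed = NULL) {
  expr <- as_tibble(expr)
  pieces <- lapply(split(expr, expr$dataset_id), function(d) {
    out <- bin_genes(d, n_bins = n_bins, tie_shuffle_seed = tie_shuffle_seed)
    out$dataset_id <- d$dataset_id[1]
    out
  })
  dplyr::bind_rows(pieces)[, c("dataset_id", "gene_id", "bin")]
}

#' TSS-associated insertion–gene pairs
#'
#' Pairs each insertion with every gene whose TSS it lies strictly upstream
#' of, within `max_dist` bp (signed TSS distance in `[-(max_dist - 1), -1]`
#' by default, or `[-(max_dist - 1), max_dist - 1]` excluding 0 when
#' `symmetric = TRUE`). An insertion in the shared upstream region of a
#' divergent gene pair yields one pair per gene.
#'
#' @param insertions A `te_insertions` tibble.
#' @param genes Gene tibble or `te_annotation`.
#' @param max_dist Window in bp (default 2000).
#' @param symmetric Also accept positions downstream of the TSS (default
#'   `FALSE`, upstream only).
#' @return Tibble `chrom`, `pos`, `gene_id`, `distance`.
#' @export
tss_associated <- function(insertions, genes, max_dist = 2000,
                           symmetric = FALSE) {
  if (inherits(genes, "te_annotation")) genes <- genes$genes
  ins <- as_tibble(insertions)
  lo <- ifelse(genes$strand == "+", genes$tss - max_dist + 1L, genes$tss + 1L)
  hi <- ifelse(genes$strand == "+", genes$tss - 1L, genes$tss + max_dist - 1L)
  if (symmetric) {
    lo <- genes$tss - max_dist + 1L
    hi <- genes$tss + max_dist - 1L
  }
  flank <- GenomicRanges::GRanges(genes$chrom, IRanges::IRanges(pmax(lo, 1L), hi))
  ins_gr <- GenomicRanges::GRanges(ins$chrom, IRanges::IRanges(ins$pos, width = 1L))
  hits <- GenomicRanges::findOverlaps(ins_gr, flank, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  d <- signed_distance(ins$pos[qh], genes$tss[sh], genes$tts[sh],
                       genes$strand[sh], "TSS")
  keep <- d != 0L
  tibble(chrom = ins$chrom[qh], pos = ins$pos[qh],
         gene_id = genes$gene_id[sh], distance = d)[keep, ]
}

#' Per-bin insertion percentage curve
#'
#' For each dataset's bin assignment, computes the percentage of
#' TSS-associated insertion–gene pairs whose gene falls in each bin, then the
#' mean and standard deviation of those percentages across datasets — each
#' RNA-seq dataset is treated as a replicate. Pairs whose gene is absent from
#' an assignment are dropped from that dataset's denominator (count reported
#' via a message).
#'
#' @param pairs Tibble from [tss_associated()] (needs `gene_id`).
#' @param assignments Tibble `dataset_id`, `gene_id`, `bin` from
#'   [bin_genes_all()].
#' @param n_bins Number of bins (default 20).
#' @return A `te_bin_curve` tibble: `bin`, `mean_pct`, `sd_pct`, with
#'   attributes `n_datasets` and the per-dataset percentage matrix.
#' @export
bin_curve <- function(pairs, assignments, n_bins = 20) {
  pairs <- as_tibble(pairs)
  if (nrow(pairs) == 0L) abort("no TSS-associated pairs for this insertion set")
  per <- lapply(split(assignments, assignments$dataset_id), function(a) {
    bins <- a$bin[match(pairs$gene_id, a$gene_id)]
    n_drop <- sum(is.na(bins))
    bins <- bins[!is.na(bins)]
    if (length(bins) == 0L) {
      abort(paste0("no binned genes for dataset ", a$dataset_id[1]))
    }
    list(pct = 100 * tabulate(bins, nbins = n_bins) / length(bins),
         dropped = n_drop)
  })
  dropped <- sum(vapply(per, `[[`, numeric(1), "dropped"))
  if (dropped > 0L) {
    inform(paste0(dropped, " pair(s) with unbinned genes dropped across datasets"))
  }
  mat <- do.call(rbind, lapply(per, `[[`, "pct"))
  out <- tibble(
    bin = seq_len(n_bins),
    mean_pct = colMeans(mat),
    sd_pct = apply(mat, 2, stats::sd)
  )
  if (nrow(mat) == 1L) out$sd_pct <- 0
  structure(out, n_datasets = nrow(mat), per_dataset = mat,
            class = c("te_bin_curve", class(out)))
}

#' Group-dominant gene sets
#'
#' Identifies genes expressed at high levels (bins in `high_bins`) in most
#' datasets of one tissue group while at mid levels (`mid_bins`) in most
#' datasets of the other — e.g. meristematic-dominant vs
#' differentiated-dominant genes with 6 tissues per group and support >= 5.
#'
#' @param assignments_a,assignments_b Bin assignments (tibbles `dataset_id`,
#'   `gene_id`, `bin`) for the two tissue groups.
#' @param high_bins,mid_bins Integer bin sets (defaults 16:20 and 8:12).
#' @param min_support Minimum number of datasets per group in which the
#'   condition must hold (default 5).
#' @return List with `a_dominant` and `b_dominant` character vectors of
#'   gene ids.
#' @export
dominant_gene_sets <- function(assignments_a, assignments_b,
                               high_bins = 16:20, mid_bins = 8:12,
                               min_support = 5) {
  n_a <- length(unique(assignments_a$dataset_id))
  n_b <- length(unique(assignments_b$dataset_id))
  if (n_a < min_support || n_b < min_support) {
    abort("each group needs at least min_support datasets")
  }
  support <- function(assign, bins) {
    x <- assign[assign$bin %in% bins, , drop = FALSE]
    tab <- table(x$gene_id)
    names(tab)[tab >= min_support]
  }
  a_high <- support(assignments_a, high_bins)
  a_mid <- support(assignments_a, mid_bins)
  b_high <- support(assignments_b, high_bins)
  b_mid <- support(assignments_b, mid_bins)
  list(a_dominant = sort(intersect(a_high, b_mid)),
       b_dominant = sort(intersect(b_high, a_mid)))
}

#' Insertion hotspot genes
#'
#' Flags genes hit near their TSS by strictly more than `min_uniform`
#' germinal-collection insertions and strictly more than `min_somatic`
#' somatic-collection insertions.
#'
#' @param uniform_counts,somatic_counts Tibbles `gene_id`, `count` of
#'   TSS-proximal insertions per gene in the two collections.
#' @param min_uniform,min_somatic Strict lower bounds (defaults 3 and 10, i.e.
#'   counts of at least 4 and 11 qualify).
#' @return Sorted character vector of hotspot gene ids.
#' @export
hotspot_genes <- function(uniform_counts, somatic_counts,
                          min_uniform = 3, min_somatic = 10) {
  u <- uniform_counts$gene_id[uniform_counts$count > min_uniform]
  s <- somatic_counts$gene_id[somatic_counts$count > min_somatic]
  sort(intersect(u, s))
}

#' Count TSS-proximal insertions per gene
#'
#' Helper feeding [hotspot_genes()]: counts [tss_associated()] pairs per gene.
#'
#' @inheritParams tss_associated
#' @return Tibble `gene_id`, `count`.
#' @export
tss_insertion_counts <- function(insertions, genes, max_dist = 2000) {
  pairs <- tss_associated(insertions, genes, max_dist = max_dist)
  dplyr::count(pairs, .data$gene_id, name = "count")
}
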