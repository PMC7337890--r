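#' Assign insertions to gene anchors
#'
#' For a TSS or TTS metaprofile, every insertion is first classified as genic
#' (inside at least one gene span) or intergenic. A genic insertion
#' contributes one record per containing gene at its signed distance to the
#' chosen anchor; an intergenic insertion contributes to both the nearest
#' gene on its left and the nearest gene on its right along the chromosome —
#' an insertion falling between two genes within reach of both is deliberately
#' counted twice. Records keep the genic-positive sign convention: genic
#' distances lie in `[0, halfwidth]`, intergenic distances in
#' `[-halfwidth, 0)`; contributions beyond `halfwidth`, and intergenic
#' distances that would cross a neighbor's gene body to its far anchor, are
#' dropped.
#'
#' @param insertions A `te_insertions` tibble (`chrom`, `pos`).
#' @param genes Gene tibble (from [load_annotation()]) or a `te_annotation`.
#' @param anchor `"TSS"` or `"TTS"`.
#' @param halfwidth Profile half-width in bp (default 4000).
#' @return Tibble with columns `gene_id`, `distance` (signed bp), `genic`
#'   (logical).
#' @export
assign_insertions_to_anchors <- function(insertions, genes,
                                         anchor = c("TSS", "TTS"),
                                         halfwidth = 4000) {
  anchor <- match.arg(anchor)
  if (inherits(genes, "te_annotation")) genes <- genes$genes
  ins <- as_tibble(insertions)[, c("chrom", "pos")]
  if (nrow(ins) == 0L || nrow(genes) == 0L) {
    return(tibble(gene_id = character(), distance = integer(), genic = logical()))
  }

  gene_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start, genes$end))
  ins_gr <- GenomicRanges::GRanges(ins$chrom, IRanges::IRanges(ins$pos, width = 1L))
  hits <- GenomicRanges::findOverlaps(ins_gr, gene_gr, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)

  genic_rec <- tibble(
    gene_id = genes$gene_id[sh],
    distance = signed_distance(ins$pos[qh], genes$tss[sh], genes$tts[sh],
                               genes$strand[sh], anchor),
    genic = TRUE
  )
  genic_rec <- genic_rec[genic_rec$distance >= 0L & genic_rec$distance <= halfwidth, ]

  inter_idx <- setdiff(seq_len(nrow(ins)), unique(qh))
  inter_rec <- tibble(gene_id = character(), distance = integer(), genic = logical())
  if (length(inter_idx) > 0L) {
    pieces <- lapply(split(inter_idx, ins$chrom[inter_idx]), function(idx) {
      chrom <- ins$chrom[idx[1]]
      g <- genes[genes$chrom == chrom, , drop = FALSE]
      if (nrow(g) == 0L) return(NULL)
      pos <- ins$pos[idx]
      ord_end <- order(g$end)
      ord_start <- order(g$start)
      ends <- g$end[ord_end]
      starts <- g$start[ord_start]
      # nearest gene wholly to the left: largest end < pos
      left_i <- findInterval(pos - 1L, ends)
      left <- ifelse(left_i >= 1L, ord_end[pmax(left_i, 1L)], NA_integer_)
      # nearest gene wholly to the right: smallest start > pos
      right_i <- findInterval(pos, starts) + 1L
      right <- ifelse(right_i <= nrow(g), ord_start[pmin(right_i, nrow(g))], NA_integer_)
      rec <- function(gi) {
        ok <- !is.na(gi)
        if (!any(ok)) return(NULL)
        gi <- gi[ok]
        tibble(
          gene_id = g$gene_id[gi],
          distance = signed_distance(pos[ok], g$tss[gi], g$tts[gi],
                                     g$strand[gi], anchor),
          genic = FALSE
        )
      }
      dplyr::bind_rows(rec(left), rec(right))
    })
    inter_rec <- dplyr::bind_rows(pieces)
    if (nrow(inter_rec) > 0L) {
      inter_rec <- inter_rec[inter_rec$distance < 0L & inter_rec$distance >= -halfwidth, ]
    }
  }
  out <- dplyr::bind_rows(genic_rec, inter_rec)
  attr(out, "anchor") <- anchor
  attr(out, "halfwidth") <- halfwidth
  out
}

#' Build a normalized insertion metaprofile
#'
#' Turns anchor-assignment records into the normalized density plotted in
#' gene-anchored metaprofiles: per-position raw counts (genic and intergenic
#' separately), a centered rolling window of `window_bp` positions
#' (`[x - 15, x + 14]` for the default 30 bp, truncated at the edges), then
#' scaling to insertions per window per 100,000 insertions per 10,000 anchors.
#'
#' @param records Tibble from [assign_insertions_to_anchors()] (`distance`,
#'   `genic`).
#' @param n_insertions Total insertions in the dataset (normalization
#'   denominator, not just those within reach of an anchor).
#' @param n_anchors Number of anchors (genes or islands) profiled.
#' @param halfwidth Profile half-width in bp (default 4000).
#' @param window_bp Rolling window width in positions (default 30).
#' @param smooth_stat `"sum"` (the rolling window total, default) or `"mean"`
#'   (divided by the effective window length).
#' @return A `te_metaprofile` tibble with columns `position`, `genic`,
#'   `intergenic`; attributes `anchor`, `n_insertions`, `n_anchors`,
#'   `window_bp`.
#' @export
metaprofile <- function(records, n_insertions, n_anchors, halfwidth = 4000,
                        window_bp = 30, smooth_stat = c("sum", "mean")) {
  smooth_stat <- match.arg(smooth_stat)
  if (window_bp < 1) abort("window_bp must be >= 1")
  if (n_insertions < 1 || n_anchors < 1) abort("normalization denominators must be >= 1")
  positions <- seq.int(-halfwidth, halfwidth)
  np <- length(positions)
  counts <- function(d) {
    d <- d[d >= -halfwidth & d <= halfwidth]
    tabulate(d + halfwidth + 1L, nbins = np)
  }
  raw_genic <- counts(records$distance[records$genic])
  raw_inter <- counts(records$distance[!records$genic])
  scale <- (1e5 / n_insertions) * (1e4 / n_anchors)
  out <- tibble(
    position = positions,
    genic = rolling_window(raw_genic, window_bp, smooth_stat) * scale,
    intergenic = rolling_window(raw_inter, window_bp, smooth_stat) * scale
  )
  structure(out,
            anchor = attr(records, "anchor") %||% "TSS",
            n_insertions = n_insertions, n_anchors = n_anchors,
            window_bp = window_bp, raw_genic = raw_genic, raw_inter = raw_inter,
            class = c("te_metaprofile", class(out)))
}

# centered rolling sum over [x - floor(w/2), x + ceiling(w/2) - 1] (for
# w = 30: [x - 15, x + 14]), edges truncated; "mean" divides by the
# effective (truncated) window length
rolling_window <- function(x, w, stat = "sum") {
  n <- length(x)
  a <- pmax(seq_len(n) - floor(w / 2), 1L)
  b <- pmin(seq_len(n) + ceiling(w / 2) - 1L, n)
  cs <- c(0, cumsum(x))
  s <- cs[b + 1L] - cs[a]
  if (stat == "mean") s <- s / (b - a + 1L)
  s
}

#' Profile insertions around an anchor in one call
#'
#' Convenience wrapper: [assign_insertions_to_anchors()] then [metaprofile()],
#' with denominators taken from the inputs (`n_insertions = nrow(insertions)`,
#' `n_anchors` = number of genes).
#'
#' @inheritParams assign_insertions_to_anchors
#' @inheritParams metaprofile
#' @return A `te_metaprofile`.
#' @export
profile_insertions <- function(insertions, genes, anchor = c("TSS", "TTS"),
                               halfwidth = 4000, window_bp = 30,
                               smooth_stat = c("sum", "mean")) {
  anchor <- match.arg(anchor)
  if (inherits(genes, "te_annotation")) genes <- genes$genes
  rec <- assign_insertions_to_anchors(insertions, genes, anchor, halfwidth)
  metaprofile(rec, n_insertions = max(nrow(insertions), 1L),
              n_anchors = max(nrow(genes), 1L),
              halfwidth = halfwidth, window_bp = window_bp,
              smooth_stat = match.arg(smooth_stat))
}

#' Metaprofile around CHH islands
#'
#' Maps each 100-bp CHH island onto the interval `[-50, 49]` with the
#' associated gene on the positive axis: islands whose gene lies to the left
#' are mirrored. Insertion offsets within `halfwidth` of each island are
#' accumulated and normalized to 100,000 insertions and 10,000 islands with
#' the same rolling window as [metaprofile()].
#'
#' @param insertions A `te_insertions` tibble.
#' @param islands Tibble with columns `chrom`, `start`, `end` (1-based,
#'   width exactly 100), `side` (`five_prime`/`three_prime`) and
#'   `gene_direction` (`left`/`right`).
#' @param halfwidth Half-width in bp (default 4000).
#' @param window_bp Rolling window width (default 30).
#' @return A `te_metaprofile` tibble with columns `position`, `value`.
#' @export
chh_profile <- function(insertions, islands, halfwidth = 4000, window_bp = 30) {
  if (any(islands$end - islands$start + 1L != 100L)) {
    abort("CHH islands must be exactly 100 bp wide")
  }
  ins <- as_tibble(insertions)
  isl_gr <- GenomicRanges::GRanges(
    islands$chrom,
    IRanges::IRanges(islands$start - halfwidth, islands$end + halfwidth)
  )
  ins_gr <- GenomicRanges::GRanges(ins$chrom, IRanges::IRanges(ins$pos, width = 1L))
  hits <- GenomicRanges::findOverlaps(ins_gr, isl_gr, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  # gene to the right: island start maps to -50; gene to the left: mirrored
  off <- ifelse(islands$gene_direction[sh] == "right",
                ins$pos[qh] - (islands$start[sh] + 50L),
                (islands$start[sh] + 49L) - ins$pos[qh])
  off <- off[off >= -halfwidth & off <= halfwidth]
  positions <- seq.int(-halfwidth, halfwidth)
  raw <- tabulate(off + halfwidth + 1L, nbins = length(positions))
  scale <- (1e5 / max(nrow(ins), 1L)) * (1e4 / max(nrow(islands), 1L))
  out <- tibble(position = positions,
                value = rolling_window(raw, window_bp) * scale)
  structure(out, anchor = "CHH", n_insertions = nrow(ins),
            n_anchors = nrow(islands), window_bp = window_bp, raw_value = raw,
            class = c("te_metaprofile", class(out)))
}

#' Pol II-distal tRNA/rRNA genes
#'
#' Returns the tRNA/rRNA genes whose own TSS lies more than `min_dist` bp from
#' the TSS of every protein-coding (Pol II) gene, isolating Pol I/III
#' transcription units from Pol II start sites.
#'
#' @param genes Gene tibble or `te_annotation`.
#' @param biotypes Biotypes to retain (default tRNA and rRNA).
#' @param min_dist Minimum TSS-to-TSS distance in bp (default 5000).
#' @return The qualifying subset of the gene tibble.
#' @export
filter_pol2_distal <- function(genes, biotypes = c("tRNA", "rRNA"),
                               min_dist = 5000) {
  if (inherits(genes, "te_annotation")) genes <- genes$genes
  cand <- genes[genes$biotype %in% biotypes, , drop = FALSE]
  pol2 <- genes[genes$biotype == "protein_coding", , drop = FALSE]
  if (nrow(cand) == 0L || nrow(pol2) == 0L) return(cand)
  keep <- vapply(seq_len(nrow(cand)), function(i) {
    same <- pol2$chrom == cand$chrom[i]
    if (!any(same)) return(TRUE)
    all(abs(pol2$tss[same] - cand$tss[i]) > min_dist)
  }, logical(1))
  cand[keep, , drop = FALSE]
}
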