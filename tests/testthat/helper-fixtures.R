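# synthetic fixtures shared across test files, built once per run
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

small_genome <- function() fixture("g400", function() simulate_genome(seed = 42))

small_expression <- function() {
  fixture("ex400", function() simulate_expression(small_genome(), seed = 7))
}

# larger genome for counting-statistics checks (flat backgrounds need many
# anchors and loci)
large_genome <- function() {
  fixture("g2000", function() {
    simulate_genome(n_chroms = 4, chrom_length = 8e6, n_genes = 2000, seed = 42)
  })
}

large_expression <- function() {
  fixture("ex2000", function() {
    simulate_expression(large_genome(), n_planted = 100, seed = 7)
  })
}

large_assignments <- function() {
  fixture("asg2000", function() bin_genes_all(large_expression()$expression))
}

# two hand-built genes with full sub-genic structure, one per strand
toy_annotation <- function() {
  genes <- tibble::tibble(
    gene_id = c("gA", "gB"),
    chrom = "chr1",
    strand = c("+", "-"),
    start = c(1000L, 10000L), end = c(3000L, 14000L),
    tss = c(1000L, 14000L), tts = c(3000L, 10000L),
    biotype = "protein_coding"
  )
  features <- tibble::tibble(
    gene_id = c("gA", "gA", "gA", "gA", "gB", "gB", "gB"),
    type = c("five_prime_UTR", "CDS", "CDS", "three_prime_UTR",
             "three_prime_UTR", "CDS", "five_prime_UTR"),
    start = c(1000L, 1201L, 2000L, 2601L, 10000L, 11000L, 13500L),
    end = c(1200L, 1800L, 2600L, 3000L, 10999L, 13499L, 14000L)
  )
  chroms <- tibble::tibble(name = "chr1", length = 50000L)
  structure(list(chroms = chroms, genes = genes, features = features),
            class = "te_annotation")
}

ins_at <- function(chrom, pos) {
  insertion_set(tibble::tibble(chrom = chrom, pos = as.integer(pos)))
}

# all-pairs oracle for anchor assignment: scans every insertion-gene pair
oracle_assign <- function(ins, genes, anchor, hw) {
  out <- list()
  for (i in seq_len(nrow(ins))) {
    g <- genes[genes$chrom == ins$chrom[i], , drop = FALSE]
    if (nrow(g) == 0L) next
    pos <- ins$pos[i]
    containing <- which(g$start <= pos & g$end >= pos)
    if (length(containing) > 0L) {
      for (j in containing) {
        d <- signed_distance(pos, g$tss[j], g$tts[j], g$strand[j], anchor)
        if (d >= 0 && d <= hw) {
          out[[length(out) + 1L]] <- tibble::tibble(
            gene_id = g$gene_id[j], distance = d, genic = TRUE)
        }
      }
    } else {
      lefts <- which(g$end < pos)
      rights <- which(g$start > pos)
      nb <- c(
        if (length(lefts)) lefts[which.max(g$end[lefts])],
        if (length(rights)) rights[which.min(g$start[rights])]
      )
      for (j in nb) {
        d <- signed_distance(pos, g$tss[j], g$tts[j], g$strand[j], anchor)
        if (d < 0 && d >= -hw) {
          out[[length(out) + 1L]] <- tibble::tibble(
            gene_id = g$gene_id[j], distance = d, genic = FALSE)
        }
      }
    }
  }
  dplyr::bind_rows(out)
}

# naive double-loop recount of the smoothed, normalized profile
oracle_profile <- function(records, n_ins, n_anch, hw, w = 30) {
  scale <- (1e5 / n_ins) * (1e4 / n_anch)
  positions <- seq.int(-hw, hw)
  count_at <- function(d) {
    vapply(positions, function(x) {
      sum(d >= x - floor(w / 2) & d <= x + ceiling(w / 2) - 1 & abs(d) <= hw)
    }, numeric(1))
  }
  tibble::tibble(
    position = positions,
    genic = count_at(records$distance[records$genic]) * scale,
    intergenic = count_at(records$distance[!records$genic]) * scale
  )
}

sort_records <- function(x) {
  y <- tibble::tibble(gene_id = as.character(x$gene_id),
                      distance = as.integer(x$distance),
                      genic = as.logical(x$genic))
  dplyr::arrange(y, gene_id, distance, genic)
}

divergent_pair <- function() {
  # gB (-) at [1000,3000] faces gA (+) at [5000,8000]: shared upstream region
  structure(list(
    chroms = tibble::tibble(name = "chr1", length = 20000L),
    genes = tibble::tibble(
      gene_id = c("gB", "gA"), chrom = "chr1", strand = c("-", "+"),
      start = c(1000L, 5000L), end = c(3000L, 8000L),
      tss = c(3000L, 5000L), tts = c(1000L, 8000L),
      biotype = "protein_coding"
    ),
    features = tibble::tibble(gene_id = character(), type = character(),
                              start = integer(), end = integer())
  ), class = "te_annotation")
}
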