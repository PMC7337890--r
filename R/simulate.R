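#' Simulate an annotated genome with CHH islands
#'
#' Packs non-overlapping genes onto a set of chromosomes. Each gene gets a
#' 5' UTR, one to `max_cds_exons` CDS exons separated by introns, and a
#' 3' UTR, laid out in gene orientation; 100-bp CHH islands are placed
#' immediately upstream of the 5' end and downstream of the 3' end of every
#' gene. Defaults emulate a compact gene-dense genome (one gene per ~11 kb
#' of intergenic space, as in rice-scale genomes) at package scale:
#' 4 chromosomes of 4 Mb carrying 400 genes.
#'
#' @param n_chroms Number of chromosomes (default 4).
#' @param chrom_length Chromosome length in bp (default 4e6).
#' @param n_genes Total genes (default 400), split evenly across chromosomes.
#' @param gene_length Length range of a gene span in bp (default 1000–6000).
#' @param utr5_length,utr3_length UTR length ranges in bp.
#' @param spacing Intergenic spacing range in bp (default 2000–20000).
#' @param max_cds_exons Maximum CDS exons per gene (default 4).
#' @param p_minus Probability a gene is on the `-` strand (default 0.5).
#' @param frac_trna_rrna Fraction of genes labeled tRNA/rRNA (default 0.02).
#' @param seed Integer RNG seed (required).
#' @return A `te_annotation` with an extra element `islands` (tibble `chrom`,
#'   `start`, `end`, `side`, `gene_direction`, `gene_id`).
#' @export
simulate_genome <- function(n_chroms = 4, chrom_length = 4e6, n_genes = 400,
                            gene_length = c(1000, 6000),
                            utr5_length = c(150, 500),
                            utr3_length = c(150, 400),
                            spacing = c(2000, 20000),
                            max_cds_exons = 4, p_minus = 0.5,
                            frac_trna_rrna = 0.02, seed) {
  if (missing(seed)) abort("simulate_genome requires an explicit seed")
  per_chrom <- rep(n_genes %/% n_chroms, n_chroms)
  extra <- n_genes %% n_chroms
  if (extra > 0L) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L
  withr::with_seed(as.integer(seed), {
    chroms <- tibble(name = paste0("chr", seq_len(n_chroms)),
                     length = as.integer(chrom_length))
    genes_list <- list()
    feats_list <- list()
    isl_list <- list()
    gid <- 0L
    for (ci in seq_len(n_chroms)) {
      cursor <- 200L  # leave room for a 5' island on the first gene
      for (k in seq_len(per_chrom[ci])) {
        gap <- round(runif(1, spacing[1], spacing[2]))
        glen <- round(runif(1, gene_length[1], gene_length[2]))
        start <- cursor + gap
        end <- start + glen - 1L
        if (end > chrom_length - 200L) {
          abort("infeasible packing: reduce n_genes or spacing, or enlarge chromosomes")
        }
        gid <- gid + 1L
        gene_id <- sprintf("gene%04d", gid)
        strand <- if (runif(1) < p_minus) "-" else "+"
        biotype <- if (runif(1) < frac_trna_rrna) {
          sample(c("tRNA", "rRNA"), 1)
        } else "protein_coding"
        genes_list[[gid]] <- tibble(
          gene_id = gene_id, chrom = chroms$name[ci], strand = strand,
          start = as.integer(start), end = as.integer(end),
          tss = if (strand == "+") as.integer(start) else as.integer(end),
          tts = if (strand == "+") as.integer(end) else as.integer(start),
          biotype = biotype
        )
        if (biotype == "protein_coding") {
          feats_list[[gid]] <- gene_structure(gene_id, start, end, strand,
                                              utr5_length, utr3_length,
                                              max_cds_exons)
        }
        five_start <- if (strand == "+") start - 100L else end + 1L
        three_start <- if (strand == "+") end + 1L else start - 100L
        isl_list[[gid]] <- tibble(
          chrom = chroms$name[ci],
          start = as.integer(c(five_start, three_start)),
          end = as.integer(c(five_start, three_start)) + 99L,
          side = c("five_prime", "three_prime"),
          gene_direction = if (strand == "+") c("right", "left")
                           else c("left", "right"),
          gene_id = gene_id
        )
        cursor <- end
      }
    }
    ann <- new_te_annotation(chroms, dplyr::bind_rows(genes_list),
                             dplyr::bind_rows(feats_list))
    ann$islands <- dplyr::bind_rows(isl_list)
    ann
  })
}

# UTR/CDS/intron layout inside one gene span, in genomic coordinates
gene_structure <- function(gene_id, start, end, strand,
                           utr5_length, utr3_length, max_cds_exons) {
  glen <- end - start + 1L
  u5 <- min(round(runif(1, utr5_length[1], utr5_length[2])), glen %/% 4L)
  u3 <- min(round(runif(1, utr3_length[1], utr3_length[2])), glen %/% 4L)
  coding <- glen - u5 - u3
  n_ex <- sample.int(max_cds_exons, 1)
  # split coding region into n_ex exons separated by introns, all >= 50 bp
  n_in <- n_ex - 1L
  min_piece <- 50L
  need <- (n_ex + n_in) * min_piece
  if (coding < need) { n_ex <- 1L; n_in <- 0L }
  pieces <- n_ex + n_in
  w <- as.vector(stats::rmultinom(1, coding - pieces * min_piece,
                                  rep(1, pieces))) + min_piece
  # local coordinates along gene orientation: 5'UTR, exon/intron alternation, 3'UTR
  bounds <- cumsum(c(u5, w))
  piece_start <- c(1L, head(bounds, -1) + 1L)[-1L]
  piece_end <- bounds[-1L]
  is_exon <- seq_len(pieces) %% 2L == 1L
  loc <- tibble(
    type = c("five_prime_UTR", ifelse(is_exon, "CDS", "intron"),
             "three_prime_UTR"),
    lstart = c(1L, piece_start, bounds[length(bounds)] + 1L),
    lend = c(u5, piece_end, glen)
  )
  loc <- loc[loc$type != "intron", , drop = FALSE]
  if (strand == "+") {
    gs <- start + loc$lstart - 1L
    ge <- start + loc$lend - 1L
  } else {
    gs <- end - loc$lend + 1L
    ge <- end - loc$lstart + 1L
  }
  out <- tibble(gene_id = gene_id, type = loc$type,
                start = as.integer(gs), end = as.integer(ge))
  dplyr::arrange(out, .data$start)
}

#' Simulate per-tissue expression tables with planted dominant genes
#'
#' Draws log-normal FPKM values for `n_datasets` datasets split into two
#' tissue groups, and plants `n_planted` group-A-dominant genes (high
#' expression rank in group A, mid rank in group B) plus `n_planted`
#' group-B-dominant genes (the mirror image). Planting is exact in rank: per
#' dataset each planted gene is assigned a target rank inside the high or mid
#' quantile window (gene-to-rank mapping shuffled per dataset) and given an
#' FPKM interpolated between the neighboring order statistics of the
#' background genes, so it lands in the intended expression bins by
#' construction.
#'
#' @param genes Gene tibble or `te_annotation`.
#' @param n_datasets Total datasets (default 12, split 6 + 6).
#' @param n_planted Planted dominant genes per direction (default 50).
#' @param high_q,mid_q Target rank-quantile windows for the high and mid
#'   levels (defaults c(0.78, 0.98) and c(0.38, 0.58), inside bins 16–20 and
#'   8–12 of a 20-bin split with half-a-bin margins). Gene counts divisible
#'   by 20 keep the bin boundaries exact.
#' @param sdlog Dataset-level log-normal noise on the log scale (default 0.5).
#' @param seed Integer RNG seed (required).
#' @return List with `expression` (long tibble `dataset_id`, `gene_id`,
#'   `fpkm`), `groups` (tibble `dataset_id`, `group` in `"A"`/`"B"`), and
#'   `truth` (list `a_dominant`, `b_dominant`).
#' @export
simulate_expression <- function(genes, n_datasets = 12, n_planted = 50,
                                high_q = c(0.78, 0.98), mid_q = c(0.38, 0.58),
                                sdlog = 0.5, seed) {
  if (missing(seed)) abort("simulate_expression requires an explicit seed")
  if (inherits(genes, "te_annotation")) genes <- genes$genes
  ids <- genes$gene_id
  n <- length(ids)
  if (n_planted > 0L && 2L * n_planted > n %/% 4L) {
    abort("n_planted too large for the gene count")
  }
  if (n_datasets %% 2L != 0L) abort("n_datasets must be even (two groups)")
  rank_targets <- function(qr) {
    lo <- ceiling(qr[1] * n)
    hi <- floor(qr[2] * n)
    if (hi - lo + 1L < n_planted) abort("quantile window too narrow for n_planted")
    unique(round(seq(lo, hi, length.out = n_planted)))
  }
  withr::with_seed(as.integer(seed), {
    planted_a <- if (n_planted > 0L) sample(ids, n_planted) else character()
    planted_b <- if (n_planted > 0L) {
      sample(setdiff(ids, planted_a), n_planted)
    } else character()
    background <- setdiff(ids, c(planted_a, planted_b))
    gene_mu <- stats::rnorm(n, mean = 1, sd = 1.2)
    names(gene_mu) <- ids
    groups <- tibble(
      dataset_id = sprintf("ds%02d", seq_len(n_datasets)),
      group = rep(c("A", "B"), each = n_datasets %/% 2L)
    )
    expr <- purrr::map2_dfr(groups$dataset_id, groups$group, function(dsid, grp) {
      fpkm <- stats::rlnorm(n, meanlog = gene_mu, sdlog = sdlog)
      names(fpkm) <- ids
      if (n_planted > 0L) {
        high_set <- if (grp == "A") planted_a else planted_b
        mid_set <- if (grp == "A") planted_b else planted_a
        plan <- tibble(
          gene = c(sample(mid_set), sample(high_set)),
          rank = c(rank_targets(mid_q), rank_targets(high_q))
        )
        bg <- sort(fpkm[background])
        # planted gene with final rank r_i (i-th smallest planted rank) sits
        # between background order statistics r_i - i and r_i - i + 1
        i <- seq_len(nrow(plan))
        below <- plan$rank - i
        fpkm[plan$gene] <- (bg[below] + bg[below + 1L]) / 2
      }
      tibble(dataset_id = dsid, gene_id = ids, fpkm = unname(fpkm))
    })
    list(expression = expr, groups = groups,
         truth = list(a_dominant = sort(planted_a),
                      b_dominant = sort(planted_b)))
  })
}

#' Targeting model for insertion simulation
#'
#' @param kind `"typeA"` (TSS-anchored, high-expression weighted), `"typeB"`
#'   (TSS + TTS double peak, medium-expression weighted), `"typeC_body"`
#'   (uniform within gene bodies) or `"uniform"` (uniform over the genome).
#' @param n_insertions Number of insertions to draw.
#' @param tss_offset_mean,tss_offset_sd Peak location and spread in bp for the
#'   anchored kinds (defaults 0 and 100).
#' @param expression_weighting `"high"`, `"medium"`, `"low"` or `"none"`;
#'   defaults to the kind's canonical weighting.
#' @param tts_weight Fraction of type-B insertions anchored at the TTS
#'   (default 0.5).
#' @param seed Integer RNG seed (required).
#' @return A `te_targeting_model` list.
#' @export
targeting_model <- function(kind = c("typeA", "typeB", "typeC_body", "uniform"),
                            n_insertions, tss_offset_mean = 0,
                            tss_offset_sd = 100,
                            expression_weighting = NULL, tts_weight = 0.5,
                            seed) {
  kind <- match.arg(kind)
  if (missing(seed)) abort("targeting_model requires an explicit seed")
  if (is.null(expression_weighting)) {
    expression_weighting <- switch(kind, typeA = "high", typeB = "medium",
                                   typeC_body = "none", uniform = "none")
  }
  structure(list(kind = kind, n_insertions = as.integer(n_insertions),
                 tss_offset_mean = tss_offset_mean,
                 tss_offset_sd = tss_offset_sd,
                 expression_weighting = expression_weighting,
                 tts_weight = tts_weight, seed = as.integer(seed)),
            class = "te_targeting_model")
}

# selection weight per gene from its expression rank percentile in (0, 1]
expression_weights <- function(rank_pct, weighting) {
  switch(weighting,
         high = rank_pct^4,
         medium = exp(-((rank_pct - 0.5) / 0.12)^2 / 2),
         low = (1 - rank_pct)^4,
         none = rep(1, length(rank_pct)),
         abort("unknown expression weighting"))
}

#' Simulate TE insertions under a targeting model
#'
#' Type-A insertions pick a gene with probability increasing in its mean
#' expression rank and land near the TSS with an asymmetric offset — sharp
#' upstream, heavier-tailed into the gene body — so the aggregate profile
#' falls off rapidly upstream of the TSS and more gradually downstream.
#' Type B mixes TSS- and TTS-anchored insertions in medium-expressed genes;
#' `typeC_body` places insertions uniformly within gene bodies; `uniform`
#' scatters them over the whole genome. Positions are clipped to chromosome
#' bounds; the draw is deterministic under the model's seed.
#'
#' @param genes Gene tibble or `te_annotation`.
#' @param model A `te_targeting_model`.
#' @param expr Optional long expression tibble used for the expression
#'   weighting (mean FPKM rank across datasets); required unless the model's
#'   weighting is `"none"`.
#' @param chroms Chromosome tibble; taken from `genes` when it is a
#'   `te_annotation`.
#' @return A `te_insertions` tibble labeled with the model kind.
#' @export
simulate_insertions <- function(genes, model, expr = NULL, chroms = NULL) {
  if (inherits(genes, "te_annotation")) {
    if (is.null(chroms)) chroms <- genes$chroms
    genes <- genes$genes
  }
  if (is.null(chroms)) abort("chromosome lengths required")
  n <- model$n_insertions
  if (n == 0L) {
    return(insertion_set(tibble(chrom = character(), pos = integer()),
                         label = model$kind))
  }
  glen <- setNames(chroms$length, chroms$name)
  withr::with_seed(model$seed, {
    if (model$kind == "uniform") {
      chrom <- sample(chroms$name, n, replace = TRUE,
                      prob = chroms$length / sum(chroms$length))
      pos <- floor(runif(n) * glen[chrom]) + 1
    } else {
      w <- rep(1, nrow(genes))
      if (model$expression_weighting != "none") {
        if (is.null(expr)) abort("expression table required for this weighting")
        mean_fpkm <- expr |>
          dplyr::group_by(.data$gene_id) |>
          dplyr::summarise(m = mean(.data$fpkm), .groups = "drop")
        m <- mean_fpkm$m[match(genes$gene_id, mean_fpkm$gene_id)]
        m[is.na(m)] <- 0
        rank_pct <- rank(m, ties.method = "average") / length(m)
        w <- expression_weights(rank_pct, model$expression_weighting)
      }
      gi <- sample.int(nrow(genes), n, replace = TRUE, prob = w)
      if (model$kind == "typeC_body") {
        offset_in_gene <- floor(runif(n) * (genes$end[gi] - genes$start[gi] + 1))
        pos <- genes$start[gi] + offset_in_gene
      } else {
        at_tts <- model$kind == "typeB" & runif(n) < model$tts_weight
        # asymmetric spread: sharp on the intergenic side, wider genic tail
        genic_side <- runif(n) < 0.7
        mag <- abs(rnorm(n, 0, model$tss_offset_sd))
        offset <- model$tss_offset_mean +
          ifelse(genic_side, mag, -round(mag / 2))
        anchor_pos <- ifelse(at_tts, genes$tts[gi], genes$tss[gi])
        # a genic-positive offset at the TTS points upstream into the body
        dir <- ifelse(genes$strand[gi] == "+", 1L, -1L) *
          ifelse(at_tts, -1L, 1L)
        pos <- anchor_pos + dir * round(offset)
      }
      chrom <- genes$chrom[gi]
      pos <- pmin(pmax(pos, 1), glen[chrom])
    }
    insertion_set(tibble(chrom = as.character(chrom), pos = as.integer(pos)),
                  label = model$kind, chroms = chroms)
  })
}

#' Simulate allele-specific count tables with known effects
#'
#' Draws a true knockdown index per record (log-normal by default, with a
#' `p_knockout` chance of complete silencing), balanced allele expression in
#' the no-insertion group, and binomial read sampling at the drawn depth in
#' both groups, emulating the shape of an allele-specific RT-PCR/RNA-seq
#' survey.
#'
#' @param n_records Number of insertion records.
#' @param index_meanlog,index_sdlog Log-normal parameters of the true index
#'   (defaults 0.7 and 1).
#' @param p_knockout Probability a record is a complete knockout (true index
#'   infinite; default 0.05).
#' @param depth Read-depth range per group (default 200–1500).
#' @param site_classes Site classes sampled uniformly for the records.
#' @param seed Integer RNG seed (required).
#' @return List with `records` (allele-count tibble) and `truth` (numeric
#'   vector of true indices, `Inf` for knockouts).
#' @export
simulate_allele_counts <- function(n_records, index_meanlog = 0.7,
                                   index_sdlog = 1, p_knockout = 0.05,
                                   depth = c(200, 1500),
                                   site_classes = c("promoter",
                                                    "five_prime_UTR",
                                                    "intron",
                                                    "three_prime_UTR", "CDS"),
                                   seed) {
  if (missing(seed)) abort("simulate_allele_counts requires an explicit seed")
  withr::with_seed(as.integer(seed), {
    true_index <- stats::rlnorm(n_records, index_meanlog, index_sdlog)
    ko <- runif(n_records) < p_knockout
    true_index[ko] <- Inf
    d_ins <- round(runif(n_records, depth[1], depth[2]))
    d_noins <- round(runif(n_records, depth[1], depth[2]))
    # no-insertion group: balanced alleles (ratio 1)
    b73_noins <- rbinom(n_records, d_noins, 0.5)
    b73_noins <- pmax(b73_noins, 1L)
    mo17_noins <- pmax(d_noins - b73_noins, 1L)
    # insertion group: mo17/b73 ratio = true_index (normalizing ratio is 1)
    p_b73 <- ifelse(is.infinite(true_index), 0, 1 / (1 + true_index))
    b73_ins <- rbinom(n_records, d_ins, p_b73)
    mo17_ins <- d_ins - b73_ins
    records <- tibble(
      gene_id = sprintf("sim_gene%04d", seq_len(n_records)),
      site_class = sample(site_classes, n_records, replace = TRUE),
      b73_ins = as.integer(b73_ins),
      mo17_ins = as.integer(mo17_ins),
      b73_noins = as.integer(b73_noins),
      mo17_noins = as.integer(mo17_noins)
    )
    list(records = records, truth = true_index)
  })
}
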