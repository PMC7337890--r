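test_that("genes split into equal-sized, order-preserving bins", {
  expr <- tibble::tibble(gene_id = sprintf("g%02d", 1:40), fpkm = (1:40) * 1.5)
  b <- bin_genes(expr)
  expect_equal(as.vector(table(b$bin)), rep(2L, 20))
  # ascending FPKM maps to ascending bins
  expect_equal(b$bin[match(expr$gene_id, b$gene_id)], rep(1:20, each = 2))
  expect_error(bin_genes(expr[1:10, ]), "fewer genes than bins")
  expect_error(bin_genes(tibble::tibble(gene_id = "a", fpkm = -1), n_bins = 1),
               "non-negative")
})

test_that("FPKM ties resolve deterministically by gene id", {
  expr <- tibble::tibble(gene_id = sprintf("g%02d", 40:1), fpkm = 0)
  b <- bin_genes(expr)
  expect_equal(as.vector(table(b$bin)), rep(2L, 20))
  expect_equal(b$gene_id, sort(expr$gene_id))
  # permutation invariance: shuffled rows give the same assignment
  withr::with_seed(3, shuffled <- expr[sample.int(40), ])
  expect_equal(dplyr::arrange(bin_genes(shuffled), gene_id),
               dplyr::arrange(b, gene_id))
})

test_that("binning equals an independent sort-then-split oracle", {
  withr::with_seed(13, {
    expr <- tibble::tibble(gene_id = sprintf("g%04d", 1:1000),
                           fpkm = rlnorm(1000))
  })
  b <- bin_genes(expr)
  # oracle: rank each gene, then map rank ranges to bins (50 genes per bin)
  r <- rank(expr$fpkm, ties.method = "first")
  oracle_bin <- ceiling(r / 50)
  expect_equal(b$bin[match(expr$gene_id, b$gene_id)], oracle_bin)

  # uneven split: extra genes enlarge the low-expression bins
  b43 <- bin_genes(expr[1:43, ])
  expect_equal(as.vector(table(b43$bin)), c(rep(3L, 3), rep(2L, 17)))
})

test_that("TSS association keeps strictly-upstream insertions within 2 kb", {
  toy <- toy_annotation()   # gA + TSS at 1000, gB - TSS at 14000
  expect_equal(tss_associated(ins_at("chr1", 900L), toy$genes)$gene_id, "gA")
  expect_equal(tss_associated(ins_at("chr1", 900L), toy$genes)$distance, -100L)
  expect_equal(nrow(tss_associated(ins_at("chr1", 16500L), toy$genes)), 0L)
  # boundary: 1999 bp upstream in, 2000 out, at the TSS out
  expect_equal(tss_associated(ins_at("chr1", 15999L), toy$genes)$distance, -1999L)
  expect_equal(nrow(tss_associated(ins_at("chr1", 16000L), toy$genes)), 0L)
  expect_equal(nrow(tss_associated(ins_at("chr1", 14000L), toy$genes)), 0L)
  # divergent pair: shared upstream insertion pairs with both genes
  ann <- divergent_pair()
  both <- tss_associated(ins_at("chr1", 4000L), ann$genes)
  expect_setequal(both$gene_id, c("gA", "gB"))

  # exhaustive-scan oracle on a simulated genome
  g <- small_genome()
  withr::with_seed(29, {
    ins <- insertion_set(tibble::tibble(
      chrom = sample(g$chroms$name, 500, replace = TRUE),
      pos = sample.int(4e6, 500)))
  })
  got <- tss_associated(ins, g$genes)
  want <- 0L
  for (i in seq_len(nrow(ins))) {
    gg <- g$genes[g$genes$chrom == ins$chrom[i], ]
    d <- signed_distance(ins$pos[i], gg$tss, gg$tts, gg$strand, "TSS")
    want <- want + sum(d <= -1 & d >= -1999)
  }
  expect_equal(nrow(got), want)
})

test_that("bin curves average per-dataset percentages with their SD", {
  pairs <- tibble::tibble(gene_id = c("a", "a", "b", "c"))
  assignments <- dplyr::bind_rows(
    tibble::tibble(dataset_id = "d1", gene_id = c("a", "b", "c"),
                   bin = c(20L, 20L, 10L)),
    tibble::tibble(dataset_id = "d2", gene_id = c("a", "b", "c"),
                   bin = c(20L, 10L, 10L))
  )
  bc <- bin_curve(pairs, assignments)
  # d1: 75% bin 20, 25% bin 10; d2: 50% bin 20, 50% bin 10
  expect_equal(bc$mean_pct[bc$bin == 20], mean(c(75, 50)))
  expect_equal(bc$mean_pct[bc$bin == 10], mean(c(25, 50)))
  expect_equal(bc$sd_pct[bc$bin == 20], sd(c(75, 50)))
  expect_equal(attr(bc, "n_datasets"), 2L)
  expect_equal(rowSums(attr(bc, "per_dataset")), c(100, 100),
               ignore_attr = TRUE)

  # single-bin degenerate case
  one <- bin_curve(tibble::tibble(gene_id = "a"),
                   tibble::tibble(dataset_id = "d1", gene_id = "a", bin = 20L))
  expect_equal(one$mean_pct, c(rep(0, 19), 100))
  expect_equal(one$sd_pct, rep(0, 20))

  expect_error(bin_curve(pairs[0, ], assignments), "no TSS-associated")
})

test_that("per-dataset bin percentages always sum to 100", {
  g <- large_genome()
  asg <- large_assignments()
  m <- targeting_model("typeB", n_insertions = 3000, seed = 8)
  ins <- simulate_insertions(g, m, expr = large_expression()$expression)
  bc <- bin_curve(tss_associated(ins, g$genes), asg)
  expect_equal(rowSums(attr(bc, "per_dataset")),
               rep(100, attr(bc, "n_datasets")), ignore_attr = TRUE,
               tolerance = 1e-9)
})

test_that("type-A curves rise with expression while uniform stays flat", {
  g <- large_genome()
  ex <- large_expression()
  asg <- large_assignments()
  m <- targeting_model("typeA", n_insertions = 5000, seed = 13)
  bca <- bin_curve(tss_associated(simulate_insertions(g, m, expr = ex$expression),
                                  g$genes), asg)
  rho_a <- suppressWarnings(cor(bca$bin, bca$mean_pct, method = "spearman"))
  expect_gt(rho_a, 0.8)

  # a flat curve's bin ranks are pure noise, so the rank-correlation bound
  # holds for the seed-ensemble mean rather than any single draw
  rhos <- vapply(1:5, function(s) {
    mu <- targeting_model("uniform", n_insertions = 50000, seed = s)
    bcu <- bin_curve(tss_associated(simulate_insertions(g, mu), g$genes), asg)
    suppressWarnings(cor(bcu$bin, bcu$mean_pct, method = "spearman"))
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.3)
})

test_that("dominant gene sets require majority support in both groups", {
  mk <- function(prefix, bins_per_gene) {
    dplyr::bind_rows(lapply(seq_along(bins_per_gene[[1]]), function(d) {
      tibble::tibble(
        dataset_id = paste0(prefix, d),
        gene_id = names(bins_per_gene),
        bin = vapply(bins_per_gene, `[`, integer(1), d)
      )
    }))
  }
  gene_bins_a <- list(g1 = rep(17L, 6), g2 = c(17L, 17L, 17L, 17L, 3L, 3L),
                      g3 = rep(10L, 6))
  gene_bins_b <- list(g1 = rep(10L, 6), g2 = rep(10L, 6), g3 = rep(17L, 6))
  dom <- dominant_gene_sets(mk("a", gene_bins_a), mk("b", gene_bins_b))
  expect_equal(dom$a_dominant, "g1")   # g2 has only 4/6 high support
  expect_equal(dom$b_dominant, "g3")
  expect_error(dominant_gene_sets(mk("a", gene_bins_a)[1:12, ],
                                  mk("b", gene_bins_b)), "min_support")
})

test_that("planted dominant genes are recovered exactly", {
  ex <- small_expression()
  asg <- bin_genes_all(ex$expression)
  in_a <- asg$dataset_id %in% ex$groups$dataset_id[ex$groups$group == "A"]
  dom <- dominant_gene_sets(asg[in_a, ], asg[!in_a, ])
  expect_setequal(dom$a_dominant, ex$truth$a_dominant)
  expect_setequal(dom$b_dominant, ex$truth$b_dominant)
})

test_that("unplanted expression yields almost no dominant calls", {
  ex0 <- simulate_expression(small_genome(), n_planted = 0, seed = 9)
  asg0 <- bin_genes_all(ex0$expression)
  in_a <- asg0$dataset_id %in% ex0$groups$dataset_id[ex0$groups$group == "A"]
  dom0 <- dominant_gene_sets(asg0[in_a, ], asg0[!in_a, ])
  n_genes <- nrow(small_genome()$genes)
  expect_lt(length(dom0$a_dominant) + length(dom0$b_dominant), 0.01 * n_genes)
})

test_that("hotspot calling uses strict count thresholds", {
  u <- tibble::tibble(gene_id = c("g1", "g2", "g3"), count = c(4L, 3L, 10L))
  s <- tibble::tibble(gene_id = c("g1", "g2", "g3"), count = c(11L, 50L, 10L))
  expect_equal(hotspot_genes(u, s), "g1")
  # brute-force filter oracle on random counts
  withr::with_seed(37, {
    uc <- tibble::tibble(gene_id = sprintf("g%03d", 1:200),
                         count = rpois(200, 4))
    sc <- tibble::tibble(gene_id = sprintf("g%03d", 1:200),
                         count = rpois(200, 11))
  })
  want <- intersect(uc$gene_id[uc$count >= 4], sc$gene_id[sc$count >= 11])
  expect_setequal(hotspot_genes(uc, sc), want)
})
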