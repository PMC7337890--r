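test_that("feature flags follow strand-aware windows and interval membership", {
  ann <- toy_annotation()
  # 100 bp upstream of gA's TSS (+ strand)
  f <- classify_features(ins_at("chr1", 900L), ann)
  expect_true(f$up500 && f$up200)
  expect_false(f$genic || f$utr5 || f$cds)
  # inside a CDS interval
  f2 <- classify_features(ins_at("chr1", 1500L), ann)
  expect_true(f2$genic && f2$cds)
  expect_false(f2$intron || f2$utr5)
  # in the unannotated gap between gA's CDS intervals
  f3 <- classify_features(ins_at("chr1", 1900L), ann)
  expect_true(f3$genic && f3$intron)
  # boundaries inclusive at exactly 200/500 bp, on both strands
  expect_true(classify_features(ins_at("chr1", 800L), ann)$up200)
  expect_false(classify_features(ins_at("chr1", 799L), ann)$up200)
  expect_true(classify_features(ins_at("chr1", 500L), ann)$up500)
  expect_false(classify_features(ins_at("chr1", 499L), ann)$up500)
  expect_true(classify_features(ins_at("chr1", 14200L), ann)$up200)  # gB is -
  expect_false(classify_features(ins_at("chr1", 14201L), ann)$up200)
  # downstream of gB's TTS at 10000 (- strand): lower coordinates
  f4 <- classify_features(ins_at("chr1", 9810L), ann)
  expect_true(f4$down200 && f4$down500)
  expect_false(classify_features(ins_at("chr1", 9799L), ann)$down200)
})

test_that("feature flags match a brute-force per-gene interval scan", {
  ann <- small_genome()
  withr::with_seed(43, {
    ins <- insertion_set(tibble::tibble(
      chrom = sample(ann$chroms$name, 200, replace = TRUE),
      pos = sample.int(4e6, 200)))
  })
  got <- classify_features(ins, ann)
  genes <- ann$genes
  feats <- dplyr::left_join(ann$features,
                            genes[, c("gene_id", "chrom")], by = "gene_id")
  for (i in seq_len(nrow(ins))) {
    pos <- ins$pos[i]
    g <- genes[genes$chrom == ins$chrom[i], ]
    fi <- feats[feats$chrom == ins$chrom[i], ]
    genic <- any(g$start <= pos & g$end >= pos)
    d_tss <- signed_distance(pos, g$tss, g$tts, g$strand, "TSS")
    d_tts <- signed_distance(pos, g$tss, g$tts, g$strand, "TTS")
    in_feat <- function(type) {
      f <- fi[fi$type == type, ]
      any(f$start <= pos & f$end >= pos)
    }
    expect_equal(got$genic[i], genic)
    expect_equal(got$up500[i], any(d_tss >= -500 & d_tss <= -1))
    expect_equal(got$up200[i], any(d_tss >= -200 & d_tss <= -1))
    expect_equal(got$utr5[i], in_feat("five_prime_UTR"))
    expect_equal(got$cds[i], in_feat("CDS"))
    expect_equal(got$utr3[i], in_feat("three_prime_UTR"))
    expect_equal(got$intron[i], genic && !in_feat("five_prime_UTR") &&
                   !in_feat("CDS") && !in_feat("three_prime_UTR"))
    expect_equal(got$down200[i], any(d_tts >= -200 & d_tts <= -1))
    expect_equal(got$down500[i], any(d_tts >= -500 & d_tts <= -1))
  }
})

test_that("enrichment folds reproduce published values from printed counts", {
  expect_equal(enrichment_fold(25142, 92702, 1268, 421280), 90.1,
               tolerance = 0.1 / 90)
  expect_equal(enrichment_fold(61393, 320044, 9188, 421280), 8.8,
               tolerance = 0.05 / 8.8)
  expect_equal(enrichment_fold(10, 100, 20, 200), 1)
  expect_warning(f0 <- enrichment_fold(5, 100, 0, 200), "Inf")
  expect_identical(f0, Inf)
  expect_error(enrichment_fold(1, 0, 1, 10), "totals")
})

test_that("fold is invariant to rescaling one set's counts", {
  withr::with_seed(53, {
    for (i in 1:20) {
      a <- sample.int(500, 1); ta <- a + sample.int(5000, 1)
      b <- sample.int(500, 1); tb <- b + sample.int(5000, 1)
      k <- sample.int(9, 1) + 1L
      expect_equal(enrichment_fold(a * k, ta * k, b, tb),
                   enrichment_fold(a, ta, b, tb))
    }
  })
})

test_that("category chi-square equals the textbook Pearson statistic", {
  # identical proportions
  eq <- category_chi2(10, 100, 20, 200)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  # hand-computed Pearson on (8,92 | 3,97)
  pearson <- function(a, ta, b, tb) {
    o <- c(a, ta - a, b, tb - b)
    n <- ta + tb
    e <- c((a + b) * ta, (n - a - b) * ta, (a + b) * tb, (n - a - b) * tb) / n
    sum((o - e)^2 / e)
  }
  got <- category_chi2(8, 100, 3, 100)
  expect_equal(got$statistic, pearson(8, 100, 3, 100))
  # property: agreement on random 2x2 tables with positive margins
  withr::with_seed(59, {
    for (i in 1:25) {
      a <- sample.int(50, 1); ta <- a + sample.int(400, 1)
      b <- sample.int(50, 1); tb <- b + sample.int(400, 1)
      expect_equal(category_chi2(a, ta, b, tb)$statistic,
                   pearson(a, ta, b, tb))
    }
  })
  # published 5' UTR contrast is overwhelming
  expect_lt(category_chi2(25142, 92702, 1268, 421280)$p_value, 1e-5)
  expect_true(category_chi2(1, 10, 1, 1000)$expected_warning)
})

test_that("a random set against itself gives unit folds and p = 1", {
  g <- small_genome()
  r <- generate_random_loci(g$chroms, spacing_bp = 2000, seed = 61)
  tab <- enrichment_table(r, r, g)
  expect_equal(tab$fold, rep(1, 8))
  expect_equal(tab$p_value, rep(1, 8))
  expect_error(enrichment_table(r[0, ], r, g), "empty")
})

test_that("type-A sets are more enriched upstream/5'UTR than in CDS", {
  g <- small_genome()
  ex <- small_expression()
  m <- targeting_model("typeA", n_insertions = 5000, seed = 67)
  ins <- simulate_insertions(g, m, expr = ex$expression)
  r <- generate_random_loci(g$chroms, spacing_bp = 400, seed = 68)
  tab <- enrichment_table(ins, r, g)
  fold <- setNames(tab$fold, tab$category)
  expect_gt(fold[["utr5"]], fold[["cds"]])
  expect_gt(fold[["up200"]], fold[["cds"]])
})

test_that("the published fold column reproduces from the printed counts", {
  cts <- mu_p_feature_counts()
  wide <- tidyr::pivot_wider(cts, names_from = "category",
                             values_from = "count")
  cats <- c("genic", "up500", "up200", "utr5", "cds", "utr3",
            "down200", "down500")
  printed <- list(
    UniformMu_Zm = c(7.62, 18.22, 35.62, 90.11, 7.03, 3.54, 3.68, 3.25),
    SomaticMu_Zm = c(7.42, 15.06, 27.91, 64.39, 8.8, 4.91, 5.03, 4.27),
    Pack_MULE_Zm = c(1.75, 12.9, 18.73, 4.85, 0.57, 4.07, 3.27, 4.23),
    P_Dm = c(1.08, 7.65, 12.99, 7.76, 0.25, 0.27, 1.16, 1.69)
  )
  for (ds in names(printed)) {
    rn <- if (grepl("_Zm$", ds)) "Random_Zm" else "Random_Dm"
    te <- wide[wide$dataset == ds, ]
    rd <- wide[wide$dataset == rn, ]
    tab <- enrichment_from_counts(
      te_counts = unlist(te[cats]), te_total = te$total,
      rand_counts = unlist(rd[cats]), rand_total = rd$total
    )
    expect_lt(max(abs(tab$fold - printed[[ds]])), 0.0055)
    # every non-random row of the published table is reported as p < 1e-5
    # except two cells printed with larger p, which agree to the order of
    # magnitude (the published continuity-correction choice is not stated)
    big_p <- (ds == "Pack_MULE_Zm" & cats == "cds") |
      (ds == "P_Dm" & cats == "down200")
    expect_true(all(tab$p_value[!big_p] < 1e-5))
    if (any(big_p)) {
      expect_true(tab$p_value[big_p] > 1e-3 && tab$p_value[big_p] < 0.05)
    }
  }
})
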