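# tetarget

Where do transposable elements (TEs) insert, and what does that cost their
host? Active TE families differ sharply in how their new insertions relate to
host transcription: some land with near-base-pair precision just upstream of
the transcription start sites (TSSs) of highly expressed Pol II genes, some
pile up at both gene ends of medium-expressed genes, and others ignore
transcription altogether. `tetarget` implements the comparative toolkit for
asking these questions from de novo insertion coordinates, a gene annotation
and per-tissue expression tables:

* **Gene-anchored metaprofiles** — normalized insertion density at signed
  distances from TSSs, transcription termination sites (TTSs) or 100-bp CHH
  methylation islands. Counts are smoothed in a centered 30-bp rolling window
  and scaled to insertions per window per 100,000 insertions per 10,000
  anchors, with intergenic insertions deliberately counted toward both
  flanking genes. The sign convention is genic-positive: into the gene body
  is positive for both anchors.
* **Expression-bin targeting curves** — per RNA-seq dataset, genes are ranked
  into 20 equal bins by FPKM; the percentage of TSS-associated insertions
  (< 2 kb upstream) per bin is averaged across datasets, with SD. Includes
  group-dominant gene-set calling (high bins 16–20 in one tissue group, mid
  bins 8–12 in the other, majority support) and hotspot-gene calling.
* **Sub-genic enrichment statistics** — per-category insertion counts
  (genic, 500/200 bp upstream, 5′ UTR, CDS, intron, 3′ UTR, 200/500 bp
  downstream) with enrichment folds over an in-silico random background,
  `fold = (n_TE/N_TE) / (n_rand/N_rand)`, and per-category 2×2 chi-square
  tests.
* **Allele-specific knockdown quantification** — for hybrid designs where
  every insertion sits on one parental allele, the knockdown index
  `(Mo17_ins/B73_ins) / (Mo17_noins/B73_noins)` measures the insertion
  allele's silencing (1 = no effect, ∞ = complete knockout), plus consequence
  classification and site-class summaries.
* **Strategy classification** — a heuristic A/B/C call from the evidence:
  type A (single TSS peak, high-expression targeting), type B (TSS + TTS
  double peak, medium expression), type C (neither).
* **Synthetic data** — generators for annotated genomes (GFF3 round-trip),
  CHH islands, expression tables with planted group-dominant genes,
  allele-count tables with known effects, and insertion sets drawn from the
  type-A/B/C and uniform targeting models, so the whole pipeline is testable
  without downloads.

The package ships the published per-category insertion counts for the maize
Mu collections and the Drosophila P element (`mu_p_feature_counts()`) and the
published B73/Mo17 allele-specific read counts (`mu_allele_counts()`) as
plain-text data.

## Worked example

Simulate a TSS-precision (type A) insertion set on a synthetic genome and
classify its strategy:

```r
library(tetarget)

genome <- simulate_genome(seed = 42)             # 400 genes on 4 x 4 Mb
expr   <- simulate_expression(genome, seed = 7)  # 12 tissue datasets
model  <- targeting_model("typeA", n_insertions = 5000, seed = 11)
mu_like <- simulate_insertions(genome, model, expr = expr$expression)

report <- strategy_report(mu_like, genome, expr$expression)
report
#> <te_strategy> type A (TSS peak fold 24.98, TTS peak fold 0.00, expression rho 0.93)
glance(report)
#> # A tibble: 1 × 5
#>   call  tss_peak_fold tts_peak_fold expr_rho peak_threshold
#>   <chr>         <dbl>         <dbl>    <dbl>          <dbl>
#> 1 A              25.0             0    0.926              3
```

The TSS profile is 25× its typical level within ±500 bp of the start site
while the TTS profile carries no peak at all, and the fraction of insertions
per expression bin rises monotonically with expression rank (Spearman ρ =
0.93) — the single-peak, high-expression signature. `autoplot()` on the
`profile_insertions()` and `bin_curve()` results draws the corresponding
figures.

Score the shipped allele-specific counts:

```r
rec <- score_allele_counts(mu_allele_counts())
head(rec[, c("gene_id", "site_class", "index", "consequence")], 4)
#> # A tibble: 4 × 4
#>   gene_id        site_class     index consequence
#>   <chr>          <chr>          <dbl> <fct>
#> 1 Zm00001d020901 five_prime_UTR Inf   knockout
#> 2 Zm00001d027950 intron         200.  knockout
#> 3 Zm00001d039733 five_prime_UTR  28.4 knockdown
#> 4 Zm00001d044446 five_prime_UTR  23.3 knockdown

s <- consequence_summary(rec)
#> 11 of 32 insertions reduce expression; 2 are complete knockouts
```

Despite Mu's extreme preference for gene 5′ ends, only about a third of these
near-gene insertions measurably reduce expression of the adjacent gene — the
package's summary reproduces that count directly from the read counts.

## Vignette

`vignettes/te-targeting.Rmd` describes the models, the normalization and
window arithmetic, the parameter defaults and what the synthetic generators
do and do not emulate.
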