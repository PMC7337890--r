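---
title: "Profiling transposon integration against the transcriptional landscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling transposon integration against the transcriptional landscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(tetarget)
```

## The question and the data model

Active transposable-element (TE) families leave collections of de novo
insertion coordinates — mutagenesis populations, somatic insertion surveys,
or annotated ancient copies. Comparing such collections across families and
species requires putting every insertion in the coordinate frame of the
nearest genes and of the host's expression landscape. `tetarget` works from
three tabular inputs:

* a gene annotation (GFF3: `gene`, `five_prime_UTR`, `CDS`,
  `three_prime_UTR`, with chromosome lengths from `##sequence-region`
  pragmas or a companion table), loaded by `load_annotation()` into tibbles
  of genes (with strand-aware TSS/TTS) and sub-genic intervals;
* insertion sets: single-base 1-based positions (`read_insertions()`
  converts BED's 0-based half-open intervals and collapses wider intervals
  to midpoints — insertion callers report points, typically the target-site
  duplication midpoint);
* per-dataset expression tables (`gene_id`, FPKM).

Coordinates are 1-based inclusive throughout, matching GFF3. Genes are
processed independently: an insertion inside one gene can simultaneously be
"upstream" of another, and nested genes each receive their own records. For
multi-isoform annotations the first listed mRNA supplies the sub-genic
intervals; genes without annotated UTRs simply contribute no 5′/3′ UTR
extent (no inference from mRNA spans).

## Metaprofiles

`assign_insertions_to_anchors()` gives every insertion a signed distance to
the TSS or TTS under a genic-positive convention: for both anchors,
offsets pointing into the gene body are positive and offsets pointing away
are negative, so a TSS profile reads upstream→genic left→right and a TTS
profile reads genic→downstream left→right with the gene body always on the
positive side.

* A genic insertion (inside any gene span) contributes to each containing
  gene at distance `d ∈ [0, halfwidth]`.
* An intergenic insertion contributes to the nearest gene on its left *and*
  the nearest on its right, at `d ∈ [-halfwidth, 0)` — double counting is
  intentional: in gene-dense stretches an insertion < 4 kb from both
  neighbors genuinely describes both flanks, and the same rule is applied to
  the random background so the comparison is fair.
* An intergenic insertion's distance to a neighbor's *far* anchor (through
  the gene body) would land on the genic-positive axis while not being
  genic; those records are dropped so the positive axis carries only genic
  signal.

`metaprofile()` turns records into the plotted density: per-position raw
counts (genic and intergenic separately), a centered rolling window of 30
positions (`[x-15, x+14]`, truncated at the profile edges), then scaling by
`1e5 / n_insertions × 1e4 / n_anchors` — insertions per 30-bp window per
100,000 insertions per 10,000 anchors, which makes profiles comparable
across collections of very different sizes. The rolling statistic is a sum
by default; `smooth_stat = "mean"` divides by the effective window length,
a constant rescale in the interior that changes no shape. Smoothing and
normalization commute (the scale factor is a constant), so their order is
immaterial. Genic insertions farther than `halfwidth` from both anchors are
out of every window and are dropped.

`chh_profile()` anchors the same machinery on 100-bp CHH methylation
islands: each island is mapped onto `[-50, 49]` and mirrored when its
associated gene lies to the left, so the gene side is always the positive
axis; normalization uses the island count as `n_anchors`.
`filter_pol2_distal()` isolates tRNA/rRNA genes more than 5 kb from every
protein-coding TSS, separating Pol I/III transcription units from Pol II
starts before profiling them.

```{r metaprofile-example, fig.width = 6, fig.height = 3.5}
genome <- simulate_genome(seed = 42)
expr <- simulate_expression(genome, seed = 7)
model <- targeting_model("typeA", n_insertions = 5000, seed = 11)
ins <- simulate_insertions(genome, model, expr = expr$expression)
autoplot(profile_insertions(ins, genome$genes, "TSS"))
```

## Expression bins and gene sets

`bin_genes()` ranks a dataset's genes by ascending FPKM and cuts them into
20 contiguous equal-sized bins (bin 1 lowest). Binning is per dataset — a
bin is a categorical expression level, not a fixed gene set. FPKM ties
(zeros are common) are broken deterministically by gene id so results are
reproducible; `tie_shuffle_seed` exposes randomized tie-breaking. When the
gene count is not divisible by 20 the extra genes go to the low bins; gene
counts divisible by 20 keep bin boundaries exact.

`tss_associated()` pairs insertions with genes they sit strictly upstream
of, within 2 kb (signed distance in `[-1999, -1]`); the upstream-only
reading is the operative definition and a `symmetric` flag admits the ±2 kb
variant. An insertion in the shared upstream region of a divergent pair
yields one pair per gene, consistent with the metaprofile double-count rule;
percentages therefore count insertion–gene pairs.

`bin_curve()` computes each dataset's per-bin percentage of pairs (summing
to 100 within a dataset) and averages across datasets, treating datasets as
replicates, with SD. `dominant_gene_sets()` identifies genes at high rank
(bins 16–20) in at least 5 of 6 datasets of one tissue group and mid rank
(bins 8–12) in at least 5 of 6 of the other, in both directions;
`hotspot_genes()` applies strict per-collection count thresholds (> 3
germinal and > 10 somatic TSS-proximal insertions by default).

## Sub-genic enrichment

`classify_features()` flags each insertion's membership in nine deliberately
overlapping categories (genic; ≤ 500 and ≤ 200 bp upstream of a TSS; 5′ UTR;
CDS; intron = genic but in no annotated interval; 3′ UTR; ≤ 200 and ≤ 500 bp
downstream of a TTS). Distances are strand-aware and boundary-inclusive at
exactly 200/500 bp. The categories are memberships, not a partition — the
200-bp window is inside the 500-bp one by construction — so each category is
tested independently: `enrichment_fold()` is the ratio of in-category
proportions between the TE set and the random background (fold 1 means
random-like), and `category_chi2()` is a Pearson 2×2 chi-square without
continuity correction (configurable; raw p-values, no multiple-testing
correction, matching how such tables are conventionally reported). The
genic category uses the gene span, not the transcript span.

`generate_random_loci()` supplies the background: `floor(length/spacing)`
loci per chromosome, drawn uniformly without replacement under an explicit
seed (a deterministic `regular_grid` mode exists for exact tests). One locus
per 5 kb suits a large genome; one per 400 bp suits compact gene-rich
genomes. No masking of gaps or repeats is applied.

## Allele-specific knockdown

In a hybrid design where all new insertions land on the B73 allele and
SNPs distinguish the parental transcripts, `knockdown_index()` computes

$$\mathrm{index} = \frac{\text{Mo17}_{ins}/\text{B73}_{ins}}
                        {\text{Mo17}_{noins}/\text{B73}_{noins}}$$

— the allelic ratio in insertion carriers normalized by the ratio in
non-carriers, cancelling mapping and expression biases shared by both
groups. The index is scale-invariant in sequencing depth, inverts under
swapping the carrier/non-carrier groups, and is infinite exactly when the
insertion allele yields zero reads. `classify_consequence()` maps indices to
labels with thresholds knockout ≥ 100 (or ∞), knockdown ≥ 10, weak
knockdown ≥ 2, weak activation ≤ 0.5; these cut-offs are this package's
reconstruction — the original survey printed labels, not thresholds — and
the test suite verifies they reproduce every published label from the
shipped counts. No pseudocount is added by default; `pseudocount` guards
against zero denominators in new data.

## Strategy classification

`classify_strategy()` reduces the evidence to two peak-fold statistics and a
rank correlation. The peak fold is the *mean* profile value within ±500 bp
of the anchor divided by the median over positions carrying signal. Two
numerical choices matter here: a maximum over ~1000 noisy positions is
extreme-value biased (its null expectation grows with sparsity, colliding
with any fixed threshold at small n), so the windowed mean is used, keeping
the null near 1 while genuine peaks score ≥ 15 at simulation scale; and the
median is restricted to positions with signal because a one-sided profile —
gene-body targeting fills only the positive axis — would otherwise divide by
zero. A fold ≥ 3 at the TSS only calls type A, at both anchors type B,
anything else type C; all-zero profiles fall back to C with a warning. The
threshold is a package default on an explicitly qualitative taxonomy, and
every evidence value is carried in the report (`tidy()`, `glance()`) so
users can re-threshold. The expression correlation `expr_rho` (Spearman,
bin index vs mean percentage) is reported but not used in the call: the
boundary between "medium" and "high" targeting is not quantitative.

## The synthetic generators: what they emulate

`simulate_genome()` packs non-overlapping genes (1–6 kb, a 5′ UTR, 1–4 CDS
exons with ≥ 50-bp pieces, a 3′ UTR) onto chromosomes with intergenic
spacing uniform on 2–20 kb — about one gene per 11 kb of intergenic space,
the density of a compact gene-rich genome. Defaults are 400 genes on 4 × 4
Mb chromosomes; 2% of genes are labeled tRNA/rRNA. 100-bp CHH islands sit
immediately upstream of every 5′ end and downstream of every 3′ end.

`simulate_expression()` draws log-normal FPKM (gene effect N(1, 1.2) on the
log scale, dataset noise sd 0.5) for 12 datasets in two groups of 6, and
plants 50 group-dominant genes per direction by *exact rank placement*:
each planted gene receives, per dataset, a value interpolated between the
neighboring order statistics of the background at a target rank inside
quantiles 0.78–0.98 (high) or 0.38–0.58 (mid) — half-a-bin margins inside
bins 16–20 and 8–12 — so recovery by `dominant_gene_sets()` is exact by
construction, which is the point of a planted-truth fixture.

`simulate_insertions()` draws from the targeting models: type A selects
genes with probability rising steeply with expression rank (weight
rank⁴) and places insertions near the TSS with an asymmetric spread —
sharp upstream, wider into the body (70% genic side, half-normal sd 100 bp)
— reproducing the rapid upstream fall-off and gradual downstream decay of
precision-targeting elements; type B mixes TSS and TTS anchoring
half-and-half with a Gaussian medium-expression weight; `typeC_body` is
uniform within gene bodies; `uniform` is uniform over the genome.
`simulate_allele_counts()` draws a true index per record (log-normal, with
a knockout probability) and binomial reads at a drawn depth in both groups.

What the generators do *not* emulate: chromatin state, sequence preferences
and target-site duplications, selection after insertion, isoform diversity,
assembly gaps, and the correlation structure of real tissue panels.
Passing tests therefore demonstrate that the statistics recover planted
targeting structure under clean sampling noise — not that any particular
biological dataset will show such structure.

## Problem sizes and numerical conventions in the test suite

The suite verifies the metaprofile against a brute-force per-position oracle
on ≤ 500-insertion sets; background flatness on a 2000-gene, 32-Mb genome
with 320,000 random loci (peak/median < 1.5) and bin-curve flatness at
50,000 loci (within 3 SD of binomial noise); type-A recovery (TSS argmax
within 50 bp of the planted offset, Spearman ρ > 0.8 at 5000 insertions);
and the strategy classifier on an 18-run grid (3 kinds × 3 seeds × n ∈
{2000, 10000}) at 100% accuracy. One statistical caveat is asserted
accordingly: for a genuinely flat curve the *ranks* of the 20 bin means are
pure noise, so the uniform-set correlation bound |ρ| < 0.3 holds for the
mean over a pre-registered seed ensemble, not for every single draw, while
the magnitude-flatness check is per-draw. All generators take explicit
seeds and no global RNG state is consumed.

## Known limitations

* Nearest-neighbor resolution for intergenic insertions uses gene spans on
  the chromosome; overlapping gene models on opposite strands are each
  counted, which can triple-count an insertion in rare dense arrangements —
  consistent with the per-gene independence rule, but worth remembering when
  comparing absolute profile heights between annotations.
* The chi-square tests are asymptotic; rows with any expected cell < 1 are
  flagged rather than switched to an exact test.
* The consequence thresholds are reconstructions validated against one
  published survey; new designs should inspect the index distribution before
  trusting the default cut-offs.
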