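---
title: "koenrich: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{koenrich: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(koenrich)
```

## The model

`koenrich` performs over-representation analysis (ORA) of KEGG pathways for
organisms whose genes can only be annotated through KEGG Orthology (KO)
ortholog groups. The sampling model is the classic urn: condition on the
foreground and background gene lists, and ask whether the `n` foreground
genes contain more members of a pathway than expected when drawing `n`
genes without replacement from the `N`-gene universe, of which `K` belong
to the pathway. Under the null of no association the foreground member
count is `Hypergeometric(N, K, n)`, and the reported p-value is the upper
tail including the observed count,

$$P(X \ge k) \;=\; \sum_{i=k}^{\min(n,K)}
  \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}},$$

which is identical to the one-sided (greater) Fisher exact test of the 2×2
table — the two phrasings commonly used for this test are the same number,
and the test suite asserts that equality against `fisher.test()` over a
grid of tables. Fold enrichment is $(k/n)/(K/N)$. Across the tested
pathway family the p-values are adjusted with the Benjamini–Hochberg
step-up procedure (`stats::p.adjust`, validated against a directly coded
step-up oracle in the tests).

Assumptions worth stating: genes are exchangeable units (no gene-length or
expression-level bias correction, as in any plain ORA); the background list
defines the sampling frame, so it should be the set of genes that *could*
have been detected, not the whole proteome by default; and pathway
membership is taken at gene level — a gene counts once for a pathway no
matter how many of its KOs belong to it. KO-level resolution is preserved
separately (the term2gene "provenance") and is used where it belongs:
highlighting KO nodes on pathway diagrams.

## The universe, and what gets dropped

The paper-style inputs are three files: a gene→KO annotation, a foreground
list and a background list. Which `N` to use is the one genuinely open
choice in any ORA implementation. `koenrich` uses

> universe = background genes annotated to ≥ 1 pathway,

the convention of annotation-based ORA tools: genes with no KO, or with KOs
that hit no catalog pathway, carry no information for or against any
pathway, but leaving them in deflates every expected count and makes all
p-values anti-conservative. Because this choice changes `N`, `make_query()`
records and warns about every dropped gene class (foreground outside the
background, unannotated foreground, unannotated background), and the run
manifest repeats the counts. Foreground genes not present in the background
are dropped with a warning rather than an error — a common artifact of
mismatched identifier versions.

## Merging annotators

Up to three annotator outputs (eggNOG-mapper `.emapper.annotations`;
BlastKOALA/KAAS two-column exports) can be combined. "Sum" and "minimum"
merging are implemented as union and intersection **of (gene, KO) pairs**:
the union keeps a pair reported by any source, the intersection only pairs
reported by all. A gene-level vote (keep a gene if all annotators annotate
it, with the union of its KOs) would be a defensible alternative reading;
the pair-level rule was chosen as the most literal set semantics and
because it makes the merge operations lattice-like (commutative,
associative, idempotent, with intersection ⊆ each input ⊆ union — all
property-tested). KO tokens are normalized (`ko:` prefix stripped, case
folded) and anything not matching `K#####` afterwards is a hard format
error: failing fast beats silently losing annotation.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha_p`, `alpha_padj` | 0.05 | strict (`<`) significance thresholds on raw and BH-adjusted p |
| `drop_empty` | `FALSE` | if `TRUE`, the BH family is only pathways with `k ≥ 1` |
| `top_n` | 20 | pathways shown in bar/lollipop/cnet/upset figures |
| `exclude` / `--exclude-pathways` | none | pathway ids removed before testing |
| `seed` | 42 (CLI) | layout seed for the force-directed network figure |

Notes on the less obvious ones. *Threshold semantics*: records with the
statistic exactly equal to the threshold are excluded (strict `<`); the
degenerate setting `alpha = 1` disables the filter entirely so that "show
everything" keeps pathways with p exactly 1. *BH family*: by default every
pathway with `K ≥ 1` in the universe is tested — pathways with `k = 0` get
p = 1 but still count toward the family size `m`, matching the behaviour of
phyper-based wrappers; `drop_empty` gives the smaller family for users who
want it, and changes only the adjusted values. *Overview maps*: KEGG's
global maps (`ko01100` and friends) aggregate everything and can dominate
results; they are **not** excluded automatically because that is a
catalog-policy decision, but `--exclude-pathways` makes the exclusion a
one-liner.

## Numerical choices

- The tail sum is accumulated in log space from `lchoose` (log-gamma)
  binomial coefficients with a max-shifted log-sum-exp, so it is exact to
  machine precision at `N` in the tens of thousands. An off-by-one in the
  upper tail is the classic bug of this statistic; the convention here is
  `P(X ≥ k)` (equivalently `phyper(k − 1, …, lower.tail = FALSE)`), pinned
  by tests against exhaustive enumeration over all admissible counts with
  `N ≤ 30` at 1e-12 relative tolerance.
- Result ordering is deterministic: records sort by adjusted p, then raw p,
  then pathway id; output files are byte-reproducible for a fixed seed.
- Ratios are written as integer fractions (`k/n`, `K/N`) and reals with 9
  significant digits, so the results table round-trips through text at
  printed precision.

## Visualizations

Each figure is built as a *plot dataset* — a pure function of the result
table, the active filter (raw p or adjusted p, with its threshold) and a
seed — and rendered separately to PNG and to self-contained HTML that
embeds the image and the canonical JSON serialization of the dataset. That
serialization, not the pixels, is what the determinism tests compare. The
CLI emits every selected figure in both significance variants.

Choices the figures embody: treeplot term similarity is the Jaccard index
of member-gene sets with average-linkage agglomeration (`stats::hclust`) —
the metric/linkage pair is not dictated by anything upstream, and this is
the default family used across the enrichment-visualization ecosystem; the
cnet layout is Fruchterman–Reingold (`igraph`) under a fixed recorded seed;
UpSet counts are exclusive intersection patterns, so the pattern counts
partition the union of the displayed gene sets; the literature-trend plot
only accepts injected year→count tables (no network access), and missing
years are gaps, not zeros. Pathway diagrams are rendered directly from KGML
graphics records; an entry is filled red when any of its KO tokens is
carried by an enriched gene, so orthologous nodes light up even where gene
identifiers are species-specific.

## The synthetic generator

`spike_design()` / `simulate_study()` generate a catalog of `n_pathways`
pathways with disjoint KO blocks (10–40 KOs each by default), annotate
every gene with 1–3 KOs drawn uniformly, and sample the foreground
uniformly; a `spike_fraction` share of the foreground then has one KO
replaced by a KO from the spiked pathways, guaranteeing membership. The
defaults (12 134 genes, 437 foreground, 120 pathways, 5 spiked at fraction
0.3) reproduce the demo scale of a typical non-model study: a rotifer-sized
annotated proteome, a DE-list-sized foreground, and a KEGG-order number of
testable pathways. The replacement construction was chosen over "sample
the foreground from existing members" because the latter caps the
achievable spike at the pathways' member count and makes strong spikes
infeasible at realistic pathway sizes.

What the generator emulates: conditional-on-lists hypergeometric sampling,
with real file formats and a truth manifest (spiked pathways plus realized
`k, n, K, N`, recomputed from the emitted data, never from generator
internals). What it does not emulate: KO sharing between pathways (KEGG
pathways overlap heavily), annotator error profiles, gene-length or
detectability bias, and correlated gene sets. Passing calibration and
recovery tests on this generator therefore shows the statistics and
plumbing are right under the model's own assumptions — it does not show
that ORA assumptions hold for any particular real dataset.

Two pipeline-level properties are asserted on top of it: under the null
design (`spike_fraction = 0`, 2 000 genes, 50 pathways, foreground 200) the
fraction of pathways with raw p < 0.05, averaged over 500 seeded
replicates, sits in 0.05 ± 0.02 — in practice ≈ 0.034, mildly conservative
because the discrete tail cannot hit 0.05 exactly; and under a strong spike
(fraction 0.5, one spiked pathway) the spiked pathway attains the smallest
adjusted p in ≥ 95% of 200 replicates (observed: all of them). The
problem sizes in the test suite (500/200 replicates at the 2 000-gene
scale, one demo-scale run at 12 134 genes) keep the whole suite in the
low minutes while leaving the Monte-Carlo bands narrow.

## Limitations

- Plain ORA: no gene scores or ranking (no GSEA-style statistic), no
  correction for gene length, expression level, or inter-gene correlation.
- Results inherit the catalog: an incomplete or stale KO→pathway table
  biases `K` and `N`; the package deliberately takes the catalog as input
  rather than fetching one.
- KO-based annotation finds orthologs, not genes — paralog families
  collapse onto shared KOs, which can both add and dilute signal, and a
  gene with no detectable ortholog is invisible to the analysis.
- Large KEGG pathway definitions make `K` big and fold enrichments small;
  interpretation should weigh pathway size, which is why the results table
  always carries the raw counts.
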