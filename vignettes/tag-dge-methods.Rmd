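---
title: "Methods: tag-based digital gene expression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tag-based digital gene expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgetag)
```

## The measurement model

Digital gene expression (DGE) tag profiling counts transcripts through
a fixed-geometry sequence tag. NlaIII cuts cDNA at every `CATG`;
bead-bound 3' fragments are retained, and MmeI then cuts 17 bp
downstream of the `CATG` nearest the poly(A) tail. Every expressed,
site-carrying transcript is therefore reduced to one canonical 21-nt
tag (`CATG` + 17 bases), and a library is a multiset of such tags —
an *absolute* count measurement, unlike the relative intensities of
microarrays. Three consequences shape the whole pipeline:

1. **Genes without a CATG site are invisible.** In a typical plant
   transcriptome roughly four genes in five carry a usable site; the
   rest can never be detected, whatever the depth.
2. **Tags are only useful if unambiguous.** A 21-mer occurring in two
   genes cannot attribute its counts; such tags are filtered, both on
   the reference side (ambiguity flags in the virtual tag library) and
   on the read side (multi-gene hits discarded).
3. **Counts are small-sample Poisson draws.** A gene's tag count is
   well modelled as Poisson because each gene occupies a tiny fraction
   of the library; inference must be exact rather than asymptotic.

### The virtual tag library

`build_tag_library()` enumerates *all* CATG+17 subsequences of every
transcript on both strands, not only the 3'-most site. The reference
must anticipate every tag a read could legitimately produce —
internal sites do appear in real libraries through incomplete
digestion and priming artefacts — whereas the *simulator* emits only
the 3'-most sense tag, modelling ideal bead capture. This asymmetry is
deliberate: the library is permissive, the generative model is strict.
Sites with fewer than 17 downstream bases yield no tag (the MmeI cut
would run off the end), candidate tags containing N are dropped
(clean tags can never contain N, so those reference tags are
unreachable), and ambiguity is defined at the tag-sequence level
across genes — multiple placements *within* one gene do not make a tag
ambiguous. Antisense placements are reported in sense-strand, 0-based
coordinates so both strands of a transcript join positionally.

### Tag cleaning

`clean_raw_tags()` applies five rules in a fixed order: adaptor
removal, empty-read removal, N removal, length filtering, and removal
of copy-number-1 tags. Because the protocol fixes the read geometry
(tag at positions 1–21, adaptor from 22), adaptor removal is
positional: the first 21 bases are kept and the remainder must match a
prefix of the adaptor with at most one mismatch. Reads that match the
adaptor from position 1 are adaptor-only; reads shorter than 21 nt,
not beginning with `CATG` (every legitimate tag is CATG-anchored by
the digest), or failing the adaptor check are malformed. The
copy-number-1 rule removes probable sequencing errors: a substitution
error almost always creates a novel 21-mer seen once. The counts
removed by each rule are retained (`filter_stats`), and raw read count
always equals clean total plus removals. Base qualities are
deliberately ignored — the copy-number filter subsumes a quality
filter for 21-mers, and no defensible quality threshold exists for
this protocol.

### Mapping with one mismatch

`map_tags()` looks clean tags up exactly, then — only for tags with no
exact hit — searches all 51 single-substitution variants of the 17
variable bases. The `CATG` anchor is enzymatically fixed, so
mismatches there are not searched. Tie-breaking is conservative: a
perfect hit never falls through to the mismatch tier, hits spanning
more than one gene (at the best tier) are filtered as ambiguous, and a
tag hitting one gene on both strands is counted once, as sense. The
same ambiguity filter is applied to sense and antisense counts — the
convention is symmetric because nothing in the chemistry distinguishes
the strands after ligation.

### Quantification

TPM (transcripts per million clean tags) is `count / total_clean *
1e6`; the denominator is the library's total *clean* tags, not its
mapped tags, following the unit's definition. For full-length mRNA-seq
reads the package provides RPKM = `1e9 * C / (N * L)` instead, which
corrects for gene length; tags need no length correction because every
transcript contributes the same number of canonical tags (one).

## The differential-expression test

With `x` tags for gene A in a library of `N1` total clean tags, the
count is Poisson. Integrating the unknown intensity out with a flat
prior, the probability of seeing `y` tags in a second library of `N2`
total under equal expression is

$$P(y \mid x) = \left(\frac{N_2}{N_1}\right)^{\!y}
  \frac{(x+y)!}{x!\,y!\,(1 + N_2/N_1)^{x+y+1}},$$

a negative-binomial distribution in `y` with size `x + 1` and success
probability `N1/(N1+N2)`. The two-sided p-value is twice the smaller
of the two tails at `y`, capped at 1 — the standard two-sided
construction for one-observation exact tests. Calls use FDR <= 0.001
(Benjamini–Hochberg across all genes tested in the comparison) and
|log2 ratio| >= 1, with TPM 0.001 substituted for zeros so a gene
absent from one library gets a finite, very large ratio. Genes with
zero counts in both libraries are excluded: there is no evidence to
test. FDR is controlled per pairwise comparison, not pooled across
comparisons — each tissue pair is a self-contained question, and
pooling would let a comparison with many strong signals loosen the
threshold of an unrelated one.

### Numerical choices

* The lower tail is summed in log space via `lgamma` and
  log-sum-exp; exactness is limited only by double rounding.
* The infinite upper tail, when it is the smaller tail, is summed
  directly by the multiplicative term recurrence
  $t_{i+1} = t_i \cdot r(x+i+1) / ((1+r)(i+1))$, truncated when a term
  falls below $10^{-30}$ of the running sum. Computing it as
  $1 - \text{lower}$ would cancel catastrophically exactly where the
  p-value is interesting.
* When the lower tail is at most 0.5 it is necessarily the smaller
  tail (the inclusive tails overlap at `y`), so the upper sum is
  skipped.
* One property this construction does **not** have is exact symmetry
  under swapping the two libraries: the test conditions on the first
  library's count, and the two conditional distributions differ by
  terms of the order of the point mass at the observed count. At
  realistic counts the discrepancy is far below any calling threshold;
  at very small counts (say `x + y < 5`) the two orientations can
  differ visibly. Callers should fix an orientation — the package
  consistently tests *second given first* and orients the log2 ratio
  the same way — rather than expect invariance.

### Calibration and power

Under a simulated Poisson null the empirical fraction of genes with
p <= alpha stays at or below alpha (exact tests are conservative).
On the simulator's study conditions — 1,000 genes, two libraries of
$10^6$ tags, 10% of genes at 4-fold change — genes that are
*assayable* (an unambiguous canonical tag site and baseline abundance
of at least 50 TPM) are recovered with sensitivity above 0.9 and the
empirical false discovery proportion among calls stays below 0.05 at
the FDR <= 0.001 threshold. The restriction to assayable genes is not
a hedge but a property of the assay: a site-less gene (18.5% of the
reference under the default site fraction) or a gene at a handful of
tags cannot be called by any method operating on these counts.

## Enrichment and clustering

Term enrichment uses the upper-tail hypergeometric probability
$P = 1 - \sum_{i=0}^{m-1} \binom{M}{i}\binom{N-M}{n-i} / \binom{N}{n}$
with `N` annotated background genes, `n` DEGs among them, `M` genes
annotated to the term, and `m` DEGs in `M`; q-values are
Benjamini–Hochberg over the tested terms and terms are significant at
q <= 0.05. BH was chosen over a Storey-style estimator as the default
because it is deterministic and has no tuning parameter; the annotation
is any flat term-to-gene table (GO and KEGG share the code path), taken
as pre-propagated — no ontology-graph ancestor inflation is performed.
Terms with no background gene are skipped rather than reported at
p = 1.

Expression-pattern clustering assembles a genes x comparisons matrix
of log2 ratios (intersection or union of the per-comparison DEG sets;
genes missing from a comparison get the ratio their zero-substituted
TPMs imply, i.e. 0) and applies average-linkage hierarchical
clustering under uncentered-correlation distance — the defaults of the
classic Eisen Cluster program, kept for comparability; centered
Pearson is available. A row with zero norm (or zero variance under
Pearson) has no defined correlation and is assigned the maximal
distance 2 with a warning. Flat clusters default to the cut at the
largest gap between consecutive merge heights — a transparent,
deterministic rule in the absence of any principled cluster count —
and `clusters_containing()` reports the clusters intersecting a seed
set (e.g. known taxane-pathway genes) with their full membership.
Published cluster sizes from comparable analyses depend on unstated
cut parameters and are treated as illustrations, not as reproduction
targets.

## The metabolite summary

`taxane_table()` ships a transcription of published UFLC-MS
concentrations (µg/g dry material) of six taxanes in *Taxus mairei*
needles and roots across collection sites. The "Average" convention
of such tables is the *unweighted* mean across sites, not a mean
weighted by each site's sample count — verified here as an arithmetic
identity against every printed average cell — so `site_mean()`
implements exactly that, despite weighting being the naive guess.
Printed row totals occasionally exceed their component sums by one
rounding unit (two root rows do); `check_totals()` flags such rows and
never corrects them, because the printed value is the citable one.
`tissue_ratio()` divides root by needle site means; for paclitaxel and
cephalomannine the ratios (about 4.8 and 4.7) sit inside the
two-to-eight-fold band expected for this species.

## The simulator: what it emulates, and what it does not

Defaults describe the study conditions the package targets:

| parameter | default | rationale |
|---|---|---|
| `n_genes` | 1,000 | desk-scale stand-in for a ~36k-Unigene reference |
| `len_min`–`len_max` | 300–2,000 bp | spans typical assembled Unigene lengths (median ~1.1 kb) |
| `gc_content` | 0.455 | gymnosperm transcriptome GC |
| `frac_with_site` | 0.815 | fraction of genes with an NlaIII site |
| `abundance_sdlog` | 1.6 | log-normal heavy tail: top 1% of genes carry >25% of tags |
| `de_fraction`, `log2fc` | 0.1, 2 | a tenth of genes at 4-fold, the regime DEG thresholds target |
| `antisense_fraction` | 0.25 | about a quarter of genes show antisense transcription |
| `antisense_level` | 0.15 | median sense/antisense ratio around 7 |
| `depth` | 3.2e6 | tags per library in a production run |
| `error_rate` | 0.001 | per-base substitution rate of a good run |
| `singleton_rate` | 0.01 | one-off junk tags exercising the copy-number filter |

Tests and the acceptance script scale `n_genes` and `depth` down
(1,000 genes and $10^6$ tags, or less for unit tests) — the chosen
sizes keep every stochastic check stable across seeds while the full
suite stays fast.

The generator emulates: multinomial tag sampling (conditionally
Poisson per gene, matching the test's model), heavy-tailed abundance,
minority antisense transcription proportional to sense, per-base
substitution errors that create both rescuable 1-mismatch tags and
singletons, and junk singleton reads. Each stage draws from a stream
derived from the single mandatory seed and restores the caller's RNG
state, so outputs are bit-reproducible.

It does **not** emulate: base-quality strings (cleaning ignores them),
PCR duplicates, isoform structure or alternative 3' ends, incomplete
NlaIII digestion (every sense emission uses the 3'-most site),
library-preparation sequence bias, or indel errors (tags are
fixed-length; the mapper searches substitutions only). Passing tests
therefore demonstrate correctness of the *accounting and inference*
given the protocol's idealised geometry, not robustness to every
artefact of real libraries.

## Known limitations

* One library per condition: the Poisson exact test has no dispersion
  parameter, so biological replication is outside its model; with
  replicates a negative-binomial framework is the right tool.
* The 1-mismatch search is exhaustive over variants, which is exact
  but sized for tag data (tens of thousands of distinct tags), not for
  genome-scale k-mer sets.
* Novel-transcript detection is exact-match only, by design: a 21-mer
  at 1 mismatch against an auxiliary genome carries little evidence.
* The default flat-cluster cut (largest height gap) is transparent but
  greedy; for publication-grade cluster delineation inspect the
  dendrogram.
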