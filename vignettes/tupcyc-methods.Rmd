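---
title: "Epistasis cohort classification of Tup1-Cyc8 mutant transcriptomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Epistasis cohort classification of Tup1-Cyc8 mutant transcriptomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tupcyc)
```

## The analysis problem

The Tup1-Cyc8 complex is the budding-yeast global co-repressor: one
Cyc8p and four Tup1p subunits, recruited to promoters by sequence-
specific DNA-binding factors. Deletion mutants of *TUP1* and *CYC8*
have historically been treated as interchangeable probes of complex
function. Comparing the transcriptomes of the *tup1*, *cyc8* and
*tup1 cyc8* single and double deletion mutants against wild type
breaks that assumption apart: the joint pattern of de-repression
across the three mutants assigns each gene to an *epistasis cohort*
that says how the two subunits share the repressive work.

`tupcyc` implements that classification and the downstream analyses
that characterise the cohorts: z-score heatmap matrices, telomere-
distance enrichment, promoter motif enrichment, ChIP-occupancy
overlap, and ChIP-qPCR normalization. The input is the *output* of a
differential-expression fit (log2 fold-changes, BH-adjusted p-values,
mean TPM per strain); the package deliberately does not re-implement
read processing or DESeq2.

## The classification model

Let $f_c(g)$ be the log2 fold-change of gene $g$ in contrast
$c \in \{tup1, cyc8, double\}$ (each mutant versus wild type) and
$p_c(g)$ its adjusted p-value.

**Differential calls.** $g$ is *up* in $c$ iff $f_c(g) \ge 1$ and
$p_c(g) \le 0.01$; *down* with $f_c(g) \le -1$. All thresholds in the
package are inclusive at the boundary because they are stated with
inclusive operators ($\ge$ 2-fold, $p \le 0.01$, TPM $\le$ 60, ...).

**Venn partition.** Every upregulated gene falls in exactly one of
the seven regions of the three-set Venn diagram over the up-sets.
Four regions seed the cohorts:

* **Unique repression** (region {single mutant, double}): candidate
  genes uniquely repressed by that subunit. Three stricter filters
  are applied: the *other* single mutant must show minimal change
  ($f \le 0.3$); de-repression must not rise further in the double
  mutant ($f_{double} \le f_{dominant}$, non-strict with zero
  tolerance — the simplest faithful reading of "not higher");
  and mean TPM across the de-repressing strains must exceed 60.
* **Redundant repression** (region {double} only): either subunit
  alone suffices; the region is the cohort verbatim.
* **Dependent repression** (region {single mutant} only): genes
  de-repressed upon losing one subunit but not in the double mutant,
  i.e. the other subunit is required for the de-repressed state.
  Genes with mean TPM $\le 60$ across the three mutants, or any
  change in the other single mutant ($|f| > 0.3$), are excluded.
* **Common repression** (region {all three}): the robustly repressed
  core. It is split by dominance: *SUC2-type* genes have
  $f_{cyc8}$ strictly maximal and $f_{tup1}$ strictly minimal (CYC8
  dominates); *FLO1-type* genes have $f_{tup1} > f_{cyc8}$ (TUP1
  dominates); everything else, including exact ties, is
  `COMMON_OTHER`. The two rules are mutually exclusive by
  construction.

Genes with wild-type mean TPM $\le 10$ carry an additional `WT_OFF`
flag ("off in wild type").

### Choices the definitions leave open

* *"Average TPM in the mutants"* is interpreted as the mean over the
  strains in which the cohort's genes are actually de-repressed
  (dominant + double mutant for the unique cohorts; all three mutants
  for the dependent cohort). Both the threshold and the strain set
  are arguments, so other readings are one call away.
* *"Any change in transcription"* for the dependent cohort is
  operationalised as $|f| \le 0.3$, reusing the 0.3 cut-off the
  unique-cohort filter already defines rather than inventing a second
  constant.
* The FLO1-/SUC2-type split uses explicit rank rules rather than
  reproducing hierarchical-cluster boundaries from a heatmap; on real
  data the resulting counts are therefore approximate, and on data
  where the dominance patterns are clean the two definitions
  coincide.

## Statistical summaries

* **Z-scores** are computed per gene across the three contrasts:
  $z = (f - \bar f)/s$ with the *sample* (n−1) standard deviation.
  With only three columns the n vs n−1 choice visibly rescales the
  map, so it is exposed (`sd_type = "population"`). Constant rows map
  to zeros with a warning instead of erroring, so heatmaps of
  degenerate inputs still render.
* **Cluster order** for heatmap rows comes from average-linkage
  agglomerative clustering on Euclidean distances (`stats::hclust`),
  read off the dendrogram. The linkage/metric for the published
  heatmaps is not documented anywhere, so this common default is the
  package's own, and it is deterministic: the same matrix always
  yields the same permutation.
* **Group comparisons** use the classical one-way ANOVA
  sum-of-squares decomposition, written out explicitly so the
  degenerate all-identical case can return $F = 0$, $p = 1$ rather
  than `NaN`; the generic case is tested against `anova(lm())`.
* **Spearman correlations** rank with average ranks and report the
  two-tailed p from the t approximation on $n-2$ degrees of freedom,
  the standard practice at the cohort sizes involved (tens of genes).
  An exact full-enumeration permutation mode exists for $n \le 8$;
  beyond that the enumeration ($n!$ permutations) costs more than it
  teaches, and the t approximation is already accurate.

## Genome position

Gene position is the ORF midpoint, $\lfloor (start+end)/2 \rfloor$ in
0-based half-open coordinates (a start-coordinate mode exists; which
one the field uses varies and is rarely stated). Telomere distance is
the distance to the nearer chromosome end, so it never exceeds half
the chromosome length.

Bin profiles tile $[0, d_{max})$ with half-open bins $[kw, (k+1)w)$ —
a gene at exactly a boundary falls in the upper bin — and report
percentages *of the full input set*, so a gene set entirely beyond
the profile shows 0% everywhere and the in-range percentages sum to
the in-range fraction. Coarsening 5 kb bins to 50 kb is exactly
consistent with direct 50 kb binning because the bins nest.

The sub-telomeric split is strict at 25 kb (`distance < cutoff`), and
the built-in surrogate for the Hda1-affected sub-telomeric (HAST)
domains is the fixed half-open window [5 kb, 40 kb); a digitised
acetylation track is deliberately not shipped.

## Promoter features

**Intergenic lengths** are strand-aware: for each gene, the gap from
each boundary to the nearest boundary of the nearest *protein-coding*
neighbour on that side (regardless of the neighbour's strand);
terminal genes are bounded by the chromosome end; an overlapping
neighbour yields 0 with a warning rather than an error, since real
annotations contain overlaps.

**Motif scanning** matches IUPAC consensus strings at every position,
counting overlapping occurrences, on both strands by default (the
consensus plus its reverse complement). A sequence `N` is matched
only by a motif `N` — an unknown base should never create evidence.
Matching is delegated to Biostrings with ambiguity codes interpreted
on the motif side only, which reproduces exactly these semantics; the
test suite checks it position-by-position against a naive scan.
Single-strand mode exists because published motif-count tables do not
always state their strand convention.

**Enrichment rule.** Presence of a motif in a cohort is the fraction
of its genes with $\ge 1$ occurrence. A motif below 40% presence in
*both* cohorts is omitted (strictly below — 40% exactly survives);
otherwise a difference of at least 10 *percentage points* (not a 10%
relative change) is called enriched toward the higher cohort, and
anything smaller is not different. Occurrence multiplicity is still
recorded for the mean motif load.

## Occupancy

Published ChIP-Exo peak sets arrive with per-peak gene assignments,
so passthrough of those labels is the default. Unlabelled peaks are
assigned to every gene whose promoter window — 1 kb upstream of the
strand-aware 5' start, half-open — contains the peak midpoint.
"Differentially transcribed" for occupancy/DE overlap means up- and
downregulated combined at the standard thresholds.

ChIP-qPCR relative occupancy is
$(IP_t/IN_t) / (IP_c/IN_c)$ — target over negative-control region —
optionally divided by the same quantity from a reference (deletion or
untagged) strain. It is scale-invariant by construction; zero
denominators raise an error naming the offending term.

## The synthetic-data generator

`synthetic_spec()` / `synthesize_cohort_data()` emit a complete study
bundle — expression table, GFF3 + lengths, promoter FASTA, motif
table, per-factor peak BEDs — plus the ground-truth table. Defaults
are the study conditions: cohorts of 13 / 6 / 131 / 14 genes, a
429-gene common cohort split 40 / 110 / 279, 2000 null genes, seed
17.

Design points worth knowing:

* **Adjusted p-values are assigned, not modelled**: tiny
  ($10^{-30}..10^{-10}$) in de-repressing contrasts, exactly 1
  elsewhere. The pipeline consumes DESeq2-style output; its tests
  should target the classification layer, not re-derive a DE fit.
* **Margins.** Every planted inequality clears its threshold by at
  least `margin_lfc` (0.5 log2 units) and `margin_tpm` (20 TPM);
  strict-inequality gaps shrink proportionally as the margin
  approaches zero, so recovery degrades gracefully rather than
  discontinuously.
* **The dependent cohort is generated faithfully**: in the double
  mutant those genes stay off (low TPM), so the single-mutant strain
  must carry the whole mean-TPM filter — visible in the generator as
  a tripled TPM floor for that strain.
* **Geometry**: 16 chromosomes with yeast-like arm lengths; cohort
  genes are placed sub-telomerically (< 25 kb) with probability 0.6
  versus 0.1 for null genes; position within the arm is uniform.
* **Motif planting is stratified, not Bernoulli.** A presence
  probability $p$ over a cohort of $n$ genes is realised by planting
  in exactly $round(pn)$ genes chosen at random. The planted
  prevalences are then the study conditions themselves; with
  per-gene Bernoulli draws at $n = 40$ the sampling noise of a
  presence difference (sd ≈ 0.11) would swamp the 10-point
  enrichment rule and make small-difference behaviour untestable.
  Insertion position and strand are uniform, and planted instances
  never overwrite one another. Background sequence is i.i.d. uniform
  A/C/G/T, so short consensus strings (4-6 bp) accrue appreciable
  background presence — exactly as they do in real promoters; tests
  that need presence to equal the planted prevalence use long
  consensus strings where the background rate is ~$10^{-4}$.
* **Peaks** are planted on genes with probability 0.23 / 0.13 when
  the gene is differential in the matching single mutant, 0.05
  otherwise, and carry their gene label in the BED name field.

What the generator does **not** emulate: replicate-level counts and
dispersion, correlated fold-change noise, realistic gene density or
overlap structure, chromatin context, and promoter base composition
(yeast promoters are AT-rich; the background here is uniform). A
passing recovery test therefore demonstrates that the classification
logic is correct under its stated assumptions — not that real data
will have planted-data separation. On real tables, genes near the
thresholds move between cohorts with measurement noise, which is why
every threshold is surfaced as an argument.

## Numerical conventions

* Coordinates are 0-based half-open everywhere internally; GFF3 is
  converted on read, BED is native. One convention kills one whole
  class of off-by-one bugs.
* Missing adjusted p-values are imputed to 1 (never differential),
  missing fold-changes to 0; both imputations are logged and can be
  disabled.
* All classification thresholds are inclusive; the sub-telomeric
  cutoff and the omission threshold are strict, as stated ("< 25 kb",
  "less than 40%").
* Ties in the dominance split fall to `COMMON_OTHER`; constant
  z-score rows become zeros with a warning; equal-distance merges in
  clustering resolve by input order.

## Problem sizes in the test suite

The suite regenerates all fixtures in code. The recovery test runs
the full default study (2593 genes); oracle comparisons use 200
random set systems (≤ 64 genes), 1000 random sequence/motif pairs,
100 seeded correlation vectors, and 100-seed detection experiments at
the 40-gene cohort design point. The whole suite runs in about a
minute on one core.

## Known limitations

* The FLO1/SUC2 rank rules approximate cluster-boundary definitions;
  counts on real data may differ by a few genes.
* Motif counts depend on the strand and overlap conventions of
  whatever produced a reference count table; both are configurable
  but reproduction of third-party tables may require toggling them.
* `peaks_to_genes` window assignment is midpoint-based; peaks
  spanning a window edge are assigned by midpoint only.
* The exact-permutation Spearman mode stops at $n = 8$.
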