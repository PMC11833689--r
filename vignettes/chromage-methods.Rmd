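---
title: "Gene age, chromatin assortativity and Pol II pausing: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene age, chromatin assortativity and Pol II pausing: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromage)
library(dplyr)
```

## The scientific problem

Genes can be dated by phylostratigraphy: the deepest phylogenetic node at
which homologs are detectable. `chromage` works with 16 such age classes,
collapsed into three broad categories — unicellular-ancestor (UC) genes,
early-metazoan (EM) genes and mammal-specific (MM) genes. The package
provides the computational chain needed to ask how a gene's evolutionary
age relates to (i) its local chromatin state (Polycomb repression, promoter
CpG density and methylation, nuclear-lamina association), (ii) its
transcriptional regulation (differential expression, RNA polymerase II
promoter-proximal pausing), and (iii) its position in the 3D contact
network measured by promoter-capture Hi-C (PCHi-C) — in particular whether
genes of the same age preferentially contact each other, and which
chromatin feature carries that preference.

## Chromatin networks

Interaction calls are consumed in a CHiCAGO-style tab-separated dialect
(`bait_chr, bait_start, bait_end, bait_name, oe_chr, oe_start, oe_end,
oe_name, N_reads, score`), 1-based inclusive on disk and converted to the
package-wide 0-based half-open convention at parse time. Only calls with
score strictly greater than 5 are kept — the conventional significance
cut-off for CHiCAGO scores. Fragments become nodes (identical coordinates
merged, gene annotations united), contacts become undirected edges;
self-contacts and duplicate contacts are dropped. A fragment is a promoter
node for gene *g* exactly when it contains *g*'s TSS base; coordinates win
over whatever name annotation the file carries, which keeps the assignment
independent of annotation versions. Age analyses run on the promoter-only
subnetwork; the strict mode (promoter–promoter edges only) is the default
because the age-clustering question is posed on promoter–promoter
interaction networks, and an inclusive mode is available for completeness.

## Chromatin assortativity (ChAs)

For a node feature $f$, ChAs is the Pearson correlation of $f$ across edge
endpoints, with every undirected edge contributing both orientations, so
the statistic is symmetric and bounded in $[-1, 1]$:

$$\mathrm{ChAs}(f) \;=\; \mathrm{cor}\big[(f_a, f_b)\ \cup\ (f_b, f_a)\big]_{(a,b) \in E}.$$

Age categories are handled in categorical mode: each category becomes a
binary indicator (a multi-gene node carries 1 for every category of its
resident genes — a documented multi-label choice), and ChAs is computed per
indicator. Nodes with no annotated gene are *undefined* and excluded
edgewise, never imputed; a constant indicator is reported as missing with a
warning rather than silently dropped.

### The distance-matched null

Contacts are strongly distance-dependent, so raw ChAs would be inflated by
linear proximity alone. Significance is therefore assessed against
randomized networks that preserve the genomic-distance profile: each cis
edge is replaced by a uniformly sampled same-chromosome node pair whose
midpoint distance falls in the same log10 bin (width 0.1; distances below
1 kb pooled), and each trans edge by a random inter-chromosomal pair, with
no self-loops or duplicates and per-bin counts preserved exactly. Pairs are
found by rejection sampling with a capped number of rounds; a bin that
cannot be re-filled falls back to its original edges (counted and
reported), which keeps the per-bin histogram exact by construction. The
null randomizes the **edges** while holding feature values fixed on nodes:
a feature shuffle could not preserve edge distances. A plain
feature-permutation null is exposed as an option for comparison.

With 100 randomizations (the default), the z-score is
$z = (\mathrm{obs} - \mu_{null}) / s_{null}$ with the sample (n−1) standard
deviation; $|z| > 2$ is the conventional significance threshold
(roughly $p = 0.05$). The null sample is retained on every result for
diagnostics, and all ChAs statistics in one report share one set of
randomized networks (common random numbers), which reduces the variance of
differences between z-scores.

### ΔChAs

To ask whether a chromatin feature *drives* a gene group's clustering, the
group (say, EM genes) is split into feature-positive and feature-negative
subgroups; each subgroup's binary indicator gets a ChAs z-score against the
shared nulls, and

$$\Delta\mathrm{ChAs} = z_{\text{with}} - z_{\text{without}}.$$

Positive values implicate the feature in the group's 3D clustering.
Because both z-scores use the same randomized networks, the planted sign is
recovered with less noise than independent nulls would give. An empty
subgroup (feature covering all or none of the group on the network) is an
error naming the offending side.

## Gene-level annotation rules

* **Polycomb target**: the single TSS base lies inside an H3K27me3 peak
  (`start <= tss < end`, half-open). "Strict TSS localization" is read as
  the TSS point; users wanting slack can widen via the promoter window.
* **LAD gene**: at least one base of the gene body overlaps a
  lamina-associated domain; constitutive and facultative LADs can be used
  together or separately.
* **Promoter window**: strand-aware, `upstream` bases 5' of the TSS plus
  `downstream` bases beginning at the TSS. The TSS base is always included
  (a zero-width request degenerates to the single TSS base). The CpG and
  methylation aggregations default to ±1 kb, configurable to ±3 kb;
  per-gene methylation is an unweighted site mean because sites are points.
* **Differential expression**: up means `log2FC > 2` and adjusted
  `p < 0.1`; down is the mirror image; missing adjusted p is unchanged.

All coordinate arithmetic is 0-based half-open internally; BED-like inputs
are consumed natively and the 1-based ibed dialect is converted at the
parser boundary, so off-by-one conventions live in exactly one place.
Overlap queries go through `GenomicRanges`; the tests check them against
brute-force interval scans, exactly, including half-open boundary and
strand-mirror cases.

## The Pol II pausing pipeline

The pausing index of a gene is the ratio of mean Pol II density in the
promoter region (TSS − 30 bp to TSS + 300 bp, transcript orientation) to
mean density in the gene body (TSS + 300 bp to TES). Density is the
unweighted mean of all track bins overlapping the region by at least one
base — the literal "overlapping bins averaged" rule — with a
length-weighted option exposed. The filter cascade, each exclusion recorded
with its reason:

1. genes shorter than 1 kb are discarded (annotation-only, applied first);
2. a zero body density makes the PI undefined, never infinite, so no
   infinities reach the quantiles;
3. per cell state, PIs outside the Tukey fences
   $[Q_1 - 1.5\,\mathrm{IQR},\ Q_3 + 1.5\,\mathrm{IQR}]$ are removed;
   quartiles use linear interpolation between order statistics (R type 7) —
   the interquartile-range method leaves the quartile convention open, so
   it is pinned and documented here;
4. genes whose surviving PIs sum to less than 0.2 across cell states are
   excluded as unexpressed; the sum runs over defined, post-outlier values
   (missing treated as absent). Whether outlier removal precedes this sum
   is ambiguous in narrative order; outliers-first is the default and the
   other order is available behind `filter_order`;
5. each cell state's survivors are min–max rescaled to [0, 1] (a single
   survivor maps to 0.5 by convention).

The pipeline accepts any number of cell states ≥ 1 (the sum threshold
applies to however many are given); the default configuration mirrors
three. Distributions are compared with two-sided Wilcoxon–Mann–Whitney
tests, exact for small untied samples and normal-approximated with tie
correction otherwise.

## Cross-cutting statistics

Age trends are Spearman correlations, by default at class-mean level: the
16 class indices against per-class mean values, which is how class-level
trends such as expression (negative) and expression variability (positive)
are summarized; a gene-level mode exists. Gene-set enrichments are
two-sided Fisher's exact tests on the 2×2 overlap table; the odds ratio is
the sample cross-product ratio, with a Haldane (+0.5) corrected companion
reported and the result flagged whenever a cell is zero. Variability groups
are rank-based deciles (group 1 = lowest), ties broken by stable gene-id
order so the assignment is deterministic. Primitives apply no multiplicity
correction; the report layer adds Benjamini–Hochberg within each family of
comparisons and keeps both raw and adjusted p.

## The synthetic-data generator

Every input the pipeline consumes can be generated with planted ground
truth, so the whole chain is testable without downloads:

* **Genome** (`sim_genome`): non-overlapping genes at jittered uniform
  spacing, log-normal lengths with ≥ 10% under 1 kb (so the length filter
  is always exercised), random strands, age classes drawn from weights
  that default to the three category proportions (38/45/17%, mirroring
  7397/8682/3325 of 19404 genes) spread uniformly within categories.
  The class-to-category bounds default to (3, 9) — a configurable choice,
  since the 16-to-3 mapping is dataset-dependent.
* **Network** (`sim_network`): one promoter fragment per gene (an option
  puts two genes on ~5% of fragments); for each edge, a uniformly drawn
  source gene connects to a same-category partner with probability
  `p_within` (scalar or per label) and to a uniform partner otherwise, so
  the same-category edge fraction is `p_within + (1 - p_within) q` with
  `q` the random-pairing rate — invertible, which is how the tests recover
  the planted value. 5% of edges are trans by default; scores are drawn
  above 5 so every simulated contact survives filtering.
* **Peaks / LADs** (`sim_peaks`, `sim_lads`): TSS-covering peaks per
  category at rates defaulting to 16/34/14% (UC/EM/MM) plus background
  peaks away from TSSs; LADs are genome segments sampled with
  category-biased weights until a target fraction (default 30%) is
  covered, with odds rising toward young genes (1 : 2 : 2.3).
* **Coverage** (`sim_coverage`): 10-bp bins anchored at the promoter edge
  so promoter and body bins never straddle the boundary — in the noiseless
  limit the pipeline recovers the planted promoter/body ratio exactly.
  Planted PIs decline from old to young genes (2 / 1.5 / 1.2) and are
  scaled per cell state (1 / 0.7 / 1.2 for the stem, somatic and cancer
  states), emulating pausing that weakens on differentiation and
  strengthens again in the malignant state. Noise is truncated Gaussian
  per bin — the simplest model with exact noiseless limits.
* **Expression / EV** (`sim_expression`): strictly monotone class-level
  trends (expression falling, variability rising with evolutionary youth)
  plus class-level noise scaled as
  $s = \sigma_{trend}\sqrt{\rho^{-2} - 1}$ so the realized class-mean
  Spearman is approximately the target (default 0.95).
* **Scenarios** (`sim_scenario`): each category's clustering is planted
  *through its own feature* — a pol2-positive UC subset (with planted high
  PI), Polycomb-target EM genes, LAD-overlapping MM genes. The
  `differentiated` scenario wires these at strengths 0.75 / 0.7 / 0.2; the
  `oncogenesis` scenario keeps UC, breaks EM (0.15) and strengthens MM
  (0.7). Re-running the full pipeline on the two bundles reproduces the
  planted qualitative pattern: all categories significantly assortative,
  EM clustering dropping and MM clustering rising across the
  differentiated-to-cancer transition, and positive ΔChAs for the
  driving feature of each category.

Seeding: one master seed; every generator derives its own stream from
(master, generator name), so adding a generator never perturbs the others,
and identical configurations are byte-identical.

What the generator does **not** emulate: read-level noise, CHiCAGO's
statistical model, restriction-fragment geometry, chromatin polymer
physics, or realistic correlation structure between features beyond what
is planted. Passing tests therefore demonstrate that the statistics
recover planted structure under controlled conditions — not that any
particular biological dataset will show such structure.

## Numerical and design choices

* Quartiles: R type 7 (linear interpolation); Tukey constant 1.5.
* Distance bins: log10 width 0.1, sub-kilobase pool; the upstream tool's
  internal binning is not published, so this is a documented reading of
  "randomizations preserving genomic distances" rather than a verified
  re-implementation of its internals.
* Rejection sampling cap: 50 vectorized rounds per distance bin, then
  fall back to original edges (logged via the `n_fallback` attribute).
* Degenerate cases: constant features error in `chas()` but are reported
  as missing in categorical sweeps; zero null standard deviation flags the
  result degenerate with an undefined z; a single min–max survivor maps to
  0.5.
* ΔChAs uses common random numbers across the two subgroups — variance
  reduction for a statistic that is exactly a difference of z-scores.
* Problem sizes in the test-suite: oracle comparisons run on graphs up to
  50 nodes / 200 edges; calibration studies use 200 trials at 40 nodes
  with 50 randomizations; the end-to-end scenario contrast uses 20
  repetitions of 400 genes / 1200 edges with 40 randomizations. These
  sizes give the calibration statistics comfortable margins while keeping
  the whole suite quick on a single CPU.

## Worked example

```{r example}
cfg <- sim_config(n_genes = 200, n_edges = 500, seed = 7)
sc <- sim_scenario("differentiated", cfg)
rep <- run_report(sc, n_rand = 30, seed = 7)
rep$chas_age
rep$delta |> filter(group == "EM", feature == "polycomb")
rep$trends
```

The per-category z-scores are all well above 2 (each age category clusters
more than distance alone explains), and the EM × Polycomb ΔChAs is
positive: the planted Polycomb-driven clustering of EM genes is recovered
from the synthetic bundle end to end.

## Known limitations

* One TSS/TES per gene; isoforms are out of scope.
* ChAs values are not compared across different networks — z-scores are
  only interpreted within one network, since the statistic depends on
  network size and composition.
* The distance-matched null is a faithful reading of
  distance-preserving randomization, not a bit-level reproduction of any
  particular implementation of it.
* Peak calling, CpG-island prediction, coverage generation and DE model
  fitting are upstream of this package: it consumes their outputs.
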