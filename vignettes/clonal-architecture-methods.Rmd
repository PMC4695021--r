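---
title: "Methods: clonal architecture of synchronous adenoma-carcinoma pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonal architecture of synchronous adenoma-carcinoma pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synclone)
```

## The analysis setting

When a colorectal carcinoma is removed together with a residual adenoma from
the same cancer mass, whole-exome sequencing of the two microdissected lesions
plus matched normal tissue gives three read-count profiles per somatic
variant. Two evolutionary scenarios can explain such a synchronous pair:

* **stepwise** — the carcinoma arises from a subclone of the pre-existing
  adenoma; mutations private to the carcinoma lineage were acquired while
  that clone was still a minor adenoma subpopulation, so they appear
  *subclonal in the adenoma but clonal in the carcinoma*;
* **parallel** — both lesions descend independently from a last common
  ancestor; mutations are then either shared and clonal in both lesions, or
  private to exactly one lesion.

The presence or absence of a mutation cluster that is subclonal in the
adenoma and clonal in the carcinoma therefore decides between the models.
`synclone` implements this decision as a pipeline over paired mutant allele
frequencies, together with the accompanying analyses a lesion-pair study
needs: regional mutation classification, microsatellite-instability (MSI)
calling, read-depth copy-number segmentation, and class-specific gene
enrichment.

## The MAF model

For a copy-neutral heterozygous somatic variant carried by a fraction $c$ of
the tumor cells (the cancer-cell fraction, CCF) in a lesion with tumor-cell
content (purity) $\rho$, the expected mutant allele frequency is

$$\mathrm{E}[\mathrm{MAF}] = \frac{\rho \, c}{2}.$$

With purities around 0.75 the clonal reference point $m^\* = \rho/2$ sits
near 0.375. The four expected mutation classes map onto anchors in the
(MAF adenoma, MAF carcinoma) plane:

| class                  | CCF (adenoma, carcinoma) | expected MAF pair          |
|------------------------|--------------------------|----------------------------|
| clonal                 | (1, 1)                   | $(m^\*_A,\ m^\*_C)$        |
| adenoma-specific       | (1, 0)                   | $(m^\*_A,\ 0)$             |
| carcinoma-specific     | (0, 1)                   | $(0,\ m^\*_C)$             |
| stepwise-intermediate  | $(f, 1)$                 | $(\rho_A f/2,\ m^\*_C)$    |

where $f$ is the carcinoma-fated subclone's CCF within the adenoma.
Restricting the clustering input to **autosomal SNVs in copy-neutral
segments** keeps this map valid without copy-number correction of the MAF;
when no segmentation is supplied, all autosomal SNVs are used, which is
appropriate for genomes with few copy-number changes (typical of
microsatellite-unstable tumors).

## Clustering and labeling

`clonal_architecture()` proceeds in five steps.

1. **DBSCAN** (`dbscan_cluster()`) on the unit square with Euclidean
   distance, `eps = 0.01` (a reachability distance of 1% in MAF units) and
   `min_pts = 5`. A point is core when its eps-neighborhood, itself included,
   holds at least `min_pts` points; clusters are connected components of core
   points; a border point joins the cluster of its first core neighbor in
   input order — a declared tie rule that makes the partition deterministic
   for a fixed input order. `min_pts` is a package default (the clustering
   literature's common choice for 2-D data); `eps` is configurable because
   binomial MAF noise at low coverage can exceed 1%: at depth $d$ the MAF
   standard deviation is $\sqrt{p(1-p)/d}$, about 0.044 at $p = 0.375,
   d = 120$, several times `eps`. DBSCAN still recovers such clouds through
   density chaining, at the price of shaving sparse fringe points into
   outliers or small satellite clusters; the size filter and the purity
   refinement below absorb that.
2. **Size filter** (`filter_small_clusters()`): clusters holding less than 1%
   of all points are treated as outliers (boundary inclusive: exactly 1% is
   retained).
3. **Purity** (`estimate_purity()`): $\hat\rho = 2 \times$ median MAF of the
   clonal cluster per lesion, clipped to $[0, 1]$. The clonal cluster is
   identified as the retained cluster maximizing the smaller of its two
   center coordinates, restricted to clusters at least half the size of the
   largest both-lesion cluster — without the size restriction a
   high-MAF satellite fragment of a few points can win the max. After a
   provisional labeling, the purity is re-estimated once from the union of
   all clusters labeled clonal and the clusters are relabeled; this
   refinement step corrects the fringe-shaving noise of step 1 and brings
   the estimator's error well inside the ±0.05 band checked by the test
   suite. Known purities can be supplied instead (specimen histology often
   provides a tumor-cell content estimate).
4. **Labels** (`label_clusters()`): per lesion, a cluster center below 0.05
   is *absent*, at or above $0.6\,m^\*$ is *clonal*, otherwise *subclonal*.
   The status pair maps to the four classes of the table above; unmatched
   pairs stay `unlabeled`. Both thresholds are package defaults: reference
   analyses of this design label clusters by visual inspection, and 0.6 sits
   halfway between a subclone at half the clonal CCF and the clonal cloud,
   while 0.05 matches the practical floor for calling a mutation present.
5. **Verdict** (`infer_evolution()`): *stepwise* when any retained cluster is
   labeled stepwise-intermediate; *parallel* when a clonal cluster coexists
   with at least one lesion-specific cluster and no stepwise-intermediate
   cluster; *indeterminate* otherwise — including when fewer than
   `min_points = 50` points survive selection, the situation of
   microsatellite-stable genomes whose low mutation burden precludes a
   confident verdict.

## The paired-lesion simulator

`simulate_lesion_pair()` draws, per variant and lesion, a Poisson depth
(mean 120 by default, whole-exome-like) and a binomial alt count at the
class's expected MAF; the matched normal always has alt count 0. Defaults:
purity 0.75 in both lesions (typical of careful needle microdissection),
400 clonal / 200 adenoma-specific / 200 carcinoma-specific variants (the
scale of a hypermutated exome after filtering), subclone fraction
$f = 0.3$, and 2% uniform-square outliers emulating artifactual calls.
Under the stepwise model the carcinoma-private variants are emitted at CCF
$(f, 1)$ — class `stepwise_intermediate` — because in that scenario the
carcinoma lineage acquired its private mutations while still an adenoma
subclone; no $(0, 1)$ class exists under stepwise. Poisson depth plus
binomial counts is the simplest model consistent with exome shot noise;
overdispersion, tumor-in-normal contamination and lesion
cross-contamination are deliberately not modeled (no reference values exist
for them in this design), so passing recovery tests demonstrates correctness
of the inference machinery, not robustness to every artifact of real exomes.
Only copy-neutral heterozygous autosomal SNVs are simulated, matching the
restriction of the clustering input.

## Microsatellite instability

`find_microsatellites()` scans for maximal perfect tandem tracts of a 1–4 bp
unit with total length 7–60 bp (partial trailing units count; tracts longer
than 60 bp are discarded; `N` breaks tracts). Units that are repetitions of
a shorter string are suppressed in favor of the smallest period, and
overlapping candidates are resolved smallest-unit-first, then
longest-tract. Perfect tracts (no mismatch tolerance) are a deliberate
divergence from mismatch-tolerant scanners: the parameters of those scoring
schemes are not published in a reproducible form, while perfect-tract
scanning is deterministic and verifiable against an exhaustive oracle — the
test suite checks identity on 1,000 random 2-kb sequences.

`extract_intraread_lengths()` turns reads into per-locus length
observations: a read must span the tract plus `min_flank = 5` anchor bases
on each side, and contributes the length of the maximal tract of the locus
unit at the expected offset, so indels inside the tract shift the observed
length. `call_msi()` then compares tumor and normal length multisets per
locus with a two-sample Kolmogorov–Smirnov test — $D$ evaluated at every
observed value, p from the asymptotic Kolmogorov distribution at
$\sqrt{n_e}\,D$ with $n_e = n_x n_y/(n_x + n_y)$ — and applies
Benjamini–Hochberg FDR across loci, separately per comparison family
(adenoma-vs-normal and carcinoma-vs-normal are corrected independently,
mirroring per-pair testing). An event is called at $q < 0.05$. Loci with
fewer than `min_reads = 10` observations in either sample are skipped: the
asymptotic p is anticonservative at tiny samples (the exact permutation
p for two-vs-two disjoint samples is 1/3, the asymptotic value is smaller),
and ties make it conservative at realistic read counts, which is the safe
direction for FDR control. Calls overlapping an indel call are flagged by
`reconcile_with_indels()` and excluded from the final event list, since they
likely duplicate clonally fixed events already counted among the indels.

The MSI simulator adds symmetric truncated-geometric stutter
($P(|d| = k) \propto s^k$, $|d| \le 3$, default $s = 0.1$) to the true tract
length — an invented but documented stand-in for PCR slippage, for which no
read-level noise model is published in this design — and, at MSI-true loci,
shifts tumor reads by −3 bp with probability 0.5 (a heterozygous somatic
slippage event). The depth-profile simulator draws per-bin GC content
uniformly in [0.35, 0.55], independent of genomic position, and applies the
smooth bias $2^{2(\mathrm{gc} - 0.45)}$ to both samples when enabled;
position-independent GC is what makes stratified-median correction
identifiable even in the presence of copy-number events.

## Copy number

`gc_correct()` divides each sample's depths by the median-depth ratio of the
bin's 2%-wide GC stratum to the global median (strata under 20 bins inherit
the nearest populated stratum), preserving each sample's global median.
`normalize_and_ratio()` masks bins with normal depth below 10, rescales the
tumor so unmasked totals match, and forms
$\log_2((t + 0.5)/(n + 0.5))$. `cbs_segment()` is a native circular binary
segmentation: over the circularized sequence it finds the arc maximizing
$|\bar x_{\mathrm{arc}} - \bar x_{\mathrm{comp}}|/\sqrt{1/k + 1/(n-k)}$
(the overall variance is permutation-invariant, so the usual variance term
is omitted without changing the test), assesses it with `n_perm = 1000`
permutations — stopping early once the exceedance count guarantees
$p > \alpha$ — and recurses when $p \le \alpha = 0.01$ with both arcs at
least `min_width = 3` bins. The variance-pruning and split-undoing
refinements of the reference segmentation algorithm are intentionally
omitted; on single-step signals of the tested scale they change nothing,
and the simplification keeps the statistic exactly checkable. Segments are
called gain/loss at mean log2 ratio ±0.25 (one extra copy at purity 1 gives
$\log_2 3/2 \approx 0.58$; ±0.25 catches single-copy events down to roughly
40% purity). The bin size and GC method of depth-based exome
copy-number tools vary; the defaults here (10-kb bins, 2% GC strata) are
declared package choices exposed as parameters.

## Enrichment and trees

`class_enrichment()` tests, per gene and direction, the pooled 2×2 table
(mutations in the gene vs all other genes) × (in the direction's class vs
the other classes) with a two-sided Fisher exact test, reported raw — no
FDR correction, matching how such screens report raw P values. The exact
margin construction of published versions of this test is not recoverable,
so printed p-values from any particular study are not reproduction targets;
the pooled construction is the package's documented choice (per-case
testing can be emulated by calling it per case). For hypermutated genomes,
`truncating_recurrence()` reports genes with ≥3 nonsense/frameshift events
in one regional class. `build_trunk_branch_tree()` emits the two-lesion
phylogeny with edge lengths equal to the class counts (conserved against
`summarize_abundance()` by construction) and a Newick serialization;
copy-number events are placed on the trunk when called in both lesions.

## Numerical and interface choices

* Presence thresholds for regional classification (`min_alt_reads = 4`,
  `min_maf = 0.05`) operationalize "observed in both lesions"; they are
  deliberately permissive so subclonal but real mutations count as present,
  and are exposed as arguments.
* High-confidence indels: MAF > 0.40 in a lesion where observed, or more
  than 50 reads of coverage in a tumor lesion.
* VCF positions are 1-based; microsatellite loci and BED outputs are 0-based
  half-open; the only conversion site is `reconcile_with_indels()`.
* MAF of a zero-coverage site is defined as 0 and flagged; DBSCAN on an
  empty point set returns an empty partition; constant input to CBS returns
  one segment; all generators are deterministic given their seed, with the
  caller's RNG state restored.
* Test-suite problem sizes: 100 seeded lesion-pair simulations for verdict
  recovery, 60 for purity recovery; 100 random DBSCAN instances (≤200
  points) and 1,000 random 2-kb sequences against brute-force oracles; KS
  exactness on every pair of multisets of size ≤8 over a 3-letter value
  alphabet; Fisher exactness on every 2×2 table with total ≤12 plus 300
  random tables with margins ≤30; 50 CBS replicates at step amplitude 1.0,
  noise 0.25, 500 bins; 50+50 MSI seeds for null calibration and power.

## Limitations

The package infers a verdict for a *pair* of lesions; multi-region designs
(more than two samples) and full subclonal deconvolution (CCF mixture
models, tree search) are out of scope. MAF clustering assumes copy-neutral
heterozygous variants, so heavily rearranged genomes need the copy-number
restriction to be effective. The simulators emulate sampling noise, stutter
and GC bias but not alignment artifacts, contamination or sequence-context
mutation spectra, and the MSI read model treats each spanning read as one
independent observation.
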