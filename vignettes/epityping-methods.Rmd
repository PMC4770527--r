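---
title: "Methods: DNA methylation epityping and its synthetic test-bed"
author: "epityper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DNA methylation epityping and its synthetic test-bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind every stage of the
package, the tunable parameters and their defaults, the numerical choices
where the published procedure leaves freedom, and what the synthetic
cohort generator does and does not emulate.

# The analysis model

## From signals to β values

A 450K-style array reports a methylated (M) and unmethylated (U) intensity
per CpG probe and sample. The methylation level is the fraction
β = M/(M+U) ∈ [0, 1]. `compute_beta_and_mask()` masks a measurement as
missing when its detection p value is strictly greater than `p_max`
(default 0.05) or its bead count is below `min_beads` (default 3); when the
input dialect carries no bead counts (TCGA level-2 style), only the
detection-p rule applies. M + U = 0 is flagged missing rather than
errored. A per-sample QC table of missing totals is attached, with a
warning (not a failure) above 10,000 missing values, the level at which a
sample would be an outlier on this platform.

## Peak normalization

The two Infinium chemistries have different dynamic ranges: type-II probes
show compressed β distributions relative to type I. Following the
peak-based correction family, `peak_normalize()` treats each sample and
each chemistry separately: the β density is estimated with an
Epanechnikov kernel, the unmethylated peak (density argmax below
`midpoint` = 0.5) is moved to 0 and the methylated peak (argmax at or
above the midpoint) to 1 by linear scaling, and rescaled values outside
[0, 1] are clamped.

Numerical choices, none of which the published description pins down:

* **Bandwidth 0.04 on a 1,001-point grid over [0, 1].** This resolves
  peaks ≥ 0.1 apart without splitting noise modes; both are arguments.
* **Boundary atoms.** Clamping creates point masses at exactly 0 and 1.
  A kernel estimate diffuses such an atom ~half a bandwidth inward, which
  would make a second normalization pass shift all values by that amount.
  When at least 5 % of a stratum sits exactly on a boundary, the peak is
  therefore taken at the boundary itself. Genuine raw data essentially
  never has atoms at 0/1, so this rule only fires on already-normalized
  input; it is what makes the operation idempotent to within one grid
  step.
* **Minimum peak separation 0.2.** A stratum whose two peaks are closer
  (effectively unimodal) would make the linear map explode; it is an error
  naming the sample and chemistry.
* Within a sample × chemistry stratum the map is affine, hence strictly
  monotone between the clamping bounds: ranks are preserved.

Each chemistry is normalized independently to its own anchors, which is
the straightforward reading of "each assay was normalized separately";
anchoring type II to the type-I peaks would be an alternative dialect and
is not implemented.

## Hypermethylation scores

Two per-sample summaries: a *global* score over all probes and a
*promoter CpG island* score over probes annotated both to a promoter
region (TSS1500 or TSS200) and to a CpG island. The published analysis
cites an external score definition without reproducing it; the package
defines both scores as the mean β over the contributing set (missing
values excluded), which preserves the intended ordering semantics (more
hypermethylated samples score higher) and keeps the score in [0, 1]. This
choice is flagged in the documentation as a package definition.

## Tumor-specific CpG selection

`call_normal_status()` calls a probe constitutively *methylated* in the
normal cohort when every non-missing normal value is strictly above 0.7,
*unmethylated* when strictly below 0.3, allowing at most `max_missing` = 2
missing normals ("allowing for 2 missing values" is read as ≤ 2). Any
value in the intermediate band excludes the probe.
`select_tumor_specific()` then keeps probes that switch status — β > 0.7
in a tumor for normally-unmethylated probes, β < 0.3 for
normally-methylated ones — in at least `ceiling(min_fraction × n_tumors)`
tumors (5 % of 188 gives 10, consistent with the published count; the
ceiling convention is the documented choice). Missing tumor values never
count as switched and the denominator stays the full tumor count, which
is conservative. The two selected sets are structurally disjoint because
they require opposite normal statuses.

## Bootstrap consensus clustering

`bootstrap_consensus()` resamples the tumors with replacement to the
cohort size `n_boot` times (default 2,000). Each resample's *unique*
samples are clustered by agglomerative Ward linkage (`ward.D`) on the
distance 1 − Pearson(βᵢ, βⱼ), and the tree is cut at every k in `k_range`
(default 3–10). The co-clustering frequency of a pair is its co-assignment
count divided by its co-presence count. The outer clustering applies the
same Ward linkage to 1 − Pearson between rows of the frequency matrix and
is cut at the same k (using 1 − frequency directly as the distance is
available behind `outer_distance = "consensus"`). The bootstrap dialect —
resample to n, cluster unique samples, normalize by co-presence — is one
of several consistent readings of the published description and is
documented and seedable; a sample never drawn in any iteration is an
error advising more iterations.

`choose_k()` declares a k admissible when every cluster has at least
`min_cluster_size` = 5 members, per-cluster mean within-cluster consensus
≥ `min_within` = 0.8, and the gap between within- and between-cluster
consensus ≥ `min_gap` = 0.6, then returns the **largest admissible k**
(the solution with the most robust clusters). The published criterion
names no statistic ("unstable clusters"); the within/gap pair was fixed by
inspecting consensus matrices of the generator at its default conditions
before the recovery tests were written: forced over-splitting of a true
cluster leaves a sub-cluster whose within-consensus falls well below 0.8,
while genuine clusters sit near 1.

## Centroids and classification

An epitype centroid is the per-site mean β over its members (missing
values excluded). When a normal-cohort mean profile is supplied, epitypes
are renamed ET1…ETk by decreasing centroid–normal correlation, a
documented convention making the most normal-like cluster ET1.
`classify_by_centroid()` assigns a sample to the centroid with the largest
Pearson correlation over sites non-missing in both (pairwise-complete
everywhere; at least `min_overlap` = 100 shared sites, else an error);
exact ties break deterministically to the earlier label in the epitype
order; a zero-variance profile is an error rather than an arbitrary call.

## Epitype-specific patterns

`extract_paper_patterns()` applies five strict mean-β rules, the
hypermethylation rules over the cancer-methylated universe and the
hypomethylation rules over the cancer-unmethylated universe (thresholds
0.5 / 0.1 / 0.7, all strict):

| set | rule |
|---|---|
| basal-methylated | mean > 0.5 in basal-like |
| luminal-methylated | mean > 0.5 in hypermethylated-luminal AND < 0.1 in basal-like |
| global-hypo-specific | mean < 0.5 in global-hypo AND > 0.7 in both hypermethylated-luminal and basal-like |
| luminal-hypo | mean < 0.5 in hypermethylated-luminal AND > 0.7 in basal-like |
| basal-hypo-specific | mean < 0.5 in basal-like AND > 0.7 in global-hypo |

Means are taken over non-missing members; a probe unobserved in a
constrained epitype fails that constraint (conservative). Which cluster
plays which role is *declared* (config/argument), not inferred — on new
data the ordinal labels carry no biology. `run_pipeline()` defaults to a
positional convention on the normal-similarity ordering, which is only a
starting point; the README shows role declaration on synthetic data.

## Expression integration

Relative expression is log2(x + 1) mean-centered per gene; absolute
expression is log2(TPM + 1) with TPM from scaled estimates. When several
array probes map to one gene, the probe with the largest variance is
kept. `correlate_meth_expr()` computes pairwise-complete Pearson
correlations per CpG mapped to exactly one gene (ambiguous and unmapped
CpGs are excluded with a recorded reason, as are zero-variance ones and
pairs with fewer than 10 complete observations) and classifies r > 0.2 as
positive, r < −0.2 as negative. The closed-form null p of such a
correlation at n = 661 (t transform, 659 df) is ≈ 2×10⁻⁷, so fewer than
one of ~325,000 tested sites exceeds the threshold by chance — the
analytic justification for the screen, exposed as
`correlation_pvalue()` / `expected_chance_correlations()`.

Promoter methylation calling for candidate drivers screens all CpG sites
within a gene's transcripts or 1 kb upstream (strand-aware, 0-based
half-open arithmetic, union over transcripts when several starts exist)
for correlation < −0.2 with the gene's expression on an explicitly
declared screening cohort, then thresholds the per-sample mean β over the
informative sites: the BRCA1-style preset calls *methylated* above 0.2,
the HORMAD1-style preset calls *unmethylated* below 0.8 (strict). Zero
informative sites yields "uncallable", never a default.

## Context, copy number, mutations, statistics

Interval work uses GenomicRanges on 0-based half-open inputs (BED) with
1-based probe positions converted on read; overlapping repeat intervals
count once; strand is ignored (CpG methylation is strand-symmetric).
Repeat enrichment is a two-sided Fisher exact test on the 2×2 overlap
table, with all non-target probes as the default background (the
platform-wide alternative is a flag). Subtelomere analysis uses the
distance min(pos, length − pos) to the nearest chromosome end, a 5 Mb
window, and a two-sided t test. FGA is altered probes / total probes;
region amplification requires mean estimate strictly > 0.8; gene
mutations are called when nonsilent in ≥ 1 experiment and substitution
counts are averaged over experiments (nonsilent excludes
Silent/Intron/UTR/IGR/Flank/RNA, configurable — the published set is not
stated). Categorical association uses χ² without continuity correction
(df = k − 1 for a k×2 table), switching to Fisher's exact test when any
expected cell count is below 5 (the published analyses use both without
stating the rule); continuous variables use Kruskal–Wallis; screens
adjust with Benjamini–Hochberg over the tested features only. Survival
uses the Kaplan–Meier estimator and the k-sample log-rank test
(hypergeometric variance, standard ties handling), with optional
administrative truncation (events after the horizon become censorings at
the horizon) and duplicate patients reduced to their first record.
Overall survival events are deaths of any cause (the published definition
is not restated).

# The synthetic cohort generator

`generate_cohort()` draws a multi-platform cohort with planted truth. Its
defaults are the conditions under which the package's end-to-end checks
run: 120 tumors, 96 normals (the published normal-cohort size), 5,000
probes, 7 epitypes in equal proportions, β peaks at 0.05/0.95,
measurement noise sd 0.05, type-II compression shifting the peaks to
0.10/0.88, 72 % type-II probes, 0.5 % censoring.

* **Noise model.** β values are drawn from a normal distribution centered
  on the planted mean and truncated to [0, 1] (inverse-CDF). The sd is
  interpreted on the β scale. A logit-scale noise model was considered and
  rejected: mapping a β-scale sd of 0.05 to the logit scale near a peak at
  0.05 gives a logit-sd near 1, which puts percent-level mass beyond the
  0.3 status threshold in every normal sample and would destroy the
  all-normals selection rule at the default noise. Truncation keeps both
  tails light and the bimodality intact.
* **Type-II bias** is a linear compression of the planted means toward
  0.5 — exactly the dialect the peak normalizer removes.
* **Site classes.** Besides constitutive probes, the generator plants:
  generic cancer-methylated/-unmethylated sites (default 5 % each)
  switching in a stratified random 6–15 % of tumors; the five pattern
  classes with graded per-epitype means following the qualitative ordering
  of the luminal gradient (exact means are config values via
  `gradient_spec`/`default_gradient()`, not claims); and 40 private marker
  CpGs for each epitype that has no pattern-class signature. The marker
  count was sized at design time so that every epitype's shared signature
  exceeds the idiosyncratic load of the generic switching sites — the
  condition for the planted partition to dominate the correlation
  structure.
* **Planted drivers.** A BRCA1-like gene (8 informative promoter CpGs,
  hypermethylated to β ≈ 0.6 with suppressed expression in half of the
  basal-like tumors; β ≈ 0.025 in normals) and a HORMAD1-like gene
  (7 informative CpGs, constitutively methylated, demethylated with
  restored expression in 70 % of basal-like tumors). The demethylated
  driver CpGs genuinely satisfy the cancer-unmethylated and
  basal-hypo-specific rules and are part of the planted truth for those
  sets.
* **Expression** is linear in the planted (noise-free) β with
  class-specific slopes (negative for luminal-methylated sites, positive
  for the hypomethylation classes, zero for the basal classes, matching
  the correlation structure the analysis expects) plus Gaussian noise,
  then mean-centered. Some probes are ambiguously annotated to two genes
  to exercise the unique-mapping filter.
* **Copy number, mutations, survival.** Altered-probe fractions rise
  across the epitypes; five recurrent amplification regions are enriched
  in the amplification-rich epitype; mutations follow epitype-dependent
  gene frequencies with a second sequencing experiment for 15 % of
  tumors; survival is exponential with per-epitype hazards (lowest in the
  early luminal epitype, highest in the amplification-rich one) under
  uniform censoring — the minimal model supporting log-rank comparisons.
  At the default cohort size the 7-group log-rank p typically lands in
  the 0.003–0.2 range across seeds, i.e. the planted differences are
  detectable but not overwhelming, as in cohorts of this size.

**What the generator does not emulate:** raw IDAT intensities, tumor
purity and stromal contamination, probe cross-hybridization, SNP-confounded
probes, batch structure, and spatial correlation along the genome. Tests
that pass on this generator therefore demonstrate the correctness of the
selection rules, clustering machinery and integration statistics under the
assumed mixture model — not robustness to the artifacts of real arrays.

# Test and check dimensions

The unit suite runs on compact cohorts (70 tumors / 24 normals / 800
probes, and a low-noise variant with sd 0.01 and no censoring for the
exact-recovery properties). The end-to-end checks use the generator's
default conditions (120 tumors, 5,000 probes, noise 0.05) with 200
bootstrap iterations and k searched over 3–10, plus a 160-tumor cohort
split 120/40 for held-out classification; `scripts/acceptance.R`
recomputes all headline quantities from scratch at those sizes. These
sizes were chosen so the whole suite completes in well under a minute per
cohort on a single core while keeping every epitype above the minimum
cluster size.

# Known limitations

* The hypermethylation score is a package definition (mean β), not the
  externally published score it stands in for semantically.
* Epitype roles for pattern extraction must be declared; the positional
  default in `run_pipeline()` is only meaningful when the
  normal-similarity ordering happens to match the biology.
* `choose_k()`'s stability thresholds were calibrated on the generator's
  default conditions; very differently structured data may need
  different values (both are arguments).
* The bootstrap and outer-distance dialects are one consistent reading of
  the published method; alternatives (item resampling, k-means inner
  loops) are out of scope.
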