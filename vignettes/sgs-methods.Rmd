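---
title: "Shared genomic segments in extended high-risk pedigrees: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shared genomic segments in extended high-risk pedigrees: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgsfam)
```

## The problem

Rare variants of appreciable effect are hard to find in case-control
samples, but they leave a long footprint in large families: distant
relatives who all inherited a risk variant from a common ancestor also
inherited the chromosomal segment around it.  Shared genomic segment (SGS)
analysis looks, within one extended pedigree, for runs of consecutive SNP
markers at which a subset of affected relatives all share at least one
allele identical by state (IBS).  Chance IBS runs are short; a run long
enough to be improbable under Mendelian transmission alone is evidence for
a segment identical by descent (IBD) around a segregating risk variant.
The design needs three ingredients this package implements end to end:

1. a way of choosing which families are worth genotyping — familial risk
   scoring and meiosis counting;
2. the sharing statistic itself — maximal IBS runs over all case subsets,
   after standard array quality control;
3. a null distribution for that statistic — gene-drop simulation through
   the exact family structure, from which per-segment empirical p-values
   and family-specific genome-wide thresholds are derived; plus
   cross-family combination and rare-variant follow-up.

## Familial risk and family selection

A family's excess of affected members is summarised by the familial
standardized incidence ratio, FSIR = O/E: the observed count of affected
members against the count expected if every member experienced the
population incidence of their sex-by-age stratum, E = sum of stratum
rates over members (`expected_count()`).  Significance is the one-sided
Poisson tail P(X >= O) with mean E (`fsir_pvalue()`): the rate table is
treated as fixed population knowledge, and under no familial clustering
the number of affected members in a family is approximately Poisson.  A
family enters segment analysis when (i) the FSIR p-value is below 0.05,
(ii) at least three affected members are genotyped, and (iii) at least 15
meioses connect the genotyped cases (`eligible_family()`), the power
floor for run-length statistics: every meiosis halves the chance that a
specific founder segment is co-inherited, so the meiosis count is the
natural measure of how surprising observed sharing is.

Meioses are counted on the minimal connecting sub-pedigree: one
transmission per child included in the union of descent paths linking the
cases through a common ancestor couple (`count_meioses()`).  A sibship of
k cases therefore counts k, first cousins count 4, an avuncular pair 3.
In multiply-connected pedigrees several ancestor trees can connect the
same cases; we return the minimum over admissible trees, computed exactly
as a minimal Steiner arborescence by dynamic programming over case
subsets.  The minimum is a reproducible canonical choice; drawn pedigrees
in practice depict a single tree, and which tree a study draws is not
recoverable from a published figure.

FSIR here is the plain O/E ratio with Poisson significance.  The
kinship-weighted variant of the statistic (which weights each affected
member by genealogical distance) is deliberately out of scope; the O and
E columns are exposed so a weighted variant can be layered on later.

## Genotype quality control

`qc_filter()` applies array QC in a fixed order: markers with more than
5% missing calls, markers failing the Hardy-Weinberg exact test at
p < 0.001, non-polymorphic markers, markers whose strand orientation
cannot be matched to the reference panel (only when a flag list is
supplied), then samples with more than 5% missingness.  The report
records removal counts per filter in application order and is
reproducible bit for bit.

The Hardy-Weinberg test (`hwe_exact_test()`) is the exact conditional
test: given the observed allele counts, every heterozygote count of the
same parity is enumerated and the p-value sums the probabilities of all
configurations no more probable than the observed one.  It is computed
across all genotyped individuals, including relatives.  Relatedness
inflates homozygote sharing slightly, making the screen conservative (it
removes a few more markers than an unrelated sample would); this mirrors
standard practice when only family cases are genotyped, and is preferable
to silently restricting to founders that may not exist in a case-only
sample.

## Sharing runs

At a biallelic marker with dosages in {0, 1, 2}, a set of individuals can
share an allele IBS unless both homozygote classes are present
(`sharing_indicator()`).  Missing genotypes are compatible with sharing
by default — a failed call should not break a true IBD run — with a
strict `"break"` policy available for sensitivity analysis.
`maximal_shared_segments()` reports every maximal run of consecutive
sharing markers per chromosome; `subset_scan()` repeats this for every
case subset of size at least `min_subset_size` (default 3), because in a
heterogeneous family only a subset of cases may carry any one risk
segment.  Segment coordinates are the base-pair positions of the first
and last sharing marker, and `length_bp = end_bp - start_bp`, matching
the arithmetic of published segment tables.

Runs spanning fewer than `min_markers_per_run` markers can be suppressed.
The scan primitive defaults to 1 (every maximal run), but the `sgs()`
pipeline raises the floor (default 10; our experiments use 15–25
depending on marker density): one- and two-marker runs occur by chance at
almost every locus, carry no linkage information, and dominate the null
store if kept.  The floor is applied identically to observed and
simulated sharing, so p-values remain comparable; observed segments below
the floor are simply not scored.  No genotyping-error tolerance is
applied inside runs — a single discordant marker ends a run — because
the run definition is exact consecutive sharing; error-tolerant runs
would need an explicit error model and are out of scope.

## The gene-drop null

The significance of an observed run is assessed against gene-drop
simulation (`simulate_null()`): founder haplotypes are drawn uniformly
with replacement from a phased reference panel — whole chromosomes, so
the panel's linkage disequilibrium is preserved exactly — and transmitted
through the actual pedigree under the Haldane model (crossover count
Poisson in genetic length, crossover positions uniform on the cM scale,
no interference).  Only the genotyped cases' genotypes are materialised,
and the pedigree is first pruned to the ancestor closure of the cases,
which is the minimal structure their genotypes depend on.  Every
simulation replays the subset scan and records the maximal sharing runs
per subset size (identical runs found by different same-size subsets are
recorded once).  The whole loop is implemented in compiled code; with a
fixed seed the run store is bit-identical across runs.

A planted segment in synthetic data is *forced* through the carrier
lineage by overwriting the transmitted haplotype inside the interval,
rather than rejection-sampling transmissions, so ground truth is exact
and generation cost is flat.

An observed segment's p-value is `(c + 1) / (n_sims + 1)`, where c counts
simulations containing a sharing run of the same or larger subset size
that covers the segment's central marker with at least the observed bp
length (`empirical_pvalue()`).  The central-marker anchor is one fixed
convention among several (whole-interval coverage would be stricter);
it is stable under boundary jitter from single-marker noise.  The +1
estimator never returns zero from finite simulation, which matters
because downstream combination takes logarithms.

## Family-specific genome-wide thresholds

Because power depends on family structure, each family gets its own
genome-wide thresholds: the p-value cutoffs at which the expected number
of false-positive segments per genome per family is 0.5 (significant) and
1.0 (suggestive).  `fit_null_model()` scores every recorded null run
against the whole null with a leave-one-out version of the same
estimator (its own simulation always covers it, so the comparable
estimate over the other n − 1 simulations is c/n), and tabulates the
expected number of distinct null segments per simulated genome at or
below a grid of cutoffs.  `genomewide_thresholds()` inverts this curve
exactly on the sorted null p-values wherever the target is observable —
the largest attained p-value whose per-genome count does not exceed the
target, with ties resolved conservatively — and only extrapolates with a
log-log linear tail fit (the lowest usable decade of the curve) when the
target lies below the simulation's resolution of 1/n_sims.  We fit only
the tail because the full exceedance curve is visibly convex in log-log
coordinates; a global line inverts systematically too lax.  An
extrapolation beyond a configurable number of decades is flagged in the
diagnostics rather than refused.

Calibration was checked by construction: on null synthetic families the
mean number of distinct segments called significant per genome is close
to the 0.5 target (the acceptance suite measures it over 200 replicate
families at 2,000 simulations each).  A mild upward residual of order
+0.1 remains, driven by sampling noise of the per-family threshold at
desk-scale simulation counts (each replicate inverts its own noisy null);
it shrinks with n_sims and sits well inside the Monte-Carlo tolerance of
the check.  Two sources of deliberate conservatism remain undocumented
nowhere else: the null distributions of a real study contain a small
number of true positives, biasing thresholds slightly upward, and the
tie-conservative inversion rounds thresholds downward.

## Combining evidence across families

Regions seen in one family are reported when they reach the family's
significant threshold; regions overlapping across two or more families
are reported when each contributing family reaches at least its
suggestive threshold, with the interval being the base-pair intersection
(`overlap_regions()`; consecutive stretches covered by the same family
set are merged, so nested combinations are each reported).  Their joint
p-value is Fisher's combination, X = −2 Σ log p against chi-square with
2k degrees of freedom (`fisher_combined()`).  Fisher's method assumes
independent families; individuals appearing in two families violate
this, so `dedup_cases()` removes each shared individual from all but one
family — preferentially a family whose sharing subset does not contain
the individual (harmless removal), otherwise the family with the larger
sharing subset, then the larger pedigree, then lexicographic order.
Families whose subset drops below two sharing cases leave the
combination; affected families are flagged for p-value and threshold
recomputation.

## Follow-up analyses

`target_genes()` collects genes whose coding or regulatory intervals
intersect a region, then removes blacklisted genes (clusters known to
produce recurrent false positives, such as olfactory-receptor arrays).
`enrichment_test()` compares the fraction of targeted genes with prior
literature support to the genome background; the acceptance surface of
this operation is the arithmetic (observed proportion, expected count),
because no standard two-proportion statistic reproduces the z-value
printed in the study this design follows, so the z here (a one-sided
two-proportion test, pooled by default, with a `"fixed"`-background
variant exposed) is documented as our formula choice.
`familial_variant_screen()` asks whether any non-synonymous array variant
with reference MAF < 10% inside a region is carried by every case of the
region's sharing subset — an empty report means the array content cannot
explain the sharing.  `select_assoc_variants()` applies the follow-up
cohort criteria (coding, non-synonymous, damaging by at least one of two
predictors with missing calls ignored, reference MAF < 20%), and
`popfreq_association()` tests case versus reference minor-allele counts:
Pearson chi-square without continuity correction when both groups have
more than 10 minor-allele chromosomes, otherwise the two-sided
(minimum-likelihood) Fisher exact test, with Bonferroni significance at
alpha/m.  The >10 rule is applied to both groups severally, the stricter
reading of the two available.

## The synthetic-data generator

`simulate_study()` produces every input with known ground truth.  What it
emulates, and what it does not:

* **Pedigrees** (`make_pedigree()`): a founding couple with a large first
  sibship (mean 3.5) expanded for 7 generations at mean sibship 2.2,
  spouses marrying in as founders.  Carriers of the planted segment are
  spread across second-generation branches, and sporadic cases are
  confined to the three most recent generations (where death records
  would exist).  These defaults reproduce the scale of the study design
  this package implements: about 6 genotyped cases (reported mean 6.2)
  and about 27 meioses between them (reported mean 29.6, within the
  20% band we require of the generator).
* **Haplotype panel** (`make_panel()`): markers at an average 1 cM/Mb;
  haplotypes assembled block-by-block from small within-block pools
  (block length 1 + Poisson, pool of 6–8 haplotypes, per-marker pool
  frequency uniform on 0.25–0.75), which yields strong within-block and
  weak between-block LD with common variants.  This is a controllable
  stand-in for a population reference panel, not a coalescent model: it
  has no allele-frequency spectrum, no recombination hotspots and no
  population structure, so passing tests say nothing about those
  features of real data.
* **Rates, gene models, annotations**: lifetime-scale sex/age incidence
  rates (male roughly three times female); genes tiling each chromosome
  with coding cores and regulatory flanks, a few blacklist-flagged; an
  annotation table over a marker subset with consequence and two
  predictor calls, a planted explanatory variant inside the planted
  segment carried by every carrier, and a planted associated variant
  with case frequency 0.9% against reference frequency 0.007% at
  follow-up-cohort chromosome counts (about 2,600 case chromosomes
  against 66,000 reference chromosomes), the regime of the strongest
  association the study design is meant to detect.

Problem sizes in the shipped experiments are deliberately desk-scale:
one or two chromosomes of 30–60 cM at 10–33 markers/cM, nulls of
2,000–10,000 simulations (the real studies use 500,000, reachable via
`n_sims`), 50 recovery replicates and 200 calibration replicates.  The
planted-segment recovery experiment uses 33 markers/cM so that a 3 cM
planted interval spans about 100 markers; at that density chance IBS
chains of equal length are rare and recovery is near-certain, which is
the regime the power analyses of the original method describe for
families with 15+ meioses.

## Numerical and design choices, in one place

* Meiosis counting: exact minimal Steiner tree; minimum over ancestor
  trees in looped pedigrees (capped at 14 cases).
* FSIR: plain O/E with Poisson tail; per-person stratum probabilities
  rather than person-years, because cross-sectional rates are what is
  available at desk scale.
* HWE on all genotyped individuals; conservative under relatedness.
* Sharing: IBS-based, missing-compatible by default; autosomes only.
* Gene drop: whole-chromosome panel resampling (exact LD preservation);
  Haldane model; founder assignment independent of case status.
* p-values: (c+1)/(n+1), central-marker anchor, same-or-larger subset
  size; null store records per subset size with within-size
  deduplication.
* Thresholds: exact inversion of the empirical exceedance where
  observable; log-log tail extrapolation below resolution; significant
  clamped at or below suggestive.
* Fisher combination requires strictly positive p-values (guaranteed by
  the +1 estimator); dedup tie-breaks as above.
* Determinism: all randomness flows through R's RNG (also inside the
  compiled code), so a seed fixes every result; simulation runs
  checkpoint every `checkpoint_every` simulations and resume
  bit-identically.

## Known limitations

* IBS runs conflate IBD sharing with chance sharing of common
  haplotypes; the method relies on marker density and the simulation
  null to separate them, and no probabilistic IBD model (HMM or
  otherwise) is fitted.
* No genotyping-error tolerance inside runs; a bad call can split a true
  segment in two (both halves are still scored).
* The exceedance tail is assumed locally log-log linear for
  extrapolation below 1/n_sims; deep extrapolation is flagged, not
  modelled.
* The kinship-weighted FSIR variant and sex-specific genetic maps are
  not implemented.
* X-chromosome transmission is undefined; inputs are expected to be
  autosomal.
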