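---
title: "Methods: array design, kinship, IBD, GWAS and selection scans for clonal orchard panels"
author: "orchardpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: array design, kinship, IBD, GWAS and selection scans for clonal orchard panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orchardpop)
```

# What this package models

`orchardpop` re-implements, as tested and reusable functions, the
computational chain of a high-density SNP-array study in a clonally
propagated orchard crop: candidate-SNP filtering for array design,
marker- and pedigree-based kinship with network clustering, shared
identity-by-descent (IBD) region discovery per kinship cluster, a linear
mixed-model association scan, LD-block haplotype analysis, a
two-population selection scan, and a small allele-specific marker panel
for classifying early-flowering accessions. Because the original
accession panel is not distributed, every analysis is exercised against
a gene-dropping simulator whose defaults encode the population structure
such a study assumes. The `analysis/` scripts in the source repository
run the chain end to end on one simulated panel.

# The synthetic population

`sim_config()` fixes the study conditions. The defaults are:

* **Genome and map.** Eight chromosomes of 28 Mb (224 Mb total) with a
  constant 4 cM/Mb, i.e. a ~900 cM map — the scale of a peach-like
  diploid genome. Crossovers per meiosis are Poisson with uniform
  positions (Haldane, no interference); this is the simplest model whose
  statistics (segment-length distributions, kinship variance) match what
  the downstream analyses consume.
* **Founders.** ALT allele frequencies are uniform on [0.05, 0.5] and
  sites are drawn independently, so founders are in linkage
  equilibrium. A fraction `inbred_founder_frac = 0.7` of founders is
  produced by one additional selfing meiosis, which realizes inbreeding
  segmentally (expected F = 0.5 for those founders, pool mean F ≈ 0.35).
  That value anchors the founder pool to the inbreeding level of
  landrace germplasm in a self-compatible orchard crop, and it places
  expected full-sib relatedness near 0.63 rather than the outbred 0.5 —
  which is why a 0.45 relatedness threshold cleanly separates families.
  Tests of Hardy–Weinberg properties, of the method-of-moments
  inbreeding estimator, and of the origin-label IBD truth set use
  `inbred_founder_frac = 0`, because those oracles assume outbred
  founders.
* **Pedigree descent.** `script_pedigree()` builds multi-family crosses
  plus clonal "sport" mutants. A sport copies its source cultivar's
  diplotype and then receives `n_mut = 5` random genotype changes, so
  its marker kinship with the source is near, but not exactly, the self
  value — the same situation that motivates assigning a fixed 0.97
  relatedness to sport pairs on the pedigree side.
* **Planted QTLs.** One major flowering locus (target PVE 0.35, forced
  to founder ALT frequency 0.10 with a negative effect, so the early
  allele is a low-frequency variant), one acidity locus (PVE 0.29) and
  one citrate locus (PVE 0.07). Effects are scaled against the realized
  dosage variance so the achieved variance share matches the target;
  realized shares are recorded in the truth attribute. Traits without a
  planted QTL are environment-only draws on their measurement scale
  (concentrations are floored at 0.1, a detection-limit convention).
  The trait scales (e.g. flowering mean day-of-year 94, SD 3.2; sugar
  means in the ratio ≈ 22.4 : 3.6 : 2.8 : 1) are invented but chosen to
  look like a temperate orchard panel; they are labelled as such and
  carry no inferential weight.
* **Genotyping artifacts.** Per-call depth is Poisson(10); zero-depth
  calls are missing and a further 2% are masked; genotype quality is the
  monotone map `min(99, 10·DP)`; 1% of surviving calls are flipped; and
  a 10% "hot" tail of variants receives missing rates of 0.4–0.8 at a
  quarter of the depth — the bad tail that the QC cascade exists to
  remove. The pre-degradation genotypes are retained so concordance is
  measurable against truth.

All randomness flows from one base seed through a named stream per
operation, so individual steps are reproducible in isolation.

**What the generator does not emulate.** Founders carry no ancestral
linkage disequilibrium (coalescent ancestry is out of scope), so
population-level LD blocks do not arise in simulated panels; LD-block
detection and haplotype construction are therefore validated on
constructed fixtures with known block structure, and the demonstration
script falls back to a fixed marker window around the association peak.
There is also no genotype-intensity model: array performance categories
are defined on called genotypes, and the intensity-cluster category
(`OffTargetVariant`) can only be assigned from an external flag. Passing
tests consequently show that the statistical machinery is correct under
the stated descent model — not that it is robust to ancestral LD,
intensity artifacts, or population stratification beyond family
structure.

# Array-design cascade

`qc_filter()` keeps variants with missing rate ≤ 0.4 (inclusive), mean
depth ≥ 2, mean genotype quality ≥ 10 and variant-level allele quality
(QUAL) ≥ 50. The depth and quality rules are interpreted per variant as
means over non-missing calls — the per-call alternative is not
distinguishable from the published description, and the per-variant mean
is what a VCF-level filter normally does; a variant missing a metric
fails that criterion. `shared_variant_filter()` keeps ALT alleles
carried by at least two accessions (inclusive at exactly two).

The proprietary probe-convertibility score of array manufacture is
replaced by `probe_uniqueness_filter()`, a deterministic surrogate that
captures the same failure mode (sequence repetition): a variant fails if
any k-mer (k = 16) of its ±35 bp probe flank occurs more than once in
the reference on either strand, if the flank runs off the contig, or if
another candidate variant sits inside the probe window.

`classify_performance()` assigns the standard genotyping categories from
called genotypes: call rate < 0.975 (strict) → `CallRateBelowThreshold`;
monomorphic → `MonoHighResolution`; heterozygote plus both homozygote
classes → `PolyHighResolution`; heterozygote plus exactly one homozygote
class → `NoMinorHom`; anything else → `Other`. The exact predicate
separating `Other` from `NoMinorHom` in intensity-based software is not
fully published; this genotype-level reconstruction is the closest
stable definition. `select_final()` retains the two highest-priority
categories, and `integrate_legacy()` merges a legacy array's positions
by exact (chromosome, position) union.

Report percentages are rendered half-up to two decimals. One published
line (61,924 of 173,925 printed as 35.61%) is not reproducible by this
— or any single-step — rounding: the quotient is 35.6047%, which renders
as 35.60%. The package keeps correct arithmetic rather than matching
what is most plausibly a double-rounding artifact in the source table.

# Kinship

`grm()` computes the centered genomic relationship matrix: dosages are
mean-imputed per variant, centered at twice the panel allele frequency,
and normalized by `sum(2 p (1-p))` so the output sits on the relatedness
scale — non-inbred self ≈ 1, parent–offspring ≈ 0.5, self with
inbreeding ≈ 1 + F. This scale is the one on which the study's
clustering threshold (0.45), its sport convention (0.97) and its
full-sib values (~0.63) are mutually coherent; a marker-count
normalization would put the matrix on an arbitrary scale. The
standardized variant (unit variance per marker, divided by marker count)
is available by argument. Note that estimating allele frequencies from a
structured panel deflates within-family values — the analysis scripts
therefore estimate the GRM on the full diverse panel before clustering
the related subset.

`pedigree_kinship()` implements the recursive tabular method with
inbreeding, treats sports as clones (their kinship row duplicates the
source's), doubles the kinship coefficient to the relatedness scale and
then overrides sport/source pairs to 0.97. It is verified against an
independent Monte-Carlo gene-dropping estimator (`kinship_mc()`) to
within 0.02 at 10^4 drops.

`inbreeding_f()` is the method-of-moments estimator
`F = (O_hom − E_hom) / (m − E_hom)` with panel allele frequencies,
monomorphic sites excluded and missing calls excluded per sample.

`kinship_network()` thresholds the matrix strictly at 0.45 ("exceeding"
the threshold), takes connected components, and calls components with at
least `min_cluster = 3` members clusters (largest = Clr1); smaller
components are reported separately as isolated pairs/small groups,
because the source distinguishes multi-member clusters from such groups
without stating its size cutoff — 3 is the smallest value that makes
that distinction meaningful, and it is configurable.

# IBD segments and shared regions

`call_ibd_segments()` is a deliberately simple IBS-run stand-in for an
HMM-based detector, for error-free or low-error phased data: for each
sample pair and each of the four haplotype combinations it finds maximal
marker runs of identity, allowing one interior mismatch, keeps runs of
at least 1 Mb and 50 markers (defaults), and unions the intervals per
pair. Externally computed RefinedIBD files are read by
`read_refined_ibd()` (haplotype rows collapsed to sample pairs by
interval union) and bypass the caller entirely. Boundary precision of
the stand-in is limited by marker spacing: chance identity extends a
called run by a few markers past the true segment end, so validation
against gene-drop truth uses marker densities at which segments are long
relative to that noise (the array's real density is far higher than any
simulated panel here).

"Most frequent shared IBD segments" is operationalized as a pair-count
pileup: `ibd_pileup()` counts, in 10 kb bins, the distinct within-cluster
pairs whose segment covers the bin midpoint; `shared_regions()` keeps
bins at or above the (1 − 0.10) lower nearest-rank quantile of the
positive counts and merges adjacent kept bins. Frequency counts pairs
(not accessions) because pairwise segments are what an IBD detector
emits; the quantile is taken over positive bins so that empty genome
does not define the threshold. Both choices are configurable.

# Mixed-model association

`fit_null()` fits `y = Wα + u + ε`, `u ~ N(0, σ²_g K)`, by the spectral
(eigendecomposition) transformation: with `K = U Λ U'`, the generalized
least-squares problem becomes weighted least squares with weights
`1/(λ_i + δ)`, `δ = σ²_e/σ²_g`, and the REML profile criterion is
maximized over `log10 δ ∈ [−5, 5]` by Brent search (boundary candidates
are also evaluated). The spectral log-likelihood is tested to equal the
dense multivariate-normal REML criterion within 10⁻⁸.

`lmm_scan()` holds the null `δ` fixed across markers (the fast
approximation used by the standard tools; exact per-marker REML would
re-optimize `δ` for every variant at ~100× the cost for a negligible
change in this setting), mean-imputes missing dosages, skips variants
with zero dosage variance, and reports Wald t-tests plus the
genomic-control inflation factor. With `K = I` every p-value equals
ordinary least squares to 10⁻⁶.

The significance threshold follows the study's printed rule `1/n`
(`mode = "paper"`) with conventional Bonferroni `0.05/n` also exposed;
the two differ by a factor of 20 and the package takes no position on
which is appropriate. Per-variant variance explained uses the standard
`PVE = β̂² · 2p(1−p) / Var(y)`, documented as an interpretation (no
formula is published); it assumes Hardy–Weinberg dosage variance and
will understate PVE by ≈ (1 + F) in inbred panels.

# Haplotype blocks and groups

`ld_r2()` is composite LD: the squared Pearson correlation of dosage
vectors over jointly non-missing samples. `find_blocks()` replaces the
clique-partition heuristic of published block finders with a greedy
contiguous extension — grow a block while the minimum r² between the
candidate SNP and all current members stays ≥ 0.6 — because it is
deterministic, oracle-checkable by exhaustive search, and the downstream
use needs only block intervals.

`build_haplotypes()` counts haplotype frequency in accessions carrying
the string (chromosome-copy counts are also reported), drops strings
carried by fewer than two accessions, and orders the rest by carrier
count. For phenotype comparisons an accession joins a haplotype group
only when both copies carry the same retained string; ambiguous
heterozygous carriers are excluded — the conservative reading of how
published haplotype/phenotype boxplots are constructed.
`haplotype_phenotype_test()` runs one-way ANOVA followed by Fisher's LSD
(pooled mean-square error, residual degrees of freedom, unadjusted
pairwise p at α = 0.05) with compact letter display; with two groups the
LSD p equals Student's t exactly. `haplotype_network()` builds the union
of all minimum spanning trees on Hamming distance (every tied minimal
edge retained) — a stand-in for median-joining networks that introduces
no inferred median vectors; this divergence from the cited method is
deliberate and documented.

# Selection scan

The scan machinery reproduces the published protocol — MAF ≥ 5% (strict
below), 50 kb windows on a 10 kb step, windows with fewer than five SNPs
unscored, top 1% of scored windows (nearest-rank, ties kept) merged into
candidate regions — around a pluggable per-SNP statistic. The default is
the symmetric allele-frequency-differentiation score
`d = (p₁ − p₂)² / (p̄(1 − p̄))`; the composite-likelihood model of the
original scan statistic is out of scope, and any replacement statistic
can be supplied without touching the windowing.

# Early-flowering marker panel

`encode_calls()` maps dosage 0/1/2/missing to `R/R`, `R/A`, `A/A`,
`missing` against the reference allele. `classify_early()` applies the
published 2-of-3 quorum rule: at least two markers carrying the
alternate allele call the accession early; missing markers never count
toward the quorum and an all-missing accession is non-early with a flag
(conservative). `evaluate_kasp()` scores predictions against observed
flowering dates with the cutoff at day-of-year 90 (March 31 of a
non-leap year, inclusive — an April 1 bloomer counts as mis-called
early), divides each group's correct calls by its size net of missing
records, and renders percentages half-up to one decimal.
`select_markers()` is a documented reconstruction of panel selection:
rank candidates by single-marker classification accuracy, tie-break by
call rate, association p, then position; assay cost criteria are not
computable here.

# Numerical conventions

* Intervals are 1-based inclusive in external formats (VCF/GFF) and in
  the segment tables; interval arithmetic converts once at the boundary.
* Missing genotypes are `NA`, never a sentinel; every numeric consumer
  states its imputation rule (GRM and scan: per-variant mean).
* Quantiles used for thresholds (shared-IBD, top windows, interval
  percentiles) are lower nearest-rank — deterministic, no interpolation.
* Report percentages round half-up (two decimals in funnel tables, one
  in classifier reports), matching how such tables are printed.
* Ties in peak-SNP selection break by larger |β̂|, then position; ties in
  network edges are all retained.

# Problem sizes used in validation

The test suite and the acceptance script validate at desk scale, chosen
so each check's sampling error is small relative to its tolerance:
parent–offspring GRM recovery uses 200 pairs × 2,000 variants; the
kinship correlation uses a 36-offspring pedigree at 5,000 variants; null
GWAS calibration uses one 400 × 10,000 panel; QTL power uses 50–100
seeds of 400 × 5,000; IBD truth recovery uses two 25 Mb chromosomes at
8,000 markers; the sweep scan uses 100 seeds of a 2 Mb region at 300
markers. Quantities that depend on the original accession data (the
published kinship correlation r = 0.60, the 93.22% array/sequencing
concordance, specific haplotype frequencies and GWAS peak positions) are
not reproducible from simulation and are covered instead by the
property-based checks above.
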