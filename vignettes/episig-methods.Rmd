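---
title: "Methods: models, parameters and design choices in episig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in episig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`episig` implements the analyses behind an epigenome-signature study of
high-risk acute promyelocytic leukemia (hrAPL): chromatin-state definition
from histone-mark peaks, differential-enrichment statistics, supervised
WGBS CpG-signature derivation, and a variant-filter cascade. This vignette
explains the models and their assumptions, the parameters that matter, the
synthetic-data generator, and the design decisions taken where the
underlying analysis description left choices open. It states no empirical
result that the package's test suite or `scripts/acceptance.R` does not
itself compute.

## Coordinates and interval arithmetic

All genomic coordinates are 0-based half-open (BED convention), matching
the peak files the pipeline consumes; the GRanges-backed internals convert
at the boundary. Chromosome names compare by exact string match — "chr1"
and "1" are different contigs — with an opt-in alias flag on the BED
reader, because silent aliasing is a classic source of silently empty
intersections.

Tag counting assigns each signal record to the region containing the
midpoint of its interval. The midpoint rule is a deliberate choice: it
gives every tag exactly one region, so region counts are additive and
never double-count a tag spanning a boundary. Normalization is RPKM-like
by default — raw / (region length in kb × library size in millions) —
with a `per-million` alternative that drops the length term, since
"normalized tag enrichment" admits both readings and the choice only
rescales columns.

## Chromatin state

Promoter candidates are H3K4me3 peaks, enhancer candidates H3K4me1 peaks,
and a peak overlapping the other mark by even one base is excluded from
both classes *as a whole*. Whole-peak exclusion (rather than trimming the
overlapping bases) keeps peak identity intact: a trimmed fragment of an
ambiguous peak is not a cleaner candidate, it is the same ambiguous
element. Candidates common to ≥ 2 samples are the base-level intersection.

Activity defaults to *peak-overlap* mode: a region is active iff it
overlaps an H3K27ac peak and no H3K27me3 peak. Peak presence is a
reproducible binarization that needs no tuned cutoff; the
*enrichment-cutoff* mode (active iff H3K27ac enrichment ≥ `h3k27ac_min`
and H3K27me3 enrichment < `h3k27me3_max`, both in RPKM-like units,
default 1) is retained for sensitivity analysis. A region carrying both
marks is classified inactive — the active state requires *low* repressive
signal, so repression dominates ties.

Gene association gates on two quantities: distance from the nearest region
edge to the TSS base (0 if the TSS falls inside the region) below
`distance_max`, and the gene's expression summed over samples above
`rpkm_sum_min`. Defaults are the enhancer gates (50 kb, RPKM sum > 100);
promoter analyses use the much lower RPKM sum > 0.5 because promoter
H3K27me3 loss concerns genes coming *on* from silence. All qualifying
genes are associated; no nearest-gene tie-break discards candidates.

## Differential statistics

**Exact rank tests.** Discovery group sizes here are tiny (2–5 vs 5–10),
where the normal approximation to Wilcoxon tests is unreliable and exactness
is cheap. The signed-rank test drops zero differences, mid-ranks tied
absolute differences, and builds the exact null of the positive-rank sum by
generating-function convolution over sign assignments — identical to
enumerating all 2^n patterns — for up to 25 non-zero pairs. The rank-sum
test enumerates all C(n, n_a) group assignments (with mid-ranks) for total
n ≤ 20. Both report two-sided p = min(1, 2·min(P(W ≤ w), P(W ≥ w))) and
fall back to the normal approximation with tie and continuity corrections
at larger n. A consequence worth internalizing: at 5 vs 10 the smallest
attainable two-sided p is 2/3003 ≈ 6.66 × 10⁻⁴, so the stringent cutoff
p < 0.0007 is passable *only* by CpGs whose beta values separate the two
groups completely — the stringent signature is exactly the
perfectly-separating subset.

**Negative-binomial count test.** Reimplemented rather than delegated, so
that every constant is explicit: median-of-ratios size factors (computed
over regions with nonzero counts in all samples), per-region dispersion by
the method of moments, α = (v − μ·mean(1/s))/μ², pooled across the two
groups and floored at 10⁻⁸, and a Wald test on the log₂ ratio of group
means with NB variance μ/s + αμ² carried through the delta method (a 0.5
normalized-count pseudocount guards empty means). The standard normal Wald
reference is mildly anti-conservative in the far tails at 5 + 5 samples,
since the variance is estimated from few observations; on a 10,000-region
null simulation the p distribution stays within Kolmogorov–Smirnov
distance ≈ 0.04 of uniform (recomputed by `scripts/acceptance.R`). A
Student-t reference would calibrate the tails more tightly but measurably
reduces power at the planted effect sizes this pipeline is designed to
detect; the conventional Wald reference is retained. Selection of
discriminating regions applies the double threshold q < 0.01 (BH) and raw
p < 0.0002 with the fold change pointing to the high-risk group. No
dispersion-trend shrinkage, design matrices or batch covariates are
offered — two-group comparisons only, by construction.

**Fold-change outlier rule.** "FC > 3×STDEV" gain *and* loss calling needs
a symmetric scale, so the rule operates on r = log₂((treated + c)/(control
+ c)) and calls gains/losses outside mean(r) ± 3·SD(r). The pseudocount
defaults to c = 1 in the units of the input (normalized counts). Because c
is additive, the calls are *equivariant*, not invariant, under rescaling:
multiplying both columns by k together with the pseudocount leaves every
call unchanged, and that is the form in which scale symmetry is asserted
in the tests. The paired rank test (Figure-2-style before/after
comparisons) and the pairwise group comparisons use the exact tests above
at p < 0.01; the same 3-SD engine serves H3K27ac and H3K27me3 changed-region
calling, as no separate procedure is defined for the repressive mark.

## Methylation signature

Processing order matters and is fixed: CG-context filtering, strand
combining, coverage filtering, completeness restriction, testing, cohort
refinement. Strand combining merges a forward call at position i with a
reverse call at i + 1 into one dyad (counts summed, conserved exactly;
unpaired calls pass through, reverse-only calls reported at the forward
position i). The coverage threshold ≥ 5 (equivalently "> 4") is applied to
the *combined* counts — combining first is what the threshold's stated
order implies, and it is also the sensible choice, since dyad coverage is
what the beta value rests on. The discovery matrix keeps only CpGs with a
beta in every hrAPL and APL sample: the supervised test is only meaningful
on complete cases, and imputation at n = 15 would manufacture signal.

The supervised test is the exact rank-sum test per CpG (vectorized over
CpGs sharing the design: the C(15,5) = 3003 assignment matrix is built once
and applied by matrix multiplication). Cutoffs: primary p < 0.005 defines
the signature, split into hypo-/hypermethylated by the sign of
mean(hrAPL β) − mean(APL β); stringent p < 0.0007 (the
complete-separation set); the final signature additionally requires a
non-missing beta in every AML column of the external cohort, applied
*after* the stringent filter per the stated order. Array-style cohort
betas enter directly as a beta matrix, without count-level processing, and
no cross-platform adjustment is applied between sequencing- and
array-derived betas — a documented simplification that a provenance flag
makes revisitable.

## Variant cascade

Thresholds: DP ≥ 20, Phred ≥ 40 (both inclusive — a DP = 20, Phred = 40
record survives), missense consequence, driver-gene membership,
1000-Genomes MAF ≤ 0.05, and ≥ 1 confirming evidence track. A variant
absent from the frequency panel has no MAF and is *retained*: absence from
the panel implies below-threshold population frequency. How many
confirming tracks are required is genuinely open; the default is 1
(either RNA-seq or ChIP-seq evidence suffices) and configurable.
Records lacking DP or quality are rejected with reason "incomplete" and
counted separately from threshold failures. Since every stage is a pure
per-record predicate, survivors are provably independent of stage order;
the attrition table reports the canonical order quality → functional →
confirmed. Consequence annotation, functional scoring and pileup
recomputation are inputs, not package functionality.

## The synthetic-data generator

The generator's defaults are the study conditions, not knobs: 5 hrAPL vs
10 APL methylation samples plus a 181-column AML cohort; negative-binomial
region counts at mean 100 and dispersion 0.05 with library sizes varying
±30%; 50 of 1,000 CpGs planted at |Δβ| = 0.5 with beta-binomial noise
(overdispersion ρ = 0.02) at mean coverage 30; 5% of 1,000 regions planted
at log₂FC = 2 in the high-risk group; two 5-Mb contigs, small enough for
sub-minute end-to-end runs. Beta-binomial (not binomial) noise is
deliberate: WGBS betas are overdispersed, and the null false-positive-rate
guarantees should hold under realistic noise, not an idealized binomial.

Two structural choices deserve explanation. First, planted hypo CpGs draw
their baseline beta high enough (and hyper CpGs low enough) that the ±Δβ
shift stays inside [0, 1]; shifts that would leave the range are clamped
with a warning rather than silently distorted. Second, missingness in the
AML cohort matrix is *probe-structured*, as in array cohorts: a fraction
(default 5%) of CpG rows fail in one or more AML samples and the rest are
complete. Independent per-cell missingness at any realistic rate would
make the probability of completeness across all 181 columns essentially
zero (0.95¹⁸¹ ≈ 10⁻⁴) and the final-signature gate would always return an
empty set — a noise model incompatible with the study design the generator
emulates, where a final signature demonstrably survives that gate.

What the generator does *not* emulate: genome sequence content, read-level
artifacts (no FASTQ), peak-caller noise, correlated CpG blocks
(differentially methylated *regions*), copy-number structure, or
platform batch effects between WGBS and array betas. Passing tests
therefore demonstrate the correctness and calibration of the statistics
under the stated noise models — not robustness to every artifact of real
patient data.

## Numerical choices and problem sizes

Exact-test enumeration bounds (25 non-zero pairs; total n = 20, i.e.
184,756 assignments) keep exactness where it changes answers and cost
negligible. Mid-ranks are doubled onto an integer lattice for the
signed-rank convolution, so tied ranks stay exact. Two-sided p values use
the 2·min(tail) convention, capped at 1; degenerate inputs (all-zero
differences, zero log-ratio spread, constant groups) yield p = 1 or zero
calls with warnings, never errors. The acceptance checks and test suite
run at 10,000 null CpGs/regions for calibration, 1,000 CpGs/regions for
recovery experiments, and ≤ 50 kb contigs with per-base bitmap oracles for
the interval engine — sizes chosen to make Monte-Carlo tolerances tight
(3 standard errors) while keeping a full run in minutes on one core.

## Known limitations

- Headline patient-data counts (e.g. region or CpG totals from the
  original cohorts) depend on data held at controlled-access archives and
  are not reproducible here; the package validates its machinery on
  planted-truth synthetic bundles instead.
- The NB test's normal Wald reference is slightly anti-conservative in the
  extreme tails at very small sample sizes (quantified above).
- Single-CpG resolution only; no DMR merging.
- Two-group designs only; no covariates or paired count designs.
- bedGraph (not bigWig) signal input; peaks and annotations are consumed,
  never called.
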