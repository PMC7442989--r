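---
title: "Methods: carrier calling and population genetics of a KIV-2 null variant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: carrier calling and population genetics of a KIV-2 null variant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lpakiv2)
```

## The problem

Lipoprotein(a) [Lp(a)] concentrations are overwhelmingly determined by the
*LPA* gene, but up to 70% of its coding sequence lies inside the kringle-IV
type 2 (KIV-2) copy-number repeat, where ordinary genotyping fails. A
nonsense variant there (R21X) truncates apolipoprotein(a) and creates a
null allele, yet it can only be observed as *carrier status*: most repeat
copies stay wild type, so no 0/1/2 genotype exists. This package
implements the complete computational chain needed to study such a
variant: qPCR-based carrier calling, population genetics for a
carrier-status locus, collapsed-repeat NGS calling, and phenotype
association with meta-analysis — together with a synthetic-data module
that generates every input with truth labels.

## qPCR carrier calling

An allele-specific TaqMan assay amplifies the mutant base early in
carriers and only late, unspecifically, in non-carriers, producing two Ct
distributions roughly 7 cycles apart (validated carrier range
30.3–31.7, non-carrier range 37.3–39.7). Within carriers the spread is
bounded by the PCR doubling law: with 1–3 mutant repeat copies the
latest-starting carrier lags the earliest by `log2(3) ≈ 1.6` cycles, and
the generator draws carrier Ct as
`mu_carrier_base + log2(r_max/r) + N(0, sigma)` with `r` uniform on
{1,2,3}. The uniform distribution over repeat counts is a modeling
choice; no published distribution exists.

Calling is per plate:

1. **Control QC.** Wells whose positive amplification control is missing
   or later than `control_cutoff` (default 35 cycles) are excluded as
   PCR failures. Instrument strings such as "Undetermined" are read as
   missing, never as a sentinel cycle number.
2. **Bagged-clustering threshold.** `n_bootstrap = 100` bootstrap
   resamples are each split by 1-D 2-means (centers initialized at the
   resample extremes); the sorted center pairs are averaged and the
   threshold is their midpoint. Bagging the clusterer makes the
   threshold smooth in the data while staying deterministic under a
   seed; the input is sorted first so the estimate is invariant to
   sample order. A minimum aggregated-center separation of 3 cycles
   gates the two-cluster model — a 384-well plate at ~2% carrier
   frequency can legitimately contain zero carriers, and forcing a split
   into a single ~38.5-cycle cluster would fabricate carriers. Such
   plates are flagged and called carrier-free.
3. **Two-component fit and exclusion.** Normal components are fitted to
   each side of the threshold (single pass, no refit after exclusion).
   The ambiguity zone is the open interval between the carrier
   component's `1 − alpha_tail` quantile and the non-carrier component's
   `alpha_tail` quantile; samples inside it are excluded rather than
   guessed. `alpha_tail = 0.025` per tail is the conservative default;
   0.01 is available. Because quantiles move toward their component
   means as the tail fraction grows, the 2.5% zone *contains* the 1%
   zone — the conservative setting excludes more. Fitted-normal
   quantiles (not empirical ones) define the zone. Zero within-group
   variance is floored at 0.01 cycles.
4. **Missing mutant channel.** No amplification with a passing control
   is a non-carrier (the assay shows no amplification at 0% mutant
   fraction).

On default synthetic plates the separation is ≈ 7 cycles and the caller
makes no misclassifications among non-excluded, non-contaminated wells
across 100 seeded plates — that is what the test suite asserts. The
generator also plants "intermediate" contaminant wells (default 0.5%)
uniformly between the component means to exercise the exclusion path;
those that fall outside the ambiguity zone are called by threshold, which
mildly inflates the called carrier frequency. This is a deliberate
stress: real contamination is presumably rarer and closer to one of the
components. Exclusion rates on synthetic plates run near 2.5–3%
(the normal tails plus contaminants), somewhat above the 0.5–1.6%
reported for real cohorts, whose empirical Ct distributions are
lighter-tailed than the fitted normals.

## Population genetics of a carrier-status locus

**Carrier/allele frequency.** Under Hardy–Weinberg equilibrium a carrier
frequency `c` converts to an allele frequency `q = 1 − sqrt(1 − c)`
(the solution of `c = 1 − (1 − q)²`); both directions are provided and
compose to the identity.

**Carrier-as-heterozygote coding.** For haplotype and LD work the
carrier-status locus is coded as heterozygous. At a ~1% allele
frequency, homozygotes are expected in well under 1 in 10,000
individuals, and no narrow-sense genotype is observable anyway. This
coding is the only one consistent with the high-D′/low-R² pattern the
analysis is designed to detect, and it is stated prominently because it
is an assumption, not data.

**EM haplotype frequencies.** With the carrier coded as heterozygous,
only double heterozygotes (carrier with one SNP minor allele) are
phase-ambiguous. The EM iteration initializes at linkage equilibrium
(product of marginals), splits double-heterozygote mass by the current
coupling/repulsion odds in the E step, re-estimates the four haplotype
frequencies in the M step, and stops when the largest change drops below
`1e-10` (cap 1000 iterations). The observed-data log-likelihood is
recorded per iteration; the test suite asserts it never decreases, and
that tables without double heterozygotes reproduce plain haplotype
counting exactly.

**LD.** `D = p11 − pA·pB`, normalized to Lewontin's
`D′ = D / Dmax` with the sign-dependent `Dmax`, and
`R² = D² / (pA(1−pA)pB(1−pB))`. `R² ≤ D′²` holds for every valid
haplotype-frequency vector (asserted over 1000 random simplex draws).
A group without carriers has a monomorphic locus and reports `NA` LD,
matching the convention for populations where the variant is absent.
High `D′` with low `R²` is the signature of nesting: essentially every
carrier of the rare variant sits on the common variant's haplotype
background, while the converse fails because the frequencies differ.

**Proxy scan.** Candidate SNPs are ranked by the two-sided Fisher exact
p-value of the carrier-status × genotype table (2×3 by default; a 2×2
option collapses genotype to carriership, since the original table shape
is unstated). Exact p-values are validated against a full-enumeration
multivariate-hypergeometric oracle.

**Allelic location.** If a fraction `f` of all population alleles falls
in one isoform-size class, the chance that `n` independently sampled
variant alleles all do is `f^n`; with `f = 0.275` and `n = 12` this is
`1.87e-7`.

## Collapsed-repeat NGS calling

All KIV-2 copies collapse onto a single reference repeat, so a variant on
1–3 of ~35 repeats appears at a 1–10% read fraction — somatic-variant
territory. A sample is called a carrier iff its mutation level
`L = m/n` reaches `level_cutoff` (default 1%) **and** a one-sided
binomial test of `m` in `n` trials against the sequencing-error rate
(default `1e-3`) rejects at 0.05; the explicit error null prevents
zero-inflated noise from producing carriers at extreme depth, where a
bare level cutoff would. The published high-confidence depths — 340×
(single-end) and 780× (paired-end, bidirectional confirmation) — are
shipped as authoritative presets, with the underlying "95% binomial CI
not crossing zero at 1% level" criterion exposed for Wald, Wilson and
Clopper–Pearson intervals. The methods disagree (Wald gives 381; Wilson
and Clopper–Pearson are positive as soon as one mutant read is
expected), which is exactly why the presets are constants rather than a
derivation. Coverage tiers are nested by construction, so raising the
filter can only shrink the called set; carrier frequencies stay stable
across tiers on simulated data.

## Association and meta-analysis

Lp(a) is strongly right-skewed, so the analysis runs on two scales:
effect sizes (β, SE, 95% CI) from ordinary least squares on the original
mg/dL scale, and p-values plus variance explained from the identical
design refit on rank-based inverse-normal transformed Lp(a). The Blom
offset (`(r − 3/8)/(n + 1/4)`, average ranks for ties) is used; the
original variant is unstated and downstream quantities are insensitive
to the offset choice. Partial R² is the R² difference between the nested
transformed-scale models with and without the carrier term — the
estimator is a documented choice, as none is prescribed. The carrier
model adjusts for age and sex only, deliberately not for isoform: a
nonsense null abolishes its isoform's entire contribution, so isoform
adjustment would absorb the effect being estimated.

Reciprocal adjustment probes nesting: regressing Lp(a) on the rare
variant adjusted for the common one (and vice versa, plus the analysis
restricted to rare-variant negatives) shows whether the nested variant
carries information beyond its haplotype background. The Wilcoxon
rank-sum test compares group medians, exact by enumeration when the
smaller group has ≤ 10 observations without ties, else the tie- and
continuity-corrected normal approximation.

Fixed-effect meta-analysis pools per-study estimates with inverse-
variance weights `w_i = 1/se_i²`; heterogeneity is Cochran's
`Q = Σ w_i(β_i − β̂)²` on `k − 1` df and `I² = 100·max(0, (Q − df)/Q)`.
The p-value is z-based, consistent with fixed-effect pooling. The
implementation is five lines of arithmetic and is cross-checked against
`metafor::rma(method = "FE")` in the tests.

## The synthetic-data generator

Defaults mirror the study conditions: cohort sizes 4771/3099/3040,
carrier frequencies 1.6–2.1%, plate parameters bracketing the validated
Ct ranges, PCR-failure and contaminant rates of 0.5% each, pileup
mutation levels on [0.01, 0.10] with a 1e-3 error rate. The Lp(a) model
had to be invented (only medians are published to calibrate against):
each expressed allele with `k` KIV repeats contributes a lognormal
amount with median `141 · 2^(−(k−11)/3.5)` mg/dL (log-scale SD 0.8),
isoform sizes follow a discretized Normal(29, 6) on 11–50, and
null-flagged alleles contribute exactly 0, with the total floored at the
0.1 mg/dL detection limit. With these choices a 5000-individual cohort
shows a median Lp(a) near 11 mg/dL and a low-/high-molecular-weight
carrier median ratio near 4–5, matching the published descriptive
magnitudes; carriers of the nonsense variant have their null allele
placed on 27–32 KIV isoforms, where the variant was experimentally
located. What the generator does **not** emulate: amplification curves
(only final Ct values), read-level sequences (only counts), isoform
inheritance beyond two independent alleles, and inter-ethnic Lp(a)
differences. Passing tests therefore demonstrate the correctness of the
calling and inference machinery under the stated generative model, not
assay performance on real plates.

## Numerical choices and problem sizes

All randomness flows through explicit integer seeds; every generator is
bit-for-bit reproducible. EM tolerance 1e-10; SD floor 0.01 cycles;
bootstrap replicates 100; minimum cluster separation 3 cycles. The test
suite simulates 100 default 384-well plates for the misclassification
property, 20,000 individuals for EM recovery, 5000 samples for pileup
and regression recovery, and 200 study triples for meta-analysis
coverage — sizes chosen so each property has comfortable Monte-Carlo
resolution while the whole suite runs in well under a minute.

## Known limitations

- Carrier-as-heterozygote coding slightly biases haplotype frequencies
  if true homozygotes exist; negligible below ~1% allele frequency.
- The exclusion-rate calibration of the synthetic plates is conservative
  (normal tails are heavier than real instrument Ct distributions).
- The minimal-coverage derivation cannot reproduce the published 340×
  constant from common CI methods; the presets are therefore data, not
  derivation.
- The Lp(a) generative model is a calibrated invention; effect-size
  recovery tests plant explicit effects rather than relying on it.
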