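---
title: "Methods and design of ovisweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of ovisweep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ovisweep` packages the statistical chain of a livestock candidate-gene
study: a two-group genome scan for selective sweeps, classical marker
statistics with a Hardy–Weinberg test and two-locus linkage
disequilibrium, a parity × genotype fixed-effects model for litter
size, and 2^−ΔΔCt relative expression. This vignette documents the
models, the choices that were genuinely open, the numerical details,
and what the built-in simulations do and do not establish.

## The sweep scan

The scan consumes per-site reference-allele frequencies of two breed
groups (`PooledSites`), read from a VCF (`readPooledVcf()`), from a
frequency TSV, or simulated. Coordinates are 1-based inclusive
throughout the package; only BED output converts to 0-based half-open.
Missing genotype calls are excluded from allele totals, never imputed,
and a site must retain at least two called alleles per group — a
"frequency" from a single allele carries no information and would
violate the container's contract.

**Per-site F<sub>ST</sub>.** With pooled frequencies only, we use the
Nei/Hudson-style estimator: for p̄ = (p_A + p_B)/2, H_T = 2p̄(1 − p̄),
H_S = [2p_A(1 − p_A) + 2p_B(1 − p_B)]/2, and
F_ST = (H_T − H_S)/H_T, defined as 0 when H_T = 0. It is exactly 0
under equal frequencies, 1 for a fixed difference, and needs no
per-sample data. We deliberately omit finite-sample corrections
(Weir–Cockerham-style estimators need allele counts per subpopulation
and behave differently near fixation); the allele totals are carried in
the container should a corrected estimator be added.

**Windowing.** F<sub>ST</sub> windows default to 50 kb with a 25-kb
step; pooled heterozygosity uses 20 kb with a 10-kb step — the
conventional scales for these statistics in sheep resequencing scans.
Window values are ratios of sums, Σ(H_T − H_S)/ΣH_T, not means of
per-site ratios: the ratio of sums weights sites by their
informativeness and is the standard aggregation for windowed
F<sub>ST</sub>. Windows with fewer than `minSites = 3` SNPs are
excluded from standardization and calling; sparse windows make the
Z-scores unstable. Terminal windows truncated by the chromosome end are
kept and flagged `partial` rather than dropped.

**Pooled heterozygosity.** Per group and window,
H = 2Σp·Σq/(Σp + Σq)², where Σp and Σq sum the major- and minor-allele
frequencies of the in-window SNPs, with major/minor assigned per site
within the group. H is computed per group by default (a `pooled` option
averages the two group frequencies first): elevated-versus-reduced
diversity is a per-population signal.

**Standardization and calling.** Z = |x − μ|/σ over all defined
windows genome-wide, with the population (n-denominator) standard
deviation. The absolute value also flags unusually *low* windows, so
region calling is restricted by default to windows whose raw statistic
exceeds the genome-wide mean — a divergence scan seeks elevated
F<sub>ST</sub> — with `restrictHigh = FALSE` to inspect both tails.
Two calling modes exist because both are in common use: a fixed
threshold (Z > 5, strict inequality) and a genome-wide quantile (top
5%, `z >= quantile(z, 0.95)`, type-7 quantiles). Significant windows
that overlap or abut on a chromosome are merged; a region records its
peak Z and window count. ΔAF = |p_A − p_B| is reported per site, with
the top-5% threshold taken as a genome-wide site quantile (no window
aggregation is standard for ΔAF). For ΔAF and Z_H we treat the top 5%
as the high tail (one-sided): for differentiation statistics the signal
of interest is elevation.

**Gene annotation** lists a gene for a region iff their intervals
overlap by ≥ 1 bp.

**Degenerate inputs.** A scan where every window statistic is equal has
σ = 0; all Z are set to 0 with a warning rather than dividing by zero.
A window whose sites are all fixed identically in both groups has
ΣH_T = 0 and is defined as F_ST = 0.

## Marker statistics

From genotype counts (n_AA, n_Aa, n_aa): p = (2n_AA + n_Aa)/2N,
HE = 1 − p² − q², PIC = HE − 2p²q², NE = 1/(p² + q²), always computed
from *unrounded* frequencies. Published tables in this field round half
away from zero, so `round2()` implements that convention for
comparisons (base `round()` rounds half to even). Note PIC ≤ HE with
equality only at monomorphism, and NE·(p² + q²) = 1 exactly — both are
asserted as test invariants.

The Hardy–Weinberg test compares observed counts with (Np², 2Npq, Nq²)
computed from the observed allele frequency:
χ² = Σ(obs − exp)²/exp, df = 1 (three classes, minus one, minus one
estimated frequency), no continuity correction — the df = 1 chi-square
without Yates matches how such tables are computed in practice.
Expected counts below 5 trigger a warning, not a switch to an exact
test: the chi-square law is the declared method. Monomorphic loci are
flagged not-testable (`NA` p-value) rather than erroring, mirroring
the blank p-cells such tables print.

## Two-locus LD by EM

No installed R package exposes unphased two-locus haplotype-frequency
EM in a reusable form, so it is authored here. Genotypes are coded
0/1/2 copies of the reference allele. Only double heterozygotes are
phase-ambiguous; the E-step splits them between coupling (11/00) and
repulsion (10/01) by the odds f₁₁f₀₀ : f₁₀f₀₁. Initialization is at
linkage equilibrium (f = product of allele frequencies), convergence
when the largest haplotype-frequency change drops below `tol = 1e-8`,
capped at `maxIter = 1000` with a warning on the (never observed in
testing) non-convergent case. The log-likelihood trace is stored; EM
guarantees it non-decreasing, and the tests assert it on every
fixture. D = f₁₁ − p₁p₂; D′ = |D|/D_max with
D_max = min(p₁q₂, q₁p₂) for D > 0 and min(p₁p₂, q₁q₂) for D < 0
(D′ defined as 0 when D = 0); r² = D²/(p₁q₁p₂q₂). A monomorphic locus
makes LD undefined and is an error, not an NA.

## The litter-size model

y_ijn = μ + P_i + G_j + I_PG + e_ijn over parities i = 1..3 and
genotypes j = 1..3 is fitted by OLS under the full cell-means
parameterization (one coefficient per non-empty cell), which is the
same linear span as the factorial parameterization but makes the
estimable quantities — cell means — explicit. MSE = SSE/(N − #cells).

Least-squares means: within a parity, the LS mean of a cell is its
cell mean with SE = √(MSE/n_ij) from the *pooled* MSE — consistent
with a single linear model, not per-cell variances. The three-parity
average of genotype j is the equally weighted mean of its three cell
means with SE = √(MSE·Σ 1/n_ij)/3. Equal weighting is the LS-means
convention (each parity counts the same regardless of how many ewes it
contributed); a pooled one-way average would instead weight by cell
size, and since printed tables report n summed over parities, both
interpretations exist in the field — the equally weighted marginal of
the interaction model is the one consistent with the fitted model, so
it is the default. The test suite cross-checks both scopes against
`emmeans` on the factorial fit and against a normal-equations solve.

LSD letters: all pairwise differences within a parity (or among the
averages) are tested with t = Δ/SE(Δ), SE from the pooled MSE and the
cell weights of each mean, two-sided against the residual-df t
distribution, *no* multiplicity adjustment — that is the least
significant difference procedure, matching an α = 0.05 decision rule.
Letters come from the insert-and-absorb algorithm (start with one
letter covering all levels; each significant pair splits every letter
containing both; absorb subset letters), which guarantees that two
levels share a letter iff their pairwise test is non-significant. The
top mean is lettered "a". On a zero-variance fit the pairwise t is
0/0; such pairs are defined not-testable and never split a letter.

Ewes appear at several parities but the model has no ewe random
effect; records are treated as independent. This is a documented
limitation of the model itself, not of the implementation — a
repeated-measures extension would change the SEs.

## Relative expression

ΔCt = Ct_target − Ct_reference per replicate; ΔΔCt subtracts the mean
ΔCt of a calibrator cell; fold = 2^−ΔΔCt. The default calibrator is a
*group applied within each tissue*, so each tissue's folds are
relative to its own calibrator cell and per-tissue group contrasts are
calibrator-invariant; a single global (tissue, group) calibrator is
available for cross-tissue profiles. Group comparisons default to the
ΔCt scale — Ct is already log2, where Gaussian errors are the natural
assumption — using pooled-variance two-sample t-tests; testing on the
fold scale is an option and agrees in the low-noise limit. Letters are
assigned per tissue at two levels (lowercase 0.05, uppercase 0.01)
with the same insert-and-absorb rule as the association module.
Amplification-efficiency correction and multi-reference normalization
are out of scope.

## What the simulators emulate

All generators are pure functions of (config, seed): the RNG state is
localized and restored, one global seed fans out to child seeds by a
fixed affine map, and identical seeds give byte-identical output.

* `simulateDivergentPools()` draws site positions uniformly, an
  ancestral frequency per site from (0.05, 0.95), and each group's
  frequency from the Balding–Nichols Beta distribution
  (shape1 = p(1−F)/F, shape2 = (1−p)(1−F)/F) with F = 0.05 in the
  background and F = 0.5 inside an implanted 100-kb interval on a 5-Mb
  chromosome of 10,000 sites. Balding–Nichols was chosen because its
  divergence parameter F is directly interpretable as the expected
  fixation index; any exchangeable divergence model would serve. The
  defaults give roughly two SNPs per kb — resequencing density — and a
  sweep contrast strong enough that localization is a property of the
  method, not luck. What it does **not** emulate: linkage
  disequilibrium between sites (frequencies are drawn independently),
  mutation/recombination dynamics, or sampling noise on top of the
  Beta draw. Passing recovery tests therefore show the scan localizes
  a frequency-divergence signal; they cannot show robustness to the
  autocorrelation structure of real genomes.
* `simulateGenotypeCounts()` is a multinomial draw over
  (p² + D, 2pq − 2D, q² + D); infeasible D errors with the feasible
  range. It calibrates the HWE test's type-I error (≈5% at D = 0).
* `simulateLitterSizes()` draws Gaussian responses from the cell means
  implied by (μ, P, G, I) with residual SD 0.75 — the order implied by
  litter-size SEs of ~0.06 at cell sizes near 150 — at 64 ewes per
  genotype, each observed at all three parities. Defaults μ = 2.3,
  parity effects (−0.2, 0, +0.6) (third parities lamb larger), genotype
  effects (−0.1, +0.2, 0) encode a heterozygote advantage, matching
  the qualitative structure such studies report. Litter size is
  simulated as continuous Gaussian although real records are small
  integers, because the model under test is the Gaussian fixed-effects
  model; accordingly the phenotype reader warns (rather than fails) on
  values below one lamb, which only simulated tables can contain.
* `simulateCtTable()` draws reference Ct ~ N(20, sd²) and target
  Ct = reference + baseline ΔCt (5 cycles) + group shift + noise, 3
  biological replicates per tissue × group across eight reproductive
  tissues, sd = 0.2 cycles. A −1.5-cycle shift encodes a true
  2^1.5 ≈ 2.83-fold elevation. At 3 replicates a single tissue's
  estimated fold has log2-scale SD 0.2·√(2/3) ≈ 0.16, so per-tissue
  folds scatter noticeably around the truth; the experiment-wide group
  ratio pooled over the eight tissues (log2 SD ≈ 0.06) is the
  quantity tested against the 2^1.5 envelope.

## Problem sizes in the test suite

The stochastic validations run at: 100 seeds of the full-scale scan
(10,000 sites over 5 Mb) for sweep localization, with one seed checked
against a brute-force interval oracle at 1e-12; 200 simulated
phenotype datasets (576 records each) for LS-mean coverage within 3
SE; 1000 replicates for HWE type-I error; 200 seeds for the expression
envelope; 10 phased-versus-EM LD comparisons. These sizes hold every
Monte-Carlo criterion with comfortable binomial margins while keeping
the default suite around a minute.

## Known limitations

* The scan operates on pooled frequencies; haplotype-based statistics
  (iHS, XP-EHH) and region-level p-values are out of scope.
* No finite-sample F<sub>ST</sub> correction; with very small pools
  the estimator is upward biased.
* PIC and NE are implemented for biallelic loci (the general formulas
  reduce to these here).
* The association model ignores repeated measures on ewes, as stated.
* The expression module assumes equal amplification efficiency of
  target and reference (the 2^−ΔΔCt premise).
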