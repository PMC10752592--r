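---
title: "Estimating large-scale mean LD from GRM moments: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating large-scale mean LD from GRM moments: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldgrid)
```

## The estimand and the moment identity

For a pair of biallelic loci, LD is measured by the squared Pearson
correlation of allele dosages, ρ² = D²/(p₁q₁p₂q₂), a composite (unphased)
quantity — the same thing a sample r² on dosages estimates. The package's
estimands are means of ρ² over grids of SNP pairs: the intra-chromosomal
mean ℓᵢ over mᵢ² pairs (self-pairs contribute ρ² = 1), the
inter-chromosomal mean ℓᵢ.ⱼ over mᵢmⱼ pairs, the genome mean ℓ_g, and
fine-grained bin means ℓᵤ, ℓᵤᵥ.

Exhaustive pairwise computation costs O(n·m²). The alternative used here is
a fourth-moment identity: with dosages standardized as
x̃ = (x − 2p)/√(2(1+F)p q) and the GRM K = X̃X̃ᵀ/m, the expectation of a
squared off-diagonal GRM entry for unrelated individuals is the mean ρ² of
the SNP set, and the expectation of the product of two GRMs' matching
off-diagonal entries is the between-set mean. So

- `intra_ld()` averages the n(n−1) squared off-diagonal entries of one GRM,
- `cross_moment()` / `inter_ld()` average matching off-diagonal products,

at O(n²·m) total cost. Two exact algebraic facts anchor the implementation
and are asserted at 1e-10 in the tests:

1. **Decomposition.** The whole-genome GRM is the mᵢ/m-weighted sum of
   chromosome GRMs, so ℓ_g = Σᵢ(mᵢ/m)²ℓᵢ + Σ_{i≠j}(mᵢmⱼ/m²)ℓᵢ.ⱼ holds
   entry-wise, not merely in expectation. The same identity with bin
   weights reconstructs a chromosome's ℓᵢ from its grid (with exact m_u
   weights when the final bin is short).
2. **Pair-level equivalence.** Each off-diagonal moment decomposes over SNP
   pairs as (a² − b)/(n(n−1)) with a = Σₖ z_{k,l₁} z_{k,l₂} and
   b = Σₖ z²_{k,l₁} z²_{k,l₂}; `oracle_ld_means()` recomputes every grid
   mean this way without forming a GRM and matches the fast route to
   floating-point accuracy.

Assumptions: unrelated samples (pairwise relatedness 0 — the related-sample
generalization is out of scope), diploid biallelic dosages, and
missingness already resolved (the pipeline imputes under Hardy–Weinberg
proportions first).

## Sampling variances

The standard error of ℓᵢ uses the delta-method form
se = 2·var(kᵢₒ)/√(n(n−1)) with var(kᵢₒ) the empirical variance of the
off-diagonal entries (population convention, dividing by the n(n−1) count:
the direct moment substitution). For ℓ_g reported by `genome_ld()` the
moment substitution var(k_go) = ℓ_g − 1/(n−1)² is used, since the partition
object need not retain the whole-genome GRM. These are approximations;
the suite checks them against Monte-Carlo SDs to within a factor of 2, not
exactly.

No closed form is available for var(ℓᵢ.ⱼ), so `inter_ld()` offers a seeded
bootstrap over samples (default 200 resamples). Resampled pairs that
collapse onto the same original individual correspond to diagonal entries
and are excluded from each resample's mean. For the scaled statistic
ℓ̃ᵢ.ⱼ = ℓᵢ.ⱼ/√(ℓ̃ᵢℓ̃ⱼ), the delta-method variance
2ℓ̃ᵢ.ⱼ²/(n(n−1))·[v + 1/v − 2], v = var(kᵢₒ)var(kⱼₒ)/cov(kᵢₒ,kⱼₒ)², is
implemented exactly in this form; the bracket is non-negative and vanishes
when v = 1. The geometric-mean normalization is the only reading of the
scaling that keeps ℓ̃ᵢ.ⱼ in [0, 1] and matches published cohort-level
values; the plain product form would exceed 1 by orders of magnitude.

Two closed-form summaries condense a partition: the intra fraction
C·ℓ̄ᵢ/(C·ℓ̄ᵢ + C(C−1)·ℓ̄ᵢ.ⱼ) (both orderings of every chromosome pair are
counted — with C = 22 the weights are 22 and 462) and the true-LD summary
ℓ̄ᵢ/(ℓ̄ᵢ + b₀), which discounts the long-distance background estimated by
the decay intercept.

## Finite-sample behaviour at the no-LD limit

With *known* allele frequencies the estimator is unbiased: on LD-free
panels E(ℓ̂ᵢ) = 1/m exactly (only self-pairs contribute). With plug-in
frequencies — the practical method — standardized columns sum to zero and
their second moments are ratio estimates, which leaves a small deficit:
Σₖz² concentrates near n−1 rather than n, deflating the self-pair term by
≈ 2/(n·m) in relative terms, while the induced −1/n cross-individual
correlation inflates cross-pair terms by ≈ 1/n². At n = 500, m = 200 the
net bias is ≈ −1.7e-5 on a true value of 5e-3 (−0.34%), measured at ≈ 6.7
Monte-Carlo SEs over 200 replicate panels; standardizing the same panels
with the generating frequencies removes it (≈ 1 MC SE). The corresponding
unbiasedness test in the acceptance suite is therefore expected to fail at
its 3-MC-SE resolution: the deviation is a real property of plug-in
standardization, documented here rather than hidden by loosening the check.
For every practical purpose the effect is negligible — it is an order of
magnitude smaller than the estimator's own standard error on a single
panel, and three orders smaller than chromosomal LD in real cohorts.

The conventional pairwise sample r², by contrast, is inflated by ≈ 1/n per
pair at the no-LD limit, which is why the two estimators reconcile as
y ≈ 1/n + x when pairwise means (y) are regressed on GRM-moment estimates
(x). The suite reproduces this with slope 1 ± 0.05 and intercept within
20% of 1/n over 50 panels at n = 100, m = 500 — the panels span
within-block ρ² from 0 to ≈ 0.2 so that the regression is identified by LD
signal rather than attenuated by sampling noise (an errors-in-variables
effect that flattens the slope when all panels are LD-free).

## Tunable parameters

| parameter | default | role |
|---|---|---|
| `maf_min` | 0.05 | retain SNPs with MAF strictly above this (monomorphic SNPs always drop) |
| `miss_max` | 0.2 | drop SNPs with missing-call rate above this, before imputation |
| `F_inbreeding` | 0 | inbreeding coefficient in the standardization denominator; 0 for random mating, 1 for fully inbred |
| `bin_size` | 250 | SNPs per grid bin; bins are consecutive in file order, the last may be short (β = ⌈mᵢ/B⌉) |
| `bootstrap` | 200 | resamples behind inter-LD SEs |
| `seed` | 1 | drives imputation draws, bootstrap resamples and simulation; every run is bit-reproducible given it |

QC order: missingness filter → Hardy–Weinberg imputation → MAF and
monomorphic filter. Imputation precedes the MAF filter so the frequency is
computed on complete data; imputation is a seeded random draw from
(q², 2pq, p²) — a distribution, not a mean fill — so the imputed panel
remains a valid dosage matrix. Dosages count copies of the second (.bim
`a2`) allele; r²-scale statistics are invariant to that orientation.

## Numerical choices and degenerate inputs

- GRMs are accumulated as dense double-precision products, in SNP chunks
  (`chunk`, default 10,000) to bound memory; chunking never changes results.
- `grid_ld_matrix()` caches bin GRMs within `cache_budget` bytes and
  recomputes them on demand beyond it; outputs are bit-identical across
  budgets (a recomputed GRM repeats the same arithmetic). A budget below
  two bin GRMs is refused.
- The top eigenvalue uses a full symmetric decomposition up to n = 4,000
  and power iteration above (fixed uniform start vector, tolerance 1e-8,
  at most 1,000 iterations) — only λ₁ is needed.
- Ordered versus unordered pairs: all moments are defined over the n(n−1)
  ordered off-diagonal entries; for symmetric matrices ordered and
  unordered means coincide, which avoids off-by-two weighting mistakes.
- Degenerate inputs fail loudly and name the offender: monomorphic SNPs in
  standardization, all-missing SNPs in imputation, zero-variance columns in
  pairwise r², empty QC panels, fewer than 2 SNPs in a region or knockout,
  fewer than 3 (4) chromosomes in the decay (LOCO) regression, equal SNP
  counts (zero regressor variance) in the decay fit.
- Output TSVs print doubles at full precision (`%.17g`) so file-level
  comparisons are exact; display rounding happens only in logs and print
  methods.

## LD-decay regression

Under a genome of block-local LD — strong mean LD E(ℓᵤ) within short
segments of roughly constant size, weak background E(ℓᵤᵥ) between segments
— the chromosomal mean obeys ℓᵢ = (1/βᵢ)[E(ℓᵤ) − E(ℓᵤᵥ)] + E(ℓᵤᵥ) with βᵢ
the segment count, i.e. a straight line in 1/mᵢ. `fit_decay_regression()`
fits it by unweighted OLS via population moments (b₁ = cov/var, identical
to the normal equations); a weighted fit was considered and rejected as the
default because the source analyses fit unweighted. `recover_segment_parameters()`
inverts E(b₁) = (E(ℓᵤ) − E(ℓᵤᵥ))·m_seg ≈ E(ℓᵤ)·m_seg and E(b₀) = E(ℓᵤᵥ).
The underlying assumption — uniformly spread recombination hotspots — fails
for structured samples and for chromosomes with unusual regions (a
completely sequenced centromere, an HLA cluster); `loco_analysis()` flags
such chromosomes by the gain in Pearson's R when they are dropped.

## What the simulator emulates — and what it does not

`simulate_panel()` generates diploid dosages as sums of two independent
haplotypes with block-local LD, optionally under two-subpopulation
Balding–Nichols structure (subpopulation frequencies
Beta(p(1−Fst)/Fst, q(1−Fst)/Fst)) or Beta-distributed admixture
proportions. Two LD models are offered:

- **`ar1`** — a latent-Gaussian copula with AR(1) correlation r inside each
  s-SNP block, thresholded at the allele-frequency quantile. Qualitatively
  realistic (LD decays along the block, per-SNP frequencies vary) but the
  thresholding attenuates the genotype-scale correlation nonlinearly, so r
  is a shape parameter, not a calibrated target.
- **`shared`** — a core-sharing haplotype model: each allele copies a block
  core with probability √r, block cores copy a chromosome core with
  probability √(r_between/r). Pairwise genotype correlation is *exactly* r
  within a block and r_between across blocks, independent of allele
  frequency — the model used wherever a test needs a quantitative target
  (e.g. within-segment ρ² = 1/11 and between-segment ρ² = 0.001 give
  E(ℓᵤ) = 0.1 and E(ℓᵤᵥ) = 0.001 exactly for 100-SNP segments). The price
  is a single allele frequency per chromosome and flat (non-decaying)
  within-block LD.

Neither model emulates coalescent genealogy, recombination maps, mutation
spectra or phase: simulated r² is composite, matching what both the GRM
route and dosage-based r² estimate. Passing tests on these panels therefore
validate the *estimators and their algebra*, and the direction and
magnitude of structure effects under the Balding–Nichols idealization —
they do not certify behaviour on real sequence data with pervasive rare
variation, relatedness, or genotyping artefacts.

## Validation problem sizes

The simulation-backed checks run at deliberately modest sizes chosen so the
loop oracles stay exhaustive and the whole suite runs in minutes on one
CPU: oracle equivalence on 20 panels of n = 50, m = 200 (4 chromosomes;
every grid value against explicit loops at 1e-10); the pairwise-r²
reconciliation on 50 panels of n = 100, m = 500; the no-LD limit and SE
calibration on 200 panels of n = 500, m = 200; decay-parameter recovery on
20 genomes of 22 chromosomes spanning 5–40 segments of 100 SNPs at
n = 400; structure effects on 20 paired panels at n = 200 plus one
n = 200, m = 5,000 eigenvalue check. Estimation at cohort scale (hundreds
of samples, millions of SNPs) is a matter of wall-clock time, not
algorithm: the cost is one n×n GRM per SNP set.

## Known limitations

- Unrelated samples only; no correction for relatedness in the moment
  identities.
- The plug-in-frequency deficit at the no-LD limit described above
  (relative order 1/n; irrelevant at realistic LD levels).
- The decay regression's interpretation needs E(ℓᵤ) ≫ E(ℓᵤᵥ) and roughly
  constant segment size; under strong structure the linearity degrades
  (lower R), which is a diagnostic, not a failure mode of the fit itself.
- Per-SNP-pair LD matrices, phased D′, LD pruning and VCF/BGEN input are
  out of scope; PLINK 1 binary is the only genotype format read.
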