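---
title: "Ancestral-haplotype mapping in advanced intercross lines: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ancestral-haplotype mapping in advanced intercross lines: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ailhap)
```

## The setting

An advanced intercross line (AIL) starts from two founder populations with
distinct phenotypes and genetic backgrounds — here called HB (the
low-trait line) and HQLA (the high-trait line) — crosses them, and
random-mates the descendants for many generations. Each final-generation
chromosome is a fine-grained mosaic of founder segments. `ailhap`
exploits that structure in three complementary ways: association tests on
the local ancestral origin of haplotypes, block-wise estimation of
per-allele effects split by origin, and a non-parametric scan for
ancestry-based dominance.

This vignette documents the models, the tunable parameters with their
defaults, the design decisions taken where several choices were
defensible, what the bundled simulator does and does not emulate, and the
package's numerical conventions.

## Haplotype blocks

Phased genotypes are tiled with non-overlapping windows of `block_size`
consecutive SNPs (default 5). A five-SNP window matches the marker density
at which linkage disequilibrium decays in a typical dense AIL panel, so a
block behaves approximately as one multi-allelic locus; the distinct
within-block sequences ("haplotype alleles") are cataloged exactly, with
no mismatch tolerance — recombinants are new alleles by construction.
Blocks are fixed in SNP count rather than base pairs so that every block
contributes the same maximal degrees of freedom downstream. A trailing
remainder of fewer than `block_size` SNPs per chromosome is dropped rather
than merged, keeping block width homogeneous; block numbering restarts per
chromosome. `block_size = 1` degenerates to per-SNP alleles and is allowed
for cross-checking.

Diversity per block and population is summarised by pooled haplotype
homozygosity: H12 = (p1+p2)^2 + sum of squared remaining frequencies, and
analogously H123/H1234 with the top three or four alleles pooled; a block
with fewer alleles than the pool size scores exactly 1. Between-population
dissimilarity uses the Jaccard distance on allele sets, the Jensen-Shannon
divergence on allele frequencies, and the Bray-Curtis dissimilarity on
allele counts. Two conventions matter and are therefore explicit in the
API: the Jensen-Shannon divergence uses the natural logarithm and the
plain (non-square-root) form — some numerics libraries return the square
root, so a `sqrt` flag is provided — and genome-level summaries are
unweighted means over blocks, labeled as such in the output. The same
ambiguity is why no single-number diversity value from the package should
be compared against externally published figures without checking both
conventions.

## Local ancestry

Two routes produce the per-haplotype, per-block origin labels:

* **Import** (`import_rfmix()`): an RFMix-style per-window posterior table
  is mapped onto blocks by midpoint containment.
* **Built-in classifier** (`infer_ancestry()`): per block, the posterior
  of HQLA origin for an allele is its Laplace-smoothed frequency in the
  HQLA founder panel divided by the sum of smoothed frequencies in both
  panels, with equal class priors regardless of panel size. The
  `pseudocount` default is 1; an optional centred running mean over
  `window` blocks (default 1, i.e. off — keeping the contract at block
  resolution) smooths isolated discordant calls.

Either way, origin 1 (HQLA) is assigned when the posterior is `>= 0.5` —
ties go to HQLA, exactly as the threshold is stated, and alleles unseen in
both panels sit at 0.5 by symmetry. The built-in classifier is
deliberately much simpler than a conditional-random-field method: it
ignores the chain dependence between windows and therefore plateaus around
75–80% per-block accuracy on simulated data whose founder pools share a
third of their alleles, while being essentially perfect (97%+) on
panel-unique alleles, which is the subset where accuracy can also be
checked empirically on real data. For production analyses of real data an
external CRF-based tool should be imported; the classifier exists so the
pipeline is self-contained and testable.

The diploid code per individual and block is the number of HQLA-origin
copies: HB/HB = 0, HB/HQLA = 1, HQLA/HQLA = 2.

## Relationship matrices

All three kinships use one estimator family:

* **SNP GRM**: `G_jk = (1/M) Σ_m (x_jm − 2p_m)(x_km − 2p_m)/(2p_m(1−p_m))`
  with 0/1/2 dosages — the per-SNP standardised form that mainstream GWAS
  tools default to, so ports can match it number for number.
* **Ancestry GRM**: the same estimator with block ancestry codes in place
  of genotypes, standardising by the block's ancestry frequency (the
  minimal reading of "calculated using all ancestry-coded haplotypes").
* **Haplotype kinship**: per block, a 2N×2N matrix scores 1 when two
  haplotypes carry the same block allele and 0 otherwise; Γ is the average
  over blocks, accumulated streaming so the per-block matrices are never
  materialised. The individual-level matrix is `H = K Γ K'/2` with
  `K = I ⊗ [1 1]`, i.e. each entry is half the sum of a 2×2 sub-block of
  Γ; diagonals are `1 + (own-haplotype identity)` ∈ [1, 2].

Columns with zero variance (monomorphic SNPs, blocks fixed for one origin,
and all-heterozygous ancestry columns) drop out of both the numerator and
the divisor. All outputs are checked against a positive-semidefiniteness
tolerance of `−1e−8 · trace/N` on the smallest eigenvalue.

## Mixed-model association

The engine fits `y = Qα + g + e`, `g ~ N(0, σ²_g K)`, by profiling the
restricted likelihood over `δ = σ²_e/σ²_g`: with `K = U D U'` the rotation
by `U'` diagonalises the covariance, so each candidate δ costs `O(nq²)`.
δ is scanned on a 61-point log grid spanning `1e−6`–`1e6` and refined by
Brent search to a relative tolerance of `1e−8`. Degenerate inputs fail
loudly: constant phenotypes, rank-deficient covariate designs, and
profiles that are −∞ everywhere are errors, not warnings.

Three design decisions shape the scans:

* **EMMAX-style approximation.** Variance components are estimated once on
  the null model and reused for every marker; each marker is then a
  generalized-least-squares fit in the whitened system with a Wald t-test
  (df = n − q − 1). With `K = I` this collapses exactly to OLS, which the
  test suite verifies to `1e−6`. Exact per-marker REML would change
  p-values only marginally at AIL sample sizes and is out of scope.
* **ML, not REML, for the block LRT.** The haplotype-combination test
  compares `y = Qα + g_h + e` against `y = Qα + X_h β + g_h + e` where
  `X_h` codes each individual's unordered block-allele pair as a factor.
  REML likelihoods are not comparable across fixed-effect structures, so
  both models are refit by full ML and twice the log-likelihood gap is
  referred to chi-square with (levels − 1) df. Combinations carried by
  fewer than `min_count` individuals (default 5; the handling of rare
  combinations is a config knob because no canonical choice exists) are
  pooled into one OTHER level. A block where everyone carries the same
  combination has coinciding models and returns LRT = 0, p = 1; a block
  collapsed to one level only by pooling is reported untestable instead.
* **BH-FDR at 0.05** across markers or blocks, with significant entries
  merged into regions when within `gap` blocks (default: adjacent) — the
  convention under which a run of consecutive significant blocks reports
  as one QTL region.

## Block-wise effect estimation

For a significant block, `y = Qα + Z_d μ + e` with `Z_d` the dosage matrix
over haplotype alleles (plain mode) or allele-by-origin labels
`"<seq>_<0|1>"` (ancestral mode); rows sum to 2 by the diploid invariant.
`μ` is a vector of independent Gaussian random effects whose variance
ratio is re-estimated by REML per block (each block is a separate model;
the eigendecomposition core is shared with the association engine), and
the reported values are BLUPs in trait units with prediction-error
standard errors. Columns with zero carriers are dropped before fitting;
a single usable column is unidentifiable and errors. BLUPs shrink toward
zero — deliberately so, since rare alleles otherwise dominate the effect
ranking. Each allele also gets a founder-exclusivity flag (unique to HB,
unique to HQLA, shared — with both panel frequencies — or novel, i.e.
created after the founder cross).

## Dominance scan

Phenotypes are first corrected by OLS for sex and batch (aliased columns
in confounded designs are dropped with a warning) and the residuals used
as the new phenotype. Per block, the three ancestry classes (0/1/2) are
screened by a tie-corrected Kruskal–Wallis test — classes below
`min_class` (default 5) make the block "untested", reported but excluded
from FDR — and BH-FDR at 0.05 is applied across tested blocks, the
conservative placement of the single stated FDR step. Survivors get
Steel–Dwass all-pairs post-hoc tests: each pair's pooled midranks form a
tie-corrected standardized rank-sum statistic, and `sqrt(2)·|t|` is
referred to the studentized-range distribution with k groups and infinite
df. A permutation mode replaces the normal approximation for small
classes: labels are permuted jointly and each pair statistic is compared
with the permutation distribution of the maximum pairwise statistic
(max-T), which estimates the same familywise quantity; the two modes agree
to ~0.02 where p is small enough to matter, with larger discrepancies deep
in the null where the normal approximation is weakest.

Labels follow the two definitions: *high-parent* requires the heterozygote
median above both homozygote medians with both heterozygote–homozygote
comparisons significant at 0.05; *mid-parent* requires the heterozygote
median strictly above the homozygote midpoint with a certifying pairwise
test. Which pairwise test certifies mid-parent dominance is genuinely
ambiguous; the default (`"any"`: either heterozygote–homozygote comparison)
is the relaxed reading consistent with treating mid-parent as the weaker
label, and `"closer"`/`"higher"` are available for stricter analyses.
High-parent blocks satisfy the mid-parent conditions by construction, and
the boundary case (heterozygote exactly at the midpoint) is not
mid-parent.

## The simulator

`simulate_ail()` generates founder panels, gene-drops an AIL, and builds a
phenotype, recording truth at every step. Design choices:

* **Pool-based founders, not coalescent.** Each population draws founder
  chromosomes uniformly from a small pool (default 8 distinct haplotypes)
  and the two pools share a configurable fraction (default 0.33). This
  yields the low within-population haplotype diversity, strong block-level
  differentiation, and substantial cross-population allele sharing
  characteristic of real divergent lines, at desk scale. Per-SNP alleles
  on pool haplotypes come from a U-shaped Beta(0.5, 0.5) frequency prior.
* **Defaults mirror the emulated study design**: 16 HQLA and 14 HB
  founders, nine generations of random mating, 585 final individuals, a
  body-weight-like trait (mean 850 g, +150 g for males, three batches,
  residual SD 80 g). The genome default is two 400-SNP chromosomes of
  100 cM — large enough for LD and drift to behave sensibly, small enough
  that a full simulation takes about two seconds. Intermediate generations
  breed 200 individuals each, a realistic AIL maintenance size (the
  emulated design reports only the genotyped subset of the parental
  generation, so this is the package's own choice).
* **Meiosis**: crossover counts are Poisson with mean equal to the map
  length in Morgans, positions uniform in cM, no interference; a
  zero-length map transmits intact chromosomes. No mutation is added —
  recombination alone generates novel block alleles, which is sufficient
  to reproduce the qualitative excess of final-generation haplotypes.
  One shared genetic map serves both sexes.
* **Truth**: per-SNP founder origin propagates through every meiosis;
  block-level truth is the majority origin over the block's SNPs (ties
  resolved by the first SNP). Causal effects act per haplotype copy and
  can depend on the allele, the origin, or both; dominance bonuses act on
  ancestral heterozygotes. All randomness derives from one seed.

What the simulator does **not** emulate: genotyping error and missingness,
phasing errors, selection during AIL maintenance, sex-specific maps,
mutation, and realistic chromosome counts. Passing tests therefore
demonstrate correctness of the algorithms under clean phased input and a
faithful drift/recombination process — not robustness to data-quality
problems, which real analyses must handle upstream.

## Problem sizes and numerical conventions

The test suite runs the full pipeline on simulations of 150–500 final
individuals over two 100–400-SNP chromosomes; statistical calibration uses
2000 markers × 20 replicates, and planted-signal recovery uses 500
individuals with effects of 0.5–1.5 residual SDs. These sizes were chosen
so the complete suite finishes in well under a minute while every
stochastic assertion retains a comfortable margin over its Monte-Carlo
noise.

Coordinates are 1-based inclusive externally (VCF, GTF) and 0-based
ordinals internally; gene overlap is any-overlap on closed intervals with
strand ignored. The MAF filter uses a strict `>` (a site at exactly the
threshold is removed). Phasing concordance aligns each sample's arbitrary
haplotype labels by majority orientation before scoring heterozygous
sites. Kinship eigenvalues are floored at zero before REML; the PSD check
tolerates `−1e−8·trace/N`. All writers emit plain TSV with fixed column
order, plus JSON sidecars recording provenance (seed, parameters,
package version).

## Known limitations

The built-in ancestry classifier ignores between-block dependence and
attenuates ancestral-scan power when founder pools overlap substantially;
import CRF-based calls for real data. The dominance labels depend on a
configurable certification rule because the underlying definition is
ambiguous. Two-way admixture is assumed throughout (the data model leaves
room for more origins, but no code path handles them). LOCO kinships,
dominance variance components, under-dominance, and epistasis are out of
scope.
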