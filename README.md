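# ailhap — ancestral-haplotype mapping in advanced intercross lines

`ailhap` is an R package for genetic mapping in two-way admixed
populations — advanced intercross lines (AILs) built by crossing two
founder populations and random-mating the descendants for many
generations. Standard SNP-based GWAS treats every variant in isolation;
haplotype-based tests pay for their extra information with many degrees of
freedom. When the founder populations differ strongly in the trait, a third
option becomes attractive: test, at every haplotype block, only the
**ancestral origin** of the two haplotype copies, regardless of their
sequence. `ailhap` implements that ancestral-haplotype GWAS together with
everything around it, and ships a gene-dropping AIL simulator so the whole
pipeline can be exercised, with known truth, on a laptop.

## What the package computes

Write the phenotype model as the mixed linear model

    y = Q a + x b + g + e,    g ~ N(0, s2_g K),  e ~ N(0, s2_e I)

where `Q` holds the covariates (intercept, sex, batch), `x` is the tested
dosage, and `K` a genetic relationship matrix (GRM). The package provides
three instances:

* **SNP mode** — `x` is the 0/1/2 genotype dosage, `K` the standard
  centered-and-scaled SNP GRM.
* **Ancestral mode** — the genome is tiled with non-overlapping blocks of
  five consecutive SNPs; each haplotype gets, per block, an origin label
  (HB = 0, HQLA = 1, the two founder lines) with posterior threshold 0.5;
  `x` is the diploid code 0/1/2 = copies of HQLA origin, and `K` the same
  estimator applied to the ancestry codes (global-ancestry GRM).
* **Haplotype mode** — each individual's unordered block-allele
  combination enters as a categorical fixed effect, tested by a
  maximum-likelihood LRT against the null model; the polygenic term uses
  the haplotype kinship `H = K Γ K'/2`, where `Γ` is the 2N×2N
  block-allele identity matrix averaged over blocks and `K = I ⊗ [1 1]`.

Variance components are fit once on the null model by profile REML over
`δ = s2_e/s2_g` via one eigendecomposition of `K` (the EMMA device), and
reused across markers (EMMAX-style). Per-block allele effects are estimated
in a second model, `y = Q a + Z_d u + e`, with `Z_d` the allele (or
allele-by-origin) dosage matrix whose rows sum to 2 and `u` independent
random effects returned as BLUPs in trait units. Dominance is scanned
non-parametrically: phenotypes are corrected for sex and batch, individuals
are classed per block as ancestral homozygotes (HB/HB, HQLA/HQLA) or
heterozygotes (HB/HQLA), and a Kruskal–Wallis screen (BH-FDR ≤ 0.05) is
followed by Steel–Dwass all-pairs post-hoc tests to label *high-parent*
(heterozygote above both homozygotes) and *mid-parent* (heterozygote above
the homozygote midpoint) dominance. Haplotype diversity and
between-population dissimilarity come as H12/H123/H1234, Jaccard,
Jensen–Shannon and Bray–Curtis statistics per block.

## Worked example

Simulate a small AIL (two 100 cM chromosomes of 200 SNPs, 500 F9
individuals) with one planted origin-tied effect (+40 g per HQLA-origin
copy at block 25), then map it:

```r
library(ailhap)

cfg <- sim_config(seed = 11,
                  chromosomes = list(c(snps = 200, cm = 100),
                                     c(snps = 200, cm = 100)),
                  n_final = 500,
                  trait = list(causal = list(list(block = 25,
                                                  by_origin = c(0, 40))),
                               residual_var = 1600))
sim <- simulate_ail(cfg)
sim
#> ail_sim: 500 final-generation individuals, 400 SNPs, 80 blocks; mean HQLA ancestry 0.524

# built-in window classifier vs the simulator's truth
tr_hat <- infer_ancestry(sim$hbs, sim$hb_ids, sim$hqla_ids, sim$f9_ids,
                         window = 3)
panel_unique_accuracy(tr_hat, sim$hbs, sim$hb_ids, sim$hqla_ids)
#> [1] 0.979

# ancestral-haplotype GWAS at perfect ancestry resolution (the truth track
# stands in for imported RFMix-style calls)
tr   <- truth_ancestry_track(sim)
code <- code_diploid(tr)
y    <- sim$phen$trait
Q    <- model.matrix(~ sex + batch, sim$phen)
fit  <- reml_fit(y, Q, ancestry_grm(code))
scan <- marker_scan(fit, t(code),
                    info = sim$hbs$blocks[, c("chrom", "chrom_block",
                                              "start_bp", "end_bp")])
fdr_and_regions(scan)$regions
#>   chrom start end start_bp end_bp n    min_p
#> 1  chr1    25  25   594839 617236 1 4.44e-09
```

The planted block is the genome-wide minimum (β̂ = 38.2 ± 6.4 g per HQLA
copy against the planted 40 g). Block-wise BLUPs then split every allele by
origin and flag founder exclusivity:

```r
eff <- block_effects(y, Q, subset_blocks_to(sim$hbs, sim$f9_ids), 25,
                     track = tr,
                     hb_spec   = spectrum(sim$hbs, sim$hb_ids),
                     hqla_spec = spectrum(sim$hbs, sim$hqla_ids))
head(eff[order(-eff$effect), c("column", "effect", "carriers", "exclusivity")], 3)
#>     column effect carriers exclusivity
#> 9  ATCTT_1  29.41       72   hqla_only
#> 11 TTATT_1  23.33       12       novel
#> 3  AGCTT_1  15.56       51      shared
```

HQLA-origin columns (`_1`) carry positive effects and HB-origin columns
(`_0`) negative ones — the origin, not the sequence, carries the signal,
which is exactly the situation the ancestral scan is designed for. A
dominance scan on the same data (`dominance_scan(correct_phenotype(sim$phen),
code, sim$hbs$blocks)`) labels 7 blocks mid-parent and none high-parent, as
expected under a purely additive architecture.

The whole pipeline (blocks → diversity → ancestry → GRM → GWAS → effects →
dominance → annotation) also runs as one call, `ail_pipeline(config, out_dir)`,
writing TSV outputs and a provenance JSON; `inst/cli/ailhap.R` is a thin
Rscript front-end over the same functions.

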