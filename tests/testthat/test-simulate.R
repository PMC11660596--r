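test_that("pool sharing controls founder-population overlap", {
  # sharing = 0: founder chromosome haplotypes are population-private
  cfg0 <- sim_config(seed = 61, chromosomes = list(c(snps = 80, cm = 100)),
                     sharing = 0, n_intermediate = 40, n_final = 50)
  set.seed(cfg0$seed)
  f0 <- simulate_founders(cfg0)
  rows_hb <- which(f0$pop[f0$genotypes$sample_of_hap] == "hb")
  rows_hq <- which(f0$pop[f0$genotypes$sample_of_hap] == "hqla")
  str_of <- function(rows) apply(f0$genotypes$hap[rows, ], 1, paste,
                                 collapse = "")
  expect_length(intersect(str_of(rows_hb), str_of(rows_hq)), 0)

  # sharing = 1: identical pools, so founder spectra nearly coincide
  cfg1 <- sim_config(seed = 62, chromosomes = list(c(snps = 80, cm = 100)),
                     sharing = 1, n_intermediate = 40, n_final = 50,
                     n_hqla = 20, n_hb = 20)
  sim1 <- simulate_ail(cfg1)
  dis <- block_dissimilarity(spectrum(sim1$hbs, sim1$hqla_ids),
                             spectrum(sim1$hbs, sim1$hb_ids))
  expect_lt(attr(dis, "genome_mean")[["JSD"]], 0.15)

  # default sharing about one third of block alleles in common
  sim3 <- small_sim()
  s_hb <- spectrum(sim3$hbs, sim3$hb_ids)
  s_hq <- spectrum(sim3$hbs, sim3$hqla_ids)
  shared <- vapply(seq_len(nrow(sim3$hbs$blocks)), function(b) {
    a <- names(s_hb$freq[[b]]); q <- names(s_hq$freq[[b]])
    length(intersect(a, q)) / length(union(a, q))
  }, numeric(1))
  expect_gt(mean(shared), 0.15)
  expect_lt(mean(shared), 0.60)
})

test_that("a zero-length map transmits intact founder chromosomes", {
  cfg <- sim_config(seed = 63, chromosomes = list(c(snps = 60, cm = 0)),
                    n_intermediate = 40, n_final = 60)
  sim <- simulate_ail(cfg)
  pool <- apply(rbind(sim$pg$hap[rep(sim$pg$samples, each = 2) %in%
                                   c(sim$hb_ids, sim$hqla_ids), ]), 1,
                paste, collapse = "")
  f9 <- apply(sim$pg_f9$hap, 1, paste, collapse = "")
  expect_true(all(f9 %in% pool))
  # ancestry blocks are chromosome-length: origin constant per haplotype
  expect_true(all(apply(sim$truth, 1, function(o) length(unique(o)) == 1)))
})

test_that("the F1 generation is ancestrally heterozygous everywhere", {
  cfg <- sim_config(seed = 64, chromosomes = list(c(snps = 60, cm = 80)),
                    generations = 2, n_intermediate = 30, n_final = 40)
  set.seed(cfg$seed)
  f0 <- simulate_founders(cfg)
  gd <- gene_drop(cfg, f0)
  f1 <- gd$penultimate
  n <- length(f1$ids)
  code <- f1$orig[seq(1, 2 * n, 2), ] + f1$orig[seq(2, 2 * n, 2), ]
  expect_true(all(code == 1))
})

test_that("pedigree records are internally consistent", {
  sim <- small_sim()
  ped <- sim$pedigree
  expect_true(all(ped$generation %in% 0:9))
  kids <- ped[ped$generation > 0, ]
  for (g in unique(kids$generation)) {
    par_ids <- ped$id[ped$generation == g - 1]
    gk <- kids[kids$generation == g, ]
    expect_true(all(gk$sire %in% par_ids))
    expect_true(all(gk$dam %in% par_ids))
    # sires are male, dams are female
    expect_true(all(ped$sex[match(gk$sire, ped$id)] == 1))
    expect_true(all(ped$sex[match(gk$dam, ped$id)] == 2))
  }
})

test_that("LD decays faster after nine generations than after two", {
  r2_at <- function(sim, lag = 15) {
    x <- ailhap:::dosage_from_haplotypes(sim$pg_f9)
    m <- ncol(x)
    pairs <- cbind(seq_len(m - lag), seq_len(m - lag) + lag)
    poly <- apply(x, 2, var) > 0
    keep <- poly[pairs[, 1]] & poly[pairs[, 2]]
    mean(vapply(which(keep), function(i)
      cor(x[, pairs[i, 1]], x[, pairs[i, 2]])^2, numeric(1)))
  }
  cfg2 <- sim_config(seed = 65, chromosomes = list(c(snps = 120, cm = 100)),
                     generations = 2, n_intermediate = 100, n_final = 200)
  cfg9 <- sim_config(seed = 65, chromosomes = list(c(snps = 120, cm = 100)),
                     generations = 9, n_intermediate = 100, n_final = 200)
  expect_lt(r2_at(simulate_ail(cfg9)), r2_at(simulate_ail(cfg2)))
})

test_that("planted effects appear in the phenotype decomposition", {
  cfg <- sim_config(seed = 66, chromosomes = list(c(snps = 100, cm = 100)),
                    n_intermediate = 80, n_final = 300,
                    trait = list(dominance = list(list(block = 3,
                      het_bonus = 60)), residual_var = 900))
  sim <- simulate_ail(cfg)
  yc <- correct_phenotype(sim$phen)
  code <- sim$truth_code[, 3]
  meds <- tapply(yc, code, median)
  expect_gt(meds[["1"]], meds[["0"]])
  expect_gt(meds[["1"]], meds[["2"]])
  # all effects zero and no polygenics: a pure-noise GWAS null
  cfg0 <- sim_config(seed = 67, chromosomes = list(c(snps = 100, cm = 100)),
                     n_intermediate = 80, n_final = 200)
  sim0 <- simulate_ail(cfg0)
  expect_equal(attr(sim0$phen, "genetic_value"), rep(0, 200))
  expect_error(simulate_ail(sim_config(seed = 68,
    chromosomes = list(c(snps = 50, cm = 50)), n_intermediate = 40,
    n_final = 50,
    trait = list(causal = list(list(block = 999, by_origin = c(0, 1)))))),
    "out of range")
})

test_that("simulated data round-trips through the VCF writer", {
  sim <- small_sim()
  dir <- tempfile("simout")
  write_sim(sim, dir)
  back <- read_phased_vcf(file.path(dir, "f9.vcf"))
  expect_identical(back$genotypes$samples, sim$f9_ids)
  expect_equal(unname(back$genotypes$hap), unname(sim$pg_f9$hap))
  expect_true(file.exists(file.path(dir, "pedigree.tsv")))
  expect_true(file.exists(file.path(dir, "truth_origins.tsv")))
})

test_that("ancestral GWAS localizes an origin-tied effect", {
  set.seed(71)
  hit <- replicate(3, {
    cfg <- sim_config(seed = sample.int(1e6, 1),
                      chromosomes = list(c(snps = 100, cm = 100),
                                         c(snps = 100, cm = 100)),
                      n_intermediate = 100, n_final = 300,
                      trait = list(causal = list(list(block = 10,
                        by_origin = c(0, 30))), residual_var = 900))
    sim <- simulate_ail(cfg)
    y <- sim$phen$trait
    Q <- model.matrix(~ sex + batch, sim$phen)
    fit <- reml_fit(y, Q, ancestry_grm(sim$truth_code))
    tab <- marker_scan(fit, t(sim$truth_code))
    abs(which.min(tab$p) - 10) <= 2 # within local ancestry LD
  })
  expect_gte(sum(hit), 2)
})
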