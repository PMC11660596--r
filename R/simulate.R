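#' Configuration for the AIL simulator
#'
#' Assembles (and validates) the simulation settings. Defaults emulate the
#' study design: founder panels of 16 HQLA and 14 HB birds drawn from small
#' within-population haplotype pools that share about a third of their
#' haplotypes, nine generations of random intercrossing, 585 final-generation
#' individuals, and a body-weight-like trait with sex and batch effects.
#'
#' @param seed RNG seed (all simulator randomness derives from it).
#' @param chromosomes list of `c(snps, cm)` pairs (default two chromosomes
#'   of 400 SNPs spanning 100 cM each -- a desk-scale genome).
#' @param n_hqla,n_hb founder individuals per population (defaults 16, 14).
#' @param pool_size distinct chromosome haplotypes per founder population
#'   (default 8; small pools give the low within-population diversity and
#'   strong block-level differentiation seen in real founder lines).
#' @param sharing fraction of pool haplotypes shared between the two
#'   populations (default 0.33).
#' @param generations intercross generations to the final one (default 9).
#' @param n_intermediate breeding individuals in each generation F1..F(g-1)
#'   (default 200, a realistic AIL maintenance size).
#' @param n_final individuals in the final generation (default 585).
#' @param block_size SNPs per haplotype block (default 5).
#' @param trait list: `mean`, `sex_effect` (added to males), `batch_effects`
#'   (one per batch; batches assigned uniformly), `causal` (list of
#'   elements `list(block =, by_origin = c(hb, hqla))`,
#'   `list(block =, by_allele = c(SEQ = eff))` or
#'   `list(block =, by_allele_origin = c(SEQ_1 = eff))`, per haplotype
#'   copy), `dominance` (list of `list(block =, het_bonus =)` applied to
#'   ancestral heterozygotes), `polygenic_var`, `residual_var` (grams^2).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chromosomes = list(c(snps = 400, cm = 100),
                                          c(snps = 400, cm = 100)),
                       n_hqla = 16L, n_hb = 14L,
                       pool_size = 8L, sharing = 0.33,
                       generations = 9L, n_intermediate = 200L,
                       n_final = 585L, block_size = 5L,
                       trait = list()) {
  stopifnot(pool_size >= 2L, sharing >= 0, sharing <= 1, generations >= 2L,
            n_hqla >= 2L, n_hb >= 2L, n_intermediate >= 4L, n_final >= 2L)
  tr <- list(mean = 850, sex_effect = 150, batch_effects = c(0, -30, 30),
             causal = list(), dominance = list(),
             polygenic_var = 0, residual_var = 6400)
  stopifnot(all(names(trait) %in% names(tr)))
  tr[names(trait)] <- trait
  stopifnot(tr$polygenic_var >= 0, tr$residual_var >= 0)
  structure(list(seed = as.integer(seed), chromosomes = chromosomes,
                 n_hqla = n_hqla, n_hb = n_hb, pool_size = pool_size,
                 sharing = sharing, generations = generations,
                 n_intermediate = n_intermediate, n_final = n_final,
                 block_size = block_size, trait = tr),
            class = "sim_config")
}

#' Simulate founder panels from shared haplotype pools
#'
#' Per chromosome and population, builds a pool of `pool_size` distinct
#' haplotypes of which `round(sharing * pool_size)` are common to both
#' populations; per-SNP alleles on pool haplotypes are drawn once from a
#' U-shaped Beta(0.5, 0.5) frequency prior. Each founder chromosome is a
#' uniform draw from its population's pool.
#'
#' @param cfg `sim_config`.
#' @return list: `variants` (variant table), `genotypes`
#'   (`phased_genotypes` for F0, HQLA samples first), `pop` (named vector
#'   "hqla"/"hb" per sample), `map` (genetic-map data.frame), `pools`
#'   (per-chromosome pool allele matrices with shared-row bookkeeping).
#' @export
simulate_founders <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n_shared <- round(cfg$sharing * cfg$pool_size)
  n_pool_tot <- 2L * cfg$pool_size - n_shared
  bases <- c("A", "C", "G", "T")
  vt_list <- list(); map_list <- list(); pools <- list()
  for (i in seq_along(cfg$chromosomes)) {
    m <- cfg$chromosomes[[i]][["snps"]]
    cm_len <- cfg$chromosomes[[i]][["cm"]]
    pos <- cumsum(sample(1000:9000, m, replace = TRUE))
    ref <- sample(bases, m, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
    vt_list[[i]] <- data.frame(chrom = paste0("chr", i), pos = pos,
                               ref = ref, alt = unname(alt),
                               index = seq_len(m) - 1L,
                               stringsAsFactors = FALSE)
    map_list[[i]] <- data.frame(chrom = paste0("chr", i), pos = pos,
                                cm = (pos - pos[1]) / (pos[m] - pos[1]) * cm_len)
    f <- stats::rbeta(m, 0.5, 0.5)
    pool <- matrix(stats::rbinom(n_pool_tot * m, 1L, rep(f, each = n_pool_tot)),
                   nrow = n_pool_tot, ncol = m)
    # rows 1..pool_size: HQLA pool; rows (pool_size - n_shared + 1)..end: HB
    pools[[i]] <- list(alleles = pool,
                       hqla = seq_len(cfg$pool_size),
                       hb = (cfg$pool_size - n_shared + 1L):n_pool_tot)
  }
  vt <- do.call(rbind, vt_list)
  map <- do.call(rbind, map_list)

  samples <- c(paste0("HQLA", seq_len(cfg$n_hqla)),
               paste0("HB", seq_len(cfg$n_hb)))
  pop <- stats::setNames(rep(c("hqla", "hb"), c(cfg$n_hqla, cfg$n_hb)), samples)
  nh <- 2L * length(samples)
  hap <- matrix(0L, nh, nrow(vt))
  col0 <- 0L
  for (i in seq_along(cfg$chromosomes)) {
    m <- ncol(pools[[i]]$alleles)
    for (h in seq_len(nh)) {
      s <- (h + 1L) %/% 2L
      pick <- if (pop[s] == "hqla") sample(pools[[i]]$hqla, 1L)
              else sample(pools[[i]]$hb, 1L)
      hap[h, (col0 + 1L):(col0 + m)] <- pools[[i]]$alleles[pick, ]
    }
    col0 <- col0 + m
  }
  rownames(hap) <- paste0(rep(samples, each = 2L), "_", rep(1:2, length(samples)))
  list(variants = vt, genotypes = new_phased_genotypes(samples, hap),
       pop = pop, map = map, pools = pools)
}

# per-chromosome SNP column ranges and cM positions
chrom_layout <- function(vt, map) {
  chroms <- unique(vt$chrom)
  lapply(stats::setNames(chroms, chroms), function(ch) {
    cols <- which(vt$chrom == ch)
    list(cols = cols, cm = map$cm[cols], cm_len = max(map$cm[cols]))
  })
}

# one meiosis: recombine the two parental haplotype/origin row pairs.
# crossover count ~ Poisson(map length in Morgans), positions uniform in cM,
# no interference.
meiosis <- function(hapA, hapB, origA, origB, layout) {
  out_h <- integer(length(hapA)); out_o <- integer(length(hapA))
  for (ly in layout) {
    ncross <- stats::rpois(1L, ly$cm_len / 100)
    start <- sample.int(2L, 1L) - 1L
    if (ncross == 0L) {
      use <- rep(start, length(ly$cols))
    } else {
      cp <- sort(stats::runif(ncross, 0, ly$cm_len))
      use <- (start + findInterval(ly$cm, cp)) %% 2L
    }
    a <- ly$cols
    out_h[a] <- ifelse(use == 0L, hapA[a], hapB[a])
    out_o[a] <- ifelse(use == 0L, origA[a], origB[a])
  }
  list(h = out_h, o = out_o)
}

#' Gene-drop an AIL from founder panels
#'
#' Crosses the two founder populations (F1: one gamete from a random HQLA
#' parent, one from a random HB parent) and then mates males and females at
#' random within each generation up to the final one, recombining each
#' meiosis with a Poisson crossover count (no interference) on the genetic
#' map. True per-SNP founder origin (0 = HB, 1 = HQLA) is propagated
#' alongside the alleles.
#'
#' @param cfg `sim_config`.
#' @param founders output of [simulate_founders()].
#' @return list: `final` and `penultimate` generations (each with `ids`,
#'   `hap`, `orig` 2N x M matrices, `sex`), `pedigree` data.frame
#'   (`id`, `sire`, `dam`, `generation`, `sex`).
#' @export
gene_drop <- function(cfg, founders) {
  layout <- chrom_layout(founders$variants, founders$map)
  f0 <- founders$genotypes
  pop <- founders$pop
  n0 <- length(f0$samples)
  sex0 <- integer(n0) # alternate sexes within each founder population
  for (lev in unique(pop)) {
    idx <- which(pop[f0$samples] == lev)
    sex0[idx] <- rep_len(1:2, length(idx))
  }
  # orig per founder haplotype row
  orig0 <- matrix(rep(ifelse(pop[f0$sample_of_hap] == "hqla", 1L, 0L),
                      ncol(f0$hap)), nrow = nrow(f0$hap))
  ped <- data.frame(id = f0$samples, sire = NA_character_,
                    dam = NA_character_, generation = 0L, sex = sex0,
                    stringsAsFactors = FALSE)

  make_gen <- function(gen, n_off, par) {
    ids <- paste0("F", gen, "_", seq_len(n_off))
    sex <- rep_len(1:2, n_off)
    hap <- matrix(0L, 2L * n_off, ncol(par$hap))
    orig <- matrix(0L, 2L * n_off, ncol(par$hap))
    sire <- dam <- character(n_off)
    males <- which(par$sex == 1L); females <- which(par$sex == 2L)
    if (length(males) == 0L || length(females) == 0L)
      stop("population extinction: a generation lacks one sex")
    for (i in seq_len(n_off)) {
      if (gen == 1L) {
        # intercross: one parent from each founder population
        si <- sample(intersect(males, which(par$popv == "hqla")), 1L)
        di <- sample(intersect(females, which(par$popv == "hb")), 1L)
        if (stats::runif(1) < 0.5) { # population-of-sire randomized
          si2 <- intersect(males, which(par$popv == "hb"))
          di2 <- intersect(females, which(par$popv == "hqla"))
          if (length(si2) > 0L && length(di2) > 0L) {
            si <- sample(si2, 1L); di <- sample(di2, 1L)
          }
        }
      } else {
        si <- if (length(males) == 1L) males else sample(males, 1L)
        di <- if (length(females) == 1L) females else sample(females, 1L)
      }
      gs <- meiosis(par$hap[2L * si - 1L, ], par$hap[2L * si, ],
                    par$orig[2L * si - 1L, ], par$orig[2L * si, ], layout)
      gd <- meiosis(par$hap[2L * di - 1L, ], par$hap[2L * di, ],
                    par$orig[2L * di - 1L, ], par$orig[2L * di, ], layout)
      hap[2L * i - 1L, ] <- gs$h; hap[2L * i, ] <- gd$h
      orig[2L * i - 1L, ] <- gs$o; orig[2L * i, ] <- gd$o
      sire[i] <- par$ids[si]; dam[i] <- par$ids[di]
    }
    rownames(hap) <- rownames(orig) <- paste0(rep(ids, each = 2L), "_",
                                              rep(1:2, n_off))
    list(ids = ids, hap = hap, orig = orig, sex = sex,
         ped = data.frame(id = ids, sire = sire, dam = dam,
                          generation = gen, sex = sex,
                          stringsAsFactors = FALSE))
  }

  par <- list(ids = f0$samples, hap = f0$hap, orig = orig0, sex = sex0,
              popv = unname(pop[f0$samples]))
  penult <- NULL
  for (gen in seq_len(cfg$generations)) {
    n_off <- if (gen == cfg$generations) cfg$n_final else cfg$n_intermediate
    g <- make_gen(gen, n_off, par)
    ped <- rbind(ped, g$ped)
    if (gen == cfg$generations - 1L) penult <- g
    par <- list(ids = g$ids, hap = g$hap, orig = g$orig, sex = g$sex,
                popv = NULL)
  }
  list(final = g, penultimate = penult, pedigree = ped)
}

# global variant columns spanned by block b
block_columns <- function(vt, hbs, b) {
  ch <- hbs$blocks$chrom[b]
  cols <- which(vt$chrom == ch)
  cols[(hbs$blocks$start_idx[b]:hbs$blocks$end_idx[b]) + 1L]
}

#' True block origins from per-SNP origin tracks
#'
#' Majority per-SNP origin within each block (ties resolved by the block's
#' first SNP), giving the simulator's truth at block resolution.
#'
#' @param orig 2N x M per-SNP origin matrix (from [gene_drop()]).
#' @param vt variant table the blocks were built on.
#' @param hbs `hap_blocks`.
#' @return 2N x n_blocks 0/1 matrix.
#' @export
truth_origins <- function(orig, vt, hbs) {
  nb <- nrow(hbs$blocks)
  out <- matrix(0L, nrow(orig), nb, dimnames = list(rownames(orig), NULL))
  for (b in seq_len(nb)) {
    cols <- block_columns(vt, hbs, b)
    frac <- rowMeans(orig[, cols, drop = FALSE])
    out[, b] <- ifelse(frac > 0.5, 1L,
                       ifelse(frac < 0.5, 0L, orig[, cols[1]]))
  }
  out
}

#' Simulate a phenotype over the final generation
#'
#' `y = mean + sex + batch + sum(block effects) + het bonuses + polygenic +
#' residual`. Block effects act per haplotype copy and may depend on the
#' allele sequence, the true origin, or both; dominance bonuses are added
#' to ancestral heterozygotes (diploid truth code 1).
#'
#' @param cfg `sim_config`.
#' @param sim an `ail_sim` (see [simulate_ail()]) or a compatible list with
#'   `hbs`, `vt`, `final`, `f9_ids`.
#' @return phenotype data.frame (`id`, `trait`, `sex`, `batch`) with
#'   attribute `genetic_value` (the summed planted effects).
#' @export
simulate_phenotype <- function(cfg, sim) {
  ids <- sim$f9_ids
  n <- length(ids)
  tr <- cfg$trait
  sexes <- sim$final$sex
  batch <- sample(rep_len(seq_along(tr$batch_effects), n))
  y <- rep(tr$mean, n) + tr$sex_effect * (sexes == 1L) +
    tr$batch_effects[batch]

  rows <- match(paste0(rep(ids, each = 2L), "_", rep(1:2, n)),
                rownames(sim$truth))
  gval <- numeric(n)
  for (cz in tr$causal) {
    b <- cz$block
    if (b > nrow(sim$hbs$blocks)) stop("causal block index out of range: ", b)
    arows <- match(paste0(rep(ids, each = 2L), "_", rep(1:2, n)),
                   rownames(sim$hbs$assign))
    alle <- sim$hbs$alleles[[b]][sim$hbs$assign[arows, b]]
    org <- sim$truth[rows, b]
    eff <- numeric(2L * n)
    if (!is.null(cz$by_origin)) eff <- eff + cz$by_origin[org + 1L]
    if (!is.null(cz$by_allele)) {
      m <- cz$by_allele[alle]; m[is.na(m)] <- 0
      eff <- eff + m
    }
    if (!is.null(cz$by_allele_origin)) {
      m <- cz$by_allele_origin[paste0(alle, "_", org)]; m[is.na(m)] <- 0
      eff <- eff + m
    }
    gval <- gval + eff[seq(1L, 2L * n, 2L)] + eff[seq(2L, 2L * n, 2L)]
  }
  for (dz in tr$dominance) {
    b <- dz$block
    if (b > nrow(sim$hbs$blocks)) stop("dominance block index out of range: ", b)
    code <- sim$truth[rows[seq(1L, 2L * n, 2L)], b] +
      sim$truth[rows[seq(2L, 2L * n, 2L)], b]
    gval <- gval + dz$het_bonus * (code == 1L)
  }
  y <- y + gval
  if (tr$polygenic_var > 0) {
    g <- snp_grm(sim$vt, sim$pg_f9)
    ev <- eigen(unclass(g), symmetric = TRUE)
    ev$values <- pmax(ev$values, 0)
    y <- y + sqrt(tr$polygenic_var) *
      drop(ev$vectors %*% (sqrt(ev$values) * stats::rnorm(n)))
  }
  y <- y + stats::rnorm(n, 0, sqrt(tr$residual_var))
  out <- data.frame(id = ids, trait = y,
                    sex = factor(ifelse(sexes == 1L, "M", "F")),
                    batch = factor(paste0("b", batch)),
                    stringsAsFactors = FALSE)
  attr(out, "genetic_value") <- gval
  out
}

#' Simulate a complete AIL dataset with truth
#'
#' Master driver: founder pools, gene dropping to the final generation,
#' block construction over founders plus final generation, truth ancestry
#' at block resolution, and the phenotype. All randomness derives from
#' `cfg$seed`.
#'
#' @param cfg `sim_config`.
#' @return list of class `ail_sim`: `vt`, `pg` (combined F0 + final
#'   generation), `pg_f9` (final generation only), `hbs` (`hap_blocks` over
#'   the combined set), `truth` (2N_f9 x n_blocks true origins), `truth_code`
#'   (N_f9 x n_blocks diploid codes), `phen`, `pedigree`, `map`, `hb_ids`,
#'   `hqla_ids`, `f9_ids`, `final`, `cfg`.
#' @export
simulate_ail <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  founders <- simulate_founders(cfg)
  drop_ <- gene_drop(cfg, founders)
  fin <- drop_$final
  f0 <- founders$genotypes
  samples <- c(f0$samples, fin$ids)
  hap <- rbind(f0$hap, fin$hap)
  pg <- new_phased_genotypes(samples, hap)
  pg_f9 <- new_phased_genotypes(fin$ids, fin$hap)
  hbs <- suppressMessages(build_blocks(founders$variants, pg,
                                       cfg$block_size))
  truth <- truth_origins(fin$orig, founders$variants, hbs)
  n <- length(fin$ids)
  truth_code <- truth[seq(1L, 2L * n, 2L), , drop = FALSE] +
    truth[seq(2L, 2L * n, 2L), , drop = FALSE]
  rownames(truth_code) <- fin$ids
  sim <- list(vt = founders$variants, pg = pg, pg_f9 = pg_f9, hbs = hbs,
              truth = truth, truth_code = truth_code,
              pedigree = drop_$pedigree, map = founders$map,
              hb_ids = names(founders$pop)[founders$pop == "hb"],
              hqla_ids = names(founders$pop)[founders$pop == "hqla"],
              f9_ids = fin$ids, final = fin, cfg = cfg)
  sim$phen <- simulate_phenotype(cfg, sim)
  class(sim) <- "ail_sim"
  sim
}

#' @export
print.ail_sim <- function(x, ...) {
  cat("ail_sim:", length(x$f9_ids), "final-generation individuals,",
      nrow(x$vt), "SNPs,", nrow(x$hbs$blocks), "blocks; mean HQLA ancestry",
      round(mean(x$truth), 3), "\n")
  invisible(x)
}

#' Ancestry track holding the simulator's true origins
#'
#' Wraps the truth origins of an `ail_sim` as an `ancestry_track` (posterior
#' 0/1), usable wherever inferred or imported local-ancestry calls are --
#' e.g. to benchmark the built-in classifier or to run the downstream
#' analyses at perfect ancestry resolution.
#'
#' @param sim `ail_sim` object.
#' @return `ancestry_track` over the final-generation samples.
#' @export
truth_ancestry_track <- function(sim) {
  structure(list(samples = sim$f9_ids, posterior = sim$truth * 1.0,
                 origin = sim$truth, blocks = sim$hbs$blocks),
            class = "ancestry_track")
}

#' Write simulated data to a directory
#'
#' Emits phased VCFs (founders, final generation), pedigree, phenotype,
#' genetic-map and truth TSVs.
#'
#' @param sim `ail_sim`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f0_ids <- c(sim$hqla_ids, sim$hb_ids)
  rows0 <- which(rep(sim$pg$samples, each = 2L) %in% f0_ids)
  write_phased_vcf(sim$vt,
                   new_phased_genotypes(f0_ids, sim$pg$hap[rows0, , drop = FALSE]),
                   file.path(dir, "founders.vcf"))
  write_phased_vcf(sim$vt, sim$pg_f9, file.path(dir, "f9.vcf"))
  utils::write.table(sim$pedigree, file.path(dir, "pedigree.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$phen, file.path(dir, "phenotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$map, file.path(dir, "map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tt <- data.frame(haplotype = rep(rownames(sim$truth), ncol(sim$truth)),
                   block = rep(seq_len(ncol(sim$truth)),
                               each = nrow(sim$truth)),
                   origin = as.vector(sim$truth))
  utils::write.table(tt, file.path(dir, "truth_origins.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(seed = sim$cfg$seed,
                            generations = sim$cfg$generations,
                            n_final = sim$cfg$n_final),
                       file.path(dir, "provenance.json"), auto_unbox = TRUE)
  invisible(dir)
}
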