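#' Run the ancestral-haplotype analysis pipeline
#'
#' End-to-end driver over in-memory or file inputs: haplotype blocks,
#' diversity/dissimilarity statistics, local-ancestry inference, the three
#' relationship matrices, the requested GWAS mode, block effect estimates
#' for significant blocks, the dominance scan, and (optionally) gene
#' annotation. Deterministic given `config$seed`; writes TSV outputs plus a
#' provenance JSON into `out_dir`.
#'
#' @param config list (or path to a YAML/JSON file readable by
#'   [jsonlite::read_json()]): either `sim = list(...)` arguments for
#'   [sim_config()] to generate data, or `vcf`, `phenotypes`, `founders_hb`,
#'   `founders_hqla` paths; plus optional `block_size` (5), `gwas_mode`
#'   (`"snp"`, `"hap"` or `"anc-hap"`), `fdr` (0.05), `min_class` (5),
#'   `min_count` (5), `ancestry` (`"builtin"` or a path for
#'   [import_rfmix()]), `gtf` (annotation path), `seed`.
#' @param out_dir output directory.
#' @return invisible list of the main result tables.
#' @export
ail_pipeline <- function(config = list(), out_dir = tempfile("ailhap")) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfgv <- function(k, d) if (!is.null(config[[k]])) config[[k]] else d
  seed <- cfgv("seed", 1L)
  block_size <- cfgv("block_size", 5L)
  mode <- match.arg(cfgv("gwas_mode", "anc-hap"), c("snp", "hap", "anc-hap"))
  fdr <- cfgv("fdr", 0.05)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$vcf)) {
    for (f in c("vcf", "phenotypes"))
      if (!file.exists(config[[f]])) stop("missing input file: ", config[[f]])
    dat <- read_phased_vcf(config$vcf)
    vt <- dat$variants; pg <- dat$genotypes
    phen <- read_phenotypes(config$phenotypes)
    hb_ids <- config$founders_hb
    hqla_ids <- config$founders_hqla
    targets <- setdiff(pg$samples, c(hb_ids, hqla_ids))
  } else {
    sim_args <- cfgv("sim", list())
    sim_args$seed <- seed
    sim <- do.call(sim_config, sim_args)
    sim <- simulate_ail(sim)
    vt <- sim$vt; pg <- sim$pg; phen <- sim$phen
    hb_ids <- sim$hb_ids; hqla_ids <- sim$hqla_ids
    targets <- sim$f9_ids
    write_sim(sim, file.path(out_dir, "sim"))
  }
  set.seed(seed)

  hbs <- suppressMessages(build_blocks(vt, pg, block_size))
  write_blocks(hbs, file.path(out_dir, "blocks.tsv"))

  s_hb <- spectrum(hbs, hb_ids)
  s_hq <- spectrum(hbs, hqla_ids)
  s_f9 <- spectrum(hbs, targets)
  div <- data.frame(h_stats(s_f9)[, c("block", "chrom")],
                    H12_f9 = h_stats(s_f9)$H12,
                    H1234_f9 = h_stats(s_f9)$H1234,
                    H1234_hb = h_stats(s_hb)$H1234,
                    H1234_hqla = h_stats(s_hq)$H1234)
  utils::write.table(div, file.path(out_dir, "divstats.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  dis <- block_dissimilarity(s_hq, s_hb)
  utils::write.table(dis, file.path(out_dir, "dissimilarity_hqla_hb.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  anc <- cfgv("ancestry", "builtin")
  track <- if (identical(anc, "builtin"))
    infer_ancestry(hbs, hb_ids, hqla_ids, targets)
  else import_rfmix(anc, hbs, targets)
  write_ancestry(track, file.path(out_dir, "ancestry.tsv"))
  code <- code_diploid(track)

  phen <- phen[match(targets, phen$id), ]
  y <- phen$trait
  Q <- stats::model.matrix(~ sex + batch, data = phen)
  rows_t <- which(rep(pg$samples, each = 2L) %in% targets)
  pg_t <- new_phased_genotypes(targets, pg$hap[rows_t, , drop = FALSE])

  if (mode == "snp") {
    kin <- snp_grm(vt, pg_t)
    fit <- reml_fit(y, Q, kin)
    dose <- t(dosage_from_haplotypes(pg_t))
    rownames(dose) <- paste0(vt$chrom, ":", vt$pos)
    tbl <- marker_scan(fit, dose, info = vt[, c("chrom", "pos", "index")])
  } else if (mode == "anc-hap") {
    kin <- ancestry_grm(code)
    fit <- reml_fit(y, Q, kin)
    tbl <- marker_scan(fit, t(code),
                       info = hbs$blocks[, c("chrom", "chrom_block",
                                             "start_bp", "end_bp")])
  } else {
    sub_rows <- match(paste0(rep(targets, each = 2L), "_", rep(1:2,
                             length(targets))), rownames(hbs$assign))
    hbs_t <- hbs
    hbs_t$assign <- hbs$assign[sub_rows, , drop = FALSE]
    hbs_t$samples <- targets
    kin <- gamma_to_h(haplotype_gamma(hbs_t), targets)
    cache <- assoc_cache(y, Q, kin)
    tbl <- hap_gwas(cache, hbs_t, min_count = cfgv("min_count", 5L))
  }
  res <- fdr_and_regions(tbl, q_threshold = fdr)
  utils::write.table(res$table, file.path(out_dir, "gwas.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(res$regions, file.path(out_dir, "regions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # effect estimates for significant blocks (block-resolved modes only)
  eff_all <- NULL
  if (mode != "snp" && any(res$table$significant)) {
    sig_blocks <- res$table$block[res$table$significant]
    eff_all <- do.call(rbind, lapply(sig_blocks, function(b) {
      e <- tryCatch(block_effects(y, Q, subset_blocks_to(hbs, targets), b,
                                  track = track, hb_spec = s_hb,
                                  hqla_spec = s_hq),
                    error = function(e) NULL)
      if (!is.null(e)) cbind(block = b, e) else NULL
    }))
    if (!is.null(eff_all))
      utils::write.table(eff_all, file.path(out_dir, "effects.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ycorr <- correct_phenotype(phen)
  dom <- dominance_scan(ycorr, code, hbs$blocks,
                        min_class = cfgv("min_class", 5L), fdr = fdr)
  utils::write.table(dom, file.path(out_dir, "dominance.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  genes <- NULL
  if (!is.null(config$gtf) && nrow(res$regions) > 0L) {
    genes <- overlap_genes(res$regions, read_gtf_genes(config$gtf))
    utils::write.table(genes, file.path(out_dir, "region_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  jsonlite::write_json(
    list(package = "ailhap",
         version = as.character(utils::packageVersion("ailhap")),
         seed = seed, gwas_mode = mode, block_size = block_size, fdr = fdr),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(blocks = hbs, gwas = res$table, regions = res$regions,
                 effects = eff_all, dominance = dom, genes = genes,
                 out_dir = out_dir))
}

#' Restrict a block set to a sample subset
#'
#' Keeps the block definitions and allele catalogs but subsets the
#' haplotype-assignment rows to the given samples (e.g. the final
#' generation, dropping founder panels).
#'
#' @param hbs `hap_blocks`.
#' @param samples sample ids to keep.
#' @return `hap_blocks` over `samples`.
#' @export
subset_blocks_to <- function(hbs, samples) {
  rows <- match(paste0(rep(samples, each = 2L), "_",
                       rep(1:2, length(samples))), rownames(hbs$assign))
  hbs$assign <- hbs$assign[rows, , drop = FALSE]
  hbs$samples <- samples
  hbs
}
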