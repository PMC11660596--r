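#' Read a phased VCF into variant and haplotype tables
#'
#' Parses a VCF 4.x file whose GT field is fully phased (`|` separator) and
#' returns the variant table together with the per-sample haplotype matrix.
#' Multi-allelic records are skipped (with a message giving the count);
#' unphased or missing genotypes are an error -- the pipeline assumes
#' imputed, phased input and never imputes itself.
#'
#' @param path path to an (uncompressed or bgzipped) VCF file.
#' @param region optional region string `"chrom"` or `"chrom:start-end"`
#'   (1-based inclusive) applied after parsing.
#' @return a list with components
#'   \describe{
#'     \item{variants}{data.frame with columns `chrom`, `pos` (1-based bp),
#'       `ref`, `alt`, `index` (0-based ordinal within chromosome).}
#'     \item{genotypes}{object of class `phased_genotypes`: `samples`
#'       (character), `hap` (2N x M integer matrix of 0/1 alleles, rows
#'       ordered sample1-hap1, sample1-hap2, sample2-hap1, ...).}
#'   }
#' @export
read_phased_vcf <- function(path, region = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, ncol = 1, dimnames = list(NULL, colnames(v@gt)[-1]))

  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    message(sum(multi), " multi-allelic site(s) skipped")
    fix <- fix[!multi, , drop = FALSE]
    gt <- gt[!multi, , drop = FALSE]
  }
  if (nrow(fix) == 0L) stop("no biallelic sites in ", path)

  bad <- which(is.na(gt) | !grepl("^[01]\\|[01]$", gt), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop("unphased or missing genotype '", gt[i, j], "' for sample ",
         colnames(gt)[j], " at ", fix$CHROM[i], ":", fix$POS[i])
  }

  vt <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                   ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)

  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+)(?::([0-9]+)-([0-9]+))?$", region))[[1]]
    keep <- vt$chrom == m[2]
    if (m[3] != "") keep <- keep & vt$pos >= as.integer(m[3]) & vt$pos <= as.integer(m[4])
    if (!any(keep)) stop("region ", region, " matches no variants")
    vt <- vt[keep, , drop = FALSE]
    gt <- gt[keep, , drop = FALSE]
  }

  o <- order(factor(vt$chrom, levels = unique(vt$chrom)), vt$pos)
  vt <- vt[o, , drop = FALSE]
  gt <- gt[o, , drop = FALSE]
  if (any(unlist(tapply(vt$pos, vt$chrom, function(p) diff(p) <= 0))))
    stop("positions not strictly increasing within chromosome")
  vt$index <- unlist(lapply(split(vt$pos, factor(vt$chrom, unique(vt$chrom))),
                            function(p) seq_along(p) - 1L), use.names = FALSE)
  rownames(vt) <- NULL

  samples <- colnames(gt)
  a1 <- matrix(as.integer(substr(gt, 1, 1)), nrow = nrow(gt))
  a2 <- matrix(as.integer(substr(gt, 3, 3)), nrow = nrow(gt))
  hap <- matrix(0L, nrow = 2L * length(samples), ncol = nrow(vt))
  hap[seq(1L, 2L * length(samples), 2L), ] <- t(a1)
  hap[seq(2L, 2L * length(samples), 2L), ] <- t(a2)
  rownames(hap) <- paste0(rep(samples, each = 2L), "_", rep(1:2, length(samples)))

  pg <- new_phased_genotypes(samples, hap)
  list(variants = vt, genotypes = pg)
}

new_phased_genotypes <- function(samples, hap) {
  stopifnot(nrow(hap) == 2L * length(samples))
  structure(list(samples = samples, hap = hap,
                 sample_of_hap = rep(samples, each = 2L)),
            class = "phased_genotypes")
}

#' @export
print.phased_genotypes <- function(x, ...) {
  cat("phased_genotypes:", length(x$samples), "samples x",
      ncol(x$hap), "variants\n")
  invisible(x)
}

#' Write phased genotypes as a minimal VCF 4.2 file
#'
#' Emits an uncompressed VCF with phased GT entries only, suitable for
#' round-tripping through [read_phased_vcf()].
#'
#' @param vt variant table as returned by [read_phased_vcf()].
#' @param pg `phased_genotypes` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(vt, pg, path) {
  n <- length(pg$samples)
  h1 <- pg$hap[seq(1L, 2L * n, 2L), , drop = FALSE]
  h2 <- pg$hap[seq(2L, 2L * n, 2L), , drop = FALSE]
  gt <- matrix(paste0(t(h1), "|", t(h2)), nrow = nrow(vt))
  lines <- c("##fileformat=VCFv4.2",
             paste0("##contig=<ID=", unique(vt$chrom), ">"),
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", pg$samples), collapse = "\t"))
  body <- paste(vt$chrom, vt$pos, ".", vt$ref, vt$alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Filter variants on minor allele frequency
#'
#' Retains sites whose minor allele frequency over all haplotypes is strictly
#' greater than `maf_min`. Phased, imputed input carries no missing calls, so
#' the `max_missing` threshold only applies when missingness is present.
#'
#' @param vt,pg variant table and `phased_genotypes` (see [read_phased_vcf()]).
#' @param maf_min minor-allele-frequency threshold in `[0, 0.5]`; sites with
#'   MAF `<= maf_min` (including monomorphic sites) are removed.
#' @param max_missing maximum tolerated fraction of missing haplotype calls
#'   per site (defensive; complete data passes unchanged).
#' @return list with filtered `variants` and `genotypes`.
#' @export
filter_variants <- function(vt, pg, maf_min = 0.01, max_missing = 0.2) {
  stopifnot(maf_min >= 0, maf_min <= 0.5)
  af <- colMeans(pg$hap, na.rm = TRUE)
  maf <- pmin(af, 1 - af)
  miss <- colMeans(is.na(pg$hap))
  keep <- maf > maf_min & miss <= max_missing
  if (!any(keep)) stop("all sites removed by MAF/missingness filter")
  vt2 <- vt[keep, , drop = FALSE]
  vt2$index <- unlist(lapply(split(vt2$pos, factor(vt2$chrom, unique(vt2$chrom))),
                             function(p) seq_along(p) - 1L), use.names = FALSE)
  rownames(vt2) <- NULL
  list(variants = vt2,
       genotypes = new_phased_genotypes(pg$samples, pg$hap[, keep, drop = FALSE]))
}

#' Phasing concordance between two phased call sets
#'
#' Fraction of heterozygous genotypes phased identically in two call sets
#' over the same samples and sites. Haplotype labels within a sample are
#' arbitrary, so each sample's orientation is first aligned by majority
#' agreement before scoring.
#'
#' @param a,b `phased_genotypes` over identical samples and sites.
#' @return fraction in `[0, 1]`.
#' @export
phasing_concordance <- function(a, b) {
  stopifnot(identical(a$samples, b$samples), ncol(a$hap) == ncol(b$hap))
  n <- length(a$samples)
  n_het <- 0L; n_conc <- 0L
  for (s in seq_len(n)) {
    i1 <- 2L * s - 1L; i2 <- 2L * s
    het <- (a$hap[i1, ] != a$hap[i2, ]) & (b$hap[i1, ] != b$hap[i2, ])
    if (!any(het)) next
    same <- sum(a$hap[i1, het] == b$hap[i1, het])
    swap <- sum(a$hap[i1, het] == b$hap[i2, het])
    n_het <- n_het + sum(het)
    n_conc <- n_conc + max(same, swap)
  }
  if (n_het == 0L) stop("no heterozygous sites shared by the two call sets")
  n_conc / n_het
}

#' Read a phenotype table
#'
#' Tab-separated with header columns `id`, `trait`, `sex`, `batch`.
#'
#' @param path TSV path.
#' @return data.frame with `id` (character), `trait` (numeric), `sex`
#'   and `batch` as factors.
#' @export
read_phenotypes <- function(path) {
  pt <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "trait", "sex", "batch")
  if (!all(need %in% names(pt)))
    stop("phenotype table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(pt$id)) stop("duplicate sample ids in phenotype table")
  pt$id <- as.character(pt$id)
  pt$trait <- as.numeric(pt$trait)
  pt$sex <- factor(pt$sex)
  pt$batch <- factor(pt$batch)
  pt
}

#' Read a genetic map
#'
#' Tab-separated with header columns `chrom`, `pos` (bp), `cm`; optional
#' `cm_female`/`cm_male`. cM must be non-decreasing with position within a
#' chromosome.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_genetic_map <- function(path) {
  gm <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("chrom", "pos", "cm") %in% names(gm)))
    stop("genetic map must have columns chrom, pos, cm")
  bad <- unlist(tapply(gm$cm, gm$chrom, function(x) any(diff(x) < 0)))
  if (any(bad)) stop("cM not non-decreasing within chromosome(s): ",
                     paste(names(bad)[bad], collapse = ", "))
  gm
}
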