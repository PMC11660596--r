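#' Partition the genome into fixed-width haplotype blocks
#'
#' Tiles each chromosome with non-overlapping windows of `block_size`
#' consecutive SNPs and catalogs the distinct haplotype alleles (base
#' strings) observed in each block. A trailing remainder of fewer than
#' `block_size` SNPs per chromosome is dropped. Block width is fixed in SNP
#' count (not bp): at the study's marker density roughly five SNPs span the
#' distance over which LD decays, so a five-SNP window behaves as a single
#' multi-allelic locus.
#'
#' @param vt variant table (see [read_phased_vcf()]).
#' @param pg `phased_genotypes`.
#' @param block_size SNPs per block, default 5 (`block_size = 1` degenerates
#'   to per-SNP alleles).
#' @return object of class `hap_blocks`:
#'   \describe{
#'     \item{block_size}{window width in SNPs.}
#'     \item{blocks}{data.frame: `block` (1-based global id), `chrom`,
#'       `chrom_block` (1-based id within chromosome), `start_idx`/`end_idx`
#'       (0-based variant ordinals), `start_bp`/`end_bp`.}
#'     \item{alleles}{list, per block, of the distinct haplotype strings
#'       (ref/alt bases, in order of first appearance).}
#'     \item{assign}{2N x n_blocks integer matrix of catalog indices,
#'       rows in haplotype order of `pg`.}
#'     \item{samples}{sample ids.}
#'   }
#' @export
build_blocks <- function(vt, pg, block_size = 5L) {
  stopifnot(block_size >= 1L)
  block_size <- as.integer(block_size)
  chroms <- unique(vt$chrom)
  rows <- list(); alleles <- list(); assign_cols <- list()
  dropped <- 0L; gid <- 0L
  for (ch in chroms) {
    idx <- which(vt$chrom == ch)
    nb <- length(idx) %/% block_size
    if (nb == 0L) {
      warning("chromosome ", ch, " has fewer than ", block_size,
              " SNPs; no blocks formed")
      dropped <- dropped + length(idx)
      next
    }
    dropped <- dropped + length(idx) - nb * block_size
    for (b in seq_len(nb)) {
      gid <- gid + 1L
      cols <- idx[((b - 1L) * block_size + 1L):(b * block_size)]
      seqs <- hap_strings(pg$hap[, cols, drop = FALSE],
                          vt$ref[cols], vt$alt[cols])
      cat_ <- unique(seqs)
      rows[[gid]] <- data.frame(block = gid, chrom = ch, chrom_block = b,
                                start_idx = vt$index[cols[1]],
                                end_idx = vt$index[cols[block_size]],
                                start_bp = vt$pos[cols[1]],
                                end_bp = vt$pos[cols[block_size]],
                                stringsAsFactors = FALSE)
      alleles[[gid]] <- cat_
      assign_cols[[gid]] <- match(seqs, cat_)
    }
  }
  if (gid == 0L) stop("no blocks could be formed")
  if (dropped > 0L) message(dropped, " trailing SNP(s) not covered by blocks")
  assign <- do.call(cbind, assign_cols)
  rownames(assign) <- rownames(pg$hap)
  structure(list(block_size = block_size,
                 blocks = do.call(rbind, rows),
                 alleles = alleles,
                 assign = assign,
                 samples = pg$samples),
            class = "hap_blocks")
}

# haplotype rows (0/1) -> base strings using ref/alt per column
hap_strings <- function(h, ref, alt) {
  m <- matrix(ref, nrow = nrow(h), ncol = ncol(h), byrow = TRUE)
  m[h == 1L] <- matrix(alt, nrow = nrow(h), ncol = ncol(h), byrow = TRUE)[h == 1L]
  apply(m, 1, paste, collapse = "")
}

#' @export
print.hap_blocks <- function(x, ...) {
  cat("hap_blocks:", nrow(x$blocks), "blocks of", x$block_size, "SNPs over",
      length(x$samples), "samples\n")
  invisible(x)
}

#' Haplotype-allele frequency spectrum of a population
#'
#' Per-block allele counts and frequencies over the `2 * |population|`
#' haplotypes of the given samples, sorted by descending frequency.
#'
#' @param hbs `hap_blocks` object.
#' @param population character vector of sample ids (subset of
#'   `hbs$samples`).
#' @return object of class `hap_spectrum`: lists `freq` and `count`, one
#'   named, descending-sorted numeric vector per block (names are haplotype
#'   strings); `n_hap` the number of haplotypes counted.
#' @export
spectrum <- function(hbs, population) {
  if (length(population) == 0L) stop("empty population")
  if (!all(population %in% hbs$samples))
    stop("unknown sample id(s): ",
         paste(setdiff(population, hbs$samples), collapse = ", "))
  rows <- which(rep(hbs$samples, each = 2L) %in% population)
  n_hap <- length(rows)
  count <- vector("list", nrow(hbs$blocks))
  freq <- vector("list", nrow(hbs$blocks))
  for (b in seq_len(nrow(hbs$blocks))) {
    tab <- tabulate(hbs$assign[rows, b], nbins = length(hbs$alleles[[b]]))
    names(tab) <- hbs$alleles[[b]]
    tab <- tab[tab > 0L]
    tab <- sort(tab, decreasing = TRUE)
    count[[b]] <- tab
    freq[[b]] <- tab / n_hap
  }
  structure(list(freq = freq, count = count, n_hap = n_hap,
                 blocks = hbs$blocks),
            class = "hap_spectrum")
}

#' Write a block summary table
#'
#' @param hbs `hap_blocks` object.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_blocks <- function(hbs, path) {
  df <- hbs$blocks
  df$n_alleles <- vapply(hbs$alleles, length, integer(1))
  df$catalog <- vapply(hbs$alleles, paste, character(1), collapse = ",")
  utils::write.table(df[, c("chrom", "chrom_block", "start_bp", "end_bp",
                            "n_alleles", "catalog")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
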