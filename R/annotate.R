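#' Read gene models from a GTF file
#'
#' Imports `gene` features (1-based inclusive coordinates) via rtracklayer.
#' Files without explicit `gene` rows fall back to the union range of each
#' gene_id's features.
#'
#' @param path GTF path.
#' @return data.frame: `gene_id`, `name`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gtf_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  if ("type" %in% names(md) && any(md$type == "gene")) {
    gr <- gr[md$type == "gene"]
    md <- S4Vectors::mcols(gr)
  }
  nm <- if ("gene_name" %in% names(md)) md$gene_name else md$gene_id
  data.frame(gene_id = md$gene_id,
             name = ifelse(is.na(nm), md$gene_id, nm),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Genes overlapping significant regions
#'
#' Any-overlap (>= 1 bp) intersection of significant regions with gene
#' models, both on 1-based closed intervals; strand is ignored.
#'
#' @param regions data.frame with `chrom`, `start_bp`, `end_bp` (e.g. from
#'   [fdr_and_regions()]).
#' @param genes data.frame from [read_gtf_genes()] (or with the same
#'   columns).
#' @return data.frame: one row per region x overlapping gene (`region`,
#'   `chrom`, `start_bp`, `end_bp`, `gene_id`, `name`); regions without hits
#'   get a single row with NA gene fields.
#' @export
overlap_genes <- function(regions, genes) {
  if (nrow(regions) == 0L)
    return(data.frame(region = integer(0), chrom = character(0),
                      start_bp = integer(0), end_bp = integer(0),
                      gene_id = character(0), name = character(0)))
  if (!any(regions$chrom %in% genes$chrom))
    stop("no shared chromosome names between regions (",
         paste(unique(regions$chrom), collapse = ","), ") and genes (",
         paste(utils::head(unique(genes$chrom), 5), collapse = ","),
         "); supply a rename map")
  gr_r <- GenomicRanges::GRanges(regions$chrom,
                                 IRanges::IRanges(regions$start_bp,
                                                  regions$end_bp))
  gr_g <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start, genes$end))
  hits <- GenomicRanges::findOverlaps(gr_r, gr_g, ignore.strand = TRUE)
  out <- lapply(seq_len(nrow(regions)), function(i) {
    g <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]
    if (length(g) == 0L)
      data.frame(region = i, chrom = regions$chrom[i],
                 start_bp = regions$start_bp[i], end_bp = regions$end_bp[i],
                 gene_id = NA_character_, name = NA_character_)
    else
      data.frame(region = i, chrom = regions$chrom[i],
                 start_bp = regions$start_bp[i], end_bp = regions$end_bp[i],
                 gene_id = genes$gene_id[g], name = genes$name[g])
  })
  do.call(rbind, out)
}
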