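# Shared fixtures, built in code.

# tiny variant table + phased genotypes from haplotype 0/1 rows
make_dataset <- function(hap_rows, chrom = "chr1", pos = NULL,
                         ref = NULL, alt = NULL) {
  hap <- do.call(rbind, hap_rows)
  m <- ncol(hap)
  samples <- paste0("S", seq_len(nrow(hap) / 2))
  rownames(hap) <- paste0(rep(samples, each = 2), "_",
                          rep(1:2, length(samples)))
  if (is.null(pos)) pos <- seq_len(m) * 100L
  if (is.null(ref)) ref <- rep("A", m)
  if (is.null(alt)) alt <- rep("C", m)
  vt <- data.frame(chrom = rep(chrom, m), pos = pos, ref = ref, alt = alt,
                   index = seq_len(m) - 1L, stringsAsFactors = FALSE)
  list(variants = vt,
       genotypes = ailhap:::new_phased_genotypes(samples, hap))
}

# write a small VCF text fixture directly (for malformed-input tests)
write_vcf_text <- function(records, samples, path) {
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t"),
               records), path)
  path
}

# small shared AIL simulation (cached per test run)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_ail(sim_config(
        seed = 42,
        chromosomes = list(c(snps = 100, cm = 100), c(snps = 100, cm = 100)),
        n_intermediate = 80, n_final = 150))
    cache
  }
})

# ancestry_track built from a simulation's truth (perfect calls)
truth_track <- function(sim) {
  structure(list(samples = sim$f9_ids, posterior = sim$truth,
                 origin = sim$truth, blocks = sim$hbs$blocks),
            class = "ancestry_track")
}
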