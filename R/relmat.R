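#' SNP-based genetic relationship matrix
#'
#' Centered-and-scaled genotype cross-product averaged over polymorphic
#' SNPs (the standard GRM estimator):
#' `G_jk = (1/M) sum_m (x_jm - 2 p_m)(x_km - 2 p_m) / (2 p_m (1 - p_m))`,
#' with `x` the 0/1/2 dosage and `p` the sample allele frequency.
#' Monomorphic SNPs are skipped.
#'
#' @param vt variant table.
#' @param pg `phased_genotypes`.
#' @return N x N `kinship` matrix (attribute `provenance = "snp"`).
#' @export
snp_grm <- function(vt, pg) {
  x <- dosage_from_haplotypes(pg)
  dosage_grm(x, "snp")
}

# N x M dosage matrix from the 2N x M haplotype matrix
dosage_from_haplotypes <- function(pg) {
  n <- length(pg$samples)
  x <- pg$hap[seq(1L, 2L * n, 2L), , drop = FALSE] +
    pg$hap[seq(2L, 2L * n, 2L), , drop = FALSE]
  rownames(x) <- pg$samples
  x
}

# shared 0/1/2-dosage GRM estimator; uninformative (zero-variance) columns
# drop out of both the sum and the divisor
dosage_grm <- function(x, provenance) {
  p <- colMeans(x) / 2
  poly <- p > 0 & p < 1 & matrixStats_colVars(x) > 0
  if (sum(poly) < 1L) stop("no polymorphic columns for GRM")
  x <- x[, poly, drop = FALSE]
  p <- p[poly]
  w <- sweep(x, 2, 2 * p, "-")
  w <- sweep(w, 2, sqrt(2 * p * (1 - p)), "/")
  g <- tcrossprod(w) / ncol(w)
  structure(g, provenance = provenance, class = c("kinship", "matrix"))
}

matrixStats_colVars <- function(x) {
  colMeans(x^2) - colMeans(x)^2
}

#' Ancestry-based relationship matrix
#'
#' The GRM estimator of [snp_grm()] applied to diploid ancestry codes
#' (0/1/2 copies of HQLA origin per block); blocks fixed for one origin are
#' skipped. Captures global ancestry for the polygenic term of the
#' ancestral-haplotype GWAS.
#'
#' @param code samples x blocks matrix of 0/1/2 ancestry codes
#'   (see [code_diploid()]).
#' @return N x N `kinship` matrix (attribute `provenance = "ancestry"`).
#' @export
ancestry_grm <- function(code) {
  dosage_grm(code, "ancestry")
}

#' Haplotype relationship matrix over all blocks
#'
#' For each block, a 2N x 2N identity-score matrix (1 when two haplotypes
#' carry the same block allele, 0 otherwise); the returned Gamma is the
#' block average, accumulated block-by-block without materialising the
#' per-block matrices.
#'
#' @param hbs `hap_blocks`.
#' @return object of class `hap_gamma`: a 2N x 2N matrix with unit diagonal
#'   and attribute `n_blocks`.
#' @export
haplotype_gamma <- function(hbs) {
  nb <- nrow(hbs$blocks)
  stopifnot(nb >= 1L)
  nh <- nrow(hbs$assign)
  g <- matrix(0, nh, nh)
  for (b in seq_len(nb)) {
    a <- hbs$assign[, b]
    z <- matrix(0, nh, max(a))
    z[cbind(seq_len(nh), a)] <- 1
    g <- g + tcrossprod(z)
  }
  g <- g / nb
  dimnames(g) <- list(rownames(hbs$assign), rownames(hbs$assign))
  structure(g, n_blocks = nb, class = c("hap_gamma", "matrix"))
}

#' Individual-level haplotype kinship H = K Gamma K' / 2
#'
#' Reduces the 2N x 2N haplotype relationship matrix to the N x N
#' individual level with `K = I (x) [1 1]` (Kronecker product), i.e. each
#' entry is the sum of the corresponding 2 x 2 sub-block of Gamma divided
#' by 2. Diagonal entries lie in `[1, 2]` (1 + within-individual haplotype
#' identity).
#'
#' @param g `hap_gamma` matrix.
#' @param samples optional sample ids for dimnames.
#' @return N x N `kinship` matrix (attribute `provenance = "haplotype"`).
#' @export
gamma_to_h <- function(g, samples = NULL) {
  nh <- nrow(g)
  stopifnot(nh %% 2L == 0L)
  odd <- seq(1L, nh, 2L); even <- seq(2L, nh, 2L)
  h <- (g[odd, odd] + g[odd, even] + g[even, odd] + g[even, even]) / 2
  h <- unclass(h)
  attributes(h) <- attributes(h)["dim"]
  if (!is.null(samples)) dimnames(h) <- list(samples, samples)
  structure(h, provenance = "haplotype", class = c("kinship", "matrix"))
}

#' @export
print.kinship <- function(x, ...) {
  cat("kinship matrix (", attr(x, "provenance"), "): ", nrow(x), " x ",
      ncol(x), "\n", sep = "")
  invisible(x)
}

#' Check a kinship matrix for symmetry and positive semidefiniteness
#'
#' @param k `kinship` matrix.
#' @param tol eigenvalue tolerance relative to `trace/N`.
#' @return TRUE invisibly; errors otherwise.
#' @export
check_kinship <- function(k, tol = 1e-8) {
  if (max(abs(k - t(k))) > 1e-10) stop("kinship matrix not symmetric")
  ev <- eigen(k, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * sum(diag(k)) / nrow(k))
    stop("kinship matrix not positive semidefinite (min eigenvalue ",
         signif(min(ev), 3), ")")
  invisible(TRUE)
}

#' Write / read a kinship matrix as TSV with a JSON sidecar
#'
#' @param k `kinship` matrix with sample dimnames.
#' @param path output TSV path; provenance goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_kinship <- function(k, path) {
  df <- as.data.frame(unclass(k))
  utils::write.table(cbind(sample = rownames(k), df), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(provenance = attr(k, "provenance"),
                            n = nrow(k)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_kinship
#' @export
read_kinship <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample
  meta <- if (file.exists(paste0(path, ".json")))
    jsonlite::read_json(paste0(path, ".json")) else list(provenance = NA)
  structure(m, provenance = meta$provenance, class = c("kinship", "matrix"))
}
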