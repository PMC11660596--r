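#' Pooled haplotype-homozygosity statistics H12, H123, H1234
#'
#' Haplotype homozygosity after pooling the top 2, 3 or 4 most frequent
#' haplotype alleles into one class:
#' `H12 = (p1 + p2)^2 + sum_{i>=3} pi^2`, and analogously for H123/H1234.
#' If a block carries fewer distinct alleles than the pool size the pooled
#' frequency is 1 and the statistic equals 1.
#'
#' @param spec `hap_spectrum` (see [spectrum()]).
#' @return data.frame with one row per block (`block`, `chrom`, `H12`,
#'   `H123`, `H1234`) plus attribute `genome_mean` (named vector of
#'   block-mean values).
#' @export
h_stats <- function(spec) {
  if (length(spec$freq) == 0L) stop("empty spectrum")
  pool <- function(p, k) {
    if (length(p) == 0L) stop("block with empty spectrum")
    (sum(p[seq_len(min(k, length(p)))]))^2 +
      if (length(p) > k) sum(p[(k + 1L):length(p)]^2) else 0
  }
  H12 <- vapply(spec$freq, pool, numeric(1), k = 2L)
  H123 <- vapply(spec$freq, pool, numeric(1), k = 3L)
  H1234 <- vapply(spec$freq, pool, numeric(1), k = 4L)
  out <- data.frame(block = spec$blocks$block, chrom = spec$blocks$chrom,
                    H12 = H12, H123 = H123, H1234 = H1234)
  attr(out, "genome_mean") <- c(H12 = mean(H12), H123 = mean(H123),
                                H1234 = mean(H1234))
  out
}

#' Jaccard distance between two allele sets
#'
#' `JD = 1 - |A intersect B| / |A union B|`.
#'
#' @param setA,setB character vectors of haplotype alleles (non-empty).
#' @return distance in `[0, 1]`.
#' @export
jaccard <- function(setA, setB) {
  if (length(setA) == 0L && length(setB) == 0L) stop("both allele sets empty")
  setA <- unique(setA); setB <- unique(setB)
  1 - length(intersect(setA, setB)) / length(union(setA, setB))
}

#' Jensen-Shannon divergence between two frequency distributions
#'
#' `JSD = KL(A || M)/2 + KL(B || M)/2` with `M = (A + B)/2`, natural
#' logarithm, and `0 * log(0/x)` taken as 0. The printed (non-square-root)
#' form is the default; `sqrt = TRUE` returns the Jensen-Shannon distance
#' `sqrt(JSD)` as returned by some numerics libraries.
#'
#' @param fA,fB numeric frequency vectors on the same (union) support, each
#'   summing to 1; zeros allowed.
#' @param sqrt return the square root (a metric) instead of the divergence.
#' @return divergence in `[0, log(2)]` (or its square root).
#' @export
jensen_shannon <- function(fA, fB, sqrt = FALSE) {
  stopifnot(length(fA) == length(fB))
  if (any(fA < 0) || any(fB < 0)) stop("negative frequencies")
  m <- (fA + fB) / 2
  kl <- function(p) {
    i <- p > 0
    sum(p[i] * log(p[i] / m[i]))
  }
  jsd <- kl(fA) / 2 + kl(fB) / 2
  if (sqrt) base::sqrt(jsd) else jsd
}

#' Bray-Curtis dissimilarity between two count vectors
#'
#' `BCD = 1 - 2 * sum(min(SA, SB)) / (sum(SA) + sum(SB))` over the union
#' support of haplotype-allele counts in the two populations.
#'
#' @param cA,cB non-negative count vectors on the same support, not both
#'   all zero.
#' @return dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(cA, cB) {
  stopifnot(length(cA) == length(cB))
  if (any(cA < 0) || any(cB < 0)) stop("negative counts")
  tot <- sum(cA) + sum(cB)
  if (tot == 0) stop("all-zero count vectors")
  1 - 2 * sum(pmin(cA, cB)) / tot
}

# align two per-block spectra onto their union support
union_support <- function(a, b) {
  alleles <- union(names(a), names(b))
  list(a = stats::setNames(ifelse(alleles %in% names(a), a[alleles], 0), alleles),
       b = stats::setNames(ifelse(alleles %in% names(b), b[alleles], 0), alleles))
}

#' Per-block dissimilarity between two populations
#'
#' Computes Jaccard distance (on allele sets), Jensen-Shannon divergence
#' (on allele frequencies) and Bray-Curtis dissimilarity (on allele counts)
#' for every block, plus genome means.
#'
#' @param specA,specB `hap_spectrum` objects over the same `hap_blocks`.
#' @param sqrt_jsd report the square-root Jensen-Shannon distance instead of
#'   the divergence.
#' @return data.frame (`block`, `chrom`, `JD`, `JSD`, `BCD`) with attribute
#'   `genome_mean`.
#' @export
block_dissimilarity <- function(specA, specB, sqrt_jsd = FALSE) {
  nb <- length(specA$freq)
  stopifnot(nb == length(specB$freq))
  JD <- JSD <- BCD <- numeric(nb)
  for (b in seq_len(nb)) {
    JD[b] <- jaccard(names(specA$freq[[b]]), names(specB$freq[[b]]))
    u <- union_support(specA$freq[[b]], specB$freq[[b]])
    JSD[b] <- jensen_shannon(u$a, u$b, sqrt = sqrt_jsd)
    uc <- union_support(specA$count[[b]], specB$count[[b]])
    BCD[b] <- bray_curtis(uc$a, uc$b)
  }
  out <- data.frame(block = specA$blocks$block, chrom = specA$blocks$chrom,
                    JD = JD, JSD = JSD, BCD = BCD)
  attr(out, "genome_mean") <- c(JD = mean(JD), JSD = mean(JSD), BCD = mean(BCD))
  out
}
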