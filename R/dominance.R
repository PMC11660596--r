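#' Sex/batch-corrected phenotypes
#'
#' Least-squares residuals of `trait ~ sex + batch`; the residuals are used
#' as the phenotype for the non-parametric dominance scan. Aliased columns
#' in a confounded design are dropped by `lm` with a warning.
#'
#' @param pt phenotype data.frame with `id`, `trait`, `sex`, `batch`
#'   (see [read_phenotypes()]).
#' @return named numeric vector of residuals (names = sample ids).
#' @export
correct_phenotype <- function(pt) {
  stopifnot(all(c("trait", "sex", "batch") %in% names(pt)))
  terms <- c("sex", "batch")[c(length(unique(pt$sex)) > 1L,
                               length(unique(pt$batch)) > 1L)]
  form <- stats::reformulate(if (length(terms)) terms else "1",
                             response = "trait")
  fit <- stats::lm(form, data = pt)
  if (any(is.na(stats::coef(fit))))
    warning("confounded sex/batch design; aliased columns dropped")
  r <- stats::residuals(fit)
  names(r) <- pt$id
  r
}

#' Kruskal-Wallis test of ancestry classes
#'
#' Tie-corrected Kruskal-Wallis rank test that the class medians are equal,
#' with a chi-square reference on (k - 1) degrees of freedom. Classes
#' smaller than `min_class` make the block untestable.
#'
#' @param values numeric phenotype values.
#' @param classes class labels (e.g. diploid ancestry codes 0/1/2).
#' @param min_class minimum class size (default 5).
#' @return list `H`, `df`, `p`; or `p = NA` with `reason` when a class is
#'   below `min_class` or fewer than 2 classes are present.
#' @export
kruskal_wallis <- function(values, classes, min_class = 5L) {
  classes <- factor(classes)
  sizes <- table(classes)
  if (length(sizes) < 2L)
    return(list(H = NA_real_, df = NA_integer_, p = NA_real_,
                reason = "fewer than 2 classes"))
  if (any(sizes < min_class))
    return(list(H = NA_real_, df = NA_integer_, p = NA_real_,
                reason = paste0("class below minimum size ", min_class)))
  kt <- stats::kruskal.test(values, classes)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Steel-Dwass all-pairs post-hoc test
#'
#' For each pair of classes, ranks the pair's pooled values (midranks for
#' ties), forms the standardized Wilcoxon rank-sum statistic with tie
#' correction, and refers `sqrt(2) * |t|` to the studentized-range
#' distribution with `k` groups and infinite degrees of freedom
#' (asymptotic mode). `mode = "permutation"` estimates the same familywise
#' quantity without the normal approximation: class labels are permuted
#' jointly and each observed pair statistic is compared with the
#' permutation distribution of the maximum pairwise statistic (max-T),
#' appropriate for small classes.
#'
#' @param values numeric phenotype values.
#' @param classes class labels (k classes, typically 3).
#' @param mode `"asymptotic"` (default) or `"permutation"`.
#' @param n_perm permutations when `mode = "permutation"` (default 2000).
#' @return symmetric k x k matrix of pairwise p-values (NA diagonal),
#'   dimnames = class levels; pairs with an empty class are NA.
#' @export
steel_dwass <- function(values, classes, mode = c("asymptotic", "permutation"),
                        n_perm = 2000L) {
  mode <- match.arg(mode)
  classes <- factor(classes)
  lev <- levels(classes)
  k <- length(lev)
  all_pair_stats <- function(v, cl) {
    s <- matrix(NA_real_, k, k)
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        vi <- v[cl == lev[i]]; vj <- v[cl == lev[j]]
        if (length(vi) == 0L || length(vj) == 0L) next
        s[i, j] <- abs(sd_pair_stat(vi, vj))
      }
    }
    s
  }
  s_obs <- all_pair_stats(values, classes)
  p <- matrix(NA_real_, k, k, dimnames = list(lev, lev))
  if (mode == "asymptotic") {
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
      if (!is.na(s_obs[i, j]))
        p[i, j] <- p[j, i] <- stats::ptukey(sqrt(2) * s_obs[i, j],
                                            nmeans = k, df = Inf,
                                            lower.tail = FALSE)
  } else {
    max_perm <- replicate(n_perm, {
      max(all_pair_stats(values, sample(classes)), na.rm = TRUE)
    })
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
      if (!is.na(s_obs[i, j]))
        p[i, j] <- p[j, i] <-
          (1 + sum(max_perm >= s_obs[i, j])) / (1 + n_perm)
  }
  p
}

# standardized tie-corrected rank-sum statistic for one pair
sd_pair_stat <- function(vi, vj) {
  ni <- length(vi); nj <- length(vj); n <- ni + nj
  r <- rank(c(vi, vj))
  w <- sum(r[seq_len(ni)])
  e <- ni * (n + 1) / 2
  v <- ni * nj / (n * (n - 1)) * (sum(r^2) - n * (n + 1)^2 / 4)
  if (v <= 0) return(0)
  (w - e) / sqrt(v)
}

#' Dominance label for one block
#'
#' Applies the high-/mid-parent definitions to the three ancestry classes
#' (0 = HB/HB, 1 = HB/HQLA heterozygote, 2 = HQLA/HQLA):
#' \itemize{
#'   \item high-parent: the heterozygote median exceeds both homozygote
#'     medians and both heterozygote-homozygote Steel-Dwass comparisons are
#'     significant at `alpha`;
#'   \item mid-parent: the heterozygote median strictly exceeds the midpoint
#'     of the two homozygote medians and a heterozygote-homozygote
#'     Steel-Dwass comparison certifies it (which one is configurable via
#'     `midparent_contrast`; the default accepts either).
#' }
#' High-parent blocks satisfy the mid-parent conditions by construction.
#'
#' @param med named numeric vector of class medians (names `"0"`, `"1"`,
#'   `"2"`).
#' @param pair_p pairwise p matrix from [steel_dwass()] (same names).
#' @param alpha pairwise significance level (default 0.05).
#' @param midparent_contrast which heterozygote-homozygote test certifies
#'   mid-parent dominance: `"any"` (default; either comparison suffices,
#'   the relaxed reading), `"closer"` (the homozygote whose median is
#'   nearer the heterozygote's) or `"higher"` (the higher-median
#'   homozygote).
#' @return `"high-parent"`, `"mid-parent"`, or `"none"`.
#' @export
label_dominance <- function(med, pair_p, alpha = 0.05,
                            midparent_contrast = c("any", "closer", "higher")) {
  midparent_contrast <- match.arg(midparent_contrast)
  if (!all(c("0", "1", "2") %in% names(med))) return("none")
  m0 <- med[["0"]]; m1 <- med[["1"]]; m2 <- med[["2"]]
  p10 <- pair_p["1", "0"]; p12 <- pair_p["1", "2"]
  high <- m1 > m0 && m1 > m2 &&
    !is.na(p10) && p10 < alpha && !is.na(p12) && p12 < alpha
  if (high) return("high-parent")
  cert <- switch(midparent_contrast,
    any = (!is.na(p10) && p10 < alpha) || (!is.na(p12) && p12 < alpha),
    closer = {
      pm <- pair_p["1", if (abs(m1 - m0) <= abs(m1 - m2)) "0" else "2"]
      !is.na(pm) && pm < alpha
    },
    higher = {
      pm <- pair_p["1", if (m0 >= m2) "0" else "2"]
      !is.na(pm) && pm < alpha
    })
  if (m1 > (m0 + m2) / 2 && cert) "mid-parent" else "none"
}

#' Genome-wide ancestry-based dominance scan
#'
#' For every block, classifies individuals into ancestral homozygotes
#' (HB/HB, HQLA/HQLA) and heterozygotes (HB/HQLA) from the diploid ancestry
#' code, tests for distributional differences of the corrected phenotype
#' with a Kruskal-Wallis test, applies BH-FDR across tested blocks, and on
#' FDR survivors runs Steel-Dwass post-hoc tests and assigns dominance
#' labels via [label_dominance()].
#'
#' @param y_corrected named corrected phenotype vector
#'   (see [correct_phenotype()]).
#' @param code samples x blocks 0/1/2 ancestry-code matrix
#'   (see [code_diploid()]); rownames must match `names(y_corrected)`.
#' @param blocks block table (`hbs$blocks`) for coordinates.
#' @param min_class minimum class size (default 5); smaller blocks are
#'   reported as untested.
#' @param fdr FDR level for the Kruskal-Wallis screen (default 0.05).
#' @param alpha pairwise post-hoc significance level (default 0.05).
#' @param midparent_contrast see [label_dominance()].
#' @return data.frame of class `dominance_table`: per block, class sizes
#'   `n00`/`n01`/`n11`, medians, `KW_H`, `KW_p`, `q`, pairwise p's, `label`.
#' @export
dominance_scan <- function(y_corrected, code, blocks, min_class = 5L,
                           fdr = 0.05, alpha = 0.05,
                           midparent_contrast = "any") {
  ids <- rownames(code)
  stopifnot(!is.null(ids), all(ids %in% names(y_corrected)))
  y <- y_corrected[ids]
  nb <- ncol(code)
  out <- data.frame(blocks[seq_len(nb), c("block", "chrom", "chrom_block",
                                          "start_bp", "end_bp")],
                    n00 = NA_integer_, n01 = NA_integer_, n11 = NA_integer_,
                    med00 = NA_real_, med01 = NA_real_, med11 = NA_real_,
                    KW_H = NA_real_, KW_p = NA_real_, q = NA_real_,
                    p_het_vs_00 = NA_real_, p_het_vs_11 = NA_real_,
                    p_00_vs_11 = NA_real_,
                    label = "untested", stringsAsFactors = FALSE)
  for (b in seq_len(nb)) {
    cl <- code[, b]
    out$n00[b] <- sum(cl == 0); out$n01[b] <- sum(cl == 1)
    out$n11[b] <- sum(cl == 2)
    out$med00[b] <- stats::median(y[cl == 0])
    out$med01[b] <- stats::median(y[cl == 1])
    out$med11[b] <- stats::median(y[cl == 2])
    kw <- kruskal_wallis(y, cl, min_class)
    out$KW_H[b] <- kw$H; out$KW_p[b] <- kw$p
  }
  tested <- !is.na(out$KW_p)
  out$q[tested] <- stats::p.adjust(out$KW_p[tested], method = "BH")
  out$label[tested] <- "none"
  for (b in which(tested & out$q <= fdr)) {
    cl <- code[, b]
    pp <- steel_dwass(y, cl)
    out$p_het_vs_00[b] <- pp["1", "0"]
    out$p_het_vs_11[b] <- pp["1", "2"]
    out$p_00_vs_11[b] <- pp["0", "2"]
    med <- c("0" = out$med00[b], "1" = out$med01[b], "2" = out$med11[b])
    out$label[b] <- label_dominance(med, pp, alpha, midparent_contrast)
  }
  class(out) <- c("dominance_table", "data.frame")
  out
}
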