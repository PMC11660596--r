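#' Mixed-model association scan over 0/1/2 dosages
#'
#' EMMAX-style scan: variance components are estimated once on the null
#' (no-marker) model with [reml_fit()] and reused for every marker; each
#' marker is then tested by generalized least squares in the pre-whitened
#' system, with a Wald t-test on the dosage coefficient. Works identically
#' for SNP dosages (SNP-based GWAS) and diploid ancestry codes
#' (ancestral-haplotype-based GWAS).
#'
#' @param fit `mlm_fit` from [reml_fit()] on the null model.
#' @param dosage markers x samples matrix with values 0/1/2 (columns aligned
#'   with the phenotype order used in `fit`).
#' @param info optional data.frame of marker metadata (one row per marker,
#'   e.g. chrom/pos/id) carried into the output.
#' @return data.frame of class `assoc_table`: `id`, `beta`, `se`, `stat`
#'   (t), `p`; monomorphic markers get NA rows. Add BH q-values with
#'   [fdr_and_regions()].
#' @export
marker_scan <- function(fit, dosage, info = NULL) {
  dosage <- as.matrix(dosage)
  if (!all(dosage %in% c(0, 1, 2)))
    stop("dosage values outside {0, 1, 2}")
  m <- nrow(dosage)
  stopifnot(ncol(dosage) == fit$n)
  w <- 1 / (fit$sigma_g2 * fit$eig$values + fit$sigma_e2)
  sw <- sqrt(w)
  ys <- sw * fit$yt
  qs <- sw * fit$xt
  # markers rotated in one multiply: U' X'  -> n x m
  xs <- sw * crossprod(fit$eig$vectors, t(dosage))
  qtq <- crossprod(qs)
  qty <- crossprod(qs, ys)
  df <- fit$n - fit$q - 1L
  beta <- se <- stat <- p <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    if (stats::var(dosage[j, ]) == 0) next
    xj <- xs[, j]
    a <- rbind(cbind(qtq, crossprod(qs, xj)),
               c(crossprod(xj, qs), sum(xj^2)))
    b <- c(qty, sum(xj * ys))
    ai <- tryCatch(solve(a), error = function(e) NULL)
    if (is.null(ai)) next
    coefs <- ai %*% b
    r <- ys - cbind(qs, xj) %*% coefs
    s2 <- sum(r^2) / df
    beta[j] <- coefs[fit$q + 1L]
    se[j] <- sqrt(s2 * ai[fit$q + 1L, fit$q + 1L])
    stat[j] <- beta[j] / se[j]
    p[j] <- 2 * stats::pt(-abs(stat[j]), df)
  }
  out <- data.frame(id = if (!is.null(rownames(dosage))) rownames(dosage)
                    else seq_len(m),
                    beta = beta, se = se, stat = stat, p = p,
                    stringsAsFactors = FALSE)
  if (!is.null(info)) out <- cbind(info, out)
  class(out) <- c("assoc_table", "data.frame")
  out
}

#' Precompute shared quantities for block LRT scans
#'
#' Eigendecomposes the haplotype kinship once and fits the null model
#' `y = Q a + g_h + e` by full maximum likelihood (ML, not REML, because the
#' likelihood-ratio test compares models with different fixed effects).
#'
#' @param y trait vector.
#' @param Q covariate design matrix.
#' @param kinship haplotype-based `kinship` matrix (see [gamma_to_h()]).
#' @return list with the eigendecomposition and the null ML fit.
#' @export
assoc_cache <- function(y, Q, kinship) {
  eig <- eigen_kinship(kinship)
  null_ml <- mm_fit(y, Q, eig = eig, reml = FALSE)
  list(y = y, Q = as.matrix(Q), eig = eig, null_ml = null_ml)
}

#' Likelihood-ratio test of one haplotype block
#'
#' Codes each individual's unordered haplotype-allele combination at the
#' block as a categorical factor, pools combinations carried by fewer than
#' `min_count` individuals into one OTHER level, and compares the ML fits of
#' `y = Q a + g_h + e` (null) and `y = Q a + X_h b + g_h + e` (alternative)
#' by a chi-square likelihood-ratio test with (levels - 1) degrees of
#' freedom.
#'
#' @param cache from [assoc_cache()].
#' @param hbs `hap_blocks` (samples aligned with `cache$y`).
#' @param block global block id.
#' @param min_count minimum carriers per combination level (default 5).
#' @return list `stat`, `df`, `p`, `n_levels`; `p` is NA with a `reason`
#'   when only one level remains after pooling.
#' @export
block_lrt <- function(cache, hbs, block, min_count = 5L) {
  combo <- block_combos(hbs, block, min_count)
  if (nlevels(combo) < 2L) {
    # one combination carried by everyone: the models coincide, LRT = 0
    if (attr(combo, "n_raw") == 1L)
      return(list(stat = 0, df = 0L, p = 1, n_levels = 1L))
    return(list(stat = NA_real_, df = NA_integer_, p = NA_real_,
                n_levels = nlevels(combo),
                reason = "single combination level after pooling"))
  }
  xh <- stats::model.matrix(~ combo)[, -1, drop = FALSE]
  alt <- mm_fit(cache$y, cbind(cache$Q, xh), eig = cache$eig, reml = FALSE)
  stat <- max(0, 2 * (alt$loglik - cache$null_ml$loglik))
  df <- nlevels(combo) - 1L
  list(stat = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE),
       n_levels = nlevels(combo))
}

# unordered haplotype-combination factor for one block, rare levels pooled
block_combos <- function(hbs, block, min_count = 5L) {
  n <- length(hbs$samples)
  a1 <- hbs$assign[seq(1L, 2L * n, 2L), block]
  a2 <- hbs$assign[seq(2L, 2L * n, 2L), block]
  combo <- paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
  tab <- table(combo)
  rare <- names(tab)[tab < min_count]
  n_raw <- length(tab)
  combo[combo %in% rare] <- "OTHER"
  structure(factor(combo), n_raw = n_raw)
}

#' Haplotype-block GWAS over all blocks
#'
#' Runs [block_lrt()] for every block and assembles an association table.
#'
#' @inheritParams block_lrt
#' @return `assoc_table` data.frame: block coordinates, LRT `stat`, `df`,
#'   `p`.
#' @export
hap_gwas <- function(cache, hbs, min_count = 5L) {
  res <- lapply(seq_len(nrow(hbs$blocks)), function(b)
    block_lrt(cache, hbs, b, min_count))
  out <- cbind(hbs$blocks,
               data.frame(stat = vapply(res, `[[`, numeric(1), "stat"),
                          df = vapply(res, function(r) as.numeric(r$df), numeric(1)),
                          p = vapply(res, `[[`, numeric(1), "p")))
  class(out) <- c("assoc_table", "data.frame")
  out
}

#' Benjamini-Hochberg FDR and significant-region merging
#'
#' Adds BH q-values to an association table and merges significant markers
#' or blocks into regions: entries on the same chromosome whose positional
#' index differs by at most `gap` are reported as one region (successive
#' significant blocks form a single QTL region).
#'
#' @param tbl `assoc_table` with a `p` column; block tables need `chrom` and
#'   `chrom_block` (or `pos`) columns for region merging.
#' @param q_threshold FDR level (default 0.05).
#' @param gap maximum index gap for merging (default 1 = adjacent).
#' @return list: `table` (input + `q` + `significant`) and `regions`
#'   (data.frame `chrom`, `start`, `end`, `start_bp`, `end_bp`, `n`,
#'   `min_p`; empty when nothing is significant).
#' @export
fdr_and_regions <- function(tbl, q_threshold = 0.05, gap = 1L) {
  tbl$q <- NA_real_
  ok <- !is.na(tbl$p)
  tbl$q[ok] <- stats::p.adjust(tbl$p[ok], method = "BH")
  tbl$significant <- !is.na(tbl$q) & tbl$q <= q_threshold
  idx_col <- if ("chrom_block" %in% names(tbl)) "chrom_block"
             else if ("index" %in% names(tbl)) "index" else NULL
  regions <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), start_bp = integer(0),
                        end_bp = integer(0), n = integer(0),
                        min_p = numeric(0))
  sig <- which(tbl$significant)
  if (length(sig) > 0L && !is.null(idx_col) && "chrom" %in% names(tbl)) {
    s <- tbl[sig, ]
    s <- s[order(s$chrom, s[[idx_col]]), ]
    brk <- c(TRUE, diff(s[[idx_col]]) > gap | s$chrom[-1] != s$chrom[-nrow(s)])
    grp <- cumsum(brk)
    regions <- do.call(rbind, lapply(split(s, grp), function(g)
      data.frame(chrom = g$chrom[1],
                 start = min(g[[idx_col]]), end = max(g[[idx_col]]),
                 start_bp = if ("start_bp" %in% names(g)) min(g$start_bp)
                            else min(g$pos),
                 end_bp = if ("end_bp" %in% names(g)) max(g$end_bp)
                          else max(g$pos),
                 n = nrow(g), min_p = min(g$p))))
    rownames(regions) <- NULL
  }
  list(table = tbl, regions = regions)
}
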