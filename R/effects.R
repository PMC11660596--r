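#' Haplotype-allele dosage matrix for one block
#'
#' Plain mode counts, for each individual, the copies of each catalog
#' haplotype allele (rows sum to 2, the diploid count). Ancestral mode
#' splits each allele by the origin of the carrying haplotype, with column
#' labels `"<alleleSeq>_<0|1>"` (0 = HB, 1 = HQLA), so the same sequence
#' inherited from different founder populations occupies different columns.
#'
#' @param hbs `hap_blocks`.
#' @param block global block id.
#' @param track optional `ancestry_track` covering all samples of `hbs`
#'   (ancestral mode when supplied).
#' @param use_bases label columns with haplotype base strings (default) or
#'   `hap<k>` catalog indices.
#' @return samples x columns integer matrix of class `dosage_matrix`; every
#'   row sums to 2.
#' @export
build_dosage <- function(hbs, block, track = NULL, use_bases = TRUE) {
  n <- length(hbs$samples)
  a1 <- hbs$assign[seq(1L, 2L * n, 2L), block]
  a2 <- hbs$assign[seq(2L, 2L * n, 2L), block]
  k <- length(hbs$alleles[[block]])
  lab <- if (use_bases) hbs$alleles[[block]] else paste0("hap", seq_len(k))
  if (is.null(track)) {
    zd <- matrix(0L, n, k, dimnames = list(hbs$samples, lab))
    for (i in seq_len(n)) {
      zd[i, a1[i]] <- zd[i, a1[i]] + 1L
      zd[i, a2[i]] <- zd[i, a2[i]] + 1L
    }
  } else {
    miss <- setdiff(hbs$samples, track$samples)
    if (length(miss) > 0L)
      stop("sample(s) missing from ancestry track: ",
           paste(miss, collapse = ", "))
    rows <- match(paste0(rep(hbs$samples, each = 2L), "_",
                         rep(1:2, n)), rownames(track$origin))
    o1 <- track$origin[rows[seq(1L, 2L * n, 2L)], block]
    o2 <- track$origin[rows[seq(2L, 2L * n, 2L)], block]
    cols <- paste0(rep(lab, each = 2L), "_", rep(0:1, k))
    zd <- matrix(0L, n, 2L * k, dimnames = list(hbs$samples, cols))
    j1 <- 2L * (a1 - 1L) + o1 + 1L
    j2 <- 2L * (a2 - 1L) + o2 + 1L
    for (i in seq_len(n)) {
      zd[i, j1[i]] <- zd[i, j1[i]] + 1L
      zd[i, j2[i]] <- zd[i, j2[i]] + 1L
    }
  }
  stopifnot(all(rowSums(zd) == 2L))
  class(zd) <- c("dosage_matrix", "matrix")
  zd
}

#' BLUP effects of haplotype alleles at one block
#'
#' Fits `y = Q a + Z_d u + e` with `u ~ N(0, sigma_u^2 I)` independent
#' per-column random effects; the variance ratio is estimated by REML via
#' the eigendecomposition of `Z_d Z_d'` and the best linear unbiased
#' predictions are returned in trait units with prediction-error SEs.
#' Columns with zero carriers are dropped before fitting.
#'
#' @param y trait vector.
#' @param Q covariate design matrix (use `matrix(1, n, 1)` when covariates
#'   were already absorbed into a corrected phenotype).
#' @param zd `dosage_matrix` from [build_dosage()].
#' @return data.frame of class `hap_effects`: `column`, `effect` (BLUP),
#'   `se`, `carriers`; attributes `sigma_u2`, `sigma_e2`.
#' @export
estimate_effects <- function(y, Q, zd) {
  zd <- unclass(zd)
  carriers <- colSums(zd > 0)
  zd <- zd[, carriers > 0, drop = FALSE]
  carriers <- carriers[carriers > 0]
  if (ncol(zd) < 2L)
    stop("fewer than 2 carried haplotype-allele columns; effects unidentifiable")
  n <- length(y)
  Q <- as.matrix(Q)
  kz <- tcrossprod(zd)
  fit <- mm_fit(y, Q, k = kz, reml = TRUE)
  su2 <- fit$sigma_g2; se2 <- fit$sigma_e2
  u <- fit$eig$vectors
  w <- 1 / (su2 * fit$eig$values + se2) # V^{-1} = U diag(w) U'
  vy <- u %*% (w * crossprod(u, y))
  vq <- u %*% (w * crossprod(u, Q))
  alpha <- solve(crossprod(Q, vq), crossprod(Q, vy))
  r <- y - Q %*% alpha
  vr <- u %*% (w * crossprod(u, r))
  blup <- su2 * crossprod(zd, vr)
  # prediction-error variance: su2 I - su2^2 Z' P Z,
  # P = V^-1 - V^-1 Q (Q' V^-1 Q)^-1 Q' V^-1
  vz <- u %*% (w * crossprod(u, zd))
  zpz <- crossprod(zd, vz) -
    crossprod(vz, Q) %*% solve(crossprod(Q, vq), crossprod(vq, zd))
  pev <- su2 - su2^2 * diag(zpz)
  out <- data.frame(column = colnames(zd), effect = drop(blup),
                    se = sqrt(pmax(pev, 0)), carriers = as.integer(carriers),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "sigma_u2") <- su2
  attr(out, "sigma_e2") <- se2
  class(out) <- c("hap_effects", "data.frame")
  out
}

#' Founder-panel exclusivity of a haplotype allele
#'
#' Classifies a block allele by its presence in the two founder-panel
#' spectra: unique to one panel, shared by both, or novel (absent from both
#' -- e.g. created by recombination after the founder cross).
#'
#' @param allele haplotype string.
#' @param hb_freq,hqla_freq named per-block frequency (or count) vectors for
#'   the HB and HQLA founder panels.
#' @return one of `"hb_only"`, `"hqla_only"`, `"shared"`, `"novel"`; for
#'   `"shared"`, attributes `hb_freq` and `hqla_freq` give the panel
#'   frequencies.
#' @export
flag_exclusivity <- function(allele, hb_freq, hqla_freq) {
  in_hb <- allele %in% names(hb_freq)
  in_hq <- allele %in% names(hqla_freq)
  if (in_hb && in_hq)
    structure("shared", hb_freq = unname(hb_freq[allele]),
              hqla_freq = unname(hqla_freq[allele]))
  else if (in_hb) "hb_only"
  else if (in_hq) "hqla_only"
  else "novel"
}

#' Per-block effect report with ancestral labels and exclusivity flags
#'
#' Convenience wrapper: builds the (ancestral-mode, when a track is given)
#' dosage matrix for a block, estimates BLUP effects, and attaches the
#' origin label and founder exclusivity of each column.
#'
#' @inheritParams build_dosage
#' @param y,Q as in [estimate_effects()].
#' @param hb_spec,hqla_spec founder `hap_spectrum`s for exclusivity flags
#'   (optional).
#' @return `hap_effects` data.frame with added `allele`, `origin`,
#'   `exclusivity` columns.
#' @export
block_effects <- function(y, Q, hbs, block, track = NULL,
                          hb_spec = NULL, hqla_spec = NULL) {
  zd <- build_dosage(hbs, block, track)
  eff <- estimate_effects(y, Q, zd)
  if (!is.null(track)) {
    eff$allele <- sub("_[01]$", "", eff$column)
    eff$origin <- as.integer(sub("^.*_", "", eff$column))
  } else {
    eff$allele <- eff$column
    eff$origin <- NA_integer_
  }
  if (!is.null(hb_spec) && !is.null(hqla_spec)) {
    eff$exclusivity <- vapply(eff$allele, function(a)
      as.character(flag_exclusivity(a, hb_spec$freq[[block]],
                                    hqla_spec$freq[[block]])), character(1))
  }
  eff
}
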