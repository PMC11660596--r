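#' Posterior probability that a haplotype allele is of HQLA origin
#'
#' Naive smoothed-frequency classifier for one block: with equal class
#' priors, the posterior of HQLA origin is the Laplace-smoothed frequency of
#' the allele in the HQLA founder panel divided by the sum of the smoothed
#' frequencies in both panels. Alleles unseen in both panels get posterior
#' 0.5 (and are assigned HQLA by the `>= 0.5` rule downstream).
#'
#' @param allele haplotype string.
#' @param hb_freq,hqla_freq named per-block count vectors for the two founder
#'   panels (as in `hap_spectrum$count`).
#' @param n_hb,n_hqla number of haplotypes in each panel.
#' @param pseudocount Laplace pseudocount added to each allele count
#'   (default 1).
#' @return posterior probability of HQLA origin in `[0, 1]`.
#' @export
classify_window <- function(allele, hb_freq, hqla_freq, n_hb, n_hqla,
                            pseudocount = 1) {
  k <- length(union(names(hb_freq), names(hqla_freq))) + 1L # +1 for unseen
  c_hb <- if (allele %in% names(hb_freq)) hb_freq[[allele]] else 0
  c_hq <- if (allele %in% names(hqla_freq)) hqla_freq[[allele]] else 0
  f_hb <- (c_hb + pseudocount) / (n_hb + pseudocount * k)
  f_hq <- (c_hq + pseudocount) / (n_hqla + pseudocount * k)
  f_hq / (f_hq + f_hb)
}

#' Infer per-haplotype local ancestry from founder panels
#'
#' For every target haplotype and block, computes the posterior of HQLA
#' origin with [classify_window()], optionally smooths posteriors along the
#' chromosome with a running mean ([smooth_track()]), and assigns origin 1
#' (HQLA) when the posterior is `>= 0.5`, else 0 (HB). This is a
#' deliberately simple window classifier; externally computed local-ancestry
#' calls can be imported with [import_rfmix()] instead.
#'
#' @param hbs `hap_blocks` covering founders and targets.
#' @param hb_ids,hqla_ids founder sample ids for the HB and HQLA panels.
#' @param targets sample ids to classify (default: all samples not in either
#'   panel).
#' @param pseudocount Laplace pseudocount (default 1).
#' @param window odd running-mean window in blocks (default 1 = no
#'   smoothing, matching the block resolution of the calls).
#' @return object of class `ancestry_track`: `samples`, `posterior` and
#'   `origin` (2T x n_blocks matrices, haplotype rows as in `hap_blocks`),
#'   `blocks` (the block table).
#' @export
infer_ancestry <- function(hbs, hb_ids, hqla_ids, targets = NULL,
                           pseudocount = 1, window = 1L) {
  if (is.null(targets))
    targets <- setdiff(hbs$samples, c(hb_ids, hqla_ids))
  stopifnot(length(targets) > 0L, length(hb_ids) > 0L, length(hqla_ids) > 0L)
  s_hb <- spectrum(hbs, hb_ids)
  s_hq <- spectrum(hbs, hqla_ids)
  rows <- which(rep(hbs$samples, each = 2L) %in% targets)
  nb <- nrow(hbs$blocks)
  post <- matrix(NA_real_, nrow = length(rows), ncol = nb,
                 dimnames = list(rownames(hbs$assign)[rows], NULL))
  for (b in seq_len(nb)) {
    cat_ <- hbs$alleles[[b]]
    p_cat <- vapply(cat_, classify_window, numeric(1),
                    hb_freq = s_hb$count[[b]], hqla_freq = s_hq$count[[b]],
                    n_hb = s_hb$n_hap, n_hqla = s_hq$n_hap,
                    pseudocount = pseudocount)
    post[, b] <- p_cat[hbs$assign[rows, b]]
  }
  tr <- structure(list(samples = targets, posterior = post,
                       origin = (post >= 0.5) * 1L, blocks = hbs$blocks),
                  class = "ancestry_track")
  if (window > 1L) tr <- smooth_track(tr, window) else tr
}

#' Smooth ancestry posteriors along the chromosome
#'
#' Replaces each block's posterior by the running mean over a centred window
#' of blocks (within chromosome; windows are clipped at chromosome ends),
#' then re-applies the `>= 0.5` origin threshold.
#'
#' @param track `ancestry_track`.
#' @param window odd window size in blocks (`>= 1`).
#' @return smoothed `ancestry_track`.
#' @export
smooth_track <- function(track, window = 1L) {
  stopifnot(window >= 1L, window %% 2L == 1L)
  if (window == 1L) return(track)
  half <- (window - 1L) %/% 2L
  post <- track$posterior
  for (ch in unique(track$blocks$chrom)) {
    cols <- which(track$blocks$chrom == ch)
    sm <- post[, cols, drop = FALSE]
    for (j in seq_along(cols)) {
      lo <- max(1L, j - half); hi <- min(length(cols), j + half)
      sm[, j] <- rowMeans(post[, cols[lo:hi], drop = FALSE])
    }
    post[, cols] <- sm
  }
  structure(list(samples = track$samples, posterior = post,
                 origin = (post >= 0.5) * 1L, blocks = track$blocks),
            class = "ancestry_track")
}

#' @export
print.ancestry_track <- function(x, ...) {
  cat("ancestry_track:", length(x$samples), "samples x",
      ncol(x$posterior), "blocks; mean HQLA fraction",
      round(mean(x$origin), 3), "\n")
  invisible(x)
}

#' Import RFMix-style local-ancestry posteriors
#'
#' Reads a whitespace-delimited per-window table with header
#' `chrom start_bp end_bp` followed by two columns per haplotype (posterior
#' of HB then of HQLA origin, haplotypes ordered sample1-hap1,
#' sample1-hap2, sample2-hap1, ...). Each block takes the posterior of the
#' window containing its midpoint; origins are assigned by the `>= 0.5`
#' HQLA-posterior threshold.
#'
#' @param path input table path.
#' @param hbs `hap_blocks` the calls are mapped onto.
#' @param samples sample ids, in haplotype-column order of the file.
#' @return `ancestry_track` over `samples`.
#' @export
import_rfmix <- function(path, hbs, samples) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  nhapcol <- ncol(tab) - 3L
  if (nhapcol != 4L * length(samples)) # 2 posterior columns per haplotype
    stop("expected ", 4L * length(samples), " posterior columns for ",
         length(samples), " samples, found ", nhapcol)
  miss <- setdiff(unique(hbs$blocks$chrom), unique(tab[[1]]))
  if (length(miss) > 0L)
    stop("ancestry file missing chromosome(s): ", paste(miss, collapse = ", "))
  nb <- nrow(hbs$blocks)
  nh <- 2L * length(samples)
  post <- matrix(NA_real_, nrow = nh, ncol = nb,
                 dimnames = list(paste0(rep(samples, each = 2L), "_",
                                        rep(1:2, length(samples))), NULL))
  hq_cols <- 3L + 2L * seq_len(nh) # second (HQLA) column of each haplotype pair
  for (b in seq_len(nb)) {
    mid <- (hbs$blocks$start_bp[b] + hbs$blocks$end_bp[b]) / 2
    w <- which(tab[[1]] == hbs$blocks$chrom[b] & tab[[2]] <= mid & tab[[3]] >= mid)
    if (length(w) == 0L)
      stop("no ancestry window covers block ", b, " midpoint at ",
           hbs$blocks$chrom[b], ":", mid)
    post[, b] <- as.numeric(tab[w[1], hq_cols])
  }
  structure(list(samples = samples, posterior = post,
                 origin = (post >= 0.5) * 1L, blocks = hbs$blocks),
            class = "ancestry_track")
}

#' Diploid ancestry dosage codes
#'
#' Per sample and block, the number of HQLA-origin haplotype copies:
#' HB/HB = 0, HB/HQLA = 1, HQLA/HQLA = 2.
#'
#' @param track `ancestry_track` with both haplotypes of every sample.
#' @return integer matrix samples x blocks with values 0/1/2.
#' @export
code_diploid <- function(track) {
  n <- length(track$samples)
  stopifnot(nrow(track$origin) == 2L * n)
  code <- track$origin[seq(1L, 2L * n, 2L), , drop = FALSE] +
    track$origin[seq(2L, 2L * n, 2L), , drop = FALSE]
  rownames(code) <- track$samples
  code
}

#' Ancestry-call accuracy against a truth track
#'
#' Fraction of haplotype-block assignments whose called origin matches the
#' true origin (e.g. the simulator's truth track).
#'
#' @param track `ancestry_track` of calls.
#' @param truth matrix of true origins with the same dimensions as
#'   `track$origin` (NA entries are excluded).
#' @return fraction in `[0, 1]`.
#' @export
ancestry_accuracy <- function(track, truth) {
  stopifnot(all(dim(truth) == dim(track$origin)))
  ok <- !is.na(truth)
  if (!any(ok)) stop("no assignable haplotype-blocks")
  mean(track$origin[ok] == truth[ok])
}

#' Ancestry-call accuracy on panel-unique alleles
#'
#' Empirical check in the absence of truth: haplotype-blocks whose allele is
#' observed in exactly one founder panel are assignable to that panel; the
#' returned value is the fraction of such haplotype-blocks whose call
#' matches.
#'
#' @param track `ancestry_track` of calls over target samples.
#' @param hbs `hap_blocks` covering panels and targets.
#' @param hb_ids,hqla_ids founder panel sample ids.
#' @return fraction in `[0, 1]`.
#' @export
panel_unique_accuracy <- function(track, hbs, hb_ids, hqla_ids) {
  s_hb <- spectrum(hbs, hb_ids)
  s_hq <- spectrum(hbs, hqla_ids)
  rows <- match(rownames(track$origin), rownames(hbs$assign))
  n_tot <- 0L; n_ok <- 0L
  for (b in seq_len(nrow(hbs$blocks))) {
    in_hb <- names(s_hb$count[[b]])
    in_hq <- names(s_hq$count[[b]])
    uniq <- c(stats::setNames(rep(0L, length(setdiff(in_hb, in_hq))),
                              setdiff(in_hb, in_hq)),
              stats::setNames(rep(1L, length(setdiff(in_hq, in_hb))),
                              setdiff(in_hq, in_hb)))
    if (length(uniq) == 0L) next
    alle <- hbs$alleles[[b]][hbs$assign[rows, b]]
    m <- alle %in% names(uniq)
    if (!any(m)) next
    n_tot <- n_tot + sum(m)
    n_ok <- n_ok + sum(track$origin[m, b] == uniq[alle[m]])
  }
  if (n_tot == 0L) stop("no assignable haplotype-blocks")
  n_ok / n_tot
}

#' Write an ancestry track as TSV
#'
#' Columns: sample, hap (1/2), chrom, block, posterior, origin.
#'
#' @param track `ancestry_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ancestry <- function(track, path) {
  nh <- nrow(track$posterior); nb <- ncol(track$posterior)
  df <- data.frame(
    sample = rep(rep(track$samples, each = 2L), nb),
    hap = rep(rep(1:2, length(track$samples)), nb),
    chrom = rep(track$blocks$chrom, each = nh),
    block = rep(track$blocks$block, each = nh),
    posterior = as.vector(track$posterior),
    origin = as.vector(track$origin))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
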