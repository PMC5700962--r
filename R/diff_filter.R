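# Differential screening between resistant and sensitive groups:
# Earth Mover's Distance on expression with permutation q-values, plus
# copy-number and somatic-mutation frequency filters.

#' One-dimensional Earth Mover's Distance between two samples
#'
#' Computes the EMD between the normalized histograms of two value vectors
#' over a shared binning of their pooled range. For one-dimensional
#' histograms on a common grid the minimum-cost transport equals the summed
#' absolute difference of the cumulative histograms times the bin width.
#'
#' Binning defaults to Freedman-Diaconis on the pooled values with a floor of
#' 10 bins; explicit \code{breaks} override \code{n_bins}.
#'
#' @param a,b Non-empty numeric vectors.
#' @param n_bins Number of equal-width bins over the pooled range.
#' @param breaks Optional explicit break points (overrides \code{n_bins}).
#' @return Non-negative EMD; 0 iff the two histograms are identical.
#' @export
emd_statistic <- function(a, b, n_bins = NULL, breaks = NULL) {
  assert_that(length(a) > 0 && length(b) > 0,
              "emd_statistic: both vectors must be non-empty")
  pooled <- c(a, b)
  assert_that(all(is.finite(pooled)), "emd_statistic: values must be finite")
  if (is.null(breaks)) {
    rng <- range(pooled)
    if (rng[2] == rng[1]) return(0)
    nb <- n_bins %||% fd_bins(pooled)
    breaks <- seq(rng[1], rng[2], length.out = nb + 1L)
  }
  emd_from_breaks(a, b, breaks)
}

fd_bins <- function(x) {
  bw <- 2 * stats::IQR(x) / length(x)^(1 / 3)
  if (bw <= 0) return(10L)
  max(10L, ceiling(diff(range(x)) / bw))
}

# core EMD given fixed breaks; callers guarantee values fall inside range
emd_from_breaks <- function(a, b, breaks) {
  nb <- length(breaks) - 1L
  ia <- pmin(pmax(findInterval(a, breaks, rightmost.closed = TRUE), 1L), nb)
  ib <- pmin(pmax(findInterval(b, breaks, rightmost.closed = TRUE), 1L), nb)
  ha <- tabulate(ia, nb) / length(a)
  hb <- tabulate(ib, nb) / length(b)
  sum(abs(cumsum(ha - hb))) * (breaks[2] - breaks[1])
}

#' Per-gene EMD differential statistics with permutation q-values
#'
#' For every gene, computes the EMD between resistant and sensitive
#' expression distributions, a permutation p-value from label shuffles (the
#' same shuffles are applied to every gene within a permutation), and
#' Benjamini-Hochberg q-values.
#'
#' @param X Gene x sample expression matrix.
#' @param labels Named resistant/sensitive vector covering the samples.
#' @param n_perm Number of label permutations (>= 100).
#' @param seed Integer seed; results are deterministic given the seed.
#' @param n_bins Optional fixed bin count (default Freedman-Diaconis per gene).
#' @return data.frame with columns gene, emd, p_value, q_value.
#' @export
emd_qvalues <- function(X, labels, n_perm = 1000L, seed = 1L, n_bins = NULL) {
  check_labels(labels, colnames(X))
  assert_that(n_perm >= 100L, "emd_qvalues: n_perm must be >= 100")
  labels <- labels[colnames(X)]
  grp <- labels == "resistant"
  m <- ncol(X)
  ng <- nrow(X)

  ## per-gene fixed binning (depends only on pooled values, so it is shared
  ## between the observed statistic and every permutation)
  breaks_list <- vector("list", ng)
  idx_list <- vector("list", ng)
  const <- logical(ng)
  for (g in seq_len(ng)) {
    x <- X[g, ]
    rng <- range(x)
    if (rng[2] == rng[1]) { const[g] <- TRUE; next }
    nb <- n_bins %||% fd_bins(x)
    br <- seq(rng[1], rng[2], length.out = nb + 1L)
    breaks_list[[g]] <- br
    idx_list[[g]] <- pmin(pmax(findInterval(x, br, rightmost.closed = TRUE), 1L), nb)
  }

  emd_for <- function(g, mask) {
    br <- breaks_list[[g]]
    nb <- length(br) - 1L
    ix <- idx_list[[g]]
    ha <- tabulate(ix[mask], nb) / sum(mask)
    hb <- tabulate(ix[!mask], nb) / sum(!mask)
    sum(abs(cumsum(ha - hb))) * (br[2] - br[1])
  }

  obs <- numeric(ng)
  for (g in seq_len(ng)) obs[g] <- if (const[g]) 0 else emd_for(g, grp)

  set.seed(seed)
  exceed <- integer(ng)
  for (p in seq_len(n_perm)) {
    pm <- sample(grp)
    for (g in seq_len(ng)) {
      s <- if (const[g]) 0 else emd_for(g, pm)
      if (s >= obs[g]) exceed[g] <- exceed[g] + 1L
    }
  }
  pval <- (exceed + 1) / (n_perm + 1)
  data.frame(gene = rownames(X), emd = obs, p_value = pval,
             q_value = stats::p.adjust(pval, method = "BH"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Map copy-number segments onto genes
#'
#' Assigns each gene, in each sample, the segment mean of the segment with
#' maximal base-pair overlap; genes overlapped by no segment get 0 (normal).
#' SEG coordinates are 1-based inclusive, BED 0-based half-open.
#'
#' @param seg SEG data.frame (see \code{\link{read_seg}}).
#' @param genes BED data.frame (see \code{\link{read_bed}}).
#' @return Numeric gene x sample log2-ratio matrix.
#' @export
map_segments_to_genes <- function(seg, genes) {
  samples <- unique(seg$sample)
  out <- matrix(0, nrow(genes), length(samples),
                dimnames = list(genes$gene, samples))
  gene_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start + 1L, genes$end))
  for (s in samples) {
    ss <- seg[seg$sample == s, , drop = FALSE]
    seg_gr <- GenomicRanges::GRanges(ss$chrom, IRanges::IRanges(ss$start, ss$end))
    hits <- GenomicRanges::findOverlaps(gene_gr, seg_gr)
    if (length(hits) == 0) next
    ov <- IRanges::width(IRanges::pintersect(gene_gr[S4Vectors::queryHits(hits)],
                                             seg_gr[S4Vectors::subjectHits(hits)]))
    df <- data.frame(g = S4Vectors::queryHits(hits),
                     j = S4Vectors::subjectHits(hits), w = ov)
    ## maximal-overlap rule; ties broken by first segment in file order
    df <- df[order(df$g, -df$w, df$j), ]
    df <- df[!duplicated(df$g), ]
    out[df$g, s] <- ss$seg_mean[df$j]
  }
  out
}

#' Call amplified/deleted/normal states from log2 copy-number ratios
#'
#' Strictly above \code{threshold} is amplified (+1), strictly below
#' \code{-threshold} deleted (-1), otherwise normal (0); boundary values are
#' normal.
#'
#' @param log2_matrix Gene x sample log2-ratio matrix.
#' @param threshold Positive call threshold (default 0.3).
#' @return Integer matrix over \{-1, 0, 1\} with the same dimnames.
#' @export
call_cnv_states <- function(log2_matrix, threshold = 0.3) {
  assert_that(threshold > 0, "call_cnv_states: threshold must be > 0")
  states <- matrix(0L, nrow(log2_matrix), ncol(log2_matrix),
                   dimnames = dimnames(log2_matrix))
  states[log2_matrix > threshold] <- 1L
  states[log2_matrix < -threshold] <- -1L
  states
}

group_freq <- function(mat, labels, what) {
  labels <- labels[colnames(mat)]
  res <- labels == "resistant"
  cbind(resistant = rowMeans(mat[, res, drop = FALSE] == what),
        sensitive = rowMeans(mat[, !res, drop = FALSE] == what))
}

#' Filter CNV genes by between-group amplification/deletion frequency
#'
#' Retains genes whose within-group amplification frequencies, or deletion
#' frequencies, differ between resistant and sensitive samples by strictly
#' more than \code{min_diff}.
#'
#' @param states CNV state matrix over \{-1, 0, 1\} (genes x samples).
#' @param labels Named resistant/sensitive vector.
#' @param min_diff Frequency-difference threshold (default 0.20).
#' @return Character vector of retained gene ids.
#' @export
cnv_frequency_filter <- function(states, labels, min_diff = 0.20) {
  check_labels(labels, colnames(states))
  amp <- group_freq(states, labels, 1L)
  del <- group_freq(states, labels, -1L)
  keep <- abs(amp[, 1] - amp[, 2]) > min_diff | abs(del[, 1] - del[, 2]) > min_diff
  rownames(states)[keep]
}

#' Filter somatic genes by within-group mutation frequency
#'
#' Retains genes mutated in strictly more than \code{min_freq} of the samples
#' of at least one group.
#'
#' @param calls Binary gene x sample mutation matrix.
#' @param labels Named resistant/sensitive vector.
#' @param min_freq Frequency threshold (default 0.02).
#' @return Character vector of retained gene ids.
#' @export
mutation_frequency_filter <- function(calls, labels, min_freq = 0.02) {
  check_labels(labels, colnames(calls))
  fr <- group_freq(calls, labels, 1L)
  rownames(calls)[fr[, 1] > min_freq | fr[, 2] > min_freq]
}
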