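# TSS-anchored integration: peak-to-TSS distances with a Fisher background
# test, the TSS-anchored heat-map matrix, expression classification from
# P/A/M flags, decile profiles, and bound-gene enrichment.

#' Signed distance from each peak to the closest TSS
#'
#' Distance is strand-oriented: `strand_sign x (peak_center - tss)` to the
#' nearest TSS by absolute distance on the same chromosome, so negative
#' values are upstream of the TSS regardless of strand. Ties between
#' equidistant TSSs break toward the smaller gene_id.
#'
#' @param peaks peak data.frame (chrom, center).
#' @param tss TSS data.frame.
#' @return data.frame: chrom, center, gene_id of the closest TSS, distance.
#' @export
peak_to_tss_distance <- function(peaks, tss) {
  if (nrow(peaks) == 0 || nrow(tss) == 0) stop("peaks and tss must be non-empty")
  gene <- character(nrow(peaks))
  dist <- rep(NA_real_, nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == ch)
    ti <- which(tss$chrom == ch)
    if (length(ti) == 0) next
    for (i in pi) {
      d_abs <- abs(peaks$center[i] - tss$tss[ti])
      best <- ti[d_abs == min(d_abs)]
      best <- best[order(tss$gene_id[best])][1]
      gene[i] <- tss$gene_id[best]
      dist[i] <- strand_sign(tss$strand[best]) * (peaks$center[i] - tss$tss[best])
    }
  }
  data.frame(chrom = peaks$chrom, center = peaks$center,
             gene_id = gene, distance = dist, stringsAsFactors = FALSE)
}

#' Per-bin enrichment of peak-to-TSS distances over a window background
#'
#' For each distance bin \[e_i, e_(i+1)) the 2x2 table is (peaks in bin,
#' peaks outside; background distances in bin, background outside), tested
#' one-sided greater — the background being the distances of all
#' probe-sufficient windows to their closest TSS.
#'
#' @param peak_distances numeric signed distances for the called peaks.
#' @param background_distances signed distances for the background windows.
#' @param breaks bin edges, bp (half-open bins).
#' @return data.frame: bin_start, bin_end, n_peaks, n_background,
#'   fold_enrichment, p_value.
#' @export
tss_distance_enrichment <- function(peak_distances, background_distances,
                                    breaks = seq(-2250, 500, by = 250)) {
  if (length(background_distances) == 0) stop("background distances must be non-empty")
  n_bin <- length(breaks) - 1
  out <- data.frame(bin_start = breaks[-length(breaks)], bin_end = breaks[-1],
                    n_peaks = integer(n_bin), n_background = integer(n_bin),
                    fold_enrichment = NA_real_, p_value = NA_real_)
  for (i in seq_len(n_bin)) {
    a <- sum(peak_distances >= breaks[i] & peak_distances < breaks[i + 1])
    cc <- sum(background_distances >= breaks[i] & background_distances < breaks[i + 1])
    res <- contingency_result(a, length(peak_distances) - a,
                              cc, length(background_distances) - cc,
                              sided = "greater")
    out$n_peaks[i] <- a
    out$n_background[i] <- cc
    out$fold_enrichment[i] <- res$fold_enrichment
    out$p_value[i] <- res$p_value
  }
  out
}

#' TSS-anchored signal matrix (heat-map matrix)
#'
#' One row per gene, one column per 600 bp window moved in 150 bp steps
#' across the strand-oriented promoter (-2200..+500 bp gives 19 columns).
#' A cell is the mean `mean_ratio` of probes whose TSS-relative midpoint
#' falls in \[center - w/2, center + w/2); cells with no probes are NA.
#'
#' @param probes probe data.frame with `mean_ratio`.
#' @param tss TSS data.frame.
#' @param heatmap_window column window width, bp.
#' @param heatmap_step column step, bp.
#' @param region_upstream,region_downstream promoter extent, bp.
#' @param sort_rows order rows by increasing mean signal near the TSS.
#' @return numeric matrix, rownames gene ids, colnames window centers.
#' @export
tss_anchored_matrix <- function(probes, tss, heatmap_window = 600L,
                                heatmap_step = 150L,
                                region_upstream = 2200L,
                                region_downstream = 500L,
                                sort_rows = FALSE) {
  if (!"mean_ratio" %in% names(probes)) stop("probes must carry mean_ratio")
  centers <- seq(-region_upstream, region_downstream, by = heatmap_step)
  half <- heatmap_window / 2
  mat <- matrix(NA_real_, nrow = nrow(tss), ncol = length(centers),
                dimnames = list(tss$gene_id, centers))
  by_chrom <- split(seq_len(nrow(probes)), probes$chrom)
  mid_all <- probe_midpoint(probes$start, probes$end)
  for (g in seq_len(nrow(tss))) {
    idx <- by_chrom[[tss$chrom[g]]]
    if (is.null(idx)) next
    rel <- strand_sign(tss$strand[g]) * (mid_all[idx] - tss$tss[g])
    keep <- rel >= -region_upstream - half & rel < region_downstream + half &
      !is.na(probes$mean_ratio[idx])
    rel <- rel[keep]
    val <- probes$mean_ratio[idx][keep]
    if (length(val) == 0) next
    for (j in seq_along(centers)) {
      inw <- rel >= centers[j] - half & rel < centers[j] + half
      if (any(inw)) mat[g, j] <- mean(val[inw])
    }
  }
  if (sort_rows) {
    near <- abs(centers) <= half
    key <- rowMeans(mat[, near, drop = FALSE], na.rm = TRUE)
    key[is.nan(key)] <- -Inf
    mat <- mat[order(key), , drop = FALSE]
  }
  mat
}

#' Classify genes from replicate presence flags
#'
#' A gene is expressed iff flagged P in every replicate, unexpressed iff
#' flagged A in every replicate, otherwise ambiguous. The mean signal is
#' the average over all replicate signals, and genes are ranked into
#' expression deciles (1 = lowest 10%) when at least 10 genes carry a
#' signal; ties break by gene_id.
#'
#' @param expr expression data.frame (gene_id, signal_<k>, flag_<k>).
#' @return data.frame: gene_id, status, mean_signal, decile.
#' @export
classify_expression <- function(expr) {
  sig_cols <- grep("^signal_[0-9]+$", names(expr), value = TRUE)
  flg_cols <- grep("^flag_[0-9]+$", names(expr), value = TRUE)
  if (length(sig_cols) == 0 || length(flg_cols) == 0) {
    stop("expression table needs signal_<k> and flag_<k> columns")
  }
  flags <- as.matrix(expr[, flg_cols, drop = FALSE])
  if (any(!flags %in% c("P", "A", "M"))) {
    stop("flag outside {P,A,M}: '", flags[!flags %in% c("P", "A", "M")][1], "'")
  }
  all_p <- rowSums(flags == "P") == ncol(flags)
  all_a <- rowSums(flags == "A") == ncol(flags)
  status <- ifelse(all_p, "expressed", ifelse(all_a, "unexpressed", "ambiguous"))
  mean_signal <- rowMeans(as.matrix(expr[, sig_cols, drop = FALSE]), na.rm = TRUE)
  out <- data.frame(gene_id = expr$gene_id, status = status,
                    mean_signal = mean_signal, decile = NA_integer_,
                    stringsAsFactors = FALSE)
  has_sig <- !is.na(out$mean_signal)
  n <- sum(has_sig)
  if (n >= 10) {
    o <- order(out$mean_signal[has_sig], out$gene_id[has_sig])
    rk <- integer(n)
    rk[o] <- seq_len(n)
    out$decile[has_sig] <- as.integer(ceiling(10 * rk / n))
  }
  out
}

#' Mean signal profile per expression decile
#'
#' Splits the TSS-anchored matrix rows by the expression decile of the
#' matching gene and returns the columnwise mean profile of each decile,
#' ignoring missing cells. Decile sizes differ by at most one.
#'
#' @param mat matrix from [tss_anchored_matrix()] (rownames = gene ids).
#' @param expression classified records from [classify_expression()].
#' @return 10 x ncol(mat) matrix of mean profiles, rownames "1".."10".
#' @export
decile_profile <- function(mat, expression) {
  common <- intersect(rownames(mat), expression$gene_id)
  if (length(common) < 10) stop("need at least 10 genes shared between matrix and expression")
  expr <- expression[match(common, expression$gene_id), , drop = FALSE]
  o <- order(expr$mean_signal, expr$gene_id)
  rk <- integer(length(common))
  rk[o] <- seq_along(common)
  dec <- ceiling(10 * rk / length(common))
  prof <- matrix(NA_real_, nrow = 10, ncol = ncol(mat),
                 dimnames = list(as.character(1:10), colnames(mat)))
  for (d in 1:10) {
    rows <- common[dec == d]
    if (length(rows) == 0) next
    cm <- colMeans(mat[rows, , drop = FALSE], na.rm = TRUE)
    cm[is.nan(cm)] <- NA_real_
    prof[d, ] <- cm
  }
  prof
}

#' Assign called peaks to the genes whose promoter contains them
#'
#' A peak belongs to a gene iff its center's strand-oriented offset from
#' the gene's TSS lies within \[-region_upstream, region_downstream\];
#' peaks in overlapping promoters count for every containing gene.
#'
#' @param peaks peak data.frame (chrom, center).
#' @param tss TSS data.frame.
#' @param region_upstream,region_downstream promoter extent, bp.
#' @return data.frame: gene_id, chrom, center (one row per peak-gene pair).
#' @export
assign_peaks_to_genes <- function(peaks, tss, region_upstream = 2200L,
                                  region_downstream = 500L) {
  rows <- list()
  for (ch in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == ch)
    ti <- which(tss$chrom == ch)
    if (length(ti) == 0) next
    for (g in ti) {
      rel <- strand_sign(tss$strand[g]) * (peaks$center[pi] - tss$tss[g])
      hit <- pi[rel >= -region_upstream & rel <= region_downstream]
      if (length(hit) > 0) {
        row <- data.frame(gene_id = tss$gene_id[g], chrom = ch,
                          center = peaks$center[hit], stringsAsFactors = FALSE)
        if (all(c("start", "end") %in% names(peaks))) {
          row$start <- peaks$start[hit]
          row$end <- peaks$end[hit]
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(gene_id = character(0), chrom = character(0),
                      center = integer(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Enrichment of bound genes among expressed versus unexpressed genes
#'
#' Builds the 2x2 table (expressed & bound, expressed & unbound;
#' unexpressed & bound, unexpressed & unbound) and reports the fold
#' enrichment of binding among expressed genes with a two-sided Fisher
#' exact p, plus the within-class bound percentages.
#'
#' @param expressed,unexpressed disjoint gene-id sets.
#' @param bound gene ids with a significant peak in their promoter.
#' @return `contingency_result` with extra fields pct_expressed_bound and
#'   pct_unexpressed_bound.
#' @export
bound_gene_enrichment <- function(expressed, unexpressed, bound) {
  if (length(expressed) == 0 || length(unexpressed) == 0) {
    stop("both expression classes must be non-empty")
  }
  if (length(intersect(expressed, unexpressed)) > 0) {
    stop("expressed and unexpressed sets must be disjoint")
  }
  a <- length(intersect(expressed, bound))
  b <- length(setdiff(expressed, bound))
  cc <- length(intersect(unexpressed, bound))
  d <- length(setdiff(unexpressed, bound))
  res <- contingency_result(a, b, cc, d, sided = "two.sided")
  res$pct_expressed_bound <- 100 * a / (a + b)
  res$pct_unexpressed_bound <- 100 * cc / (cc + d)
  res
}
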