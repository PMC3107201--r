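# Transcription-factor binding-site enrichment by base-pair counting.
#
# The training set is all DNA within a 2 kb flank of TSSs whose promoter
# contains a peak; the background is the same flank union over all array
# genes minus the training set. Per motif, the bp marked by its (merged)
# sites inside each set enter a one-sided Fisher exact test.

#' Build the training and background interval sets
#'
#' Training: merged union of \[tss - flank, tss + flank) for genes whose
#' flank interval contains at least one peak center. Background: the merged
#' flank union over all `universe_genes` minus the training set.
#' Overlapping promoters are merged before set subtraction, so the two
#' sets partition the all-gene union exactly.
#'
#' @param peaks peak data.frame (chrom, center).
#' @param tss TSS data.frame.
#' @param flank TSS flank, bp.
#' @param universe_genes gene ids on the array (defaults to all in `tss`).
#' @return list: `training` and `background` data.frames of merged disjoint
#'   0-based half-open intervals, plus `bound_genes` and sizes in bp.
#' @export
build_training_background <- function(peaks, tss, flank = 2000L,
                                      universe_genes = tss$gene_id) {
  tss_u <- tss[tss$gene_id %in% universe_genes, , drop = FALSE]
  prom <- data.frame(chrom = tss_u$chrom,
                     start = pmax(tss_u$tss - flank, 0L),
                     end = tss_u$tss + flank,
                     stringsAsFactors = FALSE)
  bound <- rep(FALSE, nrow(tss_u))
  if (nrow(peaks) > 0) {
    for (g in seq_len(nrow(tss_u))) {
      on_chr <- peaks$chrom == tss_u$chrom[g]
      bound[g] <- any(on_chr & peaks$center >= prom$start[g] &
                        peaks$center < prom$end[g])
    }
  }
  all_gr <- GenomicRanges::reduce(intervals_to_granges(prom))
  if (!any(bound)) {
    training <- prom[0, , drop = FALSE]
    background <- granges_to_intervals(all_gr)
  } else {
    train_gr <- GenomicRanges::reduce(
      intervals_to_granges(prom[bound, , drop = FALSE]))
    bg_gr <- GenomicRanges::setdiff(all_gr, train_gr)
    training <- granges_to_intervals(train_gr)
    background <- granges_to_intervals(bg_gr)
  }
  structure(list(training = training, background = background,
                 bound_genes = tss_u$gene_id[bound],
                 training_size = sum(training$end - training$start),
                 background_size = sum(background$end - background$start)),
            class = "training_background")
}

#' Base pairs marked by one motif inside a region set
#'
#' Overlapping sites of the same motif are merged first (bp semantics), then
#' intersected with the merged region set; the result is the total length
#' of the intersection.
#'
#' @param sites data.frame of intervals (chrom, start, end) for one motif.
#' @param regions data.frame of merged disjoint intervals.
#' @return total marked bp (integer).
#' @export
count_marked_bp <- function(sites, regions) {
  if (nrow(sites) == 0 || nrow(regions) == 0) return(0L)
  s_gr <- GenomicRanges::reduce(intervals_to_granges(sites))
  r_gr <- GenomicRanges::reduce(intervals_to_granges(regions))
  # sites and regions may legitimately live on disjoint chromosome sets
  ov <- suppressWarnings(GenomicRanges::intersect(s_gr, r_gr))
  sum(GenomicRanges::width(ov))
}

#' Per-motif bp enrichment in training versus background
#'
#' For each motif the 2x2 table is (bp marked in training, unmarked
#' training bp; bp marked in background, unmarked background bp), tested
#' one-sided greater; fold is the marked-bp density ratio, flagged Inf when
#' the motif marks no background bp.
#'
#' @param motif_sites data.frame with chrom, start, end, motif_id.
#' @param sets `training_background` from [build_training_background()]
#'   (or any list with training/background interval data.frames).
#' @return data.frame sorted by p: motif_id, bp_training, bp_background,
#'   training_size, background_size, fold, p_value, neg_log10_p.
#' @export
motif_enrichment <- function(motif_sites, sets) {
  tr_size <- sum(sets$training$end - sets$training$start)
  bg_size <- sum(sets$background$end - sets$background$start)
  if (tr_size <= 0 || bg_size <= 0) {
    stop("training and background sets must both be non-empty")
  }
  motifs <- sort(unique(motif_sites$motif_id))
  out <- data.frame(motif_id = motifs, bp_training = 0L, bp_background = 0L,
                    training_size = tr_size, background_size = bg_size,
                    fold = NA_real_, p_value = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(motifs)) {
    sub <- motif_sites[motif_sites$motif_id == motifs[i], , drop = FALSE]
    bp_t <- count_marked_bp(sub, sets$training)
    bp_b <- count_marked_bp(sub, sets$background)
    res <- contingency_result(bp_t, tr_size - bp_t, bp_b, bg_size - bp_b,
                              sided = "greater")
    out$bp_training[i] <- bp_t
    out$bp_background[i] <- bp_b
    out$p_value[i] <- res$p_value
    out$fold[i] <- if (bp_b == 0) {
      if (bp_t > 0) Inf else NA_real_
    } else {
      (bp_t / tr_size) / (bp_b / bg_size)
    }
  }
  out$neg_log10_p <- -log10(pmax(out$p_value, 1e-320))
  out <- out[order(out$p_value, out$motif_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bound genes carrying a motif site adjacent to a peak
#'
#' Counts the bound genes with at least one site of `motif_id` overlapping
#' a peak span or lying within `adj_flank` bp of a peak center, among the
#' peaks assigned to that gene's promoter.
#'
#' @param bound_genes gene ids with a significant peak.
#' @param peak_assignments data.frame from [assign_peaks_to_genes()]
#'   (gene_id, chrom, center).
#' @param motif_sites data.frame with chrom, start, end, motif_id.
#' @param motif_id the motif to score.
#' @param adj_flank adjacency radius around the peak center, bp.
#' @return list: count, percentage (of bound genes), genes.
#' @export
genes_with_motif_near_peak <- function(bound_genes, peak_assignments,
                                       motif_sites, motif_id,
                                       adj_flank = 300L) {
  if (length(bound_genes) == 0) stop("bound gene set must be non-empty")
  sites <- motif_sites[motif_sites$motif_id == motif_id, , drop = FALSE]
  hit_genes <- character(0)
  if (nrow(sites) > 0 && nrow(peak_assignments) > 0) {
    pa <- peak_assignments[peak_assignments$gene_id %in% bound_genes, , drop = FALSE]
    for (i in seq_len(nrow(pa))) {
      s <- sites[sites$chrom == pa$chrom[i], , drop = FALSE]
      if (nrow(s) == 0) next
      lo <- pa$center[i] - adj_flank
      hi <- pa$center[i] + adj_flank
      if (all(c("start", "end") %in% names(pa))) {
        lo <- min(lo, pa$start[i])
        hi <- max(hi, pa$end[i])
      }
      if (any(s$end > lo & s$start < hi)) {
        hit_genes <- c(hit_genes, pa$gene_id[i])
      }
    }
  }
  genes <- sort(unique(hit_genes))
  list(count = length(genes),
       percentage = 100 * length(genes) / length(unique(bound_genes)),
       genes = genes)
}
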