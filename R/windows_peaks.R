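# The windowed error model and the local-maximum peak/trough caller.
#
# A 1 kb window is moved in 250 bp steps over each chromosome; each window
# records its probe count, mean probe log2 ratio, and a one-sided Wilcoxon
# signed-rank p in the direction of its mean. A peak is the center of three
# consecutive windows with positive means, at least six probes each, every
# p below 0.016, and the middle mean strictly above both neighbors; troughs
# mirror this with negative means. The 0.016 threshold is exactly
# attainable by a six-probe window one-sided (1/2^6 = 0.015625) but not
# two-sided (minimum 0.03125), which is why the test is one-sided.

#' One-sided Wilcoxon signed-rank p-value
#'
#' Exact for n <= `exact_max_n` after zero removal: ties are assigned
#' midranks and the null distribution of the positive-rank sum over all 2^n
#' equally likely sign assignments is built by generating-function
#' convolution (midranks are half-integers, so doubled ranks index an
#' integer lattice exactly). For larger n, a normal approximation with
#' continuity correction and the standard tie correction
#' var = n(n+1)(2n+1)/24 - sum(t^3 - t)/48 is used. Exact zeros are dropped
#' before ranking; with nothing left, p = 1.
#'
#' @param values numeric probe log2 ratios.
#' @param direction "greater" tests median > 0, "less" median < 0.
#' @param exact_max_n largest n using the exact distribution.
#' @return p-value in (0, 1].
#' @export
wilcoxon_signed_rank_p <- function(values, direction = c("greater", "less"),
                                   exact_max_n = 12L) {
  direction <- match.arg(direction)
  v <- values[!is.na(values)]
  v <- v[v != 0]
  n <- length(v)
  if (n == 0L) return(1)
  r <- rank(abs(v))
  w2 <- as.integer(round(2 * sum(r[v > 0])))
  if (n <= exact_max_n) {
    ir <- as.integer(round(2 * r))
    total <- sum(ir)
    counts <- numeric(total + 1L)
    counts[1L] <- 1
    for (k in ir) {
      shifted <- c(numeric(k), counts[seq_len(total + 1L - k)])
      counts <- counts + shifted
    }
    p <- if (direction == "greater") {
      sum(counts[(w2 + 1L):(total + 1L)]) / 2^n
    } else {
      sum(counts[seq_len(w2 + 1L)]) / 2^n
    }
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48)
    w <- w2 / 2
    p <- if (direction == "greater") {
      stats::pnorm((w - mu - 0.5) / sigma, lower.tail = FALSE)
    } else {
      stats::pnorm((w - mu + 0.5) / sigma)
    }
  }
  min(max(p, .Machine$double.xmin), 1)
}

#' Build the moving-window error model
#'
#' Window centers sit at multiples of `step` (anchored at coordinate 0,
#' per chromosome) spanning the tiled extent; each window is the half-open
#' interval center +/- window_size/2. A probe belongs to a window iff its
#' midpoint falls in \[start, end). Per window: probe count, mean of
#' `mean_ratio` over members, and a one-sided Wilcoxon p in the direction
#' of the window mean (p = 1 for empty windows).
#'
#' @param probes probe data.frame carrying a `mean_ratio` column.
#' @param window_size window width, bp.
#' @param step window step, bp.
#' @return data.frame: chrom, center, start, end, n_probes, mean, p_value,
#'   ordered by (chrom, center).
#' @export
build_windows <- function(probes, window_size = 1000L, step = 250L) {
  if (!"mean_ratio" %in% names(probes)) {
    stop("probes must carry a mean_ratio column; run normalize_probes() first")
  }
  if (step > window_size) stop("step must not exceed window_size")
  half <- window_size / 2
  out <- list()
  for (ch in unique(probes$chrom)) {
    sub <- probes[probes$chrom == ch & !is.na(probes$mean_ratio), , drop = FALSE]
    if (nrow(sub) == 0L) next
    mid <- probe_midpoint(sub$start, sub$end)
    o <- order(mid)
    mid <- mid[o]
    mr <- sub$mean_ratio[o]
    # centers whose window overlaps the tiled extent
    c_lo <- step * (floor((min(mid) - half) / step) + 1)
    c_hi <- step * floor((max(mid) + half) / step)
    centers <- seq(c_lo, c_hi, by = step)
    starts <- centers - half
    lo <- findInterval(starts - 1, mid) + 1L
    hi <- findInterval(starts + window_size - 1, mid)
    n_probes <- pmax(hi - lo + 1L, 0L)
    cs <- c(0, cumsum(mr))
    means <- ifelse(n_probes > 0, (cs[hi + 1L] - cs[lo]) / n_probes, NA_real_)
    p <- rep(1, length(centers))
    for (i in which(n_probes > 0)) {
      vals <- mr[lo[i]:hi[i]]
      dir <- if (means[i] > 0) "greater" else "less"
      p[i] <- wilcoxon_signed_rank_p(vals, dir)
    }
    out[[ch]] <- data.frame(chrom = ch, center = as.integer(centers),
                            start = as.integer(starts),
                            end = as.integer(starts + window_size),
                            n_probes = n_probes, mean = means, p_value = p,
                            stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(0), center = integer(0),
                      start = integer(0), end = integer(0),
                      n_probes = integer(0), mean = numeric(0),
                      p_value = numeric(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out[order(names(out))])
  rownames(res) <- NULL
  res
}

#' Call peaks or troughs from the window table
#'
#' Scans each chromosome for triples of consecutive windows (centers exactly
#' one step apart) where all three means share the requested sign, all
#' three windows have at least `min_probes` probes and p below
#' `p_threshold`, and the middle mean strictly exceeds (peaks) or is
#' strictly below (troughs) both neighbors. Each qualifying triple yields
#' one call at the middle window; the strict local-extremum rule means no
#' two calls of the same sign can sit one step apart.
#'
#' @param windows window data.frame from [build_windows()].
#' @param p_threshold per-window p threshold.
#' @param min_probes minimum probes per window.
#' @param sign "peak" (enrichment) or "trough" (depletion).
#' @param step window step used to verify consecutiveness, bp.
#' @return data.frame: chrom, center, start, end (span of the three
#'   windows), n_probes, mean, p_value (middle window), sign.
#' @export
call_peaks <- function(windows, p_threshold = 0.016, min_probes = 6L,
                       sign = c("peak", "trough"), step = 250L) {
  sign <- match.arg(sign)
  empty <- data.frame(chrom = character(0), center = integer(0),
                      start = integer(0), end = integer(0),
                      n_probes = integer(0), mean = numeric(0),
                      p_value = numeric(0), sign = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(windows) < 3L) return(empty)
  out <- list()
  for (ch in unique(windows$chrom)) {
    w <- windows[windows$chrom == ch, , drop = FALSE]
    if (is.unsorted(w$center, strictly = TRUE)) {
      stop("windows on ", ch, " are not strictly ordered by center")
    }
    n <- nrow(w)
    if (n < 3L) next
    i <- 2:(n - 1)
    consec <- (w$center[i] - w$center[i - 1] == step) &
      (w$center[i + 1] - w$center[i] == step)
    m_l <- w$mean[i - 1]; m_c <- w$mean[i]; m_r <- w$mean[i + 1]
    sgn_ok <- if (sign == "peak") {
      m_l > 0 & m_c > 0 & m_r > 0 & m_c > m_l & m_c > m_r
    } else {
      m_l < 0 & m_c < 0 & m_r < 0 & m_c < m_l & m_c < m_r
    }
    sgn_ok[is.na(sgn_ok)] <- FALSE
    probes_ok <- w$n_probes[i - 1] >= min_probes &
      w$n_probes[i] >= min_probes & w$n_probes[i + 1] >= min_probes
    p_ok <- w$p_value[i - 1] < p_threshold & w$p_value[i] < p_threshold &
      w$p_value[i + 1] < p_threshold
    hit <- i[consec & sgn_ok & probes_ok & p_ok]
    if (length(hit) == 0L) next
    out[[ch]] <- data.frame(chrom = ch, center = w$center[hit],
                            start = w$start[hit - 1], end = w$end[hit + 1],
                            n_probes = w$n_probes[hit], mean = w$mean[hit],
                            p_value = w$p_value[hit], sign = sign,
                            stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out[order(names(out))])
  rownames(res) <- NULL
  res
}

#' Score called peaks against synthetic truth
#'
#' A call is a true positive iff a truth peak center on the same chromosome
#' lies within `match_dist` bp of the called center. Sensitivity is the
#' fraction of truth peaks matched by at least one call; FPR is the
#' fraction of calls matching no truth peak. With an empty call set the FPR
#' is reported as 0 with `fpr_defined = FALSE`.
#'
#' @param peaks called peak data.frame.
#' @param truth `synthetic_truth` object.
#' @param match_dist maximum center-to-center distance for a match, bp.
#' @return list: sensitivity, fpr, fpr_defined, n_calls, n_truth,
#'   matched_genes (truth gene ids recovered).
#' @export
evaluate_against_truth <- function(peaks, truth, match_dist = 500L) {
  if (match_dist <= 0) stop("match_dist must be positive")
  bound <- truth$bound
  n_calls <- nrow(peaks)
  n_truth <- nrow(bound)
  if (n_calls == 0L) {
    return(list(sensitivity = if (n_truth > 0) 0 else NA_real_,
                fpr = 0, fpr_defined = FALSE,
                n_calls = 0L, n_truth = n_truth,
                matched_genes = character(0)))
  }
  d_call <- min_dist_to_positions(peaks$chrom, peaks$center,
                                  bound$chrom, bound$center)
  tp <- d_call <= match_dist
  d_truth <- min_dist_to_positions(bound$chrom, bound$center,
                                   peaks$chrom, peaks$center)
  matched <- d_truth <= match_dist
  list(sensitivity = if (n_truth > 0) mean(matched) else NA_real_,
       fpr = mean(!tp), fpr_defined = TRUE,
       n_calls = n_calls, n_truth = n_truth,
       matched_genes = bound$gene_id[matched])
}
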