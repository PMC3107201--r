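# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Midpoint of a 0-based half-open interval, floor convention.
probe_midpoint <- function(start, end) {
  as.integer(floor((start + end) / 2))
}

ratio_columns <- function(probes) {
  grep("^ratio_[0-9]+$", names(probes), value = TRUE)
}

intensity_columns <- function(probes) {
  grep("^A_[0-9]+$", names(probes), value = TRUE)
}

strand_sign <- function(strand) {
  ifelse(strand == "+", 1L, -1L)
}

# Minimum absolute distance from each query position to a set of sorted
# reference positions on the same chromosome. Returns Inf where the query's
# chromosome has no reference positions.
min_dist_to_positions <- function(q_chrom, q_pos, r_chrom, r_pos) {
  out <- rep(Inf, length(q_pos))
  for (ch in unique(q_chrom)) {
    qi <- which(q_chrom == ch)
    ri <- which(r_chrom == ch)
    if (length(ri) == 0L) next
    rp <- sort(r_pos[ri])
    idx <- findInterval(q_pos[qi], rp)
    d_left <- ifelse(idx >= 1L, abs(q_pos[qi] - rp[pmax(idx, 1L)]), Inf)
    d_right <- ifelse(idx < length(rp), abs(rp[pmin(idx + 1L, length(rp))] - q_pos[qi]), Inf)
    out[qi] <- pmin(d_left, d_right)
  }
  out
}

# All permutations of 1..n as an n!-row matrix. Only used for small n.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    rest <- seq_len(n)[-i]
    out[rows, 1L] <- i
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

# data.frame of 0-based half-open intervals -> GRanges (1-based closed).
intervals_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

# GRanges -> data.frame of 0-based half-open intervals.
granges_to_intervals <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

add_provenance <- function(x, step) {
  attr(x, "provenance") <- c(attr(x, "provenance"), step)
  x
}

#' Provenance of a probe set
#'
#' Ordered record of the transforms applied to a probe table by the
#' normalization pipeline.
#'
#' @param x a probe data frame.
#' @return character vector of transform labels (possibly empty).
#' @export
provenance <- function(x) {
  p <- attr(x, "provenance")
  if (is.null(p)) character(0) else p
}
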