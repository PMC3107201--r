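# Synthetic promoter tiling-array data with known ground truth.
#
# The generators emulate the structure of a two-color RefSeq promoter array:
# promoters tiled from 2200 bp upstream to 500 bp downstream of each TSS at
# ~100 bp probe spacing, replicate log2(IP/input) ratios, planted triangular
# enrichment peaks, three-replicate P/A/M expression flags, a second-factor
# peak list, and a conserved-motif interval track. Noise is i.i.d. Gaussian
# per probe per replicate; there is no probe-affinity or spatial
# autocorrelation term.

#' Simulate a promoter tiling ChIP-chip array
#'
#' Lays out `n_genes` promoters (alternating strands, several chromosomes,
#' well separated), tiles each with probes every ~100 bp (+/- 20 bp jitter)
#' across -2200..+500 bp around the TSS, and draws per-replicate
#' log2(IP/input) ratios as N(0, `noise_sd`). A `fraction_bound` subset of
#' genes additionally receives a triangular enrichment bump of apex height
#' `effect_size` and base width `peak_width`, centered at a random offset
#' within the tiled region; the bump is shared across replicates (it is
#' signal, not noise). Per-replicate mean intensities A are drawn N(10, 1)
#' so intensity-covariate normalization is exercised.
#'
#' @param n_genes number of promoters.
#' @param fraction_bound proportion of genes given a planted peak.
#' @param effect_size apex log2 enrichment of planted peaks (use a negative
#'   value to plant troughs).
#' @param peak_width base width of the triangular bump, bp.
#' @param noise_sd per-probe per-replicate noise standard deviation, log2.
#' @param n_replicates number of replicate arrays.
#' @param seed integer RNG seed; identical seeds give identical output.
#' @param region_upstream,region_downstream tiled extent around the TSS, bp.
#' @param probe_spacing,probe_jitter,probe_length probe layout, bp.
#' @param promoter_spacing distance between neighboring TSSs, bp.
#' @param n_chroms number of chromosomes genes are spread over.
#' @return list with elements `probes` (probe data.frame as from
#'   [read_probe_table()]), `tss` (TSS data.frame) and `truth`
#'   (a `synthetic_truth` list: `bound` data.frame with gene_id, offset and
#'   absolute peak center, plus the generating parameters).
#' @export
simulate_promoter_array <- function(n_genes, fraction_bound,
                                    effect_size = 1.5, peak_width = 600L,
                                    noise_sd = 0.3, n_replicates = 2L,
                                    seed = NULL,
                                    region_upstream = 2200L,
                                    region_downstream = 500L,
                                    probe_spacing = 100L, probe_jitter = 20L,
                                    probe_length = 60L,
                                    promoter_spacing = 5000L, n_chroms = 4L) {
  if (fraction_bound < 0 || fraction_bound > 1) {
    stop("fraction_bound must lie in [0, 1]")
  }
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (!is.null(seed)) set.seed(seed)

  gene_id <- sprintf("G%05d", seq_len(n_genes))
  chrom <- paste0("chr", ((seq_len(n_genes) - 1L) %% n_chroms) + 1L)
  idx_on_chrom <- stats::ave(seq_len(n_genes), chrom, FUN = seq_along)
  tss_pos <- 5000L + (idx_on_chrom - 1L) * as.integer(promoter_spacing)
  strand <- rep_len(c("+", "-"), n_genes)
  tss <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                    tss = tss_pos, stringsAsFactors = FALSE)

  offsets0 <- seq(-region_upstream, region_downstream, by = probe_spacing)
  n_per_gene <- length(offsets0)

  n_bound <- round(fraction_bound * n_genes)
  bound_idx <- sort(sample.int(n_genes, n_bound))
  half <- peak_width / 2
  lo <- -region_upstream + half
  hi <- region_downstream - half
  if (lo > hi) stop("peak_width too large for the tiled region")
  peak_offset <- as.integer(round(stats::runif(n_bound, lo, hi)))

  gene_of_probe <- rep(seq_len(n_genes), each = n_per_gene)
  jitter <- sample.int(2L * probe_jitter + 1L,
                       n_genes * n_per_gene, replace = TRUE) - probe_jitter - 1L
  offset <- rep(offsets0, times = n_genes) + jitter
  sgn <- strand_sign(strand)[gene_of_probe]
  center <- tss_pos[gene_of_probe] + sgn * offset
  start <- as.integer(center - probe_length %/% 2L)
  end <- start + as.integer(probe_length)

  bump <- numeric(n_genes * n_per_gene)
  if (n_bound > 0) {
    peak_of_gene <- rep(NA_integer_, n_genes)
    peak_of_gene[bound_idx] <- peak_offset
    d <- abs(offset - peak_of_gene[gene_of_probe])
    has_peak <- !is.na(d)
    bump[has_peak] <- effect_size * pmax(0, 1 - d[has_peak] / half)
  }

  probes <- data.frame(
    chrom = chrom[gene_of_probe],
    start = start,
    end = end,
    probe_id = sprintf("%s_p%02d", gene_id[gene_of_probe],
                       rep(seq_len(n_per_gene), times = n_genes)),
    stringsAsFactors = FALSE
  )
  for (j in seq_len(n_replicates)) {
    probes[[paste0("ratio_", j)]] <-
      bump + stats::rnorm(nrow(probes), 0, noise_sd)
  }
  for (j in seq_len(n_replicates)) {
    probes[[paste0("A_", j)]] <- stats::rnorm(nrow(probes), 10, 1)
  }
  probes <- probes[order(probes$chrom, probes$start), , drop = FALSE]
  rownames(probes) <- NULL
  attr(probes, "n_replicates") <- n_replicates

  truth <- structure(list(
    bound = data.frame(
      gene_id = gene_id[bound_idx],
      chrom = chrom[bound_idx],
      strand = strand[bound_idx],
      tss = tss_pos[bound_idx],
      offset = peak_offset,
      center = tss_pos[bound_idx] + strand_sign(strand[bound_idx]) * peak_offset,
      stringsAsFactors = FALSE
    ),
    effect_size = effect_size,
    peak_width = as.integer(peak_width),
    noise_sd = noise_sd,
    region_upstream = as.integer(region_upstream),
    region_downstream = as.integer(region_downstream),
    cobound_genes = character(0)
  ), class = "synthetic_truth")

  list(probes = probes, tss = tss, truth = truth)
}

#' Simulate replicate expression-array calls
#'
#' Assigns each gene an expression status and draws replicate signals plus
#' Affymetrix-style P/A/M detection flags: expressed genes are flagged P in
#' every replicate, unexpressed genes A in every replicate, ambiguous genes
#' get a non-unanimous mix. When `bound_bias > 1`, genes in `bound_genes`
#' have their odds of being expressed multiplied by `bound_bias` and receive
#' a log2(`bound_bias`) shift in mean signal, so expression deciles
#' correlate with binding status.
#'
#' @param genes character vector of gene ids.
#' @param fraction_expressed overall expected expressed fraction.
#' @param fraction_ambiguous expected ambiguous fraction.
#' @param bound_bias odds multiplier for bound genes being expressed.
#' @param bound_genes gene ids treated as truth-bound (must be a subset of
#'   `genes`).
#' @param n_replicates number of expression replicates (3 in the emulated
#'   design).
#' @param seed integer RNG seed.
#' @return expression data.frame with gene_id, signal_1..k, flag_1..k.
#' @export
simulate_expression <- function(genes, fraction_expressed = 0.55,
                                fraction_ambiguous = 0.1, bound_bias = 1,
                                bound_genes = character(0),
                                n_replicates = 3L, seed = NULL) {
  if (fraction_expressed < 0 || fraction_ambiguous < 0 ||
      fraction_expressed + fraction_ambiguous > 1) {
    stop("fractions must be non-negative and sum to at most 1")
  }
  unknown <- setdiff(bound_genes, genes)
  if (length(unknown) > 0) {
    stop("bound gene(s) not in the gene list: ", paste(utils::head(unknown, 3), collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)

  n <- length(genes)
  is_bound <- genes %in% bound_genes
  ambiguous <- stats::runif(n) < fraction_ambiguous
  p_e <- if (fraction_ambiguous < 1) fraction_expressed / (1 - fraction_ambiguous) else 0
  p_e <- min(p_e, 1)
  odds <- if (p_e >= 1) Inf else p_e / (1 - p_e)
  p_gene <- ifelse(is_bound & is.finite(odds),
                   odds * bound_bias / (1 + odds * bound_bias),
                   p_e)
  expressed <- !ambiguous & stats::runif(n) < p_gene

  mu <- 6 + 2 * expressed + log2(bound_bias) * is_bound
  signals <- matrix(stats::rnorm(n * n_replicates, mean = rep(mu, n_replicates), sd = 0.5),
                    nrow = n)
  flags <- matrix("", nrow = n, ncol = n_replicates)
  flags[expressed, ] <- "P"
  flags[!ambiguous & !expressed, ] <- "A"
  amb_idx <- which(ambiguous)
  for (i in amb_idx) {
    repeat {
      f <- sample(c("P", "A", "M"), n_replicates, replace = TRUE)
      if (!all(f == "P") && !all(f == "A")) break
    }
    flags[i, ] <- f
  }

  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (j in seq_len(n_replicates)) out[[paste0("signal_", j)]] <- signals[, j]
  for (j in seq_len(n_replicates)) out[[paste0("flag_", j)]] <- flags[, j]
  out
}

#' Simulate a second factor's peak list
#'
#' Copies a `cooccupancy_fraction` subset of the truth peaks with Gaussian
#' positional jitter (truncated below `cooccupancy_dist` so the copy stays
#' co-occupied by construction) and adds `n_extra` decoy intervals placed at
#' least `cooccupancy_dist` from every truth peak center.
#'
#' @param truth `synthetic_truth` from [simulate_promoter_array()].
#' @param tss the matching TSS data.frame (decoys are placed in promoters).
#' @param cooccupancy_fraction fraction of truth peaks to copy.
#' @param jitter_sd sd of the positional jitter, bp.
#' @param n_extra number of decoy intervals.
#' @param cooccupancy_dist co-occupancy radius, bp.
#' @param peak_halfwidth half width of emitted intervals, bp.
#' @param seed integer RNG seed.
#' @return list with `intervals` (data.frame chrom, start, end, name) and
#'   `cobound_genes` (gene ids whose truth peak was copied).
#' @export
simulate_second_factor <- function(truth, tss, cooccupancy_fraction,
                                   jitter_sd = 100, n_extra = 0L,
                                   cooccupancy_dist = 1500L,
                                   peak_halfwidth = 200L, seed = NULL) {
  if (cooccupancy_fraction < 0 || cooccupancy_fraction > 1) {
    stop("cooccupancy_fraction must lie in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  bound <- truth$bound
  n_co <- round(cooccupancy_fraction * nrow(bound))
  pick <- if (n_co > 0) sort(sample.int(nrow(bound), n_co)) else integer(0)

  centers <- integer(0); chroms <- character(0); names_out <- character(0)
  for (i in pick) {
    repeat {
      d <- round(stats::rnorm(1, 0, jitter_sd))
      ctr <- bound$center[i] + d
      if (abs(d) < cooccupancy_dist && ctr - peak_halfwidth >= 0) break
    }
    centers <- c(centers, ctr)
    chroms <- c(chroms, bound$chrom[i])
    names_out <- c(names_out, paste0("co_", bound$gene_id[i]))
  }

  if (n_extra > 0) {
    if (nrow(tss) == 0) stop("need TSS annotations to place decoys")
    k <- 0L
    tries <- 0L
    while (k < n_extra) {
      tries <- tries + 1L
      if (tries > 200L * n_extra) stop("could not place decoys away from truth peaks")
      g <- sample.int(nrow(tss), 1L)
      off <- round(stats::runif(1, -truth$region_upstream, truth$region_downstream))
      ctr <- tss$tss[g] + strand_sign(tss$strand[g]) * off
      dmin <- min_dist_to_positions(tss$chrom[g], ctr, bound$chrom, bound$center)
      if (dmin >= cooccupancy_dist && ctr - peak_halfwidth >= 0) {
        k <- k + 1L
        centers <- c(centers, as.integer(ctr))
        chroms <- c(chroms, tss$chrom[g])
        names_out <- c(names_out, paste0("decoy_", k))
      }
    }
  }

  list(
    intervals = data.frame(chrom = chroms,
                           start = as.integer(centers - peak_halfwidth),
                           end = as.integer(centers + peak_halfwidth),
                           name = names_out, stringsAsFactors = FALSE),
    cobound_genes = bound$gene_id[pick]
  )
}

#' Simulate a conserved-motif interval track
#'
#' Every gene in `enriched_genes` receives one `site_length`-bp site of
#' `enriched_motif` uniformly within +/- `flank` of its TSS; every promoter
#' additionally receives Poisson(`background_rate` x 2 flank / 1000)
#' background sites with motif ids drawn from a fixed decoy pool.
#'
#' @param tss TSS data.frame.
#' @param enriched_motif motif id planted in enriched genes.
#' @param enriched_genes gene ids receiving a planted site.
#' @param background_rate background sites per kb of promoter.
#' @param flank half-width of the promoter window used for placement, bp.
#' @param site_length site length, bp (10 in the emulated track).
#' @param seed integer RNG seed.
#' @return data.frame with chrom, start, end, motif_id.
#' @export
simulate_tfbs_track <- function(tss, enriched_motif = "V$ELK1_02",
                                enriched_genes = character(0),
                                background_rate = 0.5, flank = 2000L,
                                site_length = 10L, seed = NULL) {
  if (background_rate < 0) stop("background_rate must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  decoy_pool <- c("V$SP1_01", "V$E2F_02", "V$NFY_01", "V$STAT1_01",
                  "V$AP1_01", "V$CREB_02", "V$MYC_03", "V$NFKB_01")
  chroms <- character(0); starts <- integer(0); motifs <- character(0)
  for (i in seq_len(nrow(tss))) {
    lo <- max(0L, tss$tss[i] - flank)
    hi <- tss$tss[i] + flank - site_length
    if (tss$gene_id[i] %in% enriched_genes) {
      s <- as.integer(round(stats::runif(1, lo, hi)))
      chroms <- c(chroms, tss$chrom[i]); starts <- c(starts, s)
      motifs <- c(motifs, enriched_motif)
    }
    n_bg <- stats::rpois(1, background_rate * 2 * flank / 1000)
    if (n_bg > 0) {
      s <- as.integer(round(stats::runif(n_bg, lo, hi)))
      chroms <- c(chroms, rep(tss$chrom[i], n_bg))
      starts <- c(starts, s)
      motifs <- c(motifs, sample(decoy_pool, n_bg, replace = TRUE))
    }
  }
  data.frame(chrom = chroms, start = starts,
             end = starts + as.integer(site_length),
             motif_id = motifs, stringsAsFactors = FALSE)
}

#' Write / read synthetic truth as JSON
#'
#' @param truth a `synthetic_truth` object.
#' @param path output path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$bound) || length(x$bound) == 0) {
    x$bound <- data.frame(gene_id = character(0), chrom = character(0),
                          strand = character(0), tss = integer(0),
                          offset = integer(0), center = integer(0),
                          stringsAsFactors = FALSE)
  }
  x$cobound_genes <- as.character(x$cobound_genes)
  structure(x, class = "synthetic_truth")
}
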