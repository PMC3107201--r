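# Readers and writers for the on-disk formats the pipeline touches.
#
# Every coordinate on disk and in memory is 0-based half-open (BED
# convention); conversion to 1-based display happens only in messages.

#' Read a probe-level ratio table
#'
#' Reads a tab-delimited probe table with header columns
#' `chrom start end probe_id ratio_1..ratio_k` and optionally matching
#' `A_1..A_k` mean log2 intensity columns. One row per tiled probe; the
#' ratio columns hold per-replicate log2(IP/input) values.
#'
#' @param path path to a TSV file.
#' @return data.frame sorted by (chrom, start) with attribute
#'   `n_replicates`; columns as in the file.
#' @export
read_probe_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("chrom", "start", "end", "probe_id")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("probe table ", path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  rcols <- ratio_columns(df)
  if (nrow(df) > 0 && length(rcols) == 0) {
    stop("probe table ", path, " has no ratio_<k> columns")
  }
  for (cc in c("start", "end", rcols, intensity_columns(df))) {
    if (nrow(df) > 0 && !is.numeric(df[[cc]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cc]]))))[1]
      stop("probe table ", path, ": non-numeric value in column '", cc,
           "' at data line ", if (is.na(bad)) "?" else bad)
    }
  }
  validate_probe_table(df, path)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "n_replicates") <- length(rcols)
  df
}

validate_probe_table <- function(df, label = "probe table") {
  bad <- which(df$start >= df$end)
  if (length(bad) > 0) {
    stop(label, ": start >= end at data line ", bad[1],
         " (", df$chrom[bad[1]], ":", df$start[bad[1]], "-", df$end[bad[1]], ")")
  }
  len <- df$end - df$start
  odd <- len < 30 | len > 100
  if (any(odd)) {
    warning(label, ": ", sum(odd), " probe(s) outside the typical 30-100 bp length range")
  }
  invisible(df)
}

#' Write a probe-level ratio table
#'
#' Inverse of [read_probe_table()]; ratio and intensity values are written
#' with full precision so a write/read round trip is exact.
#'
#' @param probes probe data.frame.
#' @param path output path.
#' @export
write_probe_table <- function(probes, path) {
  out <- probes
  for (cc in c(ratio_columns(out), intensity_columns(out), "mean_ratio")) {
    if (cc %in% names(out)) out[[cc]] <- format(out[[cc]], digits = 17, trim = TRUE)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write called peaks as BED6
#'
#' Score is `round(-100 * log10(p))` clamped to \[0, 1000\]; strand is ".".
#' Coordinates are the 0-based half-open span of the three qualifying
#' windows, per the BED standard.
#'
#' @param peaks peak data.frame from [call_peaks()].
#' @param path output path.
#' @export
write_peaks_bed <- function(peaks, path) {
  if (nrow(peaks) == 0) {
    file.create(path)
    return(invisible(path))
  }
  score <- round(-100 * log10(peaks$p_value))
  score <- pmin(pmax(score, 0), 1000)
  name <- if ("name" %in% names(peaks)) peaks$name else
    sprintf("%s_%d", peaks$sign, seq_len(nrow(peaks)))
  bed <- data.frame(peaks$chrom, peaks$start, peaks$end, name, score, ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read BED intervals
#'
#' @param path BED file with >= 3 columns; a 4th column is taken as the name.
#' @return data.frame with columns chrom, start, end, name (0-based
#'   half-open; name "" when absent).
#' @export
read_bed_intervals <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- vapply(fields, length, integer(1))
  if (any(n_col < 3)) {
    stop("BED file ", path, ": fewer than 3 columns at line ", which(n_col < 3)[1])
  }
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3)))
  if (anyNA(start) || anyNA(end)) {
    stop("BED file ", path, ": non-integer coordinate at line ",
         which(is.na(start) | is.na(end))[1])
  }
  if (any(start >= end)) {
    stop("BED file ", path, ": start >= end at line ", which(start >= end)[1])
  }
  name <- vapply(fields, function(f) if (length(f) >= 4) f[[4]] else "", "")
  data.frame(chrom = vapply(fields, `[[`, "", 1), start = start, end = end,
             name = name, stringsAsFactors = FALSE)
}

#' Write BED intervals
#' @param intervals data.frame with chrom, start, end and optional name.
#' @param path output path.
#' @export
write_bed_intervals <- function(intervals, path) {
  cols <- intervals[, intersect(c("chrom", "start", "end", "name", "motif_id"),
                                names(intervals)), drop = FALSE]
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a TSS annotation table
#'
#' TSV with header `gene_id chrom strand tss`; one row per gene (multi-TSS
#' genes are expected to have been resolved to the most 5' site upstream of
#' this file).
#'
#' @param path input TSV.
#' @return data.frame with one row per gene.
#' @export
read_tss_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  required <- c("gene_id", "chrom", "strand", "tss")
  if (!all(required %in% names(df))) {
    stop("TSS table ", path, " must have columns: ", paste(required, collapse = ", "))
  }
  if (any(!df$strand %in% c("+", "-"))) {
    stop("TSS table ", path, ": strand must be '+' or '-' (line ",
         which(!df$strand %in% c("+", "-"))[1], ")")
  }
  if (anyDuplicated(df$gene_id)) {
    stop("TSS table ", path, ": duplicate gene_id '",
         df$gene_id[anyDuplicated(df$gene_id)], "'")
  }
  df
}

#' Write a TSS annotation table
#' @param tss TSS data.frame.
#' @param path output path.
#' @export
write_tss_table <- function(tss, path) {
  utils::write.table(tss[, c("gene_id", "chrom", "strand", "tss")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression call table
#'
#' TSV with header `gene_id signal_1..signal_k flag_1..flag_k`; flags are
#' Affymetrix-style detection calls in \{P, A, M\}.
#'
#' @param path input TSV.
#' @return data.frame, one row per gene.
#' @export
read_expression_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  sig <- grep("^signal_[0-9]+$", names(df), value = TRUE)
  flg <- grep("^flag_[0-9]+$", names(df), value = TRUE)
  if (!"gene_id" %in% names(df) || length(sig) == 0 || length(flg) != length(sig)) {
    stop("expression table ", path,
         " must have gene_id plus matching signal_<k>/flag_<k> columns")
  }
  flags <- unlist(df[flg], use.names = FALSE)
  if (any(!flags %in% c("P", "A", "M"))) {
    stop("expression table ", path, ": flag outside {P,A,M}: '",
         flags[!flags %in% c("P", "A", "M")][1], "'")
  }
  df
}

#' Write an expression call table
#' @param expr expression data.frame.
#' @param path output path.
#' @export
write_expression_table <- function(expr, path) {
  keep <- grep("^(gene_id|signal_[0-9]+|flag_[0-9]+)$", names(expr), value = TRUE)
  utils::write.table(expr[, keep], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a window table
#' @param windows window data.frame from [build_windows()].
#' @param path output path.
#' @export
write_window_table <- function(windows, path) {
  out <- windows
  out$mean <- format(out$mean, digits = 17, trim = TRUE)
  out$p_value <- format(out$p_value, digits = 17, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a window table
#' @param path TSV written by [write_window_table()].
#' @return window data.frame.
#' @export
read_window_table <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
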