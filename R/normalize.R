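# Normalization: per-array lowess detrending, between-array
# equal-sum-of-squares scaling, probe-wise replicate averaging.
# The pipeline order is fixed: lowess -> scale -> average.

#' Lowess-normalize each replicate array
#'
#' Fits a locally weighted regression of each replicate's log2 ratio on a
#' covariate and subtracts the fitted trend, removing intensity- (or
#' position-) dependent bias. The covariate defaults to the per-probe mean
#' log2 intensity A (standard MA-style normalization for two-color arrays);
#' `covariate = "position"` uses the probe midpoint instead for tables
#' without intensity columns.
#'
#' @param probes probe data.frame with ratio_<k> columns.
#' @param covariate "intensity" (A_<k> columns) or "position".
#' @param span lowess smoother span (fraction of points).
#' @param iterations robustness iterations.
#' @return probes with detrended ratio values and an updated provenance
#'   attribute.
#' @export
lowess_normalize <- function(probes, covariate = c("intensity", "position"),
                             span = 0.3, iterations = 3L) {
  covariate <- match.arg(covariate)
  if (!(span > 0 && span <= 1)) stop("span must lie in (0, 1]")
  rcols <- ratio_columns(probes)
  if (length(rcols) == 0) stop("no ratio_<k> columns to normalize")
  acols <- intensity_columns(probes)
  if (covariate == "intensity" && length(acols) != length(rcols)) {
    stop("covariate = \"intensity\" needs one A_<k> column per replicate; ",
         "use covariate = \"position\" for tables without intensities")
  }
  pos <- probe_midpoint(probes$start, probes$end)
  for (j in seq_along(rcols)) {
    x <- if (covariate == "intensity") probes[[acols[j]]] else pos
    y <- probes[[rcols[j]]]
    if (length(unique(x)) < 2L) next
    fit <- stats::lowess(x, y, f = span, iter = iterations)
    trend <- stats::approx(fit$x, fit$y, xout = x, rule = 2, ties = mean)$y
    probes[[rcols[j]]] <- y - trend
  }
  add_provenance(probes, sprintf("lowess(covariate=%s, span=%g, iter=%d)",
                                 covariate, span, iterations))
}

#' Scale replicate arrays to an equal sum of squares
#'
#' Each replicate j is multiplied by `sqrt(target / SSQ_j)` where the target
#' is the geometric mean of the replicate sums of squares, so all replicates
#' end with identical SSQ while the overall scale is preserved symmetrically.
#'
#' @param probes probe data.frame with ratio_<k> columns.
#' @return probes with scaled ratios and updated provenance.
#' @export
scale_equal_ssq <- function(probes) {
  rcols <- ratio_columns(probes)
  if (length(rcols) == 0) stop("no ratio_<k> columns to scale")
  ssq <- vapply(rcols, function(cc) sum(probes[[cc]]^2, na.rm = TRUE), 0)
  if (any(ssq == 0)) {
    stop("degenerate array: replicate ", which(ssq == 0)[1], " has zero sum of squares")
  }
  target <- exp(mean(log(ssq)))
  for (j in seq_along(rcols)) {
    probes[[rcols[j]]] <- probes[[rcols[j]]] * sqrt(target / ssq[j])
  }
  add_provenance(probes, "scale_equal_ssq")
}

#' Average replicates into a per-probe mean ratio
#'
#' Arithmetic mean across replicates with pairwise deletion of missing
#' values; a probe missing in every replicate gets an NA mean and is counted
#' in the `n_all_missing` attribute (flagged, not imputed).
#'
#' @param probes probe data.frame with ratio_<k> columns.
#' @return probes with an added `mean_ratio` column and updated provenance.
#' @export
average_replicates <- function(probes) {
  rcols <- ratio_columns(probes)
  if (length(rcols) == 0) stop("no ratio_<k> columns to average")
  m <- as.matrix(probes[, rcols, drop = FALSE])
  mean_ratio <- rowMeans(m, na.rm = TRUE)
  all_missing <- rowSums(!is.na(m)) == 0
  mean_ratio[all_missing] <- NA_real_
  if (any(all_missing)) {
    warning(sum(all_missing), " probe(s) missing in all replicates; mean set to NA")
  }
  probes$mean_ratio <- mean_ratio
  probes <- add_provenance(probes, "average_replicates")
  attr(probes, "n_all_missing") <- sum(all_missing)
  probes
}

#' Run the full normalization pipeline
#'
#' Fixed order: lowess detrending, equal-sum-of-squares scaling, replicate
#' averaging. Set `skip_lowess = TRUE` for data already detrended.
#'
#' @inheritParams lowess_normalize
#' @param skip_lowess skip the lowess step.
#' @return probes with normalized ratios and a `mean_ratio` column.
#' @export
normalize_probes <- function(probes, covariate = c("intensity", "position"),
                             span = 0.3, iterations = 3L, skip_lowess = FALSE) {
  if (!skip_lowess) {
    probes <- lowess_normalize(probes, covariate, span, iterations)
  }
  probes <- scale_equal_ssq(probes)
  average_replicates(probes)
}
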