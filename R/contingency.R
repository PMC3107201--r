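# 2x2 contingency analysis shared by four analyses: bound-gene enrichment,
# TSS-distance enrichment, co-occupancy, and TFBS bp enrichment.

#' 2x2 contingency result with fold enrichment and Fisher exact p
#'
#' The table is (a, b; c, d) with the first row the "test" class and the
#' first column the "positive" outcome. Fold enrichment is the rate ratio
#' (a/(a+b)) / (c/(c+d)), flagged NA when undefined (empty first row, empty
#' second row, or c = 0). The p-value is Fisher's exact test, two-sided
#' (sum of all tables at most as probable as the observed one) or one-sided
#' greater.
#'
#' @param a,b,c,d non-negative integer counts.
#' @param sided "two.sided" or "greater".
#' @return list of class `contingency_result`: table, fold_enrichment,
#'   p_value, sidedness.
#' @export
contingency_result <- function(a, b, c, d, sided = c("two.sided", "greater")) {
  sided <- match.arg(sided)
  counts <- c(a, b, c, d)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("contingency counts must be non-negative integers")
  }
  tab <- matrix(as.numeric(counts), nrow = 2, byrow = TRUE,
                dimnames = list(c("test", "reference"), c("yes", "no")))
  p <- if (sum(counts) == 0) 1 else
    stats::fisher.test(tab, alternative = sided)$p.value
  fold <- if ((a + b) == 0 || (c + d) == 0 || c == 0) NA_real_ else
    (a / (a + b)) / (c / (c + d))
  structure(list(table = tab, fold_enrichment = fold,
                 p_value = min(p, 1), sidedness = sided),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat("2x2 contingency result (", x$sidedness, " Fisher exact)\n", sep = "")
  print(x$table)
  cat(sprintf("fold enrichment: %s\n",
              if (is.na(x$fold_enrichment)) "undefined" else
                format(x$fold_enrichment, digits = 3)))
  cat(sprintf("p-value: %s\n", format(x$p_value, digits = 4)))
  invisible(x)
}
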