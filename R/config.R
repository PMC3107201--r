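# Run configuration: the numeric constants of the analysis in one place.

#' Analysis run configuration
#'
#' Bundles every tunable constant of the pipeline. Defaults are the
#' published analysis settings: a 1 kb error-model window moved in 250 bp
#' steps, at least six probes per window, a per-window one-sided Wilcoxon
#' p threshold of 0.016, 600 bp / 150 bp TSS-anchored heat-map windows over
#' the tiled promoter (-2200..+500 bp), a 1.5 kb co-occupancy radius and a
#' 2 kb TSS flank for binding-site enrichment.
#'
#' @param window_size error-model window width, bp.
#' @param window_step error-model window step, bp.
#' @param min_probes minimum probes for a window to seed a peak.
#' @param p_threshold per-window Wilcoxon p threshold.
#' @param heatmap_window TSS-anchored heat-map window width, bp.
#' @param heatmap_step heat-map window step, bp.
#' @param region_upstream tiled bp upstream of the TSS.
#' @param region_downstream tiled bp downstream of the TSS.
#' @param cooccupancy_dist co-occupancy distance threshold, bp.
#' @param tfbs_flank TSS flank for the TFBS training/background sets, bp.
#' @param rng_seed integer seed for the synthetic generators (or NULL).
#' @return a list of class `run_config`.
#' @export
run_config <- function(window_size = 1000L, window_step = 250L,
                       min_probes = 6L, p_threshold = 0.016,
                       heatmap_window = 600L, heatmap_step = 150L,
                       region_upstream = 2200L, region_downstream = 500L,
                       cooccupancy_dist = 1500L, tfbs_flank = 2000L,
                       rng_seed = NULL) {
  cfg <- list(window_size = as.integer(window_size),
              window_step = as.integer(window_step),
              min_probes = as.integer(min_probes),
              p_threshold = p_threshold,
              heatmap_window = as.integer(heatmap_window),
              heatmap_step = as.integer(heatmap_step),
              region_upstream = as.integer(region_upstream),
              region_downstream = as.integer(region_downstream),
              cooccupancy_dist = as.integer(cooccupancy_dist),
              tfbs_flank = as.integer(tfbs_flank),
              rng_seed = rng_seed)
  sizes <- c("window_size", "window_step", "min_probes", "heatmap_window",
             "heatmap_step", "region_upstream", "region_downstream",
             "cooccupancy_dist", "tfbs_flank")
  for (s in sizes) {
    if (is.na(cfg[[s]]) || cfg[[s]] <= 0) stop("run_config: ", s, " must be positive")
  }
  if (cfg$window_step > cfg$window_size) {
    stop("run_config: window_step must not exceed window_size")
  }
  if (cfg$heatmap_step > cfg$heatmap_window) {
    stop("run_config: heatmap_step must not exceed heatmap_window")
  }
  if (!(cfg$p_threshold > 0 && cfg$p_threshold < 1)) {
    stop("run_config: p_threshold must lie in (0, 1)")
  }
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' A flat key-value mapping; keys absent from the file keep their defaults,
#' and explicit arguments in `...` override the file.
#'
#' @param path YAML file, or NULL for pure defaults.
#' @param ... overrides passed to [run_config()].
#' @return a `run_config` object.
#' @export
read_run_config <- function(path = NULL, ...) {
  from_file <- if (is.null(path)) list() else yaml::read_yaml(path)
  known <- names(formals(run_config))
  overrides <- list(...)
  unknown <- setdiff(c(names(from_file), names(overrides)), known)
  if (length(unknown) > 0) {
    stop("config: unknown key(s): ", paste(unknown, collapse = ", "))
  }
  args <- utils::modifyList(from_file, overrides)
  do.call(run_config, args)
}

#' Write a run configuration to YAML
#' @param cfg a `run_config` object.
#' @param path output path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("chipwin run configuration\n")
  for (k in names(x)) {
    cat(sprintf("  %-18s %s\n", k, if (is.null(x[[k]])) "NULL" else format(x[[k]])))
  }
  invisible(x)
}
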