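#' Run the full break-centric DRIP-seq pipeline on synthetic data
#'
#' Convenience wrapper tying the modules together: generates cut sites and
#' fragment libraries for the four conditions (control/knockdown siRNA x
#' +/- cut induction) with `replicates` biological replicates each, computes
#' normalized coverage, window signal, per-site fold changes, classification,
#' the pre-existing-hybrid contrast and the per-arm correlations.
#'
#' @param cfg A [sim_config()].
#' @param replicates Biological replicates per condition (default 2).
#' @param window_bp Signal window half-width; defaults to `cfg$window_bp`.
#' @param eps Pseudocount for fold changes.
#' @param tau Classification threshold.
#' @return A list: `sites`, `quants` (classified site table joined with the
#'   planted annotations), `class_counts`, `accuracy` (fraction of sites
#'   receiving their planted class), `contrast_preexisting` (dependent <
#'   independent rank-sum), and `correlations` (both arms).
#' @export
#' @examples
#' \donttest{
#' res <- run_break_pipeline(sim_config(seed = 1), replicates = 1)
#' res$class_counts
#' }
run_break_pipeline <- function(cfg, replicates = 2, window_bp = NULL,
                               eps = 0.1, tau = 0.5) {
  stopifnot(inherits(cfg, "sim_config"))
  window_bp <- window_bp %||% cfg$window_bp
  sites <- make_break_sites(cfg)
  signals <- quantify_conditions(sites, cfg, replicates = replicates,
                                 window_bp = window_bp)
  quants <- site_fold_changes(signals, eps = eps) |>
    classify_sites(tau = tau) |>
    dplyr::left_join(
      sites[, c("site_id", "repair_class", "transcription_level",
                "preexisting_hybrid", "true_class")],
      by = "site_id"
    )
  counts <- table(factor(quants$class,
                         levels = c("dependent", "independent", "increased")))
  accuracy <- mean(quants$class == quants$true_class)
  contrast <- group_compare(quants, "class", "preexisting", "less")
  correlations <- dplyr::bind_rows(
    hybrid_correlation(quants, "ctrl"),
    hybrid_correlation(quants, "kd")
  )
  list(
    sites = sites,
    quants = quants,
    class_counts = counts,
    accuracy = accuracy,
    contrast_preexisting = contrast,
    correlations = correlations
  )
}

#' Window signal for every condition and replicate
#'
#' Simulates one fragment library per (siRNA arm, OHT state, replicate),
#' computes library-size-normalized coverage, and returns the long window
#' signal table that [site_fold_changes()] consumes.
#'
#' @inheritParams run_break_pipeline
#' @param sites A `break_sites` table from [make_break_sites()].
#' @return Long tibble: site_id, sirna, oht, replicate, signal.
#' @export
quantify_conditions <- function(sites, cfg, replicates = 2, window_bp = NULL) {
  window_bp <- window_bp %||% cfg$window_bp
  grid <- tidyr::expand_grid(
    sirna = c("ctrl", "kd"), oht = c("on", "off"),
    replicate = seq_len(replicates)
  )
  purrr::pmap(grid, function(sirna, oht, replicate) {
    lib <- simulate_fragment_library(sites, cfg, sirna, oht,
                                     replicate = replicate)
    track <- normalize_coverage(coverage_depth(lib))
    window_signal(track, sites, window_bp) |>
      dplyr::transmute(.data$site_id, sirna = sirna, oht = oht,
                       replicate = replicate, signal = .data$signal)
  }) |>
    dplyr::bind_rows()
}
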