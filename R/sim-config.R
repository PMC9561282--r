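#' Configuration for the synthetic DRIP-seq experiment generator
#'
#' Bundles every tunable of the simulator: the toy genome, the number of cut
#' sites and their annotation distributions, the count model for DRIP
#' fragments, and the sequencing depth per condition. The defaults describe
#' the experiment the downstream analysis was designed for: 99 frequently cut
#' restriction loci assayed by DRIP-seq in four conditions (control vs
#' knockdown siRNA, each with and without 4 h of cut induction), with a
#' planted composition of 40 knockdown-dependent, 51 independent and 8
#' increased sites and dependence coupled to low pre-existing hybrid levels.
#'
#' @param n_sites Number of cut sites (default 99).
#' @param genome Named numeric vector of contig lengths in bp.
#' @param window_bp Half-width (bp) of the signal window centred on each cut.
#' @param background_rate Expected background fragments per site window.
#' @param preexisting_meanlog,preexisting_sdlog Log-normal parameters of the
#'   per-site pre-existing hybrid level, on the expected-fragment-count scale.
#' @param coupling Downward shift (log units) applied to the pre-existing
#'   level of knockdown-dependent sites; 0 disables the coupling between
#'   dependence and hybrid-poor loci.
#' @param induction_fold Break-induced signal expressed as a multiple of each
#'   site's basal level (background + pre-existing); the realized per-site
#'   additive magnitude is jittered log-normally (`induction_jitter_sdlog`).
#' @param induction_jitter_sdlog Log-normal sd of the per-site induction jitter.
#' @param class_weights Named weights for the dependence classes
#'   (dependent / independent / increased); converted to exact counts by
#'   largest remainder so the default 99-site run plants 40/51/8.
#' @param knockdown_effect Multiplier applied to the induction of dependent
#'   sites under knockdown (default 0 = fully abolished).
#' @param increase_effect Multiplier applied to the induction of "increased"
#'   sites under knockdown (must exceed 1).
#' @param dispersion Negative-binomial overdispersion phi, with
#'   Var = mu + phi * mu^2; 0 gives Poisson counts.
#' @param fragment_length_mean,fragment_length_sd,fragment_length_min
#'   Truncated-normal sonication fragment length model (bp).
#' @param library_size Total fragments per simulated library. The default
#'   `NULL` ("auto") sizes each library as (nominal background over the
#'   window-free genome at `background_rate` density) + (realized site
#'   fragments), so background density is uniform genome-wide and libraries
#'   from signal-rich conditions are deeper — as in a real IP. A fixed number
#'   forces exactly that many fragments, with background as the top-up.
#' @param seed Base seed; every generator derives its stream from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_sites = 5, genome = c(chr1 = 2e5))
#' cfg$n_sites
sim_config <- function(n_sites = 99,
                       genome = c(chr1 = 4e6, chr2 = 3e6, chr3 = 2e6),
                       window_bp = 2000,
                       background_rate = 80,
                       preexisting_meanlog = log(150),
                       preexisting_sdlog = 0.5,
                       coupling = 1.2,
                       induction_fold = 4,
                       induction_jitter_sdlog = 0.3,
                       class_weights = c(dependent = 40, independent = 51, increased = 8),
                       knockdown_effect = 0,
                       increase_effect = 2.5,
                       dispersion = 0.002,
                       fragment_length_mean = 300,
                       fragment_length_sd = 100,
                       fragment_length_min = 50,
                       library_size = NULL,
                       seed = 17) {
  assert_scalar_number(n_sites, "n_sites", min = 1)
  if (!is.numeric(genome) || length(genome) < 1L || is.null(names(genome)) ||
      any(!nzchar(names(genome))) || any(genome <= 0)) {
    abort("`genome` must be a named numeric vector of positive contig lengths.")
  }
  if (anyDuplicated(names(genome))) abort("`genome` contig names must be unique.")
  assert_scalar_number(window_bp, "window_bp", min = 0, strict = TRUE)
  assert_scalar_number(background_rate, "background_rate", min = 0)
  assert_scalar_number(preexisting_sdlog, "preexisting_sdlog", min = 0)
  assert_scalar_number(coupling, "coupling", min = 0)
  assert_scalar_number(induction_fold, "induction_fold", min = 0)
  assert_scalar_number(induction_jitter_sdlog, "induction_jitter_sdlog", min = 0)
  assert_scalar_number(knockdown_effect, "knockdown_effect", min = 0)
  assert_scalar_number(increase_effect, "increase_effect", min = 1, strict = TRUE)
  assert_scalar_number(dispersion, "dispersion", min = 0)
  assert_scalar_number(fragment_length_min, "fragment_length_min", min = 1)
  if (!is.null(library_size)) {
    assert_scalar_number(library_size, "library_size", min = 1)
  }
  assert_scalar_number(seed, "seed")
  if (window_bp <= fragment_length_mean) {
    abort("`window_bp` must exceed `fragment_length_mean`.")
  }
  required <- c("dependent", "independent", "increased")
  if (!is.numeric(class_weights) || !setequal(names(class_weights), required) ||
      any(class_weights < 0) || sum(class_weights) <= 0) {
    abort("`class_weights` must be non-negative weights named dependent/independent/increased.")
  }

  structure(
    list(
      n_sites = as.integer(n_sites),
      genome = genome,
      window_bp = as.integer(window_bp),
      background_rate = background_rate,
      preexisting_meanlog = preexisting_meanlog,
      preexisting_sdlog = preexisting_sdlog,
      coupling = coupling,
      induction_fold = induction_fold,
      induction_jitter_sdlog = induction_jitter_sdlog,
      class_weights = class_weights[required],
      knockdown_effect = knockdown_effect,
      increase_effect = increase_effect,
      dispersion = dispersion,
      fragment_length_mean = fragment_length_mean,
      fragment_length_sd = fragment_length_sd,
      fragment_length_min = fragment_length_min,
      library_size = if (is.null(library_size)) NULL else as.integer(library_size),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  sites:", x$n_sites, "on", length(x$genome), "contig(s) (",
      sum(x$genome), "bp )\n")
  cat("  window:", x$window_bp, "bp; background", x$background_rate,
      "frags/window; induction fold", x$induction_fold, "\n")
  counts <- class_counts(x)
  cat("  planted classes:", paste(names(counts), counts, sep = "=", collapse = ", "), "\n")
  cat("  dispersion:", x$dispersion, "; library size:",
      if (is.null(x$library_size)) "auto" else x$library_size,
      "; seed:", x$seed, "\n")
  invisible(x)
}

# Exact per-class site counts by largest remainder, so the default 99-site
# configuration plants exactly 40/51/8.
class_counts <- function(cfg) {
  w <- cfg$class_weights / sum(cfg$class_weights)
  raw <- w * cfg$n_sites
  base <- floor(raw)
  left <- cfg$n_sites - sum(base)
  if (left > 0) {
    order_rem <- order(raw - base, decreasing = TRUE)
    base[order_rem[seq_len(left)]] <- base[order_rem[seq_len(left)]] + 1
  }
  setNames(as.integer(base), names(cfg$class_weights))
}
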