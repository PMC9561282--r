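#' Simulate a DRIP-seq fragment library for one condition
#'
#' Draws per-site fragment counts from a negative-binomial model and places
#' those fragments around each cut site, then scatters background fragments
#' over the rest of the genome so the library contains exactly
#' `cfg$library_size` fragments. The expected window count at site *i* is
#'
#' \deqn{\mu_i = background + preexisting_i + [oht = on] \times induction_i
#'   \times m(sirna, class_i)}
#'
#' where the knockdown multiplier *m* is 1 on the control arm and, under
#' knockdown, `knockdown_effect` (default 0) for dependent sites, 1 for
#' independent sites and `increase_effect` for increased sites. Counts are
#' negative-binomial with `Var = mu + dispersion * mu^2` (Poisson when
#' `dispersion = 0`). Fragment midpoints are uniform within the site window;
#' lengths are truncated-normal with floor `fragment_length_min`. Background
#' midpoints avoid site windows so the planted window expectation is exact.
#'
#' @param sites A `break_sites` table from [make_break_sites()].
#' @param cfg The [sim_config()] used to generate `sites`.
#' @param sirna `"ctrl"` or `"kd"`.
#' @param oht `"on"` (damaged, +OHT 4 h) or `"off"` (undamaged).
#' @param replicate Biological replicate index (changes the random stream).
#' @return A `fragment_library`: a tibble (chrom, start, end; 0-based
#'   half-open, sorted) with attributes `sample_id`, `condition`,
#'   `library_size` and `genome`.
#' @export
#' @examples
#' cfg <- sim_config(n_sites = 3, genome = c(chr1 = 1e5), library_size = 2000)
#' lib <- simulate_fragment_library(make_break_sites(cfg), cfg, "ctrl", "on")
#' nrow(lib)
simulate_fragment_library <- function(sites, cfg, sirna = c("ctrl", "kd"),
                                      oht = c("on", "off"), replicate = 1L) {
  sirna <- rlang::arg_match(sirna)
  oht <- rlang::arg_match(oht)
  simulate_library_impl(sites, cfg, sirna, oht,
                        rnaseh = FALSE, residual = 1, replicate = replicate)
}

#' Simulate an RNase-H-pretreated control library
#'
#' As [simulate_fragment_library()], but the hybrid-derived signal
#' (pre-existing plus induced) is multiplied by `residual` (default 0:
#' complete nuclease sensitivity) while background is retained, emulating the
#' RNase-H pre-treatment control that verifies DRIP signal comes from
#' DNA:RNA hybrids. `residual = 1` reproduces the untreated library exactly
#' (same random stream).
#'
#' @inheritParams simulate_fragment_library
#' @param residual Fraction of hybrid signal surviving treatment, in \[0, 1\].
#' @return A `fragment_library`.
#' @export
simulate_rnaseh_library <- function(sites, cfg, sirna = c("ctrl", "kd"),
                                    oht = c("on", "off"), residual = 0,
                                    replicate = 1L) {
  sirna <- rlang::arg_match(sirna)
  oht <- rlang::arg_match(oht)
  assert_scalar_number(residual, "residual", min = 0)
  if (residual > 1) abort("`residual` must be in [0, 1].")
  simulate_library_impl(sites, cfg, sirna, oht,
                        rnaseh = TRUE, residual = residual, replicate = replicate)
}

simulate_library_impl <- function(sites, cfg, sirna, oht, rnaseh, residual,
                                  replicate) {
  stopifnot(inherits(cfg, "sim_config"))
  assert_data_frame(sites, "sites",
                    c("site_id", "chrom", "cut_pos", "preexisting_hybrid",
                      "true_class", "induction_magnitude"))

  mult <- dep_multiplier(sirna, sites$true_class, cfg)
  induced <- if (oht == "on") sites$induction_magnitude * mult else 0
  hybrid <- residual * (sites$preexisting_hybrid + induced)
  mu <- cfg$background_rate + hybrid

  # The RNase-H flag does not shift the stream: a residual of 1 reproduces
  # the untreated library of the same condition exactly.
  cond_code <- (sirna == "kd") * 1L + (oht == "on") * 2L
  seed <- child_seed(cfg$seed, 10L + cond_code + 4L * (as.integer(replicate) - 1L))

  with_seed(seed, {
    counts <- draw_counts(mu, cfg$dispersion)
    n_site <- sum(counts)
    if (is.null(cfg$library_size)) {
      # auto depth: background at `background_rate` density over the
      # window-free genome, so coverage density is uniform genome-wide
      free_bp <- sum(cfg$genome) - nrow(sites) * 2 * cfg$window_bp
      n_bg <- as.integer(round(
        cfg$background_rate * free_bp / (2 * cfg$window_bp)
      ))
      lib_size <- n_site + n_bg
    } else {
      lib_size <- cfg$library_size
      if (n_site > lib_size) {
        abort(paste0(
          "Site fragments (", n_site, ") exceed library_size (",
          lib_size, "); increase `library_size`."
        ))
      }
      n_bg <- lib_size - n_site
    }

    # Site-proximal fragments: midpoints uniform in [cut - W, cut + W).
    idx <- rep.int(seq_len(nrow(sites)), counts)
    mids <- sites$cut_pos[idx] + floor(runif(n_site, -cfg$window_bp, cfg$window_bp))
    lens <- rtrunc_lengths(n_site, cfg)
    site_frags <- tibble::tibble(
      chrom = sites$chrom[idx],
      start = pmax(0, mids - lens %/% 2L)
    )
    site_frags$end <- pmin(site_frags$start + lens,
                           unname(cfg$genome[site_frags$chrom]))

    # Background fragments: midpoints uniform over the genome excluding site
    # windows (window signal stays exactly the planted expectation).
    bg <- scatter_background(n_bg, sites, cfg)

    frags <- dplyr::bind_rows(site_frags, bg) |>
      dplyr::arrange(.data$chrom, .data$start, .data$end)

    new_fragment_library(
      frags,
      sample_id = paste0("sim_", sirna, "_oht-", oht,
                         if (rnaseh) "_rnaseh" else "", "_rep", replicate),
      condition = list(sirna = sirna, oht = oht, rnaseh = rnaseh,
                       replicate = as.integer(replicate)),
      genome = cfg$genome
    )
  })
}

dep_multiplier <- function(sirna, true_class, cfg) {
  if (sirna == "ctrl") {
    rep(1, length(true_class))
  } else {
    dplyr::case_match(
      true_class,
      "dependent" ~ cfg$knockdown_effect,
      "independent" ~ 1,
      "increased" ~ cfg$increase_effect
    )
  }
}

draw_counts <- function(mu, dispersion) {
  n <- length(mu)
  if (dispersion <= 0) {
    rpois(n, mu)
  } else {
    rnbinom(n, mu = mu, size = 1 / dispersion)
  }
}

# Truncated-normal fragment lengths via inverse-CDF sampling.
rtrunc_lengths <- function(n, cfg) {
  if (n == 0L) return(integer())
  p_lo <- pnorm(cfg$fragment_length_min, cfg$fragment_length_mean,
                cfg$fragment_length_sd)
  q <- qnorm(runif(n, p_lo, 1), cfg$fragment_length_mean, cfg$fragment_length_sd)
  as.integer(round(pmax(q, cfg$fragment_length_min)))
}

# Uniform midpoints over the complement of the site windows, length-weighted
# across the allowed intervals of every contig.
scatter_background <- function(n, sites, cfg) {
  if (n == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer()))
  }
  allowed <- purrr::map(names(cfg$genome), function(chrom) {
    len <- cfg$genome[[chrom]]
    cuts <- sort(sites$cut_pos[sites$chrom == chrom])
    lo <- c(0, pmin(cuts + cfg$window_bp, len))
    hi <- c(pmax(cuts - cfg$window_bp, 0), len)
    keep <- hi > lo
    tibble::tibble(chrom = chrom, lo = lo[keep], hi = hi[keep])
  }) |> dplyr::bind_rows()
  widths <- allowed$hi - allowed$lo
  pick <- sample.int(nrow(allowed), n, replace = TRUE, prob = widths)
  mids <- floor(allowed$lo[pick] + runif(n) * widths[pick])
  lens <- rtrunc_lengths(n, cfg)
  out <- tibble::tibble(
    chrom = allowed$chrom[pick],
    start = pmax(0, mids - lens %/% 2L)
  )
  out$end <- pmin(out$start + lens, unname(cfg$genome[out$chrom]))
  out
}

new_fragment_library <- function(frags, sample_id, condition, genome = NULL) {
  frags <- tibble::as_tibble(frags)
  structure(
    frags,
    sample_id = sample_id,
    condition = condition,
    library_size = nrow(frags),
    genome = genome,
    class = c("fragment_library", class(tibble::tibble()))
  )
}

#' Total fragments in a library
#'
#' @param lib A `fragment_library`.
#' @return Integer library size (equal to the number of fragments).
#' @export
library_size <- function(lib) {
  attr(lib, "library_size") %||% nrow(lib)
}
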