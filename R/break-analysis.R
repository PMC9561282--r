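#' Mean signal in windows around cut sites
#'
#' Averages a coverage track over `[cut_pos - window_bp, cut_pos + window_bp)`
#' for every site. Windows extending past a contig edge are clipped, and the
#' mean is taken over the in-bounds width actually used. Bases not covered by
#' any run count as zero.
#'
#' @param track A `coverage_track` (normally library-size normalized).
#' @param sites A data frame with `site_id`, `chrom`, `cut_pos`.
#' @param window_bp Window half-width W in bp (> 0).
#' @return A tibble (site_id, chrom, cut_pos, signal, width) with one row per
#'   site; `width` is the clipped window width used.
#' @export
window_signal <- function(track, sites, window_bp = 2000) {
  stopifnot(inherits(track, "coverage_track"))
  assert_data_frame(sites, "sites", c("site_id", "chrom", "cut_pos"))
  assert_scalar_number(window_bp, "window_bp", min = 0, strict = TRUE)
  genome <- attr(track, "genome")

  sums <- window_sums(track, sites$chrom, sites$cut_pos - window_bp,
                      sites$cut_pos + window_bp, genome)
  tibble::tibble(
    site_id = sites$site_id,
    chrom = sites$chrom,
    cut_pos = sites$cut_pos,
    signal = sums$total / sums$width,
    width = sums$width
  )
}

# Weighted coverage mass in [lo, hi) per query, clipped to contig bounds.
window_sums <- function(track, chroms, lo, hi, genome = NULL) {
  runs <- tibble::as_tibble(track)
  lo <- pmax(lo, 0)
  if (!is.null(genome)) {
    len <- unname(genome[chroms])
    if (anyNA(len)) abort("Site contig absent from track genome.")
    hi <- pmin(hi, len)
  }
  if (any(hi <= lo)) abort("Window entirely out of contig bounds.")

  total <- numeric(length(chroms))
  for (chrom in unique(chroms)) {
    r <- runs[runs$chrom == chrom, , drop = FALSE]
    qi <- which(chroms == chrom)
    if (nrow(r) == 0L) next
    cum <- c(0, cumsum(r$value * (r$end - r$start)))
    integral <- function(x) {
      i <- findInterval(x, r$start)
      ii <- pmax(i, 1L)  # safe index; masked out below where i == 0
      full <- cum[ii] +
        r$value[ii] * pmax(0, pmin(x, r$end[ii]) - r$start[ii])
      ifelse(i == 0L, 0, full)
    }
    total[qi] <- integral(hi[qi]) - integral(lo[qi])
  }
  list(total = total, width = hi - lo)
}

#' Per-site damaged/undamaged log2 fold changes and deviation score
#'
#' From per-condition window signals, computes for each site the damaged over
#' undamaged log2 fold change on each siRNA arm,
#' \deqn{log2FC_{arm} = \log_2\frac{m_{arm,+OHT} + \epsilon}
#'   {m_{arm,-OHT} + \epsilon},}
#' the deviation from the identity line \eqn{\Delta = log2FC_{kd} -
#' log2FC_{ctrl}}, and the pre-existing hybrid level (the control-arm
#' undamaged signal). Biological replicates are averaged as the mean of
#' per-replicate log2 fold changes, and the pre-existing level as the mean of
#' the per-replicate undamaged signals.
#'
#' @param signals Long tibble with columns `site_id`, `sirna` (ctrl/kd),
#'   `oht` (on/off), `replicate`, `signal` — e.g. stacked [window_signal()]
#'   results.
#' @param eps Pseudocount added to numerator and denominator (normalized
#'   units). `eps = 0` raises an error naming the first site whose
#'   denominator is zero.
#' @return A `site_quant` tibble: site_id, mean signal per condition
#'   (`m_ctrl_off`, `m_ctrl_on`, `m_kd_off`, `m_kd_on`), `log2fc_ctrl`,
#'   `log2fc_kd`, `delta`, `preexisting`.
#' @export
site_fold_changes <- function(signals, eps = 0.1) {
  assert_data_frame(signals, "signals",
                    c("site_id", "sirna", "oht", "signal"))
  assert_scalar_number(eps, "eps", min = 0)
  if (!all(signals$sirna %in% c("ctrl", "kd"))) {
    abort("`sirna` must be 'ctrl' or 'kd'.")
  }
  if (!all(signals$oht %in% c("on", "off"))) {
    abort("`oht` must be 'on' or 'off'.")
  }
  if (!"replicate" %in% names(signals)) signals$replicate <- 1L

  combos <- signals |>
    dplyr::count(.data$site_id, .data$sirna, .data$oht, .data$replicate) |>
    dplyr::filter(.data$n > 1)
  if (nrow(combos) > 0) {
    abort("Duplicate (site, condition, replicate) rows in `signals`.")
  }
  wide <- signals |>
    tidyr::pivot_wider(
      id_cols = c("site_id", "replicate"),
      names_from = c("sirna", "oht"), values_from = "signal",
      names_glue = "m_{sirna}_{oht}"
    )
  needed <- c("m_ctrl_off", "m_ctrl_on", "m_kd_off", "m_kd_on")
  missing <- setdiff(needed, names(wide))
  if (length(missing) || anyNA(wide[needed])) {
    abort("All four conditions (ctrl/kd x on/off) are required per site.")
  }
  if (eps == 0) {
    zero <- wide$site_id[wide$m_ctrl_off == 0 | wide$m_kd_off == 0]
    if (length(zero)) {
      abort(paste0("Fold change undefined with eps = 0: zero undamaged ",
                   "signal at site '", zero[1], "'."))
    }
  }
  wide |>
    dplyr::mutate(
      log2fc_ctrl = log2((.data$m_ctrl_on + eps) / (.data$m_ctrl_off + eps)),
      log2fc_kd = log2((.data$m_kd_on + eps) / (.data$m_kd_off + eps))
    ) |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(needed), mean),
      log2fc_ctrl = mean(.data$log2fc_ctrl),
      log2fc_kd = mean(.data$log2fc_kd),
      n_replicates = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      delta = .data$log2fc_kd - .data$log2fc_ctrl,
      preexisting = .data$m_ctrl_off
    )
}

#' Classify sites by deviation from the identity line
#'
#' A site whose knockdown-arm fold change deviates from the control-arm fold
#' change by less than `-tau` log2 units is knockdown-**dependent**; deviation
#' greater than `+tau` is **increased**; everything in between (including ties
#' at exactly +/- tau) is **independent**. The rule uses only the deviation
#' `delta`, so it is invariant to rescaling all four condition signals of a
#' site by a common factor.
#'
#' @param quants A `site_quant` tibble from [site_fold_changes()] (any data
#'   frame with a finite `delta` column works).
#' @param tau Deviation threshold in log2 units (default 0.5).
#' @return `quants` with a `class` column
#'   (`dependent`/`independent`/`increased`).
#' @export
#' @examples
#' classify_sites(tibble::tibble(site_id = "s", delta = -1.2))$class
classify_sites <- function(quants, tau = 0.5) {
  assert_data_frame(quants, "quants", "delta")
  assert_scalar_number(tau, "tau", min = 0)
  if (any(!is.finite(quants$delta))) abort("`delta` must be finite for all sites.")
  out <- dplyr::mutate(
    tibble::as_tibble(quants),
    class = dplyr::case_when(
      .data$delta < -tau ~ "dependent",
      .data$delta > tau ~ "increased",
      TRUE ~ "independent"
    )
  )
  structure(out, tau = tau,
            class = c("site_classification", class(tibble::tibble())))
}

#' Break-centred metagene of damaged/undamaged log2 fold change
#'
#' Tiles `[-span, +span)` around each cut site into `bin_width`-bp bins,
#' averages the damaged and undamaged coverage per site per bin, forms the
#' per-site per-bin `log2((damaged + eps) / (undamaged + eps))`, and averages
#' across sites per bin. Sites whose window runs off the contig are excluded
#' from the affected bins and the per-bin contributing count is recorded.
#'
#' @param track_damaged,track_undamaged Normalized `coverage_track`s for the
#'   +OHT and -OHT conditions of one siRNA arm.
#' @param sites Site table (`site_id`, `chrom`, `cut_pos`).
#' @param span Profile half-width in bp; must be a multiple of `bin_width`.
#' @param bin_width Bin size in bp.
#' @param eps Pseudocount (normalized units).
#' @return A `metagene_profile` tibble: `bin_center` (bp from the cut),
#'   `mean_log2fc`, `n_sites`.
#' @export
metagene_profile <- function(track_damaged, track_undamaged, sites,
                             span = 5000, bin_width = 100, eps = 0.1) {
  stopifnot(inherits(track_damaged, "coverage_track"),
            inherits(track_undamaged, "coverage_track"))
  assert_scalar_number(span, "span", min = 0, strict = TRUE)
  assert_scalar_number(bin_width, "bin_width", min = 0, strict = TRUE)
  if (span %% bin_width != 0) abort("`span` must be a multiple of `bin_width`.")
  assert_data_frame(sites, "sites", c("site_id", "chrom", "cut_pos"))

  offsets <- seq(-span, span - bin_width, by = bin_width)
  genome <- attr(track_damaged, "genome") %||% attr(track_undamaged, "genome")

  grid <- tidyr::expand_grid(
    sites[, c("site_id", "chrom", "cut_pos")],
    offset = offsets
  ) |>
    dplyr::mutate(lo = .data$cut_pos + .data$offset,
                  hi = .data$cut_pos + .data$offset + bin_width)
  # drop site/bin pairs that fall off the contig
  if (!is.null(genome)) {
    len <- unname(genome[grid$chrom])
    keep <- grid$lo >= 0 & grid$hi <= len
  } else {
    keep <- grid$lo >= 0
  }
  grid <- grid[keep, , drop = FALSE]

  dmg <- window_sums(track_damaged, grid$chrom, grid$lo, grid$hi, genome)
  und <- window_sums(track_undamaged, grid$chrom, grid$lo, grid$hi, genome)
  grid$log2fc <- log2((dmg$total / dmg$width + eps) /
                        (und$total / und$width + eps))

  profile <- grid |>
    dplyr::group_by(.data$offset) |>
    dplyr::summarise(mean_log2fc = mean(.data$log2fc),
                     n_sites = dplyr::n(), .groups = "drop") |>
    dplyr::transmute(bin_center = .data$offset + bin_width / 2,
                     mean_log2fc = .data$mean_log2fc,
                     n_sites = .data$n_sites)
  structure(profile,
            span = span, bin_width = bin_width,
            class = c("metagene_profile", class(tibble::tibble())))
}

#' Directional rank-sum contrast between site groups
#'
#' Compares a per-site variable between two groups of sites with the one-sided
#' Mann-Whitney test of [wilcoxon_one_sided()]. Groupings: `"class"` compares
#' dependent vs independent sites; `"repair"` compares HR vs NHEJ;
#' `"transcription"` splits sites at the median transcription level into high
#' vs low. `direction = "less"` tests that group 1 is shifted below group 2.
#' No multiple-testing correction is applied across contrasts; p-values are
#' per test.
#'
#' @param quants Classified site table (needs the grouping columns and the
#'   variable).
#' @param grouping One of `"class"`, `"repair"`, `"transcription"`.
#' @param variable Column to compare, e.g. `"preexisting"`,
#'   `"transcription_level"`, `"delta"`, `"log2fc_ctrl"`, `"log2fc_kd"`.
#' @param direction `"less"` or `"greater"` (group 1 vs group 2).
#' @return A one-row tibble: groups, sizes, medians, U statistic, one-sided
#'   p-value and method.
#' @export
group_compare <- function(quants,
                          grouping = c("class", "repair", "transcription"),
                          variable,
                          direction = c("less", "greater")) {
  grouping <- rlang::arg_match(grouping)
  direction <- rlang::arg_match(direction)
  assert_data_frame(quants, "quants", variable)

  groups <- switch(grouping,
    class = {
      assert_data_frame(quants, "quants", "class")
      list(g1 = quants[quants$class == "dependent", ],
           g2 = quants[quants$class == "independent", ],
           labels = c("dependent", "independent"))
    },
    repair = {
      assert_data_frame(quants, "quants", "repair_class")
      list(g1 = quants[quants$repair_class == "HR", ],
           g2 = quants[quants$repair_class == "NHEJ", ],
           labels = c("HR", "NHEJ"))
    },
    transcription = {
      assert_data_frame(quants, "quants", "transcription_level")
      cut <- median(quants$transcription_level)
      list(g1 = quants[quants$transcription_level > cut, ],
           g2 = quants[quants$transcription_level <= cut, ],
           labels = c("high_transcription", "low_transcription"))
    }
  )
  x <- groups$g1[[variable]]
  y <- groups$g2[[variable]]
  if (length(x) == 0L || length(y) == 0L) {
    abort(paste0("Empty group in '", grouping, "' contrast."))
  }
  res <- wilcoxon_one_sided(x, y, direction = direction)
  tibble::tibble(
    grouping = grouping,
    variable = variable,
    direction = direction,
    group1 = groups$labels[1],
    group2 = groups$labels[2],
    n1 = length(x),
    n2 = length(y),
    median1 = median(x),
    median2 = median(y),
    statistic = unname(res$statistic),
    p_value = res$p.value,
    method = res$method
  )
}

#' Correlation between pre-existing hybrid level and induced fold change
#'
#' Pearson correlation, across sites, of the pre-existing hybrid level
#' (undamaged control-arm signal) with the damaged/undamaged log2 fold change
#' of the requested siRNA arm. The signature pattern this detects is a
#' correlation that is absent on the control arm but positive and significant
#' on the knockdown arm: without the helicase, break-induced hybrid formation falls
#' back on each locus's innate propensity to form hybrids.
#'
#' @param quants A `site_quant` tibble.
#' @param arm `"ctrl"` or `"kd"`.
#' @return A one-row tibble: arm, n, r, t statistic, df, two-sided p-value.
#' @export
hybrid_correlation <- function(quants, arm = c("ctrl", "kd")) {
  arm <- rlang::arg_match(arm)
  col <- paste0("log2fc_", arm)
  assert_data_frame(quants, "quants", c("preexisting", col))
  x <- quants$preexisting
  y <- quants[[col]]
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) abort("Need >= 3 sites with finite values.")
  res <- pearson_test(x[ok], y[ok])
  tibble::tibble(
    arm = arm,
    n = sum(ok),
    r = unname(res$estimate),
    statistic = unname(res$statistic),
    df = res$parameter,
    p_value = res$p.value
  )
}
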