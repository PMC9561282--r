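#' Percent input from paired IP / input wells
#'
#' The input fraction is a dilution `D` of the IP material, so the input Ct is
#' first adjusted by the dilution: `Ct' = Ct_input - log2(1/D)`. Enrichment is
#' then `%input = 100 * 2^(Ct' - Ct_IP)`: equal adjusted Cts mean 100%, one
#' cycle of difference halves it. A common Ct shift of all wells (machine
#' baseline) cancels.
#'
#' @param plate Long Ct tibble with a `fraction` column containing `"IP"` and
#'   `"input"` rows plus `ct`; all remaining columns (target, condition
#'   labels, replicate) define the pairing.
#' @param dilution Input dilution factor D in (0, 1]; no default — it must be
#'   known from the experiment.
#' @return The pairing columns plus `pct_input`, one row per IP/input pair.
#' @export
#' @examples
#' plate <- tibble::tibble(
#'   target = "dsb1", replicate = 1,
#'   fraction = c("IP", "input"), ct = c(25, 25 - log2(1 / 0.1))
#' )
#' percent_input(plate, dilution = 0.1)$pct_input  # 100
percent_input <- function(plate, dilution) {
  assert_data_frame(plate, "plate", c("fraction", "ct"))
  assert_scalar_number(dilution, "dilution", min = 0, strict = TRUE)
  if (dilution > 1) abort("`dilution` must be in (0, 1].")
  if (!all(c("IP", "input") %in% plate$fraction)) {
    abort("`plate` must contain both 'IP' and 'input' fractions.")
  }
  wide <- plate |>
    tibble::as_tibble() |>
    dplyr::filter(.data$fraction %in% c("IP", "input")) |>
    tidyr::pivot_wider(names_from = "fraction", values_from = "ct")
  if (anyNA(wide$IP) || anyNA(wide$input)) {
    abort("Unpaired wells: every (target, condition, replicate) needs one IP and one input Ct.")
  }
  wide |>
    dplyr::mutate(
      pct_input = 100 * 2^((.data$input - log2(1 / dilution)) - .data$IP)
    ) |>
    dplyr::select(-"IP", -"input")
}

#' DRIP-qPCR damaged/undamaged fold change with paired t-test
#'
#' Computes percent input for every well, then for each target (and RNase-H
#' channel, if present) forms the per-replicate fold change
#' `%input(+OHT) / %input(-OHT)`, pairing replicates, and reports the mean
#' fold change, its SEM, and a paired t-test of the per-replicate +OHT vs
#' -OHT percent-input values. RNase-H-treated wells are summarised as a
#' separate control channel (expected fold change near 1: DRIP signal is
#' hybrid-derived).
#'
#' @param plate Long Ct tibble with columns `target`, `oht` ("on"/"off"),
#'   `fraction` ("IP"/"input"), `replicate`, `ct`, and optionally `rnaseh`
#'   (logical) and other condition labels.
#' @param dilution Input dilution factor D, passed to [percent_input()].
#' @param alternative Sidedness of the paired t-test (two-sided by default).
#' @return A tibble with one row per target (x RNase-H channel): n replicates,
#'   `mean_fc`, `sem_fc`, t statistic, df and p-value.
#' @export
drip_fold_change <- function(plate, dilution,
                             alternative = c("two.sided", "less", "greater")) {
  alternative <- rlang::arg_match(alternative)
  assert_data_frame(plate, "plate", c("target", "oht", "fraction", "replicate", "ct"))
  if (!"rnaseh" %in% names(plate)) plate$rnaseh <- FALSE
  pct <- percent_input(plate, dilution)
  wide <- pct |>
    tidyr::pivot_wider(names_from = "oht", values_from = "pct_input",
                       names_prefix = "oht_")
  if (!all(c("oht_on", "oht_off") %in% names(wide)) ||
      anyNA(wide$oht_on) || anyNA(wide$oht_off)) {
    abort("Unpaired replicates: every replicate needs both +OHT and -OHT wells.")
  }
  wide |>
    dplyr::group_by(.data$target, .data$rnaseh) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 2L) {
        abort(paste0("Need >= 2 paired replicates for target '",
                     key$target[[1]], "'."))
      }
      fc <- df$oht_on / df$oht_off
      d <- df$oht_on - df$oht_off
      if (stats::sd(d) == 0 && mean(d) != 0) {
        # noise-free plates: a constant non-zero shift has no within-pair
        # variance, so the t statistic is undefined
        stat <- NA_real_; dfree <- NA_real_; p <- NA_real_
      } else {
        tt <- paired_t(df$oht_on, df$oht_off, alternative = alternative)
        stat <- unname(tt$statistic); dfree <- tt$parameter; p <- tt$p.value
      }
      tibble::tibble(
        n = nrow(df),
        mean_fc = mean(fc),
        sem_fc = stats::sd(fc) / sqrt(length(fc)),
        statistic = stat,
        df = dfree,
        p_value = p
      )
    }) |>
    dplyr::ungroup()
}

#' Resection ssDNA quantification from restriction-protection qPCR
#'
#' At a resected break the 5'->3' processed strand is single-stranded, so a
#' restriction site within it escapes digestion. With `dCt = Ct_digested -
#' Ct_undigested`, the single-stranded fraction is
#' \deqn{ssDNA\% = 100 / (2^{dCt - 1} + 0.5).}
#' Fully protected template (dCt = 0) gives 100%; dsDNA (large dCt) tends to
#' 0%. dCt below -0.5 is biologically inconsistent (digestion increased the
#' template) and is flagged, with the value still reported.
#'
#' @param plate Long Ct tibble with a `fraction` column containing
#'   `"digested"` and `"undigested"` rows plus `ct`; remaining columns
#'   (target/site, condition labels, replicate) define the pairing.
#' @param tolerance Negative-dCt tolerance before flagging (default 0.5).
#' @return Pairing columns plus `delta_ct`, `ssdna_pct` and `flag_inconsistent`.
#' @export
#' @examples
#' plate <- tibble::tibble(
#'   target = "dsb1_200bp", replicate = 1,
#'   fraction = c("digested", "undigested"), ct = c(26, 25)
#' )
#' resection_ssdna(plate)$ssdna_pct  # 66.67
resection_ssdna <- function(plate, tolerance = 0.5) {
  assert_data_frame(plate, "plate", c("fraction", "ct"))
  if (!all(c("digested", "undigested") %in% plate$fraction)) {
    abort("`plate` must contain both 'digested' and 'undigested' fractions.")
  }
  wide <- plate |>
    tibble::as_tibble() |>
    dplyr::filter(.data$fraction %in% c("digested", "undigested")) |>
    tidyr::pivot_wider(names_from = "fraction", values_from = "ct")
  if (anyNA(wide$digested) || anyNA(wide$undigested)) {
    abort("Unpaired wells: every replicate needs digested and undigested Cts.")
  }
  out <- wide |>
    dplyr::mutate(
      delta_ct = .data$digested - .data$undigested,
      ssdna_pct = 100 / (2^(.data$delta_ct - 1) + 0.5),
      flag_inconsistent = .data$delta_ct < -tolerance
    ) |>
    dplyr::select(-"digested", -"undigested")
  if (any(out$flag_inconsistent)) {
    warn(paste0(sum(out$flag_inconsistent),
                " well pair(s) have dCt < -", tolerance,
                " (digestion increased signal); flagged."))
  }
  out
}

#' Paired comparison of resection between two conditions
#'
#' Pairs per-replicate ssDNA percentages between the two levels of `by`
#' (e.g. control vs knockdown siRNA) and applies [paired_t()], per target.
#'
#' @param ssdna Output of [resection_ssdna()].
#' @param by Column with exactly two levels to contrast.
#' @param alternative Test sidedness for (level1 - level2).
#' @return One row per target: levels, n pairs, means, t, df, p-value.
#' @export
compare_resection <- function(ssdna, by = "sirna",
                              alternative = c("two.sided", "less", "greater")) {
  alternative <- rlang::arg_match(alternative)
  assert_data_frame(ssdna, "ssdna", c("target", by, "replicate", "ssdna_pct"))
  levels <- sort(unique(ssdna[[by]]))
  if (length(levels) != 2L) {
    abort(paste0("`", by, "` must have exactly two levels."))
  }
  ssdna |>
    dplyr::group_by(.data$target) |>
    dplyr::group_modify(function(df, key) {
      wide <- tidyr::pivot_wider(df, id_cols = "replicate",
                                 names_from = dplyr::all_of(by),
                                 values_from = "ssdna_pct")
      a <- wide[[levels[1]]]; b <- wide[[levels[2]]]
      if (anyNA(a) || anyNA(b)) abort("Unpaired replicates across conditions.")
      tt <- paired_t(a, b, alternative = alternative)
      tibble::tibble(
        level1 = levels[1], level2 = levels[2], n = length(a),
        mean1 = mean(a), mean2 = mean(b),
        statistic = unname(tt$statistic), df = tt$parameter,
        p_value = tt$p.value
      )
    }) |>
    dplyr::ungroup()
}
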