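#' Simulate a qPCR plate from known template abundances
#'
#' Converts known (planted) template abundances into cycle-threshold values
#' under the standard exponential amplification model:
#' \deqn{Ct = baseline - \log_{E}(abundance) + N(0, noise\_sd)}
#' with amplification efficiency *E* (2 = perfect doubling). Doubling the
#' template therefore lowers Ct by exactly one cycle at `efficiency = 2` and
#' `noise_sd = 0`.
#'
#' @param abundances A data frame with an `abundance` column (> 0) plus any
#'   label columns (e.g. `target`, `sirna`, `oht`, `fraction`); each row is
#'   expanded into `replicates` wells.
#' @param replicates Technical/biological replicates per row.
#' @param noise_sd Gaussian Ct noise, in cycles.
#' @param efficiency Amplification efficiency (> 1).
#' @param baseline Ct of one abundance unit.
#' @param seed RNG seed.
#' @return A long tibble: the label columns, `replicate`, and `ct`.
#' @export
#' @examples
#' plate <- simulate_qpcr_plate(
#'   data.frame(target = "locusA", abundance = c(1, 2)),
#'   replicates = 2, noise_sd = 0, seed = 1
#' )
#' diff(unique(plate$ct))  # -1 cycle per doubling
simulate_qpcr_plate <- function(abundances, replicates = 3, noise_sd = 0.2,
                                efficiency = 2, baseline = 30, seed = 17) {
  assert_data_frame(abundances, "abundances", "abundance")
  if (any(!is.finite(abundances$abundance)) || any(abundances$abundance <= 0)) {
    abort("All `abundance` values must be finite and > 0.")
  }
  assert_scalar_number(replicates, "replicates", min = 1)
  assert_scalar_number(noise_sd, "noise_sd", min = 0)
  assert_scalar_number(efficiency, "efficiency", min = 1, strict = TRUE)

  if ("replicate" %in% names(abundances)) {
    # the table already enumerates wells; keep its replicate labels
    if (replicates != 1) {
      abort("`abundances` already has a `replicate` column; use replicates = 1.")
    }
    out <- tibble::as_tibble(abundances)
  } else {
    out <- tidyr::expand_grid(
      tibble::as_tibble(abundances),
      replicate = seq_len(replicates)
    )
  }
  with_seed(seed, {
    out$ct <- baseline - log(out$abundance) / log(efficiency) +
      rnorm(nrow(out), 0, noise_sd)
    dplyr::select(out, -"abundance")
  })
}
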