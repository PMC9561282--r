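#' Tidy a driploop hypothesis-test result
#'
#' @param x A `driploop_htest` from [wilcoxon_one_sided()], [pearson_test()]
#'   or [paired_t()].
#' @param ... Unused.
#' @return A one-row tibble: statistic, estimate (if any), df (if any),
#'   p.value, alternative, method.
#' @method tidy driploop_htest
#' @export
tidy.driploop_htest <- function(x, ...) {
  tibble::tibble(
    test = x$test,
    statistic = unname(x$statistic[1]),
    estimate = if (is.null(x$estimate)) NA_real_ else unname(x$estimate[1]),
    df = if (is.null(x$parameter)) NA_real_ else unname(x$parameter),
    p.value = x$p.value,
    alternative = x$alternative,
    method = x$method
  )
}

#' @rdname tidy.driploop_htest
#' @method glance driploop_htest
#' @export
glance.driploop_htest <- function(x, ...) {
  out <- tidy(x, ...)
  out$n_total <- sum(x$n)
  out
}

#' Summarise a classified site table
#'
#' @param x A classified site table (tibble with a `class` column), as
#'   returned by [classify_sites()].
#' @param ... Unused.
#' @return A one-row tibble: site counts per class, total, and recovery
#'   accuracy when the planted `true_class` is present.
#' @method glance site_classification
#' @export
glance.site_classification <- function(x, ...) {
  counts <- table(factor(x$class,
                         levels = c("dependent", "independent", "increased")))
  out <- tibble::tibble(
    n_sites = nrow(x),
    n_dependent = unname(counts["dependent"]),
    n_independent = unname(counts["independent"]),
    n_increased = unname(counts["increased"])
  )
  if ("true_class" %in% names(x)) {
    out$accuracy <- mean(x$class == x$true_class)
  }
  out
}
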