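#' Cross-study identification frequency table
#'
#' Counts, for every protein, the number of **distinct studies** (not
#' occurrences) in which it was identified. Identifiers are uppercased on
#' ingest and treated as opaque strings; harmonizing identifiers across
#' heterogeneous studies is the caller's responsibility.
#'
#' @param hits A long tibble (`study_id`, `protein`) such as
#'   [make_study_hit_lists()] output, or a list of per-study data frames each
#'   with a unique `study_id`.
#' @return A `frequency_table` tibble (`protein`, `k`) ordered by `k`
#'   descending then protein ascending, with attribute `n_studies`.
#' @export
#' @examples
#' hits <- tibble::tibble(study_id = c("a", "a", "b"), protein = c("P1", "P2", "P1"))
#' frequency_table(hits)
frequency_table <- function(hits) {
  if (is.list(hits) && !is.data.frame(hits)) {
    ids <- purrr::map_chr(hits, function(h) unique(h$study_id)[1])
    if (anyDuplicated(ids)) abort("Duplicate study_id across hit lists.")
    hits <- dplyr::bind_rows(hits)
  }
  assert_data_frame(hits, "hits", c("study_id", "protein"))
  if (nrow(hits) == 0L) abort("Need at least one study with hits.")
  hits <- dplyr::mutate(tibble::as_tibble(hits),
                        protein = toupper(.data$protein))
  n_studies <- dplyr::n_distinct(hits$study_id)
  tab <- hits |>
    dplyr::distinct(.data$study_id, .data$protein) |>
    dplyr::count(.data$protein, name = "k") |>
    dplyr::arrange(dplyr::desc(.data$k), .data$protein)
  structure(tab, n_studies = n_studies,
            class = c("frequency_table", class(tibble::tibble())))
}

#' Candidate proteins identified in at least `kmin` studies
#'
#' @param table A [frequency_table()].
#' @param kmin Minimum number of identifying studies (a typical choice is
#'   4 of 11).
#' @return The rows of `table` with `k >= kmin`, in the table's deterministic
#'   order (k descending, identifier ascending).
#' @export
candidates_at_threshold <- function(table, kmin) {
  assert_data_frame(table, "table", c("protein", "k"))
  n_studies <- attr(table, "n_studies") %||% max(table$k)
  assert_scalar_number(kmin, "kmin", min = 1)
  if (kmin > n_studies) {
    warn(paste0("kmin (", kmin, ") exceeds the number of studies (",
                n_studies, "); result is empty."))
  }
  out <- dplyr::filter(tibble::as_tibble(table), .data$k >= kmin) |>
    dplyr::arrange(dplyr::desc(.data$k), .data$protein)
  structure(out, n_studies = n_studies, kmin = kmin,
            class = c("frequency_table", class(tibble::tibble())))
}

#' Venn region counts for two or three study hit lists
#'
#' Computes the exact region counts of the 2- or 3-set Venn diagram of the
#' selected studies' protein sets, plus the core intersection shared by all.
#'
#' @param hits Long hit tibble (`study_id`, `category`, `protein`).
#' @param categories Optional category filter applied before intersecting
#'   (e.g. `"phosphoproteomics"` reproduces the three-study phospho overlap).
#' @param studies Optional explicit study_id selection.
#' @return A list with `regions` (tibble: region label, count), `core`
#'   (character vector shared by all studies) and `studies`.
#' @export
intersect_studies <- function(hits, categories = NULL, studies = NULL) {
  assert_data_frame(hits, "hits", c("study_id", "protein"))
  hits <- dplyr::mutate(tibble::as_tibble(hits),
                        protein = toupper(.data$protein))
  if (!is.null(categories)) {
    assert_data_frame(hits, "hits", "category")
    hits <- dplyr::filter(hits, .data$category %in% categories)
  }
  if (!is.null(studies)) hits <- dplyr::filter(hits, .data$study_id %in% studies)
  ids <- sort(unique(hits$study_id))
  if (length(ids) < 2L || length(ids) > 3L) {
    abort(paste0("Need 2 or 3 studies after filtering, got ", length(ids), "."))
  }
  sets <- purrr::map(ids, function(s) unique(hits$protein[hits$study_id == s]))
  names(sets) <- ids

  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1)
  pattern <- apply(membership, 1, function(row) {
    paste(ids[row], collapse = "&")
  })
  regions <- tibble::tibble(region = pattern) |>
    dplyr::count(.data$region, name = "count")
  # include empty regions for completeness
  all_patterns <- unlist(purrr::map(seq_along(ids), function(k) {
    apply(combn(ids, k), 2, paste, collapse = "&")
  }))
  regions <- tibble::tibble(region = all_patterns) |>
    dplyr::left_join(regions, by = "region") |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L))

  core <- sort(universe[rowSums(membership) == length(ids)])
  list(regions = regions, core = core, studies = ids)
}

#' Flag proteins in a frequency table
#'
#' Adds (or replaces) a logical annotation column that is TRUE exactly for the
#' proteins in `flag_set`; ranking is unchanged. Typical flags:
#' `hybrid_interactor`, `known_repair`.
#'
#' @param table A [frequency_table()].
#' @param flag_name Name of the annotation column.
#' @param flag_set Character vector of identifiers (case-insensitive).
#' @return The annotated `frequency_table`.
#' @export
annotate_hits <- function(table, flag_name, flag_set) {
  assert_data_frame(table, "table", "protein")
  out <- tibble::as_tibble(table)
  out[[flag_name]] <- out$protein %in% toupper(flag_set)
  structure(out, n_studies = attr(table, "n_studies"),
            class = c("frequency_table", class(tibble::tibble())))
}

#' Top-ranked flagged protein outside an exclusion set
#'
#' The nomination query of the meta-analysis: the most frequently identified
#' protein carrying `flag` (e.g. a known DNA:RNA-hybrid interactor) that is
#' *not* flagged by `exclude` (e.g. already-known repair factors). Ties break
#' by identifier, matching the table's deterministic order.
#'
#' @param table An annotated [frequency_table()].
#' @param flag Column that must be TRUE.
#' @param exclude Optional column that must be FALSE.
#' @return A one-row tibble (or zero rows if nothing qualifies).
#' @export
top_candidate <- function(table, flag, exclude = NULL) {
  assert_data_frame(table, "table", c("protein", "k", flag))
  out <- dplyr::filter(tibble::as_tibble(table), .data[[flag]])
  if (!is.null(exclude)) {
    assert_data_frame(table, "table", exclude)
    out <- dplyr::filter(out, !.data[[exclude]])
  }
  dplyr::arrange(out, dplyr::desc(.data$k), .data$protein) |>
    dplyr::slice_head(n = 1)
}

#' Count SQ (optionally TQ) motifs in a peptide
#'
#' Counts positions `i` with `peptide[i] == "S"` (or `"T"` when
#' `include_tq = TRUE`) followed by `"Q"` — the consensus substrate motif of
#' the apical DNA-damage-response kinases ATM and ATR. Case-insensitive;
#' overlapping occurrences are impossible for a two-letter motif with distinct
#' letters, so the count is a simple scan.
#'
#' @param peptide A single string over the 20 amino-acid letters.
#' @param include_tq Also count TQ.
#' @return Integer motif count.
#' @export
#' @examples
#' sq_motif_count("ASQDSQTK")  # 2
sq_motif_count <- function(peptide, include_tq = FALSE) {
  if (!is.character(peptide) || length(peptide) != 1L || is.na(peptide)) {
    abort("`peptide` must be a single string.")
  }
  chars <- strsplit(toupper(peptide), "")[[1]]
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  bad <- which(!chars %in% aa)
  if (length(bad)) {
    abort(paste0("Illegal amino-acid character '", chars[bad[1]],
                 "' at position ", bad[1], "."))
  }
  if (length(chars) < 2L) return(0L)
  first <- chars[-length(chars)]
  second <- chars[-1]
  hits <- (first == "S" | (include_tq & first == "T")) & second == "Q"
  sum(hits)
}
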