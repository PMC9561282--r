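#' Simulate cross-study proteomic hit lists with a planted core
#'
#' Generates per-study protein hit lists emulating a meta-analysis of
#' heterogeneous DNA-repair proteomic screens. A planted "core repair" set of
#' `core_size` proteins is captured by each study with probability `p_core`;
#' background proteins from a pool of `background_pool` are captured with
#' probability `p_background`. One additional planted candidate — a
#' hybrid-interacting protein with no repair annotation — is captured by every
#' study, emulating a high-frequency novel hit. Studies tagged
#' `phosphoproteomics` carry one peptide per hit for motif scanning; the
#' planted candidate's phosphopeptide is identical across those studies and
#' contains two SQ motifs.
#'
#' @param n_studies Number of studies.
#' @param categories Character vector of length `n_studies` assigning each
#'   study to one of chromatin_association / interactome / phosphoproteomics /
#'   ubiquitylomics. The default 11-study design uses 4/3/3/1.
#' @param core_size Number of planted core proteins.
#' @param p_core,p_background Per-study capture probabilities.
#' @param background_pool Size of the background protein universe.
#' @param seed RNG seed.
#' @return A long tibble of class `study_hits` with columns `study_id`,
#'   `category`, `protein` and `peptide` (NA outside phospho studies).
#'   Attributes: `core_set`, `planted_candidate`, `hybrid_interactors`,
#'   `known_repair`.
#' @export
#' @examples
#' hits <- make_study_hit_lists(n_studies = 3, core_size = 5, seed = 1)
#' dplyr::count(hits, study_id)
make_study_hit_lists <- function(n_studies = 11,
                                 categories = NULL,
                                 core_size = 30,
                                 p_core = 0.9,
                                 p_background = 0.05,
                                 background_pool = 1500,
                                 seed = 17) {
  assert_scalar_number(n_studies, "n_studies", min = 1)
  if (p_core < 0 || p_core > 1 || p_background < 0 || p_background > 1) {
    abort("Capture probabilities must lie in [0, 1].")
  }
  assert_scalar_number(core_size, "core_size", min = 0)
  valid_cat <- c("chromatin_association", "interactome", "phosphoproteomics",
                 "ubiquitylomics")
  if (is.null(categories)) {
    categories <- default_categories(n_studies)
  }
  if (length(categories) != n_studies || !all(categories %in% valid_cat)) {
    abort(paste0("`categories` must be length ", n_studies,
                 " over {", paste(valid_cat, collapse = ", "), "}."))
  }

  core <- if (core_size > 0) sprintf("CORE%03d", seq_len(core_size)) else character()
  background <- sprintf("P%04d", seq_len(background_pool))
  candidate <- "HYBX1"
  known_repair <- core
  hybrid_interactors <- c(candidate, head(core, max(0, core_size %/% 5)))
  candidate_peptide <- "ASQDLSQTKR"  # two SQ motifs, fixed across studies

  with_seed(seed, {
    rows <- purrr::map(seq_len(n_studies), function(i) {
      hit_core <- core[runif(length(core)) < p_core]
      hit_bg <- background[runif(length(background)) < p_background]
      proteins <- c(hit_core, hit_bg, candidate)
      tibble::tibble(
        study_id = sprintf("study_%02d", i),
        category = categories[i],
        protein = proteins
      )
    })
    out <- dplyr::bind_rows(rows)
    out$peptide <- NA_character_
    phospho <- out$category == "phosphoproteomics"
    out$peptide[phospho] <- random_peptides(sum(phospho))
    out$peptide[phospho & out$protein == candidate] <- candidate_peptide

    structure(
      out,
      core_set = core,
      planted_candidate = candidate,
      hybrid_interactors = hybrid_interactors,
      known_repair = known_repair,
      class = c("study_hits", class(tibble::tibble()))
    )
  })
}

default_categories <- function(n) {
  base <- c(rep("chromatin_association", 4), rep("interactome", 3),
            rep("phosphoproteomics", 3), "ubiquitylomics")
  if (n <= length(base)) head(base, n) else
    c(base, rep("chromatin_association", n - length(base)))
}

random_peptides <- function(n, min_len = 8, max_len = 20) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  lens <- sample(min_len:max_len, n, replace = TRUE)
  vapply(lens, function(l) paste(sample(aa, l, replace = TRUE), collapse = ""),
         character(1))
}

#' Write study hit lists as per-study TSVs plus a manifest
#'
#' @param hits A `study_hits` tibble.
#' @param dir Output directory (created if needed). One `<study_id>.tsv` per
#'   study (columns protein, peptide) and a `manifest.tsv`
#'   (study_id, category, path).
#' @return The manifest path, invisibly.
#' @export
write_study_hit_lists <- function(hits, dir) {
  assert_data_frame(hits, "hits", c("study_id", "category", "protein"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- hits |>
    dplyr::distinct(.data$study_id, .data$category) |>
    dplyr::mutate(path = file.path(dir, paste0(.data$study_id, ".tsv")))
  purrr::pwalk(manifest, function(study_id, category, path) {
    hits |>
      dplyr::filter(.data$study_id == !!study_id) |>
      dplyr::select("protein", "peptide") |>
      readr::write_tsv(path)
  })
  manifest_path <- file.path(dir, "manifest.tsv")
  readr::write_tsv(manifest, manifest_path)
  invisible(manifest_path)
}

#' @param manifest_path Path to a manifest TSV (study_id, category, path).
#' @rdname write_study_hit_lists
#' @export
read_study_hit_lists <- function(manifest_path) {
  manifest <- readr::read_tsv(manifest_path, show_col_types = FALSE,
                              progress = FALSE)
  assert_data_frame(manifest, "manifest", c("study_id", "category", "path"))
  rows <- purrr::pmap(manifest, function(study_id, category, path) {
    tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    tibble::tibble(
      study_id = study_id, category = category,
      protein = tab$protein,
      peptide = if ("peptide" %in% names(tab)) as.character(tab$peptide)
                else NA_character_
    )
  })
  structure(dplyr::bind_rows(rows),
            class = c("study_hits", class(tibble::tibble())))
}
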