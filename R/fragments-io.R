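#' Read aligned fragments from BEDPE or BED
#'
#' A BEDPE row `(c, s1, e1, c, s2, e2)` becomes the single fragment
#' `(c, min(s1, s2), max(e1, e2))` — the full sequenced insert spanned by the
#' mate pair. BED3 rows are taken as fragments directly. All coordinates are
#' 0-based half-open. Rows whose mates map to different contigs cannot define
#' a fragment; they are skipped with a warning and counted in the
#' `skipped_intercontig` attribute.
#'
#' @param path Input file.
#' @param format `"bedpe"` or `"bed"`.
#' @param sample_id Optional sample label.
#' @param genome Optional named contig lengths to attach.
#' @return A `fragment_library` tibble (chrom, start, end), sorted, with the
#'   library size set to the number of fragments.
#' @export
read_fragments <- function(path, format = c("bedpe", "bed"), sample_id = NULL,
                           genome = NULL) {
  format <- rlang::arg_match(format)
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(new_fragment_library(
      tibble::tibble(chrom = character(), start = integer(), end = integer()),
      sample_id = sample_id %||% basename(path),
      condition = list(), genome = genome
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_min <- if (format == "bedpe") 6L else 3L
  bad <- which(lengths(fields) < n_min)
  if (length(bad)) {
    abort(paste0("Malformed ", format, " line ", bad[1], " in '", path,
                 "': expected >= ", n_min, " tab-separated fields."))
  }

  skipped <- 0L
  if (format == "bedpe") {
    c1 <- vapply(fields, `[[`, character(1), 1L)
    c2 <- vapply(fields, `[[`, character(1), 4L)
    s1 <- parse_coord(fields, 2L, path)
    e1 <- parse_coord(fields, 3L, path)
    s2 <- parse_coord(fields, 5L, path)
    e2 <- parse_coord(fields, 6L, path)
    inter <- c1 != c2
    skipped <- sum(inter)
    if (skipped > 0L) {
      warn(paste0("Skipped ", skipped,
                  " BEDPE row(s) with mates on different contigs."))
    }
    frags <- tibble::tibble(
      chrom = c1[!inter],
      start = pmin(s1, s2)[!inter],
      end = pmax(e1, e2)[!inter]
    )
  } else {
    frags <- tibble::tibble(
      chrom = vapply(fields, `[[`, character(1), 1L),
      start = parse_coord(fields, 2L, path),
      end = parse_coord(fields, 3L, path)
    )
  }
  if (any(frags$start >= frags$end)) {
    i <- which(frags$start >= frags$end)[1]
    abort(paste0("Invalid interval (start >= end) at fragment ", i,
                 " of '", path, "'."))
  }
  frags <- dplyr::arrange(frags, .data$chrom, .data$start, .data$end)
  lib <- new_fragment_library(frags, sample_id = sample_id %||% basename(path),
                              condition = list(), genome = genome)
  attr(lib, "skipped_intercontig") <- skipped
  lib
}

parse_coord <- function(fields, k, path) {
  raw <- vapply(fields, `[[`, character(1), k)
  val <- suppressWarnings(as.integer(raw))
  if (anyNA(val)) {
    abort(paste0("Non-numeric coordinate at line ", which(is.na(val))[1],
                 ", field ", k, " of '", path, "'."))
  }
  val
}

#' Write a fragment library to disk
#'
#' `format = "bed"` writes one 3-column BED row per fragment. `format =
#' "bedpe"` writes each fragment as a synthetic mate pair: two `read_len`
#' intervals anchored at the fragment ends (the pair [read_fragments()] would
#' collapse back to the same fragment). A JSON sidecar `<path>.json` records
#' the sample id, condition labels and library size.
#'
#' @param lib A `fragment_library`.
#' @param path Output path.
#' @param format `"bed"` or `"bedpe"`.
#' @param read_len Mate length used for BEDPE output (default 75 bp).
#' @return `path`, invisibly.
#' @export
write_fragments <- function(lib, path, format = c("bed", "bedpe"),
                            read_len = 75L) {
  format <- rlang::arg_match(format)
  assert_data_frame(lib, "lib", c("chrom", "start", "end"))
  if (format == "bed") {
    lines <- sprintf("%s\t%d\t%d", lib$chrom, lib$start, lib$end)
  } else {
    m1_end <- pmin(lib$start + read_len, lib$end)
    m2_start <- pmax(lib$end - read_len, lib$start)
    lines <- sprintf(
      "%s\t%d\t%d\t%s\t%d\t%d\tfrag_%d\t0\t+\t-",
      lib$chrom, lib$start, m1_end, lib$chrom, m2_start, lib$end,
      seq_len(nrow(lib))
    )
  }
  readr::write_lines(lines, path)
  sidecar <- list(
    sample_id = attr(lib, "sample_id"),
    condition = attr(lib, "condition"),
    library_size = library_size(lib)
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
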