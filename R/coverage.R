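#' Per-base fragment depth as a run-length coverage track
#'
#' Computes `depth[p] = #\{fragments with start <= p < end\}` for every base of
#' every contig by a sweep over fragment boundaries, and stores the result as
#' merged constant-value runs (zero runs are implicit), so whole-genome tracks
#' stay memory-light.
#'
#' @param lib A `fragment_library` (or any data frame with chrom/start/end).
#' @param genome Named contig lengths; defaults to the library's `genome`
#'   attribute, else the per-contig maximum end.
#' @return A `coverage_track`: tibble (chrom, start, end, value) of non-zero
#'   constant runs with attributes `genome`, `scale = "raw"` and
#'   `library_size`.
#' @export
#' @examples
#' lib <- tibble::tibble(chrom = "c", start = c(0L, 5L), end = c(10L, 15L))
#' coverage_depth(lib, genome = c(c = 30))
coverage_depth <- function(lib, genome = NULL) {
  assert_data_frame(lib, "lib", c("chrom", "start", "end"))
  genome <- genome %||% attr(lib, "genome")
  if (is.null(genome)) {
    genome <- tapply(lib$end, lib$chrom, max)
    genome <- setNames(as.numeric(genome), names(genome))
  }
  runs <- lib |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_map(function(df, key) {
      if (nrow(df) == 0L || nrow(key) == 0L) return(NULL)
      chrom <- key$chrom[[1]]
      len <- genome[[chrom]] %||% max(df$end)
      # boundary sweep: +1 at starts, -1 at ends
      pos <- c(pmax(df$start, 0), pmin(df$end, len))
      delta <- rep(c(1L, -1L), each = nrow(df))
      o <- order(pos)
      pos <- pos[o]; delta <- delta[o]
      keep <- c(diff(pos) > 0, TRUE)
      depth <- cumsum(delta)[keep]
      bound <- pos[keep]
      out <- tibble::tibble(
        chrom = chrom,
        start = bound[-length(bound)],
        end = bound[-1],
        value = as.numeric(depth[-length(depth)])
      )
      dplyr::filter(out, .data$value != 0)
    }) |>
    dplyr::bind_rows()
  if (nrow(runs) == 0L) {
    runs <- tibble::tibble(chrom = character(), start = numeric(),
                           end = numeric(), value = numeric())
  }
  runs <- merge_runs(runs)
  new_coverage_track(runs, genome = genome, scale = "raw",
                     library_size = library_size(lib))
}

new_coverage_track <- function(runs, genome, scale, library_size = NULL,
                               scale_factor = NULL) {
  structure(
    tibble::as_tibble(runs),
    genome = genome,
    scale = scale,
    library_size = library_size,
    scale_factor = scale_factor,
    class = c("coverage_track", class(tibble::tibble()))
  )
}

#' Library-size normalization of a coverage track
#'
#' Scales raw per-base depth to fragments-per-million: every value is
#' multiplied by `1e6 / L`. The constant is arbitrary (any constant cancels in
#' damaged/undamaged fold changes) but makes tracks comparable across
#' sequencing depths.
#'
#' @param track A raw `coverage_track`.
#' @param library_size Total fragments `L`; defaults to the track's own.
#' @return A `coverage_track` with `scale = "per_million"` and the
#'   `scale_factor` recorded.
#' @export
normalize_coverage <- function(track, library_size = NULL) {
  stopifnot(inherits(track, "coverage_track"))
  if (identical(attr(track, "scale"), "per_million")) {
    abort("`track` is already normalized.")
  }
  L <- library_size %||% attr(track, "library_size")
  if (is.null(L) || !is.finite(L) || L <= 0) {
    abort("Cannot normalize: library size must be a positive number.")
  }
  s <- 1e6 / L
  out <- dplyr::mutate(tibble::as_tibble(track), value = .data$value * s)
  new_coverage_track(out, genome = attr(track, "genome"),
                     scale = "per_million", library_size = L, scale_factor = s)
}

#' Write / read a coverage track as bedGraph
#'
#' Writes 4-column bedGraph with adjacent equal-value runs merged and values
#' printed at full precision, so `read_bedgraph(write_bedgraph(x))`
#' reproduces `x` exactly. Zero-depth runs are omitted (bedGraph convention).
#'
#' @param track A `coverage_track`.
#' @param path Output path.
#' @return `write_bedgraph()` returns `path` invisibly; `read_bedgraph()`
#'   returns a `coverage_track`.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  runs <- merge_runs(tibble::as_tibble(track))
  if (nrow(runs) > 0 && any(runs$start[-1] < runs$end[-nrow(runs)] &
                            runs$chrom[-1] == runs$chrom[-nrow(runs)])) {
    abort("Internal error: overlapping runs in coverage track.")
  }
  lines <- sprintf("%s\t%s\t%s\t%s", runs$chrom, fmt_num(runs$start),
                   fmt_num(runs$end), fmt_num(runs$value))
  readr::write_lines(lines, path)
  invisible(path)
}

#' @param genome Optional contig lengths to attach on read.
#' @param scale Scale flag to attach (`"raw"` or `"per_million"`).
#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path, genome = NULL, scale = "per_million") {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    runs <- tibble::tibble(chrom = character(), start = numeric(),
                           end = numeric(), value = numeric())
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(fields) != 4L)) {
      abort(paste0("Malformed bedGraph line ",
                   which(lengths(fields) != 4L)[1], " in '", path, "'."))
    }
    runs <- tibble::tibble(
      chrom = vapply(fields, `[[`, character(1), 1L),
      start = as.numeric(vapply(fields, `[[`, character(1), 2L)),
      end = as.numeric(vapply(fields, `[[`, character(1), 3L)),
      value = as.numeric(vapply(fields, `[[`, character(1), 4L))
    )
  }
  if (is.null(genome) && nrow(runs) > 0) {
    genome <- tapply(runs$end, runs$chrom, max)
    genome <- setNames(as.numeric(genome), names(genome))
  }
  new_coverage_track(runs, genome = genome, scale = scale)
}

# canonical form: sorted, adjacent equal-value runs merged, zero runs dropped
merge_runs <- function(runs) {
  if (nrow(runs) == 0L) return(runs)
  runs <- runs[runs$value != 0, , drop = FALSE]
  runs <- runs[order(runs$chrom, runs$start), , drop = FALSE]
  if (nrow(runs) <= 1L) return(tibble::as_tibble(runs))
  same <- runs$chrom[-1] == runs$chrom[-nrow(runs)] &
    runs$start[-1] == runs$end[-nrow(runs)] &
    runs$value[-1] == runs$value[-nrow(runs)]
  grp <- cumsum(c(TRUE, !same))
  tibble::tibble(
    chrom = runs$chrom[!duplicated(grp)],
    start = runs$start[!duplicated(grp)],
    end = runs$end[rev(!duplicated(rev(grp)))],
    value = runs$value[!duplicated(grp)]
  )
}
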