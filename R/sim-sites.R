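#' Generate an annotated table of cut sites
#'
#' Places `cfg$n_sites` restriction cut sites on the configured toy genome with
#' at least `2 * window_bp` spacing (so signal windows never overlap) and draws
#' the per-site annotations the break analysis consumes: dependence class,
#' pre-existing hybrid level, relative transcriptional activity, repair-pathway
#' class, and the realized break-induced signal magnitude.
#'
#' When `cfg$coupling > 0`, knockdown-dependent sites draw their pre-existing
#' hybrid level from a log-normal shifted down by `coupling` log units,
#' emulating loci that are innately poor at forming hybrids. Transcriptional
#' activity is mildly and noisily tied to the pre-existing level, reflecting
#' that the two covary but are not proportional.
#'
#' @param cfg A [sim_config()].
#' @return A tibble of class `break_sites` with columns `site_id`, `chrom`,
#'   `cut_pos` (0-based), `repair_class`, `transcription_level`,
#'   `preexisting_hybrid`, `true_class` and `induction_magnitude` (the additive
#'   expected fragment count added on cut induction in the control arm).
#'   The genome and window are carried as attributes.
#' @export
#' @examples
#' sites <- make_break_sites(sim_config(n_sites = 4, genome = c(chr1 = 1e5)))
#' sites$true_class
make_break_sites <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  gap <- 2L * cfg$window_bp

  # Capacity check: each site consumes `gap` bp plus a window margin at both
  # contig ends.
  usable <- pmax(cfg$genome - 2 * cfg$window_bp, 0)
  capacity <- sum(floor(usable / gap + 1) * (usable > 0))
  if (capacity < cfg$n_sites) {
    abort(paste0(
      "Genome too small: can place at most ", capacity, " sites with ",
      gap, " bp spacing, need ", cfg$n_sites, "."
    ))
  }

  with_seed(child_seed(cfg$seed, 1L), {
    # Allocate sites to contigs proportionally to usable length, then fix up
    # any contig over capacity.
    alloc <- allocate_sites(cfg$n_sites, usable, gap)
    placements <- purrr::map2(names(cfg$genome), alloc, function(chrom, k) {
      if (k == 0L) return(NULL)
      len <- cfg$genome[[chrom]]
      lo <- cfg$window_bp
      hi <- len - cfg$window_bp
      # k sorted positions in [lo, hi) with pairwise gaps >= gap: draw from the
      # shrunken interval and add back cumulative gaps.
      slack <- (hi - lo) - (k - 1) * gap
      u <- sort(runif(k, 0, slack))
      pos <- floor(lo + u + (seq_len(k) - 1) * gap)
      tibble::tibble(chrom = chrom, cut_pos = as.integer(pos))
    })
    sites <- dplyr::bind_rows(placements)

    counts <- class_counts(cfg)
    classes <- sample(rep(names(counts), counts))

    meanlog <- rep(cfg$preexisting_meanlog, cfg$n_sites)
    meanlog[classes == "dependent"] <- meanlog[classes == "dependent"] - cfg$coupling
    preexisting <- rlnorm(cfg$n_sites, meanlog = meanlog, sdlog = cfg$preexisting_sdlog)

    transcription <- exp(
      0.4 * (log(preexisting) - cfg$preexisting_meanlog) +
        rnorm(cfg$n_sites, 0, 0.6)
    ) * 10

    repair <- sample(c("HR", "NHEJ", "unassigned"), cfg$n_sites,
                     replace = TRUE, prob = c(0.4, 0.4, 0.2))

    induction <- cfg$induction_fold * (cfg$background_rate + preexisting) *
      rlnorm(cfg$n_sites, 0, cfg$induction_jitter_sdlog)

    out <- sites |>
      dplyr::mutate(
        site_id = sprintf("site_%03d", dplyr::row_number()),
        repair_class = repair,
        transcription_level = transcription,
        preexisting_hybrid = preexisting,
        true_class = classes,
        induction_magnitude = induction
      ) |>
      dplyr::select(
        "site_id", "chrom", "cut_pos", "repair_class", "transcription_level",
        "preexisting_hybrid", "true_class", "induction_magnitude"
      )

    new_break_sites(out, genome = cfg$genome, window_bp = cfg$window_bp)
  })
}

new_break_sites <- function(df, genome, window_bp) {
  structure(
    tibble::as_tibble(df),
    genome = genome,
    window_bp = window_bp,
    class = c("break_sites", class(tibble::tibble()))
  )
}

allocate_sites <- function(n, usable, gap) {
  cap <- as.integer(floor(usable / gap + 1) * (usable > 0))
  w <- usable / sum(usable)
  alloc <- as.integer(floor(w * n))
  # distribute the remainder, respecting per-contig capacity
  while (sum(alloc) < n) {
    room <- cap - alloc
    i <- which.max(ifelse(room > 0, w, -Inf))
    alloc[i] <- alloc[i] + 1L
  }
  over <- alloc > cap
  while (any(over)) {
    excess <- sum(alloc[over] - cap[over])
    alloc[over] <- cap[over]
    room <- which(alloc < cap)
    for (i in room) {
      take <- min(excess, cap[i] - alloc[i])
      alloc[i] <- alloc[i] + take
      excess <- excess - take
      if (excess == 0) break
    }
    over <- alloc > cap
    if (excess > 0 && !any(alloc < cap)) break
  }
  alloc
}

#' Write and read the cut-site table
#'
#' The site table is stored as a BED6 file (chrom, cut_pos, cut_pos + 1,
#' site_id, score = transcription_level, strand ".") plus a TSV sidecar
#' carrying the annotations that do not fit BED (repair class, pre-existing
#' hybrid level, dependence class, induction magnitude).
#'
#' @param sites A `break_sites` tibble.
#' @param path Output BED path; the sidecar is written to `<path>.annot.tsv`.
#' @return `write_break_sites()` returns `path` invisibly; `read_break_sites()`
#'   returns a `break_sites` tibble.
#' @export
write_break_sites <- function(sites, path) {
  assert_data_frame(sites, "sites", c("site_id", "chrom", "cut_pos"))
  bed <- tibble::tibble(
    chrom = sites$chrom,
    start = sites$cut_pos,
    end = sites$cut_pos + 1L,
    name = sites$site_id,
    score = sites$transcription_level,
    strand = "."
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  annot <- sites |>
    dplyr::select(dplyr::any_of(c(
      "site_id", "repair_class", "preexisting_hybrid", "true_class",
      "induction_magnitude"
    )))
  readr::write_tsv(annot, paste0(path, ".annot.tsv"))
  invisible(path)
}

#' @param genome Named contig lengths to attach (required to clip windows).
#' @param window_bp Window half-width to attach.
#' @rdname write_break_sites
#' @export
read_break_sites <- function(path, genome = NULL, window_bp = NULL) {
  bed <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "name", "score", "strand"),
    col_types = "ciicdc", progress = FALSE
  )
  out <- tibble::tibble(
    site_id = bed$name,
    chrom = bed$chrom,
    cut_pos = bed$start,
    transcription_level = bed$score
  )
  sidecar <- paste0(path, ".annot.tsv")
  if (file.exists(sidecar)) {
    annot <- readr::read_tsv(sidecar, show_col_types = FALSE, progress = FALSE)
    out <- dplyr::left_join(out, annot, by = "site_id")
  }
  new_break_sites(out, genome = genome, window_bp = window_bp)
}
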