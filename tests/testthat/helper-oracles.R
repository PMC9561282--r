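# Shared fixtures and brute-force oracles used across test files.

# A small, fast configuration for unit tests (not the study-scale defaults).
tiny_cfg <- function(..., seed = 101) {
  sim_config(
    n_sites = 6,
    genome = c(chrA = 2e5, chrB = 1e5),
    window_bp = 2000,
    seed = seed,
    ...
  )
}

# all permutations of 1..n (small n only)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  for (i in seq_len(n)) {
    rows <- ((i - 1) * factorial(n - 1) + 1):(i * factorial(n - 1))
    out[rows, 1] <- i
    out[rows, -1] <- matrix(seq_len(n)[-i][sub], ncol = n - 1)
  }
  out
}

# Naive per-base depth: counts fragments covering every single base.
naive_depth <- function(frags, contig_len) {
  depth <- integer(contig_len)
  for (i in seq_len(nrow(frags))) {
    s <- max(frags$start[i], 0L) + 1L
    e <- min(frags$end[i], contig_len)
    if (e >= s) depth[s:e] <- depth[s:e] + 1L
  }
  depth
}

# Expand a run-length coverage track into a per-base vector for one contig.
track_to_vector <- function(track, chrom, contig_len) {
  v <- numeric(contig_len)
  runs <- track[track$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(runs))) {
    v[(runs$start[i] + 1):runs$end[i]] <- runs$value[i]
  }
  v
}

random_fragments <- function(n, contig_len, chrom = "c") {
  start <- sample.int(contig_len - 2L, n, replace = TRUE) - 1L
  len <- sample.int(200L, n, replace = TRUE)
  tibble::tibble(
    chrom = chrom,
    start = start,
    end = pmin(start + len, contig_len)
  )
}

# Fragments whose midpoint falls in [cut - w, cut + w), per site.
midpoint_window_counts <- function(lib, sites, w) {
  mid <- (lib$start + lib$end) %/% 2
  vapply(seq_len(nrow(sites)), function(i) {
    sum(lib$chrom == sites$chrom[i] &
          mid >= sites$cut_pos[i] - w & mid < sites$cut_pos[i] + w)
  }, numeric(1))
}
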