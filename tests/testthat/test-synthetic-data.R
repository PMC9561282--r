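# Generators: site placement, fragment libraries, RNase-H controls, qPCR
# plates, proteomic hit lists. Determinism and planted-moment checks.

test_that("site placement respects bounds and spacing; config is validated", {
  cfg1 <- sim_config(n_sites = 1, genome = c(chr1 = 1e5), window_bp = 2000,
                     seed = 3)
  s1 <- make_break_sites(cfg1)
  expect_equal(nrow(s1), 1L)
  expect_gte(s1$cut_pos, 2000)
  expect_lt(s1$cut_pos, 1e5 - 2000)

  cfg <- tiny_cfg()
  sites <- make_break_sites(cfg)
  expect_equal(nrow(sites), 6L)
  for (ch in unique(sites$chrom)) {
    cuts <- sort(sites$cut_pos[sites$chrom == ch])
    if (length(cuts) > 1) expect_true(all(diff(cuts) >= 2 * cfg$window_bp))
  }

  # genome too small for the requested spacing
  expect_error(
    make_break_sites(sim_config(n_sites = 50, genome = c(c = 1e5),
                                window_bp = 2000)),
    "too small"
  )
  expect_error(sim_config(n_sites = 0), "n_sites")
  expect_error(sim_config(window_bp = 100, fragment_length_mean = 300),
               "window_bp")
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- tiny_cfg()
  expect_identical(make_break_sites(cfg), make_break_sites(cfg))

  sites <- make_break_sites(cfg)
  a <- simulate_fragment_library(sites, cfg, "kd", "on")
  b <- simulate_fragment_library(sites, cfg, "kd", "on")
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))

  # different conditions / replicates use different streams
  c1 <- simulate_fragment_library(sites, cfg, "ctrl", "on")
  c2 <- simulate_fragment_library(sites, cfg, "ctrl", "on", replicate = 2)
  expect_false(identical(tibble::as_tibble(a), tibble::as_tibble(c1)))
  expect_false(identical(tibble::as_tibble(c1), tibble::as_tibble(c2)))
})

test_that("default 99-site configuration plants the 40/51/8 class composition", {
  cfg <- sim_config(seed = 2)
  sites <- make_break_sites(cfg)
  counts <- table(sites$true_class)
  expect_equal(unname(counts["dependent"]), 40L)
  expect_equal(unname(counts["independent"]), 51L)
  expect_equal(unname(counts["increased"]), 8L)
})

test_that("coupling gives dependent sites lower pre-existing hybrid on average", {
  diffs <- vapply(1:50, function(s) {
    sites <- make_break_sites(sim_config(seed = s))
    mean(sites$preexisting_hybrid[sites$true_class == "dependent"]) -
      mean(sites$preexisting_hybrid[sites$true_class == "independent"])
  }, numeric(1))
  expect_true(all(diffs < 0))
})

test_that("library size is exact in fixed mode and recorded in auto mode", {
  cfg <- tiny_cfg(library_size = 5000)
  sites <- make_break_sites(cfg)
  lib <- simulate_fragment_library(sites, cfg, "ctrl", "on")
  expect_equal(nrow(lib), 5000L)
  expect_equal(library_size(lib), 5000L)

  cfg_auto <- tiny_cfg()
  lib_auto <- simulate_fragment_library(make_break_sites(cfg_auto), cfg_auto,
                                        "ctrl", "off")
  expect_equal(library_size(lib_auto), nrow(lib_auto))

  # intervals are valid, sorted, and inside the genome
  expect_true(all(lib$start < lib$end))
  expect_true(all(lib$end <= cfg$genome[lib$chrom]))
  expect_true(!is.unsorted(lib$start[lib$chrom == lib$chrom[1]][
    seq_len(sum(lib$chrom == lib$chrom[1]))]))

  # impossible fixed size errors
  cfg_small <- tiny_cfg(library_size = 10)
  expect_error(
    simulate_fragment_library(make_break_sites(cfg_small), cfg_small, "ctrl", "on"),
    "exceed"
  )
})

test_that("window fragment counts match the planted negative-binomial moments", {
  cfg <- tiny_cfg(dispersion = 0.05)
  sites <- make_break_sites(cfg)
  mu <- cfg$background_rate + sites$preexisting_hybrid + sites$induction_magnitude
  counts <- sapply(1:50, function(rep) {
    lib <- simulate_fragment_library(sites, cfg, "ctrl", "on", replicate = rep)
    midpoint_window_counts(lib, sites, cfg$window_bp)
  })  # sites x 50
  v <- mu + cfg$dispersion * mu^2
  # per-site mean within 3 SE of mu
  se_mean <- sqrt(v / 50)
  expect_true(all(abs(rowMeans(counts) - mu) < 3 * se_mean))
  # pooled variance ratio near 1 (chi-square spread over 6 sites x 49 df)
  ratio <- apply(counts, 1, stats::var) / v
  expect_true(all(ratio > 0.45 & ratio < 1.9))
})

test_that("no induction and abolished knockdown reproduce the undamaged expectation", {
  cfg <- tiny_cfg(induction_fold = 0)
  sites <- make_break_sites(cfg)
  on_off_diff <- vapply(1:20, function(r) {
    cfg2 <- tiny_cfg(induction_fold = 0, seed = r)
    s2 <- make_break_sites(cfg2)
    on <- midpoint_window_counts(
      simulate_fragment_library(s2, cfg2, "ctrl", "on"), s2, cfg2$window_bp)
    off <- midpoint_window_counts(
      simulate_fragment_library(s2, cfg2, "ctrl", "off"), s2, cfg2$window_bp)
    mean(on - off)
  }, numeric(1))
  expect_lt(abs(mean(on_off_diff)), 3 * stats::sd(on_off_diff) / sqrt(20) + 1)

  # dependent site under knockdown with knockdown_effect = 0: +OHT expectation
  # equals the -OHT expectation by construction
  cfg3 <- tiny_cfg()
  s3 <- make_break_sites(cfg3)
  dep <- s3$true_class == "dependent"
  expect_true(any(dep))
  kd_on <- rowMeans(sapply(1:25, function(r) midpoint_window_counts(
    simulate_fragment_library(s3, cfg3, "kd", "on", replicate = r), s3,
    cfg3$window_bp)))
  mu_off <- cfg3$background_rate + s3$preexisting_hybrid
  se <- sqrt((mu_off + cfg3$dispersion * mu_off^2) / 25)
  expect_true(all(abs(kd_on[dep] - mu_off[dep]) < 4 * se[dep]))
})

test_that("RNase-H residual scales hybrid signal: 0 = background, 1 = identical, 0.1 = 10%", {
  cfg <- tiny_cfg()
  sites <- make_break_sites(cfg)

  # residual 1 under the same seed is the untreated library, fragment for
  # fragment
  r1 <- simulate_rnaseh_library(sites, cfg, "ctrl", "on", residual = 1)
  u1 <- simulate_fragment_library(sites, cfg, "ctrl", "on")
  expect_equal(r1$chrom, u1$chrom)
  expect_equal(r1$start, u1$start)
  expect_equal(r1$end, u1$end)

  # residual 0: expectation is pure background
  c0 <- rowMeans(sapply(1:25, function(r) midpoint_window_counts(
    simulate_rnaseh_library(sites, cfg, "ctrl", "on", residual = 0, replicate = r),
    sites, cfg$window_bp)))
  expect_true(all(abs(c0 - cfg$background_rate) <
                    4 * sqrt(cfg$background_rate / 25)))

  # residual 0.1: hybrid-derived enrichment is ~10% of untreated
  hyb <- sites$preexisting_hybrid + sites$induction_magnitude
  c10 <- rowMeans(sapply(1:25, function(r) midpoint_window_counts(
    simulate_rnaseh_library(sites, cfg, "ctrl", "on", residual = 0.1, replicate = r),
    sites, cfg$window_bp)))
  enrich <- c10 - cfg$background_rate
  expect_equal(mean(enrich / hyb), 0.1, tolerance = 0.15)

  expect_error(simulate_rnaseh_library(sites, cfg, "ctrl", "on", residual = 2),
               "0, 1")
})

test_that("qPCR plate simulator follows the amplification model", {
  ab <- data.frame(target = "t", abundance = c(1, 2))
  plate <- simulate_qpcr_plate(ab, replicates = 1, noise_sd = 0, seed = 4)
  expect_equal(diff(plate$ct), -1)  # doubling = one cycle earlier

  eq <- simulate_qpcr_plate(data.frame(target = c("a", "b"), abundance = 5),
                            replicates = 2, noise_sd = 0, seed = 4)
  expect_equal(length(unique(eq$ct)), 1L)

  # efficiency != 2 changes the slope accordingly
  p3 <- simulate_qpcr_plate(ab, replicates = 1, noise_sd = 0, efficiency = 10,
                            seed = 4)
  expect_equal(diff(p3$ct), -log10(2), tolerance = 1e-12)

  # empirical Ct noise close to its nominal sd
  pn <- simulate_qpcr_plate(data.frame(abundance = 1), replicates = 1000,
                            noise_sd = 0.2, seed = 9)
  expect_equal(stats::sd(pn$ct), 0.2, tolerance = 0.1)

  expect_error(simulate_qpcr_plate(data.frame(abundance = 0)), "> 0")
  # determinism
  expect_identical(simulate_qpcr_plate(ab, seed = 11),
                   simulate_qpcr_plate(ab, seed = 11))
})

test_that("study hit lists: planted capture, categories, peptides, determinism", {
  # capture 1 / 0: every list is exactly core + planted candidate
  h <- make_study_hit_lists(n_studies = 4, core_size = 10, p_core = 1,
                            p_background = 0, seed = 5)
  core <- attr(h, "core_set")
  for (s in unique(h$study_id)) {
    expect_setequal(h$protein[h$study_id == s],
                    c(core, attr(h, "planted_candidate")))
  }

  # binomial expectation of per-core-protein study counts
  h2 <- make_study_hit_lists(n_studies = 11, core_size = 30, p_core = 0.9,
                             p_background = 0.05, seed = 6)
  k_core <- table(h2$protein[h2$protein %in% attr(h2, "core_set")])
  se <- sqrt(11 * 0.9 * 0.1 / 30)
  expect_lt(abs(mean(k_core) - 9.9), 3 * se)

  # default 11-study design: three phospho studies carrying peptides
  cats <- unique(h2[, c("study_id", "category")])
  expect_equal(sum(cats$category == "phosphoproteomics"), 3L)
  phos <- h2[h2$category == "phosphoproteomics", ]
  expect_true(all(!is.na(phos$peptide)))
  expect_true(all(is.na(h2$peptide[h2$category != "phosphoproteomics"])))
  # the planted candidate's phosphopeptide is shared and carries two SQ motifs
  cand_pep <- unique(phos$peptide[phos$protein == attr(h2, "planted_candidate")])
  expect_equal(length(cand_pep), 1L)
  expect_equal(sq_motif_count(cand_pep), 2L)

  expect_identical(make_study_hit_lists(seed = 8), make_study_hit_lists(seed = 8))
  expect_error(make_study_hit_lists(p_core = 1.2), "\\[0, 1\\]")
})

test_that("hit lists round-trip through per-study TSVs and a manifest", {
  h <- make_study_hit_lists(n_studies = 3, core_size = 8, seed = 10)
  dir <- withr::local_tempdir()
  manifest <- write_study_hit_lists(h, dir)
  back <- read_study_hit_lists(manifest)
  expect_equal(
    dplyr::arrange(tibble::as_tibble(back), study_id, protein),
    dplyr::arrange(tibble::as_tibble(h), study_id, protein),
    ignore_attr = TRUE
  )
})

test_that("break-site tables round-trip through BED + annotation sidecar", {
  cfg <- tiny_cfg()
  sites <- make_break_sites(cfg)
  tmp <- withr::local_tempfile(fileext = ".bed")
  write_break_sites(sites, tmp)
  back <- read_break_sites(tmp, genome = cfg$genome, window_bp = cfg$window_bp)
  expect_equal(back$site_id, sites$site_id)
  expect_equal(back$cut_pos, sites$cut_pos)
  expect_equal(back$true_class, sites$true_class)
  expect_equal(back$preexisting_hybrid, sites$preexisting_hybrid)
})
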