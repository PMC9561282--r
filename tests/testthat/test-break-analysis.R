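# Window quantification, fold changes, classification, metagene and the
# site-group statistics.

make_track <- function(frags, genome, L = NULL) {
  normalize_coverage(coverage_depth(frags, genome = genome),
                     library_size = L %||% nrow(frags))
}
`%||%` <- rlang::`%||%`

test_that("window_signal: constant track returns the constant; edges are clipped", {
  # depth-1 everywhere on a 10 kb contig
  frags <- tibble::tibble(chrom = "c", start = 0L, end = 10000L)
  trk <- coverage_depth(frags, genome = c(c = 10000))
  sites <- tibble::tibble(site_id = c("a", "b"), chrom = "c",
                          cut_pos = c(5000L, 200L))
  ws <- window_signal(trk, sites, window_bp = 1000)
  expect_equal(ws$signal, c(1, 1))
  # site near the start: clipped to [0, 1200)
  expect_equal(ws$width, c(2000, 1200))

  expect_error(window_signal(trk, sites, window_bp = 0), "window_bp")
})

test_that("window_signal equals a naive slice-and-average oracle on random tracks", {
  set.seed(19)
  for (i in 1:10) {
    len <- 8000
    frags <- random_fragments(400, len)
    trk <- normalize_coverage(coverage_depth(frags, genome = c(c = len)), 999)
    v <- track_to_vector(trk, "c", len)
    sites <- tibble::tibble(
      site_id = paste0("s", 1:5), chrom = "c",
      cut_pos = sample(200:(len - 200), 5)
    )
    w <- 300
    ws <- window_signal(trk, sites, window_bp = w)
    oracle <- vapply(sites$cut_pos, function(cp) {
      lo <- max(cp - w, 0); hi <- min(cp + w, len)
      mean(v[(lo + 1):hi])
    }, numeric(1))
    expect_equal(ws$signal, oracle)
  }
})

test_that("site_fold_changes: closed forms, replicate averaging, zero-denominator error", {
  sig1 <- tidyr::expand_grid(site_id = "s1", sirna = c("ctrl", "kd"),
                             oht = c("on", "off"), replicate = 1L)
  sig1$signal <- ifelse(sig1$oht == "on", 8, 2)
  q1 <- site_fold_changes(sig1, eps = 0)
  expect_equal(q1$log2fc_ctrl, 2)
  expect_equal(q1$log2fc_kd, 2)
  expect_equal(q1$delta, 0)
  expect_equal(q1$preexisting, 2)

  # all four equal: identity
  sig2 <- sig1; sig2$signal <- 5
  q2 <- site_fold_changes(sig2, eps = 0.1)
  expect_equal(q2$log2fc_ctrl, 0)
  expect_equal(q2$delta, 0)

  # replicates averaged as mean of per-replicate log2FC, not pooled ratio
  sig3 <- dplyr::bind_rows(
    dplyr::mutate(sig1, replicate = 1L,
                  signal = ifelse(oht == "on", 4, 1)),   # log2FC = 2
    dplyr::mutate(sig1, replicate = 2L,
                  signal = ifelse(oht == "on", 16, 1))   # log2FC = 4
  )
  q3 <- site_fold_changes(sig3, eps = 0)
  expect_equal(q3$log2fc_ctrl, 3)  # mean(2, 4), not log2(20/2)
  expect_equal(q3$n_replicates, 2L)

  sig4 <- sig1; sig4$signal[sig4$sirna == "ctrl" & sig4$oht == "off"] <- 0
  expect_error(site_fold_changes(sig4, eps = 0), "site 's1'")
  expect_silent(site_fold_changes(sig4, eps = 0.1))

  # missing condition
  expect_error(site_fold_changes(sig1[-1, ]), "four conditions")
})

test_that("classification rule: strict thresholds, partition, scale invariance", {
  q <- tibble::tibble(site_id = letters[1:5],
                      delta = c(-1.2, 0, 0.7, -0.5, 0.5))
  cl <- classify_sites(q, tau = 0.5)
  expect_equal(cl$class, c("dependent", "independent", "increased",
                           "independent", "independent"))  # ties -> independent

  # partition: every site gets exactly one class
  expect_true(all(cl$class %in% c("dependent", "independent", "increased")))

  # scale invariance: multiplying all four signals (and eps) by k leaves
  # delta and the class unchanged
  base <- tidyr::expand_grid(site_id = "s", sirna = c("ctrl", "kd"),
                             oht = c("on", "off"))
  base$signal <- c(9, 2, 3.5, 2.2)
  for (k in c(0.01, 1, 250)) {
    scaled <- dplyr::mutate(base, signal = signal * k)
    d0 <- site_fold_changes(base, eps = 0.1)$delta
    dk <- site_fold_changes(scaled, eps = 0.1 * k)$delta
    expect_equal(dk, d0)
  }

  expect_error(classify_sites(tibble::tibble(delta = NaN)), "finite")
})

test_that("metagene: identical tracks give a flat zero profile; localized signal stays local", {
  set.seed(4)
  len <- 60000
  frags <- random_fragments(2000, len)
  trk <- make_track(frags, c(c = len))
  sites <- tibble::tibble(site_id = c("s1", "s2"), chrom = "c",
                          cut_pos = c(20000L, 40000L))
  prof <- metagene_profile(trk, trk, sites, span = 2000, bin_width = 200)
  expect_equal(nrow(prof), 20L)
  expect_true(all(prof$mean_log2fc == 0))
  expect_true(all(prof$n_sites == 2L))
  # bins tile [-span, span) exactly
  expect_equal(min(prof$bin_center), -2000 + 100)
  expect_equal(max(prof$bin_center), 2000 - 100)

  # signal confined to one bin appears only there
  extra <- tibble::tibble(chrom = "c",
                          start = rep(20200L, 400), end = rep(20400L, 400))
  trk_on <- make_track(dplyr::bind_rows(frags, extra), c(c = len), nrow(frags))
  prof2 <- metagene_profile(trk_on, trk, sites, span = 2000, bin_width = 200,
                            eps = 0.1)
  hot <- prof2$bin_center == 300
  expect_true(all(abs(prof2$mean_log2fc[!hot]) < 1e-9))
  expect_gt(prof2$mean_log2fc[hot], 1)

  expect_error(metagene_profile(trk, trk, sites, span = 2100, bin_width = 200),
               "multiple")
})

test_that("metagene drops off-contig bins and records contributing site counts", {
  frags <- tibble::tibble(chrom = "c", start = 0L, end = 30000L)
  trk <- make_track(frags, c(c = 30000))
  sites <- tibble::tibble(site_id = c("edge", "mid"), chrom = "c",
                          cut_pos = c(500L, 15000L))
  prof <- metagene_profile(trk, trk, sites, span = 1000, bin_width = 500)
  # bins at -1000 and -500 from the edge site fall off the contig
  expect_equal(prof$n_sites[prof$bin_center == -750], 1L)
  expect_equal(prof$n_sites[prof$bin_center == 750], 2L)
})

test_that("group_compare: exact enumeration case, identity case, errors, median split", {
  q <- tibble::tibble(
    site_id = letters[1:6],
    class = rep(c("dependent", "independent"), each = 3),
    preexisting = c(1, 2, 3, 4, 5, 6)
  )
  res <- group_compare(q, "class", "preexisting", "less")
  expect_equal(res$p_value, 0.05)  # 1 / choose(6, 3)
  expect_equal(res$n1, 3L)
  expect_equal(res$median1, 2)

  # identical groups: no shift, p >= 0.5
  q2 <- q; q2$preexisting <- rep(c(1, 2, 3), 2)
  expect_gte(group_compare(q2, "class", "preexisting", "less")$p_value, 0.5)

  q3 <- q; q3$class <- "independent"
  expect_error(group_compare(q3, "class", "preexisting", "less"), "Empty group")

  # transcription grouping splits at the median
  q4 <- tibble::tibble(site_id = letters[1:6],
                       transcription_level = 1:6, delta = rnorm(6))
  res4 <- group_compare(q4, "transcription", "delta", "greater")
  expect_equal(res4$n1, 3L)
  expect_equal(res4$n2, 3L)

  # repair grouping
  q5 <- tibble::tibble(site_id = letters[1:6],
                       repair_class = rep(c("HR", "NHEJ", "unassigned"), 2),
                       delta = c(1, 2, 3, 4, 5, 6))
  res5 <- group_compare(q5, "repair", "delta", "less")
  expect_equal(res5$n1 + res5$n2, 4L)  # unassigned excluded
})

test_that("hybrid_correlation: exact linear case and degenerate input", {
  q <- tibble::tibble(preexisting = 1:10,
                      log2fc_ctrl = 2 * (1:10) + 3,
                      log2fc_kd = rep(1, 10))
  res <- hybrid_correlation(q, "ctrl")
  expect_equal(res$r, 1)
  expect_equal(res$p_value, 0)
  expect_error(hybrid_correlation(q, "kd"), "variance")
  expect_error(hybrid_correlation(q[1:2, ], "ctrl"), ">= 3")
})

test_that("glance on a classified table reports counts and planted accuracy", {
  q <- classify_sites(tibble::tibble(
    site_id = letters[1:4],
    delta = c(-2, 0, 0.1, 2),
    true_class = c("dependent", "independent", "increased", "increased")
  ))
  g <- glance(q)
  expect_equal(g$n_dependent, 1L)
  expect_equal(g$n_independent, 2L)
  expect_equal(g$n_increased, 1L)
  expect_equal(g$accuracy, 0.75)
})
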