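test_that("gain/loss calls use strict log2 thresholds", {
  seg <- cn_segment("S1", "chr1", c(1, 101, 201, 301), c(100, 200, 300, 400),
                    c(0.31, -0.31, 0.3, 0))
  calls <- call_gain_loss(seg)$call
  expect_equal(calls, c("gain", "loss", "neutral", "neutral"))
  expect_error(call_gain_loss(seg, gain_threshold = -0.1), "loss_threshold")
})

test_that("region partitioning is the minimal breakpoint-union tiling", {
  segs <- rbind(cn_segment("A", "chr1", c(1, 101), c(100, 200), 0),
                cn_segment("B", "chr1", c(1, 151), c(150, 200), 0))
  reg <- partition_regions(segs)
  expect_equal(reg$start, c(1, 101, 151))
  expect_equal(reg$end, c(100, 150, 200))

  single <- cn_segment("A", "chr1", c(1, 51), c(50, 80), 0)
  expect_equal(partition_regions(single)[, c("start", "end")],
               data.frame(start = c(1, 51), end = c(50, 80)))

  # identical segmentations collapse to themselves
  both <- rbind(single, cn_segment("B", "chr1", c(1, 51), c(50, 80), 0))
  expect_equal(partition_regions(both), partition_regions(single))

  overlapping <- cn_segment("A", "chr1", c(1, 40), c(50, 80), 0)
  expect_error(partition_regions(overlapping), "overlapping")
})

test_that("every input segment is a union of consecutive regions", {
  withr::with_seed(3, {
    segs <- do.call(rbind, lapply(c("A", "B", "C"), function(s) {
      bp <- sort(sample(2:999, 8))
      cn_segment(s, "chr1", c(1, bp), c(bp - 1, 1000), rnorm(9, 0, 0.3))
    }))
  })
  reg <- partition_regions(segs)
  expect_true(all(reg$start[-1] > reg$end[-nrow(reg)]))  # no overlap, sorted
  for (i in seq_len(nrow(segs))) {
    inside <- reg[reg$start >= segs$start[i] & reg$end <= segs$end[i], ]
    expect_equal(min(inside$start), segs$start[i])
    expect_equal(max(inside$end), segs$end[i])
    expect_true(all(inside$start[-1] == inside$end[-nrow(inside)] + 1))
  }
})

test_that("region matrix copies parent segment values and masks gaps", {
  segs <- rbind(cn_segment("A", "chr1", c(1, 101), c(100, 200), c(0.5, -0.4)),
                cn_segment("B", "chr1", c(1, 151), c(150, 200), c(0.1, 0.9)))
  m <- build_region_matrix(segs)
  expect_equal(m$values[, "A"], c(0.5, -0.4, -0.4))
  expect_equal(m$values[, "B"], c(0.1, 0.1, 0.9))
  expect_true(all(m$mask))

  zero <- build_region_matrix(cn_segment("A", "chr1", 1, 100, 0))
  expect_equal(unname(zero$values), matrix(0))

  gap <- rbind(cn_segment("A", "chr1", 1, 200, 0.2),
               cn_segment("B", "chr1", 101, 200, 0.3))
  mg <- build_region_matrix(gap)
  expect_true(is.na(mg$values[1, "B"]))
  expect_equal(mean(mg$mask), 0.75)

  # reading a row back reproduces the sample's profile over covered span
  expect_equal(mg$values[!is.na(mg$values[, "A"]), "A"], c(0.2, 0.2))
})

test_that("profile correlations behave at the exact and degenerate limits", {
  segs <- do.call(rbind, lapply(1:20, function(i) {
    cn_segment(c("A", "B", "C"), "chr1", (i - 1) * 10 + 1, i * 10,
               c(i %% 5 - 2, i %% 5 - 2, 2 - i %% 5))
  }))
  m <- build_region_matrix(segs)
  expect_equal(pairwise_cn_correlation(m, c("A", "B")), 1.0)
  expect_equal(pairwise_cn_correlation(m, c("A", "C")), -1.0)
  expect_equal(pairwise_cn_correlation(m, c("A", "A")), 1.0)

  flat <- build_region_matrix(cn_segment(rep(c("A", "B"), each = 3), "chr1",
                                         rep(c(1, 11, 21), 2),
                                         rep(c(10, 20, 30), 2),
                                         c(1, 2, 3, 0, 0, 0)))
  expect_warning(r <- pairwise_cn_correlation(flat, c("A", "B")), "constant")
  expect_true(is.na(r))

  tiny <- build_region_matrix(cn_segment(c("A", "B"), "chr1", 1, 10, 0:1))
  expect_error(pairwise_cn_correlation(tiny, c("A", "B")), "fewer than 3")
})

test_that("independent simulated profiles stay near zero correlation", {
  ref <- generate_reference(50000, 0.4, seed = 12)
  hits <- 0L
  for (s in 1:100) {
    cfg <- sim_config(n_patients = 1, tumors_per_patient = 2,
                      relationship = "independent", n_mutations = 10L,
                      cn_model = list(n_bins = 200L, n_events = 4L,
                                      event_log2 = 0.8, noise_sd = 0.1,
                                      share_fraction = 0.8),
                      seed = 3000L + s)
    p <- simulate_patient(cfg, ref, 1)
    m <- build_region_matrix(p$segments)
    r <- pairwise_cn_correlation(m, colnames(m$values)[1:2])
    if (abs(r) < 0.3) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("background relatedness assessment flags only true clonal pairs", {
  # degenerate cohort: identical profiles everywhere
  segs <- do.call(rbind, lapply(sprintf("P%dT%d", rep(1:2, each = 2), 1:2),
    function(s) cn_segment(s, "chr1", c(1, 11, 21, 31), c(10, 20, 30, 40),
                           c(0.5, -0.5, 0.2, 0))))
  m <- build_region_matrix(segs)
  sp <- setNames(rep(c("P1", "P2"), each = 2), colnames(m$values))
  res <- relatedness_from_background(m, sp)
  expect_true(res$degenerate)
  expect_s3_class(res$pairs, "data.frame")

  # vacuous percentile: nothing can strictly exceed the maximum
  withr::with_seed(9, {
    segs2 <- do.call(rbind, lapply(sprintf("P%dT%d", rep(1:3, each = 2), 1:2),
      function(s) cn_segment(s, "chr1", seq(1, 291, 10), seq(10, 300, 10),
                             rnorm(30, 0, 0.2))))
  })
  m2 <- build_region_matrix(segs2)
  sp2 <- setNames(rep(c("P1", "P2", "P3"), each = 2), colnames(m2$values))
  res2 <- relatedness_from_background(m2, sp2, percentile = 1.0)
  expect_false(any(res2$pairs$cn_related))
  one_patient <- build_region_matrix(
    segs[segs$sample_id %in% c("P1T1", "P1T2"), ])
  expect_error(relatedness_from_background(one_patient, sp), "2 patients")
})

test_that("recurrent-region annotation merges first and applies the 50% rule", {
  segs <- call_gain_loss(cn_segment("S", "chr1",
                                    c(1, 51, 101, 201), c(50, 100, 200, 300),
                                    c(0.6, 0.8, -0.6, 0.1)))
  rec <- data.frame(contig = "chr1",
                    start = c(1, 1, 101), end = c(200, 196, 200),
                    direction = c("amplified", "amplified", "amplified"),
                    label = c("AMP_half", "AMP_49", "AMP_wrongdir"),
                    stringsAsFactors = FALSE)
  ann <- annotate_recurrent(segs, rec)
  # adjacent gains 1-50 and 51-100 merge into one 1-100 gain
  gain <- ann[ann$call == "gain", ]
  expect_equal(nrow(gain), 1L)
  expect_equal(c(gain$start, gain$end), c(1, 100))
  # covers exactly 100/200 = 50% of AMP_half (inclusive), 100/196 > 50% of
  # AMP_49; the loss segment under AMP_wrongdir direction-matches nothing
  expect_setequal(strsplit(gain$recurrent_label, ",")[[1]],
                  c("AMP_half", "AMP_49"))
  loss <- ann[ann$call == "loss", ]
  expect_equal(loss$recurrent_label, "")
})

test_that("49% coverage does not annotate", {
  segs <- call_gain_loss(cn_segment("S", "chr1", 1, 49, 0.9))
  rec <- data.frame(contig = "chr1", start = 1, end = 100,
                    direction = "amplified", label = "AMP",
                    stringsAsFactors = FALSE)
  expect_equal(annotate_recurrent(segs, rec)$recurrent_label, "")
})
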