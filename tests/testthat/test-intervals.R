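test_that("interval sets merge and are idempotent", {
  raw <- tibble::tibble(chrom = "c", start = c(0, 50, 200, 210),
                        end = c(100, 120, 250, 220))
  iv <- interval_set(raw)
  expect_equal(nrow(iv), 2L)
  expect_equal(attr(iv, "total_coverage"), 120 + 50)
  expect_identical(as.data.frame(interval_set(iv)), as.data.frame(iv))
})

test_that("base-coverage overlap handles the canonical cases", {
  A <- tibble::tibble(chrom = "c", start = 0, end = 100)
  B <- tibble::tibble(chrom = "c", start = 50, end = 150)
  ov <- base_coverage_overlap(A, B)
  expect_equal(ov$pct_A_in_B, 50)
  expect_equal(ov$shared_bp, 50)
  self <- base_coverage_overlap(A, A)
  expect_equal(self$pct_A_in_B, 100)
  expect_equal(self$pct_B_in_A, 100)
  empty <- tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric())
  expect_warning(ov2 <- base_coverage_overlap(empty, B), "undefined")
  expect_true(is.na(ov2$pct_A_in_B))
})

test_that("random overlaps match the per-base oracle", {
  set.seed(14)
  for (i in 1:50) {
    L <- 10000L
    A <- random_intervals(sample(3:10, 1), L)
    B <- random_intervals(sample(3:10, 1), L)
    ov <- base_coverage_overlap(A, B)
    # per-base masks must be computed on the merged sets
    Am <- interval_set(A)
    Bm <- interval_set(B)
    br <- oracle_base_overlap(Am, Bm, L)
    expect_equal(ov$shared_bp, br$shared_bp)
    expect_equal(ov$pct_A_in_B, br$pct_A_in_B)
    expect_equal(ov$pct_B_in_A, br$pct_B_in_A)
    expect_true(ov$pct_A_in_B >= 0 && ov$pct_A_in_B <= 100)
    expect_lte(ov$shared_bp, min(attr(Am, "total_coverage"),
                                 attr(Bm, "total_coverage")))
  }
})

test_that("peak containment follows the midpoint rule", {
  regions <- tibble::tibble(chrom = "c", start = c(0, 500), end = c(100, 600))
  peaks <- tibble::tibble(chrom = "c",
                          start = c(10, 80, 520, 300),
                          end = c(30, 118, 560, 340))
  pf <- peak_fraction_within(peaks, regions)
  expect_equal(pf$n_within, 3L)
  expect_equal(pf$pct, 75)
  whole <- tibble::tibble(chrom = "c", start = 0, end = 1000)
  expect_equal(peak_fraction_within(peaks, whole)$pct, 100)
  expect_error(peak_fraction_within(peaks[0, ], regions), "empty")
})

test_that("random peak fractions match per-peak classification", {
  set.seed(3)
  L <- 10000L
  regions <- interval_set(random_intervals(5, L, max_w = 1500L))
  for (i in 1:10) {
    peaks <- random_intervals(20, L, max_w = 200L)
    pf <- peak_fraction_within(peaks, regions)
    expect_equal(pf$n_within, oracle_peaks_within(peaks, regions))
  }
  # any_overlap counts >= 1 shared base
  peaks <- tibble::tibble(chrom = "toy", start = regions$end[1] - 1,
                          end = regions$end[1] + 50)
  expect_equal(peak_fraction_within(peaks, regions, mode = "any_overlap")$n_within, 1L)
})

test_that("boundary profiles reproduce an indicator step and constants", {
  regions <- tibble::tibble(chrom = "c", start = 2e5, end = 5e5)
  indicator <- tibble::tibble(chrom = "c", start = c(0, 2e5, 5e5),
                              end = c(2e5, 5e5, 1e6), score = c(0, 1, 0))
  p <- boundary_profile(indicator, regions, flank = 1e5, step = 1e4)
  expect_equal(p$mean[p$offset < 0], rep(0, 10))
  expect_equal(p$mean[p$offset >= 0], rep(1, 10))
  expect_equal(attr(p, "n_anchors"), 2L)

  const <- tibble::tibble(chrom = "c", start = 0, end = 1e6, score = 4.2)
  pc <- boundary_profile(const, regions, flank = 1e5, step = 1e4)
  expect_equal(pc$mean, rep(4.2, 20))
})

test_that("boundary profiles average across anchors with data", {
  # two regions with inside values 1 and 3 -> inside mean 2
  regions <- tibble::tibble(chrom = "c", start = c(2e5, 6e5),
                            end = c(35e4, 75e4))
  track <- tibble::tibble(
    chrom = "c",
    start = c(0, 2e5, 35e4, 6e5, 75e4),
    end = c(2e5, 35e4, 6e5, 75e4, 1e6),
    score = c(0, 1, 0, 3, 0)
  )
  p <- boundary_profile(track, regions, flank = 5e4, step = 1e4)
  expect_equal(p$mean[p$offset >= 0], rep(2, 5))
  expect_equal(p$mean[p$offset < 0], rep(0, 5))
  expect_equal(unique(p$n), 4L)
})

test_that("region filtering and bounds clipping behave", {
  regions <- tibble::tibble(chrom = "c", start = c(0, 5e5),
                            end = c(5e4, 8e5)) # first too short
  const <- tibble::tibble(chrom = "c", start = 0, end = 1e6, score = 1)
  p <- boundary_profile(const, regions, min_region = 1e5, flank = 1e5,
                        step = 1e4)
  expect_equal(attr(p, "n_anchors"), 2L)
  expect_error(boundary_profile(const, regions, min_region = 1e6), "min_region")
  # anchor near chromosome start: out-of-bounds bins drop from n
  a <- anchor_profile(const, tibble::tibble(chrom = "c", pos = 2e4),
                      flank = 5e4, step = 1e4)
  expect_true(all(a$n[a$offset < -2e4] == 0))
  expect_true(all(a$n[a$offset >= -2e4] == 1))
})

test_that("anchor profiles sample a ramp and preserve symmetry", {
  # piecewise track increasing by 1 per 10 kb bin: profile = ramp
  track <- tibble::tibble(chrom = "c", start = seq(0, 9e5, 1e4),
                          end = seq(1e4, 9.1e5, 1e4),
                          score = seq_len(91))
  a <- anchor_profile(track, tibble::tibble(chrom = "c", pos = 5e5),
                      flank = 5e4, step = 1e4)
  expect_equal(diff(a$mean), rep(1, 9))
  expect_equal(a$mean[a$offset == 0], 51)

  # two anchors at mirror positions of a symmetric track
  sym <- tibble::tibble(chrom = "c", start = c(0, 4e5, 6e5),
                        end = c(4e5, 6e5, 1e6), score = c(0, 5, 0))
  p2 <- anchor_profile(sym, tibble::tibble(chrom = "c", pos = c(4e5, 6e5)),
                       flank = 1e5, step = 1e4)
  expect_equal(p2$mean, rev(p2$mean))
})

test_that("random anchor profiles match brute-force window averaging", {
  set.seed(27)
  width <- 100L
  track <- make_score_track(rnorm(100), width = width, chrom = "toy")
  track$score[sample(100, 10)] <- NA
  anchors <- tibble::tibble(chrom = "toy", pos = sample(2000:8000, 5))
  p <- anchor_profile(track, anchors, flank = 500, step = 100)
  for (o in p$offset) {
    vals <- c()
    for (i in seq_len(nrow(anchors))) {
      v <- oracle_window_mean(track, "toy", anchors$pos[i] + o,
                              anchors$pos[i] + o + 100)
      if (!is.na(v)) vals <- c(vals, v)
    }
    expect_equal(p$mean[p$offset == o],
                 if (length(vals)) mean(vals) else NA_real_)
    expect_equal(p$n[p$offset == o], length(vals))
  }
})

test_that("jaccard index behaves at the limits", {
  A <- tibble::tibble(chrom = "c", start = 0, end = 100)
  B <- tibble::tibble(chrom = "c", start = 200, end = 300)
  expect_equal(interval_jaccard(A, A), 1)
  expect_equal(interval_jaccard(A, B), 0)
  expect_equal(interval_jaccard(A, tibble::tibble(chrom = "c", start = 50,
                                                  end = 150)), 50 / 150)
})
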