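test_that("prefix sums reproduce direct window summation", {
  set.seed(3)
  per_frame <- matrix(abs(rnorm(40 * 6)) + 0.1, 40, 6)
  series <- new_profile_series(seq(0.05, 0.3, length.out = 6), per_frame)
  for (rep in 1:20) {
    s <- sample(0:39, 1); e <- sample((s + 1):40, 1)
    direct <- colSums(per_frame[(s + 1):e, , drop = FALSE])
    expect_equal(series$prefix[e + 1, ] - series$prefix[s + 1, ], direct,
                 tolerance = 1e-12)
  }
  one <- new_profile_series(1:3 / 10, matrix(c(1, 2, 3), 1, 3))
  expect_equal(one$prefix[2, ] - one$prefix[1, ], c(1, 2, 3))
})

test_that("identical frames give window sums proportional to one row", {
  row <- abs(rnorm(5)) + 0.5
  series <- new_profile_series(seq(0.02, 0.2, length.out = 5),
                               matrix(row, 10, 5, byrow = TRUE))
  expect_equal(series$prefix[8, ] - series$prefix[1, ], 7 * row)
})

test_that("window evaluation applies strict inequalities", {
  inst <- random_clip_instance(12, seed = 21)
  ev <- evaluate_window(inst$series, 0, 12, inst$exp_profile,
                        clip_criteria(use_residual_band = FALSE))
  # a threshold set exactly at the achieved chi2 must fail (strict <)
  crit_eq <- clip_criteria(chi2_max = ev$fit$chi2, use_residual_band = FALSE)
  expect_false(evaluate_window(inst$series, 0, 12, inst$exp_profile,
                               crit_eq)$passes)
  crit_above <- clip_criteria(chi2_max = ev$fit$chi2 * (1 + 1e-9),
                              use_residual_band = FALSE)
  expect_true(evaluate_window(inst$series, 0, 12, inst$exp_profile,
                              crit_above)$passes)
  expect_error(evaluate_window(inst$series, 5, 5, inst$exp_profile),
               "invalid window")
})

test_that("a window matching the target exactly passes with chi2 0", {
  q <- seq(0.02, 0.25, length.out = 8)
  row <- exp(-25 * q^2)
  series <- new_profile_series(q, matrix(row, 6, 8, byrow = TRUE))
  p <- saxs_profile(q, 5 * row + 2, runif(8, 0.5, 2))
  ev <- evaluate_window(series, 1, 4, p, clip_criteria())
  expect_equal(ev$fit$chi2, 0, tolerance = 1e-18)
  expect_true(ev$passes)
})

test_that("longest and enumerated windows agree with brute force", {
  # random small instances, both criteria variants
  for (seed in 1:12) {
    inst <- random_clip_instance(n_frames = sample(6:20, 1), seed = seed)
    crit <- clip_criteria(chi2_max = sample(c(1, 3, 10), 1),
                          use_residual_band = seed %% 2 == 0)
    oracle <- brute_force_windows(inst$series$per_frame, inst$exp_profile, crit)
    res <- longest_matching_window(inst$series, inst$exp_profile, crit)
    expect_equal(res$found, oracle$found)
    if (oracle$found) {
      expect_equal(res$start_frame, unname(oracle$start))
      expect_equal(res$end_frame, unname(oracle$end))
    }
    enum <- enumerate_matching_windows(inst$series, inst$exp_profile, crit)
    if (is.null(oracle$windows)) {
      expect_equal(nrow(enum), 0)
    } else {
      expect_equal(nrow(enum), nrow(oracle$windows))
      expect_equal(enum$start, unname(oracle$windows[, "start"]))
      expect_equal(enum$end, unname(oracle$windows[, "end"]))
    }
  }
})

test_that("acceptance is not monotone in window extent", {
  # two frames with different curve shapes; the 2-frame window matches the
  # target exactly while each 1-frame sub-window fails
  q <- seq(0.02, 0.3, length.out = 12)
  a <- exp(-40 * q^2)
  b <- exp(-10 * q^2) * 0.7
  series <- new_profile_series(q, rbind(a, b))
  target <- saxs_profile(q, (a + b) / 2, pmax((a + b) * 5e-4, 1e-6))
  crit <- clip_criteria(use_residual_band = FALSE)
  expect_true(evaluate_window(series, 0, 2, target, crit)$passes)
  expect_false(evaluate_window(series, 0, 1, target, crit)$passes)
  expect_false(evaluate_window(series, 1, 2, target, crit)$passes)
  res <- longest_matching_window(series, target, crit)
  expect_equal(c(res$start_frame, res$end_frame), c(0L, 2L))
})

test_that("all-identical passing frames enumerate combinatorially", {
  q <- seq(0.02, 0.25, length.out = 8)
  row <- exp(-25 * q^2)
  series <- new_profile_series(q, matrix(row, 4, 8, byrow = TRUE))
  p <- saxs_profile(q, 3 * row, runif(8, 0.5, 1))
  enum <- enumerate_matching_windows(series, p,
                                     clip_criteria(use_residual_band = FALSE),
                                     min_length = 2)
  expect_equal(nrow(enum), 6)  # windows of length >= 2 out of 4 frames
  res <- longest_matching_window(series, p,
                                 clip_criteria(use_residual_band = FALSE))
  expect_equal(c(res$start_frame, res$end_frame), c(0L, 4L))
  only_max <- enumerate_matching_windows(series, p,
                                         clip_criteria(use_residual_band = FALSE),
                                         min_length = 2, maximal_only = TRUE)
  expect_equal(nrow(only_max), 1)
  expect_equal(c(only_max$start, only_max$end), c(0L, 4L))
})

test_that("no-match search reports found = FALSE", {
  inst <- random_clip_instance(8, seed = 4)
  crit <- clip_criteria(chi2_max = 1e-14, use_residual_band = FALSE)
  res <- longest_matching_window(inst$series, inst$exp_profile, crit)
  expect_false(res$found)
  expect_true(is.na(res$start_frame))
  expect_equal(nrow(enumerate_matching_windows(inst$series, inst$exp_profile,
                                               crit)), 0)
})

test_that("duration multiplies snapshot count by the frame interval", {
  expect_equal(clip_duration(0, 1345, 2), 2690)
  expect_equal(clip_duration(0, 1, 2), 2)
  expect_equal(clip_duration(100, 450, 2), 700)  # the minimum-duration edge
  expect_equal(clip_duration(3, 7, 0.5), 2)
  expect_error(clip_duration(5, 5), "empty window")
})

test_that("min_duration is a reporting flag, not a search filter", {
  q <- seq(0.02, 0.25, length.out = 8)
  row <- exp(-25 * q^2)
  series <- new_profile_series(q, matrix(row, 5, 8, byrow = TRUE),
                               frame_interval = 2)
  p <- saxs_profile(q, 3 * row, runif(8, 0.5, 1))
  crit <- clip_criteria(min_duration = 1e6, use_residual_band = FALSE)
  res <- longest_matching_window(series, p, crit)
  expect_true(res$found)           # still returned
  expect_false(res$meets_min_duration)
})
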