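map_from <- function(p, x_edges = 0:nrow(p), y_edges = 0:ncol(p)) {
  out <- list(x_edges = x_edges, y_edges = y_edges, p = p / sum(p))
  class(out) <- "prob_map2d"
  out
}

test_that("support region pairs C1 with its adjacent shell C2", {
  p <- matrix(0, 5, 5); p[3, 3] <- 1
  s <- support_union(map_from(p))
  expect_equal(sum(s$c1), 1)
  expect_equal(sum(s$c2), 8)            # full 8-neighbourhood, interior cell
  expect_false(any(s$c1 & s$c2))

  p <- matrix(0, 5, 5); p[1, 1] <- 1
  s <- support_union(map_from(p))
  expect_equal(sum(s$c2), 3)            # clipped at the corner

  p <- matrix(0, 5, 5); p[2, 2] <- 0.5; p[3, 3] <- 0.5
  s <- support_union(map_from(p))
  # direct set-enumeration oracle
  c2_oracle <- matrix(FALSE, 5, 5)
  for (cell in list(c(2, 2), c(3, 3)))
    for (dx in -1:1) for (dy in -1:1)
      c2_oracle[cell[1] + dx, cell[2] + dy] <- TRUE
  c2_oracle[2, 2] <- FALSE; c2_oracle[3, 3] <- FALSE
  expect_equal(s$c2, c2_oracle)

  s4 <- support_union(map_from(p), adjacency = 4)
  expect_equal(sum(s4$c2), 6)           # diagonals excluded, shared cells once

  empty <- list(x_edges = 0:2, y_edges = 0:2, p = matrix(0, 2, 2))
  class(empty) <- "prob_map2d"
  expect_error(support_union(empty), "empty map")
})

test_that("KL is zero for self-comparison and ln 2 on the two-bin example", {
  set.seed(23)
  p <- matrix(runif(25), 5, 5)
  m <- map_from(p)
  expect_equal(kl_sas_clip(m, m), 0, tolerance = 1e-12)

  # C1 = {b1} with P_clip 1, C2 contains b2; P_orig = 0.25 on each of b1, b2
  pc <- matrix(0, 4, 4); pc[2, 2] <- 1
  po <- matrix(0, 4, 4); po[2, 2] <- 0.25; po[2, 3] <- 0.25
  po[4, 1] <- 0.5   # rest of the source mass, away from C1 u C2
  expect_equal(kl_sas_clip(map_from(pc), map_from(po)), log(2),
               tolerance = 1e-12)
  # configurable log base
  expect_equal(kl_sas_clip(map_from(pc), map_from(po), base = 2), 1,
               tolerance = 1e-12)
})

test_that("KL is non-negative and errors on inconsistent supports", {
  set.seed(29)
  for (rep in 1:20) {
    po <- matrix(runif(36) + 1e-3, 6, 6)
    pc <- po * matrix(rbinom(36, 1, 0.4), 6, 6) * runif(36)
    if (all(pc == 0)) pc[3, 3] <- 1
    kl <- kl_sas_clip(map_from(pc), map_from(po))
    expect_gte(kl, -1e-12)
  }
  pc <- matrix(0, 3, 3); pc[1, 1] <- 1
  po <- matrix(0, 3, 3); po[3, 3] <- 1
  expect_error(kl_sas_clip(map_from(pc), map_from(po)), "undefined")
  expect_error(kl_sas_clip(map_from(pc),
                           map_from(matrix(1, 4, 4))), "bin edges")
})

test_that("renormalizing the source can only lower the restricted sum", {
  set.seed(37)
  for (rep in 1:10) {
    po <- matrix(runif(49) + 1e-3, 7, 7)
    pc <- matrix(0, 7, 7)
    occ <- sample(49, 6)
    pc[occ] <- runif(6)
    mc <- map_from(pc); mo <- map_from(po)
    kl <- kl_sas_clip(mc, mo)
    nz <- mc$p > 0
    unrenorm <- sum(mc$p[nz] * log(mc$p[nz] / mo$p[nz]))
    expect_lte(kl, unrenorm + 1e-12)
  }
})

test_that("frame-subset maps never trigger the undefined-divergence error", {
  set.seed(41)
  xs <- runif(400, 50, 150); ys <- runif(400, 50, 150)
  edges <- seq(50, 150, by = 10)
  full <- probability_map(xs, ys, edges, edges)
  for (rep in 1:10) {
    idx <- sample(400, sample(5:100, 1))
    sub <- probability_map(xs[idx], ys[idx], edges, edges)
    expect_no_error(kl_sas_clip(sub, full))
  }
})

test_that("KL shrinks with duration on a multi-state hinge system", {
  g <- small_hinge_system(seed = 11, n_frames = 300)
  # broad-noise target built from the whole trajectory so that windows of
  # many lengths pass the chi2 criterion
  target <- make_target_profile(g$trajectory, c(0, 300),
                                noise_fraction = 0.02, seed = 11,
                                q = seq(0.01, 0.3, length.out = 50))
  series <- build_profile_series(g$trajectory, target)
  desc <- descriptor_series(g$trajectory, g$truth$domains)
  edges <- seq(60, 170, by = 5)
  tab <- kl_vs_duration(series, target,
                        clip_criteria(use_residual_band = FALSE), desc,
                        x_edges = edges, y_edges = edges,
                        min_length = 10, max_windows = 3000)
  expect_gt(nrow(tab), 50)
  expect_true(all(tab$kl >= -1e-12))
  # full-trajectory window has KL exactly 0
  full_row <- tab[tab$start == 0 & tab$end == 300, ]
  if (nrow(full_row) == 1) expect_equal(full_row$kl, 0, tolerance = 1e-12)
  # median KL in the long-duration stratum does not exceed the short one
  med <- median(tab$duration_ns)
  kl_short <- median(tab$kl[tab$duration_ns <= med])
  kl_long <- median(tab$kl[tab$duration_ns > med])
  expect_lte(kl_long, kl_short)
})

test_that("single-frame windows sit near the KL maximum", {
  g <- small_hinge_system(seed = 12, n_frames = 120)
  desc <- descriptor_series(g$trajectory, g$truth$domains)
  edges <- seq(60, 170, by = 5)
  full <- probability_map(desc$theta_abb, desc$theta_bba, edges, edges)
  kl_one <- kl_sas_clip(probability_map(desc$theta_abb[1], desc$theta_bba[1],
                                        edges, edges), full)
  kl_half <- kl_sas_clip(probability_map(desc$theta_abb[1:60],
                                         desc$theta_bba[1:60], edges, edges),
                         full)
  expect_gt(kl_one, kl_half)
})
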