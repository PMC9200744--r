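test_that("intensity spread matches a direct column-wise statistic", {
  set.seed(51)
  per_frame <- matrix(abs(rnorm(30 * 8, 1, 0.2)) + 0.1, 30, 8)
  series <- new_profile_series(seq(0.02, 0.3, length.out = 8), per_frame)
  sp <- intensity_spread(series)
  oracle <- apply(log10(per_frame), 2, sd)
  expect_equal(sp$spread, oracle, tolerance = 1e-12)

  same <- new_profile_series(1:4 / 10, matrix(2, 5, 4))
  expect_equal(intensity_spread(same)$spread, rep(0, 4))

  two <- new_profile_series(1:3 / 10,
                            rbind(c(1, 1, 1), c(10, 1, 1)))
  expect_equal(intensity_spread(two)$spread[1], sd(c(0, 1)))

  neg <- new_profile_series(1:3 / 10, rbind(c(1, -1, 1), c(1, 1, 1)))
  expect_error(intensity_spread(neg), "non-positive")
  expect_error(intensity_spread(new_profile_series(1:3 / 10,
                                                   matrix(1, 1, 3))),
               "2 frames")
})

test_that("a planted linear family yields exactly its isosbestic point", {
  fam <- planted_linear_family()
  pts <- isosbestic_points(fam$series, q_band = c(0.06, 0.29))
  expect_equal(pts, fam$q_star, tolerance = 1e-12)

  # spread-based detection is invariant to uniform intensity rescaling
  scaled <- new_profile_series(fam$q, fam$series$per_frame * 123.4)
  expect_equal(isosbestic_points(scaled, c(0.06, 0.29)), pts,
               tolerance = 1e-12)

  # identical frames: degenerate, empty with a warning
  same <- new_profile_series(fam$q,
                             matrix(fam$A, 10, length(fam$q), byrow = TRUE))
  expect_warning(res <- isosbestic_points(same, c(0.06, 0.29)), "degenerate")
  expect_length(res, 0)

  # slope bounded away from zero: no isosbestic point
  set.seed(6)
  B2 <- 0.05 + 0.02 * fam$q
  pf <- outer(fam$x, B2) + rep(fam$A, each = length(fam$x))
  none <- isosbestic_points(new_profile_series(fam$q, pf), c(0.06, 0.29))
  expect_length(none, 0)
  expect_error(isosbestic_points(fam$series, c(0.5, 0.6)), "empty band")
})

test_that("linear response recovers a planted family perfectly", {
  fam <- planted_linear_family()
  lr <- linear_response_fit(fam$series, fam$x)
  expect_equal(lr$r2, rep(1, length(fam$q)), tolerance = 1e-10)
  expect_equal(lr$slope, fam$B, tolerance = 1e-10)
  # intercept reports I(Q, X0) at X0 = mean(x)
  expect_equal(attr(lr, "x0"), mean(fam$x))
  expect_equal(lr$intercept, fam$A + mean(fam$x) * fam$B, tolerance = 1e-10)
  # zero slope at the planted isosbestic point
  expect_lt(abs(lr$slope[fam$istar]), 1e-10 * max(abs(lr$slope)))
})

test_that("regression residuals are orthogonal to the coordinate", {
  set.seed(61)
  per_frame <- matrix(abs(rnorm(50 * 12, 1, 0.3)) + 0.2, 50, 12)
  series <- new_profile_series(seq(0.02, 0.3, length.out = 12), per_frame)
  x <- rnorm(50)
  lr <- linear_response_fit(series, x)
  xc <- x - mean(x)
  fitted <- outer(xc, lr$slope) + rep(lr$intercept, each = 50)
  resid <- per_frame - fitted
  expect_true(all(abs(crossprod(xc, resid)) < 1e-10))
  expect_error(linear_response_fit(series, rep(1, 50)), "constant x")
})

test_that("an unrelated coordinate gives near-zero explained variance", {
  set.seed(71)
  n <- 250
  per_frame <- matrix(abs(rnorm(n * 40, 1, 0.2)) + 0.1, n, 40)
  series <- new_profile_series(seq(0.02, 0.3, length.out = 40), per_frame)
  x <- rnorm(n)  # independent of the intensities
  lr <- linear_response_fit(series, x)
  expect_gte(mean(lr$r2 < 0.2), 0.95)
})

test_that("recombination recovers constructed mixtures", {
  # single series: weight 1, zero residual
  one <- recombine_ensembles(matrix(c(1, 2, 3), 3, 1), c(1, 2, 3))
  expect_equal(one$weights, 1)
  expect_equal(one$residual_norm, 0, tolerance = 1e-12)

  set.seed(81)
  A <- matrix(rnorm(40 * 2), 40, 2)
  target <- A %*% c(0.3, 0.7)
  res <- recombine_ensembles(A, target)
  expect_equal(res$weights, c(0.3, 0.7), tolerance = 1e-8)
  expect_lt(res$residual_norm, 1e-10)
})

test_that("targets outside the simplex land on its boundary", {
  set.seed(91)
  A <- matrix(rnorm(30 * 3), 30, 3)
  target <- A %*% c(1.8, -0.5, -0.3)  # outside the simplex hull
  res <- recombine_ensembles(A, target)
  expect_true(any(res$weights < 1e-9))
  expect_gt(res$residual_norm, 0)
  expect_equal(sum(res$weights), 1, tolerance = 1e-12)
  expect_true(all(res$weights >= 0))
  # dense simplex grid oracle: no grid point beats the active-set solution
  grid <- expand.grid(w1 = seq(0, 1, by = 0.02), w2 = seq(0, 1, by = 0.02))
  grid <- grid[grid$w1 + grid$w2 <= 1, ]
  rss <- apply(grid, 1, function(g) {
    w <- c(g[1], g[2], 1 - g[1] - g[2])
    sum((A %*% w - target)^2)
  })
  expect_lte(res$residual_norm^2, min(rss) + 1e-9)
})

test_that("mixture weights survive small observable noise", {
  ok <- 0
  for (seed in 1:20) {
    set.seed(seed)
    A <- matrix(rnorm(50 * 3, sd = 1), 50, 3)
    w_true <- c(0.2, 0.5, 0.3)
    target <- as.vector(A %*% w_true)
    target <- target + rnorm(50, 0, 1e-3 * pmax(abs(target), 1e-6))
    res <- recombine_ensembles(A, target)
    if (max(abs(res$weights - w_true)) < 0.01) ok <- ok + 1
  }
  expect_gte(ok, 19)
})

test_that("unconstrained mode reduces to ordinary least squares", {
  set.seed(101)
  A <- matrix(rnorm(20 * 2), 20, 2)
  target <- A %*% c(1.4, -0.6)
  res <- recombine_ensembles(A, target, constrained = FALSE)
  expect_equal(res$weights, c(1.4, -0.6), tolerance = 1e-10)
  expect_error(recombine_ensembles(A, c(1, 2)), "dimension mismatch")
})
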