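# Shared fixtures and independent oracles.

# Random bead structure with positive weights.
random_structure <- function(n = 10, weight = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bead_structure(matrix(rnorm(n * 3, sd = 8), n, 3),
                 weight = weight %||% sample(c(1, 6, 7, 8, 16), n, TRUE))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent weighted-LS oracle via R's QR-based lm():
# I_sim = c * m - offs  <=>  y ~ intercept + slope * m with
# slope = c, intercept = -offs.
lm_fit_oracle <- function(y, m, sigma) {
  w <- 1 / sigma^2
  fit <- stats::lm(y ~ m, weights = w)
  cc <- unname(coef(fit)[2]); offs <- -unname(coef(fit)[1])
  r <- (y - (cc * m - offs)) / sigma
  list(c = cc, offs = offs, chi2 = sum(r^2) / (length(y) - 1),
       squared_residuals = r^2)
}

# Iteratively refined dense grid search over (c, offs) minimizing chi2.
grid_fit_oracle <- function(y, m, sigma, rounds = 6, nsteps = 41) {
  chi2_at <- function(cc, offs)
    sum(((y - (cc * m - offs)) / sigma)^2) / (length(y) - 1)
  start <- lm_fit_oracle(y, m, sigma)
  cc <- start$c; offs <- start$offs
  span_c <- max(abs(cc), 1) * 0.5
  span_o <- max(abs(offs), 1) * 0.5
  for (r in seq_len(rounds)) {
    cs <- seq(cc - span_c, cc + span_c, length.out = nsteps)
    os <- seq(offs - span_o, offs + span_o, length.out = nsteps)
    grid <- expand.grid(c = cs, offs = os)
    vals <- mapply(chi2_at, grid$c, grid$offs)
    best <- grid[which.min(vals), ]
    cc <- best$c; offs <- best$offs
    span_c <- span_c / 8; span_o <- span_o / 8
  }
  list(c = cc, offs = offs, chi2 = chi2_at(cc, offs))
}

# Brute-force window search oracle: recomputes every window's fit with
# lm(), no prefix sums. Returns longest passing window (ties: smallest
# start) and the full passing list.
brute_force_windows <- function(per_frame, exp_profile, criteria,
                                min_length = 1) {
  n <- nrow(per_frame)
  passing <- list()
  for (s in 0:(n - 1)) {
    for (e in (s + min_length):n) {
      if (e > n) break
      m <- if (e - s == 1) per_frame[s + 1, ] else colSums(per_frame[(s + 1):e, , drop = FALSE])
      fit <- lm_fit_oracle(exp_profile$intensity, m, exp_profile$sigma)
      pass <- fit$chi2 < criteria$chi2_max
      if (pass && criteria$use_residual_band) {
        band <- exp_profile$q < criteria$resid_q_max
        pass <- !any(band) || max(fit$squared_residuals[band]) < criteria$resid_max
      }
      if (pass) passing[[length(passing) + 1]] <- c(start = s, end = e)
    }
  }
  if (length(passing) == 0) return(list(found = FALSE, windows = NULL))
  w <- do.call(rbind, passing)
  len <- w[, "end"] - w[, "start"]
  best <- w[len == max(len), , drop = FALSE]
  best <- best[which.min(best[, "start"]), ]
  list(found = TRUE, start = unname(best["start"]), end = unname(best["end"]),
       windows = w[order(w[, "start"], w[, "end"]), , drop = FALSE])
}

# Small random clipping instance: per-frame curves drawn around a smooth
# base so some windows pass and others fail.
random_clip_instance <- function(n_frames, n_q = 8, seed = 1) {
  set.seed(seed)
  q <- seq(0.02, 0.3, length.out = n_q)
  base <- exp(-q^2 * runif(1, 20, 60))
  per_frame <- t(replicate(n_frames,
                           base * (1 + rnorm(n_q, sd = runif(1, 0.05, 0.3)))))
  per_frame <- abs(per_frame) + 1e-6
  target_rows <- sample(n_frames, max(1, n_frames %/% 3))
  mwin <- colMeans(per_frame[target_rows, , drop = FALSE])
  sigma <- pmax(mwin * 0.1, 1e-8)
  y <- mwin + rnorm(n_q, 0, sigma)
  list(series = new_profile_series(q, per_frame, frame_interval = 2),
       exp_profile = saxs_profile(q, y, sigma))
}

# Planted linear family I_j(Q) = A(Q) + x_j * B(Q) with B zero at exactly
# one grid point q_star.
planted_linear_family <- function(n_frames = 60, n_q = 60, seed = 3) {
  set.seed(seed)
  q <- seq(0.05, 0.30, length.out = n_q)
  istar <- 25
  A <- exp(-60 * q^2) + 0.05
  B <- 0.2 * (q - q[istar]) * exp(-5 * q)
  x <- runif(n_frames, -0.5, 0.5)
  per_frame <- outer(x, B) + rep(A, each = n_frames)
  stopifnot(all(per_frame > 0))
  list(series = new_profile_series(q, per_frame), q = q, A = A, B = B,
       x = x, q_star = q[istar], istar = istar)
}

# Tiny synthetic system shared by slower divergence tests.
small_hinge_system <- function(seed = 11, n_frames = 300) {
  generate_hinge_trajectory(hinge_config(n_frames = n_frames,
                                         state_dwell = 25,
                                         planted_length = 100,
                                         seed = seed))
}
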