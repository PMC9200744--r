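#' Configuration for the synthetic hinge-motion generator
#'
#' Describes a multi-domain bead model undergoing open-close hinge motion
#' between discrete angular states, sampled at a fixed frame interval.
#' Defaults emulate a four-domain chain (a, b, b', a') of globular
#' pseudo-domains roughly 20 Angstrom across, switching between a closed
#' (90 degree) and an open (140 degree) hinge state with Gaussian jitter,
#' at 2 ns per stored snapshot.
#'
#' @param n_domains Number of rigid pseudo-domains (2-4, default 4).
#' @param beads_per_domain Beads per domain (default 15).
#' @param domain_radius Radius of each bead cloud, Angstrom (default 10).
#' @param hinge_angle_states List of `c(mean, sd)` hinge-angle states in
#'   degrees (default closed 90 +/- 4, open 140 +/- 4).
#' @param state_dwell Mean dwell time per state, frames (default 50).
#' @param n_frames Number of stored snapshots (default 2500).
#' @param frame_interval ns per snapshot (default 2).
#' @param planted_length Requested length (frames) of the planted target
#'   window; the generator aligns the actual window to state-run
#'   boundaries (default 500).
#' @param seed Random seed driving all randomness (default 1).
#' @return A list of class `hinge_config`.
#' @export
hinge_config <- function(n_domains = 4, beads_per_domain = 15,
                         domain_radius = 10,
                         hinge_angle_states = list(c(90, 4), c(140, 4)),
                         state_dwell = 50, n_frames = 2500,
                         frame_interval = 2, planted_length = 500,
                         seed = 1) {
  if (!n_domains %in% 2:4) abort("n_domains must be 2, 3 or 4")
  if (beads_per_domain < 1 || n_frames < 1 || state_dwell < 1)
    abort("counts must be >= 1")
  means <- vapply(hinge_angle_states, `[`, numeric(1), 1)
  if (any(means <= 0 | means >= 180))
    abort("hinge state means must lie in (0, 180) degrees")
  structure(list(n_domains = n_domains, beads_per_domain = beads_per_domain,
                 domain_radius = domain_radius,
                 hinge_angle_states = hinge_angle_states,
                 state_dwell = state_dwell, n_frames = n_frames,
                 frame_interval = frame_interval,
                 planted_length = planted_length, seed = seed),
            class = "hinge_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

#' Generate a synthetic hinge-motion trajectory with planted truth
#'
#' Builds rigid pseudo-domains (beads fixed in a local frame) arranged as
#' a chain; the terminal domains swing symmetrically about hinge points so
#' that the hinge angle equals the angle descriptor theta at the adjacent
#' centre and the end-to-end distance d_aap opens and closes with it. The
#' per-frame hinge angle follows a discrete-state Markov process
#' (geometric dwell times) with Gaussian jitter. Deterministic given the
#' config seed.
#'
#' The returned truth includes a planted window aligned to state-run
#' boundaries (both neighbours outside the window are in a different
#' state than the window's edge frames), which is what makes "exactly
#' this window" a well-posed recovery target for [make_target_profile()]
#' plus [longest_matching_window()].
#'
#' @param config A [hinge_config()].
#' @return A list with `trajectory` (a `sasclip_trajectory`), `truth`
#'   (list: `planted_window` half-open 0-based, `states`, `angles`,
#'   `domains` tibble, `motifs` list).
#' @export
generate_hinge_trajectory <- function(config = hinge_config()) {
  stopifnot(inherits(config, "hinge_config"))
  with_seed(config$seed, {
    nd <- config$n_domains; bpd <- config$beads_per_domain
    R <- config$domain_radius
    # uniform bead clouds in a ball, one rigid cloud per domain
    clouds <- lapply(seq_len(nd), function(d) {
      v <- matrix(rnorm(3 * bpd), bpd, 3)
      v <- v / sqrt(rowSums(v^2)) * R * runif(bpd)^(1 / 3)
      sweep(v, 2, colMeans(v))        # centre the cloud on its COM
    })
    nstates <- length(config$hinge_angle_states)
    states <- integer(config$n_frames)
    states[1] <- 1
    p_switch <- 1 / config$state_dwell
    for (t in seq_len(config$n_frames - 1)) {
      states[t + 1] <- if (runif(1) < p_switch && nstates > 1) {
        others <- setdiff(seq_len(nstates), states[t])
        if (length(others) == 1) others else sample(others, 1)
      } else states[t]
    }
    mu <- vapply(config$hinge_angle_states, `[`, numeric(1), 1)
    sdv <- vapply(config$hinge_angle_states, `[`, numeric(1), 2)
    angles <- mu[states] + rnorm(config$n_frames, 0, sdv[states])
    angles <- pmin(pmax(angles, 1), 179)
    # chain geometry: interior domain centres fixed on the x axis,
    # terminal domains swing by the hinge angle
    spacing <- 2.4 * R
    coords <- array(0, dim = c(nd * bpd, 3, config$n_frames))
    interior <- if (nd >= 3) seq(2, nd - 1) else integer(0)
    centers_fixed <- lapply(seq_len(nd), function(d) c((d - 1) * spacing, 0, 0))
    for (t in seq_len(config$n_frames)) {
      a <- angles[t]
      cen <- centers_fixed
      rot <- replicate(nd, diag(3), simplify = FALSE)
      if (nd >= 2) {
        # first domain swings about the second domain's centre so the
        # three-point angle at that centre equals the hinge angle
        pivot <- centers_fixed[[min(2, nd)]]
        cen[[1]] <- pivot + spacing * c(cos(a * pi / 180), sin(a * pi / 180), 0)
        rot[[1]] <- rot_z(a)
        # last domain swings about the second-to-last centre, mirrored
        pivot2 <- centers_fixed[[max(nd - 1, 1)]]
        cen[[nd]] <- pivot2 + spacing * c(-cos(a * pi / 180), sin(a * pi / 180), 0)
        rot[[nd]] <- rot_z(-a)
      }
      for (d in seq_len(nd)) {
        rows <- ((d - 1) * bpd + 1):(d * bpd)
        coords[rows, , t] <- clouds[[d]] %*% t(rot[[d]]) +
          rep(cen[[d]], each = bpd)
      }
    }
    residue <- rep(seq_len(nd), each = bpd) * 1000 +
      rep(seq_len(bpd), nd)  # unique residue per bead, domain-grouped
    topo <- tibble(atom = "BB", element = "C", weight = 6,
                   residue = as.integer(residue), role = "backbone")
    traj <- trajectory(coords, topo, config$frame_interval)
    dom_names <- list(NULL, c("a", "ap"), c("a", "b", "ap"),
                      c("a", "b", "bp", "ap"))[[nd]]
    domains <- bind_rows(lapply(seq_len(nd), function(d)
      domain_def(dom_names[d], d * 1000 + 1, d * 1000 + bpd)))
    motifs <- list(a = as.integer(1000 + 1:2),
                   ap = as.integer(nd * 1000 + 1:2))
    truth <- list(planted_window = choose_planted_window(states,
                                                         config$planted_length),
                  states = states, angles = angles,
                  domains = domains, motifs = motifs)
    list(trajectory = traj, truth = truth)
  })
}

# Pick a half-open window aligned to state-run boundaries, with total
# length closest to the requested one, interior to the trajectory and
# containing at least two runs.
choose_planted_window <- function(states, target_length) {
  r <- rle(states)
  ends <- cumsum(r$lengths)
  starts <- c(0L, head(ends, -1))
  nruns <- length(r$lengths)
  if (nruns < 4) return(c(0L, length(states)))
  best <- NULL; best_gap <- Inf
  for (i in 2:(nruns - 1)) {
    for (j in i:(nruns - 1)) {
      len <- ends[j] - starts[i]
      if (j == i) next                         # need >= 2 runs
      gap <- abs(len - target_length)
      if (gap < best_gap) { best_gap <- gap; best <- c(starts[i], ends[j]) }
      if (len > 2 * target_length) break
    }
  }
  as.integer(best)
}

#' Build a noisy target profile from a planted trajectory window
#'
#' Averages the normalized Debye curves over the window, applies an
#' arbitrary positive scale and an additive offset (mimicking absolute
#' calibration and buffer mismatch), and adds Gaussian noise with
#' sigma(Q) = `noise_fraction * I(Q)`; that sigma is reported as the
#' uncertainty column. With `noise_fraction = 0` no noise is added and a
#' unit sigma column is reported.
#'
#' @param traj A `sasclip_trajectory`.
#' @param window Half-open 0-based `c(start, end)` frame window.
#' @param noise_fraction Relative noise level (default 1e-6; see the
#'   methods vignette for why single-frame window recovery needs sigma
#'   well below the per-frame profile variation divided by the window
#'   length).
#' @param seed Seed for the noise realization (default 1).
#' @param q Q grid (default 100 points on 0.01-0.30).
#' @param scale,offset Applied calibration (defaults 1e4 and 50).
#' @return A [saxs_profile].
#' @export
make_target_profile <- function(traj, window, noise_fraction = 1e-6,
                                seed = 1, q = seq(0.01, 0.30, length.out = 100),
                                scale = 1e4, offset = 50) {
  if (window[1] < 0 || window[2] > n_frames(traj) || window[1] >= window[2])
    abort("invalid window")
  series <- build_profile_series(traj, q)
  m <- (series$prefix[window[2] + 1, ] - series$prefix[window[1] + 1, ]) /
    (window[2] - window[1])
  mean_i <- scale * m + offset
  if (noise_fraction == 0)
    return(saxs_profile(q, mean_i, rep(1, length(q))))
  sig <- noise_fraction * mean_i
  noisy <- with_seed(seed, mean_i + rnorm(length(q), 0, sig))
  saxs_profile(q, noisy, sig)
}
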