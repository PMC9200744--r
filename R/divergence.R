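#' Support region C1 and adjacent shell C2 of a clipped probability map
#'
#' C1 is the set of occupied cells (p > 0) of the clipped map; C2 is the
#' set of cells adjacent to C1 (8-neighbourhood by default, switchable to
#' 4) that are not themselves in C1, clipped at the map borders.
#'
#' @param map_clip A `prob_map2d`.
#' @param adjacency 8 (default, diagonals included) or 4.
#' @return A list of class `support_region` with logical matrices `c1`,
#'   `c2` and their union `region`.
#' @export
support_union <- function(map_clip, adjacency = 8) {
  stopifnot(inherits(map_clip, "prob_map2d"), adjacency %in% c(4, 8))
  p <- map_clip$p
  if (all(p == 0)) abort("empty map")
  c1 <- p > 0
  nx <- nrow(p); ny <- ncol(p)
  offs <- if (adjacency == 8)
    expand.grid(dx = -1:1, dy = -1:1)[-5, ]
  else data.frame(dx = c(-1, 1, 0, 0), dy = c(0, 0, -1, 1))
  neigh <- matrix(FALSE, nx, ny)
  idx <- which(c1, arr.ind = TRUE)
  for (k in seq_len(nrow(offs))) {
    i <- idx[, 1] + offs$dx[k]; j <- idx[, 2] + offs$dy[k]
    ok <- i >= 1 & i <= nx & j >= 1 & j <= ny
    neigh[cbind(i[ok], j[ok])] <- TRUE
  }
  c2 <- neigh & !c1
  structure(list(c1 = c1, c2 = c2, region = c1 | c2),
            class = "support_region")
}

#' Support-restricted Kullback-Leibler divergence between conformation maps
#'
#' Measures how far a clipped time series' binned (theta, theta)
#' distribution departs from its source trajectory's, while permitting the
#' clip to occupy only a few of the source's stable states: the sum runs
#' only over the clipped support C1 and its adjacent shell C2, and the
#' source distribution is renormalized to sum to 1 over C1 union C2
#' before taking
#' \deqn{KL = \sum_{C1 \cup C2} P_{clip} \log(P_{clip} / \tilde P_{orig})}
#' with 0 log 0 = 0.
#'
#' @param map_clip,map_orig `prob_map2d` objects on identical bin edges;
#'   the clipped support must lie inside the source support (guaranteed
#'   when the clipped frames are a subset of the source frames).
#' @param adjacency Neighbourhood for C2: 8 (default) or 4.
#' @param base Logarithm base (default `exp(1)`, i.e. nats).
#' @return The divergence (non-negative scalar).
#' @export
kl_sas_clip <- function(map_clip, map_orig, adjacency = 8, base = exp(1)) {
  stopifnot(inherits(map_clip, "prob_map2d"), inherits(map_orig, "prob_map2d"))
  if (!isTRUE(all.equal(map_clip$x_edges, map_orig$x_edges)) ||
      !isTRUE(all.equal(map_clip$y_edges, map_orig$y_edges)))
    abort("maps must share identical bin edges")
  if (any(map_clip$p > 0 & map_orig$p == 0))
    abort(paste("undefined divergence: clipped map occupies a cell empty",
                "in the source map (inconsistent inputs)"))
  sup <- support_union(map_clip, adjacency)
  po <- map_orig$p[sup$region]
  po <- po / sum(po)
  pc <- map_clip$p[sup$region]
  nz <- pc > 0
  sum(pc[nz] * log(pc[nz] / po[nz])) / log(base)
}

#' KL divergence versus clipped duration over all matching windows
#'
#' Enumerates every passing window, computes each window's binned
#' (theta_abb, theta_bba) map and its support-restricted KL divergence
#' against the full-trajectory map, and returns (L_t, KL) pairs. On
#' multi-state systems the median KL decreases as L_t grows, which is the
#' basis for requiring a minimum clipped duration.
#'
#' @inheritParams enumerate_matching_windows
#' @param descriptors Per-frame descriptor tibble from
#'   [descriptor_series()] for the same trajectory (columns `theta_abb`,
#'   `theta_bba` are used).
#' @param x_edges,y_edges Bin edges in degrees shared by all maps.
#' @param adjacency,base Passed to [kl_sas_clip()].
#' @param max_windows Deterministic cap: if more windows pass, an evenly
#'   spaced subset of this size is analysed (default `Inf`).
#' @return A tibble with `start`, `end`, `duration_ns`, `chi2`, `kl`.
#' @export
kl_vs_duration <- function(series, exp_profile, criteria, descriptors,
                           x_edges, y_edges, min_length = 1,
                           adjacency = 8, base = exp(1),
                           max_windows = Inf) {
  wins <- enumerate_matching_windows(series, exp_profile, criteria,
                                     min_length = min_length)
  if (nrow(wins) == 0)
    return(tibble(start = integer(), end = integer(),
                  duration_ns = numeric(), chi2 = numeric(),
                  kl = numeric()))
  if (nrow(wins) > max_windows)
    wins <- wins[unique(round(seq(1, nrow(wins), length.out = max_windows))), ]
  nx <- length(x_edges) - 1; ny <- length(y_edges) - 1
  ix <- bin_index(descriptors$theta_abb, x_edges)
  iy <- bin_index(descriptors$theta_bba, y_edges)
  flat <- (iy - 1L) * nx + ix
  full_counts <- tabulate(flat, nbins = nx * ny)
  map_orig <- list(x_edges = x_edges, y_edges = y_edges,
                   p = matrix(full_counts / sum(full_counts), nx, ny))
  class(map_orig) <- "prob_map2d"
  kl <- vapply(seq_len(nrow(wins)), function(i) {
    sel <- flat[(wins$start[i] + 1):wins$end[i]]
    counts <- tabulate(sel, nbins = nx * ny)
    map_clip <- list(x_edges = x_edges, y_edges = y_edges,
                     p = matrix(counts / sum(counts), nx, ny))
    class(map_clip) <- "prob_map2d"
    kl_sas_clip(map_clip, map_orig, adjacency = adjacency, base = base)
  }, numeric(1))
  tibble(start = wins$start, end = wins$end,
         duration_ns = wins$duration_ns, chi2 = wins$chi2, kl = kl)
}

#' Scatter plot of KL divergence against clipped duration
#'
#' @param kl_table Output of [kl_vs_duration()].
#' @param n_strata Number of duration bins for the overlaid median trend.
#' @return A ggplot object.
#' @export
plot_kl_vs_duration <- function(kl_table, n_strata = 8) {
  med <- kl_table |>
    mutate(stratum = cut(.data$duration_ns, breaks = n_strata)) |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(duration_ns = mean(.data$duration_ns),
                     kl = median(.data$kl), .groups = "drop")
  ggplot2::ggplot(kl_table,
                  ggplot2::aes(x = .data$duration_ns, y = .data$kl)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.6) +
    ggplot2::geom_line(data = med, colour = "red") +
    ggplot2::labs(x = expression(L[t] ~ "(ns)"), y = "KL divergence")
}
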