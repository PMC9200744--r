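#' Centre of a domain (unweighted mean of backbone beads)
#'
#' The domain centre is the averaged coordinate of backbone beads whose
#' residue number lies in the inclusive range of the domain definition
#' (an unweighted mean, not mass-weighted).
#'
#' @param frame A [bead_structure].
#' @param domain A one-row domain definition from [domain_def()], or an
#'   integer vector of residue numbers.
#' @return A length-3 numeric vector (Angstrom).
#' @export
domain_center <- function(frame, domain) {
  stopifnot(inherits(frame, "bead_structure"))
  residues <- if (is.data.frame(domain))
    seq(domain$first_residue[1], domain$last_residue[1])
  else as.integer(domain)
  sel <- frame$role == "backbone" & frame$residue %in% residues
  if (!any(sel)) abort("domain selects no backbone beads")
  c(mean(frame$x[sel]), mean(frame$y[sel]), mean(frame$z[sel]))
}

#' Angle at the middle of three points, in degrees
#'
#' @param c1,c2,c3 Length-3 numeric vectors; the angle is at `c2`.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
angle_of_three <- function(c1, c2, c3) {
  u <- c1 - c2; v <- c3 - c2
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) abort("degenerate geometry: coincident points")
  ct <- sum(u * v) / (nu * nv)
  acos(min(1, max(-1, ct))) * 180 / pi
}

#' Signed torsion of four points, in degrees
#'
#' IUPAC convention about the `c2`-`c3` axis: 0 is cis (eclipsed), 180 is
#' trans, and mirror-imaging the points flips the sign. Range (-180, 180].
#'
#' @param c1,c2,c3,c4 Length-3 numeric vectors.
#' @return Dihedral angle in degrees.
#' @export
dihedral_of_four <- function(c1, c2, c3, c4) {
  b1 <- c2 - c1; b2 <- c3 - c2; b3 <- c4 - c3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  if (sum(n1^2) == 0 || sum(n2^2) == 0 || nb2 == 0)
    abort("degenerate geometry: collinear points")
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2) / nb2
  d <- atan2(y, x) * 180 / pi
  if (d <= -180) d <- d + 360
  d
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Per-frame domain-conformation descriptors
#'
#' For a four-domain chain a, b, b', a' computes, per frame:
#' theta_abb = angle(COM_a, COM_b, COM_b'); theta_bba = angle(COM_b,
#' COM_b', COM_a'); phi_abba = dihedral(COM_a, COM_b, COM_b', COM_a');
#' the domain-orientation dihedrals phi_orient_a = dihedral(COM_b',
#' COM_b, COM_a, COM_motif_a) and phi_orient_ap = dihedral(COM_b, COM_b',
#' COM_a', COM_motif_ap) when redox-motif residue sets are supplied; and
#' d_aap = |COM_a - COM_a'|, the open-close coordinate. COMs are
#' unweighted means of backbone beads.
#'
#' @param traj A `sasclip_trajectory`.
#' @param domains Tibble of [domain_def()] rows named `a`, `b`, `bp`, `ap`.
#' @param motifs Optional named list with residue vectors `a` and `ap`
#'   locating the CGHC motifs; orientation dihedrals are `NA` otherwise.
#' @return A tibble with one row per frame: `frame` (0-based),
#'   `theta_abb`, `theta_bba`, `phi_abba`, `phi_orient_a`,
#'   `phi_orient_ap`, `d_aap`, `degenerate`.
#' @export
descriptor_series <- function(traj, domains, motifs = NULL) {
  need <- c("a", "b", "bp", "ap")
  if (!all(need %in% domains$name))
    abort("domains must include rows named a, b, bp, ap")
  dget <- function(nm) domains[domains$name == nm, ][1, ]
  nf <- n_frames(traj)
  res <- vector("list", nf)
  for (f in seq_len(nf)) {
    fr <- get_frame(traj, f - 1)
    row <- list(frame = f - 1L, theta_abb = NA_real_, theta_bba = NA_real_,
                phi_abba = NA_real_, phi_orient_a = NA_real_,
                phi_orient_ap = NA_real_, d_aap = NA_real_,
                degenerate = FALSE)
    ok <- tryCatch({
      ca <- domain_center(fr, dget("a"))
      cb <- domain_center(fr, dget("b"))
      cbp <- domain_center(fr, dget("bp"))
      cap <- domain_center(fr, dget("ap"))
      row$theta_abb <- angle_of_three(ca, cb, cbp)
      row$theta_bba <- angle_of_three(cb, cbp, cap)
      row$phi_abba <- dihedral_of_four(ca, cb, cbp, cap)
      row$d_aap <- sqrt(sum((ca - cap)^2))
      if (!is.null(motifs)) {
        ma <- domain_center(fr, motifs$a)
        map <- domain_center(fr, motifs$ap)
        row$phi_orient_a <- dihedral_of_four(cbp, cb, ca, ma)
        row$phi_orient_ap <- dihedral_of_four(cb, cbp, cap, map)
      }
      TRUE
    }, error = function(e) {
      if (grepl("degenerate", conditionMessage(e))) FALSE else stop(e)
    })
    if (!ok) row$degenerate <- TRUE
    res[[f]] <- as_tibble(row)
  }
  out <- bind_rows(res)
  if (any(out$degenerate))
    warn(sprintf("%d frame(s) flagged as geometrically degenerate",
                 sum(out$degenerate)))
  out
}

#' Binned 2-D appearance-probability map
#'
#' Counts data points in the cells of a rectangular grid and normalizes
#' the counts to sum to 1. Cells are left-closed; the last cell includes
#' its right edge. Points outside the outermost edges are clipped into
#' the edge cells with a warning.
#'
#' @param xs,ys Per-frame values of the two binned variables.
#' @param x_edges,y_edges Strictly increasing bin edges.
#' @return An object of class `prob_map2d` with elements `x_edges`,
#'   `y_edges`, `p` (matrix, rows indexed by x bins).
#' @export
probability_map <- function(xs, ys, x_edges, y_edges) {
  if (length(xs) != length(ys)) abort("xs and ys must have equal length")
  keep <- !is.na(xs) & !is.na(ys)
  xs <- xs[keep]; ys <- ys[keep]
  if (length(xs) == 0) abort("zero data points")
  if (any(diff(x_edges) <= 0) || any(diff(y_edges) <= 0))
    abort("bin edges must be strictly increasing")
  if (any(xs < min(x_edges)) || any(xs > max(x_edges)) ||
      any(ys < min(y_edges)) || any(ys > max(y_edges)))
    warn("data outside the outermost edges clipped to edge bins")
  ix <- bin_index(xs, x_edges)
  iy <- bin_index(ys, y_edges)
  nx <- length(x_edges) - 1; ny <- length(y_edges) - 1
  counts <- matrix(tabulate((iy - 1) * nx + ix, nbins = nx * ny), nx, ny)
  out <- list(x_edges = x_edges, y_edges = y_edges,
              p = counts / sum(counts))
  class(out) <- "prob_map2d"
  out
}

bin_index <- function(v, edges) {
  i <- findInterval(v, edges, left.open = FALSE, rightmost.closed = TRUE)
  pmin(pmax(i, 1L), length(edges) - 1L)
}

#' @export
tidy.prob_map2d <- function(x, ...) {
  nx <- length(x$x_edges) - 1; ny <- length(x$y_edges) - 1
  tibble(x_mid = rep((x$x_edges[-1] + head(x$x_edges, -1)) / 2, ny),
         y_mid = rep((x$y_edges[-1] + head(x$y_edges, -1)) / 2, each = nx),
         p = as.vector(x$p))
}

#' @export
autoplot.prob_map2d <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x_mid, y = .data$y_mid,
                                  fill = .data$p)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = expression(theta["a-b-b'"] ~ (degree)),
                  y = expression(theta["b-b'-a'"] ~ (degree)),
                  fill = "probability")
}
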