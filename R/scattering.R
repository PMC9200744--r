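#' Theoretical SAXS intensity by the Debye equation
#'
#' Computes the orientation-averaged intensity
#' \deqn{I(Q) = \sum_i \sum_j f_i f_j \frac{\sin(Q r_{ij})}{Q r_{ij}}}
#' over all bead pairs, with the i = j and Q -> 0 terms evaluated as the
#' analytic limit sinc -> 1. Form factors are the per-bead constant
#' scattering weights. The forward-scattering value is
#' `i_zero = (sum f_i)^2` exactly.
#'
#' @param structure A [bead_structure].
#' @param q Numeric vector of scattering-vector magnitudes (>= 0), 1/Angstrom.
#' @return A tibble of class `saxs_curve` with columns `q`, `intensity` and
#'   attribute `i_zero`.
#' @examples
#' s <- bead_structure(rbind(c(0, 0, 0), c(10, 0, 0)), weight = 1)
#' debye_intensity(s, q = 0.1)  # 2 * (1 + sin(1)/1)
#' @export
debye_intensity <- function(structure, q) {
  stopifnot(inherits(structure, "bead_structure"))
  if (nrow(structure) < 1) abort("empty structure")
  if (any(q < 0)) abort("q must be non-negative")
  intensity <- cpp_debye_curve(coords_matrix(structure), structure$weight,
                               as.numeric(q))
  new_saxs_curve(q, intensity, i_zero = sum(structure$weight)^2)
}

new_saxs_curve <- function(q, intensity, i_zero) {
  out <- tibble(q = as.numeric(q), intensity = as.numeric(intensity))
  attr(out, "i_zero") <- i_zero
  class(out) <- c("saxs_curve", class(out))
  out
}

#' Normalize a theoretical curve by its forward scattering I(0)
#'
#' Divides intensities by `i_zero` so the curve would equal 1 at Q = 0.
#' Idempotent: after normalization `i_zero` is reset to 1.
#'
#' @param curve A `saxs_curve` from [debye_intensity()].
#' @return The normalized `saxs_curve`.
#' @export
normalize_curve <- function(curve) {
  i0 <- attr(curve, "i_zero")
  if (is.null(i0) || i0 <= 0) abort("i_zero must be positive")
  new_saxs_curve(curve$q, curve$intensity / i0, i_zero = 1)
}

#' Electron-weighted pair distance distribution p(r)
#'
#' For every unordered bead pair i < j with both weights positive, adds
#' `f_i * f_j` to the bin containing the pair distance `r_ij`. All electrons
#' are treated as located at bead centres; zero-weight beads (e.g. ignored
#' hydrogens) contribute nothing; self-pairs are excluded. Bins are
#' left-closed `[r, r + bin_width)` starting at 0.
#'
#' The conservation identity `sum(p) = ((sum f)^2 - sum(f^2)) / 2` holds
#' exactly.
#'
#' @param structure A [bead_structure].
#' @param bin_width Bin width in Angstrom (default 1).
#' @return A list of class `pair_distance_distribution` with elements
#'   `r_edges` (bin edges) and `p` (per-bin summed pair weight,
#'   electrons^2, unnormalized).
#' @export
pair_distance_distribution <- function(structure, bin_width = 1) {
  stopifnot(inherits(structure, "bead_structure"))
  if (bin_width <= 0) abort("bin_width must be positive")
  keep <- structure$weight > 0
  xyz <- coords_matrix(structure)[keep, , drop = FALSE]
  w <- structure$weight[keep]
  n <- nrow(xyz)
  if (n < 2) {
    out <- list(r_edges = c(0, bin_width), p = 0)
    class(out) <- "pair_distance_distribution"
    return(out)
  }
  r <- as.vector(stats::dist(xyz))
  # pair weights in dist() ordering: (2,1),(3,1),...,(3,2),... column-major
  idx <- which(lower.tri(diag(n)), arr.ind = TRUE)
  pw <- w[idx[, 1]] * w[idx[, 2]]
  nbin <- floor(max(r) / bin_width) + 1
  bin <- floor(r / bin_width) + 1
  p <- as.vector(tapply(pw, factor(bin, levels = seq_len(nbin)), sum))
  p[is.na(p)] <- 0
  out <- list(r_edges = bin_width * (0:nbin), p = p)
  class(out) <- "pair_distance_distribution"
  out
}

#' @export
tidy.pair_distance_distribution <- function(x, ...) {
  tibble(r_lower = head(x$r_edges, -1),
         r_upper = x$r_edges[-1],
         p = x$p)
}

#' @export
autoplot.pair_distance_distribution <- function(object, ...) {
  d <- tidy(object)
  d$r_mid <- (d$r_lower + d$r_upper) / 2
  ggplot2::ggplot(d, ggplot2::aes(x = .data$r_mid, y = .data$p)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "r (Å)", y = "p(r) (electrons²)")
}
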