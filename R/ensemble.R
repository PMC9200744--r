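#' Per-Q spread of log10 intensity across frames
#'
#' The sample standard deviation of log10 of the per-frame normalized
#' intensities, computed at each Q. Narrow spread at a Q value means the
#' ensemble's curves nearly intersect there.
#'
#' @param series A `profile_series` with at least 2 frames.
#' @return A tibble with columns `q`, `spread`.
#' @export
intensity_spread <- function(series) {
  stopifnot(inherits(series, "profile_series"))
  if (nrow(series$per_frame) < 2) abort("need at least 2 frames")
  if (any(series$per_frame <= 0))
    abort("non-positive intensity: log10 spread undefined")
  lg <- log10(series$per_frame)
  tibble(q = series$q, spread = apply(lg, 2, sd))
}

#' Detect isosbestic points of an ensemble of scattering curves
#'
#' An isosbestic point is a Q value where the curves of all ensemble
#' members approximately intersect, indicating that a single
#' conformational coordinate modulates I(Q) linearly. Operationally:
#' local minima of the log10-intensity spread within a Q band whose
#' spread falls below `tol_factor` times the band's median spread.
#'
#' @param series A `profile_series`.
#' @param q_band Length-2 numeric: band limits in 1/Angstrom.
#' @param tol_factor Acceptance factor on the median band spread
#'   (default 0.25).
#' @return Sorted numeric vector of Q values (possibly empty). A series
#'   whose frames are all identical is degenerate: returns empty with a
#'   warning.
#' @export
isosbestic_points <- function(series, q_band, tol_factor = 0.25) {
  sp <- intensity_spread(series)
  sel <- sp$q >= q_band[1] & sp$q <= q_band[2]
  if (!any(sel)) abort("empty band: no grid points inside q_band")
  q <- sp$q[sel]; s <- sp$spread[sel]
  if (all(s < 1e-14)) {
    warn("degenerate series: all frames identical, every point is a minimum")
    return(numeric(0))
  }
  thr <- tol_factor * median(s)
  n <- length(s)
  if (n < 3) return(numeric(0))
  i <- 2:(n - 1)
  is_min <- s[i] <= s[i - 1] & s[i] <= s[i + 1] & s[i] < thr
  # collapse plateaus of equal spread to their first grid point
  hits <- i[is_min]
  if (length(hits) > 1)
    hits <- hits[c(TRUE, !(diff(hits) == 1 & diff(s[hits]) == 0))]
  sort(q[hits])
}

#' Per-Q linear response of intensity to a conformational coordinate
#'
#' Ordinary least-squares fit, at each Q independently, of the per-frame
#' intensity on a per-frame coordinate x (for example the inter-domain
#' distance d_aap), following the expansion
#' I(Q, X) ~ I(Q, X0) + (X - X0) dI/dX with X0 the mean coordinate.
#' A Q where the slope vanishes is an isosbestic point.
#'
#' @param series A `profile_series`.
#' @param x Numeric per-frame coordinate, not constant.
#' @return An object of class `linear_response`: a tibble with columns
#'   `q`, `intercept` (intensity at X0), `slope`, `r2`, plus attribute
#'   `x0`. Columns with zero residual variance get `r2 = 1`.
#' @export
linear_response_fit <- function(series, x) {
  stopifnot(inherits(series, "profile_series"))
  x <- as.numeric(x)
  if (length(x) != nrow(series$per_frame))
    abort("x length must equal the frame count")
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  if (sxx == 0) abort("constant x: regression undefined")
  I <- series$per_frame
  slope <- as.vector(crossprod(xc, I)) / sxx
  intercept <- colMeans(I)
  fitted <- outer(xc, slope) + rep(intercept, each = nrow(I))
  ss_res <- colSums((I - fitted)^2)
  ss_tot <- colSums((I - rep(intercept, each = nrow(I)))^2)
  r2 <- ifelse(ss_tot <= .Machine$double.eps * nrow(I),
               1, 1 - ss_res / ss_tot)
  out <- tibble(q = series$q, intercept = intercept, slope = slope,
                r2 = pmin(pmax(r2, 0), 1))
  attr(out, "x0") <- mean(x)
  class(out) <- c("linear_response", class(out))
  out
}

#' @export
autoplot.linear_response <- function(object, ...) {
  d <- tibble(q = rep(object$q, 2),
              value = c(object$slope, object$r2),
              what = rep(c("slope", "R²"), each = nrow(object)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$q, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~what, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = expression(Q ~ ("Å"^-1)), y = NULL)
}

#' Convex recombination of clipped-ensemble observables
#'
#' Finds weights c_i approximating a target observable as a linear
#' combination `X = sum_i c_i * X_i` of per-series averaged observables.
#' By default the weights are constrained to the probability simplex
#' (c_i >= 0, sum c_i = 1), the natural constraint when the weights are
#' interpreted as the population of each candidate dynamics in a mixture;
#' `constrained = FALSE` gives the unconstrained least-squares solution.
#'
#' The constrained problem is a convex QP solved exactly by enumerating
#' active sets (supports), which is fast for the handful of clipped
#' series this method produces.
#'
#' @param per_series_means Numeric matrix, one column per series, rows
#'   indexing the observable's dimensions.
#' @param target Numeric vector, length `nrow(per_series_means)`.
#' @param constrained Impose the simplex constraint (default `TRUE`).
#' @return An object of class `recombination`: list with `weights`,
#'   `residual_norm`, `fitted`.
#' @export
recombine_ensembles <- function(per_series_means, target,
                                constrained = TRUE) {
  A <- as.matrix(per_series_means)
  b <- as.numeric(target)
  if (nrow(A) != length(b)) abort("dimension mismatch between means and target")
  k <- ncol(A)
  if (k < 1) abort("need at least one series")
  if (nrow(A) < k)
    warn("observable dimension below series count: weights may be unidentifiable")
  if (!constrained) {
    w <- qr.solve(A, b)
  } else {
    if (k > 20) abort("too many series for exact active-set enumeration (> 20)")
    best <- NULL; best_rss <- Inf
    for (size in seq_len(k)) {
      for (S in utils::combn(k, size, simplify = FALSE)) {
        ws <- solve_simplex_subset(A[, S, drop = FALSE], b)
        if (is.null(ws) || any(ws < -1e-9)) next
        r <- A[, S, drop = FALSE] %*% ws - b
        rss <- sum(r^2)
        if (rss < best_rss - 1e-12) {
          best_rss <- rss
          best <- replace(numeric(k), S, ws)
        }
      }
    }
    if (is.null(best)) abort("no feasible weight vector found")
    w <- pmax(best, 0)
    w <- w / sum(w)
  }
  fitted <- as.vector(A %*% w)
  out <- list(weights = as.vector(w),
              residual_norm = sqrt(sum((fitted - b)^2)),
              fitted = fitted)
  class(out) <- "recombination"
  out
}

# Equality-constrained LS on a support: min ||A w - b|| s.t. sum w = 1.
solve_simplex_subset <- function(A, b) {
  k <- ncol(A)
  K <- rbind(cbind(crossprod(A), rep(1, k)), c(rep(1, k), 0))
  rhs <- c(crossprod(A, b), 1)
  sol <- tryCatch(solve(K, rhs), error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  sol[seq_len(k)]
}

#' @export
print.recombination <- function(x, ...) {
  cat("<recombination: weights =",
      paste(sprintf("%.4f", x$weights), collapse = ", "),
      sprintf("| residual norm = %.4g>\n", x$residual_norm))
  invisible(x)
}

#' @export
tidy.recombination <- function(x, ...) {
  tibble(series = seq_along(x$weights), weight = x$weights)
}

#' @export
glance.recombination <- function(x, ...) {
  tibble(n_series = length(x$weights), residual_norm = x$residual_norm)
}
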