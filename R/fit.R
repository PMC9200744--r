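#' Fit a model curve to an experimental profile with scale and offset
#'
#' Fits `I_sim(Q_i) = c * model_i - offs` to the experimental intensities by
#' minimizing
#' \deqn{\chi^2 = \frac{1}{N-1} \sum_i
#'   \left(\frac{I_{exp}(Q_i) - I_{sim}(Q_i)}{\sigma(Q_i)}\right)^2}
#' The two adjustment parameters are the overall scale `c` and a constant
#' offset `offs` absorbing buffer-subtraction mismatch; both solve the
#' weighted (1/sigma^2) normal equations in closed form. The divisor is
#' N - 1. The model is typically the *sum* of per-frame normalized curves
#' over a window, so `c` absorbs the 1/M averaging factor.
#'
#' @param exp_profile A [saxs_profile]; the model must be evaluated on its
#'   Q grid.
#' @param model Numeric vector of summed model intensities, same length as
#'   `exp_profile$q`.
#' @param n_models Number of frame profiles summed into `model` (stored for
#'   reporting; default `NA`).
#' @return An object of class `sasclip_fit`: a list with `c`, `offs`,
#'   `chi2`, `squared_residuals`, `n_points`, `n_models`, plus the grid and
#'   curves used (`q`, `i_exp`, `sigma`, `i_fit`).
#' @examples
#' p <- saxs_profile(c(0.1, 0.2, 0.3), c(2.0, 1.2, 0.4), c(1, 1, 1))
#' fit_scale_offset(p, c(1.0, 0.5, 0.25))
#' @export
fit_scale_offset <- function(exp_profile, model, n_models = NA_integer_) {
  stopifnot(inherits(exp_profile, "saxs_profile"))
  y <- exp_profile$intensity
  s <- exp_profile$sigma
  model <- as.numeric(model)
  n <- length(y)
  if (length(model) != n) abort("model length must equal profile length")
  if (n < 3) abort("need at least 3 data points to fit two parameters")
  w <- 1 / s^2
  Sw <- sum(w); Sm <- sum(w * model); Sy <- sum(w * y)
  Smm <- sum(w * model^2); Smy <- sum(w * model * y)
  denom <- Smm - Sm^2 / Sw
  if (abs(denom) <= 1e-12 * Smm || Smm == 0)
    abort("constant model: normal equations are singular")
  cc <- (Smy - Sy * Sm / Sw) / denom
  offs <- (cc * Sm - Sy) / Sw
  if (cc < 0) warn("fitted scale factor c is negative (physically unreasonable)")
  i_fit <- cc * model - offs
  sqres <- ((y - i_fit) / s)^2
  out <- list(c = cc, offs = offs, chi2 = sum(sqres) / (n - 1),
              squared_residuals = sqres, n_points = n,
              n_models = n_models, q = exp_profile$q, i_exp = y,
              sigma = s, i_fit = i_fit)
  class(out) <- "sasclip_fit"
  out
}

#' @export
print.sasclip_fit <- function(x, ...) {
  cat(sprintf("<sasclip_fit: chi2 = %.4g, c = %.4g, offs = %.4g, N = %d>\n",
              x$chi2, x$c, x$offs, x$n_points))
  invisible(x)
}

#' @export
tidy.sasclip_fit <- function(x, ...) {
  tibble(q = x$q, i_exp = x$i_exp, sigma = x$sigma, i_fit = x$i_fit,
         squared_residual = x$squared_residuals)
}

#' @export
glance.sasclip_fit <- function(x, ...) {
  tibble(chi2 = x$chi2, c = x$c, offs = x$offs,
         n_points = x$n_points, n_models = x$n_models)
}

#' @export
autoplot.sasclip_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$q)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      y = .data$i_exp, ymin = .data$i_exp - .data$sigma,
      ymax = .data$i_exp + .data$sigma), size = 0.2, colour = "black") +
    ggplot2::geom_line(ggplot2::aes(y = .data$i_fit), colour = "red") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(Q ~ ("Å"^-1)), y = "I(Q)")
}

#' Maximum squared residual in a low-angle band
#'
#' Returns the maximum of the per-point squared residuals over grid points
#' with Q strictly below `q_max`. Used for the improved acceptance
#' criterion requiring every squared residual below a cap in the band
#' where domain-conformation information lives (correlation lengths
#' 2*pi/Q of tens of Angstroms).
#'
#' @param fit A `sasclip_fit`.
#' @param q_max Band limit in 1/Angstrom (default 0.25).
#' @return The maximum squared residual; 0 with a warning if no grid point
#'   lies below `q_max`.
#' @export
squared_residual_band <- function(fit, q_max = 0.25) {
  stopifnot(inherits(fit, "sasclip_fit"))
  sel <- fit$q < q_max
  if (!any(sel)) {
    warn("no grid points below q_max; returning 0")
    return(0)
  }
  max(fit$squared_residuals[sel])
}
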