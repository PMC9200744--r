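#' Acceptance criteria for a clipped time series
#'
#' The first-pass criterion is reduced chi-squared below `chi2_max`; the
#' improved criteria additionally require every squared residual at
#' Q < `resid_q_max` to stay below `resid_max` (both inequalities strict).
#' `min_duration` is a reporting filter on L_t, not part of the window
#' search, so listings of all acceptable windows remain possible.
#'
#' @param chi2_max Reduced chi-squared threshold (default 3.0).
#' @param resid_max Per-point squared-residual cap in the band (default 12.5).
#' @param resid_q_max Band limit, 1/Angstrom (default 0.25).
#' @param min_duration Minimum L_t in ns used when reporting (default 700).
#' @param use_residual_band Apply the residual-band criterion (default
#'   `TRUE`, the improved criteria); `FALSE` reproduces the chi-squared-only
#'   first pass.
#' @return A list of class `clip_criteria`.
#' @export
clip_criteria <- function(chi2_max = 3.0, resid_max = 12.5,
                          resid_q_max = 0.25, min_duration = 700,
                          use_residual_band = TRUE) {
  if (chi2_max <= 0 || resid_max <= 0 || resid_q_max <= 0 || min_duration <= 0)
    abort("all thresholds must be positive")
  structure(list(chi2_max = chi2_max, resid_max = resid_max,
                 resid_q_max = resid_q_max, min_duration = min_duration,
                 use_residual_band = isTRUE(use_residual_band)),
            class = "clip_criteria")
}

#' Per-frame normalized profiles on the experimental Q grid
#'
#' Computes the Debye intensity of every trajectory frame at the
#' experimental Q values, normalizes each by its own forward scattering
#' I(0), and stores cumulative sums so any window's summed profile is an
#' O(1) difference of two prefix rows.
#'
#' @param traj A `sasclip_trajectory`.
#' @param exp_profile A [saxs_profile], or a numeric Q grid.
#' @return An object of class `profile_series` with elements `q`,
#'   `per_frame` (frames x Q matrix), `prefix` ((frames+1) x Q cumulative
#'   sums) and `frame_interval`.
#' @export
build_profile_series <- function(traj, exp_profile) {
  q <- if (inherits(exp_profile, "saxs_profile")) exp_profile$q
       else as.numeric(exp_profile)
  raw <- cpp_debye_series(traj$coords, n_beads(traj), n_frames(traj),
                          traj$topology$weight, q)
  i0 <- sum(traj$topology$weight)^2
  if (i0 <= 0) abort("total scattering weight must be positive")
  per_frame <- raw / i0
  new_profile_series(q, per_frame, traj$frame_interval)
}

#' Assemble a profile series from a precomputed frame-by-Q matrix
#'
#' @param q Q grid.
#' @param per_frame Matrix (frames x Q) of normalized per-frame intensities.
#' @param frame_interval ns/frame (default 2).
#' @return A `profile_series`.
#' @export
new_profile_series <- function(q, per_frame, frame_interval = 2) {
  per_frame <- as.matrix(per_frame)
  if (ncol(per_frame) != length(q)) abort("per_frame columns must match q")
  prefix <- rbind(0, apply(per_frame, 2, cumsum))
  if (nrow(per_frame) == 1) prefix <- rbind(0, per_frame)
  structure(list(q = as.numeric(q), per_frame = per_frame, prefix = prefix,
                 frame_interval = frame_interval),
            class = "profile_series")
}

#' @export
print.profile_series <- function(x, ...) {
  cat(sprintf("<profile_series: %d frames x %d Q points, %g ns/frame>\n",
              nrow(x$per_frame), length(x$q), x$frame_interval))
  invisible(x)
}

window_model <- function(series, start, end) {
  n <- nrow(series$per_frame)
  if (start < 0 || end > n || start >= end)
    abort("invalid window: need 0 <= start < end <= n_frames")
  series$prefix[end + 1, ] - series$prefix[start + 1, ]
}

#' Fit one window's summed profile and test it against the criteria
#'
#' @param series A `profile_series`.
#' @param start,end Half-open 0-based frame window `[start, end)`.
#' @param exp_profile The experimental [saxs_profile] (same Q grid).
#' @param criteria A [clip_criteria].
#' @return A list with elements `fit` (a `sasclip_fit`) and `passes`.
#' @export
evaluate_window <- function(series, start, end, exp_profile,
                            criteria = clip_criteria()) {
  m <- window_model(series, start, end)
  fit <- fit_scale_offset(exp_profile, m, n_models = end - start)
  passes <- fit$chi2 < criteria$chi2_max
  if (passes && criteria$use_residual_band) {
    band <- suppressWarnings(squared_residual_band(fit, criteria$resid_q_max))
    passes <- band < criteria$resid_max
  }
  list(fit = fit, passes = passes)
}

#' Duration L_t of a clipped window
#'
#' L_t is the number of snapshots in the window multiplied by the frame
#' interval (a 1345-snapshot series at 2 ns/frame has L_t = 2690 ns).
#'
#' @param start,end Half-open 0-based frame window.
#' @param frame_interval ns per frame (default 2).
#' @return Duration in ns.
#' @export
clip_duration <- function(start, end, frame_interval = 2) {
  if (any(start >= end)) abort("empty window: start must be < end")
  (end - start) * frame_interval
}

band_indices <- function(series, criteria) {
  if (criteria$use_residual_band)
    as.integer(which(series$q < criteria$resid_q_max) - 1L)
  else integer(0)
}

#' Longest contiguous window matching the experimental profile
#'
#' Exhaustively searches all contiguous frame windows (the acceptance
#' criterion is not monotone in window extent, so no pruning by inclusion
#' is sound) and returns a passing window of maximal length; ties are
#' broken by the earliest start. `criteria$min_duration` does not reject
#' windows — it is reported against via the `meets_min_duration` flag.
#'
#' @param series A `profile_series`.
#' @param exp_profile The experimental [saxs_profile].
#' @param criteria A [clip_criteria].
#' @return An object of class `clip_result` with `start_frame`,
#'   `end_frame` (half-open), `duration_ns`, `fit`, `found`,
#'   `meets_min_duration`.
#' @export
longest_matching_window <- function(series, exp_profile,
                                    criteria = clip_criteria()) {
  stopifnot(inherits(series, "profile_series"))
  res <- cpp_longest_window(series$prefix, exp_profile$intensity,
                            1 / exp_profile$sigma^2,
                            band_indices(series, criteria),
                            criteria$chi2_max, criteria$resid_max,
                            criteria$use_residual_band)
  if (res[7] == 0) {
    out <- list(start_frame = NA_integer_, end_frame = NA_integer_,
                duration_ns = NA_real_, fit = NULL, found = FALSE,
                meets_min_duration = FALSE, criteria = criteria,
                frame_interval = series$frame_interval)
    class(out) <- "clip_result"
    return(out)
  }
  start <- as.integer(res[1]); end <- as.integer(res[2])
  fit <- fit_scale_offset(exp_profile, window_model(series, start, end),
                          n_models = end - start)
  dur <- clip_duration(start, end, series$frame_interval)
  out <- list(start_frame = start, end_frame = end, duration_ns = dur,
              fit = fit, found = TRUE,
              meets_min_duration = dur > criteria$min_duration,
              criteria = criteria, frame_interval = series$frame_interval)
  class(out) <- "clip_result"
  out
}

#' @export
print.clip_result <- function(x, ...) {
  if (!x$found) cat("<clip_result: no matching window found>\n")
  else cat(sprintf(
    "<clip_result: frames [%d, %d), L_t = %g ns, chi2 = %.4g%s>\n",
    x$start_frame, x$end_frame, x$duration_ns, x$fit$chi2,
    if (x$meets_min_duration) "" else "; below min duration"))
  invisible(x)
}

#' @export
glance.clip_result <- function(x, ...) {
  if (!x$found)
    return(tibble(found = FALSE, start_frame = NA_integer_,
                  end_frame = NA_integer_, duration_ns = NA_real_,
                  chi2 = NA_real_, c = NA_real_, offs = NA_real_,
                  max_band_residual = NA_real_,
                  meets_min_duration = FALSE))
  tibble(found = TRUE, start_frame = x$start_frame, end_frame = x$end_frame,
         duration_ns = x$duration_ns, chi2 = x$fit$chi2, c = x$fit$c,
         offs = x$fit$offs,
         max_band_residual =
           suppressWarnings(squared_residual_band(x$fit,
                                                  x$criteria$resid_q_max)),
         meets_min_duration = x$meets_min_duration)
}

#' @export
tidy.clip_result <- function(x, ...) {
  if (!x$found) return(tibble())
  tidy(x$fit)
}

#' Enumerate every matching window
#'
#' Lists all contiguous windows of at least `min_length` frames that pass
#' the criteria, in lexicographic (start, end) order.
#'
#' @inheritParams longest_matching_window
#' @param min_length Minimum window length in frames (default 1).
#' @param maximal_only Keep only windows not contained in a longer passing
#'   window (default `FALSE`).
#' @return A tibble with columns `start`, `end`, `length`, `duration_ns`,
#'   `c`, `offs`, `chi2`, `max_band_residual`, `meets_min_duration`.
#' @export
enumerate_matching_windows <- function(series, exp_profile,
                                       criteria = clip_criteria(),
                                       min_length = 1,
                                       maximal_only = FALSE) {
  stopifnot(inherits(series, "profile_series"), min_length >= 1)
  m <- cpp_enumerate_windows(series$prefix, exp_profile$intensity,
                             1 / exp_profile$sigma^2,
                             band_indices(series, criteria),
                             criteria$chi2_max, criteria$resid_max,
                             criteria$use_residual_band,
                             as.integer(min_length))
  out <- tibble(start = as.integer(m[, "start"]),
                end = as.integer(m[, "end"]),
                length = as.integer(m[, "end"] - m[, "start"]),
                duration_ns = (m[, "end"] - m[, "start"]) * series$frame_interval,
                c = m[, "c"], offs = m[, "offs"], chi2 = m[, "chi2"],
                max_band_residual = m[, "band_max"])
  out$meets_min_duration <- out$duration_ns > criteria$min_duration
  out <- arrange(out, .data$start, .data$end)
  if (maximal_only && nrow(out) > 1) {
    keep <- vapply(seq_len(nrow(out)), function(i) {
      !any(out$start <= out$start[i] & out$end >= out$end[i] &
             out$length > out$length[i])
    }, logical(1))
    out <- out[keep, , drop = FALSE]
  }
  out
}

#' Write a clip report in TSV and JSON twin forms
#'
#' Emits the window bounds, L_t, fit statistics and (when available) the
#' KL divergence, both as a one-row tab-separated table and as a JSON
#' object. Numbers survive a read/write round trip bit-identically.
#'
#' @param result A `clip_result`, optionally carrying `$kl`.
#' @param path Output stem or `.tsv`/`.json` path; both twins are written.
#' @return Invisibly, the two paths written.
#' @export
write_clip_report <- function(result, path) {
  stopifnot(inherits(result, "clip_result"))
  stem <- sub("\\.(tsv|json)$", "", path)
  rec <- if (result$found) {
    list(found = TRUE, start_frame = result$start_frame,
         end_frame = result$end_frame, duration_ns = result$duration_ns,
         chi2 = result$fit$chi2, c = result$fit$c, offs = result$fit$offs,
         max_band_residual = suppressWarnings(
           squared_residual_band(result$fit, result$criteria$resid_q_max)),
         kl = result$kl %||% NA_real_)
  } else {
    list(found = FALSE, start_frame = NA, end_frame = NA,
         duration_ns = NA, chi2 = NA, c = NA, offs = NA,
         max_band_residual = NA, kl = NA)
  }
  tsv <- paste0(stem, ".tsv"); json <- paste0(stem, ".json")
  # %.17g guarantees doubles survive the text round trip bit-identically
  fmt1 <- function(v) {
    if (is.na(v)) "null"
    else if (is.logical(v)) tolower(as.character(v))
    else if (is.numeric(v)) sprintf("%.17g", v)
    else as.character(v)
  }
  fmt <- vapply(rec, fmt1, character(1))
  writeLines(c(paste(names(rec), collapse = "\t"),
               paste(ifelse(fmt == "null", "NA", fmt), collapse = "\t")), tsv)
  writeLines(c("{", paste0("  \"", names(rec), "\": ", fmt,
                           c(rep(",", length(rec) - 1), "")), "}"), json)
  invisible(c(tsv = tsv, json = json))
}

#' Read back a clip report written by [write_clip_report()]
#'
#' @param path The report stem or one of the twin paths.
#' @return A one-row tibble of the report fields.
#' @export
read_clip_report <- function(path) {
  stem <- sub("\\.(tsv|json)$", "", path)
  rec <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  rec <- lapply(rec, function(v) if (is.null(v)) NA else v)
  as_tibble(rec)
}
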