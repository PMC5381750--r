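#' KHTE peak: mean histogram mode across windows
#'
#' Captures the main mode of each column of the KHTE matrix and averages them.
#' The mode of a column is its argmax bin (ties broken toward the lowest bin
#' index); the representative value of a bin is its center, and the overflow
#' bin — which collects all hold times above `M` — is represented by
#' `M + M/(2k)`, one half bin-width past its lower edge. Psychomotor slowing
#' shifts hold times upward, so the peak rises with impairment.
#'
#' @param x A `"khte"` object.
#' @return The KHTE peak in milliseconds.
#' @export
khte_peak <- function(x) {
  stopifnot(inherits(x, "khte"))
  k <- x$params$k; M <- x$params$M
  centers <- (x$bin_edges[-1L] + x$bin_edges[-(k + 1L)]) / 2
  centers[k] <- M + M / (2 * k)
  modes <- apply(x$K, 2L, which.max)
  mean(centers[modes])
}

#' Window-to-window self-similarity matrix
#'
#' Computes the z x z matrix of Euclidean (L2) distances between the
#' normalized-histogram columns of the KHTE matrix, and its normalized form
#' where a distance of `L` (or more) maps to 1: `min(raw/L, 1)`. The
#' saturation form keeps the scale comparable across sessions, unlike a
#' per-matrix min-max rescaling.
#'
#' @param x A `"khte"` object with at least two windows.
#' @param L Saturation scale; defaults to the fit's `params$L`.
#' @return Object of class `"khte_selfsim"`: list with `values` (normalized,
#'   in `[0, 1]`, symmetric, zero diagonal), `raw` (unnormalized distances)
#'   and `L`.
#' @export
self_similarity <- function(x, L = x$params$L) {
  stopifnot(inherits(x, "khte"))
  check_scalar(L, "L", positive = TRUE)
  z <- ncol(x$K)
  if (z < 2)
    stop("self-similarity is undefined for a single window (z < 2)",
         call. = FALSE)
  raw <- as.matrix(stats::dist(t(x$K)))
  dimnames(raw) <- NULL
  values <- pmin(raw / L, 1)
  diag(values) <- 0
  structure(list(values = values, raw = raw, L = L), class = "khte_selfsim")
}

#' @export
print.khte_selfsim <- function(x, ...) {
  z <- nrow(x$values)
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("Self-similarity matrix: %d x %d, L = %g\n", z, z, x$L))
  cat(sprintf("  mean off-diagonal normalized distance: %.3f (K^s = %.3f)\n",
              mean(off), 1 - mean(off)))
  invisible(x)
}

#' KHTE self similarity: global connectivity of the window graph
#'
#' Summarises the normalized self-similarity matrix as
#' `1 - mean(off-diagonal entries)` — the simplest global-connectivity
#' measure on the fully connected window graph whose edge weights are
#' `1 - distance`. High values mean the hold-time distribution is stable over
#' time; temporal instability of typing (as under impairment) lowers it.
#'
#' @param s A `"khte_selfsim"` object (or a `"khte"` object, for which the
#'   similarity matrix is computed first).
#' @return The connectivity value in `[0, 1]`.
#' @export
khte_selfsim <- function(s) {
  if (inherits(s, "khte")) s <- self_similarity(s)
  stopifnot(inherits(s, "khte_selfsim"))
  v <- s$values
  z <- nrow(v)
  1 - sum(v) / (z * (z - 1))
}

#' Compact feature vector of one session
#'
#' Reduces a session to the 2-D feature vector `v = (K^p, K^s)`: the KHTE
#' peak in milliseconds and the KHTE self similarity (dimensionless,
#' `[0, 1]`).
#'
#' @param x A [keystroke_log()], `hold_time_series`, or fitted `"khte"`
#'   object.
#' @param params A [khte_params()] object.
#' @param ... Passed on to [khte()] methods (e.g. `duration_ms`).
#' @return Named numeric vector `c(khte_peak =, khte_selfsim =)`.
#' @export
khte_features <- function(x, params = khte_params(), ...) {
  fit <- if (inherits(x, "khte")) x else khte(x, params, ...)
  if (ncol(fit$K) < 2)
    stop("feature vector requires at least two retained windows", call. = FALSE)
  c(khte_peak = khte_peak(fit),
    khte_selfsim = khte_selfsim(self_similarity(fit)))
}

#' State-change vector between two sessions
#'
#' The component-wise difference `v' - v` between the feature vectors of two
#' sessions of the same subject, in polar form. With `v` the rested
#' reference, impairment is expected to raise the peak and lower the self
#' similarity; `selfsim_orientation = -1` flips the second axis so that the
#' expected impairment direction falls in the upper-right quadrant
#' (`angle` in `(0, pi/2)`). The orientation used is recorded in the result.
#'
#' The two feature axes carry different units (milliseconds vs a
#' dimensionless similarity), so for directional analysis the angle can be
#' computed on commensurable axes: `angle_peak_scale` divides the peak
#' change before the arctangent, and setting it to the histogram bin width
#' `M/k` expresses the peak change in bins — one bin of peak change then has
#' the same angular weight as a full unit of similarity change. The default
#' scale 1 leaves `(magnitude, angle)` as the exact polar form of
#' `(d_peak, d_selfsim)`.
#'
#' @param v,v_prime Feature vectors from [khte_features()] (reference and
#'   follow-up session).
#' @param selfsim_orientation `+1` (angle is the polar angle of
#'   `(d_peak, d_selfsim)`, the default) or `-1` (second axis flipped).
#' @param angle_peak_scale Divisor applied to `d_peak` (ms) when computing
#'   the angle; the magnitude is always the raw Euclidean norm.
#' @return Object of class `"khte_delta"`: list with `d_peak` (ms),
#'   `d_selfsim`, `angle` (radians in `(-pi, pi]`, `NA` with a `degenerate`
#'   flag when the magnitude is zero), `magnitude`, `selfsim_orientation`
#'   and `angle_peak_scale`.
#' @export
delta_vector <- function(v, v_prime, selfsim_orientation = 1,
                         angle_peak_scale = 1) {
  stopifnot(all(c("khte_peak", "khte_selfsim") %in% names(v)),
            all(c("khte_peak", "khte_selfsim") %in% names(v_prime)),
            selfsim_orientation %in% c(-1, 1))
  check_scalar(angle_peak_scale, "angle_peak_scale", positive = TRUE)
  if (!all(is.finite(c(v, v_prime))))
    stop("feature vectors must be finite", call. = FALSE)
  d_peak <- unname(v_prime[["khte_peak"]] - v[["khte_peak"]])
  d_selfsim <- unname(v_prime[["khte_selfsim"]] - v[["khte_selfsim"]])
  magnitude <- sqrt(d_peak^2 + d_selfsim^2)
  degenerate <- magnitude == 0
  angle <- if (degenerate) NA_real_
           else atan2(selfsim_orientation * d_selfsim,
                      d_peak / angle_peak_scale)
  structure(
    list(d_peak = d_peak, d_selfsim = d_selfsim, angle = angle,
         magnitude = magnitude, degenerate = degenerate,
         selfsim_orientation = selfsim_orientation,
         angle_peak_scale = angle_peak_scale),
    class = "khte_delta"
  )
}

#' @export
print.khte_delta <- function(x, ...) {
  cat(sprintf("State-change vector: d_peak = %+.2f ms, d_selfsim = %+.4f\n",
              x$d_peak, x$d_selfsim))
  if (x$degenerate) cat("  zero magnitude; angle undefined\n")
  else cat(sprintf("  magnitude = %.3f, angle = %.3f rad (orientation %+d)\n",
                   x$magnitude, x$angle, x$selfsim_orientation))
  invisible(x)
}
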