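#' Rayleigh test of circular uniformity
#'
#' Tests whether a sample of angles is uniformly distributed around the
#' circle against a unimodal (von Mises) alternative — the standard test for
#' directionality of a set of 2-D change vectors. The mean resultant length
#' is `Rbar = |sum(exp(i*theta))| / n`, the statistic is `z = n * Rbar^2`,
#' and the p-value uses the classical small-sample series approximation
#' `p = exp(-z) * [1 + (2z - z^2)/(4n) - (24z - 132z^2 + 76z^3 - 9z^4)/(288n^2)]`,
#' clipped to `(0, 1]`. The approximation is validated in the test suite
#' against Monte-Carlo calibration under the uniform null.
#'
#' @param angles Numeric vector of angles in radians (any branch; the test is
#'   rotation-invariant). Zero-magnitude change vectors must be excluded
#'   before calling (their angle is undefined). At least two finite angles
#'   are required.
#' @return An object of class `"htest"` with `statistic` (`z`), `p.value`,
#'   `parameter` (`n`) and `estimate` (mean resultant length and mean
#'   direction in radians).
#' @examples
#' rayleigh_test(rep(0.3, 14))          # maximal concentration
#' rayleigh_test(c(0, pi))              # perfect cancellation
#' @export
rayleigh_test <- function(angles) {
  dname <- deparse(substitute(angles))
  if (!is.numeric(angles) || length(angles) < 2L)
    stop("need at least two angles", call. = FALSE)
  if (!all(is.finite(angles)))
    stop("all angles must be finite", call. = FALSE)
  n <- length(angles)
  C <- sum(cos(angles)); S <- sum(sin(angles))
  rbar <- sqrt(C^2 + S^2) / n
  mu <- atan2(S, C)
  z <- n * rbar^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  p <- min(max(p, .Machine$double.xmin), 1)
  structure(
    list(statistic = c(z = z), p.value = p,
         parameter = c(n = n),
         estimate = c(mean_resultant_length = rbar, mean_direction = mu),
         method = "Rayleigh test of circular uniformity",
         data.name = dname),
    class = "htest"
  )
}

#' Circular histogram of a set of angles
#'
#' Counts angles into equal angular sectors partitioning `(-pi, pi]`; input
#' angles are wrapped into that branch first. Sector `s` covers
#' `(-pi + (s-1)*w, -pi + s*w]` with `w = 2*pi/n_sectors`.
#'
#' @param angles Numeric vector of angles in radians.
#' @param n_sectors Number of sectors (at least 4).
#' @return Object of class `"circular_histogram"`: list with `counts`
#'   (integer vector summing to `length(angles)`), `breaks` (sector
#'   boundaries) and `n`.
#' @examples
#' circular_histogram(c(0, pi / 2, pi, 3 * pi / 2), n_sectors = 4)$counts
#' @export
circular_histogram <- function(angles, n_sectors = 8L) {
  check_scalar(n_sectors, "n_sectors", positive = TRUE)
  n_sectors <- as.integer(n_sectors)
  if (n_sectors < 4L) stop("'n_sectors' must be at least 4", call. = FALSE)
  if (!all(is.finite(angles)))
    stop("all angles must be finite", call. = FALSE)
  w <- wrap_angle(angles)
  sector <- pmax(1L, as.integer(ceiling((w + pi) / (2 * pi / n_sectors))))
  structure(
    list(counts = tabulate(sector, nbins = n_sectors),
         breaks = seq(-pi, pi, length.out = n_sectors + 1L),
         n = length(angles)),
    class = "circular_histogram"
  )
}

#' @export
print.circular_histogram <- function(x, ...) {
  cat(sprintf("Circular histogram: %d angles in %d sectors\n",
              x$n, length(x$counts)))
  cat("  counts:", paste(x$counts, collapse = " "), "\n")
  invisible(x)
}

#' @export
plot.circular_histogram <- function(x, main = "Circular histogram", ...) {
  k <- length(x$counts)
  mid <- (x$breaks[-1L] + x$breaks[-(k + 1L)]) / 2
  r <- if (max(x$counts) > 0) x$counts / max(x$counts) else x$counts
  graphics::plot(NA, xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.1), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", main = main, ...)
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(cos(th), sin(th), col = "grey70")
  graphics::segments(0, 0, r * cos(mid), r * sin(mid), lwd = 6, lend = 1,
                     col = "steelblue")
  invisible(x)
}
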