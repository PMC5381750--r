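#' Analysis parameters for the key hold time evolution pipeline
#'
#' Bundles the tunable parameters of the KHTE representation: the rectangular
#' time window, the minimum occupancy filter, the histogram binning and the
#' self-similarity saturation scale.
#'
#' @param N Window length in milliseconds. Consecutive non-overlapping windows
#'   `[i*N, (i+1)*N)` partition the session. Default 60000 (one minute), which
#'   guarantees at least `Q` keystrokes per window at the slowest plausible
#'   typing speed the package models (~126 characters/minute).
#' @param Q Minimum number of hold-time samples a window must contain to be
#'   retained. Windows sparser than `Q` are dropped so every histogram column
#'   is a usable density estimate. Default 30.
#' @param k Number of histogram bins. Default 20.
#' @param M Upper edge in milliseconds of the last regular bin; together with
#'   `k` this gives bin width `M/k`. Hold times greater than `M` are collected
#'   into the last bin. Default 500, i.e. 25 ms bins, resolving the ~100 ms
#'   mode of typical hold times.
#' @param L Saturation scale for normalizing the self-similarity matrix: an L2
#'   distance of `L` (or more) between two histogram columns maps to a
#'   normalized distance of 1. Default 0.5.
#'
#' @return An object of class `"khte_params"`.
#' @seealso [khte()], [self_similarity()], [tune_khte_params()]
#' @examples
#' khte_params()
#' khte_params(N = 30000, Q = 15)
#' @export
khte_params <- function(N = 60000, Q = 30, k = 20, M = 500, L = 0.5) {
  check_scalar(N, "N", positive = TRUE)
  check_scalar(Q, "Q", positive = TRUE)
  check_scalar(k, "k", positive = TRUE)
  check_scalar(M, "M", positive = TRUE)
  check_scalar(L, "L", positive = TRUE)
  if (Q < 1) stop("'Q' must be at least 1", call. = FALSE)
  if (k < 2) stop("'k' must be at least 2", call. = FALSE)
  structure(
    list(N = as.numeric(N), Q = as.integer(round(Q)), k = as.integer(round(k)),
         M = as.numeric(M), L = as.numeric(L)),
    class = "khte_params"
  )
}

#' @export
print.khte_params <- function(x, ...) {
  cat("KHTE analysis parameters\n")
  cat(sprintf("  window length N:   %g ms\n", x$N))
  cat(sprintf("  min occupancy Q:   %d samples\n", x$Q))
  cat(sprintf("  histogram bins k:  %d\n", x$k))
  cat(sprintf("  last bin edge M:   %g ms (bin width %g ms)\n", x$M, x$M / x$k))
  cat(sprintf("  similarity scale L: %g\n", x$L))
  invisible(x)
}
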