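#' Partition a hold-time series into occupancy-filtered windows
#'
#' Cuts the session `[0, duration_ms]` into consecutive non-overlapping
#' rectangular windows of length `N` ms aligned to t = 0. A sample with press
#' time `t` belongs to window `floor(t / N)`. Windows holding fewer than `Q`
#' samples are removed; retained windows keep their original (0-based)
#' index so the time axis stays interpretable.
#'
#' @param series A `hold_time_series` from [extract_hold_times()].
#' @param params A [khte_params()] object (only `N` and `Q` are used).
#' @param duration_ms Session duration in milliseconds; must be at least `N`.
#' @return An object of class `"window_set"`: list with `windows` (list of
#'   hold-time vectors) and `indices` (integer window indices).
#' @export
partition_windows <- function(series, params = khte_params(), duration_ms) {
  stopifnot(inherits(series, "hold_time_series"),
            inherits(params, "khte_params"))
  check_scalar(duration_ms, "duration_ms", positive = TRUE)
  if (duration_ms < params$N)
    stop(sprintf("duration (%g ms) is shorter than one window (N = %g ms)",
                 duration_ms, params$N), call. = FALSE)
  n_win <- ceiling(duration_ms / params$N)
  idx <- pmin(floor(series$t / params$N), n_win - 1)
  windows <- split(series$ht, factor(idx, levels = 0:(n_win - 1)))
  keep <- lengths(windows) >= params$Q
  structure(
    list(windows = unname(windows[keep]),
         indices = as.integer(names(windows)[keep])),
    class = "window_set"
  )
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("Window set: %d retained windows (sizes %s)\n",
              length(x$windows),
              paste(lengths(x$windows), collapse = ", ")))
  invisible(x)
}

# bin assignment: k equal bins on [0, M), half-open [edge, next); the last
# bin also collects every observation >= M
assign_bins <- function(ht, k, M) {
  as.integer(pmin(floor(ht / (M / k)) + 1, k))
}

#' Fit the Key Hold Time Evolution matrix
#'
#' The central representation of the package: the session is partitioned into
#' occupancy-filtered time windows ([partition_windows()]) and each retained
#' window is summarised as a normalized hold-time histogram with `k` equal
#' bins from 0 to `M` ms, the last bin also collecting every observation
#' greater than `M`. The histograms form the columns of the k x z KHTE matrix
#' `K` — a time-evolving estimate of the hold-time probability density. Every
#' column sums to 1.
#'
#' @param x A [keystroke_log()] or a `hold_time_series`.
#' @param params A [khte_params()] object.
#' @param ... Passed to methods; `khte.hold_time_series()` requires
#'   `duration_ms`.
#' @return An object of class `"khte"`: list with `K` (k x z column-stochastic
#'   matrix), `bin_edges` (k+1 values), `window_indices`, `window_sizes`,
#'   `params` and the matched call. Methods: [print()], [summary()],
#'   [plot()], [coef()] (returns the two compact features).
#' @examples
#' log <- generate_session(typist_profile(seed = 1), duration_ms = 300000)
#' fit <- khte(log, khte_params(N = 60000, Q = 10))
#' coef(fit)
#' @export
khte <- function(x, params = khte_params(), ...) UseMethod("khte")

#' @rdname khte
#' @export
khte.keystroke_log <- function(x, params = khte_params(), ...) {
  series <- extract_hold_times(x)
  out <- khte.hold_time_series(series, params, duration_ms = x$duration_ms)
  out$call <- match.call()
  out
}

#' @rdname khte
#' @param duration_ms Session duration in milliseconds (required for the
#'   series method; taken from the log otherwise).
#' @export
khte.hold_time_series <- function(x, params = khte_params(), duration_ms, ...) {
  ws <- partition_windows(x, params, duration_ms)
  if (length(ws$windows) == 0L)
    stop(paste("no window passed the occupancy filter;",
               "relax Q or shorten the window length N"), call. = FALSE)
  k <- params$k; M <- params$M
  K <- vapply(ws$windows,
              function(w) tabulate(assign_bins(w, k, M), nbins = k) / length(w),
              numeric(k))
  K <- matrix(K, nrow = k)
  structure(
    list(K = K,
         bin_edges = seq(0, M, length.out = k + 1),
         window_indices = ws$indices,
         window_sizes = lengths(ws$windows),
         params = params,
         call = match.call()),
    class = "khte"
  )
}

#' @export
print.khte <- function(x, ...) {
  cat(sprintf("Key Hold Time Evolution matrix: %d bins x %d windows\n",
              nrow(x$K), ncol(x$K)))
  cat(sprintf("  bins: %g ms wide on [0, %g) ms + overflow; windows: %g s, Q = %d\n",
              x$params$M / x$params$k, x$params$M, x$params$N / 1000,
              x$params$Q))
  invisible(x)
}

#' @export
summary.khte <- function(object, ...) {
  z <- ncol(object$K)
  feats <- coef(object)
  out <- list(k = nrow(object$K), z = z,
              window_sizes = object$window_sizes,
              khte_peak = feats[["khte_peak"]],
              khte_selfsim = if (z >= 2) feats[["khte_selfsim"]] else NA_real_,
              params = object$params)
  class(out) <- "summary.khte"
  out
}

#' @export
print.summary.khte <- function(x, ...) {
  cat(sprintf("KHTE fit: %d x %d matrix (%d--%d samples/window)\n",
              x$k, x$z, min(x$window_sizes), max(x$window_sizes)))
  cat(sprintf("  KHTE peak (K^p):           %.2f ms\n", x$khte_peak))
  cat(sprintf("  KHTE self similarity (K^s): %.3f\n", x$khte_selfsim))
  invisible(x)
}

#' @export
coef.khte <- function(object, ...) {
  z <- ncol(object$K)
  c(khte_peak = khte_peak(object),
    khte_selfsim = if (z >= 2) khte_selfsim(self_similarity(object))
                   else NA_real_)
}

#' @export
plot.khte <- function(x, col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                      xlab = "Time window (min)", ylab = "Hold time (ms)",
                      ...) {
  centers <- (x$bin_edges[-1L] + x$bin_edges[-length(x$bin_edges)]) / 2
  graphics::image(x = x$window_indices * x$params$N / 60000,
                  y = centers, z = t(x$K), col = col,
                  xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Serialize / restore a KHTE matrix
#'
#' `write_khte()` stores the matrix as a tab-delimited text file plus a JSON
#' sidecar (`<path>.json`) holding the bin edges, window indices and
#' parameters, so a fit can be reproduced and inspected outside R.
#' `read_khte()` restores the object.
#'
#' @param x A `"khte"` object.
#' @param path Path of the matrix file; the sidecar is written at
#'   `paste0(path, ".json")`.
#' @return `write_khte()` returns `path` invisibly; `read_khte()` returns the
#'   restored `"khte"` object.
#' @export
write_khte <- function(x, path) {
  stopifnot(inherits(x, "khte"))
  utils::write.table(x$K, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  sidecar <- list(bin_edges = x$bin_edges,
                  window_indices = x$window_indices,
                  window_sizes = unname(x$window_sizes),
                  params = unclass(x$params))
  jsonlite::write_json(sidecar, paste0(path, ".json"), digits = NA,
                       auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_khte
#' @export
read_khte <- function(path) {
  K <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(K) <- NULL
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  p <- side$params
  structure(
    list(K = K, bin_edges = side$bin_edges,
         window_indices = as.integer(side$window_indices),
         window_sizes = as.integer(side$window_sizes),
         params = khte_params(p$N, p$Q, p$k, p$M, p$L),
         call = NULL),
    class = "khte"
  )
}
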