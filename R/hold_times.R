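#' Hold-time series
#'
#' Internal constructor for the (press-time, hold-time) process derived from a
#' keystroke log. Samples are sorted by press time; all hold times are
#' strictly positive.
#'
#' @param t Press times in milliseconds (non-decreasing after sorting).
#' @param ht Hold times in milliseconds, all `> 0`.
#' @param diagnostics Named list of event-accounting counters.
#' @return Object of class `c("hold_time_series", "data.frame")`.
#' @export
hold_time_series <- function(t, ht, diagnostics = list()) {
  stopifnot(length(t) == length(ht))
  if (any(ht <= 0)) stop("hold times must be strictly positive", call. = FALSE)
  ord <- order(t, method = "radix")
  out <- data.frame(t = as.numeric(t)[ord], ht = as.numeric(ht)[ord])
  attr(out, "diagnostics") <- diagnostics
  class(out) <- c("hold_time_series", "data.frame")
  out
}

# per-key matcher: ts/is_down are one key's events in log order.
# Fast path covers the common clean stream (strict down/up alternation);
# the general path is a state machine implementing the matching contract:
# each down pairs with the earliest later up of the same key, a second down
# while the key is held is OS auto-repeat and is discarded (the original
# press time is kept), ups without an open down are orphans, and zero or
# negative hold times are timer artifacts and are dropped.
match_key_events <- function(ts, is_down) {
  n <- length(ts)
  zero_diag <- c(orphan_down = 0L, orphan_up = 0L, autorepeat = 0L,
                 zero_hold = 0L)
  if (n %% 2L == 0L &&
      all(is_down == rep_len(c(TRUE, FALSE), n))) {
    down <- ts[seq.int(1L, length.out = n %/% 2L, by = 2L)]
    up <- ts[seq.int(2L, length.out = n %/% 2L, by = 2L)]
    ht <- up - down
    if (all(ht > 0))
      return(list(t = down, ht = ht, diag = zero_diag))
  }
  t_out <- numeric(n %/% 2L); ht_out <- numeric(n %/% 2L)
  m <- 0L; open <- NA_real_
  diag <- zero_diag
  for (i in seq_len(n)) {
    if (is_down[i]) {
      if (is.na(open)) open <- ts[i]
      else diag[["autorepeat"]] <- diag[["autorepeat"]] + 1L
    } else {
      if (is.na(open)) {
        diag[["orphan_up"]] <- diag[["orphan_up"]] + 1L
      } else {
        ht <- ts[i] - open
        if (ht > 0) {
          m <- m + 1L
          t_out[m] <- open; ht_out[m] <- ht
        } else {
          diag[["zero_hold"]] <- diag[["zero_hold"]] + 1L
        }
        open <- NA_real_
      }
    }
  }
  if (!is.na(open)) diag[["orphan_down"]] <- 1L
  list(t = t_out[seq_len(m)], ht = ht_out[seq_len(m)], diag = diag)
}

#' Derive the hold-time series from a keystroke log
#'
#' Matches each key-down to the earliest subsequent key-up of the same key
#' (so rollover typing, where holds of different keys overlap, is handled by
#' per-key matching) and returns the process of (press time, hold time)
#' pairs. Orphan downs (never released), orphan ups (never pressed),
#' auto-repeat downs and zero-length holds are dropped and counted in a
#' diagnostics attribute rather than failing the extraction.
#'
#' @param log A [keystroke_log()].
#' @return A `hold_time_series` data frame with columns `t` (press time, ms)
#'   and `ht` (hold time, ms), sorted by `t`. Attribute `"diagnostics"` holds
#'   the counters `n_events`, `n_matched`, `orphan_down`, `orphan_up`,
#'   `autorepeat` and `zero_hold`; attribute `"empty"` flags a log that
#'   yielded no matched pair (also signalled with a warning).
#' @examples
#' ev <- data.frame(timestamp_ms = c(0, 50, 120, 200),
#'                  key_id = c("a", "b", "a", "b"),
#'                  event_type = c("down", "down", "up", "up"))
#' extract_hold_times(keystroke_log(ev, duration_ms = 200))
#' @export
extract_hold_times <- function(log) {
  stopifnot(inherits(log, "keystroke_log"))
  ev <- log$events
  diag_total <- c(orphan_down = 0L, orphan_up = 0L, autorepeat = 0L,
                  zero_hold = 0L)
  t_all <- list(); ht_all <- list()
  if (nrow(ev)) {
    idx_by_key <- split(seq_len(nrow(ev)), ev$key_id)
    is_down <- ev$event_type == "down"
    for (kk in seq_along(idx_by_key)) {
      idx <- idx_by_key[[kk]]
      res <- match_key_events(ev$timestamp_ms[idx], is_down[idx])
      t_all[[kk]] <- res$t
      ht_all[[kk]] <- res$ht
      diag_total <- diag_total + res$diag
    }
  }
  t <- unlist(t_all, use.names = FALSE) %||% numeric(0)
  ht <- unlist(ht_all, use.names = FALSE) %||% numeric(0)
  diagnostics <- as.list(c(n_events = nrow(ev), n_matched = length(t),
                           diag_total))
  out <- hold_time_series(t, ht, diagnostics)
  empty <- length(t) == 0L
  attr(out, "empty") <- empty
  if (empty && nrow(ev) > 0L)
    warning(sprintf("log for subject %s yielded no matched down/up pair",
                    log$subject_id), call. = FALSE)
  out
}

#' Classical summary statistics of a typing session
#'
#' The two "raw" keystroke-dynamics variables used as baselines: the median
#' key hold time and the average typing speed (matched key presses per
#' minute).
#'
#' @param series A `hold_time_series` from [extract_hold_times()].
#' @param duration_ms Session duration in milliseconds.
#' @return List with `median_ht` (ms) and `typing_speed` (keys/minute).
#' @examples
#' s <- hold_time_series(t = c(0, 100, 200), ht = c(90, 100, 110))
#' hold_time_stats(s, duration_ms = 60000)
#' @export
hold_time_stats <- function(series, duration_ms) {
  stopifnot(inherits(series, "hold_time_series"))
  check_scalar(duration_ms, "duration_ms", positive = TRUE)
  if (nrow(series) == 0L)
    stop("summary statistics are undefined for an empty hold-time series",
         call. = FALSE)
  list(median_ht = stats::median(series$ht),
       typing_speed = nrow(series) / (duration_ms / 60000))
}

#' @export
print.hold_time_series <- function(x, ...) {
  d <- attr(x, "diagnostics")
  cat(sprintf("Hold-time series: %d samples", nrow(x)))
  if (nrow(x))
    cat(sprintf(" over %.1f s, median %.1f ms", diff(range(x$t)) / 1000,
                stats::median(x$ht)))
  cat("\n")
  if (!is.null(d))
    cat(sprintf("  events: %d, orphans: %d down / %d up, auto-repeat: %d, zero-holds: %d\n",
                d$n_events, d$orphan_down, d$orphan_up, d$autorepeat,
                d$zero_hold))
  invisible(x)
}
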