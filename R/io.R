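#' Construct a keystroke log
#'
#' A keystroke log holds the raw key-down/key-up events of one typing session
#' together with session metadata. Events are stored sorted by timestamp
#' (ties keep input order); timestamps are session-relative milliseconds and
#' may carry sub-millisecond fractions.
#'
#' @param events Data frame with columns `timestamp_ms` (non-negative numeric),
#'   `key_id` (character, opaque key token) and `event_type` (`"down"` or
#'   `"up"`).
#' @param subject_id Subject identifier (no whitespace or commas).
#' @param state Session state, `"rested"` or `"sleep_inertia"`.
#' @param repetition Positive integer repetition index.
#' @param duration_ms Session duration in milliseconds; defaults to the last
#'   event timestamp. All event timestamps must be `<= duration_ms`.
#'
#' @return An object of class `"keystroke_log"`.
#' @seealso [read_keystroke_log()], [extract_hold_times()]
#' @examples
#' ev <- data.frame(timestamp_ms = c(0, 110), key_id = "a",
#'                  event_type = c("down", "up"))
#' keystroke_log(ev, subject_id = "s1", state = "rested", duration_ms = 1000)
#' @export
keystroke_log <- function(events, subject_id = "unknown",
                          state = c("rested", "sleep_inertia"),
                          repetition = 1L, duration_ms = NULL) {
  state <- match.arg(state)
  check_string(subject_id, "subject_id")
  check_scalar(repetition, "repetition", positive = TRUE)
  repetition <- as.integer(repetition)

  if (!is.data.frame(events) ||
      !all(c("timestamp_ms", "key_id", "event_type") %in% names(events)))
    stop("'events' must be a data frame with columns timestamp_ms, key_id, event_type",
         call. = FALSE)
  events <- data.frame(timestamp_ms = as.numeric(events$timestamp_ms),
                       key_id = as.character(events$key_id),
                       event_type = as.character(events$event_type),
                       stringsAsFactors = FALSE)
  if (anyNA(events$timestamp_ms) || any(events$timestamp_ms < 0))
    stop("event timestamps must be non-negative numbers", call. = FALSE)
  bad <- !events$event_type %in% c("down", "up")
  if (any(bad))
    stop(sprintf("unknown event_type '%s'", events$event_type[which(bad)[1L]]),
         call. = FALSE)

  # stable sort: ties keep input order
  events <- events[order(events$timestamp_ms, method = "radix"), , drop = FALSE]
  rownames(events) <- NULL

  if (is.null(duration_ms))
    duration_ms <- if (nrow(events)) max(events$timestamp_ms) else 1
  check_scalar(duration_ms, "duration_ms", positive = TRUE)
  if (nrow(events) && max(events$timestamp_ms) > duration_ms)
    stop("event timestamps exceed duration_ms", call. = FALSE)

  structure(
    list(events = events, subject_id = subject_id, state = state,
         repetition = repetition, duration_ms = as.numeric(duration_ms)),
    class = "keystroke_log"
  )
}

#' @export
print.keystroke_log <- function(x, ...) {
  cat(sprintf("Keystroke log: subject %s, %s, repetition %d\n",
              x$subject_id, x$state, x$repetition))
  cat(sprintf("  %d events over %.1f s\n",
              nrow(x$events), x$duration_ms / 1000))
  invisible(x)
}

log_header <- "timestamp_ms,key_id,event_type"

#' Read a keystroke event log
#'
#' Reads the plain-text keystroke log dialect: UTF-8, comma-separated, header
#' `timestamp_ms,key_id,event_type`, one event per row. `#`-prefixed comment
#' lines carry session metadata of the form
#' `# subject=<id> state=<rested|sleep_inertia> repetition=<int> duration_ms=<real>`.
#' Malformed rows are rejected with an error naming the offending line.
#'
#' @param path Path to the log file.
#' @return A [keystroke_log()].
#' @seealso [write_keystroke_log()]
#' @export
read_keystroke_log <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path),
                               call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)

  meta <- list(subject = "unknown", state = "rested",
               repetition = 1L, duration_ms = NULL)
  grab <- function(line, key) {
    m <- regmatches(line, regexpr(sprintf("%s=[^[:space:]]+", key), line))
    if (length(m)) sub(sprintf("^%s=", key), "", m) else NULL
  }
  for (cl in lines[startsWith(lines, "#")]) {
    meta$subject <- grab(cl, "subject") %||% meta$subject
    meta$state <- grab(cl, "state") %||% meta$state
    rep_ <- grab(cl, "repetition")
    if (!is.null(rep_)) meta$repetition <- as.integer(rep_)
    dur <- grab(cl, "duration_ms")
    if (!is.null(dur)) meta$duration_ms <- as.numeric(dur)
  }

  body_idx <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  if (!length(body_idx))
    stop(sprintf("'%s': no header line found", path), call. = FALSE)
  if (trimws(lines[body_idx[1L]]) != log_header)
    stop(sprintf("'%s' line %d: expected header '%s'",
                 path, body_idx[1L], log_header), call. = FALSE)
  row_idx <- body_idx[-1L]

  n <- length(row_idx)
  ts <- numeric(n); key <- character(n); type <- character(n)
  if (n) {
    parts <- strsplit(lines[row_idx], ",", fixed = TRUE)
    len <- lengths(parts)
    if (any(len != 3L)) {
      i <- which(len != 3L)[1L]
      stop(sprintf("'%s' line %d: expected 3 comma-separated fields, got %d",
                   path, row_idx[i], len[i]), call. = FALSE)
    }
    m <- matrix(unlist(parts), ncol = 3L, byrow = TRUE)
    ts <- suppressWarnings(as.numeric(m[, 1L]))
    if (anyNA(ts)) {
      i <- which(is.na(ts))[1L]
      stop(sprintf("'%s' line %d: non-numeric timestamp '%s'",
                   path, row_idx[i], m[i, 1L]), call. = FALSE)
    }
    key <- m[, 2L]; type <- m[, 3L]
    bad <- !type %in% c("down", "up")
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf("'%s' line %d: unknown event_type '%s' (expected down|up)",
                   path, row_idx[i], type[i]), call. = FALSE)
    }
  }

  keystroke_log(
    data.frame(timestamp_ms = ts, key_id = key, event_type = type,
               stringsAsFactors = FALSE),
    subject_id = meta$subject, state = meta$state,
    repetition = meta$repetition, duration_ms = meta$duration_ms
  )
}

#' Write a keystroke log in canonical form
#'
#' Serializes a [keystroke_log()] to the log dialect read by
#' [read_keystroke_log()]. Output is canonical (timestamps formatted with
#' three decimals, metadata on a single comment line), so
#' `write_keystroke_log(read_keystroke_log(f))` is idempotent and identical
#' seeds yield byte-identical files.
#'
#' @param log A [keystroke_log()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_keystroke_log <- function(log, path) {
  stopifnot(inherits(log, "keystroke_log"))
  lines <- c(
    sprintf("# subject=%s state=%s repetition=%d duration_ms=%.3f",
            log$subject_id, log$state, log$repetition, log$duration_ms),
    log_header,
    sprintf("%.3f,%s,%s", log$events$timestamp_ms, log$events$key_id,
            log$events$event_type)
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
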