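# shared argument checks and small numeric helpers

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("'%s' must be non-negative", name), call. = FALSE)
  invisible(x)
}

check_string <- function(x, name) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x))
    stop(sprintf("'%s' must be a non-empty string", name), call. = FALSE)
  if (grepl("[\\s,]", x, perl = TRUE))
    stop(sprintf("'%s' must not contain whitespace or commas", name),
         call. = FALSE)
  invisible(x)
}

# trapezoidal area under a piecewise-linear curve given in sweep order
trapezoid_area <- function(x, y) {
  sum(diff(x) * (y[-1L] + y[-length(y)]) / 2)
}

# wrap angles into (-pi, pi]
wrap_angle <- function(a) {
  a - 2 * pi * ceiling((a - pi) / (2 * pi))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
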