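#' Tune KHTE parameters by maximizing the state-change norm
#'
#' Searches the parameter space for the setting that maximizes the mean
#' Euclidean norm of the state-change vector over training pairs of sessions
#' (reference and altered state of the same subject). The objective knows the
#' magnitude of the change but not its direction, and the training pairs must
#' be disjoint from any later evaluation data. Because `N`, `Q` and `k` are
#' integer-valued, the search is a coordinate descent over a user-supplied
#' discrete grid rather than a literal gradient descent: coordinates are
#' swept in turn, each set to its best grid value with the others fixed,
#' until a full sweep makes no change.
#'
#' @param pairs List of training pairs; each element is a list with
#'   components `reference` and `altered`, both [keystroke_log()] objects.
#' @param grid Named list giving the candidate values for each of `N`, `Q`,
#'   `k`, `M`, `L`. Singleton components pin a parameter.
#' @param start Optional [khte_params()] starting point; by default each
#'   coordinate starts at the grid value closest to the package default.
#' @param max_sweeps Maximum number of full coordinate sweeps.
#' @return Object of class `"khte_tuning"`: list with `params` (the selected
#'   [khte_params()]), `objective` (mean `||v^delta||` attained), `n_pairs`
#'   (pairs actually used) and `sweeps`.
#' @export
tune_khte_params <- function(pairs, grid, start = NULL, max_sweeps = 10L) {
  dims <- c("N", "Q", "k", "M", "L")
  if (!is.list(grid) || !all(dims %in% names(grid)))
    stop("'grid' must be a named list with components N, Q, k, M, L",
         call. = FALSE)
  if (any(lengths(grid[dims]) == 0L))
    stop("every grid dimension needs at least one candidate value",
         call. = FALSE)
  if (!length(pairs)) stop("no training pairs supplied", call. = FALSE)

  objective <- function(par) {
    norms <- vapply(pairs, function(p) {
      tryCatch({
        v <- khte_features(p$reference, par)
        vp <- khte_features(p$altered, par)
        delta_vector(v, vp)$magnitude
      }, error = function(e) NA_real_)
    }, numeric(1))
    if (anyNA(norms))
      warning(sprintf("%d training pair(s) skipped (empty window set)",
                      sum(is.na(norms))), call. = FALSE)
    if (all(is.na(norms))) return(list(value = -Inf, n = 0L))
    list(value = mean(norms, na.rm = TRUE), n = sum(!is.na(norms)))
  }

  defaults <- unclass(khte_params())
  current <- if (is.null(start)) {
    vapply(dims, function(d)
      grid[[d]][which.min(abs(grid[[d]] - defaults[[d]]))], numeric(1))
  } else {
    stopifnot(inherits(start, "khte_params"))
    vapply(dims, function(d) as.numeric(start[[d]]), numeric(1))
  }
  names(current) <- dims

  as_params <- function(v) khte_params(v[["N"]], v[["Q"]], v[["k"]],
                                       v[["M"]], v[["L"]])
  best <- objective(as_params(current))
  if (best$n == 0L)
    stop("no training pair produced a usable window set at the start point",
         call. = FALSE)

  sweeps <- 0L
  repeat {
    sweeps <- sweeps + 1L
    changed <- FALSE
    for (d in dims) {
      for (cand in grid[[d]]) {
        if (cand == current[[d]]) next
        trial <- current; trial[[d]] <- cand
        res <- objective(as_params(trial))
        if (res$value > best$value) {
          current <- trial; best <- res; changed <- TRUE
        }
      }
    }
    if (!changed || sweeps >= max_sweeps) break
  }

  structure(
    list(params = as_params(current), objective = best$value,
         n_pairs = best$n, sweeps = sweeps),
    class = "khte_tuning"
  )
}

#' @export
print.khte_tuning <- function(x, ...) {
  cat(sprintf("KHTE parameter tuning: mean ||v^delta|| = %.3f over %d pair(s), %d sweep(s)\n",
              x$objective, x$n_pairs, x$sweeps))
  print(x$params)
  invisible(x)
}
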