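# rank-statistic AUC (Mann-Whitney with average ranks: ties get half credit)
auc_rank <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  stopifnot(n1 > 0, n0 > 0)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve from pooled scores
#'
#' Sweeps a decision threshold through the scores (predict positive when
#' `score >= threshold`) and returns the operating points and the
#' trapezoidal area under the curve. Tied scores are grouped into a single
#' operating point, so ties contribute half, matching the rank-statistic
#' convention.
#'
#' @param scores Numeric scores, larger meaning more positive.
#' @param labels Logical vector (or factor with level `"positive"`) marking
#'   the positive class.
#' @return Object of class `"khte_roc"`: list with `thresholds`, `fpr`,
#'   `tpr` (all starting at the (0,0) point), `auc`, `scores`, `labels`.
#' @export
roc_curve <- function(scores, labels) {
  positive <- as_positive(labels)
  stopifnot(length(scores) == length(positive))
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present to build a ROC curve", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- positive[ord]
  keep <- c(s[-1L] != s[-length(s)], TRUE)  # last index of each tied block
  tpr <- c(0, cumsum(y)[keep] / n1)
  fpr <- c(0, cumsum(!y)[keep] / n0)
  structure(
    list(thresholds = c(Inf, s[keep]), fpr = fpr, tpr = tpr,
         auc = trapezoid_area(fpr, tpr),
         scores = scores, labels = positive),
    class = "khte_roc"
  )
}

as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels) || is.character(labels))
    return(as.character(labels) == "positive")
  as.logical(labels)
}

#' @export
print.khte_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (%d positive / %d negative)\n",
              x$auc, sum(x$labels), sum(!x$labels)))
  invisible(x)
}

#' @export
plot.khte_roc <- function(x, add = FALSE, col = "steelblue",
                          xlab = "False positive rate",
                          ylab = "True positive rate", ...) {
  if (add) graphics::lines(x$fpr, x$tpr, col = col, ...)
  else {
    graphics::plot(x$fpr, x$tpr, type = "l", col = col, xlim = c(0, 1),
                   ylim = c(0, 1), xlab = xlab, ylab = ylab, ...)
    graphics::abline(0, 1, lty = 3, col = "grey60")
  }
  invisible(x)
}

#' Build the positive/negative state-change datasets
#'
#' From a per-session feature table (one row per session, 2 states x 2
#' repetitions per subject) builds the two labeled change datasets used for
#' classification. For each complete subject, the positive sample of dataset
#' `repetition1` is the rested-to-impaired change within repetition 1 (and
#' within repetition 2 for dataset `repetition2`); both datasets share the
#' same negative samples — the same-state changes across the two repetitions
#' (rested r1 to rested r2, and impaired r1 to impaired r2). Subjects missing
#' any of their four sessions are skipped with a warning.
#'
#' @param features Data frame with columns `subject`, `state` (`"rested"` /
#'   `"sleep_inertia"`), `repetition` (1 or 2), `khte_peak`, `khte_selfsim`,
#'   and optionally `median_ht` and `typing_speed` (needed for the stump
#'   baselines).
#' @param selfsim_orientation Orientation of the self-similarity axis used
#'   for the stored angles (see [delta_vector()]); default `-1`, so the
#'   expected impairment direction is the upper-right quadrant.
#' @param angle_peak_scale Scale (ms) dividing `d_peak` in the angle
#'   computation so the two axes are commensurable; default 25, the default
#'   histogram bin width `M/k`. See [delta_vector()].
#' @return Named list of two `change_dataset` data frames
#'   (`repetition1`, `repetition2`) with columns `subject`, `label`
#'   (`"positive"` / `"negative"`), `d_peak`, `d_selfsim`, `angle`,
#'   `magnitude`, and the baseline differences `d_median_ht`,
#'   `d_typing_speed` when available.
#' @export
build_change_datasets <- function(features, selfsim_orientation = -1,
                                  angle_peak_scale = 25) {
  need <- c("subject", "state", "repetition", "khte_peak", "khte_selfsim")
  if (!is.data.frame(features) || !all(need %in% names(features)))
    stop("'features' must have columns subject, state, repetition, khte_peak, khte_selfsim",
         call. = FALSE)
  has_raw <- all(c("median_ht", "typing_speed") %in% names(features))

  combos <- c("rested.1", "sleep_inertia.1", "rested.2", "sleep_inertia.2")
  features$.combo <- paste(features$state, features$repetition, sep = ".")
  subjects <- unique(features$subject)
  complete <- vapply(subjects, function(s) {
    have <- features$.combo[features$subject == s]
    all(combos %in% have) && !anyDuplicated(have)
  }, logical(1))
  if (any(!complete))
    warning(sprintf("skipping %d subject(s) without a complete 2x2 session design: %s",
                    sum(!complete),
                    paste(subjects[!complete], collapse = ", ")),
            call. = FALSE)
  subjects <- subjects[complete]
  if (length(subjects) < 2L)
    stop("need at least 2 complete subjects to build change datasets",
         call. = FALSE)

  row_of <- function(s, combo) features[features$subject == s &
                                          features$.combo == combo, ]
  change_row <- function(s, from, to, label) {
    a <- row_of(s, from); b <- row_of(s, to)
    v <- c(khte_peak = a$khte_peak, khte_selfsim = a$khte_selfsim)
    vp <- c(khte_peak = b$khte_peak, khte_selfsim = b$khte_selfsim)
    d <- delta_vector(v, vp, selfsim_orientation = selfsim_orientation,
                      angle_peak_scale = angle_peak_scale)
    out <- data.frame(subject = s, label = label, d_peak = d$d_peak,
                      d_selfsim = d$d_selfsim, angle = d$angle,
                      magnitude = d$magnitude, stringsAsFactors = FALSE)
    if (has_raw) {
      out$d_median_ht <- b$median_ht - a$median_ht
      out$d_typing_speed <- b$typing_speed - a$typing_speed
    }
    out
  }

  negatives <- do.call(rbind, lapply(subjects, function(s) rbind(
    change_row(s, "rested.1", "rested.2", "negative"),
    change_row(s, "sleep_inertia.1", "sleep_inertia.2", "negative")
  )))
  make_ds <- function(rep_idx, name) {
    pos <- do.call(rbind, lapply(subjects, function(s)
      change_row(s, sprintf("rested.%d", rep_idx),
                 sprintf("sleep_inertia.%d", rep_idx), "positive")))
    ds <- rbind(pos, negatives)
    rownames(ds) <- NULL
    attr(ds, "name") <- name
    attr(ds, "selfsim_orientation") <- selfsim_orientation
    attr(ds, "angle_peak_scale") <- angle_peak_scale
    class(ds) <- c("change_dataset", "data.frame")
    ds
  }
  list(repetition1 = make_ds(1L, "repetition1"),
       repetition2 = make_ds(2L, "repetition2"))
}

#' Leave-one-subject-out SVM evaluation
#'
#' Trains a linear-kernel support vector machine with probability estimation
#' (libSVM via \pkg{e1071}) on the state-change features `(d_peak,
#' d_selfsim)` and scores every sample of a held-out unit with a model fitted
#' on the remaining units. The hold-out unit is the subject by default —
#' a subject contributes several correlated samples, and holding out single
#' samples would leak subject identity into the training fold; sample-level
#' hold-out remains available via `loo_unit = "sample"` for comparison.
#' Features are standardized using training-fold statistics only. The pooled
#' held-out probabilities define the ROC curve.
#'
#' @param ds A `change_dataset` from [build_change_datasets()].
#' @param C SVM regularization constant (default 1).
#' @param loo_unit `"subject"` (default) or `"sample"`.
#' @param seed Local seed for libSVM's internal cross-validated Platt
#'   calibration, which is stochastic; fixing it makes the evaluation
#'   deterministic without touching the caller's RNG state.
#' @return A `"khte_roc"` object (see [roc_curve()]) with additional fields
#'   `fold_assignments` (the held-out unit of each sample) and `loo_unit`.
#' @export
loo_svm_evaluate <- function(ds, C = 1, loo_unit = c("subject", "sample"),
                             seed = 1L) {
  loo_unit <- match.arg(loo_unit)
  stopifnot(is.data.frame(ds),
            all(c("d_peak", "d_selfsim", "label", "subject") %in% names(ds)))
  check_scalar(C, "C", positive = TRUE)
  y <- factor(ifelse(as_positive(ds$label), "positive", "negative"),
              levels = c("negative", "positive"))
  if (nlevels(droplevels(y)) < 2L)
    stop("both classes must be present", call. = FALSE)
  X <- as.matrix(ds[, c("d_peak", "d_selfsim")])
  unit <- if (loo_unit == "subject") as.character(ds$subject)
          else as.character(seq_len(nrow(ds)))
  units <- unique(unit)
  if (length(units) < 2L)
    stop("need at least two hold-out units", call. = FALSE)

  scores <- numeric(nrow(ds))
  withr::with_seed(as.integer(seed), for (u in units) {
    test <- unit == u
    if (length(unique(y[!test])) < 2L)
      stop(sprintf("training fold holding out unit '%s' lost one class entirely", u),
           call. = FALSE)
    mu <- colMeans(X[!test, , drop = FALSE])
    sd_ <- apply(X[!test, , drop = FALSE], 2L, stats::sd)
    sd_[sd_ == 0] <- 1
    Xs <- sweep(sweep(X, 2L, mu), 2L, sd_, "/")
    fit <- e1071::svm(Xs[!test, , drop = FALSE], y[!test],
                      kernel = "linear", cost = C, scale = FALSE,
                      probability = TRUE)
    pr <- stats::predict(fit, Xs[test, , drop = FALSE], probability = TRUE)
    scores[test] <- attr(pr, "probabilities")[, "positive"]
  })
  roc <- roc_curve(scores, y == "positive")
  roc$fold_assignments <- unit
  roc$loo_unit <- loo_unit
  roc
}

#' Decision-stump AUC of a scalar feature
#'
#' The best classification achievable with a single threshold swept through
#' one scalar variable, without any train/test split — the "theoretical
#' upper bound" baseline for a raw feature. Both orientations of the
#' threshold are considered, so the result is `max(a, 1 - a)` where `a` is
#' the rank-statistic AUC of the values.
#'
#' @param values Numeric scalar feature, one per sample.
#' @param labels Positive-class indicator (see [roc_curve()]).
#' @return List with `auc`, `orientation` (`+1` if larger values score
#'   positive, `-1` otherwise), `degenerate` (`TRUE` when all values are
#'   tied, forcing AUC 0.5) and `roc` (the oriented ROC curve).
#' @export
stump_auc <- function(values, labels) {
  positive <- as_positive(labels)
  stopifnot(length(values) == length(positive))
  if (sum(positive) == 0 || sum(!positive) == 0)
    stop("both classes must be present", call. = FALSE)
  degenerate <- length(unique(values)) == 1L
  a <- auc_rank(values, positive)
  orientation <- if (a >= 0.5) 1 else -1
  list(auc = max(a, 1 - a),
       orientation = orientation,
       degenerate = degenerate,
       roc = roc_curve(orientation * values, positive))
}
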