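#' Per-session feature table
#'
#' Runs the feature extraction over a collection of session logs and returns
#' one row per session: the compact KHTE features plus the raw baseline
#' variables (median hold time and typing speed). Sessions whose windows are
#' all filtered out are dropped with a warning.
#'
#' @param logs A `"khte_cohort"` or a list of [keystroke_log()] objects.
#' @param params A [khte_params()] object.
#' @return Data frame with columns `subject`, `state`, `repetition`,
#'   `khte_peak`, `khte_selfsim`, `median_ht`, `typing_speed`.
#' @export
session_features <- function(logs, params = khte_params()) {
  if (inherits(logs, "khte_cohort")) logs <- logs$logs
  stopifnot(is.list(logs), length(logs) > 0)
  rows <- lapply(logs, function(log) {
    stopifnot(inherits(log, "keystroke_log"))
    tryCatch({
      series <- extract_hold_times(log)
      stats_ <- hold_time_stats(series, log$duration_ms)
      feats <- khte_features(series, params, duration_ms = log$duration_ms)
      data.frame(subject = log$subject_id, state = log$state,
                 repetition = log$repetition,
                 khte_peak = feats[["khte_peak"]],
                 khte_selfsim = feats[["khte_selfsim"]],
                 median_ht = stats_$median_ht,
                 typing_speed = stats_$typing_speed,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      warning(sprintf("session %s/%s/r%d dropped: %s", log$subject_id,
                      log$state, log$repetition, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit the full state-change analysis of a cohort
#'
#' The end-to-end analysis: session logs are reduced to hold-time series and
#' KHTE feature vectors, state-change datasets are built
#' ([build_change_datasets()]), the directionality of the impaired
#' transitions is tested with the Rayleigh test, and the changes are
#' classified with a leave-one-subject-out linear SVM alongside
#' decision-stump baselines on median hold time and typing speed.
#'
#' @param x A `"khte_cohort"`, a list of [keystroke_log()]s, or a
#'   pre-computed feature table from [session_features()].
#' @param params A [khte_params()] object.
#' @param C SVM regularization constant.
#' @param selfsim_orientation Orientation of the self-similarity axis for the
#'   change angles (default `-1`: impairment direction is upper-right).
#' @param loo_unit Hold-out unit for the SVM evaluation (see
#'   [loo_svm_evaluate()]).
#' @return Object of class `"khte_study"`: list with `features` (per-session
#'   table), `datasets` (the two change datasets), and `results` — per
#'   dataset the Rayleigh test of the positive (impaired-transition) angles,
#'   the SVM ROC (`svm_roc`) and the two stump baselines; plus
#'   `rayleigh_negative`, the Rayleigh test of the shared same-state
#'   changes. Methods: [print()], [summary()], [plot()].
#' @examples
#' \donttest{
#' cohort <- generate_cohort(n_subjects = 6, master_seed = 7,
#'                           duration_ms = 300000)
#' fit <- khte_study(cohort, khte_params(Q = 20))
#' fit
#' }
#' @export
khte_study <- function(x, params = khte_params(), C = 1,
                       selfsim_orientation = -1,
                       loo_unit = c("subject", "sample")) {
  loo_unit <- match.arg(loo_unit)
  features <- if (is.data.frame(x)) x else session_features(x, params)
  datasets <- build_change_datasets(features, selfsim_orientation,
                                    angle_peak_scale = params$M / params$k)

  results <- lapply(datasets, function(ds) {
    pos <- ds[ds$label == "positive" & !is.na(ds$angle), ]
    list(
      rayleigh_positive = rayleigh_test(pos$angle),
      svm_roc = loo_svm_evaluate(ds, C = C, loo_unit = loo_unit),
      stump_median_ht = stump_auc(ds$d_median_ht, ds$label),
      stump_typing_speed = stump_auc(ds$d_typing_speed, ds$label)
    )
  })
  neg <- datasets$repetition1
  neg <- neg[neg$label == "negative" & !is.na(neg$angle), ]

  structure(
    list(features = features, datasets = datasets, results = results,
         rayleigh_negative = rayleigh_test(neg$angle),
         params = params, C = C,
         selfsim_orientation = selfsim_orientation,
         loo_unit = loo_unit, call = match.call()),
    class = "khte_study"
  )
}

#' @export
print.khte_study <- function(x, ...) {
  cat("Key hold time evolution study\n")
  cat(sprintf("  %d sessions, %d subjects in the change datasets\n",
              nrow(x$features),
              length(unique(x$datasets$repetition1$subject))))
  for (nm in names(x$results)) {
    r <- x$results[[nm]]
    cat(sprintf("  %s: KHTE SVM AUC %.3f | stump AUC: median HT %.3f, speed %.3f | Rayleigh p %.2g\n",
                nm, r$svm_roc$auc, r$stump_median_ht$auc,
                r$stump_typing_speed$auc, r$rayleigh_positive$p.value))
  }
  cat(sprintf("  same-state changes: Rayleigh p %.2g\n",
              x$rayleigh_negative$p.value))
  invisible(x)
}

#' @export
summary.khte_study <- function(object, ...) {
  tab <- do.call(rbind, lapply(names(object$results), function(nm) {
    r <- object$results[[nm]]
    data.frame(dataset = nm,
               khte_svm_auc = r$svm_roc$auc,
               stump_median_ht_auc = r$stump_median_ht$auc,
               stump_typing_speed_auc = r$stump_typing_speed$auc,
               rayleigh_p_positive = r$rayleigh_positive$p.value,
               stringsAsFactors = FALSE)
  }))
  out <- list(table = tab,
              rayleigh_p_negative = object$rayleigh_negative$p.value,
              n_subjects = length(unique(object$datasets$repetition1$subject)),
              params = object$params)
  class(out) <- "summary.khte_study"
  out
}

#' @export
print.summary.khte_study <- function(x, ...) {
  cat(sprintf("KHTE study summary (%d subjects)\n", x$n_subjects))
  print(x$table, row.names = FALSE, digits = 3)
  cat(sprintf("Rayleigh p of same-state changes: %.3g\n",
              x$rayleigh_p_negative))
  invisible(x)
}

#' @export
plot.khte_study <- function(x, which = c("roc", "deltas"), ...) {
  which <- match.arg(which)
  if (which == "roc") {
    plot(x$results$repetition1$svm_roc, col = "steelblue",
         main = "State-change classification", ...)
    plot(x$results$repetition2$svm_roc, add = TRUE, col = "firebrick")
    graphics::legend("bottomright", bty = "n",
                     col = c("steelblue", "firebrick"), lty = 1,
                     legend = sprintf("%s (AUC %.2f)",
                                      names(x$results),
                                      vapply(x$results,
                                             function(r) r$svm_roc$auc,
                                             numeric(1))))
  } else {
    ds <- rbind(x$datasets$repetition1,
                x$datasets$repetition2[x$datasets$repetition2$label ==
                                         "positive", ])
    pos <- ds$label == "positive"
    graphics::plot(ds$d_peak, ds$d_selfsim,
                   col = ifelse(pos, "firebrick", "grey40"),
                   pch = ifelse(pos, 19, 1),
                   xlab = "Change in KHTE peak (ms)",
                   ylab = "Change in KHTE self similarity", ...)
    graphics::abline(h = 0, v = 0, lty = 3, col = "grey70")
    graphics::legend("topright", bty = "n", pch = c(19, 1),
                     col = c("firebrick", "grey40"),
                     legend = c("rested to impaired", "same state"))
  }
  invisible(x)
}
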