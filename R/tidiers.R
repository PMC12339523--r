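# broom-style tidiers for fitted objects.

#' Tidy a cross-validation result
#'
#' One row per class with out-of-fold precision, recall and F1 (percent),
#' plus the one-vs-rest AUC when available.
#'
#' @param x A `pf_cv` object from [train_eval_cv()] or [fsrf_cv()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pf_cv <- function(x, ...) {
  out <- x$metrics$per_class
  if (!is.null(x$auc)) {
    out <- dplyr::left_join(out, dplyr::rename(x$auc, auc_flagged = "flagged"),
                            by = "class")
  }
  out$algo <- x$algo
  out
}

#' Glance at a cross-validation result
#'
#' One-row summary: accuracy and macro metrics (percent), fold count and
#' the spread of per-fold accuracies.
#'
#' @inheritParams tidy.pf_cv
#' @return A one-row tibble.
#' @export
glance.pf_cv <- function(x, ...) {
  tibble::tibble(algo = x$algo, accuracy = x$metrics$accuracy,
                 macro_precision = x$metrics$macro_precision,
                 macro_recall = x$metrics$macro_recall,
                 macro_f1 = x$metrics$macro_f1,
                 folds = x$folds,
                 fold_acc_mean = 100 * mean(x$fold_acc),
                 fold_acc_sd = 100 * stats::sd(x$fold_acc),
                 n = x$metrics$n)
}

#' Tidy a group-comparison table
#'
#' Returns the test table unchanged apart from class (it is already tidy:
#' one row per feature).
#'
#' @param x A `pf_group_tests` object from [compare_groups()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pf_group_tests <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Tidy metrics
#'
#' @param x A `pf_metrics` object from [confusion_metrics()].
#' @param ... Unused.
#' @return The per-class tibble.
#' @export
tidy.pf_metrics <- function(x, ...) x$per_class

#' @rdname tidy.pf_metrics
#' @export
glance.pf_metrics <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, macro_precision = x$macro_precision,
                 macro_recall = x$macro_recall, macro_f1 = x$macro_f1,
                 n = x$n)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
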