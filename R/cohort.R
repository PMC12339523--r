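# Cohort-level feature extraction: the modeling substrate.

#' Build the cohort feature table
#'
#' Runs both channel pipelines on every record of a cohort and joins the
#' demographics, pulse features and ECG features into one table with one
#' row per subject - the substrate for group statistics and modeling.
#'
#' @param cohort A cohort tibble from [synth_cohort()] (or any tibble with
#'   `id`, `group`, demographics columns and a `record` list-column).
#' @param channels Which feature sets to extract: `"both"`, `"ppw"` or
#'   `"ecg"`.
#' @param quiet Drop subjects whose records cannot be analyzed (with a
#'   message) instead of failing.
#' @param ... Passed to the extractors.
#' @return A tibble: `id`, `group`, `sex`, `age`, `bmi`, `sbp`, `dbp`,
#'   then the pulse and/or ECG feature columns.
#' @export
extract_features <- function(cohort, channels = c("both", "ppw", "ecg"),
                             quiet = TRUE, ...) {
  channels <- match.arg(channels)
  stopifnot(is.data.frame(cohort), "record" %in% names(cohort))
  rows <- list()
  for (i in seq_len(nrow(cohort))) {
    rec <- cohort$record[[i]]
    row <- cohort[i, setdiff(names(cohort), "record")]
    ok <- TRUE
    if (channels %in% c("both", "ppw")) {
      fp <- try(extract_ppw_features(rec, ...), silent = TRUE)
      if (inherits(fp, "try-error")) ok <- FALSE
      else row <- dplyr::bind_cols(row, dplyr::select(fp, -"n_cycles"))
    }
    if (ok && channels %in% c("both", "ecg")) {
      fe <- try(extract_ecg_features(rec, ...), silent = TRUE)
      if (inherits(fe, "try-error")) ok <- FALSE
      else row <- dplyr::bind_cols(row, dplyr::select(fe, -"n_beats"))
    }
    if (ok) {
      rows[[length(rows) + 1L]] <- row
    } else if (quiet) {
      message("dropping unusable record: ", rec$id)
    } else {
      pf_abort(paste0("record ", rec$id, " unusable"), "pf_unusable_record")
    }
  }
  dplyr::bind_rows(rows)
}

#' Write / read a feature table as CSV
#'
#' @param features Feature table from [extract_features()].
#' @param path Output CSV path.
#' @return `write_feature_csv()` returns `path` invisibly.
#' @export
write_feature_csv <- function(features, path) {
  readr::write_csv(features, path)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  if ("group" %in% names(out)) out$group <- factor(out$group)
  out
}
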