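# SMOTE: synthetic minority over-sampling.

#' Balance classes by SMOTE over-sampling
#'
#' Augments every minority class up to the majority class size (or an
#' explicit target) with synthetic samples. Each synthetic sample is
#' `x + u * (x_nn - x)` where `x` is a minority sample drawn uniformly with
#' replacement, `x_nn` one of its `k` nearest same-class neighbors
#' (Euclidean distance on z-scored features), and `u ~ Uniform(0, 1)`.
#' Original rows are returned unchanged and first; the majority class is
#' never altered.
#'
#' @param data Data frame of numeric features, or a feature table with a
#'   grouping column named by `labels`.
#' @param labels Class vector, or the name of the class column in `data`.
#' @param k Number of nearest neighbors (default 5).
#' @param target `"majority"` or an explicit per-class target count.
#' @param seed Integer seed for reproducible synthesis.
#' @return A list with `data` (tibble of features, original rows first),
#'   `labels` (factor), and `synthetic` (logical marker per row).
#' @export
smote_balance <- function(data, labels = "group", k = 5L,
                          target = "majority", seed = 1L) {
  if (is.character(labels) && length(labels) == 1L) {
    stopifnot(labels %in% names(data))
    y <- factor(data[[labels]])
    X <- data[, setdiff(names(data), c(labels, "id")), drop = FALSE]
  } else {
    y <- factor(labels)
    X <- data
  }
  num <- vapply(X, is.numeric, logical(1))
  X <- as.matrix(X[, num, drop = FALSE])
  if (anyNA(X)) pf_abort("feature matrix contains missing values", "pf_invalid_argument")
  counts <- table(y)
  if (length(counts) < 2L) pf_abort("need at least 2 classes", "pf_invalid_argument")
  tgt <- if (identical(target, "majority")) max(counts) else as.integer(target)

  # z-score standardization for the neighbor metric
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv < 1e-12] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")

  set.seed(as.integer(seed) %% .Machine$integer.max)
  synth_rows <- list()
  synth_lab <- character()
  for (cl in names(counts)) {
    deficit <- tgt - counts[[cl]]
    if (deficit <= 0) next
    idx <- which(y == cl)
    if (length(idx) <= k) {
      pf_abort(sprintf("class '%s' has %d members; needs more than k = %d for SMOTE",
                       cl, length(idx), k), "pf_class_too_small")
    }
    Zc <- Z[idx, , drop = FALSE]
    D <- as.matrix(stats::dist(Zc))
    diag(D) <- Inf
    nn <- t(apply(D, 1, function(r) order(r)[seq_len(k)]))
    seeds <- sample.int(length(idx), deficit, replace = TRUE)
    pick <- nn[cbind(seeds, sample.int(k, deficit, replace = TRUE))]
    u <- stats::runif(deficit)
    new_z <- Zc[seeds, , drop = FALSE] +
      u * (Zc[pick, , drop = FALSE] - Zc[seeds, , drop = FALSE])
    new_x <- sweep(sweep(new_z, 2, sdv, "*"), 2, mu, "+")
    synth_rows[[cl]] <- new_x
    synth_lab <- c(synth_lab, rep(cl, deficit))
  }
  Xb <- rbind(X, do.call(rbind, c(synth_rows, list(NULL))))
  yb <- factor(c(as.character(y), synth_lab), levels = levels(y))
  out <- tibble::as_tibble(as.data.frame(Xb))
  list(data = out, labels = yb,
       synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, length(synth_lab))))
}
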