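# Model benchmarking: grid-searched RF / BDT / SVM under stratified CV,
# importance-ranked sequential forward selection, and evaluation metrics.

#' F1 score from precision and recall
#'
#' Harmonic mean of precision and recall (vectorized); 0 where both are 0.
#' Inputs and output are on the same scale (fractions or percentages).
#'
#' @param precision,recall Numeric vectors.
#' @return F1 scores.
#' @export
f1_score <- function(precision, recall) {
  out <- ifelse(precision + recall > 0,
                2 * precision * recall / (precision + recall), 0)
  unname(out)
}

#' Metrics from a multi-class confusion matrix
#'
#' Rows are predicted classes, columns actual classes. Computes accuracy
#' (trace over total), one-vs-rest precision / recall / F1 per class, and
#' their macro (arithmetic-mean) averages, all in percent. A class with no
#' actual members gets recall 0 and is flagged; a class never predicted
#' gets precision 0 and is flagged.
#'
#' @param cm Square numeric matrix (predicted x actual).
#' @return A list of class `pf_metrics`: `accuracy`, `per_class` (tibble),
#'   `macro_precision`, `macro_recall`, `macro_f1`, `n`.
#' @export
confusion_metrics <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) pf_abort("confusion matrix must be square", "pf_invalid_argument")
  total <- sum(cm)
  if (total <= 0) pf_abort("empty confusion matrix", "pf_invalid_argument")
  classes <- colnames(cm) %||% as.character(seq_len(ncol(cm)))
  tp <- diag(cm)
  pred_tot <- rowSums(cm)
  act_tot <- colSums(cm)
  precision <- ifelse(pred_tot > 0, tp / pred_tot, 0) * 100
  recall <- ifelse(act_tot > 0, tp / act_tot, 0) * 100
  per_class <- tibble::tibble(
    class = classes,
    precision = unname(precision),
    recall = unname(recall),
    f1 = f1_score(unname(precision), unname(recall)),
    flagged = unname(pred_tot == 0 | act_tot == 0))
  structure(
    list(accuracy = 100 * sum(tp) / total,
         per_class = per_class,
         macro_precision = mean(per_class$precision),
         macro_recall = mean(per_class$recall),
         macro_f1 = mean(per_class$f1),
         n = total),
    class = "pf_metrics")
}

#' @export
print.pf_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.2f%% | macro precision %.2f%% recall %.2f%% F1 %.2f%% (n = %d)\n",
              x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1, x$n))
  print(x$per_class)
  invisible(x)
}

#' One-vs-rest ROC AUC by rank statistic
#'
#' Mann-Whitney formulation with midranks for ties: for each class, the
#' probability that a random member of the class receives a higher score
#' than a random non-member.
#'
#' @param scores Matrix or data frame of per-class scores (subjects x
#'   classes, columns named by class).
#' @param y Actual class vector.
#' @return Tibble `class`, `auc`, `flagged` (TRUE when the class is absent
#'   and the AUC undefined).
#' @export
roc_auc_ovr <- function(scores, y) {
  scores <- as.matrix(scores)
  y <- factor(y)
  classes <- colnames(scores) %||% levels(y)
  rows <- lapply(classes, function(cl) {
    s <- scores[, cl]
    pos <- y == cl
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0L || n0 == 0L) {
      return(tibble::tibble(class = cl, auc = NA_real_, flagged = TRUE))
    }
    r <- rank(s)                      # midranks for ties
    auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    tibble::tibble(class = cl, auc = auc, flagged = FALSE)
  })
  dplyr::bind_rows(rows)
}

#' Paired t-test on cross-validation accuracies
#'
#' Two-sided paired t-test on fold-wise differences. Conventions for the
#' degenerate cases: all differences zero gives `t = 0, p = 1`; a constant
#' non-zero difference (zero variance) gives `t = +/-Inf, p = 0`, flagged.
#'
#' @param acc_a,acc_b Equal-length (>= 2) accuracy vectors, paired by fold.
#' @return Tibble `t`, `p_value`, `mean_diff`, `df`, `flagged`.
#' @export
paired_cv_ttest <- function(acc_a, acc_b) {
  if (length(acc_a) != length(acc_b) || length(acc_a) < 2L) {
    pf_abort("need two equal-length vectors of >= 2 fold accuracies",
             "pf_invalid_argument")
  }
  d <- acc_a - acc_b
  if (all(abs(d) < 1e-15)) {
    return(tibble::tibble(t = 0, p_value = 1, mean_diff = 0,
                          df = length(d) - 1L, flagged = FALSE))
  }
  if (stats::sd(d) < 1e-15) {
    return(tibble::tibble(t = sign(mean(d)) * Inf, p_value = 0,
                          mean_diff = mean(d), df = length(d) - 1L,
                          flagged = TRUE))
  }
  tt <- stats::t.test(acc_a, acc_b, paired = TRUE)
  tibble::tibble(t = unname(tt$statistic), p_value = tt$p.value,
                 mean_diff = unname(tt$estimate), df = unname(tt$parameter),
                 flagged = FALSE)
}

# deterministic stratified fold assignment; fold class counts differ by at
# most one subject per class
stratified_folds <- function(y, k, seed) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  fold <- integer(length(y))
  for (cl in levels(factor(y))) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Hyperparameter grids
#'
#' Defaults follow the benchmark design: tree ensembles search the number
#' of trees in 50--200 and the minimum leaf size in 1--3; the RBF SVM
#' searches penalty C and kernel coefficient gamma on a log10 grid spanning
#' 1e-8 to 1e8.
#'
#' @param algo `"rf"`, `"bdt"` or `"svm"`.
#' @return A data frame of parameter combinations.
#' @export
default_grid <- function(algo = c("rf", "bdt", "svm")) {
  algo <- match.arg(algo)
  if (algo %in% c("rf", "bdt")) {
    expand.grid(ntree = c(50L, 100L, 150L, 200L), min_leaf = 1:3)
  } else {
    expand.grid(cost = 10^seq(-8, 8, by = 2), gamma = 10^seq(-8, 8, by = 2))
  }
}

# fit one model; X data frame of numeric features, y factor
fit_model <- function(algo, X, y, params, probability = FALSE) {
  if (algo %in% c("rf", "bdt")) {
    mtry <- if (algo == "bdt") ncol(X) else max(1L, floor(sqrt(ncol(X))))
    randomForest::randomForest(x = X, y = y, ntree = params$ntree,
                               nodesize = params$min_leaf, mtry = mtry)
  } else {
    e1071::svm(x = as.matrix(X), y = y, kernel = "radial",
               cost = params$cost, gamma = params$gamma, scale = TRUE,
               probability = probability)
  }
}

predict_model <- function(model, algo, X, scores = FALSE) {
  if (algo %in% c("rf", "bdt")) {
    cls <- stats::predict(model, X)
    if (!scores) return(list(class = cls))
    list(class = cls, scores = stats::predict(model, X, type = "prob"))
  } else {
    pred <- stats::predict(model, as.matrix(X), probability = scores)
    if (!scores) return(list(class = pred))
    list(class = pred, scores = attr(pred, "probabilities")[, , drop = FALSE])
  }
}

# inner grid search: best row of `grid` by stratified inner-CV accuracy
grid_search <- function(algo, X, y, grid, inner_folds, seed, smote, k) {
  if (nrow(grid) == 1L) return(grid[1L, , drop = FALSE])
  fold <- stratified_folds(y, inner_folds, seed)
  acc <- numeric(nrow(grid))
  for (f in seq_len(inner_folds)) {
    tr <- fold != f
    Xtr <- X[tr, , drop = FALSE]; ytr <- droplevels(y[tr])
    if (smote && min(table(ytr)) > k) {
      bal <- smote_balance(Xtr, ytr, k = k, seed = seed + f)
      Xtr <- bal$data; ytr <- bal$labels
    }
    for (g in seq_len(nrow(grid))) {
      set.seed(seed + 1000L * g + f)
      m <- fit_model(algo, Xtr, ytr, grid[g, , drop = FALSE])
      pr <- predict_model(m, algo, X[!tr, , drop = FALSE])$class
      acc[g] <- acc[g] + mean(pr == y[!tr])
    }
  }
  grid[which.max(acc), , drop = FALSE]
}

#' Grid-searched cross-validated benchmarking
#'
#' Stratified k-fold outer cross-validation with an inner grid search on
#' each training fold. By default SMOTE balancing is applied inside each
#' training fold only (validation folds never contribute to synthesis);
#' `smote_before_split = TRUE` reproduces the alternative protocol of
#' balancing once before splitting. Out-of-fold predictions are pooled into
#' a single confusion matrix (predicted x actual).
#'
#' @param data Feature table (numeric feature columns; an `id` column and
#'   the label column are dropped from the predictors).
#' @param labels Class vector or name of the class column in `data`.
#' @param algo `"rf"` (random forest), `"bdt"` (bagged trees) or `"svm"`
#'   (RBF support vector machine).
#' @param grid Hyperparameter grid; `NULL` for [default_grid()]. A
#'   single-row grid skips the inner search.
#' @param folds Number of outer folds.
#' @param inner_folds Folds of the inner grid-search CV.
#' @param seed Integer seed controlling folds, SMOTE and model fits.
#' @param smote Apply SMOTE inside training folds.
#' @param smote_before_split Balance the full dataset before splitting
#'   (leaks synthesis information into validation folds).
#' @param k SMOTE neighbor count.
#' @return A `pf_cv` object: `algo`, `fold_acc`, `cm` (pooled confusion
#'   matrix), `metrics` ([confusion_metrics()]), `auc`
#'   ([roc_auc_ovr()] on pooled out-of-fold scores), `best_params`
#'   (per fold), `oof` (tibble of out-of-fold predictions and scores).
#' @export
train_eval_cv <- function(data, labels = "group", algo = c("rf", "bdt", "svm"),
                          grid = NULL, folds = 5L, inner_folds = 3L, seed = 1L,
                          smote = TRUE, smote_before_split = FALSE, k = 5L) {
  algo <- match.arg(algo)
  if (is.character(labels) && length(labels) == 1L) {
    stopifnot(labels %in% names(data))
    y <- factor(data[[labels]])
    X <- data[, setdiff(names(data), c(labels, "id")), drop = FALSE]
  } else {
    y <- factor(labels)
    X <- data
  }
  X <- impute_median(as.data.frame(X[, vapply(X, is.numeric, logical(1)), drop = FALSE]))
  if (nlevels(y) < 2L) pf_abort("labels are constant: nothing to classify",
                                "pf_degenerate_labels")
  if (nrow(X) < 25L) pf_abort("need at least 25 subjects", "pf_invalid_argument")
  if (min(table(y)) < folds) {
    pf_abort("a class has fewer members than folds: cannot stratify",
             "pf_stratification_error")
  }
  grid <- grid %||% default_grid(algo)

  if (smote && smote_before_split) {
    bal <- smote_balance(X, y, k = k, seed = seed)
    X <- as.data.frame(bal$data); y <- bal$labels
    smote <- FALSE
  }

  fold <- stratified_folds(y, folds, seed)
  lev <- levels(y)
  oof_class <- factor(rep(NA_character_, length(y)), levels = lev)
  oof_scores <- matrix(NA_real_, length(y), length(lev),
                       dimnames = list(NULL, lev))
  fold_acc <- numeric(folds)
  best <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    Xtr <- X[tr, , drop = FALSE]; ytr <- droplevels(y[tr])
    bp <- grid_search(algo, Xtr, ytr, grid, inner_folds, seed + 17L * f,
                      smote, k)
    best[[f]] <- bp
    if (smote && min(table(ytr)) > k) {
      bal <- smote_balance(Xtr, ytr, k = k, seed = seed + 31L * f)
      Xtr <- bal$data; ytr <- bal$labels
    }
    set.seed(seed + 7L * f)
    m <- fit_model(algo, Xtr, ytr, bp, probability = TRUE)
    pr <- predict_model(m, algo, X[!tr, , drop = FALSE], scores = TRUE)
    oof_class[!tr] <- factor(as.character(pr$class), levels = lev)
    sc <- pr$scores[, lev, drop = FALSE]
    oof_scores[!tr, ] <- as.matrix(sc)
    fold_acc[f] <- mean(pr$class == y[!tr])
  }
  cm <- table(predicted = oof_class, actual = y)
  structure(
    list(algo = algo, folds = folds, fold_acc = fold_acc,
         cm = unclass(cm), metrics = confusion_metrics(unclass(cm)),
         auc = roc_auc_ovr(oof_scores, y),
         best_params = dplyr::bind_rows(best),
         oof = tibble::tibble(actual = y, predicted = oof_class,
                              fold = fold) |>
           dplyr::bind_cols(tibble::as_tibble(oof_scores)),
         seed = seed),
    class = "pf_cv")
}

#' @export
print.pf_cv <- function(x, ...) {
  cat(sprintf("<pf_cv %s> %d-fold CV, out-of-fold ", x$algo, x$folds))
  print(x$metrics)
  invisible(x)
}

#' Random-forest feature importance ranking
#'
#' Fits a random forest (500 trees by default, fixed seed) and returns
#' features ranked by mean decrease in Gini impurity, normalized to sum
#' to 1.
#'
#' @param data Feature table; @param labels class vector or column name.
#' @param seed Integer seed.
#' @param ntree Number of trees.
#' @return Tibble `feature`, `importance` (sums to 1), `rank`.
#' @export
rf_importance <- function(data, labels = "group", seed = 1L, ntree = 500L) {
  if (is.character(labels) && length(labels) == 1L) {
    stopifnot(labels %in% names(data))
    y <- factor(data[[labels]])
    X <- data[, setdiff(names(data), c(labels, "id")), drop = FALSE]
  } else {
    y <- factor(labels)
    X <- data
  }
  X <- impute_median(as.data.frame(X[, vapply(X, is.numeric, logical(1)), drop = FALSE]))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  m <- randomForest::randomForest(x = X, y = y, ntree = ntree, importance = FALSE)
  imp <- randomForest::importance(m)[, "MeanDecreaseGini"]
  imp <- pmax(imp, 0)
  imp <- if (sum(imp) > 0) imp / sum(imp) else rep(1 / length(imp), length(imp))
  out <- tibble::tibble(feature = names(imp), importance = unname(imp))
  out <- dplyr::arrange(out, dplyr::desc(.data$importance))
  out$rank <- seq_len(nrow(out))
  out
}

#' Sequential forward selection along an importance ranking
#'
#' Adds features strictly in ranking order, scoring each prefix by
#' stratified cross-validated random-forest accuracy (identical folds for
#' every prefix). The selected set is the shortest prefix achieving the
#' maximum of the accuracy curve.
#'
#' @param data Feature table; @param labels class vector or column name.
#' @param ranking Character vector of feature names in importance order
#'   (e.g., `rf_importance(...)$feature`); must cover all feature columns.
#' @param folds CV folds; @param seed seed; @param ntree trees per fit.
#' @return A list with `selected` (character vector) and `curve` (tibble
#'   `n_features`, `accuracy`).
#' @export
sfs_select <- function(data, labels = "group", ranking, folds = 5L,
                       seed = 1L, ntree = 150L) {
  if (is.character(labels) && length(labels) == 1L) {
    stopifnot(labels %in% names(data))
    y <- factor(data[[labels]])
    X <- data[, setdiff(names(data), c(labels, "id")), drop = FALSE]
  } else {
    y <- factor(labels)
    X <- data
  }
  X <- impute_median(as.data.frame(X[, vapply(X, is.numeric, logical(1)), drop = FALSE]))
  if (!setequal(ranking, names(X))) {
    pf_abort("ranking must cover exactly the feature columns", "pf_invalid_argument")
  }
  fold <- stratified_folds(y, folds, seed)
  acc <- numeric(length(ranking))
  for (p in seq_along(ranking)) {
    Xp <- X[, ranking[seq_len(p)], drop = FALSE]
    hits <- 0L
    for (f in seq_len(folds)) {
      tr <- fold != f
      set.seed(seed + 97L * p + f)
      m <- randomForest::randomForest(x = Xp[tr, , drop = FALSE],
                                      y = droplevels(y[tr]), ntree = ntree)
      pr <- stats::predict(m, Xp[!tr, , drop = FALSE])
      hits <- hits + sum(pr == y[!tr])
    }
    acc[p] <- hits / length(y)
  }
  sel_n <- which.max(acc)   # ties resolve to the fewest features
  list(selected = ranking[seq_len(sel_n)],
       curve = tibble::tibble(n_features = seq_along(ranking), accuracy = acc))
}

#' Feature-selected random forest under nested cross-validation
#'
#' The FS-RF model: features are ranked by random-forest importance and a
#' sequential forward selection picks the best prefix; a random forest is
#' then trained on the selected features. With `nested = TRUE` (default)
#' ranking and selection are redone inside every training fold, so the
#' held-out fold never informs selection; with `nested = FALSE` selection
#' uses the full data once (the protocol that reports the peak of the
#' selection curve).
#'
#' @param data Feature table; @param labels class vector or column name.
#' @param folds Outer CV folds; @param seed seed.
#' @param ntree_rank Trees for the importance ranking fit.
#' @param ntree Trees for the selection curve and final fits.
#' @param nested Redo selection inside each training fold.
#' @param smote Apply SMOTE inside training folds.
#' @param k SMOTE neighbors.
#' @return A `pf_cv`-like list with `fold_acc`, `cm`, `metrics`,
#'   `selected` (features chosen; per fold if nested), `curve` (full-data
#'   selection curve when `nested = FALSE`).
#' @export
fsrf_cv <- function(data, labels = "group", folds = 5L, seed = 1L,
                    ntree_rank = 300L, ntree = 150L, nested = TRUE,
                    smote = FALSE, k = 5L) {
  if (is.character(labels) && length(labels) == 1L) {
    stopifnot(labels %in% names(data))
    y <- factor(data[[labels]])
    X <- data[, setdiff(names(data), c(labels, "id")), drop = FALSE]
  } else {
    y <- factor(labels)
    X <- data
  }
  X <- impute_median(as.data.frame(X[, vapply(X, is.numeric, logical(1)), drop = FALSE]))
  lev <- levels(y)
  fold <- stratified_folds(y, folds, seed)
  oof <- factor(rep(NA_character_, length(y)), levels = lev)
  fold_acc <- numeric(folds)
  selected <- vector("list", folds)
  curve <- NULL
  if (!nested) {
    rk <- rf_importance(X, y, seed = seed, ntree = ntree_rank)
    sel <- sfs_select(X, y, rk$feature, folds = folds, seed = seed, ntree = ntree)
    curve <- sel$curve
    sel_features <- sel$selected
  }
  for (f in seq_len(folds)) {
    tr <- fold != f
    Xtr <- X[tr, , drop = FALSE]; ytr <- droplevels(y[tr])
    if (nested) {
      rk <- rf_importance(Xtr, ytr, seed = seed + f, ntree = ntree_rank)
      sel <- sfs_select(Xtr, ytr, rk$feature, folds = 3L, seed = seed + f,
                        ntree = ntree)
      sel_features <- sel$selected
    }
    selected[[f]] <- sel_features
    Xtr <- Xtr[, sel_features, drop = FALSE]
    if (smote && min(table(ytr)) > k) {
      bal <- smote_balance(Xtr, ytr, k = k, seed = seed + 31L * f)
      Xtr <- bal$data; ytr <- bal$labels
    }
    set.seed(seed + 7L * f)
    m <- randomForest::randomForest(x = as.data.frame(Xtr), y = ytr,
                                    ntree = ntree)
    pr <- stats::predict(m, X[!tr, sel_features, drop = FALSE])
    oof[!tr] <- factor(as.character(pr), levels = lev)
    fold_acc[f] <- mean(pr == y[!tr])
  }
  cm <- unclass(table(predicted = oof, actual = y))
  structure(
    list(algo = "fsrf", folds = folds, fold_acc = fold_acc, cm = cm,
         metrics = confusion_metrics(cm), selected = selected,
         curve = curve, seed = seed,
         oof = tibble::tibble(actual = y, predicted = oof, fold = fold)),
    class = "pf_cv")
}
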