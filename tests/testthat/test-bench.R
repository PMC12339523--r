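small_grid <- data.frame(ntree = 100L, min_leaf = 1L)

test_that("confusion metrics agree with a brute-force one-vs-rest count", {
  set.seed(4)
  cm <- matrix(sample(0:20, 16, replace = TRUE), 4, 4,
               dimnames = list(1:4, 1:4))
  m <- confusion_metrics(cm)
  # exhaustive TP/FP/FN enumeration oracle
  for (i in 1:4) {
    tp <- cm[i, i]
    fp <- sum(cm[i, ]) - tp
    fn <- sum(cm[, i]) - tp
    expect_equal(m$per_class$precision[i], 100 * tp / (tp + fp))
    expect_equal(m$per_class$recall[i], 100 * tp / (tp + fn))
  }
  expect_equal(m$accuracy, 100 * sum(diag(cm)) / sum(cm))
  expect_equal(m$macro_precision, mean(m$per_class$precision))

  # degenerate corners
  perfect <- diag(c(5, 7, 9, 3))
  mp <- confusion_metrics(perfect)
  expect_equal(mp$accuracy, 100)
  expect_equal(mp$per_class$f1, rep(100, 4))
  uniform <- matrix(3, 4, 4)
  mu <- confusion_metrics(uniform)
  expect_equal(mu$accuracy, 25)
  expect_equal(mu$per_class$precision, rep(25, 4))
  expect_equal(mu$macro_f1, 25)
})

test_that("F1 is the harmonic mean and stays between precision and recall", {
  expect_equal(f1_score(100, 100), 100)
  expect_equal(f1_score(0, 0), 0)
  set.seed(2)
  p <- runif(50, 1, 99); r <- runif(50, 1, 99)
  f <- f1_score(p, r)
  expect_true(all(f >= pmin(p, r) - 1e-9 & f <= pmax(p, r) + 1e-9))
})

test_that("one-vs-rest AUC matches exhaustive pair counting", {
  # 3 of the 4 (positive, negative) pairs correctly ordered
  sc <- cbind(A = c(0.9, 0.8, 0.7, 0.85))
  y <- factor(c("A", "A", "B", "B"), levels = c("A", "B"))
  expect_equal(roc_auc_ovr(sc, y)$auc[1], 0.75)

  # perfectly separated scores
  sc2 <- cbind(A = c(5, 4, 1, 0))
  expect_equal(roc_auc_ovr(sc2, y)$auc[1], 1.0)

  # ties get midrank treatment: all-equal scores give exactly 0.5
  sc3 <- cbind(A = rep(1, 4))
  expect_equal(roc_auc_ovr(sc3, y)$auc[1], 0.5)

  # absent class is flagged
  y2 <- factor(c("A", "A", "A", "A"), levels = c("A", "B"))
  out <- roc_auc_ovr(cbind(A = 1:4, B = 4:1), y2)
  expect_true(out$flagged[out$class == "B"])

  # label-independent scores give AUC near 1/2
  set.seed(6)
  n <- 2000
  yb <- factor(sample(c("A", "B"), n, replace = TRUE))
  scb <- cbind(A = rnorm(n))
  auc <- roc_auc_ovr(scb, yb)$auc[1]
  se <- sqrt((n + 1) / (12 * sum(yb == "A") * sum(yb == "B")))
  expect_lt(abs(auc - 0.5), 3 * se)
})

test_that("paired CV t-test honors the degenerate-case conventions", {
  a <- c(0.80, 0.81, 0.79, 0.82, 0.80)
  same <- paired_cv_ttest(a, a)
  expect_equal(same$t, 0); expect_equal(same$p_value, 1)
  shifted <- paired_cv_ttest(a, a - 0.10)
  expect_equal(shifted$p_value, 0); expect_true(shifted$flagged)
  set.seed(1)
  b <- a - 0.1 + rnorm(5, 0, 0.005)
  t1 <- paired_cv_ttest(a, b); t2 <- paired_cv_ttest(b, a)
  expect_equal(t1$t, -t2$t)
  expect_equal(t1$p_value, t2$p_value)
  expect_lt(t1$p_value, 0.001)
})

test_that("well-separated classes are classified almost perfectly", {
  d <- make_blobs(n_per = 50, delta = 6, seed = 3)
  cv <- train_eval_cv(d, "group", algo = "rf", grid = small_grid, seed = 3,
                      smote = FALSE)
  expect_gte(cv$metrics$accuracy, 95)
  expect_equal(sum(cv$cm), 200)
  # stratification: fold class counts within one subject of equality
  tab <- table(cv$oof$fold, cv$oof$actual)
  expect_lte(max(tab) - min(tab), 1)
})

test_that("degenerate labels and tiny classes raise the documented errors", {
  d <- make_blobs(n_per = 20, seed = 1)
  d$group <- factor(rep(1, nrow(d)))
  expect_error(train_eval_cv(d, "group", algo = "rf", grid = small_grid),
               class = "pf_degenerate_labels")
  d2 <- make_blobs(n_per = 20, seed = 1)
  d2 <- d2[c(which(d2$group != 4), which(d2$group == 4)[1:3]), ]
  expect_error(train_eval_cv(d2, "group", algo = "rf", grid = small_grid),
               class = "pf_stratification_error")
})

test_that("SVM and BDT train and evaluate on separable data", {
  d <- make_blobs(n_per = 25, delta = 6, seed = 5)
  svm <- train_eval_cv(d, "group", algo = "svm",
                       grid = expand.grid(cost = c(1, 100), gamma = c(0.01, 1)),
                       seed = 5, smote = FALSE)
  expect_gte(svm$metrics$accuracy, 90)
  expect_true(all(!is.na(svm$auc$auc)))
  bdt <- train_eval_cv(d, "group", algo = "bdt", grid = small_grid,
                       seed = 5, smote = FALSE)
  expect_gte(bdt$metrics$accuracy, 90)
})

test_that("importance ranking finds planted signal and ignores constants", {
  first_hits <- 0L
  for (s in 1:10) {
    set.seed(s)
    n <- 160
    d <- data.frame(signal = rnorm(n) + rep(0:3, each = n / 4) * 1.5,
                    n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n),
                    n4 = rnorm(n), n5 = rnorm(n), n6 = rnorm(n),
                    n7 = rnorm(n), n8 = rnorm(n), n9 = rnorm(n),
                    n10 = rnorm(n),
                    const = 1,
                    group = factor(rep(1:4, each = n / 4)))
    rk <- rf_importance(d, "group", seed = s, ntree = 300)
    if (rk$feature[1] == "signal") first_hits <- first_hits + 1L
    expect_lt(rk$importance[rk$feature == "const"], 0.01)
    expect_equal(sum(rk$importance), 1, tolerance = 1e-9)
  }
  expect_gte(first_hits, 9L)
})

test_that("a duplicated informative feature splits its importance", {
  set.seed(12)
  n <- 200
  d <- data.frame(a = rnorm(n) + rep(0:3, each = n / 4) * 2,
                  n1 = rnorm(n), n2 = rnorm(n),
                  group = factor(rep(1:4, each = n / 4)))
  base <- rf_importance(d, "group", seed = 1, ntree = 500)
  d2 <- d; d2$a_copy <- d$a
  dup <- rf_importance(d2, "group", seed = 1, ntree = 500)
  combined <- sum(dup$importance[dup$feature %in% c("a", "a_copy")])
  original <- base$importance[base$feature == "a"]
  each <- dup$importance[dup$feature %in% c("a", "a_copy")]
  # the signal splits across the two copies: each copy carries less than
  # the original, and the pair jointly carries a comparable share (Gini
  # importance runs somewhat above parity because duplicating the signal
  # raises its candidate-offering rate; simulated band +-45%)
  expect_true(all(each < original))
  expect_gt(combined, 0.55 * original)
  expect_lt(combined, 1.45 * original)
})

test_that("sequential forward selection keeps planted features and obeys the argmax rule", {
  d <- make_planted(21, n_per = 25, p_inf = 4, p_noise = 36, delta = 1.2)
  rk <- rf_importance(d, "group", seed = 2, ntree = 300)
  sel <- sfs_select(d, "group", rk$feature, folds = 5, seed = 2, ntree = 150)
  informative <- paste0("f", 1:4)
  # the planted features lead the ranking and survive selection
  expect_gte(sum(rk$feature[1:6] %in% informative), 3)
  expect_true(all(informative %in% sel$selected))
  # the curve peaks in the noise-dominated first half, far from full length
  expect_lte(which.max(sel$curve$accuracy), 20)
  # the selected prefix attains the curve maximum with the fewest features
  expect_equal(length(sel$selected), which.max(sel$curve$accuracy))
  expect_gte(max(sel$curve$accuracy),
             sel$curve$accuracy[nrow(sel$curve)])

  # a single feature is selected trivially
  one <- sfs_select(d[, c("f1", "group")], "group", "f1", folds = 3,
                    seed = 2, ntree = 50)
  expect_equal(one$selected, "f1")
  expect_equal(nrow(one$curve), 1L)
})

test_that("SMOTE inside folds keeps validation subjects out of synthesis", {
  # with fold-internal SMOTE the out-of-fold predictions cover exactly the
  # original subjects, in the original order
  d <- make_blobs(n_per = 15, delta = 4, seed = 9)
  d <- d[d$group != 4 | seq_len(nrow(d)) %% 2 == 0, ]  # imbalance
  cv <- train_eval_cv(d, "group", algo = "rf", grid = small_grid, seed = 9,
                      smote = TRUE, k = 3)
  expect_equal(nrow(cv$oof), nrow(d))
  expect_equal(as.character(cv$oof$actual), as.character(d$group))
})
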