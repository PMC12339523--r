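# Group-comparison statistics and chi-square power analysis.

#' Compare features across study groups
#'
#' For every feature column: a per-group Shapiro-Wilk normality screen
#' (alpha = 0.05) routes continuous features either to one-way ANOVA (all
#' groups normal; summarized as mean +/- SD) or to the Kruskal-Wallis
#' omnibus rank test (summarized as median (Q1-Q3)); categorical features
#' are tested with the chi-square test on the contingency table. Pairwise
#' comparisons against reference groups use Welch t / Mann-Whitney U tests
#' with raw p-values (no multiplicity correction by default, an optional
#' Holm adjustment is available for the omnibus p-values).
#'
#' @param table Feature table (one row per subject) containing `labels`'
#'   grouping column plus feature columns.
#' @param labels Group vector (coercible to factor), or the name of the
#'   grouping column in `table`.
#' @param features Feature columns to test; default all columns except the
#'   grouping column and an `id` column.
#' @param pairwise_ref Indices (levels) of the reference groups against
#'   which pairwise flags are computed.
#' @param alpha Significance level for the pairwise flags.
#' @param adjust Apply Holm correction across features to the omnibus
#'   p-values (off by default).
#' @return A `pf_group_tests` tibble: `feature`, `test` ("anova",
#'   "kruskal", "chisq" or "skipped"), `statistic`, `p_value`,
#'   `summary_type`, per-group summary strings, and logical pairwise flags
#'   `sig_vs_<g>`.
#' @export
compare_groups <- function(table, labels = "group", features = NULL,
                           pairwise_ref = NULL, alpha = 0.05,
                           adjust = FALSE) {
  if (is.character(labels) && length(labels) == 1L) {
    stopifnot(labels %in% names(table))
    y <- factor(table[[labels]])
    drop_cols <- c(labels, "id")
  } else {
    y <- factor(labels)
    drop_cols <- "id"
  }
  lev <- levels(y)
  if (length(lev) < 2L) pf_abort("need at least 2 groups", "pf_invalid_argument")
  if (min(table(y)) < 3L) pf_abort("every group needs >= 3 members", "pf_invalid_argument")
  if (is.null(features)) features <- setdiff(names(table), drop_cols)
  if (is.null(pairwise_ref)) pairwise_ref <- lev[-length(lev)]
  pairwise_ref <- as.character(pairwise_ref)

  rows <- lapply(features, function(f) {
    x <- table[[f]]
    flag_names <- paste0("sig_vs_", pairwise_ref)
    base <- tibble::tibble(feature = f, test = "skipped",
                           statistic = NA_real_, p_value = NA_real_,
                           summary_type = NA_character_)
    for (fn in flag_names) base[[fn]] <- NA
    if (is.numeric(x)) {
      if (stats::var(x, na.rm = TRUE) < 1e-12 || all(is.na(x))) return(base)
      normal <- all(vapply(lev, function(g) {
        xi <- x[y == g]
        xi <- xi[is.finite(xi)]
        if (length(xi) < 3L || length(xi) > 5000L) return(FALSE)
        if (stats::var(xi) < 1e-12) return(FALSE)
        stats::shapiro.test(xi)$p.value >= 0.05
      }, logical(1)))
      if (normal) {
        fit <- stats::aov(x ~ y)
        sm <- summary(fit)[[1]]
        base$test <- "anova"
        base$statistic <- sm[["F value"]][1]
        base$p_value <- sm[["Pr(>F)"]][1]
        base$summary_type <- "mean_sd"
        for (g in lev) {
          xi <- x[y == g]
          base[[paste0("g", g)]] <- sprintf("%.2f ± %.2f",
                                            mean(xi, na.rm = TRUE),
                                            stats::sd(xi, na.rm = TRUE))
        }
      } else {
        kt <- stats::kruskal.test(x, y)
        base$test <- "kruskal"
        base$statistic <- unname(kt$statistic)
        base$p_value <- kt$p.value
        base$summary_type <- "median_iqr"
        for (g in lev) {
          xi <- x[y == g]
          q <- stats::quantile(xi, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
          base[[paste0("g", g)]] <- sprintf("%.2f (%.2f,%.2f)", q[2], q[1], q[3])
        }
      }
      for (ref in pairwise_ref) {
        others <- setdiff(lev, ref)
        # the flag reports whether ANY later group differs from this
        # reference at alpha; per-pair p-values are recomputed on demand
        ps <- vapply(others[match(others, lev) > match(ref, lev)], function(g) {
          xi <- x[y == ref]; xj <- x[y == g]
          if (normal) stats::t.test(xi, xj)$p.value
          else suppressWarnings(stats::wilcox.test(xi, xj, exact = FALSE)$p.value)
        }, numeric(1))
        base[[paste0("sig_vs_", ref)]] <- if (length(ps)) any(ps < alpha) else NA
      }
    } else {
      tab <- base::table(x, y)
      if (nrow(tab) < 2L) return(base)
      ct <- suppressWarnings(stats::chisq.test(tab))
      base$test <- "chisq"
      base$statistic <- unname(ct$statistic)
      base$p_value <- ct$p.value
      base$summary_type <- "n_pct"
      for (g in lev) {
        cnt <- tab[, g]
        base[[paste0("g", g)]] <- paste(sprintf("%s %d (%.1f%%)",
                                                rownames(tab), cnt,
                                                100 * cnt / sum(cnt)),
                                        collapse = "; ")
      }
      for (ref in pairwise_ref) base[[paste0("sig_vs_", ref)]] <- NA
    }
    base
  })
  out <- dplyr::bind_rows(rows)
  if (adjust) out$p_adj <- stats::p.adjust(out$p_value, method = "holm")
  class(out) <- c("pf_group_tests", class(out))
  out
}

#' Achieved power of the chi-square test
#'
#' Survival probability of the noncentral chi-square distribution at the
#' central critical value: `P(X > qchisq(1 - alpha, df))` with
#' noncentrality `lambda = N w^2`.
#'
#' @param n Total sample size.
#' @param w Cohen's effect size.
#' @param alpha Significance level.
#' @param df Degrees of freedom.
#' @return Power in `[0, 1]`.
#' @export
chisq_power <- function(n, w, alpha = 0.05, df) {
  stats::pchisq(stats::qchisq(1 - alpha, df), df, ncp = n * w^2,
                lower.tail = FALSE)
}

#' Minimum sample size for a chi-square test
#'
#' Inverts the noncentral chi-square power function: the smallest integer N
#' such that the test with `df` degrees of freedom, significance `alpha`
#' and effect size `w` reaches the requested power. Reproduces standard
#' a-priori power-analysis results (e.g., w = 0.30, alpha = 0.05, power
#' 0.80, df = 78 gives N = 405).
#'
#' @param w Cohen's effect size (> 0).
#' @param alpha Significance level in (0, 1).
#' @param power Target power in (alpha, 1).
#' @param df Degrees of freedom (>= 1).
#' @return Minimal total sample size (integer).
#' @export
chisq_power_n <- function(w, alpha = 0.05, power = 0.80, df) {
  assert_scalar_num(w, "w", lower = 1e-12)
  assert_scalar_num(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  assert_scalar_num(power, "power", lower = alpha, upper = 1 - 1e-12)
  assert_scalar_num(df, "df", lower = 1)
  if (w < 1e-6) pf_abort("effect size too small: power unreachable", "pf_invalid_argument")
  f <- function(n) chisq_power(n, w, alpha, df) - power
  hi <- 10
  while (f(hi) < 0 && hi < 1e9) hi <- hi * 2
  if (f(hi) < 0) pf_abort("requested power unreachable", "pf_invalid_argument")
  n_star <- stats::uniroot(f, lower = 1, upper = hi, tol = 1e-8)$root
  as.integer(ceiling(n_star - 1e-9))
}
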