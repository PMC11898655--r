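#' Group comparison with normality-gated test selection
#'
#' Assesses normality per group (Shapiro-Wilk at `alpha_normality`); if all
#' groups pass, a parametric test is used (two-sample t-test for two groups,
#' one-way ANOVA for three or more), otherwise a nonparametric one
#' (two-sample Kolmogorov-Smirnov for two groups, Kruskal-Wallis for three
#' or more).
#'
#' @param groups named list of numeric vectors (one per group, each n >= 3).
#' @param alpha significance level reported alongside (default 0.05).
#' @param alpha_normality Shapiro-Wilk level for the branching (default 0.05).
#' @param metric optional metric name carried in the result.
#' @return object of class `group_comparison`: `test_used`, `statistic`,
#'   `p_value`, `significant`, `n` per group, `normality` per group.
#' @export
compare_groups <- function(groups, alpha = 0.05, alpha_normality = 0.05,
                           metric = NA_character_) {
  groups <- lapply(groups, function(v) v[is.finite(v)])
  if (length(groups) < 2) stop_config("need at least 2 groups")
  n <- vapply(groups, length, integer(1))
  if (any(n < 3)) stop_config("each group needs n >= 3")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  normality <- vapply(groups, function(v) {
    if (length(unique(v)) < 3) return(0)  # degenerate: treat as non-normal
    if (length(v) > 5000) v <- v[seq(1, length(v), length.out = 5000)]
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  parametric <- all(normality > alpha_normality)
  if (length(groups) == 2) {
    if (parametric) {
      ht <- stats::t.test(groups[[1]], groups[[2]])
      test_used <- "t_test"
    } else {
      ht <- suppressWarnings(stats::ks.test(groups[[1]], groups[[2]]))
      test_used <- "ks_2sample"
    }
    statistic <- unname(ht$statistic); p <- ht$p.value
  } else {
    values <- unlist(groups, use.names = FALSE)
    fac <- factor(rep(names(groups), n))
    if (parametric) {
      fit <- stats::aov(values ~ fac)
      tab <- summary(fit)[[1]]
      statistic <- tab[["F value"]][1]; p <- tab[["Pr(>F)"]][1]
      test_used <- "anova"
    } else {
      ht <- stats::kruskal.test(values, fac)
      statistic <- unname(ht$statistic); p <- ht$p.value
      test_used <- "kruskal_wallis"
    }
  }
  structure(list(metric = metric, test_used = test_used, statistic = statistic,
                 p_value = p, alpha = alpha, significant = p < alpha,
                 n = n, normality_p = normality, parametric = parametric),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group_comparison%s: %s, statistic %.4g, p %.3g (%ssignificant at %.2g), n = %s\n",
              if (is.na(x$metric)) "" else paste0(" [", x$metric, "]"),
              x$test_used, x$statistic, x$p_value,
              if (x$significant) "" else "not ", x$alpha,
              paste(x$n, collapse = "/")))
  invisible(x)
}

#' Per-group summary of a per-cell metrics table
#'
#' For each numeric metric column and group: n (non-missing), mean, SD, SEM,
#' median and quartiles.
#'
#' @param metrics data frame of per-cell metrics.
#' @param group character or factor vector of group labels (one per row), or
#'   the name of a column of `metrics`.
#' @return long data frame: `group`, `metric`, `n`, `mean`, `sd`, `sem`,
#'   `median`, `q25`, `q75`.
#' @export
population_summary <- function(metrics, group) {
  if (nrow(metrics) == 0) stop_config("empty metrics table")
  if (length(group) == 1 && is.character(group) && group %in% names(metrics)) {
    glab <- metrics[[group]]
    metrics <- metrics[setdiff(names(metrics), group)]
  } else {
    if (length(group) != nrow(metrics)) stop_config("group labels do not match table rows")
    glab <- group
  }
  if (anyNA(glab)) stop_config("unknown (NA) group label")
  num_cols <- names(metrics)[vapply(metrics, is.numeric, logical(1))]
  rows <- list()
  for (g in unique(glab)) {
    sub <- metrics[glab == g, , drop = FALSE]
    for (m in num_cols) {
      v <- sub[[m]]; v <- v[is.finite(v)]
      nn <- length(v)
      rows[[length(rows) + 1]] <- data.frame(
        group = g, metric = m, n = nn,
        mean = if (nn) mean(v) else NA_real_,
        sd = if (nn > 1) stats::sd(v) else NA_real_,
        sem = if (nn > 1) stats::sd(v) / sqrt(nn) else NA_real_,
        median = if (nn) stats::median(v) else NA_real_,
        q25 = if (nn) unname(stats::quantile(v, 0.25)) else NA_real_,
        q75 = if (nn) unname(stats::quantile(v, 0.75)) else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
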