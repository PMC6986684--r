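# Lineage- and cultivar-level copy-number statistics, computed from the
# sums-of-squares formulas with tail probabilities from the base
# distribution functions.

as_groups <- function(values_by_group) {
  if (is.data.frame(values_by_group)) {
    check_columns(values_by_group, c("group", "value"), "group data")
    values_by_group <- split(values_by_group$value, values_by_group$group)
  }
  if (!is.list(values_by_group) || length(values_by_group) < 2) {
    stop_invalid("need at least 2 groups")
  }
  if (any(lengths(values_by_group) < 2)) {
    stop_invalid("every group needs at least 2 observations")
  }
  values_by_group
}

#' One-way ANOVA from sums of squares
#'
#' @param values_by_group Either a named list of numeric vectors (one per
#'   group) or a data frame with columns `group` and `value`.
#' @return A list of class `anova_cn` with `F`, `df_between`, `df_within`,
#'   `p_value`, and a `groups` tibble (n, mean, median per group).
#' @export
one_way_anova <- function(values_by_group) {
  g <- as_groups(values_by_group)
  k <- length(g)
  n_i <- lengths(g)
  n <- sum(n_i)
  means <- vapply(g, mean, numeric(1))
  grand <- sum(unlist(g)) / n
  ssb <- sum(n_i * (means - grand)^2)
  ssw <- sum(vapply(g, function(v) sum((v - mean(v))^2), numeric(1)))
  if (ssw <= 0) stop_degenerate("zero within-group variance: F is undefined")
  df_b <- k - 1L
  df_w <- n - k
  f <- (ssb / df_b) / (ssw / df_w)
  out <- list(
    F = f, df_between = df_b, df_within = as.integer(df_w),
    p_value = pf(f, df_b, df_w, lower.tail = FALSE),
    ms_within = ssw / df_w,
    groups = tibble::tibble(
      group = names(g), n = as.integer(unname(n_i)),
      mean = unname(means),
      median = unname(vapply(g, median, numeric(1)))
    )
  )
  class(out) <- "anova_cn"
  out
}

#' @export
print.anova_cn <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p_value))
  print(x$groups)
  invisible(x)
}

#' @export
tidy.anova_cn <- function(x, ...) {
  tibble::tibble(statistic = x$F, df_between = x$df_between,
                 df_within = x$df_within, p.value = x$p_value)
}

#' Tukey HSD post hoc comparisons
#'
#' All pairwise mean differences with p-values adjusted via the studentized
#' range distribution, using the ANOVA's pooled within-group mean square.
#'
#' @inheritParams one_way_anova
#' @return A tibble with one row per unordered group pair: `group_i`,
#'   `group_j`, `diff` (mean_j - mean_i), `se`, `p_adj`.
#' @export
tukey_posthoc <- function(values_by_group) {
  g <- as_groups(values_by_group)
  a <- one_way_anova(g)
  k <- length(g)
  pairs <- combn(names(g), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(m) {
    i <- pairs[1, m]; j <- pairs[2, m]
    diff <- mean(g[[j]]) - mean(g[[i]])
    se <- sqrt(a$ms_within * (1 / length(g[[i]]) + 1 / length(g[[j]])))
    q <- abs(diff) / (se / sqrt(2))
    tibble::tibble(
      group_i = i, group_j = j, diff = diff, se = se,
      p_adj = ptukey(q, nmeans = k, df = a$df_within, lower.tail = FALSE)
    )
  })
}

#' Paired t-test from differences
#'
#' @param x,y Numeric vectors of equal length (paired observations).
#' @return A list with `t`, `df`, `p_value`, `mean_diff`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    stop_invalid("x and y must be equal-length vectors with n >= 2")
  }
  d <- x - y
  s <- sd(d)
  if (s == 0) stop_degenerate("zero variance of paired differences")
  n <- length(d)
  t <- mean(d) / (s / sqrt(n))
  list(t = t, df = n - 1L, p_value = 2 * pt(abs(t), n - 1, lower.tail = FALSE),
       mean_diff = mean(d))
}

#' Per-paralog lineage ANOVA and post hoc tables
#'
#' Runs a one-way ANOVA of copy number on lineage for every paralog of a
#' copy-number table, with Tukey HSD pairwise comparisons. Samples with
#' lineage `"unassigned"` are excluded; a Benjamini-Hochberg adjusted
#' p-value column across paralogs can be added (off by default).
#'
#' @param cn_table A `cn_table` from [estimate_cn_table()].
#' @param adjust Add a BH-adjusted p-value column across paralogs.
#' @return A list with `anova` (per-paralog tibble: paralog, F, dfs, p,
#'   per-lineage means and medians) and `posthoc` (per-paralog pairwise
#'   tibble).
#' @export
cn_lineage_stats <- function(cn_table, adjust = FALSE) {
  long <- cn_long(cn_table) |>
    dplyr::filter(.data$lineage != "unassigned")
  paralogs <- unique(long$paralog)
  res <- purrr::map(paralogs, function(p) {
    dat <- dplyr::filter(long, .data$paralog == p)
    groups <- split(dat$cn, dat$lineage)
    a <- one_way_anova(groups)
    summ <- tidyr::pivot_wider(
      a$groups, names_from = "group",
      values_from = c("n", "mean", "median")
    )
    list(
      anova = dplyr::bind_cols(
        tibble::tibble(paralog = p, F = a$F, df_between = a$df_between,
                       df_within = a$df_within, p_value = a$p_value),
        summ
      ),
      posthoc = dplyr::mutate(tukey_posthoc(groups), paralog = p, .before = 1)
    )
  })
  anova_tab <- purrr::map_dfr(res, "anova")
  if (adjust) anova_tab$p_bh <- stats::p.adjust(anova_tab$p_value, "BH")
  list(anova = anova_tab, posthoc = purrr::map_dfr(res, "posthoc"))
}

#' Within-cultivar comparisons for replicated cultivars
#'
#' Cultivars sequenced more than twice are compared across samples with a
#' one-way ANOVA over samples (per-paralog values as replicates); cultivars
#' with exactly two individuals get a paired t-test across paralogs.
#'
#' @param cn_table A `cn_table`.
#' @return A tibble: `cultivar`, `n_samples`, `test`, `statistic`, `df`,
#'   `p_value`.
#' @export
cn_cultivar_stats <- function(cn_table) {
  long <- cn_long(cn_table)
  counts <- long |>
    dplyr::distinct(.data$cultivar, .data$sample_id) |>
    dplyr::count(.data$cultivar, name = "n_samples")
  multi <- dplyr::filter(counts, .data$n_samples >= 2)
  purrr::map_dfr(seq_len(nrow(multi)), function(i) {
    cv <- multi$cultivar[i]
    dat <- dplyr::filter(long, .data$cultivar == cv)
    wide <- tidyr::pivot_wider(dat[c("sample_id", "paralog", "cn")],
                               names_from = "sample_id", values_from = "cn")
    if (multi$n_samples[i] == 2) {
      r <- paired_t(wide[[2]], wide[[3]])
      tibble::tibble(cultivar = cv, n_samples = 2L, test = "paired_t",
                     statistic = r$t, df = as.numeric(r$df), p_value = r$p_value)
    } else {
      groups <- split(dat$cn, dat$sample_id)
      a <- one_way_anova(groups)
      tibble::tibble(cultivar = cv, n_samples = multi$n_samples[i],
                     test = "anova", statistic = a$F,
                     df = as.numeric(a$df_within), p_value = a$p_value)
    }
  })
}
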