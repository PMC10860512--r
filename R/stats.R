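# Statistical comparison of segmentation methods: one-way ANOVA across
# method arms, Tukey HSD post hoc pairwise tests, and distribution
# summaries (median, range, interquartile range).

#' One-way analysis of variance across method groups
#'
#' Classical between/within mean-square F ratio with `(k-1, N-k)` degrees
#' of freedom, fitted with `stats::aov()`.
#'
#' @param data Data frame of scores.
#' @param score,group Column names (strings) of the score and the grouping
#'   label.
#' @return Object of class `gtv_anova` wrapping the fit, with `statistic`
#'   (F), `p_value`, and `df`.
#' @export
one_way_anova <- function(data, score = "dsc", group = "arm") {
  df <- tibble::tibble(y = as.numeric(data[[score]]),
                       g = factor(data[[group]]))
  df <- df[stats::complete.cases(df), ]
  counts <- table(df$g)
  if (length(counts) < 2) stop("ANOVA needs at least two groups")
  if (any(counts < 2)) stop("every group needs at least two values")
  fit <- stats::aov(y ~ g, data = df)
  an <- summary(fit)[[1]]
  degenerate <- an["Residuals", "Sum Sq"] <= .Machine$double.eps *
    max(1, abs(sum(df$y)))
  structure(list(fit = fit, data = df,
                 statistic = an["g", "F value"],
                 p_value = an["g", "Pr(>F)"],
                 df = c(an["g", "Df"], an["Residuals", "Df"]),
                 degenerate = isTRUE(degenerate)),
            class = "gtv_anova")
}

#' @export
print.gtv_anova <- function(x, ...) {
  cat(sprintf("<gtv_anova> F(%d, %d) = %.4g, p = %.4g%s\n", x$df[1], x$df[2],
              x$statistic, x$p_value,
              if (x$degenerate) " (degenerate: no residual variance)" else ""))
  invisible(x)
}

#' Tidy an ANOVA fit
#' @param x A `gtv_anova`.
#' @param ... Unused.
#' @return One-row tibble: `df_between`, `df_within`, `statistic`,
#'   `p_value`.
#' @export
tidy.gtv_anova <- function(x, ...) {
  tibble::tibble(df_between = x$df[1], df_within = x$df[2],
                 statistic = x$statistic, p_value = x$p_value)
}

#' @rdname tidy.gtv_anova
#' @export
glance.gtv_anova <- function(x, ...) tidy.gtv_anova(x)

#' Tukey Honestly Significant Differences post hoc test
#'
#' Studentized-range based pairwise comparisons for every unordered group
#' pair, via `stats::TukeyHSD()`.
#'
#' @inheritParams one_way_anova
#' @param alpha Family-wise error level for the reject flags.
#' @return Object of class `gtv_tukey`; its `table` element is a tibble
#'   with one row per pair: `pair`, `diff` (mean difference), `lwr`,
#'   `upr`, `p_adj`, `reject`.
#' @export
tukey_hsd <- function(data, score = "dsc", group = "arm", alpha = 0.05) {
  an <- one_way_anova(data, score, group)
  th <- stats::TukeyHSD(an$fit, conf.level = 1 - alpha)$g
  tab <- tibble::tibble(pair = rownames(th),
                        diff = unname(th[, "diff"]),
                        lwr = unname(th[, "lwr"]),
                        upr = unname(th[, "upr"]),
                        p_adj = unname(th[, "p adj"]),
                        reject = unname(th[, "p adj"] < alpha))
  structure(list(table = tab, alpha = alpha, anova = an),
            class = "gtv_tukey")
}

#' @export
print.gtv_tukey <- function(x, ...) {
  cat(sprintf("<gtv_tukey> %d pairwise comparisons at alpha = %g\n",
              nrow(x$table), x$alpha))
  print(x$table)
  invisible(x)
}

#' @rdname tidy.gtv_anova
#' @export
tidy.gtv_tukey <- function(x, ...) x$table

#' Distribution summary: median, range and interquartile range
#'
#' Quartiles use the linear-interpolation convention
#' (`stats::quantile(type = 7)`), fixed so summaries are reproducible.
#'
#' @param data Data frame of scores.
#' @param score Score column name.
#' @param by Character vector of grouping columns (may be empty).
#' @return Tibble with `n`, `median`, `min`, `max`, `q1`, `q3` per group.
#' @export
summarize_scores <- function(data, score = "dsc", by = character(0)) {
  df <- dplyr::filter(data, !is.na(.data[[score]]))
  if (nrow(df) == 0) stop("no non-missing scores to summarize")
  one <- function(v) tibble::tibble(
    n = length(v), median = stats::median(v), min = min(v), max = max(v),
    q1 = unname(stats::quantile(v, 0.25, type = 7)),
    q3 = unname(stats::quantile(v, 0.75, type = 7)))
  if (length(by) == 0) return(one(df[[score]]))
  df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::reframe(one(.data[[score]]))
}
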