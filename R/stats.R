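#' Welch group comparison of per-subject metrics
#'
#' Runs a Welch (unequal-variance) two-sample t-test for each requested
#' metric between the two groups of a per-subject metrics table.
#'
#' @param data A data frame with one row per subject, a grouping column and
#'   the metric columns (e.g. the `metrics` element of
#'   [run_landscape_pipeline()]).
#' @param metrics Character vector of metric column names (defaults to
#'   [dynamic_metric_names()] intersected with `data`).
#' @param group_col Name of the grouping column (must have exactly two
#'   levels).
#' @param adjust Multiple-testing adjustment passed to
#'   [stats::p.adjust()]; the default `"none"` reports raw p-values.
#' @return A tibble with one row per metric: group means and standard
#'   errors, Welch `t`, `df`, `p_value` and significance `stars`
#'   (`*` < .05, `**` < .01, `***` < .001). Metrics with zero variance in
#'   both groups get `NA` statistics.
#' @export
compare_groups <- function(data, metrics = NULL, group_col = "group",
                           adjust = "none") {
  stopifnot(is.data.frame(data), group_col %in% names(data))
  groups <- sort(unique(as.character(data[[group_col]])))
  if (length(groups) != 2L) {
    stop("`", group_col, "` must have exactly two levels; got ",
         length(groups), ".", call. = FALSE)
  }
  if (is.null(metrics)) metrics <- intersect(dynamic_metric_names(), names(data))
  g1 <- data[data[[group_col]] == groups[1L], , drop = FALSE]
  g2 <- data[data[[group_col]] == groups[2L], , drop = FALSE]
  if (nrow(g1) < 2L || nrow(g2) < 2L) {
    stop("Need at least two subjects per group.", call. = FALSE)
  }
  rows <- purrr::map(metrics, function(m) {
    x <- g1[[m]]
    y <- g2[[m]]
    out <- tibble::tibble(
      metric = m,
      group1 = groups[1L], group2 = groups[2L],
      mean1 = mean(x), mean2 = mean(y),
      se1 = stats::sd(x) / sqrt(length(x)),
      se2 = stats::sd(y) / sqrt(length(y)),
      t = NA_real_, df = NA_real_, p_value = NA_real_)
    if (stats::sd(x) > 0 || stats::sd(y) > 0) {
      tt <- stats::t.test(x, y)
      out$t <- unname(tt$statistic)
      out$df <- unname(tt$parameter)
      out$p_value <- tt$p.value
    }
    out
  })
  res <- dplyr::bind_rows(rows)
  res$p_value <- stats::p.adjust(res$p_value, method = adjust)
  res$stars <- significance_stars(res$p_value)
  res
}

significance_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "")
}

#' Pearson correlation of metrics with a clinical score
#'
#' Correlates each per-subject metric with a clinical score (e.g. an
#' MMSE-like 0-30 cognition score) and reports the two-sided test.
#'
#' @inheritParams compare_groups
#' @param score_col Name of the score column.
#' @return A tibble with one row per metric: Pearson `r`, `p_value`, `n`
#'   and `stars`. Metrics (or scores) with zero variance give `NA`.
#' @export
correlate_with_score <- function(data, metrics = NULL, score_col = "score") {
  stopifnot(is.data.frame(data), score_col %in% names(data))
  if (is.null(metrics)) metrics <- intersect(dynamic_metric_names(), names(data))
  score <- data[[score_col]]
  if (length(score) < 3L) stop("Need at least three subjects.", call. = FALSE)
  rows <- purrr::map(metrics, function(m) {
    x <- data[[m]]
    ok <- stats::sd(x) > 0 && stats::sd(score) > 0
    if (ok) {
      ct <- stats::cor.test(x, score, method = "pearson")
      tibble::tibble(metric = m, r = unname(ct$estimate),
                     p_value = ct$p.value, n = length(x))
    } else {
      tibble::tibble(metric = m, r = NA_real_, p_value = NA_real_, n = length(x))
    }
  })
  res <- dplyr::bind_rows(rows)
  res$stars <- significance_stars(res$p_value)
  res
}
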