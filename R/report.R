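# Study report assembly: method summary tables, ANOVA/Tukey comparisons,
# consensus-recall gradients, and a machine-readable JSON bundle.

#' Assemble the study report
#'
#' Takes tidy per-record score tables and produces the study's summary
#' tables: (a) per-arm metric summaries with ANOVA p-values per test set
#' and metric, with Tukey HSD post hoc pairs wherever three arms are
#' available; (b) consensus-level recall summaries per model with per-level
#' ANOVA p-values; (c) a per-subject score listing ordered by reference
#' volume.
#'
#' @param records Tibble with columns `test_set`, `arm`, `subject_id`,
#'   `predictor`, `reference`, and metric columns `dsc` (plus optionally
#'   `precision`, `recall`, `ref_voxels`).
#' @param consensus Optional tibble from [consensus_recall()] rows with a
#'   `model` column.
#' @param alpha Significance level.
#' @param manual_unit How the manual (inter-observer) arm enters the
#'   ANOVA: every observer pair score (`"pair"`, default) or one median
#'   per subject (`"subject_median"`).
#' @return Object of class `gtv_report`: a list of tibbles
#'   (`method_summary`, `anova`, `tukey`, `consensus_summary`,
#'   `consensus_anova`, `per_subject`) plus `alpha`.
#' @export
build_report <- function(records, consensus = NULL, alpha = 0.05,
                         manual_unit = c("pair", "subject_median")) {
  manual_unit <- match.arg(manual_unit)
  stopifnot(all(c("test_set", "arm", "subject_id", "dsc") %in%
                  colnames(records)))
  if (manual_unit == "subject_median") {
    man <- records |>
      dplyr::filter(.data$arm == "manual") |>
      dplyr::group_by(.data$test_set, .data$arm, .data$subject_id) |>
      dplyr::summarise(dsc = stats::median(.data$dsc), .groups = "drop")
    records <- dplyr::bind_rows(
      dplyr::filter(records, .data$arm != "manual"), man)
  }
  metrics <- intersect(c("dsc", "precision", "recall"), colnames(records))
  long <- records |>
    tidyr::pivot_longer(dplyr::all_of(metrics), names_to = "metric",
                        values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  method_summary <- long |>
    dplyr::group_by(.data$test_set, .data$metric, .data$arm) |>
    dplyr::reframe(summarize_scores(dplyr::pick(dplyr::everything()),
                                    score = "value"))
  anova_rows <- list(); tukey_rows <- list()
  for (ts in unique(long$test_set)) for (mt in unique(long$metric)) {
    sub <- dplyr::filter(long, .data$test_set == ts, .data$metric == mt)
    counts <- table(sub$arm)
    if (length(counts) < 2 || any(counts < 2)) next
    an <- one_way_anova(sub, score = "value", group = "arm")
    anova_rows[[length(anova_rows) + 1]] <-
      dplyr::bind_cols(tibble::tibble(test_set = ts, metric = mt),
                       tidy(an))
    if (length(counts) >= 3) {
      tk <- tukey_hsd(sub, score = "value", group = "arm", alpha = alpha)
      tukey_rows[[length(tukey_rows) + 1]] <-
        dplyr::bind_cols(tibble::tibble(test_set = ts, metric = mt),
                         tidy(tk))
    }
  }
  consensus_summary <- NULL; consensus_anova <- NULL
  if (!is.null(consensus) && nrow(consensus)) {
    consensus_summary <- consensus |>
      dplyr::filter(!is.na(.data$recall)) |>
      dplyr::group_by(.data$model, .data$level) |>
      dplyr::reframe(summarize_scores(dplyr::pick(dplyr::everything()),
                                      score = "recall"))
    ca <- list()
    for (lv in sort(unique(consensus$level))) {
      sub <- dplyr::filter(consensus, .data$level == lv, !is.na(.data$recall))
      counts <- table(sub$model)
      if (length(counts) < 2 || any(counts < 2)) next
      an <- one_way_anova(sub, score = "recall", group = "model")
      ca[[length(ca) + 1]] <-
        dplyr::bind_cols(tibble::tibble(level = lv), tidy(an))
    }
    consensus_anova <- dplyr::bind_rows(ca)
  }
  per_subject <- records |>
    dplyr::arrange(.data$test_set,
                   if ("ref_voxels" %in% colnames(records))
                     .data$ref_voxels else .data$subject_id,
                   .data$subject_id)
  structure(list(method_summary = method_summary,
                 anova = dplyr::bind_rows(anova_rows),
                 tukey = dplyr::bind_rows(tukey_rows),
                 consensus_summary = consensus_summary,
                 consensus_anova = consensus_anova,
                 per_subject = per_subject, alpha = alpha),
            class = "gtv_report")
}

#' @export
print.gtv_report <- function(x, ...) {
  cat("<gtv_report>\nMethod summaries:\n")
  print(x$method_summary, n = 30)
  cat("\nANOVA:\n"); print(x$anova)
  if (!is.null(x$consensus_summary)) {
    cat("\nConsensus recall:\n"); print(x$consensus_summary, n = 20)
  }
  invisible(x)
}

report_json <- function(report) {
  keep <- c("method_summary", "anova", "tukey", "consensus_summary",
            "consensus_anova", "per_subject", "alpha")
  obj <- report[keep]
  obj <- obj[!vapply(obj, is.null, logical(1))]
  jsonlite::toJSON(obj, dataframe = "rows", digits = NA, auto_unbox = TRUE,
                   na = "null", pretty = TRUE)
}

#' Write a report bundle to disk
#'
#' Writes each table as tab-delimited text plus a single `report.json`
#' holding all statistics; the JSON is deterministic for identical inputs.
#'
#' @param report A `gtv_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- c("method_summary", "anova", "tukey", "consensus_summary",
            "consensus_anova", "per_subject")
  for (nm in tabs) {
    if (is.null(report[[nm]]) || nrow(report[[nm]]) == 0) next
    utils::write.table(report[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  writeLines(report_json(report), file.path(dir, "report.json"))
  invisible(dir)
}

#' Per-subject score strip plot
#'
#' Scores per subject ordered by reference (tumour) volume, one panel per
#' test set, coloured by arm — the study's per-subject agreement view.
#'
#' @param records Tibble with `test_set`, `arm`, `subject_id`, `dsc` and
#'   `ref_voxels` columns (e.g. `report$per_subject`).
#' @param metric Metric column to plot.
#' @return A ggplot object.
#' @export
plot_subject_scores <- function(records, metric = "dsc") {
  ord <- records |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(vol = max(.data$ref_voxels, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::arrange(.data$vol)
  records$subject_id <- factor(records$subject_id, levels = ord$subject_id)
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$subject_id,
                               y = .data[[metric]],
                               colour = .data$arm)) +
    ggplot2::geom_point(alpha = 0.8, position = ggplot2::position_dodge(0.4)) +
    ggplot2::facet_wrap(~test_set, scales = "free_x") +
    ggplot2::labs(x = "subject (ordered by tumour volume)", y = metric) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Training-history curve plot
#' @param object A history tibble from [train()] or [fine_tune()].
#' @param ... Unused.
#' @return A ggplot object with loss and validation-Dice curves.
#' @export
autoplot.gtv_history <- function(object, ...) {
  long <- object |>
    tidyr::pivot_longer(-"epoch", names_to = "series",
                        values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "epoch", y = NULL)
}
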