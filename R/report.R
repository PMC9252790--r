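report_columns <- c("variant_id", "chrom", "pos", "ref", "alt", "tf_name",
                    "combined_S", "category", "n_models_used",
                    "tffm_only_used", "known_tfbs", "known_sources",
                    "model_scores")

#' Write the results report as TSV
#'
#' Produces deterministic tab-separated output from a [scan_variants()]
#' result:
#'
#' * `<prefix>.tsv` — one row per (variant, transcription factor), sorted by
#'   variant input order and then by `|combined_S|` descending. The fixed
#'   column order is `variant_id, chrom, pos, ref, alt, tf_name, combined_S,
#'   category, n_models_used, tffm_only_used, known_tfbs, known_sources,
#'   model_scores`; `model_scores` packs the per-model results as
#'   `model_id|kind|WT|MT|S` triplets joined by `;`.
#' * `<prefix>_summary.tsv` — the same schema restricted by the active
#'   `summary_filters`; an empty result writes the header only and raises a
#'   notice.
#' * `<prefix>_models.tsv` — the detailed per-model section: for each
#'   variant and TF the individual model scores followed by a `combined`
#'   row.
#'
#' @param scan A `"tf_scan"` object.
#' @param prefix Output path prefix.
#' @param summary_filters Optional list with any of `min_abs_S` (numeric),
#'   `direction` (`"loss"` or `"gain"`), `known_only` (logical), `tf_names`
#'   (character).
#' @return Invisibly, a character vector of the files written.
#' @export
write_report <- function(scan, prefix, summary_filters = NULL) {
  stopifnot(inherits(scan, "tf_scan"))
  preds <- scan$predictions
  if (nrow(preds) == 0L) stop("no results to report", call. = FALSE)
  model_pack <- scan$outcomes |>
    dplyr::group_by(.data$variant_id, .data$tf_name) |>
    dplyr::summarise(model_scores = paste(
      sprintf("%s|%s|%.6g|%.6g|%.6g", .data$model_id, .data$model_kind,
              .data$WT, .data$MT, .data$S), collapse = ";"),
      .groups = "drop")
  rows <- preds |>
    dplyr::left_join(scan$variants, by = "variant_id") |>
    dplyr::left_join(model_pack, by = c("variant_id", "tf_name")) |>
    dplyr::mutate(order = match(.data$variant_id, scan$variants$variant_id)) |>
    dplyr::arrange(.data$order, dplyr::desc(abs(.data$combined_S)),
                   .data$tf_name) |>
    dplyr::select(dplyr::all_of(report_columns))
  main_path <- paste0(prefix, ".tsv")
  readr::write_tsv(rows, main_path, progress = FALSE)

  f <- summary_filters %||% list()
  kept <- rows
  if (!is.null(f$min_abs_S)) kept <- kept[abs(kept$combined_S) >= f$min_abs_S, ]
  if (!is.null(f$direction)) {
    kept <- switch(f$direction,
                   loss = kept[kept$combined_S < 0, ],
                   gain = kept[kept$combined_S > 0, ],
                   stop("direction must be 'loss' or 'gain'", call. = FALSE))
  }
  if (isTRUE(f$known_only)) kept <- kept[kept$known_tfbs %in% TRUE, ]
  if (!is.null(f$tf_names)) kept <- kept[kept$tf_name %in% f$tf_names, ]
  summary_path <- paste0(prefix, "_summary.tsv")
  readr::write_tsv(kept, summary_path, progress = FALSE)
  if (nrow(kept) == 0L) {
    message("summary is empty after filters; header-only file written")
  }

  detail <- scan$outcomes |>
    dplyr::transmute(.data$variant_id, .data$tf_name, row_type = "model",
                     .data$model_id, kind = .data$model_kind,
                     WT = .data$WT, MT = .data$MT, S = .data$S)
  combined <- preds |>
    dplyr::transmute(.data$variant_id, .data$tf_name, row_type = "combined",
                     model_id = sprintf("mean_of_%d", .data$n_models_used),
                     kind = ifelse(.data$tffm_only_used, "TFFM_only", "all_models"),
                     WT = NA_real_, MT = NA_real_, S = .data$combined_S)
  detail_all <- dplyr::bind_rows(detail, combined) |>
    dplyr::mutate(order = match(.data$variant_id, scan$variants$variant_id)) |>
    dplyr::arrange(.data$order, .data$tf_name,
                   match(.data$row_type, c("model", "combined")),
                   .data$model_id) |>
    dplyr::select(-"order")
  models_path <- paste0(prefix, "_models.tsv")
  readr::write_tsv(detail_all, models_path, progress = FALSE)
  invisible(c(main_path, summary_path, models_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
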