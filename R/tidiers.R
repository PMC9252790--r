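#' Tidy a variant scan
#'
#' `tidy()` returns the per-TF predictions (one row per variant and
#' transcription factor, with the nested per-model outcomes dropped);
#' `glance()` returns a one-row summary of the whole scan.
#'
#' @param x A `"tf_scan"` object from [scan_variants()].
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.tf_scan <- function(x, ...) {
  dplyr::select(x$predictions, -dplyr::any_of("outcomes"))
}

#' @rdname tidy.tf_scan
#' @exportS3Method generics::glance
glance.tf_scan <- function(x, ...) {
  p <- x$predictions
  tibble::tibble(
    n_variants = nrow(x$variants),
    n_skipped = nrow(x$skipped),
    n_tfs = length(unique(p$tf_name)),
    n_model_outcomes = nrow(x$outcomes),
    n_loss = sum(p$combined_S < 0),
    n_gain = sum(p$combined_S > 0),
    max_abs_S = if (nrow(p)) max(abs(p$combined_S)) else NA_real_,
    alpha = x$config$alpha,
    window_halfwidth = x$config$window_halfwidth,
    tffm_only = x$config$tffm_only
  )
}

#' Heatmap of combined scores per variant and transcription factor
#'
#' Variants in columns, transcription factors in rows; cells are coloured by
#' the combined joint score (red = predicted binding loss, blue = predicted
#' gain), mirroring the usual presentation of variant-effect matrices.
#'
#' @param object A `"tf_scan"` object.
#' @param top_n Show at most this many TFs, ranked by their largest
#'   `|combined_S|` across variants (default 25).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.tf_scan <- function(object, top_n = 25L, ...) {
  p <- object$predictions
  keep <- p |>
    dplyr::group_by(.data$tf_name) |>
    dplyr::summarise(m = max(abs(.data$combined_S)), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$m)) |>
    dplyr::slice_head(n = top_n)
  p <- dplyr::filter(p, .data$tf_name %in% keep$tf_name)
  ggplot2::ggplot(p, ggplot2::aes(x = .data$variant_id, y = .data$tf_name,
                                  fill = .data$combined_S)) +
    ggplot2::geom_tile(colour = "grey85") +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", limits = c(-1, 1),
                                  name = "S") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-model score detail for one variant and TF
#'
#' Dumbbell-style view of the wild-type and mutated window scores of each
#' contributing model, annotated with the per-model joint score.
#'
#' @param scan A `"tf_scan"` object.
#' @param variant_id,tf_name Which cell of the prediction matrix to detail.
#' @return A ggplot object.
#' @export
plot_model_scores <- function(scan, variant_id, tf_name) {
  stopifnot(inherits(scan, "tf_scan"))
  o <- dplyr::filter(scan$outcomes,
                     .data$variant_id == !!variant_id,
                     .data$tf_name == !!tf_name)
  if (nrow(o) == 0L) stop("no outcomes for that variant/TF", call. = FALSE)
  long <- tidyr::pivot_longer(o, c("WT", "MT"), names_to = "allele",
                              values_to = "score")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$score, y = .data$model_id)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$model_id), colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$allele), size = 3) +
    ggplot2::geom_text(data = o,
                       ggplot2::aes(x = 1.02, y = .data$model_id,
                                    label = sprintf("S=%+.2f", .data$S)),
                       hjust = 0, size = 3, inherit.aes = FALSE) +
    ggplot2::scale_colour_manual(values = c(WT = "#4d4d4d", MT = "#d6604d")) +
    ggplot2::coord_cartesian(xlim = c(0, 1.15)) +
    ggplot2::labs(x = "normalised window score", y = NULL,
                  title = sprintf("%s / %s", variant_id, tf_name)) +
    ggplot2::theme_minimal()
}
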