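#' Risk plot: measure of effect vs measure of mobility and persistence
#'
#' Log-log scatter of the two risk axes, one point per formulation. Point
#' shape distinguishes thresholds derived at the 95% protection level
#' (closed) from potential biomagnifiers derived at 99% (open); fontface
#' encodes threshold reliability (italic for moderate or better). PAIs
#' further towards the top right pose a larger aquatic risk.
#'
#' @param results risk table from [pdst_compute()].
#' @param table the [pai_table()] the results came from (supplies percentile
#'   and reliability); defaults to the bundled reference data.
#' @param highlight optional character vector of labels (or names) to keep;
#'   all others are dropped.
#' @return A ggplot object.
#' @export
pdst_plot <- function(results, table = pdst_reference_data(),
                      highlight = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("pdst_plot requires the ggplot2 package")
  if (!is.null(highlight))
    results <- results[results$label %in% highlight |
                       results$name %in% highlight, , drop = FALSE]
  if (nrow(results) == 0)
    pdst_validation_error("no results to plot")
  e <- table$etvs[match(results$name, table$etvs$name), ]
  results$percentile <- ifelse(is.na(e$percentile), "none (AF)",
                               paste0("PC", e$percentile))
  results$reliable <- e$reliability %in% c("moderate", "high", "very_high")
  positive <- results$mobility_persistence > 0
  if (!all(positive)) results <- results[positive, , drop = FALSE]

  ggplot2::ggplot(results,
                  ggplot2::aes(x = mobility_persistence, y = effect,
                               shape = percentile)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = label,
                                    fontface = ifelse(reliable, "italic",
                                                      "plain")),
                       hjust = -0.1, vjust = 0.5, size = 2.6,
                       check_overlap = TRUE) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::scale_shape_manual(values = c("PC95" = 16, "PC99" = 1,
                                           "none (AF)" = 2)) +
    ggplot2::labs(x = "Measure of mobility and persistence",
                  y = "Measure of effect (ML/ha)",
                  shape = "Protection level") +
    ggplot2::theme_bw()
}

utils::globalVariables(c("mobility_persistence", "effect", "percentile",
                         "label", "reliable"))
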