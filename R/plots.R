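#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of peak calls per day
#'
#' @param object A [call_peaks()] result.
#' @param ... Unused.
#' @method autoplot peak_calls
#' @export
autoplot.peak_calls <- function(object, ...) {
  object %>%
    tibble::as_tibble() %>%
    dplyr::count(.data$peak_day) %>%
    ggplot2::ggplot(ggplot2::aes(factor(.data$peak_day), .data$n)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(
      x = "peak day", y = "miRNAs",
      title = "miRNAs with single-day expression peaks"
    ) +
    ggplot2::theme_minimal()
}

#' Cross-study correlation scatter of candidate interactions
#'
#' In vivo tau on the x axis against in vitro tau on the y axis, one point
#' per interaction; pairs within the conservation band (|delta tau| below
#' the threshold) are highlighted and the anti-correlation cut-offs drawn
#' as dashed lines.
#'
#' @param object An [intersect_studies()] (or downstream) table.
#' @param delta_max,tau_max Thresholds drawn on the plot.
#' @param ... Unused.
#' @method autoplot conserved_candidates
#' @export
autoplot.conserved_candidates <- function(object, delta_max = 0.2,
                                          tau_max = -0.2, ...) {
  object %>%
    tibble::as_tibble() %>%
    dplyr::mutate(conserved = .data$delta < delta_max) %>%
    ggplot2::ggplot(ggplot2::aes(.data$tau_vivo, .data$tau_vitro,
      colour = .data$conserved)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = tau_max, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = tau_max, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
      `FALSE` = "grey60")) +
    ggplot2::labs(
      x = "Kendall tau (in vivo)", y = "Kendall tau (in vitro)",
      colour = sprintf("|delta| < %.2g", delta_max)
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot conserved_interactions
#' @export
autoplot.conserved_interactions <- autoplot.conserved_candidates

#' Volcano plot of a differential-expression result
#'
#' @param object A [diff_expression()] result.
#' @param ... Unused.
#' @method autoplot de_result
#' @export
autoplot.de_result <- function(object, ...) {
  object %>%
    tibble::as_tibble() %>%
    ggplot2::ggplot(ggplot2::aes(.data$log2fc, -log10(.data$p_adj),
      colour = .data$is_de)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::facet_wrap(~day) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
      `FALSE` = "grey60")) +
    ggplot2::labs(x = "log2 fold change vs reference",
      y = "-log10 adjusted p", colour = "DE") +
    ggplot2::theme_minimal()
}

#' Dot plot of conditioned enrichment results
#'
#' @param object A [conditional_enrichment()] result.
#' @param alpha Significance line (default 0.01).
#' @param max_terms Terms shown (most significant first).
#' @param ... Unused.
#' @method autoplot enrichment_results
#' @export
autoplot.enrichment_results <- function(object, alpha = 0.01,
                                        max_terms = 20, ...) {
  object %>%
    tibble::as_tibble() %>%
    dplyr::slice_min(.data$p_value, n = max_terms, with_ties = FALSE) %>%
    ggplot2::ggplot(ggplot2::aes(-log10(.data$p_value),
      stats::reorder(.data$term_id, -.data$p_value),
      size = .data$overlap, colour = .data$conditioned)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::labs(x = "-log10 conditioned p", y = NULL,
      size = "overlap", colour = "conditioned") +
    ggplot2::theme_minimal()
}

#' Line plot of Min-Max normalised day profiles
#'
#' @param profiles A [day_mean_profiles()] table.
#' @param features Optional subset of features to draw.
#' @param normalize Min-Max normalise each profile first (default TRUE).
#' @export
plot_profiles <- function(profiles, features = NULL, normalize = TRUE) {
  if (!is.null(features)) {
    profiles <- dplyr::filter(profiles, .data$feature_id %in% features)
  }
  if (normalize) profiles <- suppressWarnings(minmax_normalize(profiles))
  ggplot2::ggplot(profiles, ggplot2::aes(.data$day, .data$value,
    colour = .data$feature_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "day",
      y = if (normalize) "scaled expression" else "log2 expression",
      colour = NULL) +
    ggplot2::theme_minimal()
}
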