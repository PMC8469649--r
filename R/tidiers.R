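#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the stage counts of a pipeline run
#'
#' @param x A [run_pipeline()] manifest.
#' @param ... Unused.
#' @return A tibble with one row per recorded stage count.
#' @method tidy run_manifest
#' @export
tidy.run_manifest <- function(x, ...) {
  flat <- unlist(x$counts)
  tibble::tibble(stage = names(flat), n = unname(flat))
}

#' One-row summary of a pipeline run
#'
#' @param x A [run_pipeline()] manifest.
#' @param ... Unused.
#' @method glance run_manifest
#' @export
glance.run_manifest <- function(x, ...) {
  tibble::tibble(
    n_peaks = sum(unlist(x$counts$peaks_per_day)),
    n_merged = x$counts$merged,
    n_overlap = x$counts$overlap,
    n_gene_set = x$counts$gene_set,
    n_conserved = x$counts$conserved,
    n_conserved_mirnas = x$counts$conserved_unique_mirnas,
    n_conserved_genes = x$counts$conserved_unique_genes
  )
}

#' Per-day summary of a differential-expression result
#'
#' @param x A [diff_expression()] result.
#' @param ... Unused.
#' @return One row per contrast day: features tested, DE calls, and the
#'   up/down split.
#' @method glance de_result
#' @export
glance.de_result <- function(x, ...) {
  x %>%
    tibble::as_tibble() %>%
    dplyr::group_by(.data$day) %>%
    dplyr::summarise(
      n_features = dplyr::n(),
      n_de = sum(.data$is_de),
      n_up = sum(.data$is_de & .data$log2fc > 0),
      n_down = sum(.data$is_de & .data$log2fc < 0),
      .groups = "drop"
    )
}

#' Flatten a miRNA priority table for export
#'
#' @param x A [rank_mirnas()] result.
#' @param ... Unused.
#' @return The same table with `target_genes` comma-joined.
#' @method tidy mirna_priority
#' @export
tidy.mirna_priority <- function(x, ...) {
  x %>%
    tibble::as_tibble() %>%
    dplyr::mutate(
      target_genes = purrr::map_chr(.data$target_genes, paste, collapse = ",")
    )
}
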