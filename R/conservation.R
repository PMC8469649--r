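#' Overlap interaction correlations between two studies
#'
#' Keeps the (miRNA, gene) pairs annotated with a correlation in both the
#' in vitro and the in vivo study and carries both tau values plus their
#' absolute difference.
#'
#' @param vitro,vivo [annotate_correlations()] outputs for the two studies.
#' @return Tibble of class `conserved_candidates`: `mirna_id`, `gene_id`,
#'   `tau_vitro`, `tau_vivo`, `delta`.
#' @export
intersect_studies <- function(vitro, vivo) {
  out <- dplyr::inner_join(
    dplyr::select(vitro, "mirna_id", "gene_id", tau_vitro = "tau"),
    dplyr::select(vivo, "mirna_id", "gene_id", tau_vivo = "tau"),
    by = c("mirna_id", "gene_id")
  ) %>%
    dplyr::mutate(delta = abs(.data$tau_vitro - .data$tau_vivo)) %>%
    dplyr::arrange(.data$mirna_id, .data$gene_id)
  class(out) <- c("conserved_candidates", class(out))
  out
}

#' Restrict candidates to a designated gene set
#'
#' Typically the descendant-closure gene set of a heart-development
#' ontology term, supplied as a plain file-loaded set so runs are
#' reproducible without network access.
#'
#' @param candidates [intersect_studies()] output.
#' @param gene_set Character vector of gene ids.
#' @return The filtered candidates.
#' @export
restrict_gene_set <- function(candidates, gene_set) {
  if (length(gene_set) == 0) {
    warn("Empty gene set: all candidates will be removed.")
  }
  out <- dplyr::filter(candidates, .data$gene_id %in% gene_set)
  class(out) <- unique(c("conserved_candidates", class(out)))
  out
}

#' Select interactions with conserved negative correlation
#'
#' Keeps candidates whose correlations differ between studies by less than
#' `delta_max` and are below `tau_max` in both studies. Strict
#' inequalities by default ("a maximal threshold of 0.2" read as < 0.2);
#' `strict = FALSE` switches to non-strict comparisons.
#'
#' @param candidates [intersect_studies()] output (possibly gene-set
#'   restricted).
#' @param delta_max Maximum |tau_vitro - tau_vivo| (default 0.2).
#' @param tau_max Upper bound on each study's tau (default -0.2).
#' @param strict Strict (<) vs non-strict (<=) comparisons.
#' @return The conserved subset, class `conserved_interactions`.
#' @export
select_conserved <- function(candidates, delta_max = 0.2, tau_max = -0.2,
                             strict = TRUE) {
  # Tau on an n-day profile lies on a discrete grid (multiples of 2/(n(n-1))
  # without ties), so threshold comparisons see exact boundary cases whose
  # floating-point representations differ from the threshold by ~1e-16
  # (e.g. |-0.4 - (-0.6)| < 0.2 in doubles). Comparisons therefore treat
  # values within 1e-8 of a threshold as equal to it.
  eps <- 1e-8
  out <- if (strict) {
    dplyr::filter(candidates,
      .data$delta - delta_max < -eps,
      .data$tau_vitro - tau_max < -eps,
      .data$tau_vivo - tau_max < -eps
    )
  } else {
    dplyr::filter(candidates,
      .data$delta - delta_max <= eps,
      .data$tau_vitro - tau_max <= eps,
      .data$tau_vivo - tau_max <= eps
    )
  }
  class(out) <- unique(c("conserved_interactions", class(out)))
  out
}

#' Rank miRNAs by conserved-target count and regulator reach
#'
#' One row per miRNA, ordered by decreasing number of conserved targets
#' (ties by miRNA id). `n_regulators` counts targets that are
#' transcriptional regulators — a proxy for the breadth of a miRNA's
#' downstream influence.
#'
#' @param conserved [select_conserved()] output.
#' @param regulator_genes Character set of regulator gene ids.
#' @return Tibble of class `mirna_priority`: `mirna_id`, `n_targets`,
#'   `target_genes` (list column), `n_regulators`.
#' @export
rank_mirnas <- function(conserved, regulator_genes = character()) {
  out <- conserved %>%
    tibble::as_tibble() %>%
    dplyr::group_by(.data$mirna_id) %>%
    dplyr::summarise(
      n_targets = dplyr::n_distinct(.data$gene_id),
      target_genes = list(sort(unique(.data$gene_id))),
      n_regulators = sum(sort(unique(.data$gene_id)) %in% regulator_genes),
      .groups = "drop"
    ) %>%
    dplyr::arrange(dplyr::desc(.data$n_targets), .data$mirna_id)
  class(out) <- c("mirna_priority", class(out))
  out
}

#' Summary counts of a conserved-interaction set
#'
#' @param conserved A conserved-interaction tibble.
#' @return One-row tibble: `n_interactions`, `n_unique_mirnas`,
#'   `n_unique_genes`.
#' @export
summarize_run <- function(conserved) {
  tibble::tibble(
    n_interactions = nrow(conserved),
    n_unique_mirnas = dplyr::n_distinct(conserved$mirna_id),
    n_unique_genes = dplyr::n_distinct(conserved$gene_id)
  )
}
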