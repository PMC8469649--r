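#' Read one interaction resource from TSV
#'
#' Expects columns `mirna_id` and `gene_id`; `score` and `evidence` are
#' optional. A per-resource score threshold is available as a pass-through
#' confidence hook for resources distributed with a recommended cut-off;
#' rows with `score < score_min` are dropped.
#'
#' @param path File path.
#' @param resource Resource name recorded on each row (default: file stem).
#' @param score_min Optional minimum score.
#' @return Tibble `mirna_id`, `gene_id`, (`score`), `evidence`, `resource`.
#' @export
read_interaction_tsv <- function(path, resource = NULL, score_min = NULL) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("mirna_id", "gene_id") %in% names(tab))) {
    abort("Interaction TSVs need mirna_id and gene_id columns.")
  }
  if (is.null(resource)) {
    resource <- tools::file_path_sans_ext(basename(path))
  }
  if (!"evidence" %in% names(tab)) tab$evidence <- "predicted"
  if (!is.null(score_min)) {
    if (!"score" %in% names(tab)) {
      abort("`score_min` given but the table has no score column.")
    }
    tab <- dplyr::filter(tab, .data$score >= score_min)
  }
  tab$resource <- resource
  dplyr::select(tab, "mirna_id", "gene_id", dplyr::any_of("score"),
    "evidence", "resource")
}

#' Merge interaction resources into one deduplicated candidate table
#'
#' Takes the union over (miRNA, gene) pairs. Each merged record carries the
#' sorted, comma-joined set of contributing resource names and is marked
#' `experimental` if any contributing record was, else `predicted`.
#' Merging is associative, commutative and idempotent; already-merged
#' tables (with a `sources` column) can be merged again.
#'
#' @param tables A list of interaction tibbles (from
#'   [read_interaction_tsv()] or [simulate_resources()]), or a single
#'   tibble.
#' @return Tibble `mirna_id`, `gene_id`, `sources`, `n_sources`, `evidence`.
#' @export
merge_resources <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  if (length(tables) < 1) abort("Need at least one interaction table.")
  long <- purrr::map(tables, function(tab) {
    if ("sources" %in% names(tab) && !"resource" %in% names(tab)) {
      tab <- tab %>%
        dplyr::mutate(resource = strsplit(.data$sources, ",", fixed = TRUE)) %>%
        tidyr::unnest("resource")
    }
    if (!"resource" %in% names(tab)) {
      abort("Each table needs a `resource` (or merged `sources`) column.")
    }
    if (!"evidence" %in% names(tab)) tab$evidence <- "predicted"
    dplyr::select(tab, "mirna_id", "gene_id", "evidence", "resource")
  }) %>% dplyr::bind_rows()
  long %>%
    dplyr::group_by(.data$mirna_id, .data$gene_id) %>%
    dplyr::summarise(
      sources = paste(sort(unique(.data$resource)), collapse = ","),
      n_sources = dplyr::n_distinct(.data$resource),
      evidence = if (any(.data$evidence == "experimental")) "experimental" else "predicted",
      .groups = "drop"
    ) %>%
    dplyr::arrange(.data$mirna_id, .data$gene_id)
}

#' Drop interactions whose partners are not expressed
#'
#' @param table Merged interaction tibble.
#' @param expressed_mirnas,expressed_genes Character sets of expressed
#'   feature ids (typically `feature_id` of [filter_expressed()] output).
#' @return The filtered table.
#' @export
restrict_to_expressed <- function(table, expressed_mirnas, expressed_genes) {
  dplyr::filter(table,
    .data$mirna_id %in% expressed_mirnas,
    .data$gene_id %in% expressed_genes
  )
}

#' Kendall rank correlation (tau-b) by exact pair enumeration
#'
#' Counts concordant, discordant and tied pairs over all n(n-1)/2 pairs and
#' applies the tie-corrected form
#' \deqn{\tau_b = (C - D) / \sqrt{(C + D + T_x)(C + D + T_y)},}
#' where `Tx`/`Ty` count pairs tied in only one of the vectors. Profiles
#' here have as many entries as time points, so the quadratic enumeration
#' is exact and cheap. With `tie_correction = FALSE` the plain tau-a
#' denominator n(n-1)/2 is used.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param tie_correction Use the tau-b denominator (default `TRUE`).
#' @return Tau in \[-1, 1\], or `NA` with a warning when either vector is
#'   fully tied (undefined correlation).
#' @export
kendall_tau <- function(x, y, tie_correction = TRUE) {
  n <- length(x)
  if (length(y) != n) abort("`x` and `y` must have equal length.")
  if (n < 3) abort("Need at least 3 observations.")
  conc <- 0L; disc <- 0L; tx_only <- 0L; ty_only <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[j] - x[i])
      dy <- sign(y[j] - y[i])
      if (dx == 0 && dy == 0) next
      if (dx == 0) tx_only <- tx_only + 1L
      else if (dy == 0) ty_only <- ty_only + 1L
      else if (dx == dy) conc <- conc + 1L
      else disc <- disc + 1L
    }
  }
  if (tie_correction) {
    denom <- sqrt((conc + disc + tx_only) * (conc + disc + ty_only))
  } else {
    denom <- n * (n - 1) / 2
  }
  if (denom == 0) {
    warn("All-tied vector: Kendall correlation is undefined.")
    return(NA_real_)
  }
  (conc - disc) / denom
}

#' Annotate candidate interactions with per-pair Kendall correlation
#'
#' Joins each (miRNA, gene) record with the day-mean profiles of its two
#' partners — which must live on the same day grid — and computes tau-b.
#' Records with a missing partner profile or an undefined correlation are
#' dropped, with an informational message of the count.
#'
#' @param table Merged interaction tibble.
#' @param mirna_profiles,mrna_profiles Long day-mean profile tibbles
#'   ([day_mean_profiles()]) from the miRNA and mRNA studies of the same
#'   experiment.
#' @return Tibble with the table's columns plus `tau` and `n_days`.
#' @export
annotate_correlations <- function(table, mirna_profiles, mrna_profiles) {
  mirna_days <- sort(unique(mirna_profiles$day))
  mrna_days <- sort(unique(mrna_profiles$day))
  if (!identical(mirna_days, mrna_days)) {
    abort("miRNA and mRNA studies are on different day grids.")
  }
  profile_list <- function(profiles) {
    profiles %>%
      dplyr::arrange(.data$feature_id, .data$day) %>%
      dplyr::summarise(values = list(.data$value), .by = "feature_id")
  }
  mir <- profile_list(mirna_profiles)
  gen <- profile_list(mrna_profiles)
  n_in <- nrow(table)
  out <- table %>%
    dplyr::inner_join(dplyr::rename(mir, mirna_values = "values"),
      by = c(mirna_id = "feature_id")) %>%
    dplyr::inner_join(dplyr::rename(gen, gene_values = "values"),
      by = c(gene_id = "feature_id")) %>%
    dplyr::mutate(
      tau = suppressWarnings(purrr::map2_dbl(
        .data$mirna_values, .data$gene_values, kendall_tau
      )),
      n_days = length(mirna_days)
    ) %>%
    dplyr::select(-"mirna_values", -"gene_values") %>%
    dplyr::filter(!is.na(.data$tau))
  n_skip <- n_in - nrow(out)
  if (n_skip > 0) {
    inform(sprintf(
      "Skipped %d interaction(s) without computable profiles.", n_skip
    ))
  }
  out
}

#' Keep anti-correlated interactions
#'
#' Retains interactions whose tau lies strictly below `tau_max`
#' (default -0.2): effective miRNA repression should show as diminished
#' target levels when the miRNA is high.
#'
#' @param table Tibble with a `tau` column ([annotate_correlations()]).
#' @param tau_max Strict upper bound on tau (default -0.2).
#' @return The filtered tibble.
#' @export
filter_anticorrelated <- function(table, tau_max = -0.2) {
  # grid-valued tau: boundary equality is excluded up to fp error (see
  # select_conserved)
  dplyr::filter(table, .data$tau - tau_max < -1e-8)
}
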