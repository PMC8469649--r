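#' Read an expression matrix, sample sheet, or probe map from TSV
#'
#' Expression TSVs carry a `feature_id` first column and one log2-scale
#' column per sample; sample sheets carry `sample_id`, `day`, `replicate`;
#' probe maps carry `probe_id`, `feature_id`.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_expression_tsv <- function(path) {
  expr <- readr::read_tsv(path, show_col_types = FALSE)
  names(expr)[1] <- "feature_id"
  assert_expression(expr)
  expr
}

#' @rdname read_expression_tsv
#' @export
read_sample_sheet <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      day = readr::col_double(),
      replicate = readr::col_integer()
    )
  )
}

#' @rdname read_expression_tsv
#' @export
read_probe_map <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
}

# Features x days matrix of per-day replicate means.
day_mean_matrix <- function(expr, samples) {
  m <- expr_matrix(expr, samples)
  days <- sort(unique(samples$day))
  out <- vapply(days, function(d) {
    cols <- samples$sample_id[samples$day == d]
    rowMeans(m[, cols, drop = FALSE])
  }, numeric(nrow(m)))
  out <- matrix(out, nrow = nrow(m), dimnames = list(expr$feature_id, days))
  out
}

#' Keep features expressed above a detection floor
#'
#' A feature is considered expressed when its day-mean log2 intensity
#' strictly exceeds `floor` at one or more time points; everything else is
#' removed. The boundary value itself (a day mean exactly equal to the
#' floor) does not count. Row order is preserved, and an empty result is a
#' warning, not an error, so batch runs keep going.
#'
#' @param expr Wide expression table.
#' @param samples Sample sheet.
#' @param floor Log2 detection floor (default 5).
#' @return The filtered expression tibble.
#' @export
filter_expressed <- function(expr, samples, floor = 5) {
  assert_expression(expr)
  assert_samples(expr, samples)
  dm <- day_mean_matrix(expr, samples)
  keep <- apply(dm, 1, max) > floor
  if (!any(keep)) {
    warn("No features exceed the expression floor; returning an empty table.")
  }
  expr[keep, , drop = FALSE]
}

#' Collapse probe-level rows to one row per mapped feature
#'
#' For each feature the representative probe is the one with the highest
#' mean log2 intensity across all samples (ties broken by probe id);
#' unmapped probes are dropped.
#'
#' @param expr Wide probe-level expression table (`feature_id` column holds
#'   probe ids).
#' @param probe_map Tibble with columns `probe_id`, `feature_id`.
#' @return Feature-level expression tibble.
#' @export
collapse_probes <- function(expr, probe_map) {
  assert_expression(expr)
  if (missing(probe_map) || is.null(probe_map)) {
    abort("`probe_map` is required to collapse probes.")
  }
  if (!all(c("probe_id", "feature_id") %in% names(probe_map))) {
    abort("`probe_map` must have columns probe_id and feature_id.")
  }
  value_cols <- setdiff(names(expr), "feature_id")
  expr %>%
    dplyr::rename(probe_id = "feature_id") %>%
    dplyr::inner_join(probe_map, by = "probe_id") %>%
    dplyr::mutate(.overall = rowMeans(dplyr::pick(dplyr::all_of(value_cols)))) %>%
    dplyr::arrange(dplyr::desc(.data$.overall), .data$probe_id) %>%
    dplyr::distinct(.data$feature_id, .keep_all = TRUE) %>%
    dplyr::arrange(.data$feature_id) %>%
    dplyr::select("feature_id", dplyr::all_of(value_cols))
}

#' Per-day mean expression profiles
#'
#' Averages replicate log2 values within each day. All downstream
#' correlations (peak templates, Kendall screening) operate on these
#' day-mean profiles, whose length equals the number of time points.
#'
#' @param expr Wide expression table.
#' @param samples Sample sheet.
#' @param features Optional feature subset.
#' @return Long tibble `feature_id`, `day`, `value`, days ascending.
#' @export
day_mean_profiles <- function(expr, samples, features = NULL) {
  assert_expression(expr)
  assert_samples(expr, samples)
  if (!is.null(features)) {
    missing <- setdiff(features, expr$feature_id)
    if (length(missing) > 0) {
      abort(sprintf("Unknown feature(s): %s", paste(missing, collapse = ", ")))
    }
    expr <- expr[expr$feature_id %in% features, , drop = FALSE]
  }
  dm <- day_mean_matrix(expr, samples)
  tibble::tibble(
    feature_id = rep(rownames(dm), times = ncol(dm)),
    day = rep(as.numeric(colnames(dm)), each = nrow(dm)),
    value = as.vector(dm)
  ) %>% dplyr::arrange(.data$feature_id, .data$day)
}

#' Min-Max normalise profiles to the unit interval
#'
#' Each feature's profile is linearly rescaled to `(x - min) / (max - min)`,
#' so its minimum maps to 0 and its maximum to 1. Constant profiles cannot
#' be rescaled and map to all zeros (with a warning), rather than aborting a
#' batch: constant features legitimately survive the expression filter.
#'
#' @param profiles Long profile tibble from [day_mean_profiles()].
#' @return The same tibble with `value` rescaled per feature.
#' @export
minmax_normalize <- function(profiles) {
  if (!all(c("feature_id", "value") %in% names(profiles))) {
    abort("`profiles` must have feature_id and value columns.")
  }
  out <- profiles %>%
    dplyr::group_by(.data$feature_id) %>%
    dplyr::mutate(
      .range = max(.data$value) - min(.data$value),
      value = dplyr::if_else(
        .data$.range > 0,
        (.data$value - min(.data$value)) / .data$.range,
        0
      )
    ) %>%
    dplyr::ungroup()
  n_const <- out %>%
    dplyr::filter(.data$.range == 0) %>%
    dplyr::distinct(.data$feature_id) %>%
    nrow()
  if (n_const > 0) {
    warn(sprintf(
      "%d constant profile(s) mapped to all-zeros by Min-Max normalisation.",
      n_const
    ))
  }
  dplyr::select(out, -".range")
}

#' Log2 fold changes of day means against a reference day
#'
#' On the log2 scale the fold change is a difference of day means; the
#' reference day's column is identically zero.
#'
#' @param expr Wide expression table.
#' @param samples Sample sheet.
#' @param reference_day Day label used as baseline (default: earliest day).
#' @return Long tibble `feature_id`, `day`, `log2fc`.
#' @export
log2_fold_changes <- function(expr, samples, reference_day = NULL) {
  assert_expression(expr)
  assert_samples(expr, samples)
  days <- sort(unique(samples$day))
  if (is.null(reference_day)) reference_day <- days[1]
  if (!reference_day %in% days) {
    abort(sprintf("Reference day %s is not present in the sample sheet.",
      format(reference_day)))
  }
  dm <- day_mean_matrix(expr, samples)
  ref <- dm[, as.character(reference_day)]
  lfc <- dm - ref
  tibble::tibble(
    feature_id = rep(rownames(lfc), times = ncol(lfc)),
    day = rep(as.numeric(colnames(lfc)), each = nrow(lfc)),
    log2fc = as.vector(lfc)
  ) %>% dplyr::arrange(.data$feature_id, .data$day)
}
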