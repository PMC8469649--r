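#' @importFrom rlang abort warn inform .data %||%
#' @importFrom dplyr %>%
NULL

# Wide expression table contract: first column `feature_id`, one numeric
# column per sample, values on the log2 scale.
assert_expression <- function(expr, arg = "expr") {
  if (!is.data.frame(expr) || !"feature_id" %in% names(expr)) {
    abort(sprintf("`%s` must be a data frame with a `feature_id` column.", arg))
  }
  if (anyDuplicated(expr$feature_id)) {
    abort(sprintf("`%s` has duplicated feature_ids.", arg))
  }
  invisible(expr)
}

assert_samples <- function(expr, samples) {
  need <- c("sample_id", "day", "replicate")
  if (!is.data.frame(samples) || !all(need %in% names(samples))) {
    abort("`samples` must have columns sample_id, day and replicate.")
  }
  missing <- setdiff(samples$sample_id, names(expr))
  if (length(missing) > 0) {
    abort(sprintf(
      "Samples absent from the expression table: %s",
      paste(utils::head(missing, 5), collapse = ", ")
    ))
  }
  invisible(samples)
}

expr_matrix <- function(expr, samples) {
  m <- as.matrix(expr[, samples$sample_id, drop = FALSE])
  rownames(m) <- expr$feature_id
  m
}

#' Pivot a wide expression table to one row per measurement
#'
#' @param expr Wide expression table (`feature_id` plus one column per sample,
#'   log2 scale).
#' @param samples Sample sheet with `sample_id`, `day`, `replicate`.
#' @return A tibble with columns `feature_id`, `sample_id`, `day`,
#'   `replicate`, `value`.
#' @export
expression_long <- function(expr, samples) {
  assert_expression(expr)
  assert_samples(expr, samples)
  expr %>%
    dplyr::select("feature_id", dplyr::all_of(samples$sample_id)) %>%
    tidyr::pivot_longer(-"feature_id",
      names_to = "sample_id", values_to = "value"
    ) %>%
    dplyr::inner_join(
      dplyr::select(samples, "sample_id", "day", "replicate"),
      by = "sample_id"
    ) %>%
    dplyr::select("feature_id", "sample_id", "day", "replicate", "value") %>%
    dplyr::arrange(.data$feature_id, .data$day, .data$replicate)
}
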