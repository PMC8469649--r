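#' One-hot peak template for a time point
#'
#' The binary template against which profiles are cross-correlated: 1 at
#' the given time-point position, 0 at the others. For a five-day series
#' the first-day template is `(1,0,0,0,0)` and the second-day template is
#' `(0,1,0,0,0)`.
#'
#' @param day_index Position of the peak day (1-based).
#' @param n_days Number of time points (>= 3).
#' @return Numeric 0/1 vector of length `n_days`.
#' @export
one_hot_vector <- function(day_index, n_days) {
  if (n_days < 3) abort("`n_days` must be >= 3.")
  if (day_index < 1 || day_index > n_days) {
    abort(sprintf("`day_index` must be in 1..%d.", n_days))
  }
  v <- numeric(n_days)
  v[day_index] <- 1
  v
}

#' Pearson correlation of a profile with a one-hot peak template
#'
#' A profile scores close to 1 when it is high at the template's day and at
#' a common baseline elsewhere; the score is invariant to positive affine
#' transforms of the profile. Constant profiles have no defined correlation
#' and yield `NA` with a warning.
#'
#' @param profile Numeric day-mean profile.
#' @param day_index Template peak position (1-based).
#' @return Pearson r in \[-1, 1\], or `NA` for a constant profile.
#' @export
peak_correlation <- function(profile, day_index) {
  template <- one_hot_vector(day_index, length(profile))
  if (stats::sd(profile) == 0) {
    warn("Constant profile: peak correlation is undefined.")
    return(NA_real_)
  }
  stats::cor(profile, template)
}

#' Call single-day expression peaks by one-hot cross-correlation
#'
#' For every feature, the profile is correlated with each day's one-hot
#' template. A peak is called when the best correlation reaches `r_min`;
#' the peak day is the argmax (ties resolved to the earliest day, with a
#' message). Each feature receives at most one peak day. Constant profiles
#' are skipped with a warning.
#'
#' The input may be day-mean profiles ([day_mean_profiles()]; templates of
#' length = number of days, the default analysis level) or replicate-level
#' values ([expression_long()]), in which case each day's template value is
#' repeated across that day's replicates.
#'
#' @param profiles Long tibble with `feature_id`, `day`, `value` (one or
#'   more rows per feature-day).
#' @param r_min Minimum Pearson correlation for a call (default 0.6).
#' @return Tibble of class `peak_calls`: `mirna_id`, `peak_day`, `r_peak`,
#'   plus one `r_<day>` column per day.
#' @export
call_peaks <- function(profiles, r_min = 0.6) {
  if (!all(c("feature_id", "day", "value") %in% names(profiles))) {
    abort("`profiles` must have feature_id, day and value columns.")
  }
  days <- sort(unique(profiles$day))
  n_days <- length(days)
  if (n_days < 3) abort("Need at least 3 distinct days to call peaks.")

  per_feature <- profiles %>%
    dplyr::arrange(.data$feature_id, .data$day) %>%
    dplyr::group_by(.data$feature_id) %>%
    dplyr::group_map(function(rows, key) {
      x <- rows$value
      if (stats::sd(x) == 0) {
        return(tibble::tibble(mirna_id = key$feature_id, constant = TRUE))
      }
      r <- vapply(seq_len(n_days), function(i) {
        template <- as.numeric(rows$day == days[i])
        stats::cor(x, template)
      }, numeric(1))
      best <- which.max(r) # which.max takes the first (earliest) maximum
      tibble::tibble(
        mirna_id = key$feature_id,
        constant = FALSE,
        peak_day = days[best],
        r_peak = r[best],
        tied = sum(r == r[best]) > 1,
        r_all = list(stats::setNames(r, paste0("r_", days)))
      )
    }) %>%
    dplyr::bind_rows()

  n_const <- sum(per_feature$constant)
  if (n_const > 0) {
    warn(sprintf("Skipped %d constant profile(s) when calling peaks.", n_const))
  }
  calls <- per_feature %>% dplyr::filter(!.data$constant)
  if (nrow(calls) > 0) {
    n_tied <- sum(calls$tied & calls$r_peak >= r_min)
    if (n_tied > 0) {
      inform(sprintf(
        "%d peak call(s) had tied correlations; earliest day kept.", n_tied
      ))
    }
    calls <- calls %>%
      dplyr::filter(.data$r_peak >= r_min) %>%
      dplyr::select("mirna_id", "peak_day", "r_peak", "r_all") %>%
      tidyr::unnest_wider("r_all")
  }
  if (nrow(calls) == 0) {
    calls <- tibble::tibble(
      mirna_id = character(), peak_day = numeric(), r_peak = numeric()
    )
  }
  calls <- dplyr::arrange(calls, .data$peak_day, dplyr::desc(.data$r_peak),
    .data$mirna_id)
  class(calls) <- c("peak_calls", class(calls))
  attr(calls, "days") <- days
  attr(calls, "r_min") <- r_min
  calls
}

#' Select the strongest peak calls per day
#'
#' Per peak day, ranks calls by decreasing correlation (ties broken by
#' miRNA id) and keeps at most `k`, mirroring the per-day candidate
#' selection used before functional analysis of peak-miRNA targets.
#'
#' @param calls A [call_peaks()] result.
#' @param k Maximum calls kept per day (default 10).
#' @return Tibble `peak_day`, `mirna_id`, `r_peak`, `rank`.
#' @export
top_k_by_day <- function(calls, k = 10) {
  calls %>%
    tibble::as_tibble() %>%
    dplyr::select("peak_day", "mirna_id", "r_peak") %>%
    dplyr::arrange(.data$peak_day, dplyr::desc(.data$r_peak), .data$mirna_id) %>%
    dplyr::group_by(.data$peak_day) %>%
    dplyr::mutate(rank = dplyr::row_number()) %>%
    dplyr::filter(.data$rank <= k) %>%
    dplyr::ungroup()
}
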