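#' Moderated two-sample t-statistic
#'
#' Empirical-Bayes two-sample t with a shrunken variance: the residual
#' variance of each feature is pulled towards a prior value `s0²` with
#' weight `d0` prior degrees of freedom,
#' \deqn{\tilde{s}^2 = (d_0 s_0^2 + d s^2) / (d_0 + d),}
#' and the statistic \eqn{t = \Delta\bar{x} / (\tilde{s}\sqrt{1/n_a + 1/n_b})}
#' is referred to a t distribution with \eqn{d + d_0} degrees of freedom.
#' With `prior_df = 0` this reduces exactly to the ordinary pooled-variance
#' two-sample t; with infinite `prior_df` the variance is fixed at `s0²` and
#' the reference distribution is normal.
#'
#' @param group_a,group_b Numeric replicate vectors (log2 scale), each of
#'   length >= 2.
#' @param prior_df Prior degrees of freedom `d0` (>= 0, may be `Inf`).
#' @param prior_var Prior variance `s0²`; required when `prior_df > 0`.
#' @return A list with `t_mod`, `df_total`, `p_raw` (two-sided).
#' @export
moderated_t <- function(group_a, group_b, prior_df = 0, prior_var = NULL) {
  na <- length(group_a)
  nb <- length(group_b)
  if (na < 2 || nb < 2) abort("Both groups need at least two replicates.")
  if (prior_df < 0) abort("`prior_df` must be >= 0.")
  if (prior_df > 0 && is.null(prior_var)) {
    abort("`prior_var` is required when `prior_df` > 0.")
  }
  d <- na + nb - 2
  s2 <- (sum((group_a - mean(group_a))^2) + sum((group_b - mean(group_b))^2)) / d
  res <- moderated_t_stat(
    mean_diff = mean(group_a) - mean(group_b),
    s2 = s2, na = na, nb = nb,
    d0 = prior_df, s0_sq = if (is.null(prior_var)) 0 else prior_var
  )
  if (!is.finite(res$t_mod) && prior_df == 0 && s2 == 0) {
    abort("Zero pooled variance with no prior: the statistic is undefined.")
  }
  res
}

# Vectorised core shared by moderated_t() and diff_expression().
moderated_t_stat <- function(mean_diff, s2, na, nb, d0, s0_sq) {
  d <- na + nb - 2
  if (is.infinite(d0)) {
    s2_post <- rep_len(s0_sq, length(s2))
    df_total <- Inf
  } else {
    s2_post <- (d0 * s0_sq + d * s2) / (d0 + d)
    df_total <- d + d0
  }
  t_mod <- mean_diff / sqrt(s2_post * (1 / na + 1 / nb))
  p_raw <- 2 * stats::pt(-abs(t_mod), df = df_total)
  list(t_mod = t_mod, df_total = df_total, p_raw = p_raw)
}

# Newton solve of trigamma(x) = y, used by the moment estimator.
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

#' Estimate empirical-Bayes variance hyperparameters
#'
#' Method-of-moments fit on the log sample variances: for residual
#' variances distributed as \eqn{s^2 \sim s_0^2 \chi^2_d/d} scaled by a
#' scaled-inverse-chi-squared prior with `d0` degrees of freedom, the
#' excess variance of `log(s²)` over `trigamma(d/2)` identifies `d0`
#' through the trigamma function, and the mean identifies `s0²`. When the
#' observed log-variances are no more dispersed than sampling alone
#' explains, `d0` is flagged infinite and `s0²` is the geometric mean of
#' the variances (equal to the common value in the degenerate all-equal
#' case).
#'
#' @param sample_variances Per-feature residual variances (>= 10 positive
#'   values required).
#' @param residual_df Residual degrees of freedom `d` shared by features.
#' @return A list with `d0` (possibly `Inf`) and `s0_sq`.
#' @export
estimate_prior <- function(sample_variances, residual_df) {
  v <- sample_variances[is.finite(sample_variances) & sample_variances > 0]
  if (length(v) < 10) {
    abort("Need at least 10 features with positive variance to estimate the prior.")
  }
  z <- log(v)
  e <- z - digamma(residual_df / 2) + log(residual_df / 2)
  emean <- mean(e)
  if (stats::var(z) < 1e-12) {
    # literally identical variances: no sampling scatter to correct for
    return(list(d0 = Inf, s0_sq = exp(mean(z))))
  }
  evar <- stats::var(e) - trigamma(residual_df / 2)
  if (evar <= 0) {
    # scatter fully explained by chi-squared sampling of one common variance;
    # exp(emean) is the bias-corrected estimate of that variance on the log
    # scale (E[log s2] = log sigma2 + digamma(d/2) - log(d/2))
    return(list(d0 = Inf, s0_sq = exp(emean)))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Sorts the raw p-values ascending, takes
#' `adj_(i) = min_(j >= i) p_(j) * m / j` capped at 1, and returns the
#' adjusted values in input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric())
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    abort("All p-values must lie in [0, 1].")
  }
  m <- length(p_values)
  o <- order(p_values, decreasing = TRUE)
  adj <- pmin(1, cummin(m / (m:1) * p_values[o]))
  adj[order(o)]
}

#' Flag differentially expressed features
#'
#' A feature-day result is differentially expressed when its adjusted
#' p-value falls below `alpha` and its absolute log2 fold change exceeds
#' `lfc_min`. With `strict = TRUE` (the default) both comparisons are
#' strict, so boundary values do not qualify.
#'
#' @param results Tibble with at least `p_adj` and `log2fc` columns.
#' @param alpha Adjusted-p threshold (default 1e-5).
#' @param lfc_min Absolute log2 fold-change threshold (default 2).
#' @param strict Use strict (`<`, `>`) rather than non-strict comparisons.
#' @return `results` with an `is_de` logical column.
#' @export
call_de <- function(results, alpha = 1e-5, lfc_min = 2, strict = TRUE) {
  if (strict) {
    dplyr::mutate(results,
      is_de = .data$p_adj < alpha & abs(.data$log2fc) > lfc_min
    )
  } else {
    dplyr::mutate(results,
      is_de = .data$p_adj <= alpha & abs(.data$log2fc) >= lfc_min
    )
  }
}

#' Differential expression against a reference day
#'
#' Fits, for every feature and every non-reference day, the moderated
#' two-sample t contrast of that day's replicates against the reference
#' day's replicates. The variance prior is estimated per contrast from all
#' features' pooled residual variances ([estimate_prior()]), p-values are
#' Benjamini-Hochberg adjusted within each contrast, and features are
#' flagged by the joint adjusted-p / fold-change rule of [call_de()].
#'
#' @param expr Wide expression table.
#' @param samples Sample sheet.
#' @param reference_day Baseline day (default: earliest).
#' @param alpha,lfc_min,strict Passed to [call_de()].
#' @param moderate Set `FALSE` for ordinary pooled t (prior df 0).
#' @return A tibble of class `de_result` with columns `feature_id`, `day`,
#'   `log2fc`, `t_mod`, `p_raw`, `p_adj`, `is_de`.
#' @export
diff_expression <- function(expr, samples, reference_day = NULL,
                            alpha = 1e-5, lfc_min = 2, strict = TRUE,
                            moderate = TRUE) {
  assert_expression(expr)
  assert_samples(expr, samples)
  days <- sort(unique(samples$day))
  if (is.null(reference_day)) reference_day <- days[1]
  if (!reference_day %in% days) {
    abort(sprintf("Reference day %s not present in the sample sheet.",
      format(reference_day)))
  }
  m <- expr_matrix(expr, samples)
  ref_cols <- samples$sample_id[samples$day == reference_day]
  if (length(ref_cols) < 2) abort("Reference day needs >= 2 replicates.")
  ref <- m[, ref_cols, drop = FALSE]
  ref_mean <- rowMeans(ref)
  ref_ss <- rowSums((ref - ref_mean)^2)

  out <- purrr::map(setdiff(days, reference_day), function(d) {
    cols <- samples$sample_id[samples$day == d]
    if (length(cols) < 2) abort(sprintf("Day %s needs >= 2 replicates.", format(d)))
    grp <- m[, cols, drop = FALSE]
    grp_mean <- rowMeans(grp)
    na <- length(cols)
    nb <- length(ref_cols)
    df <- na + nb - 2
    s2 <- (rowSums((grp - grp_mean)^2) + ref_ss) / df
    if (moderate && sum(s2 > 0) >= 10) {
      prior <- estimate_prior(s2, df)
    } else {
      prior <- list(d0 = 0, s0_sq = 0)
    }
    stat <- moderated_t_stat(grp_mean - ref_mean, s2, na, nb,
      prior$d0, prior$s0_sq)
    t_mod <- stat$t_mod
    p_raw <- stat$p_raw
    # exactly replicated values (e.g. noiseless fixtures): the contrast is
    # deterministic, so a zero difference is a sure null and a non-zero
    # difference a sure call
    degenerate <- is.nan(t_mod)
    t_mod[degenerate] <- 0
    p_raw[degenerate] <- 1
    tibble::tibble(
      feature_id = expr$feature_id,
      day = d,
      log2fc = grp_mean - ref_mean,
      t_mod = t_mod,
      p_raw = p_raw,
      p_adj = bh_adjust(p_raw)
    )
  }) %>% dplyr::bind_rows()
  out <- call_de(out, alpha = alpha, lfc_min = lfc_min, strict = strict)
  class(out) <- c("de_result", class(out))
  attr(out, "reference_day") <- reference_day
  out
}
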