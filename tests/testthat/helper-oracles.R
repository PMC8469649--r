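# Independent brute-force oracles and tiny fixture builders shared by the
# suite. Oracles deliberately use different code paths than the package.

# Pearson by raw sum formula.
pearson_sums <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Kendall tau-b from explicit pair sign matrices.
kendall_brute <- function(x, y) {
  n <- length(x)
  sx <- sign(outer(x, x, "-"))
  sy <- sign(outer(y, y, "-"))
  up <- upper.tri(sx)
  conc <- sum(sx[up] * sy[up] > 0)
  disc <- sum(sx[up] * sy[up] < 0)
  tx_only <- sum(sx[up] == 0 & sy[up] != 0)
  ty_only <- sum(sy[up] == 0 & sx[up] != 0)
  den <- sqrt((conc + disc + tx_only) * (conc + disc + ty_only))
  if (den == 0) return(NA_real_)
  (conc - disc) / den
}

# Upper-tail hypergeometric by summing density terms from stats::dhyper.
hyper_enum <- function(k, K, n, N) {
  sum(stats::dhyper(k:min(K, n), K, N - K, n))
}

# Ordinary pooled two-sample t with its two-sided p.
pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * stats::pt(-abs(t), na + nb - 2))
}

# Wide expression table from a day-mean profile matrix (features x days),
# each day value repeated over `reps` replicates, plus optional noise.
make_study <- function(profiles, days, reps = 2, noise_sd = 0, prefix = "s") {
  if (is.null(rownames(profiles))) {
    rownames(profiles) <- sprintf("f%02d", seq_len(nrow(profiles)))
  }
  samples <- tidyr::expand_grid(day = days, replicate = seq_len(reps)) |>
    dplyr::mutate(sample_id = sprintf("%s_d%g_r%d", prefix, day, replicate)) |>
    dplyr::select(sample_id, day, replicate)
  values <- profiles[, rep(seq_along(days), each = reps), drop = FALSE]
  if (noise_sd > 0) values <- values + stats::rnorm(length(values), sd = noise_sd)
  colnames(values) <- samples$sample_id
  list(
    expr = dplyr::bind_cols(
      tibble::tibble(feature_id = rownames(profiles)),
      tibble::as_tibble(values)
    ),
    samples = samples
  )
}

# Small three-level ontology: root <- parent <- child, with direct
# annotation sets given as a named list.
chain_dag <- function(child_genes, parent_genes = character(),
                      root_genes = character()) {
  switchmir::ontology_dag(
    edges = tibble::tibble(
      child = c("child", "parent"),
      parent = c("parent", "root")
    ),
    annotations = dplyr::bind_rows(
      tibble::tibble(gene_id = child_genes, term_id = "child"),
      tibble::tibble(gene_id = parent_genes, term_id = "parent"),
      tibble::tibble(gene_id = root_genes, term_id = "root")
    )
  )
}
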