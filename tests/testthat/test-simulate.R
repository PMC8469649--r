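test_that("identical configs give identical studies and truth", {
  cfg <- simulation_config(n_genes = 40, n_mirnas = 20,
    n_true_interactions = 5, n_decoy_interactions = 10, seed = 42)
  a <- simulate_study_pair(cfg)
  b <- simulate_study_pair(cfg)
  expect_identical(a$vitro_mrna, b$vitro_mrna)
  expect_identical(a$vivo_mirna, b$vivo_mirna)
  expect_identical(a$truth, b$truth)
  ra <- simulate_resources(a$truth, cfg)
  rb <- simulate_resources(b$truth, cfg)
  expect_identical(ra, rb)
})

test_that("noiseless construction plants exact peaks and tau = -1 interactions", {
  cfg <- simulation_config(n_genes = 40, n_mirnas = 30, noise_sd = 0,
    peak_amplitude = 4, frac_peaked_mirnas = 0.1,
    n_true_interactions = 6, frac_conserved = 1,
    n_decoy_interactions = 0, seed = 3)
  sim <- simulate_study_pair(cfg)
  prof <- day_mean_profiles(sim$vitro_mirna$expr, sim$vitro_mirna$samples)

  # peaked miRNA: peak day exceeds every other day by exactly the amplitude
  pk <- sim$truth$peaked_mirnas[1, ]
  p <- dplyr::filter(prof, feature_id == pk$mirna_id)
  at_peak <- p$value[p$day == pk$peak_day_vitro]
  expect_equal(at_peak - max(p$value[p$day != pk$peak_day_vitro]), 4)
  expect_equal(length(unique(p$value[p$day != pk$peak_day_vitro])), 1)

  # every planted repressive pair is perfectly anti-monotone on day means
  gene_prof <- day_mean_profiles(sim$vitro_mrna$expr, sim$vitro_mrna$samples)
  for (i in seq_len(nrow(sim$truth$true_interactions))) {
    row <- sim$truth$true_interactions[i, ]
    x <- dplyr::filter(prof, feature_id == row$mirna_id)$value
    y <- dplyr::filter(gene_prof, feature_id == row$gene_id)$value
    expect_equal(kendall_tau(x, y), -1)
  }
})

test_that("truth bookkeeping holds: disjoint decoys, conserved identity, presence", {
  cfg <- simulation_config(n_genes = 100, n_mirnas = 40,
    n_true_interactions = 20, frac_conserved = 0.5,
    n_decoy_interactions = 50, seed = 11)
  sim <- simulate_study_pair(cfg)
  tr <- sim$truth
  true_keys <- paste(tr$true_interactions$mirna_id, tr$true_interactions$gene_id)
  decoy_keys <- paste(tr$decoy_interactions$mirna_id, tr$decoy_interactions$gene_id)
  expect_length(intersect(true_keys, decoy_keys), 0)
  expect_false(anyDuplicated(decoy_keys) > 0)
  expect_true(all(tr$peaked_mirnas$mirna_id %in% sim$vitro_mirna$expr$feature_id))
  expect_true(all(tr$peaked_mirnas$mirna_id %in% sim$vivo_mirna$expr$feature_id))
  expect_true(all(tr$true_interactions$membership %in% c("vitro", "vivo", "both")))
  # sample sheets: every day has the configured number of replicates
  tab <- table(sim$vitro_mrna$samples$day)
  expect_true(all(tab == cfg$n_replicates))
})

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(simulation_config(n_genes = -1), "n_genes")
  expect_error(simulation_config(frac_conserved = 1.5), "frac_conserved")
  expect_error(simulation_config(noise_sd = -0.1), "noise_sd")
  expect_error(simulation_config(baseline_range = c(5, 5)), "baseline_range")
  expect_error(simulation_config(days_vitro = c(0, 4)), "days_vitro")
  expect_error(simulation_config(days_vivo = c(0, 4, 2)), "days_vivo")
})

test_that("resource coverage extremes and determinism behave as specified", {
  cfg1 <- simulation_config(n_genes = 50, n_mirnas = 20,
    n_true_interactions = 10, n_decoy_interactions = 20,
    resource_coverage = 1, n_resources = 3, seed = 5)
  sim <- simulate_study_pair(cfg1)
  res <- simulate_resources(sim$truth, cfg1)
  expect_length(res, 3)
  for (tab in res) expect_equal(nrow(tab), 30)
  expect_true(all(res[[1]]$evidence == "predicted"))
  expect_true(all(res[[3]]$evidence == "experimental"))

  cfg0 <- simulation_config(n_genes = 50, n_mirnas = 20,
    n_true_interactions = 10, n_decoy_interactions = 20,
    resource_coverage = 0, n_resources = 3, seed = 5)
  res0 <- simulate_resources(sim$truth, cfg0)
  for (tab in res0) expect_equal(nrow(tab), 0)

  cfg_half <- simulation_config(n_genes = 500, n_mirnas = 50,
    n_true_interactions = 100, n_decoy_interactions = 400,
    resource_coverage = 0.5, n_resources = 2, seed = 9)
  sim2 <- simulate_study_pair(cfg_half)
  draw1 <- simulate_resources(sim2$truth, cfg_half)
  draw2 <- simulate_resources(sim2$truth, cfg_half) # independent re-draw oracle
  expect_identical(purrr::map_int(draw1, nrow), purrr::map_int(draw2, nrow))
  # coverage 0.5 over 500 candidates: counts near 250 in each resource
  expect_true(all(abs(purrr::map_int(draw1, nrow) - 250) < 60))
})

test_that("simulated ontology is a single-rooted DAG with the heart term exact", {
  cfg <- simulation_config(n_genes = 80, n_mirnas = 20,
    n_true_interactions = 10, n_decoy_interactions = 0, seed = 2)
  sim <- simulate_study_pair(cfg)

  bare <- simulate_ontology(sim$truth, n_filler_terms = 0, seed = 1)
  expect_setequal(bare$terms, c("term_root", "term_heart"))

  dag <- simulate_ontology(sim$truth, n_filler_terms = 25, seed = 1)
  expect_silent(propagate_annotations(dag)) # topological sort succeeds
  heart <- dag$annotations$gene_id[dag$annotations$term_id == "term_heart"]
  expect_setequal(heart, sim$truth$cardiac_genes)
  # single root: only term_root has no parent
  has_parent <- unique(dag$edges$child)
  expect_setequal(setdiff(dag$terms, has_parent), "term_root")
})

test_that("fixture files round-trip and are byte-stable under the same seed", {
  cfg <- simulation_config(n_genes = 30, n_mirnas = 12,
    n_true_interactions = 4, n_decoy_interactions = 6, seed = 21)
  sim <- simulate_study_pair(cfg)
  res <- simulate_resources(sim$truth, cfg)
  ont <- simulate_ontology(sim$truth, n_filler_terms = 5, seed = 21)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fixture_set(sim, res, ont, d1)
  write_fixture_set(sim, res, ont, d2)
  files <- list.files(d1)
  expect_true(length(files) >= 12)
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
      unname(tools::md5sum(file.path(d2, f))))
  }
  back <- read_expression_tsv(file.path(d1, "vitro_mrna_expr.tsv"))
  expect_equal(back$feature_id, sim$vitro_mrna$expr$feature_id)
  expect_equal(as.data.frame(back), as.data.frame(sim$vitro_mrna$expr),
    tolerance = 1e-12)
})
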