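res_tab <- function(pairs, resource, evidence = "predicted") {
  tibble::tibble(
    mirna_id = pairs[, 1], gene_id = pairs[, 2],
    evidence = evidence, resource = resource
  )
}

test_that("kendall tau-b matches hand counts and the brute-force oracle", {
  expect_equal(kendall_tau(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(kendall_tau(1:4, c(1, 3, 2, 4)), 2 / 3)
  expect_equal(kendall_tau(c(1, 1, 2), c(1, 2, 3)), 2 / sqrt(6))
  expect_warning(expect_true(is.na(kendall_tau(c(2, 2, 2), c(1, 2, 3)))),
    "All-tied")
  expect_error(kendall_tau(1:3, 1:4), "equal length")
  expect_error(kendall_tau(1:2, 1:2), "at least 3")

  # tau-a option: plain n(n-1)/2 denominator
  expect_equal(kendall_tau(c(1, 1, 2), c(1, 2, 3), tie_correction = FALSE), 2 / 3)

  withr::with_seed(71, {
    for (i in 1:200) {
      n <- sample(3:8, 1)
      x <- sample(1:4, n, replace = TRUE) # frequent ties
      y <- sample(1:4, n, replace = TRUE)
      got <- suppressWarnings(kendall_tau(x, y))
      expect_identical(got, kendall_brute(x, y))
      if (!is.na(got)) {
        expect_equal(got, suppressWarnings(cor(x, y, method = "kendall")),
          tolerance = 1e-12)
      }
    }
  })
})

test_that("resource merging has set-union semantics", {
  t1 <- res_tab(cbind(c("m1", "m1", "m2"), c("g1", "g2", "g1")), "A")
  t2 <- res_tab(cbind(c("m1", "m3"), c("g1", "g9")), "B", evidence = "experimental")
  merged <- merge_resources(list(t1, t2))
  expect_equal(nrow(merged), 4)
  both <- merged[merged$mirna_id == "m1" & merged$gene_id == "g1", ]
  expect_equal(both$sources, "A,B")
  expect_equal(both$n_sources, 2)
  expect_equal(both$evidence, "experimental")
  expect_equal(merged$evidence[merged$gene_id == "g2"], "predicted")

  # disjoint tables add up
  d1 <- res_tab(cbind(paste0("m", 1:3), paste0("g", 1:3)), "A")
  d2 <- res_tab(cbind(paste0("m", 4:7), paste0("g", 4:7)), "B")
  expect_equal(nrow(merge_resources(list(d1, d2))), 7)

  # idempotent, commutative, associative
  expect_identical(merge_resources(list(merged, merged)), merged)
  expect_identical(
    merge_resources(list(t1, t2)),
    merge_resources(list(t2, t1))
  )
  t3 <- res_tab(cbind("m9", "g9"), "C")
  expect_identical(
    merge_resources(list(merge_resources(list(t1, t2)), t3)),
    merge_resources(list(t1, merge_resources(list(t2, t3))))
  )
})

test_that("expression restriction keeps only pairs with both partners expressed", {
  tab <- merge_resources(list(
    res_tab(cbind(c("m1", "m1", "m2"), c("g1", "g2", "g2")), "A")
  ))
  out <- restrict_to_expressed(tab, c("m1"), c("g1"))
  expect_equal(nrow(out), 1)
  expect_equal(out$gene_id, "g1")
  expect_equal(nrow(restrict_to_expressed(tab, character(), character())), 0)

  # commutes with merging
  t1 <- res_tab(cbind(c("m1", "m2"), c("g1", "g2")), "A")
  t2 <- res_tab(cbind(c("m1", "m3"), c("g1", "g3")), "B")
  a <- restrict_to_expressed(merge_resources(list(t1, t2)), c("m1", "m3"), c("g1", "g3"))
  b <- merge_resources(list(
    restrict_to_expressed(t1, c("m1", "m3"), c("g1", "g3")),
    restrict_to_expressed(t2, c("m1", "m3"), c("g1", "g3"))
  ))
  expect_identical(a, b)
})

test_that("correlation annotation joins profiles on a shared day grid", {
  days <- c(0, 4, 8, 12, 16)
  mirna_prof <- tibble::tibble(
    feature_id = "m1", day = days, value = c(2, 3, 4, 5, 6)
  )
  mrna_prof <- tibble::tibble(
    feature_id = c(rep("g_down", 5), rep("g_const", 5)),
    day = rep(days, 2),
    value = c(10, 9, 8, 7, 6, rep(4, 5))
  )
  tab <- merge_resources(list(res_tab(
    cbind(c("m1", "m1", "m1"), c("g_down", "g_const", "g_absent")), "A"
  )))
  out <- suppressMessages(annotate_correlations(tab, mirna_prof, mrna_prof))
  expect_equal(nrow(out), 1) # constant target and absent target both skipped
  expect_equal(out$gene_id, "g_down")
  expect_equal(out$tau, -1)
  expect_equal(out$n_days, 5)

  # a miRNA "targeting" itself correlates at +1
  self <- suppressMessages(annotate_correlations(
    merge_resources(list(res_tab(cbind("m1", "m1"), "A"))),
    mirna_prof,
    dplyr::mutate(mirna_prof, feature_id = "m1")
  ))
  expect_equal(self$tau, 1)

  shifted <- dplyr::mutate(mrna_prof, day = day + 1)
  expect_error(annotate_correlations(tab, mirna_prof, shifted), "day grid")
})

test_that("independent profiles have near-zero mean tau", {
  withr::with_seed(99, {
    taus <- replicate(1000, {
      suppressWarnings(kendall_tau(rnorm(5), rnorm(5)))
    })
  })
  expect_lt(abs(mean(taus)), 0.05)
})

test_that("anti-correlation filtering is strict at the boundary", {
  tab <- tibble::tibble(
    mirna_id = "m", gene_id = c("a", "b", "c"),
    tau = c(-0.5, -0.2, 0.3)
  )
  out <- filter_anticorrelated(tab, tau_max = -0.2)
  expect_equal(out$gene_id, "a")
})

test_that("interaction TSVs round-trip through the reader with a score hook", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    mirna_id = c("m1", "m2"), gene_id = c("g1", "g2"),
    score = c(0.9, 0.2), evidence = "predicted"
  ), path)
  tab <- read_interaction_tsv(path, resource = "toy", score_min = 0.5)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$resource, "toy")
  bare <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(mirna_id = "m1", gene_id = "g1"), bare)
  expect_error(read_interaction_tsv(bare, score_min = 0.5), "no score column")
})
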