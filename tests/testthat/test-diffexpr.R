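test_that("moderated t with no prior equals the pooled two-sample t", {
  res <- moderated_t(c(1, 2, 3), c(4, 5, 6), prior_df = 0)
  expect_equal(res$t_mod, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(round(res$t_mod, 3), -3.674)
  expect_equal(res$df_total, 4)
  expect_equal(res$p_raw, pooled_t(c(1, 2, 3), c(4, 5, 6))$p, tolerance = 1e-12)
  expect_equal(res$p_raw, 0.0213, tolerance = 5e-3)

  withr::with_seed(8, {
    for (i in 1:25) {
      a <- rnorm(sample(2:6, 1))
      b <- rnorm(sample(2:6, 1))
      got <- moderated_t(a, b, prior_df = 0)
      ref <- pooled_t(a, b)
      expect_equal(got$t_mod, ref$t, tolerance = 1e-12)
      expect_equal(got$p_raw, ref$p, tolerance = 1e-12)
    }
  })
})

test_that("strong priors dominate the variance and zero variance without one errors", {
  a <- c(1, 2, 3); b <- c(2, 4, 6)
  limit <- (mean(a) - mean(b)) / sqrt(0.5 * (2 / 3))
  big <- moderated_t(a, b, prior_df = 1e9, prior_var = 0.5)
  expect_equal(big$t_mod, limit, tolerance = 1e-6)
  inf <- moderated_t(a, b, prior_df = Inf, prior_var = 0.5)
  expect_equal(inf$t_mod, limit, tolerance = 1e-12)
  expect_equal(inf$df_total, Inf)

  expect_error(moderated_t(c(1, 1, 1), c(2, 2, 2), prior_df = 0), "undefined")
  expect_error(moderated_t(c(1), c(2, 3), prior_df = 0), "two replicates")
  expect_error(moderated_t(a, b, prior_df = 2), "prior_var")
})

test_that("the variance prior is recovered from scaled inverse-chi-squared draws", {
  d <- 4; d0 <- 4; s0 <- 1
  withr::with_seed(33, {
    sigma2 <- d0 * s0 / rchisq(5000, df = d0)
    s2 <- sigma2 * rchisq(5000, df = d) / d
  })
  est <- estimate_prior(s2, residual_df = d)
  expect_lt(abs(est$d0 - d0), 1)
  expect_lt(abs(est$s0_sq - s0) / s0, 0.10)

  # permutation invariance
  est2 <- estimate_prior(rev(s2), residual_df = d)
  expect_equal(est, est2)

  # degenerate case: identical variances flag an infinite prior df
  flat <- estimate_prior(rep(0.25, 100), residual_df = d)
  expect_true(is.infinite(flat$d0))
  expect_equal(flat$s0_sq, 0.25)

  expect_error(estimate_prior(rep(0.2, 5), residual_df = d), "at least 10")
})

test_that("BH adjustment matches hand computations and stats::p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.5, 7)), rep(0.5, 7))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  withr::with_seed(4, {
    for (i in 1:20) {
      p <- runif(sample(1:50, 1))
      expect_equal(bh_adjust(p), stats::p.adjust(p, method = "BH"),
        tolerance = 1e-14)
      # permutation invariance
      o <- sample(length(p))
      expect_equal(bh_adjust(p)[o], bh_adjust(p[o]), tolerance = 1e-14)
    }
    # monotonicity: raising one raw p never lowers any adjusted value
    p <- runif(30)
    base <- bh_adjust(p)
    p2 <- p; i <- which.min(p); p2[i] <- min(p2[i] + 0.3, 1)
    expect_true(all(bh_adjust(p2) >= base - 1e-14))
  })
})

test_that("DE flags respect joint strict thresholds on adjusted p and fold change", {
  res <- tibble::tibble(
    p_adj = c(1e-6, 1e-6, 1e-4, 1e-5),
    log2fc = c(2.5, 2.0, 5.0, 3.0)
  )
  flags <- call_de(res, alpha = 1e-5, lfc_min = 2)$is_de
  expect_identical(flags, c(TRUE, FALSE, FALSE, FALSE))
  lax <- call_de(res, alpha = 1e-5, lfc_min = 2, strict = FALSE)$is_de
  expect_identical(lax, c(TRUE, TRUE, FALSE, TRUE))
})

test_that("diff_expression recovers strong planted effects and reports tidy results", {
  n_feat <- 400; n_planted <- 40
  withr::with_seed(19, {
    prof <- matrix(8, n_feat, 3,
      dimnames = list(sprintf("f%03d", 1:n_feat), NULL))
    prof[seq_len(n_planted), 2] <- 8 + 4 # +4 log2 at day 4
    st <- make_study(prof, c(0, 4, 8), reps = 3, noise_sd = 0.1)
  })
  de <- diff_expression(st$expr, st$samples, reference_day = 0)
  expect_s3_class(de, "de_result")
  expect_true(all(c("feature_id", "day", "log2fc", "t_mod", "p_raw",
    "p_adj", "is_de") %in% names(de)))
  hits <- dplyr::filter(de, day == 4, is_de)
  expect_setequal(hits$feature_id, sprintf("f%03d", seq_len(n_planted)))
  expect_equal(sum(dplyr::filter(de, day == 8)$is_de), 0)
  g <- glance(de)
  expect_equal(g$n_de[g$day == 4], n_planted)
})

test_that("moderated statistics agree with limma on a shared fit", {
  skip_if_not_installed("limma")
  withr::with_seed(55, {
    m <- matrix(rnorm(300 * 6, mean = 7, sd = 0.4), nrow = 300,
      dimnames = list(sprintf("f%03d", 1:300), sprintf("s%d", 1:6)))
    m[1:20, 4:6] <- m[1:20, 4:6] + 2
  })
  design <- cbind(intercept = 1, day4 = rep(c(0, 1), each = 3))
  fit <- limma::eBayes(limma::lmFit(m, design))

  st <- make_study(m[, c(1, 2, 3, 1, 2, 3)] * 0, c(0, 4), reps = 3)
  st$expr[, -1] <- tibble::as_tibble(m)
  de <- diff_expression(st$expr, st$samples, reference_day = 0)
  ord <- match(de$feature_id, rownames(m))
  expect_gt(cor(de$t_mod, fit$t[ord, "day4"]), 0.999)
  expect_equal(de$log2fc, fit$coefficients[ord, "day4"], tolerance = 1e-10,
    ignore_attr = TRUE)
})
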