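test_that("prevalence fractions are exact and sum to one", {
  tbl <- tibble::tibble(
    cohort = rep(c("A", "B"), c(10, 38)),
    gene_present = c(rep(c(TRUE, FALSE), c(3, 7)), rep(c(TRUE, FALSE), c(30, 8))))
  pr <- prevalence(tbl, cohort)
  expect_equal(pr$frac_positive[pr$cohort == "A"], 0.30)
  # 30 of 38 -> 0.789..., the worked 79% fraction
  expect_equal(pr$frac_positive[pr$cohort == "B"], 30 / 38)
  expect_equal(pr$frac_positive + pr$frac_negative, c(1, 1))

  all_pos <- tibble::tibble(gene_present = rep(TRUE, 5))
  expect_equal(prevalence(all_pos)$frac_positive, 1.0)
})

test_that("Mann-Whitney exact path matches complete enumeration", {
  # complete separation at n1 = n2 = 3: P(U = 0) = 1/20 per tail -> p = 0.10
  r <- mwu_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p_two_sided, 0.10)
  expect_equal(r$method, "exact")

  # exact p equals the permutation oracle for group splits of 8 distinct values
  vals <- c(2.1, 3.5, 1.2, 8.8, 5.0, 7.3, 0.4, 6.6)
  for (n1 in c(3, 4)) {
    splits <- utils::combn(8, n1)
    for (ci in seq_len(ncol(splits))) {
      a <- vals[splits[, ci]]
      b <- vals[-splits[, ci]]
      expect_equal(mwu_test(a, b)$p_two_sided, oracle_mwu_exact_p(a, b),
                   tolerance = 1e-12)
    }
  }
})

test_that("U statistics are complementary and ties fall back to approximation", {
  a <- c(1.5, 9.2, 4.4, 7.7, 2.0)
  b <- c(3.3, 6.1, 8.5, 0.9)
  expect_equal(mwu_test(a, b)$U + mwu_test(b, a)$U, length(a) * length(b))

  # identical multisets: approximation path, U = n1 n2 / 2, p = 1
  x <- c(1, 2, 3, 4, 5, 6, 7)
  r <- mwu_test(x, x)
  expect_equal(r$method, "normal-approximation-with-tie-correction")
  expect_equal(r$U, length(x)^2 / 2)
  expect_equal(r$p_two_sided, 1.0)
})

test_that("exact and approximate p agree within 0.02 at n1 = n2 = 6", {
  vals <- seq_len(12)   # tie-free; exhaustive over all 6/6 splits
  splits <- utils::combn(12, 6)
  worst <- 0
  for (ci in seq_len(ncol(splits))) {
    a <- vals[splits[, ci]]
    b <- vals[-splits[, ci]]
    p_exact <- mwu_test(a, b)$p_two_sided
    p_approx <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
    worst <- max(worst, abs(p_exact - p_approx))
  }
  expect_lt(worst, 0.02)
})

test_that("metabolite association reports medians, means and per-stratum tests", {
  withr::with_seed(191, {
    tbl <- tibble::tibble(
      cohort = rep(c("A", "B"), each = 40),
      gene_present = rep(c(TRUE, FALSE), 40),
      gbb = exp(rnorm(80, mean = 3 - 0.8 * rep(c(1, 0), 40), sd = 0.5)))
  })
  res <- associate_presence_with_metabolite(tbl, gbb, stratify_by = cohort)
  expect_equal(nrow(res), 2)
  for (i in 1:2) {
    sub <- tbl[tbl$cohort == res$stratum[i], ]
    expect_equal(res$median_positive[i], median(sub$gbb[sub$gene_present]))
    expect_equal(res$median_negative[i], median(sub$gbb[!sub$gene_present]))
    expect_equal(res$mean_positive[i], mean(sub$gbb[sub$gene_present]))
  }

  # insufficient data in a stratum is skipped with a warning
  tbl2 <- tbl
  tbl2$gbb[tbl2$cohort == "B" & tbl2$gene_present] <- NA
  expect_warning(res2 <- associate_presence_with_metabolite(
    tbl2, gbb, stratify_by = cohort), "skipped")
  expect_equal(res2$stratum, "A")
})

test_that("the test is calibrated under the null and powered at one SD shift", {
  withr::with_seed(192, {
    n_rep <- 1000
    p_null <- p_alt <- numeric(n_rep)
    for (i in seq_len(n_rep)) {
      p_null[i] <- mwu_test(rnorm(30), rnorm(30))$p_two_sided
      p_alt[i] <- mwu_test(rnorm(30, mean = -1), rnorm(30))$p_two_sided
    }
    type1 <- mean(p_null < 0.05)
    power <- mean(p_alt < 0.05)
    # binomial CI around 0.05 at 1000 replicates
    expect_lt(abs(type1 - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep))
    expect_gt(power, 0.8)
  })
})

test_that("gene/transcript concordance tallies the 2x2 table", {
  # constructed table (10,5; 4,21): fractions 10/15 and 4/25
  tbl <- tibble::tibble(
    gene_present = rep(c(TRUE, FALSE), c(15, 25)),
    transcript_present = c(rep(c(TRUE, FALSE), c(10, 5)),
                           rep(c(TRUE, FALSE), c(4, 21))))
  cc <- gene_transcript_concordance(tbl)
  expect_equal(cc$frac_transcript_pos_given_gene_pos, 10 / 15)
  expect_equal(cc$frac_transcript_pos_given_gene_neg, 4 / 25)

  # all gene-positive: gene-negative fraction undefined with n = 0
  all_pos <- tibble::tibble(gene_present = TRUE,
                            transcript_present = TRUE)[rep(1, 6), ]
  cc2 <- gene_transcript_concordance(all_pos)
  expect_equal(cc2$frac_transcript_pos_given_gene_pos, 1.0)
  expect_equal(cc2$n_gene_negative, 0)
  expect_true(is.na(cc2$frac_transcript_pos_given_gene_neg))

  expect_error(gene_transcript_concordance(
    tibble::tibble(gene_present = TRUE, transcript_present = NA)),
    "non-missing")
})
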