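test_that("HWE chi-square matches hand-computed expectations", {
  r <- hwe_chisq(c(49, 42, 9))
  expect_equal(r$p_hat, 0.7)
  expect_equal(r$chi2, 0)
  expect_equal(r$p_value, 1)
  expect_equal(hwe_chisq(c(25, 50, 25))$chi2, 0)
  # p_hat = 0.45: expected (20.25, 49.5, 30.25) out of 100
  r2 <- hwe_chisq(c(30, 30, 40))
  expect_equal(r2$chi2,
               9.75^2 / 20.25 + 19.5^2 / 49.5 + 9.75^2 / 30.25,
               tolerance = 1e-12)
  expect_equal(r2$chi2, 15.51882461, tolerance = 1e-8)
  expect_equal(r2$p_value, pchisq(r2$chi2, 1, lower.tail = FALSE))
  mono <- hwe_chisq(c(10, 0, 0))
  expect_true(mono$monomorphic)
  expect_equal(mono$chi2, 0)
  expect_error(hwe_chisq(c(0, 0, 0)), "positive")
})

test_that("exact 2x3 Fisher matches the enumeration oracle and fisher.test", {
  tab <- genotype_counts(c(2, 2, 2), c(2, 2, 2))
  expect_equal(fisher_exact_2x3(tab)$p_value, 1)

  tab2 <- genotype_counts(c(3, 1, 0), c(0, 1, 3))
  m2 <- rbind(c(3, 1, 0), c(0, 1, 3))
  p2 <- fisher_exact_2x3(tab2)$p_value
  expect_equal(p2, oracle_fisher_2xk(m2), tolerance = 1e-12)
  expect_equal(p2, 0.0571428571, tolerance = 1e-8)

  withr::with_seed(41, {
    for (i in 1:20) {
      m <- matrix(rpois(6, 4), nrow = 2)
      if (any(rowSums(m) == 0) || sum(colSums(m) > 0) <= 1) next
      p_pkg <- fisher_exact_2x3(genotype_counts(m[1, ], m[2, ]))$p_value
      expect_equal(p_pkg, oracle_fisher_2xk(m), tolerance = 1e-10)
      expect_equal(p_pkg, stats::fisher.test(m[, colSums(m) > 0])$p.value,
                   tolerance = 1e-7)
    }
  })
})

test_that("a zero genotype column reduces the 2x3 test to the 2x2 tail sum", {
  tab <- genotype_counts(c(8, 2, 0), c(5, 5, 0))
  res <- fisher_exact_2x3(tab)
  expect_true("zero_column_dropped" %in% res$flags)
  expect_equal(res$p_value,
               stats::fisher.test(rbind(c(8, 2), c(5, 5)))$p.value,
               tolerance = 1e-10)
  # single non-zero column: fully degenerate
  expect_equal(fisher_exact_2x3(genotype_counts(c(5, 0, 0),
                                                c(7, 0, 0)))$p_value, 1)
})

test_that("allele collapse and 2x2 allele Fisher follow the closed forms", {
  ac <- allele_counts(genotype_counts(c(49, 42, 9), c(1, 1, 1)))
  expect_equal(ac$n_ref[1], 140)
  expect_equal(ac$n_alt[1], 60)
  # equal allele frequencies, equal row sizes
  expect_equal(
    fisher_exact_allele_2x2(genotype_counts(c(4, 2, 4), c(4, 2, 4)))$p_value,
    1
  )
  # fully separated alleles: the two extreme tables of the hypergeometric
  expect_equal(
    fisher_exact_allele_2x2(genotype_counts(c(5, 0, 0), c(0, 0, 5)))$p_value,
    2 / choose(20, 10), tolerance = 1e-12
  )
  withr::with_seed(42, {
    for (i in 1:10) {
      m <- matrix(rpois(6, 5) + 1, nrow = 2)
      a <- allele_counts(genotype_counts(m[1, ], m[2, ]))
      am <- as.matrix(a[, c("n_ref", "n_alt")])
      expect_equal(
        fisher_exact_allele_2x2(genotype_counts(m[1, ], m[2, ]))$p_value,
        stats::fisher.test(am)$p.value, tolerance = 1e-7
      )
    }
  })
})

test_that("asymptotic Armitage equals the classical trend test", {
  tab <- genotype_counts(c(10, 20, 30), c(10, 20, 30))
  r <- armitage_trend(tab)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  withr::with_seed(43, {
    for (i in 1:10) {
      m <- matrix(rpois(6, 8) + 1, nrow = 2)
      r_pkg <- armitage_trend(genotype_counts(m[1, ], m[2, ]))
      ref <- suppressWarnings(
        stats::prop.trend.test(m[1, ], colSums(m), score = c(0, 1, 2))
      )
      expect_equal(r_pkg$statistic, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(r_pkg$p_value, ref$p.value, tolerance = 1e-10)
    }
  })
  # zero variance of scores under the margins
  degenerate <- armitage_trend(genotype_counts(c(0, 5, 0), c(0, 7, 0)))
  expect_equal(degenerate$p_value, 1)
  expect_true("zero_variance" %in% degenerate$flags)
})

test_that("Monte-Carlo Armitage respects the estimator floor and symmetry", {
  tab <- genotype_counts(c(30, 10, 2), c(10, 20, 12))
  mc <- armitage_trend(tab, mode = "monte_carlo", reps = 200, seed = 5)
  expect_gte(mc$p_value, 1 / 201)
  expect_lte(mc$p_value, 1)
  # invariance under swapping case/control labels together with score
  # reversal, at the same seed
  swapped <- genotype_counts(c(10, 20, 12), c(30, 10, 2))
  mc_swapped <- armitage_trend(swapped, scores = c(2, 1, 0),
                               mode = "monte_carlo", reps = 200, seed = 5)
  expect_equal(mc$p_value, mc_swapped$p_value)
  expect_equal(mc$statistic, mc_swapped$statistic)
  # determinism at a fixed seed
  expect_equal(
    armitage_trend(tab, mode = "monte_carlo", reps = 500, seed = 9)$p_value,
    armitage_trend(tab, mode = "monte_carlo", reps = 500, seed = 9)$p_value
  )
})

test_that("genotype frequencies normalize per arm", {
  freq <- genotype_frequencies(genotype_counts(c(0, 0, 10), c(96, 4, 0)))
  expect_equal(as.numeric(freq[1, -1]), c(0, 0, 100))
  expect_equal(as.numeric(freq[2, -1]), c(96, 4, 0))
  withr::with_seed(44, {
    for (i in 1:10) {
      m <- matrix(rpois(6, 6) + 1, nrow = 2)
      freqs <- genotype_frequencies(genotype_counts(m[1, ], m[2, ]))
      expect_equal(rowSums(as.matrix(freqs[, -1])), c(100, 100),
                   ignore_attr = TRUE)
    }
  })
})

test_that("rejection rate is non-decreasing in the genotype relative risk", {
  grrs <- c(1, 1.5, 2, 3)
  reps <- 250L
  rates <- vapply(grrs, function(grr) {
    rejected <- vapply(seq_len(reps), function(i) {
      tab <- simulate_cohort_table(cohort_sim_spec(
        allele_freq = 0.2, n_cases = 109, n_controls = 111, grr = grr,
        seed = 5000L + i  # paired seeds across grr values
      ))
      fisher_exact_2x3(tab)$p_value < 0.05
    }, TRUE)
    mean(rejected)
  }, 0)
  expect_true(all(diff(rates) >= 0))
  expect_lt(rates[1], 0.1)
  expect_gt(rates[4], 0.9)
})

test_that("tidy and glance return one-row summaries", {
  tab <- genotype_counts(c(30, 10, 2), c(10, 20, 12))
  td <- tidy(fisher_exact_2x3(tab))
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1L)
  expect_equal(td$method, "fisher_exact_2x3")
  th <- glance(hwe_chisq(c(30, 30, 40)))
  expect_equal(nrow(th), 1L)
  expect_named(th, c("method", "statistic", "df", "p.value", "p.hat", "n",
                     "monomorphic"))
})
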