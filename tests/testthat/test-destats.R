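test_that("reads-per-million normalization is exact and conserves mass", {
  m <- matrix(c(12L, 0L, 30L, 4L, 6L, 10L), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("XX", "XY")))
  em <- normalize_expression(m, totals = c(XX = 6e6, XY = 2e6))
  expect_equal(em$ne[["a", "XX"]], 2.0, tolerance = 1e-12)
  expect_identical(em$ne[["b", "XX"]], 0)
  # totals = column sums: NE columns sum to 1e6
  em2 <- normalize_expression(m)
  expect_equal(unname(colSums(em2$ne)), c(1e6, 1e6), tolerance = 1e-9)
  expect_error(normalize_expression(m, totals = c(0, 1)), "positive")
})

test_that("Audic-Claverie closed forms hold at the boundary", {
  expect_identical(audic_claverie_p(0, 0, 1e6, 1e6), 1)
  expect_equal(audic_claverie_p(10, 0, 1e6, 1e6), 2 * 2^-11,
               tolerance = 1e-12)
  expect_error(audic_claverie_p(-1, 0, 1, 1), "non-negative")
})

test_that("Audic-Claverie behaves symmetrically under (x,N1) <-> (y,N2) exchange", {
  # the conditional pmf obeys the exact exchange identity
  # p(y|x; N1,N2) = (N1/N2) p(x|y; N2,N1); the two-sided tail statistic
  # inherits approximate symmetry (the inclusive point mass sits in
  # different tails), so the doubled-tail p-values agree within a factor
  # of two and the calls they imply coincide
  set.seed(41)
  pmf <- function(x, y, N1, N2) {
    r <- N2 / N1
    exp(y * log(r) + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
          (x + y + 1) * log1p(r))
  }
  for (i in 1:50) {
    x <- sample(0:150, 1); y <- sample(0:150, 1)
    N1 <- sample(1e4:1e6, 1); N2 <- sample(1e4:1e6, 1)
    expect_equal(pmf(x, y, N1, N2), (N1 / N2) * pmf(y, x, N2, N1),
                 tolerance = 1e-12)
    # equal library sizes: exchange changes the p-value by at most the
    # boundary point mass, i.e. a factor <= 2
    N <- sample(1e4:1e7, 1)
    a <- audic_claverie_p(x, y, N, N)
    b <- audic_claverie_p(y, x, N, N)
    expect_lte(max(a, b) / min(a, b), 2)
  }
})

test_that("log-space AC agrees with direct summation and with Fisher", {
  set.seed(42)
  for (i in 1:100) {
    x <- sample(0:200, 1); y <- sample(0:200, 1)
    N1 <- sample(1e3:1e7, 1); N2 <- sample(1e3:1e7, 1)
    p <- audic_claverie_p(x, y, N1, N2)
    expect_equal(p, oracle_ac_direct(x, y, N1, N2), tolerance = 1e-10)
  }
  # moderate counts on equal totals: AC tracks the Fisher exact p
  p_ac <- audic_claverie_p(50, 55, 1e6, 1e6)
  p_f <- contingency_tests(50, 55, 1e6, 1e6)$p_fisher
  expect_lt(abs(p_ac - p_f) / p_f, 0.10)
})

test_that("contingency tests match enumeration and handle degenerate tables", {
  expect_equal(contingency_tests(5, 5, 100, 100)$p_fisher, 1)
  ct <- contingency_tests(10, 10, 100, 100)
  expect_equal(ct$p_chi2, 1)
  # exhaustive hypergeometric oracle on a small table
  got <- contingency_tests(8, 1, 10, 10)$p_fisher
  expect_equal(got, oracle_fisher_enum(8, 1, 10, 10), tolerance = 1e-9)
  expect_error(contingency_tests(20, 0, 10, 10), "exceeds")
})

test_that("three tests agree asymptotically in the moderate regime", {
  # the chi-squared approximation deviates from the exact tests by orders
  # of magnitude in deep tails, so asymptotic consistency is a statement
  # about large counts at moderate significance
  set.seed(77)
  n_checked <- 0
  for (i in 1:200) {
    x <- sample(100:500, 1); y <- sample(100:500, 1)
    p <- c(audic_claverie_p(x, y, 1e6, 1e6),
           unlist(contingency_tests(x, y, 1e6, 1e6)))
    if (p[2] >= 0.05) {
      expect_lt(max(p) / min(p) - 1, 0.15)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 20)
})

test_that("DE calls apply the filter, specific and fold-change rules", {
  counts <- matrix(c(
    200, 800, 500,    # clear up in XY vs XX (log2fc = 2)
    100, 105, 100,    # null
    0,   50,  10,     # specific to XY (zero in XX)
    40,  0,   20,     # specific to XX within the pair
    0,   0,   90,     # undetected in the pair, present in YY
    2,   1,   1),     # NE < 1 in all three -> filtered
    ncol = 3, byrow = TRUE,
    dimnames = list(sprintf("m%d", 1:6), c("XX", "XY", "YY")))
  em <- normalize_expression(counts, totals = c(XX = 4e6, XY = 4e6,
                                                YY = 4e6))
  de <- call_de(em, c("XY", "XX"))
  st <- stats::setNames(de$status, de$mirna)
  expect_identical(unname(st["m1"]), "up")
  expect_identical(unname(st["m2"]), "not_significant")
  expect_identical(unname(st["m3"]), "specific_A")
  expect_identical(unname(st["m4"]), "specific_B")
  expect_identical(unname(st["m5"]), "not_significant")
  expect_identical(unname(st["m6"]), "filtered")
  # specific and filtered rows are never tested
  expect_true(all(is.na(de$p_adjusted[de$status %in%
                                        c("specific_A", "specific_B",
                                          "filtered")])))
  # Bonferroni family = tested rows only (m1, m2)
  expect_equal(de$p_adjusted[de$mirna == "m1"],
               min(1, de$p_ac[de$mirna == "m1"] * 2))
  # significance without |log2fc| > 1 stays not_significant
  counts2 <- matrix(c(4000, 2200, 3000), ncol = 3,
                    dimnames = list("m", c("XX", "XY", "YY")))
  em2 <- normalize_expression(counts2, totals = c(XX = 1e6, XY = 1e6,
                                                  YY = 1e6))
  de2 <- call_de(em2, c("XX", "XY"))
  expect_lt(de2$p_adjusted, 0.05)
  expect_lt(abs(de2$log2fc), 1)
  expect_identical(de2$status, "not_significant")
})

test_that("plot values revise zeros to 0.01 without touching the matrix", {
  counts <- matrix(c(0, 5, 3, 0, 4, 0), ncol = 3,
                   dimnames = list(c("a", "b"), c("XX", "XY", "YY")))
  em <- normalize_expression(counts, totals = c(XX = 1e6, XY = 1e6,
                                                YY = 1e6))
  pv <- plot_values(em, c("XX", "XY"))
  expect_identical(pv$ne_a, c(0.01, 5))
  expect_identical(pv$ne_b, c(3, 0.01))
  pv2 <- plot_values(em, c("XY", "YY"))
  expect_identical(pv2$ne_b[2], 0.01)
  expect_identical(em$ne[["a", "XX"]], 0)  # matrix unchanged
})

test_that("abundance tiers follow the copy-number boundaries", {
  expect_identical(abundance_tier(5, 40), "Low")
  expect_identical(abundance_tier(50, 40), "High")
  expect_identical(abundance_tier(11, 100), "Middle")
  # boundary cases assigned downward
  expect_identical(abundance_tier(10, 100), "Low")
  expect_identical(abundance_tier(100, 100), "Middle")
})

test_that("2^-ddCt relative quantification follows the formula", {
  expect_identical(ddct(20, 15, 22, 15), 4)
  expect_identical(ddct(18, 12, 18, 12), 1)  # treated = control
  expect_identical(ddct(21, 15, 20, 15), 0.5)
  expect_error(ddct(Inf, 15, 20, 15), "finite")
})

test_that("Welch t-test handles identity, separation and its null level", {
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_identical(same$t, 0)
  expect_equal(same$p, 1)
  sep <- welch_t(c(0, 0, 0), c(10, 10, 10.0001))
  expect_lt(sep$p, 0.001)
  expect_error(welch_t(1, c(1, 2)), "at least two")
  # Monte-Carlo type-I error at alpha = 0.05
  set.seed(123)
  rej <- 0L
  n_rep <- 10000L
  for (i in seq_len(n_rep)) {
    if (welch_t(rnorm(5), rnorm(5))$p < 0.05) rej <- rej + 1L
  }
  expect_gt(rej / n_rep, 0.04)
  expect_lt(rej / n_rep, 0.06)
})
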