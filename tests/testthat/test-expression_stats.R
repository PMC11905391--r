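test_that("TPM normalization is exact and conserves a million per library", {
  expect_equal(tpm_normalize(10, 2e6), 5.0)
  expect_equal(tpm_normalize(0, 1000), 0.0)
  set.seed(40)
  counts <- rpois(200, 50)
  expect_equal(sum(tpm_normalize(counts, sum(counts))), 1e6)
  expect_error(tpm_normalize(1, 0), "> 0")
})

test_that("fold change reproduces the published worked rows", {
  # group means printed for novel-miR04 and cre-miR910
  r1 <- fold_change(32.48, 375.57)
  expect_equal(r1$log2fc, -3.531, tolerance = 0.01)
  r2 <- fold_change(24703.94, 40883.05)
  expect_equal(r2$log2fc, -0.727, tolerance = 0.01)
  expect_equal(fold_change(7, 7)$log2fc, 0)
  expect_false(fold_change(0, 0)$defined)
  # zero-mean guard uses the pseudocount
  expect_equal(fold_change(0, 10)$log2fc, log2(0.01 / 10))
})

test_that("log2 fold change is antisymmetric under group swap", {
  set.seed(41)
  for (i in 1:20) {
    a <- runif(1, 0.1, 1e4); b <- runif(1, 0.1, 1e4)
    expect_equal(fold_change(a, b)$log2fc, -fold_change(b, a)$log2fc)
  }
})

test_that("the Welch test handles degenerate and clear-cut inputs", {
  expect_equal(de_test(c(5, 5, 5), c(5, 5, 5)), 1)
  expect_equal(de_test(c(5, 5, 5), c(50, 50, 50)), 0)
  set.seed(42)
  x <- c(100, 100, 100) + rnorm(3, 0, 0.5)
  y <- c(10, 10, 10) + rnorm(3, 0, 0.5)
  expect_lt(de_test(x, y), 0.05)
  # agreement with stats::t.test on non-degenerate data
  for (i in 1:20) {
    a <- rlnorm(3, 5, 0.5); b <- rlnorm(3, 4, 0.5)
    expect_equal(de_test(a, b),
                 t.test(log2(a + 1), log2(b + 1))$p.value)
  }
  # cross-check against an exhaustive permutation test: a clearly separated
  # pair is extreme under every test
  a <- c(100, 110, 105); b <- c(9, 11, 10)
  expect_lt(de_test(a, b), 0.05)
  expect_equal(oracle_permutation_p(a, b), 0.1)  # 2/20 label splits
})

test_that("type-I error is controlled under the generator null", {
  set.seed(43)
  n <- 400L
  base <- 10^runif(n, 1, 3.6)
  m <- simulate_locus_counts(base, 1, 3L, 0.1)
  tpm <- m / 2e5 * 1e6
  p <- vapply(seq_len(n), function(i) de_test(tpm[i, 4:6], tpm[i, 1:3]), 0)
  frac <- mean(p < 0.05)
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / n)
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})

test_that("DE classification applies the fold-change and tier thresholds", {
  expect_equal(classify_de(-3.531, 0.01), list(status = "down", tier = "high"))
  expect_equal(classify_de(-0.893, 0.01), list(status = "down", tier = "medium"))
  expect_equal(classify_de(-0.3, 0.001), list(status = "ns", tier = "none"))
  expect_equal(classify_de(2.2, 0.001), list(status = "up", tier = "none"))
  expect_equal(classify_de(-2, 0.2)$status, "ns")
  # boundary: exactly -1 goes to the high tier; exactly -log2(1.5) is down
  expect_equal(classify_de(-1, 0.01)$tier, "high")
  expect_equal(classify_de(-log2(1.5), 0.01),
               list(status = "down", tier = "medium"))
  # every significantly down record lands in exactly one tier
  set.seed(44)
  for (l2 in runif(50, -5, 0)) {
    cl <- classify_de(l2, 0.01)
    if (cl$status == "down") expect_true(cl$tier %in% c("high", "medium"))
  }
})

test_that("2^-ddCt quantification matches its closed form", {
  expect_equal(ddct(20, 15, 20, 15)$relative_expression, 1.0)
  expect_equal(ddct(21, 15, 20, 15)$relative_expression, 0.5)
  expect_equal(ddct(18, 15, 20, 15)$relative_expression, 4.0)
  expect_equal(ddct(25.3, 18.1, 24.8, 18.4)$ddct,
               (25.3 - 18.1) - (24.8 - 18.4))
})

test_that("the expression table assembles TPM, fold change and tiers", {
  counts <- rbind(m1 = c(100, 120, 110, 10, 12, 11),
                  m2 = c(50, 55, 45, 50, 52, 48))
  libs <- c("W1", "W2", "W3", "K1", "K2", "K3")
  colnames(counts) <- libs
  totals <- setNames(rep(1e5, 6), libs)
  groups <- setNames(rep(c("control", "mutant"), each = 3), libs)
  tab <- expression_table(counts, totals, groups)
  r1 <- tab[tab$name == "m1", ]
  expect_equal(r1$mean_control, mean(c(100, 120, 110)) * 10)
  expect_equal(r1$log2fc, log2(11 / 110), tolerance = 1e-9)
  expect_equal(r1$status, "down")
  expect_equal(r1$tier, "high")
  expect_equal(tab[tab$name == "m2", ]$status, "ns")
})
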