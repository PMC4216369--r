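test_that("permutation test handles constant and degenerate inputs", {
  res <- permutation_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(res$p_value, 1)
  expect_equal(res$statistic, 0)
  expect_error(permutation_test(numeric(0), 1:3), "non-empty")
})

test_that("enumerated permutation p equals the brute-force oracle", {
  res <- permutation_test(c(5, 6, 7, 8), c(1, 2, 3, 4))
  expect_true(res$exact)
  expect_equal(res$p_value, oracle_perm_p(c(5, 6, 7, 8), c(1, 2, 3, 4)))
  expect_equal(res$p_value, 2 / 70)  # only the two extreme splits qualify

  set.seed(401)
  for (sizes in list(c(2, 2), c(3, 3), c(4, 4), c(3, 7), c(5, 5))) {
    x <- round(rnorm(sizes[1]), 2)
    y <- round(rnorm(sizes[2], 0.5), 2)
    res <- permutation_test(x, y)
    expect_true(res$exact)
    expect_equal(res$p_value, oracle_perm_p(x, y), tolerance = 1e-12)
  }
})

test_that("Monte-Carlo permutation p converges to the enumerated p", {
  set.seed(402)
  x <- rnorm(5); y <- rnorm(5, 1)
  p_exact <- oracle_perm_p(x, y)
  res <- permutation_test(x, y, n_perm = 200, seed = 9)  # C(10,5) = 252 > 200
  expect_false(res$exact)
  se <- sqrt(p_exact * (1 - p_exact) / 200)
  expect_lt(abs(res$p_value - p_exact), 3 * se + 1 / 201)
})

test_that("signed-rank test matches enumeration oracle and conventions", {
  res <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5))
  expect_equal(res$statistic, 15)
  expect_equal(res$p_value, 2 / 32)
  expect_true(res$exact)

  expect_equal(wilcoxon_signed_rank(c(0, 0, 0))$p_value, 1)

  # balanced symmetric ties give a p deep inside the support
  res <- wilcoxon_signed_rank(c(1, -1, 2, -2))
  expect_equal(res$p_value, oracle_signed_rank_p(c(1, -1, 2, -2)))
  expect_gt(res$p_value, 0.9)

  set.seed(403)
  for (n in c(4, 7, 10, 12)) {
    d <- round(rnorm(n, 0.4), 2)
    expect_equal(wilcoxon_signed_rank(d)$p_value, oracle_signed_rank_p(d),
                 tolerance = 1e-12)
  }
})

test_that("signed-rank normal approximation tracks the reference", {
  set.seed(404)
  d <- rnorm(40, 0.3)
  ours <- wilcoxon_signed_rank(d)
  ref <- stats::wilcox.test(d, exact = FALSE, correct = TRUE)
  expect_false(ours$exact)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-8)
})

test_that("Benjamini-Hochberg equals the literal step-up on random input", {
  expect_equal(benjamini_hochberg(0.03), 0.03)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04, 0.05)),
               rep(0.05, 5))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(405)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    q <- benjamini_hochberg(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12) && all(q <= 1))
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in p-order
  }
})

test_that("Fisher 2x2 equals hypergeometric enumeration and is symmetric", {
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2))$p_value, 1 / 3)
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  expect_error(fisher_exact_2x2(matrix(c(-1, 0, 0, 2), 2)), "non-negative")

  tab <- matrix(c(10, 2, 10, 18), 2)  # rows: disrupted yes/no
  ref <- stats::fisher.test(tab)$p.value
  expect_equal(fisher_exact_2x2(tab)$p_value, ref, tolerance = 1e-9)

  set.seed(406)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 6), 2)
    p <- fisher_exact_2x2(tab)$p_value
    expect_equal(fisher_exact_2x2(t(tab))$p_value, p, tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(tab[2:1, ])$p_value, p, tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(tab[, 2:1])$p_value, p, tolerance = 1e-12)
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("chi-square independence matches the hand formula", {
  expect_equal(chi_square_independence(matrix(c(5, 5, 5, 5), 2))$statistic, 0)
  expect_equal(chi_square_independence(matrix(5, 3, 3))$p_value, 1)

  tab <- matrix(c(20, 5, 5, 20), 2)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  by_hand <- sum((tab - expected)^2 / expected)
  res <- chi_square_independence(tab)
  expect_equal(res$statistic, by_hand)
  ref <- stats::chisq.test(tab, correct = FALSE)
  expect_equal(res$p_value, unname(ref$p.value), tolerance = 1e-10)

  expect_error(chi_square_independence(matrix(c(1, 0, 2, 0), 2)), "Fisher")
})

test_that("Kruskal-Wallis matches the reference with and without ties", {
  expect_equal(kruskal_wallis(list(1:3, 1:3, 1:3))$p_value, 1)
  expect_error(kruskal_wallis(list(1:3)), "at least 2")

  groups <- list(c(1, 2), c(3, 4), c(5, 6))
  res <- kruskal_wallis(groups)
  ref <- stats::kruskal.test(groups)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res$p_value, unname(ref$p.value), tolerance = 1e-10)

  tied <- list(c(1, 1, 1), c(1, 1, 2))
  res <- kruskal_wallis(tied)
  ref <- stats::kruskal.test(tied)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-10)
})

test_that("Wilks MANOVA reduces to ANOVA and matches the scatter oracle", {
  # identical group means: lambda 1, F 0
  y <- matrix(rep(c(1, 2, 3, 2, 2, 4), 4), ncol = 2, byrow = TRUE)
  res <- manova_wilks(y, rep(c("a", "a", "b", "b"), 3))
  expect_equal(res$statistic, 1)
  expect_equal(res$f_value, 0)

  # single response: F equals one-way ANOVA F exactly
  set.seed(407)
  v <- rnorm(30); g <- rep(letters[1:3], 10)
  res <- manova_wilks(matrix(v, ncol = 1), g)
  ref <- anova(stats::lm(v ~ g))
  expect_equal(res$univariate$f_value, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(res$f_value, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(res$p_value, ref$`Pr(>F)`[1], tolerance = 1e-10)

  # two groups, two responses: against stats::manova Wilks
  Y <- matrix(rnorm(60), ncol = 2)
  g2 <- rep(c("x", "y"), 15)
  res <- manova_wilks(Y, g2)
  ref <- summary(stats::manova(Y ~ g2), test = "Wilks")$stats
  expect_equal(res$statistic, ref[1, "Wilks"], tolerance = 1e-8)
  expect_equal(res$p_value, ref[1, "Pr(>F)"], tolerance = 1e-8)

  # collinear responses are refused with the offending column named
  Yc <- cbind(a = rnorm(20), b = 0)
  Yc[, "b"] <- Yc[, "a"] * 2
  expect_error(manova_wilks(Yc, rep(c("x", "y"), 10)), "singular")
})

test_that("test results tidy into one-row tibbles", {
  td <- tidy(permutation_test(c(5, 6, 7, 8), c(1, 2, 3, 4)))
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_named(td, c("statistic", "p.value", "method", "exact", "n"))
  expect_equal(glance(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2)))$n, 4)
})
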