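test_that("well-separated blobs are recovered perfectly at k = 2", {
  set.seed(701)
  n_feat <- 30
  blob <- function(center, n, prefix) {
    m <- matrix(exp(rnorm(n_feat * n, center, 0.2)), n_feat, n)
    colnames(m) <- paste0(prefix, seq_len(n))
    m
  }
  # two blobs differ strongly on half the features
  a <- blob(1, 8, "a"); b <- blob(1, 8, "b")
  b[1:15, ] <- b[1:15, ] * 50
  expr <- tibble::as_tibble(cbind(
    tibble::tibble(mirna_id = sprintf("m%02d", 1:n_feat)),
    tibble::as_tibble(a), tibble::as_tibble(b)
  ))
  assign <- ward_cluster(expr, k = 2)
  got <- split(assign$sample_id, assign$cluster)
  expect_setequal(got[[1]], paste0("a", 1:8))
  expect_setequal(got[[2]], paste0("b", 1:8))
})

test_that("agglomeration follows the Lance-Williams Ward update", {
  # four samples on one feature; merge order and heights are hand-checkable
  expr <- make_expr("m1", s1 = 0, s2 = 1, s3 = 10, s4 = 11.5)
  assign <- ward_cluster(expr, k = 2)
  tree <- attr(assign, "tree")

  # oracle: naive Lance-Williams agglomeration on the same scaled distances
  lg <- log2(as.matrix(expr[-1]) + 1)
  z <- as.numeric(scale(as.numeric(lg)))
  d <- stats::dist(z)
  ref <- oracle_ward_d2(d)
  expect_equal(tree$height, ref$heights, tolerance = 1e-10)
  # closest pair on the scaled log2 axis is {s3,s4}, then {s1,s2}
  expect_setequal(-tree$merge[1, ], c(3, 4))
  expect_setequal(-tree$merge[2, ], c(1, 2))
})

test_that("k = n makes every sample its own cluster; k > n errors", {
  expr <- make_expr(c("m1", "m2"), s1 = c(1, 8), s2 = c(5, 2),
                    s3 = c(9, 4))
  assign <- ward_cluster(expr, k = 3)
  expect_equal(sort(assign$cluster), 1:3)
  expect_error(ward_cluster(expr, k = 4), "exceeds")
})

test_that("composition test picks Fisher for 2x2 and chi-square beyond", {
  assign <- tibble::tibble(sample_id = sprintf("s%02d", 1:40),
                           cluster = rep(1:2, each = 20))
  labels <- setNames(rep(c("tumor", "normal"), each = 20),
                     assign$sample_id)
  res <- cluster_composition_test(assign, labels)
  expect_match(res$method, "Fisher")
  # perfectly aligned split: agrees with the reference implementation
  ref <- stats::fisher.test(table(assign$cluster, labels))$p.value
  expect_equal(res$p_value, ref, tolerance = 1e-9)
  expect_lt(res$p_value, 1e-10)

  labels3 <- setNames(rep(c("CS", "FS", "NS", "CS"), 10), assign$sample_id)
  res3 <- cluster_composition_test(assign, labels3)
  expect_match(res3$method, "chi-square")

  expect_error(cluster_composition_test(assign,
                                        setNames(rep("x", 40),
                                                 assign$sample_id)),
               "degenerate")
})

test_that("composition p-values are calibrated under label independence", {
  set.seed(702)
  n <- 40
  pvals <- replicate(400, {
    assign <- tibble::tibble(sample_id = sprintf("s%02d", 1:n),
                             cluster = rep(1:2, each = n / 2))
    labels <- setNames(sample(rep(c("A", "B"), n / 2)), assign$sample_id)
    cluster_composition_test(assign, labels)$p_value
  })
  # discrete exact test: check conservative uniformity at two cutoffs
  expect_lte(mean(pvals < 0.05), 0.08)
  expect_gte(mean(pvals < 0.5), 0.30)
})

test_that("covariate scan flags separated covariates and handles edge cases", {
  assign <- tibble::tibble(sample_id = sprintf("s%02d", 1:30),
                           cluster = rep(1:2, each = 15))
  meta <- make_meta(assign$sample_id, paste0("p", 1:30), "tumor", "CS")
  meta$age <- c(rnorm(15, 50, 2), rnorm(15, 75, 2))  # cluster-separated
  meta$pack_years <- 30                               # constant
  scan <- suppressWarnings(
    cluster_covariate_scan(assign, meta, c("age", "pack_years"))
  )
  age_row <- scan[scan$covariate == "age", ]
  expect_lt(age_row$p_value, 0.05)
  const_row <- scan[scan$covariate == "pack_years", ]
  expect_equal(const_row$f_value, 0)
  expect_equal(const_row$p_value, 1)

  tt <- cluster_covariate_ttest(assign, meta, "age")
  expect_lt(tt$p.value, 0.05)
  meta2 <- meta
  meta2$age <- rep(seq(55, 70, length.out = 15), 2)  # identical per cluster
  expect_gt(cluster_covariate_ttest(assign, meta2, "age")$p.value, 0.99)
})

test_that("between-cluster DE finds planted rows and reports overlap", {
  set.seed(703)
  n_per <- 10
  ids <- sprintf("s%02d", 1:(2 * n_per))
  base <- matrix(exp(rnorm(20 * 2 * n_per, 2, 0.3)), 20)
  base[1:4, seq_len(n_per)] <- base[1:4, seq_len(n_per)] * 8  # planted
  expr <- tibble::as_tibble(cbind(
    tibble::tibble(mirna_id = sprintf("m%02d", 1:20)),
    tibble::as_tibble(stats::setNames(as.data.frame(base), ids))
  ))
  assign <- tibble::tibble(sample_id = ids, cluster = rep(1:2, each = n_per))
  de <- between_cluster_de(expr, assign)
  expect_true(all(de$significant[1:4]))
  expect_lte(sum(de$significant[-(1:4)]), 1)

  # identical expression in both clusters: nothing significant
  same <- expr
  same[ids[(n_per + 1):(2 * n_per)]] <- same[ids[1:n_per]]
  de0 <- between_cluster_de(same, assign)
  expect_equal(sum(de0$significant), 0)

  ov <- overlap_report(sprintf("x%03d", 1:100),
                       sprintf("x%03d", 44:193))
  expect_equal(ov$n_common, 57)
  expect_equal(ov$frac_of_a, 0.57)
  expect_equal(round(100 * ov$frac_of_b), 38)
})
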