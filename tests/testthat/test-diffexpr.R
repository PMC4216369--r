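test_that("fold change floors both sides at the detection limit", {
  expect_equal(fold_change(0.5, 0.2), 1)
  expect_equal(fold_change(4, 1), 4)
  expect_equal(fold_change(2.5, 5), 0.5)
  expect_equal(fold_change(c(0.5, 4), c(0.2, 1)), c(1, 4))
  expect_error(fold_change(-1, 2), ">= 0")
})

test_that("identical group compositions yield no smoke-response calls", {
  set.seed(501)
  vals <- rlnorm(20, 2, 1)
  expr <- make_expr(sprintf("m%02d", 1:20),
                    a1 = vals, a2 = vals, a3 = vals,
                    b1 = vals, b2 = vals, b3 = vals)
  meta <- make_meta(c("a1", "a2", "a3", "b1", "b2", "b3"),
                    paste0("p", 1:6), tissue = "normal",
                    smoking = rep(c("CS", "NS"), each = 3))
  de <- smoke_response_de(expr, meta, cfg = analysis_config(n_perm = 200))
  expect_equal(sum(de$status != "none"), 0)
  expect_true(all(de$mean_fold == 1))
})

test_that("the dual criterion is strict on both gates", {
  # q at/above threshold, or fold inside the gates, is never called
  status <- function(q, fold, cfg = analysis_config()) {
    dplyr::case_when(
      q < cfg$q_threshold & fold > cfg$fc_over ~ "over",
      q < cfg$q_threshold & fold < cfg$fc_under ~ "under",
      TRUE ~ "none"
    )
  }
  expect_equal(status(0.051, 3), "none")
  expect_equal(status(0.049, 2.0), "none")  # fold must exceed 2
  expect_equal(status(0.049, 2.01), "over")
})

test_that("recurrence frequency is inclusive at the 25% boundary", {
  fx <- make_paired_expr(
    list(hit = c(3, 3, 1, 1, 1, 1, 1, 1),
         flat = rep(1, 8)),
    n_pairs = 8
  )
  pairs <- build_pairs(fx$meta)
  res <- recurrence_scan(fx$expr, pairs)
  hit <- res[res$mirna_id == "hit", ]
  expect_equal(hit$freq_over, 0.25)   # 2 of 8 pairs, boundary met
  flat <- res[res$mirna_id == "flat", ]
  expect_equal(flat$direction, "none")
  expect_equal(flat$wilcoxon_p, 1)

  expect_error(recurrence_scan(fx$expr, pairs[1:3, ]), "at least 4")
})

test_that("planted recurrent rows are called in their group", {
  cfg <- small_sim_config(seed = 23, n_per_group = c(CS = 24L, FS = 8L,
                                                     NS = 8L))
  co <- simulate_cohort(cfg)
  f <- filter_expressed(co$expression)
  pairs <- build_pairs(co$metadata)
  res <- recurrence_scan(f, pairs[pairs$group == "CS", ])
  planted_over <- co$truth$mirna_id[co$truth$label == "CS-specific" &
                                      co$truth$direction == "over"]
  called <- res$mirna_id[res$direction == "over"]
  expect_gte(length(intersect(planted_over, called)),
             length(planted_over) - 1L)
})

test_that("B-H for recurrence is invariant to miRNA row order", {
  fx <- make_paired_expr(
    setNames(lapply(1:12, function(i) {
      set.seed(600 + i)
      exp(rnorm(10, ifelse(i <= 3, 1.5, 0), 0.4))
    }), sprintf("m%02d", 1:12)),
    n_pairs = 10
  )
  pairs <- build_pairs(fx$meta)
  res1 <- recurrence_scan(fx$expr, pairs)
  set.seed(601)
  shuffled <- fx$expr[sample(nrow(fx$expr)), ]
  res2 <- recurrence_scan(shuffled, pairs)
  merged <- dplyr::inner_join(res1, res2, by = "mirna_id")
  expect_equal(merged$bh_q.x, merged$bh_q.y, tolerance = 1e-12)
})

test_that("specificity patterns partition by qualifying group count", {
  calls <- tidyr::expand_grid(
    mirna_id = c("mA", "mB", "mC"),
    group = c("CS", "FS", "NS")
  )
  calls$direction <- "none"
  calls$direction[calls$mirna_id == "mA" & calls$group == "CS"] <- "over"
  calls$direction[calls$mirna_id == "mB"] <- "over"
  # opposite directions in different groups: two specific calls
  calls$direction[calls$mirna_id == "mC" & calls$group == "CS"] <- "under"
  calls$direction[calls$mirna_id == "mC" & calls$group == "NS"] <- "over"

  spec <- classify_specificity(calls)
  expect_equal(spec$pattern[spec$mirna_id == "mA"], "CS-specific")
  expect_equal(spec$pattern[spec$mirna_id == "mB"], "shared-all")
  mc <- spec[spec$mirna_id == "mC", ]
  expect_setequal(mc$pattern, c("CS-specific", "NS-specific"))
  expect_setequal(mc$direction, c("under", "over"))

  expect_error(classify_specificity(calls[calls$group != "FS", ]),
               "missing")
})

test_that("reversibility classes follow the former-smoker comparison", {
  de_tbl <- function(status, fold) {
    tibble::tibble(mirna_id = c("m1", "m2", "m3", "m4"),
                   statistic = 0, p = 0.5, q = 0.5,
                   mean_fold = fold, status = status)
  }
  csn <- de_tbl(c("over", "over", "none", "under"), c(4, 4, 1, 0.25))
  fsn <- de_tbl(c("over", "none", "none", "over"), c(4, 1, 1, 4))
  expect_warning(rev <- classify_reversibility(csn, fsn), "opposite")
  expect_equal(rev$class[rev$mirna_id == "m1"], "irreversible")
  expect_equal(rev$class[rev$mirna_id == "m2"], "reversible")
  expect_equal(rev$class[rev$mirna_id == "m3"], "not-smoke-responsive")
  # m4: conflicting direction in former smokers
  expect_equal(rev$class[rev$mirna_id == "m4"], "not-smoke-responsive")
  expect_true(rev$conflict[rev$mirna_id == "m4"])
})

test_that("external validation needs both the test and the frequency gate", {
  res <- external_validation(tibble::tibble(
    mirna_id = c("a", "b", "c"),
    k_focal = c(10, 10, 0), n_focal = 20,
    k_rest = c(2, 8, 0), n_rest = 20
  ))
  # 10/20 vs 2/20: frequency gap 0.40; Fisher decides
  expect_equal(res$freq_diff[1], 0.4)
  expect_equal(res$validated[1],
               stats::fisher.test(matrix(c(10, 10, 2, 18), 2,
                                         byrow = TRUE))$p.value < 0.05)
  # 10/20 vs 8/20: gap 0.10 fails the gate regardless of p
  expect_false(res$validated[2])
  # nothing disrupted anywhere
  expect_equal(res$fisher_p[3], 1)
  expect_false(res$validated[3])

  expect_error(external_validation(tibble::tibble(
    mirna_id = "x", k_focal = 0, n_focal = 0, k_rest = 0, n_rest = 10
  )), "empty group")
})

test_that("raising focal disruption never un-validates via the gate", {
  base <- tibble::tibble(mirna_id = "x", k_focal = 5, n_focal = 20,
                         k_rest = 2, n_rest = 20)
  gaps <- vapply(5:20, function(k) {
    external_validation(dplyr::mutate(base, k_focal = k))$freq_diff
  }, numeric(1))
  expect_true(all(diff(gaps) >= 0))
})
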