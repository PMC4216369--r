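test_that("detectability gate applies the two-thirds ceiling rule", {
  # 145 of 218 misses ceiling(2*218/3) = 146; 146 makes it
  n <- 218
  row_vals <- function(k) c(rep(5, k), rep(0.2, n - k))
  expr <- tibble::as_tibble(c(
    list(mirna_id = c("just_below", "at_boundary", "everywhere", "nowhere")),
    stats::setNames(
      lapply(seq_len(n), function(j) {
        c(row_vals(145)[j], row_vals(146)[j], 5, 0.2)
      }),
      sprintf("s%03d", seq_len(n))
    )
  ))
  kept <- detectability_gate(expr)
  expect_false("just_below" %in% kept)
  expect_true("at_boundary" %in% kept)
  expect_true("everywhere" %in% kept)
  expect_false("nowhere" %in% kept)
})

test_that("tertile split takes floor(n/3) tails and drops the middle", {
  ids <- letters[1:9]
  sp <- tertile_split(1:9, ids)
  expect_equal(sp$low, c("a", "b", "c"))
  expect_equal(sp$high, c("g", "h", "i"))

  sp10 <- tertile_split(1:10, letters[1:10])
  expect_equal(length(sp10$low), 3)
  expect_equal(length(sp10$high), 3)
  expect_equal(length(intersect(sp10$low, sp10$high)), 0)

  expect_warning(sp_tied <- tertile_split(rep(1, 9), ids), "tied")
  expect_equal(sp_tied$low, c("a", "b", "c"))  # deterministic id order
  expect_error(tertile_split(1:5, letters[1:5]), "at least 6")
})

test_that("Kaplan-Meier matches the hand product-limit computation", {
  # 4 patients: event at t=1 (1 of 4 at risk), event at t=2 (1 of 3),
  # censored at 3 and 4
  km <- km_estimate(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(km$survival[km$time == 1], 0.75)
  expect_equal(km$survival[km$time == 2], 0.5)

  # no events: flat at 1
  km0 <- km_estimate(c(5, 6, 7), c(FALSE, FALSE, FALSE))
  expect_true(all(km0$survival == 1))

  # everyone dies at t=1
  km1 <- km_estimate(c(1, 1, 1), c(TRUE, TRUE, TRUE))
  expect_equal(km1$survival[km1$time == 1], 0)

  # without censoring the estimator is 1 - ECDF
  t_all <- c(2, 4, 4, 7, 9)
  km2 <- km_estimate(t_all, rep(TRUE, 5))
  ecdf_vals <- 1 - stats::ecdf(t_all)(km2$time)
  expect_equal(km2$survival, ecdf_vals)

  expect_error(km_estimate(numeric(0), logical(0)), "empty")
})

test_that("log-rank matches the hand O-E/V table and is symmetric", {
  ta <- c(1, 2); ea <- c(1, 1)
  tb <- c(3, 4); eb <- c(1, 1)
  res <- logrank_test(ta, ea, tb, eb)
  expect_equal(res$statistic, oracle_logrank_chi2(ta, ea, tb, eb),
               tolerance = 1e-10)
  swapped <- logrank_test(tb, eb, ta, ea)
  expect_equal(swapped$statistic, res$statistic, tolerance = 1e-12)
  expect_equal(swapped$p_value, res$p_value, tolerance = 1e-12)

  same <- logrank_test(ta, ea, ta, ea)
  expect_equal(same$statistic, 0, tolerance = 1e-12)

  none <- logrank_test(c(1, 2), c(0, 0), c(3, 4), c(0, 0))
  expect_equal(none$p_value, 1)

  set.seed(801)
  for (i in 1:10) {
    ta <- round(rexp(12, 0.1), 1); ea <- rbinom(12, 1, 0.7)
    tb <- round(rexp(15, 0.2), 1); eb <- rbinom(15, 1, 0.7)
    if (sum(ea) + sum(eb) == 0) next
    expect_equal(logrank_test(ta, ea, tb, eb)$statistic,
                 oracle_logrank_chi2(ta, ea, tb, eb), tolerance = 1e-8)
  }
})

test_that("Cox fit matches a brute-force partial-likelihood search", {
  x <- c(0, 1, 0, 1)
  time <- c(2, 1, 4, 3)
  event <- c(1, 1, 1, 1)
  fit <- coxph_fit(tibble::tibble(x = x), time, event)
  beta_ref <- oracle_cox_beta(x, time, event)
  expect_equal(fit$estimate, beta_ref, tolerance = 2e-3)

  expect_error(coxph_fit(tibble::tibble(x = rep(1, 4)), time, event),
               "zero-variance covariate: x")
})

test_that("Cox estimates are consistent for a two-group hazard ratio", {
  set.seed(802)
  n <- 1000
  x <- rbinom(n, 1, 0.5)
  true_beta <- 0.7
  time <- rexp(n, rate = 0.05 * exp(true_beta * x))
  event <- rep(1L, n)
  fit <- coxph_fit(tibble::tibble(x = x), time, event)
  expect_lt(abs(fit$estimate - true_beta), 0.1)
})

test_that("survival scan flags a planted prognostic miRNA and skips tiny strata", {
  cfg <- small_sim_config(seed = 31,
                          n_per_group = c(CS = 30L, FS = 2L, NS = 30L),
                          surv_loghr = 1.0)
  co <- simulate_cohort(cfg)
  f <- filter_expressed(co$expression)
  expect_warning(
    scan <- survival_scan(f, co$metadata, strata = c("ALL", "FS")),
    "skipped"
  )
  expect_false("FS" %in% scan$stratum)
  prog <- co$truth$mirna_id[co$truth$label == "prognostic"]
  prow <- scan[scan$mirna_id == prog & scan$stratum == "ALL", ]
  expect_equal(nrow(prow), 1)
  expect_lt(prow$bh_q, 0.05)
})

test_that("tertiles are computed within cohort of origin on merged data", {
  # cohort B is the same biology as A but scaled down 10x; pooling raw
  # values would put all of B in the low tertile
  set.seed(803)
  vals <- exp(rnorm(12, 3, 0.5))
  expr_cols <- c(vals, vals / 10)
  ids <- sprintf("s%02d", 1:24)
  names(expr_cols) <- ids
  cohort <- rep(c("A", "B"), each = 12)
  split_ids <- mirsmoke:::pooled_tertiles(expr_cols, setNames(cohort, ids))
  expect_equal(sum(startsWith(split_ids$low, "s0") |
                     as.integer(sub("s", "", split_ids$low)) <= 12), 4)
  expect_equal(sum(as.integer(sub("s", "", split_ids$high)) > 12), 4)
})

test_that("expression-covariate MANOVA flags a planted stage association", {
  set.seed(804)
  n <- 90
  stage <- sample(c("I", "II", "III"), n, replace = TRUE)
  expr <- rnorm(n, as.integer(factor(stage)), 0.5)
  covs <- tibble::tibble(stage = stage,
                         noise = rnorm(n),
                         single = rep("x", n))
  expect_warning(res <- expression_covariate_manova(expr, covs),
                 "single level")
  expect_lt(res$p_value[res$covariate == "stage"], 0.01)
  expect_gt(res$p_value[res$covariate == "noise"], 0.05)
  expect_false("single" %in% res$covariate)
})
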