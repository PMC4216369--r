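# Shared fixtures and independent oracle implementations. Oracles here are
# deliberately naive (enumeration / brute force) and never call the package
# functions they check.

# small expression tibble from a named list of sample columns
make_expr <- function(mirna_ids, ...) {
  tibble::tibble(mirna_id = mirna_ids, ...)
}

# metadata tibble with sensible defaults; smoking/tissue vectors recycled
make_meta <- function(sample_id, patient_id, tissue, smoking,
                      surv_time = NA_real_, event = NA) {
  n <- length(sample_id)
  tibble::tibble(
    sample_id = sample_id, patient_id = patient_id,
    tissue = rep_len(tissue, n), smoking = rep_len(smoking, n),
    age = rep(65, n), sex = rep("M", n), stage = rep("I", n),
    ethnicity = rep("european", n),
    pack_years = ifelse(rep_len(smoking, n) == "NS", 0, 30),
    years_quit = ifelse(rep_len(smoking, n) == "FS", 5, NA_real_),
    surv_time = rep_len(surv_time, n), event = rep_len(event, n)
  )
}

# a small paired cohort: n patients per group, tumor value = fold * normal
# for chosen miRNAs; otherwise tumor == normal == base
make_paired_expr <- function(folds_by_mirna, n_pairs, group = "CS",
                             base = 10) {
  patients <- sprintf("%s%02d", group, seq_len(n_pairs))
  meta <- make_meta(
    sample_id = c(paste0(patients, "T"), paste0(patients, "N")),
    patient_id = rep(patients, 2),
    tissue = rep(c("tumor", "normal"), each = n_pairs),
    smoking = group
  )
  cols <- list()
  for (p in seq_len(n_pairs)) {
    cols[[paste0(patients[p], "T")]] <-
      vapply(folds_by_mirna, function(f) base * f[p], numeric(1))
    cols[[paste0(patients[p], "N")]] <-
      rep(base, length(folds_by_mirna))
  }
  expr <- tibble::as_tibble(
    c(list(mirna_id = names(folds_by_mirna)), cols)
  )
  list(expr = expr, meta = meta)
}

# compact simulation config for fast tests
small_sim_config <- function(seed = 7, ...) {
  args <- list(
    seed = seed, n_per_group = c(CS = 10L, FS = 8L, NS = 8L),
    n_mirna = 150L, frac_undetectable = 0.2,
    planted_shared = c(over = 12L, under = 4L),
    planted_specific = list(CS = c(over = 3L, under = 2L),
                            FS = c(over = 2L, under = 1L),
                            NS = c(over = 3L, under = 1L)),
    smoke_response = list(up = 4L, down = 2L, n_irreversible = 3L,
                          fold = 4)
  )
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(simulation_config, args)
}

# ---- oracles -------------------------------------------------------------

# full-enumeration two-sided permutation p on the difference of means
oracle_perm_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  t_obs <- abs(mean(x) - mean(y))
  idx <- utils::combn(n, nx)
  stats <- apply(idx, 2, function(i) {
    abs(mean(pooled[i]) - mean(pooled[-i]))
  })
  mean(stats >= t_obs - 1e-12)
}

# brute-force 2^n sign enumeration of the signed-rank two-sided p
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  min(1, 2 * min(mean(w_all >= w_obs - 1e-9), mean(w_all <= w_obs + 1e-9)))
}

# literal step-up definition: q_i = min over j with p_(j) >= p_i of m p_(j)/j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- vapply(seq_len(m), function(i) {
    min(1, min(m * ps[i:m] / seq(i, m)))
  }, numeric(1))
  out <- numeric(m)
  out[o] <- q
  out
}

# hand log-rank: O - E and hypergeometric variance over pooled event times
oracle_logrank_chi2 <- function(ta, ea, tb, eb) {
  times <- sort(unique(c(ta[ea == 1], tb[eb == 1])))
  o_minus_e <- 0; v <- 0
  for (t in times) {
    n1 <- sum(ta >= t); n2 <- sum(tb >= t); n <- n1 + n2
    d1 <- sum(ta == t & ea == 1); d2 <- sum(tb == t & eb == 1)
    d <- d1 + d2
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# brute-force maximization of the Breslow partial likelihood for a single
# covariate (grid search, no ties assumed beyond Breslow handling)
oracle_cox_loglik <- function(beta, x, time, event) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}
oracle_cox_beta <- function(x, time, event, grid = seq(-5, 5, 1e-3)) {
  grid[which.max(vapply(grid, oracle_cox_loglik, numeric(1),
                        x = x, time = time, event = event))]
}

# naive Ward.D2 agglomeration via the Lance-Williams update, for tiny n
oracle_ward_d2 <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  sizes <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(0)
  merges <- list()
  repeat {
    if (length(active) == 1) break
    best <- c(NA, NA); best_d <- Inf
    for (i in active) for (j in active) {
      if (i < j && d[i, j] < best_d) { best_d <- d[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, best_d)
    merges[[length(merges) + 1]] <- sort(c(i, j))
    # Lance-Williams for Ward.D2 on squared distances
    for (k in setdiff(active, c(i, j))) {
      ni <- sizes[i]; nj <- sizes[j]; nk <- sizes[k]
      dik2 <- d[i, k]^2; djk2 <- d[j, k]^2; dij2 <- d[i, j]^2
      dk2 <- ((ni + nk) * dik2 + (nj + nk) * djk2 - nk * dij2) /
        (ni + nj + nk)
      d[i, k] <- d[k, i] <- sqrt(dk2)
    }
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
  }
  list(heights = heights, merges = merges)
}
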