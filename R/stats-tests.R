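#' Hypothesis-test result container
#'
#' All testing primitives in mirsmoke return a `mir_test` object: a light
#' list holding the statistic, the p-value, a method label, per-group sample
#' sizes, and whether the p-value came from full enumeration of the null
#' support (`exact = TRUE`) or from an approximation / Monte-Carlo scheme.
#' Use [tidy()] to get a one-row tibble.
#'
#' @param statistic observed test statistic.
#' @param p_value p-value in \[0, 1\].
#' @param method human-readable method label.
#' @param n_used integer vector of per-group sample sizes actually used.
#' @param exact logical; `TRUE` only when the full null support was enumerated.
#' @param ... extra fields (e.g. `df`, `seed`) stored alongside.
#'
#' @return An object of class `mir_test`.
#' @keywords internal
new_mir_test <- function(statistic, p_value, method, n_used, exact, ...) {
  stopifnot(is.numeric(p_value), length(p_value) == 1L)
  if (is.finite(p_value) && (p_value < 0 || p_value > 1)) {
    stop("p_value outside [0, 1]: ", p_value)
  }
  structure(
    c(
      list(
        statistic = unname(statistic), p_value = unname(p_value),
        method = method, n_used = n_used, exact = isTRUE(exact)
      ),
      list(...)
    ),
    class = "mir_test"
  )
}

#' @export
print.mir_test <- function(x, ...) {
  cat(x$method, "\n")
  cat("  statistic =", format(x$statistic, digits = 6),
      " p =", format.pval(x$p_value, digits = 4),
      if (x$exact) " (exact)" else "", "\n")
  cat("  n =", paste(x$n_used, collapse = ", "), "\n")
  invisible(x)
}

# shared tolerance for "as extreme as observed" comparisons on real-valued
# statistics: relative, so enumeration is robust to floating-point noise
.as_extreme <- function(values, observed) {
  values >= observed * (1 - 1e-10) - 1e-12
}

#' Two-sample permutation test on the difference of means
#'
#' Nonparametric two-sided test of location difference between two groups,
#' with the difference of group means as the statistic. When the number of
#' distinct label reassignments `choose(nx+ny, nx)` does not exceed `n_perm`
#' the full permutation null is enumerated and the p-value is exact;
#' otherwise `n_perm` random reassignments are drawn and the add-one
#' estimator `(1 + #extreme) / (n_perm + 1)` is used, which can never return
#' zero. Intended for log2(RPKM + 1)-transformed expression.
#'
#' @param x,y numeric vectors, both non-empty.
#' @param n_perm number of random permutations for Monte-Carlo mode (and the
#'   enumeration cutoff). Default 10000.
#' @param seed optional integer seed for the Monte-Carlo draw; recorded in
#'   the result.
#'
#' @return A [mir_test][new_mir_test] with fields `statistic` (mean(x) -
#'   mean(y)), `p_value`, `exact`, and `seed`.
#' @examples
#' permutation_test(c(5, 6, 7, 8), c(1, 2, 3, 4))
#' @export
permutation_test <- function(x, y, n_perm = 10000, seed = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) stop("both groups must be non-empty")
  pooled <- c(x, y)
  nx <- length(x); n <- length(pooled)
  t_obs <- mean(x) - mean(y)
  if (isTRUE(all.equal(min(pooled), max(pooled)))) {
    return(new_mir_test(0, 1, "two-sample permutation test (constant data)",
                        c(nx, n - nx), exact = TRUE, seed = seed))
  }
  n_splits <- choose(n, nx)
  if (n_splits <= n_perm) {
    idx <- utils::combn(n, nx)
    tot <- sum(pooled)
    stats <- apply(idx, 2L, function(i) {
      sx <- sum(pooled[i])
      sx / nx - (tot - sx) / (n - nx)
    })
    p <- mean(.as_extreme(abs(stats), abs(t_obs)))
    return(new_mir_test(t_obs, p, "two-sample permutation test (enumerated)",
                        c(nx, n - nx), exact = TRUE, seed = seed))
  }
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  tot <- sum(pooled)
  for (b in seq_len(n_perm)) {
    i <- sample.int(n, nx)
    sx <- sum(pooled[i])
    t_b <- sx / nx - (tot - sx) / (n - nx)
    if (.as_extreme(abs(t_b), abs(t_obs))) hits <- hits + 1L
  }
  p <- (1 + hits) / (n_perm + 1)
  new_mir_test(t_obs, p, "two-sample permutation test (Monte-Carlo)",
               c(nx, n - nx), exact = FALSE, seed = seed, n_perm = n_perm)
}

# Row-wise permutation test for an expression matrix (rows = miRNAs,
# columns = samples), difference of group means per row. One shared set of
# label permutations is used for all rows so the whole scan is a single
# matrix product per permutation batch. Returns add-one Monte-Carlo
# p-values. Used by the differential-expression scans.
perm_test_rows <- function(mat, is_group1, n_perm = 10000, seed = NULL) {
  stopifnot(is.matrix(mat), is.logical(is_group1),
            length(is_group1) == ncol(mat))
  n1 <- sum(is_group1); n2 <- sum(!is_group1)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 samples")
  if (!is.null(seed)) set.seed(seed)
  n <- ncol(mat)
  w_obs <- ifelse(is_group1, 1 / n1, -1 / n2)
  t_obs <- as.vector(mat %*% w_obs)
  # permutation weight matrix: each column is one relabelling
  W <- matrix(-1 / n2, nrow = n, ncol = n_perm)
  for (b in seq_len(n_perm)) W[sample.int(n, n1), b] <- 1 / n1
  Tb <- abs(mat %*% W)                      # rows x n_perm
  thr <- abs(t_obs) * (1 - 1e-10) - 1e-12
  hits <- rowSums(Tb >= thr)
  p <- (1 + hits) / (n_perm + 1)
  list(statistic = t_obs, p_value = unname(p))
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Two-sided one-sample signed-rank test for a location shift of paired
#' differences (e.g. per-pair log2 tumor/normal fold values). Zero
#' differences are dropped before ranking (Wilcoxon's original treatment).
#' For `n <= exact_max` retained differences the p-value is computed by full
#' enumeration of all `2^n` sign assignments of the (mid)ranks, and the
#' two-sided p is twice the smaller tail probability, capped at 1. For
#' larger n a normal approximation with tie correction and a 0.5 continuity
#' correction is used.
#'
#' @param diffs numeric vector of paired differences.
#' @param exact_max largest n for which the sign assignments are enumerated
#'   (default 15, i.e. at most 32768 assignments).
#'
#' @return A [mir_test][new_mir_test]; `statistic` is W+, the sum of ranks
#'   of the positive differences. All differences zero (or empty input)
#'   gives p = 1 by convention.
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3, 4, 5))  # W = 15, exact p = 2/32
#' @export
wilcoxon_signed_rank <- function(diffs, exact_max = 15) {
  diffs <- as.numeric(diffs)
  d <- diffs[diffs != 0]
  n <- length(d)
  if (n == 0L) {
    return(new_mir_test(0, 1, "Wilcoxon signed-rank (all zero differences)",
                        length(diffs), exact = TRUE))
  }
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  if (n <= exact_max) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_all <- as.vector(signs %*% r)           # W+ under all sign patterns
    tol <- 1e-9
    p_ge <- mean(w_all >= w_pos - tol)
    p_le <- mean(w_all <= w_pos + tol)
    p <- min(1, 2 * min(p_ge, p_le))
    return(new_mir_test(w_pos, p, "Wilcoxon signed-rank (enumerated)",
                        n, exact = TRUE))
  }
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sigma2 <= 0) {
    return(new_mir_test(w_pos, 1, "Wilcoxon signed-rank (degenerate ranks)",
                        n, exact = FALSE))
  }
  z <- (w_pos - mu - sign(w_pos - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * pnorm(-abs(z)))
  new_mir_test(w_pos, p, "Wilcoxon signed-rank (normal approximation)",
               n, exact = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Converts raw p-values into q-values controlling the false discovery rate:
#' `q_(i) = min_{j >= i} m * p_(j) / j` on the sorted p-values, clipped to 1,
#' then mapped back to the input order.
#'
#' @param pvals numeric vector of p-values, all in \[0, 1\]; NAs not allowed.
#'
#' @return Numeric vector of q-values, same length and order as `pvals`.
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04, 0.05))
#' @export
benjamini_hochberg <- function(pvals) {
  pvals <- as.numeric(pvals)
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1)) {
    stop("all p-values must lie in [0, 1]")
  }
  m <- length(pvals)
  if (m == 0L) return(numeric(0))
  o <- order(pvals)
  q_sorted <- pmin(1, rev(cummin(rev(m * pvals[o] / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact two-sided test of independence for a 2x2 contingency table,
#' conditioning on the margins. The two-sided p-value follows the
#' point-probability rule: the sum of hypergeometric probabilities of all
#' tables (under the fixed margins) no more probable than the observed one.
#' The doubling rule (twice the smaller one-sided tail) is a common
#' alternative not used here.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#'
#' @return A [mir_test][new_mir_test]; `statistic` is the sample odds ratio.
#' @examples
#' fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2))  # p = 1/3
#' @export
fisher_exact_2x2 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) stop("table must be 2x2")
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be non-negative integers")
  }
  a <- tab[1, 1]
  m1 <- sum(tab[1, ]); m2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  support <- max(0, c1 - m2):min(c1, m1)
  probs <- stats::dhyper(support, m1, m2, c1)
  p_obs <- stats::dhyper(a, m1, m2, c1)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  new_mir_test(or, p, "Fisher's exact test (2x2, point-probability rule)",
               c(m1, m2), exact = TRUE)
}

#' Pearson chi-square test of independence
#'
#' Classic Pearson X-squared statistic on an r x c contingency table, no
#' continuity correction, with `(r-1)(c-1)` degrees of freedom. Any expected
#' cell of zero is an error (use [fisher_exact_2x2()] for sparse 2x2 tables).
#'
#' @param table r x c matrix of non-negative counts.
#'
#' @return A [mir_test][new_mir_test] with `statistic` = X-squared and `df`.
#' @export
chi_square_independence <- function(table) {
  tab <- as.matrix(table)
  if (any(tab < 0)) stop("counts must be non-negative")
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  expected <- outer(rs, cs) / n
  if (any(expected == 0)) {
    stop("zero expected cell count; consider Fisher's exact test")
  }
  x2 <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  p <- pchisq(x2, df, lower.tail = FALSE)
  new_mir_test(x2, p, "Pearson chi-square test of independence",
               rs, exact = FALSE, df = df)
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected Kruskal-Wallis H statistic across k groups, with the
#' chi-square approximation on k - 1 degrees of freedom.
#'
#' @param groups list of two or more non-empty numeric vectors.
#'
#' @return A [mir_test][new_mir_test] with `statistic` = H and `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need a list of at least 2 groups")
  }
  sizes <- lengths(groups)
  if (any(sizes == 0L)) stop("all groups must be non-empty")
  pooled <- unlist(groups, use.names = FALSE)
  n <- length(pooled)
  r <- rank(pooled)
  grp <- rep(seq_along(groups), sizes)
  rank_sums <- tapply(r, grp, sum)
  h <- 12 / (n * (n + 1)) * sum(rank_sums^2 / sizes) - 3 * (n + 1)
  ties <- table(r)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr <= 0) {                           # all observations tied
    h <- 0
  } else {
    h <- h / corr
  }
  df <- length(groups) - 1L
  p <- pchisq(h, df, lower.tail = FALSE)
  new_mir_test(h, p, "Kruskal-Wallis rank-sum test (tie-corrected)",
               as.integer(sizes), exact = FALSE, df = df)
}

#' One-way MANOVA via Wilks' lambda
#'
#' Multivariate one-way analysis of variance: Wilks' lambda
#' `det(W) / det(W + B)` from the within- and between-group scatter
#' matrices, with Rao's F approximation for the p-value. Also returns the
#' univariate one-way ANOVA F for each response column, so single-response
#' calls reduce exactly to ordinary ANOVA.
#'
#' @param responses numeric matrix (n observations x p responses), complete
#'   cases only.
#' @param group_labels grouping vector of length n with at least 2 levels.
#'
#' @return A [mir_test][new_mir_test] with `statistic` = Wilks' lambda,
#'   `f_value`, `df` (the F numerator/denominator dfs) and `univariate`, a
#'   tibble of per-response F statistics and p-values.
#' @export
manova_wilks <- function(responses, group_labels) {
  Y <- as.matrix(responses)
  storage.mode(Y) <- "double"
  g <- as.factor(group_labels)
  if (anyNA(Y)) stop("responses must be complete cases")
  if (nlevels(droplevels(g)) < 2L) stop("need at least 2 groups")
  g <- droplevels(g)
  n <- nrow(Y); p <- ncol(Y); k <- nlevels(g)
  if (n <= p + k) stop("need n > p + number of groups")
  grand <- colMeans(Y)
  W <- matrix(0, p, p); B <- matrix(0, p, p)
  for (lev in levels(g)) {
    Yi <- Y[g == lev, , drop = FALSE]
    mi <- colMeans(Yi)
    Ci <- sweep(Yi, 2L, mi)
    W <- W + crossprod(Ci)
    d <- mi - grand
    B <- B + nrow(Yi) * tcrossprod(d)
  }
  qrW <- qr(W)
  if (qrW$rank < p) {
    nm <- colnames(Y) %||% paste0("y", seq_len(p))
    bad <- nm[qrW$pivot[(qrW$rank + 1L):p]]
    stop("within-group scatter is singular; collinear response column(s): ",
         paste(bad, collapse = ", "))
  }
  lambda <- det(W) / det(W + B)
  df_h <- k - 1L; df_e <- n - k
  tt <- if (p^2 + df_h^2 - 5 > 0) {
    sqrt((p^2 * df_h^2 - 4) / (p^2 + df_h^2 - 5))
  } else 1
  df1 <- p * df_h
  df2 <- (df_e + df_h - (p + df_h + 1) / 2) * tt - (p * df_h - 2) / 2
  lam_t <- lambda^(1 / tt)
  f_val <- if (lambda >= 1) 0 else (1 - lam_t) / lam_t * df2 / df1
  p_val <- stats::pf(f_val, df1, df2, lower.tail = FALSE)
  f_uni <- (diag(B) / df_h) / (diag(W) / df_e)
  univariate <- tibble::tibble(
    response = colnames(Y) %||% paste0("y", seq_len(p)),
    f_value = unname(f_uni),
    p_value = stats::pf(f_uni, df_h, df_e, lower.tail = FALSE)
  )
  new_mir_test(lambda, p_val, "one-way MANOVA (Wilks' lambda, Rao's F)",
               as.integer(table(g)), exact = FALSE,
               f_value = f_val, df = c(df1, df2), univariate = univariate)
}
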