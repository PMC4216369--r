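#' Ward hierarchical clustering of expression profiles
#'
#' Clusters samples by their miRNA expression profiles: each miRNA row is
#' z-scored on the log2(RPKM + 1) scale (constant rows are dropped, since
#' they carry no distance information), samples are compared by Euclidean
#' distance, and the tree is built with Ward's minimum-variance criterion
#' (the `ward.D2` form of the Lance-Williams update, which operates on the
#' distances themselves) and cut into `k` clusters.
#'
#' @param expr expression tibble.
#' @param k number of clusters (at most the number of samples).
#'
#' @return A `cluster_assignment`: tibble with `sample_id` and `cluster`
#'   (integer 1..k, labelled in order of first appearance), with the
#'   `hclust` merge tree in attribute `tree`.
#' @export
ward_cluster <- function(expr, k) {
  expr <- validate_expression(expr)
  m <- expr_matrix(expr)
  n <- ncol(m)
  if (k > n) stop("k = ", k, " exceeds the ", n, " samples")
  lg <- log2(m + 1)
  keep <- apply(lg, 1L, sd) > 0
  z <- t(scale(t(lg[keep, , drop = FALSE])))
  d <- stats::dist(t(z), method = "euclidean")
  tree <- stats::hclust(d, method = "ward.D2")
  raw <- stats::cutree(tree, k = k)
  relab <- match(raw, unique(raw))      # contiguous labels from 1
  out <- tibble::tibble(sample_id = colnames(m), cluster = relab)
  attr(out, "tree") <- tree
  class(out) <- c("cluster_assignment", class(out))
  out
}

#' Test cluster composition against a categorical label
#'
#' Checks whether cluster membership is associated with a sample label
#' (malignancy, smoking status, ...): Fisher's exact test for a 2x2
#' cluster-by-label table, Pearson chi-square for anything larger.
#'
#' @param assign cluster assignment from [ward_cluster()].
#' @param labels named (by sample_id) or assignment-ordered categorical
#'   vector.
#'
#' @return A [mir_test][new_mir_test].
#' @export
cluster_composition_test <- function(assign, labels) {
  if (!is.null(names(labels))) labels <- labels[assign$sample_id]
  if (anyNA(labels)) stop("labels must cover every clustered sample")
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2L) {
    stop("labels are degenerate (single level)")
  }
  tab <- table(assign$cluster, labels)
  if (all(dim(tab) == c(2L, 2L))) {
    fisher_exact_2x2(tab)
  } else {
    chi_square_independence(tab)
  }
}

#' Scan clinical covariates for association with cluster membership
#'
#' For each covariate, tests whether its distribution differs across
#' clusters with a one-way ANOVA F (the single-response reduction of the
#' Wilks MANOVA). Categorical covariates are encoded numerically first:
#' stage as the ordinal I < II < III < IV, other factors as integer codes.
#' Covariates that are entirely missing or constant on the complete cases
#' are skipped with a warning.
#'
#' @param assign cluster assignment from [ward_cluster()].
#' @param meta metadata tibble with `sample_id`.
#' @param covariates character vector of metadata column names.
#'
#' @return Tibble with `covariate`, `f_value`, `p_value`, `n_used`.
#' @export
cluster_covariate_scan <- function(assign, meta,
                                   covariates = c("smoking", "age", "sex",
                                                  "stage", "ethnicity",
                                                  "pack_years",
                                                  "years_quit")) {
  meta <- tibble::as_tibble(meta)
  joined <- dplyr::inner_join(tibble::as_tibble(assign), meta,
                              by = "sample_id")
  purrr::map_dfr(covariates, function(cv) {
    if (!cv %in% names(joined)) {
      warning("covariate not in metadata, skipped: ", cv)
      return(tibble::tibble())
    }
    v <- encode_covariate(joined[[cv]], cv)
    ok <- !is.na(v)
    v <- v[ok]; cl <- joined$cluster[ok]
    if (length(v) == 0L) {
      warning("covariate skipped (all missing): ", cv)
      return(tibble::tibble())
    }
    if (length(unique(v)) < 2L || length(unique(cl)) < 2L) {
      # a constant covariate cannot separate clusters: F = 0 by definition
      return(tibble::tibble(covariate = cv, f_value = 0, p_value = 1,
                            n_used = length(v)))
    }
    res <- manova_wilks(matrix(v, ncol = 1), cl)
    tibble::tibble(covariate = cv, f_value = res$univariate$f_value,
                   p_value = res$univariate$p_value, n_used = length(v))
  })
}

# numeric encoding for the covariate scan; stage keeps its clinical order
encode_covariate <- function(v, name) {
  if (is.numeric(v)) return(v)
  if (name == "stage") {
    out <- match(v, c("I", "II", "III", "IV"))
    return(as.numeric(out))
  }
  v[v == "unknown"] <- NA
  as.numeric(as.factor(v))
}

#' Compare a numeric covariate between two named clusters
#'
#' Two-sample Student's t-test of a metadata covariate (pack-years,
#' years-quit, ...) between two clusters of an assignment.
#'
#' @param assign cluster assignment.
#' @param meta metadata tibble.
#' @param covariate metadata column name (numeric).
#' @param clusters length-2 integer vector naming the clusters compared.
#'
#' @return The `htest` from [stats::t.test()].
#' @export
cluster_covariate_ttest <- function(assign, meta, covariate,
                                    clusters = c(1L, 2L)) {
  joined <- dplyr::inner_join(tibble::as_tibble(assign), meta,
                              by = "sample_id")
  a <- joined[[covariate]][joined$cluster == clusters[1]]
  b <- joined[[covariate]][joined$cluster == clusters[2]]
  stats::t.test(a[!is.na(a)], b[!is.na(b)])
}

#' Per-miRNA Kruskal-Wallis differential expression between clusters
#'
#' Tests each miRNA for expression differences across the clusters of an
#' assignment (Kruskal-Wallis on log2(RPKM + 1)), with Benjamini-Hochberg
#' correction across miRNAs. Clusters with fewer than 2 samples are
#' excluded from the test with a warning.
#'
#' @param expr expression tibble.
#' @param assign cluster assignment covering `expr`'s samples.
#' @param cfg an [analysis_config()] supplying the q threshold.
#'
#' @return Tibble with `mirna_id`, `h`, `p`, `q`, `significant`.
#' @export
between_cluster_de <- function(expr, assign, cfg = analysis_config()) {
  expr <- validate_expression(expr)
  m <- log2(expr_matrix(expr) + 1)
  cl <- setNames(assign$cluster, assign$sample_id)[colnames(m)]
  if (anyNA(cl)) stop("assignment must cover every expression sample")
  sizes <- table(cl)
  keep_cl <- names(sizes)[sizes >= 2L]
  if (length(keep_cl) < length(sizes)) {
    warning("cluster(s) with < 2 samples excluded: ",
            paste(setdiff(names(sizes), keep_cl), collapse = ", "))
  }
  if (length(keep_cl) < 2L) stop("need at least 2 clusters with >= 2 samples")
  cols <- cl %in% keep_cl
  mm <- m[, cols, drop = FALSE]; cc <- cl[cols]
  res <- apply(mm, 1L, function(row) {
    kw <- kruskal_wallis(split(row, cc))
    c(kw$statistic, kw$p_value)
  })
  p <- res[2, ]
  q <- benjamini_hochberg(p)
  tibble::tibble(
    mirna_id = expr$mirna_id, h = unname(res[1, ]), p = unname(p), q = q,
    significant = q < cfg$q_threshold
  )
}

#' Overlap between two significant miRNA sets
#'
#' Reports `|A intersect B| / |A|` and `|A intersect B| / |B|`, the two
#' directional overlap fractions used to compare cluster-discriminating
#' miRNA sets between tissue compartments.
#'
#' @param set_a,set_b character vectors of miRNA identifiers.
#'
#' @return Tibble with `n_a`, `n_b`, `n_common`, `frac_of_a`, `frac_of_b`.
#' @export
overlap_report <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  common <- intersect(set_a, set_b)
  tibble::tibble(
    n_a = length(set_a), n_b = length(set_b), n_common = length(common),
    frac_of_a = if (length(set_a) == 0L) NA_real_
                else length(common) / length(set_a),
    frac_of_b = if (length(set_b) == 0L) NA_real_
                else length(common) / length(set_b)
  )
}
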