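#' Analysis thresholds for differential-expression calling
#'
#' Collects the decision thresholds used throughout the DE stages: the
#' Benjamini-Hochberg q cutoff, the fold-change gates for over- and
#' underexpression (reciprocal of each other by construction), the
#' recurrence fraction ("altered in at least this fraction of a group's
#' pairs"), the permutation count, the external-validation minimum
#' disruption-frequency difference, the RPKM detection floor, and the seed
#' for Monte-Carlo permutations.
#'
#' @param q_threshold B-H q cutoff (default 0.05; strict `<`).
#' @param fc_over fold-change gate for overexpression (default 2.0;
#'   strict `>`). The underexpression gate is its reciprocal.
#' @param recurrence_frac minimum fraction of pairs beyond the fold gate
#'   (default 0.25; inclusive `>=`).
#' @param n_perm permutations for group-comparison tests (default 10000).
#' @param validation_min_freq_diff minimum disruption-frequency difference
#'   for external validation (default 0.15; inclusive).
#' @param detection_floor RPKM detection floor (default 1.0).
#' @param seed integer seed recorded and used for permutation draws.
#'
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(q_threshold = 0.05, fc_over = 2.0,
                            recurrence_frac = 0.25, n_perm = 10000,
                            validation_min_freq_diff = 0.15,
                            detection_floor = 1.0, seed = 1L) {
  stopifnot(q_threshold > 0, fc_over > 1,
            recurrence_frac > 0, recurrence_frac <= 1,
            n_perm >= 1, detection_floor >= 0)
  structure(list(
    q_threshold = q_threshold, fc_over = fc_over, fc_under = 1 / fc_over,
    recurrence_frac = recurrence_frac, n_perm = as.integer(n_perm),
    validation_min_freq_diff = validation_min_freq_diff,
    detection_floor = detection_floor, seed = as.integer(seed)
  ), class = "analysis_config")
}

#' Detection-floored tumor/normal fold change
#'
#' RPKM below the detection floor is indistinguishable from absence, so
#' both numerator and denominator are floored before the ratio:
#' `max(tumor, floor) / max(normal, floor)`. Two undetectable values give a
#' fold of exactly 1. Vectorized over its arguments.
#'
#' @param tumor_rpkm,normal_rpkm non-negative RPKM values.
#' @param floor detection floor (default 1.0).
#'
#' @return Numeric fold change(s).
#' @examples
#' fold_change(0.5, 0.2)  # 1: both below the floor
#' fold_change(4, 1)      # 4
#' @export
fold_change <- function(tumor_rpkm, normal_rpkm, floor = 1.0) {
  stopifnot(all(tumor_rpkm >= 0), all(normal_rpkm >= 0))
  pmax(tumor_rpkm, floor) / pmax(normal_rpkm, floor)
}

# internal: pick expression columns for samples of one tissue/group
sample_columns <- function(meta, tissue = NULL, smoking = NULL) {
  keep <- rep(TRUE, nrow(meta))
  if (!is.null(tissue)) keep <- keep & meta$tissue %in% tissue
  if (!is.null(smoking)) keep <- keep & meta$smoking %in% smoking
  meta$sample_id[keep]
}

#' Group-level differential expression by permutation test
#'
#' Compares two sets of samples (by default current-smoker vs never-smoker
#' normal tissue) per miRNA with a two-sided permutation test on
#' log2(RPKM + 1) (difference of group means, shared Monte-Carlo
#' permutations across miRNAs, add-one p-values), corrects across miRNAs by
#' Benjamini-Hochberg, and combines the q-value with an average fold
#' change: the ratio of detection-floored group mean RPKMs. A miRNA is
#' flagged `over` when q < `q_threshold` and fold > `fc_over`, `under` when
#' q < `q_threshold` and fold < `fc_under`, otherwise `none`. The same
#' machinery compares tumor groups by setting `tissue = "tumor"`.
#'
#' @param expr expression tibble (already detection-filtered).
#' @param meta metadata tibble covering the samples to compare.
#' @param group_a,group_b smoking groups compared (fold = a over b).
#' @param tissue tissue compartment to compare within (default "normal").
#' @param cfg an [analysis_config()].
#'
#' @return Tibble with `mirna_id`, `statistic` (mean log2 difference), `p`,
#'   `q`, `mean_fold`, `status`.
#' @export
smoke_response_de <- function(expr, meta, group_a = "CS", group_b = "NS",
                              tissue = "normal", cfg = analysis_config()) {
  expr <- validate_expression(expr)
  cols_a <- intersect(names(expr), sample_columns(meta, tissue, group_a))
  cols_b <- intersect(names(expr), sample_columns(meta, tissue, group_b))
  if (length(cols_a) < 2L || length(cols_b) < 2L) {
    stop("each group needs at least 2 samples in the expression table")
  }
  m <- expr_matrix(expr[c("mirna_id", cols_a, cols_b)])
  lg <- log2(m + 1)
  is_a <- c(rep(TRUE, length(cols_a)), rep(FALSE, length(cols_b)))
  pt <- perm_test_rows(lg, is_a, n_perm = cfg$n_perm, seed = cfg$seed)
  q <- benjamini_hochberg(pt$p_value)
  mean_a <- rowMeans(m[, cols_a, drop = FALSE])
  mean_b <- rowMeans(m[, cols_b, drop = FALSE])
  fold <- fold_change(mean_a, mean_b, cfg$detection_floor)
  status <- dplyr::case_when(
    q < cfg$q_threshold & fold > cfg$fc_over ~ "over",
    q < cfg$q_threshold & fold < cfg$fc_under ~ "under",
    TRUE ~ "none"
  )
  tibble::tibble(
    mirna_id = expr$mirna_id, statistic = pt$statistic, p = pt$p_value,
    q = q, mean_fold = fold, status = status
  )
}

# internal: per-pair fold matrix (miRNA x pair) for one paired cohort
pair_folds <- function(expr, pairs, floor = 1.0) {
  m <- expr_matrix(expr)
  missing_ids <- setdiff(c(pairs$tumor_sample_id, pairs$normal_sample_id),
                         colnames(m))
  if (length(missing_ids) > 0L) {
    stop("pair sample(s) absent from expression table: ",
         paste(missing_ids, collapse = ", "))
  }
  folds <- fold_change(m[, pairs$tumor_sample_id, drop = FALSE],
                       m[, pairs$normal_sample_id, drop = FALSE], floor)
  dimnames(folds) <- list(rownames(m), pairs$patient_id)
  folds
}

#' Recurrence ("penetrance") differential-expression calling
#'
#' The paired recurrence criterion for one smoking group: a miRNA is called
#' deregulated when (i) the Wilcoxon signed-rank test on per-pair
#' log2(tumor/normal fold) values survives Benjamini-Hochberg correction at
#' q < `q_threshold` across all miRNAs of the group, and (ii) its fold
#' change exceeds `fc_over` (overexpression) or falls below `fc_under`
#' (underexpression) in at least `recurrence_frac` of the group's pairs
#' (inclusive, so 2 of 8 pairs meets the default 25%). If both directions
#' pass the frequency gate the more frequent one wins; a tie gives `none`.
#' `recurrence_scan()` processes every miRNA of a group (the B-H family is
#' the group's full miRNA set); `recurrence_call()` returns a single
#' miRNA's row.
#'
#' @param expr expression tibble.
#' @param pairs one group's pair tibble from [build_pairs()] (at least 4
#'   pairs).
#' @param cfg an [analysis_config()].
#'
#' @return Tibble with `mirna_id`, `group`, `wilcoxon_p`, `bh_q`,
#'   `freq_over`, `freq_under`, `direction` (over/under/none).
#' @export
recurrence_scan <- function(expr, pairs, cfg = analysis_config()) {
  expr <- validate_expression(expr)
  pairs <- tibble::as_tibble(pairs)
  if (nrow(pairs) < 4L) stop("need at least 4 tumor/normal pairs")
  group <- unique(pairs$group)
  if (length(group) != 1L) stop("pairs must all share one smoking group")
  folds <- pair_folds(expr, pairs, cfg$detection_floor)
  lf <- log2(folds)
  pvals <- apply(lf, 1L, function(d) wilcoxon_signed_rank(d)$p_value)
  q <- benjamini_hochberg(pvals)
  freq_over <- rowMeans(folds > cfg$fc_over)
  freq_under <- rowMeans(folds < cfg$fc_under)
  sig <- q < cfg$q_threshold
  over_ok <- sig & freq_over >= cfg$recurrence_frac
  under_ok <- sig & freq_under >= cfg$recurrence_frac
  direction <- dplyr::case_when(
    over_ok & (!under_ok | freq_over > freq_under) ~ "over",
    under_ok & (!over_ok | freq_under > freq_over) ~ "under",
    TRUE ~ "none"
  )
  tibble::tibble(
    mirna_id = expr$mirna_id, group = group, wilcoxon_p = unname(pvals),
    bh_q = q, freq_over = unname(freq_over), freq_under = unname(freq_under),
    direction = direction
  )
}

#' @rdname recurrence_scan
#' @param mirna single miRNA identifier to report.
#' @export
recurrence_call <- function(expr, pairs, mirna, cfg = analysis_config()) {
  out <- recurrence_scan(expr, pairs, cfg)
  row <- out[out$mirna_id == mirna, ]
  if (nrow(row) == 0L) stop("miRNA not in expression table: ", mirna)
  row
}

#' Smoking-status specificity classification
#'
#' Pools the per-group recurrence calls and classifies each (miRNA,
#' direction): deregulated in exactly one smoking group = that group's
#' specific miRNA; in all three = shared across smoking histories
#' (`shared-all`); in two = `partial`. A miRNA can legitimately carry two
#' calls of opposite direction in different groups (e.g. underexpressed in
#' current-smoker tumors while overexpressed in never-smoker tumors).
#'
#' @param calls row-bound [recurrence_scan()] output covering all three
#'   smoking groups for every miRNA.
#'
#' @return Tibble with `mirna_id`, `direction`, `n_groups` (how many groups
#'   met the criteria), `groups` (comma-joined), and `pattern`
#'   (`CS-specific`, `FS-specific`, `NS-specific`, `shared-all`,
#'   `partial`). miRNAs with no qualifying direction are absent.
#' @export
classify_specificity <- function(calls) {
  calls <- tibble::as_tibble(calls)
  have <- calls |> dplyr::distinct(.data$mirna_id, .data$group)
  n_groups_per <- table(have$mirna_id)
  if (any(n_groups_per < 3L)) {
    stop("recurrence calls missing for some miRNA/group combinations")
  }
  calls |>
    dplyr::filter(.data$direction != "none") |>
    dplyr::group_by(.data$mirna_id, .data$direction) |>
    dplyr::summarise(
      n_groups = dplyr::n(),
      groups = paste(sort(.data$group), collapse = ","),
      .groups = "drop"
    ) |>
    dplyr::mutate(pattern = dplyr::case_when(
      .data$n_groups == 1L ~ paste0(.data$groups, "-specific"),
      .data$n_groups == 3L ~ "shared-all",
      TRUE ~ "partial"
    ))
}

#' Reversibility of smoke-responsive miRNAs in former-smoker normals
#'
#' A miRNA is smoke-responsive when differentially expressed between
#' current-smoker and never-smoker normal tissue. Among those, expression
#' in former-smoker normals decides the class: still differentially
#' expressed versus never-smoker normals in the same direction =
#' `irreversible`; returned to never-smoker levels (not DE) = `reversible`.
#' A former-smoker shift in the opposite direction is recorded as a
#' conflict and the miRNA is classed `not-smoke-responsive` with a warning.
#'
#' @param csn_de [smoke_response_de()] result for CS-normal vs NS-normal.
#' @param fsn_de [smoke_response_de()] result for FS-normal vs NS-normal
#'   (same miRNA universe).
#' @param cfg an [analysis_config()] (thresholds already baked into the
#'   `status` columns; retained for the record).
#'
#' @return Tibble with `mirna_id`, `class`, `cs_status`, `fs_status`,
#'   `cs_fold`, `fs_fold`, `conflict`.
#' @export
classify_reversibility <- function(csn_de, fsn_de, cfg = analysis_config()) {
  stopifnot(setequal(csn_de$mirna_id, fsn_de$mirna_id))
  joined <- dplyr::inner_join(
    csn_de |> dplyr::select("mirna_id", cs_status = "status",
                            cs_fold = "mean_fold"),
    fsn_de |> dplyr::select("mirna_id", fs_status = "status",
                            fs_fold = "mean_fold"),
    by = "mirna_id"
  )
  out <- joined |>
    dplyr::mutate(
      conflict = .data$cs_status != "none" & .data$fs_status != "none" &
        .data$cs_status != .data$fs_status,
      class = dplyr::case_when(
        .data$cs_status == "none" ~ "not-smoke-responsive",
        .data$conflict ~ "not-smoke-responsive",
        .data$fs_status == .data$cs_status ~ "irreversible",
        TRUE ~ "reversible"
      )
    )
  if (any(out$conflict)) {
    warning(sum(out$conflict), " miRNA(s) shifted in the opposite direction ",
            "in former-smoker normals; classed not-smoke-responsive")
  }
  out |>
    dplyr::select("mirna_id", "class", "cs_status", "fs_status",
                  "cs_fold", "fs_fold", "conflict")
}

#' Disruption frequencies of tumors against pooled normals
#'
#' For external cohorts lacking matched normals, each tumor's fold change
#' is computed against the pooled mean of the cohort's normal samples of
#' the same smoking status, and a tumor counts as disrupted when that fold
#' passes the over/under gate in the stated direction.
#'
#' @param expr expression tibble of the external cohort.
#' @param meta its metadata tibble.
#' @param mirnas miRNAs to tabulate (default: all in `expr`).
#' @param direction "over" or "under".
#' @param cfg an [analysis_config()].
#'
#' @return Tibble with `mirna_id`, `group`, `k` (disrupted tumors), `n`
#'   (group tumors).
#' @export
disruption_table <- function(expr, meta, mirnas = NULL, direction = "over",
                             cfg = analysis_config()) {
  expr <- validate_expression(expr)
  direction <- match.arg(direction, c("over", "under"))
  if (!is.null(mirnas)) expr <- expr[expr$mirna_id %in% mirnas, ]
  m <- expr_matrix(expr)
  purrr::map_dfr(SMOKING_LEVELS, function(g) {
    tcols <- intersect(colnames(m), sample_columns(meta, "tumor", g))
    ncols <- intersect(colnames(m), sample_columns(meta, "normal", g))
    if (length(tcols) == 0L || length(ncols) == 0L) {
      return(tibble::tibble(mirna_id = character(0), group = character(0),
                            k = integer(0), n = integer(0)))
    }
    pooled_normal <- rowMeans(m[, ncols, drop = FALSE])
    folds <- fold_change(m[, tcols, drop = FALSE],
                         matrix(pooled_normal, nrow(m), length(tcols)),
                         cfg$detection_floor)
    disrupted <- if (direction == "over") folds > cfg$fc_over
                 else folds < cfg$fc_under
    tibble::tibble(mirna_id = rownames(m), group = g,
                   k = as.integer(rowSums(disrupted)), n = length(tcols))
  })
}

#' External-cohort validation of smoking-status-specific calls
#'
#' A specific miRNA validates in an external cohort when the frequency of
#' disruption in its focal smoking group differs from the other groups both
#' statistically (Fisher's exact test on the 2x2 disrupted/not x
#' focal/rest table, p < 0.05) and materially (absolute frequency
#' difference at least `validation_min_freq_diff`, default 15 percentage
#' points).
#'
#' @param freqs tibble with one row per miRNA: `mirna_id`, `k_focal`,
#'   `n_focal`, `k_rest`, `n_rest` (disrupted counts over group sizes).
#' @param cfg an [analysis_config()].
#'
#' @return Input tibble with added `freq_focal`, `freq_rest`, `fisher_p`,
#'   `freq_diff`, `validated`.
#' @export
external_validation <- function(freqs, cfg = analysis_config()) {
  freqs <- tibble::as_tibble(freqs)
  stopifnot(all(c("mirna_id", "k_focal", "n_focal", "k_rest", "n_rest")
                %in% names(freqs)))
  if (any(freqs$n_focal == 0L) || any(freqs$n_rest == 0L)) {
    stop("empty group: every miRNA needs n_focal > 0 and n_rest > 0")
  }
  stopifnot(all(freqs$k_focal <= freqs$n_focal),
            all(freqs$k_rest <= freqs$n_rest))
  freqs |>
    dplyr::mutate(
      freq_focal = .data$k_focal / .data$n_focal,
      freq_rest = .data$k_rest / .data$n_rest,
      fisher_p = purrr::pmap_dbl(
        list(.data$k_focal, .data$n_focal, .data$k_rest, .data$n_rest),
        function(kf, nf, kr, nr) {
          tab <- matrix(c(kf, nf - kf, kr, nr - kr), 2, byrow = TRUE)
          fisher_exact_2x2(tab)$p_value
        }
      ),
      freq_diff = abs(.data$freq_focal - .data$freq_rest),
      validated = .data$fisher_p < 0.05 &
        .data$freq_diff >= cfg$validation_min_freq_diff
    )
}
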