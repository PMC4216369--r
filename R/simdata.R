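#' Configuration of the synthetic miRNA cohort generator
#'
#' Bundles every knob of the simulated paired tumor/normal miRNA-seq cohort.
#' The defaults emulate the statistical shape of a 94-patient lung
#' adenocarcinoma cohort sequenced as matched tumor/normal pairs and split
#' by smoking history (43 current, 24 former, 27 never smokers; 188
#' libraries), with heavy-tailed log-normal RPKM, 1372 annotated miRNAs of
#' which 445 are undetectable everywhere (so 927 survive the detection
#' filter), mostly-overexpressed planted tumor effects, smoking-group
#' specific miRNAs, reversible/irreversible smoke-response patterns in
#' normal tissue, and one expression-linked prognostic miRNA.
#'
#' @param seed integer RNG seed; identical configs reproduce bit-identical
#'   cohorts (Mersenne-Twister, recorded in the output).
#' @param n_per_group named patient counts for CS, FS, NS.
#' @param n_mirna total simulated miRNA features.
#' @param baseline_log_mean,baseline_log_sd natural-log mean/sd of the
#'   per-miRNA resting expression (log-normal across features).
#' @param frac_undetectable fraction of features forced below the detection
#'   floor in every sample.
#' @param planted_shared named counts `c(over=, under=)` of miRNAs
#'   deregulated in tumors of all three smoking groups.
#' @param planted_specific list `CS/FS/NS`, each `c(over=, under=)`: counts
#'   of miRNAs deregulated in tumors of exactly one group.
#' @param tumor_fc multiplicative tumor/normal effect for planted rows.
#' @param penetrance probability that an individual pair carries a planted
#'   tumor effect (Bernoulli per pair, mirroring recurrence-style calling).
#' @param smoke_response list with `up`, `down` (counts of smoke-responsive
#'   miRNAs shifted up/down in current-smoker normal tissue),
#'   `n_irreversible` (how many of them stay shifted in former-smoker
#'   normals; the rest revert, i.e. are reversible) and `fold`.
#' @param noise_log_sd per-measurement natural-log noise sd.
#' @param surv_baseline_hazard exponential event rate, events/month.
#' @param surv_loghr log hazard ratio per standard deviation of the
#'   designated prognostic miRNA's log2 tumor expression.
#' @param censor_rate target fraction of patients administratively censored
#'   (uniform-entry censoring calibrated at the baseline hazard).
#'
#' @return A `sim_config` list, validated.
#' @export
simulation_config <- function(seed = 1L,
                              n_per_group = c(CS = 43L, FS = 24L, NS = 27L),
                              n_mirna = 1372L,
                              baseline_log_mean = 1.5,
                              baseline_log_sd = 1.5,
                              frac_undetectable = 445 / 1372,
                              planted_shared = c(over = 196L, under = 36L),
                              planted_specific = list(
                                CS = c(over = 14L, under = 11L),
                                FS = c(over = 12L, under = 2L),
                                NS = c(over = 26L, under = 1L)
                              ),
                              tumor_fc = 4.0,
                              penetrance = 0.5,
                              smoke_response = list(up = 25L, down = 12L,
                                                    n_irreversible = 15L,
                                                    fold = 4.0),
                              noise_log_sd = 0.25,
                              surv_baseline_hazard = 0.02,
                              surv_loghr = 0.7,
                              censor_rate = 0.3) {
  # accept list-shaped inputs (e.g. parsed from YAML) transparently
  n_per_group <- unlist(n_per_group)
  planted_shared <- unlist(planted_shared)
  planted_specific <- lapply(planted_specific, unlist)
  cfg <- list(
    seed = as.integer(seed), n_per_group = n_per_group, n_mirna = n_mirna,
    baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
    frac_undetectable = frac_undetectable, planted_shared = planted_shared,
    planted_specific = planted_specific, tumor_fc = tumor_fc,
    penetrance = penetrance, smoke_response = smoke_response,
    noise_log_sd = noise_log_sd,
    surv_baseline_hazard = surv_baseline_hazard, surv_loghr = surv_loghr,
    censor_rate = censor_rate, rng_kind = "Mersenne-Twister"
  )
  stopifnot(
    all(SMOKING_LEVELS %in% names(cfg$n_per_group)),
    all(cfg$n_per_group >= 0), cfg$n_mirna >= 1,
    cfg$frac_undetectable >= 0, cfg$frac_undetectable < 1,
    cfg$penetrance > 0, cfg$penetrance <= 1,
    cfg$tumor_fc > 0, all(cfg$planted_shared >= 0),
    cfg$smoke_response$n_irreversible <=
      cfg$smoke_response$up + cfg$smoke_response$down
  )
  n_undet <- round(cfg$frac_undetectable * cfg$n_mirna)
  n_planted <- sum(cfg$planted_shared) +
    sum(vapply(cfg$planted_specific, sum, numeric(1))) +
    cfg$smoke_response$up + cfg$smoke_response$down + 1L  # + prognostic row
  if (n_planted > cfg$n_mirna - n_undet) {
    stop("infeasible planting: ", n_planted,
         " planted rows exceed the ", cfg$n_mirna - n_undet,
         " detectable features")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a paired tumor/normal miRNA cohort with known ground truth
#'
#' Draws a full synthetic cohort under a [simulation_config()]: a log-normal
#' RPKM expression table (miRNA x sample), per-sample clinical metadata, and
#' a ground-truth label table. Planted tumor effects multiply the tumor
#' sample of a carrier pair by `tumor_fc` (or its inverse for
#' underexpression), with carriers drawn per pair at the configured
#' penetrance. Smoke-responsive rows are shifted in all current-smoker
#' normal samples; the irreversible subset stays shifted in former-smoker
#' normals while the reversible remainder reverts to never-smoker levels.
#' Survival is exponential with hazard
#' `surv_baseline_hazard * exp(surv_loghr * z)` where `z` is the patient's
#' standardized log2 tumor expression of the designated prognostic miRNA,
#' under independent uniform-entry administrative censoring calibrated to
#' the target censoring fraction.
#'
#' @param cfg a [simulation_config()].
#'
#' @return A list with `expression` (tibble), `metadata` (tibble), `truth`
#'   (tibble with `mirna_id`, `label`, `direction`, `group`, `loghr`), and
#'   `config` (the input, echoed).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed, kind = cfg$rng_kind)

  groups <- rep(SMOKING_LEVELS, times = cfg$n_per_group[SMOKING_LEVELS])
  n_pat <- length(groups)
  patient_id <- sprintf("P%03d", seq_len(n_pat))
  tumor_id <- paste0(patient_id, "T")
  normal_id <- paste0(patient_id, "N")
  sample_id <- c(rbind(tumor_id, normal_id))
  sample_group <- rep(groups, each = 2L)
  sample_tissue <- rep(c("tumor", "normal"), times = n_pat)
  n_samp <- 2L * n_pat

  n_undet <- round(cfg$frac_undetectable * cfg$n_mirna)
  mirna_id <- sprintf("mir-%04d", seq_len(cfg$n_mirna))
  undet_rows <- sort(sample.int(cfg$n_mirna, n_undet))
  det_rows <- setdiff(seq_len(cfg$n_mirna), undet_rows)

  # assign planted roles among the detectable rows
  labels <- rep("null", cfg$n_mirna)
  direction <- rep(NA_character_, cfg$n_mirna)
  grp_label <- rep(NA_character_, cfg$n_mirna)
  labels[undet_rows] <- "undetectable"
  pool <- sample(det_rows)      # random placement of planted rows
  take <- function(k) {
    if (k == 0L) return(integer(0))
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }
  plant <- list()
  plant$shared_over <- take(cfg$planted_shared[["over"]])
  plant$shared_under <- take(cfg$planted_shared[["under"]])
  for (g in SMOKING_LEVELS) {
    plant[[paste0(g, "_over")]] <- take(cfg$planted_specific[[g]][["over"]])
    plant[[paste0(g, "_under")]] <- take(cfg$planted_specific[[g]][["under"]])
  }
  sr_n <- cfg$smoke_response$up + cfg$smoke_response$down
  sr_rows <- take(sr_n)
  sr_dir <- rep(c("over", "under"),
                c(cfg$smoke_response$up, cfg$smoke_response$down))
  irrev <- rep(FALSE, sr_n)
  if (cfg$smoke_response$n_irreversible > 0) {
    # irreversible rows spread across both directions proportionally
    irrev[sample.int(sr_n, cfg$smoke_response$n_irreversible)] <- TRUE
  }
  prog_row <- take(1L)

  labels[plant$shared_over] <- "shared"
  labels[plant$shared_under] <- "shared"
  direction[plant$shared_over] <- "over"
  direction[plant$shared_under] <- "under"
  for (g in SMOKING_LEVELS) {
    ro <- plant[[paste0(g, "_over")]]; ru <- plant[[paste0(g, "_under")]]
    labels[c(ro, ru)] <- paste0(g, "-specific")
    direction[ro] <- "over"; direction[ru] <- "under"
    grp_label[c(ro, ru)] <- g
  }
  labels[sr_rows] <- ifelse(irrev, "irreversible", "reversible")
  direction[sr_rows] <- sr_dir
  labels[prog_row] <- "prognostic"

  # baseline expression and measurement noise on the natural-log scale.
  # Planted rows draw their baseline from the detectable part of the
  # distribution (resting RPKM >= 4 x the unit floor): a detection-floored
  # fold-change criterion cannot represent a planted effect on a sub-floor
  # miRNA (underexpression in particular needs baseline >= fc x floor), and
  # the candidate miRNAs such criteria produce on real data are by
  # construction detectably expressed.
  mu <- stats::rnorm(cfg$n_mirna, cfg$baseline_log_mean, cfg$baseline_log_sd)
  planted_rows <- setdiff(which(!labels %in% c("null", "undetectable")),
                          integer(0))
  mu_floor <- log(4)
  redraw <- planted_rows[mu[planted_rows] < mu_floor]
  while (length(redraw) > 0L) {
    mu[redraw] <- stats::rnorm(length(redraw), cfg$baseline_log_mean,
                               cfg$baseline_log_sd)
    redraw <- redraw[mu[redraw] < mu_floor]
  }
  logex <- matrix(stats::rnorm(cfg$n_mirna * n_samp, 0, cfg$noise_log_sd),
                  cfg$n_mirna, n_samp) + mu

  lfc <- log(cfg$tumor_fc)
  tumor_cols <- which(sample_tissue == "tumor")
  add_tumor_effect <- function(rows, dir, target_groups) {
    if (length(rows) == 0L) return()
    cols <- tumor_cols[sample_group[tumor_cols] %in% target_groups]
    eff <- if (dir == "over") lfc else -lfc
    carrier <- matrix(
      stats::runif(length(rows) * length(cols)) < cfg$penetrance,
      length(rows), length(cols)
    )
    logex[rows, cols] <<- logex[rows, cols] + eff * carrier
  }
  add_tumor_effect(plant$shared_over, "over", SMOKING_LEVELS)
  add_tumor_effect(plant$shared_under, "under", SMOKING_LEVELS)
  for (g in SMOKING_LEVELS) {
    add_tumor_effect(plant[[paste0(g, "_over")]], "over", g)
    add_tumor_effect(plant[[paste0(g, "_under")]], "under", g)
  }

  # smoke response: the exposure shifts the whole lung compartment of the
  # exposed group — normals AND the tumors that arise from them — so
  # tumor/normal folds within a pair are untouched. Irreversible rows keep
  # the shift in former smokers; reversible rows revert to never-smoker
  # levels after cessation.
  sr_fold <- log(cfg$smoke_response$fold)
  cols_cs <- which(sample_group == "CS")
  cols_fs <- which(sample_group == "FS")
  eff_vec <- ifelse(sr_dir == "over", sr_fold, -sr_fold)
  if (sr_n > 0L) {
    logex[sr_rows, cols_cs] <- logex[sr_rows, cols_cs] + eff_vec
    ir <- which(irrev)
    if (length(ir) > 0L) {
      logex[sr_rows[ir], cols_fs] <- logex[sr_rows[ir], cols_fs] +
        eff_vec[ir]
    }
  }

  values <- exp(logex)
  values[undet_rows, ] <- matrix(
    stats::runif(n_undet * n_samp, 0, 0.99), n_undet, n_samp
  )
  # a detectable row must clear the detection floor somewhere: rescale the
  # rare low-baseline rows so exactly the configured rows are undetectable
  det_max <- apply(values[det_rows, , drop = FALSE], 1L, max)
  low <- det_max < 1
  if (any(low)) {
    values[det_rows[low], ] <-
      values[det_rows[low], , drop = FALSE] * (1.01 / det_max[low])
  }

  # survival: exponential hazard scaled by the prognostic miRNA's
  # standardized log2 tumor expression; uniform administrative censoring
  prog_expr <- log2(values[prog_row, tumor_cols] + 1)
  z <- as.numeric(scale(prog_expr))
  haz <- cfg$surv_baseline_hazard * exp(cfg$surv_loghr * z)
  t_event <- stats::rexp(n_pat, rate = haz)
  d_max <- censor_horizon(cfg$surv_baseline_hazard, cfg$censor_rate)
  t_cens <- stats::runif(n_pat, 0, d_max)
  surv_time <- pmin(t_event, t_cens)
  event <- t_event <= t_cens

  age <- pmin(90, pmax(40, round(stats::rnorm(n_pat, 68, 9))))
  sex <- sample(c("M", "F"), n_pat, replace = TRUE)
  stage <- sample(c("I", "II", "III", "IV"), n_pat, replace = TRUE,
                  prob = c(0.45, 0.25, 0.2, 0.1))
  ethnicity <- sample(c("european", "asian", "other"), n_pat,
                      replace = TRUE, prob = c(0.7, 0.2, 0.1))
  pack_years <- numeric(n_pat)
  pack_years[groups == "CS"] <- stats::rgamma(sum(groups == "CS"), 9, 0.2)
  pack_years[groups == "FS"] <- stats::rgamma(sum(groups == "FS"), 7, 0.2)
  years_quit <- rep(NA_real_, n_pat)
  years_quit[groups == "FS"] <- stats::runif(sum(groups == "FS"), 1, 30)

  per_pat <- tibble::tibble(
    patient_id = patient_id, smoking = groups, age = age, sex = sex,
    stage = stage, ethnicity = ethnicity, pack_years = pack_years,
    years_quit = years_quit, surv_time = surv_time, event = event
  )
  metadata <- dplyr::bind_rows(
    per_pat |> dplyr::mutate(sample_id = tumor_id, tissue = "tumor"),
    per_pat |> dplyr::mutate(sample_id = normal_id, tissue = "normal")
  ) |>
    dplyr::arrange(match(.data$sample_id, .env$sample_id)) |>
    dplyr::select("sample_id", "patient_id", "tissue", "smoking", "age",
                  "sex", "stage", "ethnicity", "pack_years", "years_quit",
                  "surv_time", "event")

  expression <- tibble::as_tibble(
    c(list(mirna_id = mirna_id),
      setNames(lapply(seq_len(n_samp), function(j) values[, j]), sample_id))
  )
  truth <- tibble::tibble(
    mirna_id = mirna_id, label = labels, direction = direction,
    group = grp_label,
    loghr = ifelse(labels == "prognostic", cfg$surv_loghr, 0)
  )
  list(expression = validate_expression(expression),
       metadata = validate_metadata(metadata),
       truth = truth, config = cfg)
}

# solve for the administrative censoring horizon D (months) such that a
# baseline-hazard exponential survivor censored at Uniform(0, D) is censored
# with the requested probability: P(cens) = (1 - exp(-lambda D)) / (lambda D)
censor_horizon <- function(lambda, censor_rate) {
  stopifnot(lambda > 0, censor_rate > 0, censor_rate < 1)
  f <- function(d) (1 - exp(-lambda * d)) / (lambda * d) - censor_rate
  stats::uniroot(f, lower = 1e-6, upper = 1e6, tol = 1e-8)$root
}

#' Score classifier calls against simulation ground truth
#'
#' Per planted label, sensitivity is the fraction of planted rows recovered
#' with the matching call; the false-discovery proportion is the fraction of
#' all calls whose truth label differs from the call. With no calls at all,
#' the FDP is defined as 0 (documented convention: an empty call set makes
#' no false discoveries).
#'
#' @param calls tibble with `mirna_id` and `label` (the called class).
#' @param truth truth tibble from [simulate_cohort()].
#'
#' @return A list with `per_label` (tibble: label, n_planted, n_recovered,
#'   sensitivity) and `fdp`.
#' @export
score_recovery <- function(calls, truth) {
  calls <- tibble::as_tibble(calls)
  stopifnot(all(c("mirna_id", "label") %in% names(calls)))
  if (!all(calls$mirna_id %in% truth$mirna_id)) {
    stop("calls reference miRNAs absent from the truth universe")
  }
  planted <- truth |> dplyr::filter(!.data$label %in% c("null", "undetectable"))
  joined <- planted |>
    dplyr::left_join(calls, by = "mirna_id", suffix = c("_true", "_called"))
  per_label <- joined |>
    dplyr::group_by(label = .data$label_true) |>
    dplyr::summarise(
      n_planted = dplyr::n(),
      n_recovered = sum(!is.na(.data$label_called) &
                          .data$label_called == .data$label_true),
      sensitivity = .data$n_recovered / .data$n_planted,
      .groups = "drop"
    )
  if (nrow(calls) == 0L) {
    fdp <- 0
  } else {
    truth_lookup <- setNames(truth$label, truth$mirna_id)
    fdp <- mean(truth_lookup[calls$mirna_id] != calls$label)
  }
  list(per_label = per_label, fdp = fdp)
}
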