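#' Two-thirds detectability gate for survival testing
#'
#' Only miRNAs detectably expressed (RPKM at or above the floor) in at
#' least two thirds of the patients supplied — `ceiling(2n/3)`, so 146 of
#' 218 — are eligible for tertile survival testing; anything sparser cannot
#' separate high from low expressers.
#'
#' @param expr expression tibble whose sample columns are the patients'
#'   tumor libraries under consideration.
#' @param floor RPKM detection floor (default 1.0).
#'
#' @return Character vector of eligible miRNA identifiers.
#' @export
detectability_gate <- function(expr, floor = 1.0) {
  expr <- validate_expression(expr)
  m <- expr_matrix(expr)
  n <- ncol(m)
  need <- ceiling(2 * n / 3)
  rownames(m)[rowSums(m >= floor) >= need]
}

#' Split patients into expression tertiles
#'
#' Sorts patients by expression (ties broken by patient identifier, so the
#' split is deterministic), takes the bottom `floor(n/3)` as the low
#' tertile and the top `floor(n/3)` as the high tertile, and discards the
#' middle. All-tied values still split deterministically, with a warning.
#'
#' @param values numeric expression per patient.
#' @param ids patient identifiers, same length.
#'
#' @return List with `low` and `high` character vectors of patient ids.
#' @export
tertile_split <- function(values, ids) {
  stopifnot(length(values) == length(ids))
  n <- length(values)
  if (n < 6L) stop("tertile split needs at least 6 patients, got ", n)
  if (length(unique(values)) == 1L) {
    warning("all expression values tied; tertile split falls back to ",
            "patient-id order")
  }
  o <- order(values, ids)
  k <- floor(n / 3)
  list(low = ids[o[seq_len(k)]], high = ids[o[seq.int(n - k + 1L, n)]])
}

#' Kaplan-Meier product-limit estimate
#'
#' Survival step function from right-censored follow-up, with the standard
#' convention that censoring at an event time is processed after the
#' events. Backed by [survival::survfit()].
#'
#' @param times follow-up times (months), non-negative.
#' @param events event indicator (TRUE/1 = death observed).
#'
#' @return A `km_fit`: tibble with `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival` (one row per distinct follow-up time).
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0L) stop("empty survival input")
  stopifnot(all(times >= 0), length(times) == length(events))
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1)
  out <- tibble::tibble(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    n_censor = fit$n.censor, survival = fit$surv
  )
  class(out) <- c("km_fit", class(out))
  out
}

# survival probability just after time t (step-function evaluation)
km_survival_at <- function(km, t) {
  s <- c(1, km$survival)
  brk <- c(-Inf, km$time)
  s[findInterval(t, brk)]
}

#' Log-rank (Mantel-Haenszel) test for two survival curves
#'
#' One-degree-of-freedom chi-square from the observed-minus-expected event
#' counts over the pooled event times with the hypergeometric variance
#' term, via [survival::survdiff()]. With zero events in total the test is
#' undefined and p = 1 is returned by convention.
#'
#' @param time_a,event_a follow-up and event indicator, group A.
#' @param time_b,event_b follow-up and event indicator, group B.
#'
#' @return A [mir_test][new_mir_test] with the chi-square statistic and
#'   `df = 1`.
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  if (length(time_a) == 0L || length(time_b) == 0L) {
    stop("both groups must be non-empty")
  }
  if (sum(event_a) + sum(event_b) == 0) {
    return(new_mir_test(0, 1, "log-rank (Mantel-Haenszel), no events",
                        c(length(time_a), length(time_b)), exact = FALSE,
                        df = 1L))
  }
  grp <- rep(c("A", "B"), c(length(time_a), length(time_b)))
  sd <- survival::survdiff(
    survival::Surv(c(time_a, time_b),
                   as.integer(c(event_a, event_b))) ~ grp
  )
  p <- pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  new_mir_test(sd$chisq, p, "log-rank (Mantel-Haenszel) test",
               c(length(time_a), length(time_b)), exact = FALSE, df = 1L)
}

#' Tertile log-rank survival scan across miRNAs and smoking strata
#'
#' For each stratum (all patients plus each smoking group): restricts to
#' patients with survival data, applies the two-thirds detectability gate
#' to their tumor expression, splits each eligible miRNA's patients into
#' expression tertiles — within cohort of origin when a `cohort` column is
#' present, then pooled, so systematic between-cohort RPKM scale shifts
#' cannot masquerade as biology — and compares top against bottom tertile
#' by log-rank. P-values are Benjamini-Hochberg-corrected within stratum;
#' `direction` records which tertile's Kaplan-Meier curve lies lower at the
#' stratum's median follow-up. Strata with fewer than 6 patients are
#' skipped with a warning.
#'
#' @param expr expression tibble (tumor libraries).
#' @param meta metadata tibble with survival fields (and optionally
#'   `cohort`).
#' @param strata subset of `c("ALL", "CS", "FS", "NS")`.
#' @param cfg an [analysis_config()].
#'
#' @return Tibble with `mirna_id`, `stratum`, `n_low`, `n_high`,
#'   `logrank_chi2`, `p`, `bh_q`, `direction` (`high-worse` / `low-worse` /
#'   `tied`).
#' @export
survival_scan <- function(expr, meta, strata = c("ALL", SMOKING_LEVELS),
                          cfg = analysis_config()) {
  expr <- validate_expression(expr)
  meta <- tibble::as_tibble(meta)
  tumors <- meta |>
    dplyr::filter(.data$tissue == "tumor", !is.na(.data$surv_time),
                  .data$sample_id %in% names(expr))
  purrr::map_dfr(strata, function(st) {
    sub <- if (st == "ALL") tumors else tumors[tumors$smoking == st, ]
    if (nrow(sub) < 6L) {
      warning("stratum ", st, " has ", nrow(sub), " patients; skipped")
      return(tibble::tibble())
    }
    ex <- expr[c("mirna_id", sub$sample_id)]
    eligible <- detectability_gate(ex, cfg$detection_floor)
    if (length(eligible) == 0L) return(tibble::tibble())
    m <- expr_matrix(ex[ex$mirna_id %in% eligible, ])
    surv <- setNames(sub$surv_time, sub$sample_id)
    evt <- setNames(sub$event, sub$sample_id)
    cohort <- if ("cohort" %in% names(sub)) {
      setNames(sub$cohort, sub$sample_id)
    } else {
      setNames(rep("all", nrow(sub)), sub$sample_id)
    }
    t_med <- median(sub$surv_time)
    rows <- purrr::map_dfr(rownames(m), function(mir) {
      vals <- m[mir, ]
      split_ids <- tryCatch(
        pooled_tertiles(vals, cohort), error = function(e) NULL
      )
      if (is.null(split_ids)) return(tibble::tibble())
      lo <- split_ids$low; hi <- split_ids$high
      lr <- logrank_test(surv[hi], evt[hi], surv[lo], evt[lo])
      s_hi <- km_survival_at(km_estimate(surv[hi], evt[hi]), t_med)
      s_lo <- km_survival_at(km_estimate(surv[lo], evt[lo]), t_med)
      tibble::tibble(
        mirna_id = mir, stratum = st, n_low = length(lo),
        n_high = length(hi), logrank_chi2 = lr$statistic, p = lr$p_value,
        direction = if (s_hi < s_lo) "high-worse"
                    else if (s_lo < s_hi) "low-worse" else "tied"
      )
    })
    if (nrow(rows) == 0L) return(rows)
    rows$bh_q <- benjamini_hochberg(rows$p)
    rows[c("mirna_id", "stratum", "n_low", "n_high", "logrank_chi2",
           "p", "bh_q", "direction")]
  })
}

# tertile split computed within each cohort of origin, tails then pooled
pooled_tertiles <- function(values, cohort) {
  ids <- names(values)
  parts <- split(ids, cohort[ids])
  lows <- character(0); highs <- character(0)
  for (part in parts) {
    sp <- tertile_split(values[part], part)
    lows <- c(lows, sp$low); highs <- c(highs, sp$high)
  }
  list(low = lows, high = highs)
}

#' Multivariate Cox proportional-hazards fit
#'
#' Cox regression of survival on miRNA expression plus clinical covariates,
#' maximizing the Breslow-tie partial likelihood (Newton-Raphson, at most
#' 50 iterations) via [survival::coxph()]. Expression should be supplied on
#' the log2(RPKM + 1) scale; factors are one-hot encoded against their
#' first level; a column named `stage` with values I-IV is converted to the
#' ordinal 1-4. Zero-variance covariates are an error naming the offender;
#' non-convergence is flagged rather than silently reported.
#'
#' @param covariates data frame of covariate columns (complete cases).
#' @param times follow-up times.
#' @param events event indicators.
#'
#' @return A `cox_result`: tibble with `term`, `estimate`, `std_error`,
#'   `z`, `p`, plus attributes `converged` and `n`.
#' @export
coxph_fit <- function(covariates, times, events) {
  covariates <- tibble::as_tibble(covariates)
  stopifnot(nrow(covariates) == length(times),
            length(times) == length(events))
  if (anyNA(covariates) || anyNA(times) || anyNA(events)) {
    stop("complete cases required")
  }
  df <- covariates
  if ("stage" %in% names(df) && !is.numeric(df$stage)) {
    df$stage <- as.numeric(match(df$stage, c("I", "II", "III", "IV")))
    if (anyNA(df$stage)) stop("stage must be one of I, II, III, IV")
  }
  for (nm in names(df)) {
    v <- df[[nm]]
    if (length(unique(v)) < 2L) stop("zero-variance covariate: ", nm)
    if (!is.numeric(v)) df[[nm]] <- as.factor(v)
  }
  df$.time <- times
  df$.event <- as.integer(events)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", setdiff(names(df), c(".time", ".event"))),
          collapse = " + ")
  ))
  fit <- survival::coxph(fml, data = df, ties = "breslow",
                         control = survival::coxph.control(iter.max = 50))
  sm <- summary(fit)
  out <- tibble::tibble(
    term = rownames(sm$coefficients),
    estimate = sm$coefficients[, "coef"],
    std_error = sm$coefficients[, "se(coef)"],
    z = sm$coefficients[, "z"],
    p = sm$coefficients[, "Pr(>|z|)"]
  )
  attr(out, "converged") <- fit$iter < 50 && !any(is.na(fit$coefficients))
  attr(out, "n") <- fit$n
  attr(out, "loglik") <- fit$loglik
  class(out) <- c("cox_result", class(out))
  out
}

#' MANOVA of miRNA expression against clinical covariates
#'
#' Screens whether a miRNA's expression is associated with (confounded by)
#' clinical covariates: for each covariate, a one-way Wilks MANOVA with
#' expression as the response and the covariate as grouping. Numeric
#' covariates are discretized into tertile bins for grouping; single-level
#' covariates are skipped with a warning.
#'
#' @param expression numeric vector (or n x p matrix) of expression per
#'   patient, log2(RPKM + 1) scale.
#' @param covariates data frame of covariates, one row per patient.
#'
#' @return Tibble with `covariate`, `wilks_lambda`, `f_value`, `p_value`,
#'   `n_used`.
#' @export
expression_covariate_manova <- function(expression, covariates) {
  Y <- as.matrix(expression)
  covariates <- tibble::as_tibble(covariates)
  stopifnot(nrow(covariates) == nrow(Y))
  purrr::map_dfr(names(covariates), function(cv) {
    g <- covariates[[cv]]
    if (is.numeric(g)) {
      qs <- quantile(g, c(1 / 3, 2 / 3), na.rm = TRUE)
      g <- cut(g, breaks = c(-Inf, qs, Inf), labels = c("lo", "mid", "hi"))
    }
    ok <- !is.na(g) & stats::complete.cases(Y)
    gg <- droplevels(as.factor(g[ok]))
    if (nlevels(gg) < 2L) {
      warning("covariate skipped (single level): ", cv)
      return(tibble::tibble())
    }
    res <- manova_wilks(Y[ok, , drop = FALSE], gg)
    tibble::tibble(covariate = cv, wilks_lambda = res$statistic,
                   f_value = res$f_value, p_value = res$p_value,
                   n_used = sum(ok))
  })
}
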