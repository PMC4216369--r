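#' Run the full smoking-status miRNA analysis pipeline
#'
#' Orchestrates every stage over a single configuration: (optional)
#' synthetic-cohort simulation or reading of RPKM/metadata TSVs, detection
#' filtering, Ward clustering with composition tests, current- vs
#' never-smoker normal-tissue differential expression, per-group recurrence
#' calling with specificity classification, reversibility classification in
#' former-smoker normals, optional external-cohort validation, tertile
#' log-rank survival scanning, a multivariate Cox fit for the top survival
#' miRNA, and optional target-network construction. Each stage writes TSV
#' outputs into `out_dir` and the run ends with a JSON manifest recording
#' the config snapshot, seed, input digests, per-stage row counts and
#' outcome. Reruns with an identical config reproduce every stochastic
#' stage bit-identically.
#'
#' @param config a YAML file path or an equivalent nested list. Recognized
#'   entries: `seed`; `simulate` (logical) with `sim` (arguments to
#'   [simulation_config()]); `input` (`expression`, `metadata` TSV paths,
#'   used when not simulating); `analysis` (arguments to
#'   [analysis_config()]); `cluster_k` (default 2); `external`
#'   (`expression`, `metadata` paths for validation); `predictions` and
#'   `gene_list` paths plus `min_sources`/`min_degree` for the network
#'   stage.
#' @param out_dir output directory, created if needed.
#'
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- config
  seed <- as.integer(cfg$seed %||% 1L)

  # pre-flight: every referenced file must exist before any stage runs
  refs <- c(cfg$input$expression, cfg$input$metadata,
            cfg$external$expression, cfg$external$metadata,
            cfg$predictions, cfg$gene_list)
  missing_refs <- refs[!vapply(refs, file.exists, logical(1))]
  if (length(missing_refs) > 0L) {
    stop("referenced input file(s) not found: ",
         paste(missing_refs, collapse = ", "))
  }
  if (!isTRUE(cfg$simulate) && is.null(cfg$input$expression)) {
    stop("either simulate: true or input files must be configured")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  acfg <- do.call(analysis_config,
                  c(cfg$analysis %||% list(), list(seed = seed)))
  manifest <- list(
    config = cfg, seed = seed,
    package_version = as.character(utils::packageVersion("mirsmoke")),
    started = format(Sys.time(), tz = "UTC"),
    input_digests = as.list(tools::md5sum(unlist(refs) %||% character(0))),
    stages = list(), status = "running"
  )
  log_stage <- function(name, ...) {
    manifest$stages[[name]] <<- list(...)
  }
  out_tsv <- function(x, name) {
    readr::write_tsv(x, file.path(out_dir, name), progress = FALSE)
  }
  finish <- function(status, failed_stage = NULL) {
    manifest$status <<- status
    manifest$failed_stage <<- failed_stage
    manifest$finished <<- format(Sys.time(), tz = "UTC")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
  }
  stage <- "preflight"
  result <- tryCatch({
    # --- simulate or load -------------------------------------------------
    stage <- "simulate"
    if (isTRUE(cfg$simulate)) {
      scfg <- do.call(simulation_config,
                      c(cfg$sim %||% list(), list(seed = seed)))
      cohort <- simulate_cohort(scfg)
      expr <- cohort$expression; meta <- cohort$metadata
      out_tsv(cohort$truth, "truth.tsv")
      write_expression(expr, file.path(out_dir, "expression.tsv"))
      write_metadata(meta, file.path(out_dir, "metadata.tsv"))
      log_stage("simulate", n_mirna = nrow(expr), n_samples = ncol(expr) - 1L)
    } else {
      expr <- read_expression(cfg$input$expression)
      meta <- read_metadata(cfg$input$metadata)
      log_stage("load", n_mirna = nrow(expr), n_samples = ncol(expr) - 1L)
    }

    # --- detection filter -------------------------------------------------
    stage <- "filter"
    filtered <- filter_expressed(expr, acfg$detection_floor)
    write_expression(filtered, file.path(out_dir, "expression_filtered.tsv"))
    log_stage("filter", rows_in = nrow(expr), rows_out = nrow(filtered))

    # --- clustering ---------------------------------------------------------
    stage <- "cluster"
    k <- cfg$cluster_k %||% 2L
    assign <- ward_cluster(filtered, k = k)
    tissue_lab <- setNames(meta$tissue, meta$sample_id)
    comp <- cluster_composition_test(assign, tissue_lab)
    out_tsv(tibble::as_tibble(assign), "clusters.tsv")
    out_tsv(tidy(comp), "cluster_composition.tsv")
    log_stage("cluster", k = k, composition_p = comp$p_value)

    # --- smoke-response DE --------------------------------------------------
    stage <- "de"
    csn <- smoke_response_de(filtered, meta, "CS", "NS", "normal", acfg)
    fsn <- smoke_response_de(filtered, meta, "FS", "NS", "normal", acfg)
    out_tsv(csn, "de_csn_vs_nsn.tsv")
    out_tsv(fsn, "de_fsn_vs_nsn.tsv")
    log_stage("de", n_csn_calls = sum(csn$status != "none"),
              n_fsn_calls = sum(fsn$status != "none"))

    # --- recurrence + specificity --------------------------------------------
    stage <- "specificity"
    pairs <- build_pairs(meta)
    rec <- purrr::map_dfr(SMOKING_LEVELS, function(g) {
      recurrence_scan(filtered, pairs[pairs$group == g, ], acfg)
    })
    spec <- classify_specificity(rec)
    out_tsv(rec, "recurrence_calls.tsv")
    out_tsv(spec, "specificity.tsv")
    log_stage("specificity", n_calls = nrow(spec),
              n_specific = sum(grepl("-specific$", spec$pattern)))

    # --- reversibility -------------------------------------------------------
    stage <- "reversibility"
    rev_calls <- classify_reversibility(csn, fsn, acfg)
    out_tsv(rev_calls, "reversibility.tsv")
    log_stage("reversibility",
              n_reversible = sum(rev_calls$class == "reversible"),
              n_irreversible = sum(rev_calls$class == "irreversible"))

    # --- external validation (optional) ---------------------------------------
    stage <- "validate"
    if (!is.null(cfg$external$expression)) {
      ext_expr <- read_expression(cfg$external$expression)
      ext_meta <- read_metadata(cfg$external$metadata)
      specific <- spec[grepl("-specific$", spec$pattern), ]
      val <- purrr::map_dfr(seq_len(nrow(specific)), function(i) {
        row <- specific[i, ]
        dt <- disruption_table(ext_expr, ext_meta, row$mirna_id,
                               row$direction, acfg)
        if (nrow(dt) == 0L || !row$groups %in% dt$group) {
          return(tibble::tibble())
        }
        focal <- dt[dt$group == row$groups, ]
        rest <- dt[dt$group != row$groups, ]
        external_validation(tibble::tibble(
          mirna_id = row$mirna_id, k_focal = sum(focal$k),
          n_focal = sum(focal$n), k_rest = sum(rest$k),
          n_rest = sum(rest$n)
        ), acfg) |>
          dplyr::mutate(group = row$groups, direction = row$direction)
      })
      out_tsv(val, "validation.tsv")
      log_stage("validate", n_tested = nrow(val),
                n_validated = sum(val$validated %||% logical(0)))
    } else {
      log_stage("validate", skipped = "no external cohort configured")
    }

    # --- survival -------------------------------------------------------------
    stage <- "survival"
    surv <- survival_scan(filtered, meta, cfg = acfg)
    out_tsv(surv, "survival_scan.tsv")
    log_stage("survival", n_tested = nrow(surv),
              n_significant = sum(surv$p < 0.05))

    # --- Cox fit for the top survival miRNA ------------------------------------
    stage <- "coxph"
    if (nrow(surv) > 0L) {
      top <- surv$mirna_id[which.min(surv$p)]
      tum <- meta[meta$tissue == "tumor" & !is.na(meta$surv_time) &
                    meta$sample_id %in% names(filtered), ]
      exprs <- as.numeric(unlist(filtered[filtered$mirna_id == top,
                                          tum$sample_id]))
      covs <- tibble::tibble(
        expression = log2(exprs + 1), age = tum$age, sex = tum$sex,
        stage = tum$stage, smoking = tum$smoking,
        ethnicity = tum$ethnicity
      )
      covs <- covs[, vapply(covs, function(v) length(unique(v)) > 1L,
                            logical(1)), drop = FALSE]
      cox <- coxph_fit(covs, tum$surv_time, tum$event)
      out_tsv(tidy(cox), "coxph_top_mirna.tsv")
      log_stage("coxph", mirna = top, converged = attr(cox, "converged"))
    } else {
      log_stage("coxph", skipped = "no survival results")
    }

    # --- network (optional) -----------------------------------------------------
    stage <- "network"
    if (!is.null(cfg$predictions)) {
      preds <- read_predictions(cfg$predictions) |>
        filter_predictions(cfg$min_sources %||% 6L)
      specific <- spec[grepl("-specific$", spec$pattern), ]
      tags <- setNames(specific$groups, specific$mirna_id)
      shared <- spec[spec$pattern == "shared-all", ]
      tags <- c(tags, setNames(rep("common", nrow(shared)),
                               shared$mirna_id))
      preds <- preds[preds$mirna_id %in% names(tags), ]
      genes <- if (!is.null(cfg$gene_list)) read_gene_list(cfg$gene_list)
               else NULL
      net <- build_network(preds, tags, restrict_genes = genes,
                           min_degree = cfg$min_degree %||% 1L)
      write_network(net, file.path(out_dir, "network"))
      log_stage("network", n_mirnas = nrow(net$mirnas),
                n_genes = nrow(net$genes), n_edges = net$summary$n_edges)
    } else {
      log_stage("network", skipped = "no prediction table configured")
    }
    TRUE
  }, error = function(e) e)

  if (inherits(result, "error")) {
    finish("failed", failed_stage = stage)
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(result))
  }
  finish("ok")
  invisible(manifest)
}
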