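#' Expression tables
#'
#' The pipeline's universal input is an expression table: a tibble whose
#' first column, `mirna_id`, holds unique miRNA identifiers and whose
#' remaining columns are one numeric RPKM column per sample. RPKM (reads
#' per kilobase of transcript per million mapped reads) is non-negative, so
#' negative values are rejected, as are duplicate miRNA or sample
#' identifiers.
#'
#' @param x a data frame to validate as an expression table.
#'
#' @return `x` as a tibble, invisibly validated; errors describe the first
#'   violated invariant.
#' @export
validate_expression <- function(x) {
  x <- tibble::as_tibble(x)
  if (ncol(x) < 1L || names(x)[1] != "mirna_id") {
    stop("first column must be 'mirna_id'")
  }
  ids <- x$mirna_id
  if (anyDuplicated(ids)) {
    stop("duplicate miRNA identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  samples <- names(x)[-1]
  if (anyDuplicated(samples)) stop("duplicate sample identifiers")
  for (s in samples) {
    v <- x[[s]]
    if (!is.numeric(v)) stop("sample column '", s, "' is not numeric")
    if (anyNA(v)) stop("missing value in sample column '", s, "'")
    if (any(v < 0)) {
      stop("negative RPKM in sample '", s, "', miRNA '",
           ids[which(v < 0)[1]], "'")
    }
  }
  x
}

#' Read / write an expression table
#'
#' Tab-separated format: header line `mirna_id<TAB>sample1<TAB>...`, one row
#' per miRNA, "."-decimal floats in the body. `read_expression()` rejects
#' malformed numeric cells (naming the row and column), duplicate
#' identifiers and negative values; `write_expression()` writes a file that
#' reads back value-exact.
#'
#' @param path file path of the TSV.
#'
#' @return `read_expression()` returns a validated expression tibble;
#'   `write_expression()` returns `path` invisibly.
#' @export
read_expression <- function(path) {
  # parsing problems surface as our own error below, not readr's warning
  x <- suppressWarnings(readr::read_tsv(path, col_types = readr::cols(
    mirna_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE))
  pr <- readr::problems(x)
  if (nrow(pr) > 0L) {
    stop("malformed numeric cell at row ", pr$row[1], ", column ",
         pr$col[1], " of ", path)
  }
  validate_expression(x)
}

#' @rdname read_expression
#' @param x expression tibble to write.
#' @export
write_expression <- function(x, path) {
  x <- validate_expression(x)
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Drop miRNAs below the expression-detection floor everywhere
#'
#' An RPKM below 1 is treated as "not expressed"; miRNAs not detected in any
#' sample carry no usable signal and are removed before analysis. The
#' comparison is strict: a miRNA whose best sample reaches exactly the floor
#' is kept. Row order and values of retained rows are unchanged, so the
#' operation is idempotent.
#'
#' @param x expression tibble.
#' @param floor detection floor in RPKM units (default 1.0).
#'
#' @return Expression tibble containing only rows detectable in at least
#'   one sample.
#' @export
filter_expressed <- function(x, floor = 1.0) {
  x <- validate_expression(x)
  if (ncol(x) == 1L) return(x[0, ])
  mx <- do.call(pmax, x[-1])
  x[mx >= floor, , drop = FALSE]
}

# internal: expression tibble -> numeric matrix with miRNA rownames
expr_matrix <- function(x) {
  m <- as.matrix(x[-1])
  rownames(m) <- x$mirna_id
  m
}

#' Read / write sample metadata
#'
#' One row per sequencing library with the fixed column set: `sample_id`,
#' `patient_id`, `tissue` (tumor/normal), `smoking` (CS current smoker, FS
#' former smoker who quit at least one year before diagnosis, NS never
#' smoker), `age`, `sex` (M/F/unknown), `stage` (I-IV/unknown), `ethnicity`,
#' `pack_years`, `years_quit`, `surv_time` (months), `event` (death
#' indicator). Missing values are the literal "NA". Extra columns are
#' preserved but ignored by the pipeline. Invariants enforced: `years_quit`
#' only for former smokers, zero pack-years only for never smokers, and
#' survival time and event are missing together.
#'
#' @param path TSV file path.
#'
#' @return A validated metadata tibble.
#' @export
read_metadata <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    patient_id = readr::col_character(),
    tissue = readr::col_character(),
    smoking = readr::col_character(),
    age = readr::col_double(),
    sex = readr::col_character(),
    stage = readr::col_character(),
    ethnicity = readr::col_character(),
    pack_years = readr::col_double(),
    years_quit = readr::col_double(),
    surv_time = readr::col_double(),
    event = readr::col_logical(),
    .default = readr::col_character()
  ), progress = FALSE)
  validate_metadata(x)
}

#' @rdname read_metadata
#' @param x metadata tibble to validate or write.
#' @export
validate_metadata <- function(x) {
  x <- tibble::as_tibble(x)
  required <- c("sample_id", "patient_id", "tissue", "smoking", "age", "sex",
                "stage", "ethnicity", "pack_years", "years_quit",
                "surv_time", "event")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0L) {
    stop("missing metadata column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(x$sample_id)) stop("duplicate sample_id in metadata")
  if (!all(x$tissue %in% TISSUE_LEVELS)) {
    stop("tissue must be one of: ", paste(TISSUE_LEVELS, collapse = ", "))
  }
  if (!all(x$smoking %in% SMOKING_LEVELS)) {
    stop("smoking must be one of: ", paste(SMOKING_LEVELS, collapse = ", "))
  }
  bad_quit <- !is.na(x$years_quit) & x$smoking != "FS"
  if (any(bad_quit)) {
    stop("years_quit present for non-former-smoker sample(s): ",
         paste(x$sample_id[bad_quit], collapse = ", "))
  }
  bad_py <- !is.na(x$pack_years) & x$pack_years == 0 & x$smoking != "NS"
  if (any(bad_py)) {
    stop("pack_years = 0 implies never smoker; offending sample(s): ",
         paste(x$sample_id[bad_py], collapse = ", "))
  }
  bad_surv <- xor(is.na(x$surv_time), is.na(x$event))
  if (any(bad_surv)) {
    stop("surv_time and event must be missing together; offending sample(s): ",
         paste(x$sample_id[bad_surv], collapse = ", "))
  }
  x
}

#' @rdname read_metadata
#' @export
write_metadata <- function(x, path) {
  x <- validate_metadata(x)
  readr::write_tsv(x, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Assemble patient-matched tumor/normal pairs per smoking group
#'
#' Pairs each patient's tumor and normal libraries; patients contributing
#' only one tissue are reported in the `unpaired` attribute (and a message)
#' rather than silently dropped. Two libraries of the same tissue for one
#' patient is an error.
#'
#' @param meta metadata tibble (see [read_metadata()]).
#'
#' @return A tibble with columns `patient_id`, `tumor_sample_id`,
#'   `normal_sample_id`, `group` (CS/FS/NS), one row per paired patient,
#'   with attribute `unpaired`: a tibble of patient_id/tissue for patients
#'   lacking the companion tissue.
#' @export
build_pairs <- function(meta) {
  meta <- validate_metadata(meta)
  dup <- meta |>
    dplyr::count(.data$patient_id, .data$tissue) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    stop("ambiguous pairing: patient ", dup$patient_id[1], " has ",
         dup$n[1], " ", dup$tissue[1], " samples")
  }
  wide <- meta |>
    dplyr::select("patient_id", "tissue", "sample_id", "smoking") |>
    tidyr::pivot_wider(names_from = "tissue", values_from = "sample_id")
  if (!"tumor" %in% names(wide)) wide$tumor <- NA_character_
  if (!"normal" %in% names(wide)) wide$normal <- NA_character_
  paired <- wide |>
    dplyr::filter(!is.na(.data$tumor), !is.na(.data$normal)) |>
    dplyr::transmute(
      patient_id = .data$patient_id,
      tumor_sample_id = .data$tumor,
      normal_sample_id = .data$normal,
      group = .data$smoking
    )
  unpaired <- wide |>
    dplyr::filter(is.na(.data$tumor) | is.na(.data$normal)) |>
    dplyr::transmute(
      patient_id = .data$patient_id,
      tissue = ifelse(is.na(.data$tumor), "normal", "tumor")
    )
  if (nrow(unpaired) > 0L) {
    message(nrow(unpaired), " patient(s) lack a matched tissue and were ",
            "left unpaired: ", paste(unpaired$patient_id, collapse = ", "))
  }
  attr(paired, "unpaired") <- unpaired
  paired
}

#' Merge two cohorts' metadata with cohort-of-origin tags
#'
#' Concatenates two metadata tables after prefixing sample and patient
#' identifiers with a cohort tag, and records the tag in a `cohort` column
#' so downstream stages (notably tertile stratification on the merged
#' survival cohort) can stratify within cohort of origin.
#'
#' @param a,b metadata tibbles.
#' @param tags character vector of two distinct cohort tags.
#'
#' @return Combined metadata tibble with a `cohort` column; per-smoking-group
#'   patient counts are the sums of the inputs'.
#' @export
merge_cohorts <- function(a, b, tags = c("A", "B")) {
  stopifnot(length(tags) == 2L, tags[1] != tags[2])
  tag_one <- function(x, tag) {
    if (nrow(x) == 0L) {
      x$cohort <- character(0)
      return(x)
    }
    x |>
      dplyr::mutate(
        cohort = tag,
        sample_id = paste(tag, .data$sample_id, sep = ":"),
        patient_id = paste(tag, .data$patient_id, sep = ":")
      )
  }
  a <- tag_one(validate_metadata(a), tags[1])
  b <- tag_one(validate_metadata(b), tags[2])
  merged <- dplyr::bind_rows(a, b)
  if (anyDuplicated(merged$sample_id)) {
    stop("sample id collision after cohort tagging")
  }
  merged
}

#' Read a miRNA-to-gene target-prediction table
#'
#' TSV with columns `mirna_id`, `gene`, `support_count` — the number of
#' independent prediction sources supporting the pair. Pairs must be unique
#' and support counts at least 1.
#'
#' @param path TSV file path.
#'
#' @return A validated tibble of predictions.
#' @export
read_predictions <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    mirna_id = readr::col_character(),
    gene = readr::col_character(),
    support_count = readr::col_integer()
  ), progress = FALSE)
  validate_predictions(x)
}

#' @rdname read_predictions
#' @param x prediction tibble to validate.
#' @export
validate_predictions <- function(x) {
  x <- tibble::as_tibble(x)
  stopifnot(all(c("mirna_id", "gene", "support_count") %in% names(x)))
  if (any(is.na(x$support_count)) || any(x$support_count < 1L)) {
    stop("support_count must be a positive integer")
  }
  if (anyDuplicated(x[c("mirna_id", "gene")])) {
    stop("duplicate (mirna_id, gene) prediction pair")
  }
  x
}

#' Read a plain-text gene list
#'
#' One HGNC-style symbol per line; blank lines and `#` comments are ignored.
#'
#' @param path file path.
#'
#' @return Character vector of unique gene symbols, file order preserved.
#' @export
read_gene_list <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  unique(lines[nzchar(lines)])
}
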