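#' Filter target predictions by source support
#'
#' Keeps only miRNA-gene predictions supported by at least `min_sources`
#' independent prediction sources (inclusive), preserving row order.
#' Idempotent at a fixed threshold.
#'
#' @param predictions prediction tibble (`mirna_id`, `gene`,
#'   `support_count`).
#' @param min_sources minimum source support (default 6).
#'
#' @return Filtered prediction tibble.
#' @export
filter_predictions <- function(predictions, min_sources = 6L) {
  predictions <- validate_predictions(predictions)
  predictions[predictions$support_count >= min_sources, ]
}

#' Build a bipartite miRNA-target network
#'
#' Assembles the miRNA-gene interaction network from a prediction table:
#' every miRNA carries a group tag (its smoking-status specificity, or
#' `common` for miRNAs deregulated across groups) which is inherited by its
#' edges; gene nodes may optionally be restricted to a reference list
#' (e.g. lung cancer prognostic genes); miRNA nodes below `min_degree`
#' connections — the operational reading of "only the most highly
#' connected" — are dropped with their edges, and degrees are recomputed
#' afterwards. The summary tabulates, per group tag, the genes targeted
#' exclusively by that tag's miRNAs, plus the genes shared between tags.
#'
#' @param predictions prediction tibble (already support-filtered).
#' @param mirna_groups named character vector mapping every predicted
#'   miRNA to its group tag (`CS`, `FS`, `NS`, `common`, ...).
#' @param restrict_genes optional character vector; gene nodes outside it
#'   are removed before anything else.
#' @param min_degree minimum miRNA connectivity kept (default 1).
#'
#' @return A `target_network`: list with `edges` (tibble `mirna_id`,
#'   `gene`, `group`), `mirnas` and `genes` (node tibbles with degrees),
#'   and `summary` (`unique_targets` named count per tag, `shared_targets`,
#'   `n_edges`).
#' @export
build_network <- function(predictions, mirna_groups, restrict_genes = NULL,
                          min_degree = 1L) {
  predictions <- validate_predictions(predictions)
  untagged <- setdiff(unique(predictions$mirna_id), names(mirna_groups))
  if (length(untagged) > 0L) {
    stop("miRNA(s) without a group tag: ",
         paste(head(untagged, 5), collapse = ", "))
  }
  edges <- predictions |>
    dplyr::transmute(
      mirna_id = .data$mirna_id, gene = .data$gene,
      group = unname(mirna_groups[.data$mirna_id])
    )
  if (!is.null(restrict_genes)) {
    if (length(restrict_genes) == 0L) {
      stop("gene restriction list is empty after parsing")
    }
    edges <- edges[edges$gene %in% restrict_genes, ]
    if (nrow(edges) == 0L) {
      warning("gene restriction removed every edge; network is empty")
    }
  }
  # drop weakly connected miRNAs, then recompute all degrees
  mir_deg <- table(edges$mirna_id)
  keep <- names(mir_deg)[mir_deg >= min_degree]
  edges <- edges[edges$mirna_id %in% keep, ]
  mirnas <- edges |>
    dplyr::count(.data$mirna_id, .data$group, name = "degree") |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$mirna_id)
  genes <- edges |>
    dplyr::count(.data$gene, name = "degree") |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$gene)
  tag_sets <- edges |>
    dplyr::distinct(.data$gene, .data$group) |>
    dplyr::count(.data$gene, name = "n_tags")
  singles <- edges |>
    dplyr::distinct(.data$gene, .data$group) |>
    dplyr::semi_join(tag_sets[tag_sets$n_tags == 1L, ], by = "gene")
  unique_targets <- table(singles$group)
  structure(list(
    edges = edges, mirnas = mirnas, genes = genes,
    summary = list(
      unique_targets = setNames(as.integer(unique_targets),
                                names(unique_targets)),
      shared_targets = sum(tag_sets$n_tags >= 2L),
      n_edges = nrow(edges)
    )
  ), class = "target_network")
}

#' @export
print.target_network <- function(x, ...) {
  cat("miRNA-target network:", nrow(x$mirnas), "miRNAs,",
      nrow(x$genes), "genes,", x$summary$n_edges, "edges\n")
  if (length(x$summary$unique_targets) > 0L) {
    cat("  unique targets per group:",
        paste(names(x$summary$unique_targets), x$summary$unique_targets,
              sep = "=", collapse = ", "), "\n")
    cat("  shared targets:", x$summary$shared_targets, "\n")
  }
  invisible(x)
}

#' Connectivity ranking and reference-list coverage
#'
#' Ranks the network's nodes by degree (descending, ties by identifier)
#' and, when a reference gene list is supplied, reports what fraction of
#' it appears among the network's gene nodes.
#'
#' @param net a [build_network()] result.
#' @param top_n how many nodes to return per node type (default all).
#' @param reference_genes optional character vector (e.g. a prognostic
#'   gene list).
#'
#' @return List with `mirnas` and `genes` (ranked tibbles, `rank` column
#'   added), and when `reference_genes` is given, `coverage`: a list with
#'   `n_reference`, `n_covered`, `fraction` and `percent` (nearest
#'   integer).
#' @export
connectivity_report <- function(net, top_n = Inf, reference_genes = NULL) {
  stopifnot(inherits(net, "target_network"))
  rank_tbl <- function(tb) {
    tb$rank <- seq_len(nrow(tb))
    head(tb, top_n)
  }
  out <- list(mirnas = rank_tbl(net$mirnas), genes = rank_tbl(net$genes))
  if (!is.null(reference_genes)) {
    reference_genes <- unique(reference_genes)
    covered <- intersect(reference_genes, net$genes$gene)
    frac <- if (length(reference_genes) == 0L) NA_real_
            else length(covered) / length(reference_genes)
    out$coverage <- list(
      n_reference = length(reference_genes), n_covered = length(covered),
      fraction = frac, percent = round(100 * frac)
    )
  }
  out
}

#' Export a target network
#'
#' Writes the network as a flat TSV edge list (`<prefix>_edges.tsv`) and as
#' GraphML (`<prefix>.graphml`) with node type, group tag and degree
#' attributes, for downstream visualization tools.
#'
#' @param net a [build_network()] result.
#' @param prefix output path prefix.
#'
#' @return Invisibly, the two file paths written.
#' @export
write_network <- function(net, prefix) {
  stopifnot(inherits(net, "target_network"))
  edge_path <- paste0(prefix, "_edges.tsv")
  readr::write_tsv(net$edges, edge_path, progress = FALSE)
  vertices <- dplyr::bind_rows(
    net$mirnas |>
      dplyr::transmute(name = .data$mirna_id, type = "mirna",
                       group = .data$group, degree = .data$degree),
    net$genes |>
      dplyr::transmute(name = .data$gene, type = "gene",
                       group = NA_character_, degree = .data$degree)
  )
  g <- igraph::graph_from_data_frame(
    net$edges[c("mirna_id", "gene", "group")],
    directed = FALSE, vertices = vertices
  )
  gml_path <- paste0(prefix, ".graphml")
  igraph::write_graph(g, gml_path, format = "graphml")
  invisible(c(edge_path, gml_path))
}
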