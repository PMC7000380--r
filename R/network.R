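#' Build a CO/ME network from events
#'
#' Genes are nodes; each retained event contributes a typed edge (CO or ME)
#' between its canonical gene pair.  Duplicate (pair, type) records — e.g.
#' the same event called in several cancers — merge into a single edge whose
#' supporting-cancer set is the union.  A CO edge and an ME edge between the
#' same pair are distinct edges.
#'
#' @param events Tibble with `gene_a`, `gene_b`, `type` and either a
#'   `cancer` column (one cancer per row) or a `cancers` column (comma-joined
#'   string or list of character vectors).
#' @return A `come_network`: list with `nodes` (character vector), `edges`
#'   (tibble: `gene_a`, `gene_b`, `type`, `cancers` list-column) and
#'   `degree` (named integer vector, CO and ME edges counted equally).
#' @export
build_network <- function(events) {
  ev <- as_tibble(events)
  if (nrow(ev) == 0) {
    return(structure(list(nodes = character(),
                          edges = tibble(gene_a = character(),
                                         gene_b = character(),
                                         type = character(),
                                         cancers = list()),
                          degree = integer()),
                     class = "come_network"))
  }
  key <- canonical_pair(ev$gene_a, ev$gene_b)
  ev$gene_a <- key$gene_a
  ev$gene_b <- key$gene_b
  if (any(ev$gene_a == ev$gene_b)) stop("self-loop event (gene paired with itself)")
  canc <- if ("cancer" %in% colnames(ev)) {
    lapply(ev$cancer, function(x) if (is.na(x)) character() else x)
  } else if ("cancers" %in% colnames(ev)) {
    if (is.list(ev$cancers)) ev$cancers
    else strsplit(ifelse(is.na(ev$cancers), "", ev$cancers), ",")
  } else {
    rep(list(character()), nrow(ev))
  }
  ev$..cancers <- canc
  edges <- ev |>
    dplyr::group_by(.data$gene_a, .data$gene_b, .data$type) |>
    dplyr::summarise(cancers = list(sort(unique(unlist(.data$..cancers)))),
                     .groups = "drop") |>
    dplyr::arrange(.data$gene_a, .data$gene_b, .data$type)
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  deg <- table(factor(c(edges$gene_a, edges$gene_b), levels = nodes))
  structure(list(nodes = nodes, edges = edges,
                 degree = setNames(as.integer(deg), nodes)),
            class = "come_network")
}

#' @export
print.come_network <- function(x, ...) {
  cat(sprintf("<come_network> %d nodes, %d edges (%d CO, %d ME)\n",
              length(x$nodes), nrow(x$edges),
              sum(x$edges$type == "CO"), sum(x$edges$type == "ME")))
  invisible(x)
}

#' Merge per-cancer networks into a pan-cancer network
#'
#' Union of nodes and typed edges; supporting-cancer sets are unioned.  The
#' operation is associative, commutative and idempotent.
#'
#' @param networks List of `come_network` objects.
#' @return A `come_network`.
#' @export
merge_pan_cancer <- function(networks) {
  stopifnot(length(networks) >= 1)
  all_edges <- dplyr::bind_rows(lapply(networks, function(nw) {
    ed <- nw$edges
    ed$cancers <- lapply(ed$cancers, identity)
    ed
  }))
  if (nrow(all_edges) == 0) return(build_network(all_edges))
  all_edges$cancers <- vapply(all_edges$cancers,
                              function(x) paste(x, collapse = ","),
                              character(1))
  build_network(all_edges)
}

#' Hub table: cancer-gene / TSG fraction among top-degree genes
#'
#' Genes are ranked by degree (descending, ties alphabetical); for every
#' prefix of size N up to `top_n` the fraction of genes flagged as cancer
#' gene or tumor suppressor is reported.
#'
#' @param net A `come_network`.
#' @param annotation Tibble with `gene_id`, `is_cancer_gene`, `is_tsg`.
#' @param top_n Largest prefix size (capped at the node count).
#' @return Tibble with one row per rank: `rank`, `gene_id`, `degree`,
#'   `is_cancer_gene`, `is_tsg`, `flagged`, `fraction_flagged` (cumulative).
#' @export
hub_table <- function(net, annotation, top_n = 10) {
  stopifnot(top_n >= 1)
  nodes <- net$nodes
  deg <- net$degree
  ord <- order(-deg, nodes)
  n <- min(top_n, length(nodes))
  sel <- ord[seq_len(n)]
  idx <- match(nodes[sel], annotation$gene_id)
  cg <- !is.na(idx) & annotation$is_cancer_gene[idx] %in% TRUE
  tsg <- !is.na(idx) & annotation$is_tsg[idx] %in% TRUE
  flagged <- cg | tsg
  tibble(rank = seq_len(n), gene_id = nodes[sel],
         degree = unname(deg[sel]),
         is_cancer_gene = cg, is_tsg = tsg, flagged = flagged,
         fraction_flagged = cumsum(flagged) / seq_len(n))
}

#' Fraction of network genes that are cancer genes or TSGs
#'
#' @param net A `come_network`.
#' @param annotation Tibble with `gene_id`, `is_cancer_gene`, `is_tsg`.
#' @return A one-row tibble: `n_genes`, `n_flagged`, `fraction`.
#' @export
cancer_gene_fraction <- function(net, annotation) {
  idx <- match(net$nodes, annotation$gene_id)
  flagged <- (!is.na(idx) & annotation$is_cancer_gene[idx] %in% TRUE) |
    (!is.na(idx) & annotation$is_tsg[idx] %in% TRUE)
  tibble(n_genes = length(net$nodes), n_flagged = sum(flagged),
         fraction = if (length(net$nodes) == 0) NA_real_
                    else sum(flagged) / length(net$nodes))
}

# igraph view of a come_network (used by the module finder)
.as_igraph <- function(net) {
  ed <- unique(net$edges[c("gene_a", "gene_b")])
  igraph::graph_from_data_frame(ed, directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}
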