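new_coex_network <- function(graph, network_id) {
  structure(list(graph = graph, network_id = network_id),
    class = "coex_network"
  )
}

#' @export
print.coex_network <- function(x, ...) {
  cat(sprintf(
    "<coex_network %s> %d genes, %d edges\n",
    x$network_id, igraph::vcount(x$graph), igraph::ecount(x$graph)
  ))
  invisible(x)
}

#' Assemble condition-specific co-expression networks
#'
#' PO and NO edges (pairs correlated only in the response state) form the
#' response network PONO; OP and ON edges form the non-response network
#' OPON. Both are undirected simple graphs; duplicate pairs with the same
#' class collapse to one edge (with a message), and isolated genes are not
#' represented.
#'
#' @param edges classified edge tibble from [build_differential_edges()].
#' @return named list with `coex_network` elements `PONO` and `OPON`.
#' @export
assemble_networks <- function(edges) {
  build <- function(sub, id) {
    if (nrow(sub) == 0) {
      return(new_coex_network(igraph::make_empty_graph(0, directed = FALSE), id))
    }
    o <- orient_pairs(as.character(sub$gene_a), as.character(sub$gene_b))
    sub$gene_a <- o$gene_a
    sub$gene_b <- o$gene_b
    if (any(sub$gene_a == sub$gene_b)) {
      stop_pononet("Self-loop edge encountered", class = "pononet_validation_error")
    }
    dup <- duplicated(sub[, c("gene_a", "gene_b")])
    if (any(dup)) {
      inform(sprintf("%s: collapsed %d duplicate edge(s)", id, sum(dup)))
      sub <- sub[!dup, , drop = FALSE]
    }
    g <- igraph::graph_from_data_frame(
      data.frame(
        from = sub$gene_a, to = sub$gene_b,
        class = as.character(sub$class),
        r_response = sub$r_response,
        r_nonresponse = sub$r_nonresponse,
        stringsAsFactors = FALSE
      ),
      directed = FALSE
    )
    new_coex_network(g, id)
  }
  list(
    PONO = build(edges[edges$class %in% c("PO", "NO"), , drop = FALSE], "PONO"),
    OPON = build(edges[edges$class %in% c("OP", "ON"), , drop = FALSE], "OPON")
  )
}

#' Degree and betweenness centrality per node
#'
#' Degree is the incident-edge count; betweenness is the unnormalized
#' undirected shortest-path betweenness (Brandes' algorithm via igraph),
#' computed per connected component, with unreachable pairs contributing 0.
#'
#' @param network a `coex_network`.
#' @return tibble with columns `gene`, `degree`, `betweenness`.
#' @export
node_metrics <- function(network) {
  g <- network$graph
  if (igraph::vcount(g) == 0) {
    return(tibble(gene = character(), degree = integer(), betweenness = numeric()))
  }
  tibble(
    gene = igraph::V(g)$name,
    degree = unname(as.integer(igraph::degree(g))),
    betweenness = unname(igraph::betweenness(g, directed = FALSE, weights = NA))
  )
}

#' Select the hub module of a network
#'
#' Candidate hubs are the intersection of the top `k_degree` genes by degree
#' and the top `k_betweenness` genes by betweenness (each top list ordered
#' by the metric, ties broken towards higher degree then lexicographic gene
#' id). Candidates are ranked by the sum of their two rank positions and
#' truncated to `module_size`. An empty intersection falls back to the
#' union, with a warning.
#'
#' @param metrics tibble from [node_metrics()].
#' @param k_degree,k_betweenness top-list sizes.
#' @param module_size number of hub genes retained.
#' @param network optional `coex_network`; when given, the induced subgraph
#'   on the hubs is attached to the result.
#' @return object of class `hub_module`: list with `network_id`, `hubs`
#'   (ranked character vector), `metrics` (hub rows), `module` (igraph or
#'   NULL) and `params`.
#' @export
rank_hubs <- function(metrics, k_degree = 10, k_betweenness = 10,
                      module_size = 5, network = NULL) {
  if (nrow(metrics) == 0) {
    stop_pononet("Cannot rank hubs of an empty network",
      class = "pononet_validation_error"
    )
  }
  ord_deg <- order(-metrics$degree, -metrics$betweenness, metrics$gene)
  ord_bet <- order(-metrics$betweenness, -metrics$degree, metrics$gene)
  top_deg <- metrics$gene[head(ord_deg, k_degree)]
  top_bet <- metrics$gene[head(ord_bet, k_betweenness)]
  candidates <- intersect(top_deg, top_bet)
  if (length(candidates) == 0) {
    warn("Top-degree and top-betweenness sets are disjoint; falling back to their union")
    candidates <- union(top_deg, top_bet)
  }
  rank_deg <- rank(-metrics$degree, ties.method = "min")
  rank_bet <- rank(-metrics$betweenness, ties.method = "min")
  names(rank_deg) <- names(rank_bet) <- metrics$gene
  rank_sum <- rank_deg[candidates] + rank_bet[candidates]
  deg <- setNames(metrics$degree, metrics$gene)[candidates]
  ord <- order(rank_sum, -deg, candidates)
  hubs <- candidates[head(ord, module_size)]
  module <- NULL
  if (!is.null(network)) {
    module <- igraph::induced_subgraph(network$graph, hubs)
  }
  structure(
    list(
      network_id = if (!is.null(network)) network$network_id else NA_character_,
      hubs = hubs,
      metrics = metrics[match(hubs, metrics$gene), , drop = FALSE],
      module = module,
      params = list(
        k_degree = k_degree, k_betweenness = k_betweenness,
        module_size = module_size
      )
    ),
    class = "hub_module"
  )
}

#' @export
print.hub_module <- function(x, ...) {
  cat(sprintf(
    "<hub_module%s> %s\n",
    if (is.na(x$network_id)) "" else paste0(" ", x$network_id),
    paste(x$hubs, collapse = ", ")
  ))
  invisible(x)
}

#' Paired-triangle correlation matrix of a hub module
#'
#' Square matrix over the hub genes with unit diagonal, the response-state
#' correlation in the lower triangle and the nonresponse-state correlation
#' in the upper triangle (so transposition swaps the two states).
#'
#' @param datasets expression dataset(s).
#' @param phenotypes matching phenotype table(s).
#' @param hub_genes character vector of module genes.
#' @param combine pooling mode, see [condition_correlations()].
#' @return matrix of class `module_cor_matrix`.
#' @export
module_cor_matrix <- function(datasets, phenotypes, hub_genes,
                              combine = c("per_stratum_z", "per_dataset_z",
                                "concat")) {
  first <- if (inherits(datasets, "pononet_expr")) datasets else datasets[[1]]
  missing <- setdiff(hub_genes, first$gene)
  if (length(missing) > 0) {
    stop_pononet(
      paste0("Hub gene(s) absent from expression: ", paste(missing, collapse = ", ")),
      class = "pononet_validation_error"
    )
  }
  cors <- condition_correlations(datasets, phenotypes, hub_genes, combine)
  genes <- sort(unique(hub_genes))
  k <- length(genes)
  m <- diag(1, k)
  dimnames(m) <- list(genes, genes)
  for (i in seq_len(nrow(cors))) {
    a <- cors$gene_a[i]
    b <- cors$gene_b[i] # a < b: (b, a) is lower triangle
    m[b, a] <- cors$r_response[i]
    m[a, b] <- cors$r_nonresponse[i]
  }
  structure(m, class = c("module_cor_matrix", class(m)))
}
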