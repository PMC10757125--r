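#' Overlay transcription-factor targets on a network
#'
#' Matches the target column of a TF interaction table against the genes of
#' a co-expression network (exact, case-insensitive symbol match) and
#' summarizes, per TF, the set and count of in-network targets. TFs with no
#' target in the network are omitted. A TF that is itself a network gene and
#' targets itself counts as its own target (reported as a message).
#'
#' @param network a `coex_network`.
#' @param tf_table tibble with `tf` and `target` columns (see
#'   [read_tf_table()]).
#' @return tibble of class `tf_summary`: columns `tf`, `coverage`, `targets`
#'   (list-column of in-network target genes), sorted by decreasing
#'   coverage; the network id travels in the `network_id` attribute.
#' @export
map_tf_targets <- function(network, tf_table) {
  if (nrow(tf_table) == 0) {
    stop_pononet("TF interaction table is empty", class = "pononet_validation_error")
  }
  nodes <- igraph::V(network$graph)$name
  if (is.null(nodes)) nodes <- character()
  hit <- match(tolower(tf_table$target), tolower(nodes))
  inside <- tf_table[!is.na(hit), , drop = FALSE]
  inside$target <- nodes[hit[!is.na(hit)]]
  selfhits <- inside$tf[tolower(inside$tf) == tolower(inside$target)]
  if (length(selfhits) > 0) {
    inform(paste0(
      "TF(s) counted as their own target: ", paste(unique(selfhits), collapse = ", ")
    ))
  }
  out <- inside |>
    group_by(tf = .data$tf) |>
    summarise(targets = list(sort(unique(.data$target))), .groups = "drop") |>
    mutate(coverage = lengths(.data$targets)) |>
    select("tf", "coverage", "targets") |>
    arrange(desc(.data$coverage), .data$tf)
  attr(out, "network_id") <- network$network_id
  class(out) <- c("tf_summary", class(out))
  out
}

#' Top network regulators by target coverage
#'
#' @param summary a `tf_summary` from [map_tf_targets()].
#' @param k number of TFs to return (ties broken lexicographically; if `k`
#'   exceeds the number of TFs, all are returned).
#' @return tibble of the top `k` rows.
#' @export
top_regulators <- function(summary, k) {
  if (!is.numeric(k) || k <= 0) {
    stop_pononet("k must be a positive integer", class = "pononet_validation_error")
  }
  if (nrow(summary) == 0) {
    stop_pononet("TF summary is empty", class = "pononet_validation_error")
  }
  summary |>
    arrange(desc(.data$coverage), .data$tf) |>
    head(k)
}

#' Genes co-regulated by a set of TFs
#'
#' Intersection of the in-network target sets of the named TFs.
#'
#' @param summary a `tf_summary`.
#' @param tf_set character vector of TF symbols present in `summary`.
#' @return sorted character vector of co-regulated genes.
#' @export
coregulated_genes <- function(summary, tf_set) {
  missing <- setdiff(tf_set, summary$tf)
  if (length(missing) > 0) {
    stop_pononet(
      paste0("TF(s) absent from summary: ", paste(missing, collapse = ", ")),
      class = "pononet_validation_error"
    )
  }
  sets <- summary$targets[match(tf_set, summary$tf)]
  sort(Reduce(intersect, sets))
}
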