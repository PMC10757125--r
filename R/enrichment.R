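#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether the query genes overlap it more than
#' expected under sampling without replacement from the universe: with
#' universe size N, set size K (after intersecting the set with the
#' universe), query size n and overlap k, the p-value is the upper tail
#' P(X >= k) of Hypergeometric(N, K, n). One-sided over-representation only;
#' p-values are BH-adjusted across sets. The recommended universe is the set
#' of genes actually measured on the platform, not the genome.
#'
#' @param query character vector of genes of interest.
#' @param collection named list of gene sets (see [read_gene_sets()]).
#' @param universe character vector of background genes; the query must be a
#'   subset.
#' @return tibble with columns `set`, `k`, `K`, `n`, `N`, `p`, `adj_p`,
#'   sorted by `p`.
#' @export
hypergeometric_ora <- function(query, collection, universe) {
  universe <- unique(universe)
  query <- unique(query)
  if (length(universe) == 0 || length(query) == 0) {
    stop_pononet("Query and universe must be non-empty",
      class = "pononet_validation_error"
    )
  }
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    stop_pononet(
      paste0("Query gene(s) outside the universe: ", paste(outside, collapse = ", ")),
      class = "pononet_validation_error"
    )
  }
  N <- length(universe)
  n <- length(query)
  rows <- purrr::map(names(collection), function(nm) {
    members <- intersect(collection[[nm]], universe)
    K <- length(members)
    k <- length(intersect(members, query))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble(set = nm, k = k, K = K, n = n, N = N, p = p)
  })
  out <- bind_rows(rows)
  out$adj_p <- adjust_bh(out$p)
  arrange(out, .data$p, .data$set)
}
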