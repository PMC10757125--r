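# Small in-code fixtures shared across test files.

make_expr <- function(values, genes = NULL, samples = NULL, dataset_id = "test") {
  genes <- genes %||% sprintf("g%d", seq_len(nrow(values)))
  samples <- samples %||% sprintf("s%d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  as_expr_df(values, dataset_id = dataset_id)
}

make_phenotypes <- function(samples, conditions) {
  as_phenotypes(tibble::tibble(sample_id = samples, condition = conditions))
}

two_group_phenotypes <- function(n1, n2, prefix = "s") {
  make_phenotypes(
    sprintf("%s%d", prefix, seq_len(n1 + n2)),
    rep(c("response", "nonresponse"), c(n1, n2))
  )
}

# Edge tibble in the shape produced by build_differential_edges().
make_edges <- function(gene_a, gene_b, class,
                       r_response = NA_real_, r_nonresponse = NA_real_) {
  tibble::tibble(
    gene_a = gene_a, gene_b = gene_b,
    r_response = rep_len(r_response, length(gene_a)),
    r_nonresponse = rep_len(r_nonresponse, length(gene_a)),
    ratio = NA_real_,
    class = factor(class, levels = c("PO", "NO", "OP", "ON"))
  )
}

coex_network_from_edges <- function(...) {
  assemble_networks(make_edges(...))
}

`%||%` <- rlang::`%||%`
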