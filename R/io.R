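#' Expression dataset container
#'
#' An expression dataset is a tibble whose first column `gene` holds unique
#' gene symbols and whose remaining columns hold log2-scale expression values,
#' one column per sample. The dataset label travels in the `dataset_id`
#' attribute so that multi-cohort steps (per-dataset standardization,
#' cross-dataset DEG intersection) can tell cohorts apart.
#'
#' @param x a genes-by-samples numeric matrix with rownames (gene symbols) and
#'   colnames (sample identifiers), or a data frame with a `gene` column.
#' @param dataset_id single string labelling the dataset.
#' @return a tibble of class `pononet_expr`.
#' @export
#' @examples
#' m <- matrix(rnorm(6), 2, 3, dimnames = list(c("A", "B"), c("s1", "s2", "s3")))
#' as_expr_df(m, "demo")
as_expr_df <- function(x, dataset_id = "dataset") {
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      stop_pononet("Matrix input needs gene rownames and sample colnames",
        class = "pononet_format_error"
      )
    }
    x <- tibble(gene = rownames(x), as_tibble(x, .name_repair = "minimal"))
  }
  x <- as_tibble(x)
  if (!identical(names(x)[1], "gene")) {
    stop_pononet("First column of an expression dataset must be `gene`",
      class = "pononet_format_error"
    )
  }
  validate_expr_df(x)
  attr(x, "dataset_id") <- dataset_id
  class(x) <- c("pononet_expr", class(x))
  x
}

validate_expr_df <- function(x) {
  genes <- x$gene
  samples <- names(x)[-1]
  if (anyDuplicated(genes)) {
    stop_pononet(
      paste0("Duplicate gene identifiers: ",
        paste(unique(genes[duplicated(genes)]), collapse = ", ")),
      class = "pononet_format_error"
    )
  }
  if (anyDuplicated(samples)) {
    stop_pononet(
      paste0("Duplicate sample identifiers: ",
        paste(unique(samples[duplicated(samples)]), collapse = ", ")),
      class = "pononet_format_error"
    )
  }
  vals <- as.matrix(x[, -1, drop = FALSE])
  if (!is.numeric(vals) || any(!is.finite(vals))) {
    stop_pononet("Expression values must all be finite numerics",
      class = "pononet_format_error"
    )
  }
  invisible(x)
}

#' Extract the genes-by-samples matrix from an expression dataset
#'
#' @param x an expression dataset (see [as_expr_df()]).
#' @return numeric matrix, genes in rows.
#' @export
expr_matrix <- function(x) {
  m <- as.matrix(x[, setdiff(names(x), "gene"), drop = FALSE])
  rownames(m) <- x$gene
  m
}

#' Dataset label of an expression dataset
#' @param x an expression dataset.
#' @return single string.
#' @export
dataset_id <- function(x) attr(x, "dataset_id") %||% "dataset"

#' Read a tab-separated expression matrix
#'
#' Expects a header row of unique sample identifiers and a first column of
#' gene symbols; all remaining cells must parse as finite numbers (values are
#' assumed to be on the log2 scale already). Rows sharing a gene symbol are
#' collapsed according to `duplicate_policy`.
#'
#' @param path file path.
#' @param dataset_id label stored on the returned dataset.
#' @param duplicate_policy how to collapse duplicate gene rows:
#'   `"highest_mean"` keeps the row with the highest mean expression (common
#'   microarray practice), `"mean"` averages the rows, `"error"` refuses.
#' @return an expression dataset tibble.
#' @export
read_expression <- function(path, dataset_id = basename(path),
                            duplicate_policy = c("highest_mean", "mean", "error")) {
  duplicate_policy <- match.arg(duplicate_policy)
  raw <- utils::read.delim(path,
    header = TRUE, sep = "\t", colClasses = "character",
    check.names = FALSE, quote = ""
  )
  if (ncol(raw) < 2) {
    stop_pononet("Expression file needs a gene column plus sample columns",
      class = "pononet_format_error"
    )
  }
  samples <- names(raw)[-1]
  if (all(!is.na(suppressWarnings(as.numeric(samples))))) {
    stop_pononet("Header row looks numeric; sample identifiers expected",
      class = "pononet_format_error"
    )
  }
  if (anyDuplicated(samples)) {
    stop_pononet(
      paste0("Duplicate sample identifiers in header: ",
        paste(unique(samples[duplicated(samples)]), collapse = ", ")),
      class = "pononet_format_error"
    )
  }
  genes <- raw[[1]]
  vals <- suppressWarnings(
    vapply(raw[-1], as.numeric, numeric(nrow(raw)))
  )
  vals <- matrix(vals, nrow = nrow(raw),
    dimnames = list(NULL, samples))
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_pononet(
      sprintf(
        "Non-numeric expression value '%s' at row %d (gene %s), column '%s'",
        raw[bad[1, 1], bad[1, 2] + 1], bad[1, 1], genes[bad[1, 1]],
        samples[bad[1, 2]]
      ),
      class = "pononet_parse_error"
    )
  }
  if (anyDuplicated(genes)) {
    dup_genes <- unique(genes[duplicated(genes)])
    if (duplicate_policy == "error") {
      stop_pononet(
        paste0("Duplicate gene rows: ", paste(dup_genes, collapse = ", ")),
        class = "pononet_format_error"
      )
    }
    inform(sprintf(
      "Collapsing %d duplicated gene symbol(s) by policy '%s'",
      length(dup_genes), duplicate_policy
    ))
    if (duplicate_policy == "highest_mean") {
      keep <- order(-rowMeans(vals))
      keep <- keep[!duplicated(genes[keep])]
      keep <- sort(keep)
      vals <- vals[keep, , drop = FALSE]
      genes <- genes[keep]
    } else {
      vals <- rowsum(vals, genes, reorder = FALSE) /
        as.vector(table(factor(genes, levels = unique(genes))))
      genes <- rownames(vals)
    }
  }
  rownames(vals) <- genes
  as_expr_df(vals, dataset_id = dataset_id)
}

#' Write an expression dataset to tab-separated text
#' @param x expression dataset.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  utils::write.table(as.data.frame(x), path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

phenotype_levels <- c("response", "nonresponse")

#' Read a sample phenotype table
#'
#' Two-column TSV (`sample_id`, `condition`). Condition labels are normalized
#' case-insensitively to `response` / `nonresponse`. Any other label (for
#' example `stable`, the conventional no-response/no-progression category)
#' is rejected rather than silently dropped, unless `drop_unknown = TRUE`.
#'
#' @param path file path.
#' @param drop_unknown drop samples with unrecognized labels (with a message)
#'   instead of erroring.
#' @return tibble with columns `sample_id`, `condition` (factor).
#' @export
read_phenotypes <- function(path, drop_unknown = FALSE) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
    colClasses = "character", check.names = FALSE)
  if (!all(c("sample_id", "condition") %in% names(raw))) {
    stop_pononet("Phenotype table needs columns sample_id and condition",
      class = "pononet_format_error"
    )
  }
  as_phenotypes(tibble(
    sample_id = raw$sample_id,
    condition = raw$condition
  ), drop_unknown = drop_unknown)
}

#' Validate and normalize a phenotype table
#' @param x data frame with `sample_id` and `condition` columns.
#' @inheritParams read_phenotypes
#' @return tibble with normalized condition factor.
#' @export
as_phenotypes <- function(x, drop_unknown = FALSE) {
  x <- as_tibble(x)
  cond <- tolower(trimws(as.character(x$condition)))
  unknown <- !cond %in% phenotype_levels
  if (any(unknown)) {
    if (!drop_unknown) {
      stop_pononet(
        sprintf(
          "Unknown condition label(s): %s. Allowed labels: %s",
          paste(unique(x$condition[unknown]), collapse = ", "),
          paste(phenotype_levels, collapse = ", ")
        ),
        class = "pononet_validation_error"
      )
    }
    inform(sprintf("Dropping %d sample(s) with unrecognized labels", sum(unknown)))
    x <- x[!unknown, , drop = FALSE]
    cond <- cond[!unknown]
  }
  if (anyDuplicated(x$sample_id)) {
    stop_pononet(
      paste0("Duplicated sample_id in phenotype table: ",
        paste(unique(x$sample_id[duplicated(x$sample_id)]), collapse = ", ")),
      class = "pononet_validation_error"
    )
  }
  tibble(
    sample_id = x$sample_id,
    condition = factor(cond, levels = phenotype_levels)
  )
}

#' Write a phenotype table
#' @param x phenotype tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(x, path) {
  utils::write.table(as.data.frame(x), path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Read a transcription-factor / target interaction table
#'
#' Reads a TSV of experimentally validated TF-to-target edges (HTRIdb-style
#' exports work: pick the symbol columns with `tf_col` / `target_col`).
#' Duplicate (tf, target) pairs are removed with a message.
#'
#' @param path file path.
#' @param tf_col,target_col column name or index of the TF symbol and target
#'   symbol columns.
#' @return tibble with columns `tf`, `target`.
#' @export
read_tf_table <- function(path, tf_col = 1, target_col = 2) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
    colClasses = "character", check.names = FALSE)
  if (nrow(raw) == 0) {
    stop_pononet("TF interaction table is empty", class = "pononet_format_error")
  }
  pick <- function(col, what) {
    if (is.character(col) && !col %in% names(raw)) {
      stop_pononet(sprintf("Missing %s column '%s'", what, col),
        class = "pononet_format_error"
      )
    }
    if (is.numeric(col) && col > ncol(raw)) {
      stop_pononet(sprintf("%s column index %d out of range", what, col),
        class = "pononet_format_error"
      )
    }
    trimws(raw[[col]])
  }
  out <- tibble(tf = pick(tf_col, "TF"), target = pick(target_col, "target"))
  if (any(out$tf == "" | out$target == "")) {
    stop_pononet("Empty TF or target symbol in interaction table",
      class = "pononet_validation_error"
    )
  }
  n0 <- nrow(out)
  out <- dplyr::distinct(out)
  if (nrow(out) < n0) {
    inform(sprintf("Dropped %d duplicate TF-target pair(s)", n0 - nrow(out)))
  }
  out
}

#' Write a TF-target table
#' @param x tibble with `tf` and `target` columns.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tf_table <- function(x, path) {
  utils::write.table(as.data.frame(x[, c("tf", "target")]), path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`. Member lists are
#' de-duplicated per set.
#'
#' @param path file path.
#' @return named list of character vectors; descriptions kept in the
#'   `descriptions` attribute.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    stop_pononet("Gene-set file is empty", class = "pononet_format_error")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    stop_pononet(
      sprintf("Malformed GMT line %d: fewer than 3 tab-separated fields", short[1]),
      class = "pononet_format_error"
    )
  }
  names_ <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(names_)) {
    stop_pononet("Duplicate gene-set names in GMT", class = "pononet_format_error")
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- names_
  attr(sets, "descriptions") <- setNames(
    vapply(fields, `[[`, character(1), 2), names_
  )
  sets
}

#' Write a gene-set collection to GMT
#' @param sets named list of character vectors.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  desc <- attr(sets, "descriptions") %||% setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a survival table
#'
#' TSV with columns `sample_id`, `time` (non-negative), `event` (1 = event,
#' 0 = censored).
#'
#' @param path file path.
#' @return tibble with validated columns.
#' @export
read_survival <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (!all(c("sample_id", "time", "event") %in% names(raw))) {
    stop_pononet("Survival table needs columns sample_id, time, event",
      class = "pononet_format_error"
    )
  }
  as_survival_table(raw)
}

#' Validate a survival table
#' @param x data frame with `sample_id`, `time`, `event`.
#' @return tibble.
#' @export
as_survival_table <- function(x) {
  x <- as_tibble(x)[, c("sample_id", "time", "event")]
  x$sample_id <- as.character(x$sample_id)
  if (anyDuplicated(x$sample_id)) {
    stop_pononet("Duplicated sample_id in survival table",
      class = "pononet_validation_error"
    )
  }
  if (any(!is.finite(x$time)) || any(x$time < 0)) {
    stop_pononet("Survival times must be finite and non-negative",
      class = "pononet_validation_error"
    )
  }
  if (!all(x$event %in% c(0, 1))) {
    stop_pononet("Event indicator must be 0 (censored) or 1 (event)",
      class = "pononet_validation_error"
    )
  }
  x
}

#' Write a survival table
#' @param x survival tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_survival <- function(x, path) {
  utils::write.table(as.data.frame(x), path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Export a co-expression network to SIF or GraphML
#'
#' SIF lines take the form `geneA <class> geneB` with the differential
#' co-expression class (PO/NO/OP/ON) as the interaction token, in stable
#' lexicographic order. GraphML (written through igraph) carries edge
#' attributes `class`, `r_response`, `r_nonresponse` and node attributes
#' `degree`, `betweenness` and `is_hub` when present.
#'
#' @param network a `coex_network` (see [assemble_networks()]).
#' @param path output file.
#' @param format `"sif"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  g <- network$graph
  if (igraph::vcount(g) == 0) {
    warn(sprintf("Network %s is empty; writing an empty file", network$network_id))
    file.create(path)
    return(invisible(path))
  }
  if (format == "sif") {
    el <- igraph::as_data_frame(g, what = "edges")
    o <- orient_pairs(el$from, el$to)
    lines <- sprintf("%s\t%s\t%s", o$gene_a, el$class, o$gene_b)
    writeLines(sort(lines), path)
  } else {
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a GraphML network written by [write_network()]
#' @param path GraphML file.
#' @param network_id label for the returned network.
#' @return a `coex_network`.
#' @export
read_network_graphml <- function(path, network_id = basename(path)) {
  g <- igraph::read_graph(path, format = "graphml")
  new_coex_network(g, network_id)
}
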