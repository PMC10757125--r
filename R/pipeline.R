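pipeline_param_defaults <- list(
  adj_p = 0.05, fc = 1.5, down_rule = "reciprocal", moderation = TRUE,
  intersect_mode = "any_direction", tau = 0.7, ratio_min = 1,
  combine = "per_stratum_z", k_degree = 10, k_betweenness = 10,
  module_size = 5, split = "median", ties = "efron", top_k_tfs = 10,
  seed = 1
)

#' Pipeline configuration
#'
#' Collects the input paths and every stage parameter of the analysis.
#' Input paths other than the first cohort are optional; stages without
#' inputs (TF overlay, enrichment, prognosis) are skipped. Unknown
#' parameters are rejected.
#'
#' @param expression_a,phenotypes_a first cohort (required).
#' @param expression_b,phenotypes_b optional second cohort for
#'   cross-dataset DEG intersection.
#' @param tf_table optional TF interaction TSV.
#' @param gene_sets optional GMT file for over-representation analysis.
#' @param survival,survival_expression optional survival table and the
#'   expression of the survival cohort.
#' @param outdir output directory.
#' @param ... stage parameters overriding the defaults: `adj_p`, `fc`,
#'   `down_rule`, `moderation`, `intersect_mode`, `tau`, `ratio_min`,
#'   `combine`, `k_degree`, `k_betweenness`, `module_size`, `split`,
#'   `ties`, `top_k_tfs`, `seed`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(expression_a, phenotypes_a,
                            expression_b = NULL, phenotypes_b = NULL,
                            tf_table = NULL, gene_sets = NULL,
                            survival = NULL, survival_expression = NULL,
                            outdir = tempfile("pononet_run_"), ...) {
  params <- utils::modifyList(pipeline_param_defaults, list(...))
  unknown <- setdiff(names(list(...)), names(pipeline_param_defaults))
  if (length(unknown) > 0) {
    stop_pononet(
      paste0("Unknown pipeline parameter(s): ", paste(unknown, collapse = ", ")),
      class = "pononet_config_error"
    )
  }
  structure(
    list(
      inputs = list(
        expression_a = expression_a, phenotypes_a = phenotypes_a,
        expression_b = expression_b, phenotypes_b = phenotypes_b,
        tf_table = tf_table, gene_sets = gene_sets,
        survival = survival, survival_expression = survival_expression
      ),
      params = params,
      outdir = outdir
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys are the input paths and `outdir`; stage parameters live
#' under `params`. Unknown keys at either level are rejected before any
#' stage runs.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  input_keys <- c(
    "expression_a", "phenotypes_a", "expression_b", "phenotypes_b",
    "tf_table", "gene_sets", "survival", "survival_expression", "outdir"
  )
  unknown <- setdiff(names(y), c(input_keys, "params"))
  if (length(unknown) > 0) {
    stop_pononet(
      paste0("Unknown configuration key(s): ", paste(unknown, collapse = ", ")),
      class = "pononet_config_error"
    )
  }
  args <- y[intersect(names(y), input_keys)]
  do.call(pipeline_config, c(args, y$params))
}

#' Write a pipeline configuration to YAML
#' @param config a `pipeline_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  y <- c(
    Filter(Negate(is.null), config$inputs),
    list(outdir = config$outdir, params = config$params)
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

write_tsv_plain <- function(x, path) {
  df <- as.data.frame(x)
  for (j in seq_along(df)) {
    if (is.list(df[[j]])) {
      df[[j]] <- vapply(df[[j]], paste, character(1), collapse = ";")
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full differential co-expression analysis
#'
#' Executes the stage sequence: differential expression per cohort, mutual
#' DEG intersection, per-condition correlations and pair classification,
#' network assembly (PONO/OPON), hub-module selection, TF overlay,
#' over-representation analysis and prognostic evaluation. Every stage's
#' tables are written under `config$outdir` together with a run manifest
#' (parameters, input checksums, package version, per-stage status and
#' timing). Given a fixed seed and identical inputs the analysis outputs
#' are deterministic.
#'
#' @param config a [pipeline_config()].
#' @return the run summary (list), invisibly; also serialized as
#'   `summary.json` in the output directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  p <- config$params
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(p$seed)

  stages <- list()
  run_stage <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fn(), error = function(e) {
      stages[[name]] <<- list(status = "failed", error = conditionMessage(e))
      write_manifest(config, stages)
      stop_pononet(
        sprintf("Stage '%s' failed: %s", name, conditionMessage(e)),
        class = "pononet_stage_error"
      )
    })
    stages[[name]] <<- list(
      status = "completed",
      seconds = round(proc.time()[["elapsed"]] - t0, 3)
    )
    res
  }

  inp <- config$inputs
  expr_a <- read_expression(inp$expression_a, dataset_id = "datasetA")
  pheno_a <- read_phenotypes(inp$phenotypes_a)
  two_cohorts <- !is.null(inp$expression_b)
  if (two_cohorts) {
    expr_b <- read_expression(inp$expression_b, dataset_id = "datasetB")
    pheno_b <- read_phenotypes(inp$phenotypes_b)
  }

  degs <- run_stage("degs", function() {
    tab_a <- diff_expression(expr_a, pheno_a, moderation = p$moderation)
    write_tsv_plain(tab_a, file.path(outdir, "degs_datasetA.tsv"))
    set_a <- call_degs(tab_a, p$adj_p, p$fc, p$down_rule)
    out <- list(a = set_a)
    if (two_cohorts) {
      tab_b <- diff_expression(expr_b, pheno_b, moderation = p$moderation)
      write_tsv_plain(tab_b, file.path(outdir, "degs_datasetB.tsv"))
      out$b <- call_degs(tab_b, p$adj_p, p$fc, p$down_rule)
    }
    out
  })

  universe <- run_stage("mutual_degs", function() {
    u <- if (two_cohorts) {
      intersect_degs(degs$a, degs$b, mode = p$intersect_mode)
    } else {
      sort(unique(c(degs$a$up, degs$a$down)))
    }
    writeLines(u, file.path(outdir, "mutual_degs.txt"))
    u
  })

  edges <- run_stage("coexpr", function() {
    datasets <- if (two_cohorts) list(expr_a, expr_b) else expr_a
    phenos <- if (two_cohorts) list(pheno_a, pheno_b) else pheno_a
    cors <- condition_correlations(datasets, phenos, universe, combine = p$combine)
    th <- coex_thresholds(tau = p$tau, ratio_min = p$ratio_min)
    e <- build_differential_edges(cors, th)
    write_tsv_plain(e, file.path(outdir, "differential_edges.tsv"))
    e
  })

  networks <- run_stage("networks", function() {
    nets <- assemble_networks(edges)
    for (nm in names(nets)) {
      write_network(nets[[nm]], file.path(outdir, paste0(nm, ".sif")), "sif")
      write_network(nets[[nm]], file.path(outdir, paste0(nm, ".graphml")), "graphml")
    }
    nets
  })

  modules <- run_stage("hubs", function() {
    out <- list()
    for (nm in names(networks)) {
      met <- node_metrics(networks[[nm]])
      if (nrow(met) == 0) next
      hub <- rank_hubs(met, p$k_degree, p$k_betweenness, p$module_size,
        network = networks[[nm]])
      met$is_hub <- met$gene %in% hub$hubs
      write_tsv_plain(met, file.path(outdir, paste0("metrics_", nm, ".tsv")))
      mcm <- module_cor_matrix(
        if (two_cohorts) list(expr_a, expr_b) else expr_a,
        if (two_cohorts) list(pheno_a, pheno_b) else pheno_a,
        hub$hubs, combine = p$combine
      )
      utils::write.table(unclass(mcm),
        file.path(outdir, paste0("module_cor_", nm, ".tsv")),
        sep = "\t", quote = FALSE
      )
      out[[nm]] <- hub
    }
    out
  })

  tf_summaries <- run_stage("regulators", function() {
    if (is.null(inp$tf_table)) return(NULL)
    tf_tbl <- read_tf_table(inp$tf_table)
    out <- list()
    for (nm in names(networks)) {
      if (igraph::vcount(networks[[nm]]$graph) == 0) next
      s <- map_tf_targets(networks[[nm]], tf_tbl)
      if (nrow(s) == 0) next
      top <- top_regulators(s, p$top_k_tfs)
      write_tsv_plain(top, file.path(outdir, paste0("tf_", nm, ".tsv")))
      out[[nm]] <- top
    }
    out
  })

  enrich <- run_stage("enrichment", function() {
    if (is.null(inp$gene_sets)) return(NULL)
    sets <- read_gene_sets(inp$gene_sets)
    bg <- expr_a$gene
    out <- list()
    for (nm in names(networks)) {
      nodes <- igraph::V(networks[[nm]]$graph)$name
      nodes <- intersect(nodes, bg)
      if (length(nodes) == 0) next
      tab <- hypergeometric_ora(nodes, sets, bg)
      write_tsv_plain(tab, file.path(outdir, paste0("enrichment_", nm, ".tsv")))
      out[[nm]] <- tab
    }
    out
  })

  prognosis <- run_stage("prognosis", function() {
    if (is.null(inp$survival)) return(NULL)
    surv_tbl <- read_survival(inp$survival)
    surv_expr <- if (!is.null(inp$survival_expression)) {
      read_expression(inp$survival_expression, dataset_id = "survival")
    } else {
      expr_a
    }
    out <- list()
    for (nm in names(modules)) {
      genes <- intersect(modules[[nm]]$hubs, surv_expr$gene)
      if (length(genes) < 2) next
      res <- evaluate_prognosis(surv_expr, surv_tbl, genes,
        split = p$split, ties = p$ties)
      write_tsv_plain(res$km, file.path(outdir, paste0("km_", nm, ".tsv")))
      jsonlite::write_json(
        as.list(glance(res)),
        file.path(outdir, paste0("prognosis_", nm, ".json")),
        auto_unbox = TRUE, digits = NA
      )
      out[[nm]] <- res
    }
    out
  })

  write_manifest(config, stages)

  summary <- list(
    degs = lapply(degs, function(s) list(
      dataset = s$dataset_id, up = length(s$up), down = length(s$down)
    )),
    mutual_degs = length(universe),
    edge_classes = as.list(table(edges$class)),
    networks = lapply(networks, function(nw) list(
      id = nw$network_id,
      genes = igraph::vcount(nw$graph),
      edges = igraph::ecount(nw$graph)
    )),
    modules = lapply(modules, function(h) h$hubs),
    top_tfs = lapply(tf_summaries %||% list(), function(t_) t_$tf),
    prognosis = lapply(prognosis %||% list(), function(r) list(
      hazard_ratio = r$hazard_ratio$hr,
      hr_ci = r$hazard_ratio$ci,
      logrank_p = r$logrank$p,
      optimistic_p = r$split$optimistic_p
    ))
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(summary)
}

write_manifest <- function(config, stages) {
  inputs <- Filter(Negate(is.null), config$inputs)
  manifest <- list(
    package = "pononet",
    version = as.character(utils::packageVersion("pononet")),
    parameters = config$params,
    inputs = lapply(inputs, function(f) list(
      path = f, md5 = unname(tools::md5sum(f))
    )),
    stages = stages
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' One-command synthetic demonstration
#'
#' Generates the complete synthetic study ([simulate_study()]), writes it to
#' disk in the standard text formats, runs [run_pipeline()] on the written
#' files, and prints a compact summary of the result funnel: DEG counts per
#' cohort, mutual DEGs, network sizes, hub modules, top regulators and the
#' prognostic hazard ratios.
#'
#' @param seed RNG seed for the synthetic study and the pipeline.
#' @param outdir output directory (a fresh temporary directory by default).
#' @return the pipeline summary, invisibly.
#' @export
run_demo <- function(seed = 7, outdir = tempfile("pononet_demo_")) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fixdir <- file.path(outdir, "fixture")
  dir.create(fixdir, showWarnings = FALSE)
  study <- simulate_study(seed)
  paths <- list(
    expression_a = file.path(fixdir, "expression_a.tsv"),
    phenotypes_a = file.path(fixdir, "phenotypes_a.tsv"),
    expression_b = file.path(fixdir, "expression_b.tsv"),
    phenotypes_b = file.path(fixdir, "phenotypes_b.tsv"),
    tf_table = file.path(fixdir, "tf_table.tsv"),
    gene_sets = file.path(fixdir, "gene_sets.gmt"),
    survival = file.path(fixdir, "survival.tsv"),
    survival_expression = file.path(fixdir, "expression_survival.tsv")
  )
  write_expression(study$cohort_a$expression, paths$expression_a)
  write_phenotypes(study$cohort_a$phenotypes, paths$phenotypes_a)
  write_expression(study$cohort_b$expression, paths$expression_b)
  write_phenotypes(study$cohort_b$phenotypes, paths$phenotypes_b)
  write_tf_table(study$tf_table, paths$tf_table)
  sets <- list(
    RESPONSE_MODULE = study$truth$hubs[[1]],
    NONRESPONSE_MODULE = study$truth$hubs[[2]],
    PLANTED_UP = study$truth$degs$gene[study$truth$degs$direction == "up"],
    PLANTED_DOWN = study$truth$degs$gene[study$truth$degs$direction == "down"]
  )
  write_gene_sets(sets, paths$gene_sets)
  write_survival(study$survival$table, paths$survival)
  write_expression(study$survival$expression, paths$survival_expression)

  config <- do.call(pipeline_config, c(paths,
    list(outdir = file.path(outdir, "results"), seed = seed)))
  summary <- suppressMessages(run_pipeline(config))

  cat("Synthetic study demo\n")
  for (nm in names(summary$degs)) {
    cat(sprintf(
      "  DEGs %s: %d up, %d down\n",
      summary$degs[[nm]]$dataset, summary$degs[[nm]]$up, summary$degs[[nm]]$down
    ))
  }
  cat(sprintf("  mutual DEGs: %d\n", summary$mutual_degs))
  for (nw in summary$networks) {
    cat(sprintf("  network %s: %d genes, %d edges\n", nw$id, nw$genes, nw$edges))
  }
  for (nm in names(summary$modules)) {
    cat(sprintf("  module %s: %s\n", nm, paste(summary$modules[[nm]], collapse = ", ")))
  }
  for (nm in names(summary$top_tfs)) {
    cat(sprintf("  top TFs %s: %s\n", nm,
      paste(head(summary$top_tfs[[nm]], 3), collapse = ", ")))
  }
  for (nm in names(summary$prognosis)) {
    cat(sprintf(
      "  prognosis %s: HR = %.2f, log-rank p = %.2g\n",
      nm, summary$prognosis[[nm]]$hazard_ratio, summary$prognosis[[nm]]$logrank_p
    ))
  }
  invisible(summary)
}
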