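#' Specify a planted correlation block
#'
#' A block is a set of genes drawn from a multivariate normal with
#' compound-symmetry correlation: pairwise correlation `rho_on` in the
#' block's "on" condition and `rho_off` in the other condition. Compound
#' symmetry keeps the target pairwise correlation exact by construction.
#' `rho_off` defaults to a small negative value rather than 0 because the
#' differential-ratio criterion |(r_resp - r_non)/r_resp| >= 1 for a
#' positively correlated pair passes exactly when the correlation in the
#' "no correlation" condition is at or below zero; planting `rho_off = 0`
#' would leave recovery at the mercy of the sampling sign (about 50%).
#'
#' @param size number of member genes (>= 2).
#' @param rho_on within-block correlation in the "on" condition.
#' @param rho_off within-block correlation in the other condition.
#' @param on condition in which the block is "on".
#' @return a list of class `block_spec`.
#' @export
block_spec <- function(size, rho_on = 0.85, rho_off = -0.3,
                       on = c("response", "nonresponse")) {
  on <- match.arg(on)
  stopifnot(size >= 2, abs(rho_on) < 1, abs(rho_off) < 1)
  for (r in c(rho_on, rho_off)) {
    if (r < -1 / (size - 1)) {
      stop_pononet(
        sprintf(
          "Compound symmetry invalid: rho = %g < -1/(size-1) = %g",
          r, -1 / (size - 1)
        ),
        class = "pononet_config_error"
      )
    }
  }
  structure(list(size = size, rho_on = rho_on, rho_off = rho_off, on = on),
    class = "block_spec"
  )
}

#' Simulation configuration
#'
#' Describes a two-phenotype expression cohort with planted structure:
#' mean-shift differentially expressed genes (the first `n_up` genes are
#' shifted up by `delta` log2 units in the response condition, the next
#' `n_down` shifted down) and correlation blocks (see [block_spec()]),
#' whose members are taken from the up-regulated genes first so that the
#' planted co-expression structure survives the DEG filter, exactly as a
#' differential co-expression analysis assumes. All other genes are
#' independent Gaussian noise around `baseline` with standard deviation
#' `noise_sd` (0.5 log2 units, a typical residual spread for normalized
#' microarray data).
#'
#' @param n_genes total number of genes.
#' @param n_response,n_nonresponse samples per condition.
#' @param n_up,n_down planted up-/down-regulated gene counts.
#' @param delta log2 mean shift of planted DEGs (>= 0).
#' @param blocks list of [block_spec()] objects.
#' @param noise_sd residual standard deviation (log2 units).
#' @param baseline baseline log2 expression level.
#' @param batch_sd standard deviation of per-gene dataset batch offsets.
#' @param seed RNG seed; a fixed seed gives bit-reproducible output.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_genes, n_response, n_nonresponse,
                       n_up = 0, n_down = 0, delta = 1,
                       blocks = list(), noise_sd = 0.5, baseline = 8,
                       batch_sd = 0, seed = 1) {
  stopifnot(
    n_genes >= 1, n_response >= 0, n_nonresponse >= 0,
    n_up >= 0, n_down >= 0, delta >= 0, noise_sd > 0, batch_sd >= 0
  )
  blocks <- lapply(blocks, function(b) {
    if (!inherits(b, "block_spec")) do.call(block_spec, b) else b
  })
  need <- n_up + n_down + sum(vapply(blocks, `[[`, numeric(1), "size"))
  if (need > n_genes) {
    stop_pononet("Planted genes exceed n_genes", class = "pononet_config_error")
  }
  structure(
    list(
      n_genes = n_genes, n_response = n_response, n_nonresponse = n_nonresponse,
      n_up = n_up, n_down = n_down, delta = delta, blocks = blocks,
      noise_sd = noise_sd, baseline = baseline, batch_sd = batch_sd,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Allocate planted gene identities for a configuration
#' @keywords internal
#' @noRd
plant_layout <- function(config) {
  genes <- sprintf("G%05d", seq_len(config$n_genes))
  up <- genes[seq_len(config$n_up)]
  down <- genes[config$n_up + seq_len(config$n_down)]
  # block members come out of the up-regulated pool first
  pool <- c(up, genes[config$n_up + config$n_down + seq_len(
    config$n_genes - config$n_up - config$n_down
  )])
  block_genes <- list()
  taken <- 0
  for (i in seq_along(config$blocks)) {
    sz <- config$blocks[[i]]$size
    block_genes[[i]] <- pool[taken + seq_len(sz)]
    taken <- taken + sz
  }
  list(genes = genes, up = up, down = down, block_genes = block_genes)
}

#' Generate a synthetic two-phenotype expression cohort
#'
#' Samples each condition from the configured model and returns the
#' expression dataset, its phenotype table, and the ground truth needed to
#' score recovery downstream.
#'
#' @param config a [sim_config()].
#' @param dataset_id label for the generated dataset.
#' @return list with elements `expression` (expression dataset),
#'   `phenotypes` (tibble) and `truth` (list of class `sim_truth`: planted
#'   `degs` tibble, planted `pairs` tibble with their expected
#'   differential-co-expression class, per-block `hubs`, and the layout).
#' @export
simulate_expression <- function(config, dataset_id = "sim") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  lay <- plant_layout(config)
  n <- c(response = config$n_response, nonresponse = config$n_nonresponse)
  sd_ <- config$noise_sd
  cols <- list()
  for (cond in phenotype_levels) {
    nc <- n[[cond]]
    if (nc == 0) next
    m <- matrix(rnorm(config$n_genes * nc, config$baseline, sd_),
      nrow = config$n_genes,
      dimnames = list(lay$genes, NULL)
    )
    for (i in seq_along(config$blocks)) {
      b <- config$blocks[[i]]
      rho <- if (b$on == cond) b$rho_on else b$rho_off
      sigma <- sd_^2 * ((1 - rho) * diag(b$size) + rho)
      draws <- MASS::mvrnorm(nc, mu = rep(config$baseline, b$size), Sigma = sigma)
      m[lay$block_genes[[i]], ] <- t(matrix(draws, nrow = nc))
    }
    if (cond == "response" && config$delta > 0) {
      m[lay$up, ] <- m[lay$up, , drop = FALSE] + config$delta
      m[lay$down, ] <- m[lay$down, , drop = FALSE] - config$delta
    }
    cols[[cond]] <- m
  }
  mat <- do.call(cbind, cols)
  if (config$batch_sd > 0) {
    mat <- mat + rnorm(config$n_genes, 0, config$batch_sd)
  }
  sample_ids <- sprintf("%s_s%03d", dataset_id, seq_len(ncol(mat)))
  colnames(mat) <- sample_ids
  phenotypes <- tibble(
    sample_id = sample_ids,
    condition = factor(
      rep(names(cols), vapply(cols, ncol, integer(1))),
      levels = phenotype_levels
    )
  )
  truth <- build_sim_truth(config, lay)
  list(
    expression = as_expr_df(mat, dataset_id = dataset_id),
    phenotypes = phenotypes,
    truth = truth
  )
}

build_sim_truth <- function(config, lay) {
  degs <- tibble(
    gene = c(lay$up, lay$down),
    direction = rep(c("up", "down"), c(length(lay$up), length(lay$down)))
  )
  pair_rows <- list()
  for (i in seq_along(config$blocks)) {
    b <- config$blocks[[i]]
    gs <- sort(lay$block_genes[[i]])
    if (length(gs) < 2) next
    cmb <- utils::combn(gs, 2)
    rho_resp <- if (b$on == "response") b$rho_on else b$rho_off
    rho_non <- if (b$on == "nonresponse") b$rho_on else b$rho_off
    cls <- classify_pairs(rho_resp, rho_non)
    pair_rows[[i]] <- tibble(
      gene_a = cmb[1, ], gene_b = cmb[2, ],
      rho_response = rho_resp, rho_nonresponse = rho_non,
      expected_class = as.character(cls),
      block = i
    )
  }
  structure(
    list(
      degs = degs,
      pairs = if (length(pair_rows)) bind_rows(pair_rows) else
        tibble(gene_a = character(), gene_b = character(),
          rho_response = numeric(), rho_nonresponse = numeric(),
          expected_class = character(), block = integer()),
      hubs = lay$block_genes,
      layout = lay,
      config = config
    ),
    class = "sim_truth"
  )
}

#' Generate survival outcomes driven by expression
#'
#' Event times are exponential with rate `baseline_rate * exp(PI)` where
#' `PI = sum_g beta_g * z_g` over the genes named in `betas` (z-scored per
#' gene across samples) — the simplest model consistent with proportional
#' hazards. Censoring is an independent exponential with rate
#' `censor_rate`; observed time is the minimum, and the event indicator
#' marks true events.
#'
#' @param expression expression dataset supplying the covariates.
#' @param betas named numeric vector of log-hazard coefficients per gene
#'   (may be empty or all zero for a null cohort).
#' @param baseline_rate baseline event rate (> 0).
#' @param censor_rate exponential censoring rate (0 disables censoring).
#' @param seed RNG seed.
#' @return survival tibble (`sample_id`, `time`, `event`).
#' @export
simulate_survival <- function(expression, betas = numeric(),
                              baseline_rate = 0.1, censor_rate = 0, seed = 1) {
  stopifnot(baseline_rate > 0, censor_rate >= 0)
  set.seed(seed)
  m <- expr_matrix(expression)
  nsamp <- ncol(m)
  pi_values <- rep(0, nsamp)
  if (length(betas) > 0) {
    missing <- setdiff(names(betas), rownames(m))
    if (length(missing) > 0) {
      stop_pononet(
        paste0("Beta gene(s) absent from expression: ",
          paste(missing, collapse = ", ")),
        class = "pononet_validation_error"
      )
    }
    x <- m[names(betas), , drop = FALSE]
    z <- (x - rowMeans(x)) / sqrt(row_vars(x))
    pi_values <- drop(crossprod(z, betas))
  }
  event_time <- rexp(nsamp, rate = baseline_rate * exp(pi_values))
  censor_time <- if (censor_rate > 0) rexp(nsamp, censor_rate) else rep(Inf, nsamp)
  as_survival_table(tibble(
    sample_id = colnames(m),
    time = pmin(event_time, censor_time),
    event = as.numeric(event_time <= censor_time)
  ))
}

#' Censoring rate achieving a target censoring fraction
#'
#' For exponential event times with per-sample rates `event_rates` and
#' independent exponential censoring at rate `c`, the expected censored
#' fraction is `mean(c / (c + event_rates))`; this helper solves for `c`.
#'
#' @param target_fraction desired censoring fraction in (0, 1).
#' @param event_rates per-sample event rates.
#' @return censoring rate.
#' @export
censor_rate_for <- function(target_fraction, event_rates) {
  stopifnot(target_fraction > 0, target_fraction < 1, all(event_rates > 0))
  f <- function(cc) mean(cc / (cc + event_rates)) - target_fraction
  stats::uniroot(f, lower = 1e-10, upper = 1e6 * max(event_rates))$root
}

#' Generate a synthetic TF-target interaction table
#'
#' "Master" TFs target a stated fraction of the planted module genes (or
#' explicit target sets via `master_targets`), while decoy TFs target
#' random genes outside the network, emulating a curated genome-wide
#' interaction table in which only some regulators touch the network.
#'
#' @param module_genes genes the masters should cover.
#' @param decoy_pool genes decoys draw targets from (non-network genes).
#' @param n_masters number of master TFs (named `TF_M1`, `TF_M2`, ...).
#' @param master_coverage fraction of `module_genes` each master targets.
#' @param master_targets optional list of explicit target sets overriding
#'   the coverage rule (one element per master).
#' @param n_decoys number of decoy TFs (named `TF_D1`, ...).
#' @param targets_per_decoy targets drawn per decoy.
#' @param seed RNG seed.
#' @return tibble with columns `tf`, `target`.
#' @export
simulate_tf_table <- function(module_genes, decoy_pool = character(),
                              n_masters = 1, master_coverage = 1,
                              master_targets = NULL,
                              n_decoys = 0, targets_per_decoy = 5, seed = 1) {
  set.seed(seed)
  rows <- list()
  if (is.null(master_targets)) {
    k <- ceiling(master_coverage * length(module_genes))
    master_targets <- replicate(n_masters, module_genes[seq_len(k)],
      simplify = FALSE)
  }
  for (i in seq_along(master_targets)) {
    rows[[length(rows) + 1]] <- tibble(
      tf = sprintf("TF_M%d", i), target = master_targets[[i]]
    )
  }
  if (n_decoys > 0) {
    if (length(decoy_pool) < targets_per_decoy) {
      stop_pononet("Decoy pool smaller than targets_per_decoy",
        class = "pononet_config_error"
      )
    }
    for (i in seq_len(n_decoys)) {
      rows[[length(rows) + 1]] <- tibble(
        tf = sprintf("TF_D%d", i),
        target = sample(decoy_pool, targets_per_decoy)
      )
    }
  }
  dplyr::distinct(bind_rows(rows))
}

#' Generate the complete two-cohort synthetic study
#'
#' Emulates the structure of a two-cohort treatment-response study: cohort A
#' has 53 samples (9 responders, 44 non-responders), cohort B has 26 (13 /
#' 13); both share 2000 genes with 100 planted mutual DEGs (50 up, 50 down,
#' log2 shift 1.5) and two planted 5-gene correlation blocks, one "on" in
#' the response state (the response-network module analog) and one "on" in
#' the non-response state. Cohort B carries per-gene batch offsets
#' (N(0, 0.2^2)) to exercise per-dataset standardization. A separate
#' 200-sample survival cohort carries the same correlation blocks plus
#' exponential survival driven by the response-module genes, with
#' coefficients sized so the designed high-versus-low hazard ratio is about
#' 4, and censoring calibrated to about 30%.
#'
#' @param seed RNG seed driving every cohort.
#' @param n_survival survival-cohort size.
#' @param design_hr designed hazard ratio between prognostic-index halves.
#' @return list with `cohort_a`, `cohort_b` (each `expression` +
#'   `phenotypes`), `truth`, `tf_table`, and `survival` (`expression`,
#'   `table`, `betas`).
#' @export
simulate_study <- function(seed = 7, n_survival = 200, design_hr = 4) {
  set.seed(seed)
  subseeds <- sample.int(1e8, 5)
  # rho_off is bounded below by -1/(m-1) = -0.25 for 5-gene blocks (compound
  # symmetry validity); -0.2 keeps the off-state correlation negative, which
  # the ratio criterion needs, while staying inside the valid range
  blocks <- list(
    block_spec(5, rho_on = 0.85, rho_off = -0.2, on = "response"),
    block_spec(5, rho_on = 0.85, rho_off = -0.2, on = "nonresponse")
  )
  base <- list(
    n_genes = 2000, n_up = 50, n_down = 50, delta = 1.5,
    blocks = blocks, noise_sd = 0.5, baseline = 8
  )
  cfg_a <- do.call(sim_config, c(base,
    list(n_response = 9, n_nonresponse = 44, seed = subseeds[1])))
  cfg_b <- do.call(sim_config, c(base,
    list(n_response = 13, n_nonresponse = 13, batch_sd = 0.2, seed = subseeds[2])))
  cohort_a <- simulate_expression(cfg_a, dataset_id = "cohortA")
  cohort_b <- simulate_expression(cfg_b, dataset_id = "cohortB")
  truth <- cohort_a$truth # identical layout in both cohorts

  cfg_s <- do.call(sim_config, c(base,
    list(n_response = n_survival, n_nonresponse = 0, seed = subseeds[3])))
  surv_expr <- simulate_expression(cfg_s, dataset_id = "survival")$expression

  module_resp <- truth$hubs[[1]]
  m <- length(module_resp)
  rho <- blocks[[1]]$rho_on
  # PI variance for equal betas on an exchangeable block: b^2 (m + m(m-1) rho);
  # halves of a normal PI differ by 1.5958 sd, so exp(1.5958 * sd) = design_hr
  beta_each <- log(design_hr) / (sqrt(2 / pi) * 2 * sqrt(m + m * (m - 1) * rho))
  betas <- setNames(rep(beta_each, m), module_resp)

  xz <- expr_matrix(surv_expr)[module_resp, , drop = FALSE]
  xz <- (xz - rowMeans(xz)) / sqrt(row_vars(xz))
  rates <- 0.1 * exp(drop(crossprod(xz, betas)))
  censor_rate <- censor_rate_for(0.3, rates)
  surv_tbl <- simulate_survival(surv_expr,
    betas = betas,
    baseline_rate = 0.1, censor_rate = censor_rate, seed = subseeds[4]
  )

  network_genes <- unique(unlist(truth$hubs))
  tf_table <- simulate_tf_table(
    module_genes = truth$hubs[[1]],
    decoy_pool = setdiff(truth$layout$genes, c(network_genes, truth$degs$gene)),
    n_masters = 1, master_coverage = 1,
    n_decoys = 20, targets_per_decoy = 5, seed = subseeds[5]
  )
  tf_table <- bind_rows(
    tf_table,
    tibble(tf = "TF_M2", target = truth$hubs[[2]])
  )

  list(
    cohort_a = cohort_a[c("expression", "phenotypes")],
    cohort_b = cohort_b[c("expression", "phenotypes")],
    truth = truth,
    tf_table = tf_table,
    survival = list(
      expression = surv_expr,
      table = surv_tbl,
      betas = betas,
      censor_rate = censor_rate
    )
  )
}
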