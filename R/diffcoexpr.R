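#' Thresholds for differential co-expression classification
#'
#' `tau` is the Pearson-correlation magnitude above which a pair counts as
#' co-expressed within a phenotype (0.7, the conventional "significant PCC"
#' level); `tau_low` bounds the magnitude that still counts as "no
#' correlation" in the other phenotype (the same tau unless a stricter value
#' is requested); `ratio_min` is the minimum relative-difference ratio
#' |(r_response - r_nonresponse) / r_response| for a pair to be called
#' differentially co-expressed; `epsilon` guards the zero denominator.
#'
#' @param tau correlation threshold in (0, 1).
#' @param ratio_min minimum differential ratio (> 0).
#' @param epsilon near-zero guard for the ratio denominator.
#' @param tau_low "no correlation" bound, defaults to `tau`.
#' @return a list of class `coex_thresholds`.
#' @export
coex_thresholds <- function(tau = 0.7, ratio_min = 1, epsilon = 1e-12,
                            tau_low = tau) {
  stopifnot(tau > 0, tau < 1, ratio_min > 0, epsilon > 0,
    tau_low > 0, tau_low <= tau)
  structure(
    list(tau = tau, ratio_min = ratio_min, epsilon = epsilon, tau_low = tau_low),
    class = "coex_thresholds"
  )
}

#' Pearson correlation with strict input validation
#'
#' Unlike [stats::cor()], a constant vector is an error (an undefined
#' correlation must never be silently reported as 0), and round-off is
#' clamped so the result is always inside \[-1, 1\].
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return the sample Pearson correlation coefficient.
#' @export
#' @examples
#' pearson_cor(c(1, 2, 3, 4), c(1, 3, 2, 4)) # 0.8
pearson_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop_pononet("pearson_cor needs two equal-length vectors of length >= 3",
      class = "pononet_validation_error"
    )
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop_pononet("Correlation undefined for a constant vector",
      class = "pononet_constant_gene"
    )
  }
  clamp(cor(x, y))
}

#' Differential co-expression ratio
#'
#' The relative difference |(r_response - r_nonresponse) / r_response|.
#' When the denominator is numerically zero the ratio is reported as `Inf`
#' (a pass-through sentinel) if the correlations actually differ, and 0
#' otherwise, so the downstream `>= ratio_min` comparison behaves sensibly
#' for OP/ON pairs whose response-state correlation vanishes.
#'
#' @param r_response,r_nonresponse correlation values in \[-1, 1\]
#'   (vectorized).
#' @param epsilon near-zero guard.
#' @return numeric vector of ratios (`Inf` = guarded pass).
#' @export
#' @examples
#' differential_ratio(0.8, 0) # 1
#' differential_ratio(0.5, -0.5) # 2
differential_ratio <- function(r_response, r_nonresponse, epsilon = 1e-12) {
  stopifnot(length(r_response) == length(r_nonresponse))
  num <- r_response - r_nonresponse
  out <- abs(num / r_response)
  zero_den <- which(!is.na(r_response) & abs(r_response) < epsilon)
  out[zero_den] <- ifelse(abs(num[zero_den]) > epsilon, Inf, 0)
  out
}

#' Classify gene pairs into differential co-expression categories
#'
#' A pair is assigned one of four classes when both conditions hold:
#' * the correlation pattern: `PO` (positive in response, none in
#'   nonresponse: r_response >= tau, |r_nonresponse| < tau_low), `NO`
#'   (negative in response, none in nonresponse), `OP` / `ON` (the
#'   mirror-image classes for the nonresponse state);
#' * the differential ratio |(r_response - r_nonresponse)/r_response| is at
#'   least `ratio_min` (the guarded `Inf` sentinel passes).
#'
#' Pairs failing either condition are `NONE`. Note the ratio criterion is
#' strictly stronger than the pattern: for example (0.9, 0.1) satisfies the
#' PO pattern but has ratio 8/9 < 1, hence `NONE`.
#'
#' @param r_response,r_nonresponse correlation vectors.
#' @param thresholds a [coex_thresholds()] object.
#' @return factor with levels PO, NO, OP, ON, NONE.
#' @export
#' @examples
#' classify_pairs(c(0.8, 0.9), c(0, 0.1), coex_thresholds())
classify_pairs <- function(r_response, r_nonresponse,
                           thresholds = coex_thresholds()) {
  stopifnot(inherits(thresholds, "coex_thresholds"))
  tau <- thresholds$tau
  tau_low <- thresholds$tau_low
  ratio <- differential_ratio(r_response, r_nonresponse, thresholds$epsilon)
  none_in_non <- abs(r_nonresponse) < tau_low
  none_in_resp <- abs(r_response) < tau_low
  cls <- rep("NONE", length(r_response))
  cls[r_response >= tau & none_in_non] <- "PO"
  cls[r_response <= -tau & none_in_non] <- "NO"
  cls[none_in_resp & r_nonresponse >= tau] <- "OP"
  cls[none_in_resp & r_nonresponse <= -tau] <- "ON"
  cls[!(ratio >= thresholds$ratio_min)] <- "NONE"
  cls[is.na(r_response) | is.na(r_nonresponse)] <- "NONE"
  factor(cls, levels = c("PO", "NO", "OP", "ON", "NONE"))
}

#' Per-condition Pearson correlations over a gene universe
#'
#' Computes, for every unordered gene pair in `gene_universe`, the Pearson
#' correlation among response-labelled samples and among
#' nonresponse-labelled samples. Several cohorts can be pooled:
#' * `"per_stratum_z"` (default) z-scores each gene within each
#'   dataset-by-condition stratum before pooling. This removes both
#'   per-dataset batch offsets and the condition-composition artifact:
#'   when cohorts differ in their response fraction, z-scoring across a
#'   whole dataset leaves every strong DEG with dataset-specific
#'   condition means, which masquerade as co-expression among
#'   same-direction DEGs once samples are pooled.
#' * `"per_dataset_z"` z-scores each gene within each whole dataset
#'   (protects against batch offsets only).
#' * `"concat"` pools raw values.
#'
#' For a single dataset all modes coincide: the correlation within a
#' condition is invariant to any per-dataset or per-condition affine
#' rescaling.
#'
#' @param datasets an expression dataset or list of them.
#' @param phenotypes a phenotype tibble or list matching `datasets`.
#' @param gene_universe character vector of genes (subset of every dataset).
#' @param combine pooling mode.
#' @return tibble with columns `gene_a`, `gene_b` (a < b), `r_response`,
#'   `r_nonresponse`; pairs involving a gene that is constant within a
#'   condition carry `NA` there (and are logged), never a silent 0.
#' @export
condition_correlations <- function(datasets, phenotypes, gene_universe,
                                   combine = c("per_stratum_z", "per_dataset_z",
                                     "concat")) {
  combine <- match.arg(combine)
  if (inherits(datasets, "pononet_expr")) datasets <- list(datasets)
  if (is.data.frame(phenotypes)) phenotypes <- list(phenotypes)
  stopifnot(length(datasets) == length(phenotypes))
  gene_universe <- sort(unique(gene_universe))
  if (length(gene_universe) < 2) {
    stop_pononet("Gene universe needs at least two genes",
      class = "pononet_validation_error"
    )
  }
  mats <- vector("list", length(datasets))
  conds <- vector("list", length(datasets))
  for (i in seq_along(datasets)) {
    m <- expr_matrix(datasets[[i]])
    missing <- setdiff(gene_universe, rownames(m))
    if (length(missing) > 0) {
      stop_pononet(
        paste0("Genes absent from dataset ", dataset_id(datasets[[i]]), ": ",
          paste(missing, collapse = ", ")),
        class = "pononet_validation_error"
      )
    }
    ph <- phenotypes[[i]]
    keep <- intersect(colnames(m), ph$sample_id)
    m <- m[gene_universe, keep, drop = FALSE]
    cond <- ph$condition[match(keep, ph$sample_id)]
    if (combine == "per_dataset_z") {
      mu <- rowMeans(m)
      s <- sqrt(row_vars(m))
      s[s == 0] <- 1 # constant genes: centred only, flagged downstream
      m <- (m - mu) / s
    } else if (combine == "per_stratum_z") {
      for (lev in phenotype_levels) {
        sel <- which(cond == lev)
        if (length(sel) < 2) next
        sub <- m[, sel, drop = FALSE]
        mu <- rowMeans(sub)
        s <- sqrt(row_vars(sub))
        s[s == 0] <- 1
        m[, sel] <- (sub - mu) / s
      }
    }
    mats[[i]] <- m
    conds[[i]] <- cond
  }
  m <- do.call(cbind, mats)
  cond <- do.call(c, lapply(conds, as.character))
  out <- list()
  for (lev in phenotype_levels) {
    sub <- m[, cond == lev, drop = FALSE]
    if (ncol(sub) < 4) {
      stop_pononet(
        sprintf("Condition '%s' has %d samples; at least 4 required",
          lev, ncol(sub)),
        class = "pononet_validation_error"
      )
    }
    constant <- sqrt(row_vars(sub)) == 0
    if (any(constant)) {
      inform(sprintf(
        "%d gene(s) constant in condition '%s'; their pairs are recorded as NA",
        sum(constant), lev
      ))
    }
    cc <- suppressWarnings(cor(t(sub)))
    cc[constant, ] <- NA_real_
    cc[, constant] <- NA_real_
    out[[lev]] <- clamp(cc)
  }
  idx <- which(upper.tri(out$response), arr.ind = TRUE)
  tibble(
    gene_a = gene_universe[idx[, "row"]],
    gene_b = gene_universe[idx[, "col"]],
    r_response = out$response[idx],
    r_nonresponse = out$nonresponse[idx]
  )
}

#' Filter and classify a correlation table into differential edges
#'
#' Applies [classify_pairs()] to every pair and keeps those with a class
#' other than `NONE`. Per-class counts are reported as a message.
#'
#' @param cor_tbl output of [condition_correlations()].
#' @param thresholds a [coex_thresholds()].
#' @return tibble with columns `gene_a`, `gene_b`, `r_response`,
#'   `r_nonresponse`, `ratio`, `class`.
#' @export
build_differential_edges <- function(cor_tbl, thresholds = coex_thresholds()) {
  if (nrow(cor_tbl) == 0) {
    return(tibble(
      gene_a = character(), gene_b = character(),
      r_response = numeric(), r_nonresponse = numeric(),
      ratio = numeric(),
      class = factor(character(), levels = c("PO", "NO", "OP", "ON", "NONE"))
    ))
  }
  n_na <- sum(is.na(cor_tbl$r_response) | is.na(cor_tbl$r_nonresponse))
  if (n_na > 0) {
    inform(sprintf("%d pair(s) with undefined correlation treated as NONE", n_na))
  }
  out <- cor_tbl |>
    mutate(
      ratio = differential_ratio(.data$r_response, .data$r_nonresponse,
        thresholds$epsilon),
      class = classify_pairs(.data$r_response, .data$r_nonresponse, thresholds)
    ) |>
    filter(.data$class != "NONE") |>
    mutate(class = droplevels(.data$class, exclude = NULL))
  counts <- table(factor(out$class, levels = c("PO", "NO", "OP", "ON")))
  inform(paste0(
    "Differential edges: ",
    paste(sprintf("%s=%d", names(counts), as.integer(counts)), collapse = ", ")
  ))
  out$class <- factor(as.character(out$class), levels = c("PO", "NO", "OP", "ON"))
  out
}
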