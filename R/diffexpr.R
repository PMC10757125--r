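#' Two-group differential expression with an empirical-Bayes moderated t
#'
#' For every gene the difference of condition means (log2 fold change,
#' response minus nonresponse) is tested with a pooled-variance two-sample
#' t-statistic. With `moderation = TRUE` the gene-wise variances are shrunk
#' towards a common prior: the marginal distribution of the sample variances
#' is fit by method of moments on the log scale (Smyth-style), yielding a
#' prior variance `s0^2` with `d0` prior degrees of freedom, and each gene
#' uses the posterior variance `(d0*s0^2 + d*s^2)/(d0 + d)` with `d0 + d`
#' degrees of freedom. `d0 = Inf` (fully pooled variance) can arise when the
#' gene-wise variances are over-dispersed less than chi-square sampling alone
#' would imply.
#'
#' @param expression an expression dataset (log2 scale).
#' @param phenotypes phenotype tibble labelling the dataset's samples.
#' @param moderation logical; `FALSE` gives the ordinary pooled t-test.
#' @param var_epsilon variance floor used when a gene has zero variance in
#'   both groups but a nonzero mean difference and moderation is off.
#' @return tibble with one row per gene: `gene`, `mean_response`,
#'   `mean_nonresponse`, `log2_fc`, `t`, `df`, `p_value`, `adj_p`. The
#'   estimated moderation parameters are attached as the `moderation`
#'   attribute (`d0`, `s0_sq`).
#' @export
diff_expression <- function(expression, phenotypes, moderation = TRUE,
                            var_epsilon = 1e-8) {
  m <- expr_matrix(expression)
  keep <- intersect(colnames(m), phenotypes$sample_id)
  m <- m[, keep, drop = FALSE]
  cond <- phenotypes$condition[match(keep, phenotypes$sample_id)]
  n1 <- sum(cond == "response")
  n2 <- sum(cond == "nonresponse")
  if (n1 < 2 || n2 < 2) {
    stop_pononet(
      sprintf("Each condition needs >= 2 samples (got %d response, %d nonresponse)",
        n1, n2),
      class = "pononet_validation_error"
    )
  }
  x1 <- m[, cond == "response", drop = FALSE]
  x2 <- m[, cond == "nonresponse", drop = FALSE]
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  fc <- m1 - m2
  d <- n1 + n2 - 2
  s2 <- ((n1 - 1) * row_vars(x1) + (n2 - 1) * row_vars(x2)) / d

  if (moderation) {
    fit <- fit_variance_prior(s2, d)
    d0 <- fit$d0
    s0_sq <- fit$s0_sq
    if (is.infinite(d0)) {
      s2_post <- rep(s0_sq, length(s2))
      df_post <- rep(Inf, length(s2))
    } else {
      s2_post <- (d0 * s0_sq + d * s2) / (d0 + d)
      df_post <- rep(d0 + d, length(s2))
    }
  } else {
    d0 <- 0
    s0_sq <- NA_real_
    s2_post <- s2
    df_post <- rep(d, length(s2))
    degenerate <- s2_post == 0 & fc != 0
    if (any(degenerate)) {
      inform(sprintf(
        "%d gene(s) with zero pooled variance but nonzero difference; variance floored at %g",
        sum(degenerate), var_epsilon
      ))
      s2_post[degenerate] <- var_epsilon
    }
  }

  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_stat <- ifelse(fc == 0 & se == 0, 0, fc / se)
  t_stat[se == 0 & fc != 0] <- sign(fc[se == 0 & fc != 0]) * Inf
  p <- 2 * pt(abs(t_stat), df = df_post, lower.tail = FALSE)
  p[t_stat == 0] <- 1

  out <- tibble(
    gene = rownames(m),
    mean_response = unname(m1),
    mean_nonresponse = unname(m2),
    log2_fc = unname(fc),
    t = unname(t_stat),
    df = unname(df_post),
    p_value = unname(p),
    adj_p = unname(adjust_bh(p))
  )
  attr(out, "moderation") <- list(
    enabled = moderation, d0 = d0, s0_sq = s0_sq,
    residual_df = d, n_response = n1, n_nonresponse = n2
  )
  attr(out, "dataset_id") <- dataset_id(expression)
  out
}

#' Method-of-moments fit of the variance prior
#'
#' Fits a scaled inverse-chi-square prior to gene-wise sample variances
#' `s2` with `d` residual degrees of freedom each, by matching the first
#' two moments of `log(s2)` (corrected for chi-square sampling noise).
#'
#' @param s2 gene-wise pooled sample variances.
#' @param d residual degrees of freedom (scalar).
#' @return list with `d0` (prior df, possibly `Inf`) and `s0_sq`.
#' @export
fit_variance_prior <- function(s2, d) {
  stopifnot(d >= 1, length(s2) >= 2)
  med <- median(s2)
  if (med == 0) {
    stop_pononet("More than half the gene variances are exactly zero",
      class = "pononet_validation_error"
    )
  }
  x <- pmax(s2, 1e-5 * med) # offset exact zeros away from log(0)
  e <- log(x) - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(d / 2)
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- mean(x)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Inverse of the trigamma function (Newton iteration)
#' @param x positive value.
#' @return y with `trigamma(y) = x`.
#' @keywords internal
trigamma_inverse <- function(x) {
  stopifnot(length(x) == 1, is.finite(x), x > 0)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate (a
#' validating wrapper around [stats::p.adjust()]).
#'
#' @param p p-values in \[0, 1\].
#' @return adjusted p-values in the original order.
#' @export
#' @examples
#' adjust_bh(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
adjust_bh <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop_pononet("p-values must lie in [0, 1]", class = "pononet_validation_error")
  }
  p.adjust(p, method = "BH")
}

#' Call differentially expressed genes
#'
#' A gene is up-regulated when `adj_p < adj_p_max` and its fold change is at
#' least `fc_cutoff` (log2 fold change >= log2(fc_cutoff)); down-regulation
#' uses either the reciprocal cutoff (`down_rule = "reciprocal"`, FC <=
#' 1/fc_cutoff, the symmetric choice and the default) or a literal FC < 0.5
#' rule (`down_rule = "strict_half"`), both of which appear in practice.
#'
#' @param records tibble from [diff_expression()].
#' @param adj_p_max adjusted-p threshold.
#' @param fc_cutoff fold-change cutoff on the natural scale.
#' @param down_rule down-regulation rule (see Details).
#' @return an object of class `deg_set`: list with `dataset_id`, `up`,
#'   `down` (character vectors, disjoint) and the thresholds used.
#' @export
call_degs <- function(records, adj_p_max = 0.05, fc_cutoff = 1.5,
                      down_rule = c("reciprocal", "strict_half")) {
  down_rule <- match.arg(down_rule)
  sig <- records$adj_p < adj_p_max
  up <- sig & records$log2_fc >= log2(fc_cutoff)
  down <- if (down_rule == "reciprocal") {
    sig & records$log2_fc <= -log2(fc_cutoff)
  } else {
    sig & records$log2_fc < log2(0.5)
  }
  structure(
    list(
      dataset_id = attr(records, "dataset_id") %||% "dataset",
      up = records$gene[up],
      down = records$gene[down],
      thresholds = list(
        adj_p_max = adj_p_max, fc_cutoff = fc_cutoff, down_rule = down_rule
      )
    ),
    class = "deg_set"
  )
}

#' @export
print.deg_set <- function(x, ...) {
  cat(sprintf(
    "<deg_set %s> %d up, %d down (adj p < %g, FC cutoff %g, down rule %s)\n",
    x$dataset_id, length(x$up), length(x$down),
    x$thresholds$adj_p_max, x$thresholds$fc_cutoff, x$thresholds$down_rule
  ))
  invisible(x)
}

#' @export
tidy.deg_set <- function(x, ...) {
  tibble(
    gene = c(x$up, x$down),
    direction = rep(c("up", "down"), c(length(x$up), length(x$down)))
  )
}

#' Intersect DEG sets across datasets
#'
#' @param set_a,set_b `deg_set` objects.
#' @param mode `"any_direction"` intersects the unions of up- and
#'   down-regulated genes; `"same_direction"` additionally requires the
#'   direction to agree.
#' @return sorted character vector of mutual DEGs.
#' @export
intersect_degs <- function(set_a, set_b, mode = c("any_direction", "same_direction")) {
  mode <- match.arg(mode)
  if (mode == "any_direction") {
    out <- intersect(c(set_a$up, set_a$down), c(set_b$up, set_b$down))
  } else {
    out <- c(intersect(set_a$up, set_b$up), intersect(set_a$down, set_b$down))
  }
  sort(unique(out))
}
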