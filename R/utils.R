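#' @keywords internal
#' @noRd
stop_pononet <- function(message, class, ...) {
  abort(message, class = c(class, "pononet_error"), ...)
}

#' Z-score the columns of a matrix
#'
#' @param x numeric matrix (samples in rows).
#' @param center,scale optional pre-computed statistics (training values).
#' @return matrix with attributes `center` and `scale`.
#' @keywords internal
#' @noRd
zscore_cols <- function(x, center = NULL, scale = NULL) {
  center <- center %||% colMeans(x)
  scale <- scale %||% apply(x, 2, sd)
  if (any(scale == 0)) {
    stop_pononet(
      paste0(
        "Constant covariate(s): ",
        paste(colnames(x)[scale == 0], collapse = ", ")
      ),
      class = "pononet_constant_covariate"
    )
  }
  out <- sweep(sweep(x, 2, center, "-"), 2, scale, "/")
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  out
}

#' Row variances of a matrix
#' @keywords internal
#' @noRd
row_vars <- function(x) {
  n <- ncol(x)
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}

#' Clamp values into an interval
#' @keywords internal
#' @noRd
clamp <- function(x, lo = -1, hi = 1) pmin(pmax(x, lo), hi)

#' Canonical unordered pair orientation (gene_a < gene_b)
#' @keywords internal
#' @noRd
orient_pairs <- function(gene_a, gene_b) {
  swap <- gene_a > gene_b
  tmp <- gene_a[swap]
  gene_a[swap] <- gene_b[swap]
  gene_b[swap] <- tmp
  list(gene_a = gene_a, gene_b = gene_b)
}
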