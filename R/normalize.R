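#' Median-center each gene across samples
#'
#' Subtracts the per-gene median so every row has median 0, the
#' normalization expected by the signature and receptor-activity scores.
#'
#' @param matrix an [expression_matrix()] with >= 1 sample.
#' @return the centered matrix, same shape and identifiers.
#' @export
median_center <- function(matrix) {
  m <- as_expr(matrix)
  if (ncol(m) < 1) stop("at least one sample required")
  med <- apply(unclass(m), 1, stats::median, na.rm = TRUE)
  out <- sweep(unclass(m), 1, med)
  expression_matrix(out, rownames(m), colnames(m),
                    platform = attr(m, "platform"))
}

#' Standardize each sample to mean 0, sd 1
#'
#' Per-sample N(0,1) normalization of the expression columns, applied
#' after variable-gene selection and before consensus factorization.
#' Standard deviations use the n-1 denominator.
#'
#' @param matrix an [expression_matrix()] with >= 2 genes.
#' @return the standardized matrix.
#' @export
zscore_samples <- function(matrix) {
  m <- as_expr(matrix)
  if (nrow(m) < 2) stop("at least two genes required")
  sds <- apply(unclass(m), 2, stats::sd)
  zero <- which(sds == 0 | !is.finite(sds))
  if (length(zero)) {
    stop("zero-variance sample column: ",
         paste(colnames(m)[zero], collapse = ", "))
  }
  out <- scale(unclass(m))
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  expression_matrix(out, rownames(m), colnames(m),
                    platform = attr(m, "platform"))
}
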