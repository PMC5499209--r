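#' Nearest template prediction
#'
#' Classifies each sample by its correlation distance to binary class
#' templates over the union of signature genes: d = (1 - Pearson(x, t)) / 2
#' where t marks the class's genes within the union. The nominal p-value of
#' a sample is the fraction of random template systems -- built by
#' redrawing the union of genes from all measured genes and rebuilding one
#' template per class with the observed sizes -- whose minimum distance is
#' at least as small as the sample's best observed distance; this null
#' replicates the argmin selection, so p-values are calibrated on noise.
#' Per-sample q-values come from [bh_fdr()] across all samples of the run,
#' and samples at or above `threshold` are left [UNASSIGNED]. Expression is
#' median-centered per gene internally.
#'
#' @param matrix an [expression_matrix()].
#' @param signatures a [gene_signature_set()]; at least half of every
#'   class's genes must be present in the matrix.
#' @param n_resamples random templates per class (default 1000).
#' @param threshold FDR below which a sample is assigned (default 0.2).
#' @param seed integer seed.
#' @return an `ntp_result`: `assignments` data.frame (sample_id,
#'   predicted_class, distance, p_value, fdr), `distance_matrix`
#'   (sample x class), `n_resamples`, `threshold`.
#' @export
ntp_classify <- function(matrix, signatures, n_resamples = 1000,
                         threshold = 0.2, seed = NULL) {
  m <- median_center(as_expr(matrix))
  stopifnot(inherits(signatures, "gene_signature_set"))
  present <- lapply(signatures, intersect, y = rownames(m))
  frac <- vapply(present, length, 0L) / vapply(signatures, length, 0L)
  if (any(frac < 0.5)) {
    bad <- names(signatures)[frac < 0.5]
    stop("less than 50% of signature genes measured for class ",
         paste(sprintf("%s (%.0f%%)", bad, 100 * frac[bad]), collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  classes <- names(signatures)
  union_genes <- unique(unlist(present))
  x <- unclass(m)
  templates <- vapply(present, function(g)
    as.numeric(union_genes %in% g), numeric(length(union_genes)))
  cors <- suppressWarnings(stats::cor(x[union_genes, , drop = FALSE],
                                      templates))
  cors[is.na(cors)] <- 0   # constant sample over the union: no information
  dist_mat <- (1 - cors) / 2
  dimnames(dist_mat) <- list(colnames(m), classes)

  best <- apply(dist_mat, 1, which.min)
  tied <- apply(dist_mat, 1, function(d) sum(d == min(d)) > 1)
  if (any(tied)) {
    message(sum(tied), " sample(s) with an exact distance tie left ",
            "unassigned")
  }
  predicted <- classes[best]

  # null replicates the whole decision rule: each resample redraws the
  # union of genes, rebuilds one template per class (same sizes) and takes
  # the minimum distance, so nominal p-values are calibrated under noise
  n_genes <- nrow(x)
  n_union <- length(union_genes)
  sizes <- vapply(present, length, 0L)
  bounds <- c(0L, cumsum(sizes))   # disjoint blocks partition the draw
  exceed <- integer(ncol(m))
  d_best <- dist_mat[cbind(seq_along(best), best)]
  for (r in seq_len(n_resamples)) {
    draw <- sample.int(n_genes, n_union)
    xs <- x[draw, , drop = FALSE]
    sum_s <- colSums(xs)
    sum_sq <- colSums(xs^2)
    var_part <- pmax(sum_sq - sum_s^2 / n_union, 0)
    null_min <- rep(Inf, ncol(m))
    for (k in seq_along(sizes)) {
      m_k <- sizes[k]
      sum_o <- colSums(xs[(bounds[k] + 1):bounds[k + 1], , drop = FALSE])
      num <- sum_o - (m_k / n_union) * sum_s
      den <- sqrt(var_part * (m_k * (1 - m_k / n_union)))
      cors <- ifelse(den > 0, num / den, 0)
      null_min <- pmin(null_min, (1 - cors) / 2)
    }
    exceed <- exceed + (null_min <= d_best)
  }
  p <- (1 + exceed) / (n_resamples + 1)
  p[tied] <- 1
  fdr <- bh_fdr(p)
  predicted[fdr >= threshold | tied] <- UNASSIGNED
  assignments <- data.frame(sample_id = colnames(m),
                            predicted_class = predicted,
                            distance = dist_mat[cbind(seq_along(best), best)],
                            p_value = p, fdr = fdr,
                            stringsAsFactors = FALSE)
  structure(list(assignments = assignments, distance_matrix = dist_mat,
                 n_resamples = n_resamples, threshold = threshold),
            class = "ntp_result")
}

#' @export
print.ntp_result <- function(x, ...) {
  tab <- table(factor(x$assignments$predicted_class,
                      c(colnames(x$distance_matrix), UNASSIGNED)))
  cat("NTP classification of", nrow(x$assignments), "samples",
      sprintf("(FDR < %g):\n", x$threshold))
  print(tab)
  invisible(x)
}

#' Hierarchical similarity tree of classes from NTP distances
#'
#' Clusters classes by the correlation distance between their per-sample
#' NTP distance profiles (average linkage), summarizing which subtypes
#' behave as families.
#'
#' @param ntp_result an `ntp_result` from [ntp_classify()].
#' @return an object of class `hclust` with one leaf per class.
#' @export
class_similarity_tree <- function(ntp_result) {
  stopifnot(inherits(ntp_result, "ntp_result"))
  dm <- ntp_result$distance_matrix
  if (ncol(dm) < 3) stop("need at least 3 classes to build a tree")
  d <- stats::as.dist(1 - stats::cor(dm))
  stats::hclust(d, method = "average")
}
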