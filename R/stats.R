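#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return q-values in the original order.
#' @export
bh_fdr <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Cohen's kappa between two labelings
#'
#' Chance-corrected agreement kappa = (p_o - p_e) / (1 - p_e), with expected
#' agreement p_e from the product of the marginal class frequencies. Pairs
#' where either labeling is [UNASSIGNED] are dropped by default, so kappa
#' measures concordance among confidently classified samples; set
#' `exclude_unassigned = FALSE` to score UNASSIGNED as an ordinary class.
#'
#' @param labels_a,labels_b equal-length label vectors over a shared class
#'   alphabet.
#' @param exclude_unassigned drop pairs with UNASSIGNED on either side.
#' @return kappa, a single number in [-1, 1].
#' @export
cohen_kappa <- function(labels_a, labels_b, exclude_unassigned = TRUE) {
  a <- as.character(labels_a)
  b <- as.character(labels_b)
  if (length(a) != length(b)) stop("labelings must have equal length")
  if (exclude_unassigned) {
    keep <- a != UNASSIGNED & b != UNASSIGNED
    a <- a[keep]
    b <- b[keep]
  }
  if (!length(a)) stop("no label pairs left to compare")
  classes <- sort(unique(c(a, b)))
  tab <- table(factor(a, classes), factor(b, classes)) / length(a)
  p_o <- sum(diag(tab))
  p_e <- sum(rowSums(tab) * colSums(tab))
  if (isTRUE(all.equal(p_e, 1)) || p_e >= 1) {
    stop("expected agreement is 1; kappa undefined")
  }
  (p_o - p_e) / (1 - p_e)
}

#' Compare matched vs unmatched cross-cohort sample correlations
#'
#' For two expression matrices sharing a gene space (e.g. original tumours
#' and their xenograft derivatives), computes Pearson correlations over
#' high-variance genes for every cross-cohort sample pair and contrasts the
#' matched pairs against all unmatched pairs with a Wilcoxon rank-sum test.
#'
#' @param matrix_a,matrix_b expression matrices sharing gene identifiers.
#' @param pairing two-column data.frame (or named character vector) mapping
#'   samples of `matrix_a` to their matched samples in `matrix_b`.
#' @param sd_threshold genes with across-sample sd in `matrix_a` above this
#'   value enter the correlations (default 0.8).
#' @return list with `matched`, `unmatched` correlation vectors, the
#'   rank-sum `statistic` and its `p_value`, and `genes_used`.
#' @export
matched_correlation_test <- function(matrix_a, matrix_b, pairing,
                                     sd_threshold = 0.8) {
  a <- as_expr(matrix_a)
  b <- as_expr(matrix_b)
  if (is.data.frame(pairing)) {
    pairing <- stats::setNames(as.character(pairing[[2]]),
                               as.character(pairing[[1]]))
  }
  if (!all(names(pairing) %in% colnames(a)) ||
      !all(pairing %in% colnames(b))) {
    stop("pairing refers to unknown sample identifiers")
  }
  shared <- intersect(rownames(a), rownames(b))
  sds <- apply(unclass(a)[shared, , drop = FALSE], 1, stats::sd)
  genes <- shared[sds > sd_threshold]
  if (length(genes) < 3) {
    stop("fewer than 3 genes pass sd threshold ", sd_threshold)
  }
  cors <- stats::cor(unclass(a)[genes, , drop = FALSE],
                     unclass(b)[genes, , drop = FALSE])
  idx <- cbind(match(names(pairing), colnames(a)),
               match(pairing, colnames(b)))
  matched <- cors[idx]
  mask <- matrix(TRUE, nrow(cors), ncol(cors))
  mask[idx] <- FALSE
  unmatched <- cors[mask]
  wt <- stats::wilcox.test(matched, unmatched)
  list(matched = matched, unmatched = unmatched,
       statistic = unname(wt$statistic), p_value = wt$p.value,
       genes_used = genes)
}
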