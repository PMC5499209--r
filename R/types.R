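#' Reserved label for samples that no classifier could call
#'
#' Samples whose classification does not reach significance (NTP) or whose
#' vote proportions tie (k-TSP) receive this label instead of a class.
#' @export
UNASSIGNED <- "UNASSIGNED"

#' Construct a validated expression matrix
#'
#' The universal currency of the pipeline: a numeric genes x samples matrix
#' of log2-scale expression with unique gene and sample identifiers.
#' Identifiers are opaque, case-sensitive strings; no symbol-alias
#' resolution is performed.
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param gene_ids,sample_ids character vectors of unique identifiers;
#'   default to the dimnames of `values`.
#' @param platform optional platform label stored as an attribute.
#' @return a numeric matrix of class `expression_matrix` with rownames =
#'   gene ids and colnames = sample ids.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              platform = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("gene and sample identifiers are required")
  }
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values)) {
    stop("dimensions of values do not match identifier lists")
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene identifiers: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (nrow(values) > 0) {
    all_na <- rowSums(is.finite(values)) == 0
    if (any(all_na)) {
      stop("rows without any finite value: ",
           paste(gene_ids[all_na], collapse = ", "))
    }
  }
  dimnames(values) <- list(as.character(gene_ids), as.character(sample_ids))
  if (!is.null(platform)) attr(values, "platform") <- as.character(platform)
  class(values) <- c("expression_matrix", class(values))
  values
}

# Accept plain matrices wherever an expression_matrix is expected.
as_expr <- function(m) {
  if (inherits(m, "expression_matrix")) return(m)
  expression_matrix(m)
}

#' Construct a gene signature set
#'
#' Disjoint per-class marker gene lists, the artifact consumed by
#' nearest-template prediction. Class order is preserved.
#'
#' @param genes_by_class named list, one non-empty character vector of gene
#'   ids per class; lists must be mutually disjoint.
#' @return an object of class `gene_signature_set`.
#' @export
gene_signature_set <- function(genes_by_class) {
  if (is.null(names(genes_by_class)) || any(names(genes_by_class) == "")) {
    stop("every class must be named")
  }
  if (anyDuplicated(names(genes_by_class))) stop("duplicate class labels")
  genes_by_class <- lapply(genes_by_class, as.character)
  empty <- vapply(genes_by_class, length, 0L) == 0
  if (any(empty)) {
    stop("empty gene list for class: ",
         paste(names(genes_by_class)[empty], collapse = ", "))
  }
  for (cl in names(genes_by_class)) {
    if (anyDuplicated(genes_by_class[[cl]])) {
      dup <- unique(genes_by_class[[cl]][duplicated(genes_by_class[[cl]])])
      stop("gene repeated within class ", cl, ": ", paste(dup, collapse = ", "))
    }
  }
  all_genes <- unlist(genes_by_class, use.names = FALSE)
  if (anyDuplicated(all_genes)) {
    dup <- unique(all_genes[duplicated(all_genes)])
    stop("gene assigned to more than one class: ",
         paste(dup, collapse = ", "))
  }
  structure(genes_by_class, class = "gene_signature_set")
}

#' @export
print.gene_signature_set <- function(x, ...) {
  cat("Gene signature set:", length(x), "classes,",
      length(unlist(x)), "genes\n")
  for (cl in names(x)) cat("  ", cl, ": ", length(x[[cl]]), " genes\n", sep = "")
  invisible(x)
}

#' Construct a per-sample score table
#'
#' @param sample_ids character vector of unique sample identifiers.
#' @param scores finite numeric vector, one value per sample.
#' @param score_name name of the score.
#' @return a data.frame of class `score_table` with columns `sample_id` and
#'   `score`; the score name is kept in attribute `score_name`.
#' @export
score_table <- function(sample_ids, scores, score_name = "score") {
  if (length(sample_ids) != length(scores)) {
    stop("one score per sample required")
  }
  if (anyDuplicated(sample_ids)) stop("duplicate sample identifiers")
  if (any(!is.finite(scores))) stop("scores must be finite")
  out <- data.frame(sample_id = as.character(sample_ids),
                    score = as.numeric(scores),
                    stringsAsFactors = FALSE)
  attr(out, "score_name") <- score_name
  class(out) <- c("score_table", class(out))
  out
}
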