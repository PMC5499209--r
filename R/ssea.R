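#' Per-sample signature score
#'
#' Score_j = mean expression of the up-module genes minus mean expression
#' of the down-module genes in sample j, computed on per-gene
#' median-centered values (centering is applied internally over the input
#' cohort). An empty down module gives the plain up-module mean.
#'
#' @param matrix an [expression_matrix()].
#' @param up_genes genes positively associated with the phenotype.
#' @param down_genes genes anti-correlated with the phenotype (may be
#'   empty).
#' @param score_name name recorded in the output (default "signature").
#' @return a [score_table()].
#' @export
signature_score <- function(matrix, up_genes, down_genes = character(),
                            score_name = "signature") {
  m <- median_center(as_expr(matrix))
  up <- intersect(up_genes, rownames(m))
  if (!length(up)) stop("no up-module gene present in the matrix")
  down <- intersect(down_genes, rownames(m))
  s <- colMeans(unclass(m)[up, , drop = FALSE])
  if (length(down)) s <- s - colMeans(unclass(m)[down, , drop = FALSE])
  score_table(colnames(m), s, score_name)
}

#' Per-sample receptor activity score
#'
#' Score_j = (Receptor_j + mean(Ligands_j)) / 2 on per-gene median-centered
#' values: the receptor's own expression averaged with the mean expression
#' of its ligands, weighting the receptor as much as the ligand block.
#'
#' @param matrix an [expression_matrix()].
#' @param receptor_gene the receptor gene id (must be measured).
#' @param ligand_genes ligand gene ids (>= 1 must be measured).
#' @return a [score_table()] named after the receptor.
#' @export
receptor_activity_score <- function(matrix, receptor_gene, ligand_genes) {
  m <- median_center(as_expr(matrix))
  if (!receptor_gene %in% rownames(m)) {
    stop("receptor not measured: ", receptor_gene)
  }
  ligands <- intersect(ligand_genes, rownames(m))
  if (!length(ligands)) stop("no ligand of ", receptor_gene, " is measured")
  s <- (unclass(m)[receptor_gene, ] +
          colMeans(unclass(m)[ligands, , drop = FALSE])) / 2
  score_table(colnames(m), s, paste0(receptor_gene, "_activity"))
}

#' Stromal infiltration scores
#'
#' Mean per-sample expression (median-centered per gene) of
#' cancer-associated fibroblast, endothelial and leukocyte signatures, the
#' three components used to estimate stromal content.
#'
#' @param matrix an [expression_matrix()].
#' @param caf_genes,endo_genes,leuko_genes the three signatures; each must
#'   overlap the matrix.
#' @return named list of three [score_table()]s: `caf`, `endothelial`,
#'   `leukocyte`.
#' @export
stromal_scores <- function(matrix, caf_genes, endo_genes, leuko_genes) {
  m <- median_center(as_expr(matrix))
  one <- function(genes, name) {
    g <- intersect(genes, rownames(m))
    if (!length(g)) stop("no ", name, " signature gene present")
    score_table(colnames(m), colMeans(unclass(m)[g, , drop = FALSE]), name)
  }
  list(caf = one(caf_genes, "caf"),
       endothelial = one(endo_genes, "endothelial"),
       leukocyte = one(leuko_genes, "leukocyte"))
}

running_es <- function(hit, weights, p) {
  n <- length(hit)
  w <- abs(weights)^p
  w[!hit] <- 0
  nr <- sum(w)
  nh <- sum(hit)
  step <- ifelse(hit, w / nr, -1 / (n - nh))
  running <- cumsum(step)
  running[which.max(abs(running))]
}

#' Preranked enrichment of item sets along a ranking
#'
#' The weighted Kolmogorov-Smirnov statistic of gene set enrichment
#' analysis: along the ranking (decreasing value), a set member increments
#' the running sum proportionally to |value|^p (normalized), a non-member
#' decrements it by 1/(N - N_hits); the enrichment score ES is the maximum
#' deviation. Significance comes from permuting set membership; NES is ES
#' divided by the mean |null ES| of matching sign.
#'
#' @param ranked_ids unique item identifiers.
#' @param ranking_values the ranking metric (items are sorted by decreasing
#'   value internally).
#' @param item_sets named list of item id vectors; sets smaller than 2 or
#'   larger than N - 2 are skipped with a warning.
#' @param weight_p weighting exponent (default 1; 0 gives the classical
#'   unweighted statistic).
#' @param n_permutations membership permutations (default 1000).
#' @param seed integer seed.
#' @param fdr_method `"nes_pool"` (standard pooled-null NES procedure) or
#'   `"bh"` (Benjamini-Hochberg on the nominal p-values).
#' @return data.frame with one row per scored set: set_name, size, es, nes,
#'   nominal_p, fdr_q, n_permutations.
#' @export
preranked_enrichment <- function(ranked_ids, ranking_values, item_sets,
                                 weight_p = 1, n_permutations = 1000,
                                 seed = NULL, fdr_method = c("nes_pool",
                                                             "bh")) {
  fdr_method <- match.arg(fdr_method)
  if (anyDuplicated(ranked_ids)) stop("ranked ids must be unique")
  if (length(ranked_ids) != length(ranking_values)) {
    stop("one ranking value per item required")
  }
  unknown <- setdiff(unlist(item_sets), ranked_ids)
  if (length(unknown)) {
    stop("set items absent from the ranking: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  ord <- order(ranking_values, decreasing = TRUE)
  ids <- ranked_ids[ord]
  vals <- ranking_values[ord]
  n <- length(ids)
  keep <- vapply(item_sets, function(s)
    length(s) >= 2 && length(s) <= n - 2, TRUE)
  if (any(!keep)) {
    warning("skipping degenerate set(s): ",
            paste(names(item_sets)[!keep], collapse = ", "))
  }
  item_sets <- item_sets[keep]
  rows <- lapply(names(item_sets), function(nm) {
    size <- length(item_sets[[nm]])
    hit <- ids %in% item_sets[[nm]]
    es <- running_es(hit, vals, weight_p)
    null_es <- vapply(seq_len(n_permutations), function(b) {
      h <- logical(n)
      h[sample.int(n, size)] <- TRUE
      running_es(h, vals, weight_p)
    }, 0)
    same <- null_es[sign(null_es) == sign(es)]
    if (length(same)) {
      nominal_p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
      nes <- es / mean(abs(same))
      null_nes <- null_es
      pos <- null_es > 0
      if (any(pos)) null_nes[pos] <- null_es[pos] / mean(null_es[pos])
      if (any(!pos)) null_nes[!pos] <- -null_es[!pos] / mean(null_es[!pos])
    } else {
      # no null ES of matching sign: more extreme than every permutation
      nominal_p <- 1 / (1 + n_permutations)
      nes <- es / mean(abs(null_es))
      null_nes <- numeric()
    }
    list(row = data.frame(set_name = nm, size = size, es = es, nes = nes,
                          nominal_p = nominal_p,
                          n_permutations = n_permutations,
                          stringsAsFactors = FALSE),
         null_nes = null_nes)
  })
  out <- do.call(rbind, lapply(rows, `[[`, "row"))
  if (fdr_method == "bh") {
    out$fdr_q <- bh_fdr(out$nominal_p)
  } else {
    pool <- unlist(lapply(rows, `[[`, "null_nes"))
    out$fdr_q <- vapply(out$nes, function(nes) {
      same_null <- pool[sign(pool) == sign(nes)]
      same_obs <- out$nes[sign(out$nes) == sign(nes)]
      if (!length(same_null)) return(0)
      num <- mean(abs(same_null) >= abs(nes))
      den <- mean(abs(same_obs) >= abs(nes))
      min(1, num / max(den, .Machine$double.eps))
    }, 0)
  }
  out[, c("set_name", "size", "es", "nes", "nominal_p", "fdr_q",
          "n_permutations")]
}

#' Sample set enrichment analysis
#'
#' Tests whether the samples of each class concentrate at one end of a
#' per-sample score: samples are ranked by the score and per-class sample
#' memberships play the role of the sets in [preranked_enrichment()].
#' Unassigned samples are excluded; classes with fewer than 2 assigned
#' samples are skipped.
#'
#' @param score a [score_table()].
#' @param class_assignments an `ntp_result`, a data.frame with columns
#'   `sample_id` and `predicted_class`, or a named label vector.
#' @param n_permutations membership permutations (default 1000).
#' @param seed integer seed.
#' @param weight_p weighting exponent passed on (default 1).
#' @param fdr_method see [preranked_enrichment()].
#' @return data.frame as in [preranked_enrichment()], one row per class.
#' @export
ssea <- function(score, class_assignments, n_permutations = 1000,
                 seed = NULL, weight_p = 1,
                 fdr_method = c("nes_pool", "bh")) {
  stopifnot(inherits(score, "score_table"))
  labels <- extract_labels(class_assignments)
  shared <- intersect(score$sample_id, names(labels))
  labels <- labels[shared]
  labels <- labels[labels != UNASSIGNED]
  if (!length(labels)) stop("no assigned, scored sample available")
  sc <- stats::setNames(score$score, score$sample_id)[names(labels)]
  sets <- split(names(labels), labels)
  preranked_enrichment(names(labels), unname(sc), sets,
                       weight_p = weight_p,
                       n_permutations = n_permutations, seed = seed,
                       fdr_method = match.arg(fdr_method))
}

extract_labels <- function(x) {
  if (inherits(x, "ntp_result")) {
    return(stats::setNames(x$assignments$predicted_class,
                           x$assignments$sample_id))
  }
  if (is.data.frame(x)) {
    return(stats::setNames(x$predicted_class, x$sample_id))
  }
  if (is.null(names(x))) stop("label vector must be named by sample id")
  stats::setNames(as.character(x), names(x))
}
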