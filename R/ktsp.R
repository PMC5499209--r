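#' Number of candidate gene pairs
#'
#' @param n_genes number of genes available for pairing (>= 2).
#' @return `choose(n_genes, 2)` as a plain number.
#' @export
count_candidate_pairs <- function(n_genes) {
  if (n_genes < 2) stop("need at least 2 genes to form a pair")
  choose(n_genes, 2)
}

#' Integrative correlation of genes across datasets
#'
#' A phenotype-free gene reproducibility index: within each dataset the
#' gene-gene correlation of rank-transformed expression is computed; a
#' gene's pairwise index for two datasets is the Pearson correlation of its
#' correlation profiles (self excluded) across the two, and its total index
#' is the mean over all dataset pairs.
#'
#' @param datasets list of >= 2 expression matrices sharing >= 10 genes.
#' @return data.frame with `gene`, one column per dataset pair, and `icor`
#'   (the mean across pairs).
#' @export
integrative_correlation <- function(datasets) {
  if (length(datasets) < 2) stop("need at least 2 datasets")
  datasets <- lapply(datasets, as_expr)
  shared <- Reduce(intersect, lapply(datasets, rownames))
  if (length(shared) < 10) {
    stop("fewer than 10 genes shared across datasets")
  }
  profiles <- lapply(datasets, function(d) {
    ranked <- t(apply(unclass(d)[shared, , drop = FALSE], 1, rank))
    stats::cor(t(ranked))
  })
  pairs <- utils::combn(length(datasets), 2)
  out <- data.frame(gene = shared, stringsAsFactors = FALSE)
  for (p in seq_len(ncol(pairs))) {
    r1 <- profiles[[pairs[1, p]]]
    r2 <- profiles[[pairs[2, p]]]
    v <- vapply(seq_along(shared), function(g)
      stats::cor(r1[g, -g], r2[g, -g]), 0)
    out[[sprintf("icor_%d_%d", pairs[1, p], pairs[2, p])]] <- v
  }
  out$icor <- rowMeans(out[, -1, drop = FALSE])
  out
}

#' Dichotomize a reproducibility index with a two-component Gaussian mixture
#'
#' Fits a two-component univariate Gaussian mixture by
#' expectation-maximization and splits the values at the point where the
#' two components have equal posterior probability; values in the upper
#' component are kept as reproducible.
#'
#' @param icor_values named numeric vector of >= 20 values.
#' @param seed integer seed (the fit is deterministic; kept for interface
#'   symmetry).
#' @return list with `threshold`, `kept` (names, or indices when unnamed,
#'   of upper-component values), `means`, `model`.
#' @importFrom mclust Mclust mclustBIC
#' @export
em_dichotomize <- function(icor_values, seed = NULL) {
  v <- icor_values
  if (length(v) < 20) stop("need at least 20 values to fit a mixture")
  if (stats::sd(v) == 0) stop("values are identical; mixture degenerate")
  if (!is.null(seed)) set.seed(seed)
  fit <- tryCatch(
    mclust::Mclust(v, G = 2, modelNames = "V", verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit)) {
    stop("mixture fit did not converge (n = ", length(v), ", sd = ",
         signif(stats::sd(v), 3), ")")
  }
  mu <- fit$parameters$mean
  sdv <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sdv) == 1) sdv <- rep(sdv, 2)
  pro <- fit$parameters$pro
  lo <- which.min(mu)
  hi <- which.max(mu)
  post_diff <- function(x) {
    pro[hi] * stats::dnorm(x, mu[hi], sdv[hi]) -
      pro[lo] * stats::dnorm(x, mu[lo], sdv[lo])
  }
  threshold <- tryCatch(
    stats::uniroot(post_diff, c(mu[lo], mu[hi]))$root,
    error = function(e) mean(mu))
  kept_idx <- which(v > threshold)
  kept <- if (is.null(names(v))) kept_idx else names(v)[kept_idx]
  list(threshold = threshold, kept = kept, means = sort(unname(mu)),
       model = fit)
}

#' Rank genes by class-vs-rest rank-sum separation
#'
#' Genes are ranked by the absolute deviation of the rank-sum AUC
#' (probability that a class sample exceeds a non-class sample) from 0.5,
#' the effect size underlying the Wilcoxon rank-sum test.
#'
#' @param matrix an [expression_matrix()].
#' @param labels class label per sample.
#' @param class the class of interest.
#' @param n_top genes to return (default 50); fewer if unavailable.
#' @return character vector of gene ids, strongest first.
#' @export
select_class_markers <- function(matrix, labels, class, n_top = 50) {
  m <- as_expr(matrix)
  labels <- align_labels(labels, colnames(m))
  if (!class %in% labels) stop("class not present in labels: ", class)
  in_class <- labels == class
  n1 <- sum(in_class)
  n2 <- sum(!in_class)
  x <- unclass(m)
  ranks <- t(apply(x, 1, rank))
  w <- rowSums(ranks[, in_class, drop = FALSE]) - n1 * (n1 + 1) / 2
  auc <- w / (n1 * n2)
  ord <- order(abs(auc - 0.5), decreasing = TRUE)
  rownames(m)[utils::head(ord, n_top)]
}

# P(x_i < x_j) per class with within-sample ties counting 0.5
order_prob <- function(xi, xj) mean((xi < xj) + 0.5 * (xi == xj))

#' Score a single top-scoring pair
#'
#' The primary score delta is the absolute difference, between the two
#' classes of the comparison, of the within-class probability that
#' `gene_i` is expressed below `gene_j` (within-sample ties count 0.5).
#' The secondary score gamma is the absolute between-class difference of
#' the mean within-sample rank gap of the two genes.
#'
#' @param matrix an [expression_matrix()].
#' @param labels class label per sample.
#' @param gene_i,gene_j the pair of genes.
#' @param comparison length-2 character vector of class labels.
#' @return list with `delta`, `gamma`, `gene_high`, `gene_low`,
#'   `vote_if_high_gt_low` and `vote_otherwise`.
#' @export
tsp_delta <- function(matrix, labels, gene_i, gene_j, comparison) {
  m <- as_expr(matrix)
  labels <- align_labels(labels, colnames(m))
  stopifnot(length(comparison) == 2)
  for (cl in comparison) {
    if (!cl %in% labels) stop("no samples for class ", cl)
  }
  x <- unclass(m)
  sx <- labels == comparison[1]
  sy <- labels == comparison[2]
  p_x <- order_prob(x[gene_i, sx], x[gene_j, sx])
  p_y <- order_prob(x[gene_i, sy], x[gene_j, sy])
  ranks <- apply(x, 2, rank)
  gap <- ranks[gene_i, ] - ranks[gene_j, ]
  gamma <- abs(mean(gap[sx]) - mean(gap[sy]))
  # i > j more typical of the class with the smaller P(i < j)
  vote <- if (p_x <= p_y) comparison[1] else comparison[2]
  other <- setdiff(comparison, vote)
  list(delta = abs(p_x - p_y), gamma = gamma,
       gene_high = gene_i, gene_low = gene_j,
       vote_if_high_gt_low = vote, vote_otherwise = other)
}

#' Plan the order of pairwise class comparisons
#'
#' Comparisons led by the `priority` classes come first (each against all
#' others, ordered by ascending combined candidate-pool size); the
#' remaining comparisons follow, also by ascending pool size.
#'
#' @param candidates_by_class named list of candidate gene vectors.
#' @param priority class labels to search first, in order.
#' @return list of length-2 character vectors covering every comparison.
#' @export
plan_comparisons <- function(candidates_by_class, priority = character()) {
  classes <- names(candidates_by_class)
  sizes <- vapply(candidates_by_class, length, 0L)
  all_pairs <- utils::combn(classes, 2, simplify = FALSE)
  done <- character()
  out <- list()
  key <- function(p) paste(sort(p), collapse = "|")
  for (lead in priority) {
    rest <- setdiff(classes, lead)
    rest <- rest[order(sizes[lead] + sizes[rest])]
    for (other in rest) {
      p <- c(lead, other)
      if (!key(p) %in% done) {
        out <- c(out, list(p))
        done <- c(done, key(p))
      }
    }
  }
  remaining <- Filter(function(p) !key(p) %in% done, all_pairs)
  remaining <- remaining[order(vapply(remaining, function(p)
    sizes[p[1]] + sizes[p[2]], 0L))]
  c(out, remaining)
}

#' Build a multiclass k-TSP classifier with disjoint pairs
#'
#' Comparisons are processed in the given order; within each, the k
#' highest-delta pairs between the two classes' candidate genes are chosen
#' greedily (gamma breaks delta ties, then lexicographic gene ids), genes
#' already used by any earlier pair are excluded, and the selected genes
#' are removed from all subsequent searches, so all genes across all pairs
#' are distinct.
#'
#' @param matrix training [expression_matrix()].
#' @param labels class label per sample.
#' @param candidates_by_class named list of candidate gene vectors, one per
#'   class (e.g. from [select_class_markers()] after reproducibility
#'   filtering).
#' @param k pairs per comparison (default 4).
#' @param comparison_order list of length-2 class vectors covering every
#'   pairwise comparison; defaults to [plan_comparisons()].
#' @return a `ktsp_classifier`: `pairs` data.frame (gene_high, gene_low,
#'   class_x, class_y, vote_if_high_gt_low, vote_otherwise, delta, gamma),
#'   `k`, `classes`.
#' @export
build_ktsp <- function(matrix, labels, candidates_by_class, k = 4,
                       comparison_order = NULL) {
  m <- as_expr(matrix)
  labels <- align_labels(labels, colnames(m))
  classes <- names(candidates_by_class)
  if (is.null(comparison_order)) {
    comparison_order <- plan_comparisons(candidates_by_class)
  }
  keys <- vapply(comparison_order, function(p)
    paste(sort(p), collapse = "|"), "")
  want <- apply(utils::combn(sort(classes), 2), 2, paste, collapse = "|")
  if (!setequal(keys, want) || anyDuplicated(keys)) {
    stop("comparison_order must cover every pairwise comparison exactly once")
  }
  x <- unclass(m)
  ranks <- apply(x, 2, rank)
  used <- character()
  rows <- list()
  for (cmp in comparison_order) {
    cx <- cmp[1]
    cy <- cmp[2]
    a <- setdiff(intersect(candidates_by_class[[cx]], rownames(m)), used)
    b <- setdiff(intersect(candidates_by_class[[cy]], rownames(m)), used)
    b <- setdiff(b, a)
    sx <- which(labels == cx)
    sy <- which(labels == cy)
    if (!length(sx) || !length(sy)) stop("no samples for comparison ",
                                         cx, " vs ", cy)
    if (!length(a) || !length(b)) {
      stop("candidate exhaustion in comparison ", cx, " vs ", cy)
    }
    # P(a < b | class) for every candidate pair, ties counting 0.5
    acc <- function(samples) {
      p <- matrix(0, length(a), length(b), dimnames = list(a, b))
      for (s in samples) {
        p <- p + outer(x[a, s], x[b, s], `<`) +
          0.5 * outer(x[a, s], x[b, s], `==`)
      }
      p / length(samples)
    }
    p_x <- acc(sx)
    p_y <- acc(sy)
    delta <- abs(p_x - p_y)
    rd_x <- rowMeans(ranks[, sx, drop = FALSE])
    rd_y <- rowMeans(ranks[, sy, drop = FALSE])
    gamma <- abs(outer(rd_x[a], rd_x[b], `-`) - outer(rd_y[a], rd_y[b], `-`))
    idx <- expand.grid(i = seq_along(a), j = seq_along(b))
    ord <- order(-delta[cbind(idx$i, idx$j)], -gamma[cbind(idx$i, idx$j)],
                 a[idx$i], b[idx$j])
    taken <- 0L
    local_used <- character()
    for (o in ord) {
      if (taken == k) break
      gi <- a[idx$i[o]]
      gj <- b[idx$j[o]]
      if (gi %in% local_used || gj %in% local_used) next
      px <- p_x[idx$i[o], idx$j[o]]
      py <- p_y[idx$i[o], idx$j[o]]
      vote <- if (px <= py) cx else cy
      rows <- c(rows, list(data.frame(
        gene_high = gi, gene_low = gj, class_x = cx, class_y = cy,
        vote_if_high_gt_low = vote,
        vote_otherwise = if (vote == cx) cy else cx,
        delta = delta[idx$i[o], idx$j[o]],
        gamma = gamma[idx$i[o], idx$j[o]],
        stringsAsFactors = FALSE)))
      local_used <- c(local_used, gi, gj)
      taken <- taken + 1L
    }
    if (taken < k) {
      stop("candidate exhaustion in comparison ", cx, " vs ", cy,
           ": only ", taken, " of ", k, " pairs available")
    }
    used <- c(used, local_used)
  }
  pairs <- do.call(rbind, rows)
  structure(list(pairs = pairs, k = k, classes = classes),
            class = "ktsp_classifier")
}

#' @export
print.ktsp_classifier <- function(x, ...) {
  cat("k-TSP classifier:", nrow(x$pairs), "pairs (k =", x$k, ") over",
      length(x$classes), "classes,",
      length(unique(c(x$pairs$gene_high, x$pairs$gene_low))),
      "distinct genes\n")
  invisible(x)
}

ktsp_classify_one <- function(xs, classifier) {
  pr <- classifier$pairs
  have <- pr$gene_high %in% names(xs) & pr$gene_low %in% names(xs)
  have[have] <- is.finite(xs[pr$gene_high[have]]) &
    is.finite(xs[pr$gene_low[have]])
  if (!any(have)) stop("no evaluable pair for this sample")
  pr <- pr[have, , drop = FALSE]
  vote <- ifelse(xs[pr$gene_high] > xs[pr$gene_low],
                 pr$vote_if_high_gt_low, pr$vote_otherwise)
  cmp_key <- paste(pr$class_x, pr$class_y, sep = "|")
  classes <- classifier$classes
  # per-comparison vote share, then proportion over evaluable comparisons
  share <- stats::setNames(numeric(length(classes)), classes)
  n_cmp <- stats::setNames(numeric(length(classes)), classes)
  cmp_share <- list()
  for (key in unique(cmp_key)) {
    sel <- cmp_key == key
    cx <- pr$class_x[sel][1]
    cy <- pr$class_y[sel][1]
    sx <- mean(vote[sel] == cx)
    share[cx] <- share[cx] + sx
    share[cy] <- share[cy] + (1 - sx)
    n_cmp[cx] <- n_cmp[cx] + 1
    n_cmp[cy] <- n_cmp[cy] + 1
    cmp_share[[key]] <- stats::setNames(c(sx, 1 - sx), c(cx, cy))
  }
  prop <- ifelse(n_cmp > 0, share / pmax(n_cmp, 1), -Inf)
  top <- which(prop == max(prop))
  if (length(top) == 1) return(classes[top])
  if (length(top) >= 3) return(UNASSIGNED)
  # two-way tie: head-to-head comparison decides
  duo <- classes[top]
  key <- paste(duo[1], duo[2], sep = "|")
  key2 <- paste(duo[2], duo[1], sep = "|")
  hh <- cmp_share[[key]]
  if (is.null(hh)) hh <- cmp_share[[key2]]
  if (is.null(hh) || hh[1] == hh[2]) return(UNASSIGNED)
  names(hh)[which.max(hh)]
}

#' Classify samples with a k-TSP classifier
#'
#' Applies the voting rule: each evaluable pair votes within its
#' comparison (pairs whose genes are missing are skipped); per-class vote
#' proportions are averaged over the comparisons involving the class that
#' have at least one evaluable pair; the unique maximum wins; ties among
#' three or more classes leave the sample [UNASSIGNED]; two-way ties are
#' resolved by the head-to-head comparison's vote share, or left
#' [UNASSIGNED] when that too is tied. The rule depends only on
#' within-sample gene orderings, so it is invariant under any strictly
#' increasing per-sample transform.
#'
#' @param sample_expression named numeric vector for one sample, or an
#'   [expression_matrix()] (classified column by column).
#' @param classifier a `ktsp_classifier` from [build_ktsp()].
#' @return class label (or [UNASSIGNED]); for matrix input, a named vector.
#' @export
ktsp_classify <- function(sample_expression, classifier) {
  stopifnot(inherits(classifier, "ktsp_classifier"))
  if (is.matrix(sample_expression)) {
    m <- as_expr(sample_expression)
    return(vapply(colnames(m), function(s)
      ktsp_classify_one(unclass(m)[, s], classifier), ""))
  }
  ktsp_classify_one(sample_expression, classifier)
}

#' Convert a k-TSP classifier into disjoint NTP signatures
#'
#' Each gene is assigned to the class its ordering calls: the high gene of
#' a pair to the class voted when it exceeds the low gene, and the low gene
#' to the opposite class. With k pairs per comparison and n classes every
#' class receives k * (n - 1) genes.
#'
#' @param classifier a `ktsp_classifier`.
#' @return a [gene_signature_set()].
#' @export
tsp_to_ntp_signatures <- function(classifier) {
  stopifnot(inherits(classifier, "ktsp_classifier"))
  pr <- classifier$pairs
  if (is.null(pr$vote_if_high_gt_low) || anyNA(pr$vote_if_high_gt_low)) {
    stop("pair orientation missing")
  }
  genes <- c(pr$gene_high, pr$gene_low)
  votes <- c(pr$vote_if_high_gt_low, pr$vote_otherwise)
  gene_signature_set(split(genes, factor(votes, classifier$classes)))
}

#' Serialize a k-TSP classifier as TSV
#'
#' One row per pair: gene_high, gene_low, class_x, class_y,
#' vote_if_high_gt_low, vote_otherwise, delta, gamma.
#'
#' @param classifier a `ktsp_classifier`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ktsp <- function(classifier, path) {
  stopifnot(inherits(classifier, "ktsp_classifier"))
  utils::write.table(classifier$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a k-TSP classifier from TSV
#'
#' @param path path written by [write_ktsp()].
#' @return a `ktsp_classifier`.
#' @export
read_ktsp <- function(path) {
  pr <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene_high", "gene_low", "class_x", "class_y",
           "vote_if_high_gt_low", "vote_otherwise", "delta", "gamma")
  if (!all(req %in% names(pr))) {
    stop("classifier file needs columns: ", paste(req, collapse = ", "))
  }
  classes <- sort(unique(c(pr$class_x, pr$class_y)))
  k <- max(table(paste(pr$class_x, pr$class_y)))
  structure(list(pairs = pr, k = k, classes = classes),
            class = "ktsp_classifier")
}

#' Stratified train/test split
#'
#' Splits samples into training and test sets with proportions preserved
#' on the stratification grid (e.g. platform x class).
#'
#' @param labels named class label vector (names = sample ids).
#' @param platform optional platform label per sample (same names).
#' @param train_fraction fraction in the training set (default 2/3).
#' @param seed integer seed.
#' @return list with `train` and `test` sample id vectors.
#' @export
stratified_split <- function(labels, platform = NULL, train_fraction = 2 / 3,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- names(labels)
  strata <- if (is.null(platform)) as.character(labels) else
    paste(labels, platform[ids], sep = "|")
  train <- unlist(lapply(split(ids, strata), function(g) {
    n <- max(1L, round(length(g) * train_fraction))
    sample(g, n)
  }), use.names = FALSE)
  list(train = train, test = setdiff(ids, train))
}

#' Train a k-TSP classifier end to end
#'
#' Convenience wrapper over the k-TSP construction: optionally filters
#' genes by cross-platform reproducibility (integrative correlation
#' dichotomized by a Gaussian-mixture EM fit), ranks class markers by
#' rank-sum separation, plans the comparison order and searches the
#' disjoint pairs.
#'
#' @param matrix training [expression_matrix()].
#' @param labels class label per sample; [UNASSIGNED] samples are dropped.
#' @param datasets optional list of expression matrices (multiple
#'   platforms) used for the reproducibility filter.
#' @param k pairs per comparison (default 4).
#' @param n_top class markers entering the pair search (default 50).
#' @param priority classes whose comparisons are searched first.
#' @param seed integer seed.
#' @return list with `classifier`, `icor` (or NULL), `icor_threshold`,
#'   `candidates_by_class`.
#' @export
train_ktsp <- function(matrix, labels, datasets = NULL, k = 4, n_top = 50,
                       priority = character(), seed = NULL) {
  m <- as_expr(matrix)
  labels <- align_labels(labels, colnames(m))
  keep <- labels != UNASSIGNED
  m <- m[, keep, drop = FALSE]
  labels <- labels[keep]
  if (!is.null(seed)) set.seed(seed)
  icor <- NULL
  threshold <- NULL
  gene_pool <- rownames(m)
  if (!is.null(datasets)) {
    icor <- integrative_correlation(datasets)
    em <- em_dichotomize(stats::setNames(icor$icor, icor$gene))
    threshold <- em$threshold
    gene_pool <- intersect(gene_pool, em$kept)
  }
  sub <- as_expr(unclass(m)[gene_pool, , drop = FALSE])
  classes <- sort(unique(labels))
  candidates <- stats::setNames(lapply(classes, function(cl)
    select_class_markers(sub, labels, cl, n_top)), classes)
  order_plan <- plan_comparisons(candidates, priority)
  classifier <- build_ktsp(sub, labels, candidates, k = k,
                           comparison_order = order_plan)
  list(classifier = classifier, icor = icor, icor_threshold = threshold,
       candidates_by_class = candidates)
}
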