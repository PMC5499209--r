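#' Select high-variance genes
#'
#' @param matrix an [expression_matrix()] of log2 expression.
#' @param sd_threshold keep genes with across-sample sd strictly above this
#'   value (default 0.8).
#' @return character vector of gene ids, original order preserved.
#' @export
select_variable_genes <- function(matrix, sd_threshold = 0.8) {
  m <- as_expr(matrix)
  sds <- apply(unclass(m), 1, stats::sd)
  keep <- rownames(m)[sds > sd_threshold]
  if (!length(keep)) {
    stop("no gene exceeds sd threshold ", sd_threshold,
         "; consider lowering it")
  }
  keep
}

# One KL-divergence NMF run (multiplicative updates); returns the hard
# sample partition given by the dominant metagene of H.
nmf_run <- function(v, k, max_iter = 2000, conn_stable = 40, eps = 1e-12) {
  n <- ncol(v)
  w <- matrix(stats::runif(nrow(v) * k, 0.1, 1), nrow(v), k)
  h <- matrix(stats::runif(k * n, 0.1, 1), k, n)
  last <- max.col(t(h))
  stable <- 0L
  for (it in seq_len(max_iter)) {
    wh <- w %*% h
    h <- h * (crossprod(w, v / (wh + eps))) / (colSums(w) + eps)
    wh <- w %*% h
    w <- w * ((v / (wh + eps)) %*% t(h)) / rep(rowSums(h) + eps,
                                               each = nrow(w))
    cl <- max.col(t(h))
    if (identical(cl, last)) {
      stable <- stable + 1L
      if (stable >= conn_stable) break
    } else {
      stable <- 0L
      last <- cl
    }
  }
  last
}

#' Consensus non-negative matrix factorization over a range of ranks
#'
#' For each candidate number of clusters K, runs `n_runs` randomly restarted
#' NMF factorizations (multiplicative KL-divergence updates) and averages
#' the sample connectivity matrices into a consensus matrix. Hard labels
#' come from average-linkage hierarchical clustering of 1 - consensus, and
#' clustering stability is summarized by the cophenetic coefficient: the
#' correlation between the consensus-derived distances and the cophenetic
#' distances of their dendrogram.
#'
#' The input is expected variable-gene filtered and per-sample standardized;
#' it is made non-negative by row splitting (each gene contributes a
#' positive-part row and a negated-negative-part row), the standard device
#' for factorizing centered data.
#'
#' @param matrix an [expression_matrix()], typically z-scored per sample.
#' @param K_range integer vector of ranks to evaluate (default 2:6).
#' @param n_runs random restarts per rank (default 50).
#' @param seed integer seed.
#' @param max_iter,conn_stable per-run update budget and the number of
#'   consecutive iterations the sample partition must stay unchanged to
#'   declare convergence.
#' @return named list (one element per K) of `consensus_result` objects
#'   with fields `K`, `consensus`, `cophenetic`, `hard_labels`.
#' @export
nmf_consensus <- function(matrix, K_range = 2:6, n_runs = 50, seed = NULL,
                          max_iter = 2000, conn_stable = 40) {
  m <- as_expr(matrix)
  n <- ncol(m)
  if (any(K_range >= n)) stop("K must be smaller than the number of samples")
  if (any(K_range < 2)) stop("K must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  v <- rbind(pmax(unclass(m), 0), pmax(-unclass(m), 0))
  out <- lapply(K_range, function(k) {
    consensus <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
    for (r in seq_len(n_runs)) {
      cl <- nmf_run(v, k, max_iter, conn_stable)
      consensus <- consensus + outer(cl, cl, `==`)
    }
    consensus <- consensus / n_runs
    d <- stats::as.dist(1 - consensus)
    hc <- stats::hclust(d, method = "average")
    coph <- stats::cor(stats::cophenetic(hc), d)
    structure(list(K = k, consensus = consensus,
                   cophenetic = unname(coph),
                   hard_labels = stats::setNames(
                     paste0("C", stats::cutree(hc, k)), colnames(m))),
              class = "consensus_result")
  })
  names(out) <- paste0("K", K_range)
  out
}

#' Drop poorly clustered samples by silhouette width
#'
#' Computes the silhouette width s(i) = (b - a) / max(a, b) of every sample
#' under the consensus-derived distance 1 - consensus and removes samples
#' with negative width, keeping only core representatives of each cluster.
#'
#' @param consensus_result a `consensus_result` from [nmf_consensus()].
#' @return list with `core` and `dropped` sample id vectors.
#' @export
silhouette_filter <- function(consensus_result) {
  stopifnot(inherits(consensus_result, "consensus_result"))
  labels <- consensus_result$hard_labels
  d <- 1 - consensus_result$consensus
  sil <- cluster::silhouette(as.integer(factor(labels)), dmatrix = d)
  widths <- sil[, "sil_width"]
  core <- names(labels)[widths >= 0]
  dropped <- names(labels)[widths < 0]
  remaining <- table(labels[core])
  gone <- setdiff(unique(labels), names(remaining[remaining > 0]))
  if (length(gone)) {
    stop("silhouette filter removed every member of cluster ",
         paste(gone, collapse = ", "))
  }
  list(core = core, dropped = dropped)
}

# multiclass moderated contrast statistic: between-class spread over
# (pooled within-class sd + fudge)
sam_stat <- function(x, labels, s0 = NULL) {
  f <- factor(labels)
  k <- nlevels(f)
  n <- ncol(x)
  n_k <- as.numeric(table(f))
  ind <- stats::model.matrix(~ f - 1)
  class_means <- (x %*% ind) / rep(n_k, each = nrow(x))
  overall <- rowMeans(x)
  between <- sqrt(rowSums(sweep(class_means, 1, overall)^2 *
                            rep(n_k, each = nrow(x))) / (k - 1))
  within_ss <- rowSums(x^2) - rowSums(class_means^2 *
                                        rep(n_k, each = nrow(x)))
  s <- sqrt(pmax(within_ss, 0) / (n - k))
  if (is.null(s0)) s0 <- stats::median(s)
  list(stat = between / (s + s0), s = s, s0 = s0)
}

#' Multiclass differential expression with permutation FDR
#'
#' SAM-style analysis: a per-gene moderated statistic (between-class
#' contrast over pooled within-class sd plus a fudge factor s0, the median
#' of the per-gene sds) whose null distribution is obtained by permuting
#' class labels. The gene-level q-value at each statistic cut-off is the
#' median permutation count of exceedances divided by the observed count.
#'
#' @param matrix an [expression_matrix()].
#' @param labels class label per sample (named or ordered as columns).
#' @param fdr_threshold select genes with q <= this value (default 0.005).
#' @param n_permutations label permutations (>= 25; default 200).
#' @param seed integer seed.
#' @return list with `selected` gene ids and a `table` data.frame
#'   (gene, statistic, q_value) in decreasing statistic order.
#' @export
sam_multiclass <- function(matrix, labels, fdr_threshold = 0.005,
                           n_permutations = 200, seed = NULL) {
  m <- as_expr(matrix)
  labels <- align_labels(labels, colnames(m))
  if (n_permutations < 25) {
    stop("fewer than 25 permutations gives an unstable FDR")
  }
  f <- factor(labels)
  if (nlevels(f) < 2) stop("need at least 2 classes")
  if (any(table(f) < 2)) stop("need at least 2 samples per class")
  if (!is.null(seed)) set.seed(seed)
  x <- unclass(m)
  obs <- sam_stat(x, f)
  ord <- order(obs$stat, decreasing = TRUE)
  sorted <- obs$stat[ord]
  exceed <- matrix(0L, n_permutations, length(sorted))
  for (b in seq_len(n_permutations)) {
    perm <- sam_stat(x, sample(f), s0 = obs$s0)$stat
    # count of permuted statistics >= each observed cut-off
    exceed[b, ] <- length(perm) -
      findInterval(sorted, sort(perm), left.open = TRUE)
  }
  v <- apply(exceed, 2, stats::median)
  r <- seq_along(sorted)
  q <- pmin(1, v / r)
  q <- rev(cummin(rev(q)))          # q-value: best FDR over attainable cuts
  tab <- data.frame(gene = rownames(m)[ord], statistic = sorted,
                    q_value = q, stringsAsFactors = FALSE)
  list(selected = tab$gene[tab$q_value <= fdr_threshold], table = tab)
}

# match a label vector (possibly named) to a sample id order
align_labels <- function(labels, sample_ids) {
  if (!is.null(names(labels))) {
    missing <- setdiff(sample_ids, names(labels))
    if (length(missing)) {
      stop("labels missing for samples: ", paste(missing, collapse = ", "))
    }
    labels <- labels[sample_ids]
  } else if (length(labels) != length(sample_ids)) {
    stop("one label per sample required")
  }
  as.character(labels)
}

pam_stats <- function(x, f) {
  n <- ncol(x)
  k <- nlevels(f)
  n_k <- as.numeric(table(f))
  ind <- stats::model.matrix(~ f - 1)
  centroids <- (x %*% ind) / rep(n_k, each = nrow(x))
  colnames(centroids) <- levels(f)
  overall <- rowMeans(x)
  within_ss <- rowSums(x^2) - rowSums(centroids^2 * rep(n_k, each = nrow(x)))
  s <- sqrt(pmax(within_ss, 0) / (n - k))
  s0 <- stats::median(s)
  m_k <- sqrt(1 / n_k - 1 / n)
  d <- sweep(centroids, 1, overall) /
    (outer(s + s0, m_k))
  list(centroids = centroids, overall = overall, s = s, s0 = s0,
       m_k = m_k, d = d, classes = levels(f))
}

shrink_scores <- function(d, delta) sign(d) * pmax(abs(d) - delta, 0)

pam_predict_scores <- function(st, dshr, x) {
  # discriminant: squared standardized distance to shrunken centroids
  shrunken <- st$overall + sweep(dshr, 1, st$s + st$s0, `*`) *
    rep(st$m_k, each = nrow(dshr))
  denom <- (st$s + st$s0)^2
  sc <- vapply(seq_along(st$classes), function(k)
    colSums((x - shrunken[, k])^2 / denom), numeric(ncol(x)))
  matrix(sc, nrow = ncol(x), dimnames = list(colnames(x), st$classes))
}

#' Train a nearest shrunken centroid (PAM) model
#'
#' Standardized centroid scores d_ik = (xbar_ik - xbar_i) / (m_k (s_i + s0))
#' are soft-thresholded by Delta; the shrinkage level is chosen from
#' `delta_grid` to minimize leave-one-out cross-validation error, with ties
#' broken toward the smallest Delta, i.e. the largest gene set compatible
#' with the minimal error. Class priors are uniform.
#'
#' @param matrix an [expression_matrix()], typically restricted to
#'   differentially expressed genes.
#' @param labels class label per sample.
#' @param delta_grid candidate shrinkage levels; default 30 values from 0
#'   to the largest |d_ik|.
#' @return a `pam_model`: shrunken scores `d_shrunk`, chosen `delta`,
#'   `cv_error`, per-class `centroids`, pooled sds `s`, fudge `s0`,
#'   `active` gene flags, `classes`.
#' @export
pam_train <- function(matrix, labels, delta_grid = NULL) {
  m <- as_expr(matrix)
  labels <- align_labels(labels, colnames(m))
  f <- factor(labels)
  if (any(table(f) < 2)) {
    stop("every class needs >= 2 samples for leave-one-out cross-validation")
  }
  x <- unclass(m)
  st <- pam_stats(x, f)
  if (is.null(delta_grid)) {
    delta_grid <- seq(0, max(abs(st$d)), length.out = 30)
  }
  n <- ncol(x)
  errs <- matrix(0, n, length(delta_grid))
  for (j in seq_len(n)) {
    fj <- droplevels(f[-j])
    if (nlevels(fj) < nlevels(f)) {
      stop("class with a single sample: leave-one-out degenerate")
    }
    stj <- pam_stats(x[, -j, drop = FALSE], fj)
    for (g in seq_along(delta_grid)) {
      sc <- pam_predict_scores(stj, shrink_scores(stj$d, delta_grid[g]),
                               x[, j, drop = FALSE])
      pred <- stj$classes[which.min(sc[1, ])]
      errs[j, g] <- pred != as.character(f[j])
    }
  }
  cv <- colMeans(errs)
  # tie -> smallest delta: retain every gene compatible with the minimal
  # cross-validation error (gene selection favours sensitivity)
  best <- min(which(cv == min(cv)))
  dshr <- shrink_scores(st$d, delta_grid[best])
  structure(list(d = st$d, d_shrunk = dshr, delta = delta_grid[best],
                 delta_grid = delta_grid, cv_curve = cv,
                 cv_error = cv[best], centroids = st$centroids,
                 overall = st$overall, s = st$s, s0 = st$s0, m_k = st$m_k,
                 active = rowSums(dshr != 0) > 0, classes = st$classes,
                 genes = rownames(m)),
            class = "pam_model")
}

#' Classify samples with a trained PAM model
#'
#' @param model a `pam_model` from [pam_train()].
#' @param matrix expression matrix containing the model's genes.
#' @return character vector of predicted classes, named by sample.
#' @export
pam_classify <- function(model, matrix) {
  m <- as_expr(matrix)
  missing <- setdiff(model$genes, rownames(m))
  if (length(missing)) {
    stop("matrix lacks model genes: ", paste(utils::head(missing, 5),
                                             collapse = ", "))
  }
  x <- unclass(m)[model$genes, , drop = FALSE]
  st <- list(overall = model$overall, s = model$s, s0 = model$s0,
             m_k = model$m_k, classes = model$classes)
  sc <- pam_predict_scores(st, model$d_shrunk, x)
  stats::setNames(model$classes[apply(sc, 1, which.min)], colnames(m))
}

#' Remove genes dominated by stromal signal
#'
#' Genes whose estimated stromal contribution exceeds the threshold
#' (strictly) are removed from a candidate list; a contribution of exactly
#' the threshold is kept. Genes absent from the table are kept with a
#' warning, since stroma-content estimates may not cover every gene.
#'
#' @param gene_list candidate gene ids.
#' @param stromal_fraction_table data.frame with columns `gene` and
#'   `fraction` (or a named numeric vector), fractions in [0, 1].
#' @param threshold removal threshold on the stromal fraction (default 0.5).
#' @return list with `kept` and `removed` gene id vectors.
#' @export
stromal_filter <- function(gene_list, stromal_fraction_table,
                           threshold = 0.5) {
  if (is.data.frame(stromal_fraction_table)) {
    frac <- stats::setNames(stromal_fraction_table$fraction,
                            stromal_fraction_table$gene)
  } else {
    frac <- stromal_fraction_table
  }
  if (any(!is.finite(frac)) || any(frac < 0 | frac > 1)) {
    stop("stromal fractions must lie in [0, 1]")
  }
  missing <- setdiff(gene_list, names(frac))
  if (length(missing)) {
    warning(length(missing), " gene(s) missing from the stromal table ",
            "kept by default: ", paste(utils::head(missing, 5),
                                       collapse = ", "))
  }
  f <- frac[gene_list]
  f[is.na(f)] <- 0
  removed <- gene_list[f > threshold]
  list(kept = setdiff(gene_list, removed), removed = removed)
}

#' Assign genes non-redundantly to their best class
#'
#' Nearest-template prediction requires disjoint per-class signatures. A
#' gene with a positive shrunken score for exactly one class goes to that
#' class; a gene positive for several classes goes to its best-scoring
#' class only when the margin over the second-best positive score is at
#' least `gap`, and is excluded otherwise. Genes with no positive score are
#' excluded.
#'
#' @param pam_model a `pam_model` from [pam_train()].
#' @param gap minimum lead of the best over the second-best score
#'   (default 0.2).
#' @param genes optional subset of genes to consider (e.g. after the
#'   stromal filter); defaults to all model genes.
#' @return list with `signatures` (a [gene_signature_set()]),
#'   `excluded_redundant` and `no_positive_score` gene id vectors.
#' @export
assign_nonredundant <- function(pam_model, gap = 0.2, genes = NULL) {
  stopifnot(inherits(pam_model, "pam_model"))
  d <- pam_model$d_shrunk
  rownames(d) <- pam_model$genes
  if (!is.null(genes)) d <- d[intersect(pam_model$genes, genes), ,
                              drop = FALSE]
  assigned <- stats::setNames(vector("list", length(pam_model$classes)),
                              pam_model$classes)
  excluded <- character()
  no_positive <- character()
  for (g in rownames(d)) {
    sc <- d[g, ]
    pos <- sc[sc > 0]
    if (!length(pos)) {
      no_positive <- c(no_positive, g)
    } else if (length(pos) == 1) {
      assigned[[names(pos)]] <- c(assigned[[names(pos)]], g)
    } else {
      o <- order(pos, decreasing = TRUE)
      if (pos[o[1]] - pos[o[2]] >= gap) {
        assigned[[names(pos)[o[1]]]] <- c(assigned[[names(pos)[o[1]]]], g)
      } else {
        excluded <- c(excluded, g)
      }
    }
  }
  empty <- names(assigned)[vapply(assigned, length, 0L) == 0]
  if (length(empty)) {
    stop("class left with no genes after non-redundant assignment: ",
         paste(empty, collapse = ", "))
  }
  list(signatures = gene_signature_set(assigned),
       excluded_redundant = excluded, no_positive_score = no_positive)
}

#' Arithmetic ledger of the classifier gene filtering cascade
#'
#' Checks the bookkeeping of the marker-selection funnel: starting
#' candidates, minus genes without a positive class score, minus
#' stroma-dominated genes, gives the pre-redundancy pool; removing genes
#' excluded by the non-redundancy rule gives the final classifier size.
#'
#' @param candidates genes entering the funnel.
#' @param no_positive_score genes dropped for lacking a positive score.
#' @param stromal_removed genes dropped by the stromal filter.
#' @param redundancy_excluded genes dropped by the non-redundancy rule
#'   (default 0).
#' @return list with `pool` (pre-redundancy count) and `final`.
#' @export
filter_cascade_report <- function(candidates, no_positive_score,
                                  stromal_removed, redundancy_excluded = 0) {
  pool <- candidates - no_positive_score - stromal_removed
  if (pool < 0) stop("negative pre-redundancy pool: cascade inconsistent")
  final <- pool - redundancy_excluded
  if (final < 0) stop("negative final classifier size: cascade inconsistent")
  list(candidates = candidates, pool = pool, final = final)
}

#' End-to-end subtype discovery pipeline
#'
#' Runs the full discovery stage: variable-gene selection, per-sample
#' standardization, consensus NMF over `K_range` with the rank chosen by
#' the cophenetic coefficient, silhouette filtering of core samples,
#' permutation-FDR differential expression, shrunken-centroid gene
#' selection, stromal filtering and non-redundant class assignment.
#'
#' @param matrix an [expression_matrix()] of log2 expression.
#' @param stromal_fractions per-gene stromal fraction table (data.frame
#'   `gene`, `fraction`) or NULL to skip the stromal filter.
#' @param sd_threshold variable-gene sd cut-off (default 0.8).
#' @param K_range candidate cluster numbers (default 2:6).
#' @param n_runs NMF restarts per K (default 50).
#' @param sam_fdr differential-expression FDR threshold (default 0.005).
#' @param sam_permutations label permutations for the FDR (default 200).
#' @param stromal_threshold stromal-fraction removal threshold (default 0.5).
#' @param gap non-redundancy margin (default 0.2).
#' @param seed integer seed.
#' @return list with `signatures`, `K`, `consensus` (all ranks),
#'   `labels` (hard labels at the chosen K), `core_samples`, `pam_model`,
#'   `sam`, `cascade`.
#' @export
discover_signature <- function(matrix, stromal_fractions = NULL,
                               sd_threshold = 0.8, K_range = 2:6,
                               n_runs = 50, sam_fdr = 0.005,
                               sam_permutations = 200,
                               stromal_threshold = 0.5, gap = 0.2,
                               seed = NULL) {
  m <- as_expr(matrix)
  if (!is.null(seed)) set.seed(seed)
  genes <- select_variable_genes(m, sd_threshold)
  z <- zscore_samples(m[genes, , drop = FALSE])
  cons <- nmf_consensus(z, K_range = K_range, n_runs = n_runs)
  coph <- vapply(cons, `[[`, 0, "cophenetic")
  best <- cons[[which.max(coph)]]
  core <- silhouette_filter(best)$core
  labels <- best$hard_labels[core]
  sam <- sam_multiclass(m[genes, core, drop = FALSE], labels,
                        fdr_threshold = sam_fdr,
                        n_permutations = sam_permutations)
  pam <- pam_train(m[sam$selected, core, drop = FALSE], labels)
  active <- pam$genes[pam$active]
  positive <- pam$genes[rowSums(pam$d_shrunk > 0) > 0]
  no_positive <- setdiff(active, positive)
  if (!is.null(stromal_fractions)) {
    sf <- stromal_filter(positive, stromal_fractions, stromal_threshold)
  } else {
    sf <- list(kept = positive, removed = character())
  }
  nr <- assign_nonredundant(pam, gap = gap, genes = sf$kept)
  cascade <- filter_cascade_report(length(active), length(no_positive),
                                   length(sf$removed),
                                   length(nr$excluded_redundant))
  list(signatures = nr$signatures, K = best$K, consensus = cons,
       labels = best$hard_labels, core_samples = core, pam_model = pam,
       sam = sam, cascade = cascade)
}
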