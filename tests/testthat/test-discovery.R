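test_that("variable-gene selection applies a strict sd threshold in order", {
  vals <- rbind(rep(c(-2, 2), 5), rep(c(-0.1, 0.1), 5), rep(0, 10))
  m <- expression_matrix(vals, c("hi", "lo", "flat"), sprintf("s%d", 1:10))
  expect_identical(select_variable_genes(m, 0.8), "hi")
  expect_identical(select_variable_genes(m, 0), c("hi", "lo"))
  expect_error(select_variable_genes(m, 100), "no gene exceeds")
})

test_that("consensus NMF recovers a planted 3-cluster structure", {
  sim <- simulate_expression(
    subtype_model(n_classes = 3, markers_per_class = 8, effect_size = 3,
                  n_background_genes = 20, noise_sd = 0.4,
                  stromal_fraction_range = c(0, 0)),
    n_samples_per_class = 10, seed = 43)
  z <- zscore_samples(sim$matrix[select_variable_genes(sim$matrix, 0.8), ])
  cons <- nmf_consensus(z, K_range = 2:5, n_runs = 10, seed = 44)
  coph <- vapply(cons, `[[`, 0, "cophenetic")
  expect_equal(names(which.max(coph)), "K3")
  expect_true(all(coph >= 0 & coph <= 1))
  # clean separation: the consensus at the true K is exactly block 0/1 and
  # its tree is ultrametric-consistent
  expect_equal(cons$K3$cophenetic, 1.0, tolerance = 1e-8)
  expect_true(all(cons$K3$consensus %in% c(0, 1)))
  # consensus is symmetric with unit diagonal
  expect_equal(cons$K2$consensus, t(cons$K2$consensus))
  expect_true(all(diag(cons$K2$consensus) == 1))
  # a single run gives a 0/1 connectivity matrix
  one <- nmf_consensus(z, K_range = 2, n_runs = 1, seed = 45)
  expect_true(all(one$K2$consensus %in% c(0, 1)))
  expect_error(nmf_consensus(z, K_range = ncol(z)), "smaller than")
})

test_that("silhouette filter keeps clean blocks and drops misplaced samples", {
  ids <- sprintf("s%02d", 1:10)
  block <- matrix(0.05, 10, 10, dimnames = list(ids, ids))
  block[1:5, 1:5] <- 0.95
  block[6:10, 6:10] <- 0.95
  diag(block) <- 1
  cr <- structure(list(K = 2, consensus = block, cophenetic = 1,
                       hard_labels = setNames(rep(c("C1", "C2"), each = 5),
                                              ids)),
                  class = "consensus_result")
  res <- silhouette_filter(cr)
  expect_length(res$dropped, 0)
  # sample s01 closer to the other cluster than to its own
  bad <- block
  bad[1, 2:5] <- bad[2:5, 1] <- 0.1
  bad[1, 6:10] <- bad[6:10, 1] <- 0.9
  cr$consensus <- bad
  res2 <- silhouette_filter(cr)
  expect_identical(res2$dropped, "s01")
})

test_that("multiclass permutation FDR controls nulls and finds markers", {
  # null fixture: no class structure
  m <- random_matrix(100, 45, seed = 47)
  labels <- rep(c("a", "b", "c"), each = 15)
  null_res <- sam_multiclass(m, labels, fdr_threshold = 0.005,
                             n_permutations = 100, seed = 48)
  expect_lte(length(null_res$selected), 5)
  # planted markers: all recovered with q ~ 0
  sim <- small_sim(seed = 49)
  res <- sam_multiclass(sim$matrix, sim$labels, fdr_threshold = 0.005,
                        n_permutations = 100, seed = 50)
  markers <- unlist(sim$marker_sets)
  expect_true(all(markers %in% res$selected))
  expect_true(all(res$table$q_value[res$table$gene %in% markers] < 0.01))
  # constant gene scores zero and is never selected
  vals <- rbind(unclass(sim$matrix), flat = 0)
  res2 <- sam_multiclass(expression_matrix(vals), sim$labels,
                         n_permutations = 50, seed = 51)
  expect_equal(res2$table$statistic[res2$table$gene == "flat"], 0)
  expect_false("flat" %in% res2$selected)
  expect_error(sam_multiclass(sim$matrix, sim$labels, n_permutations = 10),
               "unstable")
})

test_that("unshrunken PAM equals plain nearest standardized centroid", {
  sim <- small_sim(seed = 53)
  model <- pam_train(sim$matrix, sim$labels, delta_grid = 0)
  expect_equal(model$delta, 0)
  expect_equal(model$d_shrunk, model$d)
  # manual nearest standardized centroid on the training data
  x <- unclass(sim$matrix)
  denom <- (model$s + model$s0)^2
  manual <- apply(x, 2, function(v) {
    sc <- colSums((v - model$centroids)^2 / denom)
    model$classes[which.min(sc)]
  })
  expect_identical(unname(pam_classify(model, sim$matrix)), unname(manual))
})

test_that("PAM cross-validation is zero on separable classes and degrades
           to the majority baseline under total shrinkage", {
  sim <- small_sim(seed = 59)
  model <- pam_train(sim$matrix, sim$labels)
  expect_equal(model$cv_error, 0)
  expect_true(any(model$active))
  # delta beyond max|d|: every gene inactive, error at chance level
  huge <- pam_train(sim$matrix, sim$labels,
                    delta_grid = max(abs(pam_train(sim$matrix, sim$labels,
                                                   delta_grid = 0)$d)) + 1)
  expect_false(any(huge$active))
  expect_gte(huge$cv_error, 1 - 1 / 3 - 0.1)
  # degenerate leave-one-out
  m <- random_matrix(10, 4, seed = 60)
  expect_error(pam_train(m, c("a", "a", "a", "b")), ">= 2 samples")
})

test_that("stromal filter removes strictly above the threshold", {
  tab <- data.frame(gene = c("g1", "g2", "g3"),
                    fraction = c(0.6, 0.5, 0))
  res <- stromal_filter(c("g1", "g2", "g3"), tab)
  expect_identical(res$removed, "g1")
  expect_identical(res$kept, c("g2", "g3"))
  expect_length(stromal_filter(c("g1", "g2", "g3"), tab,
                               threshold = 1)$removed, 0)
  zero <- data.frame(gene = c("g1", "g2"), fraction = c(0, 0))
  expect_length(stromal_filter(c("g1", "g2"), zero)$removed, 0)
  expect_error(stromal_filter("g1", data.frame(gene = "g1",
                                               fraction = 1.2)),
               "\\[0, 1\\]")
  expect_warning(stromal_filter(c("g1", "gX"), tab), "missing")
})

test_that("non-redundant assignment respects the positivity and gap rules", {
  d <- rbind(only_a = c(0.5, -0.1, -0.2),
             wide = c(0.5, 0.1, -0.3),
             narrow = c(0.5, 0.4, -0.1),
             negative = c(-0.2, -0.5, -0.9),
             only_b = c(-1, 0.3, 0),
             only_c = c(0, -0.2, 0.8))
  colnames(d) <- c("A", "B", "C")
  fake <- structure(list(d_shrunk = d, genes = rownames(d),
                         classes = colnames(d)),
                    class = "pam_model")
  res <- assign_nonredundant(fake, gap = 0.2)
  expect_identical(res$signatures$A, c("only_a", "wide"))
  expect_identical(res$signatures$B, "only_b")
  expect_identical(res$signatures$C, "only_c")
  expect_identical(res$excluded_redundant, "narrow")
  expect_identical(res$no_positive_score, "negative")
  expect_true(anyDuplicated(unlist(res$signatures)) == 0)
  # a class ending with no genes is an error
  empty <- fake
  empty$d_shrunk <- d[c("only_a", "negative"), ]
  empty$genes <- c("only_a", "negative")
  expect_error(assign_nonredundant(empty), "no genes")
})

test_that("filter cascade arithmetic is internally consistent", {
  expect_equal(filter_cascade_report(100, 0, 0)$final, 100)
  expect_equal(filter_cascade_report(100, 10, 5, 7)$final, 78)
  expect_error(filter_cascade_report(10, 8, 5), "negative")
})
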