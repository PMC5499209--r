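test_that("candidate pair counts match explicit enumeration", {
  expect_equal(count_candidate_pairs(3), 3)
  for (n in c(4, 6, 9)) {
    ids <- seq_len(n)
    expect_equal(count_candidate_pairs(n), ncol(combn(ids, 2)))
  }
  expect_error(count_candidate_pairs(1), "at least 2")
})

test_that("integrative correlation is 1 for identical datasets and ~0 for
           a noise-replaced gene", {
  m <- random_matrix(15, 200, seed = 61)
  res <- integrative_correlation(list(m, m))
  expect_true(all(abs(res$icor - 1) < 1e-12))
  # shared signal across two platforms, ten genes replaced by noise in one
  set.seed(62)
  G <- 150
  X <- matrix(rnorm(G * 200), G, 200)
  d1 <- X + matrix(rnorm(G * 200, sd = 0.3), G, 200)
  d2 <- X + matrix(rnorm(G * 200, sd = 0.3), G, 200)
  noise_idx <- 1:10
  d2[noise_idx, ] <- rnorm(10 * 200)
  ids <- sprintf("g%03d", 1:G)
  res2 <- integrative_correlation(list(
    expression_matrix(d1, ids, sprintf("s%03d", 1:200)),
    expression_matrix(d2, ids, sprintf("s%03d", 1:200))))
  expect_lt(abs(mean(res2$icor[noise_idx])), 0.1)
  expect_gt(min(res2$icor[-noise_idx]), 0.5)
  expect_error(integrative_correlation(list(m[1:5, ], m[1:5, ])),
               "fewer than 10")
})

test_that("reproducibility filter separates signal from noise genes", {
  sim <- small_sim(seed = 63)
  plats <- simulate_multiplatform(sim$matrix, 3, seed = 64)
  icor <- integrative_correlation(plats)
  v <- setNames(icor$icor, icor$gene)
  markers <- unlist(sim$marker_sets)
  background <- grep("^BG", icor$gene, value = TRUE)
  expect_gt(mean(v[markers]), mean(v[background]))
})

test_that("EM dichotomization splits a two-component mixture", {
  set.seed(65)
  v <- setNames(c(rnorm(120, 0, 0.1), rnorm(80, 0.8, 0.1)),
                sprintf("g%03d", 1:200))
  res <- em_dichotomize(v)
  expect_gt(res$threshold, 0.2)
  expect_lt(res$threshold, 0.6)
  truth <- names(v)[121:200]
  accuracy <- (length(intersect(res$kept, truth)) +
                 length(setdiff(names(v)[1:120], res$kept))) / 200
  expect_gte(accuracy, 0.99)
  expect_error(em_dichotomize(rep(0.5, 30)), "degenerate")
  expect_error(em_dichotomize(rnorm(5)), "at least 20")
})

test_that("class markers are ranked consistently with the rank-sum test", {
  sim <- small_sim(seed = 67)
  for (cl in names(sim$marker_sets)) {
    top <- select_class_markers(sim$matrix, sim$labels, cl, n_top = 15)
    expect_true(all(sim$marker_sets[[cl]] %in% top))
  }
  # agreement with stats::wilcox.test on a small case
  m <- random_matrix(8, 30, seed = 68)
  labels <- rep(c("a", "b"), 15)
  ours <- select_class_markers(m, labels, "a", n_top = 8)
  pvals <- apply(unclass(m), 1, function(v)
    wilcox.test(v[labels == "a"], v[labels == "b"], exact = TRUE)$p.value)
  expect_identical(ours[1], names(which.min(pvals)))
  expect_length(select_class_markers(m, labels, "a", n_top = 99), 8)
  expect_error(select_class_markers(m, labels, "zz"), "not present")
})

test_that("tsp_delta matches the direct counting oracle", {
  ids <- c("gi", "gj")
  labels <- rep(c("X", "Y"), each = 4)
  # X: i<j in all samples; Y: i>j in all samples
  vals <- rbind(c(1, 1, 1, 1, 5, 5, 5, 5), c(2, 3, 4, 2, 1, 2, 0, 3))
  m <- expression_matrix(vals, ids, sprintf("s%d", 1:8))
  res <- tsp_delta(m, labels, "gi", "gj", c("X", "Y"))
  expect_equal(res$delta, 1)
  expect_identical(res$vote_if_high_gt_low, "Y")
  # identical distributions
  same <- expression_matrix(rbind(rep(1:4, 2), rep(c(2, 1, 4, 3), 2)),
                            ids, sprintf("s%d", 1:8))
  expect_equal(tsp_delta(same, labels, "gi", "gj", c("X", "Y"))$delta, 0)
  # X: i<j in 3/4; Y: i<j in 1/4
  mix <- expression_matrix(rbind(c(1, 1, 1, 9, 9, 9, 9, 1),
                                 c(2, 2, 2, 2, 2, 2, 2, 2)),
                           ids, sprintf("s%d", 1:8))
  res3 <- tsp_delta(mix, labels, "gi", "gj", c("X", "Y"))
  expect_equal(res3$delta, 0.5)
  expect_equal(res3$delta,
               delta_oracle(unclass(mix), labels, "gi", "gj", "X", "Y"))
  expect_error(tsp_delta(m, labels, "gi", "gj", c("X", "Z")),
               "no samples")
})

test_that("two-class single-pair search equals exhaustive argmax delta", {
  set.seed(71)
  n_genes <- 20
  m <- random_matrix(n_genes, 40, seed = 71)
  labels <- rep(c("X", "Y"), 20)
  # shift a few genes to create order structure
  x <- unclass(m)
  x[1:3, labels == "X"] <- x[1:3, labels == "X"] + 1.5
  m <- expression_matrix(x, rownames(m), colnames(m))
  cands <- list(X = rownames(m)[1:10], Y = rownames(m)[11:20])
  built <- build_ktsp(m, labels, cands, k = 1,
                      comparison_order = list(c("X", "Y")))
  brute <- expand.grid(i = cands$X, j = cands$Y, stringsAsFactors = FALSE)
  brute$delta <- mapply(function(i, j)
    delta_oracle(x, labels, i, j, "X", "Y"), brute$i, brute$j)
  expect_equal(built$pairs$delta, max(brute$delta))
})

test_that("k-TSP construction yields disjoint pairs in the planned order", {
  sim <- small_sim(seed = 73)
  tk <- train_ktsp(sim$matrix, sim$labels, k = 2, n_top = 10, seed = 74)
  pr <- tk$classifier$pairs
  genes <- c(pr$gene_high, pr$gene_low)
  expect_equal(anyDuplicated(genes), 0)
  expect_equal(nrow(pr), 2 * choose(3, 2))
  # candidate exhaustion raises a named error
  tiny <- list(C1 = rownames(sim$matrix)[1:2],
               C2 = rownames(sim$matrix)[3:4],
               C3 = rownames(sim$matrix)[5:6])
  expect_error(build_ktsp(sim$matrix, sim$labels, tiny, k = 5),
               "candidate exhaustion")
})

test_that("comparison planning covers all pairs with priorities first", {
  cands <- list(A = letters[1:5], B = letters[6:8], C = letters[9:18],
                D = letters[19:22])
  plan <- plan_comparisons(cands, priority = c("B", "C"))
  expect_length(plan, choose(4, 2))
  expect_identical(plan[[1]][1], "B")
  # B's opponents ordered by ascending pool size: D(4), A(5), C(10)
  expect_identical(vapply(plan[1:3], `[`, "", 2), c("D", "A", "C"))
  keys <- vapply(plan, function(p) paste(sort(p), collapse = "|"), "")
  expect_setequal(keys, apply(combn(names(cands), 2), 2, paste,
                              collapse = "|"))
})

test_that("voting rule handles clear wins, missing genes and ties", {
  pairs <- data.frame(
    gene_high = c("g1", "g3", "g5"),
    gene_low = c("g2", "g4", "g6"),
    class_x = c("A", "A", "B"),
    class_y = c("B", "C", "C"),
    vote_if_high_gt_low = c("A", "A", "B"),
    vote_otherwise = c("B", "C", "C"),
    delta = 1, gamma = 1, stringsAsFactors = FALSE)
  cls <- structure(list(pairs = pairs, k = 1, classes = c("A", "B", "C")),
                   class = "ktsp_classifier")
  # wins every pair for A
  x <- c(g1 = 5, g2 = 1, g3 = 5, g4 = 1, g5 = 1, g6 = 5)
  expect_identical(ktsp_classify(x, cls), "A")
  # all three comparisons lost by the voted class: three-way tie 1/2 each
  y <- c(g1 = 5, g2 = 1, g3 = 1, g4 = 5, g5 = 5, g6 = 1)
  # A beats B, C beats A, B beats C -> every class at 1/2
  expect_identical(ktsp_classify(y, cls), UNASSIGNED)
  # missing genes: only the A-vs-B pair evaluable
  z <- c(g1 = 5, g2 = 1)
  expect_identical(ktsp_classify(z, cls), "A")
  expect_error(ktsp_classify(c(g9 = 1), cls), "no evaluable")
})

test_that("two-way ties are resolved by the head-to-head comparison", {
  pairs <- data.frame(
    gene_high = c("g1", "g3", "g5", "g7"),
    gene_low = c("g2", "g4", "g6", "g8"),
    class_x = c("A", "A", "A", "B"),
    class_y = c("B", "B", "C", "C"),
    vote_if_high_gt_low = c("A", "B", "A", "B"),
    vote_otherwise = c("B", "A", "C", "C"),
    delta = 1, gamma = 1, stringsAsFactors = FALSE)
  cls <- structure(list(pairs = pairs, k = 2, classes = c("A", "B", "C")),
                   class = "ktsp_classifier")
  # A and B split their comparison 1/2-1/2; A beats C, B beats C;
  # A and B tie overall at 3/4 and head-to-head at 1/2: unassigned
  x <- c(g1 = 5, g2 = 1, g3 = 5, g4 = 1, g5 = 5, g6 = 1, g7 = 5, g8 = 1)
  expect_identical(ktsp_classify(x, cls), UNASSIGNED)
  # drop one A-vs-B pair: head-to-head now goes to A
  cls2 <- cls
  cls2$pairs <- pairs[-2, ]
  expect_identical(ktsp_classify(x[-(3:4)], cls2), "A")
})

test_that("classification is invariant under monotone transforms", {
  sim <- small_sim(seed = 75)
  tk <- train_ktsp(sim$matrix, sim$labels, k = 2, n_top = 10, seed = 76)
  calls <- ktsp_classify(unclass(sim$matrix), tk$classifier)
  warped <- apply(unclass(sim$matrix), 2, function(v) exp(v / 2) + v^3)
  rownames(warped) <- rownames(sim$matrix)
  calls2 <- ktsp_classify(warped, tk$classifier)
  expect_identical(calls, calls2)
  expect_true(all(calls %in% c(tk$classifier$classes, UNASSIGNED)))
})

test_that("pair genes convert to disjoint per-class signatures", {
  sim <- small_sim(seed = 77)
  tk <- train_ktsp(sim$matrix, sim$labels, k = 1, n_top = 10, seed = 78)
  sig <- tsp_to_ntp_signatures(tk$classifier)
  expect_s3_class(sig, "gene_signature_set")
  expect_true(all(vapply(sig, length, 0L) == 1 * (3 - 1)))
})

test_that("classifier TSV round-trips", {
  sim <- small_sim(seed = 79)
  tk <- train_ktsp(sim$matrix, sim$labels, k = 2, n_top = 10, seed = 80)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ktsp(tk$classifier, path)
  back <- read_ktsp(path)
  expect_equal(back$pairs$gene_high, tk$classifier$pairs$gene_high)
  expect_equal(back$k, tk$classifier$k)
  calls1 <- ktsp_classify(unclass(sim$matrix), tk$classifier)
  calls2 <- ktsp_classify(unclass(sim$matrix), back)
  expect_identical(calls1, calls2)
})

test_that("stratified split preserves class proportions", {
  labels <- setNames(rep(c("A", "B", "C"), times = c(30, 60, 90)),
                     sprintf("s%03d", 1:180))
  sp <- stratified_split(labels, train_fraction = 2 / 3, seed = 81)
  expect_setequal(c(sp$train, sp$test), names(labels))
  tr <- table(labels[sp$train])
  expect_equal(as.numeric(tr / table(labels)), rep(2 / 3, 3),
               tolerance = 0.05)
})
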