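# fixture builders and independent oracles shared across test files

random_matrix <- function(n_genes, n_samples, seed = 1) {
  set.seed(seed)
  expression_matrix(
    matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples),
    sprintf("g%03d", seq_len(n_genes)),
    sprintf("s%03d", seq_len(n_samples)))
}

# small 3-class simulation used by several module tests
small_sim <- function(seed = 7) {
  simulate_expression(
    subtype_model(n_classes = 3, markers_per_class = 10, effect_size = 3,
                  n_background_genes = 60, noise_sd = 0.5,
                  stromal_program = rep(4, 10)),
    n_samples_per_class = 15, seed = seed)
}

# brute-force BH step-up: q_i = min over j >= rank(i) of n * p_(j) / j
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    r <- which(o == i)
    q[i] <- min(1, min(n * p[o][r:n] / (r:n)))
  }
  q
}

# unweighted running-sum enrichment score (classical KS form)
es_oracle <- function(hit) {
  n <- length(hit)
  nh <- sum(hit)
  running <- cumsum(ifelse(hit, 1 / nh, -1 / (n - nh)))
  running[which.max(abs(running))]
}

# map discovered class labels to planted classes by marker overlap
map_classes <- function(discovered, planted) {
  ov <- sapply(discovered, function(g)
    sapply(planted, function(p) length(intersect(g, p))))
  stats::setNames(rownames(ov)[apply(ov, 2, which.max)], colnames(ov))
}

# direct-counting delta oracle: P(i<j) per class, ties 0.5
delta_oracle <- function(x, labels, gi, gj, cx, cy) {
  p <- function(cl) {
    s <- labels == cl
    mean((x[gi, s] < x[gj, s]) + 0.5 * (x[gi, s] == x[gj, s]))
  }
  abs(p(cx) - p(cy))
}
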