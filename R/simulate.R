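#' Define a latent subtype model for synthetic expression data
#'
#' The generator emulates the structure the pipeline assumes: K latent
#' subtypes each over-expressing a disjoint block of marker genes, a block
#' of stromal-program genes mixed into every sample in proportion to its
#' stromal content, and uninformative background genes.
#'
#' Expression is simulated on the log2 scale as a convex mixture,
#' `(1 - f_s) * cancer + f_s * stroma + noise`, a linear approximation of
#' stromal contamination applied directly to log-scale values.
#'
#' @param n_classes number of latent subtypes (>= 2).
#' @param markers_per_class marker genes over-expressed per subtype.
#' @param effect_size mean log2 shift of a marker gene in its own class.
#' @param n_background_genes uninformative genes.
#' @param noise_sd sd of the additive Gaussian measurement noise.
#' @param stromal_program log2 expression of the stromal program over the
#'   stromal gene block (length = number of stromal genes).
#' @param stromal_fraction_range `c(lo, hi)` in [0, 1]; each sample's
#'   stromal mixing fraction f_s is drawn uniformly from this range.
#' @return an object of class `subtype_model`.
#' @export
subtype_model <- function(n_classes = 5, markers_per_class = 30,
                          effect_size = 3, n_background_genes = 500,
                          noise_sd = 0.5, stromal_program = rep(4, 40),
                          stromal_fraction_range = c(0, 0.3)) {
  stopifnot(n_classes >= 2, markers_per_class >= 1, n_background_genes >= 0)
  if (effect_size < 0) stop("effect_size must be >= 0")
  r <- stromal_fraction_range
  if (length(r) != 2 || any(r < 0 | r > 1) || r[1] > r[2]) {
    stop("stromal_fraction_range must be [lo, hi] within [0, 1]")
  }
  structure(list(n_classes = n_classes,
                 markers_per_class = markers_per_class,
                 effect_size = effect_size,
                 n_background_genes = n_background_genes,
                 noise_sd = noise_sd,
                 stromal_program = as.numeric(stromal_program),
                 stromal_fraction_range = r),
            class = "subtype_model")
}

#' Simulate a subtype-structured expression matrix
#'
#' @param model a [subtype_model()].
#' @param n_samples_per_class samples simulated per subtype (default 40).
#' @param seed integer seed for reproducibility.
#' @return list with `matrix` (the expression_matrix), `labels` (named
#'   character vector of true classes), `stromal_fractions` (per-gene
#'   data.frame with the expected share of signal of stromal origin),
#'   `sample_stromal_fraction` (per-sample f_s), `marker_sets` (the planted
#'   [gene_signature_set()]) and `stromal_genes`.
#' @export
simulate_expression <- function(model, n_samples_per_class = 40,
                                seed = NULL) {
  stopifnot(inherits(model, "subtype_model"))
  if (n_samples_per_class < 1) stop("need at least one sample per class")
  if (!is.null(seed)) set.seed(seed)
  K <- model$n_classes
  classes <- paste0("C", seq_len(K))
  n_markers <- K * model$markers_per_class
  n_stromal <- length(model$stromal_program)
  marker_ids <- unlist(lapply(seq_len(K), function(k)
    sprintf("MK%d_%03d", k, seq_len(model$markers_per_class))))
  stromal_ids <- if (n_stromal) sprintf("STR_%03d", seq_len(n_stromal)) else character()
  bg_ids <- if (model$n_background_genes)
    sprintf("BG_%04d", seq_len(model$n_background_genes)) else character()
  genes <- c(marker_ids, stromal_ids, bg_ids)
  n <- K * n_samples_per_class
  samples <- sprintf("S%03d", seq_len(n))
  labels <- stats::setNames(rep(classes, each = n_samples_per_class), samples)

  # cancer component: marker blocks shifted up in their own class
  cancer <- matrix(0, length(genes), n, dimnames = list(genes, samples))
  for (k in seq_len(K)) {
    rows <- ((k - 1) * model$markers_per_class + 1):(k * model$markers_per_class)
    cancer[rows, labels == classes[k]] <- model$effect_size
  }
  # stromal component: the stromal program, identical in every sample
  stroma <- matrix(0, length(genes), n, dimnames = list(genes, samples))
  if (n_stromal) stroma[stromal_ids, ] <- model$stromal_program

  f_s <- stats::runif(n, model$stromal_fraction_range[1],
                      model$stromal_fraction_range[2])
  names(f_s) <- samples
  mix <- sweep(cancer, 2, 1 - f_s, `*`) + sweep(stroma, 2, f_s, `*`)
  noise <- matrix(stats::rnorm(length(mix), sd = model$noise_sd),
                  nrow(mix), ncol(mix))
  m <- expression_matrix(mix + noise, genes, samples)

  # expected share of each gene's signal that is of stromal origin
  f_bar <- mean(model$stromal_fraction_range)
  cancer_strength <- stats::setNames(rep(0, length(genes)), genes)
  cancer_strength[marker_ids] <- model$effect_size
  stromal_strength <- stats::setNames(rep(0, length(genes)), genes)
  if (n_stromal) stromal_strength[stromal_ids] <- abs(model$stromal_program)
  denom <- f_bar * stromal_strength + (1 - f_bar) * cancer_strength
  frac <- ifelse(denom > 0, f_bar * stromal_strength / denom, 0)

  marker_sets <- gene_signature_set(stats::setNames(
    lapply(seq_len(K), function(k)
      marker_ids[((k - 1) * model$markers_per_class + 1):
                   (k * model$markers_per_class)]),
    classes))

  list(matrix = m,
       labels = labels,
       stromal_fractions = data.frame(gene = genes, fraction = unname(frac),
                                      stringsAsFactors = FALSE),
       sample_stromal_fraction = f_s,
       marker_sets = marker_sets,
       stromal_genes = stromal_ids)
}

#' Replicate an expression matrix across simulated platforms
#'
#' Each platform applies a strictly increasing per-platform distortion
#' (shift, positive scale and a cubic term) plus Gaussian noise, so
#' within-sample gene ranks are preserved in expectation while absolute
#' values differ across platforms.
#'
#' @param matrix an [expression_matrix()].
#' @param n_platforms number of platforms (>= 2).
#' @param distortion list with `shift_range`, `scale_range` (per-platform
#'   affine terms; scales must be positive), `cubic` (max cubic
#'   coefficient, default 0.02) and `noise_sd` (per-platform measurement
#'   noise, default 0.3). Setting shift 0, scale 1, cubic 0 and noise 0
#'   reproduces the input identically.
#' @param seed integer seed.
#' @return list of expression matrices, one per platform, sharing the gene
#'   space of the input.
#' @export
simulate_multiplatform <- function(matrix, n_platforms,
                                   distortion = list(), seed = NULL) {
  m <- as_expr(matrix)
  if (n_platforms < 2) stop("need at least 2 platforms")
  if (!is.null(seed)) set.seed(seed)
  d <- utils::modifyList(list(shift_range = c(-1, 1),
                              scale_range = c(0.5, 2),
                              cubic = 0.02, noise_sd = 0.3), distortion)
  if (any(d$scale_range <= 0)) stop("scales must be positive (monotone)")
  lapply(seq_len(n_platforms), function(p) {
    a <- stats::runif(1, d$shift_range[1], d$shift_range[2])
    b <- stats::runif(1, d$scale_range[1], d$scale_range[2])
    cc <- stats::runif(1, 0, d$cubic)
    noise_sd <- d$noise_sd
    v <- a + b * unclass(m) + cc * unclass(m)^3
    if (noise_sd > 0) {
      v <- v + matrix(stats::rnorm(length(v), sd = noise_sd),
                      nrow(v), ncol(v))
    }
    expression_matrix(v, rownames(m), colnames(m),
                      platform = paste0("platform", p))
  })
}

#' Simulate segmented copy-number profiles
#'
#' Per sample, random breakpoints tile a single synthetic chromosome; a
#' random subset of segments totalling approximately `altered_fraction` of
#' the genome receives |segment mean| = `amplitude`, the rest stay near 0.
#'
#' @param n_samples number of samples.
#' @param genome_length genome size in nucleotides (default 3e6, a
#'   scaled-down genome for fast tests).
#' @param altered_fraction target fraction of nucleotides altered, in [0,1].
#' @param amplitude absolute segment mean of altered segments.
#' @param seed integer seed.
#' @param segments_per_sample segments tiling the genome (default 50).
#' @return data.frame in SEG layout (sample_id, chromosome, start, end,
#'   n_markers, seg_mean).
#' @export
simulate_segments <- function(n_samples, genome_length = 3e6,
                              altered_fraction = 0.2, amplitude = 0.8,
                              seed = NULL, segments_per_sample = 50) {
  if (altered_fraction < 0 || altered_fraction > 1) {
    stop("altered_fraction must lie in [0, 1]")
  }
  if (amplitude <= 0.3 && altered_fraction > 0) {
    warning("amplitude <= 0.3: no segment will count as altered at the ",
            "default calling threshold")
  }
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    cuts <- sort(sample.int(genome_length - 1, segments_per_sample - 1))
    start <- c(1, cuts + 1)
    end <- c(cuts, genome_length)
    len <- end - start + 1
    seg_mean <- stats::rnorm(segments_per_sample, 0, 0.05)
    target <- round(altered_fraction * genome_length)
    got <- 0
    extra <- NULL
    for (i in sample.int(segments_per_sample)) {
      if (got >= target) break
      need <- target - got
      if (len[i] <= need) {
        seg_mean[i] <- sample(c(-1, 1), 1) * amplitude
        got <- got + len[i]
      } else if (need >= 1) {
        # split the boundary segment so the altered fraction is exact
        extra <- rbind(extra, data.frame(
          start = start[i] + need, end = end[i],
          seg_mean = seg_mean[i], stringsAsFactors = FALSE))
        end[i] <- start[i] + need - 1
        len[i] <- need
        seg_mean[i] <- sample(c(-1, 1), 1) * amplitude
        got <- target
      }
    }
    d <- data.frame(start = start, end = end, seg_mean = seg_mean,
                    stringsAsFactors = FALSE)
    if (!is.null(extra)) d <- rbind(d, extra)
    d <- d[order(d$start), ]
    out[[s]] <- data.frame(sample_id = sprintf("S%03d", s),
                           chromosome = "1", start = d$start, end = d$end,
                           n_markers = pmax(1L, as.integer(
                             (d$end - d$start + 1) / 1000)),
                           seg_mean = d$seg_mean,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate per-sample somatic mutation counts
#'
#' Counts are Poisson with mean `rate_per_mb * exome_mb`, so the derived
#' mutational load recovers `rate_per_mb` in expectation.
#'
#' @param n_samples number of samples.
#' @param rate_per_mb expected somatic mutations per megabase.
#' @param exome_mb exome size in megabases (default 30).
#' @param seed integer seed.
#' @return data.frame with columns sample_id, mutation_count.
#' @export
simulate_mutation_counts <- function(n_samples, rate_per_mb = 2,
                                     exome_mb = 30, seed = NULL) {
  if (rate_per_mb < 0) stop("rate_per_mb must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  data.frame(sample_id = sprintf("S%03d", seq_len(n_samples)),
             mutation_count = stats::rpois(n_samples, rate_per_mb * exome_mb),
             stringsAsFactors = FALSE)
}
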