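#' Per-sample mutational load
#'
#' Somatic mutation counts normalized by an approximate exome size, giving
#' mutations per megabase.
#'
#' @param mutation_counts data.frame with columns `sample_id` and
#'   `mutation_count`, or a named numeric vector of counts.
#' @param exome_mb exome size in megabases (default 30).
#' @return a [score_table()] of mutations per Mb.
#' @export
mutational_load <- function(mutation_counts, exome_mb = 30) {
  if (is.data.frame(mutation_counts)) {
    counts <- stats::setNames(mutation_counts$mutation_count,
                              mutation_counts$sample_id)
  } else {
    counts <- mutation_counts
  }
  if (anyDuplicated(names(counts))) stop("duplicate sample identifiers")
  if (any(counts < 0)) stop("negative mutation count")
  score_table(names(counts), counts / exome_mb, "mutational_load")
}

#' Per-sample copy-number alteration load
#'
#' Fraction of the profiled genome that is altered: the nucleotides covered
#' by segments with |segment mean| strictly greater than `threshold`,
#' relative to the nucleotides in all the sample's segments. Coordinates
#' are 1-based inclusive; segments overlapping within a sample make the
#' nucleotide count ambiguous and raise an error.
#'
#' @param segments data.frame as returned by [read_seg()] or
#'   [simulate_segments()].
#' @param threshold calling threshold on |segment mean| (default 0.3).
#' @return a [score_table()] of loads in [0, 1].
#' @export
copy_number_load <- function(segments, threshold = 0.3) {
  req <- c("sample_id", "chromosome", "start", "end", "seg_mean")
  if (!all(req %in% names(segments))) {
    stop("segments need columns: ", paste(req, collapse = ", "))
  }
  if (any(segments$end < segments$start)) stop("segment with end < start")
  loads <- vapply(split(segments, segments$sample_id), function(d) {
    for (chr in unique(d$chromosome)) {
      s <- d[d$chromosome == chr, ]
      s <- s[order(s$start), ]
      if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)])) {
        stop("overlapping segments in sample ", d$sample_id[1],
             " chromosome ", chr, ": nucleotide count ambiguous")
      }
    }
    len <- d$end - d$start + 1
    sum(len[abs(d$seg_mean) > threshold]) / sum(len)
  }, 0)
  score_table(names(loads), loads, "copy_number_load")
}
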