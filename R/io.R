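#' Read a GCT 1.2 expression matrix
#'
#' GCT is the tab-delimited matrix format used by the NTP/GSEA tool family:
#' a `#1.2` version line, a dimensions line, then a header row with `Name`,
#' `Description` and sample identifiers.
#'
#' @param path path to a GCT 1.2 file.
#' @return an [expression_matrix()].
#' @export
read_gct <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("GCT file too short: ", path)
  if (trimws(lines[1]) != "#1.2") {
    stop("line 1: expected GCT version header '#1.2', got '", lines[1], "'")
  }
  dims <- strsplit(trimws(lines[2]), "\t")[[1]]
  if (length(dims) < 2 || anyNA(suppressWarnings(as.integer(dims[1:2])))) {
    stop("line 2: expected '<n_genes>\\t<n_samples>'")
  }
  n_genes <- as.integer(dims[1])
  n_samples <- as.integer(dims[2])
  header <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  if (length(header) != n_samples + 2) {
    stop("line 3: header has ", length(header) - 2,
         " sample columns, dimensions line declares ", n_samples)
  }
  body <- lines[-(1:3)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n_genes) {
    stop("line 2: declared ", n_genes, " genes but file contains ",
         length(body), " data rows")
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 0L) != n_samples + 2)
  if (length(bad)) {
    stop("line ", bad[1] + 3, ": expected ", n_samples + 2, " fields, got ",
         length(fields[[bad[1]]]))
  }
  gene_ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(gene_ids)) {
    first_dup <- which(duplicated(gene_ids))[1]
    stop("line ", first_dup + 3, ": duplicate gene identifier '",
         gene_ids[first_dup], "'")
  }
  values <- matrix(NA_real_, n_genes, n_samples)
  for (i in seq_len(n_genes)) {
    values[i, ] <- as.numeric(fields[[i]][-(1:2)])
  }
  expression_matrix(values, gene_ids, header[-(1:2)])
}

#' Write an expression matrix as GCT 1.2
#'
#' @param matrix an [expression_matrix()] (or plain genes x samples matrix
#'   with dimnames).
#' @param path output path.
#' @param descriptions optional per-gene Description column; written as
#'   `"na"` when absent.
#' @return `path`, invisibly.
#' @export
write_gct <- function(matrix, path, descriptions = NULL) {
  m <- as_expr(matrix)
  if (is.null(descriptions)) descriptions <- rep("na", nrow(m))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(m), ncol(m), sep = "\t")), con)
  writeLines(paste(c("Name", "Description", colnames(m)), collapse = "\t"), con)
  body <- apply(unclass(m), 1, function(v)
    paste(format(v, digits = 15, trim = TRUE, scientific = FALSE),
          collapse = "\t"))
  writeLines(paste(rownames(m), descriptions, body, sep = "\t"), con)
  invisible(path)
}

#' Read a GMT gene signature set
#'
#' One class per line: name, description, then tab-separated gene ids.
#' Classes must be non-empty and mutually disjoint.
#'
#' @param path path to a GMT file.
#' @return a [gene_signature_set()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 0L) < 3)
  if (length(short)) {
    stop("line ", short[1], ": GMT line needs name, description and >=1 gene")
  }
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, "", 1L)
  gene_signature_set(sets)
}

#' Write a gene signature set as GMT
#'
#' @param sets a [gene_signature_set()].
#' @param path output path.
#' @param descriptions optional per-class descriptions (default `"na"`).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(inherits(sets, "gene_signature_set"))
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(name, desc, genes)
    paste(c(name, desc, genes), collapse = "\t"),
    names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Read a SEG segmented copy-number table
#'
#' Tab-delimited with header: Sample, Chromosome, Start, End, Num_Probes,
#' Segment_Mean. Coordinates are 1-based inclusive.
#'
#' @param path path to a SEG file.
#' @return data.frame with columns sample_id, chromosome, start, end,
#'   n_markers, seg_mean.
#' @export
read_seg <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(d) < 6) stop("SEG file needs 6 columns, found ", ncol(d))
  names(d)[1:6] <- c("sample_id", "chromosome", "start", "end",
                     "n_markers", "seg_mean")
  bad <- which(d$end < d$start)
  if (length(bad)) stop("segment with end < start at data row ", bad[1])
  d
}

#' Write segments as SEG
#' @param segments data.frame as returned by [read_seg()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_seg <- function(segments, path) {
  out <- segments[, c("sample_id", "chromosome", "start", "end",
                      "n_markers", "seg_mean")]
  names(out) <- c("Sample", "Chromosome", "Start", "End", "Num_Probes",
                  "Segment_Mean")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
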