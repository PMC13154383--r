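## Detection-filtered, length- and depth-normalised vOTU abundances.
##
## A vOTU is detected in a sample when the coverage breadth of its
## representative (fraction of positions covered by at least one read) is
## STRICTLY above 0.75. Detected read counts are normalised to reads per
## kbp of contig per million sample reads.

#' Coverage breadth from alignment intervals
#'
#' @param intervals data.frame with 0-based half-open `start`, `end` columns
#'   (or a 2-column matrix); overlapping intervals are merged before
#'   measuring.
#' @param contig_length_bp length of the contig.
#' @return fraction of positions covered, in `[0, 1]`.
#' @export
#' @examples
#' coverage_breadth(data.frame(start = c(0, 400), end = c(600, 1000)), 1000)
coverage_breadth <- function(intervals, contig_length_bp) {
  if (is.matrix(intervals)) {
    intervals <- data.frame(start = intervals[, 1], end = intervals[, 2])
  }
  if (is.null(intervals) || nrow(intervals) == 0) return(0)
  if (any(intervals$start < 0) || any(intervals$end > contig_length_bp) ||
      any(intervals$end <= intervals$start)) {
    stop("coverage interval outside [0, ", contig_length_bp,
         ") or empty; coordinates are 0-based half-open")
  }
  ir <- IRanges::reduce(IRanges::IRanges(start = intervals$start + 1L,
                                         end = intervals$end))
  sum(IRanges::width(ir)) / contig_length_bp
}

#' Detection by strict breadth threshold
#'
#' @param breadth coverage breadth in `[0, 1]`.
#' @param threshold detection threshold; detection requires
#'   `breadth > threshold` (strict, so exactly 0.75 is NOT detected).
#' @return logical.
#' @export
detect_votu <- function(breadth, threshold = 0.75) {
  stopifnot(all(breadth >= 0 & breadth <= 1))
  breadth > threshold
}

#' Length- and depth-normalised relative abundance
#'
#' reads / (length in kbp) / (millions of reads in the sample).
#'
#' @param read_count mapped reads.
#' @param length_bp contig (representative) length, > 0.
#' @param sample_total_reads total reads in the metagenome, > 0.
#' @return relative abundance (reads per kbp per million reads).
#' @export
#' @examples
#' normalize_abundance(1000, 10000, 1e7)  # 10
normalize_abundance <- function(read_count, length_bp, sample_total_reads) {
  if (any(length_bp <= 0)) stop("length_bp must be positive")
  if (any(sample_total_reads <= 0)) stop("sample_total_reads must be positive")
  read_count / (length_bp / 1000) / (sample_total_reads / 1e6)
}

#' Build the vOTU x sample abundance matrix
#'
#' Sums mapped reads over all member contigs of each vOTU per sample,
#' evaluates breadth on the representative, zeroes non-detected cells in the
#' normalised matrix, and keeps the raw per-vOTU count matrix untouched for
#' the temporal pipeline (which uses counts regardless of breadth).
#'
#' @param counts data.frame in the `read_counts` schema
#'   (`sample_id`, `contig_id`, `reads`).
#' @param coverage data.frame in the `coverage` schema
#'   (`sample_id`, `contig_id`, `start`, `end`).
#' @param votus a `votu_set`.
#' @param contig_lengths named integer vector of contig lengths (bp).
#' @param sample_depths named numeric vector: total reads per sample; every
#'   sample in `counts` must be present.
#' @param breadth_threshold strict detection threshold (default 0.75).
#' @return object of class `abundance_matrix`: list with `values`
#'   (normalised, detection-filtered vOTU x sample matrix), `detected`
#'   (logical matrix), `counts` (unfiltered vOTU x sample counts),
#'   `breadth`, `lengths` (representative lengths), `sample_depths`.
#' @export
build_abundance_matrix <- function(counts, coverage, votus, contig_lengths,
                                   sample_depths, breadth_threshold = 0.75) {
  stopifnot(inherits(votus, "votu_set"))
  missing_s <- setdiff(unique(counts$sample_id), names(sample_depths))
  if (length(missing_s)) {
    stop("sample present in counts but absent from metadata/depths: ",
         missing_s[1])
  }
  samples <- names(sample_depths)
  vt <- votus$votus
  assign <- setNames(votus$assignment$votu_id, votus$assignment$contig_id)
  rep_len <- setNames(as.numeric(contig_lengths[vt$representative]), vt$votu_id)

  cmat <- matrix(0, nrow = nrow(vt), ncol = length(samples),
                 dimnames = list(vt$votu_id, samples))
  known <- counts$contig_id %in% names(assign)
  cc <- counts[known, , drop = FALSE]
  if (nrow(cc)) {
    vids <- assign[cc$contig_id]
    agg <- aggregate(list(reads = cc$reads),
                     by = list(votu = vids, sample = cc$sample_id), FUN = sum)
    cmat[cbind(agg$votu, agg$sample)] <- agg$reads
  }

  bmat <- matrix(0, nrow = nrow(vt), ncol = length(samples),
                 dimnames = list(vt$votu_id, samples))
  cov_rep <- coverage[coverage$contig_id %in% vt$representative, , drop = FALSE]
  if (nrow(cov_rep)) {
    key <- split(cov_rep, list(cov_rep$contig_id, cov_rep$sample_id), drop = TRUE)
    for (g in key) {
      vid <- vt$votu_id[match(g$contig_id[1], vt$representative)]
      bmat[vid, g$sample_id[1]] <-
        coverage_breadth(g, contig_lengths[[g$contig_id[1]]])
    }
  }
  detected <- detect_votu(bmat, breadth_threshold)
  values <- normalize_abundance(cmat, matrix(rep_len, nrow = nrow(cmat),
                                             ncol = ncol(cmat)),
                                matrix(sample_depths, nrow = nrow(cmat),
                                       ncol = ncol(cmat), byrow = TRUE))
  values[!detected] <- 0
  hv_log("build_matrix", votus = nrow(cmat), samples = ncol(cmat),
         detected_cells = sum(detected))
  out <- list(values = values, detected = detected, counts = cmat,
              breadth = bmat, lengths = rep_len, sample_depths = sample_depths,
              breadth_threshold = breadth_threshold)
  class(out) <- "abundance_matrix"
  out
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat("abundance_matrix: ", nrow(x$values), " vOTUs x ", ncol(x$values),
      " samples; ", sum(x$detected), " detected cells (breadth > ",
      x$breadth_threshold, ")\n", sep = "")
  invisible(x)
}
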