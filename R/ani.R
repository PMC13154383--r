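## Average nucleotide identity between two contigs.
##
## Seed-and-extend on exact k-mer matches: seeds sharing a diagonal are merged
## and extended without gaps under an X-drop rule; ANI is the match fraction
## over all retained block columns (gap-free blocks, so gap-excluded by
## construction) and the aligned fraction is the unioned block footprint on
## the SHORTER sequence. Both strands are seeded because assembly strand is
## arbitrary; the better-scoring strand is reported.

hv_char_codes <- function(seq) as.integer(charToRaw(toupper(seq)))

hv_revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

## all k-mers of a sequence as character vector (position i -> kmer at i)
hv_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1), k:n)
}

## extend right from index `from` along match vector m (TRUE = match),
## returning the furthest index with X-drop termination
hv_extend <- function(m, from, step, xdrop = 30L, match_s = 1L, mis_s = -2L) {
  n <- length(m)
  idx <- if (step > 0) seq(from, n, by = 1L) else seq(from, 1L, by = -1L)
  if (!length(idx)) return(from - step)
  sc <- cumsum(ifelse(m[idx], match_s, mis_s))
  best <- cummax(sc)
  stop_at <- which(best - sc > xdrop)
  upto <- if (length(stop_at)) stop_at[1] - 1L else length(idx)
  if (upto < 1L) return(from - step)
  idx[which.max(sc[seq_len(upto)])]
}

## score all alignment blocks of query (codes qc, kmers qk) against a target
## index; returns per-block (matches, length, q_start, q_end)
hv_blocks_one_strand <- function(tc, t_kmers, qc, qk, k, min_block, xdrop = 30L) {
  hit <- match(qk, t_kmers)            # first occurrence; repeats are rare
  qpos <- which(!is.na(hit))
  if (!length(qpos)) return(NULL)
  tpos <- hit[qpos]
  diag <- tpos - qpos
  out <- list()
  nT <- length(tc); nQ <- length(qc)
  for (d in unique(diag)) {
    q0 <- max(1L, 1L - d); q1 <- min(nQ, nT - d)
    if (q1 - q0 + 1L < min_block) next
    m <- tc[(q0:q1) + d] == qc[q0:q1]
    sp <- qpos[diag == d]
    ## merge seed intervals (query coords, relative to overlap window)
    iv <- unname(cbind(sp, pmin(sp + k - 1L, q1))) - q0 + 1L
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    merged <- list(); cur <- iv[1, ]
    if (nrow(iv) > 1) for (i in 2:nrow(iv)) {
      if (iv[i, 1] <= cur[2] + 200L) cur[2] <- max(cur[2], iv[i, 2])
      else { merged[[length(merged) + 1L]] <- cur; cur <- iv[i, ] }
    }
    merged[[length(merged) + 1L]] <- cur
    for (b in merged) {
      lo <- hv_extend(m, b[1], -1L, xdrop)
      hi <- hv_extend(m, b[2], +1L, xdrop)
      if (hi - lo + 1L < min_block) next
      out[[length(out) + 1L]] <- c(matches = sum(m[lo:hi]),
                                   len = hi - lo + 1L,
                                   q_start = unname(lo) + q0 - 1L,
                                   q_end = unname(hi) + q0 - 1L)
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

## union length of [start, end] integer intervals (1-based closed)
hv_union_len <- function(starts, ends) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  tot <- 0L; cs <- starts[1]; ce <- ends[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= ce + 1L) ce <- max(ce, ends[i])
    else { tot <- tot + (ce - cs + 1L); cs <- starts[i]; ce <- ends[i] }
  }
  tot + (ce - cs + 1L)
}

#' Pairwise average nucleotide identity and aligned fraction
#'
#' Computes ANI (identity over aligned block columns) and the aligned
#' fraction of the shorter sequence, using k-mer-seeded ungapped block
#' alignment on both strands. These are the quantities thresholded at
#' 0.95 / 0.85 during vOTU dereplication.
#'
#' @param seq_a,seq_b nucleotide strings (non-empty).
#' @param kmer seed length (default 15).
#' @param min_block minimum retained block length in bp (default 100).
#' @param both_strands also seed against the reverse complement of `seq_b`.
#' @return list with elements `ani` and `aligned_fraction`, both in `[0, 1]`
#'   (`ani = NA` when no block passes `min_block`, with `aligned_fraction 0`).
#' @export
#' @examples
#' s <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE), collapse = "")
#' pairwise_ani(s, s)   # ani 1, aligned fraction 1
pairwise_ani <- function(seq_a, seq_b, kmer = 15L, min_block = 100L,
                         both_strands = TRUE) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  hv_ani_core(hv_seq_index(seq_a, kmer, with_rev = FALSE),
              hv_seq_index(seq_b, kmer, with_rev = both_strands),
              kmer, min_block, both_strands)
}

## prebuilt index of one sequence: byte codes + k-mers, both strands
hv_seq_index <- function(seq, kmer, with_rev = TRUE) {
  seq <- toupper(seq)
  out <- list(codes = hv_char_codes(seq), kmers = hv_kmers(seq, kmer))
  if (with_rev) {
    rc <- hv_revcomp(seq)
    out$rev_codes <- hv_char_codes(rc)
    out$rev_kmers <- hv_kmers(rc, kmer)
  }
  out
}

## ANI/AF between a target index and a query index (both prebuilt)
hv_ani_core <- function(target_idx, query_idx, kmer, min_block,
                        both_strands = TRUE) {
  res <- list(fwd = hv_blocks_one_strand(target_idx$codes, target_idx$kmers,
                                         query_idx$codes, query_idx$kmers,
                                         kmer, min_block))
  if (both_strands && !is.null(query_idx$rev_codes)) {
    res$rev <- hv_blocks_one_strand(target_idx$codes, target_idx$kmers,
                                    query_idx$rev_codes, query_idx$rev_kmers,
                                    kmer, min_block)
  }
  score <- vapply(res, function(b) if (is.null(b)) 0 else sum(b[, "matches"]),
                  numeric(1))
  best <- res[[which.max(score)]]
  short_len <- min(length(target_idx$codes), length(query_idx$codes))
  if (is.null(best) || max(score) == 0) {
    return(list(ani = NA_real_, aligned_fraction = 0))
  }
  ani <- sum(best[, "matches"]) / sum(best[, "len"])
  af <- hv_union_len(best[, "q_start"], best[, "q_end"]) / short_len
  list(ani = ani, aligned_fraction = min(af, 1))
}
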