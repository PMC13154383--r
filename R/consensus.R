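## Ensemble consensus over multiple virus predictors.
##
## Predictor outputs are concatenated, exact duplicate sequences collapsed,
## trimmed name-variants collapsed to the shortest variant, and the result
## filtered to contigs strictly longer than 10 kbp that were called by at
## least two distinct predictors.

#' Collapse predictor calls to one consensus record per base contig name
#'
#' Several provirus-trimming predictors emit shortened variants of a contig
#' under the same base name. Calls are grouped by base name (trim suffix
#' stripped), exact duplicate sequences are collapsed, the SHORTEST variant
#' is retained as the kept contig, and the supporting-predictor set is the
#' union over all variants of that base name. Ties among equally short
#' variants break lexicographically by contig id.
#'
#' @param calls data.frame in the `predictor_calls` schema
#'   (`contig_id`, `predictor`, `called_length_bp`).
#' @param contigs named character vector of contig sequences covering every
#'   called id (full-length and trimmed variants).
#' @param trim_delim delimiter separating base name from trim coordinates.
#' @return data.frame with one row per base name: `base_name`,
#'   `kept_contig_id`, `kept_length_bp`, `supporting_predictors`
#'   (comma-separated, sorted), `n_predictors`.
#' @export
dedupe_calls <- function(calls, contigs, trim_delim = "||") {
  stopifnot(is.data.frame(calls))
  unknown <- setdiff(unique(calls$contig_id), names(contigs))
  if (length(unknown)) {
    stop("call references unknown contig: ", unknown[1])
  }
  if (nrow(calls) == 0) {
    return(data.frame(base_name = character(0), kept_contig_id = character(0),
                      kept_length_bp = integer(0),
                      supporting_predictors = character(0),
                      n_predictors = integer(0)))
  }
  calls <- calls[order(calls$contig_id, calls$predictor), , drop = FALSE]
  ## exact duplicate sequences under different ids collapse to one canonical
  ## id (first lexicographically); canonical strand only, reverse complements
  ## are distinct on purpose
  called_ids <- sort(unique(calls$contig_id))
  seqs <- unname(contigs[called_ids])
  canon <- called_ids[match(seqs, seqs)]   # first (lexicographic) id per sequence
  calls$contig_id <- canon[match(calls$contig_id, called_ids)]
  calls$base <- base_name(calls$contig_id, trim_delim)

  res <- lapply(split(calls, calls$base), function(g) {
    ids <- unique(g$contig_id)
    lens <- nchar(contigs[ids])
    keep <- ids[order(lens, ids)][1]
    preds <- sort(unique(g$predictor))
    data.frame(base_name = g$base[1], kept_contig_id = keep,
               kept_length_bp = unname(lens[keep]),
               supporting_predictors = paste(preds, collapse = ","),
               n_predictors = length(preds))
  })
  out <- do.call(rbind, res)
  out <- out[order(out$base_name), , drop = FALSE]
  rownames(out) <- NULL
  hv_log("dedupe_calls", calls_in = nrow(calls), records_out = nrow(out))
  out
}

#' Filter consensus records by length and predictor vote
#'
#' A contig passes when its kept length is STRICTLY greater than
#' `min_length` (default 10,000 bp) and at least `min_tools` distinct
#' predictors called it (default 2). The vote counts distinct predictors,
#' not calls.
#'
#' @param records output of [dedupe_calls()].
#' @param min_length minimum length, exclusive (bp).
#' @param min_tools minimum number of distinct supporting predictors.
#' @return `records` with logical `passed` and `fail_reason` in
#'   `{"none", "too_short", "insufficient_votes"}` (length checked first).
#' @export
consensus_filter <- function(records, min_length = 10000L, min_tools = 2L) {
  too_short <- records$kept_length_bp <= min_length
  few_votes <- records$n_predictors < min_tools
  records$passed <- !too_short & !few_votes
  records$fail_reason <- ifelse(too_short, "too_short",
                         ifelse(few_votes, "insufficient_votes", "none"))
  hv_log("consensus_filter", records_in = nrow(records),
         passed = sum(records$passed), too_short = sum(too_short),
         insufficient_votes = sum(few_votes & !too_short))
  records
}
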