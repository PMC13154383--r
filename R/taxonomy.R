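## Gene-level majority-rule taxonomy and source-environment assignment.
##
## A rank label is assigned when STRICTLY more than half of the annotated
## genes agree; the first rank without a strict majority and every deeper
## rank become "Unknown <deepest assigned ancestor>". The denominator is
## annotated genes only; genes without a hit never dilute the vote.

hv_ranks <- c("realm", "kingdom", "phylum", "class", "order", "family")

hv_environments <- c("marine", "freshwater", "non-marine saline/alkaline",
                     "unknown")

#' Majority-rule lineage for one vOTU
#'
#' Walks ranks from realm to family. The vote denominator is the number of
#' annotated genes (genes with any lineage label); at each rank the label
#' carried by strictly more than `majority` of the annotated genes is
#' assigned. At the first *contested* rank (votes exist but none exceeds
#' the threshold) the lineage becomes `"Unknown <deepest assigned>"` for
#' that rank and everything below it. Ranks at which the reference lineages
#' simply carry no label (a common gap at e.g. order level) are marked
#' Unknown-qualified but do not stop deeper, fully supported ranks.
#'
#' @param gene_hits data.frame of per-gene reference lineages with columns
#'   `realm`, `kingdom`, `phylum`, `class`, `order`, `family` (NA where the
#'   reference lineage is partial). Zero rows yield a fully Unknown lineage.
#' @param majority vote threshold, strict (default 0.5).
#' @return named character vector over the six ranks.
#' @export
#' @examples
#' hits <- data.frame(realm = "Duplodnaviria", kingdom = "Heunggongvirae",
#'                    phylum = "Uroviricota", class = "Caudoviricetes",
#'                    order = NA, family = c(rep("Zobellviridae", 4), rep(NA, 6)))
#' assign_taxonomy(hits)   # class Caudoviricetes, family Unknown Caudoviricetes
assign_taxonomy <- function(gene_hits, majority = 0.5) {
  out <- setNames(rep(NA_character_, length(hv_ranks)), hv_ranks)
  lab_mat <- lapply(hv_ranks, function(r) {
    v <- gene_hits[[r]]
    if (is.null(v)) v <- rep(NA_character_, nrow(gene_hits))
    v[v == ""] <- NA
    v
  })
  names(lab_mat) <- hv_ranks
  annotated <- Reduce(`|`, lapply(lab_mat, function(v) !is.na(v)), FALSE)
  denom <- sum(annotated)
  if (denom > 0) {
    for (r in hv_ranks) {
      votes <- lab_mat[[r]][!is.na(lab_mat[[r]])]
      if (length(votes) / denom <= majority) next  # majority arithmetically
                                                   # impossible: reference gap
      tab <- sort(table(votes), decreasing = TRUE)
      if (tab[1] / denom > majority) out[[r]] <- names(tab)[1]
      else break                         # genuinely contested: stop below
    }
  }
  filled <- out
  last <- "Unknown"
  for (r in hv_ranks) {
    if (is.na(filled[[r]])) filled[[r]] <- if (last == "Unknown") "Unknown"
                                           else paste("Unknown", last)
    else last <- filled[[r]]
  }
  filled
}

## label with strictly > majority support among non-NA votes, else NA
## (used for flat single-label votes such as source environment)
hv_majority_label <- function(votes, majority) {
  votes <- votes[!is.na(votes) & votes != ""]
  if (!length(votes)) return(NA_character_)
  tab <- sort(table(votes), decreasing = TRUE)
  if (tab[1] / length(votes) > majority) names(tab)[1] else NA_character_
}

#' Majority-rule source environment for one vOTU
#'
#' Strict majority over the environment-labelled genes; anything else
#' (including no labels, or ties) is `"unknown"`. Labels outside the fixed
#' vocabulary (marine, freshwater, non-marine saline/alkaline, unknown) map
#' to unknown with a warning.
#'
#' @param gene_hits data.frame with an `environment` column (NA = unlabelled).
#' @param majority vote threshold, strict (default 0.5).
#' @return one of the four environment categories.
#' @export
assign_source_environment <- function(gene_hits, majority = 0.5) {
  env <- gene_hits$environment
  env <- env[!is.na(env) & env != ""]
  bad <- setdiff(unique(env), hv_environments)
  if (length(bad)) {
    warning("unrecognised environment label(s) mapped to unknown: ",
            paste(bad, collapse = ", "))
    env[env %in% bad] <- "unknown"
  }
  env <- env[env != "unknown"]
  if (!length(env)) return("unknown")
  lab <- hv_majority_label(env, majority)
  if (is.na(lab)) "unknown" else lab
}

#' Taxonomy and source environment for every vOTU
#'
#' By default votes are taken over the representative contig's genes;
#' set `pool_genes = TRUE` to pool annotations across all member contigs.
#'
#' @param gene_table data.frame in the `gene_taxonomy` schema.
#' @param votus a `votu_set`.
#' @param majority strict vote threshold.
#' @param pool_genes pool all members' genes instead of the representative's.
#' @return data.frame: one row per vOTU with the six rank columns,
#'   `environment`, and `n_genes` used in the vote.
#' @export
votu_taxonomy <- function(gene_table, votus, majority = 0.5,
                          pool_genes = FALSE) {
  stopifnot(inherits(votus, "votu_set"))
  vt <- votus$votus
  res <- lapply(seq_len(nrow(vt)), function(i) {
    ids <- if (pool_genes) {
      votus$assignment$contig_id[votus$assignment$votu_id == vt$votu_id[i]]
    } else vt$representative[i]
    hits <- gene_table[gene_table$contig_id %in% ids, , drop = FALSE]
    lin <- assign_taxonomy(hits, majority)
    env <- assign_source_environment(hits, majority)
    data.frame(votu_id = vt$votu_id[i], t(lin), environment = env,
               n_genes = nrow(hits))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  hv_log("taxonomy", votus = nrow(out),
         family_assigned = sum(!startsWith(out$family, "Unknown")))
  out
}
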