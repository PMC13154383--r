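## Dereplication of viral contigs into vOTUs at 95% ANI / 85% aligned
## fraction by greedy centroid clustering, longest contig first.

#' Cluster viral contigs into vOTUs
#'
#' Greedy centroid clustering: contigs are sorted by length descending (ties
#' by id), each contig is compared against the representatives founded so
#' far and joins the eligible representative (ANI >= `ani_min` AND aligned
#' fraction >= `af_min`) with the highest ANI (tie: earlier founded);
#' otherwise it founds a new vOTU. The partition is exhaustive and disjoint,
#' and the representative is always the longest member.
#'
#' @param contigs named character vector of passing viral contig sequences.
#' @param origin optional data.frame mapping `contig_id` to `sample_id` and
#'   `site` (used for metagenome/site membership).
#' @param ani_min,af_min clustering thresholds (defaults 0.95 / 0.85).
#' @param kmer,min_block seeding parameters passed to the ANI engine.
#' @param trim_delim trim-suffix delimiter used to derive the vOTU name
#'   from its representative's base contig name.
#' @return an object of class `votu_set`: list with `assignment`
#'   (data.frame `contig_id`, `votu_id`, `is_representative`), `votus`
#'   (data.frame `votu_id`, `representative`, `n_members`, `n_metagenomes`,
#'   `site_class`), and `params`.
#' @export
cluster_votus <- function(contigs, origin = NULL, ani_min = 0.95,
                          af_min = 0.85, kmer = 15L, min_block = 100L,
                          trim_delim = "||") {
  if (length(contigs) == 0) {
    out <- list(assignment = data.frame(contig_id = character(0),
                                        votu_id = character(0),
                                        is_representative = logical(0)),
                votus = data.frame(votu_id = character(0),
                                   representative = character(0),
                                   n_members = integer(0)),
                params = list(ani_min = ani_min, af_min = af_min))
    class(out) <- "votu_set"
    return(out)
  }
  ids <- names(contigs)
  lens <- nchar(contigs)
  ord <- order(-lens, ids)
  ids <- ids[ord]

  rep_idx <- list()      # per vOTU: prebuilt index of the representative
  rep_id <- character(0)
  assign_votu <- integer(length(ids))
  for (i in seq_along(ids)) {
    qidx <- hv_seq_index(contigs[[ids[i]]], kmer, with_rev = TRUE)
    best_votu <- 0L; best_ani <- -1
    for (v in seq_along(rep_idx)) {
      r <- hv_ani_core(rep_idx[[v]], qidx, kmer, min_block)
      if (!is.na(r$ani) && r$ani >= ani_min && r$aligned_fraction >= af_min &&
          r$ani > best_ani) {
        best_ani <- r$ani; best_votu <- v
      }
    }
    if (best_votu == 0L) {
      rep_idx[[length(rep_idx) + 1L]] <-
        list(codes = qidx$codes, kmers = qidx$kmers)
      rep_id <- c(rep_id, ids[i])
      best_votu <- length(rep_idx)
    }
    assign_votu[i] <- best_votu
  }
  ## vOTUs are named after their representative's base contig name so that
  ## downstream tables (host predictions, AMGs) can reference them stably
  votu_ids <- paste0("vOTU_", base_name(rep_id, trim_delim))
  assignment <- data.frame(contig_id = ids,
                           votu_id = votu_ids[assign_votu],
                           is_representative = ids == rep_id[assign_votu])
  votus <- data.frame(votu_id = votu_ids, representative = rep_id,
                      n_members = as.integer(table(assign_votu)[as.character(seq_along(rep_id))]))
  if (!is.null(origin)) {
    m <- merge(assignment, origin, by = "contig_id")
    mm <- tapply(m$sample_id, m$votu_id, function(x) length(unique(x)))
    sites <- tapply(m$site, m$votu_id, function(x) sort(unique(x)))
    votus$n_metagenomes <- as.integer(mm[votus$votu_id])
    votus$site_class <- vapply(sites[votus$votu_id], function(s) {
      if (length(s) > 1) "both" else paste0(s, "-only")
    }, character(1))
  }
  out <- list(assignment = assignment, votus = votus,
              params = list(ani_min = ani_min, af_min = af_min,
                            kmer = kmer, min_block = min_block))
  class(out) <- "votu_set"
  hv_log("cluster_votus", contigs_in = length(contigs), votus = nrow(votus))
  out
}

#' @export
print.votu_set <- function(x, ...) {
  cat("vOTU set: ", nrow(x$votus), " vOTUs from ", nrow(x$assignment),
      " contigs (ANI >= ", x$params$ani_min, ", AF >= ", x$params$af_min,
      ")\n", sep = "")
  if ("site_class" %in% names(x$votus)) {
    print(table(x$votus$site_class))
  }
  invisible(x)
}

#' @export
summary.votu_set <- function(object, ...) summarize_membership(object)

#' Summarise cross-sample and cross-site membership of vOTUs
#'
#' For each vOTU, the number of distinct metagenomes contributing members and
#' its site class (one site only, or both); aggregates report counts per site
#' class and, for each number of metagenomes, the fraction of vOTUs with
#' members from both sites (the quantity that rises with metagenome count in
#' well-mixed systems).
#'
#' @param votus a `votu_set` built with an `origin` table.
#' @return list with `per_votu` (data.frame), `site_class_counts` (table),
#'   `site_class_fractions`, and `both_fraction_by_n` (data.frame
#'   `n_metagenomes`, `n_votus`, `fraction_both`).
#' @export
summarize_membership <- function(votus) {
  stopifnot(inherits(votus, "votu_set"))
  v <- votus$votus
  if (!"site_class" %in% names(v)) {
    stop("votu_set was built without an origin table; membership unknown")
  }
  counts <- table(v$site_class)
  byn <- aggregate(list(n_votus = v$votu_id), by = list(n_metagenomes = v$n_metagenomes),
                   FUN = length)
  fb <- tapply(v$site_class == "both", v$n_metagenomes, mean)
  byn$fraction_both <- as.numeric(fb[as.character(byn$n_metagenomes)])
  list(per_votu = v[, c("votu_id", "n_metagenomes", "site_class")],
       site_class_counts = counts,
       site_class_fractions = counts / sum(counts),
       both_fraction_by_n = byn)
}
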