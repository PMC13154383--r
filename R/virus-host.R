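## Virus-host prediction filtering and the order-level bipartite network.
##
## Host predictions may target arbitrary reference genomes; only matches
## between clustered vOTUs and quality-passing MAGs are retained. The MAG
## table is expected to have had viral contigs excluded before binning
## (an upstream precondition, not a step implemented here).

#' Classify MAG quality from completion and contamination
#'
#' high: completion > 90 AND contamination < 5;
#' medium: completion > 50 AND contamination < 10 (and not high);
#' otherwise fail (excluded downstream). Boundaries are strict.
#'
#' @param mags data.frame in the `mags` schema (`mag_id`, `completion`,
#'   `contamination`, lineage columns).
#' @return `mags` with a `quality` column in `{"high", "medium", "fail"}`.
#' @export
#' @examples
#' classify_mags(data.frame(mag_id = c("a", "b", "c"),
#'                          completion = c(95, 90, 49),
#'                          contamination = c(4, 4, 2)))$quality
classify_mags <- function(mags) {
  if (any(mags$completion < 0 | mags$completion > 100) ||
      any(mags$contamination < 0 | mags$contamination > 100)) {
    stop("completion/contamination must be percentages in [0, 100]")
  }
  high <- mags$completion > 90 & mags$contamination < 5
  medium <- !high & mags$completion > 50 & mags$contamination < 10
  mags$quality <- ifelse(high, "high", ifelse(medium, "medium", "fail"))
  hv_log("classify_mags", mags_in = nrow(mags), high = sum(high),
         medium = sum(medium), fail = sum(mags$quality == "fail"))
  mags
}

#' Filter host predictions to vOTU-MAG edges
#'
#' Keeps only predictions whose virus is a clustered vOTU and whose host is
#' a quality-passing MAG (high or medium); duplicate vOTU-MAG pairs collapse
#' to the best-scoring row. Edges are annotated with host order/class and,
#' when supplied, the vOTU's temporal cluster and site class.
#'
#' @param predictions data.frame in the `host_predictions` schema
#'   (`votu_id`, `host_genome`, `score`).
#' @param votus a `votu_set`.
#' @param mags output of [classify_mags()].
#' @param votu_clusters optional named vector: vOTU id -> temporal cluster.
#' @return data.frame of host edges: `votu_id`, `mag_id`, `host_order`,
#'   `host_class`, `score`, `votu_cluster`, `votu_site_class`.
#' @export
filter_host_predictions <- function(predictions, votus, mags,
                                    votu_clusters = NULL) {
  stopifnot(inherits(votus, "votu_set"))
  pass <- mags[mags$quality %in% c("high", "medium"), , drop = FALSE]
  keep <- predictions$votu_id %in% votus$votus$votu_id &
          predictions$host_genome %in% pass$mag_id
  dropped <- sum(!keep)
  e <- predictions[keep, , drop = FALSE]
  if (nrow(e)) {
    ## best score per vOTU-MAG pair
    e <- e[order(e$votu_id, e$host_genome, -e$score), , drop = FALSE]
    e <- e[!duplicated(e[, c("votu_id", "host_genome")]), , drop = FALSE]
  }
  mi <- match(e$host_genome, pass$mag_id)
  vi <- match(e$votu_id, votus$votus$votu_id)
  n_e <- nrow(e)
  out <- data.frame(votu_id = e$votu_id, mag_id = e$host_genome,
                    host_order = pass$order[mi], host_class = pass$class[mi],
                    score = e$score,
                    votu_cluster = if (is.null(votu_clusters)) rep(NA, n_e)
                                   else unname(votu_clusters[e$votu_id]),
                    votu_site_class =
                      if ("site_class" %in% names(votus$votus))
                        votus$votus$site_class[vi] else rep(NA, n_e))
  rownames(out) <- NULL
  hv_log("filter_host_predictions", predictions_in = nrow(predictions),
         edges = nrow(out), dropped = dropped)
  out
}

#' Order-level summary of the virus-host network
#'
#' Per host order: numbers of MAGs and vOTUs; overall distinct counts; and
#' the list of vOTUs linked to more than one host order (with whether the
#' orders span phyla/classes). Multi-order detection is idempotent under
#' edge duplication and independent of edge order.
#'
#' @param edges output of [filter_host_predictions()].
#' @param mag_abundance optional named vector of MAG total relative
#'   abundances (summed into the per-order table when given).
#' @return list: `per_order` (data.frame), `n_votus`, `n_mags`,
#'   `multi_order` (data.frame `votu_id`, `orders`, `classes`,
#'   `spans_class`).
#' @export
host_network_summary <- function(edges, mag_abundance = NULL) {
  if (nrow(edges) == 0) {
    return(list(per_order = data.frame(host_order = character(0),
                                       n_mags = integer(0),
                                       n_votus = integer(0)),
                n_votus = 0L, n_mags = 0L,
                multi_order = data.frame(votu_id = character(0),
                                         orders = character(0),
                                         classes = character(0),
                                         spans_class = logical(0))))
  }
  e <- unique(edges[, c("votu_id", "mag_id", "host_order", "host_class")])
  per_order <- do.call(rbind, lapply(split(e, e$host_order), function(g) {
    data.frame(host_order = g$host_order[1],
               n_mags = length(unique(g$mag_id)),
               n_votus = length(unique(g$votu_id)),
               total_mag_abundance =
                 if (is.null(mag_abundance)) NA_real_
                 else sum(mag_abundance[unique(g$mag_id)], na.rm = TRUE))
  }))
  rownames(per_order) <- NULL
  by_votu <- split(e, e$votu_id)
  multi <- by_votu[vapply(by_votu, function(g)
    length(unique(g$host_order)) > 1, logical(1))]
  multi_order <- do.call(rbind, c(lapply(multi, function(g) {
    data.frame(votu_id = g$votu_id[1],
               orders = paste(sort(unique(g$host_order)), collapse = ","),
               classes = paste(sort(unique(g$host_class)), collapse = ","),
               spans_class = length(unique(g$host_class)) > 1)
  }), list(make.row.names = FALSE)))
  if (is.null(multi_order)) {
    multi_order <- data.frame(votu_id = character(0), orders = character(0),
                              classes = character(0), spans_class = logical(0))
  }
  list(per_order = per_order,
       n_votus = length(unique(e$votu_id)),
       n_mags = length(unique(e$mag_id)),
       multi_order = multi_order)
}
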