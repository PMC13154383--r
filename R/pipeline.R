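## End-to-end orchestration of the analysis stages on a fixture.

#' Read a fixture directory written by [write_fixture()]
#'
#' @param dir fixture directory.
#' @return a list shaped like a `virome_sim` (without `truth`/`config`).
#' @export
read_fixture <- function(dir) {
  p <- function(f) file.path(dir, f)
  depths <- read.delim(p("sample_depths.tsv"), sep = "\t")
  list(contigs = read_fasta(p("contigs.fasta")),
       metadata = suppressWarnings(read_table(p("metadata.tsv"), "metadata")),
       origin = read_table(p("contig_origin.tsv"), "contig_origin"),
       calls = read_table(p("predictor_calls.tsv"), "predictor_calls"),
       read_counts = read_table(p("read_counts.tsv"), "read_counts"),
       coverage = read_table(p("coverage.tsv"), "coverage"),
       sample_depths = setNames(depths$total_reads, depths$sample_id),
       gene_taxonomy = read_table(p("gene_taxonomy.tsv"), "gene_taxonomy"),
       amg = read_table(p("amg.tsv"), "amg"),
       host_predictions = read_table(p("host_predictions.tsv"),
                                     "host_predictions"),
       mags = read_table(p("mags.tsv"), "mags"))
}

#' Run the full virome community analysis
#'
#' Chains the stages on a fixture (in-memory `virome_sim` or a fixture
#' directory): ensemble consensus, vOTU dereplication, breadth-filtered
#' abundance, majority-rule taxonomy, community statistics (diversity,
#' ordination, ANOSIM/PERMANOVA by site and season), temporal k-medoid
#' clustering with model selection, cluster profiling, and virus-host
#' network filtering.
#'
#' @param input a `virome_sim` or a fixture directory path.
#' @param config run configuration from [load_config()].
#' @param stats run the permutation statistics and ordination (slowest
#'   optional part; default TRUE).
#' @return object of class `virome_analysis`: list with `consensus`,
#'   `votus`, `abundance`, `taxonomy`, `diversity`, `ordination`, `anosim`,
#'   `permanova`, `temporal` (`zprofiles`, `model`, `profiles`), `hosts`
#'   (`mags`, `edges`, `network`).
#' @export
run_virome_pipeline <- function(input, config = load_config(), stats = TRUE) {
  sim <- if (is.character(input)) read_fixture(input) else input
  ## 1. consensus
  recs <- dedupe_calls(sim$calls, sim$contigs, trim_delim = config$trim_delim)
  recs <- consensus_filter(recs, config$min_length, config$min_tools)
  passing <- recs$kept_contig_id[recs$passed]
  ## 2. vOTU clustering (trimmed variants inherit their base's origin)
  origin <- sim$origin
  keep_seqs <- setNames(sim$contigs[passing], passing)
  ko <- origin[match(base_name(passing, config$trim_delim),
                     origin$contig_id), , drop = FALSE]
  ko$contig_id <- passing
  votus <- cluster_votus(keep_seqs, origin = ko, ani_min = config$ani,
                         af_min = config$af, kmer = config$kmer,
                         min_block = config$min_block,
                         trim_delim = config$trim_delim)
  ## 3. abundance (counts keyed by original ids; map trimmed kept ids back)
  counts <- sim$read_counts
  counts$contig_id <- hv_remap_trimmed(counts$contig_id, passing,
                                       config$trim_delim)
  coverage <- hv_remap_coverage(sim$coverage, passing, config$trim_delim)
  lens <- setNames(nchar(sim$contigs), names(sim$contigs))
  abund <- build_abundance_matrix(counts, coverage, votus, lens,
                                  sim$sample_depths,
                                  breadth_threshold = config$breadth)
  ## 4. taxonomy
  gene_tab <- sim$gene_taxonomy
  gene_tab$contig_id <- hv_remap_trimmed(gene_tab$contig_id, passing,
                                         config$trim_delim)
  taxonomy <- votu_taxonomy(gene_tab, votus, majority = config$majority,
                            pool_genes = config$pool_genes)
  ## 5. community statistics on detected relative abundances
  diversity <- ordination <- anosim_site <- permanova_site <- NULL
  anosim_season <- permanova_season <- NULL
  mat <- t(abund$values)   # samples x vOTUs
  meta_key <- paste(sim$metadata$site, format(sim$metadata$date), sep = "_")
  site_of <- setNames(sim$metadata$site, meta_key)[rownames(mat)]
  season_of <- setNames(sim$metadata$season, meta_key)[rownames(mat)]
  if (stats) {
    keep_s <- rowSums(mat) > 0
    m2 <- mat[keep_s, colSums(mat[keep_s, , drop = FALSE]) > 0, drop = FALSE]
    diversity <- do.call(rbind, lapply(rownames(m2), function(s) {
      di <- diversity_indices(m2[s, ])
      data.frame(sample_id = s, shannon = di$shannon, pielou = di$pielou,
                 richness = di$richness)
    }))
    d <- community_distance(m2, method = if (config$distance == "bray")
      "bray" else "clr_euclidean")
    ordination <- nmds_ordination(d, restarts = config$nmds_restarts,
                                  seed = config$seed)
    anosim_site <- anosim_test(d, site_of[keep_s], config$permutations,
                               config$seed)
    permanova_site <- permanova_test(d, site_of[keep_s], config$permutations,
                                     config$seed)
    if (all(table(season_of[keep_s]) >= 2)) {
      anosim_season <- anosim_test(d, season_of[keep_s], config$permutations,
                                   config$seed)
      permanova_season <- permanova_test(d, season_of[keep_s],
                                         config$permutations, config$seed)
    }
  }
  ## 6. temporal clustering on unfiltered counts (chronological within site)
  ord_samples <- meta_key[order(sim$metadata$site, sim$metadata$date)]
  cmat <- abund$counts[, ord_samples, drop = FALSE]
  zp <- normalize_detrend_scale(cmat)
  kr <- config$k_min:config$k_max
  model <- select_k(zp, k_range = kr, seed = config$seed)
  profiles <- profile_clusters(model, zp, abund, taxonomy, sim$amg)
  ## 7. virus-host network
  mags <- classify_mags(sim$mags)
  edges <- filter_host_predictions(sim$host_predictions, votus, mags,
                                   votu_clusters = model$assignment)
  network <- host_network_summary(edges)
  out <- list(consensus = recs, votus = votus, abundance = abund,
              taxonomy = taxonomy, diversity = diversity,
              ordination = ordination,
              anosim = list(site = anosim_site, season = anosim_season),
              permanova = list(site = permanova_site,
                               season = permanova_season),
              temporal = list(zprofiles = zp, model = model,
                              profiles = profiles),
              hosts = list(mags = mags, edges = edges, network = network),
              config = config)
  class(out) <- "virome_analysis"
  out
}

## map an original contig id to its kept (possibly trimmed) variant id
hv_remap_trimmed <- function(ids, passing, delim) {
  bases <- base_name(passing, delim)
  m <- match(ids, bases)
  ifelse(is.na(m), ids, passing[m])
}

## re-key coverage intervals from assembly contigs to kept variants,
## translating assembly coordinates into variant-local coordinates when the
## kept variant is a trimmed one (suffix "<start>-<end>", 1-based inclusive)
hv_remap_coverage <- function(coverage, passing, delim) {
  bases <- base_name(passing, delim)
  rows <- lapply(seq_len(nrow(coverage)), function(i) {
    r <- coverage[i, , drop = FALSE]
    m <- match(r$contig_id, bases)
    if (is.na(m)) return(r)
    kept <- passing[m]
    if (kept != r$contig_id) {
      parts <- strsplit(kept, delim, fixed = TRUE)[[1]]
      se <- as.integer(strsplit(parts[length(parts)], "-", fixed = TRUE)[[1]])
      s0 <- se[1] - 1L                     # 0-based variant origin
      r$start <- max(r$start - s0, 0L)
      r$end <- min(r$end - s0, se[2] - s0)
      if (r$end <= r$start) return(NULL)
    }
    r$contig_id <- kept
    r
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.virome_analysis <- function(x, ...) {
  cat("Virome community analysis\n")
  cat("  consensus: ", sum(x$consensus$passed), "/", nrow(x$consensus),
      " contigs passed\n", sep = "")
  cat("  vOTUs:     ", nrow(x$votus$votus), "\n", sep = "")
  if (!is.null(x$anosim$site)) {
    cat("  ANOSIM by site: R = ", signif(x$anosim$site$R, 4), ", p = ",
        signif(x$anosim$site$p, 3), "\n", sep = "")
  }
  if (!is.null(x$ordination)) {
    cat("  NMDS stress: ", signif(x$ordination$stress, 3), "\n", sep = "")
  }
  cat("  temporal clusters: k = ", x$temporal$model$chosen_k, "\n", sep = "")
  cat("  host network: ", x$hosts$network$n_votus, " vOTUs -> ",
      x$hosts$network$n_mags, " MAGs\n", sep = "")
  invisible(x)
}
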