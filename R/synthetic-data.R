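## Synthetic virome fixture generator.
##
## Emulates the statistical structure of a two-site (LOC hypersaline
## tributary, RB confluence), eight-timepoint virome survey with one
## low-salinity freshwater pulse sample per site and two post-freeze winter
## samples: planted vOTUs with known contig membership, planted temporal
## dynamic clusters with disturbance responses, ensemble predictor calls
## with configurable sensitivity/false-positive rates, negative-binomial
## read counts with coverage breadth consistent with planted presence, and
## annotation/host tables with planted majorities and enrichments. All
## outputs are deterministic functions of the configuration seed.

hv_bases <- c("A", "C", "G", "T")

hv_amg_pathways <- c("Photosynthesis", "Oxidative phosphorylation",
                     "Sulfur metabolism",
                     "Carbon fixation pathways in prokaryotes",
                     "Methane metabolism", "Nitrogen metabolism")

## viral lineage pool: realm..family rows (NA = rank unresolved in reference)
hv_lineage_pool <- data.frame(
  realm   = c(rep("Duplodnaviria", 5), rep("Varidnaviria", 3)),
  kingdom = c(rep("Heunggongvirae", 5), rep("Bamfordvirae", 3)),
  phylum  = c(rep("Uroviricota", 5), rep("Nucleocytoviricota", 2),
              "Preplasmiviricota"),
  class   = c(rep("Caudoviricetes", 5), rep("Megaviricetes", 2),
              "Maveriviricetes"),
  order   = c(NA, NA, "Autographivirales", NA, NA, "Algavirales", NA,
              "Priklausovirales"),
  family  = c("Zobellviridae", "Schitoviridae", "Autographiviridae",
              "Kyanoviridae", "Corticoviridae", "Phycodnaviridae",
              "Mesyanzhinovviridae", "Lavidaviridae"),
  stringsAsFactors = FALSE)

## host taxonomy pool for MAGs
hv_host_pool <- data.frame(
  domain = "Bacteria",
  phylum = c("Bacteroidota", "Pseudomonadota", "Pseudomonadota",
             "Cyanobacteriota", "Bacteroidota", "Bdellovibrionota",
             "Pseudomonadota", "Deinococcota"),
  class  = c("Bacteroidia", "Alphaproteobacteria", "Gammaproteobacteria",
             "Cyanobacteriia", "Bacteroidia", "Bdellovibrionia",
             "Gammaproteobacteria", "Deinococci"),
  order  = c("Flavobacteriales", "Rhodobacterales", "Cellvibrionales",
             "Synechococcales", "Chitinophagales", "Bacteriovoracales",
             "Chromatiales", "Deinococcales"),
  stringsAsFactors = FALSE)

#' Simulation configuration
#'
#' Defaults encode the emulated study design: 16 samples (2 sites x 8
#' dates), 40 planted vOTUs in 5 temporal dynamic clusters, within-vOTU
#' substitution divergence 0.02 (sibling identity ~0.96, coherent at the
#' 0.95 ANI threshold), between-vOTU divergence 0.2 for related ancestor
#' pairs, four predictors with realistic sensitivity/false-positive rates,
#' negative-binomial counts with dispersion 0.3, and 3-4x disturbance
#' boosts of the pulse-responsive and freeze-responsive clusters.
#'
#' @param seed integer master seed; every generated artefact is a
#'   deterministic function of it.
#' @param n_samples even sample count (two sites; default 16).
#' @param n_votus planted vOTUs (default 40).
#' @param contigs_per_votu integer range, members per vOTU (default 1..3).
#' @param contig_length_range bp range for in-cluster contigs (min must
#'   exceed 10,000 so planted members pass the length filter).
#' @param within_votu_divergence substitution rate of members from their
#'   ancestor (< 0.025 keeps sibling pairs above 95% identity).
#' @param between_votu_divergence substitution rate for related ancestor
#'   pairs (> 0.15 keeps them below the merge threshold).
#' @param related_votu_fraction fraction of vOTUs whose ancestor is a
#'   mutated copy of another ancestor (near-threshold separation exercise).
#' @param site_overlap_fraction fraction of temporal clusters whose vOTUs
#'   occur at both sites.
#' @param n_planted_temporal_clusters planted dynamic clusters (default 5).
#' @param predictor_sensitivity,predictor_fpr named per-predictor call
#'   probabilities for viral and non-viral contigs.
#' @param trimmed_fraction probability that a predictor call reports a
#'   trimmed variant of the contig (provirus-trimming emulation).
#' @param trim_delim delimiter for trim suffixes (default `"||"`).
#' @param decoy_fraction non-viral decoy contigs as a fraction of viral ones.
#' @param short_viral_fraction additional short (< 10 kbp) viral contigs as
#'   a fraction of `n_votus` (exercise the length filter).
#' @param nb_dispersion negative-binomial dispersion (default 0.3,
#'   over-Poisson noise typical of metagenomic counts).
#' @param disturbance_effects multipliers: `pulse_boost` / `freeze_boost`
#'   applied to the pulse- and freeze-responsive clusters in the disturbed
#'   samples, `pulse_suppress` applied to all other clusters in the pulse
#'   sample (freshwater homogenisation).
#' @param depth_range total reads per sample (uniform draw).
#' @param majority_fraction fraction of annotated genes carrying the true
#'   lineage/environment (> 0.5 makes majority-rule taxonomy recoverable).
#' @param amg_enrichment probability an AMG row carries its cluster's
#'   enriched pathway.
#' @param host_fraction fraction of vOTUs with a MAG host prediction.
#' @param nonmag_fraction fraction with a non-MAG reference host (to be
#'   filtered out).
#' @param n_mags MAG count.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_samples = 16L,
                       n_votus = 40L,
                       contigs_per_votu = c(1L, 3L),
                       contig_length_range = c(10050L, 12000L),
                       within_votu_divergence = 0.02,
                       between_votu_divergence = 0.2,
                       related_votu_fraction = 0.1,
                       site_overlap_fraction = 0.4,
                       n_planted_temporal_clusters = 5L,
                       predictor_sensitivity = c(vibrant = 0.95,
                                                 virsorter2 = 0.9,
                                                 checkv = 0.9,
                                                 genomad = 0.95),
                       predictor_fpr = c(vibrant = 0.02, virsorter2 = 0.05,
                                         checkv = 0.02, genomad = 0.02),
                       trimmed_fraction = 0.15,
                       trim_delim = "||",
                       decoy_fraction = 0.2,
                       short_viral_fraction = 0.1,
                       nb_dispersion = 0.3,
                       disturbance_effects = c(pulse_boost = 4,
                                               freeze_boost = 4,
                                               pulse_suppress = 0.4),
                       depth_range = c(8e6, 1.2e7),
                       majority_fraction = 0.7,
                       amg_enrichment = 0.7,
                       host_fraction = 0.35,
                       nonmag_fraction = 0.1,
                       n_mags = 20L) {
  cfg <- as.list(environment())
  if (cfg$n_samples <= 0) stop("invalid config: n_samples must be positive")
  if (cfg$n_samples %% 2 != 0) stop("invalid config: n_samples must be even")
  if (cfg$contig_length_range[1] < 1) {
    stop("invalid config: contig lengths must be positive")
  }
  if (any(c(predictor_sensitivity, predictor_fpr) < 0) ||
      any(c(predictor_sensitivity, predictor_fpr) > 1)) {
    stop("invalid config: predictor probabilities must be in [0, 1]")
  }
  if (within_votu_divergence >= 0.05) {
    stop("invalid config: within_votu_divergence must be below 0.05")
  }
  class(cfg) <- "sim_config"
  cfg
}

## sample ids, dates, seasons for the emulated design
hv_design <- function(config) {
  n_dates <- config$n_samples / 2
  base_dates <- as.Date(c("2020-05-18", "2020-06-18", "2020-09-15",
                          "2020-10-15", "2021-01-20", "2021-02-22",
                          "2021-03-15", "2021-06-18"))
  dates <- if (n_dates <= 8) base_dates[seq_len(n_dates)] else
    c(base_dates, seq(as.Date("2021-07-15"), by = "month",
                      length.out = n_dates - 8))
  seasons <- c("Spring", "Summer", "Fall", "Fall", "Winter", "Winter",
               "Spring", "Summer")[pmin(seq_len(n_dates), 8)]
  seasons[is.na(seasons)] <- "Summer"
  pulse_idx <- n_dates
  freeze_idx <- if (n_dates >= 6) c(5L, 6L) else
    unique(pmax(1L, c(n_dates - 2L, n_dates - 1L)))
  sites <- c("LOC", "RB")
  samples <- data.frame(
    sample_id = paste(rep(sites, each = n_dates), format(rep(dates, 2)),
                      sep = "_"),
    site = rep(sites, each = n_dates),
    date = rep(dates, 2),
    season = rep(seasons, 2),
    date_idx = rep(seq_len(n_dates), 2))
  list(samples = samples, n_dates = n_dates, pulse_idx = pulse_idx,
       freeze_idx = freeze_idx)
}

#' Generate the sample-metadata table
#'
#' One row per site-date with all abiotic columns, drawn from site-specific
#' normal distributions (means/SDs recorded in the header on write).
#' Exactly one date per site (the last, the freshwater pulse) has salinity
#' below 32 ppt; the two consecutive winter dates are flagged post-freeze.
#'
#' @param config a [sim_config()].
#' @return data.frame in the `metadata` schema plus a `post_freeze` column;
#'   attribute `dist_params` documents the sampled distributions.
#' @export
generate_metadata <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  des <- hv_design(config)
  set.seed(config$seed + 101L)
  ## site-specific normal parameters (mean, sd); salinity split into
  ## non-pulse and pulse regimes so the 8-date site means land near
  ## 61.7 (LOC) and 43.7 (RB)
  pars <- list(
    LOC = list(temp_C = c(26.05, 4.7), do_mg_per_L = c(3.25, 1.9),
               salinity_ppt = c(70.10, 4.1), salinity_pulse = c(2.57, 1.0),
               pH = c(8.24, 0.33), nh4_uM = c(22.0, 16),
               no3_uM = c(4.5, 3.4), no2_uM = c(0.14, 0.25),
               autofluor_cells_per_mL = c(470000, 300000)),
    RB  = list(temp_C = c(24.61, 4.5), do_mg_per_L = c(6.15, 1.4),
               salinity_ppt = c(47.67, 2.2), salinity_pulse = c(16.05, 3.0),
               pH = c(8.14, 0.15), nh4_uM = c(76.2, 40),
               no3_uM = c(4.5, 3.9), no2_uM = c(0.09, 0.09),
               autofluor_cells_per_mL = c(38000, 30000)))
  md <- des$samples
  out <- md[, c("site", "date", "season")]
  cols <- c("temp_C", "do_mg_per_L", "salinity_ppt", "pH", "nh4_uM",
            "no3_uM", "no2_uM", "autofluor_cells_per_mL")
  for (v in cols) out[[v]] <- NA_real_
  for (s in c("LOC", "RB")) {
    sel <- out$site == s
    p <- pars[[s]]
    for (v in cols) {
      out[[v]][sel] <- pmax(0, rnorm(sum(sel), p[[v]][1], p[[v]][2]))
    }
    pulse_row <- which(sel)[des$pulse_idx]
    out$salinity_ppt[pulse_row] <-
      min(31.9, max(0, rnorm(1, p$salinity_pulse[1], p$salinity_pulse[2])))
    nonpulse <- setdiff(which(sel), pulse_row)
    ## all non-pulse salinities stay hypersaline
    out$salinity_ppt[nonpulse] <- pmax(33, out$salinity_ppt[nonpulse])
  }
  out$post_freeze <- out$date %in% des$samples$date[des$freeze_idx]
  attr(out, "dist_params") <- pars
  out
}

hv_random_seq <- function(len) {
  paste(sample(hv_bases, len, replace = TRUE), collapse = "")
}

hv_mutate_seq <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  if (length(hit)) {
    ch[hit] <- vapply(ch[hit], function(b)
      sample(setdiff(hv_bases, b), 1), character(1))
  }
  paste(ch, collapse = "")
}

## cluster archetypes: each cluster is "active" (high abundance) inside its
## own contiguous window of dates and at baseline outside — the window
## pattern of bloom-and-decline dynamics (pre-freeze, post-freeze, pulse,
## seasonal blocks). Windows are disjoint across clusters, so dynamic
## groups are genuinely distinct. Falls back to gaussian bumps when there
## are more clusters than dates.
hv_archetype <- function(k, n_dates) {
  if (k <= n_dates) {
    bounds <- round(seq(0, n_dates, length.out = k + 1))
    lo <- bounds[-length(bounds)] + 1L
    hi <- bounds[-1]
    function(j, d) 0.8 + 20 * (d >= lo[j] & d <= hi[j])
  } else {
    centers <- seq(1, n_dates, length.out = k)
    function(j, d) 0.8 + 20 * exp(-(d - centers[j])^2 / (2 * 0.8^2))
  }
}

## window midpoints (used to identify pulse- and freeze-responsive clusters)
hv_archetype_centers <- function(k, n_dates) {
  if (k <= n_dates) {
    bounds <- round(seq(0, n_dates, length.out = k + 1))
    (bounds[-length(bounds)] + 1 + bounds[-1]) / 2
  } else {
    seq(1, n_dates, length.out = k)
  }
}

#' Generate contigs and the planted ground truth
#'
#' Plants `n_votus` vOTUs: each is a random ancestor sequence (a
#' configurable fraction mutated from another ancestor at
#' `between_votu_divergence`) with 1..`contigs_per_votu` members mutated at
#' `within_votu_divergence`; adds short viral contigs (below the length
#' filter) and non-viral decoys. Each vOTU belongs to a planted temporal
#' cluster whose archetype (a seasonal bump, plus disturbance multipliers
#' in the pulse and post-freeze samples) defines its expected abundance in
#' every sample; contig sample-of-origin is drawn proportional to that
#' abundance.
#'
#' @param config a [sim_config()].
#' @return list: `contigs` (named character vector), `origin` (data.frame
#'   in the `contig_origin` schema), `truth` (list: `votu_assignment`,
#'   `temporal_cluster`, `true_abundance`, `viral_flag`, `representative`,
#'   `site_class`, `enriched_pathway`, `samples`).
#' @export
generate_contigs <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$contig_length_range[1] < 1) stop("contig lengths must be positive")
  des <- hv_design(config)
  set.seed(config$seed + 202L)
  k <- config$n_planted_temporal_clusters
  nv <- config$n_votus
  arch <- hv_archetype(k, des$n_dates)

  ## cluster roles: pulse cluster peaks at the last date, freeze cluster in
  ## winter; site classes cycle with ~site_overlap_fraction of clusters both
  centers <- hv_archetype_centers(k, des$n_dates)
  pulse_cluster <- which.min(abs(centers - des$pulse_idx))
  freeze_cluster <- which.min(abs(centers - mean(des$freeze_idx)))
  n_both <- max(1L, round(config$site_overlap_fraction * k))
  classes <- character(k)
  both_set <- unique(c(pulse_cluster, seq_len(k)))[seq_len(n_both)]
  classes[both_set] <- "both"
  rest <- setdiff(seq_len(k), both_set)
  classes[rest] <- rep(c("LOC", "RB"), length.out = length(rest))

  votu_ids <- sprintf("planted_%03d", seq_len(nv))
  votu_cluster <- rep(seq_len(k), length.out = nv)
  eff <- config$disturbance_effects

  ## expected relative abundance per vOTU x sample
  ta <- matrix(0, nv, nrow(des$samples),
               dimnames = list(votu_ids, des$samples$sample_id))
  site_w <- matrix(0, nv, 2, dimnames = list(votu_ids, c("LOC", "RB")))
  scale_v <- rlnorm(nv, 0, 0.3)
  for (i in seq_len(nv)) {
    cl <- votu_cluster[i]
    w <- switch(classes[cl],
                both = runif(2, 0.6, 1.4),
                LOC = c(runif(1, 0.6, 1.4), 0),
                RB = c(0, runif(1, 0.6, 1.4)))
    names(w) <- c("LOC", "RB")
    site_w[i, ] <- w
    for (r in seq_len(nrow(des$samples))) {
      d <- des$samples$date_idx[r]
      val <- arch(cl, d) * w[[des$samples$site[r]]] * scale_v[i]
      if (d == des$pulse_idx) {
        val <- val * if (cl == pulse_cluster) eff[["pulse_boost"]]
                     else eff[["pulse_suppress"]]
      }
      if (d %in% des$freeze_idx && cl == freeze_cluster) {
        val <- val * eff[["freeze_boost"]]
      }
      ta[i, r] <- val
    }
  }

  ## sequences
  contigs <- character(0)
  origin <- list()
  votu_assignment <- character(0)
  viral_flag <- logical(0)
  representative <- setNames(character(nv), votu_ids)
  ancestors <- vector("list", nv)
  cnt <- 0L
  for (i in seq_len(nv)) {
    len_max <- round(runif(1, mean(config$contig_length_range),
                           config$contig_length_range[2]))
    if (i > 1 && runif(1) < config$related_votu_fraction) {
      src <- sample(i - 1, 1)
      anc_full <- hv_mutate_seq(ancestors[[src]], config$between_votu_divergence)
      anc <- if (nchar(anc_full) >= len_max) substr(anc_full, 1, len_max)
             else paste0(anc_full, hv_random_seq(len_max - nchar(anc_full)))
    } else {
      anc <- hv_random_seq(len_max)
    }
    ancestors[[i]] <- anc
    n_mem <- sample(seq(config$contigs_per_votu[1], config$contigs_per_votu[2]), 1)
    pos_samples <- which(ta[i, ] > 0)
    for (m in seq_len(n_mem)) {
      cnt <- cnt + 1L
      sid <- des$samples$sample_id[
        pos_samples[sample.int(length(pos_samples), 1,
                               prob = ta[i, pos_samples])]]
      id <- sprintf("c%05d_%s", cnt, sid)
      if (m == 1) {
        sq <- anc                      # longest member = exact ancestor
        representative[i] <- id
      } else {
        len_m <- round(runif(1, config$contig_length_range[1], len_max))
        sq <- hv_mutate_seq(substr(anc, 1, len_m),
                            config$within_votu_divergence)
      }
      contigs[id] <- sq
      votu_assignment[id] <- votu_ids[i]
      viral_flag[id] <- TRUE
      origin[[id]] <- data.frame(contig_id = id, sample_id = sid,
                                 site = des$samples$site[
                                   des$samples$sample_id == sid],
                                 date = des$samples$date[
                                   des$samples$sample_id == sid],
                                 fraction = "viral")
    }
  }
  ## short viral contigs (fail the strict > 10 kbp filter)
  n_short <- round(config$short_viral_fraction * nv)
  for (j in seq_len(n_short)) {
    cnt <- cnt + 1L
    sid <- des$samples$sample_id[sample(nrow(des$samples), 1)]
    id <- sprintf("c%05d_%s", cnt, sid)
    contigs[id] <- hv_random_seq(round(runif(1, 5000, 9500)))
    votu_assignment[id] <- sprintf("short_%03d", j)
    viral_flag[id] <- TRUE
    origin[[id]] <- data.frame(contig_id = id, sample_id = sid,
                               site = sub("_.*", "", sid),
                               date = des$samples$date[
                                 des$samples$sample_id == sid],
                               fraction = "viral")
  }
  ## non-viral decoys
  n_decoy <- round(config$decoy_fraction * sum(viral_flag))
  for (j in seq_len(n_decoy)) {
    cnt <- cnt + 1L
    sid <- des$samples$sample_id[sample(nrow(des$samples), 1)]
    id <- sprintf("c%05d_%s", cnt, sid)
    contigs[id] <- hv_random_seq(round(runif(1, 2000, 15000)))
    votu_assignment[id] <- sprintf("decoy_%03d", j)
    viral_flag[id] <- FALSE
    origin[[id]] <- data.frame(contig_id = id, sample_id = sid,
                               site = sub("_.*", "", sid),
                               date = des$samples$date[
                                 des$samples$sample_id == sid],
                               fraction = "bacterial")
  }
  origin <- do.call(rbind, origin)
  rownames(origin) <- NULL

  enriched <- setNames(hv_amg_pathways[(seq_len(k) - 1L) %%
                                         length(hv_amg_pathways) + 1L],
                       seq_len(k))
  truth <- list(votu_assignment = votu_assignment,
                temporal_cluster = setNames(votu_cluster, votu_ids),
                true_abundance = ta,
                viral_flag = viral_flag,
                representative = representative,
                site_class = setNames(classes[votu_cluster], votu_ids),
                cluster_site_class = classes,
                pulse_cluster = pulse_cluster,
                freeze_cluster = freeze_cluster,
                enriched_pathway = enriched,
                samples = des$samples)
  list(contigs = contigs, origin = origin, truth = truth)
}

#' Generate ensemble predictor calls
#'
#' Each viral contig is called by predictor p with probability
#' `predictor_sensitivity[p]`, each decoy with `predictor_fpr[p]`. A
#' configurable fraction of calls reports a trimmed variant (same base name
#' plus a coordinate suffix, shorter sequence) to exercise the
#' retain-shortest dedup rule.
#'
#' @param contigs named character vector of contig sequences.
#' @param truth ground-truth list from [generate_contigs()].
#' @param config a [sim_config()].
#' @return list: `calls` (data.frame, `predictor_calls` schema) and
#'   `variant_seqs` (named character vector of trimmed-variant sequences to
#'   append to the contig set).
#' @export
generate_predictor_calls <- function(contigs, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  sens <- config$predictor_sensitivity
  fpr <- config$predictor_fpr
  if (any(c(sens, fpr) < 0 | c(sens, fpr) > 1)) {
    stop("predictor probabilities must be in [0, 1]")
  }
  set.seed(config$seed + 303L)
  preds <- names(sens)
  rows <- list(); variants <- character(0)
  for (id in names(contigs)) {
    p_call <- if (truth$viral_flag[[id]]) sens else fpr
    for (p in preds) {
      if (runif(1) >= p_call[[p]]) next
      len <- nchar(contigs[[id]])
      if (truth$viral_flag[[id]] && runif(1) < config$trimmed_fraction) {
        start <- sample.int(max(1L, round(0.06 * len)), 1)
        end <- len - sample.int(max(1L, round(0.06 * len)), 1) + 1L
        vid <- paste0(id, config$trim_delim, start, "-", end)
        variants[vid] <- substr(contigs[[id]], start, end)
        rows[[length(rows) + 1L]] <- data.frame(
          contig_id = vid, predictor = p,
          called_length_bp = end - start + 1L)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          contig_id = id, predictor = p, called_length_bp = len)
      }
    }
  }
  calls <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig_id = character(0), predictor = character(0),
               called_length_bp = integer(0))
  hv_log("generate_predictor_calls", contigs = length(contigs),
         calls = nrow(calls), trimmed_variants = length(variants))
  list(calls = calls, variant_seqs = variants)
}

#' Generate per-sample read counts and coverage intervals
#'
#' Per-contig read counts are negative binomial with mean proportional to
#' planted abundance x contig length (kbp) x sample depth (millions);
#' coverage intervals on each representative give breadth above 0.75 where
#' the vOTU is planted present and at most 0.6 (usually 0) where absent.
#'
#' @param contigs named character vector (lengths are taken from it).
#' @param truth ground-truth list from [generate_contigs()].
#' @param config a [sim_config()].
#' @return list: `read_counts`, `coverage` (schema data.frames),
#'   `sample_depths` (named numeric).
#' @export
generate_alignments <- function(contigs, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 404L)
  samples <- truth$samples
  depths <- setNames(round(runif(nrow(samples), config$depth_range[1],
                                 config$depth_range[2])),
                     samples$sample_id)
  size <- 1 / config$nb_dispersion
  counts <- list(); cov <- list()
  emit_cov <- function(sid, cid, breadth, len) {
    covered <- round(breadth * len)
    if (covered <= 0) return(NULL)
    if (covered >= len) {
      return(data.frame(sample_id = sid, contig_id = cid, start = 0L,
                        end = len))
    }
    gap <- len - covered
    x <- sample.int(covered + 1L, 1) - 1L   # gap position
    out <- list()
    if (x > 0) out[[1]] <- data.frame(sample_id = sid, contig_id = cid,
                                      start = 0L, end = x)
    if (covered - x > 0) out[[length(out) + 1L]] <-
      data.frame(sample_id = sid, contig_id = cid, start = x + gap,
                 end = len)
    do.call(rbind, out)
  }
  members <- split(names(truth$votu_assignment), truth$votu_assignment)
  planted <- rownames(truth$true_abundance)
  for (v in planted) {
    mem <- members[[v]]
    rep_id <- truth$representative[[v]]
    for (s in samples$sample_id) {
      ab <- truth$true_abundance[v, s]
      if (ab > 0) {
        for (cid in mem) {
          mu <- ab * nchar(contigs[[cid]]) / 1000 * depths[[s]] / 1e6
          n <- rnbinom(1, mu = mu, size = size)
          if (n > 0) counts[[length(counts) + 1L]] <-
            data.frame(sample_id = s, contig_id = cid, reads = n)
          ## reads blanket every member contig where the vOTU is present
          cov[[length(cov) + 1L]] <-
            emit_cov(s, cid, runif(1, 0.85, 1.0), nchar(contigs[[cid]]))
        }
      } else {
        ## planted absence: low-level cross-mapping background scaled with
        ## sequencing depth (read mapping almost never yields exact
        ## zeros); breadth kept below the detection threshold
        n <- rnbinom(1, mu = 8 * depths[[s]] / 1e7, size = size)
        if (n > 0) counts[[length(counts) + 1L]] <-
          data.frame(sample_id = s, contig_id = rep_id, reads = n)
        if (runif(1) < 0.3) cov[[length(cov) + 1L]] <-
          emit_cov(s, rep_id, runif(1, 0.1, 0.6), nchar(contigs[[rep_id]]))
      }
    }
  }
  ## decoys and short contigs: sparse counts in their origin sample only
  others <- setdiff(names(contigs), unlist(members[planted]))
  for (cid in others) {
    sid <- sub("^c\\d+_", "", cid)
    n <- rnbinom(1, mu = 5, size = size)
    if (n > 0) counts[[length(counts) + 1L]] <-
      data.frame(sample_id = sid, contig_id = cid, reads = n)
    cov[[length(cov) + 1L]] <-
      emit_cov(sid, cid, runif(1, 0.85, 1.0), nchar(contigs[[cid]]))
  }
  read_counts <- do.call(rbind, counts); rownames(read_counts) <- NULL
  coverage <- do.call(rbind, cov); rownames(coverage) <- NULL
  hv_log("generate_alignments", count_rows = nrow(read_counts),
         coverage_rows = nrow(coverage))
  list(read_counts = read_counts, coverage = coverage,
       sample_depths = depths)
}

#' Generate annotation, AMG, host-prediction, and MAG tables
#'
#' Gene rows on each planted representative carry the vOTU's true lineage
#' and source environment at the configured majority fraction (the rest
#' drawn from other pool entries); AMG rows are enriched for each cluster's
#' planted KEGG pathway; host predictions link a subset of vOTUs to MAGs
#' and a subset to non-MAG reference genomes (exercising the MAG-only
#' filter); the MAG table spans the quality classes.
#'
#' @param truth ground-truth list from [generate_contigs()].
#' @param config a [sim_config()].
#' @param lineage_pool,environment_pool optional custom pools.
#' @return list: `gene_taxonomy`, `amg`, `host_predictions`, `mags`
#'   (schema data.frames), plus `truth_extras` (true family / environment /
#'   host per vOTU).
#' @export
generate_annotations_and_hosts <- function(truth, config,
                                           lineage_pool = hv_lineage_pool,
                                           environment_pool =
                                             c("marine", "freshwater",
                                               "non-marine saline/alkaline")) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(lineage_pool) == 0) stop("empty lineage pool")
  set.seed(config$seed + 505L)
  votu_ids <- rownames(truth$true_abundance)
  k <- config$n_planted_temporal_clusters
  ## cluster-preferred families cycle through the pool
  pref_family <- (seq_len(k) - 1L) %% nrow(lineage_pool) + 1L
  maj <- config$majority_fraction

  genes <- list(); amg <- list()
  true_family <- true_env <- setNames(character(length(votu_ids)), votu_ids)
  for (v in votu_ids) {
    cl <- truth$temporal_cluster[[v]]
    fam_i <- if (runif(1) < 0.6) pref_family[cl] else
      sample(nrow(lineage_pool), 1)
    true_family[v] <- lineage_pool$family[fam_i]
    env <- switch(truth$site_class[[v]],
                  RB = "marine",
                  LOC = sample(c("freshwater", "non-marine saline/alkaline"), 1),
                  both = if (cl == truth$pulse_cluster) "freshwater"
                         else sample(environment_pool, 1))
    true_env[v] <- env
    rep_id <- truth$representative[[v]]
    ## every member contig carries gene annotations, as real protein-
    ## alignment tables do
    mem <- names(truth$votu_assignment)[truth$votu_assignment == v]
    for (cid in mem) {
      n_genes <- sample(8:15, 1)
      for (g in seq_len(n_genes)) {
        if (runif(1) < maj) {
          lin <- lineage_pool[fam_i, ]
          e <- env
        } else {
          lin <- lineage_pool[
            sample(setdiff(seq_len(nrow(lineage_pool)), fam_i), 1), ]
          e <- if (runif(1) < 0.5) NA_character_
               else sample(environment_pool, 1)
        }
        genes[[length(genes) + 1L]] <- data.frame(
          contig_id = cid, gene_id = sprintf("%s_g%02d", cid, g),
          realm = lin$realm, kingdom = lin$kingdom, phylum = lin$phylum,
          class = lin$class, order = lin$order, family = lin$family,
          environment = e)
      }
    }
    ## AMGs: 0-3 rows, enriched for the cluster's planted pathway
    for (a in seq_len(sample(1:5, 1))) {
      pw <- if (runif(1) < config$amg_enrichment)
        truth$enriched_pathway[[as.character(cl)]]
      else sample(setdiff(hv_amg_pathways,
                          truth$enriched_pathway[[as.character(cl)]]), 1)
      amg[[length(amg) + 1L]] <- data.frame(
        votu_id = paste0("vOTU_", rep_id), contig_id = rep_id,
        kegg_pathway = pw)
    }
  }
  gene_taxonomy <- do.call(rbind, genes); rownames(gene_taxonomy) <- NULL
  amg <- if (length(amg)) do.call(rbind, amg) else
    data.frame(votu_id = character(0), contig_id = character(0),
               kegg_pathway = character(0))

  ## MAGs spanning quality classes
  n_mags <- config$n_mags
  hosts_i <- sample(nrow(hv_host_pool), n_mags, replace = TRUE)
  mags <- data.frame(mag_id = sprintf("MAG_%03d", seq_len(n_mags)),
                     completion = round(runif(n_mags, 40, 100), 1),
                     contamination = round(runif(n_mags, 0, 12), 1),
                     domain = hv_host_pool$domain[hosts_i],
                     phylum = hv_host_pool$phylum[hosts_i],
                     class = hv_host_pool$class[hosts_i],
                     order = hv_host_pool$order[hosts_i])
  pass_mags <- mags$mag_id[mags$completion > 50 & mags$contamination < 10]

  hp <- list()
  n_host <- round(config$host_fraction * length(votu_ids))
  hosted <- sample(votu_ids, n_host)
  for (v in hosted) {
    hp[[length(hp) + 1L]] <- data.frame(
      votu_id = paste0("vOTU_", truth$representative[[v]]),
      host_genome = pass_mags[sample.int(length(pass_mags), 1)],
      score = round(runif(1, 0.7, 1), 3))
  }
  ## two planted multi-order viruses (predictions to MAGs in two orders)
  if (length(hosted) >= 2 && length(unique(mags$order)) >= 2) {
    for (v in hosted[1:2]) {
      cur <- hp[[match(v, hosted)]]$host_genome
      cur_order <- mags$order[mags$mag_id == cur]
      alt <- pass_mags[mags$order[match(pass_mags, mags$mag_id)] != cur_order]
      if (length(alt)) hp[[length(hp) + 1L]] <- data.frame(
        votu_id = paste0("vOTU_", truth$representative[[v]]),
        host_genome = alt[sample.int(length(alt), 1)],
        score = round(runif(1, 0.7, 1), 3))
    }
  }
  ## predictions to non-MAG reference genomes (must be filtered out)
  n_ref <- round(config$nonmag_fraction * length(votu_ids))
  for (v in sample(votu_ids, n_ref)) {
    hp[[length(hp) + 1L]] <- data.frame(
      votu_id = paste0("vOTU_", truth$representative[[v]]),
      host_genome = sprintf("RefG_%04d", sample.int(9999, 1)),
      score = round(runif(1, 0.7, 1), 3))
  }
  host_predictions <- if (length(hp)) do.call(rbind, hp) else
    data.frame(votu_id = character(0), host_genome = character(0),
               score = numeric(0))
  rownames(host_predictions) <- NULL
  list(gene_taxonomy = gene_taxonomy, amg = amg,
       host_predictions = host_predictions, mags = mags,
       truth_extras = list(family = true_family, environment = true_env))
}

#' Generate a complete synthetic virome fixture
#'
#' Runs every generator with one configuration and, optionally, writes the
#' fixture directory (FASTA + TSV tables + ground-truth tables).
#'
#' @param config a [sim_config()].
#' @param outdir optional directory to write the fixture into.
#' @return object of class `virome_sim`: list with `config`, `metadata`,
#'   `contigs` (including trimmed variant sequences), `origin`, `calls`,
#'   `read_counts`, `coverage`, `sample_depths`, `gene_taxonomy`, `amg`,
#'   `host_predictions`, `mags`, `truth`.
#' @export
#' @examples
#' sim <- simulate_virome(sim_config(seed = 7, n_votus = 6L,
#'                                   contig_length_range = c(10050L, 10500L)))
#' length(sim$contigs)
simulate_virome <- function(config = sim_config(), outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  metadata <- generate_metadata(config)
  gc_out <- generate_contigs(config)
  calls <- generate_predictor_calls(gc_out$contigs, gc_out$truth, config)
  aln <- generate_alignments(gc_out$contigs, gc_out$truth, config)
  ann <- generate_annotations_and_hosts(gc_out$truth, config)
  sim <- list(config = config, metadata = metadata,
              contigs = c(gc_out$contigs, calls$variant_seqs),
              origin = gc_out$origin, calls = calls$calls,
              read_counts = aln$read_counts, coverage = aln$coverage,
              sample_depths = aln$sample_depths,
              gene_taxonomy = ann$gene_taxonomy, amg = ann$amg,
              host_predictions = ann$host_predictions, mags = ann$mags,
              truth = c(gc_out$truth, ann$truth_extras))
  class(sim) <- "virome_sim"
  if (!is.null(outdir)) write_fixture(sim, outdir)
  sim
}

#' @export
print.virome_sim <- function(x, ...) {
  cat("Synthetic virome fixture (seed ", x$config$seed, "): ",
      length(x$contigs), " contig sequences, ",
      nrow(x$truth$true_abundance), " planted vOTUs in ",
      x$config$n_planted_temporal_clusters, " temporal clusters, ",
      nrow(x$metadata), " samples\n", sep = "")
  invisible(x)
}

#' Write a fixture directory
#'
#' @param sim a `virome_sim`.
#' @param outdir output directory (created if needed).
#' @return invisibly, `outdir`.
#' @export
write_fixture <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  write_fasta(sim$contigs, p("contigs.fasta"))
  pars <- attr(sim$metadata, "dist_params")
  hdr <- unlist(lapply(names(pars), function(s)
    vapply(names(pars[[s]]), function(v)
      sprintf("%s %s: mean=%g sd=%g", s, v, pars[[s]][[v]][1],
              pars[[s]][[v]][2]), character(1))))
  write_tsv(sim$metadata, p("metadata.tsv"), header_comments = hdr)
  write_tsv(sim$origin, p("contig_origin.tsv"))
  write_tsv(sim$calls, p("predictor_calls.tsv"))
  write_tsv(sim$read_counts, p("read_counts.tsv"))
  write_tsv(sim$coverage, p("coverage.tsv"))
  write_tsv(data.frame(sample_id = names(sim$sample_depths),
                       total_reads = unname(sim$sample_depths)),
            p("sample_depths.tsv"))
  write_tsv(sim$gene_taxonomy, p("gene_taxonomy.tsv"))
  write_tsv(sim$amg, p("amg.tsv"))
  write_tsv(sim$host_predictions, p("host_predictions.tsv"))
  write_tsv(sim$mags, p("mags.tsv"))
  write_tsv(data.frame(contig_id = names(sim$truth$votu_assignment),
                       votu_id = unname(sim$truth$votu_assignment),
                       viral = unname(sim$truth$viral_flag)),
            p("truth_votu_assignment.tsv"))
  write_tsv(data.frame(votu_id = names(sim$truth$temporal_cluster),
                       cluster = unname(sim$truth$temporal_cluster)),
            p("truth_temporal_cluster.tsv"))
  invisible(outdir)
}
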