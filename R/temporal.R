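## Clustering of vOTU temporal abundance profiles.
##
## Counts (including sub-breadth ones) are size-factor normalised, log(1+x)
## transformed, linearly detrended over the sample index, and standardised
## to Z-profiles; PAM k-medoids partitions the profiles, with k selected by
## the elbow of the within-cluster SSE curve (confirmed against a
## Ward-linkage hierarchical partition) followed by average silhouette.

#' Median-of-ratios size factors
#'
#' Per-sample scaling factors: the median over features of
#' count / geometric-mean(feature), computed over features positive in every
#' sample; when no feature qualifies, each sample falls back to the median
#' over its own positive features. Factors are normalised to geometric
#' mean 1.
#'
#' @param counts feature x sample matrix of non-negative counts; every
#'   sample must have at least one positive feature.
#' @return named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(colSums(counts) == 0)) {
    stop("sample with all-zero counts: ",
         colnames(counts)[colSums(counts) == 0][1])
  }
  allpos <- rowSums(counts > 0) == ncol(counts)
  sf <- if (any(allpos)) {
    sub <- counts[allpos, , drop = FALSE]
    gm <- exp(rowMeans(log(sub)))
    apply(sub / gm, 2, median)
  } else {
    apply(counts, 2, function(x) {
      pos <- x > 0
      gm <- exp(mean(log(x[pos])))
      median(x[pos] / gm)
    })
  }
  sf <- sf / exp(mean(log(sf)))
  setNames(sf, colnames(counts))
}

#' Normalise, detrend, and scale counts into Z-profiles
#'
#' Counts are divided by size factors, log(1+x) transformed, the per-feature
#' least-squares linear trend over the sample index is removed, and the
#' residuals are standardised to mean 0 / SD 1. Profiles that are constant
#' after detrending are dropped (count logged).
#'
#' @param counts feature x sample count matrix; columns must already be in
#'   chronological order within site.
#' @return matrix of Z-profiles (rows = retained features); attribute
#'   `dropped` holds the ids of constant profiles.
#' @export
normalize_detrend_scale <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 3) stop("need at least 3 samples to detrend")
  sf <- size_factors(counts)
  x <- log1p(sweep(counts, 2, sf, "/"))
  t_idx <- seq_len(ncol(x))
  tc <- t_idx - mean(t_idx)
  ## vectorised per-row linear detrend
  beta <- (x %*% tc) / sum(tc^2)
  resid <- x - outer(as.vector(beta), tc) - rowMeans(x)
  sds <- apply(resid, 1, sd)
  keep <- sds > 1e-8
  z <- sweep(resid[keep, , drop = FALSE] -
               rowMeans(resid[keep, , drop = FALSE]),
             1, sds[keep], "/")
  attr(z, "dropped") <- rownames(counts)[!keep]
  hv_log("normalize_detrend_scale", profiles = sum(keep),
         dropped_constant = sum(!keep))
  z
}

## row-wise minima over selected columns of a matrix
hv_rowmin <- function(D, cols) {
  Reduce(pmin, lapply(cols, function(j) D[, j]))
}

#' PAM k-medoids clustering
#'
#' Partitioning Around Medoids on Euclidean distances between profiles:
#' greedy BUILD initialisation followed by best-improvement SWAP until no
#' swap lowers the objective (total distance of points to their medoid).
#' The objective is non-increasing across SWAP steps by construction, and
#' the procedure is deterministic.
#'
#' @param profiles feature x sample matrix (rows clustered), or a `dist`.
#' @param k number of clusters, `1 <= k <= n`.
#' @param seed recorded for provenance (the algorithm is deterministic).
#' @return list: `medoids` (row ids), `assignment` (named integer vector),
#'   `objective`, `objective_trace` (one value per accepted SWAP).
#' @export
kmedoids_pam <- function(profiles, k, seed = 1L) {
  D <- if (inherits(profiles, "dist")) as.matrix(profiles)
       else as.matrix(dist(profiles))
  n <- nrow(D)
  if (k < 1 || k > n) stop("k must be in [1, ", n, "]")
  ids <- rownames(D)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  ## BUILD
  meds <- which.min(colSums(D))
  while (length(meds) < k) {
    cur <- hv_rowmin(D, meds)
    gains <- vapply(seq_len(n), function(j) {
      if (j %in% meds) return(-Inf)
      sum(cur - pmin(cur, D[, j]))
    }, numeric(1))
    meds <- c(meds, which.max(gains))
  }
  cost <- function(m) sum(hv_rowmin(D, m))
  obj <- cost(meds)
  trace <- obj
  ## SWAP (best improvement)
  repeat {
    best_delta <- 0; best_swap <- NULL
    for (mi in seq_along(meds)) {
      others <- meds[-mi]
      for (h in seq_len(n)) {
        if (h %in% meds) next
        newc <- if (length(others)) sum(pmin(hv_rowmin(D, others), D[, h]))
                else sum(D[, h])
        delta <- newc - obj
        if (delta < best_delta - 1e-12) {
          best_delta <- delta; best_swap <- c(mi, h)
        }
      }
    }
    if (is.null(best_swap)) break
    meds[best_swap[1]] <- best_swap[2]
    obj <- obj + best_delta
    trace <- c(trace, obj)
  }
  assignment <- apply(D[, meds, drop = FALSE], 1, which.min)
  names(assignment) <- ids
  list(medoids = ids[meds], assignment = assignment, objective = obj,
       objective_trace = trace, seed = seed)
}

## within-cluster sum of squared distances to each cluster's medoid
hv_sse <- function(D2, assignment) {
  sum(vapply(split(seq_along(assignment), assignment), function(ix) {
    sub <- D2[ix, ix, drop = FALSE]
    min(colSums(sub))
  }, numeric(1)))
}

#' Select the number of temporal clusters
#'
#' Computes within-cluster SSE curves for PAM and for Ward-linkage
#' hierarchical partitions over `k_range`, locates the elbow (maximum
#' second difference of the PAM SSE curve, with the hierarchical elbow as a
#' confirming candidate), and picks the final k by average silhouette among
#' the elbow-region candidates.
#'
#' @param profiles feature x sample Z-profile matrix (>= 4 rows).
#' @param k_range integer range of k to scan (default 1..20, truncated to
#'   n - 1).
#' @param seed recorded; clustering itself is deterministic.
#' @return object of class `cluster_model`: list with `chosen_k`, `medoids`,
#'   `assignment`, `sse_pam`, `sse_hier`, `silhouette` (named by k over the
#'   candidates scanned), `candidates`, `k_range`, `seed`.
#' @export
select_k <- function(profiles, k_range = 1:20, seed = 1L) {
  n <- nrow(profiles)
  if (n < 4) stop("need at least 4 profiles for model selection")
  k_range <- k_range[k_range >= 1 & k_range <= n - 1]
  D <- dist(profiles)
  Dm <- as.matrix(D); D2 <- Dm^2
  hc <- hclust(D, method = "ward.D2")
  fits <- list()
  sse_pam <- sse_hier <- setNames(numeric(length(k_range)), k_range)
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    fit <- kmedoids_pam(D, k, seed)
    fits[[as.character(k)]] <- fit
    sse_pam[i] <- hv_sse(D2, fit$assignment)
    sse_hier[i] <- hv_sse(D2, cutree(hc, k))
  }
  ## elbow region = where the curve stops declining steeply: the last k
  ## whose marginal SSE drop still exceeds 5% of the curve's total range,
  ## plus its neighbours; both curves contribute candidates
  elbow_of <- function(sse) {
    if (length(sse) < 3) return(k_range[which.min(sse)])
    drops <- -diff(sse)
    rng <- sse[1] - min(sse)
    big <- which(drops >= 0.05 * rng)
    if (length(big)) k_range[max(big) + 1L] else k_range[2]
  }
  k_elbow <- elbow_of(sse_pam)
  k_elbow_h <- elbow_of(sse_hier)
  candidates <- sort(unique(c(k_elbow - 1L, k_elbow, k_elbow + 1L,
                              k_elbow_h - 1L, k_elbow_h, k_elbow_h + 1L)))
  candidates <- candidates[candidates >= 2 & candidates %in% k_range]
  if (!length(candidates)) candidates <- min(k_range[k_range >= 2])
  sil <- vapply(candidates, function(k) {
    mean(cluster::silhouette(fits[[as.character(k)]]$assignment, D)[, 3])
  }, numeric(1))
  names(sil) <- candidates
  chosen <- candidates[which.max(sil)]
  fit <- fits[[as.character(chosen)]]
  out <- list(chosen_k = chosen, medoids = fit$medoids,
              assignment = fit$assignment, sse_pam = sse_pam,
              sse_hier = sse_hier, silhouette = sil,
              candidates = candidates, k_range = k_range, seed = seed)
  class(out) <- "cluster_model"
  hv_log("select_k", elbow = k_elbow, hier_elbow = k_elbow_h,
         chosen_k = chosen)
  out
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("Temporal cluster model: chosen k = ", x$chosen_k,
      " (candidates ", paste(x$candidates, collapse = ", "),
      "; silhouette ", paste(signif(x$silhouette, 3), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' @export
plot.cluster_model <- function(x, ...) {
  op <- par(mfrow = c(1, 2)); on.exit(par(op))
  plot(x$k_range, x$sse_pam, type = "b", xlab = "k", ylab = "within SSE",
       main = "PAM (solid) vs Ward (dashed)", ...)
  lines(x$k_range, x$sse_hier, type = "b", lty = 2)
  abline(v = x$chosen_k, col = 2)
  plot(as.integer(names(x$silhouette)), x$silhouette, type = "b", xlab = "k",
       ylab = "average silhouette", main = "candidate silhouettes")
  abline(v = x$chosen_k, col = 2)
  invisible(x)
}

#' Profile clusters by trajectory, viral family, and AMG pathway
#'
#' Per cluster: the mean Z trajectory of its member profiles; total member
#' relative abundance per viral family, Z-scored across clusters; total
#' member relative abundance per AMG KEGG pathway, Z-scored across clusters.
#' Families and pathways absent from a cluster are flagged.
#'
#' @param model a `cluster_model` (or a named assignment vector).
#' @param zprofiles the Z-profile matrix used for clustering.
#' @param abundance an `abundance_matrix` (for total relative abundances).
#' @param taxonomy output of [votu_taxonomy()] (needs `votu_id`, `family`).
#' @param amg data.frame in the `amg` schema (`votu_id`, `kegg_pathway`).
#' @return list: `trajectories` (cluster x sample mean Z), `family_z`,
#'   `family_absent`, `amg_z`, `amg_absent` (family/pathway x cluster).
#' @export
profile_clusters <- function(model, zprofiles, abundance, taxonomy, amg) {
  assignment <- if (inherits(model, "cluster_model")) model$assignment else model
  ks <- sort(unique(assignment))
  traj <- t(vapply(ks, function(k) {
    colMeans(zprofiles[names(assignment)[assignment == k], , drop = FALSE])
  }, numeric(ncol(zprofiles))))
  rownames(traj) <- paste0("cluster_", ks)

  tot <- rowSums(abundance$values)   # total relative abundance per vOTU
  cluster_of <- assignment

  sum_by <- function(map_df, key) {
    ## map_df: votu_id + key column; returns key x cluster total matrix
    map_df <- map_df[map_df$votu_id %in% names(cluster_of), , drop = FALSE]
    lev <- sort(unique(map_df[[key]]))
    m <- matrix(0, length(lev), length(ks), dimnames = list(lev, rownames(traj)))
    if (nrow(map_df)) {
      for (r in seq_len(nrow(map_df))) {
        v <- map_df$votu_id[r]
        m[map_df[[key]][r], paste0("cluster_", cluster_of[[v]])] <-
          m[map_df[[key]][r], paste0("cluster_", cluster_of[[v]])] +
          tot[[v]]
      }
    }
    m
  }
  zrow <- function(m) {
    t(apply(m, 1, function(x) {
      s <- sd(x)
      if (s < 1e-12) rep(0, length(x)) else (x - mean(x)) / s
    }))
  }
  fam_tot <- sum_by(data.frame(votu_id = taxonomy$votu_id,
                               family = taxonomy$family), "family")
  amg_tot <- sum_by(amg[, c("votu_id", "kegg_pathway")], "kegg_pathway")
  list(trajectories = traj,
       family_z = zrow(fam_tot), family_absent = fam_tot == 0,
       amg_z = zrow(amg_tot), amg_absent = amg_tot == 0)
}
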