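## Community ecology statistics implemented from their defining formulas:
## diversity indices, the centred log-ratio transform, non-metric
## multidimensional scaling (isotonic regression + majorization), ANOSIM,
## PERMANOVA, environmental vector fitting, best-subset environmental
## correlation, exact Wilcoxon signed-rank, and two-site abiotic summaries.

## ---------------------------------------------------------------------------
## Diversity
## ---------------------------------------------------------------------------

#' Diversity, evenness, and richness of one sample
#'
#' Shannon H = -sum p_i ln p_i (nats) over nonzero proportions; Pielou
#' J = H / ln S; Chao1 = S + F1(F1-1)/(2(F2+1)) with F1/F2 the singleton and
#' doubleton counts (reported only for integer count input).
#'
#' @param x non-negative abundance or count vector for one sample.
#' @return list: `shannon`, `pielou`, `richness`, `chao1` (NA for
#'   non-integer input).
#' @export
#' @examples
#' diversity_indices(rep(5L, 10))   # H = ln 10, J = 1
diversity_indices <- function(x) {
  if (any(x < 0)) stop("abundances must be non-negative")
  if (all(x == 0)) stop("all-zero abundance vector")
  p <- x[x > 0] / sum(x)
  shannon <- -sum(p * log(p))
  S <- length(p)
  pielou <- if (S > 1) shannon / log(S) else NA_real_
  chao1 <- NA_real_
  if (all(x == round(x))) {
    f1 <- sum(x == 1); f2 <- sum(x == 2)
    chao1 <- S + f1 * (f1 - 1) / (2 * (f2 + 1))
  }
  list(shannon = shannon, pielou = pielou, richness = S, chao1 = chao1)
}

## ---------------------------------------------------------------------------
## CLR and community distances
## ---------------------------------------------------------------------------

#' Centred log-ratio transform
#'
#' Per sample (row): `x -> ln(x + eps) - mean(ln(x + eps))`, so each row
#' sums to zero. The default pseudocount is half the smallest nonzero value
#' in the matrix (compositional practice for zero-laden abundance tables).
#'
#' @param mat samples x features non-negative matrix.
#' @param pseudocount additive epsilon; `NULL` = half the minimum nonzero
#'   value (0 allowed only for strictly positive data).
#' @return matrix of the same shape, rows centred to zero.
#' @export
clr_transform <- function(mat, pseudocount = NULL) {
  if (any(mat < 0)) stop("negative values are not compositional")
  if (is.null(pseudocount)) {
    nz <- mat[mat > 0]
    if (!length(nz)) stop("all-zero matrix")
    pseudocount <- min(nz) / 2
  }
  if (pseudocount == 0 && any(mat == 0)) stop("zero pseudocount with zeros present")
  lx <- log(mat + pseudocount)
  sweep(lx, 1, rowMeans(lx))
}

#' Community distance matrix
#'
#' Default is Euclidean distance on CLR-transformed relative abundances;
#' Bray-Curtis on raw abundances is available as an alternative.
#'
#' @param mat samples x features abundance matrix.
#' @param method `"clr_euclidean"` or `"bray"`.
#' @param pseudocount passed to [clr_transform()].
#' @return a `dist` object over samples.
#' @export
community_distance <- function(mat, method = c("clr_euclidean", "bray"),
                               pseudocount = NULL) {
  method <- match.arg(method)
  if (method == "clr_euclidean") {
    return(dist(clr_transform(mat, pseudocount)))
  }
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    num <- sum(abs(mat[i, ] - mat[j, ]))
    den <- sum(mat[i, ] + mat[j, ])
    d[i, j] <- d[j, i] <- if (den > 0) num / den else 0
  }
  as.dist(d)
}

## ---------------------------------------------------------------------------
## Non-metric multidimensional scaling
## ---------------------------------------------------------------------------

## one majorization run: isotonic disparities + Guttman transform
hv_nmds_run <- function(dvec, n, k, X, max_iter = 300, tol = 1e-7) {
  ord <- order(dvec)
  lower <- lower.tri(matrix(0, n, n))   # column-major, matches dist order
  stress_trace <- numeric(0)
  stress_old <- Inf
  for (it in seq_len(max_iter)) {
    D <- as.vector(dist(X))
    fit <- isoreg(x = seq_along(ord), y = D[ord])   # dvec[ord] nondecreasing
    dhat <- numeric(length(D)); dhat[ord] <- fit$yf
    stress <- sqrt(sum((D - dhat)^2) / sum(D^2))
    stress_trace <- c(stress_trace, stress)
    if (abs(stress_old - stress) < tol) break
    stress_old <- stress
    ## Guttman transform with unit weights
    B <- matrix(0, n, n)
    B[lower] <- -ifelse(D > 0, dhat / D, 0)
    B[upper.tri(B)] <- t(B)[upper.tri(B)]
    diag(B) <- -rowSums(B)
    X <- (B %*% X) / n
  }
  list(X = X, stress = stress_trace[length(stress_trace)],
       stress_trace = stress_trace)
}

#' Non-metric multidimensional scaling
#'
#' Kruskal-style NMDS: disparities by isotonic (monotone) regression of
#' configuration distances on dissimilarity ranks, configuration updates by
#' iterative majorization (Guttman transform), stress-1 reported. Restarts
#' are initialised from classical metric scaling plus seeded jitter; the
#' lowest-stress restart is returned.
#'
#' @param d symmetric dissimilarities (`dist` or matrix, zero diagonal).
#' @param dims embedding dimension (default 2).
#' @param restarts number of random restarts (default 20).
#' @param seed integer seed controlling the jitter.
#' @return object of class `hv_nmds`: list with `points` (samples x dims),
#'   `stress` (Kruskal stress-1), `stress_trace` of the winning restart,
#'   `restarts`, `seed`.
#' @export
nmds_ordination <- function(d, dims = 2L, restarts = 20L, seed = 1L) {
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d))) stop("distance matrix must be symmetric")
    d <- as.dist(d)
  }
  n <- attr(d, "Size")
  dvec <- as.vector(d)
  X0 <- suppressWarnings(cmdscale(d, k = dims))
  if (ncol(X0) < dims) {
    X0 <- cbind(X0, matrix(0, n, dims - ncol(X0)))
  }
  scale0 <- max(sd(as.vector(X0)), 1e-8)
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    Xs <- if (r == 1) X0 else X0 + matrix(rnorm(n * dims, sd = 0.25 * scale0),
                                          n, dims)
    run <- hv_nmds_run(dvec, n, dims, Xs)
    if (is.null(best) || run$stress < best$stress) best <- run
  }
  pts <- best$X
  rownames(pts) <- attr(d, "Labels")
  out <- list(points = pts, stress = best$stress,
              stress_trace = best$stress_trace,
              restarts = restarts, seed = seed)
  class(out) <- "hv_nmds"
  out
}

#' @export
print.hv_nmds <- function(x, ...) {
  cat("NMDS ordination: ", nrow(x$points), " points in ", ncol(x$points),
      "-D, stress-1 = ", signif(x$stress, 4), " (", x$restarts,
      " restarts, seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' @export
plot.hv_nmds <- function(x, groups = NULL, ...) {
  col <- if (is.null(groups)) 1 else as.integer(factor(groups))
  plot(x$points, col = col, pch = 19,
       xlab = "NMDS1", ylab = "NMDS2",
       main = sprintf("NMDS (stress = %.3f)", x$stress), ...)
  invisible(x)
}

## ---------------------------------------------------------------------------
## Permutation machinery
## ---------------------------------------------------------------------------

## all distinct unordered partitions induced by permuting a label vector;
## returns a list of label vectors (one per distinct partition), or NULL
## when there are more than `cap`
hv_enumerate_partitions <- function(grouping, cap = 10000) {
  g <- as.character(grouping)
  sizes <- table(g)
  n_labeled <- exp(lgamma(length(g) + 1) - sum(lgamma(sizes + 1)))
  dup <- table(as.vector(sizes))
  n_part <- n_labeled / prod(factorial(dup))
  if (n_part > cap) return(NULL)
  labs <- names(sizes)
  res <- list()
  seen <- new.env(hash = TRUE)
  rec <- function(remaining_counts, acc) {
    if (!any(remaining_counts > 0)) {
      v <- unlist(acc)
      key <- paste(vapply(split(seq_along(v), v), paste, character(1),
                          collapse = ","), collapse = ";")
      key <- paste(sort(strsplit(key, ";")[[1]]), collapse = ";")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        res[[length(res) + 1L]] <<- v
      }
      return(invisible())
    }
    for (k in which(remaining_counts > 0)) {
      remaining_counts[k] <- remaining_counts[k] - 1L
      rec(remaining_counts, c(acc, labs[k]))
      remaining_counts[k] <- remaining_counts[k] + 1L
    }
  }
  counts <- as.integer(sizes)
  rec(counts, list())
  res
}

## ---------------------------------------------------------------------------
## ANOSIM
## ---------------------------------------------------------------------------

hv_anosim_R <- function(rk, between, n) {
  (mean(rk[between]) - mean(rk[!between])) / (n * (n - 1) / 4)
}

#' Analysis of similarities (ANOSIM)
#'
#' R = (mean between-group rank - mean within-group rank) / (n(n-1)/4) on
#' mid-ranked distances; R = 1 when every between-group distance outranks
#' every within-group one. The p-value uses exhaustive enumeration of
#' distinct relabelings when there are at most 10,000 of them, otherwise
#' random permutations with the add-one rule
#' p = (1 + #{R* >= R}) / (1 + n_perm).
#'
#' @param d `dist` or symmetric matrix.
#' @param grouping factor-like with >= 2 groups of >= 2 members each.
#' @param n_perm random permutations when enumeration is infeasible.
#' @param seed integer seed for the permutation stream.
#' @return list: `R`, `p`, `n_permutations`, `exhaustive`, `seed`.
#' @export
anosim_test <- function(d, grouping, n_perm = 9999L, seed = 1L) {
  if (is.matrix(d)) d <- as.dist(d)
  n <- attr(d, "Size")
  grouping <- as.character(grouping)
  stopifnot(length(grouping) == n)
  sizes <- table(grouping)
  if (length(sizes) < 2) stop("need at least two groups")
  if (any(sizes < 2)) stop("every group needs at least two members")
  rk <- rank(as.vector(d))
  pairs <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  between_of <- function(g) g[pairs[, 1]] != g[pairs[, 2]]
  R_obs <- hv_anosim_R(rk, between_of(grouping), n)
  parts <- hv_enumerate_partitions(grouping)
  if (!is.null(parts)) {
    Rs <- vapply(parts, function(g) hv_anosim_R(rk, between_of(g), n),
                 numeric(1))
    p <- mean(Rs >= R_obs - 1e-12)
    return(list(R = R_obs, p = p, n_permutations = length(parts),
                exhaustive = TRUE, seed = seed))
  }
  set.seed(seed)
  cnt <- 0L
  for (b in seq_len(n_perm)) {
    if (hv_anosim_R(rk, between_of(sample(grouping)), n) >= R_obs - 1e-12)
      cnt <- cnt + 1L
  }
  list(R = R_obs, p = (1 + cnt) / (1 + n_perm), n_permutations = n_perm,
       exhaustive = FALSE, seed = seed)
}

## ---------------------------------------------------------------------------
## PERMANOVA
## ---------------------------------------------------------------------------

hv_permanova_stats <- function(d2vec, pairs, g, n) {
  ss_total <- sum(d2vec) / n
  ss_within <- 0
  for (lev in unique(g)) {
    ing <- g == lev
    sel <- ing[pairs[, 1]] & ing[pairs[, 2]]
    ss_within <- ss_within + sum(d2vec[sel]) / sum(ing)
  }
  ss_between <- ss_total - ss_within
  a <- length(unique(g))
  F <- (ss_between / (a - 1)) / (ss_within / (n - a))
  c(F = F, R2 = ss_between / ss_total)
}

#' Permutational multivariate analysis of variance (one factor)
#'
#' Sums of squares from squared inter-point distances (Gower
#' decomposition): total SS = sum of all squared distances / n, within SS
#' summed per group; pseudo-F = (SS_b/df_b)/(SS_w/df_w); R2 = SS_b/SS_total;
#' permutation p as in [anosim_test()].
#'
#' @inheritParams anosim_test
#' @return list: `pseudo_F`, `R2`, `p`, `n_permutations`, `seed`.
#' @export
permanova_test <- function(d, grouping, n_perm = 9999L, seed = 1L) {
  if (is.matrix(d)) d <- as.dist(d)
  n <- attr(d, "Size")
  grouping <- as.character(grouping)
  stopifnot(length(grouping) == n)
  if (length(unique(grouping)) < 2) stop("need at least two groups")
  d2 <- as.vector(d)^2
  pairs <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  obs <- hv_permanova_stats(d2, pairs, grouping, n)
  parts <- hv_enumerate_partitions(grouping)
  if (!is.null(parts)) {
    Fs <- vapply(parts, function(g) hv_permanova_stats(d2, pairs, g, n)[["F"]],
                 numeric(1))
    p <- mean(Fs >= obs[["F"]] - 1e-12)
    return(list(pseudo_F = obs[["F"]], R2 = obs[["R2"]], p = p,
                n_permutations = length(parts), exhaustive = TRUE, seed = seed))
  }
  set.seed(seed)
  cnt <- 0L
  for (b in seq_len(n_perm)) {
    if (hv_permanova_stats(d2, pairs, sample(grouping), n)[["F"]] >=
        obs[["F"]] - 1e-12) cnt <- cnt + 1L
  }
  list(pseudo_F = obs[["F"]], R2 = obs[["R2"]], p = (1 + cnt) / (1 + n_perm),
       n_permutations = n_perm, exhaustive = FALSE, seed = seed)
}

## ---------------------------------------------------------------------------
## Environmental fitting
## ---------------------------------------------------------------------------

#' Fit one environmental variable onto an ordination
#'
#' r2 is the squared multiple correlation of the variable regressed on the
#' ordination coordinates; the p-value permutes the variable.
#'
#' @param ordination an `hv_nmds` object or a samples x dims coordinate matrix.
#' @param env numeric variable, one value per sample, no missing values.
#' @param n_perm permutations (add-one rule).
#' @param seed integer seed.
#' @return list: `r2`, `p`, `n_permutations`, `seed`.
#' @export
envfit_vector <- function(ordination, env, n_perm = 999L, seed = 1L) {
  X <- if (inherits(ordination, "hv_nmds")) ordination$points else ordination
  stopifnot(length(env) == nrow(X), !anyNA(env))
  if (var(env) == 0) {
    warning("constant environmental variable; r2 = 0")
    return(list(r2 = 0, p = 1, n_permutations = n_perm, seed = seed))
  }
  ## lm warns on exactly collinear (perfect-fit) input; the r2 is still valid
  r2_of <- function(y) suppressWarnings(summary(lm(y ~ X))$r.squared)
  r2 <- r2_of(env)
  set.seed(seed)
  cnt <- 0L
  for (b in seq_len(n_perm)) {
    if (r2_of(sample(env)) >= r2 - 1e-12) cnt <- cnt + 1L
  }
  list(r2 = r2, p = (1 + cnt) / (1 + n_perm), n_permutations = n_perm,
       seed = seed)
}

#' Best environmental-variable subset by rank correlation (bioenv)
#'
#' Exhaustively searches all non-empty subsets of the standardised
#' environmental variables up to `max_size`; for each subset, Euclidean
#' distances over the subset are Spearman-rank-correlated with the community
#' distances (upper triangles); the subset maximising rho is returned with
#' the full search table.
#'
#' @param d_comm community `dist` over samples.
#' @param env data.frame / matrix of numeric variables (columns), no missing
#'   values; standardised internally to zero mean, unit variance.
#' @param max_size largest subset searched; required when more than 20
#'   variables are supplied (combinatorial guard).
#' @return list: `best_subset` (character), `rho`, `table` (data.frame
#'   `subset`, `size`, `rho` for every subset searched).
#' @export
bioenv_search <- function(d_comm, env, max_size = NULL) {
  env <- as.data.frame(env)
  stopifnot(!anyNA(env))
  p <- ncol(env)
  if (p > 20 && is.null(max_size)) {
    stop("more than 20 variables: specify max_size explicitly")
  }
  if (is.null(max_size)) max_size <- p
  Z <- scale(as.matrix(env))
  dv <- as.vector(d_comm)
  rows <- list()
  for (sz in seq_len(min(max_size, p))) {
    for (cols in as.data.frame(combn(p, sz))) {
      de <- as.vector(dist(Z[, cols, drop = FALSE]))
      rho <- suppressWarnings(cor(dv, de, method = "spearman"))
      rows[[length(rows) + 1L]] <- data.frame(
        subset = paste(colnames(env)[cols], collapse = "+"),
        size = sz, rho = rho)
    }
  }
  tab <- do.call(rbind, rows)
  best <- tab[which.max(tab$rho), ]
  list(best_subset = strsplit(best$subset, "+", fixed = TRUE)[[1]],
       rho = best$rho, table = tab)
}

## ---------------------------------------------------------------------------
## Wilcoxon signed-rank (exact)
## ---------------------------------------------------------------------------

#' Paired Wilcoxon signed-rank test with exact two-sided p
#'
#' Zero differences are dropped; ties get mid-ranks. For n <= 25 the null
#' distribution of the positive rank sum is built by complete sign
#' enumeration (dynamic-programming convolution over 2^n assignments); above
#' that a normal approximation with tie correction is used.
#'
#' @param a,b paired numeric vectors (>= 3 nonzero differences).
#' @return list: `w_plus`, `w_minus`, `statistic` (min of the two), `n`,
#'   `p` (two-sided), `exact`.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all paired differences are zero")
  if (n < 3) stop("need at least 3 nonzero differences")
  rk <- rank(abs(d))
  w_plus <- sum(rk[d > 0]); w_minus <- sum(rk[d < 0])
  W <- min(w_plus, w_minus)
  if (n <= 25) {
    ## counts over 2*ranksum (doubling keeps mid-ranks integral)
    r2 <- as.integer(round(2 * rk))
    tot <- sum(r2)
    dp <- numeric(tot + 1); dp[1] <- 1
    for (r in r2) {
      shifted <- c(numeric(r), dp[seq_len(tot + 1 - r)])
      dp <- dp + shifted
    }
    probs <- dp / 2^n
    sums <- (0:tot) / 2
    p <- sum(probs[sums <= min(w_plus, w_minus) + 1e-9]) +
         sum(probs[sums >= max(w_plus, w_minus) - 1e-9])
    p <- min(1, p)
    return(list(w_plus = w_plus, w_minus = w_minus, statistic = W, n = n,
                p = p, exact = TRUE))
  }
  mu <- n * (n + 1) / 4
  ties <- table(rk)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (w_plus - mu) / sqrt(sigma2)
  list(w_plus = w_plus, w_minus = w_minus, statistic = W, n = n,
       p = 2 * pnorm(-abs(z)), exact = FALSE)
}

## ---------------------------------------------------------------------------
## Two-site abiotic summary
## ---------------------------------------------------------------------------

#' Per-site means, contrasts, and paired tests for abiotic variables
#'
#' For each abiotic column: the mean at each site, the first-minus-second
#' site difference, both ratio directions, and the paired Wilcoxon
#' signed-rank p-value over shared sampling dates. With exactly the sites
#' LOC and RB, the contrast is LOC - RB.
#'
#' @param metadata data.frame in the `metadata` schema (two sites).
#' @param variables abiotic columns to summarise (default: all numeric).
#' @return data.frame, one row per variable: `variable`, `mean_<site1>`,
#'   `mean_<site2>`, `difference`, `ratio_12`, `ratio_21`, `wilcoxon_p`.
#' @export
#' @examples
#' site_summary(abiotic_conditions())
site_summary <- function(metadata,
                         variables = c("temp_C", "do_mg_per_L", "salinity_ppt",
                                       "pH", "nh4_uM", "no3_uM", "no2_uM",
                                       "autofluor_cells_per_mL")) {
  sites <- sort(unique(metadata$site))
  if (length(sites) != 2) stop("site_summary expects exactly two sites")
  s1 <- metadata[metadata$site == sites[1], , drop = FALSE]
  s2 <- metadata[metadata$site == sites[2], , drop = FALSE]
  shared <- intersect(as.character(s1$date), as.character(s2$date))
  if (length(shared) < max(nrow(s1), nrow(s2))) {
    warning("unpaired sampling dates; paired test restricted to ",
            length(shared), " shared dates")
  }
  s1 <- s1[match(shared, as.character(s1$date)), , drop = FALSE]
  s2 <- s2[match(shared, as.character(s2$date)), , drop = FALSE]
  rows <- lapply(variables, function(v) {
    m1 <- mean(s1[[v]]); m2 <- mean(s2[[v]])
    p <- tryCatch(wilcoxon_signed_rank(s1[[v]], s2[[v]])$p,
                  error = function(e) NA_real_)
    df <- data.frame(variable = v, m1 = m1, m2 = m2, difference = m1 - m2,
                     ratio_12 = if (m2 != 0) m1 / m2 else NA_real_,
                     ratio_21 = if (m1 != 0) m2 / m1 else NA_real_,
                     wilcoxon_p = p)
    names(df)[2:3] <- paste0("mean_", sites)
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
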