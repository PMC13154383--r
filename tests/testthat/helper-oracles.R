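## Independent oracles and small fixture builders shared across tests.
## Every oracle here is deliberately implemented by a different route than
## the package (full dynamic programming, complete enumeration, naive
## recomputation) so that agreement is evidence, not tautology.

options(halovir.log_level = "quiet")

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_seq <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  if (length(hit)) {
    ch[hit] <- vapply(ch[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  }
  paste(ch, collapse = "")
}

## full dynamic-programming ANI oracle: global alignment, identity over
## aligned (non-gap) columns
dp_ani <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                       Biostrings::DNAString(b),
                                       type = "global")
  nm <- Biostrings::nmatch(aln)
  nm / (nm + Biostrings::nmismatch(aln))
}

## oracle greedy clustering: all pairwise ANI/AF via the DP aligner, then
## the same greedy longest-first rule applied to the full pairwise table
oracle_cluster <- function(contigs, ani_min = 0.95, af_min = 0.85) {
  ids <- names(contigs)[order(-nchar(contigs), names(contigs))]
  dp_pair <- function(a, b) {
    aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                         Biostrings::DNAString(b),
                                         type = "local")
    nm <- Biostrings::nmatch(aln)
    cols <- nm + Biostrings::nmismatch(aln)
    af <- nchar(as.character(Biostrings::pattern(aln))) /
      min(nchar(a), nchar(b))
    ## also try the reverse complement; keep the better-scoring strand
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(b)))
    aln2 <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                          Biostrings::DNAString(rc),
                                          type = "local")
    if (Biostrings::score(aln2) > Biostrings::score(aln)) {
      nm <- Biostrings::nmatch(aln2)
      cols <- nm + Biostrings::nmismatch(aln2)
      af <- nchar(as.character(Biostrings::pattern(aln2))) /
        min(nchar(a), nchar(b))
    }
    c(ani = if (cols > 0) nm / cols else 0, af = min(af, 1))
  }
  reps <- character(0)
  assignment <- setNames(character(length(ids)), ids)
  for (id in ids) {
    best <- NULL; best_ani <- -1
    for (r in reps) {
      p <- dp_pair(contigs[[r]], contigs[[id]])
      if (p["ani"] >= ani_min && p["af"] >= af_min && p["ani"] > best_ani) {
        best <- r; best_ani <- p["ani"]
      }
    }
    if (is.null(best)) { reps <- c(reps, id); best <- id }
    assignment[id] <- best
  }
  assignment
}

## naive bioenv recomputation (independent loop, no shared helpers)
naive_bioenv <- function(d_comm, env, max_size = ncol(env)) {
  Z <- scale(as.matrix(env))
  dv <- as.vector(d_comm)
  best_rho <- -Inf; best <- NULL; n_eval <- 0L
  p <- ncol(env)
  for (sz in seq_len(max_size)) {
    combs <- combn(p, sz)
    for (ci in seq_len(ncol(combs))) {
      n_eval <- n_eval + 1L
      de <- as.vector(dist(Z[, combs[, ci], drop = FALSE]))
      rho <- suppressWarnings(cor(dv, de, method = "spearman"))
      if (rho > best_rho) { best_rho <- rho; best <- colnames(env)[combs[, ci]] }
    }
  }
  list(best_subset = best, rho = best_rho, n_eval = n_eval)
}

## literal complete sign enumeration for the Wilcoxon signed-rank null
enum_wilcoxon_p <- function(a, b) {
  d <- a - b; d <- d[d != 0]
  rk <- rank(abs(d))
  n <- length(d)
  w_plus <- sum(rk[d > 0]); w_minus <- sum(rk[d < 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  sums <- as.vector(signs %*% rk)
  mean(sums <= min(w_plus, w_minus) + 1e-9) +
    mean(sums >= max(w_plus, w_minus) - 1e-9)
}

## adjusted Rand index via mclust (independent of the package)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

## small default simulation shared by recovery tests (kept modest for
## runtime; problem sizes documented in the methods vignette)
small_sim_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_votus = 24L, contigs_per_votu = c(1L, 2L),
         contig_length_range = c(10050L, 11000L)),
    list(...))
  do.call(sim_config, args)
}

## map a fitted pipeline's vOTUs to planted temporal clusters
planted_clusters_of <- function(res, sim) {
  rep_base <- base_name(res$votus$votus$representative)
  tc <- sim$truth$temporal_cluster[sim$truth$votu_assignment[rep_base]]
  setNames(tc, res$votus$votus$votu_id)
}
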