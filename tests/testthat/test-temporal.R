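test_that("size factors follow the median-of-ratios contract", {
  A <- matrix(rpois(40, 50) + 1, 10, 4)
  colnames(A) <- paste0("s", 1:4)
  ## doubling a column doubles its factor relative to the others
  B <- cbind(A[, 1, drop = FALSE], A[, 1, drop = FALSE] * 2)
  colnames(B) <- c("x", "y")
  sf <- size_factors(B)
  expect_equal(unname(sf[["y"]] / sf[["x"]]), 2)
  expect_equal(exp(mean(log(sf))), 1)
  ## identical columns: all factors 1
  C <- cbind(A[, 1], A[, 1], A[, 1]); colnames(C) <- paste0("c", 1:3)
  expect_equal(unname(size_factors(C)), rep(1, 3))
  ## single feature: factors proportional to its counts
  D <- matrix(c(10, 20, 40), 1, dimnames = list("f", paste0("d", 1:3)))
  sfd <- size_factors(D)
  expect_equal(unname(sfd / sfd[1]), c(1, 2, 4))
  ## a fully zero sample is an error
  E <- cbind(A[, 1], 0); colnames(E) <- c("ok", "empty")
  expect_error(size_factors(E), "empty")
})

test_that("Z-profiles are standardised, linear profiles drop out, spikes
           dominate", {
  set.seed(91)
  n_s <- 8
  ## constant background rows keep all size factors exactly 1
  counts <- matrix(rep(c(60, 45, 80), each = n_s), 3, n_s, byrow = TRUE)
  counts <- rbind(counts, counts[1, ], counts[1, ])
  dimnames(counts) <- list(paste0("v", 1:5), paste0("s", 1:n_s))
  ## v1: count + 1 = 3^t, so log1p is exactly linear in time and the
  ## detrended residual is identically zero
  counts[1, ] <- 3^(1:n_s) - 1
  ## v2: single spike
  counts[2, ] <- 50; counts[2, 7] <- 5000
  z <- normalize_detrend_scale(counts)
  expect_false("v1" %in% rownames(z))
  expect_true("v1" %in% attr(z, "dropped"))
  expect_identical(unname(which.max(z["v2", ])), 7L)
  expect_equal(unname(rowMeans(z)), rep(0, nrow(z)), tolerance = 1e-10)
  expect_equal(unname(apply(z, 1, sd)), rep(1, nrow(z)), tolerance = 1e-10)
  expect_error(normalize_detrend_scale(counts[, 1:2]), "3 samples")
})

test_that("PAM: k = 1 medoid minimises total distance (brute force); k = n is
           trivial; the objective never increases across swaps", {
  set.seed(92)
  X <- matrix(rnorm(24), 8, 3, dimnames = list(paste0("p", 1:8), NULL))
  D <- as.matrix(dist(X))
  fit1 <- kmedoids_pam(X, 1)
  brute <- rownames(D)[which.min(colSums(D))]
  expect_identical(fit1$medoids, brute)
  expect_equal(fit1$objective, min(colSums(D)))

  fitn <- kmedoids_pam(X, 8)
  expect_equal(fitn$objective, 0)
  expect_setequal(fitn$medoids, rownames(X))

  fit3 <- kmedoids_pam(X, 3)
  expect_true(all(diff(fit3$objective_trace) <= 1e-12))
  expect_error(kmedoids_pam(X, 9), "k must be")
})

test_that("PAM separates two planted groups and matches cluster::pam's
           objective on random data", {
  set.seed(93)
  X <- rbind(matrix(rnorm(30, 0, 0.3), 10, 3),
             matrix(rnorm(30, 6, 0.3), 10, 3))
  rownames(X) <- paste0("q", 1:20)
  fit <- kmedoids_pam(X, 2)
  expect_equal(ari(fit$assignment, rep(1:2, each = 10)), 1)

  Y <- matrix(rnorm(60), 15, 4, dimnames = list(paste0("y", 1:15), NULL))
  mine <- kmedoids_pam(Y, 3)
  ref <- cluster::pam(dist(Y), 3)
  ## both optimise the same criterion to a local optimum; ours must be at
  ## least as good as the reference solution it is compared with
  ref_obj <- sum(as.matrix(dist(Y))[cbind(seq_len(15),
                                          match(ref$medoids, rownames(Y))[
                                            ref$clustering])])
  expect_lte(mine$objective, ref_obj + 1e-8)
  expect_equal(mine$objective, ref_obj, tolerance = 0.05)
})

test_that("select_k scans both curves and returns the planted k on separated
           fixtures", {
  set.seed(94)
  ## three well-separated profile groups
  mk <- function(center, n) {
    t(vapply(seq_len(n), function(i) center + rnorm(8, 0, 0.3),
             numeric(8)))
  }
  prof <- rbind(mk(c(3, 3, 0, 0, 0, 0, 0, 0), 7),
                mk(c(0, 0, 0, 3, 3, 0, 0, 0), 7),
                mk(c(0, 0, 0, 0, 0, 0, 3, 3), 7))
  rownames(prof) <- paste0("z", 1:21)
  model <- select_k(prof, k_range = 1:10, seed = 1)
  expect_identical(model$chosen_k, 3L)
  expect_equal(ari(model$assignment, rep(1:3, each = 7)), 1)
  expect_identical(length(model$sse_pam), 10L)
  expect_true(all(model$silhouette >= -1 & model$silhouette <= 1))
  ## determinism
  model2 <- select_k(prof, k_range = 1:10, seed = 1)
  expect_identical(model$assignment, model2$assignment)

  ## a single gaussian blob: low silhouettes, but curves return cleanly
  blob <- matrix(rnorm(160), 20, 8, dimnames = list(paste0("b", 1:20), NULL))
  mb <- select_k(blob, k_range = 1:8, seed = 1)
  expect_true(all(mb$silhouette < 0.5))
  expect_identical(length(mb$sse_hier), 8L)
  expect_error(select_k(prof[1:3, ]), "at least 4")
})

test_that("cluster profiles recover planted family and AMG enrichment", {
  sim <- simulate_virome(small_sim_config(seed = 95))
  res <- run_virome_pipeline(sim, load_config(), stats = FALSE)
  pr <- res$temporal$profiles
  ## planted AMG pathway has the top Z in its planted cluster
  model <- res$temporal$model
  tc <- planted_clusters_of(res, sim)
  ## map each fitted cluster to its dominant planted cluster
  common <- names(model$assignment)[!is.na(tc[names(model$assignment)])]
  maj <- tapply(tc[common], model$assignment[common], function(x)
    as.integer(names(sort(table(x), decreasing = TRUE))[1]))
  hits <- 0L; tot <- 0L
  for (fc in names(maj)) {
    planted_k <- maj[[fc]]
    pw <- sim$truth$enriched_pathway[[as.character(planted_k)]]
    col <- paste0("cluster_", fc)
    if (!pw %in% rownames(pr$amg_z)) next
    tot <- tot + 1L
    if (which.max(pr$amg_z[, col]) == match(pw, rownames(pr$amg_z)))
      hits <- hits + 1L
  }
  expect_gte(hits / tot, 0.6)
  ## absent pathways are flagged
  expect_identical(dim(pr$amg_absent), dim(pr$amg_z))
  ## trajectories have one row per cluster
  expect_identical(nrow(pr$trajectories), length(unique(model$assignment)))
})
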