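test_that("diversity indices match their closed forms", {
  u <- diversity_indices(rep(5L, 10))
  expect_equal(u$shannon, log(10))
  expect_equal(u$pielou, 1)
  expect_identical(u$richness, 10L)

  one <- diversity_indices(c(7L, 0L, 0L))
  expect_equal(one$shannon, 0)
  expect_identical(one$richness, 1L)

  ## no singletons -> chao1 equals richness; with them it exceeds it
  expect_equal(diversity_indices(c(5L, 3L, 8L))$chao1, 3)
  rich <- diversity_indices(c(1L, 1L, 2L, 5L))
  expect_equal(rich$chao1, 4 + 2 * 1 / (2 * 2))
  expect_true(is.na(diversity_indices(c(0.5, 1.3))$chao1))
  expect_error(diversity_indices(c(0, 0)), "all-zero")

  ## shannon <= ln(richness) on random abundance vectors
  set.seed(81)
  for (i in 1:20) {
    x <- rpois(30, 3)
    if (all(x == 0)) next
    d <- diversity_indices(x)
    expect_lte(d$shannon, log(d$richness) + 1e-12)
  }
})

test_that("CLR rows centre to zero and ignore per-sample scaling", {
  m <- matrix(c(4, 4, 4, 1, 2, 3), nrow = 2, byrow = TRUE)
  z <- clr_transform(m, pseudocount = 0)
  expect_equal(z[1, ], rep(0, 3))
  expect_equal(rowSums(z), c(0, 0))
  ## scale invariance per sample with zero pseudocount on positive data
  z2 <- clr_transform(m * c(10, 0.5), pseudocount = 0)
  expect_equal(z, z2)
  ## default pseudocount = half the smallest nonzero value
  m0 <- matrix(c(0, 2, 8, 4), 2)
  z0 <- clr_transform(m0)
  expect_equal(rowSums(z0), c(0, 0))
})

test_that("NMDS embeds planar and 3-point configurations at ~zero stress,
           deterministically", {
  set.seed(82)
  X <- matrix(rnorm(20), 10, 2)
  ord <- nmds_ordination(dist(X), restarts = 5, seed = 9)
  expect_lt(ord$stress, 0.01)
  ## stress trace non-increasing within the winning restart
  expect_true(all(diff(ord$stress_trace) <= 1e-8))

  d3 <- matrix(c(0, 2, 5, 2, 0, 4, 5, 4, 0), 3)
  expect_lt(nmds_ordination(d3, restarts = 3, seed = 1)$stress, 1e-3)

  ord2 <- nmds_ordination(dist(X), restarts = 5, seed = 9)
  expect_identical(ord$points, ord2$points)
  expect_error(nmds_ordination(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("ANOSIM: exhaustive enumeration on the separated 3+3 toy gives
           R = 1, p = 1/10; degenerate inputs behave", {
  ## two tight groups far apart: all between-ranks exceed within-ranks
  x <- c(0, 0.1, 0.2, 10, 10.1, 10.2)
  d <- dist(x)
  g <- rep(c("a", "b"), each = 3)
  r <- anosim_test(d, g)
  expect_equal(r$R, 1)
  expect_true(r$exhaustive)
  expect_identical(r$n_permutations, 10L)
  expect_equal(r$p, 1 / 10)

  ## all distances equal -> R = 0
  deq <- as.dist(matrix(1, 4, 4) - diag(4))
  expect_equal(anosim_test(deq, c("a", "a", "b", "b"))$R, 0)

  expect_error(anosim_test(d, c("a", rep("b", 5))), "at least two members")
  ## rank-based: any monotone transform of distances leaves R unchanged
  r2 <- anosim_test(d^2, g)
  expect_equal(r2$R, r$R)
})

test_that("ANOSIM R is near zero under shuffled labels", {
  set.seed(83)
  d <- dist(matrix(rnorm(40), 20, 2))
  Rs <- replicate(30, anosim_test(d, sample(rep(c("a", "b"), 10)),
                                  n_perm = 19, seed = 1)$R)
  expect_lt(abs(mean(Rs)), 0.1)
})

test_that("PERMANOVA matches direct sums-of-squares computation and vegan", {
  set.seed(84)
  ## two tight, well-separated clouds
  X <- rbind(matrix(rnorm(20, 0, 0.1), 10, 2),
             matrix(rnorm(20, 5, 0.1), 10, 2))
  g <- rep(c("a", "b"), each = 10)
  d <- dist(X)
  r <- permanova_test(d, g, n_perm = 199, seed = 2)
  expect_gt(r$R2, 0.9)
  ## direct SS computation
  n <- 20
  ss_tot <- sum(as.vector(d)^2) / n
  dm <- as.matrix(d)
  ss_w <- sum(dm[1:10, 1:10][lower.tri(dm[1:10, 1:10])]^2) / 10 +
    sum(dm[11:20, 11:20][lower.tri(dm[11:20, 11:20])]^2) / 10
  expect_equal(r$R2, (ss_tot - ss_w) / ss_tot)
  expect_equal(r$pseudo_F, ((ss_tot - ss_w) / 1) / (ss_w / 18))
  ## agreement with the independent vegan implementation
  av <- vegan::adonis2(d ~ g, permutations = 99)
  expect_equal(r$pseudo_F, av$F[1])
  expect_equal(r$R2, av$R2[1])

  ## duplicated points within groups, distinct across -> R2 = 1
  Y <- rbind(matrix(1, 3, 2), matrix(9, 3, 2))
  rdup <- permanova_test(dist(Y), rep(c("a", "b"), each = 3))
  expect_equal(rdup$R2, 1)
  expect_error(permanova_test(d, rep("a", 20)), "two groups")
})

test_that("PERMANOVA R2 under label-independent distances concentrates near
           df_b/(n-1)", {
  set.seed(85)
  n <- 16
  d <- dist(matrix(rnorm(n * 4), n, 4))
  r2s <- replicate(60, {
    g <- sample(rep(c("a", "b"), n / 2))
    permanova_test(d, g, n_perm = 9, seed = 1)$R2
  })
  expect_equal(mean(r2s), 1 / (n - 1), tolerance = 0.35)
})

test_that("ANOSIM agrees with vegan on random data", {
  set.seed(86)
  d <- dist(matrix(rnorm(24), 12, 2))
  g <- rep(c("a", "b"), each = 6)
  mine <- anosim_test(d, g, n_perm = 99, seed = 1)
  veg <- vegan::anosim(d, g, permutations = 99)
  expect_equal(mine$R, unname(veg$statistic))
})

test_that("environmental vector fitting gives r2 = 1 on a coordinate and 0
           on a constant", {
  set.seed(87)
  X <- matrix(rnorm(40), 20, 2)
  expect_equal(envfit_vector(X, X[, 1], n_perm = 49, seed = 1)$r2, 1)
  expect_warning(r0 <- envfit_vector(X, rep(2, 20)), "constant")
  expect_equal(r0$r2, 0)
  rn <- envfit_vector(X, rnorm(20), n_perm = 49, seed = 1)
  expect_lt(rn$r2, 0.4)
})

test_that("bioenv equals its naive re-computation and finds the generating
           variable", {
  set.seed(88)
  n <- 14
  env <- data.frame(sal = rnorm(n), temp = rnorm(n), ph = rnorm(n),
                    no3 = rnorm(n))
  ## community distances generated from sal alone
  d <- dist(scale(env$sal))
  r <- bioenv_search(d, env)
  expect_identical(nrow(r$table), 15L)     # 2^4 - 1 subsets
  expect_identical(r$best_subset, "sal")
  expect_gt(r$rho, 0.99)
  nb <- naive_bioenv(d, env)
  expect_identical(sort(r$best_subset), sort(nb$best_subset))
  expect_equal(r$rho, nb$rho)
  expect_identical(nrow(r$table), nb$n_eval)

  ## all-noise environment: best rho stays small
  set.seed(89)
  d2 <- dist(matrix(rnorm(n * 6), n, 6))
  r2 <- bioenv_search(d2, env)
  expect_lt(r2$rho, 0.5)
})

test_that("exact Wilcoxon signed-rank matches complete sign enumeration", {
  md <- abiotic_conditions()
  loc <- md[md$site == "LOC", ]
  rb <- md[md$site == "RB", ]
  w <- wilcoxon_signed_rank(loc$salinity_ppt, rb$salinity_ppt)
  expect_identical(w$w_minus, 1)
  expect_equal(w$p, 0.015625)
  expect_equal(w$p, enum_wilcoxon_p(loc$salinity_ppt, rb$salinity_ppt))
  expect_true(w$exact)

  ## all differences one-signed: analytically forced minimum 2/2^n two-sided
  a <- 1:8; b <- a - 1
  expect_equal(wilcoxon_signed_rank(a, b)$p, 2 / 256)
  expect_error(wilcoxon_signed_rank(a, a), "zero")

  ## agreement with stats::wilcox.test exact p on tie-free data
  set.seed(90)
  for (i in 1:5) {
    x <- rnorm(10); y <- rnorm(10)
    expect_equal(wilcoxon_signed_rank(x, y)$p,
                 wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value)
  }
})

test_that("site summary reproduces the abiotic contrasts of the two sites", {
  ss <- site_summary(abiotic_conditions())
  row <- function(v) ss[ss$variable == v, ]
  expect_equal(round(row("temp_C")$difference, 1), 1.4)
  expect_equal(round(row("salinity_ppt")$difference, 1), 17.9)
  expect_equal(round(row("autofluor_cells_per_mL")$ratio_12, 1), 12.3)
  expect_equal(round(row("nh4_uM")$ratio_21, 1), 3.5)
  expect_lt(row("salinity_ppt")$wilcoxon_p, 0.05)
  ## identical columns give difference 0 and ratio 1
  md <- abiotic_conditions()
  md$pH <- rep(md$pH[1:8], 2)
  ss2 <- site_summary(md)
  expect_equal(ss2$difference[ss2$variable == "pH"], 0)
  expect_equal(ss2$ratio_12[ss2$variable == "pH"], 1)
  expect_true(is.na(ss2$wilcoxon_p[ss2$variable == "pH"]))
})
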