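test_that("coverage breadth merges overlaps and respects bounds", {
  expect_equal(coverage_breadth(data.frame(start = 0, end = 7600), 10000), 0.76)
  expect_equal(coverage_breadth(data.frame(start = c(0, 400),
                                           end = c(600, 1000)), 1000), 1.0)
  expect_equal(coverage_breadth(data.frame(start = integer(0),
                                           end = integer(0)), 1000), 0)
  expect_error(coverage_breadth(data.frame(start = 0, end = 1200), 1000),
               "0-based half-open")
})

test_that("detection is strictly above the threshold", {
  expect_true(detect_votu(0.76))
  expect_false(detect_votu(0.75))
  expect_false(detect_votu(0))
  ## monotone: adding intervals never un-detects
  iv <- data.frame(start = c(0, 5000), end = c(4000, 9000))
  b1 <- coverage_breadth(iv, 10000)
  b2 <- coverage_breadth(rbind(iv, data.frame(start = 9000, end = 9500)), 10000)
  expect_gte(b2, b1)
  expect_true(!detect_votu(b1) || detect_votu(b2))
})

test_that("normalisation follows reads / kbp / million reads", {
  expect_equal(normalize_abundance(1000, 10000, 1e7), 10)
  expect_equal(normalize_abundance(0, 10000, 1e7), 0)
  x <- normalize_abundance(500, 12000, 8e6)
  expect_equal(normalize_abundance(500, 12000, 1.6e7), x / 2)
  expect_error(normalize_abundance(10, 0, 1e6), "length")
  expect_error(normalize_abundance(10, 1000, 0), "total")
})

make_two_votu_world <- function() {
  set.seed(61)
  s1 <- rand_seq(1000); s2 <- rand_seq(2000)
  contigs <- c(r1 = s1, r1b = mutate_seq(s1, 0.02), r2 = s2)
  votus <- cluster_votus(contigs)
  list(contigs = contigs, votus = votus,
       lens = setNames(nchar(contigs), names(contigs)),
       depths = c(sA = 1e6, sB = 2e6))
}

test_that("matrix build sums member counts, filters by representative breadth,
           and keeps raw counts intact", {
  w <- make_two_votu_world()
  counts <- data.frame(sample_id = c("sA", "sA", "sA", "sB"),
                       contig_id = c("r1", "r1b", "r2", "r2"),
                       reads = c(100L, 50L, 80L, 40L))
  ## full breadth for vOTU(r2) in both samples; none for vOTU(r1)
  coverage <- data.frame(sample_id = c("sA", "sB"),
                         contig_id = c("r2", "r2"),
                         start = c(0L, 0L), end = c(2000L, 2000L))
  am <- build_abundance_matrix(counts, coverage, w$votus, w$lens, w$depths)
  v1 <- w$votus$assignment$votu_id[w$votus$assignment$contig_id == "r1"]
  v2 <- w$votus$assignment$votu_id[w$votus$assignment$contig_id == "r2"]
  expect_equal(am$counts[v1, "sA"], 150)       # member sum preserved
  expect_equal(am$values[v1, "sA"], 0)         # not detected -> zeroed
  expect_equal(am$values[v2, "sA"], 80 / 2 / 1)  # 80 reads, 2 kbp, 1 M reads
  expect_equal(am$values[v2, "sB"], 40 / 2 / 2)
  expect_true(all(am$values[!am$detected] == 0))
  expect_error(build_abundance_matrix(
    transform(counts, sample_id = "ghost"), coverage, w$votus, w$lens,
    w$depths), "ghost")
})

test_that("full breadth everywhere reduces filtering to plain normalisation", {
  w <- make_two_votu_world()
  counts <- data.frame(sample_id = rep(c("sA", "sB"), each = 2),
                       contig_id = rep(c("r1", "r2"), 2),
                       reads = c(10L, 20L, 30L, 40L))
  coverage <- expand.grid(sample_id = c("sA", "sB"),
                          contig_id = c("r1", "r2"),
                          stringsAsFactors = FALSE)
  coverage$start <- 0L
  coverage$end <- w$lens[coverage$contig_id]
  am <- build_abundance_matrix(counts, coverage, w$votus, w$lens, w$depths)
  expect_true(all(am$detected))
  manual <- normalize_abundance(
    am$counts, matrix(am$lengths, nrow = 2, ncol = 2),
    matrix(w$depths, nrow = 2, ncol = 2, byrow = TRUE))
  expect_equal(am$values, manual)
  ## conservation: values x lengths x depth / 1e9 re-sums to mapped reads
  recon <- sweep(sweep(am$values, 1, am$lengths / 1000, "*"), 2,
                 w$depths / 1e6, "*")
  expect_equal(sum(recon), sum(am$counts))
})

test_that("on the synthetic fixture the detected set equals planted presence", {
  sim <- simulate_virome(small_sim_config(seed = 62))
  cfg <- load_config()
  res <- run_virome_pipeline(sim, cfg, stats = FALSE)
  det <- res$abundance$detected
  truth_presence <- sim$truth$true_abundance > 0
  rep_base <- base_name(res$votus$votus$representative)
  planted <- sim$truth$votu_assignment[rep_base]
  keep <- !is.na(planted) & planted %in% rownames(truth_presence)
  agree <- mapply(function(vid, pid) {
    identical(unname(det[vid, colnames(truth_presence)]),
              unname(truth_presence[pid, ]))
  }, res$votus$votus$votu_id[keep], planted[keep])
  expect_gte(mean(agree), 0.95)
})
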