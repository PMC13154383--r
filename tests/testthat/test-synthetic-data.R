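test_that("configuration validation catches degenerate settings", {
  expect_error(sim_config(n_samples = 0L), "positive")
  expect_error(sim_config(n_samples = 7L), "even")
  expect_error(sim_config(contig_length_range = c(0L, 100L)), "positive")
  expect_error(sim_config(predictor_fpr = c(a = -0.1, b = 0, c = 0, d = 0)),
               "\\[0, 1\\]")
  expect_error(sim_config(within_votu_divergence = 0.06), "0.05")
})

test_that("metadata has the pulse and freeze structure and site contrasts", {
  cfg <- sim_config(seed = 7)
  md <- generate_metadata(cfg)
  expect_identical(nrow(md), 16L)
  for (s in c("LOC", "RB")) {
    sal <- md$salinity_ppt[md$site == s]
    expect_identical(sum(sal < 32), 1L)          # exactly one pulse date
  }
  expect_identical(sum(md$post_freeze), 4L)       # two winter dates x 2 sites
  fr <- sort(unique(md$date[md$post_freeze]))
  expect_identical(length(fr), 2L)
  ## distribution parameters are recorded for the output header
  expect_false(is.null(attr(md, "dist_params")))

  ## over seeds, the LOC - RB salinity contrast reproduces ~17.9 ppt
  diffs <- vapply(1:20, function(s) {
    m <- generate_metadata(sim_config(seed = s))
    mean(m$salinity_ppt[m$site == "LOC"]) -
      mean(m$salinity_ppt[m$site == "RB"])
  }, numeric(1))
  expect_equal(mean(diffs), 17.9, tolerance = 0.15)
})

test_that("generation is deterministic: same seed, byte-identical outputs", {
  cfg <- small_sim_config(seed = 8)
  s1 <- simulate_virome(cfg)
  s2 <- simulate_virome(small_sim_config(seed = 8))
  expect_identical(s1$contigs, s2$contigs)
  expect_identical(s1$calls, s2$calls)
  expect_identical(s1$read_counts, s2$read_counts)
  expect_identical(s1$metadata, s2$metadata)
  ## and FASTA bytes on disk
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fixture(s1, d1); write_fixture(s2, d2)
  expect_identical(readLines(file.path(d1, "contigs.fasta")),
                   readLines(file.path(d2, "contigs.fasta")))
  ## a different seed changes the sequences
  s3 <- simulate_virome(small_sim_config(seed = 9))
  expect_false(identical(s1$contigs, s3$contigs))
})

test_that("planted vOTU structure: sibling contigs stay above 95% DP identity,
           single-member config gives a bijection", {
  set.seed(110)
  sim <- simulate_virome(small_sim_config(seed = 10))
  truth <- sim$truth
  planted <- rownames(truth$true_abundance)
  checked <- 0L
  for (v in planted) {
    mem <- names(truth$votu_assignment)[truth$votu_assignment == v]
    if (length(mem) < 2 || checked >= 6) next
    checked <- checked + 1L
    pair <- sample(mem, 2)
    a <- substr(sim$contigs[[pair[1]]], 1, 2000)
    b <- substr(sim$contigs[[pair[2]]], 1, 2000)
    expect_gte(dp_ani(a, b), 0.95)
  }
  expect_gt(checked, 0L)

  one <- simulate_virome(small_sim_config(seed = 11,
                                          contigs_per_votu = c(1L, 1L),
                                          decoy_fraction = 0,
                                          short_viral_fraction = 0))
  expect_identical(anyDuplicated(one$truth$votu_assignment), 0L)
  expect_identical(length(one$truth$votu_assignment),
                   length(unique(one$truth$votu_assignment)))
})

test_that("every contig appears exactly once in the ground truth and
           alignments respect planted absences", {
  sim <- simulate_virome(small_sim_config(seed = 12))
  base_ids <- setdiff(names(sim$contigs),
                      grep("\\|\\|", names(sim$contigs), value = TRUE))
  expect_setequal(names(sim$truth$votu_assignment), base_ids)
  ## zero planted abundance -> no detectable breadth for the representative
  truth <- sim$truth
  for (v in rownames(truth$true_abundance)[1:5]) {
    rep_id <- truth$representative[[v]]
    for (s in colnames(truth$true_abundance)) {
      if (truth$true_abundance[v, s] > 0) next
      cov <- sim$coverage[sim$coverage$contig_id == rep_id &
                            sim$coverage$sample_id == s, ]
      b <- coverage_breadth(cov, nchar(sim$contigs[[rep_id]]))
      expect_lte(b, 0.75)
    }
  }
})

test_that("generated tables round-trip losslessly through the readers", {
  sim <- simulate_virome(small_sim_config(seed = 13))
  d <- withr::local_tempdir()
  write_fixture(sim, d)
  back <- read_fixture(d)
  expect_identical(back$contigs, sim$contigs)
  expect_equal(back$calls, sim$calls, ignore_attr = TRUE)
  expect_equal(back$read_counts, sim$read_counts, ignore_attr = TRUE)
  expect_equal(back$coverage, sim$coverage, ignore_attr = TRUE)
  expect_equal(back$mags, sim$mags, ignore_attr = TRUE)
  expect_equal(back$sample_depths, sim$sample_depths)
  ## metadata column set (post_freeze travels as an extra column)
  expect_true(all(c("site", "date", "salinity_ppt") %in% names(back$metadata)))
})
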