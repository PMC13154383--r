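make_calls <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(contig_id = r[[1]], predictor = r[[2]],
               called_length_bp = nchar(r[[3]]))))
}

test_that("retain-shortest collapses trimmed variants with supporter union", {
  set.seed(21)
  full <- rand_seq(15000)
  trimmed <- substr(full, 1001, 13000)
  contigs <- c(c1 = full, `c1||1001-13000` = trimmed)
  calls <- make_calls(list("c1", "A", full),
                      list("c1||1001-13000", "B", trimmed))
  rec <- dedupe_calls(calls, contigs)
  expect_identical(nrow(rec), 1L)
  expect_identical(rec$kept_contig_id, "c1||1001-13000")
  expect_identical(rec$kept_length_bp, 12000L)
  expect_identical(rec$supporting_predictors, "A,B")
  expect_identical(rec$n_predictors, 2L)
})

test_that("exact duplicate sequences under two names collapse to one record", {
  set.seed(22)
  s <- rand_seq(11000)
  contigs <- c(x1 = s, x2 = s)
  calls <- make_calls(list("x1", "A", s), list("x2", "B", s))
  rec <- dedupe_calls(calls, contigs)
  expect_identical(nrow(rec), 1L)
  expect_identical(rec$kept_contig_id, "x1")   # lexicographic canonical id
  expect_identical(rec$supporting_predictors, "A,B")
})

test_that("single calls pass through; unknown contigs are errors; the vote
           counts distinct predictors", {
  set.seed(23)
  s <- rand_seq(12000)
  rec <- dedupe_calls(make_calls(list("c9", "A", s)), c(c9 = s))
  expect_identical(rec$kept_contig_id, "c9")
  expect_identical(rec$n_predictors, 1L)

  expect_error(dedupe_calls(make_calls(list("ghost", "A", s)), c(c9 = s)),
               "ghost")

  ## two calls from one predictor still count once
  rec2 <- dedupe_calls(rbind(make_calls(list("c9", "A", s)),
                             make_calls(list("c9", "A", s))), c(c9 = s))
  expect_identical(rec2$n_predictors, 1L)
})

test_that("length and vote filters use strict > 10 kbp and >= 2 tools", {
  rec <- data.frame(base_name = c("a", "b", "c"),
                    kept_contig_id = c("a", "b", "c"),
                    kept_length_bp = c(12000L, 10000L, 50000L),
                    supporting_predictors = c("A,B", "A,B,C,D", "A"),
                    n_predictors = c(2L, 4L, 1L))
  out <- consensus_filter(rec)
  expect_identical(out$passed, c(TRUE, FALSE, FALSE))
  expect_identical(out$fail_reason,
                   c("none", "too_short", "insufficient_votes"))
  ## 10,001 bp passes the strict bound
  rec$kept_length_bp[2] <- 10001L
  expect_true(consensus_filter(rec)$passed[2])
})

test_that("consensus output is order-independent and monotone in thresholds", {
  set.seed(24)
  contigs <- setNames(vapply(rep(11000, 6), rand_seq, character(1)),
                      paste0("c", 1:6))
  calls <- do.call(rbind, lapply(1:6, function(i) {
    preds <- sample(LETTERS[1:4], sample(1:4, 1))
    data.frame(contig_id = paste0("c", i), predictor = preds,
               called_length_bp = 11000L)
  }))
  a <- consensus_filter(dedupe_calls(calls, contigs))
  b <- consensus_filter(dedupe_calls(calls[sample(nrow(calls)), ], contigs))
  expect_identical(a, b)
  ## monotone: raising either threshold never grows the passing set
  n_pass <- function(len, tools)
    sum(consensus_filter(dedupe_calls(calls, contigs), len, tools)$passed)
  expect_true(n_pass(10000, 2) >= n_pass(12000, 2))
  expect_true(n_pass(10000, 2) >= n_pass(10000, 3))
})

test_that("perfect predictors recover exactly the long viral contigs", {
  cfg <- small_sim_config(seed = 31,
                          predictor_sensitivity = c(vibrant = 1, virsorter2 = 1,
                                                    checkv = 1, genomad = 1),
                          predictor_fpr = c(vibrant = 0, virsorter2 = 0,
                                            checkv = 0, genomad = 0),
                          trimmed_fraction = 0)
  sim <- simulate_virome(cfg)
  rec <- consensus_filter(dedupe_calls(sim$calls, sim$contigs))
  passing <- rec$kept_contig_id[rec$passed]
  truth_long <- names(sim$contigs)[sim$truth$viral_flag[names(sim$contigs)] &
                                     nchar(sim$contigs) > 10000]
  expect_setequal(passing, truth_long)
  ## every call is predictor x viral contig
  expect_identical(nrow(sim$calls), 4L * sum(sim$truth$viral_flag))
})

test_that("vote arithmetic follows predictor sensitivity patterns", {
  cfg2 <- small_sim_config(seed = 32,
                           predictor_sensitivity = c(vibrant = 1, virsorter2 = 1,
                                                     checkv = 0, genomad = 0),
                           predictor_fpr = c(vibrant = 0, virsorter2 = 0,
                                             checkv = 0, genomad = 0),
                           trimmed_fraction = 0)
  sim2 <- simulate_virome(cfg2)
  rec2 <- consensus_filter(dedupe_calls(sim2$calls, sim2$contigs))
  expect_true(all(rec2$n_predictors == 2L))
  expect_true(all(rec2$fail_reason != "insufficient_votes"))

  cfg1 <- small_sim_config(seed = 33,
                           predictor_sensitivity = c(vibrant = 1, virsorter2 = 0,
                                                     checkv = 0, genomad = 0),
                           predictor_fpr = c(vibrant = 0, virsorter2 = 0,
                                             checkv = 0, genomad = 0),
                           trimmed_fraction = 0)
  sim1 <- simulate_virome(cfg1)
  rec1 <- consensus_filter(dedupe_calls(sim1$calls, sim1$contigs))
  expect_identical(sum(rec1$passed), 0L)
})
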