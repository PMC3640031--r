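test_that("trimmed mean removes one maximum and one minimum occurrence", {
  expect_equal(trimmed_mean(c(1000, 2000, 3000)), 2000)
  expect_equal(trimmed_mean(rep(7.5, 5)), 7.5)
  expect_equal(trimmed_mean(c(5, 1, 9, 7, 3)), 5)
  expect_message(out <- trimmed_mean(c(2, 4)), "plain mean")
  expect_equal(out, 3)
  expect_error(trimmed_mean(numeric()), "empty")
  set.seed(41)
  for (i in 1:100) {
    x <- stats::rlnorm(sample(3:20, 1), 7, 1)
    expect_equal(trimmed_mean(x), oracle_trimmed_mean(x))
  }
})

test_that("response scores are bounded, clipped and undefined at PM+MM=0", {
  rs <- response_scores(pm = c(5, 99, 1, 0), mm = c(5, 1, 9, 0),
                        background = 0.5)
  expect_equal(rs$score[1:3], c(0, 0.98, 0))
  expect_true(is.na(rs$score[4]))
  expect_equal(rs$usable, c(TRUE, TRUE, TRUE, FALSE))
  rs2 <- response_scores(pm = c(100, 200), mm = c(1, 1), background = 0,
                         saturation = 150)
  expect_equal(rs2$usable, c(TRUE, FALSE))
})

test_that("stage1 quantile metrics match a brute-force percentile oracle", {
  m <- stage1_metrics(rep(1, 10), rep(TRUE, 10))
  expect_equal(c(m$q1, m$q2, m$q3), c(1, 1, 1))
  expect_equal(m$pairs_counted, 10L)

  m6 <- stage1_metrics(seq(0, 1, length.out = 8), c(rep(TRUE, 6), FALSE, FALSE))
  expect_equal(m6$pairs_counted, 6L)   # fails the >=7 rule downstream
  expect_false(stage1_call(m6, "bacteria"))

  m0 <- stage1_metrics(numeric(), logical())
  expect_equal(m0$pairs_counted, 0L)
  expect_true(is.na(m0$q2))

  set.seed(17)
  for (i in 1:100) {
    sc <- runif(sample(2:15, 1))
    m <- stage1_metrics(sc, rep(TRUE, length(sc)))
    expect_equal(m$q1, oracle_quantile(sc, 0.25))
    expect_equal(m$q2, oracle_quantile(sc, 0.50))
    expect_equal(m$q3, oracle_quantile(sc, 0.75))
    expect_true(m$q1 <= m$q2 && m$q2 <= m$q3)
  }
})

test_that("stage1 cutoffs are inclusive and domain-specific", {
  mk <- function(pc, ps, q1, q2, q3) {
    structure(list(pairs_counted = pc, pairs_scored = ps,
                   q1 = q1, q2 = q2, q3 = q3), class = "stage1_metrics")
  }
  expect_true(stage1_call(mk(7, 7, 0.5, 0.93, 0.98), "bacteria"))
  expect_false(stage1_call(mk(7, 7, 0.5, 0.93, 0.979), "bacteria"))
  expect_false(stage1_call(mk(6, 6, 1, 1, 1), "bacteria"))
  # archaea: loosened quantiles but an OTU-level trimmed-mean gate
  expect_true(stage1_call(mk(2, 2, 0.1, 0.85, 0.95), "archaea",
                          otu_max_trimmed_mean = 1000))
  expect_false(stage1_call(mk(2, 2, 0.1, 0.85, 0.95), "archaea",
                           otu_max_trimmed_mean = 999))
  expect_false(stage1_call(mk(9, 9, 0.9, 0.79, 0.95), "archaea",
                           otu_max_trimmed_mean = 5000))
  expect_error(stage1_call(mk(9, 9, 1, 1, 1), "fungi"), "unknown domain")
})

test_that("spike scaling equalizes spike means, is idempotent, errors on zeros", {
  sim <- toy_sim(seed = 31)
  ex <- sim$experiment
  # noise-free world: all spike means equal, scaling is the identity
  sc1 <- spike_scale(ex, sim$library)
  expect_equal(unname(attr(sc1, "scale_factors")), rep(1, 6))
  expect_equal(sc1$intensities, ex$intensities)

  ex2 <- ex
  ex2$intensities[, 2] <- ex2$intensities[, 2] * 2
  sc2 <- spike_scale(ex2, sim$library)
  sm <- colMeans(sc2$intensities[sim$library$spike_probes, ])
  expect_lt(stats::sd(sm) / mean(sm), 1e-9)

  jit <- simulate_array(sim_config(n_phyla = 2, otus_per_phylum = 3,
                                   array_scale_jitter = 0.4, seed = 13))
  sc3 <- spike_scale(jit$experiment, jit$library)
  sm3 <- colMeans(sc3$intensities[jit$library$spike_probes, ])
  expect_lt(stats::sd(sm3) / mean(sm3), 1e-9)
  sc4 <- spike_scale(sc3, jit$library)
  expect_equal(sc4$intensities, sc3$intensities, tolerance = 1e-9)

  ex0 <- ex
  ex0$intensities[sim$library$spike_probes, 1] <- 0
  expect_error(spike_scale(ex0, sim$library), "spike")
})

test_that("cross-hybridization penalty recomputes q3 over unflagged pairs", {
  # two OTUs sharing half their pairs, both present in one sample
  mkps <- function(o, ids) data.frame(pair_id = ids,
                                      pm = paste0(o, "pm", seq_along(ids)),
                                      mm = paste0(o, "mm", seq_along(ids)),
                                      stringsAsFactors = FALSE)
  shared <- paste0("cx", 1:4)
  lib <- probe_library(list(A = mkps("A", c(paste0("a", 1:4), shared)),
                            B = mkps("B", c(shared, paste0("b", 1:4)))),
                       crosshyb = data.frame(otu_a = "A", otu_b = "B",
                                             pair_id = shared))
  set.seed(9)
  mk_scores <- function(ids) {
    m <- matrix(runif(length(ids)), ncol = 1,
                dimnames = list(ids, "s1"))
    list(score = m, usable = matrix(TRUE, length(ids), 1,
                                    dimnames = dimnames(m)))
  }
  scores <- list(A = mk_scores(lib$probe_sets$A$pair_id),
                 B = mk_scores(lib$probe_sets$B$pair_id))
  st1 <- matrix(TRUE, 2, 1, dimnames = list(c("A", "B"), "s1"))
  adj <- crosshyb_adjust(st1, lib, scores)
  for (o in c("A", "B")) {
    keep <- !(rownames(scores[[o]]$score) %in% shared)
    expect_equal(adj$q3_adjusted[o, 1],
                 oracle_quantile(scores[[o]]$score[keep, 1], 0.75))
  }

  # neighbor absent: no pairs flagged, q3 unchanged
  st1b <- st1; st1b["B", 1] <- FALSE
  adj2 <- crosshyb_adjust(st1b, lib, scores)
  expect_equal(adj2$q3_adjusted["A", 1],
               oracle_quantile(scores$A$score[, 1], 0.75))

  # every pair shared with a co-present OTU: q3_adjusted = 0, call removed
  lib_all <- probe_library(list(A = mkps("A", shared), B = mkps("B", shared)),
                           crosshyb = data.frame(otu_a = "A", otu_b = "B",
                                                 pair_id = shared))
  scores_all <- list(A = mk_scores(shared), B = mk_scores(shared))
  adj3 <- crosshyb_adjust(st1, lib_all, scores_all)
  expect_equal(unname(adj3$q3_adjusted[, 1]), c(0, 0))
  expect_false(any(adj3$present))

  # empty crosshyb map is the identity on calls
  lib_none <- probe_library(list(A = mkps("A", paste0("a", 1:8)),
                                 B = mkps("B", paste0("b", 1:8))))
  scores_none <- list(A = mk_scores(paste0("a", 1:8)),
                      B = mk_scores(paste0("b", 1:8)))
  adj4 <- crosshyb_adjust(st1, lib_none, scores_none)
  expect_identical(adj4$present, st1)
  expect_equal(adj4$q3_adjusted["A", 1],
               oracle_quantile(scores_none$A$score[, 1], 0.75))
})

test_that("raising quantile cutoffs never increases the number of calls", {
  sim <- simulate_array(sim_config(n_phyla = 3, otus_per_phylum = 6,
                                   lognormal_sigma = 0.6, presence_prob = 0.6,
                                   mm_leak_fraction = 0.2, seed = 77))
  n_prev <- Inf
  for (q3min in c(0.5, 0.8, 0.95, 0.99)) {
    th <- calling_thresholds(bacteria = list(min_pairs_counted = 7L,
                                             min_pairs_scored = 7L,
                                             q1_min = 0.2, q2_min = 0.4,
                                             q3_min = q3min))
    calls <- call_otus(sim$experiment, sim$library, sim$taxonomy, th)
    n <- sum(calls$present)
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("stage2 never adds calls beyond stage1", {
  sim <- simulate_array(sim_config(n_phyla = 3, otus_per_phylum = 6,
                                   crosshyb_rate = 0.5, seed = 55))
  calls <- call_otus(sim$experiment, sim$library, sim$taxonomy)
  expect_true(all(calls$present <= calls$stage1_present))
})

test_that("noise-free synthetic calls recover the ground truth", {
  sim <- toy_sim(n_phyla = 3, otus_per_phylum = 6, seed = 101,
                 presence_prob = 0.5)
  calls <- call_otus(sim$experiment, sim$library, sim$taxonomy)
  expect_identical(calls$present, sim$truth$present)
})

test_that("call tables round-trip through the long TSV format", {
  sim <- toy_sim(seed = 61)
  calls <- call_otus(sim$experiment, sim$library, sim$taxonomy)
  f <- withr::local_tempfile(fileext = ".tsv")
  fd <- withr::local_tempfile(fileext = ".tsv")
  write_calls(calls, f, fd)
  back <- read_calls(f, fd)
  expect_equal(back$present, calls$present)
  expect_equal(back$intensity, calls$intensity, tolerance = 1e-6)
  expect_equal(back$q3_adjusted, calls$q3_adjusted, tolerance = 1e-6)
})
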