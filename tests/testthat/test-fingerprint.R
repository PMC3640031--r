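toy_profiles <- function(n_lanes = 4, grid = 30, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::runif(grid * n_lanes, 0.1, 1), grid, n_lanes,
              dimnames = list(NULL, paste0("L", seq_len(n_lanes))))
  m
}

test_that("similarity matrix is Pearson x 100 with the expected extremes", {
  m <- toy_profiles(4)
  m[, 2] <- m[, 1]                        # duplicate lane
  m[, 3] <- 2 * mean(m[, 1]) - m[, 1]     # negation about the mean
  s <- similarity_matrix(m)
  expect_equal(diag(s), rep(100, 4), ignore_attr = TRUE)
  expect_equal(s[1, 2], 100)
  expect_equal(s[1, 3], -100)
  expect_true(isSymmetric(s))

  for (i in 1:100) {
    m <- toy_profiles(sample(3:6, 1), grid = sample(10:40, 1), seed = i + 10)
    fp <- fingerprint_set(
      `rownames<-`(m, format(seq(0, 1, length.out = nrow(m)))),
      rand_design(colnames(m)))
    expect_equal(similarity_matrix(fp), oracle_similarity(m),
                 tolerance = 1e-9)
  }

  flat <- toy_profiles(3)
  flat[, 2] <- 0.7
  expect_error(similarity_matrix(flat), "zero-variance lane: L2")
})

test_that("lane correlations are invariant to positive affine rescaling", {
  m <- toy_profiles(5, seed = 3)
  s1 <- similarity_matrix(m)
  m2 <- sweep(m, 2, stats::runif(5, 0.5, 3), `*`)
  s2 <- similarity_matrix(m2)
  expect_equal(s2, s1, tolerance = 1e-9)
  perm <- c(3, 1, 2, 5, 4)
  s3 <- similarity_matrix(m[, perm])
  expect_equal(s3, s1[perm, perm], tolerance = 1e-12)
})

test_that("upgma merges identical lanes first and solves the 3-leaf case", {
  s <- matrix(c(100, 90, 50,
                90, 100, 50,
                50, 50, 100), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma(s)
  expect_equal(tr$height, c(10, 50))
  expect_equal(tr$merge[1, ], c(-2, -1))          # A and B merge first
  co <- stats::cophenetic(tr)
  expect_equal(as.matrix(co)["A", "B"], 10)
  expect_equal(as.matrix(co)["A", "C"], 50)

  s2 <- s; s2["A", "B"] <- s2["B", "A"] <- 100    # duplicate lanes
  expect_equal(upgma(s2)$height[1], 0)
})

test_that("upgma agrees with average-linkage hclust on random matrices", {
  for (i in 1:100) {
    set.seed(i)
    m <- toy_profiles(6, grid = 25, seed = i)
    s <- similarity_matrix(m)
    mine <- upgma(s)
    ref <- stats::hclust(stats::as.dist(100 - s), method = "average")
    expect_equal(as.matrix(stats::cophenetic(mine))[colnames(s), colnames(s)],
                 as.matrix(stats::cophenetic(ref))[colnames(s), colnames(s)],
                 tolerance = 1e-9)
    expect_false(is.unsorted(mine$height))         # ultrametric heights
  }
})

test_that("newick export preserves the tree", {
  s <- similarity_matrix(toy_profiles(5, seed = 21))
  tr <- upgma(s)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  ph <- ape::read.tree(f)
  expect_equal(sort(ph$tip.label), sort(tr$labels))
  expect_equal(ape::cophenetic.phylo(ph)[tr$labels, tr$labels],
               as.matrix(stats::cophenetic(tr))[tr$labels, tr$labels],
               tolerance = 1e-6)
})

test_that("block-structured similarity gives d = 20 at the enumeration minimum", {
  lanes <- c(paste0("IN_", 1:4), paste0("OUT_", 1:4))
  s <- matrix(75, 8, 8, dimnames = list(lanes, lanes))
  s[1:4, 1:4] <- 95
  s[5:8, 5:8] <- 95
  diag(s) <- 100
  des <- data.frame(sample_id = lanes, group = rep(c("IN", "OUT"), each = 4),
                    site = "site1", pool = as.character(1:8),
                    stringsAsFactors = FALSE)
  res <- permutation_group_test(s, des, n_perm = 1000)
  expect_true(res$exact)
  expect_equal(res$n_perm, 70L)
  expect_equal(res$d, 20)
  # ties: every labeling with the same block split attains d_obs
  expect_equal(res$p, 2 / 70)
  expect_gte(res$p, 1 / (res$n_perm + 1))
})

test_that("d on a 2v2 toy matches the 6-pair hand computation", {
  lanes <- c("a1", "a2", "b1", "b2")
  s <- matrix(0, 4, 4, dimnames = list(lanes, lanes))
  s["a1", "a2"] <- s["a2", "a1"] <- 80
  s["b1", "b2"] <- s["b2", "b1"] <- 60
  s["a1", "b1"] <- s["b1", "a1"] <- 30
  s["a1", "b2"] <- s["b2", "a1"] <- 40
  s["a2", "b1"] <- s["b1", "a2"] <- 50
  s["a2", "b2"] <- s["b2", "a2"] <- 20
  diag(s) <- 100
  des <- data.frame(sample_id = lanes, group = c("A", "A", "B", "B"),
                    site = "s", pool = as.character(1:4),
                    stringsAsFactors = FALSE)
  res <- permutation_group_test(s, des)
  # within = (80+60)/2 = 70; between = (30+40+50+20)/4 = 35
  expect_equal(res$d, 70 - 35)
  # swapping which pairs count as within: labels (A,B,A,B)
  des2 <- des; des2$group <- c("A", "B", "A", "B")
  res2 <- permutation_group_test(s, des2)
  expect_equal(res2$d, (30 + 20) / 2 - (80 + 60 + 40 + 50) / 4)
})

test_that("permutation p is reproducible under a fixed seed", {
  fsim <- simulate_fingerprints(sim_config(seed = 12, n_marker_bands = 2))
  s <- similarity_matrix(fsim$fingerprints)
  des <- fsim$fingerprints$design
  r1 <- permutation_group_test(s, des, n_perm = 200, seed = 5)
  r2 <- permutation_group_test(s, des, n_perm = 200, seed = 5)
  expect_false(r1$exact)   # 70^4 stratified labelings >> 200
  expect_identical(r1$p, r2$p)
  expect_gte(r1$p, 1 / 201)
})

test_that("the multi-site report tests per site, pooled and among sites", {
  fsim <- simulate_fingerprints(sim_config(seed = 41, n_marker_bands = 8))
  rep <- multi_site_report(fsim$fingerprints, seed = 2)
  expect_setequal(rep$comparison,
                  c("Total", paste0("site", 1:4), "Among sites"))
  per_site <- rep[grepl("^site", rep$comparison), ]
  expect_true(all(per_site$significant))
  expect_true(rep$significant[rep$comparison == "Total"])

  # single-site input: Total equals that site's row
  one <- simulate_fingerprints(sim_config(seed = 43, fingerprint_sites = 1,
                                          n_marker_bands = 8))
  rep1 <- multi_site_report(one$fingerprints, seed = 3)
  tot <- rep1[rep1$comparison == "Total", ]
  st <- rep1[rep1$comparison == "site1", ]
  expect_equal(tot$d, st$d)
  expect_equal(tot$p, st$p)
  expect_true(is.na(rep1$p[rep1$comparison == "Among sites"]))

  # a site with only one group is untestable
  fp <- one$fingerprints
  fp$design$group <- "IN"
  rep2 <- multi_site_report(fp, seed = 4)
  expect_true(all(is.na(rep2$p)))
})
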