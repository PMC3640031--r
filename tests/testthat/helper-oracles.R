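# Independent brute-force oracles; deliberately written from first
# principles, not by calling the package's own code paths.

# Linearly interpolated percentile: sort, take h = (n-1)p, interpolate.
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p
  lo <- floor(h)
  if (lo + 1 >= n) return(unname(x[n]))
  unname(x[lo + 1] + (h - lo) * (x[lo + 2] - x[lo + 1]))
}

oracle_trimmed_mean <- function(x) {
  mean(sort(x)[2:(length(x) - 1)])
}

# Pearson similarity (x100) by the covariance/sd formula, elementwise loops.
oracle_similarity <- function(m) {
  norm <- sweep(m, 2, colSums(m), `/`)
  k <- ncol(norm)
  out <- matrix(100, k, k, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    a <- norm[, i]; b <- norm[, j]
    out[i, j] <- 100 * sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  out
}

# Set-algebra overlap fractions by explicit loops over OTUs.
oracle_overlap <- function(present, grp) {
  g <- unique(grp)
  det <- which(apply(present, 1, any))
  both <- all_s <- 0
  for (i in det) {
    if (any(present[i, grp == g[1]]) && any(present[i, grp == g[2]])) {
      both <- both + 1
    }
    if (all(present[i, ])) all_s <- all_s + 1
  }
  c(both = 100 * both / length(det), all = 100 * all_s / length(det))
}

# Heatmap filter by an explicit per-OTU loop.
oracle_heatmap_filter <- function(p, fc, fold_min, alpha) {
  keep <- logical(length(p))
  for (i in seq_along(p)) {
    if (is.na(p[i])) next
    sym <- max(fc[i], 1 / fc[i])
    keep[i] <- (p[i] < alpha) && (sym >= fold_min)
  }
  keep
}

# A tiny array world for direct-call tests: otus x samples with the given
# presence matrix, noise-free intensities.
toy_sim <- function(n_phyla = 2, otus_per_phylum = 4, seed = 1, ...) {
  simulate_array(sim_config(n_phyla = n_phyla,
                            otus_per_phylum = otus_per_phylum,
                            lognormal_sigma = 0, mm_leak_fraction = 0,
                            array_scale_jitter = 0, crosshyb_rate = 0,
                            seed = seed, ...))
}

rand_design <- function(samples, groups = c("IN", "OUT"), site = "site1") {
  n <- length(samples)
  data.frame(sample_id = samples,
             group = rep(groups, each = ceiling(n / 2))[seq_len(n)],
             site = site, pool = as.character(seq_len(n)),
             stringsAsFactors = FALSE)
}

design_3v3 <- function() {
  data.frame(sample_id = c("IN_1", "IN_2", "IN_3", "OUT_1", "OUT_2", "OUT_3"),
             group = rep(c("IN", "OUT"), each = 3), site = "site1",
             pool = as.character(rep(1:3, 2)), stringsAsFactors = FALSE)
}
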