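# Community-structure comparison per taxon: PCA of the samples on the
# taxon's standardized log OTU intensities, an eigenvalue-weighted squared
# separation of the two group centroids over the first few components, and
# an exact enumeration null over all relabelings of the samples.

#' Principal-component structure test for one taxon
#'
#' The samples are the observations, the taxon's standardized log OTU
#' intensities the variables.  The statistic is
#' `T = sum_k w_k * (mean score of group 1 - mean score of group 2)^2` over
#' the first `min(n_pcs, rank)` components, with `w_k` the fraction of total
#' variance carried by component `k`.  The p-value enumerates all distinct
#' relabelings of the samples into two groups of the observed sizes
#' (observed labeling included; for a 3v3 design there are 10 distinct
#' splits, so the smallest attainable p is 0.1) and is the fraction with
#' `T >= T_observed`.
#'
#' @param z numeric OTU x sample matrix of standardized log intensities for
#'   one taxon (see [standardize_log()]).
#' @param design sample design with a two-level `group` column.
#' @param n_pcs number of leading components (default 3).
#' @param min_otus taxa with fewer OTUs are not tested (default 10).
#' @return An object of class `structure_test_result`: `tested`, `n_otus`,
#'   `statistic`, `p`, `n_splits`, `variance_explained` (retained
#'   components), plus the `scores` and `weights` used.
#' @export
taxon_structure_test <- function(z, design, n_pcs = 3L, min_otus = 10L) {
  z <- as.matrix(z)
  if (n_pcs < 1L) stop("n_pcs must be at least 1")
  if (nrow(z) < min_otus) {
    return(structure(list(tested = FALSE, n_otus = nrow(z),
                          statistic = NA_real_, p = NA_real_,
                          n_splits = NA_integer_,
                          variance_explained = numeric()),
                     class = "structure_test_result"))
  }
  design <- validate_design(design, colnames(z))
  g <- design_groups(design)
  grp <- design$group
  pc <- stats::prcomp(t(z), center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  total <- sum(ev)
  keep <- which(ev / max(ev, 1) > 1e-12 & ev > 0)
  if (total <= 0 || !length(keep)) stop("taxon matrix has rank < 1")
  k <- min(n_pcs, length(keep))
  w <- ev[seq_len(k)] / total
  scores <- pc$x[, seq_len(k), drop = FALSE]

  stat_for <- function(is_g1) {
    d <- colMeans(scores[is_g1, , drop = FALSE]) -
      colMeans(scores[!is_g1, , drop = FALSE])
    sum(w * d^2)
  }
  obs_g1 <- grp == g[1L]
  t_obs <- stat_for(obs_g1)
  n <- length(grp)
  combos <- utils::combn(n, sum(obs_g1))
  t_perm <- apply(combos, 2L, function(ix) {
    stat_for(seq_len(n) %in% ix)
  })
  p <- mean(t_perm >= t_obs - 1e-12)
  n_splits <- ncol(combos) / if (sum(obs_g1) * 2L == n) 2L else 1L
  structure(list(tested = TRUE, n_otus = nrow(z), statistic = t_obs, p = p,
                 n_splits = as.integer(n_splits),
                 variance_explained = w, weights = w, scores = scores,
                 groups = g),
            class = "structure_test_result")
}

#' Structure tests for every taxon at a rank
#'
#' Standardizes the detected OTUs' log10 intensities and runs
#' [taxon_structure_test()] on each taxon's OTU block.
#'
#' @param calls an [otu_calls()].
#' @param taxonomy a [taxonomy_table()] covering the called OTUs.
#' @param rank rank at which to group OTUs.
#' @param n_pcs,min_otus passed to [taxon_structure_test()].
#' @return Data frame with one row per taxon: `taxon`, `n_otus`, `tested`,
#'   `statistic`, `p`, `ve1`..`ve3` (variance fractions of the retained
#'   components).
#' @export
structure_test_table <- function(calls, taxonomy, rank = "phylum",
                                 n_pcs = 3L, min_otus = 10L) {
  det <- detected_otus(calls)
  z <- standardize_log(calls$intensity[det, , drop = FALSE])
  lab <- taxon_at(taxonomy, rank)[rownames(z)]
  rows <- lapply(sort(unique(lab)), function(tx) {
    res <- taxon_structure_test(z[lab == tx, , drop = FALSE], calls$design,
                                n_pcs = n_pcs, min_otus = min_otus)
    ve <- rep(NA_real_, 3L)
    ve[seq_along(res$variance_explained)] <-
      res$variance_explained[seq_len(min(3L, length(res$variance_explained)))]
    data.frame(taxon = tx, n_otus = res$n_otus, tested = res$tested,
               statistic = res$statistic, p = res$p,
               ve1 = ve[1L], ve2 = ve[2L], ve3 = ve[3L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.structure_test_result <- function(x, ...) {
  if (!x$tested) {
    cat("Structure test: not tested (", x$n_otus, "OTUs )\n")
  } else {
    cat("Structure test on", x$n_otus, "OTUs: T =",
        signif(x$statistic, 4), ", p =", signif(x$p, 3),
        "( exact over", x$n_splits, "distinct splits )\n")
    cat("  variance explained:",
        paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = ", "),
        "\n")
  }
  invisible(x)
}
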