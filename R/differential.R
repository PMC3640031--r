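# Discriminative-OTU detection from scaled trimmed-mean intensities:
# log10 transform, per-OTU centering/standardization, per-OTU two-group
# t-tests (unadjusted by default), fold-change heatmap selection, and
# per-taxon discriminative-proportion summaries.

#' Log-transform and row-standardize an intensity matrix
#'
#' Each OTU row is log10-transformed, centered to mean 0 and scaled to SD 1
#' across all samples.  Rows containing a nonpositive value, and rows with
#' zero variance, are excluded (names recorded in attributes, counts
#' messaged).
#'
#' @param x numeric OTU x sample matrix.
#' @return The standardized matrix, with attributes `excluded_nonpositive`
#'   and `excluded_zero_variance`.
#' @export
standardize_log <- function(x) {
  x <- as.matrix(x)
  bad <- rowSums(!(x > 0)) > 0L
  if (any(bad)) {
    message("standardize_log: excluding ", sum(bad),
            " OTU(s) with nonpositive intensities")
  }
  l <- log10(x[!bad, , drop = FALSE])
  s <- apply(l, 1L, stats::sd)
  flat <- s == 0
  if (any(flat)) {
    message("standardize_log: excluding ", sum(flat),
            " zero-variance OTU(s)")
  }
  l <- l[!flat, , drop = FALSE]
  z <- (l - rowMeans(l)) / s[!flat]
  attr(z, "excluded_nonpositive") <- rownames(x)[bad]
  attr(z, "excluded_zero_variance") <- rownames(x)[!bad][flat]
  z
}

#' Per-OTU two-group t-tests on a standardized matrix
#'
#' Two-sided Welch t-test per row (pooled variance behind
#' `var_equal = TRUE`); no multiplicity adjustment.
#'
#' @param z numeric OTU x sample matrix (typically from
#'   [standardize_log()]; the t statistic is invariant to that row-affine
#'   transformation).
#' @param design sample design with a two-level `group` column.
#' @param var_equal use the pooled-variance t-test.
#' @return Data frame with `otu_id`, `t`, `df`, `p`.
#' @export
per_otu_tests <- function(z, design, var_equal = FALSE) {
  design <- validate_design(design, colnames(z))
  design_groups(design)
  tt <- rowwise_t(z, design$group, var_equal = var_equal)
  degen <- !is.finite(tt$t)
  tt$p[degen] <- NA_real_                 # degenerate variance: p undefined
  data.frame(otu_id = rownames(z), t = tt$t, df = tt$df, p = tt$p,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Differential intensity test between the two niches
#'
#' Tests every detected OTU (present in at least one sample) on standardized
#' log10 intensities and reports the fold-change as the ratio of the
#' untransformed group means of the trimmed-mean intensities.  An OTU's
#' `direction` is the group label with the higher mean when `p < alpha`,
#' `"none"` otherwise (including OTUs excluded from testing).
#'
#' @param calls an [otu_calls()].
#' @param alpha unadjusted significance level (strict `<`).
#' @param var_equal use the pooled-variance t-test.
#' @return A [differential_result()] covering all detected OTUs.
#' @export
differential_test <- function(calls, alpha = 0.05, var_equal = FALSE) {
  design <- validate_design(calls$design, colnames(calls$present))
  g <- design_groups(design)
  det <- detected_otus(calls)
  if (!length(det)) stop("no detected OTUs to test")
  x <- calls$intensity[det, , drop = FALSE]
  z <- standardize_log(x)
  tests <- per_otu_tests(z, design, var_equal = var_equal)
  p <- stats::setNames(rep(NA_real_, length(det)), det)
  tstat <- dfree <- p
  p[tests$otu_id] <- tests$p
  tstat[tests$otu_id] <- tests$t
  dfree[tests$otu_id] <- tests$df
  grp <- design$group
  m1 <- rowMeans(x[, grp == g[1L], drop = FALSE])
  m2 <- rowMeans(x[, grp == g[2L], drop = FALSE])
  direction <- ifelse(!is.na(p) & p < alpha,
                      ifelse(m1 > m2, g[1L], g[2L]), "none")
  differential_result(otu_id = det, mean1 = m1, mean2 = m2,
                      log_mean1 = log10(pmax(m1, .Machine$double.xmin)),
                      log_mean2 = log10(pmax(m2, .Machine$double.xmin)),
                      fold_change = m1 / m2, t = tstat, df = dfree, p = p,
                      direction = direction, groups = g, alpha = alpha)
}

#' Construct a differential test result
#'
#' Mostly used internally by [differential_test()]; exposed so externally
#' computed per-OTU results (for example a published table of
#' discriminative-OTU counts) can be summarized with
#' [discriminative_taxon_summary()].
#'
#' @param otu_id OTU identifiers (unique).
#' @param direction per OTU: one of the two group labels or `"none"`.
#' @param groups the two group labels, "inside" niche first.
#' @param mean1,mean2,log_mean1,log_mean2,fold_change,t,df,p optional per-OTU
#'   statistics.
#' @param alpha the significance level the directions were called at.
#' @return A data frame of class `differential_result`.
#' @export
differential_result <- function(otu_id, direction, groups,
                                mean1 = NA_real_, mean2 = NA_real_,
                                log_mean1 = NA_real_, log_mean2 = NA_real_,
                                fold_change = NA_real_, t = NA_real_,
                                df = NA_real_, p = NA_real_, alpha = 0.05) {
  if (anyDuplicated(otu_id)) stop_format("duplicate otu_id in result")
  if (!all(direction %in% c(groups, "none"))) {
    stop_format("direction must be a group label or 'none'")
  }
  out <- data.frame(otu_id = as.character(otu_id),
                    mean1 = mean1, mean2 = mean2,
                    log_mean1 = log_mean1, log_mean2 = log_mean2,
                    fold_change = fold_change, t = t, df = df, p = p,
                    direction = direction,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "groups") <- groups
  attr(out, "alpha") <- alpha
  class(out) <- c("differential_result", "data.frame")
  out
}

#' Select OTUs for a heatmap
#'
#' An OTU is selected iff its unadjusted `p < alpha` (strict) and its
#' symmetric fold-change `max(fc, 1/fc)` is at least `fold_min` (inclusive).
#' Returns the untransformed trimmed-mean intensity submatrix ordered by
#' taxonomy (lineage string) and then decreasing symmetric fold-change.
#'
#' @param result a [differential_result()].
#' @param intensity the untransformed OTU x sample intensity matrix (for
#'   example `calls$intensity`).
#' @param fold_min minimum symmetric fold-change (default 1.8, inclusive).
#' @param alpha significance cutoff (strict).
#' @param taxonomy optional [taxonomy_table()] used for row ordering.
#' @return List with `otu_id` and `matrix`.
#' @export
select_heatmap_otus <- function(result, intensity, fold_min = 1.8,
                                alpha = 0.05, taxonomy = NULL) {
  fc <- result$fold_change
  sym <- pmax(fc, 1 / fc)
  sel <- !is.na(result$p) & result$p < alpha & sym >= fold_min
  ids <- result$otu_id[sel]
  sym <- sym[sel]
  if (length(ids)) {
    key <- if (!is.null(taxonomy)) {
      format_lineage(taxonomy[match(ids, taxonomy$otu_id), , drop = FALSE])
    } else rep("", length(ids))
    ord <- order(key, -sym)
    ids <- ids[ord]
  }
  list(otu_id = ids, matrix = intensity[ids, , drop = FALSE])
}

#' Per-taxon summary of discriminative OTUs
#'
#' For every taxon at each requested rank: the number of OTUs with
#' significantly higher intensity in the first group (`n_in`), in the second
#' group (`n_out`), the total number of detected OTUs (`n_total`), and the
#' corresponding percentages rounded half-up to integers.
#'
#' @param result a [differential_result()] covering the detected OTUs.
#' @param taxonomy a [taxonomy_table()] covering the same OTUs.
#' @param ranks ranks to walk (default phylum through genus).
#' @return A data frame of class `discriminative_taxon_summary` with columns
#'   `rank`, `taxon`, `n_in`, `n_out`, `n_total`, `pct_in`, `pct_out`.
#' @export
discriminative_taxon_summary <- function(result, taxonomy,
                                         ranks = TAXONOMY_RANKS[-1L]) {
  g <- attr(result, "groups")
  idx <- match(result$otu_id, taxonomy$otu_id)
  if (anyNA(idx)) stop("taxonomy does not cover all tested OTUs")
  tx <- taxonomy[idx, , drop = FALSE]
  rows <- lapply(ranks, function(rank) {
    lab <- taxon_at(tx, rank)
    n_in <- rowsum(as.integer(result$direction == g[1L]), lab)[, 1L]
    n_out <- rowsum(as.integer(result$direction == g[2L]), lab)[, 1L]
    n_tot <- rowsum(rep(1L, nrow(tx)), lab)[, 1L]
    data.frame(rank = rank, taxon = names(n_tot),
               n_in = as.integer(n_in), n_out = as.integer(n_out),
               n_total = as.integer(n_tot),
               pct_in = ifelse(n_tot > 0, round_half_up(100 * n_in / n_tot), 0),
               pct_out = ifelse(n_tot > 0, round_half_up(100 * n_out / n_tot), 0),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  attr(out, "groups") <- g
  class(out) <- c("discriminative_taxon_summary", "data.frame")
  out
}

#' @export
print.differential_result <- function(x, ...) {
  g <- attr(x, "groups")
  n <- table(factor(x$direction, levels = c(g, "none")))
  cat("Differential test over", nrow(x), "detected OTUs (",
      g[1L], "vs", g[2L], ", alpha =", attr(x, "alpha"), ")\n")
  cat("  higher in", g[1L], ":", n[[g[1L]]],
      "| higher in", g[2L], ":", n[[g[2L]]], "| not significant:",
      n[["none"]], "\n")
  invisible(x)
}
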