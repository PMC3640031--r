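# Per-taxon relative richness (numbers of detected OTUs) and overlap
# summaries between the two niches.

design_groups <- function(design) {
  g <- unique(design$group)
  if (length(g) != 2L) stop("exactly two sample groups are required")
  counts <- table(factor(design$group, levels = g))
  if (any(counts < 2L)) stop("each group needs at least 2 samples")
  g
}

# Row-wise Welch (or pooled) two-sided t-test on a matrix of per-sample
# values; returns t, df, p.  Zero variance in both groups gives p = 1 when
# the means agree and p = 0 otherwise (with a message), never an error.
rowwise_t <- function(x, grp, var_equal = FALSE) {
  g <- unique(grp)
  x1 <- x[, grp == g[1L], drop = FALSE]
  x2 <- x[, grp == g[2L], drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- apply(x1, 1L, stats::var); v2 <- apply(x2, 1L, stats::var)
  if (var_equal) {
    sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(m1))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(t), df)
  degen <- se == 0
  if (any(degen)) {
    message(sum(degen), " test(s) with zero variance in both groups")
    p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
    t[degen] <- ifelse(m1[degen] == m2[degen], 0, Inf * sign(m1 - m2)[degen])
    df[degen] <- NA_real_
  }
  list(mean1 = m1, mean2 = m2, t = t, df = df, p = p)
}

#' Per-taxon relative-richness table
#'
#' Counts the OTUs called present per sample within each taxon at a chosen
#' rank, compares the two groups with a two-sided Welch t-test (pooled
#' variance behind `var_equal = TRUE`), and reports the union total (OTUs
#' detected in at least one of all samples).  Taxa whose union total falls
#' below `min_total` are pooled into an `"others"` row, and archaeal OTUs
#' are reported as a single `Archaea` row.
#'
#' @param calls an [otu_calls()].
#' @param taxonomy a [taxonomy_table()] covering the called OTUs.
#' @param rank rank at which to aggregate (default `"phylum"`).
#' @param min_total taxa with a union total below this go to `"others"`
#'   (default 1 = no pooling).
#' @param collapse_archaea report all archaeal OTUs as one row (default
#'   `TRUE`).
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @param alpha significance level for the flag column (no multiplicity
#'   adjustment, mirroring how such tables are usually printed).
#' @return A data frame of class `richness_table` with per-group mean and SD
#'   of per-sample counts, the union `total`, `p` and `significant`; the
#'   group order is kept in `attr(, "groups")`.
#' @export
richness_table <- function(calls, taxonomy, rank = "phylum", min_total = 1L,
                           collapse_archaea = TRUE, var_equal = FALSE,
                           alpha = 0.05) {
  design <- validate_design(calls$design, colnames(calls$present))
  grp <- design$group
  g <- design_groups(design)
  otus <- rownames(calls$present)
  lab <- taxon_at(taxonomy, rank)[otus]
  if (anyNA(lab)) stop("taxonomy does not cover all called OTUs")
  if (collapse_archaea) lab[calls$domain[otus] == "archaea"] <- "Archaea"

  pres <- calls$present * 1L
  counts <- rowsum(pres, lab)                       # taxon x sample
  union_total <- rowsum(as.integer(rowSums(calls$present) > 0L), lab)[, 1L]

  pool <- rownames(counts) != "Archaea" & union_total < min_total
  if (any(pool)) {
    counts <- rbind(counts[!pool, , drop = FALSE],
                    others = colSums(counts[pool, , drop = FALSE]))
    union_total <- c(union_total[!pool], others = sum(union_total[pool]))
  }
  tt <- rowwise_t(counts, grp, var_equal = var_equal)
  ord <- order(rownames(counts) == "Archaea", rownames(counts) == "others",
               -union_total)
  out <- data.frame(taxon = rownames(counts),
                    mean1 = tt$mean1, sd1 = apply(counts[, grp == g[1L],
                                                         drop = FALSE], 1L, stats::sd),
                    mean2 = tt$mean2, sd2 = apply(counts[, grp == g[2L],
                                                         drop = FALSE], 1L, stats::sd),
                    total = as.integer(union_total),
                    p = tt$p, significant = tt$p < alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  colnames(out)[c(2, 3, 4, 5)] <- c(paste0("mean_", g[1L]), paste0("sd_", g[1L]),
                                    paste0("mean_", g[2L]), paste0("sd_", g[2L]))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "groups") <- g
  attr(out, "rank") <- rank
  class(out) <- c("richness_table", "data.frame")
  out
}

#' Overlap of detected OTUs across groups and samples
#'
#' Over the OTUs detected in at least one sample: the percentage detected in
#' both groups (present in at least one sample of each) and the percentage
#' detected in every sample.
#'
#' @param calls an [otu_calls()].
#' @return List with `pct_both_groups`, `pct_all_samples` (percent) and
#'   `n_detected`.
#' @export
overlap_summary <- function(calls) {
  if (!nrow(calls$present)) stop("empty call table")
  design <- validate_design(calls$design, colnames(calls$present))
  g <- design_groups(design)
  grp <- design$group
  det <- rowSums(calls$present) > 0L
  if (!any(det)) return(list(pct_both_groups = NA_real_,
                             pct_all_samples = NA_real_, n_detected = 0L))
  p <- calls$present[det, , drop = FALSE]
  in1 <- rowSums(p[, grp == g[1L], drop = FALSE]) > 0L
  in2 <- rowSums(p[, grp == g[2L], drop = FALSE]) > 0L
  list(pct_both_groups = 100 * mean(in1 & in2),
       pct_all_samples = 100 * mean(rowSums(p) == ncol(p)),
       n_detected = sum(det))
}

#' @export
print.richness_table <- function(x, digits = 1, ...) {
  g <- attr(x, "groups")
  cat("Relative richness at rank", attr(x, "rank"), "(", g[1L], "vs", g[2L],
      ")\n")
  df <- as.data.frame(x)
  df$p <- signif(df$p, 3)
  num <- vapply(df, is.numeric, logical(1)) & !(colnames(df) %in% c("p", "total"))
  df[num] <- lapply(df[num], round, digits)
  print(df, row.names = FALSE)
  invisible(x)
}
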