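# Gel-fingerprint comparison: Pearson lane similarity, UPGMA clustering with
# newick export, and permutation tests of within- versus between-group mean
# similarity ("percent dissimilarity" d, in percent points).

#' Pearson similarity matrix of fingerprint lanes
#'
#' Lanes of a [fingerprint_set()] are first normalized to unit total
#' intensity (Pearson correlation is unchanged by this positive rescaling,
#' but the normalized profiles are what get clustered and reported); a plain
#' matrix is used as given.  Values are `100 * r`.
#'
#' @param x a [fingerprint_set()] or a numeric grid x lane matrix.
#' @return Symmetric lane x lane matrix with diagonal 100.
#' @export
similarity_matrix <- function(x) {
  m <- if (inherits(x, "fingerprint_set")) {
    tot <- colSums(x$profiles)
    if (any(tot <= 0)) {
      stop("zero total intensity in lane ",
           colnames(x$profiles)[which(tot <= 0)[1L]])
    }
    sweep(x$profiles, 2L, tot, `/`)
  } else {
    as.matrix(x)
  }
  if (ncol(m) < 2L || nrow(m) < 2L) stop("need at least 2 lanes on a grid")
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance lane: ", colnames(m)[which(sds == 0)[1L]])
  }
  s <- 100 * stats::cor(m)
  diag(s) <- 100
  s
}

#' UPGMA clustering of a similarity matrix
#'
#' Agglomerates by maximum average similarity (unweighted average over all
#' original lane pairs); merge heights are dissimilarities `100 -
#' similarity`.  Ties are broken deterministically in favor of the candidate
#' pair whose sorted member labels come first lexicographically.
#'
#' @param similarity symmetric similarity matrix as from
#'   [similarity_matrix()].
#' @return A [stats::hclust] object (method `"average"`, ultrametric
#'   heights).
#' @export
upgma <- function(similarity) {
  s <- as.matrix(similarity)
  n <- ncol(s)
  labels <- colnames(s)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (n < 2L) stop("need at least 2 lanes to cluster")
  members <- lapply(seq_len(n), function(i) labels[i])
  size <- rep(1L, n)
  id <- -seq_len(n)                      # hclust convention: negatives = leaves
  active <- seq_len(n)
  sim <- s
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    best <- NULL; best_s <- -Inf; best_key <- NULL
    for (ii in seq_along(active)[-length(active)]) {
      for (jj in (ii + 1L):length(active)) {
        a <- active[ii]; b <- active[jj]
        v <- sim[a, b]
        key <- paste(sort(c(members[[a]], members[[b]])), collapse = "\r")
        if (v > best_s + 1e-12 ||
            (abs(v - best_s) <= 1e-12 && !is.null(best_key) && key < best_key)) {
          best <- c(a, b); best_s <- v; best_key <- key
        }
      }
    }
    a <- best[1L]; b <- best[2L]
    merge[step, ] <- sort(c(id[a], id[b]))
    height[step] <- 100 - best_s
    # unweighted average similarity of the merged cluster to the rest
    for (c_ in setdiff(active, c(a, b))) {
      v <- (size[a] * sim[a, c_] + size[b] * sim[b, c_]) / (size[a] + size[b])
      sim[a, c_] <- sim[c_, a] <- v
    }
    members[[a]] <- c(members[[a]], members[[b]])
    size[a] <- size[a] + size[b]
    id[a] <- step
    active <- setdiff(active, b)
  }
  order_of <- function(node) {
    if (node < 0L) return(-node)
    c(order_of(merge[node, 1L]), order_of(merge[node, 2L]))
  }
  structure(list(merge = merge, height = height,
                 order = order_of(n - 1L), labels = labels,
                 method = "average", call = match.call(),
                 dist.method = "100 - Pearson similarity"),
            class = "hclust")
}

#' Write a dendrogram as newick
#'
#' @param tree an [stats::hclust] object (for example from [upgma()]).
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

# All distinct relabelings keeping per-stratum group counts: list of label
# vectors.  Only called when the count is small.
enumerate_labelings <- function(labels, strata) {
  per_stratum <- lapply(split(seq_along(labels), strata), function(ix) {
    lapply(unique_perms(labels[ix]), function(p) list(ix = ix, lab = p))
  })
  grids <- expand.grid(lapply(per_stratum, seq_along))
  lapply(seq_len(nrow(grids)), function(r) {
    lab <- labels
    for (sname in seq_along(per_stratum)) {
      choice <- per_stratum[[sname]][[grids[r, sname]]]
      lab[choice$ix] <- choice$lab
    }
    lab
  })
}

# Distinct permutations of a label multiset (recursive).
unique_perms <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (v in unique(x)) {
    rest <- x[-match(v, x)]
    for (p in unique_perms(rest)) out[[length(out) + 1L]] <- c(v, p)
  }
  out
}

count_labelings <- function(labels, strata) {
  prod(vapply(split(labels, strata), function(g) {
    exp(lfactorial(length(g)) - sum(lfactorial(table(g))))
  }, numeric(1)))
}

# within-minus-between mean similarity for a label vector (k >= 2 groups);
# make_d_fun precomputes the upper-triangle pair index for repeated calls.
make_d_fun <- function(s) {
  ut <- which(upper.tri(s), arr.ind = TRUE)
  sv <- s[upper.tri(s)]
  i <- ut[, 1L]; j <- ut[, 2L]
  function(labels) {
    same <- labels[i] == labels[j]
    mean(sv[same]) - mean(sv[!same])
  }
}

similarity_d <- function(s, labels) make_d_fun(s)(labels)

#' Permutation test of group difference on a similarity matrix
#'
#' The statistic is `d = (mean within-group similarity) - (mean
#' between-group similarity)`, in percent points ("percent dissimilarity").
#' The null permutes group labels over lanes, within each site when
#' `stratify = TRUE` and the design has several sites.  When the number of
#' distinct labelings does not exceed `n_perm` they are enumerated exactly
#' (observed labeling included, `p = #(d_perm >= d_obs) / N`); otherwise
#' `n_perm` random permutations are drawn and
#' `p = (#(d_perm >= d_obs) + 1) / (n_perm + 1)`.
#'
#' @param similarity lane x lane matrix from [similarity_matrix()].
#' @param design lane design; `group_col` names the grouping column, so
#'   `group_col = "site"` tests among-site differences.
#' @param n_perm permutations requested (default 1000).
#' @param seed optional RNG seed for the random-permutation path.
#' @param stratify permute within sites (ignored when grouping by site).
#' @param group_col design column holding the group labels.
#' @return An object of class `fingerprint_test`: `d`, `p`, `n_perm`
#'   (distinct labelings when exact), `exact`, `groups`, `stratified`.
#' @export
permutation_group_test <- function(similarity, design, n_perm = 1000L,
                                   seed = NULL, stratify = TRUE,
                                   group_col = "group") {
  s <- as.matrix(similarity)
  design <- validate_design(design, colnames(s))
  labels <- design[[group_col]]
  tab <- table(labels)
  if (length(tab) < 2L) stop("need at least two groups of lanes")
  if (any(tab < 2L)) stop("each group needs at least 2 lanes")
  strata <- if (stratify && group_col != "site") design$site
            else rep("all", nrow(design))
  d_fun <- make_d_fun(s)
  d_obs <- d_fun(labels)
  n_distinct <- count_labelings(labels, strata)
  exact <- n_distinct <= n_perm
  if (exact) {
    labs <- enumerate_labelings(labels, strata)
    d_perm <- vapply(labs, d_fun, numeric(1))
    p <- mean(d_perm >= d_obs - 1e-12)
    n_eff <- length(labs)
  } else {
    stratum_ix <- split(seq_along(labels), strata)
    d_perm <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        l <- labels
        for (ix in stratum_ix) {
          l[ix] <- l[sample(ix)]
        }
        d_fun(l)
      }, numeric(1))
    })
    p <- (sum(d_perm >= d_obs - 1e-12) + 1) / (n_perm + 1)
    n_eff <- n_perm
  }
  structure(list(d = d_obs, p = p, n_perm = as.integer(round(n_eff)),
                 exact = exact, groups = names(tab),
                 stratified = length(unique(strata)) > 1L),
            class = "fingerprint_test")
}

#' Per-site, pooled and among-site fingerprint report
#'
#' Runs the group permutation test inside each site, pooled over all lanes
#' (stratified by site), and among sites (site as the grouping factor), in
#' the shape of a published percent-dissimilarity table.
#'
#' @param fingerprints a [fingerprint_set()].
#' @param n_perm,seed,alpha test settings; per-row seeds are derived from
#'   `seed`.
#' @return Data frame of class `multi_site_report` with columns `comparison`,
#'   `d`, `p`, `n_perm`, `exact`, `significant`.
#' @export
multi_site_report <- function(fingerprints, n_perm = 1000L, seed = NULL,
                              alpha = 0.05) {
  s <- similarity_matrix(fingerprints)
  design <- fingerprints$design
  sites <- unique(design$site)
  rows <- list()
  add <- function(comparison, res) {
    rows[[length(rows) + 1L]] <<- data.frame(
      comparison = comparison,
      d = if (is.null(res)) NA_real_ else res$d,
      p = if (is.null(res)) NA_real_ else res$p,
      n_perm = if (is.null(res)) NA_integer_ else res$n_perm,
      exact = if (is.null(res)) NA else res$exact,
      significant = if (is.null(res)) NA else res$p < alpha,
      stringsAsFactors = FALSE)
  }
  pooled <- tryCatch(
    permutation_group_test(s, design, n_perm = n_perm, seed = seed,
                           stratify = TRUE),
    error = function(e) NULL)
  add("Total", pooled)
  for (i in seq_along(sites)) {
    keep <- design$site == sites[i]
    res <- tryCatch(
      permutation_group_test(s[keep, keep, drop = FALSE],
                             design[keep, , drop = FALSE],
                             n_perm = n_perm,
                             seed = if (is.null(seed)) NULL else seed + i),
      error = function(e) NULL)
    add(sites[i], res)
  }
  among <- if (length(sites) >= 2L) {
    tryCatch(
      permutation_group_test(s, design, n_perm = n_perm,
                             seed = if (is.null(seed)) NULL
                                    else seed + length(sites) + 1L,
                             group_col = "site"),
      error = function(e) NULL)
  } else NULL
  add("Among sites", among)
  out <- do.call(rbind, rows)
  class(out) <- c("multi_site_report", "data.frame")
  out
}

#' @export
print.fingerprint_test <- function(x, ...) {
  cat("Fingerprint permutation test (", paste(x$groups, collapse = " vs "),
      if (x$stratified) ", stratified by site" else "", ")\n", sep = "")
  cat("  d =", signif(x$d, 4), "percent points; p =", signif(x$p, 4),
      if (x$exact) paste("( exact over", x$n_perm, "labelings )")
      else paste("(", x$n_perm, "random permutations )"), "\n")
  invisible(x)
}

#' @export
print.multi_site_report <- function(x, ...) {
  cat("Percent dissimilarity (within minus between mean similarity)\n")
  df <- as.data.frame(x)
  df$d <- signif(df$d, 4); df$p <- signif(df$p, 4)
  df$sig <- ifelse(is.na(df$significant), "",
                   ifelse(df$significant, "*", ""))
  print(df[c("comparison", "d", "p", "sig")], row.names = FALSE)
  invisible(x)
}
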