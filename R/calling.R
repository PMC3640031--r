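# Probe-level intensities -> per-sample OTU presence/absence calls and
# spike-scaled trimmed-mean intensities.
#
# Stage1: a probe set is scored pair by pair with the bounded response score
# r = max(0, (PM - MM)/(PM + MM)); q1/q2/q3 are the 25/50/75th percentiles of
# the scores of "usable" pairs (PM above the array's background level and,
# optionally, below saturation).  Presence requires, for bacteria,
# pairs_counted >= 7, pairs_scored >= 7, q1 >= 0.5, q2 >= 0.93, q3 >= 0.98;
# for archaea the loosened q2 >= 0.8 and q3 >= 0.9, restricted to OTUs with
# at least one sample whose trimmed mean intensity reaches 1000 units.
# Stage2: pairs shared with another probe set that is itself Stage1-present
# in the same sample are removed and q3 recomputed; the call survives iff the
# adjusted q3 >= 0.1.  All comparisons are inclusive (>=).

#' Presence-calling thresholds
#'
#' Defaults are the published Stage1/Stage2 cutoffs; every value is
#' configurable.
#'
#' @param bacteria,archaea named lists of domain-specific cutoffs (see
#'   defaults).
#' @param stage2_q3_min minimum cross-hybridization-adjusted q3.
#' @param background_quantile quantile of all probe intensities on an array
#'   that defines its background level; a pair is usable only if its PM
#'   exceeds it.
#' @param saturation_value optional intensity above which a PM is considered
#'   saturated and its pair unusable (`NULL` = no ceiling).
#' @return A list of class `calling_thresholds`.
#' @export
calling_thresholds <- function(bacteria = list(min_pairs_counted = 7L,
                                               min_pairs_scored = 7L,
                                               q1_min = 0.5, q2_min = 0.93,
                                               q3_min = 0.98),
                               archaea = list(q2_min = 0.8, q3_min = 0.9,
                                              min_trimmed_mean = 1000),
                               stage2_q3_min = 0.1,
                               background_quantile = 0.02,
                               saturation_value = NULL) {
  stopifnot(is_prob(background_quantile), is_prob(stage2_q3_min),
            is_prob(bacteria$q1_min), is_prob(bacteria$q2_min),
            is_prob(bacteria$q3_min), is_prob(archaea$q2_min),
            is_prob(archaea$q3_min))
  structure(list(bacteria = bacteria, archaea = archaea,
                 stage2_q3_min = stage2_q3_min,
                 background_quantile = background_quantile,
                 saturation_value = saturation_value),
            class = "calling_thresholds")
}

#' Trimmed mean of a probe set's intensities
#'
#' Arithmetic mean after removing exactly one occurrence of the maximum and
#' one of the minimum.  With fewer than three values the plain mean is
#' returned (with a message).
#'
#' @param x numeric vector of intensities.
#' @return A single number.
#' @export
trimmed_mean <- function(x) {
  if (length(x) == 0L) stop("trimmed_mean of empty input")
  if (length(x) < 3L) {
    message("trimmed_mean: fewer than 3 values, using plain mean")
    return(mean(x))
  }
  (sum(x) - max(x) - min(x)) / (length(x) - 2L)
}

#' Per-pair response scores and usability of a probe set in one sample
#'
#' @param pm,mm PM and MM intensities of the probe set's pairs.
#' @param background background level of the array (pairs with `pm <=
#'   background` are unusable).
#' @param saturation optional saturation ceiling (pairs with `pm >=
#'   saturation` are unusable).
#' @return List with `score` (`max(0, (PM-MM)/(PM+MM))`, `NA` where
#'   undefined because `PM + MM = 0`) and logical `usable`.
#' @export
response_scores <- function(pm, mm, background = 0, saturation = NULL) {
  tot <- pm + mm
  score <- ifelse(tot == 0, NA_real_, pmax(0, (pm - mm) / tot))
  usable <- pm > background
  if (!is.null(saturation)) usable <- usable & pm < saturation
  list(score = score, usable = usable)
}

#' Stage1 quantile metrics of a probe set in one sample
#'
#' `pairs_counted` is the number of usable pairs, `pairs_scored` the usable
#' pairs with a defined score; q1/q2/q3 are the linearly interpolated
#' 25/50/75th percentiles of the usable scores (`NA` when none).  Zero
#' usable pairs never raise an error.
#'
#' @param score,usable as returned by [response_scores()].
#' @return List of class `stage1_metrics`.
#' @export
stage1_metrics <- function(score, usable) {
  scored <- usable & !is.na(score)
  q <- if (any(scored)) quantile7(score[scored], c(0.25, 0.5, 0.75))
       else rep(NA_real_, 3L)
  structure(list(pairs_counted = sum(usable), pairs_scored = sum(scored),
                 q1 = q[1L], q2 = q[2L], q3 = q[3L]),
            class = "stage1_metrics")
}

#' Stage1 presence call for one probe set in one sample
#'
#' @param metrics a [stage1_metrics()].
#' @param domain `"bacteria"` or `"archaea"`.
#' @param otu_max_trimmed_mean the OTU's maximum trimmed-mean intensity over
#'   all samples (the archaeal eligibility gate: at least one sample must
#'   reach `min_trimmed_mean`).
#' @param thresholds a [calling_thresholds()].
#' @return `TRUE` or `FALSE`.
#' @export
stage1_call <- function(metrics, domain, otu_max_trimmed_mean = Inf,
                        thresholds = calling_thresholds()) {
  ok <- function(x, cut) !is.na(x) && x >= cut
  if (domain == "bacteria") {
    th <- thresholds$bacteria
    metrics$pairs_counted >= th$min_pairs_counted &&
      metrics$pairs_scored >= th$min_pairs_scored &&
      ok(metrics$q1, th$q1_min) && ok(metrics$q2, th$q2_min) &&
      ok(metrics$q3, th$q3_min)
  } else if (domain == "archaea") {
    th <- thresholds$archaea
    otu_max_trimmed_mean >= th$min_trimmed_mean &&
      ok(metrics$q2, th$q2_min) && ok(metrics$q3, th$q3_min)
  } else {
    stop("unknown domain label: ", domain)
  }
}

#' Scale arrays to a common spike-in intensity level
#'
#' Each sample's intensities are multiplied by (grand mean of the per-sample
#' spike-probe means) / (that sample's spike mean), so that after scaling all
#' samples share the same spike mean.  Idempotent.
#'
#' @param experiment an [array_experiment()].
#' @param library a [probe_library()] with at least one spike probe.
#' @return The rescaled experiment, with the factors in
#'   `attr(, "scale_factors")`.
#' @export
spike_scale <- function(experiment, library) {
  if (!length(library$spike_probes)) {
    stop("spike_scale: library has no spike probes")
  }
  sp <- experiment$intensities[library$spike_probes, , drop = FALSE]
  m <- colMeans(sp)
  if (any(!is.finite(m)) || any(m <= 0)) {
    stop("spike_scale: zero or absent spike intensities in sample ",
         colnames(sp)[which(!(m > 0))[1L]])
  }
  f <- mean(m) / m
  experiment$intensities <- sweep(experiment$intensities, 2L, f, `*`)
  attr(experiment, "scale_factors") <- f
  experiment
}

# Per-OTU score/usable/PM arrays for all samples at once.
otu_score_arrays <- function(experiment, library, thresholds) {
  intens <- experiment$intensities
  bg <- apply(intens, 2L, stats::quantile, probs = thresholds$background_quantile,
              names = FALSE, type = 7)
  sat <- thresholds$saturation_value
  lapply(library$probe_sets, function(ps) {
    pm <- intens[ps$pm, , drop = FALSE]
    mm <- intens[ps$mm, , drop = FALSE]
    tot <- pm + mm
    score <- (pm - mm) / tot
    score[tot == 0] <- NA_real_
    score <- pmax(score, 0)
    usable <- sweep(pm, 2L, bg, `>`)
    if (!is.null(sat)) usable <- usable & pm < sat
    rownames(score) <- rownames(usable) <- rownames(pm) <- ps$pair_id
    list(score = score, usable = usable, pm = pm)
  })
}

#' Cross-hybridization penalty (Stage2)
#'
#' For every Stage1-present OTU and sample, pairs shared (per the library's
#' crosshyb table) with any *other* OTU that is also Stage1-present in that
#' sample are flagged; q3 is recomputed over the unflagged usable pairs (0 if
#' none remain) and the call is kept iff the adjusted q3 is at least
#' `stage2_q3_min`.  OTUs with no crosshyb entries pass through unchanged.
#'
#' @param stage1_present logical OTU x sample matrix of Stage1 calls.
#' @param library a [probe_library()].
#' @param scores list per OTU of `score`/`usable` pair x sample matrices with
#'   `pair_id` rownames (as built inside [call_otus()]).
#' @param thresholds a [calling_thresholds()].
#' @return List with logical matrix `present` and numeric matrix
#'   `q3_adjusted`.
#' @export
crosshyb_adjust <- function(stage1_present, library, scores,
                            thresholds = calling_thresholds()) {
  otus <- rownames(stage1_present)
  samples <- colnames(stage1_present)
  q3_adj <- matrix(NA_real_, nrow(stage1_present), ncol(stage1_present),
                   dimnames = dimnames(stage1_present))
  present <- stage1_present
  ch <- library$crosshyb
  neighbors <- function(o) {
    rows <- ch$otu_a == o | ch$otu_b == o
    if (!any(rows)) return(NULL)
    data.frame(other = ifelse(ch$otu_a[rows] == o, ch$otu_b[rows],
                              ch$otu_a[rows]),
               pair_id = ch$pair_id[rows], stringsAsFactors = FALSE)
  }
  for (o in otus) {
    sc <- scores[[o]]
    nb <- neighbors(o)
    for (s in samples) {
      if (!stage1_present[o, s]) next
      ok <- sc$usable[, s] & !is.na(sc$score[, s])
      if (!is.null(nb)) {
        flagged <- nb$pair_id[stage1_present[cbind(nb$other, s)]]
        ok <- ok & !(rownames(sc$score) %in% flagged)
      }
      q3 <- if (any(ok)) quantile7(sc$score[ok, s], 0.75) else 0
      q3_adj[o, s] <- q3
      present[o, s] <- q3 >= thresholds$stage2_q3_min
    }
  }
  list(present = present, q3_adjusted = q3_adj)
}

#' Call OTU presence/absence and summarize intensities
#'
#' Runs the full calling pipeline: spike-in scaling, per-pair response
#' scores, Stage1 quantile cutoffs (domain-specific), trimmed-mean probe-set
#' summarization, and the Stage2 cross-hybridization re-check.
#'
#' @param experiment an [array_experiment()].
#' @param library a [probe_library()].
#' @param taxonomy optional [taxonomy_table()] supplying bacteria/archaea
#'   domain labels (falls back to the experiment's labels, then to
#'   all-bacteria).
#' @param thresholds a [calling_thresholds()].
#' @return An [otu_calls()] object.
#' @export
call_otus <- function(experiment, library, taxonomy = NULL,
                      thresholds = calling_thresholds()) {
  experiment <- spike_scale(experiment, library)
  otus <- names(library$probe_sets)
  samples <- colnames(experiment$intensities)
  domain <- if (!is.null(taxonomy)) domain_labels(otus, taxonomy)
            else if (!is.null(experiment$otu_domain)) experiment$otu_domain[otus]
            else domain_labels(otus)
  scores <- otu_score_arrays(experiment, library, thresholds)

  dims <- list(otus, samples)
  intensity <- q1m <- q2m <- q3m <- matrix(NA_real_, length(otus),
                                           length(samples), dimnames = dims)
  pcm <- psm <- matrix(0L, length(otus), length(samples), dimnames = dims)
  stage1 <- matrix(FALSE, length(otus), length(samples), dimnames = dims)
  for (o in otus) {
    sc <- scores[[o]]
    intensity[o, ] <- apply(sc$pm, 2L, trimmed_mean)
    for (s in samples) {
      m <- stage1_metrics(sc$score[, s], sc$usable[, s])
      pcm[o, s] <- m$pairs_counted
      psm[o, s] <- m$pairs_scored
      q1m[o, s] <- m$q1; q2m[o, s] <- m$q2; q3m[o, s] <- m$q3
    }
  }
  max_tm <- apply(intensity, 1L, max)
  for (o in otus) {
    for (s in samples) {
      m <- structure(list(pairs_counted = pcm[o, s], pairs_scored = psm[o, s],
                          q1 = q1m[o, s], q2 = q2m[o, s], q3 = q3m[o, s]),
                     class = "stage1_metrics")
      stage1[o, s] <- stage1_call(m, domain[o], max_tm[o], thresholds)
    }
  }
  st2 <- crosshyb_adjust(stage1, library, scores, thresholds)
  otu_calls(present = st2$present, intensity = intensity,
            design = experiment$design, domain = domain,
            stage1_present = stage1, q1 = q1m, q2 = q2m, q3 = q3m,
            q3_adjusted = st2$q3_adjusted,
            pairs_counted = pcm, pairs_scored = psm,
            thresholds = thresholds)
}

#' Construct an OTU call table
#'
#' Container for per-OTU, per-sample presence flags and spike-scaled
#' trimmed-mean intensities, as produced by [call_otus()] or imported from
#' external calling software.
#'
#' @param present logical OTU x sample matrix.
#' @param intensity numeric OTU x sample matrix of trimmed-mean intensities.
#' @param design sample design (columns `sample_id`, `group`, `site`,
#'   `pool`).
#' @param domain optional named bacteria/archaea vector per OTU.
#' @param ... further matrices kept alongside (q1..q3, q3_adjusted, ...).
#' @param thresholds optional [calling_thresholds()] used.
#' @return An object of class `otu_calls`.
#' @export
otu_calls <- function(present, intensity, design, domain = NULL, ...,
                      thresholds = NULL) {
  present <- as.matrix(present)
  intensity <- as.matrix(intensity)
  if (!identical(dim(present), dim(intensity)) ||
      !identical(dimnames(present), dimnames(intensity))) {
    stop_format("present and intensity matrices must agree in shape")
  }
  if (is.null(rownames(present)) || is.null(colnames(present))) {
    stop_format("call matrices need OTU rownames and sample colnames")
  }
  if (any(present & !is.finite(intensity))) {
    stop_format("present OTUs must have finite trimmed-mean intensities")
  }
  design <- validate_design(design, colnames(present))
  if (is.null(domain)) domain <- domain_labels(rownames(present))
  structure(c(list(present = present, intensity = intensity, design = design,
                   domain = domain, thresholds = thresholds), list(...)),
            class = "otu_calls")
}

#' OTUs detected in at least one sample
#'
#' @param calls an [otu_calls()].
#' @return Character vector of OTU ids.
#' @export
detected_otus <- function(calls) {
  rownames(calls$present)[rowSums(calls$present) > 0L]
}

#' Write / read an OTU call table
#'
#' Long tab-separated format with one row per (OTU, sample):
#' `otu_id, sample_id, present, trimmed_mean_intensity, q1, q2, q3,
#' q3_adjusted`.
#'
#' @param calls an [otu_calls()].
#' @param path calls table path.
#' @param design_path design table path.
#' @export
write_calls <- function(calls, path, design_path) {
  otus <- rownames(calls$present)
  samples <- colnames(calls$present)
  grab <- function(nm) {
    if (!is.null(calls[[nm]])) as.vector(calls[[nm]]) else NA_real_
  }
  df <- data.frame(otu_id = rep(otus, times = length(samples)),
                   sample_id = rep(samples, each = length(otus)),
                   present = as.vector(calls$present),
                   trimmed_mean_intensity = as.vector(calls$intensity),
                   q1 = grab("q1"), q2 = grab("q2"), q3 = grab("q3"),
                   q3_adjusted = grab("q3_adjusted"),
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
  write_tsv(calls$design, design_path)
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path, design_path) {
  df <- read_tsv(path)
  need <- c("otu_id", "sample_id", "present", "trimmed_mean_intensity")
  if (!all(need %in% colnames(df))) {
    stop_format("calls table must have columns ", paste(need, collapse = ", "))
  }
  otus <- unique(df$otu_id)
  samples <- unique(df$sample_id)
  shape <- function(x) matrix(x, length(otus), length(samples),
                              dimnames = list(otus, samples))
  num <- function(col) {
    if (!col %in% colnames(df)) return(NULL)
    suppressWarnings(shape(as.numeric(df[[col]])))
  }
  extras <- Filter(Negate(is.null),
                   list(q1 = num("q1"), q2 = num("q2"), q3 = num("q3"),
                        q3_adjusted = num("q3_adjusted")))
  do.call(otu_calls,
          c(list(present = shape(df$present == "TRUE"),
                 intensity = shape(as.numeric(df$trimmed_mean_intensity)),
                 design = read_tsv(design_path)),
            extras))
}

#' @export
print.otu_calls <- function(x, ...) {
  det <- detected_otus(x)
  cat("OTU calls:", nrow(x$present), "OTUs x", ncol(x$present), "samples;",
      length(det), "detected in >= 1 sample\n")
  if (any(x$domain == "archaea")) {
    cat("  archaeal OTUs:", sum(x$domain == "archaea"),
        "( detected:", sum(x$domain[det] == "archaea"), ")\n")
  }
  invisible(x)
}
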