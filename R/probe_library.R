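# Probe library: OTU probe sets of perfect-match/mismatch (PM/MM) pairs,
# spike-in control probes, and the cross-hybridization adjacency between
# probe sets that share pairs.

#' Construct a probe library
#'
#' @param probe_sets named list (names are OTU ids); each element a data frame
#'   with columns `pair_id`, `pm`, `mm` giving the perfect-match and mismatch
#'   probe id of every pair.  Pairs shared between two cross-hybridizing probe
#'   sets use the same `pair_id` in both sets (with their own probe ids).
#' @param spike_probes character vector of probe ids belonging to the spiked
#'   internal-standard amplicons; must be disjoint from OTU probe ids.
#' @param crosshyb `NULL` or a data frame with columns `otu_a`, `otu_b`,
#'   `pair_id` listing pairs shared between two probe sets.
#'
#' @return An object of class `probe_library`.
#' @export
probe_library <- function(probe_sets, spike_probes = character(),
                          crosshyb = NULL) {
  if (length(probe_sets) == 0L || is.null(names(probe_sets)) ||
      any(!nzchar(names(probe_sets)))) {
    stop_format("probe_sets must be a non-empty named list")
  }
  if (anyDuplicated(names(probe_sets))) {
    stop_format("duplicate OTU id among probe sets")
  }
  probe_sets <- lapply(probe_sets, function(ps) {
    ps <- as.data.frame(ps, stringsAsFactors = FALSE)
    if (!all(c("pair_id", "pm", "mm") %in% colnames(ps))) {
      stop_format("each probe set needs columns pair_id, pm, mm")
    }
    if (nrow(ps) < 1L) stop_format("every probe set must have at least one pair")
    if (anyDuplicated(ps$pair_id)) {
      stop_format("pair_id not unique within a probe set")
    }
    if (any(ps$pm == ps$mm)) {
      stop_format("PM and MM probe of a pair must differ")
    }
    ps[c("pair_id", "pm", "mm")]
  })
  otu_probes <- unlist(lapply(probe_sets, function(ps) c(ps$pm, ps$mm)),
                       use.names = FALSE)
  if (anyDuplicated(otu_probes)) {
    stop_format("duplicate probe_id across probe sets: ",
                otu_probes[duplicated(otu_probes)][1L])
  }
  spike_probes <- as.character(spike_probes)
  if (any(spike_probes %in% otu_probes)) {
    stop_format("spike probe ids must be disjoint from OTU probe ids")
  }
  if (!is.null(crosshyb) && nrow(crosshyb) > 0L) {
    crosshyb <- as.data.frame(crosshyb, stringsAsFactors = FALSE)
    if (!all(c("otu_a", "otu_b", "pair_id") %in% colnames(crosshyb))) {
      stop_format("crosshyb table needs columns otu_a, otu_b, pair_id")
    }
    # store symmetrically with otu_a < otu_b
    swap <- crosshyb$otu_a > crosshyb$otu_b
    tmp <- crosshyb$otu_a[swap]
    crosshyb$otu_a[swap] <- crosshyb$otu_b[swap]
    crosshyb$otu_b[swap] <- tmp
    for (i in seq_len(nrow(crosshyb))) {
      a <- crosshyb$otu_a[i]; b <- crosshyb$otu_b[i]; pid <- crosshyb$pair_id[i]
      if (!a %in% names(probe_sets) || !b %in% names(probe_sets)) {
        stop_format("crosshyb references unknown OTU: ", a, "/", b)
      }
      if (!pid %in% probe_sets[[a]]$pair_id ||
          !pid %in% probe_sets[[b]]$pair_id) {
        stop_format("crosshyb pair_id ", pid,
                    " not present in both probe sets ", a, " and ", b)
      }
    }
    crosshyb <- crosshyb[c("otu_a", "otu_b", "pair_id")]
  } else {
    crosshyb <- data.frame(otu_a = character(), otu_b = character(),
                           pair_id = character(), stringsAsFactors = FALSE)
  }
  structure(list(probe_sets = probe_sets, spike_probes = spike_probes,
                 crosshyb = crosshyb),
            class = "probe_library")
}

#' All probe ids of a library
#'
#' @param library a [probe_library()].
#' @return Character vector of PM, MM and spike probe ids.
#' @export
library_probes <- function(library) {
  c(unlist(lapply(library$probe_sets, function(ps) rbind(ps$pm, ps$mm)),
           use.names = FALSE),
    library$spike_probes)
}

#' Read a probe map (and optional cross-hybridization table)
#'
#' The probe map is tab-separated with columns `probe_id`, `otu_id`, `role`,
#' `pair_id`.  Rows with `otu_id == "SPIKE"` list spike-in control probes
#' (role `PM`); all other rows must come in complete PM/MM pairs.  The
#' optional cross-hybridization table has columns `otu_a`, `otu_b`,
#' `pair_id`.
#'
#' @param path probe map path.
#' @param crosshyb_path optional path of the shared-pair table.
#' @return A [probe_library()].
#' @export
read_probe_map <- function(path, crosshyb_path = NULL) {
  df <- read_tsv(path)
  need <- c("probe_id", "otu_id", "role", "pair_id")
  if (!all(need %in% colnames(df))) {
    stop_format("probe map must have columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$probe_id)) {
    stop_format("duplicate probe_id in probe map: ",
                df$probe_id[duplicated(df$probe_id)][1L])
  }
  if (!all(df$role %in% c("PM", "MM"))) {
    stop_format("unknown probe role: ",
                setdiff(unique(df$role), c("PM", "MM"))[1L])
  }
  spike <- df$otu_id == "SPIKE"
  spike_probes <- df$probe_id[spike]
  df <- df[!spike, , drop = FALSE]
  probe_sets <- lapply(split(df, df$otu_id), function(sub) {
    pairs <- split(sub, sub$pair_id)
    rows <- lapply(pairs, function(p) {
      if (nrow(p) != 2L || !setequal(p$role, c("PM", "MM"))) {
        stop_format("pair ", p$pair_id[1L], " of OTU ", p$otu_id[1L],
                    " lacks a PM or MM row")
      }
      data.frame(pair_id = p$pair_id[1L],
                 pm = p$probe_id[p$role == "PM"],
                 mm = p$probe_id[p$role == "MM"],
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out[order(out$pair_id), , drop = FALSE]
  })
  ch <- NULL
  if (!is.null(crosshyb_path)) {
    ch <- read_tsv(crosshyb_path)
  }
  probe_library(probe_sets, spike_probes, ch)
}

#' Write a probe library to a probe map (and cross-hybridization table)
#'
#' @param library a [probe_library()].
#' @param path probe map path.
#' @param crosshyb_path optional path of the shared-pair table.
#' @export
write_probe_map <- function(library, path, crosshyb_path = NULL) {
  rows <- lapply(names(library$probe_sets), function(otu) {
    ps <- library$probe_sets[[otu]]
    data.frame(probe_id = c(ps$pm, ps$mm),
               otu_id = otu,
               role = rep(c("PM", "MM"), each = nrow(ps)),
               pair_id = c(ps$pair_id, ps$pair_id),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (length(library$spike_probes)) {
    df <- rbind(df, data.frame(probe_id = library$spike_probes,
                               otu_id = "SPIKE", role = "PM",
                               pair_id = "spike", stringsAsFactors = FALSE))
  }
  write_tsv(df, path)
  if (!is.null(crosshyb_path)) {
    write_tsv(library$crosshyb, crosshyb_path)
  }
  invisible(path)
}

#' @export
print.probe_library <- function(x, ...) {
  np <- vapply(x$probe_sets, nrow, integer(1))
  cat("Probe library:", length(x$probe_sets), "OTU probe sets,",
      sum(np), "pairs (", min(np), "-", max(np), "per set ),",
      length(x$spike_probes), "spike probes,",
      nrow(x$crosshyb), "shared cross-hybridizing pairs\n")
  invisible(x)
}
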