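# Greengenes-style taxonomy: one OTU per row, six ranked lineage slots.

#' Taxonomic ranks used throughout the package
#'
#' The lineage of every OTU carries exactly six slots, domain through genus;
#' species-level identity is the OTU itself.
#'
#' @export
TAXONOMY_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

RANK_PREFIXES <- c("k__", "p__", "c__", "o__", "f__", "g__")

#' Construct a taxonomy table
#'
#' @param otu_id character vector of unique OTU identifiers.
#' @param lineage data frame or matrix with one column per rank in
#'   [TAXONOMY_RANKS]; empty strings mark ranks the OTU is unclassified at.
#'
#' @return A data frame of class `taxonomy_table` with columns `otu_id` and
#'   the six ranks.
#' @export
taxonomy_table <- function(otu_id, lineage) {
  otu_id <- as.character(otu_id)
  if (anyDuplicated(otu_id)) {
    stop_format("duplicate otu_id in taxonomy: ",
                paste(unique(otu_id[duplicated(otu_id)])[1:3], collapse = ", "))
  }
  lineage <- as.data.frame(lineage, stringsAsFactors = FALSE)
  if (!identical(colnames(lineage), TAXONOMY_RANKS)) {
    if (ncol(lineage) != length(TAXONOMY_RANKS)) {
      stop_format("lineage must have exactly ", length(TAXONOMY_RANKS),
                  " rank columns")
    }
    colnames(lineage) <- TAXONOMY_RANKS
  }
  if (nrow(lineage) != length(otu_id)) {
    stop_format("otu_id and lineage disagree in length")
  }
  lineage[] <- lapply(lineage, function(x) {
    x <- as.character(x)
    x[is.na(x)] <- ""
    x
  })
  out <- cbind(data.frame(otu_id = otu_id, stringsAsFactors = FALSE), lineage)
  class(out) <- c("taxonomy_table", "data.frame")
  out
}

# Split "k__Bacteria;p__Firmicutes;..." strings into a 6-column matrix.
parse_lineage <- function(x) {
  parts <- strsplit(as.character(x), ";", fixed = TRUE)
  out <- matrix("", nrow = length(x), ncol = length(TAXONOMY_RANKS),
                dimnames = list(NULL, TAXONOMY_RANKS))
  for (i in seq_along(parts)) {
    p <- trimws(parts[[i]])
    p <- p[nzchar(p)]
    if (length(p) > length(TAXONOMY_RANKS)) {
      stop_format("lineage has more than ", length(TAXONOMY_RANKS),
                  " ranks: ", x[i])
    }
    for (j in seq_along(p)) {
      if (!startsWith(p[j], RANK_PREFIXES[j])) {
        stop_format("malformed rank prefix in lineage (expected ",
                    RANK_PREFIXES[j], "): ", x[i])
      }
      out[i, j] <- substring(p[j], nchar(RANK_PREFIXES[j]) + 1L)
    }
  }
  out
}

format_lineage <- function(taxonomy) {
  m <- as.matrix(taxonomy[TAXONOMY_RANKS])
  apply(m, 1L, function(r) paste0(RANK_PREFIXES, r, collapse = ";"))
}

#' Read a taxonomy table
#'
#' Expects a tab-separated file with columns `otu_id` and `lineage`, the
#' latter in the Greengenes rank-prefix convention
#' (`k__...;p__...;c__...;o__...;f__...;g__...`).  Missing trailing ranks are
#' filled with empty strings.
#'
#' @param path file path.
#' @return A [taxonomy_table()].
#' @export
read_taxonomy <- function(path) {
  df <- read_tsv(path)
  if (!all(c("otu_id", "lineage") %in% colnames(df))) {
    stop_format("taxonomy file must have columns otu_id and lineage")
  }
  taxonomy_table(df$otu_id, parse_lineage(df$lineage))
}

#' Write a taxonomy table
#'
#' @param taxonomy a [taxonomy_table()].
#' @param path file path.
#' @export
write_taxonomy <- function(taxonomy, path) {
  write_tsv(data.frame(otu_id = taxonomy$otu_id,
                       lineage = format_lineage(taxonomy)), path)
  invisible(path)
}

#' Taxon label of every OTU at a chosen rank
#'
#' OTUs unclassified at `rank` are grouped into an `"unclassified <parent>"`
#' taxon named after the nearest classified ancestor rank, so that the labels
#' always partition the OTU set.
#'
#' @param taxonomy a [taxonomy_table()].
#' @param rank one of [TAXONOMY_RANKS].
#' @return Named character vector (names are `otu_id`).
#' @export
taxon_at <- function(taxonomy, rank) {
  rank <- match.arg(rank, TAXONOMY_RANKS)
  j <- match(rank, TAXONOMY_RANKS)
  m <- as.matrix(taxonomy[TAXONOMY_RANKS])
  lab <- m[, j]
  missing <- !nzchar(lab)
  if (any(missing)) {
    parent <- rep("root", sum(missing))
    if (j > 1L) {
      sub <- m[missing, seq_len(j - 1L), drop = FALSE]
      parent <- apply(sub, 1L, function(r) {
        nz <- which(nzchar(r))
        if (length(nz)) r[max(nz)] else "root"
      })
    }
    lab[missing] <- paste("unclassified", parent)
  }
  stats::setNames(lab, taxonomy$otu_id)
}

#' @export
print.taxonomy_table <- function(x, ...) {
  cat("Taxonomy table:", nrow(x), "OTUs\n")
  for (r in c("phylum", "family", "genus")) {
    cat(sprintf("  %-7s %d taxa\n", r, length(unique(taxon_at(x, r)))))
  }
  invisible(x)
}
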