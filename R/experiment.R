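# Experiment containers: probe-level intensity matrices with a sample design,
# and fingerprint lane profiles on a shared migration grid.

validate_design <- function(design, samples) {
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "site", "pool")
  if (!all(need %in% colnames(design))) {
    stop_format("design must have columns ", paste(need, collapse = ", "))
  }
  design[need] <- lapply(design[need], as.character)
  if (anyDuplicated(design$sample_id)) {
    stop_format("duplicate sample_id in design")
  }
  miss <- setdiff(samples, design$sample_id)
  if (length(miss)) {
    stop_format("samples absent from design: ", paste(miss, collapse = ", "))
  }
  design[match(samples, design$sample_id), need, drop = FALSE]
}

#' Construct an array experiment
#'
#' @param intensities numeric matrix, probes in rows (rownames are probe ids),
#'   samples in columns (colnames are sample ids); nonnegative, no missing
#'   cells.
#' @param design data frame with columns `sample_id`, `group`, `site`,
#'   `pool` covering every sample.
#' @param library optional [probe_library()]; when given, the matrix rows must
#'   contain every library probe exactly once.
#' @param taxonomy optional [taxonomy_table()] used to attach a
#'   bacteria/archaea domain label to each OTU (domain rank `Archaea`,
#'   case-insensitive, marks archaeal OTUs).
#'
#' @return An object of class `array_experiment` with elements `intensities`,
#'   `design` and `otu_domain`.
#' @export
array_experiment <- function(intensities, design, library = NULL,
                             taxonomy = NULL) {
  intensities <- as.matrix(intensities)
  if (is.null(rownames(intensities)) || is.null(colnames(intensities))) {
    stop_format("intensity matrix needs probe rownames and sample colnames")
  }
  if (anyDuplicated(rownames(intensities))) {
    stop_format("duplicate probe_id rows in intensity matrix")
  }
  storage.mode(intensities) <- "double"
  if (anyNA(intensities) || any(!is.finite(intensities))) {
    stop_format("intensity matrix has missing or non-finite cells")
  }
  if (any(intensities < 0)) {
    stop_format("negative intensity in matrix")
  }
  design <- validate_design(design, colnames(intensities))
  otu_domain <- NULL
  if (!is.null(library)) {
    probes <- library_probes(library)
    if (!setequal(rownames(intensities), probes) ||
        nrow(intensities) != length(probes)) {
      stop_format("intensity rows do not match the probe library exactly")
    }
    otu_domain <- domain_labels(names(library$probe_sets), taxonomy)
  }
  structure(list(intensities = intensities, design = design,
                 otu_domain = otu_domain),
            class = "array_experiment")
}

# bacteria/archaea label per OTU from the taxonomy's domain rank.
domain_labels <- function(otu_ids, taxonomy = NULL) {
  lab <- rep("bacteria", length(otu_ids))
  if (!is.null(taxonomy)) {
    dom <- taxonomy$domain[match(otu_ids, taxonomy$otu_id)]
    lab[!is.na(dom) & tolower(dom) == "archaea"] <- "archaea"
  }
  stats::setNames(lab, otu_ids)
}

read_matrix_tsv <- function(path, key) {
  df <- read_tsv(path)
  if (colnames(df)[1L] != key) {
    stop_format("first column of ", path, " must be ", key)
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "double")
  if (anyNA(m)) stop_format("non-numeric or missing cells in ", path)
  rownames(m) <- df[[1L]]
  m
}

#' Read a probe intensity matrix and its sample design
#'
#' The matrix file is tab-separated with first column `probe_id` and one
#' column per sample; the design file has columns `sample_id`, `group`,
#' `site`, `pool`.
#'
#' @param path intensity matrix path.
#' @param design_path design table path.
#' @inheritParams array_experiment
#' @return An [array_experiment()].
#' @export
read_intensities <- function(path, design_path, library = NULL,
                             taxonomy = NULL) {
  m <- read_matrix_tsv(path, "probe_id")
  design <- read_tsv(design_path)
  array_experiment(m, design, library = library, taxonomy = taxonomy)
}

#' Write an array experiment
#'
#' @param experiment an [array_experiment()].
#' @param path intensity matrix path.
#' @param design_path design table path.
#' @export
write_intensities <- function(experiment, path, design_path) {
  df <- data.frame(probe_id = rownames(experiment$intensities),
                   experiment$intensities, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
  write_tsv(experiment$design, design_path)
  invisible(path)
}

#' Construct a fingerprint set
#'
#' @param profiles numeric matrix: rows are positions of a shared migration
#'   grid in `[0, 1]` (rownames are the positions), columns are lanes
#'   (colnames are sample ids); intensities nonnegative.
#' @param design data frame with columns `sample_id`, `group`, `site`,
#'   `pool` covering every lane.
#' @return An object of class `fingerprint_set`.
#' @export
fingerprint_set <- function(profiles, design) {
  profiles <- as.matrix(profiles)
  storage.mode(profiles) <- "double"
  if (nrow(profiles) < 2L) stop_format("migration grid needs length >= 2")
  if (is.null(colnames(profiles))) stop_format("lanes need sample colnames")
  if (anyNA(profiles) || any(profiles < 0)) {
    stop_format("fingerprint intensities must be nonnegative and complete")
  }
  grid <- as.numeric(rownames(profiles))
  if (anyNA(grid) || is.unsorted(grid) || any(grid < 0) || any(grid > 1)) {
    stop_format("grid positions must be increasing numbers in [0, 1]")
  }
  design <- validate_design(design, colnames(profiles))
  structure(list(profiles = profiles, grid = grid, design = design),
            class = "fingerprint_set")
}

#' Read fingerprint lane profiles and their design
#'
#' The profile file is tab-separated with first column `position` (normalized
#' migration position in `[0, 1]`) and one column per lane.
#'
#' @param path profile matrix path.
#' @param design_path design table path.
#' @return A [fingerprint_set()].
#' @export
read_fingerprints <- function(path, design_path) {
  m <- read_matrix_tsv(path, "position")
  fingerprint_set(m, read_tsv(design_path))
}

#' Write a fingerprint set
#'
#' @param fingerprints a [fingerprint_set()].
#' @param path profile matrix path.
#' @param design_path design table path.
#' @export
write_fingerprints <- function(fingerprints, path, design_path) {
  df <- data.frame(position = rownames(fingerprints$profiles),
                   fingerprints$profiles, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
  write_tsv(fingerprints$design, design_path)
  invisible(path)
}

#' @export
print.array_experiment <- function(x, ...) {
  cat("Array experiment:", nrow(x$intensities), "probes x",
      ncol(x$intensities), "samples\n")
  print(table(group = x$design$group, site = x$design$site))
  invisible(x)
}

#' @export
print.fingerprint_set <- function(x, ...) {
  cat("Fingerprint set:", ncol(x$profiles), "lanes on a",
      nrow(x$profiles), "point grid\n")
  print(table(group = x$design$group, site = x$design$site))
  invisible(x)
}
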