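# Synthetic two-niche experiments with known ground truth.  The array arm
# emulates a phylogenetic microarray run on 3 replicate DNA pools per niche
# from one site; the fingerprint arm emulates gel lane profiles from 4
# replicate pools per niche at each of 4 sites.

#' Simulation configuration
#'
#' Defaults describe a desk-scale version of the two-niche study design:
#' three replicate pools per group hybridized to arrays carrying probe sets
#' of 12 PM/MM pairs plus spiked internal standards, and four sites with
#' four replicate lanes per group for the fingerprint arm.  Intensities are
#' lognormal (positive, right-skewed); a mismatch probe leaks a small
#' fraction of its partner's specific signal on top of background.
#'
#' @param n_phyla,otus_per_phylum,n_archaeal_phyla,genera_per_phylum shape of
#'   the synthetic taxonomy (`n_archaeal_phyla` of the phyla are archaeal).
#' @param pairs_per_probe_set PM/MM pairs per OTU probe set.
#' @param n_spike_sets,spike_probes_per_set,spike_mean spiked
#'   internal-standard probe sets and their fixed mean intensity.
#' @param groups two group labels; the first is the "inside" niche that
#'   planted effects apply to.
#' @param array_replicates replicate pools per group on the array arm.
#' @param fingerprint_sites,fingerprint_replicates sites and replicate lanes
#'   per group and site on the fingerprint arm.
#' @param presence_prob probability that an OTU is truly present in a sample.
#' @param presence_effect named numeric: multiplier on `presence_prob` in the
#'   first group; names are OTU ids or taxon labels at any rank.
#' @param effect named numeric: intensity fold-change of the first group over
#'   the second for truly present OTUs; names as in `presence_effect`.
#' @param pm_signal_mean,background_mean lognormal median of the specific PM
#'   signal and of the per-probe background, in intensity units.
#' @param mm_leak_fraction fraction of specific signal leaking into the MM
#'   probe (`MM = background + leak * signal`).
#' @param lognormal_sigma log-scale SD of all intensity draws.
#' @param crosshyb_rate probability that two neighboring probe sets share
#'   `crosshyb_shared_pairs` pairs (non-specific hybridization).
#' @param crosshyb_shared_pairs shared pairs per cross-hybridizing link; at
#'   most half of `pairs_per_probe_set`.
#' @param array_scale_jitter log-scale SD of the per-array scale factor that
#'   multiplies every probe on an array (what spike-in scaling removes).
#' @param n_bands,band_sd,band_presence common fingerprint bands, their
#'   Gaussian width on the `[0, 1]` migration grid, and their per-lane
#'   presence probability (same in both groups).
#' @param n_marker_bands extra bands present only in first-group lanes
#'   (presence probability 1 vs 0) — the planted fingerprint effect.
#' @param site_band_prob probability that a common band occurs at a site at
#'   all (site-to-site community differences).
#' @param grid_length number of migration grid points.
#' @param band_noise_sd SD of the nonnegative (folded normal) baseline noise.
#' @param seed integer seed; a fixed seed makes outputs byte-identical.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_phyla = 10L, otus_per_phylum = 50L,
                       n_archaeal_phyla = 1L, genera_per_phylum = 5L,
                       pairs_per_probe_set = 12L,
                       n_spike_sets = 2L, spike_probes_per_set = 12L,
                       spike_mean = 10000,
                       groups = c("IN", "OUT"), array_replicates = 3L,
                       fingerprint_sites = 4L, fingerprint_replicates = 4L,
                       presence_prob = 0.6,
                       presence_effect = numeric(),
                       effect = numeric(),
                       pm_signal_mean = 20000, background_mean = 50,
                       mm_leak_fraction = 0.005, lognormal_sigma = 0.25,
                       crosshyb_rate = 0.05, crosshyb_shared_pairs = 4L,
                       array_scale_jitter = 0.15,
                       n_bands = 30L, band_sd = 0.012, band_presence = 0.9,
                       n_marker_bands = 0L, site_band_prob = 0.8,
                       grid_length = 400L, band_noise_sd = 0.01,
                       seed = NULL) {
  cfg <- as.list(environment())
  counts <- c("n_phyla", "otus_per_phylum", "genera_per_phylum",
              "pairs_per_probe_set", "n_spike_sets", "spike_probes_per_set",
              "array_replicates", "fingerprint_sites",
              "fingerprint_replicates", "n_bands", "grid_length")
  for (nm in counts) {
    if (!is_count(cfg[[nm]]) || cfg[[nm]] < 1) {
      stop_format(nm, " must be a positive integer")
    }
  }
  for (nm in c("n_archaeal_phyla", "n_marker_bands", "crosshyb_shared_pairs")) {
    if (!is_count(cfg[[nm]])) stop_format(nm, " must be a nonnegative integer")
  }
  if (n_archaeal_phyla > n_phyla) stop_format("n_archaeal_phyla > n_phyla")
  if (crosshyb_shared_pairs > pairs_per_probe_set %/% 2L) {
    stop_format("crosshyb_shared_pairs must be at most half the pairs per set")
  }
  for (nm in c("presence_prob", "mm_leak_fraction", "crosshyb_rate",
               "band_presence", "site_band_prob")) {
    if (!is_prob(cfg[[nm]])) stop_format(nm, " must lie in [0, 1]")
  }
  for (nm in c("pm_signal_mean", "background_mean", "spike_mean")) {
    if (cfg[[nm]] <= 0) stop_format(nm, " must be positive")
  }
  for (nm in c("lognormal_sigma", "array_scale_jitter", "band_sd",
               "band_noise_sd")) {
    if (cfg[[nm]] < 0) stop_format(nm, " must be nonnegative")
  }
  if (length(groups) != 2L || anyDuplicated(groups)) {
    stop_format("groups must be two distinct labels")
  }
  if (length(effect) && (is.null(names(effect)) || any(effect <= 0))) {
    stop_format("effect must be a named vector of positive fold-changes")
  }
  if (length(presence_effect) &&
      (is.null(names(presence_effect)) || any(presence_effect < 0))) {
    stop_format("presence_effect must be a named nonnegative vector")
  }
  if (grid_length < 2L) stop_format("grid_length must be at least 2")
  structure(cfg, class = "sim_config")
}

# Synthetic taxonomy: the first n_archaeal_phyla phyla are archaeal; each
# phylum has one class/order/family and genera_per_phylum genera.
simulate_taxonomy <- function(config) {
  n <- config$n_phyla * config$otus_per_phylum
  phy_idx <- rep(seq_len(config$n_phyla), each = config$otus_per_phylum)
  arch <- phy_idx <= config$n_archaeal_phyla
  phylum <- ifelse(arch, sprintf("ArchPhylum%02d", phy_idx),
                   sprintf("Phylum%02d", phy_idx))
  within <- rep(seq_len(config$otus_per_phylum), times = config$n_phyla)
  genus <- sprintf("%s_gen%02d", phylum,
                   ((within - 1L) %% config$genera_per_phylum) + 1L)
  taxonomy_table(sprintf("otu%05d", seq_len(n)),
                 data.frame(domain = ifelse(arch, "Archaea", "Bacteria"),
                            phylum = phylum,
                            class = paste0(phylum, "_cls"),
                            order = paste0(phylum, "_ord"),
                            family = paste0(phylum, "_fam"),
                            genus = genus,
                            stringsAsFactors = FALSE))
}

# Resolve a named effect map (otu id or taxon label at any rank) to one value
# per OTU; more specific names win (otu > genus > ... > domain).
resolve_effect <- function(map, taxonomy, default) {
  out <- rep(default, nrow(taxonomy))
  names(out) <- taxonomy$otu_id
  if (!length(map)) return(out)
  for (rank in rev(TAXONOMY_RANKS)) {       # domain first, genus overrides
    lab <- taxon_at(taxonomy, rank)
    hit <- lab %in% names(map)
    out[hit] <- map[lab[hit]]
  }
  hit <- taxonomy$otu_id %in% names(map)
  out[hit] <- map[taxonomy$otu_id[hit]]
  out
}

simulate_library <- function(config, taxonomy) {
  pp <- config$pairs_per_probe_set
  otus <- taxonomy$otu_id
  probe_sets <- lapply(otus, function(o) {
    data.frame(pair_id = sprintf("%s_pr%02d", o, seq_len(pp)),
               pm = sprintf("%s_pm%02d", o, seq_len(pp)),
               mm = sprintf("%s_mm%02d", o, seq_len(pp)),
               stringsAsFactors = FALSE)
  })
  names(probe_sets) <- otus
  contrib <- lapply(probe_sets, function(ps) rep(NA_character_, nrow(ps)))
  ch <- list()
  k <- config$crosshyb_shared_pairs
  if (k > 0L && length(otus) > 1L && config$crosshyb_rate > 0) {
    linked <- which(stats::runif(length(otus) - 1L) < config$crosshyb_rate)
    for (li in seq_along(linked)) {
      i <- linked[li]
      a <- otus[i]; b <- otus[i + 1L]
      shared <- sprintf("cx%05d_%02d", i, seq_len(k))
      ia <- (pp - k + 1L):pp                     # tail of a, head of b
      ib <- seq_len(k)
      probe_sets[[a]]$pair_id[ia] <- shared
      probe_sets[[b]]$pair_id[ib] <- shared
      contrib[[a]][ia] <- b
      contrib[[b]][ib] <- a
      ch[[li]] <- data.frame(otu_a = a, otu_b = b, pair_id = shared,
                             stringsAsFactors = FALSE)
    }
  }
  spikes <- sprintf("spk%02d_%02d",
                    rep(seq_len(config$n_spike_sets),
                        each = config$spike_probes_per_set),
                    rep(seq_len(config$spike_probes_per_set),
                        times = config$n_spike_sets))
  lib <- probe_library(probe_sets, spikes,
                       if (length(ch)) do.call(rbind, ch) else NULL)
  list(library = lib, contrib = contrib)
}

#' Simulate a two-niche array experiment with known ground truth
#'
#' Truly present OTUs receive a specific PM signal
#' `lognormal(log(pm_signal_mean * fold), lognormal_sigma)` on top of a
#' lognormal background; the paired MM probe carries the background plus
#' `mm_leak_fraction` of the specific signal.  Absent OTUs show background
#' only.  Spike probes are drawn at a fixed mean, then every probe on an
#' array is multiplied by a per-array lognormal scale factor; pairs shared
#' between cross-hybridizing probe sets sum the signals of all their present
#' contributors.
#'
#' @param config a [sim_config()].
#' @return A list of class `array_simulation` with elements `library`,
#'   `taxonomy`, `experiment` and `truth` (ground truth: logical presence
#'   matrix `present`, per-OTU `fold`, and the config).
#' @export
simulate_array <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    taxonomy <- simulate_taxonomy(config)
    lb <- simulate_library(config, taxonomy)
    lib <- lb$library
    otus <- taxonomy$otu_id
    n_otus <- length(otus)
    pp <- config$pairs_per_probe_set
    g1 <- config$groups[1L]
    samples <- paste(rep(config$groups, each = config$array_replicates),
                     rep(seq_len(config$array_replicates), 2L), sep = "_")
    grp <- rep(config$groups, each = config$array_replicates)
    ns <- length(samples)
    design <- data.frame(sample_id = samples, group = grp, site = "site1",
                         pool = as.character(rep(seq_len(config$array_replicates), 2L)),
                         stringsAsFactors = FALSE)

    p_base <- resolve_effect(config$presence_effect, taxonomy, default = 1)
    p_mat <- outer(rep(config$presence_prob, n_otus), rep(1, ns))
    p_mat[, grp == g1] <- pmin(1, p_mat[, grp == g1] * p_base)
    present <- matrix(stats::runif(n_otus * ns) < p_mat, n_otus, ns,
                      dimnames = list(otus, samples))
    fold <- resolve_effect(config$effect, taxonomy, default = 1)

    sigma <- config$lognormal_sigma
    bg <- config$background_mean
    leak <- config$mm_leak_fraction
    # log-scale specific-signal mean of each OTU in each sample
    meanlog <- matrix(log(config$pm_signal_mean), n_otus, ns) +
      outer(log(fold), as.numeric(grp == g1))
    probes <- library_probes(lib)
    intens <- matrix(0, length(probes), ns, dimnames = list(probes, samples))
    for (i in seq_len(n_otus)) {
      ps <- lib$probe_sets[[otus[i]]]
      B <- matrix(stats::rlnorm(pp * ns, log(bg), sigma), pp, ns)
      own <- matrix(stats::rlnorm(pp * ns, rep(meanlog[i, ], each = pp), sigma),
                    pp, ns)
      sig <- sweep(own, 2L, as.numeric(present[i, ]), `*`)
      alt <- lb$contrib[[otus[i]]]
      for (j in which(!is.na(alt))) {
        ci <- match(alt[j], otus)
        extra <- stats::rlnorm(ns, meanlog[ci, ], sigma) *
          as.numeric(present[ci, ])
        sig[j, ] <- sig[j, ] + extra
      }
      intens[ps$pm, ] <- sig + B
      intens[ps$mm, ] <- B + leak * sig
    }
    if (length(lib$spike_probes)) {
      intens[lib$spike_probes, ] <-
        matrix(stats::rlnorm(length(lib$spike_probes) * ns,
                             log(config$spike_mean), sigma),
               length(lib$spike_probes), ns)
    }
    scale <- stats::rlnorm(ns, 0, config$array_scale_jitter)
    intens <- sweep(intens, 2L, scale, `*`)

    experiment <- array_experiment(intens, design, library = lib,
                                   taxonomy = taxonomy)
    truth <- structure(list(present = present, fold = fold,
                            scale_factors = stats::setNames(scale, samples),
                            config = config),
                       class = "ground_truth")
    structure(list(library = lib, taxonomy = taxonomy,
                   experiment = experiment, truth = truth),
              class = "array_simulation")
  })
}

#' Simulate gel fingerprint lanes with known ground truth
#'
#' Each lane is a sum of Gaussian band profiles.  A band occurs at a site
#' with probability `site_band_prob` and, where it occurs, is present in a
#' lane with its group's probability (`band_presence` for common bands; 1 vs
#' 0 for the `n_marker_bands` planted marker bands).  Folded-normal baseline
#' noise keeps intensities nonnegative.
#'
#' @param config a [sim_config()].
#' @return A list of class `fingerprint_simulation` with elements
#'   `fingerprints` (a [fingerprint_set()]) and `truth` (band table and
#'   per-lane band presence matrix).
#' @export
simulate_fingerprints <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    nb <- config$n_bands + config$n_marker_bands
    marker <- c(rep(FALSE, config$n_bands), rep(TRUE, config$n_marker_bands))
    pos <- stats::runif(nb, 0.05, 0.95)
    amp <- stats::rlnorm(nb, 0, 0.3)
    sites <- sprintf("site%d", seq_len(config$fingerprint_sites))
    at_site <- matrix(stats::runif(length(sites) * nb) < config$site_band_prob,
                      length(sites), nb, dimnames = list(sites, NULL))
    at_site[, marker] <- TRUE
    p_grp <- rbind(ifelse(marker, 1, config$band_presence),
                   ifelse(marker, 0, config$band_presence))
    rownames(p_grp) <- config$groups

    design <- expand.grid(pool = seq_len(config$fingerprint_replicates),
                          group = config$groups, site = sites,
                          stringsAsFactors = FALSE)
    design <- data.frame(
      sample_id = sprintf("%s_%s_%d", design$site, design$group, design$pool),
      group = design$group, site = design$site,
      pool = as.character(design$pool), stringsAsFactors = FALSE)

    grid <- seq(0, 1, length.out = config$grid_length)
    shapes <- exp(-outer(grid, pos, `-`)^2 / (2 * config$band_sd^2))
    profiles <- matrix(0, config$grid_length, nrow(design),
                       dimnames = list(format(grid, digits = 6, trim = TRUE),
                                       design$sample_id))
    lane_presence <- matrix(FALSE, nb, nrow(design),
                            dimnames = list(NULL, design$sample_id))
    for (l in seq_len(nrow(design))) {
      here <- at_site[design$site[l], ]
      pres <- here & (stats::runif(nb) < p_grp[design$group[l], ])
      lane_presence[, l] <- pres
      if (any(pres)) {
        heights <- amp[pres] * stats::rlnorm(sum(pres), 0, 0.2)
        profiles[, l] <- shapes[, pres, drop = FALSE] %*% heights
      }
      profiles[, l] <- profiles[, l] +
        abs(stats::rnorm(config$grid_length, 0, config$band_noise_sd))
    }
    bands <- data.frame(band = seq_len(nb), position = pos, amplitude = amp,
                        marker = marker,
                        p1 = p_grp[1L, ], p2 = p_grp[2L, ],
                        stringsAsFactors = FALSE)
    colnames(bands)[5:6] <- paste0("p_", config$groups)
    truth <- structure(list(bands = bands, lane_presence = lane_presence,
                            config = config),
                       class = "ground_truth")
    structure(list(fingerprints = fingerprint_set(profiles, design),
                   truth = truth),
              class = "fingerprint_simulation")
  })
}
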