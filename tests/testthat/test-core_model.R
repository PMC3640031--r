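test_that("probe map parsing builds the library and rejects malformed files", {
  lines <- c("probe_id\totu_id\trole\tpair_id",
             sprintf("o1p%d\totu1\tPM\tpr%d", 1:4, 1:4),
             sprintf("o1m%d\totu1\tMM\tpr%d", 1:4, 1:4),
             sprintf("o2p%d\totu2\tPM\tpr%d", 1:4, 1:4),
             sprintf("o2m%d\totu2\tMM\tpr%d", 1:4, 1:4),
             "sp1\tSPIKE\tPM\tspike")
  f <- withr::local_tempfile(lines = lines, fileext = ".tsv")
  lib <- read_probe_map(f)
  expect_length(lib$probe_sets, 2L)
  expect_equal(vapply(lib$probe_sets, nrow, integer(1)),
               c(otu1 = 4L, otu2 = 4L))
  expect_equal(lib$spike_probes, "sp1")

  f2 <- withr::local_tempfile(lines = lines[-2], fileext = ".tsv")
  expect_error(read_probe_map(f2), "lacks a PM or MM",
               class = "soilniche_format_error")
  f3 <- withr::local_tempfile(lines = c(lines, lines[2]), fileext = ".tsv")
  expect_error(read_probe_map(f3), "duplicate probe_id",
               class = "soilniche_format_error")
  f4 <- withr::local_tempfile(
    lines = sub("\tPM\t", "\tXX\t", lines), fileext = ".tsv")
  expect_error(read_probe_map(f4), "role", class = "soilniche_format_error")
})

test_that("probe library round-trips through files, crosshyb included", {
  for (i in 1:30) {
    sim <- simulate_array(sim_config(n_phyla = 2, otus_per_phylum = 3,
                                     pairs_per_probe_set = 8,
                                     crosshyb_rate = 0.5, seed = i))
    f <- withr::local_tempfile(fileext = ".tsv")
    fc <- withr::local_tempfile(fileext = ".tsv")
    write_probe_map(sim$library, f, fc)
    back <- read_probe_map(f, fc)
    expect_equal(back$probe_sets[order(names(back$probe_sets))],
                 lapply(sim$library$probe_sets[order(names(sim$library$probe_sets))],
                        function(ps) ps[order(ps$pair_id), ]),
                 ignore_attr = TRUE)
    expect_setequal(back$spike_probes, sim$library$spike_probes)
    ch_key <- function(ch) sort(paste(ch$otu_a, ch$otu_b, ch$pair_id))
    expect_equal(ch_key(back$crosshyb), ch_key(sim$library$crosshyb))
  }
})

test_that("taxonomy lineages parse, truncate and reject malformed input", {
  f <- withr::local_tempfile(lines = c(
    "otu_id\tlineage",
    "otu1\tk__Bacteria;p__Firmicutes;c__Bacilli;o__Bacillales;f__Bacillaceae;g__Bacillus",
    "otu2\tk__Bacteria;p__Firmicutes;c__Bacilli;o__Bacillales;f__Bacillaceae"),
    fileext = ".tsv")
  tax <- read_taxonomy(f)
  expect_equal(tax$genus, c("Bacillus", ""))
  expect_equal(tax$family, c("Bacillaceae", "Bacillaceae"))

  bad <- withr::local_tempfile(lines = c("otu_id\tlineage",
                                         "otu1\tp__Firmicutes;k__Bacteria"),
                               fileext = ".tsv")
  expect_error(read_taxonomy(bad), "prefix", class = "soilniche_format_error")
  toomany <- withr::local_tempfile(
    lines = c("otu_id\tlineage",
              paste0("otu1\t", paste(rep("k__x", 7), collapse = ";"))),
    fileext = ".tsv")
  expect_error(read_taxonomy(toomany), class = "soilniche_format_error")
})

test_that("a 1000-row synthetic taxonomy round-trips losslessly", {
  tax <- simulate_array(sim_config(n_phyla = 20, otus_per_phylum = 50,
                                   pairs_per_probe_set = 1,
                                   crosshyb_rate = 0, crosshyb_shared_pairs = 0,
                                   seed = 3))$taxonomy
  expect_equal(nrow(tax), 1000L)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_taxonomy(tax, f)
  expect_equal(read_taxonomy(f), tax)
})

test_that("rank aggregation partitions the OTU set at every rank", {
  tax <- simulate_array(sim_config(n_phyla = 3, otus_per_phylum = 7,
                                   seed = 5))$taxonomy
  tax$genus[2] <- ""   # unclassified OTUs form their own parent bucket
  tax$family[3] <- tax$genus[3] <- ""
  for (rank in TAXONOMY_RANKS) {
    lab <- taxon_at(tax, rank)
    expect_length(lab, nrow(tax))
    expect_false(anyNA(lab))
    expect_equal(sum(table(lab)), nrow(tax))
  }
  expect_match(taxon_at(tax, "genus")[2], "^unclassified ")
})

test_that("intensity matrices and designs read, validate and round-trip", {
  sim <- toy_sim(seed = 11)
  f <- withr::local_tempfile(fileext = ".tsv")
  fd <- withr::local_tempfile(fileext = ".tsv")
  write_intensities(sim$experiment, f, fd)
  back <- read_intensities(f, fd, library = sim$library,
                           taxonomy = sim$taxonomy)
  expect_equal(back$intensities, sim$experiment$intensities, tolerance = 1e-12)
  expect_equal(back$design, sim$experiment$design)
  expect_equal(back$otu_domain, sim$experiment$otu_domain)

  d <- sim$experiment$design[-1, ]
  fd2 <- withr::local_tempfile(fileext = ".tsv")
  write_tsv <- function(df, p) utils::write.table(df, p, sep = "\t",
                                                  quote = FALSE, row.names = FALSE)
  write_tsv(d, fd2)
  expect_error(read_intensities(f, fd2, library = sim$library),
               "absent from design", class = "soilniche_format_error")

  neg <- sim$experiment$intensities
  neg[1, 1] <- -5
  expect_error(array_experiment(neg, sim$experiment$design),
               "negative", class = "soilniche_format_error")
})

test_that("fingerprint sets round-trip and reject bad input", {
  for (i in 1:10) {
    fsim <- simulate_fingerprints(sim_config(fingerprint_sites = 2,
                                             fingerprint_replicates = 2,
                                             grid_length = 40, n_bands = 6,
                                             seed = i))
    f <- withr::local_tempfile(fileext = ".tsv")
    fd <- withr::local_tempfile(fileext = ".tsv")
    write_fingerprints(fsim$fingerprints, f, fd)
    back <- read_fingerprints(f, fd)
    expect_equal(back$profiles, fsim$fingerprints$profiles, tolerance = 1e-6)
    expect_equal(back$design, fsim$fingerprints$design)
  }
  expect_error(fingerprint_set(matrix(1, 1, 2, dimnames = list("0", c("a", "b"))),
                               rand_design(c("a", "b"))),
               "grid", class = "soilniche_format_error")
})
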