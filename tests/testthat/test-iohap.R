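test_that("reading a haplotype table maps cells, missing codes and errors", {
  tsv <- tempfile(fileext = ".tsv")
  hdr <- c("SampleID", "Population", "Region", YFILER <- yfiler_panel()$loci)
  rows <- list(
    c("S1", "Roma_East", "East", 14, 13, 30, 24, 10, 11, 13, 11, 14, 15,
      11, 12, 19, 15, 16, 23, 12),
    c("S2", "Roma_East", "East", 15, 13, 30, 24, 10, 11, 13, 11, 14, 15,
      11, "99", 19, 15, "13.2", 23, 12)
  )
  writeLines(c(paste(hdr, collapse = "\t"),
               sapply(rows, paste, collapse = "\t")), tsv)
  ds <- read_haplotype_table(tsv)
  expect_equal(n_haplotypes(ds), 2)
  expect_equal(ds$tab$DYS19[1], 14)
  expect_true(is.na(ds$tab$DYS439[2]))        # '99' is missing
  expect_equal(ds$tab$DYS458[2], 13.2)        # intermediate preserved

  # unknown locus column -> warning and ignored
  writeLines(c(paste(c(hdr, "DYS999"), collapse = "\t"),
               paste(c(rows[[1]], 7), collapse = "\t")), tsv)
  expect_warning(ds2 <- read_haplotype_table(tsv), "DYS999")
  expect_false("DYS999" %in% names(ds2$tab))

  # non-numeric cell -> hard error naming the locus
  bad <- rows[[1]]; bad[4] <- "xx"
  writeLines(c(paste(hdr, collapse = "\t"),
               paste(bad, collapse = "\t")), tsv)
  expect_error(read_haplotype_table(tsv), "DYS19")

  # duplicate sample id -> hard error
  writeLines(c(paste(hdr, collapse = "\t"),
               paste(rows[[1]], collapse = "\t"),
               paste(rows[[1]], collapse = "\t")), tsv)
  expect_error(read_haplotype_table(tsv), "duplicate")
})

test_that("delimiter auto-detection handles comma and semicolon dialects", {
  csv <- tempfile(fileext = ".csv")
  ds0 <- mini_dataset(rbind(c(10, 11, 12), c(10, 12, 12)))
  for (d in c(",", ";")) {
    hdr <- paste(c("SampleID", "Population", "L1", "L2", "L3"),
                 collapse = d)
    writeLines(c(hdr, paste(c("a", "P1", 10, 11, 12), collapse = d)), csv)
    ds <- read_haplotype_table(csv, panel = mini_panel(3))
    expect_equal(ds$tab$L2, 11)
  }
})

test_that("intermediate alleles round to nearest, halves away from zero", {
  ds <- mini_dataset(rbind(c(13.2, 14.0, 13.5), c(13.7, 13.5, 14.49)))
  r <- round_intermediate_alleles(ds)
  expect_equal(unname(unlist(r$tab[1, c("L1", "L2", "L3")])), c(13, 14, 14))
  expect_equal(unname(unlist(r$tab[2, c("L1", "L2", "L3")])), c(14, 14, 14))
  expect_identical(round_intermediate_alleles(r)$tab, r$tab)  # idempotent
})

test_that("views apply the per-analysis marker conventions", {
  ds <- yfiler_dataset(list(
    yfiler_row("a", "P1", list(DYS389I = 13, DYS389II = 30, DYS385a = 14,
                               DYS385b = 11)),
    yfiler_row("b", "P1", list(DYS389II = NA))
  ))
  vnet <- make_view(ds, "NETWORK")
  expect_false(any(c("DYS385a", "DYS385b") %in% vnet$loci))
  expect_equal(unname(vnet$matrix["a", "DYS389II"]), 17)   # 30 - 13
  expect_true(is.na(vnet$matrix["b", "DYS389II"]))         # NA propagates

  vdist <- make_view(ds, "DISTANCE")
  expect_equal(length(vdist$loci), 17)
  expect_equal(unname(vdist$matrix["a", c("DYS385a", "DYS385b")]),
               c(11, 14))                                  # sorted ascending

  vpred <- make_view(ds, "PREDICTION")
  expect_equal(unname(vpred$matrix["a", "DYS389II"]), 30)  # sum untouched

  # view construction never alters the source dataset
  expect_equal(ds$tab$DYS385a[1], 14)

  # impossible composite genotype
  bad <- yfiler_dataset(list(
    yfiler_row("x", "P1", list(DYS389I = 14, DYS389II = 13))))
  expect_error(make_view(bad, "NETWORK"), "DYS389I")
})

test_that("arp export declares counts and groups and round-trips", {
  ds <- yfiler_dataset(list(
    yfiler_row("a1", "A"), yfiler_row("a2", "A",
                                      list(DYS19 = 15, DYS439 = NA)),
    yfiler_row("a3", "A"), yfiler_row("b1", "B"),
    yfiler_row("b2", "B", list(DYS390 = 25))
  ))
  arp <- tempfile(fileext = ".arp")
  write_arlequin_arp(ds, arp, grouping = c(A = "G1", B = "G2"))
  txt <- readLines(arp)
  expect_true(any(grepl("NbSamples=2", txt)))
  expect_equal(sum(grepl("SampleSize=3", txt)), 1)
  expect_equal(sum(grepl("SampleSize=2", txt)), 1)
  expect_true(any(grepl("NbGroups=2", txt)))
  expect_true(any(grepl("MissingData='\\?'", txt)))

  parsed <- oracle_parse_arp(arp)
  expect_equal(parsed$pop, ds$tab$population)
  expect_equal(parsed$alleles,
               unname(as.matrix(ds$tab[, ds$panel$loci])))
})

test_that("read-write-read round trip is allele-exact", {
  sim <- simulate_scenario(scenario_config(
    "DIVERGENCE", pop_labels = c("East", "West"), pop_sizes = 60,
    split_time = 30, burn_in = 20, sample_sizes = 15, seed = 11))
  ds <- sim$dataset
  f <- tempfile(fileext = ".tsv")
  write_haplotype_table(ds, f)
  back <- read_haplotype_table(f)
  expect_equal(back$tab[, back$panel$loci], ds$tab[, ds$panel$loci])
  expect_equal(back$tab$population, ds$tab$population)
})

test_that("merging pools rows and intersects panels", {
  simA <- simulate_scenario(scenario_config(
    "PANMIXIA", pop_labels = "Roma_new", pop_sizes = 200, split_time = 0,
    burn_in = 30, sample_sizes = 20, seed = 3))
  simB <- simulate_scenario(scenario_config(
    "PANMIXIA", pop_labels = "Roma_ref", pop_sizes = 200, split_time = 0,
    burn_in = 30, sample_sizes = 12, seed = 4))
  m <- merge_datasets(simA$dataset, simB$dataset)
  expect_equal(n_haplotypes(m), 32)
  expect_equal(sort(unique(m$tab$population)), c("Roma_new", "Roma_ref"))

  # merge with empty dataset is the identity
  empty <- ystr_dataset(simA$dataset$tab[0, ], yfiler_panel())
  expect_equal(merge_datasets(simA$dataset, empty)$tab, simA$dataset$tab)

  # 27-locus + 17-locus tables retain the 17 shared loci
  tab27 <- simB$dataset$tab
  tab27$sample_id <- paste0("plus_", tab27$sample_id)
  for (l in setdiff(yfiler_plus_panel()$loci, yfiler_panel()$loci))
    tab27[[l]] <- 12
  ds27 <- ystr_dataset(tab27, yfiler_plus_panel())
  expect_warning(m2 <- merge_datasets(ds27, simA$dataset), "dropping")
  expect_equal(sort(m2$panel$loci), sort(yfiler_panel()$loci))
  expect_equal(n_haplotypes(m2), 32)

  # sample_id collision is fatal
  expect_error(merge_datasets(simA$dataset, simA$dataset), "collision")
})
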