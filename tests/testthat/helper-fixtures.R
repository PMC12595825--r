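# Small programmatic fixtures used across test files.

# A dataset over an arbitrary mini-panel: loci L1..Lk, no special handling.
mini_panel <- function(k = 3) marker_panel("mini", paste0("L", seq_len(k)))

mini_dataset <- function(alleles, pop = NULL, ids = NULL) {
  alleles <- as.matrix(alleles)
  k <- ncol(alleles)
  n <- nrow(alleles)
  tab <- as.data.frame(alleles)
  names(tab) <- paste0("L", seq_len(k))
  tab$sample_id <- if (is.null(ids)) sprintf("S%02d", seq_len(n)) else ids
  tab$population <- if (is.null(pop)) "P1" else pop
  ystr_dataset(tab, mini_panel(k))
}

mini_view <- function(alleles, pop = NULL, mode = "DISTANCE") {
  make_view(mini_dataset(alleles, pop), mode)
}

# A complete 17-locus Yfiler row around the typical modal haplotype.
yfiler_row <- function(id, pop, overrides = list(), region = NA) {
  base <- list(
    DYS19 = 14, DYS389I = 13, DYS389II = 30, DYS390 = 24, DYS391 = 10,
    DYS392 = 11, DYS393 = 13, DYS385a = 11, DYS385b = 14, DYS437 = 15,
    DYS438 = 11, DYS439 = 12, DYS448 = 19, DYS456 = 15, DYS458 = 16,
    DYS635 = 23, YGATAH4 = 12
  )
  for (nm in names(overrides)) base[[nm]] <- overrides[[nm]]
  c(list(sample_id = id, population = pop, region = region), base)
}

yfiler_dataset <- function(rows) {
  tab <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  ystr_dataset(tab, yfiler_panel())
}
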