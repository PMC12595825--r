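#' Read a delimited Y-STR haplotype table
#'
#' Reads a TSV/CSV/semicolon-delimited table with columns `SampleID`,
#' `Population`, optionally `Region`, followed by locus columns. Cells equal
#' to the literal missing code `'99'`, an empty string, or any configured
#' null token are stored as `NA`. Intermediate alleles such as `"13.2"` are
#' preserved as-is at this stage; rounding is a separate, explicit step
#' ([round_intermediate_alleles()]).
#'
#' @param path input file.
#' @param panel a [marker_panel()]; defaults to the 17-locus Yfiler set.
#' @param delim field delimiter; `NULL` auto-detects among tab, comma and
#'   semicolon from the header line.
#' @param na_tokens cell values treated as missing in addition to `"99"`.
#' @param provenance free-text source note recorded in the dataset.
#' @return A [ystr_dataset()].
#' @export
read_haplotype_table <- function(path, panel = yfiler_panel(), delim = NULL,
                                 na_tokens = c("", "NA"),
                                 provenance = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  if (is.null(delim)) {
    cand <- c("\t", ",", ";")
    hits <- vapply(cand, function(d)
      length(strsplit(header, d, fixed = TRUE)[[1]]), integer(1))
    delim <- cand[which.max(hits)]
  }
  raw <- utils::read.table(path, sep = delim, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           strip.white = TRUE, comment.char = "",
                           quote = "\"")
  names(raw) <- sub("^SampleID$", "sample_id",
                sub("^Population$", "population",
                sub("^Region$", "region", names(raw))))
  if (!all(c("sample_id", "population") %in% names(raw)))
    stop("header must name SampleID and Population columns")
  unknown <- setdiff(names(raw),
                     c("sample_id", "population", "region", panel$loci))
  if (length(unknown) > 0) {
    warning("ignoring unknown locus column(s): ",
            paste(unknown, collapse = ", "))
    raw <- raw[, setdiff(names(raw), unknown), drop = FALSE]
  }
  absent <- setdiff(panel$loci, names(raw))
  if (length(absent) > 0)
    stop("panel loci missing from header: ", paste(absent, collapse = ", "))
  na_tokens <- union(na_tokens, "99")
  for (l in panel$loci) {
    cell <- raw[[l]]
    cell[cell %in% na_tokens] <- NA
    val <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & is.na(val))
    if (length(bad) > 0)
      stop("non-numeric allele '", cell[bad[1]], "' at row ", bad[1],
           ", locus ", l)
    raw[[l]] <- val
  }
  ystr_dataset(raw, panel, provenance = provenance)
}

#' Write a dataset as a normalised TSV
#'
#' Emits the canonical column layout (`SampleID`, `Population`, `Region`,
#' then panel loci in panel order) with missing alleles coded as `99`,
#' matching the convention of the input tables.
#'
#' @param ds a [ystr_dataset()].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_haplotype_table <- function(ds, path) {
  stopifnot(inherits(ds, "ystr_dataset"))
  out <- ds$tab
  for (l in ds$panel$loci) {
    col <- as.character(out[[l]])
    col[is.na(col)] <- "99"
    out[[l]] <- col
  }
  out$region[is.na(out$region)] <- ""
  names(out)[1:3] <- c("SampleID", "Population", "Region")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a dataset as an Arlequin project (.arp) file
#'
#' Writes a haploid microsatellite Arlequin project: `DataType=MICROSAT`,
#' `GenotypicData=0`, one sample block per population listing
#' `id<TAB>frequency<TAB>allele allele ...` in panel locus order, and an
#' optional `[[Structure]]` section built from a population-to-group map.
#' Missing alleles are written as the configured missing character
#' (default `?`).
#'
#' @param ds a [ystr_dataset()] with rounded alleles.
#' @param path output file.
#' @param grouping optional named character vector mapping population label
#'   to group label; populations absent from the map form their own group.
#' @param missing_char single character used for missing data.
#' @param title project title string.
#' @return Invisibly, `path`.
#' @export
write_arlequin_arp <- function(ds, path, grouping = NULL, missing_char = "?",
                               title = "ystrpop export") {
  stopifnot(inherits(ds, "ystr_dataset"), nchar(missing_char) == 1)
  .check_rounded(ds)
  pops <- unique(ds$tab$population)
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write to ", path)
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("[Profile]")
  w("  Title=\"", title, "\"")
  w("  NbSamples=", length(pops))
  w("  DataType=MICROSAT")
  w("  GenotypicData=0")
  w("  GameticPhase=0")
  w("  MissingData='", missing_char, "'")
  w("  LocusSeparator=WHITESPACE")
  w("")
  w("[Data]")
  w("  [[Samples]]")
  for (p in pops) {
    sub <- ds$tab[ds$tab$population == p, , drop = FALSE]
    w("    SampleName=\"", p, "\"")
    w("    SampleSize=", nrow(sub))
    w("    SampleData={")
    for (i in seq_len(nrow(sub))) {
      al <- as.character(unlist(sub[i, ds$panel$loci]))
      al[is.na(sub[i, ds$panel$loci])] <- missing_char
      w("      ", sub$sample_id[i], "\t1\t", paste(al, collapse = " "))
    }
    w("    }")
  }
  if (!is.null(grouping)) {
    grp <- grouping[pops]
    grp[is.na(grp)] <- pops[is.na(grp)]
    w("  [[Structure]]")
    w("    StructureName=\"grouping\"")
    w("    NbGroups=", length(unique(grp)))
    for (g in unique(grp)) {
      w("    Group={")
      for (p in pops[grp == g]) w("      \"", p, "\"")
      w("    }")
    }
  }
  invisible(path)
}

.check_rounded <- function(ds) {
  m <- as.matrix(ds$tab[, ds$panel$loci])
  if (any(m[!is.na(m)] != round(m[!is.na(m)])))
    stop("alleles must be rounded to integers first ",
         "(see round_intermediate_alleles)")
  invisible(TRUE)
}
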