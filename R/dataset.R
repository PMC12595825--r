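#' Construct a haplotype dataset
#'
#' A dataset bundles a marker panel with a table of haploid multilocus
#' haplotypes. The table holds one row per individual with a `sample_id`,
#' a `population` label, an optional `region` label drawn from the five
#' Iberian regions (Centre, North, South, West, East), and one numeric
#' column per panel locus giving the repeat count. Missing alleles are `NA`.
#'
#' @param tab data frame with columns `sample_id`, `population`, optionally
#'   `region`, and one numeric column per panel locus.
#' @param panel a [marker_panel()].
#' @param provenance free-text source note.
#' @return An object of class `ystr_dataset`.
#' @export
ystr_dataset <- function(tab, panel = yfiler_panel(), provenance = "") {
  stopifnot(is.data.frame(tab))
  tab <- as.data.frame(tab, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "population") %in% names(tab)))
    stop("table must have sample_id and population columns")
  if (!"region" %in% names(tab)) tab$region <- NA_character_
  missing_loci <- setdiff(panel$loci, names(tab))
  for (l in missing_loci) tab[[l]] <- NA_real_
  tab <- tab[, c("sample_id", "population", "region", panel$loci)]
  tab$sample_id <- as.character(tab$sample_id)
  tab$population <- as.character(tab$population)
  tab$region <- as.character(tab$region)
  tab$region[!is.na(tab$region) & tab$region == ""] <- NA_character_
  if (anyDuplicated(tab$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(tab$sample_id[duplicated(tab$sample_id)]),
               collapse = ", "))
  if (any(is.na(tab$population) | tab$population == ""))
    stop("population labels must be non-empty")
  bad_region <- !is.na(tab$region) & !(tab$region %in% REGIONS)
  if (any(bad_region))
    stop("region labels must be one of: ", paste(REGIONS, collapse = ", "))
  for (l in panel$loci) {
    tab[[l]] <- as.numeric(tab[[l]])
    if (any(!is.na(tab[[l]]) & tab[[l]] <= 0))
      stop("allele values must be > 0 at locus ", l)
  }
  rownames(tab) <- NULL
  structure(list(panel = panel, tab = tab, provenance = provenance),
            class = "ystr_dataset")
}

#' @export
print.ystr_dataset <- function(x, ...) {
  cat("Y-STR dataset: ", nrow(x$tab), " haplotypes, ",
      length(unique(x$tab$population)), " population(s), panel ",
      x$panel$name, "\n", sep = "")
  if (nzchar(x$provenance)) cat("  source: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Number of haplotypes in a dataset
#' @param ds a `ystr_dataset`.
#' @return Integer count of individuals.
#' @export
n_haplotypes <- function(ds) nrow(ds$tab)

#' Merge two haplotype datasets
#'
#' Concatenates two datasets after intersecting their panels to the shared
#' loci; non-shared loci are dropped with a warning. This mirrors the usual
#' practice of pooling genotypes typed with different kit versions by
#' restricting the analysis to the common marker set.
#'
#' @param a,b `ystr_dataset` objects.
#' @return A `ystr_dataset` with `n_haplotypes(a) + n_haplotypes(b)` rows.
#' @export
merge_datasets <- function(a, b) {
  stopifnot(inherits(a, "ystr_dataset"), inherits(b, "ystr_dataset"))
  if (nrow(b$tab) == 0) return(a)
  if (nrow(a$tab) == 0) return(b)
  shared <- intersect(a$panel$loci, b$panel$loci)
  if (length(shared) == 0) stop("datasets share no loci")
  dropped <- setdiff(union(a$panel$loci, b$panel$loci), shared)
  if (length(dropped) > 0)
    warning("dropping non-shared loci: ", paste(dropped, collapse = ", "))
  collide <- intersect(a$tab$sample_id, b$tab$sample_id)
  if (length(collide) > 0)
    stop("sample_id collision: ", paste(collide, collapse = ", "))
  base <- if (length(shared) == length(a$panel$loci)) a$panel else b$panel
  panel <- marker_panel(
    base$name, shared,
    duplicated_loci = intersect(base$duplicated_loci, shared),
    composite_pairs = Filter(function(cp) all(cp %in% shared),
                             base$composite_pairs)
  )
  cols <- c("sample_id", "population", "region", shared)
  tab <- rbind(a$tab[, cols], b$tab[, cols])
  ystr_dataset(tab, panel,
               provenance = paste(a$provenance, b$provenance, sep = " + "))
}
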