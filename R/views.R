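#' Round intermediate alleles to whole repeat counts
#'
#' Intermediate alleles (partial repeats such as 13.2) are rounded to the
#' nearest integer before any arithmetic on repeat counts. Exact half values
#' round away from zero (13.5 becomes 14), so that the rule is deterministic
#' and independent of floating-point parity conventions.
#'
#' @param ds a [ystr_dataset()].
#' @return A new `ystr_dataset` with all non-missing alleles integral.
#' @export
round_intermediate_alleles <- function(ds) {
  stopifnot(inherits(ds, "ystr_dataset"))
  for (l in ds$panel$loci) {
    x <- ds$tab[[l]]
    ds$tab[[l]] <- sign(x) * floor(abs(x) + 0.5)
  }
  ds
}

#' Derive an analysis view of a dataset
#'
#' Different analyses use different transformations of the raw marker panel:
#'
#' * `"PREDICTION"` keeps all loci as reported; in particular DYS389II stays
#'   the sum of its two parts, the representation haplogroup predictors
#'   expect.
#' * `"DISTANCE"` keeps all loci, with the duplicated DYS385a/b alleles
#'   sorted ascending within each individual so that the arbitrary a/b
#'   labelling cannot contribute spurious squared-step differences.
#' * `"NETWORK"` and `"RHO"` drop the constitutively duplicated DYS385a/b
#'   and replace DYS389II by DYS389II - DYS389I, so every retained locus
#'   evolves as an independent stepwise-mutating unit.
#'
#' Missing alleles propagate: any derived value involving a missing allele
#' is missing.
#'
#' @param ds a [ystr_dataset()] with rounded alleles.
#' @param mode one of `"PREDICTION"`, `"DISTANCE"`, `"NETWORK"`, `"RHO"`.
#' @return An object of class `ystr_view`: a list with the `mode`, the
#'   effective `loci`, an integer allele `matrix` (rows = samples, `NA` =
#'   missing) and a `meta` data frame (`sample_id`, `population`, `region`).
#' @export
make_view <- function(ds, mode = c("PREDICTION", "DISTANCE", "NETWORK",
                                   "RHO")) {
  stopifnot(inherits(ds, "ystr_dataset"))
  mode <- match.arg(mode)
  .check_rounded(ds)
  tab <- ds$tab
  panel <- ds$panel
  m <- as.matrix(tab[, panel$loci, drop = FALSE])
  rownames(m) <- tab$sample_id

  for (cp in panel$composite_pairs) {
    part <- m[, cp[1]]; whole <- m[, cp[2]]
    bad <- which(!is.na(part) & !is.na(whole) & whole < part)
    if (length(bad) > 0)
      stop("impossible genotype: ", cp[2], " < ", cp[1], " for sample ",
           rownames(m)[bad[1]])
  }

  if (mode %in% c("NETWORK", "RHO")) {
    m <- m[, setdiff(colnames(m), panel$duplicated_loci), drop = FALSE]
    for (cp in panel$composite_pairs) {
      if (!all(cp %in% colnames(m))) next
      m[, cp[2]] <- m[, cp[2]] - m[, cp[1]]  # NA propagates
    }
  } else if (mode == "DISTANCE") {
    dup <- panel$duplicated_loci
    # sort each duplicated-marker pair ascending within individuals
    if (length(dup) >= 2) {
      for (k in seq(1, length(dup) - 1, by = 2)) {
        pair <- m[, dup[c(k, k + 1)], drop = FALSE]
        sorted <- t(apply(pair, 1, function(v)
          if (anyNA(v)) v else sort(v)))
        m[, dup[c(k, k + 1)]] <- sorted
      }
    }
  }
  structure(
    list(mode = mode, loci = colnames(m), matrix = m,
         meta = tab[, c("sample_id", "population", "region")]),
    class = "ystr_view"
  )
}

#' @export
print.ystr_view <- function(x, ...) {
  cat("Y-STR analysis view [", x$mode, "]: ", nrow(x$matrix),
      " haplotypes x ", length(x$loci), " effective loci\n", sep = "")
  invisible(x)
}

#' Restrict a view to a subset of individuals
#' @param view a `ystr_view`.
#' @param idx logical or integer row index, or a character vector of
#'   population labels.
#' @return A `ystr_view` over the selected rows.
#' @export
subset_view <- function(view, idx) {
  stopifnot(inherits(view, "ystr_view"))
  if (is.character(idx)) idx <- view$meta$population %in% idx
  view$matrix <- view$matrix[idx, , drop = FALSE]
  view$meta <- view$meta[idx, , drop = FALSE]
  rownames(view$meta) <- NULL
  view
}
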