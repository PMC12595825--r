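#' @keywords internal
"_PACKAGE"

## The five Iberian sampling regions used for regional grouping.
REGIONS <- c("Centre", "North", "South", "West", "East")

YFILER17 <- c(
  "DYS19", "DYS389I", "DYS389II", "DYS390", "DYS391", "DYS392", "DYS393",
  "DYS385a", "DYS385b", "DYS437", "DYS438", "DYS439", "DYS448", "DYS456",
  "DYS458", "DYS635", "YGATAH4"
)

YFILER27 <- c(
  YFILER17,
  "DYS449", "DYS460", "DYS481", "DYS518", "DYS533", "DYS570", "DYS576",
  "DYS627", "DYF387S1a", "DYF387S1b"
)

#' Construct a Y-STR marker panel
#'
#' A panel records the ordered locus list together with the loci that need
#' special handling: constitutively duplicated loci (reported as two alleles
#' per individual, e.g. DYS385a/b) and composite pairs where one locus
#' contains the other (DYS389I is a subset of the DYS389II amplicon, so the
#' reported DYS389II repeat count is the sum of both parts).
#'
#' @param name panel identifier.
#' @param loci character vector of unique locus names.
#' @param duplicated_loci loci treated as the two copies of a multi-copy
#'   marker; must be members of `loci`.
#' @param composite_pairs list of `c(part, whole)` character pairs with a
#'   containment relation, e.g. `c("DYS389I", "DYS389II")`.
#' @return An object of class `ystr_panel`.
#' @export
marker_panel <- function(name, loci, duplicated_loci = character(),
                         composite_pairs = list()) {
  stopifnot(is.character(loci), length(loci) >= 1)
  if (anyDuplicated(loci)) stop("panel locus names must be unique")
  if (!all(duplicated_loci %in% loci))
    stop("duplicated_loci must be panel members")
  for (cp in composite_pairs) {
    if (length(cp) != 2 || !all(cp %in% loci))
      stop("composite pairs must be length-2 vectors of panel loci")
  }
  structure(
    list(name = name, loci = loci, duplicated_loci = duplicated_loci,
         composite_pairs = composite_pairs),
    class = "ystr_panel"
  )
}

#' Built-in Yfiler marker panels
#'
#' `yfiler_panel()` is the 17-locus AmpFlSTR Yfiler set; `yfiler_plus_panel()`
#' is the 27-locus Yfiler Plus superset. Both flag DYS385a/b (and DYF387S1a/b
#' for the Plus kit) as duplicated loci and DYS389I/II as a composite pair.
#'
#' @return An object of class `ystr_panel`.
#' @export
yfiler_panel <- function() {
  marker_panel("Yfiler17", YFILER17,
               duplicated_loci = c("DYS385a", "DYS385b"),
               composite_pairs = list(c("DYS389I", "DYS389II")))
}

#' @rdname yfiler_panel
#' @export
yfiler_plus_panel <- function() {
  marker_panel("YfilerPlus27", YFILER27,
               duplicated_loci = c("DYS385a", "DYS385b",
                                   "DYF387S1a", "DYF387S1b"),
               composite_pairs = list(c("DYS389I", "DYS389II")))
}

#' @export
print.ystr_panel <- function(x, ...) {
  cat("Y-STR marker panel '", x$name, "': ", length(x$loci), " loci\n",
      sep = "")
  cat(" ", paste(x$loci, collapse = ", "), "\n")
  invisible(x)
}
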