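#' Analysis of molecular variance on squared-step distances
#'
#' Hierarchical decomposition of molecular variance for haploid STR data,
#' in the distance formulation: the sum of squared deviations of a set of
#' individuals equals the sum of pairwise squared-step distances divided by
#' the set size. Designs:
#'
#' * one-level (`groups = NULL`): among populations / within populations,
#'   with the fixation index Phi_ST;
#' * two-level: among groups (Phi_CT), among populations within groups
#'   (Phi_SC), within populations (Phi_ST), with unequal-size coefficients
#'   from the standard unbalanced-design moment equations.
#'
#' Negative variance components (sampling noise) are reported as computed;
#' they are floored at zero only when percentages are formed. Permutation
#' p-values use the +1 correction: individuals are permuted among
#' populations for Phi_ST, whole populations among groups for Phi_CT, and
#' individuals among populations within their group for Phi_SC.
#'
#' @param view a DISTANCE-mode [make_view()] result.
#' @param partition factor/character of population labels per individual;
#'   default the view's population column.
#' @param groups optional named character vector mapping population label to
#'   group label (two-level design).
#' @param permutations permutation count for p-values (0 = skip).
#' @param seed RNG seed.
#' @return An object of class `ystr_amova`: `design`, `rows` (data frame
#'   with `source`, `df`, `SS`, `sigma2`, `percent`), `phi`, `pvalues`,
#'   `permutations`, `seed`.
#' @export
amova <- function(view, partition = NULL, groups = NULL,
                  permutations = 1000, seed = 1L) {
  stopifnot(inherits(view, "ystr_view"))
  pop <- if (is.null(partition)) view$meta$population
         else as.character(partition)
  stopifnot(length(pop) == nrow(view$matrix))
  if (length(unique(pop)) < 2) stop("need at least 2 populations")
  D <- smm_distance_matrix(view)
  if (anyNA(D)) stop("undefined pairwise distances; cannot run AMOVA")
  set.seed(seed)
  if (is.null(groups)) {
    .amova_one_level(D, pop, permutations, seed)
  } else {
    grp <- as.character(groups[pop])
    if (anyNA(grp)) stop("groups map must cover every population")
    .amova_two_level(D, pop, grp, groups, permutations, seed)
  }
}

.ss_of <- function(D, idx) {
  if (length(idx) < 2) return(0)
  sub <- D[idx, idx, drop = FALSE]
  sum(sub[upper.tri(sub)]) / length(idx)
}

.amova_one_level <- function(D, pop, permutations, seed) {
  cmp <- .phi_st(D, pop)
  sig <- c(among = cmp$sigma_a, within = cmp$sigma_w)
  pos <- pmax(sig, 0)
  pct <- if (sum(pos) > 0) 100 * pos / sum(pos) else rep(NA_real_, 2)
  rows <- data.frame(
    source = c("Among populations", "Within populations", "Total"),
    df = c(cmp$df_a, cmp$df_w, cmp$df_a + cmp$df_w),
    SS = c(cmp$ss_a, cmp$ss_w, cmp$ss_t),
    sigma2 = c(sig, sum(sig)),
    percent = c(pct, 100)
  )
  p_st <- NA_real_
  if (permutations > 0) {
    ge <- 0L
    for (b in seq_len(permutations)) {
      if (.phi_st(D, sample(pop))$phi >= cmp$phi) ge <- ge + 1L
    }
    p_st <- (ge + 1) / (permutations + 1)
  }
  structure(
    list(design = "POPS", rows = rows, phi = c(phi_st = cmp$phi),
         pvalues = c(phi_st = p_st), permutations = permutations,
         seed = seed),
    class = "ystr_amova"
  )
}

## Two-level variance components for possibly unbalanced designs.
## Moment equations (haploid individuals within populations within groups):
##   E[MS_WP]  = sc
##   E[MS_AP/WG] = sc + n1 * sb
##   E[MS_AG]  = sc + n2 * sb + n3 * sa
.amova_two_components <- function(D, pop, grp) {
  n <- length(pop)
  pops <- unique(pop)
  pgroups <- vapply(pops, function(p) grp[match(p, pop)], character(1))
  gs <- unique(grp)
  G <- length(gs); P <- length(pops)
  ss_t <- .ss_of(D, seq_len(n))
  ss_wp <- sum(vapply(pops, function(p) .ss_of(D, which(pop == p)),
                      numeric(1)))
  ss_g <- sum(vapply(gs, function(g) .ss_of(D, which(grp == g)),
                     numeric(1)))
  ss_ap <- ss_g - ss_wp          # among populations within groups
  ss_ag <- ss_t - ss_g           # among groups
  df_ag <- G - 1; df_ap <- P - G; df_wp <- n - P
  n_p <- vapply(pops, function(p) sum(pop == p), numeric(1))
  N_g <- vapply(gs, function(g) sum(grp == g), numeric(1))
  sum_np2_by_g <- vapply(gs, function(g)
    sum(n_p[pgroups == g]^2), numeric(1))
  n1 <- (n - sum(sum_np2_by_g / N_g)) / df_ap
  n2 <- (sum(sum_np2_by_g / N_g) - sum(n_p^2) / n) / df_ag
  n3 <- (n - sum(N_g^2) / n) / df_ag
  sc <- if (df_wp > 0) ss_wp / df_wp else 0
  sb <- if (df_ap > 0) (ss_ap / df_ap - sc) / n1 else NA_real_
  sa <- (ss_ag / df_ag - sc - n2 * sb) / n3
  tot <- sa + sb + sc
  list(sa = sa, sb = sb, sc = sc,
       phi_ct = sa / tot,
       phi_sc = sb / (sb + sc),
       phi_st = (sa + sb) / tot,
       ss = c(ag = ss_ag, ap = ss_ap, wp = ss_wp, t = ss_t),
       df = c(ag = df_ag, ap = df_ap, wp = df_wp))
}

.amova_two_level <- function(D, pop, grp, groups_map, permutations, seed) {
  singleton <- names(which(table(unique(
    data.frame(pop, grp))$grp) < 2))
  if (length(singleton) > 0)
    warning("group(s) with a single population: ",
            paste(singleton, collapse = ", "),
            "; Phi_SC is not informative for these strata")
  cmp <- .amova_two_components(D, pop, grp)
  sig <- c(among_groups = cmp$sa, among_pops_within_groups = cmp$sb,
           within_pops = cmp$sc)
  pos <- pmax(sig, 0)
  pct <- if (sum(pos) > 0) 100 * pos / sum(pos) else rep(NA_real_, 3)
  rows <- data.frame(
    source = c("Among groups", "Among populations within groups",
               "Within populations", "Total"),
    df = c(cmp$df, sum(cmp$df)),
    SS = c(cmp$ss["ag"], cmp$ss["ap"], cmp$ss["wp"], cmp$ss["t"]),
    sigma2 = c(sig, sum(sig)),
    percent = c(pct, 100)
  )
  pv <- c(phi_ct = NA_real_, phi_sc = NA_real_, phi_st = NA_real_)
  if (permutations > 0) {
    pops <- unique(pop)
    pop_grp <- vapply(pops, function(p) grp[match(p, pop)], character(1))
    ge <- c(ct = 0L, sc = 0L, st = 0L)
    for (b in seq_len(permutations)) {
      # Phi_ST: individuals among populations (labels shuffled globally)
      perm_pop <- sample(pop)
      if (.amova_two_components(D, perm_pop,
                                as.character(groups_map[perm_pop]))$phi_st >=
          cmp$phi_st) ge["st"] <- ge["st"] + 1L
      # Phi_CT: whole populations among groups
      perm_map <- stats::setNames(sample(pop_grp), pops)
      if (.amova_two_components(D, pop,
                                as.character(perm_map[pop]))$phi_ct >=
          cmp$phi_ct) ge["ct"] <- ge["ct"] + 1L
      # Phi_SC: individuals among populations within their group
      perm_within <- pop
      for (g in unique(grp)) {
        idx <- which(grp == g)
        perm_within[idx] <- sample(pop[idx])
      }
      if (.amova_two_components(D, perm_within, grp)$phi_sc >=
          cmp$phi_sc) ge["sc"] <- ge["sc"] + 1L
    }
    pv <- c(phi_ct = (ge[["ct"]] + 1) / (permutations + 1),
            phi_sc = (ge[["sc"]] + 1) / (permutations + 1),
            phi_st = (ge[["st"]] + 1) / (permutations + 1))
  }
  structure(
    list(design = "GROUPS_POPS", rows = rows,
         phi = c(phi_ct = cmp$phi_ct, phi_sc = cmp$phi_sc,
                 phi_st = cmp$phi_st),
         pvalues = pv, permutations = permutations, seed = seed),
    class = "ystr_amova"
  )
}

#' @export
print.ystr_amova <- function(x, digits = 4, ...) {
  cat("AMOVA (", x$design, "), ", x$permutations, " permutations, seed ",
      x$seed, "\n", sep = "")
  out <- x$rows
  out$SS <- round(out$SS, digits)
  out$sigma2 <- round(out$sigma2, digits)
  out$percent <- round(out$percent, 2)
  print(out, row.names = FALSE)
  cat("Phi: ", paste(sprintf("%s = %.4f (p = %s)", names(x$phi), x$phi,
                             formatC(x$pvalues, digits = 4)),
                     collapse = ", "), "\n")
  invisible(x)
}

#' Contrast regional differentiation between two cohorts
#'
#' Runs a one-level AMOVA by region within each cohort (e.g. Roma vs
#' non-Roma) and reports the ratio of among-region variance percentages,
#' the quantity used to compare the strength of regional substructure
#' between the two cohorts. Regions with fewer than two individuals are
#' dropped with a warning.
#'
#' @param view a DISTANCE-mode [make_view()] over both cohorts.
#' @param cohort_a,cohort_b logical index vectors (or population-label
#'   vectors) selecting the two cohorts within `view`.
#' @param permutations,seed passed to [amova()].
#' @return List with the two `ystr_amova` tables (`amova_a`, `amova_b`),
#'   their among-region percentages and `ratio` = percent_a / percent_b.
#' @export
regional_contrast <- function(view, cohort_a, cohort_b,
                              permutations = 1000, seed = 1L) {
  run_one <- function(sel, tag) {
    v <- subset_view(view, sel)
    reg <- v$meta$region
    if (any(is.na(reg)))
      stop("cohort ", tag, " has individuals without a region label")
    keep <- reg %in% names(which(table(reg) >= 2))
    if (!all(keep)) {
      warning("cohort ", tag, ": dropping region(s) with < 2 samples")
      v <- subset_view(v, keep)
      reg <- reg[keep]
    }
    if (length(unique(reg)) < 2)
      stop("cohort ", tag, " has fewer than 2 usable regions")
    amova(v, partition = reg, permutations = permutations, seed = seed)
  }
  a <- run_one(cohort_a, "A")
  b <- run_one(cohort_b, "B")
  pa <- a$rows$percent[1]
  pb <- b$rows$percent[1]
  list(amova_a = a, amova_b = b, percent_a = pa, percent_b = pb,
       ratio = pa / pb)
}
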