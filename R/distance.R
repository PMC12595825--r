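#' Squared stepwise-mutation distance between two haplotypes
#'
#' Sum over loci of squared repeat-count differences, the molecular distance
#' implied by the stepwise mutation model (SMM). Loci missing in either
#' haplotype are skipped (pairwise deletion).
#'
#' @param a,b numeric allele vectors over the same loci (`NA` = missing).
#' @return Sum of squared differences over shared non-missing loci; `NA`
#'   with a warning if no locus is shared.
#' @export
smm_distance <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) {
    warning("no shared non-missing loci; distance undefined")
    return(NA_real_)
  }
  sum((a[ok] - b[ok])^2)
}

#' Pairwise squared-step distance matrix for a view
#'
#' @param view a [make_view()] result (DISTANCE mode is the convention).
#' @return Symmetric numeric matrix of squared-step distances with pairwise
#'   deletion of missing loci.
#' @export
smm_distance_matrix <- function(view) {
  stopifnot(inherits(view, "ystr_view"))
  m <- view$matrix
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  shared <- matrix(0L, n, n)
  for (l in seq_len(ncol(m))) {
    x <- m[, l]
    ok <- !is.na(x)
    xf <- ifelse(ok, x, 0)
    diff2 <- outer(xf, xf, "-")^2
    okm <- outer(ok, ok, "&")
    D <- D + diff2 * okm
    shared <- shared + okm
  }
  if (any(shared == 0 & upper.tri(shared))) {
    warning("some haplotype pairs share no non-missing locus; ",
            "their distance is undefined (NA)")
    D[shared == 0] <- NA_real_
  }
  diag(D) <- 0
  D
}

## Phi_ST for a two-or-more population one-level design from a precomputed
## distance matrix; lean path shared by pairwise_rst permutations and amova.
.phi_st <- function(D, pop) {
  n <- length(pop)
  pops <- unique(pop)
  ss_t <- sum(D[upper.tri(D)]) / n
  ss_w <- 0
  sizes <- numeric(length(pops))
  for (k in seq_along(pops)) {
    idx <- which(pop == pops[k])
    sizes[k] <- length(idx)
    if (length(idx) > 1) {
      sub <- D[idx, idx, drop = FALSE]
      ss_w <- ss_w + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  ss_a <- ss_t - ss_w
  df_a <- length(pops) - 1
  df_w <- n - length(pops)
  sigma_w <- if (df_w > 0) ss_w / df_w else 0
  n0 <- (n - sum(sizes^2) / n) / df_a
  sigma_a <- (ss_a / df_a - sigma_w) / n0
  denom <- sigma_a + sigma_w
  list(phi = if (denom == 0) NA_real_ else sigma_a / denom,
       sigma_a = sigma_a, sigma_w = sigma_w,
       ss_t = ss_t, ss_a = ss_a, ss_w = ss_w,
       df_a = df_a, df_w = df_w, n0 = n0)
}

#' Pairwise Slatkin R_ST matrix with permutation significance
#'
#' For every population pair, R_ST is the Phi_ST of the two-population
#' molecular-variance decomposition on squared-step distances:
#' `sigma2_among / (sigma2_among + sigma2_within)`, with variance components
#' from the AMOVA sums of squares. Significance is assessed by permuting
#' individuals between the two populations; p-values carry the +1
#' correction `(b + 1) / (B + 1)`. Negative R_ST values (sampling noise
#' around zero differentiation) are reported as computed.
#'
#' @param view a DISTANCE-mode [make_view()] result.
#' @param populations population labels to include (default: all with
#'   `min_n` or more individuals).
#' @param permutations permutations per pair (the field convention is
#'   10,000).
#' @param seed RNG seed.
#' @param min_n minimum population size; smaller populations are skipped
#'   with a warning.
#' @return A `ystr_pairwise` object: `labels`, symmetric `values`, symmetric
#'   `pvalues`, `statistic = "RST"`.
#' @export
pairwise_rst <- function(view, populations = NULL, permutations = 10000,
                         seed = 1L, min_n = 2L) {
  stopifnot(inherits(view, "ystr_view"))
  pop_all <- view$meta$population
  if (is.null(populations)) populations <- unique(pop_all)
  sizes <- table(pop_all)[populations]
  small <- populations[is.na(sizes) | sizes < min_n]
  if (length(small) > 0) {
    warning("skipping population(s) below minimum size: ",
            paste(small, collapse = ", "))
    populations <- setdiff(populations, small)
  }
  if (length(populations) < 2) stop("need at least 2 usable populations")
  P <- length(populations)
  vals <- matrix(0, P, P, dimnames = list(populations, populations))
  pvals <- matrix(NA_real_, P, P, dimnames = list(populations, populations))
  set.seed(seed)
  for (i in seq_len(P - 1)) {
    for (j in seq(i + 1, P)) {
      sel <- pop_all %in% populations[c(i, j)]
      sub <- subset_view(view, sel)
      D <- smm_distance_matrix(sub)
      lab <- sub$meta$population
      obs <- .phi_st(D, lab)$phi
      ge <- 0L
      for (b in seq_len(permutations)) {
        perm <- sample(lab)
        if (.phi_st(D, perm)$phi >= obs) ge <- ge + 1L
      }
      vals[i, j] <- vals[j, i] <- obs
      pvals[i, j] <- pvals[j, i] <- (ge + 1) / (permutations + 1)
    }
  }
  structure(
    list(labels = populations, values = vals, pvalues = pvals,
         statistic = "RST", permutations = permutations, seed = seed),
    class = "ystr_pairwise"
  )
}

#' @export
print.ystr_pairwise <- function(x, digits = 4, ...) {
  cat("pairwise ", x$statistic, " (", length(x$labels),
      " populations)\n", sep = "")
  print(round(x$values, digits))
  invisible(x)
}

#' Convert an R_ST matrix to island-model migration rates
#'
#' Applies the haploid equilibrium island-model estimator
#' `M = (1 - R_ST) / (2 * R_ST)`, the effective number of migrants per
#' generation implied by a fixation index under haploid (Y-chromosome)
#' data. Non-positive R_ST maps to `Inf` (no detectable differentiation,
#' unbounded gene flow) rather than being clamped, so regimes such as
#' M > 40 stay visible; R_ST = 1 maps to 0.
#'
#' @param rst a `ystr_pairwise` object with `statistic = "RST"`.
#' @return A `ystr_pairwise` object with `statistic = "M"` (p-values carried
#'   over from the R_ST permutations).
#' @export
migration_rate <- function(rst) {
  stopifnot(inherits(rst, "ystr_pairwise"), rst$statistic == "RST")
  R <- rst$values
  M <- ifelse(R <= 0, Inf, (1 - R) / (2 * R))
  diag(M) <- 0
  rst$values <- M
  rst$statistic <- "M"
  rst
}

#' Nonmetric MDS embedding of a pairwise distance matrix
#'
#' Embeds populations in `dims` dimensions by nonmetric multidimensional
#' scaling (Kruskal stress-1, monotone regression), taking the best of
#' several random starts. Negative distances (negative R_ST) are clamped to
#' zero before embedding.
#'
#' @param mat a `ystr_pairwise` object or symmetric numeric matrix.
#' @param dims embedding dimensionality (default 2).
#' @param restarts random starts (default 20).
#' @param seed RNG seed.
#' @return List with `coordinates` (labelled matrix), `stress` (final
#'   Kruskal stress-1, in \[0, 1\]) and `degenerate` flag.
#' @export
nmds_embed <- function(mat, dims = 2, restarts = 20, seed = 1L) {
  V <- if (inherits(mat, "ystr_pairwise")) mat$values else as.matrix(mat)
  if (nrow(V) < 3) stop("need at least 3 labels to embed")
  V[V < 0] <- 0
  if (all(V == 0)) {
    coords <- matrix(0, nrow(V), dims,
                     dimnames = list(rownames(V),
                                     paste0("dim", seq_len(dims))))
    return(list(coordinates = coords, stress = 0, degenerate = TRUE))
  }
  set.seed(seed)
  fit <- suppressMessages(suppressWarnings(
    vegan::metaMDS(stats::as.dist(V), k = dims, trymax = restarts,
                   autotransform = FALSE, wascores = FALSE, trace = 0)
  ))
  coords <- fit$points
  colnames(coords) <- paste0("dim", seq_len(dims))
  list(coordinates = coords, stress = fit$stress, degenerate = FALSE)
}
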