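#' Train an allele-frequency table for haplogroup prediction
#'
#' Estimates per-(haplogroup, locus) allele frequencies from a reference
#' dataset with known haplogroup labels, with additive smoothing over an
#' allele support spanning the observed range plus/minus two repeats. The
#' smoothing pseudocount guarantees every in-support allele a strictly
#' positive probability, so one unobserved allele cannot knock out an
#' entire haplogroup's likelihood.
#'
#' @param ds a [ystr_dataset()] with rounded alleles (PREDICTION
#'   representation: DYS389II as reported).
#' @param haplogroups character vector of haplogroup labels, one per row of
#'   `ds`.
#' @param pseudocount additive smoothing mass per in-support allele
#'   (default 5e-4).
#' @param loci loci to use (default: panel loci).
#' @return An object of class `ystr_freqtable`: list with `haplogroups`,
#'   `loci`, `pseudocount`, and `freq[[hg]][[locus]]` named probability
#'   vectors over the support (summing to 1).
#' @export
build_frequency_table <- function(ds, haplogroups, pseudocount = 5e-4,
                                  loci = NULL) {
  stopifnot(inherits(ds, "ystr_dataset"),
            length(haplogroups) == nrow(ds$tab))
  .check_rounded(ds)
  if (is.null(loci)) loci <- ds$panel$loci
  hgs <- sort(unique(as.character(haplogroups)))
  freq <- list()
  for (hg in hgs) {
    rows <- ds$tab[haplogroups == hg, , drop = FALSE]
    any_obs <- FALSE
    freq[[hg]] <- list()
    for (l in loci) {
      a <- rows[[l]]
      a <- a[!is.na(a)]
      if (length(a) == 0) next
      any_obs <- TRUE
      support <- seq(min(a) - 2, max(a) + 2)
      cnt <- vapply(support, function(s) sum(a == s), numeric(1))
      p <- (cnt + pseudocount) / (length(a) + pseudocount * length(support))
      names(p) <- as.character(support)
      freq[[hg]][[l]] <- p
    }
    if (!any_obs)
      stop("haplogroup ", hg, " has no non-missing alleles at any locus")
  }
  structure(list(haplogroups = hgs, loci = loci, pseudocount = pseudocount,
                 freq = freq),
            class = "ystr_freqtable")
}

#' Predict the haplogroup of a single haplotype
#'
#' Bayesian allele-frequency classification: the posterior of haplogroup g
#' is proportional to `prior(g)` times the product over non-missing loci of
#' the allele frequency `f(allele | g, locus)`. Missing loci are skipped.
#' The fitness score of g is the mean log10 per-locus likelihood over the
#' loci used. A call is made iff the maximum posterior reaches `threshold`
#' and the fitness of the winning haplogroup reaches `fitness_floor`;
#' because per-locus likelihoods never exceed 1, the fitness is always
#' non-positive and a floor of 0 (the conventional published setting)
#' disables the filter. Exact posterior ties yield NO_CALL.
#'
#' @param h named numeric allele vector (PREDICTION view row) or a one-row
#'   subset of a view matrix.
#' @param table a [build_frequency_table()] result.
#' @param prior named haplogroup prior (default equal priors).
#' @param threshold posterior call threshold (default 0.85).
#' @param fitness_floor minimum fitness for a call; values >= 0 disable the
#'   filter (default 0).
#' @return An object of class `ystr_prediction`: `posterior`, `fitness`,
#'   `call` (label or `"NO_CALL"`), `n_loci_used`, `threshold`.
#' @export
predict_haplogroup <- function(h, table, prior = NULL, threshold = 0.85,
                               fitness_floor = 0) {
  stopifnot(inherits(table, "ystr_freqtable"))
  hgs <- table$haplogroups
  if (is.null(prior)) prior <- stats::setNames(rep(1 / length(hgs),
                                                   length(hgs)), hgs)
  stopifnot(abs(sum(prior) - 1) < 1e-9, all(hgs %in% names(prior)))
  use <- intersect(names(h)[!is.na(h)], table$loci)
  loglik <- stats::setNames(rep(0, length(hgs)), hgs)
  fitness <- stats::setNames(rep(NA_real_, length(hgs)), hgs)
  n_used <- 0L
  if (length(use) == 0) {
    warning("no informative loci; returning prior with NO_CALL")
    post <- prior[hgs] / sum(prior[hgs])
  } else {
    logf <- matrix(NA_real_, length(hgs), length(use),
                   dimnames = list(hgs, use))
    for (g in hgs) for (l in use) {
      p <- table$freq[[g]][[l]]
      if (is.null(p)) next
      hit <- p[as.character(h[[l]])]
      # out-of-support alleles get the smoothing floor of that row
      logf[g, l] <- log10(if (is.na(hit)) min(p) else unname(hit))
    }
    # drop loci unobserved for some haplogroup to keep likelihoods comparable
    usable <- colSums(is.na(logf)) == 0
    logf <- logf[, usable, drop = FALSE]
    n_used <- ncol(logf)
    if (n_used == 0) {
      warning("no loci shared by all haplogroups; returning prior")
      post <- prior[hgs] / sum(prior[hgs])
    } else {
      ll <- rowSums(logf)
      fitness <- ll / n_used
      lp <- log10(prior[hgs]) + ll
      lp <- lp - max(lp)
      post <- 10^lp / sum(10^lp)
    }
  }
  best <- which.max(post)
  tied <- sum(abs(post - post[best]) < 1e-12) > 1
  ok_fit <- fitness_floor >= 0 || (!is.na(fitness[best]) &&
                                   fitness[best] >= fitness_floor)
  call <- if (!tied && n_used > 0 && post[best] >= threshold && ok_fit)
    hgs[best] else "NO_CALL"
  structure(
    list(posterior = post, fitness = fitness, call = call,
         n_loci_used = n_used, threshold = threshold),
    class = "ystr_prediction"
  )
}

#' @export
print.ystr_prediction <- function(x, ...) {
  cat("call:", x$call, sprintf("(max posterior %.3f over %d loci)\n",
                               max(x$posterior), x$n_loci_used))
  invisible(x)
}

#' Predict haplogroups for every individual in a dataset
#'
#' @param ds a [ystr_dataset()] with rounded alleles.
#' @param table a [build_frequency_table()] result.
#' @param ... passed to [predict_haplogroup()] (prior, threshold,
#'   fitness_floor).
#' @return List with `predictions` (data frame: sample_id, population,
#'   call, max posterior, fitness), `frequencies` (per-population relative
#'   haplogroup frequencies over called samples) and `no_call_rate`.
#' @export
predict_dataset <- function(ds, table, ...) {
  stopifnot(inherits(ds, "ystr_dataset"))
  view <- make_view(ds, "PREDICTION")
  n <- nrow(view$matrix)
  calls <- character(n); post <- numeric(n); fit <- numeric(n)
  for (i in seq_len(n)) {
    res <- predict_haplogroup(view$matrix[i, ], table, ...)
    calls[i] <- res$call
    post[i] <- max(res$posterior)
    fit[i] <- if (res$call == "NO_CALL") NA_real_ else res$fitness[res$call]
  }
  pred <- data.frame(sample_id = view$meta$sample_id,
                     population = view$meta$population,
                     call = calls, posterior = post, fitness = fit)
  called <- pred[pred$call != "NO_CALL", , drop = FALSE]
  freqs <- lapply(split(called$call, called$population),
                  function(x) prop.table(table(x)))
  list(predictions = pred, frequencies = freqs,
       no_call_rate = 1 - nrow(called) / n)
}
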