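#' Haplotype frequencies by direct counting
#'
#' Haplotypes are compared as full allele vectors over the view's effective
#' loci. A missing allele matches nothing, so every haplotype containing a
#' missing value forms its own singleton class.
#'
#' @param view a [make_view()] result.
#' @param populations optional character vector restricting the count to
#'   these population labels.
#' @return Named integer vector of counts (names are allele strings);
#'   counts sum to the number of selected individuals.
#' @export
haplotype_frequencies <- function(view, populations = NULL) {
  stopifnot(inherits(view, "ystr_view"))
  if (!is.null(populations)) view <- subset_view(view, populations)
  m <- view$matrix
  if (nrow(m) == 0) stop("empty selection")
  key <- apply(m, 1, paste, collapse = "-")
  has_na <- apply(m, 1, anyNA)
  key[has_na] <- paste0(key[has_na], "#", which(has_na))
  cnt <- table(key)
  out <- as.integer(cnt)
  names(out) <- names(cnt)
  out
}

#' Nei haplotype diversity
#'
#' HD = n/(n-1) * (1 - sum(p_i^2)) over haplotype class frequencies
#' p_i = count_i / n.
#'
#' @param counts named integer vector of haplotype counts, e.g. from
#'   [haplotype_frequencies()].
#' @return The diversity in `[0, 1]`.
#' @export
nei_hd <- function(counts) {
  n <- sum(counts)
  if (n < 2) stop("need at least 2 individuals")
  p <- counts / n
  (n / (n - 1)) * (1 - sum(p^2))
}

#' Bootstrap confidence interval for Nei haplotype diversity
#'
#' Resamples individuals with replacement and recomputes HD per replicate;
#' the interval is the percentile interval of the bootstrap distribution.
#'
#' @param view a [make_view()] result.
#' @param population population label to estimate (NULL = all individuals).
#' @param replicates bootstrap replicates (>= 100; the field convention is
#'   10,000).
#' @param seed RNG seed for reproducibility.
#' @param level interval coverage level.
#' @return A list with `n`, `k` (distinct haplotypes), `hd`, `ci_low`,
#'   `ci_high`, `replicates`, `seed`, of class `ystr_diversity`.
#' @export
bootstrap_hd_ci <- function(view, population = NULL, replicates = 10000,
                            seed = 1L, level = 0.95) {
  stopifnot(replicates >= 100)
  if (!is.null(population)) view <- subset_view(view, population)
  m <- view$matrix
  key <- apply(m, 1, paste, collapse = "-")
  has_na <- apply(m, 1, anyNA)
  key[has_na] <- paste0(key[has_na], "#", which(has_na))
  n <- length(key)
  hd_of <- function(kk) {
    p <- table(kk) / length(kk)
    (length(kk) / (length(kk) - 1)) * (1 - sum(p^2))
  }
  set.seed(seed)
  bt <- boot::boot(key, function(d, idx) hd_of(d[idx]), R = replicates)
  qs <- stats::quantile(bt$t[, 1], c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  hd_point <- hd_of(key)
  if (hd_point < qs[1] || hd_point > qs[2])
    message("note: point HD ", signif(hd_point, 4),
            " falls outside the percentile interval; the bootstrap HD ",
            "distribution is skewed for this sample")
  structure(
    list(n = n, k = length(unique(key)), hd = hd_of(key),
         ci_low = qs[1], ci_high = qs[2], replicates = replicates,
         seed = seed, level = level),
    class = "ystr_diversity"
  )
}

#' @export
print.ystr_diversity <- function(x, ...) {
  cat(sprintf("n = %d, k = %d, HD = %.4f, %g%% CI [%.4f, %.4f] (%d reps)\n",
              x$n, x$k, x$hd, 100 * x$level, x$ci_low, x$ci_high,
              x$replicates))
  invisible(x)
}

#' Permutation test for the number of distinct haplogroups
#'
#' Compares the number of distinct haplogroup labels observed in a focal
#' population against a null in which the focal sample is drawn at random
#' (without replacement, a rarefaction-style draw) from the pooled label
#' multiset of focal plus comparison populations. Two-sided p-value
#' `2 * min(P(>= obs), P(<= obs))` capped at 1, each tail with the +1
#' correction `(b + 1) / (B + 1)`.
#'
#' @param focal character vector of haplogroup labels in the focal
#'   population (NO_CALL entries should be removed beforehand).
#' @param others character vector of pooled haplogroup labels from the
#'   comparison populations.
#' @param permutations number of random draws (>= 100).
#' @param seed RNG seed.
#' @return List with `observed`, `null_mean`, `p_value`, `permutations`,
#'   `seed`, of class `ystr_permtest`.
#' @export
distinct_hg_permutation_test <- function(focal, others, permutations = 10000,
                                         seed = 1L) {
  stopifnot(length(focal) >= 1, permutations >= 100)
  pool <- c(focal, others)
  if (length(focal) > length(pool)) stop("focal larger than pool")
  obs <- length(unique(focal))
  set.seed(seed)
  null <- vapply(seq_len(permutations), function(i)
    length(unique(sample(pool, length(focal), replace = FALSE))),
    integer(1))
  p_hi <- (sum(null >= obs) + 1) / (permutations + 1)
  p_lo <- (sum(null <= obs) + 1) / (permutations + 1)
  structure(
    list(observed = obs, null_mean = mean(null),
         p_value = min(1, 2 * min(p_hi, p_lo)),
         p_upper = p_hi, p_lower = p_lo,
         permutations = permutations, seed = seed),
    class = "ystr_permtest"
  )
}

#' @export
print.ystr_permtest <- function(x, ...) {
  cat(sprintf(
    "distinct haplogroups: observed %d, null mean %.2f, p = %.4f (%d perms, seed %d)\n",
    x$observed, x$null_mean, x$p_value, x$permutations, x$seed))
  invisible(x)
}
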