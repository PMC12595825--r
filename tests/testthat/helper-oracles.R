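# Independent brute-force oracles. These deliberately avoid the package's
# internal code paths: sums of squares come from explicit double loops and
# variance components from solving the moment equations with solve().

oracle_sq_dist <- function(m) {
  n <- nrow(m)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ok <- !is.na(m[i, ]) & !is.na(m[j, ])
    D[i, j] <- sum((m[i, ok] - m[j, ok])^2)
  }
  D
}

oracle_ss <- function(D, idx) {
  s <- 0
  for (i in idx) for (j in idx) s <- s + D[i, j]
  s / (2 * length(idx))
}

# One-level AMOVA by explicit enumeration + linear solve of the moment
# equations E[MS_among] = sw + n0*sa, E[MS_within] = sw.
oracle_amova1 <- function(m, pop) {
  D <- oracle_sq_dist(m)
  n <- nrow(m)
  pops <- unique(pop)
  ss_t <- oracle_ss(D, 1:n)
  ss_w <- sum(sapply(pops, function(p) oracle_ss(D, which(pop == p))))
  ss_a <- ss_t - ss_w
  df_a <- length(pops) - 1
  df_w <- n - length(pops)
  sizes <- sapply(pops, function(p) sum(pop == p))
  n0 <- (n - sum(sizes^2) / n) / df_a
  A <- rbind(c(1, n0), c(1, 0))
  comp <- solve(A, c(ss_a / df_a, ss_w / df_w))
  sw <- comp[1]; sa <- comp[2]
  list(ss_t = ss_t, ss_a = ss_a, ss_w = ss_w, sigma_a = sa, sigma_w = sw,
       phi_st = sa / (sa + sw))
}

# Two-level AMOVA oracle: explicit SS plus a 3x3 moment-equation solve.
oracle_amova2 <- function(m, pop, grp) {
  D <- oracle_sq_dist(m)
  n <- nrow(m)
  pops <- unique(pop); gs <- unique(grp)
  P <- length(pops); G <- length(gs)
  pgrp <- sapply(pops, function(p) grp[which(pop == p)[1]])
  ss_t <- oracle_ss(D, 1:n)
  ss_wp <- sum(sapply(pops, function(p) oracle_ss(D, which(pop == p))))
  ss_g <- sum(sapply(gs, function(g) oracle_ss(D, which(grp == g))))
  ss_ap <- ss_g - ss_wp
  ss_ag <- ss_t - ss_g
  df <- c(ag = G - 1, ap = P - G, wp = n - P)
  n_p <- sapply(pops, function(p) sum(pop == p))
  N_g <- sapply(gs, function(g) sum(grp == g))
  s_np2_g <- sapply(gs, function(g) sum(n_p[pgrp == g]^2))
  n1 <- (n - sum(s_np2_g / N_g)) / df["ap"]
  n2 <- (sum(s_np2_g / N_g) - sum(n_p^2) / n) / df["ag"]
  n3 <- (n - sum(N_g^2) / n) / df["ag"]
  # rows: MS_ag, MS_ap, MS_wp; unknowns: (sc, sb, sa)
  A <- rbind(c(1, n2, n3), c(1, n1, 0), c(1, 0, 0))
  ms <- as.numeric(c(ss_ag / df["ag"], ss_ap / df["ap"], ss_wp / df["wp"]))
  comp <- as.numeric(solve(A, ms))
  sc <- comp[1]; sb <- comp[2]; sa <- comp[3]
  list(sigma_a = sa, sigma_b = sb, sigma_c = sc,
       phi_ct = sa / (sa + sb + sc), phi_sc = sb / (sb + sc),
       phi_st = (sa + sb) / (sa + sb + sc))
}

# Minimum spanning cost over a set of integer haplotype vectors under
# weighted L1 distance, by Prim's algorithm written independently.
oracle_span_cost <- function(A, w) {
  k <- nrow(A)
  if (k < 2) return(0)
  D <- matrix(0, k, k)
  for (i in 1:k) for (j in 1:k)
    D[i, j] <- sum(w * abs(A[i, ] - A[j, ]))
  in_tree <- c(TRUE, rep(FALSE, k - 1))
  cost <- 0
  for (step in seq_len(k - 1)) {
    best <- Inf
    for (i in which(in_tree)) for (j in which(!in_tree))
      if (D[i, j] < best) { best <- D[i, j]; pick <- j }
    cost <- cost + best
    in_tree[pick] <- TRUE
  }
  cost
}

# Exact Steiner pruning oracle: minimum spanning cost of the observed nodes
# over all subsets of available median nodes.
oracle_steiner_min <- function(obs, med, w) {
  best <- oracle_span_cost(obs, w)
  nm <- nrow(med)
  if (is.null(nm) || nm == 0) return(best)
  for (mask in 0:(2^nm - 1)) {
    sel <- which(bitwAnd(bitwShiftL(1, seq_len(nm) - 1), mask) != 0)
    cost <- oracle_span_cost(rbind(obs, med[sel, , drop = FALSE]), w)
    if (cost < best) best <- cost
  }
  best
}

# Minimal independent parser for the haploid microsatellite .arp files the
# package writes: returns list(pop = character, alleles = matrix).
oracle_parse_arp <- function(path) {
  lines <- readLines(path)
  pops <- character(); ids <- character(); rows <- list()
  current <- NULL
  in_block <- FALSE
  for (ln in lines) {
    if (grepl("SampleName=", ln)) {
      current <- gsub('.*SampleName="([^"]*)".*', "\\1", ln)
    } else if (grepl("SampleData=\\{", ln)) {
      in_block <- TRUE
    } else if (in_block && grepl("\\}", ln)) {
      in_block <- FALSE
    } else if (in_block) {
      parts <- strsplit(trimws(ln), "[ \t]+")[[1]]
      ids <- c(ids, parts[1])
      pops <- c(pops, current)
      al <- parts[-(1:2)]
      rows[[length(rows) + 1]] <- suppressWarnings(
        ifelse(al == "?", NA_real_, as.numeric(al)))
    }
  }
  list(pop = pops, ids = ids, alleles = do.call(rbind, rows))
}
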