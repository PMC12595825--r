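#' Inverse-variance locus weights for network construction
#'
#' Assigns each locus an integer weight on a 1-10 scale, inversely
#' proportional to its repeat-count variance: the least variable locus gets
#' 10, the most variable gets 1, and intermediate loci are placed by linear
#' interpolation on the inverse-variance scale. Zero-variance loci get 10;
#' if all loci have equal positive variance every locus gets the midpoint
#' weight 5.
#'
#' @param view a NETWORK-mode [make_view()] result.
#' @param clamp two-element integer range of admissible weights.
#' @return An object of class `ystr_weights`: list with integer `weights`
#'   and the underlying `variances`, both named by locus.
#' @export
compute_weights <- function(view, clamp = c(1L, 10L)) {
  stopifnot(inherits(view, "ystr_view"))
  m <- view$matrix
  if (nrow(unique(m[stats::complete.cases(m), , drop = FALSE])) < 2)
    stop("need at least 2 distinct complete haplotypes")
  v <- apply(m, 2, stats::var, na.rm = TRUE)
  lo <- clamp[1]; hi <- clamp[2]
  w <- rep(NA_real_, length(v)); names(w) <- names(v)
  pos <- which(v > 0)
  w[v == 0 | is.na(v)] <- hi
  if (length(pos) > 0) {
    inv <- 1 / v[pos]
    if (max(inv) == min(inv)) {
      w[pos] <- floor((lo + hi) / 2)
    } else {
      w[pos] <- floor(lo + (hi - lo) * (inv - min(inv)) /
                        (max(inv) - min(inv)) + 0.5)
    }
  }
  structure(list(weights = as.integer(w), variances = v, loci = names(v)),
            class = "ystr_weights")
}

## Weighted L1 (step-count) distance matrix between rows of allele matrix A.
.wdist_matrix <- function(A, w) {
  k <- nrow(A)
  D <- matrix(0, k, k)
  for (l in seq_len(ncol(A))) {
    D <- D + w[l] * abs(outer(A[, l], A[, l], "-"))
  }
  D
}

## Minimum spanning tree info over a complete weighted graph given by D:
## total cost, tree edge list, and the bottleneck (max edge weight on the
## tree path) for every node pair.
.mst_info <- function(D) {
  k <- nrow(D)
  D <- unname((D + t(D)) / 2)  # exact symmetry, no dimnames
  g <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                           weighted = TRUE)
  t <- igraph::mst(g)
  el <- igraph::as_edgelist(t, names = FALSE)
  wts <- igraph::E(t)$weight
  adj <- vector("list", k)
  for (e in seq_len(nrow(el))) {
    i <- el[e, 1]; j <- el[e, 2]
    adj[[i]] <- rbind(adj[[i]], c(j, wts[e]))
    adj[[j]] <- rbind(adj[[j]], c(i, wts[e]))
  }
  B <- matrix(0, k, k)
  for (root in seq_len(k)) {
    visited <- rep(FALSE, k); visited[root] <- TRUE
    stack <- root
    while (length(stack) > 0) {
      u <- stack[length(stack)]; stack <- stack[-length(stack)]
      nb <- adj[[u]]
      if (is.null(nb)) next
      for (r in seq_len(nrow(nb))) {
        v <- nb[r, 1]
        if (!visited[v]) {
          visited[v] <- TRUE
          B[root, v] <- max(B[root, u], nb[r, 2])
          stack <- c(stack, v)
        }
      }
    }
  }
  list(cost = sum(wts), edges = el, bottleneck = B)
}

## epsilon-relaxed minimum spanning network: all edges whose weight is
## within eps of the bottleneck distance between their endpoints. At eps = 0
## this is exactly the union of all minimum spanning trees.
.msn_edges <- function(D, eps) {
  B <- .mst_info(D)$bottleneck
  which(D <= B + eps + 1e-9 & upper.tri(D), arr.ind = TRUE)
}

.mst_cost <- function(D) .mst_info(D)$cost

#' Median-joining network of STR haplotypes
#'
#' Builds a median-joining network over the distinct haplotypes of a
#' NETWORK-mode view under weighted step distance (edge length = sum over
#' loci of weight times absolute repeat difference). The algorithm
#' alternates between (1) the epsilon-relaxed minimum spanning network over
#' the current node set, (2) generating candidate median (Steiner) vectors
#' as component-wise medians of connected node triplets, and (3) adding the
#' median that most reduces the minimum spanning cost, until no candidate
#' helps. Samples with missing alleles at any network locus are excluded
#' with a warning; input row order does not affect the result (nodes are
#' ordered canonically).
#'
#' @param view a NETWORK-mode [make_view()] result with integer alleles.
#' @param weights a [compute_weights()] result, or NULL for unit weights.
#' @param epsilon non-negative tolerance for the relaxed spanning network
#'   (default 0).
#' @return An object of class `ystr_mjnet`: node allele matrix `alleles`,
#'   `type` (OBSERVED/MEDIAN), `multiplicity`, `populations` (per-node
#'   composition strings), `edges` data frame (from, to, length, steps),
#'   `cost` (minimum spanning cost of the node set), `epsilon`, `weights`.
#' @export
median_joining <- function(view, weights = NULL, epsilon = 0) {
  stopifnot(inherits(view, "ystr_view"), epsilon >= 0)
  m <- view$matrix
  if (any(m[!is.na(m)] != round(m[!is.na(m)])))
    stop("non-integer alleles; round before network construction")
  keep <- stats::complete.cases(m)
  if (!all(keep)) {
    warning(sum(!keep), " sample(s) with missing network loci excluded")
    m <- m[keep, , drop = FALSE]
  }
  if (nrow(m) == 0) stop("no complete haplotypes")
  pops <- view$meta$population[keep]
  w <- if (is.null(weights)) rep(1L, ncol(m)) else weights$weights
  stopifnot(length(w) == ncol(m))

  key <- apply(m, 1, paste, collapse = "-")
  ord <- order(key)
  ukey <- unique(key[ord])
  A <- m[match(ukey, key), , drop = FALSE]
  mult <- as.integer(table(key)[ukey])
  popcomp <- vapply(ukey, function(k) {
    tt <- table(pops[key == k])
    paste(paste0(names(tt), ":", tt), collapse = "|")
  }, character(1))
  n_obs <- nrow(A)

  nodes <- A
  repeat {
    D <- .wdist_matrix(nodes, w)
    cur <- .mst_cost(D)
    msn <- .msn_edges(D, epsilon)
    adj <- vector("list", nrow(nodes))
    for (r in seq_len(nrow(msn))) {
      i <- msn[r, 1]; j <- msn[r, 2]
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
    cand <- NULL
    for (v in seq_len(nrow(nodes))) {
      nb <- adj[[v]]
      if (length(nb) < 2) next
      prs <- utils::combn(nb, 2)
      for (c2 in seq_len(ncol(prs))) {
        trip <- nodes[c(prs[1, c2], v, prs[2, c2]), , drop = FALSE]
        cand <- rbind(cand, apply(trip, 2, function(x) sort(x)[2]))
      }
    }
    if (is.null(cand)) break
    cand <- unique(cand)
    existing <- apply(nodes, 1, paste, collapse = "-")
    cand <- cand[!(apply(cand, 1, paste, collapse = "-") %in% existing),
                 , drop = FALSE]
    if (nrow(cand) == 0) break
    gains <- vapply(seq_len(nrow(cand)), function(r) {
      dn <- colSums(w * t(abs(sweep(nodes, 2, cand[r, ]))))
      D2 <- rbind(cbind(D, dn), c(dn, 0))
      cur - .mst_cost(D2)
    }, numeric(1))
    best <- max(gains)
    if (best <= 1e-9) break
    # deterministic tie-break: lexicographically smallest best median
    top <- which(gains >= best - 1e-9)
    top_keys <- apply(cand[top, , drop = FALSE], 1, paste, collapse = "-")
    nodes <- rbind(nodes, cand[top[order(top_keys)[1]], ])
  }

  .mjnet_build(nodes, n_obs, mult, popcomp, w, epsilon,
               loci = colnames(m))
}

## Assemble the ystr_mjnet object: MSN edges + attributes over `nodes`.
.mjnet_build <- function(nodes, n_obs, mult, popcomp, w, epsilon, loci) {
  k <- nrow(nodes)
  rownames(nodes) <- c(paste0("H", seq_len(n_obs)),
                       if (k > n_obs) paste0("M", seq_len(k - n_obs)))
  colnames(nodes) <- loci
  D <- .wdist_matrix(nodes, w)
  msn <- if (k > 1) .msn_edges(D, epsilon) else
    matrix(integer(), 0, 2)
  steps <- character(nrow(msn))
  for (r in seq_len(nrow(msn))) {
    d <- nodes[msn[r, 2], ] - nodes[msn[r, 1], ]
    nz <- which(d != 0)
    steps[r] <- paste(paste0(loci[nz], ":", ifelse(d[nz] > 0, "+", ""),
                             d[nz]), collapse = ";")
  }
  edges <- data.frame(
    from = rownames(nodes)[msn[, 1]],
    to = rownames(nodes)[msn[, 2]],
    length = D[msn],
    steps = steps,
    stringsAsFactors = FALSE
  )
  structure(
    list(alleles = nodes,
         type = c(rep("OBSERVED", n_obs), rep("MEDIAN", k - n_obs)),
         multiplicity = c(mult, rep(0L, k - n_obs)),
         populations = c(popcomp, rep("", k - n_obs)),
         edges = edges, cost = .mst_cost(D), epsilon = epsilon,
         weights = w, loci = loci),
    class = "ystr_mjnet"
  )
}

#' @export
print.ystr_mjnet <- function(x, ...) {
  cat("median-joining network: ", sum(x$type == "OBSERVED"),
      " observed + ", sum(x$type == "MEDIAN"), " median nodes, ",
      nrow(x$edges), " links, spanning cost ", x$cost, "\n", sep = "")
  invisible(x)
}

#' Maximum-parsimony pruning of a median-joining network
#'
#' Removes median nodes that are not needed by any minimum-cost spanning
#' subgraph connecting the observed haplotypes. With at most `exact_limit`
#' median nodes the optimum is found by exhaustive enumeration over median
#' subsets (exact Steiner pruning); larger networks use greedy elimination
#' of medians whose removal does not increase the spanning cost. The result
#' stays connected over observed nodes, the spanning cost never increases,
#' and the operation is idempotent.
#'
#' @param g a [median_joining()] result.
#' @param exact_limit maximum median count for exhaustive enumeration
#'   (default 12).
#' @return A pruned `ystr_mjnet`.
#' @export
mp_prune <- function(g, exact_limit = 12L) {
  stopifnot(inherits(g, "ystr_mjnet"))
  med <- which(g$type == "MEDIAN")
  obs <- which(g$type == "OBSERVED")
  if (length(med) == 0) return(g)
  D <- .wdist_matrix(g$alleles, g$weights)
  if (length(med) <= exact_limit) {
    best_cost <- Inf
    keep_union <- integer(0)
    for (mask in 0:(2^length(med) - 1)) {
      sel <- med[bitwAnd(bitwShiftL(1, seq_along(med) - 1), mask) != 0]
      idx <- c(obs, sel)
      cost <- if (length(idx) > 1) .mst_cost(D[idx, idx, drop = FALSE])
              else 0
      if (cost < best_cost - 1e-9) {
        best_cost <- cost
        keep_union <- sel
      } else if (cost <= best_cost + 1e-9) {
        keep_union <- union(keep_union, sel)
      }
    }
    keep <- c(obs, sort(keep_union))
  } else {
    keep <- c(obs, med)
    cur <- .mst_cost(D[keep, keep, drop = FALSE])
    repeat {
      meds_left <- setdiff(keep, obs)
      if (length(meds_left) == 0) break
      costs <- vapply(meds_left, function(mi) {
        idx <- setdiff(keep, mi)
        .mst_cost(D[idx, idx, drop = FALSE])
      }, numeric(1))
      if (min(costs) <= cur + 1e-9) {
        drop <- meds_left[which.min(costs)]
        keep <- setdiff(keep, drop)
        cur <- min(costs)
      } else break
    }
  }
  nodes <- g$alleles[keep, , drop = FALSE]
  n_obs <- length(obs)
  out <- .mjnet_build(nodes, n_obs, g$multiplicity[obs],
                      g$populations[obs], g$weights, g$epsilon, g$loci)
  out$cost <- .mst_cost(D[keep, keep, drop = FALSE])
  out
}

#' Export a network as GraphML or DOT
#'
#' Node attributes: `type` (OBSERVED/MEDIAN), `multiplicity`, `populations`
#' (composition string `pop:count|...`). Edge attributes: `length`
#' (weighted step length) and `steps` (the mutated loci with signed repeat
#' changes, `locus:+1;...`).
#'
#' @param g a [median_joining()] result.
#' @param path output file.
#' @param format `"graphml"` or `"dot"`.
#' @return Invisibly, `path`.
#' @export
export_graph <- function(g, path, format = c("graphml", "dot")) {
  stopifnot(inherits(g, "ystr_mjnet"))
  format <- match.arg(format)
  ig <- as_igraph(g)
  igraph::write_graph(ig, path, format = format)
  invisible(path)
}

#' Convert a network to an igraph object
#' @param g a [median_joining()] result.
#' @return An igraph graph with node and edge attributes.
#' @export
as_igraph <- function(g) {
  stopifnot(inherits(g, "ystr_mjnet"))
  verts <- data.frame(name = rownames(g$alleles), type = g$type,
                      multiplicity = g$multiplicity,
                      populations = g$populations,
                      stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(g$edges, directed = FALSE,
                                vertices = verts)
}
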