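test_that("locus weights are inverse to variance on the 1-10 scale", {
  v <- mini_view(rbind(c(10, 10, 10), c(10, 11, 12), c(11, 11, 13),
                       c(10, 10, 12), c(10, 11, 13), c(11, 12, 17)),
                 mode = "NETWORK")
  vars <- apply(v$matrix, 2, var)
  w <- compute_weights(v)
  # independent recomputation of the interpolation formula
  inv <- 1 / vars
  expected <- floor(1 + 9 * (inv - min(inv)) / (max(inv) - min(inv)) + 0.5)
  expect_equal(w$weights, as.integer(expected))
  expect_true(all(w$weights >= 1 & w$weights <= 10))
  expect_equal(w$weights[which.min(vars)], 10L)
  expect_equal(w$weights[which.max(vars)], 1L)
  # weights weakly decreasing in variance
  expect_true(all(diff(w$weights[order(vars)]) <= 0))
})

test_that("weight boundary rules: zero variance -> 10, all equal -> 5", {
  vz <- mini_view(rbind(c(10, 11, 12), c(10, 12, 13), c(10, 13, 14)),
                  mode = "NETWORK")
  wz <- compute_weights(vz)
  expect_equal(wz$weights[1], 10L)

  ve <- mini_view(rbind(c(10, 11, 12), c(11, 12, 13)), mode = "NETWORK")
  we <- compute_weights(ve)
  expect_true(all(we$weights == we$weights[1]))
  expect_equal(we$weights[1], 5L)

  expect_error(compute_weights(mini_view(rbind(c(1, 1, 1), c(1, 1, 1)),
                                         mode = "NETWORK")),
               "distinct")
})

test_that("two haplotypes one step apart give a single edge, no medians", {
  v <- mini_view(rbind(c(10, 11, 12), c(10, 11, 13)), mode = "NETWORK")
  g <- median_joining(v)
  expect_equal(sum(g$type == "MEDIAN"), 0)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$length, 1)
  expect_equal(g$edges$steps, "L3:+1")
})

test_that("the three-haplotype toy gains median (1,0,0), cost 4 -> 3", {
  v <- mini_view(rbind(A = c(10, 10, 10), B = c(11, 11, 10),
                       C = c(11, 10, 11)) + 0, mode = "NETWORK")
  g <- median_joining(v)
  med <- g$alleles[g$type == "MEDIAN", , drop = FALSE]
  expect_equal(nrow(med), 1)
  expect_equal(unname(med[1, ]), c(11, 10, 10))   # (1,0,0) + founder offset
  expect_equal(g$cost, 3)
  expect_equal(oracle_steiner_min(v$matrix, med, rep(1, 3)), 3)
  # MST over observed alone costs 4
  expect_equal(oracle_span_cost(v$matrix, rep(1, 3)), 4)
})

test_that("a star stays a star and the centre has maximal degree", {
  centre <- c(12, 12, 12, 12)
  nb <- rbind(c(13, 12, 12, 12), c(12, 13, 12, 12), c(12, 12, 13, 12),
              c(12, 12, 12, 13), c(11, 12, 12, 12))
  v <- mini_view(rbind(centre, nb), mode = "NETWORK")
  g <- median_joining(v)
  expect_equal(sum(g$type == "MEDIAN"), 0)
  expect_equal(nrow(g$edges), 5)
  deg <- table(c(g$edges$from, g$edges$to))
  centre_id <- rownames(g$alleles)[apply(g$alleles, 1, function(x)
    all(x == centre))]
  expect_equal(names(which.max(deg)), centre_id)
})

test_that("median joining never costs more than the observed-only MST", {
  set.seed(61)
  for (rep in 1:10) {
    m <- matrix(sample(10:13, 15, replace = TRUE), 5, 3)
    m <- unique(m)
    if (nrow(m) < 3) next
    v <- mini_view(m, mode = "NETWORK")
    w <- rep(1, 3)
    g <- median_joining(v)
    expect_lte(g$cost, oracle_span_cost(unique(v$matrix), w) + 1e-9)
  }
})

test_that("network construction is invariant to input row order", {
  set.seed(67)
  m <- matrix(sample(10:13, 18, replace = TRUE), 6, 3)
  v1 <- mini_view(m, mode = "NETWORK")
  v2 <- mini_view(m[sample(nrow(m)), ], mode = "NETWORK")
  g1 <- median_joining(v1)
  g2 <- median_joining(v2)
  expect_equal(g1$alleles, g2$alleles)
  expect_equal(g1$edges, g2$edges)
})

test_that("samples missing a network locus are dropped with a warning", {
  v <- mini_view(rbind(c(10, 11, 12), c(10, 11, 13), c(10, NA, 12)),
                 mode = "NETWORK")
  expect_warning(g <- median_joining(v), "excluded")
  expect_equal(sum(g$multiplicity), 2)
  expect_error(
    median_joining(mini_view(rbind(c(10.2, 11, 12), c(10, 11, 13)),
                             mode = "NETWORK")),
    "round")
})

test_that("MP pruning is exact, idempotent and cost-non-increasing", {
  # an MST-only graph passes through unchanged
  v <- mini_view(rbind(c(10, 11, 12), c(10, 11, 13), c(10, 11, 14)),
                 mode = "NETWORK")
  g <- median_joining(v)
  expect_equal(sum(g$type == "MEDIAN"), 0)
  p <- mp_prune(g)
  expect_equal(p$alleles, g$alleles)
  expect_equal(p$cost, g$cost)

  # random toys: pruned cost equals the exhaustive Steiner optimum
  set.seed(71)
  for (rep in 1:25) {
    m <- unique(matrix(sample(10:12, 16, replace = TRUE), 4, 4))
    if (nrow(m) < 3) next
    g <- median_joining(mini_view(m, mode = "NETWORK"))
    pr <- mp_prune(g)
    expect_lte(pr$cost, g$cost + 1e-9)
    obs <- g$alleles[g$type == "OBSERVED", , drop = FALSE]
    med <- g$alleles[g$type == "MEDIAN", , drop = FALSE]
    expect_equal(pr$cost, oracle_steiner_min(obs, med, g$weights),
                 tolerance = 1e-9)
    pr2 <- mp_prune(pr)
    expect_equal(pr2$alleles, pr$alleles)   # idempotent
    # still connected over observed nodes
    ig <- as_igraph(pr)
    expect_true(igraph::is_connected(ig))
  }
})

test_that("an essential Steiner point survives pruning", {
  v <- mini_view(rbind(c(10, 10, 10), c(11, 11, 10), c(11, 10, 11)) + 0,
                 mode = "NETWORK")
  g <- median_joining(v)
  pr <- mp_prune(g)
  expect_equal(sum(pr$type == "MEDIAN"), 1)
  expect_equal(pr$cost, 3)
})

test_that("GraphML export round-trips topology and attributes", {
  v <- mini_view(rbind(c(10, 10, 10), c(11, 11, 10), c(11, 10, 11),
                       c(10, 10, 10)), pop = c("A", "A", "B", "B"),
                 mode = "NETWORK")
  g <- median_joining(v)
  f <- tempfile(fileext = ".graphml")
  export_graph(g, f)
  back <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::vcount(back), nrow(g$alleles))
  expect_equal(igraph::ecount(back), nrow(g$edges))
  expect_equal(sum(igraph::V(back)$multiplicity), 4)  # sample conservation
  # edge step labels list exactly the changed loci
  for (r in seq_len(nrow(g$edges))) {
    d <- g$alleles[g$edges$to[r], ] - g$alleles[g$edges$from[r], ]
    loci_lab <- sub(":.*", "", strsplit(g$edges$steps[r], ";")[[1]])
    expect_setequal(loci_lab, names(which(d != 0)))
  }
})
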