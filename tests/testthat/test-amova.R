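test_that("the worked two-population toy decomposes exactly", {
  v <- mini_view(cbind(c(10, 10, 12, 12)), pop = c("A", "A", "B", "B"))
  am <- amova(v, permutations = 0)
  expect_equal(am$rows$SS[am$rows$source == "Total"], 4)
  expect_equal(am$rows$SS[am$rows$source == "Within populations"], 0)
  expect_equal(am$rows$sigma2[1], 2)         # among-population component
  expect_equal(unname(am$phi["phi_st"]), 1)
  expect_equal(am$rows$percent[1], 100)
  expect_equal(am$rows$df[1:2], c(1, 2))
})

test_that("monomorphic data give zero sums of squares", {
  v <- mini_view(matrix(12, 6, 2), pop = rep(c("A", "B"), each = 3))
  am <- amova(v, permutations = 0)
  expect_equal(am$rows$SS, rep(0, 3))
  expect_true(all(is.na(am$rows$percent[1:2])))  # degenerate percentages
})

test_that("one-level components match the moment-equation oracle", {
  set.seed(13)
  for (rep in 1:5) {
    m <- matrix(sample(8:16, 36, replace = TRUE), 12, 3)
    pop <- rep(c("A", "B", "C"), each = 4)
    am <- amova(mini_view(m, pop = pop), permutations = 0)
    oracle <- oracle_amova1(m, pop)
    expect_equal(am$rows$SS[3], oracle$ss_t, tolerance = 1e-10)
    expect_equal(am$rows$sigma2[1], oracle$sigma_a, tolerance = 1e-10)
    expect_equal(am$rows$sigma2[2], oracle$sigma_w, tolerance = 1e-10)
    expect_equal(unname(am$phi["phi_st"]), oracle$phi_st, tolerance = 1e-10)
  }
})

test_that("two-level components match the nested oracle on unbalanced data", {
  set.seed(19)
  for (rep in 1:4) {
    sizes <- c(3, 5, 4, 6)
    pop <- rep(c("P1", "P2", "P3", "P4"), times = sizes)
    grp_map <- c(P1 = "G1", P2 = "G1", P3 = "G2", P4 = "G2")
    m <- matrix(sample(8:18, length(pop) * 3, replace = TRUE),
                length(pop), 3)
    am <- amova(mini_view(m, pop = pop), groups = grp_map,
                permutations = 0)
    oracle <- oracle_amova2(m, pop, unname(grp_map[pop]))
    expect_equal(am$rows$sigma2[1], oracle$sigma_a, tolerance = 1e-10)
    expect_equal(am$rows$sigma2[2], oracle$sigma_b, tolerance = 1e-10)
    expect_equal(am$rows$sigma2[3], oracle$sigma_c, tolerance = 1e-10)
    expect_equal(unname(am$phi), unname(unlist(
      oracle[c("phi_ct", "phi_sc", "phi_st")])), tolerance = 1e-10)
    expect_equal(sum(am$rows$df[1:3]), length(pop) - 1)
    if (all(am$rows$sigma2[1:3] >= 0))
      expect_equal(sum(am$rows$percent[1:3]), 100, tolerance = 0.01)
  }
})

test_that("two-population AMOVA Phi_ST equals pairwise R_ST exactly", {
  set.seed(29)
  m <- matrix(sample(8:16, 40, replace = TRUE), 10, 4)
  pop <- rep(c("A", "B"), each = 5)
  v <- mini_view(m, pop = pop)
  am <- amova(v, permutations = 0)
  rst <- pairwise_rst(v, permutations = 0)
  expect_identical(unname(am$phi[["phi_st"]]), rst$values["A", "B"][[1]])
})

test_that("pooling all populations into one removes among-group variance", {
  set.seed(37)
  m <- matrix(sample(8:16, 30, replace = TRUE), 10, 3)
  v <- mini_view(m, pop = rep("ALL", 10))
  expect_error(amova(v), "at least 2")
  # nearly-pooled: two labels over an exchangeable sample should put the
  # bulk of variance within populations
  am <- amova(mini_view(m, pop = rep(c("A", "B"), 5)), permutations = 0)
  expect_lt(abs(am$rows$sigma2[1]), am$rows$sigma2[2])
})

test_that("permutation p-values match exhaustive enumeration on a toy", {
  m <- cbind(c(10, 10, 13, 14))
  pop <- c("A", "A", "B", "B")
  v <- mini_view(m, pop = pop)
  obs <- unname(amova(v, permutations = 0)$phi["phi_st"])
  # enumerate all 4!/(2!2!) label assignments via index permutations
  perms <- combn(4, 2)
  stats <- apply(perms, 2, function(idx) {
    lab <- rep("B", 4); lab[idx] <- "A"
    oracle_amova1(m, lab)$phi_st
  })
  exact_p <- mean(stats >= obs - 1e-12)
  am <- amova(v, permutations = 2000, seed = 5)
  expect_equal(unname(am$pvalues["phi_st"]), exact_p, tolerance = 0.05)
})

test_that("regional contrast recovers ratio 1 for identical cohorts", {
  set.seed(43)
  reg <- rep(c("Centre", "North", "South", "West"), each = 5)
  # real regional structure: region-specific allele offsets plus noise
  m <- matrix(sample(8:10, 80, replace = TRUE), 20, 4) +
    3 * as.integer(factor(reg))
  tab <- data.frame(sample_id = sprintf("s%02d", 1:20),
                    population = rep(c("Roma", "nonRoma"), 10),
                    region = reg,
                    L1 = m[, 1], L2 = m[, 2], L3 = m[, 3], L4 = m[, 4])
  ds <- ystr_dataset(tab, marker_panel("mini", paste0("L", 1:4)))
  v <- make_view(ds, "DISTANCE")
  # identical cohorts: contrast the whole view with itself
  rc <- regional_contrast(v, rep(TRUE, 20), rep(TRUE, 20),
                          permutations = 0)
  expect_equal(rc$ratio, 1)

  # single-region cohort errors
  one_reg <- v$meta$region == "Centre"
  expect_error(regional_contrast(v, one_reg, rep(TRUE, 20),
                                 permutations = 0), "fewer than 2")
})

test_that("simulated cohorts with ~6x regional structure give ratio near 6", {
  # two cohorts over four regions: deme divergence tuned to Phi ~ 3% vs
  # ~0.5% (split times in a 6:1 ratio at matched deme size)
  pa <- numeric(6); pb <- numeric(6)
  for (s in seq_along(pa)) {
    strong <- simulate_scenario(scenario_config(
      "DIVERGENCE", pop_labels = c("Centre", "North", "South", "West"),
      pop_sizes = 400, split_time = 24, burn_in = 40, sample_sizes = 40,
      seed = 100 + s))
    weak <- simulate_scenario(scenario_config(
      "DIVERGENCE", pop_labels = c("Centre", "North", "South", "West"),
      pop_sizes = 400, split_time = 4, burn_in = 40, sample_sizes = 40,
      seed = 200 + s))
    weak$dataset$tab$sample_id <- paste0("w_", weak$dataset$tab$sample_id)
    weak$dataset$tab$population <- "weak"
    strong$dataset$tab$population <- "strong"
    both <- merge_datasets(strong$dataset, weak$dataset)
    v <- make_view(both, "DISTANCE")
    rc <- regional_contrast(v, v$meta$population == "strong",
                            v$meta$population == "weak", permutations = 0)
    pa[s] <- rc$percent_a; pb[s] <- rc$percent_b
  }
  # ratio of mean among-region percentages across seeds (per-seed ratios
  # are unstable when the weak cohort's component is near zero)
  expect_gt(mean(pa) / mean(pb), 2.5)
  expect_lt(mean(pa) / mean(pb), 15)
})
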