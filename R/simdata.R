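## Founder repeat counts for the 17 evolving units of the Yfiler panel.
## DYS389II is stored internally as the extension (DYS389II - DYS389I) so
## that every unit mutates independently; the reported DYS389II allele is
## reconstructed as the sum when a dataset is written out.
FOUNDER_UNITS <- c(
  DYS19 = 14, DYS389I = 13, DYS389II = 16, DYS390 = 24, DYS391 = 10,
  DYS392 = 11, DYS393 = 13, DYS385a = 11, DYS385b = 14, DYS437 = 15,
  DYS438 = 11, DYS439 = 12, DYS448 = 19, DYS456 = 15, DYS458 = 16,
  DYS635 = 23, YGATAH4 = 12
)

#' Demographic scenario configuration for the haplotype simulator
#'
#' Describes a forward-time Wright-Fisher scenario for haploid multilocus
#' STR haplotypes evolving under strict single-step mutation: per
#' generation each locus mutates with probability `mu` to +1 or -1 repeat
#' (equal probability), optionally reflecting at allele bounds.
#'
#' Models (the five demographic topologies used for migration-model
#' comparison, plus panmixia as the null):
#' * `PANMIXIA` — one deme; sampled individuals are partitioned into the
#'   population labels purely nominally.
#' * `CHAIN_EAST_WEST` — demes arranged in a chain with unidirectional
#'   east-to-west gene flow between adjacent demes.
#' * `DIVERGENCE` — demes split from a common ancestral deme at
#'   `split_time` and evolve in isolation.
#' * `DIVERGENCE_MIGRATION` — divergence plus ongoing unidirectional
#'   (east-to-west) migration between adjacent demes.
#' * `DIVERGENCE_BIDIR` — divergence plus bidirectional migration between
#'   adjacent demes.
#'
#' @param model one of the five model names.
#' @param pop_labels deme labels, ordered east to west where order matters.
#' @param pop_sizes haploid deme sizes (recycled).
#' @param split_time generations before present at which demes split from
#'   the ancestral deme (ignored for PANMIXIA).
#' @param burn_in ancestral-deme generations simulated before the split,
#'   to provide standing variation.
#' @param migration either a per-generation rate applied to the model's
#'   adjacency pattern, or a full `[src, dst]` matrix of per-offspring
#'   parent-choice probabilities.
#' @param admixture_pulses list of `list(target=, time=, fraction=)` pulses
#'   from a deeply diverged HOST deme (emulating introgression of host
#'   lineages such as R1b).
#' @param host_divergence generations separating the HOST deme's founder
#'   phase (default 2000, deep enough for unambiguous lineage labels).
#' @param host_size haploid HOST deme size.
#' @param mu per-locus mutation rate per generation (default 2.5e-3).
#' @param loci locus names to simulate (default: 17-locus Yfiler units).
#' @param range_constraint optional `c(min, max)` reflecting allele bounds.
#' @param sample_sizes individuals sampled per deme at present (recycled;
#'   default 50, capped at deme size).
#' @param n_founder_lineages number of distinct founder lineage labels in
#'   the ancestral deme.
#' @param seed RNG seed.
#' @return An object of class `ystr_scenario`.
#' @export
scenario_config <- function(model = c("PANMIXIA", "CHAIN_EAST_WEST",
                                      "DIVERGENCE", "DIVERGENCE_MIGRATION",
                                      "DIVERGENCE_BIDIR"),
                            pop_labels = REGIONS,
                            pop_sizes = 250,
                            split_time = 20,
                            burn_in = 50,
                            migration = 0.002,
                            admixture_pulses = list(),
                            host_divergence = 2000,
                            host_size = 250,
                            mu = 2.5e-3,
                            loci = names(FOUNDER_UNITS),
                            range_constraint = NULL,
                            sample_sizes = 50,
                            n_founder_lineages = 4,
                            seed = 1L) {
  model <- match.arg(model)
  P <- length(pop_labels)
  pop_sizes <- rep_len(pop_sizes, P)
  explicit_sample <- !missing(sample_sizes)
  sample_sizes <- rep_len(sample_sizes, P)
  if (explicit_sample && any(sample_sizes > pop_sizes))
    stop("sample size exceeds deme size")
  sample_sizes <- pmin(sample_sizes, pop_sizes)
  stopifnot(mu >= 0, split_time >= 0, burn_in >= 0)
  for (pl in admixture_pulses) {
    stopifnot(all(c("target", "time", "fraction") %in% names(pl)),
              pl$fraction >= 0, pl$fraction <= 1,
              pl$target %in% pop_labels)
  }
  if (is.matrix(migration)) {
    stopifnot(nrow(migration) == P, ncol(migration) == P,
              all(migration >= 0))
    mig <- migration
    dimnames(mig) <- list(pop_labels, pop_labels)
  } else {
    mig <- matrix(0, P, P, dimnames = list(pop_labels, pop_labels))
    if (model == "CHAIN_EAST_WEST" || model == "DIVERGENCE_MIGRATION") {
      for (i in seq_len(P - 1)) mig[i, i + 1] <- migration  # east -> west
    } else if (model == "DIVERGENCE_BIDIR") {
      for (i in seq_len(P - 1)) {
        mig[i, i + 1] <- migration
        mig[i + 1, i] <- migration
      }
    }
  }
  structure(
    list(model = model, pop_labels = pop_labels, pop_sizes = pop_sizes,
         split_time = split_time, burn_in = burn_in, migration = mig,
         admixture_pulses = admixture_pulses,
         host_divergence = host_divergence, host_size = host_size,
         mu = mu, loci = loci, range_constraint = range_constraint,
         sample_sizes = sample_sizes,
         n_founder_lineages = n_founder_lineages, seed = seed),
    class = "ystr_scenario"
  )
}

#' Named preset scenarios
#'
#' Five presets for the Iberian regional topologies (panmixia,
#' east-to-west gene flow, divergence, divergence with unidirectional
#' migration, divergence with bidirectional migration) over the five
#' regions, plus one continental east-to-west chain spanning Greece,
#' Romania, Slovakia and Spain. Regional defaults reflect the study
#' system: small endogamous haploid deme sizes (250), a regional split
#' about 20 generations ago (roughly the six centuries since arrival in
#' Iberia at ~30 years/generation), and the median pedigree mutation rate
#' 2.5e-3.
#'
#' @param name preset name; omit to list available presets.
#' @param seed RNG seed stored in the returned configuration.
#' @return A `ystr_scenario` (or the preset names if `name` is missing).
#' @export
scenario_library <- function(name = NULL, seed = 1L) {
  presets <- c("panmixia_regions", "gene_flow_east_west_regions",
               "divergence_regions", "divergence_migration_regions",
               "divergence_bidir_regions", "chain_continental")
  if (is.null(name)) return(presets)
  regions_ew <- c("East", "North", "Centre", "South", "West")
  switch(
    name,
    panmixia_regions = scenario_config(
      "PANMIXIA", pop_labels = regions_ew, pop_sizes = 1000,
      split_time = 0, burn_in = 200, seed = seed),
    gene_flow_east_west_regions = scenario_config(
      "CHAIN_EAST_WEST", pop_labels = regions_ew, split_time = 200,
      migration = 0.01, seed = seed),
    divergence_regions = scenario_config(
      "DIVERGENCE", pop_labels = regions_ew, migration = 0, seed = seed),
    divergence_migration_regions = scenario_config(
      "DIVERGENCE_MIGRATION", pop_labels = regions_ew, migration = 0.01,
      seed = seed),
    divergence_bidir_regions = scenario_config(
      "DIVERGENCE_BIDIR", pop_labels = regions_ew, migration = 0.01,
      seed = seed),
    chain_continental = scenario_config(
      "CHAIN_EAST_WEST",
      pop_labels = c("Roma_Greece", "Roma_Romania", "Roma_Slovakia",
                     "Roma_Spain"),
      pop_sizes = 400, split_time = 300, migration = 0.01, seed = seed),
    stop("unknown preset: ", name)
  )
}

## One generation of single-step mutation on an integer allele matrix.
.mutate <- function(G, mu, bounds) {
  nm <- length(G)
  k <- stats::rbinom(1, nm, mu)
  if (k > 0) {
    idx <- sample.int(nm, k)
    G[idx] <- G[idx] + sample(c(-1L, 1L), k, replace = TRUE)
    if (!is.null(bounds)) {
      G[idx] <- ifelse(G[idx] < bounds[1], 2 * bounds[1] - G[idx], G[idx])
      G[idx] <- ifelse(G[idx] > bounds[2], 2 * bounds[2] - G[idx], G[idx])
    }
  }
  G
}

#' Simulate a demographic scenario
#'
#' Forward-time Wright-Fisher simulation of the configured scenario. Each
#' offspring picks a parent uniformly from its deme (or, with the
#' configured migration probability, from a source deme; admixture pulses
#' replace a binomial fraction of parents with HOST-deme parents at the
#' pulse generation), then every locus mutates with probability `mu` by
#' +/- 1 repeat. Founder-lineage labels are inherited alongside the
#' haplotypes, so every sampled individual carries a truth label.
#'
#' @param config a [scenario_config()] or preset name for
#'   [scenario_library()].
#' @return List with `dataset` (a [ystr_dataset()] in the 17-locus panel
#'   convention when simulating the default loci) and `truth`: founder
#'   depth per population, realised migrant counts per deme pair, lineage
#'   labels per sampled individual, and the scenario echo.
#' @export
simulate_scenario <- function(config) {
  if (is.character(config)) config <- scenario_library(config)
  stopifnot(inherits(config, "ystr_scenario"))
  set.seed(config$seed)
  L <- length(config$loci)
  founder <- if (all(config$loci %in% names(FOUNDER_UNITS)))
    FOUNDER_UNITS[config$loci] else stats::setNames(rep(15, L), config$loci)
  P <- length(config$pop_labels)
  mig_counts <- matrix(0, P, P,
                       dimnames = list(config$pop_labels,
                                       config$pop_labels))

  new_deme <- function(n, labels) {
    list(G = matrix(rep(founder, each = n), n, L,
                    dimnames = list(NULL, config$loci)),
         lab = labels)
  }

  # HOST deme: deep independent evolution from the same founder
  host <- NULL
  if (length(config$admixture_pulses) > 0) {
    host <- new_deme(config$host_size, rep("HOST", config$host_size))
    for (g in seq_len(config$host_divergence))
      host$G <- .mutate(host$G, config$mu, config$range_constraint)
  }

  anc_size <- max(config$pop_sizes)
  anc_labels <- paste0("L", rep_len(seq_len(config$n_founder_lineages),
                                    anc_size))
  anc <- new_deme(anc_size, anc_labels)

  split_time <- if (config$model == "PANMIXIA") 0 else config$split_time
  # ancestral phase
  for (g in seq_len(config$burn_in +
                    if (config$model == "PANMIXIA") config$split_time
                    else 0)) {
    par <- sample.int(nrow(anc$G), nrow(anc$G), replace = TRUE)
    anc$G <- .mutate(anc$G[par, , drop = FALSE], config$mu,
                     config$range_constraint)
    anc$lab <- anc$lab[par]
  }

  if (config$model == "PANMIXIA") {
    # run the single deme to the present, then partition nominally
    demes <- NULL
    pool <- anc
    total_draw <- sum(config$sample_sizes)
    stopifnot(total_draw <= nrow(pool$G))
    pick <- sample.int(nrow(pool$G), total_draw)
    groups <- rep(config$pop_labels, config$sample_sizes)
    samp_G <- pool$G[pick, , drop = FALSE]
    samp_lab <- pool$lab[pick]
    samp_pop <- groups
  } else {
    demes <- lapply(seq_len(P), function(k) {
      pick <- sample.int(nrow(anc$G), config$pop_sizes[k], replace = TRUE)
      list(G = anc$G[pick, , drop = FALSE], lab = anc$lab[pick])
    })
    names(demes) <- config$pop_labels
    pulses <- config$admixture_pulses
    for (t in if (split_time >= 1) seq(split_time, 1) else integer(0)) {
      for (k in seq_len(P)) {
        n <- config$pop_sizes[k]
        src <- rep(k, n)
        for (s in seq_len(P)) {
          if (s == k || config$migration[s, k] == 0) next
          mig <- stats::runif(n) < config$migration[s, k]
          src[mig] <- s
        }
        # admixture pulse from HOST at this generation?
        from_host <- rep(FALSE, n)
        for (pl in pulses) {
          if (pl$target == config$pop_labels[k] && pl$time == t)
            from_host <- stats::runif(n) < pl$fraction
        }
        G_new <- matrix(0L, n, L, dimnames = list(NULL, config$loci))
        lab_new <- character(n)
        for (s in unique(src)) {
          rows <- which(src == s & !from_host)
          if (length(rows) > 0) {
            par <- sample.int(nrow(demes[[s]]$G), length(rows),
                              replace = TRUE)
            G_new[rows, ] <- demes[[s]]$G[par, , drop = FALSE]
            lab_new[rows] <- demes[[s]]$lab[par]
            if (s != k) mig_counts[s, k] <- mig_counts[s, k] + length(rows)
          }
        }
        if (any(from_host)) {
          rows <- which(from_host)
          par <- sample.int(nrow(host$G), length(rows), replace = TRUE)
          G_new[rows, ] <- host$G[par, , drop = FALSE]
          lab_new[rows] <- host$lab[par]
        }
        demes[[k]] <- list(G = .mutate(G_new, config$mu,
                                       config$range_constraint),
                           lab = lab_new)
      }
    }
    samp_G <- NULL; samp_lab <- NULL; samp_pop <- NULL
    for (k in seq_len(P)) {
      ns <- config$sample_sizes[k]
      if (ns > nrow(demes[[k]]$G)) stop("sample size exceeds deme size")
      pick <- sample.int(nrow(demes[[k]]$G), ns)
      samp_G <- rbind(samp_G, demes[[k]]$G[pick, , drop = FALSE])
      samp_lab <- c(samp_lab, demes[[k]]$lab[pick])
      samp_pop <- c(samp_pop, rep(config$pop_labels[k], ns))
    }
  }

  ds <- .units_to_dataset(samp_G, samp_pop, config$loci,
                          provenance = paste0("simulated:", config$model))
  truth <- list(
    founder_depth = stats::setNames(
      rep(if (config$model == "PANMIXIA") 0 else split_time, P),
      config$pop_labels),
    realized_migrants = mig_counts,
    haplogroup_labels = stats::setNames(samp_lab, ds$tab$sample_id),
    scenario = config
  )
  list(dataset = ds, truth = truth)
}

## Convert an internal unit matrix to a ystr_dataset (DYS389II = I + ext;
## region set when the deme labels are region names).
.units_to_dataset <- function(G, pop, loci, provenance) {
  tab <- as.data.frame(G)
  if (all(c("DYS389I", "DYS389II") %in% loci))
    tab$DYS389II <- tab$DYS389II + tab$DYS389I
  tab$sample_id <- sprintf("%s_%03d", pop,
                           stats::ave(seq_along(pop), pop,
                                      FUN = seq_along))
  tab$population <- pop
  tab$region <- ifelse(pop %in% REGIONS, pop, NA_character_)
  panel <- if (identical(sort(loci), sort(YFILER17))) yfiler_panel()
           else marker_panel("custom", loci)
  ystr_dataset(tab, panel, provenance = provenance)
}

#' Star-genealogy founder simulation
#'
#' Every sampled lineage descends independently from a single founder
#' exactly `depth` generations back (a star genealogy): the fixture for
#' TMRCA-estimator recovery. Per lineage and locus the number of mutations
#' is Binomial(depth, mu), each mutation stepping +1 or -1 with equal
#' probability.
#'
#' @param n number of sampled lineages.
#' @param depth generations since the founder.
#' @param mu per-locus mutation rate per generation.
#' @param loci locus names (default: the 17 Yfiler units, so the RHO view
#'   retains 15 loci).
#' @param seed RNG seed.
#' @return List with `dataset` (a [ystr_dataset()], one population
#'   "STAR"), and `truth` (`tmrca = depth`, the founder haplotype).
#' @export
founder_star <- function(n, depth, mu = 2.5e-3,
                         loci = names(FOUNDER_UNITS), seed = 1L) {
  stopifnot(depth >= 0, n >= 1)
  set.seed(seed)
  L <- length(loci)
  founder <- if (all(loci %in% names(FOUNDER_UNITS)))
    FOUNDER_UNITS[loci] else stats::setNames(rep(15, L), loci)
  muts <- stats::rbinom(n * L, depth, mu)
  net <- 2L * stats::rbinom(n * L, muts, 0.5) - muts
  G <- matrix(rep(founder, each = n) + net, n, L,
              dimnames = list(NULL, loci))
  ds <- .units_to_dataset(G, rep("STAR", n), loci,
                          provenance = "simulated:founder_star")
  list(dataset = ds,
       truth = list(tmrca = depth, founder = founder, mu = mu))
}
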