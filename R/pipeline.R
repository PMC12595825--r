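#' Run the full Y-STR analysis pipeline
#'
#' Orchestrates the standard analysis sequence on a haplotype dataset:
#' allele rounding, view construction, optional haplogroup prediction,
#' per-population diversity, pairwise R_ST with migration-rate conversion,
#' AMOVA, nonmetric MDS, the median-joining network, and rho-based TMRCA.
#' Every stage output is written under `out_dir` along with a JSON manifest
#' recording inputs, settings, seeds and per-stage output files; any stage
#' failure aborts with a stage-named error.
#'
#' This function (together with the exported per-stage functions) is the
#' package's command-line surface: each stage can equally be driven from
#' `Rscript -e` against a saved table.
#'
#' @param ds a [ystr_dataset()] or path to a haplotype table readable by
#'   [read_haplotype_table()].
#' @param out_dir output directory (created if needed).
#' @param freq_table optional [build_frequency_table()] for haplogroup
#'   prediction; NULL skips the prediction stage.
#' @param grouping optional population-to-group map for a two-level AMOVA
#'   and the Arlequin export.
#' @param permutations permutation count for R_ST and AMOVA.
#' @param bootstrap bootstrap replicates for diversity intervals.
#' @param rates a [mutation_rates()] configuration for TMRCA.
#' @param epsilon median-joining tolerance.
#' @param seed seed used for every stochastic stage.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(ds, out_dir, freq_table = NULL, grouping = NULL,
                         permutations = 1000, bootstrap = 1000,
                         rates = mutation_rates(), epsilon = 0,
                         seed = 1L) {
  if (is.character(ds)) ds <- read_haplotype_table(ds)
  stopifnot(inherits(ds, "ystr_dataset"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "ystrpop",
                   version = as.character(utils::packageVersion("ystrpop")),
                   seed = seed, permutations = permutations,
                   bootstrap = bootstrap, provenance = ds$provenance,
                   n = n_haplotypes(ds), started = format(Sys.time()),
                   stages = list())
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    res
  }
  note <- function(name, files) {
    manifest$stages[[name]] <<- list(outputs = files)
  }

  ds <- stage("round", round_intermediate_alleles(ds))
  f_tab <- file.path(out_dir, "haplotypes.tsv")
  write_haplotype_table(ds, f_tab)
  note("read_round", f_tab)

  f_arp <- file.path(out_dir, "haplotypes.arp")
  stage("export_arp", write_arlequin_arp(ds, f_arp, grouping = grouping))
  note("export_arp", f_arp)

  vdist <- stage("views", make_view(ds, "DISTANCE"))
  vnet <- make_view(ds, "NETWORK")
  vrho <- make_view(ds, "RHO")

  if (!is.null(freq_table)) {
    pred <- stage("predict", predict_dataset(ds, freq_table))
    f_pred <- file.path(out_dir, "predictions.tsv")
    utils::write.table(pred$predictions, f_pred, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    note("predict", f_pred)
  }

  pops <- unique(ds$tab$population)
  div <- stage("diversity", {
    do.call(rbind, lapply(pops, function(p) {
      n_p <- sum(ds$tab$population == p)
      if (n_p < 2) return(NULL)
      d <- bootstrap_hd_ci(vdist, p, replicates = bootstrap, seed = seed)
      data.frame(population = p, n = d$n, k = d$k, hd = d$hd,
                 ci_low = d$ci_low, ci_high = d$ci_high, seed = seed)
    }))
  })
  f_div <- file.path(out_dir, "diversity.tsv")
  utils::write.table(div, f_div, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  note("diversity", f_div)

  results <- list()
  if (length(pops) >= 2) {
    rst <- stage("rst", pairwise_rst(vdist, permutations = permutations,
                                     seed = seed))
    m <- migration_rate(rst)
    f_rst <- file.path(out_dir, "rst_matrix.tsv")
    long <- do.call(rbind, lapply(seq_along(rst$labels)[-1], function(j)
      do.call(rbind, lapply(seq_len(j - 1), function(i)
        data.frame(popA = rst$labels[i], popB = rst$labels[j],
                   RST = rst$values[i, j], p = rst$pvalues[i, j],
                   M = m$values[i, j], seed = seed)))))
    utils::write.table(long, f_rst, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    note("rst", f_rst)
    results$rst <- rst

    am <- stage("amova", amova(vdist, groups = grouping,
                               permutations = permutations, seed = seed))
    f_am <- file.path(out_dir, "amova.json")
    jsonlite::write_json(
      list(design = am$design, rows = am$rows, phi = as.list(am$phi),
           pvalues = as.list(am$pvalues), permutations = permutations,
           seed = seed),
      f_am, auto_unbox = TRUE, digits = NA)
    note("amova", f_am)
    results$amova <- am

    if (length(rst$labels) >= 3) {
      mds <- stage("mds", nmds_embed(rst, seed = seed))
      f_mds <- file.path(out_dir, "mds_coordinates.tsv")
      con <- file(f_mds, "w")
      writeLines(sprintf("# stress = %.6f; seed = %d", mds$stress, seed),
                 con)
      utils::write.table(
        data.frame(label = rownames(mds$coordinates), mds$coordinates),
        con, sep = "\t", quote = FALSE, row.names = FALSE)
      close(con)
      note("mds", f_mds)
      results$mds <- mds
    }
  }

  net <- stage("network", {
    wts <- compute_weights(vnet)
    mp_prune(median_joining(vnet, wts, epsilon = epsilon))
  })
  f_net <- file.path(out_dir, "network.graphml")
  export_graph(net, f_net)
  note("network", f_net)
  results$network <- net

  tm <- stage("tmrca", tmrca(vrho, rates = rates))
  f_tm <- file.path(out_dir, "tmrca.json")
  jsonlite::write_json(
    list(rho = tm$rho, se_rho = tm$se_rho,
         tmrca_generations = tm$tmrca_generations,
         tmrca_years = tm$tmrca_years, n = tm$n, loci = tm$loci,
         mode = tm$mode, generation_years = tm$generation_years,
         root = as.list(tm$root)),
    f_tm, auto_unbox = TRUE, digits = NA)
  note("tmrca", f_tm)
  results$tmrca <- tm

  manifest$finished <- format(Sys.time())
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(manifest, results))
}
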