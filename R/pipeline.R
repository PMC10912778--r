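# End-to-end orchestration: one configuration drives
# simulate/load -> normalize -> GRN inference -> structure -> DGE/profiles ->
# NEAT -> cleavage -> target tracing -> FDGENEA, writing every table under
# one artifact directory with a manifest.

#' Pipeline configuration
#'
#' Either a synthetic block (a [sim_config()]) or a set of input paths must
#' be given, never both. Stage parameters default to the study's reporting
#' conventions: top-10 inbound edges, 1000 trees, spline df 3, profile gate
#' q < 0.1, NEAT and FDGENEA FDR 0.01, 5 SLC categories, 10 PCs, Pearson
#' residual threshold 4.
#'
#' @param synthetic a [sim_config()] or NULL.
#' @param paths named list (expression, samples, regulators, fasta, sites,
#'   traits) or NULL.
#' @param seed global seed; per-stage child seeds are derived from it.
#' @param outdir artifact directory.
#' @param k,n_trees,spline_df,q_profiles,q_traits,neat_fdr,slc_k,n_pcs,residual_threshold
#'   stage parameters.
#' @param wt,mut,oex genotype names used for the three profile contrasts.
#' @param timecourse_genotypes genotypes whose samples define the
#'   time-course correlation set for edge signs (wild type plus the
#'   protease deletion mutants; the overexpressor is excluded because
#'   strong attenuation suppresses the regulator-target covariation the
#'   sign is read from).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = sim_config(), paths = NULL,
                            seed = 1, outdir = tempfile("calpain_run_"),
                            k = 10, n_trees = 1000, spline_df = 3,
                            q_profiles = 0.1, q_traits = 0.01,
                            neat_fdr = 0.01, slc_k = 5, n_pcs = 10,
                            residual_threshold = 4,
                            wt = "WT", mut = "dek1", oex = "oex1",
                            timecourse_genotypes = c("WT", "dek1",
                                                     "dek1_loop",
                                                     "dek1_lg3")) {
  .assert(xor(is.null(synthetic), is.null(paths)),
          "exactly one of synthetic / paths must be given")
  if (!is.null(synthetic))
    .assert(inherits(synthetic, "sim_config"), "synthetic must be a sim_config")
  for (q in c(q_profiles, q_traits, neat_fdr))
    .assert(q > 0 && q < 1, "thresholds must lie in (0, 1)")
  structure(list(synthetic = synthetic, paths = paths, seed = seed,
                 outdir = outdir, k = k, n_trees = n_trees,
                 spline_df = spline_df, q_profiles = q_profiles,
                 q_traits = q_traits, neat_fdr = neat_fdr, slc_k = slc_k,
                 n_pcs = n_pcs, residual_threshold = residual_threshold,
                 wt = wt, mut = mut, oex = oex,
                 timecourse_genotypes = timecourse_genotypes),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes all stages in order on synthetic or loaded data, writes every
#' table as TSV (plus GraphML networks, a FASTA proteome and a JSON ground
#' truth for synthetic runs) under `config$outdir`, and records a manifest
#' with per-stage seeds, input hashes and runtimes. Any stage failure aborts
#' with a stage-tagged error; partial outputs are retained.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return (invisibly) list of class `pipeline_result` with all in-memory
#'   stage results and `outdir`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  .assert(inherits(config, "pipeline_config"), "config must be a pipeline_config")
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$outdir, "pipeline.log")
  manifest <- list()
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    cat(msg, "\n", file = log_path, append = TRUE)
    if (!quiet) message(msg)
  }
  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    manifest[[name]] <<- list(stage = name,
                              seed = .stage_seed(config$seed, name),
                              runtime_s = round(proc.time()[["elapsed"]] - t0,
                                                3))
    say("stage ", name, " done (",
        manifest[[name]]$runtime_s, "s)")
    out
  }
  res <- list(config = config, outdir = config$outdir)

  if (!is.null(config$synthetic)) {
    sim_cfg <- config$synthetic
    sim <- stage("simulate", function() simulate_dataset(sim_cfg))
    res$truth <- sim$truth
    expr <- sim$expr
    regulators <- sim$truth$tf_ids
    proteome <- sim$proteome
    traits <- sim$traits
    write_tsv(data.frame(gene = rownames(expr$values), expr$values,
                         check.names = FALSE),
              file.path(config$outdir, "expression.tsv"))
    write_tsv(expr$samples, file.path(config$outdir, "samples.tsv"))
    write_tsv(data.frame(gene = regulators, class = "TF"),
              file.path(config$outdir, "regulators.tsv"))
    write_fasta(proteome$sequences,
                file.path(config$outdir, "proteome.fasta"))
    write_tsv(proteome$sites, file.path(config$outdir, "sites.tsv"))
    write_tsv(traits, file.path(config$outdir, "traits.tsv"))
    jsonlite::write_json(
      list(edges = sim$truth$edges,
           cleaved = as.list(sim$truth$cleaved),
           planted_profile = as.list(sim$truth$planted_profile),
           trait_truth = sim$truth$trait_truth),
      file.path(config$outdir, "ground_truth.json"), auto_unbox = TRUE)
    cfg_echo <- sim_cfg
    cfg_echo$trait_genotype_map <- lapply(cfg_echo$trait_genotype_map, I)
    yaml::write_yaml(unclass(cfg_echo),
                     file.path(config$outdir, "config.yaml"))
  } else {
    p <- config$paths
    raw <- stage("load", function() {
      tab <- read_tsv(p$expression)
      m <- as.matrix(tab[, -1, drop = FALSE])
      rownames(m) <- tab[[1]]
      m
    })
    samples <- read_tsv(p$samples)
    expr <- normalize_expression(raw, samples)
    regulators <- read_tsv(p$regulators)$gene
    proteome <- list(sequences = read_fasta(p$fasta),
                     sites = read_tsv(p$sites))
    traits <- if (!is.null(p$traits)) read_tsv(p$traits) else NULL
  }

  tc_geno <- intersect(config$timecourse_genotypes,
                       unique(expr$samples$genotype))
  if (length(tc_geno) == 0) tc_geno <- NULL
  net <- stage("grn", function()
    infer_grn(expr, regulators, k = config$k, n_trees = config$n_trees,
              seed = .stage_seed(config$seed, "grn"),
              column_sets = default_column_sets(expr$samples, tc_geno)))
  write_tsv(net$edges, file.path(config$outdir, "network.tsv"))

  partition <- stage("structure", function()
    detect_communities(net, seed = .stage_seed(config$seed, "structure")))
  centr <- local_reaching_centrality(net)
  hier <- rank_regulators(partition, centr)
  write_tsv(as.data.frame(partition),
            file.path(config$outdir, "partition.tsv"))
  write_tsv(hier, file.path(config$outdir, "hierarchy.tsv"))
  inter <- tryCatch(
    interconnection_analysis(net, partition, config$residual_threshold),
    error = function(e) NULL)
  if (!is.null(inter))
    write_tsv(inter$enriched,
              file.path(config$outdir, "interconnections.tsv"))
  write_network_graphml(net, file.path(config$outdir, "network.graphml"),
                        partition = partition)

  dge <- stage("dge", function() {
    list(mut_wt = timecourse_dge(expr, c(config$wt, config$mut),
                                 config$spline_df),
         oex_wt = timecourse_dge(expr, c(config$wt, config$oex),
                                 config$spline_df),
         mut_oex = timecourse_dge(expr, c(config$oex, config$mut),
                                  config$spline_df))
  })
  profiles_tab <- classify_profiles(dge$mut_wt, dge$oex_wt, dge$mut_oex,
                                    wt = config$wt, mut = config$mut,
                                    oex = config$oex,
                                    q_max = config$q_profiles)
  cum <- cumulative_misregulation(dge$mut_wt, dge$oex_wt, dge$mut_oex)
  profiles_tab$cumulative_effect <- unname(cum[profiles_tab$gene])
  for (nm in names(dge))
    write_tsv(dge[[nm]], file.path(config$outdir,
                                   paste0("dge_", nm, ".tsv")))
  write_tsv(profiles_tab, file.path(config$outdir, "profiles.tsv"))

  profiles <- stats::setNames(profiles_tab$profile, profiles_tab$gene)
  deg_sets <- list(
    activator_targets =
      profiles_tab$gene[profiles_tab$profile == "activator-target"],
    repressor_targets =
      profiles_tab$gene[profiles_tab$profile == "repressor-target"])
  deg_sets$upstream_unchanged_tfs <-
    upstream_unchanged_tfs(net, unlist(deg_sets[1:2]), profiles)
  neat <- stage("neat", function()
    neat_batch(net, deg_sets, partition, fdr = config$neat_fdr))
  write_tsv(neat$table, file.path(config$outdir, "neat.tsv"))

  cleav <- stage("cleavage", function()
    cleavage_profiles(proteome$sites, proteome$sequences,
                      k = config$slc_k, n_pcs = config$n_pcs,
                      seed = .stage_seed(config$seed, "cleavage")))
  write_tsv(cleav, file.path(config$outdir, "cleavage_profiles.tsv"))
  nerd_like <- stats::setNames(cleav$nerd_like, cleav$protein)

  targets <- stage("targets", function()
    filter_dek1_targets(net, nerd_like, profiles, partition))
  write_tsv(targets$edges, file.path(config$outdir, "target_edges.tsv"))
  write_tsv(data.frame(
    gene = c(targets$direct_targets, targets$indirect_targets),
    type = c(rep("direct", length(targets$direct_targets)),
             rep("indirect", length(targets$indirect_targets)))),
    file.path(config$outdir, "target_calls.tsv"))
  regulons <- stage("regulons", function()
    regulon_table(net, nerd_like = nerd_like, profiles = profiles,
                  regulators = regulators))
  write_tsv(regulons, file.path(config$outdir, "regulons.tsv"))

  fdg <- NULL
  if (!is.null(traits)) {
    trait_names <- setdiff(names(traits), "sample")
    usable <- trait_names[vapply(trait_names, function(tr)
      length(unique(traits[[tr]])) == 2, TRUE)]
    fdg <- stage("fdgenea", function()
      stats::setNames(lapply(usable, function(tr)
        fdgenea(expr, tr, traits, net, partition,
                q_max = config$q_traits, fdr = config$neat_fdr,
                regulators = regulators)), usable))
    for (tr in names(fdg)) {
      write_tsv(fdg[[tr]]$association,
                file.path(config$outdir,
                          paste0("fdgenea_", tr, "_association.tsv")))
      write_tsv(fdg[[tr]]$neat$combined$table,
                file.path(config$outdir,
                          paste0("fdgenea_", tr, "_neat.tsv")))
      if (length(fdg[[tr]]$node_stats))
        write_tsv(do.call(rbind, fdg[[tr]]$node_stats),
                  file.path(config$outdir,
                            paste0("fdgenea_", tr, "_node_stats.tsv")))
      for (cmp in fdg[[tr]]$components)
        write_network_graphml(
          cmp$edges,
          file.path(config$outdir,
                    sprintf("fdgenea_%s_component_%02d.graphml", tr,
                            cmp$id)))
    }
  }

  files <- sort(setdiff(list.files(config$outdir),
                        c("manifest.json", "pipeline.log")))
  hashes <- as.list(tools::md5sum(file.path(config$outdir, files)))
  names(hashes) <- files
  jsonlite::write_json(list(seed = config$seed, stages = manifest,
                            files = hashes),
                       file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("pipeline complete: ", length(files), " artifact file(s)")

  res <- c(res, list(expr = expr, network = net, partition = partition,
                     hierarchy = hier, interconnections = inter,
                     dge = dge, profiles = profiles_tab, neat = neat,
                     cleavage = cleav, targets = targets,
                     regulons = regulons, fdgenea = fdg))
  class(res) <- "pipeline_result"
  invisible(res)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline run:", x$outdir, "\n")
  print(x$network)
  cat(sprintf("  %d subnetworks (modularity %.3f)\n",
              length(unique(x$partition$subnetwork)),
              attr(x$partition, "modularity")))
  cat(sprintf("  profiles: %d activator-target, %d repressor-target\n",
              sum(x$profiles$profile == "activator-target"),
              sum(x$profiles$profile == "repressor-target")))
  print(x$targets)
  invisible(x)
}
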