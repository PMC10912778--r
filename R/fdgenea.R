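# FDGENEA: factorial differential gene expression network enrichment
# analysis. Binary phenotypic traits are mapped to associated genes
# (trait-wise spline-LRT differential expression), to enriched subnetworks
# (NEAT), and to isolated regulatory subgraphs with cumulative signed
# effect-size statistics per node.

#' Encode phenotype observations as a binary trait matrix
#'
#' Expands a trait -> genotype-set map to sample-level logical columns.
#' Constant columns (all TRUE or all FALSE) carry no contrast and are
#' flagged unusable for testing.
#'
#' @param trait_genotype_map named list: trait -> genotype names with value
#'   `TRUE`.
#' @param samples sample sheet (needs `sample` and `genotype`).
#' @return data.frame with `sample` plus one logical column per trait; the
#'   attribute `degenerate` names the constant columns.
#' @export
encode_traits <- function(trait_genotype_map, samples) {
  .assert(is.list(trait_genotype_map) && !is.null(names(trait_genotype_map)),
          "trait_genotype_map must be a named list")
  out <- data.frame(sample = samples$sample, stringsAsFactors = FALSE)
  degenerate <- character()
  for (tr in names(trait_genotype_map)) {
    gset <- trait_genotype_map[[tr]]
    unknown <- setdiff(gset, unique(samples$genotype))
    .assert(length(unknown) == 0,
            paste("unknown genotype(s) for trait", tr, ":",
                  paste(unknown, collapse = ", ")))
    v <- samples$genotype %in% gset
    if (length(unique(v)) < 2) degenerate <- c(degenerate, tr)
    out[[tr]] <- v
  }
  attr(out, "degenerate") <- degenerate
  out
}

#' Trait-wise differential expression
#'
#' Shares the spline-LRT engine of [timecourse_dge()], with the binary trait
#' indicator replacing the genotype contrast: null model is the spline of
#' day, full model adds the trait. `b > 0` means higher expression in
#' trait-TRUE samples. Directions are called at `q_max` (default 0.01).
#'
#' @param expr an [expression_dataset()].
#' @param trait logical vector along the samples (or a trait name present in
#'   `traits`).
#' @param traits optional trait table from [encode_traits()].
#' @param spline_df time-basis degrees of freedom.
#' @param q_max significance threshold for the `direction` calls.
#' @return data.frame (class `trait_association`): gene, lrt_stat, p, q, b,
#'   direction in {up, down, ns}.
#' @export
trait_dge <- function(expr, trait, traits = NULL, spline_df = 3,
                      q_max = 0.01) {
  if (is.character(trait)) {
    .assert(!is.null(traits) && trait %in% names(traits),
            paste("trait", trait, "not found in traits table"))
    nm <- trait
    trait <- traits[[trait]][match(expr$samples$sample, traits$sample)]
  } else nm <- "trait"
  .assert(length(trait) == ncol(expr$values),
          "trait must align with the samples")
  .assert(sum(trait) >= 2 && sum(!trait) >= 2,
          "both trait levels need >= 2 samples")
  res <- .fit_lrt(expr$values, expr$samples$day, trait, spline_df)
  res$q <- bh_adjust(res$p)
  res$direction <- ifelse(res$q < q_max, ifelse(res$b > 0, "up", "down"),
                          "ns")
  res <- res[, c("gene", "lrt_stat", "p", "q", "b", "direction")]
  attr(res, "trait") <- nm
  attr(res, "q_max") <- q_max
  class(res) <- c("trait_association", "data.frame")
  res
}

#' @export
print.trait_association <- function(x, ...) {
  cat(sprintf("Trait association '%s': %d genes, %d up, %d down (q < %g)\n",
              attr(x, "trait"), nrow(x), sum(x$direction == "up"),
              sum(x$direction == "down"), attr(x, "q_max")))
  invisible(x)
}

#' Trait network enrichment (three NEAT runs)
#'
#' Runs NEAT for the positively associated set, the negatively associated
#' set and their union against all subnetworks, BH-adjusted within each run.
#' The combined run drives the heatmap; the directional runs provide the
#' "+" / "-" cell annotations.
#'
#' @param assoc a [trait_dge()] result.
#' @param network a `grn_network` or edge data.frame.
#' @param partition a [detect_communities()] result.
#' @param fdr NEAT call threshold (default 0.01).
#' @return list of class `trait_neat`: `up`, `down`, `combined`
#'   ([neat_batch()] results) and `annotations` (subnetwork, up, down,
#'   combined_call, annotation).
#' @export
trait_network_enrichment <- function(assoc, network, partition, fdr = 0.01) {
  tr <- attr(assoc, "trait")
  sets <- list(up = assoc$gene[assoc$direction == "up"],
               down = assoc$gene[assoc$direction == "down"])
  sets$combined <- union(sets$up, sets$down)
  run <- function(set, label) {
    gs <- stats::setNames(list(set), label)
    neat_batch(network, gs, partition, fdr = fdr)
  }
  up <- run(sets$up, paste0(tr, "_up"))
  down <- run(sets$down, paste0(tr, "_down"))
  combined <- run(sets$combined, tr)
  subs <- unique(partition$subnetwork)
  ann <- data.frame(subnetwork = subs,
                    up = up$table$call[match(subs, up$table$setB)],
                    down = down$table$call[match(subs, down$table$setB)],
                    combined_call =
                      combined$table$call[match(subs, combined$table$setB)])
  ann$annotation <- paste0(ifelse(ann$up == "+", "+", ""),
                           ifelse(ann$down == "+", "-", ""))
  structure(list(up = up, down = down, combined = combined,
                 annotations = ann, trait = tr),
            class = "trait_neat")
}

#' Isolate trait-associated subgraphs
#'
#' Induces the subgraph on significantly associated genes plus their direct
#' upstream regulators (attached even when themselves not significant) and
#' extracts weakly connected components. Per component, regulators
#' controlling at least two associated genes are reported as common
#' upstream TFs.
#'
#' @param network a `grn_network` or edge data.frame.
#' @param assoc a [trait_dge()] result.
#' @param q_max significance threshold (default 0.01).
#' @return list of class `fdgenea_components`; each element has `id`,
#'   `nodes`, `sig_genes`, `regulators_attached`, `common_upstream`,
#'   `edges`.
#' @export
isolate_components <- function(network, assoc, q_max = 0.01) {
  edges <- .edge_df(network)
  nodes_all <- unique(c(edges$regulator, edges$target))
  sig <- intersect(assoc$gene[assoc$q < q_max], nodes_all)
  if (length(sig) == 0)
    return(structure(list(), class = "fdgenea_components",
                     trait = attr(assoc, "trait")))
  ups <- unique(edges$regulator[edges$target %in% sig])
  nodes <- union(sig, ups)
  sub <- edges[edges$regulator %in% nodes & edges$target %in% nodes, ,
               drop = FALSE]
  g <- igraph::graph_from_data_frame(sub[, c("regulator", "target")],
                                     directed = TRUE,
                                     vertices = data.frame(name = nodes))
  comp <- igraph::components(g, mode = "weak")
  ord <- order(-comp$csize)
  out <- vector("list", comp$no)
  for (i in seq_len(comp$no)) {
    cid <- ord[i]
    members <- names(comp$membership)[comp$membership == cid]
    cedges <- sub[sub$regulator %in% members & sub$target %in% members, ,
                  drop = FALSE]
    csig <- intersect(members, sig)
    to_sig <- cedges[cedges$target %in% csig, , drop = FALSE]
    common <- sort(names(which(table(unique(
      to_sig[, c("regulator", "target")])$regulator) >= 2)))
    out[[i]] <- list(id = i, nodes = sort(members), sig_genes = sort(csig),
                     regulators_attached = sort(setdiff(members, sig)),
                     common_upstream = common, edges = cedges)
  }
  structure(out, class = "fdgenea_components", trait = attr(assoc, "trait"))
}

#' @export
print.fdgenea_components <- function(x, ...) {
  cat(sprintf("FDGENEA components for trait '%s': %d component(s)\n",
              attr(x, "trait"), length(x)))
  for (cmp in x)
    cat(sprintf("  #%d: %d nodes (%d significant), %d common upstream TF(s)\n",
                cmp$id, length(cmp$nodes), length(cmp$sig_genes),
                length(cmp$common_upstream)))
  invisible(x)
}

#' Cumulative node statistics within a component
#'
#' Per node, the signed effect is s = sign(b) * lrt_stat for significant
#' genes and 0 otherwise. Cumulative sums are taken over two downstream
#' scopes inside the component: direct targets (first-order) and all
#' reachable genes (total, visited-set, focal node excluded). `cb_*` sums
#' the signed effects, `cab_*` their absolute values; downstream regulator
#' and TF counts are recorded for both scopes.
#'
#' @param component one element of [isolate_components()].
#' @param assoc the [trait_dge()] result that produced the components.
#' @param regulators character vector of regulator ids (for downstream
#'   regulator counts); TFs are the regulators present as edge sources.
#' @param q_max significance threshold matching the isolation step.
#' @return data.frame, one row per component node: gene, s, cb_first,
#'   cab_first, cb_total, cab_total, n_down_first, n_down_total,
#'   n_down_regulators_first, n_down_regulators_total, n_down_tfs_first,
#'   n_down_tfs_total.
#' @export
node_stats <- function(component, assoc, regulators = NULL, q_max = 0.01) {
  edges <- component$edges
  nodes <- component$nodes
  s <- stats::setNames(rep(0, length(nodes)), nodes)
  idx <- match(nodes, assoc$gene)
  ok <- !is.na(idx) & assoc$q[idx] < q_max
  s[ok] <- sign(assoc$b[idx[ok]]) * assoc$lrt_stat[idx[ok]]
  if (is.null(regulators)) regulators <- unique(edges$regulator)
  children <- split(edges$target, edges$regulator)
  rows <- lapply(nodes, function(v) {
    first <- setdiff(unique(children[[v]]), v)
    total <- character()
    frontier <- first
    seen <- v
    while (length(frontier)) {
      seen <- c(seen, frontier)
      total <- union(total, frontier)
      frontier <- setdiff(unique(unlist(children[frontier],
                                        use.names = FALSE)), seen)
    }
    data.frame(gene = v, s = s[[v]],
               cb_first = sum(s[first]), cab_first = sum(abs(s[first])),
               cb_total = sum(s[total]), cab_total = sum(abs(s[total])),
               n_down_first = length(first), n_down_total = length(total),
               n_down_regulators_first = sum(first %in% regulators),
               n_down_regulators_total = sum(total %in% regulators),
               n_down_tfs_first = sum(first %in% regulators),
               n_down_tfs_total = sum(total %in% regulators))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full FDGENEA for one trait
#'
#' Convenience wrapper: trait DGE, the three NEAT runs, component isolation
#' and node statistics.
#'
#' @param expr an [expression_dataset()].
#' @param trait trait name or logical vector, see [trait_dge()].
#' @param traits trait table from [encode_traits()].
#' @param network a `grn_network` or edge data.frame.
#' @param partition a [detect_communities()] result.
#' @param q_max association significance threshold (default 0.01).
#' @param fdr NEAT call threshold (default 0.01).
#' @param regulators regulator universe for node statistics.
#' @return list of class `fdgenea_result`: `association`, `neat`,
#'   `components`, `node_stats` (one data.frame per component).
#' @export
fdgenea <- function(expr, trait, traits = NULL, network, partition,
                    q_max = 0.01, fdr = 0.01, regulators = NULL) {
  assoc <- trait_dge(expr, trait, traits, q_max = q_max)
  nt <- trait_network_enrichment(assoc, network, partition, fdr = fdr)
  comps <- isolate_components(network, assoc, q_max = q_max)
  stats_list <- lapply(comps, node_stats, assoc = assoc,
                       regulators = regulators, q_max = q_max)
  structure(list(association = assoc, neat = nt, components = comps,
                 node_stats = stats_list),
            class = "fdgenea_result")
}

#' @export
print.fdgenea_result <- function(x, ...) {
  print(x$association)
  print(x$components)
  invisible(x)
}
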