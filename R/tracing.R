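# Upstream regulon tracing: quantify direct (cleaved-TF) vs indirect
# (misregulated-TF) protease control of every gene, the dependency of target
# misregulation on regulon composition, and the final direct/indirect target
# filter.

# Reverse adjacency restricted to regulator nodes: target -> its direct
# regulator parents.
.parent_map <- function(edges, regulators = NULL) {
  if (!is.null(regulators))
    edges <- edges[edges$regulator %in% regulators, , drop = FALSE]
  split(edges$regulator, edges$target)
}

#' Upstream regulon of one gene
#'
#' Breadth-first traversal along reversed regulatory edges up to
#' `max_order` steps (TF3 -> TF2 -> TF1 -> gene), restricted to regulator
#' nodes. Cycles are handled with a visited set and the focal gene is
#' excluded from its own regulon. Returned sets are cumulative:
#' order k holds all regulators within k steps.
#'
#' @param network a `grn_network` or edge data.frame.
#' @param gene focal gene id (must be a network node).
#' @param max_order traversal depth (default 3).
#' @param regulators regulator universe; defaults to all edge sources.
#' @return list of `max_order` character vectors (cumulative TF sets).
#' @export
upstream_regulon <- function(network, gene, max_order = 3,
                             regulators = NULL) {
  edges <- .edge_df(network)
  nodes <- unique(c(edges$regulator, edges$target))
  .assert(gene %in% nodes, paste("gene", gene, "not in network"))
  pm <- .parent_map(edges, regulators)
  orders <- vector("list", max_order)
  seen <- character()
  frontier <- gene
  for (k in seq_len(max_order)) {
    frontier <- setdiff(unique(unlist(pm[frontier], use.names = FALSE)),
                        c(seen, gene))
    seen <- c(seen, frontier)
    orders[[k]] <- sort(seen)
    if (length(frontier) == 0) {
      for (j in seq_len(max_order)) if (j > k) orders[[j]] <- orders[[k]]
      break
    }
  }
  names(orders) <- paste0("order", seq_len(max_order))
  orders
}

#' Control fractions of a regulon
#'
#' Fractions of the (order-3) upstream TF set that are direct protease
#' targets (NERD-like cleavage pattern), indirect targets (misregulated
#' profile), or either. An empty regulon yields `NA` fractions with a flag.
#'
#' @param regulon character vector of upstream TF ids.
#' @param nerd_like named logical: protein has a NERD-like cleavage pattern.
#' @param profiles named character of misregulation profiles
#'   (`"none"` = unchanged).
#' @return one-row data.frame: n_tfs, pct_direct, pct_indirect, pct_either,
#'   flagged.
#' @export
regulon_control_fractions <- function(regulon, nerd_like, profiles) {
  if (length(regulon) == 0)
    return(data.frame(n_tfs = 0L, pct_direct = NA_real_,
                      pct_indirect = NA_real_, pct_either = NA_real_,
                      flagged = TRUE))
  direct <- nerd_like[regulon]
  direct[is.na(direct)] <- FALSE
  indirect <- profiles[regulon] != "none"
  indirect[is.na(indirect)] <- FALSE
  data.frame(n_tfs = length(regulon),
             pct_direct = mean(direct),
             pct_indirect = mean(indirect),
             pct_either = mean(direct | indirect),
             flagged = FALSE)
}

#' Regulon table for a set of genes
#'
#' Batch computation of upstream regulons (orders 1..3) and their control
#' fractions.
#'
#' @param network a `grn_network` or edge data.frame.
#' @param genes focal genes; default all network nodes.
#' @param nerd_like,profiles see [regulon_control_fractions()].
#' @param max_order traversal depth.
#' @param regulators regulator universe; defaults to all edge sources.
#' @return data.frame: gene, n_order1..n_order3, pct_direct, pct_indirect,
#'   pct_either, flagged.
#' @export
regulon_table <- function(network, genes = NULL, nerd_like, profiles,
                          max_order = 3, regulators = NULL) {
  edges <- .edge_df(network)
  nodes <- unique(c(edges$regulator, edges$target))
  if (is.null(genes)) genes <- sort(nodes)
  rows <- lapply(genes, function(g) {
    reg <- upstream_regulon(edges, g, max_order, regulators)
    fr <- regulon_control_fractions(reg[[max_order]], nerd_like, profiles)
    sizes <- as.data.frame(as.list(lengths(reg)))
    names(sizes) <- paste0("n_", names(reg))
    cbind(data.frame(gene = g), sizes, fr)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Dependency of misregulation on regulon control
#'
#' Regresses cumulative misregulation scores on each regulon control
#' fraction and reports Kendall and Pearson correlation tests, optionally
#' per subnetwork. Genes with undefined (flagged) fractions are dropped.
#'
#' @param regulons a [regulon_table()] result.
#' @param scores named numeric, cumulative misregulation per gene.
#' @param partition optional [detect_communities()] result for
#'   per-subnetwork slopes.
#' @return list of class `misregulation_dependency`: `overall` (data.frame
#'   per predictor: slope, kendall_tau, kendall_p, pearson_r, pearson_p,
#'   n), `by_subnetwork` (or NULL).
#' @export
misregulation_dependency <- function(regulons, scores, partition = NULL) {
  tab <- regulons[!regulons$flagged & regulons$gene %in% names(scores), ]
  .assert(nrow(tab) >= 10, "need >= 10 genes with defined fractions")
  y <- scores[tab$gene]
  one <- function(d, yy) {
    preds <- c("pct_direct", "pct_indirect", "pct_either")
    out <- lapply(preds, function(p) {
      x <- d[[p]]
      if (stats::sd(x) == 0)
        return(data.frame(predictor = p, slope = NA_real_,
                          kendall_tau = NA_real_, kendall_p = NA_real_,
                          pearson_r = NA_real_, pearson_p = NA_real_,
                          n = length(x), flagged = TRUE))
      fit <- stats::lm(yy ~ x)
      kt <- suppressWarnings(stats::cor.test(x, yy, method = "kendall"))
      pr <- stats::cor.test(x, yy, method = "pearson")
      data.frame(predictor = p, slope = unname(stats::coef(fit)[2]),
                 kendall_tau = unname(kt$estimate),
                 kendall_p = kt$p.value,
                 pearson_r = unname(pr$estimate), pearson_p = pr$p.value,
                 n = length(x), flagged = FALSE)
    })
    do.call(rbind, out)
  }
  overall <- one(tab, y)
  by_sub <- NULL
  if (!is.null(partition)) {
    comm <- stats::setNames(partition$subnetwork, partition$gene)
    tab$subnetwork <- comm[tab$gene]
    keep <- !is.na(tab$subnetwork)
    by_sub <- do.call(rbind, lapply(split(tab[keep, ], tab$subnetwork[keep]),
                                    function(d) {
      if (nrow(d) < 10) return(NULL)
      cbind(subnetwork = d$subnetwork[1], one(d, scores[d$gene]))
    }))
    rownames(by_sub) <- NULL
  }
  structure(list(overall = overall, by_subnetwork = by_sub),
            class = "misregulation_dependency")
}

#' @export
print.misregulation_dependency <- function(x, ...) {
  cat("Misregulation ~ regulon control fractions\n")
  print(x$overall, digits = 3)
  invisible(x)
}

#' Cross-table of regulon status vs misregulation
#'
#' Dichotomizes each gene's regulon by whether it contains any direct
#' (NERD-like) and any indirect (misregulated) TF, cross-tabulates the four
#' strata against target misregulation, and reports the chi-squared test
#' with Pearson residuals plus the misregulated proportion per stratum.
#'
#' @param regulons a [regulon_table()] result.
#' @param misregulated named logical per gene.
#' @return list of class `regulon_crosstab`: `table`, `statistic`, `df`,
#'   `p`, `residuals`, `proportions`, `flagged`.
#' @export
crosstab_regulon_status <- function(regulons, misregulated) {
  tab <- regulons[!regulons$flagged, ]
  .assert(nrow(tab) > 0, "no genes with defined regulon fractions")
  status <- paste0(ifelse(tab$pct_direct > 0, "direct>0", "direct=0"), " & ",
                   ifelse(tab$pct_indirect > 0, "indirect>0", "indirect=0"))
  mis <- misregulated[tab$gene]
  mis[is.na(mis)] <- FALSE
  ct <- table(status = status,
              misregulated = factor(mis, levels = c(TRUE, FALSE)))
  if (any(rowSums(ct) == 0)) warning("empty stratum in cross-table")
  res <- .chisq_residuals(ct)
  props <- prop.table(ct, 1)[, "TRUE"]
  structure(list(table = ct, statistic = res$statistic, df = res$df,
                 p = res$p, residuals = res$residuals,
                 proportions = props, flagged = res$flagged),
            class = "regulon_crosstab")
}

#' @export
print.regulon_crosstab <- function(x, ...) {
  cat(sprintf("Regulon status x misregulation: chi2 = %.3f (df %d), p = %.3g\n",
              x$statistic, x$df, x$p))
  print(round(x$proportions, 3))
  invisible(x)
}

#' Filter the final set of protease-controlled interactions
#'
#' Keeps edges whose TF regulator has a NERD-like cleavage pattern and whose
#' target is significantly misregulated. Direct targets are the retained
#' (cleaved) TFs; indirect targets the retained misregulated genes; the
#' "both" set holds TFs qualifying on both routes.
#'
#' @param network a `grn_network` or edge data.frame.
#' @param nerd_like named logical over proteins.
#' @param profiles named character of misregulation profiles.
#' @param partition optional partition for the per-subnetwork composition
#'   report.
#' @return list of class `target_calls`: `edges` (kept edges),
#'   `direct_targets`, `indirect_targets`, `both`, `composition`
#'   (per-subnetwork edge counts or NULL).
#' @export
filter_dek1_targets <- function(network, nerd_like, profiles,
                                partition = NULL) {
  edges <- .edge_df(network)
  src_nerd <- nerd_like[edges$regulator]
  src_nerd[is.na(src_nerd)] <- FALSE
  tgt_mis <- profiles[edges$target] != "none"
  tgt_mis[is.na(tgt_mis)] <- FALSE
  kept <- edges[src_nerd & tgt_mis, , drop = FALSE]
  rownames(kept) <- NULL
  direct <- sort(unique(kept$regulator))
  indirect <- sort(unique(kept$target))
  composition <- NULL
  if (!is.null(partition) && nrow(kept) > 0) {
    comm <- stats::setNames(partition$subnetwork, partition$gene)
    composition <- as.data.frame(table(subnetwork = comm[kept$target]),
                                 responseName = "n_edges")
  }
  structure(list(edges = kept, direct_targets = direct,
                 indirect_targets = indirect,
                 both = intersect(direct, indirect),
                 composition = composition),
            class = "target_calls")
}

#' @export
print.target_calls <- function(x, ...) {
  cat(sprintf(paste0("Protease-controlled interactions: %d edges kept; ",
                     "%d direct-target TFs, %d indirect targets, %d both\n"),
              nrow(x$edges), length(x$direct_targets),
              length(x$indirect_targets), length(x$both)))
  invisible(x)
}

#' Extend a gene set by its highest-ranking cleaved upstream TFs
#'
#' For each gene, attaches up to `max_tfs` upstream NERD-like TFs with the
#' highest local reaching centrality, and returns the induced subgraph plus
#' a connectivity statistic (fraction of input genes in the largest weakly
#' connected component).
#'
#' @param genes character vector of focal genes.
#' @param network a `grn_network` or edge data.frame.
#' @param hierarchy a [rank_regulators()] result (needs gene +
#'   local_reaching_centrality).
#' @param nerd_like named logical over proteins.
#' @param max_tfs maximum attached TFs per gene (default 5).
#' @return list of class `extended_regulon`: `nodes`, `attached_tfs`,
#'   `edges` (induced), `connectivity`.
#' @export
extend_regulon <- function(genes, network, hierarchy, nerd_like,
                           max_tfs = 5) {
  edges <- .edge_df(network)
  lrc <- stats::setNames(hierarchy$local_reaching_centrality, hierarchy$gene)
  pm <- .parent_map(edges)
  attached <- character()
  for (g in intersect(genes, names(pm))) {
    ups <- pm[[g]]
    ups <- ups[!is.na(nerd_like[ups]) & nerd_like[ups]]
    if (length(ups) == 0) next
    ups <- ups[order(-lrc[ups], ups)]
    attached <- union(attached, utils::head(ups, max_tfs))
  }
  nodes <- union(genes, attached)
  sub <- edges[edges$regulator %in% nodes & edges$target %in% nodes, ,
               drop = FALSE]
  connectivity <- 0
  if (nrow(sub) > 0) {
    g <- igraph::graph_from_data_frame(
      sub[, c("regulator", "target")], directed = TRUE,
      vertices = data.frame(name = nodes))
    comp <- igraph::components(g, mode = "weak")
    biggest <- which.max(comp$csize)
    in_big <- names(comp$membership)[comp$membership == biggest]
    connectivity <- mean(genes %in% in_big)
  }
  structure(list(nodes = nodes, attached_tfs = attached, edges = sub,
                 connectivity = connectivity),
            class = "extended_regulon")
}

#' Unchanged TFs upstream of misregulated genes
#'
#' TFs whose own expression profile is unchanged (`"none"`) but that
#' directly regulate at least one misregulated gene — candidates for purely
#' post-translational protease control.
#'
#' @param network a `grn_network` or edge data.frame.
#' @param misregulated character vector of misregulated gene ids.
#' @param profiles named character of profiles over the gene universe.
#' @return sorted character vector of TF ids.
#' @export
upstream_unchanged_tfs <- function(network, misregulated, profiles) {
  edges <- .edge_df(network)
  hit <- edges$target %in% misregulated
  tfs <- unique(edges$regulator[hit])
  own <- profiles[tfs]
  sort(tfs[is.na(own) | own == "none"])
}
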