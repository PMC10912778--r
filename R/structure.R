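# Network structure: subnetwork detection (Louvain on the weighted
# undirected projection), regulator hierarchy via local reaching centrality,
# and sign-split inter-subnetwork connection analysis.

# Directed igraph from a grn_network or an edge data.frame; edge attributes
# (importance/weight, sign) are carried along when present.
as_grn_igraph <- function(network) {
  edges <- if (inherits(network, "grn_network")) network$edges else network
  .assert(is.data.frame(edges) && all(c("regulator", "target") %in%
                                        names(edges)),
          "network must be a grn_network or an edge data.frame")
  w <- if (!is.null(edges$importance)) edges$importance
       else if (!is.null(edges$weight)) edges$weight else rep(1, nrow(edges))
  df <- data.frame(from = edges$regulator, to = edges$target, weight = w)
  if (!is.null(edges$sign)) df$sign <- edges$sign
  igraph::graph_from_data_frame(df, directed = TRUE)
}

#' Detect regulatory subnetworks
#'
#' Louvain modularity maximization on the undirected projection of the
#' network, weighted by the sum of directed edge weights. Community labels
#' are Roman numerals ordered by descending community size (I = largest),
#' mirroring the usual subnetwork nomenclature.
#'
#' @param network a `grn_network` or edge data.frame.
#' @param seed RNG seed (Louvain sweeps are order-randomized).
#' @return object of class `subnetwork_partition`: data.frame (gene,
#'   community, subnetwork) with the modularity score as attribute.
#' @export
detect_communities <- function(network, seed = 1) {
  g <- as_grn_igraph(network)
  .assert(igraph::vcount(g) > 0, "network is empty")
  und <- igraph::as_undirected(g, mode = "collapse",
                               edge.attr.comb = list(weight = "sum",
                                                     sign = "first"))
  set.seed(seed)
  cl <- igraph::cluster_louvain(und, weights = igraph::E(und)$weight)
  memb <- igraph::membership(cl)
  # label by descending size; ties broken by the lexicographically smallest
  # member so labels are invariant to node input order
  first_member <- tapply(names(memb), memb, min)
  sizes <- table(memb)
  ord <- order(-sizes, first_member[names(sizes)])
  relabel <- stats::setNames(seq_along(ord), names(sizes)[ord])
  community <- unname(relabel[as.character(memb)])
  out <- data.frame(gene = names(memb), community = community,
                    subnetwork = .roman_labels(length(sizes))[community])
  out <- out[order(out$community, out$gene), ]
  rownames(out) <- NULL
  attr(out, "modularity") <- igraph::modularity(und, memb,
                                                weights =
                                                  igraph::E(und)$weight)
  class(out) <- c("subnetwork_partition", "data.frame")
  out
}

#' Local reaching centrality and degrees
#'
#' For every node, the fraction of the remaining network reachable along
#' directed regulator-to-target edges: LRC(v) = |reachable from v| / (N - 1).
#' Master regulators sit near 1, pure targets at 0.
#'
#' @param network a `grn_network` or edge data.frame.
#' @return data.frame: gene, local_reaching_centrality, out_degree,
#'   in_degree.
#' @export
local_reaching_centrality <- function(network) {
  g <- as_grn_igraph(network)
  n <- igraph::vcount(g)
  d <- igraph::distances(g, mode = "out", weights = NA)
  reach <- rowSums(is.finite(d)) - 1L
  data.frame(gene = igraph::V(g)$name,
             local_reaching_centrality =
               if (n > 1) reach / (n - 1) else 0,
             out_degree = igraph::degree(g, mode = "out"),
             in_degree = igraph::degree(g, mode = "in"),
             row.names = NULL)
}

#' Rank regulators into a hierarchy
#'
#' Within each subnetwork, nodes are sorted by local reaching centrality
#' (descending), ties broken by out-degree (descending) then gene id
#' (ascending); rank 1 is the subnetwork's master regulator.
#'
#' @param partition a [detect_communities()] result.
#' @param centralities a [local_reaching_centrality()] result.
#' @return merged data.frame with a `hierarchy_rank` column (a permutation
#'   of 1..N within each subnetwork).
#' @export
rank_regulators <- function(partition, centralities) {
  tab <- merge(as.data.frame(partition), centralities, by = "gene")
  ord <- order(tab$community, -tab$local_reaching_centrality,
               -tab$out_degree, tab$gene)
  tab <- tab[ord, ]
  tab$hierarchy_rank <- stats::ave(seq_len(nrow(tab)), tab$community,
                                   FUN = seq_along)
  rownames(tab) <- NULL
  tab
}

#' Inter-subnetwork connection analysis split by sign
#'
#' Counts inter-subnetwork edges by (source subnetwork, target subnetwork)
#' pair and regulatory sign, tests the flattened pair-by-sign table for
#' independence (chi-squared, no continuity correction), and reports cells
#' whose Pearson residual exceeds `residual_threshold` as enriched
#' connections — e.g. an enriched ("V", "II", "-") triple reads "V -| II".
#'
#' @param network a `grn_network` or edge data.frame with a `sign` column.
#' @param partition a [detect_communities()] result.
#' @param residual_threshold enrichment cutoff on Pearson residuals
#'   (default 4).
#' @return list of class `interconnection_result`: `table` (counts),
#'   `statistic`, `df`, `p`, `residuals`, `expected`, `enriched`
#'   (data.frame: source, target, sign, count, residual, label), `flagged`.
#' @export
interconnection_analysis <- function(network, partition,
                                     residual_threshold = 4) {
  edges <- if (inherits(network, "grn_network")) network$edges else network
  .assert(!is.null(edges$sign), "edges must carry signs")
  comm <- stats::setNames(partition$subnetwork, partition$gene)
  .assert(length(unique(partition$subnetwork)) >= 2,
          "need >= 2 subnetworks")
  src <- comm[edges$regulator]
  tgt <- comm[edges$target]
  inter <- which(src != tgt)
  .assert(length(inter) > 0, "no inter-subnetwork edges")
  pair <- paste(src[inter], tgt[inter], sep = " -> ")
  sign_lab <- ifelse(edges$sign[inter] > 0, "+", "-")
  tab <- table(pair = pair, sign = factor(sign_lab, levels = c("+", "-")))
  ct <- .chisq_residuals(tab)
  hits <- which(ct$residuals > residual_threshold, arr.ind = TRUE)
  enriched <- data.frame(source = character(), target = character(),
                         sign = character(), count = integer(),
                         residual = numeric(), label = character())
  if (nrow(hits) > 0) {
    pr <- rownames(ct$residuals)[hits[, 1]]
    sg <- colnames(ct$residuals)[hits[, 2]]
    parts <- strsplit(pr, " -> ", fixed = TRUE)
    enriched <- data.frame(
      source = vapply(parts, `[`, "", 1),
      target = vapply(parts, `[`, "", 2),
      sign = sg,
      count = ct$observed[hits],
      residual = ct$residuals[hits])
    enriched$label <- paste0(enriched$source,
                             ifelse(enriched$sign == "+", " -> ", " -| "),
                             enriched$target)
    enriched <- enriched[order(-enriched$residual), ]
    rownames(enriched) <- NULL
  }
  structure(list(table = tab, statistic = ct$statistic, df = ct$df,
                 p = ct$p, residuals = ct$residuals,
                 expected = ct$expected, enriched = enriched,
                 flagged = ct$flagged),
            class = "interconnection_result")
}

#' @export
print.interconnection_result <- function(x, ...) {
  cat(sprintf("Inter-subnetwork connection test: chi2 = %.3f (df %d), p = %.3g\n",
              x$statistic, x$df, x$p))
  if (nrow(x$enriched)) {
    cat("  enriched connections:",
        paste(x$enriched$label, collapse = ", "), "\n")
  } else cat("  no enriched connections above threshold\n")
  invisible(x)
}
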