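# Network enrichment analysis test (NEAT): are there more (or fewer)
# directed edges from gene set A to gene set B than expected under a
# hypergeometric null that fixes total out-degree of A, total in-degree of B
# and the overall edge count?

.edge_df <- function(network) {
  if (inherits(network, "grn_network")) network$edges else network
}

#' Network enrichment analysis test for one pair of gene sets
#'
#' Counts directed edges with source in `setA` and target in `setB`. Under
#' the null of no preferential wiring, that count follows a hypergeometric
#' law: of the `D` edges in the network, `d_B` end in B, and the `o_A` edges
#' leaving A are a random draw from them. The expected count is
#' `o_A * d_B / D`. The two-sided p doubles the smaller tail (capped at 1);
#' a one-sided alternative tests enrichment only.
#'
#' @param network a `grn_network` or edge data.frame.
#' @param setA,setB character vectors of gene ids (subsets of the network
#'   node universe).
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @return one-row data.frame: n_obs, o_A, d_B, D, n_exp, p, call
#'   (`"+"` enriched, `"-"` depleted, `"ns"`).
#' @export
neat_test <- function(network, setA, setB, alternative = "two.sided") {
  edges <- .edge_df(network)
  D <- nrow(edges)
  .assert(D >= 1, "network has no edges")
  nodes <- unique(c(edges$regulator, edges$target))
  .assert(all(setA %in% nodes) && all(setB %in% nodes),
          "sets must be subsets of the network nodes")
  o_A <- sum(edges$regulator %in% setA)
  d_B <- sum(edges$target %in% setB)
  n_obs <- sum(edges$regulator %in% setA & edges$target %in% setB)
  n_exp <- o_A * d_B / D
  if (o_A == 0 || d_B == 0) {
    p <- 1
  } else {
    p_le <- stats::phyper(n_obs, d_B, D - d_B, o_A)
    p_ge <- stats::phyper(n_obs - 1, d_B, D - d_B, o_A, lower.tail = FALSE)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                greater = p_ge,
                stop("unknown alternative"))
  }
  call <- if (p >= 1 || n_obs == n_exp) "ns"
          else if (n_obs > n_exp) "+" else "-"
  data.frame(n_obs = n_obs, o_A = o_A, d_B = d_B, D = D, n_exp = n_exp,
             p = p, call = call)
}

#' Batch NEAT over gene sets and subnetworks
#'
#' Tests every gene set against every subnetwork block of the partition:
#' per pair, the directed edge count from the subnetwork (sources) into the
#' gene set (targets) — "how strongly does this subnetwork regulate the
#' set" — is referred to the hypergeometric null. p-values are
#' Benjamini-Hochberg adjusted across the whole batch and enrichment (+) /
#' depletion (-) is called at `fdr`. Also returns the observed/expected
#' ratio matrix used for heatmap export.
#'
#' @param network a `grn_network` or edge data.frame.
#' @param gene_sets named list of gene-id vectors (ids outside the network
#'   are dropped; an empty set yields an `ns` row with a flag).
#' @param partition a [detect_communities()] result.
#' @param fdr q-value threshold for calls (default 0.01).
#' @param alternative passed to [neat_test()].
#' @return list of class `neat_result`: `table` (setA = gene set, setB =
#'   subnetwork, n_obs, o_A, d_B, D, n_exp, ratio, p, q, call, flagged)
#'   and `ratio` matrix (sets x subnetworks).
#' @export
neat_batch <- function(network, gene_sets, partition, fdr = 0.01,
                       alternative = "two.sided") {
  .assert(length(gene_sets) >= 1 && !is.null(names(gene_sets)),
          "gene_sets must be a named list")
  edges <- .edge_df(network)
  nodes <- unique(c(edges$regulator, edges$target))
  blocks <- split(partition$gene, partition$subnetwork)
  blocks <- blocks[order(match(names(blocks),
                               unique(partition$subnetwork)))]
  rows <- list()
  for (a in names(gene_sets)) {
    setA <- intersect(gene_sets[[a]], nodes)
    for (b in names(blocks)) {
      if (length(setA) == 0) {
        row <- data.frame(n_obs = 0L,
                          o_A = sum(edges$regulator %in% blocks[[b]]),
                          d_B = 0L,
                          D = nrow(edges), n_exp = 0, p = 1, call = "ns")
        row$flagged <- TRUE
      } else {
        row <- neat_test(edges, blocks[[b]], setA, alternative)
        row$flagged <- FALSE
      }
      rows[[length(rows) + 1L]] <- cbind(setA = a, setB = b, row)
    }
  }
  tab <- do.call(rbind, rows)
  tab$q <- bh_adjust(tab$p)
  tab$call[tab$q >= fdr] <- "ns"
  tab$ratio <- ifelse(tab$n_exp > 0, tab$n_obs / tab$n_exp, NA_real_)
  tab <- tab[, c("setA", "setB", "n_obs", "o_A", "d_B", "D", "n_exp",
                 "ratio", "p", "q", "call", "flagged")]
  ratio <- matrix(NA_real_, length(gene_sets), length(blocks),
                  dimnames = list(names(gene_sets), names(blocks)))
  ratio[cbind(tab$setA, tab$setB)] <- tab$ratio
  structure(list(table = tab, ratio = ratio, fdr = fdr), class = "neat_result")
}

#' @export
print.neat_result <- function(x, ...) {
  sig <- x$table[x$table$call != "ns", , drop = FALSE]
  cat(sprintf("NEAT: %d test(s), %d significant at q < %g\n",
              nrow(x$table), nrow(sig), x$fdr))
  if (nrow(sig))
    cat(paste0("  ", sig$setA, " x ", sig$setB, ": ", sig$call,
               " (obs ", sig$n_obs, ", exp ", round(sig$n_exp, 2), ")",
               collapse = "\n"), "\n")
  invisible(x)
}
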