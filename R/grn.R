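# GENIE3-style signed network inference: per-target random-forest regressions
# on regulator profiles, importance ranking, Pearson-correlation edge signs,
# and top-k inbound edge selection.

#' Rank candidate regulatory edges by tree-ensemble importance
#'
#' For every gene, fits a random-forest regression of its expression profile
#' on the profiles of all regulators (excluding the gene itself), with
#' sqrt(p) feature subsampling and fully grown trees — the GENIE3
#' convention. The importance of a regulator for a target is its total
#' impurity (variance) reduction, normalized to sum to one per target;
#' constant targets receive all-zero importances.
#'
#' @param expr an [expression_dataset()].
#' @param regulators character vector of regulator gene ids (>= 2, all
#'   present in `expr`).
#' @param n_trees trees per forest (default 1000).
#' @param seed RNG seed; results are deterministic given the seed.
#' @return data.frame: regulator, target, importance (one row per candidate
#'   pair; a regulator is never a candidate for itself).
#' @export
rank_edges <- function(expr, regulators, n_trees = 1000, seed = 1) {
  .assert(inherits(expr, "expression_dataset"), "expr must be a dataset")
  .assert(length(regulators) >= 2, "need >= 2 regulators")
  .assert(all(regulators %in% rownames(expr$values)),
          "all regulators must be present in the expression matrix")
  .assert(ncol(expr$values) >= 5, "need >= 5 samples")
  vals <- expr$values
  genes <- rownames(vals)
  res <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    feats <- setdiff(regulators, g)
    y <- vals[g, ]
    if (stats::sd(y) == 0) {
      imp <- stats::setNames(rep(0, length(feats)), feats)
    } else {
      X <- t(vals[feats, , drop = FALSE])
      fit <- ranger::ranger(
        x = X, y = y, num.trees = n_trees,
        mtry = max(1L, floor(sqrt(length(feats)))),
        min.node.size = 1, importance = "impurity",
        num.threads = 1, seed = .stage_seed(seed, g))
      imp <- pmax(fit$variable.importance, 0)[feats]
      if (sum(imp) > 0) imp <- imp / sum(imp)
    }
    res[[i]] <- data.frame(regulator = feats, target = g,
                           importance = unname(imp))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Default correlation column sets
#'
#' Edge directionality is read from Pearson correlations computed over two
#' sample subsets: the developmental time course of the wild type plus the
#' protease mutant lines, and globally over all samples.
#'
#' @param samples a sample sheet.
#' @param timecourse_genotypes genotypes defining the time-course subset;
#'   defaults to every genotype (use e.g. `c("WT", "dek1")` to restrict).
#' @return named list of sample-id vectors `timecourse` and `global`.
#' @export
default_column_sets <- function(samples, timecourse_genotypes = NULL) {
  tc <- if (is.null(timecourse_genotypes)) samples$sample else
    samples$sample[samples$genotype %in% timecourse_genotypes]
  list(timecourse = tc, global = samples$sample)
}

#' Assign correlation-based signs to candidate edges
#'
#' Pearson correlation between regulator and target profiles is computed for
#' each configured column set. The sign of an edge is the sign of the
#' time-course correlation, falling back to the global correlation when the
#' former is numerically zero. Zero-variance genes in a column set yield a
#' correlation recorded as 0 with a flag.
#'
#' @param expr an [expression_dataset()].
#' @param edges data.frame with `regulator` and `target` columns.
#' @param column_sets named list with elements `timecourse` and `global`
#'   (sample ids, >= 3 each); see [default_column_sets()].
#' @return `edges` with columns r_global, r_timecourse, sign, r_flagged.
#' @export
assign_edge_signs <- function(expr, edges,
                              column_sets = default_column_sets(expr$samples)) {
  .assert(all(c("timecourse", "global") %in% names(column_sets)),
          "column_sets needs 'timecourse' and 'global'")
  for (nm in names(column_sets))
    .assert(length(column_sets[[nm]]) >= 3,
            paste("column set", nm, "needs >= 3 samples"))
  corr_for <- function(cols) {
    V <- expr$values[, cols, drop = FALSE]
    sds <- apply(V, 1, stats::sd)
    Z <- (V - rowMeans(V)) / ifelse(sds > 0, sds, 1)
    r <- rowSums(Z[edges$regulator, , drop = FALSE] *
                   Z[edges$target, , drop = FALSE]) / (ncol(V) - 1)
    r[sds[edges$regulator] == 0 | sds[edges$target] == 0] <- NA
    r
  }
  r_tc <- corr_for(column_sets$timecourse)
  r_gl <- corr_for(column_sets$global)
  edges$r_flagged <- is.na(r_tc) | is.na(r_gl)
  edges$r_timecourse <- ifelse(is.na(r_tc), 0, r_tc)
  edges$r_global <- ifelse(is.na(r_gl), 0, r_gl)
  src <- ifelse(abs(edges$r_timecourse) >= 1e-12,
                edges$r_timecourse, edges$r_global)
  edges$sign <- ifelse(src >= 0, 1, -1)
  edges
}

#' Select the top-k inbound edges per target
#'
#' Keeps the `k` highest-importance inbound edges of every target
#' (fewer if fewer candidates have nonzero importance). Ties are broken by
#' higher absolute time-course correlation, then lexicographic regulator id.
#'
#' @param edges signed candidate edges from [assign_edge_signs()].
#' @param k edges retained per target (default 10).
#' @param regulators optional data.frame (gene, class) describing the
#'   regulator universe, stored in the result.
#' @return object of class `grn_network`: list with `edges` (regulator,
#'   target, importance, rank, r_global, r_timecourse, sign) and
#'   `regulators`.
#' @export
select_top_k <- function(edges, k = 10, regulators = NULL) {
  .assert(.is_count(k), "k must be a count >= 1")
  if (is.null(edges$r_timecourse)) edges$r_timecourse <- 0
  edges <- edges[edges$importance > 0, , drop = FALSE]
  ord <- order(edges$target, -edges$importance, -abs(edges$r_timecourse),
               edges$regulator)
  edges <- edges[ord, , drop = FALSE]
  idx <- stats::ave(seq_len(nrow(edges)), edges$target, FUN = seq_along)
  edges$rank <- idx
  edges <- edges[idx <= k, , drop = FALSE]
  rownames(edges) <- NULL
  if (is.null(regulators)) {
    regs <- sort(unique(edges$regulator))
    regulators <- data.frame(gene = regs,
                             class = rep("TF", length(regs)))
  }
  structure(list(edges = edges, regulators = regulators),
            class = "grn_network")
}

#' @export
print.grn_network <- function(x, ...) {
  cat(sprintf("Signed regulatory network: %d edges, %d regulators, %d targets\n",
              nrow(x$edges), length(unique(x$edges$regulator)),
              length(unique(x$edges$target))))
  cat(sprintf("  signs: %d activating (+), %d repressive (-)\n",
              sum(x$edges$sign > 0), sum(x$edges$sign < 0)))
  invisible(x)
}

#' Infer a signed regulatory network
#'
#' One-call wrapper: rank candidate edges by tree-ensemble importance,
#' assign correlation signs, and keep the top-k inbound edges per target.
#'
#' @inheritParams rank_edges
#' @inheritParams select_top_k
#' @param column_sets see [assign_edge_signs()].
#' @return a `grn_network`.
#' @export
infer_grn <- function(expr, regulators, k = 10, n_trees = 1000, seed = 1,
                      column_sets = default_column_sets(expr$samples)) {
  cand <- rank_edges(expr, regulators, n_trees = n_trees, seed = seed)
  cand <- assign_edge_signs(expr, cand, column_sets)
  reg_df <- data.frame(gene = regulators, class = "TF")
  select_top_k(cand, k = k, regulators = reg_df)
}

#' Area under the precision-recall curve of an edge ranking
#'
#' Evaluates a candidate edge ranking against a set of true edges over the
#' scored candidate universe, plus the random baseline (the prevalence of
#' true edges among candidates).
#'
#' @param edges data.frame with regulator, target, importance.
#' @param true_edges data.frame with regulator, target.
#' @return list with `aupr`, `baseline` and their ratio.
#' @export
edge_ranking_aupr <- function(edges, true_edges) {
  key <- function(d) paste(d$regulator, d$target, sep = "\r")
  lab <- key(edges) %in% key(true_edges)
  ord <- order(-edges$importance)
  lab <- lab[ord]
  tp <- cumsum(lab)
  prec <- tp / seq_along(lab)
  npos <- sum(lab)
  .assert(npos > 0, "no true edge lies in the candidate universe")
  aupr <- sum(prec[lab]) / npos
  baseline <- npos / length(lab)
  list(aupr = aupr, baseline = baseline, ratio = aupr / baseline)
}
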