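# N-degron (N-end rule) classification of predicted calpain cleavage sites
# and clustering of proteins by cleavage-pattern profiles.

#' Default N-terminal residue class table
#'
#' A cleavage between P1 and P1' exposes the P1' residue as a neo-N-terminus.
#' The default table encodes the canonical N-end-rule residue classes:
#' primary, secondary and tertiary destabilizing residues route the protein
#' to N-degron (NERD) ubiquitin-proteasome degradation; the small residues
#' that are substrates of N-terminal acetylation form the "other" route; Met
#' and Pro leave the protein effectively unchanged. The table is
#' user-replaceable; classes must be disjoint and cover all 20 residues.
#'
#' @return named list of character vectors `NERD`, `other`, `unchanged`.
#' @seealso [read_nterm_classes()] to load a custom table from TSV.
#' @export
default_nterm_classes <- function() {
  list(NERD = c("R", "K", "H", "F", "W", "Y", "L", "I", "D", "E", "N", "Q"),
       other = c("A", "S", "T", "C", "G", "V"),
       unchanged = c("M", "P"))
}

#' Read an N-terminal class table from TSV
#'
#' The file needs columns `class` and `residues` (comma-separated one-letter
#' codes); see `system.file("extdata", "nterm_classes_default.tsv",
#' package = "calpainGRN")` for the shipped default.
#'
#' @param file TSV path.
#' @return named list of residue vectors, validated like the default table.
#' @export
read_nterm_classes <- function(file) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  .assert(all(c("class", "residues") %in% names(tab)),
          "class table needs 'class' and 'residues' columns")
  classes <- stats::setNames(strsplit(gsub(" ", "", tab$residues), ","),
                             tab$class)
  .check_classes(classes)
}

# Mclust resolves `mclustBIC` in the caller's frame, so give it one where the
# function is in scope without attaching the whole package.
.fit_mixture <- function(scores, G) {
  env <- new.env()
  env$mclustBIC <- mclust::mclustBIC
  env$scores <- scores
  env$G <- G
  eval(quote(mclust::Mclust(scores, G = G, verbose = FALSE)), env)
}

.check_classes <- function(classes) {
  all_res <- unlist(classes)
  .assert(!anyDuplicated(all_res), "residue classes must be disjoint")
  .assert(setequal(all_res, strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]),
          "residue classes must cover all 20 amino acids")
  classes
}

#' Classify the N-terminal fate of cleavage sites
#'
#' For each site, looks up the residue immediately after the cut (P1', at
#' `position + 1`) in the class table. A cut at the final residue has no P1'
#' and is classified `unchanged` with a flag.
#'
#' @param sites data.frame with columns `protein`, `position` (1-based index
#'   of P1; the cut lies between P1 and P1').
#' @param sequences named character vector of protein sequences.
#' @param classes class table, see [default_nterm_classes()].
#' @return `sites` with added columns `p1prime`, `class` and logical
#'   `flagged` (cut at the final residue).
#' @export
classify_sites <- function(sites, sequences,
                           classes = default_nterm_classes()) {
  classes <- .check_classes(classes)
  .assert(all(sites$protein %in% names(sequences)),
          "every site's protein must be present in sequences")
  len <- nchar(sequences)[sites$protein]
  .assert(all(sites$position >= 1 & sites$position <= len),
          "site position outside protein sequence")
  at_end <- sites$position == len
  p1p <- substring(sequences[sites$protein], sites$position + 1L,
                   sites$position + 1L)
  lookup <- stats::setNames(rep(names(classes), lengths(classes)),
                            unlist(classes))
  cls <- unname(lookup[p1p])
  cls[at_end] <- "unchanged"
  p1p[at_end] <- ""
  sites$p1prime <- p1p
  sites$class <- cls
  sites$flagged <- at_end
  sites
}

#' Classify a single cleavage site
#'
#' @param protein protein id.
#' @param position 1-based P1 residue index.
#' @param sequences named character vector of sequences.
#' @param classes class table.
#' @return class name, one of `"NERD"`, `"other"`, `"unchanged"`.
#' @export
classify_nterminus <- function(protein, position, sequences,
                               classes = default_nterm_classes()) {
  classify_sites(data.frame(protein = protein, position = position),
                 sequences, classes)$class
}

#' Per-protein cleavage profiles
#'
#' Counts sites by N-terminal class and scales each count by protein length,
#' giving per-residue site frequencies. Proteins without sites get all-zero
#' frequencies. Duplicate (protein, position) rows are deduplicated with a
#' warning.
#'
#' @param sites site table (classified or not; classification is applied).
#' @param sequences named character vector of sequences.
#' @param classes class table.
#' @return data.frame: protein, length, n_sites, freq_total, freq_NERD,
#'   freq_other, freq_unchanged.
#' @export
protein_profiles <- function(sites, sequences,
                             classes = default_nterm_classes()) {
  if (nrow(sites) > 0) {
    dup <- duplicated(sites[, c("protein", "position")])
    if (any(dup)) {
      warning(sum(dup), " duplicate (protein, position) row(s) removed")
      sites <- sites[!dup, , drop = FALSE]
    }
    sites <- classify_sites(sites, sequences, classes)
  }
  prot <- names(sequences)
  out <- data.frame(protein = prot, length = unname(nchar(sequences)))
  cnt <- function(cl) {
    if (nrow(sites) == 0) return(integer(length(prot)))
    tab <- table(factor(sites$protein[sites$class == cl], levels = prot))
    as.integer(tab)
  }
  n_nerd <- cnt("NERD"); n_other <- cnt("other"); n_unch <- cnt("unchanged")
  out$n_sites <- n_nerd + n_other + n_unch
  out$freq_total <- out$n_sites / out$length
  out$freq_NERD <- n_nerd / out$length
  out$freq_other <- n_other / out$length
  out$freq_unchanged <- n_unch / out$length
  out
}

#' Site abundance level categories (SLC)
#'
#' One-dimensional k-means on log-transformed length-scaled overall site
#' frequencies, labels ordered by ascending centroid so SLC 1 holds the
#' proteins with the fewest sites. The log offset is half the minimal
#' nonzero frequency. With fewer distinct values than `k`, `k` is reduced
#' with a warning.
#'
#' @param profiles output of [protein_profiles()].
#' @param k number of categories (default 5).
#' @param seed RNG seed for k-means starts.
#' @return `profiles` with an integer `slc` column.
#' @export
slc_categories <- function(profiles, k = 5, seed = 1) {
  f <- profiles$freq_total
  nz <- f[f > 0]
  eps <- if (length(nz)) min(nz) / 2 else 1
  x <- log(f + eps)
  n_distinct <- length(unique(x))
  if (n_distinct < k) {
    warning("fewer distinct frequencies (", n_distinct,
            ") than k = ", k, "; k reduced")
    k <- n_distinct
  }
  if (k == 1) {
    profiles$slc <- 1L
    return(profiles)
  }
  set.seed(seed)
  km <- stats::kmeans(x, centers = k, nstart = 25)
  relabel <- order(order(km$centers))   # ascending centroid -> 1..k
  profiles$slc <- relabel[km$cluster]
  profiles
}

#' Model-based clustering of cleavage patterns
#'
#' Builds a feature matrix of log-transformed length-scaled site frequencies
#' (per N-terminal class plus the overall frequency), reduces it by centered
#' and scaled PCA, and fits Gaussian mixtures with 1..9 components selected
#' by BIC. A tiny seeded jitter (sd 0.01 on the PC scores) breaks the exact
#' ties produced by site-free proteins, which otherwise make the mixture
#' covariances singular. A cluster is flagged NERD-like when its mean
#' per-length NERD-site frequency exceeds the global mean.
#'
#' @param profiles output of [protein_profiles()] or [slc_categories()].
#' @param n_pcs number of principal components used for clustering
#'   (truncated with a warning if fewer are available).
#' @param seed RNG seed.
#' @param G integer vector of mixture sizes to score by BIC.
#' @return `profiles` with `pattern_cluster` (integer) and `nerd_like`
#'   (logical) columns.
#' @export
cluster_cleavage_patterns <- function(profiles, n_pcs = 10, seed = 1,
                                      G = 1:9) {
  .assert(nrow(profiles) >= 2, "need at least 2 proteins")
  lg <- function(f) {
    nz <- f[f > 0]
    eps <- if (length(nz)) min(nz) / 2 else 1
    log(f + eps)
  }
  feat <- cbind(freq_NERD = lg(profiles$freq_NERD),
                freq_other = lg(profiles$freq_other),
                freq_unchanged = lg(profiles$freq_unchanged),
                freq_total = lg(profiles$freq_total))
  keep <- apply(feat, 2, stats::sd) > 0
  if (!any(keep)) {
    profiles$pattern_cluster <- 1L
    profiles$nerd_like <- FALSE
    return(profiles)
  }
  pc <- stats::prcomp(feat[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  avail <- ncol(pc$x)
  if (n_pcs > avail) {
    warning("n_pcs truncated to ", avail, " available component(s)")
    n_pcs <- avail
  }
  set.seed(seed)
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  scores <- scores + matrix(stats::rnorm(length(scores), sd = 0.01),
                            nrow(scores))
  fit <- .fit_mixture(scores, G)
  cl <- if (is.null(fit)) rep(1L, nrow(profiles)) else fit$classification
  profiles$pattern_cluster <- as.integer(cl)
  mu_global <- mean(profiles$freq_NERD)
  mu_cluster <- tapply(profiles$freq_NERD, profiles$pattern_cluster, mean)
  profiles$nerd_like <-
    unname(mu_cluster[as.character(profiles$pattern_cluster)] > mu_global)
  profiles
}

#' Full cleavage profiling pipeline for one proteome
#'
#' Convenience wrapper: classify sites, build per-protein profiles, assign
#' SLC categories and mixture clusters with the NERD-like flag.
#'
#' @param sites site table.
#' @param sequences named character vector of sequences.
#' @param classes class table.
#' @param k number of SLC categories.
#' @param n_pcs principal components for mixture clustering.
#' @param seed RNG seed.
#' @return the cleavage profile table, see [cluster_cleavage_patterns()].
#' @export
cleavage_profiles <- function(sites, sequences,
                              classes = default_nterm_classes(),
                              k = 5, n_pcs = 10, seed = 1) {
  prof <- protein_profiles(sites, sequences, classes)
  prof <- slc_categories(prof, k = k, seed = seed)
  cluster_cleavage_patterns(prof, n_pcs = n_pcs, seed = seed)
}
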