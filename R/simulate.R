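# Synthetic-data generator: ground-truth regulatory networks, multi-genotype
# time-course expression, proteomes with planted cleavage sites, and binary
# trait tables. Every downstream stage of the pipeline has a recovery test
# against these ground truths.

# Rejection-sample a parent set whose activity curves are mutually weakly
# correlated (|r| <= cap over the sampling days). Decorrelated regulators keep
# the sign of every true edge identifiable from expression covariation; see
# the methods vignette for why the cap guarantees sign fidelity.
.pick_parents <- function(candidates, k, fluct, cap = 0.3, tries = 100) {
  if (length(candidates) == 1) return(candidates)
  best <- NULL
  best_cc <- Inf
  for (i in seq_len(tries)) {
    set <- sample(candidates, k)
    if (k == 1) return(set)
    cc <- max(abs(stats::cor(t(fluct[set, , drop = FALSE]))[
      upper.tri(diag(k))]))
    if (cc <= cap) return(set)
    if (cc < best_cc) { best_cc <- cc; best <- set }
  }
  best
}

#' Simulate a layered signed regulatory network with ground truth
#'
#' Layer-1 transcription factors (TFs) have no parents; TFs in deeper layers
#' and all target genes draw `edges_per_target` parents from regulators above
#' them. A configured fraction of TFs is marked as cleaved by the calpain and
#' routed to N-degron decay. For each target, the edges coming from cleaved
#' parents share one sign, which defines the planted misregulation profile:
#' net activation by cleaved TFs makes the gene an activator-target (higher in
#' the protease null, lower in the overexpressor), net repression the reverse.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `grn_truth` with elements `edges` (regulator,
#'   target, weight, sign), `cleaved` (named logical per TF),
#'   `planted_profile` (named character per gene), `trait_truth`, the TF
#'   activity `curves` over the configured days, and the `config` itself.
#' @export
simulate_grn <- function(config) {
  .assert(inherits(config, "sim_config"), "config must be a sim_config")
  set.seed(config$seed)
  n_tf <- config$n_tf
  tf_ids <- sprintf("TF%03d", seq_len(n_tf))
  target_ids <- sprintf("G%04d", seq_len(config$n_targets))
  layer <- sort(rep_len(seq_len(config$layers), n_tf))
  names(layer) <- tf_ids
  days <- config$days
  span <- diff(range(days))
  epl <- config$edges_per_target

  # TF activity curves: positive, smooth, genotype-invariant (regulation of
  # the TFs themselves is post-transcriptionally buffered in this model).
  curves <- matrix(0, n_tf, length(days),
                   dimnames = list(tf_ids, paste0("d", days)))
  tf_scale <- stats::setNames(rep(1, n_tf), tf_ids)
  edges <- list()
  for (j in seq_len(n_tf)) {
    if (layer[j] == 1) {
      amp <- stats::runif(1, .TF_AMP[1], .TF_AMP[2])
      period <- stats::runif(1, 0.75, 1.5) * span
      phase <- stats::runif(1, 0, 2 * pi)
      curves[j, ] <- .TF_LEVEL + amp * sin(2 * pi * days / period + phase)
    } else {
      avail <- tf_ids[layer < layer[j]]
      if (epl > length(avail)) stop("insufficient regulators", call. = FALSE)
      fluct <- curves - rowMeans(curves)
      parents <- .pick_parents(avail, epl, fluct)
      w <- stats::runif(length(parents), 0.8, 1.2)
      s <- ifelse(stats::runif(length(parents)) <
                    config$sign_fraction_negative, -1, 1)
      combo <- drop(crossprod(fluct[parents, , drop = FALSE], s * w))
      amp <- stats::runif(1, .TF_AMP[1], .TF_AMP[2])
      if (max(abs(combo)) > 0) {
        tf_scale[j] <- amp / max(abs(combo))
        combo <- combo * tf_scale[j]
      }
      curves[j, ] <- .TF_LEVEL + combo
      edges[[length(edges) + 1L]] <-
        data.frame(regulator = parents, target = tf_ids[j],
                   weight = w, sign = s)
    }
  }

  n_cleaved <- round(config$frac_tf_cleaved * n_tf)
  cleaved_ids <- if (n_cleaved > 0) sample(tf_ids, n_cleaved) else character()
  cleaved <- stats::setNames(tf_ids %in% cleaved_ids, tf_ids)

  fluct <- curves - rowMeans(curves)
  planted <- stats::setNames(rep("none", n_tf + config$n_targets),
                             c(tf_ids, target_ids))
  for (t in target_ids) {
    if (epl > n_tf) stop("insufficient regulators", call. = FALSE)
    parents <- .pick_parents(tf_ids, epl, fluct)
    w <- stats::runif(length(parents), 0.8, 1.2)
    s <- ifelse(stats::runif(length(parents)) <
                  config$sign_fraction_negative, -1, 1)
    cle <- cleaved[parents]
    if (any(cle)) {
      # cleaved parents act with one shared sign so the planted profile is
      # unambiguous (no cancellation between cleaved activators/repressors)
      s_cl <- if (stats::runif(1) < config$sign_fraction_negative) -1 else 1
      s[cle] <- s_cl
      planted[t] <- if (s_cl > 0) "activator-target" else "repressor-target"
    }
    edges[[length(edges) + 1L]] <-
      data.frame(regulator = parents, target = t, weight = w, sign = s)
  }
  edges <- do.call(rbind, edges)
  rownames(edges) <- NULL

  # Trait truth: a trait is linked to the planted profile genes whenever its
  # genotype split separates mean protein-level attenuation.
  m_g <- exp(-config$kappa * config$genotypes)
  trait_truth <- lapply(config$trait_genotype_map, function(gset) {
    m_true <- m_g[names(config$genotypes) %in% gset]
    m_false <- m_g[!names(config$genotypes) %in% gset]
    if (length(m_true) == 0 || length(m_false) == 0 ||
        abs(mean(m_true) - mean(m_false)) < 1e-9 || !any(cleaved))
      return(character())
    names(planted)[planted != "none"]
  })

  structure(list(config = config, tf_ids = tf_ids, target_ids = target_ids,
                 layer = layer, curves = curves, tf_scale = tf_scale,
                 edges = edges, cleaved = cleaved, planted_profile = planted,
                 trait_truth = trait_truth),
            class = "grn_truth")
}

#' @export
print.grn_truth <- function(x, ...) {
  cat(sprintf(paste0("Ground-truth regulatory network: %d TFs (%d cleaved), ",
                     "%d targets, %d edges\n"),
              length(x$tf_ids), sum(x$cleaved), length(x$target_ids),
              nrow(x$edges)))
  cat(sprintf("  planted profiles: %d activator-target, %d repressor-target\n",
              sum(x$planted_profile == "activator-target"),
              sum(x$planted_profile == "repressor-target")))
  invisible(x)
}

#' Simulate multi-genotype time-course expression from a ground truth
#'
#' TF mRNA follows its smooth activity curve independently of genotype
#' (post-translational control leaves regulator transcripts unchanged in
#' expectation), plus intrinsic biological fluctuation (`tf_noise_sd`) that
#' propagates down the regulatory cascade. TF protein activity is mRNA times
#' \eqn{exp(-\kappa a_g)} for cleaved TFs and mRNA otherwise. A target's
#' log-mean is its baseline plus the signed, weighted sum of parent protein
#' activities; observed values add Gaussian measurement noise on the log
#' scale, or negative-binomial counts when `nb_dispersion` is set.
#'
#' @param truth a `grn_truth` from [simulate_grn()].
#' @param config defaults to the configuration stored in `truth`.
#' @return an [expression_dataset()] covering all TFs and targets.
#' @export
simulate_expression <- function(truth, config = truth$config) {
  .assert(inherits(truth, "grn_truth"), "truth must come from simulate_grn")
  .assert(all(config$genotypes >= 0), "calpain activities a_g must be >= 0")
  set.seed(.stage_seed(config$seed, "expression"))
  samples <- .sample_sheet(config)
  n_s <- nrow(samples)
  day_idx <- match(samples$day, config$days)

  # Realized TF mRNA: smooth day curve + intrinsic fluctuation, propagated
  # through the regulator hierarchy in layer order. Genotype-invariant.
  tf_ids <- truth$tf_ids
  eta <- matrix(stats::rnorm(length(tf_ids) * n_s, sd = config$tf_noise_sd),
                length(tf_ids), n_s, dimnames = list(tf_ids, samples$sample))
  mrna <- matrix(0, length(tf_ids), n_s,
                 dimnames = list(tf_ids, samples$sample))
  tf_edges <- truth$edges[truth$edges$target %in% tf_ids, , drop = FALSE]
  for (j in order(truth$layer)) {
    id <- tf_ids[j]
    if (truth$layer[j] == 1) {
      mrna[id, ] <- truth$curves[id, day_idx] + eta[id, ]
    } else {
      pe <- tf_edges[tf_edges$target == id, , drop = FALSE]
      combo <- drop(crossprod(mrna[pe$regulator, , drop = FALSE] - .TF_LEVEL,
                              pe$sign * pe$weight))
      mrna[id, ] <- .TF_LEVEL + truth$tf_scale[[id]] * combo + eta[id, ]
    }
  }
  m_g <- exp(-config$kappa * config$genotypes)   # per genotype
  mult_mat <- matrix(1, length(tf_ids), n_s,
                     dimnames = list(tf_ids, samples$sample))
  for (g in names(config$genotypes)) {
    cols <- samples$genotype == g
    mult_mat[truth$cleaved, cols] <- m_g[[g]]
  }
  protein <- mrna * mult_mat

  W <- matrix(0, length(truth$target_ids), length(truth$tf_ids),
              dimnames = list(truth$target_ids, truth$tf_ids))
  tgt_edges <- truth$edges[truth$edges$target %in% truth$target_ids, ]
  W[cbind(tgt_edges$target, tgt_edges$regulator)] <-
    tgt_edges$weight * tgt_edges$sign
  baseline <- stats::runif(length(truth$target_ids), 1, 3)
  target_mean <- baseline + W %*% protein

  mu <- rbind(mrna, target_mean)
  if (is.null(config$nb_dispersion)) {
    values <- mu + matrix(stats::rnorm(length(mu), sd = config$noise_sd),
                          nrow(mu))
  } else {
    # counts around a depth of ~30 at log-mean 0; normalize() maps them back
    lambda <- 30 * 2^mu
    values <- matrix(stats::rnbinom(length(mu), mu = lambda,
                                    size = 1 / config$nb_dispersion),
                     nrow(mu), dimnames = dimnames(mu))
  }
  dimnames(values) <- list(c(truth$tf_ids, truth$target_ids), samples$sample)
  expression_dataset(values, samples)
}

#' Simulate a proteome with planted calpain cleavage sites
#'
#' One random amino-acid sequence is generated per gene product. Every
#' cleaved TF receives 2-4 sites whose P1' residue (immediately after the
#' cut) is drawn from the N-degron (NERD) destabilizing class; all other
#' proteins receive 0-2 sites yielding stabilizing or acetylation-route
#' residues only. Site windows are the 20-mer spanning P10..P1 | P1'..P10'.
#'
#' @param truth a `grn_truth`.
#' @param config defaults to the configuration stored in `truth`.
#' @param classes an N-terminal residue class table, see
#'   [default_nterm_classes()].
#' @return list with `sequences` (named character vector of amino-acid
#'   sequences, one per gene product) and `sites` (data.frame: protein,
#'   position, window, score).
#' @export
simulate_proteome <- function(truth, config = truth$config,
                              classes = default_nterm_classes()) {
  .assert(inherits(truth, "grn_truth"), "truth must come from simulate_grn")
  set.seed(.stage_seed(config$seed, "proteome"))
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  stabilizing <- c(classes$other, classes$unchanged)
  prot_ids <- c(truth$tf_ids, truth$target_ids)
  cleaved <- stats::setNames(prot_ids %in% names(truth$cleaved)[truth$cleaved],
                             prot_ids)
  seqs <- character(length(prot_ids))
  names(seqs) <- prot_ids
  sites <- list()
  for (p in prot_ids) {
    len <- sample(seq(config$protein_length_range[1],
                      config$protein_length_range[2]), 1)
    chars <- sample(aa, len, replace = TRUE)
    n_sites <- if (cleaved[[p]]) sample(2:4, 1) else sample(0:2, 1)
    if (n_sites > 0) {
      pos <- sample(seq(10L, len - 10L), n_sites)
      p1prime <- if (cleaved[[p]]) {
        sample(classes$NERD, n_sites, replace = TRUE)
      } else {
        sample(stabilizing, n_sites, replace = TRUE)
      }
      chars[pos + 1L] <- p1prime
      seqs[p] <- paste(chars, collapse = "")
      sites[[p]] <- data.frame(
        protein = p, position = pos,
        window = substring(seqs[p], pos - 9L, pos + 10L),
        score = round(stats::runif(n_sites, 0.5, 1), 4))
    } else {
      seqs[p] <- paste(chars, collapse = "")
    }
  }
  sites <- if (length(sites)) do.call(rbind, sites) else
    data.frame(protein = character(), position = integer(),
               window = character(), score = numeric())
  rownames(sites) <- NULL
  list(sequences = seqs, sites = sites)
}

#' Simulate a binary trait table
#'
#' One logical column per configured trait: a sample is `TRUE` iff its
#' genotype belongs to the trait's genotype set.
#'
#' @param config a [sim_config()].
#' @param samples sample sheet; defaults to the one implied by `config`.
#' @return data.frame with a `sample` column and one logical column per trait.
#' @export
simulate_traits <- function(config, samples = .sample_sheet(config)) {
  .assert(inherits(config, "sim_config"), "config must be a sim_config")
  out <- data.frame(sample = samples$sample, stringsAsFactors = FALSE)
  for (tr in names(config$trait_genotype_map)) {
    gset <- config$trait_genotype_map[[tr]]
    unknown <- setdiff(gset, names(config$genotypes))
    .assert(length(unknown) == 0,
            paste("unknown genotype(s):", paste(unknown, collapse = ", ")))
    out[[tr]] <- samples$genotype %in% gset
  }
  out
}

#' Run the whole generator
#'
#' Convenience wrapper producing every synthetic artifact from one
#' configuration: ground truth, expression, proteome and traits.
#'
#' @param config a [sim_config()].
#' @return list of class `calpain_sim` with `truth`, `expr`, `proteome`,
#'   `traits` and `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  truth <- simulate_grn(config)
  list2 <- list(config = config,
                truth = truth,
                expr = simulate_expression(truth, config),
                proteome = simulate_proteome(truth, config),
                traits = simulate_traits(config))
  structure(list2, class = "calpain_sim")
}

#' @export
print.calpain_sim <- function(x, ...) {
  print(x$truth)
  cat(sprintf("  expression: %d genes x %d samples; %d protein(s); %d trait(s)\n",
              nrow(x$expr$values), ncol(x$expr$values),
              length(x$proteome$sequences), ncol(x$traits) - 1L))
  invisible(x)
}

# Mean log-scale activity level of regulator transcripts. The genotype effect
# on a target scales with this level (protein = mRNA x attenuation), while
# the intrinsic fluctuation does not, so it sets the effect-to-noise ratio of
# the mutant contrasts.
.TF_LEVEL <- 4

# Amplitude range of the smooth developmental component of regulator
# activity. Kept below the intrinsic fluctuation scale so that regulator
# profiles are not dominated by the (shared, hence confounding) day shape.
.TF_AMP <- c(0.4, 0.7)
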