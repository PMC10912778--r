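#' Simulation configuration
#'
#' Builds the configuration object for the synthetic-data generator. The
#' defaults define the desk-scale study conditions used throughout the test
#' suite: five genotypes of a calpain mutant series (wild type, a null mutant,
#' two partial-activity deletion lines and an overexpressor) sampled at five
#' developmental days with three replicates, a layered signed regulatory
#' network of 20 transcription factors over 300 target genes, and
#' post-translational attenuation of cleaved TF proteins.
#'
#' @param seed integer; fully determines every generator output.
#' @param n_tf number of transcription-factor regulators.
#' @param n_targets number of non-regulator target genes.
#' @param layers depth of the regulator hierarchy; layer-1 TFs have no parents.
#' @param edges_per_target number of parents drawn for each downstream node.
#' @param sign_fraction_negative probability that an edge (or a target's
#'   cleaved-parent edge group) is repressive.
#' @param genotypes named numeric vector of calpain activity levels
#'   \eqn{a_g \ge 0}; the wild type is conventionally 1.
#' @param days numeric sampling days.
#' @param replicates replicates per genotype and day.
#' @param kappa positive attenuation rate: the protein-level multiplier of a
#'   cleaved TF in genotype g is \eqn{exp(-\kappa a_g)}.
#' @param noise_sd Gaussian measurement noise SD on the log-expression scale.
#' @param tf_noise_sd SD of intrinsic biological fluctuation of regulator
#'   transcripts. Unlike measurement noise it propagates to downstream
#'   targets, which is what makes parent identity recoverable from
#'   expression covariation (with only smooth day curves all regulators
#'   would be collinear at desk scale).
#' @param nb_dispersion optional negative-binomial dispersion; `NULL` (the
#'   default) keeps Gaussian noise on the log scale so the DGE model is exact.
#' @param frac_tf_cleaved fraction of TFs whose protein is cleaved and routed
#'   to N-degron decay.
#' @param protein_length_range integer range of simulated protein lengths.
#' @param trait_genotype_map named list: trait name -> character vector of
#'   genotype names whose samples are `TRUE` for that trait.
#'
#' @return an object of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_tf = 4, n_targets = 10)
#' cfg$genotypes
sim_config <- function(seed = 1L,
                       n_tf = 20L,
                       n_targets = 300L,
                       layers = 3L,
                       edges_per_target = 2L,
                       sign_fraction_negative = 0.3,
                       genotypes = c(WT = 1, dek1 = 0, dek1_loop = 0,
                                     dek1_lg3 = 0.5, oex1 = 2),
                       days = c(3, 5, 9, 12, 14),
                       replicates = 3L,
                       kappa = 1,
                       noise_sd = 0.05,
                       tf_noise_sd = 0.5,
                       nb_dispersion = NULL,
                       frac_tf_cleaved = 0.5,
                       protein_length_range = c(80L, 300L),
                       trait_genotype_map = list(
                         overbudding = c("dek1", "dek1_loop"))) {
  .assert(.is_count(seed + 1), "seed must be a single integer")
  for (nm in c("n_tf", "n_targets", "layers", "edges_per_target", "replicates"))
    .assert(.is_count(get(nm)), paste(nm, "must be a count >= 1"))
  .assert(.is_prop(sign_fraction_negative),
          "sign_fraction_negative must be in [0, 1]")
  .assert(.is_prop(frac_tf_cleaved), "frac_tf_cleaved must be in [0, 1]")
  .assert(is.numeric(genotypes) && length(genotypes) >= 1,
          "genotypes must be a named numeric vector")
  .assert(!is.null(names(genotypes)) && !anyDuplicated(names(genotypes)),
          "genotype names must be unique and non-empty")
  .assert(all(is.finite(genotypes)) && all(genotypes >= 0),
          "calpain activities a_g must be nonnegative")
  .assert(length(days) >= 2 && !anyDuplicated(days), "need >= 2 distinct days")
  .assert(is.numeric(kappa) && length(kappa) == 1 && kappa >= 0,
          "kappa must be a nonnegative rate")
  .assert(is.numeric(noise_sd) && noise_sd >= 0, "noise_sd must be >= 0")
  .assert(is.numeric(tf_noise_sd) && tf_noise_sd >= 0,
          "tf_noise_sd must be >= 0")
  if (!is.null(nb_dispersion))
    .assert(is.numeric(nb_dispersion) && nb_dispersion > 0,
            "nb_dispersion must be positive or NULL")
  .assert(length(protein_length_range) == 2 &&
            protein_length_range[1] >= 25 &&
            protein_length_range[2] >= protein_length_range[1],
          "protein_length_range must be (min, max) with min >= 25")
  .assert(is.list(trait_genotype_map), "trait_genotype_map must be a list")
  .assert(layers <= n_tf, "layers cannot exceed n_tf")
  unknown <- setdiff(unlist(trait_genotype_map), names(genotypes))
  .assert(length(unknown) == 0,
          paste("unknown genotype(s) in trait_genotype_map:",
                paste(unknown, collapse = ", ")))

  structure(list(
    seed = as.integer(seed), n_tf = as.integer(n_tf),
    n_targets = as.integer(n_targets), layers = as.integer(layers),
    edges_per_target = as.integer(edges_per_target),
    sign_fraction_negative = sign_fraction_negative,
    genotypes = genotypes, days = sort(days),
    replicates = as.integer(replicates), kappa = kappa,
    noise_sd = noise_sd, tf_noise_sd = tf_noise_sd,
    nb_dispersion = nb_dispersion,
    frac_tf_cleaved = frac_tf_cleaved,
    protein_length_range = as.integer(protein_length_range),
    trait_genotype_map = trait_genotype_map
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  %d TFs in %d layer(s), %d targets, %d parents/node\n",
              x$n_tf, x$layers, x$n_targets, x$edges_per_target))
  cat(sprintf("  genotypes: %s\n",
              paste(sprintf("%s (a=%g)", names(x$genotypes), x$genotypes),
                    collapse = ", ")))
  cat(sprintf("  days: %s, %d replicate(s); kappa=%g, noise_sd=%g\n",
              paste(x$days, collapse = ", "), x$replicates, x$kappa,
              x$noise_sd))
  cat(sprintf("  %.0f%% of TFs cleaved; %d trait(s); seed %d\n",
              100 * x$frac_tf_cleaved, length(x$trait_genotype_map), x$seed))
  invisible(x)
}

# Sample sheet implied by a configuration: one row per genotype x day x rep.
.sample_sheet <- function(config) {
  grid <- expand.grid(replicate = seq_len(config$replicates),
                      day = config$days,
                      genotype = names(config$genotypes),
                      stringsAsFactors = FALSE)
  grid <- grid[, c("genotype", "day", "replicate")]
  grid$sample <- sprintf("%s_d%02d_r%d", grid$genotype, grid$day,
                         grid$replicate)
  grid[, c("sample", "genotype", "day", "replicate")]
}
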