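# Synthetic-data generator: construction rules, determinism, and the
# biological orderings the planted ground truth promises.

test_that("same configuration reproduces identical outputs bitwise", {
  cfg <- tiny_config(seed = 42)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$truth$edges, s2$truth$edges)
  expect_identical(s1$expr$values, s2$expr$values)
  expect_identical(s1$proteome$sequences, s2$proteome$sequences)
  expect_identical(s1$proteome$sites, s2$proteome$sites)
  expect_identical(s1$traits, s2$traits)
})

test_that("network construction follows the layer contract", {
  cfg <- sim_config(seed = 1, n_tf = 2, n_targets = 3, layers = 1,
                    edges_per_target = 1)
  tr <- simulate_grn(cfg)
  expect_equal(nrow(tr$edges), 3)
  expect_true(all(tr$edges$regulator %in% tr$tf_ids))
  expect_true(all(tr$edges$target %in% tr$target_ids))
  # no self-edges, weights positive, signs in {-1, 1}
  expect_false(any(tr$edges$regulator == tr$edges$target))
  expect_true(all(tr$edges$weight > 0))
  expect_true(all(tr$edges$sign %in% c(-1, 1)))
})

test_that("sign_fraction_negative = 0 forces all activating edges", {
  cfg <- tiny_config(seed = 3, sign_fraction_negative = 0)
  tr <- simulate_grn(cfg)
  expect_true(all(tr$edges$sign == 1))
  expect_true(all(tr$planted_profile %in% c("none", "activator-target")))
})

test_that("too few regulators for the requested in-degree errors", {
  cfg <- sim_config(seed = 1, n_tf = 3, n_targets = 5, layers = 3,
                    edges_per_target = 2)
  expect_error(simulate_grn(cfg), "insufficient regulators")
})

test_that("negative calpain activity is rejected", {
  expect_error(sim_config(genotypes = c(WT = 1, bad = -0.5)), "nonnegative")
})

test_that("planted profiles give the promised genotype mean orderings", {
  cfg <- sim_config(seed = 5, n_tf = 10, n_targets = 60, layers = 2,
                    noise_sd = 0)
  tr <- simulate_grn(cfg)
  ex <- simulate_expression(tr, cfg)
  gmean <- function(g) rowMeans(ex$values[, ex$samples$genotype == g])
  prof <- tr$planted_profile
  act <- names(prof)[prof == "activator-target"]
  rep_ <- names(prof)[prof == "repressor-target"]
  expect_gt(length(act), 0)
  expect_gt(length(rep_), 0)
  expect_true(all(gmean("dek1")[act] > gmean("WT")[act] &
                    gmean("WT")[act] > gmean("oex1")[act]))
  expect_true(all(gmean("dek1")[rep_] < gmean("WT")[rep_] &
                    gmean("WT")[rep_] < gmean("oex1")[rep_]))
})

test_that("without any noise, genotype effects vanish exactly where promised", {
  # kappa = 0 switches off all attenuation: every genotype has identical
  # expected expression, and with all noise off, identical values
  cfg <- sim_config(seed = 2, n_tf = 6, n_targets = 20, layers = 2,
                    kappa = 0, noise_sd = 0, tf_noise_sd = 0,
                    replicates = 1)
  tr <- simulate_grn(cfg)
  ex <- simulate_expression(tr, cfg)
  by_g <- lapply(names(cfg$genotypes), function(g)
    unname(ex$values[, ex$samples$genotype == g]))
  for (i in seq_along(by_g)[-1])
    expect_equal(by_g[[i]], by_g[[1]], tolerance = 1e-12)

  # uncleaved TFs' targets are genotype-invariant even with kappa > 0
  cfg2 <- sim_config(seed = 2, n_tf = 6, n_targets = 20, layers = 2,
                     noise_sd = 0, tf_noise_sd = 0, replicates = 1,
                     frac_tf_cleaved = 0)
  tr2 <- simulate_grn(cfg2)
  ex2 <- simulate_expression(tr2, cfg2)
  by_g2 <- lapply(names(cfg2$genotypes), function(g)
    unname(ex2$values[, ex2$samples$genotype == g]))
  for (i in seq_along(by_g2)[-1])
    expect_equal(by_g2[[i]], by_g2[[1]], tolerance = 1e-12)
})

test_that("proteome plants NERD sites exactly on cleaved TFs", {
  cfg <- tiny_config(seed = 11)
  tr <- simulate_grn(cfg)
  pr <- simulate_proteome(tr, cfg)
  cls <- classify_sites(pr$sites, pr$sequences)
  nerd_by_protein <- tapply(cls$class == "NERD", cls$protein, sum)
  cleaved <- names(tr$cleaved)[tr$cleaved]
  uncleaved <- setdiff(names(pr$sequences), cleaved)
  expect_true(all(nerd_by_protein[cleaved] >= 1))
  hit_unc <- intersect(names(nerd_by_protein), uncleaved)
  expect_true(all(nerd_by_protein[hit_unc] == 0))
  # site windows are consistent with the sequences
  expect_identical(
    cls$window,
    unname(substring(pr$sequences[cls$protein], cls$position - 9,
                     cls$position + 10)))
})

test_that("trait tables are genotype lookups with degenerate-column flags", {
  cfg <- tiny_config(seed = 1)
  traits <- simulate_traits(cfg)
  sheet <- simulate_expression(simulate_grn(cfg), cfg)$samples
  expect_true(all(traits$overbudding[sheet$genotype == "dek1"]))
  expect_true(all(traits$overbudding[sheet$genotype == "dek1_loop"]))
  expect_false(any(traits$overbudding[sheet$genotype == "WT"]))

  cfg2 <- tiny_config(seed = 1, trait_genotype_map = list(none_true = character()))
  expect_false(any(simulate_traits(cfg2)$none_true))

  all_g <- names(cfg$genotypes)
  enc <- encode_traits(list(all_true = all_g, ok = c("dek1")), sheet)
  expect_identical(attr(enc, "degenerate"), "all_true")
  expect_true(all(enc$all_true))

  expect_error(
    simulate_traits(tiny_config(trait_genotype_map = list(x = "nope"))),
    "unknown genotype")
})
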