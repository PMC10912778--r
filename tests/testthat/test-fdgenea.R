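# FDGENEA: trait encoding, trait-wise DGE, component isolation and
# cumulative node statistics.

test_that("trait encoding supports the 17-trait study scale", {
  cfg <- tiny_config(seed = 1)
  sheet <- calpainGRN:::.sample_sheet(cfg)
  map <- stats::setNames(
    lapply(1:17, function(i) sample(names(cfg$genotypes), 2)),
    sprintf("trait%02d", 1:17))
  set.seed(1)
  enc <- encode_traits(map, sheet)
  expect_equal(ncol(enc), 18)
  expect_true(all(vapply(enc[-1], is.logical, TRUE)))
  expect_error(encode_traits(list(t = "missing_genotype"), sheet),
               "unknown genotype")
})

test_that("a noise-free trait shift is called 'up'", {
  expr <- toy_expression(n_genes = 10, sd = 0.01, shift = 1.5, seed = 6)
  trait <- expr$samples$genotype == "B"
  assoc <- trait_dge(expr, trait)
  expect_true(all(assoc$direction == "up"))
  expect_true(all(assoc$b > 1.3))
})

test_that("a trait orthogonal to expression yields uniform p-values", {
  expr <- toy_expression(n_genes = 800, sd = 1, shift = 0, seed = 7)
  set.seed(7)
  trait <- sample(rep(c(TRUE, FALSE), ncol(expr$values) / 2))
  assoc <- trait_dge(expr, trait)
  expect_gt(stats::ks.test(assoc$p, "punif")$p.value, 0.01)
  # constant trait carries no contrast
  expect_error(trait_dge(expr, rep(TRUE, ncol(expr$values))),
               ">= 2 samples")
})

test_that("component isolation attaches regulators and finds common TFs", {
  edges <- data.frame(regulator = c("r", "r", "q"),
                      target = c("g1", "g2", "g3"),
                      importance = 1, sign = 1)
  assoc <- data.frame(gene = c("g1", "g2", "g3", "r", "q"),
                      lrt_stat = c(30, 25, 20, 0.1, 0.2),
                      p = c(1e-8, 1e-7, 1e-6, 0.9, 0.8),
                      q = c(1e-7, 1e-6, 1e-5, 0.95, 0.9),
                      b = c(2, 2, -1, 0, 0),
                      direction = c("up", "up", "down", "ns", "ns"))
  attr(assoc, "trait") <- "demo"
  comps <- isolate_components(edges, assoc, q_max = 0.01)
  expect_equal(length(comps), 2)
  big <- comps[[1]]
  expect_setequal(big$nodes, c("r", "g1", "g2"))
  expect_equal(big$regulators_attached, "r")  # attached though ns itself
  expect_equal(big$common_upstream, "r")      # regulates two sig genes
  small <- comps[[2]]
  expect_setequal(small$nodes, c("q", "g3"))
  expect_equal(small$common_upstream, character())
  # no significant genes: empty component list
  assoc0 <- assoc; assoc0$q <- 1
  expect_equal(length(isolate_components(edges, assoc0)), 0)
})

test_that("node statistics follow the first-order vs total scopes", {
  edges <- data.frame(regulator = c("r", "r", "t"),
                      target = c("g1", "t", "g2"),
                      importance = 1, sign = 1)
  assoc <- data.frame(gene = c("r", "g1", "t", "g2"),
                      lrt_stat = c(0, 3, 1, 2),
                      p = c(0.9, 1e-6, 1e-4, 1e-5),
                      q = c(0.95, 1e-5, 1e-3, 1e-4),
                      b = c(0, 1, 1, 1),
                      direction = c("ns", "up", "up", "up"))
  attr(assoc, "trait") <- "demo"
  comps <- isolate_components(edges, assoc, q_max = 0.01)
  expect_equal(length(comps), 1)
  st <- node_stats(comps[[1]], assoc, regulators = c("r", "t"),
                   q_max = 0.01)
  r <- st[st$gene == "r", ]
  # direct targets of r: g1 (s=+3) and t (s=+1); g2 reachable via t (s=+2)
  expect_equal(r$cb_first, 4)
  expect_equal(r$cab_first, 4)
  expect_equal(r$cb_total, 6)
  expect_equal(r$cab_total, 6)
  expect_equal(r$n_down_first, 2)
  expect_equal(r$n_down_total, 3)
  expect_equal(r$n_down_tfs_first, 1)  # t is the only downstream regulator
  leaf <- st[st$gene == "g2", ]
  expect_true(all(leaf[, c("cb_first", "cab_first", "cb_total",
                           "cab_total")] == 0))
  # signed vs absolute sums: flip one b downward
  assoc2 <- assoc; assoc2$b[assoc2$gene == "g1"] <- -1
  st2 <- node_stats(comps[[1]], assoc2, q_max = 0.01)
  r2 <- st2[st2$gene == "r", ]
  expect_equal(r2$cb_first, -2)
  expect_equal(r2$cab_first, 4)
  expect_true(all(st2$cab_total >= abs(st2$cb_total)))
  expect_true(all(st2$cab_first >= abs(st2$cb_first)))
})

test_that("directional NEAT annotations merge up and down calls", {
  # wire an up-set into subnetwork I, a down-set into II, and unassociated
  # background genes into III (without background no set can be enriched)
  edges <- rbind(
    data.frame(regulator = "ru", target = sprintf("u%d", 1:8)),
    data.frame(regulator = "rd", target = sprintf("d%d", 1:8)),
    data.frame(regulator = "rb", target = sprintf("b%d", 1:16)))
  edges$importance <- 1; edges$sign <- 1
  part <- data.frame(gene = c("ru", sprintf("u%d", 1:8),
                              "rd", sprintf("d%d", 1:8),
                              "rb", sprintf("b%d", 1:16)),
                     community = rep(1:3, c(9, 9, 17)),
                     subnetwork = rep(c("I", "II", "III"), c(9, 9, 17)))
  assoc <- data.frame(
    gene = c(sprintf("u%d", 1:8), sprintf("d%d", 1:8),
             sprintf("b%d", 1:16), "ru", "rd", "rb"),
    lrt_stat = c(rep(30, 16), rep(0, 19)),
    p = c(rep(1e-9, 16), rep(0.9, 19)),
    q = c(rep(1e-8, 16), rep(0.9, 19)),
    b = c(rep(2, 8), rep(-2, 8), rep(0, 19)),
    direction = c(rep("up", 8), rep("down", 8), rep("ns", 19)))
  attr(assoc, "trait") <- "demo"
  nt <- trait_network_enrichment(assoc, edges, part, fdr = 0.05)
  ann <- nt$annotations
  expect_equal(ann$annotation[ann$subnetwork == "I"], "+")
  expect_equal(ann$annotation[ann$subnetwork == "II"], "-")
  expect_true(all(nt$combined$table$call[
    nt$combined$table$setB %in% c("I", "II")] == "+"))
})
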