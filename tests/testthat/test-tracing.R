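# Upstream regulon tracing, control fractions, dependency statistics and
# the final direct/indirect target filter.

test_that("regulons accumulate along reversed edges with self-exclusion", {
  chain <- data.frame(regulator = c("TF3", "TF2", "TF1"),
                      target = c("TF2", "TF1", "g"))
  reg <- upstream_regulon(chain, "g", max_order = 3)
  expect_equal(reg$order1, "TF1")
  expect_equal(reg$order2, c("TF1", "TF2"))
  expect_equal(reg$order3, c("TF1", "TF2", "TF3"))
  # 2-cycle: the focal gene never joins its own regulon
  cyc <- data.frame(regulator = c("a", "b"), target = c("b", "a"))
  reg2 <- upstream_regulon(cyc, "a", max_order = 3)
  expect_equal(reg2$order3, "b")
  # no parents: empty sets at every order
  iso <- data.frame(regulator = "a", target = "b")
  reg3 <- upstream_regulon(iso, "a", max_order = 3)
  expect_equal(lengths(reg3), c(order1 = 0L, order2 = 0L, order3 = 0L))
  expect_error(upstream_regulon(iso, "zz"), "not in network")
})

test_that("control fractions are plain proportions with an empty-set flag", {
  nerd <- c(TF1 = TRUE, TF2 = FALSE, TF3 = FALSE)
  prof <- c(TF1 = "none", TF2 = "activator-target",
            TF3 = "repressor-target")
  fr <- regulon_control_fractions(c("TF1", "TF2", "TF3"), nerd, prof)
  expect_equal(fr$pct_direct, 1 / 3)
  expect_equal(fr$pct_indirect, 2 / 3)
  expect_equal(fr$pct_either, 1)
  expect_false(fr$flagged)
  all_mis <- regulon_control_fractions(c("TF2", "TF3"), nerd, prof)
  expect_equal(all_mis$pct_indirect, 1)
  empty <- regulon_control_fractions(character(), nerd, prof)
  expect_true(empty$flagged)
  expect_true(is.na(empty$pct_direct))
})

test_that("pct_either dominates both component fractions over random cases", {
  set.seed(21)
  for (i in 1:25) {
    tfs <- sprintf("T%02d", 1:8)
    nerd <- stats::setNames(stats::runif(8) < 0.4, tfs)
    prof <- stats::setNames(ifelse(stats::runif(8) < 0.4,
                                   "activator-target", "none"), tfs)
    sub <- sample(tfs, sample(1:8, 1))
    fr <- regulon_control_fractions(sub, nerd, prof)
    expect_gte(fr$pct_either, max(fr$pct_direct, fr$pct_indirect))
  }
})

test_that("dependency statistics recover exact and null relationships", {
  n <- 500
  set.seed(31)
  pct <- stats::runif(n)
  regulons <- data.frame(gene = sprintf("g%03d", 1:n), n_order1 = 1,
                         n_order2 = 1, n_order3 = 1,
                         pct_direct = pct, pct_indirect = pct,
                         pct_either = pct, flagged = FALSE)
  scores <- stats::setNames(2 * pct, regulons$gene)
  dep <- misregulation_dependency(regulons, scores)
  row <- dep$overall[dep$overall$predictor == "pct_direct", ]
  expect_equal(row$slope, 2, tolerance = 1e-9)
  expect_equal(row$pearson_r, 1, tolerance = 1e-9)
  # independent scores: tau near zero
  scores2 <- stats::setNames(sample(scores), regulons$gene)
  dep2 <- misregulation_dependency(regulons, scores2)
  expect_lt(abs(dep2$overall$kendall_tau[1]), 0.1)
  # zero-variance predictor flagged
  regulons$pct_direct <- 0.5
  dep3 <- misregulation_dependency(regulons, scores)
  expect_true(dep3$overall$flagged[dep3$overall$predictor == "pct_direct"])
})

test_that("regulon-status cross-table reuses the chi-squared machinery", {
  regulons <- data.frame(
    gene = sprintf("g%02d", 1:40),
    pct_direct = rep(c(0, 0.5), each = 20),
    pct_indirect = rep(c(0, 0.5, 0, 0.5), each = 10),
    flagged = FALSE)
  mis <- stats::setNames(rep(c(FALSE, TRUE), each = 20), regulons$gene)
  ct <- crosstab_regulon_status(regulons, mis)
  expect_equal(sum(ct$table), 40)
  expect_equal(sum(ct$residuals^2), ct$statistic, tolerance = 1e-9)
  # equal proportions across strata: residuals vanish
  flat_mis <- stats::setNames(rep(c(TRUE, FALSE), 20), regulons$gene)
  ct2 <- crosstab_regulon_status(regulons, flat_mis)
  expect_true(all(abs(ct2$residuals) < 1e-9))
})

test_that("the final target filter keeps cleaved-TF -> misregulated edges", {
  edges <- data.frame(regulator = c("A", "B", "A"),
                      target = c("t1", "t2", "t3"),
                      importance = 1, sign = 1)
  nerd <- c(A = TRUE, B = FALSE)
  prof <- c(t1 = "activator-target", t2 = "repressor-target", t3 = "none",
            A = "none", B = "none")
  calls <- filter_dek1_targets(edges, nerd, prof)
  expect_equal(nrow(calls$edges), 1)
  expect_equal(calls$edges$regulator, "A")
  expect_equal(calls$edges$target, "t1")
  expect_equal(calls$direct_targets, "A")
  expect_equal(calls$indirect_targets, "t1")
  expect_equal(calls$both, character())
  # a cleaved AND misregulated TF with a cleaved upstream regulator joins both
  edges2 <- rbind(edges,
                  data.frame(regulator = "C", target = "A",
                             importance = 1, sign = 1))
  nerd2 <- c(nerd, C = TRUE)
  prof2 <- prof; prof2["A"] <- "activator-target"
  calls2 <- filter_dek1_targets(edges2, nerd2, prof2)
  expect_true("A" %in% calls2$both)
  expect_true(all(calls2$both %in% calls2$direct_targets))
  # empty network
  empty <- filter_dek1_targets(edges[0, ], nerd, prof)
  expect_equal(nrow(empty$edges), 0)
  expect_equal(length(empty$direct_targets), 0)
})

test_that("regulon extension attaches top-ranked cleaved TFs and connects genes", {
  # star: one cleaved hub regulates every focal gene
  edges <- data.frame(regulator = c(rep("hub", 4), "minor"),
                      target = c(sprintf("g%d", 1:4), "g1"),
                      importance = 1, sign = 1)
  hier <- data.frame(gene = c("hub", "minor", sprintf("g%d", 1:4)),
                     local_reaching_centrality = c(0.9, 0.1, 0, 0, 0, 0))
  nerd <- c(hub = TRUE, minor = TRUE)
  ext <- extend_regulon(sprintf("g%d", 1:4), edges, hier, nerd, max_tfs = 1)
  expect_true("hub" %in% ext$attached_tfs)
  expect_false("minor" %in% ext$attached_tfs)  # g1 prefers the higher-LRC hub
  expect_equal(ext$connectivity, 1)
  # no qualifying TFs: subgraph reduces to the input genes
  ext2 <- extend_regulon(sprintf("g%d", 1:4), edges, hier,
                         c(hub = FALSE, minor = FALSE))
  expect_equal(sort(ext2$nodes), sort(sprintf("g%d", 1:4)))
})

test_that("unchanged upstream TFs require a misregulated target", {
  edges <- data.frame(regulator = c("u", "u", "m", "x"),
                      target = c("t1", "t2", "t3", "t4"),
                      importance = 1, sign = 1)
  prof <- c(u = "none", m = "activator-target", x = "none",
            t1 = "activator-target", t2 = "repressor-target",
            t3 = "activator-target", t4 = "none")
  mis <- names(prof)[prof != "none"]
  got <- upstream_unchanged_tfs(edges, mis, prof)
  expect_true("u" %in% got)        # unchanged, two misregulated targets
  expect_false("m" %in% got)       # itself misregulated
  expect_false("x" %in% got)       # no misregulated target
})
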