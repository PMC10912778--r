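# Spline-LRT differential expression: effect recovery, degenerate inputs,
# BH adjustment, profile classification and phase clustering.

test_that("a pure genotype shift is recovered exactly without noise", {
  expr <- toy_expression(n_genes = 20, sd = 0, shift = 2, seed = 1)
  # sd = 0 makes genes constant within genotype; add a day trend inside the
  # spline span so the full model fits exactly and the shift stays delta=+2
  day_curve <- 0.5 * expr$samples$day
  expr$values <- expr$values + matrix(day_curve, nrow(expr$values),
                                      ncol(expr$values), byrow = TRUE)
  res <- timecourse_dge(expr, c("A", "B"))
  expect_equal(res$b, rep(2, 20), tolerance = 1e-8)
  expect_true(all(res$p < 1e-12))
  expect_true(all(res$lrt_stat > 0))
})

test_that("constant genes yield zero statistic and p = 1", {
  expr <- toy_expression(n_genes = 5, sd = 1, seed = 2)
  expr$values[3, ] <- 7
  res <- timecourse_dge(expr, c("A", "B"))
  expect_equal(res$lrt_stat[3], 0)
  expect_equal(res$p[3], 1)
})

test_that("identical genotypes give null-calibrated results", {
  expr <- toy_expression(n_genes = 500, sd = 1, seed = 3, shift = 0)
  res <- timecourse_dge(expr, c("A", "B"))
  expect_gt(stats::ks.test(res$p, "punif")$p.value, 0.01)
  expect_lt(mean(res$q < 0.1), 0.12)
})

test_that("BH adjustment matches the step-up hand computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  # monotone w.r.t. the p ordering
  p <- c(0.001, 0.2, 0.04, 0.9, 0.015)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

# Build a dge_result-like object with prescribed b and q.
fake_dge <- function(genes, b, q, contrast) {
  out <- data.frame(gene = genes, lrt_stat = abs(b) * 10, p = q, q = q,
                    b = b)
  attr(out, "contrast") <- contrast
  class(out) <- c("dge_result", "data.frame")
  out
}

test_that("profile classification implements the two sign patterns", {
  genes <- c("g1", "g2", "g3", "g4")
  # g1: (+,-,+) all significant -> activator-target
  # g2: (-,+,-) all significant -> repressor-target
  # g3: (+,-,+) but one contrast not significant -> none
  # g4: inconsistent signs -> none
  mut_wt <- fake_dge(genes, b = c(2, -2, 2, 2), q = c(.01, .01, .01, .01),
                     contrast = c("WT", "dek1"))
  oex_wt <- fake_dge(genes, b = c(-1, 1, -1, 1), q = c(.01, .01, .5, .01),
                     contrast = c("WT", "oex1"))
  mut_oex <- fake_dge(genes, b = c(3, -3, 3, 3), q = c(.01, .01, .01, .01),
                      contrast = c("oex1", "dek1"))
  prof <- classify_profiles(mut_wt, oex_wt, mut_oex)
  expect_equal(prof$profile,
               c("activator-target", "repressor-target", "none", "none"))
})

test_that("profile classification reorients flipped contrasts", {
  genes <- c("g1", "g2")
  mut_wt <- fake_dge(genes, b = c(2, -2), q = c(.01, .01), c("WT", "dek1"))
  # same information entered with the opposite orientation
  wt_oex <- fake_dge(genes, b = c(1, -1), q = c(.01, .01), c("oex1", "WT"))
  mut_oex <- fake_dge(genes, b = c(3, -3), q = c(.01, .01), c("oex1", "dek1"))
  prof <- classify_profiles(mut_wt, wt_oex, mut_oex)
  expect_equal(prof$profile, c("activator-target", "repressor-target"))
})

test_that("cumulative misregulation is the plain sum of LRT statistics", {
  genes <- c("a", "b")
  d1 <- fake_dge(genes, b = c(1, 1), q = c(.5, .5), c("WT", "dek1"))
  d2 <- fake_dge(genes, b = c(1, 1), q = c(.5, .5), c("WT", "oex1"))
  d3 <- fake_dge(genes, b = c(1, 1), q = c(.5, .5), c("oex1", "dek1"))
  d1$lrt_stat <- c(2.5, 0); d2$lrt_stat <- c(3.5, 0); d3$lrt_stat <- c(4, 0)
  cum <- cumulative_misregulation(d1, d2, d3)
  expect_equal(unname(cum), c(10, 0))
  expect_equal(cumulative_misregulation(d3, d1, d2), cum)
})

test_that("phase clustering separates early from late peaking genes", {
  days <- c(3, 5, 9, 12, 14)
  grid <- expand.grid(replicate = 1:2, day = days, genotype = "WT",
                      stringsAsFactors = FALSE)
  grid$sample <- sprintf("s%02d", seq_len(nrow(grid)))
  early <- exp(-(grid$day - 3)^2 / 4)
  late <- exp(-(grid$day - 14)^2 / 4)
  vals <- rbind(matrix(rep(early, each = 4), 4, byrow = FALSE),
                matrix(rep(late, each = 4), 4, byrow = FALSE))
  vals <- matrix(c(rep(early, 4), rep(late, 4)), 8, length(early),
                 byrow = TRUE)
  rownames(vals) <- sprintf("g%d", 1:8)
  colnames(vals) <- grid$sample
  expr <- expression_dataset(vals, grid[, c("sample", "genotype", "day",
                                            "replicate")])
  labs <- cluster_phases(expr, rownames(vals), k = 2, seed = 1)
  expect_equal(length(unique(labs[1:4])), 1)
  expect_equal(length(unique(labs[5:8])), 1)
  expect_false(labs[1] == labs[5])
  # degenerate: identical profiles collapse to one cluster
  expect_warning(one <- cluster_phases(expr, rownames(vals)[1:4], k = 3,
                                       seed = 1),
                 "reduced")
  expect_equal(length(unique(one)), 1)
})
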