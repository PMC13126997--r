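# Independent brute-force median-of-ratios, written against the definition.
oracle_size_factors <- function(counts) {
  keep <- apply(counts > 0, 1, all)
  geo <- exp(rowMeans(log(counts[keep, , drop = FALSE])))
  sf <- vapply(seq_len(ncol(counts)), function(s) {
    exp(median(log(counts[keep, s] / geo)))
  }, numeric(1))
  sf / exp(mean(log(sf)))
}

test_that("size factors match the brute-force median-of-ratios oracle", {
  set.seed(11)
  counts <- matrix(rnbinom(300, mu = 50, size = 5) + 1, nrow = 100)
  colnames(counts) <- paste0("s", 1:3)
  expect_equal(unname(compute_size_factors(counts)), oracle_size_factors(counts),
               tolerance = 1e-12)
  # doubling one sample doubles its factor (up to the geometric rescale)
  doubled <- cbind(counts[, 1], counts[, 1] * 2)
  colnames(doubled) <- c("a", "b")
  sf <- compute_size_factors(doubled)
  expect_equal(unname(sf["b"] / sf["a"]), 2, tolerance = 1e-12)
  # identical samples give unit factors
  same <- cbind(counts[, 1], counts[, 1])
  colnames(same) <- c("a", "b")
  expect_equal(unname(compute_size_factors(same)), c(1, 1), tolerance = 1e-12)
})

test_that("size factors agree with the established median-of-ratios implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(12)
  counts <- matrix(rnbinom(600, mu = 80, size = 5), nrow = 100)
  counts[1:50, ] <- counts[1:50, ] + 1
  colnames(counts) <- paste0("s", 1:6)
  ours <- compute_size_factors(counts)
  ref <- DESeq2::estimateSizeFactorsForMatrix(counts)
  ref <- ref / exp(mean(log(ref)))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-8)
})

test_that("all-zero-overlap matrices fall back to total-count factors", {
  counts <- matrix(c(5L, 0L, 0L, 10L), nrow = 2,
                   dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_warning(sf <- compute_size_factors(counts), "total-count")
  expect_equal(unname(sf["b"] / sf["a"]), 2, tolerance = 1e-12)
})

test_that("NB Wald fit recovers exact group-mean ratios on balanced designs", {
  groups <- rep(c("A", "B"), each = 5)
  sf <- rep(1, 10)
  res <- fit_gene_nb(rep(100L, 10), groups, sf)
  expect_equal(res$log2_fc, 0, tolerance = 1e-9)

  res2 <- fit_gene_nb(c(rep(100L, 5), rep(200L, 5)), groups, sf)
  expect_equal(res2$log2_fc, 1, tolerance = 1e-6)
  expect_lt(res2$p_value, 0.01)

  res3 <- fit_gene_nb(rep(0L, 10), groups, sf)
  expect_equal(res3$log2_fc, 0)
  expect_equal(res3$p_value, 1)
  expect_identical(res3$flag, "all_zero")

  expect_error(fit_gene_nb(rep(1L, 4), c("A", "A", "A", "B"), rep(1, 4)),
               class = "lumi_validation_error")
})

test_that("Wald log2FC equals the log group-mean ratio for large counts", {
  set.seed(21)
  groups <- rep(c("A", "B"), each = 5)
  for (i in 1:5) {
    y <- c(rnbinom(5, mu = 2000, size = 10), rnbinom(5, mu = 5000, size = 10))
    res <- fit_gene_nb(y, groups, rep(1, 10))
    expect_equal(res$log2_fc, log2(mean(y[6:10]) / mean(y[1:5])), tolerance = 1e-3)
  }
})

test_that("BH matches the step-up oracle exhaustively for short p-vectors", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(0.37), 0.37)
  expect_equal(adjust_bh(rep(1, 4)), rep(1, 4))
  grid <- c(0.001, 0.01, 0.05, 0.5, 1)
  for (len in 1:6) {
    combos <- as.matrix(expand.grid(rep(list(grid), len)))
    ours <- apply(combos, 1, function(p) adjust_bh(unname(p)))
    oracle <- apply(combos, 1, function(p) oracle_bh(unname(p)))
    expect_equal(ours, oracle, tolerance = 1e-12)
  }
  expect_error(adjust_bh(c(0.5, 1.2)), class = "lumi_validation_error")
})

test_that("q-values never fall below raw p-values", {
  set.seed(31)
  for (i in 1:20) {
    p <- runif(50)^2
    expect_true(all(adjust_bh(p) >= p - 1e-12))
  }
})

test_that("RPKM satisfies the unit case and scale invariance", {
  counts <- matrix(c(10L, 999990L), nrow = 2,
                   dimnames = list(c("g1", "g2"), "s1"))
  em <- expression_matrix(counts, c(g1 = 1000L, g2 = 1000L),
                          tibble::tibble(sample_id = "s1", group = "CTRL",
                                         compartment = "LAC", replicate = 1L))
  rpkm <- compute_rpkm(em)
  expect_equal(rpkm["g1", "s1"], 10)

  set.seed(41)
  counts <- matrix(rpois(200, 50) + 1L, nrow = 50)
  rownames(counts) <- paste0("g", 1:50); colnames(counts) <- paste0("s", 1:4)
  em <- expression_matrix(counts, setNames(rep(500L, 50), rownames(counts)),
                          tibble::tibble(sample_id = colnames(counts), group = "CTRL",
                                         compartment = "LAC", replicate = 1:4))
  em2 <- expression_matrix(counts * 3L, em$gene_lengths, em$samples)
  expect_equal(compute_rpkm(em), compute_rpkm(em2), tolerance = 1e-12)
  counts0 <- counts; counts0[1, 1] <- 0L
  em0 <- expression_matrix(counts0, em$gene_lengths, em$samples)
  expect_equal(compute_rpkm(em0)[1, 1], 0)
})

test_that("DEG calling applies both thresholds with direction", {
  ct <- tibble::tibble(gene_id = c("up", "weak_fc", "weak_q", "down"),
                       log2_fc = c(log2(2.5), log2(1.5), log2(3), -log2(4)),
                       q_value = c(0.01, 0.001, 0.2, 0.04))
  ct$des <- compute_des(ct$log2_fc, ct$q_value)
  degs <- call_degs(ct, 2, 0.05)
  expect_setequal(degs$gene_id, c("up", "down"))
  expect_equal(degs$direction[degs$gene_id == "up"], 1)
  expect_equal(degs$direction[degs$gene_id == "down"], -1)
  # relaxed fold threshold admits the 1.5-fold gene
  expect_true("weak_fc" %in% call_degs(ct, 1.25, 0.05)$gene_id)
})

test_that("sensitivity filter reports the retained fraction", {
  ct <- tibble::tibble(gene_id = paste0("g", 1:10),
                       log2_fc = rep(2, 10), q_value = rep(0.01, 10))
  ct$des <- compute_des(ct$log2_fc, ct$q_value)
  degs <- call_degs(ct)
  rpkm <- setNames(c(rep(1, 9), 0.001), ct$gene_id)
  res <- sensitivity_filter(degs, rpkm, floor = 0.01)
  expect_equal(res$retained_fraction, 0.9)
  expect_equal(nrow(res$degs), 9)
  all_low <- sensitivity_filter(degs, setNames(rep(0.001, 10), ct$gene_id))
  expect_equal(all_low$retained_fraction, 0)
  expect_equal(nrow(all_low$degs), 0)
  all_high <- sensitivity_filter(degs, setNames(rep(5, 10), ct$gene_id))
  expect_equal(all_high$retained_fraction, 1)
})

test_that("fold over control normalizes to the control mean", {
  expect_equal(fold_over_control(c(2, 4), c(2, 2)), c(1, 2))
  expect_equal(fold_over_control(6, c(1, 3)), 3)
  ctrl <- c(1.5, 2.5, 2)
  expect_equal(mean(fold_over_control(ctrl, ctrl)), 1)
  expect_error(fold_over_control(1, c(0, 0)), class = "lumi_validation_error")
})

test_that("a true 4-fold effect is detected with high power at study settings", {
  set.seed(51)
  groups <- rep(c("A", "B"), each = 5)
  n_genes <- 150
  res <- purrr::map_dfr(seq_len(n_genes), function(g) {
    y <- c(rnbinom(5, mu = 100, size = 10), rnbinom(5, mu = 400, size = 10))
    fit_gene_nb(y, groups, rep(1, 10))
  })
  q <- adjust_bh(res$p_value)
  detected <- abs(res$log2_fc) >= 1 & q < 0.05
  expect_gte(mean(detected), 0.9)
})

test_that("contrast tables satisfy their invariants on synthetic data", {
  ct <- small_contrast("CTRL", "DH")
  expect_true(all(ct$q_value >= ct$p_value - 1e-12))
  expect_true(all(ct$q_value <= 1))
  nz <- ct$q_value < 1 & ct$log2_fc != 0
  expect_true(all(sign(ct$des[nz]) == sign(ct$log2_fc[nz])))
  expect_true(all(ct$des[ct$log2_fc == 0] == 0))
  expect_identical(attr(ct, "contrast"), "DH v CTRL")
})
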