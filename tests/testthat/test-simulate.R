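test_that("planted truths have exactly k regulators per gene, reproducibly", {
  tr <- simulate_truth(n_tfs = 50, n_genes = 30, k_per_gene = 5, seed = 1)
  expect_equal(unname(colSums(tr$B != 0)), rep(5L, 30))
  nz <- abs(tr$B[tr$B != 0])
  expect_true(all(nz >= 0.5 & nz <= 2))
  expect_identical(tr$B, simulate_truth(seed = 1)$B)
  expect_false(identical(tr$B, simulate_truth(seed = 2)$B))
  expect_error(simulate_truth(n_tfs = 3, k_per_gene = 5), "exceed")

  pooled <- simulate_truth(n_tfs = 50, n_genes = 30, k_per_gene = 5,
                           regulator_pool = 8, seed = 3)
  active <- which(rowSums(pooled$B != 0) > 0)
  expect_true(all(active <= 8))
})

test_that("noiseless fully observed data is exactly linear in the drivers", {
  tr <- simulate_truth(n_tfs = 10, n_genes = 4, k_per_gene = 3,
                       noise_sd = 0, missing_rate = 0, seed = 5)
  sim <- simulate_data(tr, n_cells = 300, seed = 5)
  expect_false(anyNA(sim$velocity))
  for (g in tr$gene_ids) {
    fit <- lm(sim$velocity[, g] ~ sim$latent)
    r2 <- suppressWarnings(summary(fit)$r.squared) # fit is essentially perfect
    expect_gt(r2, 0.99)
  }
  # and the log-RPKM transform recovers an affine image of the drivers
  lx <- log_rpkm(sim$expression)
  keep <- colSums(sim$latent < -10 / 3) == 0 # clamp-free TFs
  expect_equal(unname(lx[, keep]), unname(0.3 * sim$latent[, keep] + 1),
               tolerance = 1e-12)
})

test_that("missingness matches the binomial rate and is reproducible", {
  tr <- simulate_truth(n_tfs = 5, n_genes = 10, k_per_gene = 2,
                       missing_rate = 0.3, seed = 6)
  sim <- simulate_data(tr, n_cells = 1000, seed = 6)
  frac <- mean(is.na(sim$velocity))
  sd4 <- 4 * sqrt(0.3 * 0.7 / length(sim$velocity))
  expect_lt(abs(frac - 0.3), sd4)
  sim2 <- simulate_data(tr, n_cells = 1000, seed = 6)
  expect_identical(sim$velocity, sim2$velocity)
})

test_that("the toy genome makes activity scores informative about the truth", {
  tr <- simulate_truth(n_tfs = 12, n_genes = 6, k_per_gene = 3, seed = 7)
  sim <- simulate_data(tr, n_cells = 10, seed = 7)
  cat <- assign_sites_to_promoters(sim$sites, sim$genes)
  act <- compute_activity(cat, normalize_peaks(sim$peaks),
                          tf_ids = tr$tf_ids, gene_ids = tr$gene_ids)
  regulators <- act$a_sum[tr$B != 0]
  decoys <- act$a_sum[tr$B == 0]
  expect_true(all(regulators > 0))
  expect_true(all(decoys == 0))
})

test_that("drop-out zeroes the stated fraction of raw entries, seeded", {
  set.seed(8)
  x <- matrix(runif(20000, 1, 100), 200, 100)
  expect_identical(apply_dropout(x, 0, seed = 1), x)
  d <- apply_dropout(x, 0.6, seed = 1)
  frac <- mean(d == 0)
  expect_lt(abs(frac - 0.6), 4 * sqrt(0.6 * 0.4 / length(x)))
  expect_identical(d, apply_dropout(x, 0.6, seed = 1))
  expect_false(identical(d, apply_dropout(x, 0.6, seed = 2)))
  expect_error(apply_dropout(x, 1), "rate")
})

test_that("per-cell simulation emits a usable ownership map", {
  tr <- simulate_truth(n_tfs = 6, n_genes = 4, k_per_gene = 2, seed = 9)
  sim <- simulate_data(tr, n_cells = 5, seed = 9, per_cell = TRUE)
  expect_length(sim$peaks$cell_assignment, 5)
  expect_true(all(lengths(sim$peaks$cell_assignment) >= 1))
  pc <- compute_activity_per_cell(
    assign_sites_to_promoters(sim$sites, sim$genes), sim$peaks,
    tf_ids = tr$tf_ids, gene_ids = tr$gene_ids)
  expect_equal(pc$mode, "per_cell")
})
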