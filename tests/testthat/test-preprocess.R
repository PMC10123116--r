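test_that("ChIP-seq QC filter applies the five criteria with inclusive bounds", {
  meta <- tibble::tibble(
    sample_id = c("s1", "s2", "s3"),
    median_quality_score = c(30, 25, 20),
    uniquely_mapped_ratio = c(70, 60, 70),
    pbc = c(85, 80, 85),
    frip = c(2, 1, 2),
    peaks_fold_change_above_10 = c(600, 500, 600))
  expect_equal(filter_chipseq_samples(meta), c("s1", "s2"))

  # each criterion rejects independently
  for (col in names(meta)[-1]) {
    m <- meta[1, ]
    m[[col]] <- 0
    expect_equal(filter_chipseq_samples(m), character(0))
  }
  m <- meta
  m$frip[2] <- NA
  expect_error(filter_chipseq_samples(m), "s2.*frip")
})

test_that("gene filtering uses a strict < threshold and drops emptied cells", {
  set.seed(1)
  v <- matrix(rnorm(40), 10, 4,
              dimnames = list(paste0("c", 1:10), paste0("g", 1:4)))
  v[1:8, 1] <- NA  # g1: 2 observed
  v[1:5, 2] <- NA  # g2: 5 observed
  out <- filter_genes(v, min_cells = 5)
  expect_equal(colnames(out), c("g2", "g3", "g4"))
  out2 <- filter_genes(v, min_cells = 2)
  expect_equal(ncol(out2), 4)
  expect_error(filter_genes(v, min_cells = 100), "lower min_cells")

  # cells with no remaining observed gene are dropped
  v2 <- matrix(NA_real_, 3, 2, dimnames = list(paste0("c", 1:3), c("g1", "g2")))
  v2[1:2, 1] <- 1:2
  v2[1, 2] <- 3
  out3 <- filter_genes(v2, min_cells = 2)
  expect_equal(rownames(out3), c("c1", "c2"))
})

test_that("filter_genes is monotone in min_cells", {
  set.seed(2)
  v <- matrix(rnorm(200), 20, 10,
              dimnames = list(paste0("c", 1:20), paste0("g", 1:10)))
  v[sample(length(v), 120)] <- NA
  kept <- lapply(c(2, 5, 8), function(k) {
    colnames(tryCatch(filter_genes(v, k), error = function(e) v[, 0]))
  })
  expect_true(all(kept[[2]] %in% kept[[1]]))
  expect_true(all(kept[[3]] %in% kept[[2]]))
})

test_that("log transform uses a +1 pseudocount and rejects negatives", {
  x <- matrix(c(0, 9, 99, 999), 2, 2)
  expect_equal(log_rpkm(x), matrix(c(0, 1, 2, 3), 2, 2))
  expect_error(log_rpkm(matrix(-1)), "negative")
})

test_that("column standardization: population sd, constant guard, idempotence, masks", {
  m <- cbind(a = c(1, 2, 3))
  s <- standardize_columns(m)
  expect_equal(as.numeric(s), c(-1, 0, 1) * sqrt(1.5), tolerance = 1e-12)

  expect_equal(as.numeric(standardize_columns(cbind(c(5, 5, 5)))), c(0, 0, 0))

  set.seed(3)
  big <- matrix(rnorm(300), 60, 5)
  once <- standardize_columns(big)
  expect_equal(colMeans(once), rep(0, 5), tolerance = 1e-9)
  expect_equal(standardize_columns(once), once, tolerance = 1e-9)

  withNA <- big
  withNA[sample(length(big), 50)] <- NA
  s2 <- standardize_columns(withNA)
  expect_equal(is.na(s2), is.na(withNA))
  expect_equal(colMeans(s2, na.rm = TRUE), rep(0, 5), tolerance = 1e-9)
  obs_sd <- apply(s2, 2, function(cl) {
    cl <- cl[!is.na(cl)]
    sqrt(mean((cl - mean(cl))^2))
  })
  expect_equal(obs_sd, rep(1, 5), tolerance = 1e-9)
})

test_that("cell splits are 9:1 by default, deterministic, and a partition", {
  ids <- paste0("c", 1:100)
  sp <- split_cells(ids, seed = 5)
  expect_length(sp$train, 90)
  expect_length(sp$test, 10)
  expect_identical(sp, split_cells(ids, seed = 5))
  expect_false(identical(sp, split_cells(ids, seed = 6)))
  expect_setequal(c(sp$train, sp$test), ids)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_error(split_cells("c1"), "at least 2")
  expect_error(split_cells(ids, ratio = 1.2), "ratio")
})

test_that("task assembly keeps only velocity-bearing cells and broadcasts activity", {
  tf_ids <- c("TF1", "TF2")
  a_sum <- matrix(c(1, 0), 2, 1, dimnames = list(tf_ids, "gA"))
  act <- scale_activity(tf_activity(a_sum, a_sum / 2))
  x <- matrix(rnorm(8), 4, 2, dimnames = list(paste0("c", 1:4), tf_ids))
  y <- matrix(c(0.5, NA, -0.2, NA), 4, 1, dimnames = list(rownames(x), "gA"))
  td <- assemble_task_dataset("gA", x, y, act, rownames(x))
  expect_equal(td$cell_ids, c("c1", "c3"))
  expect_equal(nrow(td$features), 2)
  expect_equal(td$features[1, 1:4], td$features[2, 1:4]) # broadcast activity
  expect_equal(unname(td$features[, "x.TF1"]), unname(x[c(1, 3), "TF1"]))
  expect_equal(td$targets, unname(y[c(1, 3), 1]))
  y_none <- y; y_none[] <- NA
  expect_error(assemble_task_dataset("gA", x, y_none, act, rownames(x)), "no cell")
  expect_error(assemble_task_dataset("missing", x, y, act, rownames(x)), "absent")
})

test_that("per-cell activity gives rows cell-specific features", {
  genes <- data.frame(gene_id = "gA", chrom = "chr1", strand = "+", tss = 5000)
  sites <- tibble::tibble(tf = c("TF1", "TF2"), chrom = "chr1",
                          start = c(4500, 4600), end = c(4700, 4800))
  peaks_tbl <- tibble::tibble(chrom = "chr1", start = c(4500, 4600), end = c(4700, 4800))
  cat <- assign_sites_to_promoters(sites, genes)
  pc <- compute_activity_per_cell(
    cat, peak_set(peaks_tbl, cell_assignment = list(c1 = 1L, c2 = 2L)),
    tf_ids = c("TF1", "TF2"), gene_ids = "gA")
  act <- scale_activity(pc)
  x <- matrix(0, 2, 2, dimnames = list(c("c1", "c2"), c("TF1", "TF2")))
  y <- matrix(c(1, -1), 2, 1, dimnames = list(rownames(x), "gA"))
  td <- assemble_task_dataset("gA", x, y, act, rownames(x))
  expect_false(isTRUE(all.equal(td$features[1, ], td$features[2, ])))
})

test_that("training and testing splits are standardized independently", {
  sim <- tiny_sim()
  act <- compute_activity(
    assign_sites_to_promoters(sim$data$sites, sim$data$genes),
    normalize_peaks(sim$data$peaks),
    tf_ids = sim$truth$tf_ids, gene_ids = sim$truth$gene_ids)
  prep <- prepare_inputs(sim$data$expression, sim$data$velocity, act, seed = 4)
  # means of the x-block are ~0 within each split separately
  n <- length(prep$tf_ids)
  for (tasks in list(prep$train_tasks, prep$test_tasks)) {
    xblock <- do.call(rbind, lapply(tasks, function(d) d$features[, 2 * n + seq_len(n)]))
    expect_lt(max(abs(colMeans(xblock))), 0.35)
  }
  expect_equal(colMeans(prep$x_train), setNames(rep(0, n), prep$tf_ids),
               tolerance = 1e-9)
})
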