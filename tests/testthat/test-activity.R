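make_catalog <- function(sites, genes, ...) {
  assign_sites_to_promoters(sites, genes, ...)
}

test_that("a_sum sums overlap fractions and a_mean averages them", {
  genes <- data.frame(gene_id = "gA", chrom = "chr1", strand = "+", tss = 10000)
  # site 1: [9000,9100) half-covered; site 2: [10000,10100) fully covered
  sites <- tibble::tibble(tf = "TF1", chrom = "chr1",
                          start = c(9000, 10000), end = c(9100, 10100))
  peaks <- normalize_peaks(peak_set(data.frame(chrom = "chr1",
                                               start = c(9050, 9950),
                                               end = c(9100, 10200))))
  act <- compute_activity(make_catalog(sites, genes), peaks)
  expect_equal(act$a_sum["TF1", "gA"], 1.5)
  expect_equal(act$a_mean["TF1", "gA"], 0.75)
  expect_false(act$scaled)
})

test_that("pairs absent from the catalog score zero; single covered site gives 1", {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                      strand = "+", tss = c(10000, 50000))
  sites <- tibble::tibble(tf = "TF1", chrom = "chr1", start = 10000, end = 10100)
  peaks <- normalize_peaks(peak_set(data.frame(chrom = "chr1", start = 9000, end = 11000)))
  act <- compute_activity(make_catalog(sites, genes), peaks,
                          tf_ids = c("TF1", "TF2"), gene_ids = c("gA", "gB"))
  expect_equal(act$a_sum["TF1", "gA"], 1)
  expect_equal(act$a_mean["TF1", "gA"], 1)
  expect_equal(act$a_sum["TF2", "gA"], 0)
  expect_equal(act$a_sum["TF1", "gB"], 0)
})

test_that("a_sum = m * a_mean identically on random toy genomes", {
  set.seed(202)
  for (i in 1:25) {
    genes <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                        strand = sample(c("+", "-"), 2, replace = TRUE),
                        tss = c(4000, 7000))
    sites <- dplyr::bind_rows(
      dplyr::mutate(rand_intervals(sample(2:12, 1)), tf = "TF1"),
      dplyr::mutate(rand_intervals(sample(2:12, 1)), tf = "TF2"))
    peaks <- normalize_peaks(peak_set(rand_intervals(sample(1:20, 1))))
    cat <- make_catalog(sites, genes, upstream = 2000, downstream = 2000)
    if (!nrow(cat)) next
    act <- compute_activity(cat, peaks)
    m <- table(factor(cat$tf, rownames(act$a_sum)),
               factor(cat$gene_id, colnames(act$a_sum)))
    expect_equal(act$a_sum, act$a_mean * unclass(as.matrix(m)), ignore_attr = TRUE)
    expect_true(all(act$a_mean >= 0 & act$a_mean <= 1))
  }
})

test_that("log2(x+1) scaling maps 0 to 0 and refuses to run twice", {
  genes <- data.frame(gene_id = "gA", chrom = "chr1", strand = "+", tss = 10000)
  sites <- tibble::tibble(tf = "TF1", chrom = "chr1", start = c(9000, 10000),
                          end = c(9100, 10100))
  peaks <- normalize_peaks(peak_set(data.frame(chrom = "chr1", start = c(9050, 9950),
                                               end = c(9100, 10200))))
  act <- compute_activity(make_catalog(sites, genes), peaks)
  sc <- scale_activity(act)
  expect_true(sc$scaled)
  expect_equal(sc$a_sum["TF1", "gA"], log2(2.5))
  expect_equal(sc$a_mean["TF1", "gA"], log2(1.75))
  expect_error(scale_activity(sc), "twice")

  zero <- act
  zero$a_sum[] <- 0; zero$a_mean[] <- 0
  z <- scale_activity(zero)
  expect_true(all(z$a_sum == 0))
})

test_that("per-cell mode with one all-owning cell reproduces tissue mode", {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                      strand = "+", tss = c(4000, 8000))
  sites <- dplyr::bind_rows(
    dplyr::mutate(rand_intervals(6), tf = "TF1"),
    dplyr::mutate(rand_intervals(6), tf = "TF2"))
  peaks_tbl <- rand_intervals(10)
  cat <- make_catalog(sites, genes, upstream = 2500, downstream = 2500)
  tissue <- compute_activity(cat, normalize_peaks(peak_set(peaks_tbl)),
                             tf_ids = c("TF1", "TF2"), gene_ids = genes$gene_id)
  pc <- compute_activity_per_cell(
    cat, peak_set(peaks_tbl, cell_assignment = list(cell1 = seq_len(nrow(peaks_tbl)))),
    tf_ids = c("TF1", "TF2"), gene_ids = genes$gene_id)
  expect_identical(as.matrix(pc$per_cell$cell1$a_sum), tissue$a_sum)
  expect_identical(as.matrix(pc$per_cell$cell1$a_mean), tissue$a_mean)
  expect_identical(pc$a_sum, tissue$a_sum)
})

test_that("per-cell scores respect each cell's peak ownership", {
  set.seed(303)
  genes <- data.frame(gene_id = "gA", chrom = "chr1", strand = "+", tss = 5000)
  sites <- dplyr::mutate(rand_intervals(5), tf = "TF1")
  peaks_tbl <- rand_intervals(12)
  cat <- make_catalog(sites, genes)
  own <- list(c1 = 1:6, c2 = 7:12, empty = integer(0))
  pc <- compute_activity_per_cell(cat, peak_set(peaks_tbl, cell_assignment = own),
                                  tf_ids = "TF1", gene_ids = "gA")
  for (cl in c("c1", "c2")) {
    sub <- peaks_tbl[own[[cl]], ]
    oracle <- sum(vapply(seq_len(nrow(cat)), function(j) {
      coverage_oracle(cat$start[j], cat$end[j], sub)
    }, numeric(1)))
    expect_equal(as.numeric(pc$per_cell[[cl]]$a_sum["TF1", "gA"]), oracle)
  }
  expect_equal(as.numeric(pc$per_cell$empty$a_sum["TF1", "gA"]), 0)
  expect_error(
    compute_activity_per_cell(cat, peak_set(peaks_tbl, cell_assignment = list(c1 = 99)),
                              tf_ids = "TF1", gene_ids = "gA"),
    "unknown peak index")
})
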