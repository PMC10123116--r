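# Shared fixtures, built in code at test time.

# Random half-open intervals on one chromosome within [0, span)
rand_intervals <- function(n, span = 10000, max_len = 400, chrom = "chr1") {
  start <- sample.int(span - max_len, n, replace = TRUE) - 1
  len <- sample.int(max_len, n, replace = TRUE)
  tibble::tibble(chrom = chrom, start = start, end = start + len)
}

# Independent per-basepair coverage oracle: fraction of the site's bases
# lying inside any peak, computed by enumerating positions.
coverage_oracle <- function(site_start, site_end, peaks) {
  pos <- seq(site_start, site_end - 1)
  covered <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(peaks))) {
    covered <- covered | (pos >= peaks$start[i] & pos < peaks$end[i])
  }
  sum(covered) / length(pos)
}

# Small random regression task with the package's feature layout
mk_task <- function(gene_id, n_rows = 30, n_tfs = 6, seed = 1) {
  set.seed(seed)
  tf_ids <- paste0("TF", seq_len(n_tfs))
  f <- matrix(rnorm(n_rows * 3 * n_tfs), n_rows, 3 * n_tfs)
  colnames(f) <- c(paste0("a_sum.", tf_ids), paste0("a_mean.", tf_ids),
                   paste0("x.", tf_ids))
  rownames(f) <- paste0("c", seq_len(n_rows))
  structure(
    list(gene_id = gene_id, features = f, targets = rnorm(n_rows),
         cell_ids = rownames(f), tf_ids = tf_ids),
    class = "task_dataset"
  )
}

# A tiny simulated data set shared by several files
tiny_sim <- function(seed = 11, n_tfs = 8, n_genes = 6, n_cells = 80,
                     k_per_gene = 2, noise_sd = 0.2, missing_rate = 0.2) {
  truth <- simulate_truth(n_tfs = n_tfs, n_genes = n_genes,
                          k_per_gene = k_per_gene, noise_sd = noise_sd,
                          missing_rate = missing_rate, seed = seed)
  list(truth = truth, data = simulate_data(truth, n_cells = n_cells, seed = seed))
}

write_bed_lines <- function(lines) {
  path <- tempfile(fileext = ".bed")
  writeLines(lines, path)
  path
}

# Exact hypergeometric upper tail by direct enumeration (small N only)
hyper_tail_oracle <- function(N, K, n, x) {
  ks <- x:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}
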