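#' Filter ChIP-seq samples on standard QC metrics
#'
#' Keeps a sample iff all five criteria hold (boundaries inclusive):
#' median sequence quality >= 25, uniquely mapped ratio >= 60%,
#' PBC >= 80%, FRiP >= 1%, and >= 500 peaks with fold change above 10.
#'
#' @param meta Data frame with columns `sample_id`, `median_quality_score`,
#'   `uniquely_mapped_ratio`, `pbc`, `frip`, `peaks_fold_change_above_10`.
#' @param thresholds Named list overriding any of the five defaults
#'   (`quality = 25`, `mapped = 60`, `pbc = 80`, `frip = 1`, `peaks = 500`).
#' @return Character vector of kept `sample_id`s.
#' @export
filter_chipseq_samples <- function(meta, thresholds = list()) {
  meta <- as_tibble(meta)
  th <- utils::modifyList(
    list(quality = 25, mapped = 60, pbc = 80, frip = 1, peaks = 500),
    thresholds
  )
  cols <- c("sample_id", "median_quality_score", "uniquely_mapped_ratio",
            "pbc", "frip", "peaks_fold_change_above_10")
  miss <- setdiff(cols, names(meta))
  if (length(miss)) abort_velonet(sprintf("metadata missing column(s): %s", paste(miss, collapse = ", ")))
  for (cl in cols[-1]) {
    if (anyNA(meta[[cl]])) {
      bad <- meta$sample_id[which(is.na(meta[[cl]]))[1]]
      abort_velonet(sprintf("sample '%s' is missing metric '%s'", bad, cl))
    }
  }
  keep <- meta$median_quality_score >= th$quality &
    meta$uniquely_mapped_ratio >= th$mapped &
    meta$pbc >= th$pbc &
    meta$frip >= th$frip &
    meta$peaks_fold_change_above_10 >= th$peaks
  meta$sample_id[keep]
}

#' Drop genes with too few cells carrying a velocity value
#'
#' Genes whose number of non-missing velocity entries is strictly below
#' `min_cells` are removed; cells left without any non-missing gene are then
#' removed too.
#'
#' @param v Cells x genes velocity matrix with `NA` marking missing entries.
#' @param min_cells Minimum non-missing cell count per gene.
#' @return The reduced matrix.
#' @export
filter_genes <- function(v, min_cells) {
  stopifnot(is.matrix(v), min_cells >= 0)
  counts <- colSums(!is.na(v))
  keep <- counts >= min_cells
  if (!any(keep)) {
    abort_velonet(sprintf(
      "all %d genes have < %d cells with velocity; lower min_cells", ncol(v), min_cells))
  }
  v <- v[, keep, drop = FALSE]
  cell_keep <- rowSums(!is.na(v)) > 0
  v[cell_keep, , drop = FALSE]
}

#' log10(x + 1) transform of a raw RPKM matrix
#'
#' @param x Non-negative cells x TFs matrix of raw RPKM values.
#' @return The transformed matrix (zeros stay zero).
#' @export
log_rpkm <- function(x) {
  stopifnot(is.matrix(x))
  if (any(x < 0, na.rm = TRUE)) abort_velonet("raw RPKM matrix contains negative entries")
  log10(x + 1)
}

#' Column-wise standardization to zero mean and unit variance
#'
#' Means and standard deviations (population, denominator n) are computed
#' over observed entries only; `NA` entries stay `NA`. Columns with fewer
#' than two observed values or zero variance map to all zeros.
#'
#' @param m Numeric matrix; `NA` marks missing entries.
#' @return Matrix of the same shape.
#' @export
#' @examples
#' standardize_columns(cbind(a = c(1, 2, 3)))
standardize_columns <- function(m) {
  stopifnot(is.matrix(m))
  obs <- !is.na(m)
  n_obs <- colSums(obs)
  mu <- colMeans(m, na.rm = TRUE)
  mu[n_obs == 0] <- 0
  centered <- sweep(m, 2, mu, "-")
  ssq <- colSums(centered^2, na.rm = TRUE)
  sd_pop <- sqrt(ssq / pmax(1, n_obs))
  const <- n_obs < 2 | sd_pop < 1e-12
  out <- sweep(centered, 2, ifelse(const, 1, sd_pop), "/")
  if (any(const)) out[, const] <- ifelse(is.na(m[, const, drop = FALSE]), NA, 0)
  out
}

#' Random train/test split of cells
#'
#' Uniform partition with `|train| = round(ratio * n)`; deterministic for a
#' given seed. Default ratio follows the 9:1 train:test protocol.
#'
#' @param cell_ids Character vector of cell ids (n >= 2).
#' @param ratio Train fraction in (0, 1).
#' @param seed Integer seed.
#' @return List with `train` and `test` id vectors (disjoint, exhaustive).
#' @export
split_cells <- function(cell_ids, ratio = 0.9, seed = 1) {
  n <- length(cell_ids)
  if (n < 2) abort_velonet("need at least 2 cells to split")
  if (ratio <= 0 || ratio >= 1) abort_velonet("ratio must lie in (0, 1)")
  n_train <- max(1L, min(n - 1L, as.integer(round(ratio * n))))
  train <- with_seed(derive_seed(seed, "split"), sample(cell_ids, n_train))
  list(train = sort(train), test = sort(setdiff(cell_ids, train)))
}

#' Assemble the per-gene regression dataset
#'
#' Rows are the cells of the chosen split that carry a velocity value for
#' the gene. Each row's feature vector has length 3 x n_tfs laid out as
#' three blocks `[a_sum | a_mean | expression]` in a fixed TF order. In
#' tissue mode the gene's activity columns are broadcast to every row; in
#' per-cell mode each row uses its own cell's scores.
#'
#' @param gene_id Target gene.
#' @param x Standardized cells x TFs expression matrix (rownames = cells).
#' @param y Standardized cells x genes velocity matrix with `NA` missing.
#' @param a A scaled [tf_activity()].
#' @param cells Cell ids of the split subset.
#' @return A `task_dataset`: list with `gene_id`, `features` (rows x 3n),
#'   `targets`, `cell_ids`, `tf_ids`.
#' @export
assemble_task_dataset <- function(gene_id, x, y, a, cells) {
  stopifnot(inherits(a, "tf_activity"))
  if (!gene_id %in% colnames(y)) abort_velonet(sprintf("gene '%s' absent from velocity matrix", gene_id))
  if (!gene_id %in% colnames(a$a_sum)) abort_velonet(sprintf("gene '%s' absent from activity matrices", gene_id))
  tf_ids <- rownames(a$a_sum)
  if (!all(tf_ids %in% colnames(x))) abort_velonet("expression matrix lacks some activity TFs")
  cells <- intersect(cells, rownames(y))
  yv <- y[cells, gene_id]
  keep <- cells[!is.na(yv)]
  if (!length(keep)) abort_velonet(sprintf("gene '%s' has no cell with velocity in this split", gene_id))
  act <- activity_gene_features(a, gene_id, keep)
  feats <- cbind(act$a_sum, act$a_mean, x[keep, tf_ids, drop = FALSE])
  colnames(feats) <- c(paste0("a_sum.", tf_ids), paste0("a_mean.", tf_ids), paste0("x.", tf_ids))
  rownames(feats) <- keep
  structure(
    list(gene_id = gene_id, features = feats, targets = unname(y[keep, gene_id]),
         cell_ids = keep, tf_ids = tf_ids),
    class = "task_dataset"
  )
}

#' @exportS3Method base::print
print.task_dataset <- function(x, ...) {
  cat(sprintf("<task_dataset> gene %s: %d cells x %d features (%d TFs)\n",
              x$gene_id, nrow(x$features), ncol(x$features), length(x$tf_ids)))
  invisible(x)
}
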