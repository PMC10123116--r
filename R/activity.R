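#' TF activity score matrices
#'
#' Container for the accessibility-weighted TF binding activity scores used
#' as model inputs. For TF i and gene j with m binding sites assigned to the
#' gene's promoter, `a_sum[i, j]` is the sum over sites of the fraction of
#' the site covered by open-chromatin peaks, and `a_mean[i, j]` is that sum
#' divided by m. Pairs with no assigned site score 0 in both matrices.
#'
#' @param a_sum,a_mean TF x gene numeric matrices with dimnames.
#' @param mode `"tissue"` (one matrix pair per data set) or `"per_cell"`
#'   (one pair per cell, stored sparsely in `per_cell`).
#' @param per_cell For per-cell mode: named list (cell id) of lists with
#'   sparse `a_sum`, `a_mean` matrices.
#' @param scaled Whether `log2(x + 1)` scaling has been applied.
#' @return A `tf_activity` object.
#' @export
tf_activity <- function(a_sum, a_mean, mode = c("tissue", "per_cell"),
                        per_cell = NULL, scaled = FALSE) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(a_sum), is.matrix(a_mean),
            identical(dim(a_sum), dim(a_mean)),
            identical(dimnames(a_sum), dimnames(a_mean)))
  if (any(a_sum < 0) || any(a_mean < 0)) abort_velonet("activity scores must be non-negative")
  structure(
    list(a_sum = a_sum, a_mean = a_mean, mode = mode,
         per_cell = per_cell, scaled = isTRUE(scaled)),
    class = "tf_activity"
  )
}

#' @exportS3Method base::print
print.tf_activity <- function(x, ...) {
  cat(sprintf("<tf_activity> %d TFs x %d genes; mode: %s; scaled: %s\n",
              nrow(x$a_sum), ncol(x$a_sum), x$mode, x$scaled))
  if (x$mode == "per_cell") cat(sprintf("  per-cell scores for %d cells\n", length(x$per_cell)))
  invisible(x)
}

activity_from_catalog <- function(catalog, peaks_norm, tf_ids, gene_ids) {
  a_sum <- matrix(0, length(tf_ids), length(gene_ids), dimnames = list(tf_ids, gene_ids))
  a_mean <- a_sum
  if (nrow(catalog)) {
    frac <- site_overlap_fraction(catalog, peaks_norm)
    agg <- dplyr::summarise(
      dplyr::group_by(tibble(tf = catalog$tf, gene_id = catalog$gene_id, frac = frac),
                      .data$tf, .data$gene_id),
      s = sum(.data$frac), m = dplyr::n(), .groups = "drop"
    )
    idx <- cbind(match(agg$tf, tf_ids), match(agg$gene_id, gene_ids))
    a_sum[idx] <- agg$s
    a_mean[idx] <- agg$s / agg$m
  }
  list(a_sum = a_sum, a_mean = a_mean)
}

#' Compute tissue-level TF activity scores
#'
#' Scores every (TF, gene) pair in the binding-site catalog against a merged
#' open-chromatin peak set: each site contributes the fraction of its length
#' covered by peaks; `a_sum` sums these fractions over the gene's m sites
#' and `a_mean` averages them.
#'
#' @param catalog A `site_catalog` from [assign_sites_to_promoters()].
#' @param peaks A normalized [peak_set()] of open-chromatin regions.
#' @param tf_ids,gene_ids Row/column universes for the output matrices;
#'   default to the TFs/genes present in the catalog. Pairs absent from the
#'   catalog score 0.
#' @return A [tf_activity()] with `mode = "tissue"`, unscaled.
#' @export
compute_activity <- function(catalog, peaks, tf_ids = NULL, gene_ids = NULL) {
  stopifnot(inherits(peaks, "peak_set"))
  if (!peaks$normalized) abort_velonet("peaks must be normalized; call normalize_peaks()")
  if (!nrow(catalog) && (is.null(tf_ids) || is.null(gene_ids))) {
    abort_velonet("catalog is empty and no tf_ids/gene_ids universe was supplied")
  }
  tf_ids <- sort(tf_ids %||% unique(catalog$tf))
  gene_ids <- sort(gene_ids %||% unique(catalog$gene_id))
  m <- activity_from_catalog(catalog, peaks, tf_ids, gene_ids)
  tf_activity(m$a_sum, m$a_mean, mode = "tissue")
}

#' Compute per-cell TF activity scores
#'
#' For jointly profiled data where every peak can be traced back to the
#' cells whose reads produced it, activity is computed per cell using only
#' that cell's peaks (merged per cell before overlap computation). Cells
#' owning no peaks score all-zero. The `a_sum`/`a_mean` slots of the result
#' hold the across-cell mean scores; per-cell matrices are kept sparsely in
#' `per_cell`.
#'
#' @param catalog A `site_catalog`.
#' @param peaks A [peak_set()] carrying a `cell_assignment`.
#' @inheritParams compute_activity
#' @return A [tf_activity()] with `mode = "per_cell"`.
#' @export
compute_activity_per_cell <- function(catalog, peaks, tf_ids = NULL, gene_ids = NULL) {
  stopifnot(inherits(peaks, "peak_set"))
  if (is.null(peaks$cell_assignment)) {
    abort_velonet("peaks must carry a cell_assignment for per-cell activity")
  }
  tf_ids <- sort(tf_ids %||% unique(catalog$tf))
  gene_ids <- sort(gene_ids %||% unique(catalog$gene_id))
  per_cell <- lapply(peaks$cell_assignment, function(idx) {
    sub <- normalize_peaks(peak_set(peaks$intervals[idx, , drop = FALSE]))
    m <- activity_from_catalog(catalog, sub, tf_ids, gene_ids)
    list(a_sum = Matrix::Matrix(m$a_sum, sparse = TRUE),
         a_mean = Matrix::Matrix(m$a_mean, sparse = TRUE))
  })
  n_cells <- length(per_cell)
  acc_sum <- matrix(0, length(tf_ids), length(gene_ids), dimnames = list(tf_ids, gene_ids))
  acc_mean <- acc_sum
  for (pc in per_cell) {
    acc_sum <- acc_sum + as.matrix(pc$a_sum)
    acc_mean <- acc_mean + as.matrix(pc$a_mean)
  }
  tf_activity(acc_sum / max(1, n_cells), acc_mean / max(1, n_cells),
              mode = "per_cell", per_cell = per_cell)
}

#' Apply log2(x + 1) scaling to activity scores
#'
#' @param a A [tf_activity()] with `scaled = FALSE`.
#' @return The scaled `tf_activity` (`scaled = TRUE`); applying it twice is
#'   an error.
#' @export
scale_activity <- function(a) {
  stopifnot(inherits(a, "tf_activity"))
  if (a$scaled) abort_velonet("activity scores are already scaled; refusing to scale twice")
  a$a_sum <- log2(a$a_sum + 1)
  a$a_mean <- log2(a$a_mean + 1)
  if (!is.null(a$per_cell)) {
    a$per_cell <- lapply(a$per_cell, function(pc) {
      list(a_sum = log2(pc$a_sum + 1), a_mean = log2(pc$a_mean + 1))
    })
  }
  a$scaled <- TRUE
  a
}

#' Activity columns for one gene, per cell or broadcast
#' @noRd
activity_gene_features <- function(a, gene_id, cell_ids) {
  tf_ids <- rownames(a$a_sum)
  if (a$mode == "tissue") {
    asum <- matrix(a$a_sum[, gene_id], length(cell_ids), length(tf_ids), byrow = TRUE)
    amean <- matrix(a$a_mean[, gene_id], length(cell_ids), length(tf_ids), byrow = TRUE)
  } else {
    missing_cells <- setdiff(cell_ids, names(a$per_cell))
    if (length(missing_cells)) {
      abort_velonet(sprintf("no per-cell activity for cell '%s'", missing_cells[1]))
    }
    asum <- t(vapply(cell_ids, function(cl) as.numeric(a$per_cell[[cl]]$a_sum[, gene_id]),
                     numeric(length(tf_ids))))
    amean <- t(vapply(cell_ids, function(cl) as.numeric(a$per_cell[[cl]]$a_mean[, gene_id]),
                      numeric(length(tf_ids))))
  }
  colnames(asum) <- colnames(amean) <- tf_ids
  list(a_sum = asum, a_mean = amean)
}
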