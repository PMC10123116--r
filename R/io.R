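#' Write / read a dense named matrix as TSV
#'
#' First column holds row ids (default `cell`); remaining columns are the
#' matrix columns. `NA` entries round-trip (missing velocities).
#'
#' @param m Numeric matrix with dimnames.
#' @param path File path.
#' @param id_col Name of the row-id column.
#' @return `write_matrix_tsv` returns `path` invisibly; `read_matrix_tsv`
#'   returns the matrix.
#' @export
write_matrix_tsv <- function(m, path, id_col = "cell") {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  tbl <- as_tibble(m, rownames = id_col)
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path, id_col = "cell") {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  if (!id_col %in% names(tbl)) {
    abort_velonet(sprintf("matrix TSV %s lacks id column '%s'", path, id_col))
  }
  ids <- tbl[[id_col]]
  m <- as.matrix(tbl[setdiff(names(tbl), id_col)])
  rownames(m) <- ids
  m
}

#' Write a peak set (and any cell assignment) to disk
#'
#' Intervals go to BED; a per-cell ownership map, when present, is written
#' as a sparse MatrixMarket peak x cell binary matrix plus a barcode list.
#'
#' @param ps A [peak_set()].
#' @param bed_path Output BED path.
#' @param mtx_path,barcodes_path Outputs for the ownership map (required
#'   when `ps` carries one).
#' @return `bed_path`, invisibly.
#' @export
write_peaks <- function(ps, bed_path, mtx_path = NULL, barcodes_path = NULL) {
  stopifnot(inherits(ps, "peak_set"))
  tbl <- ps$intervals
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", tbl$chrom, as.integer(tbl$start),
                   as.integer(tbl$end), ifelse(is.na(tbl$name), ".", tbl$name), tbl$strand)
  writeLines(lines, bed_path)
  if (!is.null(ps$cell_assignment)) {
    if (is.null(mtx_path) || is.null(barcodes_path)) {
      abort_velonet("peak set has a cell_assignment: mtx_path and barcodes_path are required")
    }
    cells <- names(ps$cell_assignment)
    i <- unlist(ps$cell_assignment, use.names = FALSE)
    j <- rep(seq_along(cells), lengths(ps$cell_assignment))
    m <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                              dims = c(nrow(tbl), length(cells)))
    Matrix::writeMM(m, mtx_path)
    writeLines(cells, barcodes_path)
  }
  invisible(bed_path)
}

#' Read a peak x cell ownership matrix (MatrixMarket + barcodes)
#'
#' @param mtx_path MatrixMarket file, peaks x cells, nonzero = owned.
#' @param barcodes_path One cell barcode per line (matrix columns).
#' @return Named list, cell id -> integer vector of peak row indices.
#' @export
read_cell_assignment <- function(mtx_path, barcodes_path) {
  m <- Matrix::readMM(mtx_path)
  cells <- readLines(barcodes_path)
  if (length(cells) != ncol(m)) {
    abort_velonet(sprintf("barcode count (%d) does not match matrix columns (%d)",
                          length(cells), ncol(m)))
  }
  m <- methods::as(m, "CsparseMatrix")
  lapply(setNames(seq_along(cells), cells), function(j) {
    which(m[, j] != 0)
  })
}
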