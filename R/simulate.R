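#' Plant a ground-truth TF -> gene regulatory network
#'
#' Draws, for every gene, `k_per_gene` regulator TFs (uniformly from all
#' TFs, or from a restricted `regulator_pool` to plant shared structure
#' across genes) with effect sizes drawn uniformly from
#' `±[effect_range[1], effect_range[2]]`.
#'
#' @param n_tfs,n_genes Universe sizes.
#' @param k_per_gene Regulators per gene (`<= n_tfs`).
#' @param effect_range Magnitude range `c(lo, hi)` of nonzero effects.
#' @param noise_sd Gaussian noise sd added to velocities.
#' @param missing_rate Per-gene probability that a cell's velocity is
#'   missing.
#' @param dropout_rate Default drop-out (zero-inflation) rate recorded for
#'   the truth; applied by [apply_dropout()].
#' @param regulator_pool Optional integer: draw regulators only from the
#'   first `regulator_pool` TFs, so gene programs share a low-dimensional
#'   structure.
#' @param seed Integer seed; everything is reproducible from it.
#' @return A `synthetic_truth`: list with coefficient matrix `B`
#'   (TFs x genes), `tf_ids`, `gene_ids` and the simulation parameters.
#' @export
simulate_truth <- function(n_tfs = 50, n_genes = 30, k_per_gene = 5,
                           effect_range = c(0.5, 2), noise_sd = 0.5,
                           missing_rate = 0.3, dropout_rate = 0,
                           regulator_pool = NULL, seed = 1) {
  if (k_per_gene > n_tfs) abort_velonet("k_per_gene cannot exceed n_tfs")
  pool <- seq_len(regulator_pool %||% n_tfs)
  if (k_per_gene > length(pool)) abort_velonet("k_per_gene cannot exceed the regulator pool size")
  tf_ids <- sprintf("TF%03d", seq_len(n_tfs))
  gene_ids <- sprintf("G%03d", seq_len(n_genes))
  B <- with_seed(derive_seed(seed, "truth"), {
    B <- matrix(0, n_tfs, n_genes, dimnames = list(tf_ids, gene_ids))
    for (j in seq_len(n_genes)) {
      regs <- sample(pool, k_per_gene)
      eff <- runif(k_per_gene, effect_range[1], effect_range[2]) *
        sample(c(-1, 1), k_per_gene, replace = TRUE)
      B[regs, j] <- eff
    }
    B
  })
  structure(
    list(B = B, tf_ids = tf_ids, gene_ids = gene_ids,
         k_per_gene = as.integer(k_per_gene), effect_range = effect_range,
         noise_sd = noise_sd, missing_rate = missing_rate,
         dropout_rate = dropout_rate, seed = as.integer(seed)),
    class = "synthetic_truth"
  )
}

#' Regulators of each gene in a planted truth
#'
#' @param truth A `synthetic_truth`.
#' @return Named list, gene id -> character vector of regulator TF ids.
#' @export
truth_regulators <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  lapply(setNames(truth$gene_ids, truth$gene_ids),
         function(g) truth$tf_ids[truth$B[, g] != 0])
}

#' Simulate a full input data set from a planted truth
#'
#' Latent TF drivers are standard normal per cell; velocities are the
#' linear (or optionally tanh) readout of the planted coefficients plus
#' Gaussian noise, with per-gene missingness. Raw RPKM is emitted as
#' `10^(0.3 z + 1) - 1` (clamped at 0), so the pipeline's `log10(x + 1)`
#' recovers an affine image of the driver; zeroing raw entries therefore
#' emulates drop-out upstream of the log transform. A toy genome (one
#' chromosome, genes 20 kb apart) is emitted in which each true regulator's
#' binding site falls inside an open-chromatin peak in its target's
#' promoter, while non-regulators get promoter sites with no peak overlap
#' — so activity scores are informative about the planted network.
#'
#' @param truth A [simulate_truth()] result.
#' @param n_cells Number of cells.
#' @param seed Integer seed.
#' @param link `"linear"` (default) or `"tanh"` applied to the linear
#'   predictor before noise (a nonlinearity stressor).
#' @param per_cell Also emit a random peak -> cell ownership map (each
#'   cell owns each peak independently with probability 0.5), enabling the
#'   per-cell activity mode.
#' @return List with `expression` (raw RPKM cells x TFs), `velocity`
#'   (cells x genes, `NA` = missing), `latent` (the standard-normal
#'   drivers), `peaks` ([peak_set()]), `sites` (tibble `tf, chrom, start,
#'   end`), `genes` (annotation tibble) and `truth`.
#' @export
simulate_data <- function(truth, n_cells = 2000, seed = 1,
                          link = c("linear", "tanh"), per_cell = FALSE) {
  stopifnot(inherits(truth, "synthetic_truth"))
  link <- match.arg(link)
  n_tfs <- length(truth$tf_ids)
  n_genes <- length(truth$gene_ids)
  cell_ids <- sprintf("cell%05d", seq_len(n_cells))

  z <- with_seed(derive_seed(seed, "latent"),
                 matrix(rnorm(n_cells * n_tfs), n_cells, n_tfs,
                        dimnames = list(cell_ids, truth$tf_ids)))
  eta <- z %*% truth$B
  if (link == "tanh") eta <- tanh(eta)
  noise <- with_seed(derive_seed(seed, "noise"),
                     matrix(rnorm(n_cells * n_genes, sd = truth$noise_sd),
                            n_cells, n_genes))
  y <- eta + noise
  dimnames(y) <- list(cell_ids, truth$gene_ids)
  miss <- with_seed(derive_seed(seed, "missing"),
                    matrix(runif(n_cells * n_genes) < truth$missing_rate,
                           n_cells, n_genes))
  y[miss] <- NA

  expression <- pmax(10^(0.3 * z + 1) - 1, 0)
  dimnames(expression) <- dimnames(z)

  tss <- 10000 + (seq_len(n_genes) - 1) * 20000
  genes <- tibble(gene_id = truth$gene_ids, chrom = "chrS", strand = "+", tss = tss)
  peaks_tbl <- tibble(chrom = "chrS", start = tss - 500, end = tss + 500,
                      strand = ".", name = paste0("peak_", truth$gene_ids))
  # regulator sites sit inside the open peak; decoy sites sit in the
  # promoter window but outside any peak, so their overlap fraction is 0
  site_rows <- lapply(seq_len(n_genes), function(j) {
    regs <- truth$tf_ids[truth$B[, j] != 0]
    others <- setdiff(truth$tf_ids, regs)
    dplyr::bind_rows(
      tibble(tf = regs, chrom = "chrS", start = tss[j] - 100, end = tss[j] + 100),
      tibble(tf = others, chrom = "chrS", start = tss[j] + 1000, end = tss[j] + 1200)
    )
  })
  sites <- dplyr::bind_rows(site_rows)

  cell_assignment <- NULL
  if (per_cell) {
    cell_assignment <- with_seed(derive_seed(seed, "ownership"), {
      lapply(setNames(cell_ids, cell_ids), function(cl) {
        own <- which(runif(nrow(peaks_tbl)) < 0.5)
        if (!length(own)) own <- sample.int(nrow(peaks_tbl), 1)
        own
      })
    })
  }
  peaks <- peak_set(peaks_tbl, cell_assignment = cell_assignment)

  list(expression = expression, velocity = y, latent = z,
       peaks = peaks, sites = sites, genes = genes, truth = truth)
}

#' Zero raw expression entries to emulate drop-out
#'
#' Each raw entry is independently set to 0 with probability `rate`,
#' upstream of the log transform.
#'
#' @param x Raw cells x TFs RPKM matrix.
#' @param rate Drop-out probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return Matrix of the same shape.
#' @export
apply_dropout <- function(x, rate, seed = 1) {
  stopifnot(is.matrix(x))
  if (rate < 0 || rate >= 1) abort_velonet("dropout rate must lie in [0, 1)")
  if (rate == 0) return(x)
  mask <- with_seed(derive_seed(seed, "dropout"),
                    matrix(runif(length(x)) < rate, nrow(x), ncol(x)))
  x[mask] <- 0
  x
}
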