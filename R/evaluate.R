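#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`, the standard R-squared of predictions against
#' observations (at most 1; negative when predictions do worse than the
#' mean).
#'
#' @param y_true,y_pred Numeric vectors of equal length >= 2.
#' @return Scalar R-squared.
#' @export
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 4)) # 0.5
r_squared <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2)
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) abort_velonet("y_true is constant; R2 undefined")
  1 - sum((y_true - y_pred)^2) / ss_tot
}

#' Recall of ground-truth TFs
#'
#' `TP / (TP + FN)`: the fraction of ground-truth TFs recovered by the
#' prediction. Precision is deliberately not offered, since ground-truth TF
#' catalogs are incomplete and predicted TFs absent from them are not
#' necessarily false.
#'
#' @param predicted Character vector (or set) of predicted TF ids.
#' @param truth Non-empty character vector of ground-truth TF ids.
#' @return Scalar recall in `[0, 1]`.
#' @export
recall_tfs <- function(predicted, truth) {
  truth <- unique(truth)
  if (!length(truth)) abort_velonet("truth TF set is empty")
  length(intersect(unique(predicted), truth)) / length(truth)
}

#' Upper-tail hypergeometric enrichment p-value
#'
#' For a population of `n_population` items containing a set of size
#' `n_set1`, and a draw of `n_set2` items, returns `P(X >= overlap)` with
#' `X ~ Hypergeometric` — the standard one-sided overrepresentation test
#' for the overlap of two gene/TF sets. Computed in log space via
#' [stats::phyper()] for numerical stability.
#'
#' @param n_population Population (background) size N.
#' @param n_set1 Size of the first set K.
#' @param n_set2 Size of the second set (the draw) n.
#' @param overlap Observed overlap x.
#' @return p-value in `(0, 1]`.
#' @export
#' @examples
#' hypergeom_enrichment(1827, 266, 184, 65) # ~5.14e-14
hypergeom_enrichment <- function(n_population, n_set1, n_set2, overlap) {
  if (overlap < 0 || n_set1 > n_population || n_set2 > n_population ||
      overlap > min(n_set1, n_set2)) {
    abort_velonet("inconsistent counts: need 0 <= overlap <= min(n_set1, n_set2) <= n_population")
  }
  exp(phyper(overlap - 1, n_set1, n_population - n_set1, n_set2,
             lower.tail = FALSE, log.p = TRUE))
}

#' Benjamini-Hochberg adjustment of enrichment p-values
#'
#' Convenience wrapper over [stats::p.adjust()] for evaluating many TF sets
#' at once.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values (FDR).
#' @export
adjust_bh <- function(p) p.adjust(p, method = "BH")
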