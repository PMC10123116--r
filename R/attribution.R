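#' Reference example for attribution
#'
#' The single reference input against which cells are attributed: per-TF
#' mean of the standardized training expressions in the expression block,
#' exact zeros in both activity blocks.
#'
#' @param x_train Standardized training cells x TFs expression matrix.
#' @return Named numeric vector of length `3 * n_tfs`, laid out
#'   `[a_sum | a_mean | x]` like task features.
#' @export
reference_example <- function(x_train) {
  stopifnot(is.matrix(x_train), nrow(x_train) >= 1)
  tf_ids <- colnames(x_train) %||% paste0("TF", seq_len(ncol(x_train)))
  ref <- c(rep(0, 2L * ncol(x_train)), colMeans(x_train))
  names(ref) <- c(paste0("a_sum.", tf_ids), paste0("a_mean.", tf_ids), paste0("x.", tf_ids))
  ref
}

# Rescale multiplier of an activation: (f(z) - f(zref)) / (z - zref),
# falling back to the derivative where the denominator vanishes (the two
# coincide in the limit).
rescale_multiplier <- function(Z, Zref, activation) {
  a <- act_fun(activation)
  dZ <- sweep(Z, 2, Zref, "-")
  num <- sweep(a$f(Z), 2, as.numeric(a$f(matrix(Zref, 1))), "-")
  m <- num / dZ
  tiny <- abs(dZ) < 1e-9
  if (any(tiny)) m[tiny] <- a$df(Z)[tiny]
  m
}

#' Per-feature attributions against a reference example
#'
#' Backpropagates rescale-rule multipliers through the network, yielding an
#' attribution for every input feature of every row that satisfies the
#' completeness identity: the attributions of a row sum to
#' `f(row) - f(reference)`. Violations beyond
#' `1e-3 * max(1, |f(row) - f(reference)|)` on more than 1% of rows raise
#' an error.
#'
#' @param model An `mtl_model`.
#' @param gene_id Task to attribute.
#' @param features Rows x (3 x n_tfs) input matrix (`[a_sum | a_mean | x]`).
#' @param reference Reference vector from [reference_example()].
#' @return Rows x (3 x n_tfs) matrix of attributions.
#' @export
attribute <- function(model, gene_id, features, reference) {
  stopifnot(inherits(model, "mtl_model"))
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  params <- model$tasks[[gene_id]]
  if (is.null(params)) abort_velonet(sprintf("gene '%s' is not a task of this model", gene_id))
  n <- model$n_tfs
  if (ncol(features) != 3L * n || length(reference) != 3L * n) {
    abort_velonet("features/reference must have length 3 * n_tfs")
  }
  act <- model$config$activation
  fx <- forward_task(params, features, act, keep_cache = TRUE)
  fr <- forward_task(params, matrix(reference, nrow = 1), act, keep_cache = TRUE)

  M3 <- rescale_multiplier(fx$Z3, as.numeric(fr$Z3), act)
  M2 <- rescale_multiplier(fx$Z2, as.numeric(fr$Z2), act)
  M1 <- rescale_multiplier(fx$Z1, as.numeric(fr$Z1), act)
  M0 <- rescale_multiplier(fx$Z0, as.numeric(fr$Z0), act)

  C_H3 <- matrix(1, nrow(features), 1) %*% t(params$W4) # d(out)/d(H3) chain start
  C_Z3 <- C_H3 * M3
  C_H2 <- C_Z3 %*% t(params$W3)
  C_Z2 <- C_H2 * M2
  C_H1 <- C_Z2 %*% t(params$W2)
  C_Z1 <- C_H1 * M1
  C_H0 <- C_Z1 %*% t(params$W1)
  C_Z0 <- C_H0 * M0

  ia <- seq_len(n); im <- n + ia; ix <- 2L * n + ia
  delta <- sweep(features, 2, reference, "-")
  attr <- cbind(
    t(t(C_Z0) * params$w_agg[1, ]) * delta[, ia, drop = FALSE],
    t(t(C_Z0) * params$w_agg[2, ]) * delta[, im, drop = FALSE],
    t(t(C_Z0) * params$w_agg[3, ]) * delta[, ix, drop = FALSE]
  )
  colnames(attr) <- names(reference) %||% colnames(features)

  gap <- abs(rowSums(attr) - (fx$pred - fr$pred))
  tol <- 1e-3 * pmax(1, abs(fx$pred - fr$pred))
  frac_bad <- mean(gap > tol)
  if (frac_bad > 0.01) {
    abort_velonet(sprintf(
      "attribution completeness violated on %.1f%% of rows (max gap %.3g)",
      100 * frac_bad, max(gap)))
  }
  attr
}

#' Aggregate attributions into one non-negative importance per TF
#'
#' Sums absolute attributions over all rows, then over the TF's three
#' features (`a_sum`, `a_mean`, expression).
#'
#' @param attributions Rows x (3 x n_tfs) attribution matrix.
#' @param tf_ids TF identifiers (defaults from column names).
#' @return Tibble `tf, importance`, one row per TF.
#' @export
tf_importance <- function(attributions, tf_ids = NULL) {
  if (is.null(dim(attributions))) attributions <- matrix(attributions, nrow = 1)
  n <- ncol(attributions) / 3L
  stopifnot(n == round(n))
  if (is.null(tf_ids)) {
    cn <- colnames(attributions)
    tf_ids <- if (!is.null(cn)) sub("^a_sum\\.", "", cn[seq_len(n)]) else paste0("TF", seq_len(n))
  }
  tot <- unname(colSums(abs(attributions)))
  tibble(tf = tf_ids,
         importance = tot[seq_len(n)] + tot[n + seq_len(n)] + tot[2L * n + seq_len(n)])
}

#' Rank TFs for every task of a trained model
#'
#' Attributes all training rows of every gene against the shared reference
#' example and aggregates to per-TF importances.
#'
#' @param model A trained `mtl_model`.
#' @param train_tasks Named list of `task_dataset`s used for training.
#' @param reference Reference vector from [reference_example()].
#' @return Tibble `gene_id, tf, importance`.
#' @export
rank_tfs <- function(model, train_tasks, reference) {
  dplyr::bind_rows(lapply(names(model$tasks), function(g) {
    att <- attribute(model, g, train_tasks[[g]]$features, reference)
    dplyr::mutate(tf_importance(att, model$tf_ids), gene_id = g, .before = 1)
  }))
}
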