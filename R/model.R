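#' Training configuration for the multi-task velocity models
#'
#' @param lambda_l1 L1 penalty strength on all layer weights of every task.
#' @param gamma_trace Trace-norm (nuclear norm) penalty strength on the
#'   stacked shared-layer weights; ignored when `sharing_enabled = FALSE`.
#' @param batch_size Per-task batch size b.
#' @param epochs Training epochs.
#' @param learning_rate Adam step size.
#' @param seed Integer seed controlling initialization and batch sampling.
#' @param share_layers Which layers are softly shared across the tasks of a
#'   cluster; subset of `c("FC1", "FC2")`.
#' @param sharing_enabled `FALSE` drops the trace-norm term entirely (the
#'   no-sharing baseline with the same architecture).
#' @param activation Hidden activation: `"leaky_relu"` (default; negative
#'   slope 0.01), `"relu"`, `"tanh"` or `"linear"`.
#' @param repeats Independent training repetitions averaged for R2 scoring.
#' @param rounds Train+rank rounds used for consensus networks.
#' @param top_k Top-ranked TFs retained per gene and round.
#' @param mse_batch_mean Normalize each task's squared-error term by its
#'   batch size (default) rather than summing, so `lambda_l1`/`gamma_trace`
#'   scales are batch-size independent.
#' @param penalize_biases Include bias vectors in the L1 term and in the
#'   shared stacks (default `FALSE`: weights only).
#' @param engine `"cpp"` (compiled inner loop, default) or `"r"` (the plain
#'   R reference implementation of the same updates).
#' @return A list of class `mtl_config`.
#' @export
mtl_config <- function(lambda_l1 = 0.002, gamma_trace = 0.01, batch_size = 128,
                       epochs = 100, learning_rate = 0.01, seed = 1,
                       share_layers = c("FC1", "FC2"), sharing_enabled = TRUE,
                       activation = c("leaky_relu", "relu", "tanh", "linear"),
                       repeats = 3, rounds = 5, top_k = 50,
                       mse_batch_mean = TRUE, penalize_biases = FALSE,
                       engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  activation <- match.arg(activation)
  stopifnot(lambda_l1 >= 0, gamma_trace >= 0, batch_size >= 1, epochs >= 0,
            learning_rate > 0, repeats >= 1, rounds >= 1, top_k >= 1)
  if (!all(share_layers %in% c("FC1", "FC2"))) {
    abort_velonet("share_layers must be a subset of c('FC1','FC2')")
  }
  structure(
    list(lambda_l1 = lambda_l1, gamma_trace = gamma_trace,
         batch_size = as.integer(batch_size), epochs = as.integer(epochs),
         learning_rate = learning_rate, seed = as.integer(seed),
         share_layers = share_layers, sharing_enabled = isTRUE(sharing_enabled),
         activation = activation, repeats = as.integer(repeats),
         rounds = as.integer(rounds), top_k = as.integer(top_k),
         mse_batch_mean = isTRUE(mse_batch_mean),
         penalize_biases = isTRUE(penalize_biases), engine = engine),
    class = "mtl_config"
  )
}

FC_WIDTHS <- c(FC1 = 64L, FC2 = 32L, FC3 = 16L)

act_fun <- function(name) {
  switch(name,
         relu = list(f = function(z) pmax(z, 0), df = function(z) (z > 0) * 1),
         # slope 0.01 on the negative side keeps every unit trainable, so a
         # task's whole network cannot die under the L1 pull
         leaky_relu = list(f = function(z) pmax(z, 0) + 0.01 * pmin(z, 0),
                           df = function(z) (z > 0) + 0.01 * (z <= 0)),
         tanh = list(f = tanh, df = function(z) 1 - tanh(z)^2),
         linear = list(f = identity, df = function(z) array(1, dim(z))))
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

init_task_params <- function(n_tfs, seed) {
  with_seed(seed, {
    list(
      # each aggregation neuron is a 3 -> 1 unit; Glorot limit sqrt(6/(3+1))
      w_agg = matrix(runif(3 * n_tfs, -sqrt(1.5), sqrt(1.5)), 3, n_tfs),
      W1 = glorot(n_tfs, 64L), b1 = numeric(64L),
      W2 = glorot(64L, 32L), b2 = numeric(32L),
      W3 = glorot(32L, 16L), b3 = numeric(16L),
      W4 = glorot(16L, 1L), b4 = numeric(1L)
    )
  })
}

#' Initialize a cluster's multi-task model
#'
#' One network per gene: a TF aggregation layer (one neuron per TF mixing
#' that TF's `a_sum`, `a_mean` and expression with three learned weights),
#' followed by fully connected layers of 64, 32 and 16 units (FC1-FC3) and
#' a linear scalar output. Weights use Glorot-uniform initialization from a
#' per-task seed derived only from the configuration seed and the gene id,
#' so a task's initialization does not depend on its cluster companions.
#'
#' @param n_tfs Number of TFs (aggregation neurons).
#' @param gene_ids Genes (tasks) of the cluster.
#' @param config An [mtl_config()].
#' @param tf_ids Optional TF names (defaults to `TF1..TFn`).
#' @return An `mtl_model`.
#' @export
init_model <- function(n_tfs, gene_ids, config, tf_ids = NULL) {
  stopifnot(n_tfs >= 1, length(gene_ids) >= 1)
  tf_ids <- tf_ids %||% paste0("TF", seq_len(n_tfs))
  tasks <- lapply(gene_ids, function(g) {
    init_task_params(n_tfs, derive_seed(config$seed, "init", g))
  })
  names(tasks) <- gene_ids
  structure(
    list(tasks = tasks, n_tfs = as.integer(n_tfs), tf_ids = tf_ids,
         gene_ids = gene_ids, config = config),
    class = "mtl_model"
  )
}

#' @exportS3Method base::print
print.mtl_model <- function(x, ...) {
  cat(sprintf("<mtl_model> %d task(s), %d TFs; FC widths 64/32/16/1; activation %s\n",
              length(x$tasks), x$n_tfs, x$config$activation))
  invisible(x)
}

# Forward pass for one task on a rows x 3n feature matrix.
# Returns prediction vector plus caches needed for backprop/attribution.
forward_task <- function(params, X, activation = "relu", keep_cache = FALSE) {
  n <- ncol(params$w_agg)
  if (ncol(X) != 3L * n) {
    abort_velonet(sprintf("features must have 3 * n_tfs = %d columns, got %d",
                          3L * n, ncol(X)))
  }
  a <- act_fun(activation)
  ia <- seq_len(n); im <- n + ia; ix <- 2L * n + ia
  Z0 <- t(t(X[, ia, drop = FALSE]) * params$w_agg[1, ]) +
    t(t(X[, im, drop = FALSE]) * params$w_agg[2, ]) +
    t(t(X[, ix, drop = FALSE]) * params$w_agg[3, ])
  H0 <- a$f(Z0)
  Z1 <- H0 %*% params$W1; Z1 <- sweep(Z1, 2, params$b1, "+"); H1 <- a$f(Z1)
  Z2 <- H1 %*% params$W2; Z2 <- sweep(Z2, 2, params$b2, "+"); H2 <- a$f(Z2)
  Z3 <- H2 %*% params$W3; Z3 <- sweep(Z3, 2, params$b3, "+"); H3 <- a$f(Z3)
  pred <- drop(H3 %*% params$W4 + params$b4[1])
  if (!keep_cache) return(list(pred = pred))
  list(pred = pred, Z0 = Z0, H0 = H0, Z1 = Z1, H1 = H1,
       Z2 = Z2, H2 = H2, Z3 = Z3, H3 = H3, X = X)
}

#' Predicted velocities for one task
#'
#' @param model An `mtl_model`.
#' @param gene_id Task to evaluate.
#' @param features Rows x (3 x n_tfs) matrix laid out `[a_sum | a_mean | x]`.
#' @return Numeric vector of predicted velocities.
#' @export
forward <- function(model, gene_id, features) {
  stopifnot(inherits(model, "mtl_model"))
  if (!gene_id %in% names(model$tasks)) {
    abort_velonet(sprintf("gene '%s' is not a task of this model", gene_id))
  }
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  forward_task(model$tasks[[gene_id]], features, model$config$activation)$pred
}

# Gradients of the (optionally batch-mean) squared error for one task.
backward_task <- function(params, cache, y, activation = "relu", batch_mean = TRUE) {
  a <- act_fun(activation)
  r <- length(y)
  dpred <- 2 * (cache$pred - y)
  if (batch_mean) dpred <- dpred / r
  dpred <- matrix(dpred, r, 1)
  gW4 <- crossprod(cache$H3, dpred); gb4 <- sum(dpred)
  dH3 <- dpred %*% t(params$W4); dZ3 <- dH3 * a$df(cache$Z3)
  gW3 <- crossprod(cache$H2, dZ3); gb3 <- colSums(dZ3)
  dH2 <- dZ3 %*% t(params$W3); dZ2 <- dH2 * a$df(cache$Z2)
  gW2 <- crossprod(cache$H1, dZ2); gb2 <- colSums(dZ2)
  dH1 <- dZ2 %*% t(params$W2); dZ1 <- dH1 * a$df(cache$Z1)
  gW1 <- crossprod(cache$H0, dZ1); gb1 <- colSums(dZ1)
  dH0 <- dZ1 %*% t(params$W1); dZ0 <- dH0 * a$df(cache$Z0)
  n <- ncol(params$w_agg)
  ia <- seq_len(n); im <- n + ia; ix <- 2L * n + ia
  g_agg <- rbind(colSums(dZ0 * cache$X[, ia, drop = FALSE]),
                 colSums(dZ0 * cache$X[, im, drop = FALSE]),
                 colSums(dZ0 * cache$X[, ix, drop = FALSE]))
  list(w_agg = g_agg, W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
       W3 = gW3, b3 = gb3, W4 = gW4, b4 = gb4)
}

#' Trace norm (nuclear norm) of a matrix
#'
#' Sum of singular values.
#'
#' @param w Numeric matrix.
#' @return Scalar nuclear norm.
#' @export
#' @examples
#' trace_norm(diag(c(3, 4))) # 7
trace_norm <- function(w) {
  stopifnot(is.matrix(w), length(w) > 0)
  sum(svd(w, nu = 0, nv = 0)$d)
}

#' Subgradient of the trace norm
#'
#' Returns `U V^T` from the thin SVD `w = U S V^T`; a numerically stable
#' subgradient of the nuclear norm whose spectral norm never exceeds 1.
#'
#' @param w Numeric matrix.
#' @return Matrix of the same shape as `w`.
#' @export
trace_norm_subgradient <- function(w) {
  stopifnot(is.matrix(w), length(w) > 0)
  s <- svd(w)
  s$u %*% t(s$v)
}

stack_layer_names <- function(config) {
  if (!config$sharing_enabled || config$gamma_trace <= 0) return(character())
  intersect(c("FC1", "FC2"), config$share_layers)
}

layer_weight_field <- c(FC1 = "W1", FC2 = "W2")
layer_bias_field <- c(FC1 = "b1", FC2 = "b2")

# Columns are the flattened (column-major over in x out) layer weights of
# each task, biases appended last when penalize_biases is set.
shared_stack <- function(model, layer) {
  wf <- layer_weight_field[[layer]]
  bf <- layer_bias_field[[layer]]
  cols <- lapply(model$tasks, function(p) {
    if (model$config$penalize_biases) c(as.vector(p[[wf]]), p[[bf]]) else as.vector(p[[wf]])
  })
  do.call(cbind, cols)
}

l1_fields <- function(config) {
  if (config$penalize_biases) {
    c("w_agg", "W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4")
  } else {
    c("w_agg", "W1", "W2", "W3", "W4")
  }
}

#' Multi-task training loss on given batches
#'
#' Squared-error term per task (mean over its batch by default, sum when
#' `mse_batch_mean = FALSE`), plus the L1 penalty over every task's layer
#' weights, plus the trace-norm penalty over each shared-layer stack
#' (omitted for the no-sharing baseline).
#'
#' @param model An `mtl_model`.
#' @param batches Named list (gene id) of lists with `features`, `targets`.
#' @param config Optional [mtl_config()] overriding the model's.
#' @return Scalar loss.
#' @export
multitask_loss <- function(model, batches, config = NULL) {
  config <- config %||% model$config
  mse <- 0
  for (g in names(batches)) {
    b <- batches[[g]]
    pred <- forward_task(model$tasks[[g]], b$features, config$activation)$pred
    err <- sum((b$targets - pred)^2)
    mse <- mse + if (config$mse_batch_mean) err / length(b$targets) else err
  }
  l1 <- 0
  if (config$lambda_l1 > 0) {
    for (p in model$tasks) {
      for (f in l1_fields(config)) l1 <- l1 + sum(abs(p[[f]]))
    }
  }
  tn <- 0
  for (layer in stack_layer_names(config)) {
    tn <- tn + trace_norm(shared_stack(model, layer))
  }
  mse + config$lambda_l1 * l1 + config$gamma_trace * tn
}

#' Per-epoch ensemble batch plan
#'
#' One epoch runs `ceiling(C_max / b)` ensemble batches, where `C_max` is
#' the largest training-example count among the cluster's tasks; every
#' ensemble batch holds one size-`b` batch per task. Tasks with fewer
#' examples are resampled by cycling independently reshuffled permutations,
#' which guarantees each training example of every task is used at least
#' once per epoch.
#'
#' @param task_sizes Named integer vector: training examples per task.
#' @param b Batch size.
#' @param seed Integer seed (per-task streams derived from it and the task
#'   name only).
#' @return List with `batches_per_epoch`, `c_max`, and `index_streams`, a
#'   named list of `batches_per_epoch x b` index matrices (one row per
#'   ensemble batch).
#' @export
sample_epoch_batches <- function(task_sizes, b, seed = 1) {
  stopifnot(b >= 1)
  if (!length(task_sizes) || any(task_sizes < 1)) {
    abort_velonet("every task needs at least one training example")
  }
  if (is.null(names(task_sizes))) names(task_sizes) <- paste0("task", seq_along(task_sizes))
  c_max <- max(task_sizes)
  n_batches <- as.integer(ceiling(c_max / b))
  draws <- n_batches * b
  streams <- lapply(names(task_sizes), function(g) {
    n_i <- task_sizes[[g]]
    idx <- with_seed(derive_seed(seed, "batches", g), {
      reps <- ceiling(draws / n_i)
      unlist(lapply(seq_len(reps), function(r) sample.int(n_i)))[seq_len(draws)]
    })
    matrix(idx, nrow = n_batches, ncol = b, byrow = TRUE)
  })
  names(streams) <- names(task_sizes)
  list(batches_per_epoch = n_batches, c_max = c_max, index_streams = streams)
}
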