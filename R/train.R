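adam_state_init <- function(params) {
  lapply(params, function(p) {
    zero <- p * 0
    list(m = zero, v = zero)
  })
}

adam_update <- function(p, g, st, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$m <- beta1 * st$m + (1 - beta1) * g
  st$v <- beta2 * st$v + (1 - beta2) * g^2
  mhat <- st$m / (1 - beta1^t)
  vhat <- st$v / (1 - beta2^t)
  list(p = p - lr * mhat / (sqrt(vhat) + eps), state = st)
}

# Pre-sample every epoch's batch plan and stack it into one 0-based
# steps x b index matrix per task (rows = consecutive ensemble batches).
stacked_index_streams <- function(task_sizes, config, run_seed) {
  per_task <- lapply(names(task_sizes), function(g) list())
  names(per_task) <- names(task_sizes)
  for (epoch in seq_len(config$epochs)) {
    plan <- sample_epoch_batches(task_sizes, config$batch_size,
                                 seed = derive_seed(run_seed, "epoch", epoch))
    for (g in names(task_sizes)) {
      per_task[[g]][[epoch]] <- plan$index_streams[[g]]
    }
  }
  lapply(per_task, function(mats) do.call(rbind, mats))
}

# One full training run (no repeats) for a cluster of tasks, dispatching on
# the configured engine. The C++ engine computes the same updates as the R
# reference implementation below, just faster.
train_once <- function(train_tasks, config, run_seed) {
  gene_ids <- names(train_tasks)
  n_tfs <- length(train_tasks[[1]]$tf_ids)
  cfg <- config
  cfg$seed <- run_seed
  model <- init_model(n_tfs, gene_ids, cfg, tf_ids = train_tasks[[1]]$tf_ids)
  if (identical(config$engine, "r") || config$epochs == 0L) {
    return(train_once_r(train_tasks, config, run_seed, model))
  }
  task_sizes <- vapply(train_tasks, function(d) nrow(d$features), integer(1))
  names(task_sizes) <- gene_ids
  streams <- stacked_index_streams(task_sizes, cfg, run_seed)
  act_code <- match(cfg$activation, c("leaky_relu", "relu", "tanh", "linear")) - 1L
  trained <- .train_cluster_cpp(
    lapply(train_tasks, function(d) d$features),
    lapply(train_tasks, function(d) d$targets),
    model$tasks,
    lapply(streams[gene_ids], function(m) m - 1L),
    cfg$lambda_l1,
    if (cfg$sharing_enabled) cfg$gamma_trace else 0,
    cfg$learning_rate, act_code, cfg$mse_batch_mean,
    "FC1" %in% cfg$share_layers, "FC2" %in% cfg$share_layers,
    cfg$penalize_biases)
  for (j in seq_along(gene_ids)) {
    p <- trained[[j]]
    p$b1 <- as.numeric(p$b1); p$b2 <- as.numeric(p$b2)
    p$b3 <- as.numeric(p$b3); p$b4 <- as.numeric(p$b4)
    model$tasks[[gene_ids[j]]] <- p
  }
  model
}

# Reference implementation in plain R; kept as the slow path the C++ engine
# is cross-checked against.
train_once_r <- function(train_tasks, config, run_seed, model = NULL) {
  gene_ids <- names(train_tasks)
  n_tfs <- length(train_tasks[[1]]$tf_ids)
  cfg <- config
  cfg$seed <- run_seed
  if (is.null(model)) {
    model <- init_model(n_tfs, gene_ids, cfg, tf_ids = train_tasks[[1]]$tf_ids)
  }
  opt <- lapply(model$tasks, adam_state_init)
  task_sizes <- vapply(train_tasks, function(d) nrow(d$features), integer(1))
  names(task_sizes) <- gene_ids
  shared <- stack_layer_names(cfg)
  l1f <- l1_fields(cfg)
  t_step <- 0L

  for (epoch in seq_len(cfg$epochs)) {
    plan <- sample_epoch_batches(task_sizes, cfg$batch_size,
                                 seed = derive_seed(run_seed, "epoch", epoch))
    for (bi in seq_len(plan$batches_per_epoch)) {
      t_step <- t_step + 1L
      grads <- vector("list", length(gene_ids))
      names(grads) <- gene_ids
      for (g in gene_ids) {
        idx <- plan$index_streams[[g]][bi, ]
        X <- train_tasks[[g]]$features[idx, , drop = FALSE]
        y <- train_tasks[[g]]$targets[idx]
        cache <- forward_task(model$tasks[[g]], X, cfg$activation, keep_cache = TRUE)
        if (!all(is.finite(cache$pred))) {
          abort_velonet(sprintf(
            "non-finite predictions for gene '%s' at epoch %d; lower the learning rate",
            g, epoch))
        }
        gr <- backward_task(model$tasks[[g]], cache, y, cfg$activation, cfg$mse_batch_mean)
        if (cfg$lambda_l1 > 0) {
          for (f in l1f) gr[[f]] <- gr[[f]] + cfg$lambda_l1 * sign(model$tasks[[g]][[f]])
        }
        grads[[g]] <- gr
      }
      for (layer in shared) {
        G <- trace_norm_subgradient(shared_stack(model, layer))
        wf <- layer_weight_field[[layer]]
        bf <- layer_bias_field[[layer]]
        wlen <- length(model$tasks[[1]][[wf]])
        for (j in seq_along(gene_ids)) {
          g <- gene_ids[j]
          col <- G[, j]
          grads[[g]][[wf]] <- grads[[g]][[wf]] +
            cfg$gamma_trace * matrix(col[seq_len(wlen)], nrow(model$tasks[[g]][[wf]]))
          if (cfg$penalize_biases) {
            grads[[g]][[bf]] <- grads[[g]][[bf]] + cfg$gamma_trace * col[-seq_len(wlen)]
          }
        }
      }
      for (g in gene_ids) {
        for (f in names(grads[[g]])) {
          upd <- adam_update(model$tasks[[g]][[f]], grads[[g]][[f]], opt[[g]][[f]],
                             cfg$learning_rate, t_step)
          # strip dimnames picked up from feature matrices so both engines
          # return byte-identical parameter objects
          p <- upd$p
          if (is.matrix(p)) dimnames(p) <- NULL else names(p) <- NULL
          model$tasks[[g]][[f]] <- p
          opt[[g]][[f]] <- upd$state
        }
      }
    }
  }
  model
}

#' Train a cluster of per-gene models with soft parameter sharing
#'
#' Runs Adam on the multi-task loss: per-task squared error plus L1 on all
#' layer weights plus the trace norm of the stacked shared-layer weights,
#' whose gradient is supplied analytically as `U V^T` from the stack's SVD
#' at every step. The whole procedure is repeated `config$repeats` times
#' from seeds derived from `config$seed`, and per-gene test R2 is averaged
#' across repeats.
#'
#' @param train_tasks Named list of `task_dataset`s (one per gene) built on
#'   the training split.
#' @param test_tasks Optional named list of `task_dataset`s on the test
#'   split; genes missing from it get `NA` R2.
#' @param config An [mtl_config()].
#' @return An object of class `mtl_fit`: list with `models` (one trained
#'   `mtl_model` per repeat), `r2` (tibble `gene_id, repeat, r2`), and
#'   `config`.
#' @export
train_cluster <- function(train_tasks, test_tasks = NULL, config = mtl_config()) {
  stopifnot(length(train_tasks) >= 1)
  if (is.null(names(train_tasks))) {
    names(train_tasks) <- vapply(train_tasks, function(d) d$gene_id, character(1))
  }
  models <- vector("list", config$repeats)
  r2_rows <- list()
  for (r in seq_len(config$repeats)) {
    run_seed <- derive_seed(config$seed, "run", r)
    models[[r]] <- train_once(train_tasks, config, run_seed)
    if (!is.null(test_tasks)) {
      for (g in names(train_tasks)) {
        r2 <- NA_real_
        if (g %in% names(test_tasks)) {
          td <- test_tasks[[g]]
          pred <- forward_task(models[[r]]$tasks[[g]], td$features, config$activation)$pred
          if (length(td$targets) >= 2 && sd(td$targets) > 0) {
            r2 <- r_squared(td$targets, pred)
          }
        }
        r2_rows[[length(r2_rows) + 1L]] <- tibble(gene_id = g, run = r, r2 = r2)
      }
    }
  }
  r2 <- if (length(r2_rows)) dplyr::bind_rows(r2_rows) else {
    tibble(gene_id = character(), run = integer(), r2 = double())
  }
  structure(list(models = models, r2 = r2, config = config,
                 gene_ids = names(train_tasks)),
            class = "mtl_fit")
}

#' @exportS3Method base::print
print.mtl_fit <- function(x, ...) {
  cat(sprintf("<mtl_fit> %d gene(s), %d repeat(s)\n", length(x$gene_ids), length(x$models)))
  if (nrow(x$r2)) {
    m <- mean(dplyr::summarise(dplyr::group_by(x$r2, .data$gene_id),
                               r2 = mean(.data$r2, na.rm = TRUE))$r2, na.rm = TRUE)
    cat(sprintf("  mean per-gene test R2: %.4f\n", m))
  }
  invisible(x)
}
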