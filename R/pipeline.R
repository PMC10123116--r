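#' Prepare per-gene task datasets from raw inputs
#'
#' Applies the full preprocessing protocol: gene filtering on velocity
#' coverage, 9:1 (by default) cell split, `log10(x + 1)` then column
#' standardization of expression, column standardization of velocity —
#' each performed separately on the training and testing cells — and
#' `log2(x + 1)` scaling of activity scores, then assembles one
#' `task_dataset` per gene and split.
#'
#' @param expression Raw cells x TFs RPKM matrix.
#' @param velocity Cells x genes velocity matrix, `NA` = missing.
#' @param activity A [tf_activity()] (scaled or not; scaling is applied
#'   once).
#' @param min_cells Minimum non-missing velocity cells per gene.
#' @param train_frac Train fraction of the cell split.
#' @param seed Integer seed for the split.
#' @param standardize_with_train_stats Use training means/sds to
#'   standardize the test split instead of test-only statistics (off by
#'   default, matching the protocol of standardizing the two splits
#'   independently).
#' @return List with `train_tasks`, `test_tasks` (named lists of
#'   `task_dataset`), `x_train` (standardized training expression),
#'   `y_train`, `split`, `gene_ids`, `tf_ids`.
#' @export
prepare_inputs <- function(expression, velocity, activity, min_cells = 0,
                           train_frac = 0.9, seed = 1,
                           standardize_with_train_stats = FALSE) {
  stopifnot(inherits(activity, "tf_activity"))
  velocity <- filter_genes(velocity, min_cells)
  cells <- intersect(rownames(expression), rownames(velocity))
  if (length(cells) < 2) abort_velonet("expression and velocity share fewer than 2 cells")
  expression <- expression[cells, , drop = FALSE]
  velocity <- velocity[cells, , drop = FALSE]
  if (!activity$scaled) activity <- scale_activity(activity)
  tf_ids <- rownames(activity$a_sum)
  gene_ids <- intersect(colnames(velocity), colnames(activity$a_sum))
  if (!length(gene_ids)) abort_velonet("no gene shared between velocity and activity matrices")

  split <- split_cells(cells, ratio = train_frac, seed = seed)
  logged <- log_rpkm(expression)
  x_train <- standardize_columns(logged[split$train, , drop = FALSE])
  y_train <- standardize_columns(velocity[split$train, , drop = FALSE])
  if (standardize_with_train_stats) {
    std_with <- function(ref_raw, new_raw) {
      mu <- colMeans(ref_raw, na.rm = TRUE)
      centered_ref <- sweep(ref_raw, 2, mu, "-")
      sd_pop <- sqrt(colSums(centered_ref^2, na.rm = TRUE) /
                       pmax(1, colSums(!is.na(ref_raw))))
      sd_pop[sd_pop < 1e-12] <- 1
      sweep(sweep(new_raw, 2, mu, "-"), 2, sd_pop, "/")
    }
    x_test <- std_with(logged[split$train, , drop = FALSE], logged[split$test, , drop = FALSE])
    y_test <- std_with(velocity[split$train, , drop = FALSE], velocity[split$test, , drop = FALSE])
  } else {
    x_test <- standardize_columns(logged[split$test, , drop = FALSE])
    y_test <- standardize_columns(velocity[split$test, , drop = FALSE])
  }

  make_tasks <- function(x, y, cell_subset) {
    out <- list()
    for (g in gene_ids) {
      td <- tryCatch(assemble_task_dataset(g, x, y, activity, cell_subset),
                     velonet_error = function(e) NULL)
      if (!is.null(td)) out[[g]] <- td
    }
    out
  }
  train_tasks <- make_tasks(x_train, y_train, split$train)
  if (!length(train_tasks)) abort_velonet("no gene has training cells with velocity")
  test_tasks <- make_tasks(x_test, y_test, split$test)

  list(train_tasks = train_tasks, test_tasks = test_tasks,
       x_train = x_train[, tf_ids, drop = FALSE], y_train = y_train,
       split = split, gene_ids = names(train_tasks), tf_ids = tf_ids)
}

#' Repeated train-and-rank rounds over gene clusters
#'
#' Runs `config$rounds` rounds; each round trains every cluster from a
#' round-specific seed (one repetition per round) and ranks TFs for every
#' gene by attribution against the shared reference example.
#'
#' @param prep Output of [prepare_inputs()].
#' @param clusters A `cluster_assignment` (tibble `gene_id, cluster`)
#'   covering the prepared genes.
#' @param config An [mtl_config()].
#' @return List with `importances` (tibble `gene_id, tf, importance,
#'   round`) and `r2` (tibble `gene_id, round, r2`).
#' @export
run_rounds <- function(prep, clusters, config = mtl_config()) {
  clusters <- as_tibble(clusters)
  stopifnot(all(c("gene_id", "cluster") %in% names(clusters)))
  genes <- intersect(clusters$gene_id, names(prep$train_tasks))
  if (!length(genes)) abort_velonet("cluster assignment covers none of the prepared genes")
  reference <- reference_example(prep$x_train)
  imp_rows <- list()
  r2_rows <- list()
  for (r in seq_len(config$rounds)) {
    round_cfg <- config
    round_cfg$seed <- derive_seed(config$seed, "round", r)
    round_cfg$repeats <- 1L
    for (cl in sort(unique(clusters$cluster))) {
      members <- intersect(clusters$gene_id[clusters$cluster == cl], genes)
      if (!length(members)) next
      fit <- train_cluster(prep$train_tasks[members],
                           prep$test_tasks[intersect(members, names(prep$test_tasks))],
                           round_cfg)
      imp <- rank_tfs(fit$models[[1]], prep$train_tasks[members], reference)
      imp$round <- r
      imp_rows[[length(imp_rows) + 1L]] <- imp
      if (nrow(fit$r2)) {
        r2_rows[[length(r2_rows) + 1L]] <-
          tibble(gene_id = fit$r2$gene_id, round = r, r2 = fit$r2$r2)
      }
    }
  }
  list(importances = dplyr::bind_rows(imp_rows),
       r2 = dplyr::bind_rows(r2_rows))
}

pipeline_schema <- list(
  seed = 1L, out_dir = "velonet_out",
  input = list(genes = NULL, peaks = NULL, sites = NULL, expression = NULL,
               velocity = NULL, peak_cells_mtx = NULL, peak_cells_barcodes = NULL),
  simulate = list(n_tfs = 50L, n_genes = 30L, k_per_gene = 5L, n_cells = 2000L,
                  noise_sd = 0.5, missing_rate = 0.3, dropout_rate = 0,
                  regulator_pool = NULL),
  activity = list(upstream = 3000, downstream = 3000, per_cell = FALSE),
  filter = list(min_cells = 0L),
  split = list(train_frac = 0.9, standardize_with_train_stats = FALSE),
  cluster = list(min_size = 24L, max_size = 25L, n_clusters = NULL),
  train = list(lambda_l1 = 0.002, gamma_trace = 0.01, batch_size = 128L,
               epochs = 100L, learning_rate = 0.01, repeats = 3L,
               sharing_enabled = TRUE, activation = "leaky_relu"),
  network = list(rounds = 5L, top_k = 50L)
)

merge_config_section <- function(defaults, given, path) {
  if (is.null(given)) return(defaults)
  unknown <- setdiff(names(given), names(defaults))
  if (length(unknown)) {
    abort_velonet(sprintf("unknown config key '%s%s'", path, unknown[1]))
  }
  for (k in names(given)) defaults[[k]] <- given[[k]]
  defaults
}

#' Load and validate a pipeline configuration
#'
#' YAML with sections `input` (paths) or `simulate` (generator settings),
#' plus `activity`, `filter`, `split`, `cluster`, `train`, `network`, and
#' top-level `seed` and `out_dir`. Unknown keys are rejected by name;
#' defaults fill everything omitted.
#'
#' @param path Path to a YAML file, or a named list with the same shape.
#' @return A validated `pipeline_config` list.
#' @export
load_config <- function(path) {
  raw <- if (is.character(path)) yaml::read_yaml(path) else path
  if (!is.list(raw)) abort_velonet("config must be a YAML mapping")
  unknown <- setdiff(names(raw), c(names(pipeline_schema)))
  if (length(unknown)) abort_velonet(sprintf("unknown config key '%s'", unknown[1]))
  cfg <- list(
    seed = as.integer(raw$seed %||% pipeline_schema$seed),
    out_dir = raw$out_dir %||% pipeline_schema$out_dir
  )
  for (sec in c("input", "simulate", "activity", "filter", "split",
                "cluster", "train", "network")) {
    cfg[[sec]] <- merge_config_section(pipeline_schema[[sec]], raw[[sec]],
                                       paste0(sec, "."))
  }
  cfg$use_simulation <- !is.null(raw$simulate) || is.null(raw$input)
  if (!cfg$use_simulation) {
    needed <- c("genes", "peaks", "sites", "expression", "velocity")
    for (k in needed) {
      if (is.null(cfg$input[[k]])) abort_velonet(sprintf("config input.%s is required", k))
      if (!file.exists(cfg$input[[k]])) {
        abort_velonet(sprintf("config input.%s: file not found: %s", k, cfg$input[[k]]))
      }
    }
  }
  structure(cfg, class = "pipeline_config")
}

read_sites_tsv <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("tf", "chrom", "start", "end") %in% names(tbl))) {
    abort_velonet(sprintf("sites file %s needs columns tf, chrom, start, end", path))
  }
  tbl
}

#' Run the full inference pipeline from a configuration
#'
#' Executes activity scoring, preprocessing, gene clustering, repeated
#' train+rank rounds, consensus network construction, and (when a planted
#' truth is available) evaluation; writes every artifact under
#' `config$out_dir`. Re-running with an identical configuration reproduces
#' identical outputs.
#'
#' @param config A `pipeline_config` from [load_config()], a path to one,
#'   or a named list.
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with the in-memory results (`activity`,
#'   `prep`, `clusters`, `rounds`, `network`, `metrics`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) config <- load_config(config)
  t0 <- Sys.time()
  say <- function(stage, ...) {
    if (!quiet) message(sprintf("[velonet %s +%.1fs] %s", stage,
                                as.numeric(Sys.time() - t0, units = "secs"),
                                sprintf(...)))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- NULL

  if (config$use_simulation) {
    sim_cfg <- config$simulate
    say("simulate", "n_tfs=%d n_genes=%d n_cells=%d", sim_cfg$n_tfs,
        sim_cfg$n_genes, sim_cfg$n_cells)
    truth <- simulate_truth(
      n_tfs = sim_cfg$n_tfs, n_genes = sim_cfg$n_genes,
      k_per_gene = sim_cfg$k_per_gene, noise_sd = sim_cfg$noise_sd,
      missing_rate = sim_cfg$missing_rate, dropout_rate = sim_cfg$dropout_rate,
      regulator_pool = sim_cfg$regulator_pool,
      seed = derive_seed(config$seed, "truth"))
    sim <- simulate_data(truth, n_cells = sim_cfg$n_cells,
                         seed = derive_seed(config$seed, "data"),
                         per_cell = isTRUE(config$activity$per_cell))
    expression <- sim$expression
    if (sim_cfg$dropout_rate > 0) {
      expression <- apply_dropout(expression, sim_cfg$dropout_rate,
                                  seed = derive_seed(config$seed, "dropout"))
    }
    velocity <- sim$velocity
    peaks <- sim$peaks
    sites <- sim$sites
    genes <- sim$genes
  } else {
    say("load", "reading inputs")
    genes <- readr::read_tsv(config$input$genes, show_col_types = FALSE)
    peaks <- read_bed(config$input$peaks)
    sites <- read_sites_tsv(config$input$sites)
    expression <- read_matrix_tsv(config$input$expression)
    velocity <- read_matrix_tsv(config$input$velocity)
    if (isTRUE(config$activity$per_cell)) {
      if (is.null(config$input$peak_cells_mtx) || is.null(config$input$peak_cells_barcodes)) {
        abort_velonet("per-cell activity requires input.peak_cells_mtx and input.peak_cells_barcodes")
      }
      peaks <- peak_set(peaks$intervals,
                        cell_assignment = read_cell_assignment(
                          config$input$peak_cells_mtx, config$input$peak_cells_barcodes))
    }
  }

  say("activity", "scoring %d sites against %d peaks", nrow(sites), nrow(peaks$intervals))
  catalog <- assign_sites_to_promoters(sites, genes,
                                       upstream = config$activity$upstream,
                                       downstream = config$activity$downstream)
  tf_universe <- sort(unique(sites$tf))
  activity <- if (isTRUE(config$activity$per_cell)) {
    compute_activity_per_cell(catalog, peaks, tf_ids = tf_universe,
                              gene_ids = genes$gene_id)
  } else {
    compute_activity(catalog, normalize_peaks(peaks), tf_ids = tf_universe,
                     gene_ids = genes$gene_id)
  }
  write_matrix_tsv(activity$a_sum, file.path(config$out_dir, "activity_sum.tsv"), id_col = "tf")
  write_matrix_tsv(activity$a_mean, file.path(config$out_dir, "activity_mean.tsv"), id_col = "tf")

  say("preprocess", "filter min_cells=%d, split %.0f:%.0f",
      config$filter$min_cells, 100 * config$split$train_frac,
      100 * (1 - config$split$train_frac))
  prep <- prepare_inputs(
    expression, velocity, activity,
    min_cells = config$filter$min_cells,
    train_frac = config$split$train_frac,
    seed = derive_seed(config$seed, "split"),
    standardize_with_train_stats = isTRUE(config$split$standardize_with_train_stats))

  say("cluster", "%d genes", length(prep$gene_ids))
  y_all <- standardize_columns(velocity[, prep$gene_ids, drop = FALSE])
  feats <- cluster_feature_matrix(y_all)
  n_genes <- nrow(feats)
  n_clusters <- config$cluster$n_clusters
  min_size <- config$cluster$min_size
  max_size <- config$cluster$max_size
  if (!is.null(n_clusters)) {
    # explicit cluster count overrides size bounds with near-equal sizes
    min_size <- floor(n_genes / n_clusters)
    max_size <- ceiling(n_genes / n_clusters)
  }
  clusters <- constrained_kmeans(feats, min_size = min_size, max_size = max_size,
                                 n_clusters = n_clusters,
                                 seed = derive_seed(config$seed, "cluster"))
  readr::write_tsv(clusters, file.path(config$out_dir, "clusters.tsv"))

  train_cfg <- mtl_config(
    lambda_l1 = config$train$lambda_l1, gamma_trace = config$train$gamma_trace,
    batch_size = config$train$batch_size, epochs = config$train$epochs,
    learning_rate = config$train$learning_rate, repeats = config$train$repeats,
    sharing_enabled = config$train$sharing_enabled,
    activation = config$train$activation,
    rounds = config$network$rounds, top_k = config$network$top_k,
    seed = derive_seed(config$seed, "train"))
  say("train", "%d cluster(s) x %d round(s), epochs=%d",
      length(unique(clusters$cluster)), train_cfg$rounds, train_cfg$epochs)
  rounds <- run_rounds(prep, clusters, train_cfg)
  readr::write_tsv(rounds$importances, file.path(config$out_dir, "importance.tsv"))
  readr::write_tsv(rounds$r2, file.path(config$out_dir, "r2.tsv"))

  say("network", "consensus over %d rounds, top-%d", train_cfg$rounds, train_cfg$top_k)
  network <- build_network(rounds$importances, k = train_cfg$top_k)
  write_network(network, file.path(config$out_dir, "network.tsv"))

  metrics <- list(
    n_genes = length(prep$gene_ids), n_tfs = length(prep$tf_ids),
    n_edges = nrow(network),
    mean_test_r2 = if (nrow(rounds$r2)) mean(rounds$r2$r2, na.rm = TRUE) else NA_real_
  )
  if (!is.null(truth)) {
    regs <- truth_regulators(truth)
    per_gene <- vapply(prep$gene_ids, function(g) {
      pred <- network$tf[network$gene_id == g]
      recall_tfs(pred, regs[[g]])
    }, numeric(1))
    metrics$mean_edge_recall <- mean(per_gene)
  }
  run_info <- list(seed = config$seed, config_hash = rlang::hash(unclass(config)),
                   finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(metrics, file.path(config$out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(run_info, file.path(config$out_dir, "run_info.json"),
                         auto_unbox = TRUE)
  }
  say("done", "%d edges", nrow(network))
  invisible(list(activity = activity, prep = prep, clusters = clusters,
                 rounds = rounds, network = network, metrics = metrics,
                 truth = truth))
}
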