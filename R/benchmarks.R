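#' Regulator-recovery experiment on planted synthetic data
#'
#' Simulates a planted TF -> gene network, runs the full pipeline (activity
#' scoring on the toy genome, preprocessing, size-constrained clustering,
#' repeated train+rank rounds, consensus network), then scores how well the
#' top-ranked TFs of each gene recover its planted regulators.
#'
#' @param seed Integer seed driving every stage.
#' @param n_tfs,n_genes,k_per_gene,n_cells,noise_sd,missing_rate Generator
#'   settings (see [simulate_truth()] / [simulate_data()]).
#' @param dropout_rate Optional drop-out rate applied to raw expression.
#' @param regulator_pool Optional shared regulator pool size.
#' @param n_clusters Gene clusters trained jointly.
#' @param rounds Train+rank rounds for the consensus network.
#' @param top_k Top-k cutoff within each round.
#' @param top_m Ranked TFs per gene scored against the planted regulators.
#' @param config An [mtl_config()] supplying training hyperparameters
#'   (its `seed`, `rounds` and `top_k` are overridden here).
#' @return List with `mean_recall`, `per_gene` (tibble `gene_id, recall`),
#'   `r2` (per-gene, per-round test R2), `network`, and `truth`.
#' @export
benchmark_recovery <- function(seed = 1, n_tfs = 50, n_genes = 30, k_per_gene = 5,
                               n_cells = 2000, noise_sd = 0.5, missing_rate = 0.3,
                               dropout_rate = 0, regulator_pool = NULL,
                               n_clusters = 2, rounds = 3, top_k = 10, top_m = 5,
                               config = mtl_config()) {
  truth <- simulate_truth(n_tfs = n_tfs, n_genes = n_genes, k_per_gene = k_per_gene,
                          noise_sd = noise_sd, missing_rate = missing_rate,
                          dropout_rate = dropout_rate, regulator_pool = regulator_pool,
                          seed = derive_seed(seed, "truth"))
  sim <- simulate_data(truth, n_cells = n_cells, seed = derive_seed(seed, "data"))
  expression <- sim$expression
  if (dropout_rate > 0) {
    expression <- apply_dropout(expression, dropout_rate,
                                seed = derive_seed(seed, "dropout"))
  }
  catalog <- assign_sites_to_promoters(sim$sites, sim$genes)
  activity <- compute_activity(catalog, normalize_peaks(sim$peaks),
                               tf_ids = truth$tf_ids, gene_ids = truth$gene_ids)
  prep <- prepare_inputs(expression, sim$velocity, activity,
                         seed = derive_seed(seed, "split"))
  feats <- cluster_feature_matrix(standardize_columns(sim$velocity[, prep$gene_ids, drop = FALSE]))
  clusters <- constrained_kmeans(feats,
                                 min_size = floor(nrow(feats) / n_clusters),
                                 max_size = ceiling(nrow(feats) / n_clusters),
                                 n_clusters = n_clusters,
                                 seed = derive_seed(seed, "cluster"))
  cfg <- config
  cfg$seed <- derive_seed(seed, "train")
  cfg$rounds <- as.integer(rounds)
  cfg$top_k <- as.integer(top_k)
  res <- run_rounds(prep, clusters, cfg)
  network <- build_network(res$importances, k = top_k)
  regs <- truth_regulators(truth)
  per_gene <- tibble(
    gene_id = prep$gene_ids,
    recall = vapply(prep$gene_ids, function(g) {
      edges <- network[network$gene_id == g, ]
      pred <- head(edges$tf[order(-edges$importance, edges$tf)], top_m)
      recall_tfs(pred, regs[[g]])
    }, numeric(1))
  )
  list(mean_recall = mean(per_gene$recall), per_gene = per_gene,
       r2 = res$r2, network = network, truth = truth)
}

#' Soft parameter sharing versus independent training
#'
#' On low-sample synthetic data whose gene programs share a low-dimensional
#' regulator pool, trains the same architecture once with trace-norm
#' sharing on and once with sharing off (the baseline), for each seed, and
#' records the median per-gene test R2 of both.
#'
#' @param seeds Integer vector of seeds (one paired comparison per seed).
#' @param n_cells Cells per simulated data set (low-sample regime).
#' @param regulator_pool Shared regulator pool size planting the common
#'   structure.
#' @param gamma Trace-norm strength of the sharing arm.
#' @inheritParams benchmark_recovery
#' @return Tibble `seed, r2_shared, r2_baseline`.
#' @export
benchmark_sharing <- function(seeds = 1:10, n_cells = 200, n_tfs = 50,
                              n_genes = 30, k_per_gene = 5, regulator_pool = 8,
                              noise_sd = 0.5, missing_rate = 0.3, n_clusters = 2,
                              gamma = 0.1, config = mtl_config()) {
  one_arm <- function(seed, sharing, gamma_trace) {
    truth <- simulate_truth(n_tfs = n_tfs, n_genes = n_genes, k_per_gene = k_per_gene,
                            noise_sd = noise_sd, missing_rate = missing_rate,
                            regulator_pool = regulator_pool,
                            seed = derive_seed(seed, "truth"))
    sim <- simulate_data(truth, n_cells = n_cells, seed = derive_seed(seed, "data"))
    catalog <- assign_sites_to_promoters(sim$sites, sim$genes)
    activity <- compute_activity(catalog, normalize_peaks(sim$peaks),
                                 tf_ids = truth$tf_ids, gene_ids = truth$gene_ids)
    prep <- prepare_inputs(sim$expression, sim$velocity, activity,
                           seed = derive_seed(seed, "split"))
    feats <- cluster_feature_matrix(standardize_columns(sim$velocity[, prep$gene_ids, drop = FALSE]))
    clusters <- constrained_kmeans(feats,
                                   min_size = floor(nrow(feats) / n_clusters),
                                   max_size = ceiling(nrow(feats) / n_clusters),
                                   n_clusters = n_clusters,
                                   seed = derive_seed(seed, "cluster"))
    cfg <- config
    cfg$seed <- derive_seed(seed, "train")
    cfg$repeats <- 1L
    cfg$sharing_enabled <- sharing
    cfg$gamma_trace <- gamma_trace
    r2 <- numeric(0)
    for (cl in sort(unique(clusters$cluster))) {
      members <- intersect(clusters$gene_id[clusters$cluster == cl],
                           names(prep$train_tasks))
      fit <- train_cluster(prep$train_tasks[members],
                           prep$test_tasks[intersect(members, names(prep$test_tasks))],
                           cfg)
      r2 <- c(r2, fit$r2$r2)
    }
    stats::median(r2, na.rm = TRUE)
  }
  dplyr::bind_rows(lapply(seeds, function(s) {
    tibble(seed = s,
           r2_shared = one_arm(s, TRUE, gamma),
           r2_baseline = one_arm(s, FALSE, 0))
  }))
}
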