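#' Gene clustering features from a standardized velocity matrix
#'
#' One row per gene holding its standardized velocities across cells;
#' missing entries are imputed as 0, the per-column mean after
#' standardization, so they are neutral in Euclidean distances.
#'
#' @param y Standardized cells x genes velocity matrix with `NA` missing.
#' @return A genes x cells dense matrix (rownames = gene ids).
#' @export
cluster_feature_matrix <- function(y) {
  stopifnot(is.matrix(y))
  f <- t(y)
  f[is.na(f)] <- 0
  f
}

kmeanspp_centers <- function(features, k, seed) {
  n <- nrow(features)
  with_seed(seed, {
    centers <- matrix(NA_real_, k, ncol(features))
    idx <- sample.int(n, 1)
    centers[1, ] <- features[idx, ]
    d2 <- rowSums(sweep(features, 2, centers[1, ], "-")^2)
    if (k > 1) {
      for (j in 2:k) {
        p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
        idx <- sample.int(n, 1, prob = p)
        centers[j, ] <- features[idx, ]
        d2 <- pmin(d2, rowSums(sweep(features, 2, centers[j, ], "-")^2))
      }
    }
    centers
  })
}

# Exact size-bounded assignment of points to centers via a balanced
# transportation problem: each cluster exposes min_size "required" slots
# (fed only by genes) and max_size - min_size "optional" slots (fed by
# genes or by a zero-cost dummy supply absorbing the spare capacity).
assign_constrained <- function(cost_mat, min_size, max_size) {
  n <- nrow(cost_mat)
  k <- ncol(cost_mat)
  opt_cap <- max_size - min_size
  src <- 0L
  gene <- seq_len(n)                  # 1..n
  req <- n + seq_len(k)               # required slot nodes
  opt <- n + k + seq_len(k)           # optional slot nodes
  dummy <- n + 2L * k + 1L
  sink <- n + 2L * k + 2L

  from <- c(rep(src, n),
            rep(gene, each = 2L * k),
            rep(dummy, k),
            req, opt,
            src)
  to <- c(gene,
          rep(c(req, opt), n),
          opt,
          rep(sink, 2L * k),
          dummy)
  cap <- c(rep(1L, n),
           rep(1L, 2L * k * n),
           rep(opt_cap, k),
           rep(min_size, k), rep(opt_cap, k),
           k * max_size - n)
  cost <- c(rep(0, n),
            as.double(t(cost_mat[, rep(seq_len(k), 2L), drop = FALSE])),
            rep(0, k + 2L * k + 1L))

  res <- .mcf_solve(n + 2L * k + 3L, c(from), c(to), cap, cost, src, sink)
  if (res$max_flow != k * max_size) {
    abort_velonet("size-constrained assignment infeasible")
  }
  gene_edges <- n + seq_len(2L * k * n)
  flow <- res$flow[gene_edges]
  # per gene: 2k arcs ordered (req_1..req_k, opt_1..opt_k)
  assign <- integer(n)
  for (g in seq_len(n)) {
    arcs <- flow[(g - 1L) * 2L * k + seq_len(2L * k)]
    slot <- which(arcs == 1L)
    if (length(slot) != 1L) abort_velonet("assignment step did not route one unit per gene")
    assign[g] <- ((slot - 1L) %% k) + 1L
  }
  assign
}

#' Size-constrained k-means clustering of genes
#'
#' Standard k-means alternation (k-means++ seeding, centroid updates) in
#' which the assignment step solves a min-cost transportation problem so
#' every cluster size s satisfies `min_size <= s <= max_size`. The
#' within-cluster sum of squares is non-increasing across iterations and
#' the result is deterministic for a given seed.
#'
#' @param features Genes x cells numeric matrix (rownames = gene ids), e.g.
#'   from [cluster_feature_matrix()].
#' @param min_size,max_size Inclusive bounds on every cluster's size.
#' @param n_clusters Number of clusters; defaults to
#'   `ceiling(n_genes / max_size)`.
#' @param seed Integer seed.
#' @param max_iter Iteration cap (assignment-unchanged convergence).
#' @return A tibble `gene_id, cluster` with class `cluster_assignment` and
#'   attributes `n_clusters`, `min_size`, `max_size`, `objective`,
#'   `iterations`.
#' @export
#' @examples
#' f <- matrix(rnorm(40), 20, 2, dimnames = list(paste0("g", 1:20), NULL))
#' constrained_kmeans(f, min_size = 10, max_size = 10, seed = 1)
constrained_kmeans <- function(features, min_size = 24, max_size = 25,
                               n_clusters = NULL, seed = 1, max_iter = 100) {
  stopifnot(is.matrix(features))
  n <- nrow(features)
  if (min_size > max_size) abort_velonet("min_size must be <= max_size")
  if (n < min_size) {
    abort_velonet(sprintf("infeasible: n_genes (%d) < min_size (%d)", n, min_size))
  }
  k <- n_clusters %||% ceiling(n / max_size)
  if (min_size * k > n || max_size * k < n) {
    abort_velonet(sprintf(
      "infeasible size bounds: need min_size * k <= n_genes <= max_size * k, got %d * %d <= %d <= %d * %d",
      min_size, k, n, max_size, k))
  }
  gene_ids <- rownames(features) %||% paste0("g", seq_len(n))

  centers <- kmeanspp_centers(features, k, derive_seed(seed, "kmeanspp"))
  assign <- integer(n)
  objective <- Inf
  it <- 0L
  repeat {
    it <- it + 1L
    # squared distances without sweeping per cluster
    d2 <- outer(rowSums(features^2), rep(1, k)) - 2 * features %*% t(centers) +
      outer(rep(1, n), rowSums(centers^2))
    d2[d2 < 0] <- 0
    new_assign <- assign_constrained(d2, min_size, max_size)
    new_obj <- sum(d2[cbind(seq_len(n), new_assign)])
    if (identical(new_assign, assign) || it >= max_iter) {
      assign <- new_assign
      objective <- new_obj
      break
    }
    assign <- new_assign
    objective <- new_obj
    for (j in seq_len(k)) {
      members <- which(assign == j)
      if (length(members)) centers[j, ] <- colMeans(features[members, , drop = FALSE])
    }
  }
  out <- tibble(gene_id = gene_ids, cluster = assign)
  structure(out,
            class = c("cluster_assignment", class(out)),
            n_clusters = k, min_size = min_size, max_size = max_size,
            objective = objective, iterations = it)
}
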