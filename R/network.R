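#' Top-k TFs of one gene's importance ranking
#'
#' Sorted by importance descending; ties broken by lexicographic TF id so
#' rankings are reproducible.
#'
#' @param importance Tibble with columns `tf`, `importance` (one gene).
#' @param k Number of TFs to keep (`k <= n_tfs`).
#' @return Character vector of TF ids, best first.
#' @export
top_k_tfs <- function(importance, k) {
  importance <- as_tibble(importance)
  stopifnot(all(c("tf", "importance") %in% names(importance)))
  if (k > nrow(importance)) abort_velonet("k exceeds the number of TFs")
  ord <- order(-importance$importance, importance$tf)
  importance$tf[ord][seq_len(k)]
}

#' Build a consensus regulatory network from repeated ranking rounds
#'
#' For each gene, the regulators are the TFs present in the top-k list of
#' *every* round; their edge importance is the mean importance across
#' rounds. Genes whose round-wise top-k sets share no TF get no edges.
#'
#' @param round_importances Tibble `gene_id, tf, importance, round` holding
#'   every round's full ranking (same gene and TF universe in all rounds).
#' @param k Top-k cutoff applied within each round (default 50).
#' @return A `regulatory_network`: tibble `tf, gene_id, importance,
#'   n_rounds_supporting`, sorted by gene then descending importance.
#' @export
build_network <- function(round_importances, k = 50) {
  ri <- as_tibble(round_importances)
  req <- c("gene_id", "tf", "importance", "round")
  if (!all(req %in% names(ri))) {
    abort_velonet(sprintf("round importances need columns %s", paste(req, collapse = ", ")))
  }
  rounds <- sort(unique(ri$round))
  universes <- lapply(rounds, function(r) sort(unique(ri$tf[ri$round == r])))
  if (length(unique(vapply(universes, paste, character(1), collapse = "\r"))) != 1L) {
    abort_velonet("TF universes differ across rounds")
  }
  edges <- dplyr::bind_rows(lapply(split(ri, ri$gene_id), function(gi) {
    tops <- lapply(split(gi, gi$round), top_k_tfs, k = k)
    common <- Reduce(intersect, tops)
    if (!length(common)) return(NULL)
    kept <- gi[gi$tf %in% common, ]
    agg <- dplyr::summarise(dplyr::group_by(kept, .data$tf),
                            importance = mean(.data$importance), .groups = "drop")
    tibble(tf = agg$tf, gene_id = gi$gene_id[1], importance = agg$importance,
           n_rounds_supporting = length(tops))
  }))
  if (is.null(edges) || !nrow(edges)) {
    edges <- tibble(tf = character(), gene_id = character(),
                    importance = double(), n_rounds_supporting = integer())
  }
  edges <- edges[order(edges$gene_id, -edges$importance, edges$tf), ]
  structure(edges, class = c("regulatory_network", class(edges)))
}

#' Rank TFs of a network by out-degree
#'
#' @param net A `regulatory_network` (or any edge tibble with `tf`).
#' @return Tibble `tf, degree` in descending degree, ties by TF id.
#' @export
degree_ranking <- function(net) {
  net <- as_tibble(net)
  if (!nrow(net)) return(tibble(tf = character(), degree = integer()))
  d <- dplyr::count(net, .data$tf, name = "degree")
  d[order(-d$degree, d$tf), ]
}

#' Write / read a regulatory network as TSV
#'
#' Columns `tf, gene_id, importance, n_rounds_supporting`; importances are
#' serialized with 6 significant digits.
#'
#' @param net A `regulatory_network`.
#' @param path Output file.
#' @return `write_network` returns `path` invisibly; `read_network` returns
#'   the network.
#' @export
write_network <- function(net, path) {
  out <- as_tibble(net)
  out$importance <- signif(out$importance, 6)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  tbl <- suppressWarnings(readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           tf = readr::col_character(),
                           gene_id = readr::col_character(),
                           importance = readr::col_double(),
                           n_rounds_supporting = readr::col_integer()
                         )))
  prob <- readr::problems(tbl)
  if (nrow(prob)) {
    abort_velonet(sprintf("malformed network row at line %d of %s", prob$row[1] + 1L, path),
                  class = "velonet_parse_error")
  }
  structure(as_tibble(tbl), class = c("regulatory_network", class(as_tibble(tbl))))
}
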