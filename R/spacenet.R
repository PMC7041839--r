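#' Build a weighted space-sharing network from a visit table
#'
#' Two bats share a foraging site when both have a visit record at the same
#' site on the same night; spatial co-occurrence is the proxy for
#' association. The edge weight is the number of co-used sites divided by
#' the number of distinct sites either bat visited (a Jaccard-style
#' proportion in \[0, 1\]; `denominator` selects alternatives). An edge
#' exists whenever at least one site was shared.
#'
#' @param visits Visit tibble (`bat_id`, `night`, `site_id`).
#' @param nodes Optional tibble (`bat_id`, ...) or character vector fixing
#'   node identity and order; nodes without visits are dropped with a
#'   warning. Defaults to the bats present in `visits`, sorted.
#' @param denominator `"union"` (default, |S_i U S_j|), `"min"`
#'   (min(|S_i|, |S_j|)) or `"mean"` of the two set sizes.
#' @return An object of class `sharing_network`: list with `nodes` (tibble),
#'   `W` (symmetric weight matrix, zero diagonal), `shared` (integer matrix
#'   of co-used site counts) and `denominator`. Use [tidy()] for the edge
#'   list and [network_metrics()] for summaries.
#' @export
build_sharing_network <- function(visits, nodes = NULL,
                                  denominator = c("union", "min", "mean")) {
  denominator <- match.arg(denominator)
  v <- dplyr::distinct(tibble::as_tibble(visits),
                       .data$bat_id, .data$night, .data$site_id)
  if (is.null(nodes)) nodes <- sort(unique(v$bat_id))
  node_tbl <- if (is.data.frame(nodes)) tibble::as_tibble(nodes)
              else tibble::tibble(bat_id = as.character(nodes))
  seen <- node_tbl$bat_id %in% v$bat_id
  if (!all(seen)) {
    warning(sprintf("excluding %d node(s) with no visits: %s",
                    sum(!seen), paste(node_tbl$bat_id[!seen], collapse = ", ")),
            call. = FALSE)
    node_tbl <- node_tbl[seen, ]
  }
  ids <- node_tbl$bat_id
  v <- v[v$bat_id %in% ids, ]
  n <- length(ids)
  sites_by_bat <- lapply(split(v$site_id, v$bat_id)[ids], unique)
  n_sites <- vapply(sites_by_bat, length, 1L)
  # same-night, same-site co-occurrence
  co <- dplyr::inner_join(v, v, by = c("night", "site_id"),
                          relationship = "many-to-many",
                          suffix = c("_a", "_b"))
  co <- co[co$bat_id_a < co$bat_id_b, ]
  shared_pairs <- dplyr::distinct(co, .data$bat_id_a, .data$bat_id_b,
                                  .data$site_id) |>
    dplyr::count(.data$bat_id_a, .data$bat_id_b, name = "n_shared")
  shared <- matrix(0L, n, n, dimnames = list(ids, ids))
  ia <- match(shared_pairs$bat_id_a, ids); ib <- match(shared_pairs$bat_id_b, ids)
  shared[cbind(ia, ib)] <- shared_pairs$n_shared
  shared[cbind(ib, ia)] <- shared_pairs$n_shared
  denom <- switch(denominator,
    union = outer(n_sites, n_sites, "+") -
      outer(seq_len(n), seq_len(n),
            Vectorize(function(i, j)
              length(intersect(sites_by_bat[[i]], sites_by_bat[[j]])))),
    min = outer(n_sites, n_sites, pmin),
    mean = outer(n_sites, n_sites, "+") / 2
  )
  W <- ifelse(denom > 0, shared / denom, 0)
  diag(W) <- 0
  structure(
    list(nodes = node_tbl, W = W, shared = shared, denominator = denominator),
    class = "sharing_network"
  )
}

#' @export
print.sharing_network <- function(x, ...) {
  n <- nrow(x$W)
  e <- sum(x$W[upper.tri(x$W)] > 0)
  cat(sprintf("Space-sharing network: %d nodes, %d edges (density %.3f)\n",
              n, e, e / (n * (n - 1) / 2)))
  invisible(x)
}

#' Edge list of a sharing network
#'
#' @param x A `sharing_network`.
#' @param ... Unused.
#' @return Tibble `id_a`, `id_b`, `weight` (proportion), `weight_pct`,
#'   `n_shared_sites`, one row per edge with positive weight.
#' @method tidy sharing_network
#' @export
tidy.sharing_network <- function(x, ...) {
  ids <- rownames(x$W)
  ut <- which(upper.tri(x$W) & x$W > 0, arr.ind = TRUE)
  tibble::tibble(
    id_a = ids[ut[, 1]], id_b = ids[ut[, 2]],
    weight = x$W[ut], weight_pct = 100 * x$W[ut],
    n_shared_sites = x$shared[ut]
  ) |> dplyr::arrange(.data$id_a, .data$id_b)
}

#' Restrict a sharing network to related pairs
#'
#' Keeps an edge only when the pair's relatedness estimate reaches the
#' threshold; all nodes are retained. Pairs with missing relatedness are
#' treated as below threshold.
#'
#' @param net A `sharing_network`.
#' @param rel A `relatedness_df` or square relatedness matrix covering every
#'   node of `net` (else an error).
#' @param threshold Minimum relatedness to keep an edge (default 0.25, the
#'   half-sib level; configurable).
#' @return A `sharing_network` with filtered `W` and `shared`.
#' @export
filter_by_relatedness <- function(net, rel, threshold = 0.25) {
  M <- if (is.matrix(rel)) rel else relatedness_matrix(rel)
  ids <- rownames(net$W)
  if (!all(ids %in% rownames(M))) {
    stop("relatedness matrix does not cover all network nodes", call. = FALSE)
  }
  R <- M[ids, ids]
  keep <- !is.na(R) & R >= threshold
  net$W <- ifelse(keep, net$W, 0)
  net$shared <- ifelse(keep, net$shared, 0L)
  diag(net$W) <- 0; diag(net$shared) <- 0L
  net
}

#' Co-roosting matrix from day-roost records
#'
#' Entry (i, j) is the number of days bats i and j occupied the same day
#' roost. When a bat has several records for one day the first is used.
#'
#' @param roost_records Tibble (`bat_id`, `day`, `roost_id`).
#' @param ids Optional node ordering (default: bats present, sorted).
#' @return Symmetric integer matrix with zero diagonal.
#' @export
build_coroost_matrix <- function(roost_records, ids = NULL) {
  rr <- tibble::as_tibble(roost_records) |>
    dplyr::distinct(.data$bat_id, .data$day, .keep_all = TRUE)
  if (is.null(ids)) ids <- sort(unique(rr$bat_id))
  n <- length(ids)
  M <- matrix(0L, n, n, dimnames = list(ids, ids))
  co <- dplyr::inner_join(rr, rr, by = c("day", "roost_id"),
                          relationship = "many-to-many",
                          suffix = c("_a", "_b"))
  co <- co[co$bat_id_a < co$bat_id_b, ]
  if (nrow(co) > 0L) {
    cnt <- dplyr::count(co, .data$bat_id_a, .data$bat_id_b)
    ia <- match(cnt$bat_id_a, ids); ib <- match(cnt$bat_id_b, ids)
    keep <- !is.na(ia) & !is.na(ib)
    M[cbind(ia[keep], ib[keep])] <- cnt$n[keep]
    M[cbind(ib[keep], ia[keep])] <- cnt$n[keep]
  }
  M
}

#' Network metrics: density, degree, clustering, strength
#'
#' Computes the network density rho (edges over possible edges), per-node
#' normalized degree k (edges over n - 1), the unweighted local clustering
#' coefficient C (fraction of a node's neighbour pairs that are themselves
#' connected; 0 for degree < 2) and the weighted degree (strength)
#' s = sum of edge weights. Binary adjacency drives rho, k and C; weights
#' enter only through s.
#'
#' @param net A `sharing_network` or a symmetric weight matrix.
#' @return An object of class `network_summary`: tibble (`bat_id`,
#'   `degree`, `k`, `clustering`, `strength`) with network-level `density`,
#'   `n`, and node means accessible via [glance()].
#' @export
network_metrics <- function(net) {
  W <- if (inherits(net, "sharing_network")) net$W else as.matrix(net)
  n <- nrow(W)
  if (n < 2L) stop("need at least 2 nodes", call. = FALSE)
  if (is.null(rownames(W))) rownames(W) <- colnames(W) <- paste0("n", seq_len(n))
  A <- (W > 0) * 1
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  deg <- igraph::degree(g)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  node_tbl <- tibble::tibble(
    bat_id = rownames(W),
    degree = as.integer(unname(deg)),
    k = unname(deg) / (n - 1),
    clustering = unname(cc),
    strength = unname(rowSums(W))
  )
  structure(
    list(nodes = node_tbl,
         density = igraph::edge_density(g),
         n = n),
    class = "network_summary"
  )
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf(
    "Network summary: n = %d, density = %.3f, mean k = %.3f, mean C = %.3f, mean s = %.3f\n",
    x$n, x$density, mean(x$nodes$k), mean(x$nodes$clustering),
    mean(x$nodes$strength)))
  invisible(x)
}

#' Per-node metrics of a network summary
#' @param x A `network_summary`.
#' @param ... Unused.
#' @return The per-node tibble (`bat_id`, `degree`, `k`, `clustering`,
#'   `strength`).
#' @method tidy network_summary
#' @export
tidy.network_summary <- function(x, ...) x$nodes

#' One-row network-level summary
#' @param x A `network_summary`.
#' @param ... Unused.
#' @return Tibble with `n`, `density`, `mean_k`, `mean_clustering`,
#'   `mean_strength`.
#' @method glance network_summary
#' @export
glance.network_summary <- function(x, ...) {
  tibble::tibble(
    n = x$n, density = x$density,
    mean_k = mean(x$nodes$k),
    mean_clustering = mean(x$nodes$clustering),
    mean_strength = mean(x$nodes$strength)
  )
}

#' Export a sharing network as GraphML
#'
#' @param net A `sharing_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  g <- igraph::graph_from_adjacency_matrix(net$W, mode = "undirected",
                                           weighted = TRUE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
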