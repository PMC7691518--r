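#' Weighted participation coefficients
#'
#' For each node `i`, `P_i = 1 - sum_m (k_im / k_i)^2`, where `k_i` is the
#' node's total strength and `k_im` its strength into module `m` of the
#' partition — 0 when all of a node's weight stays inside one module,
#' approaching 1 as its strength spreads evenly across modules. Isolated
#' nodes (zero strength) score 0.
#'
#' @param W Symmetric non-negative weighted adjacency matrix with zero
#'   diagonal.
#' @param partition A `network_partition` covering the nodes of `W`.
#' @return Numeric vector of per-node coefficients in [0, 1].
#' @export
participation_coefficients <- function(W, partition) {
  W <- as.matrix(W)
  check_symmetric(W, what = "weight matrix")
  if (any(W < 0)) abort_data("negative weights")
  diag(W) <- 0
  groups <- group_nodes_by_network(partition)
  k <- rowSums(W)
  frac_sq <- matrix(0, nrow(W), length(groups))
  for (m in seq_along(groups)) {
    km <- rowSums(W[, groups[[m]], drop = FALSE])
    frac_sq[, m] <- ifelse(k > 0, (km / k)^2, 0)
  }
  p <- 1 - rowSums(frac_sq)
  p[k == 0] <- 0
  pmin(pmax(p, 0), 1)
}

#' Weighted global efficiency
#'
#' Mean inverse shortest-path length over ordered node pairs, with
#' connection lengths the inverse weights (`L_ij = 1/W_ij` for positive
#' weights, infinite otherwise) and shortest paths by Dijkstra — the
#' standard weighted-efficiency convention for brain graphs. Disconnected
#' pairs contribute 0; graphs with fewer than two nodes score 0.
#'
#' @param W_sub Symmetric non-negative weighted adjacency (sub)matrix.
#' @return Scalar efficiency, >= 0 (and <= 1 for weights in [0, 1]).
#' @export
#' @examples
#' W <- matrix(c(0, 0.5, 0, 0.5, 0, 0.25, 0, 0.25, 0), 3, 3)
#' global_efficiency(W)
global_efficiency <- function(W_sub) {
  W <- as.matrix(W_sub)
  if (length(W) == 1) return(0)
  check_symmetric(W, what = "weight matrix")
  if (any(W < 0)) abort_data("negative weights")
  diag(W) <- 0
  n <- nrow(W)
  if (n < 2 || all(W == 0)) return(0)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected", weighted = TRUE)
  D <- igraph::distances(g, weights = 1 / igraph::E(g)$weight, algorithm = "dijkstra")
  inv <- 1 / D
  diag(inv) <- 0
  inv[is.infinite(D)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Per-day, per-network topology table
#'
#' For every day and network: the network's participation coefficient (the
#' mean of its member nodes' coefficients computed on the full graph — the
#' between-network notion needs cross-network edges) and its global
#' efficiency (computed on the within-network submatrix). Optionally
#' participation can instead be computed per network block.
#'
#' @param stack List of per-day coherence matrices
#'   ([daily_coherence_matrix()] objects or plain matrices).
#' @param partition A `network_partition`.
#' @param participation_graph `"full"` (default) or `"block"`.
#' @return A tibble with columns `day`, `network`, `participation`,
#'   `efficiency` — one row per day x network.
#' @export
daily_topology <- function(stack, partition, participation_graph = c("full", "block")) {
  participation_graph <- match.arg(participation_graph)
  groups <- group_nodes_by_network(partition)
  purrr::imap_dfr(stack, function(cm, idx) {
    W <- if (is.list(cm)) cm$values else cm
    day <- if (is.list(cm) && !is.null(cm$day) && !is.na(cm$day)) cm$day else as.integer(idx)
    W <- as.matrix(W)
    diag(W) <- 0
    if (participation_graph == "full") {
      pc <- participation_coefficients(W, partition)
    }
    purrr::imap_dfr(groups, function(members, net) {
      Wsub <- W[members, members, drop = FALSE]
      part <- if (participation_graph == "full") {
        mean(pc[members])
      } else {
        mean(participation_coefficients(Wsub, partition[members, ]))
      }
      tibble::tibble(
        day = as.integer(day), network = net,
        participation = part, efficiency = global_efficiency(Wsub)
      )
    })
  })
}
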