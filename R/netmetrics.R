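#' All-pairs shortest-path distances on a weighted graph
#'
#' Functional coupling weights are inverted (length = 1/weight) so that
#' shortest paths favour the strongest couplings; unreachable pairs get
#' `Inf`.
#'
#' @param weights symmetric nonnegative N x N coupling matrix.
#' @param mask optional logical N x N matrix of retained edges.
#' @return N x N distance matrix, zero diagonal, symmetric.
#' @export
shortest_distances <- function(weights, mask = NULL) {
  w <- as.matrix(weights)
  if (!is.null(mask)) w <- w * (mask != 0)
  w[w < 0] <- 0
  lengths <- ifelse(w > 0, 1 / w, 0)
  g <- igraph::graph_from_adjacency_matrix(lengths, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  D <- igraph::distances(g, weights = igraph::E(g)$weight)
  diag(D) <- 0
  unname(D)
}

#' Nodal global efficiency
#'
#' `GE_i = (1/(N-1)) * sum_{j != i} 1/d_ij`, with `1/Inf = 0` (unreachable
#' pairs contribute nothing).
#'
#' @param d distance matrix from [shortest_distances].
#' @return numeric vector of length N.
#' @export
nodal_global_efficiency <- function(d) {
  N <- nrow(d)
  if (N < 2) stop("need at least 2 nodes")
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  rowSums(inv) / (N - 1)
}

# network-mean GE of a weighted graph restricted to a mask
mean_global_efficiency <- function(weights, mask = NULL) {
  mean(nodal_global_efficiency(shortest_distances(weights, mask)))
}

#' Network metric time series of nodal global efficiency
#'
#' Column `t` holds the nodal GE profile of window `t`'s statistically and
#' topologically filtered graph.
#'
#' @param idfcg an [build_idfcg] result.
#' @param mask edge-mask array `[T, N, N]` from [filter_idfcg] (or `NULL`
#'   to use all significant edges).
#' @return matrix `[N, T]` with the window scheme attached as attribute
#'   `scheme`.
#' @export
build_nmts <- function(idfcg, mask = NULL) {
  Tn <- dim(idfcg$strength)[1]; N <- dim(idfcg$strength)[2]
  out <- matrix(0, N, Tn)
  for (t in seq_len(Tn)) {
    m <- if (is.null(mask)) NULL else mask[t, , ]
    out[, t] <- nodal_global_efficiency(
      shortest_distances(idfcg$strength[t, , ], m))
  }
  attr(out, "scheme") <- idfcg$scheme
  out
}

#' Strength time series of retained connections
#'
#' Per window, the sum of retained edge weights (each undirected edge counted
#' once); the substrate for the sample-entropy feature.
#'
#' @inheritParams build_nmts
#' @return numeric vector of length T.
#' @export
strength_series <- function(idfcg, mask = NULL) {
  Tn <- dim(idfcg$strength)[1]
  vapply(seq_len(Tn), function(t) {
    w <- idfcg$strength[t, , ]
    if (!is.null(mask)) w <- w * (mask[t, , ] != 0)
    sum(w[upper.tri(w)])
  }, 0)
}
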