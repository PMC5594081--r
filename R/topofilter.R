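#' Minimum spanning tree favouring strong couplings
#'
#' Kruskal-style MST on edge lengths `1/weight`, i.e. the spanning tree (or
#' forest, per connected component) that keeps the strongest couplings while
#' connecting the whole network without cycles.
#'
#' @param weights symmetric nonnegative N x N coupling matrix.
#' @return logical N x N edge mask of the tree.
#' @export
kruskal_mst <- function(weights) {
  w <- as.matrix(weights)
  if (all(w == 0)) stop("empty graph: no edges to span")
  lengths <- ifelse(w > 0, 1 / w, 0)
  g <- igraph::graph_from_adjacency_matrix(lengths, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  mt <- igraph::mst(g, weights = igraph::E(g)$weight)
  m <- igraph::as_adjacency_matrix(mt, sparse = FALSE) > 0
  dimnames(m) <- NULL
  m
}

#' Orthogonal-MST topological filtering
#'
#' Iteratively extracts minimum spanning trees over the edges unused by
#' previous rounds (orthogonality), accumulating their union.  After each
#' round `m` the quality function `J(m) = GE(union) - Cost(union)` is
#' evaluated, where `Cost` is the summed retained weight over the total
#' weight and GE is the network-mean global efficiency of the union.  The
#' union at the maximizing round is the filtered backbone.
#'
#' @param weights symmetric nonnegative N x N matrix (statistically filtered:
#'   non-significant edges already zero).
#' @param m_max maximum rounds (default `floor((N-1)/2)`).
#' @param early_stop stop after this many consecutive decreases of J.
#' @return list with `mask` (logical N x N), `m_star`, and `report`
#'   (data.frame of round, n_edges, cost, ge, J).
#' @export
omst_filter <- function(weights, m_max = NULL, early_stop = 2L) {
  w <- as.matrix(weights)
  N <- nrow(w)
  if (is.null(m_max)) m_max <- max(1L, floor((N - 1) / 2))
  total_w <- sum(w[upper.tri(w)])
  if (total_w <= 0) {
    return(list(mask = matrix(FALSE, N, N), m_star = 0L,
                report = data.frame(round = integer(), n_edges = integer(),
                                    cost = numeric(), ge = numeric(),
                                    J = numeric())))
  }
  remaining <- w
  union_mask <- matrix(FALSE, N, N)
  masks <- list()
  rep_rows <- list()
  decreases <- 0L
  for (m in seq_len(m_max)) {
    if (all(remaining == 0)) break
    tree <- kruskal_mst(remaining)
    if (!any(tree)) break
    union_mask <- union_mask | tree
    remaining[tree] <- 0
    cost <- sum((w * union_mask)[upper.tri(w)]) / total_w
    ge <- mean_global_efficiency(w, union_mask)
    J <- ge - cost
    masks[[m]] <- union_mask
    rep_rows[[m]] <- data.frame(round = m, n_edges = sum(union_mask) / 2,
                                cost = cost, ge = ge, J = J)
    if (m > 1 && J < rep_rows[[m - 1]]$J) decreases <- decreases + 1L
    else decreases <- 0L
    if (decreases >= early_stop) break
  }
  report <- do.call(rbind, rep_rows)
  m_star <- report$round[which.max(report$J)]
  list(mask = masks[[m_star]], m_star = m_star, report = report)
}

#' Arbitrary thresholding schemes
#'
#' The conventional comparators to OMST: keep edges above an absolute weight
#' (`absolute`), the strongest fraction of all possible edges (`density`),
#' or the strongest `param * N / 2` edges (`mean_degree`).
#'
#' @param weights symmetric nonnegative N x N matrix.
#' @param scheme one of `"absolute"`, `"density"`, `"mean_degree"`.
#' @param param threshold (>= 0), density in (0, 1], or mean degree in
#'   `[1, N-1]` respectively.
#' @return logical N x N edge mask.
#' @export
threshold_arbitrary <- function(weights,
                                scheme = c("absolute", "density", "mean_degree"),
                                param) {
  scheme <- match.arg(scheme)
  w <- as.matrix(weights)
  N <- nrow(w)
  ut <- which(upper.tri(w))
  vals <- w[ut]
  keep <- switch(scheme,
    absolute = {
      if (param < 0) stop("absolute threshold must be >= 0")
      ut[vals >= param & vals > 0]
    },
    density = {
      if (param <= 0 || param > 1) stop("density must be in (0, 1]")
      k <- ceiling(param * N * (N - 1) / 2)
      cand <- ut[vals > 0]
      cand[order(-vals[vals > 0])][seq_len(min(k, length(cand)))]
    },
    mean_degree = {
      if (param < 1 || param > N - 1) stop("mean degree must be in [1, N-1]")
      k <- ceiling(param * N / 2)
      cand <- ut[vals > 0]
      cand[order(-vals[vals > 0])][seq_len(min(k, length(cand)))]
    })
  mask <- matrix(FALSE, N, N)
  mask[keep] <- TRUE
  mask | t(mask)
}

#' Topologically filter every window of an IDFCG
#'
#' Applies [omst_filter] (default) or an arbitrary scheme to each window's
#' statistically filtered graph.
#'
#' @param idfcg a [build_idfcg] result.
#' @param scheme `"omst"`, `"absolute"`, `"density"`, or `"mean_degree"`.
#' @param param parameter for the arbitrary schemes (ignored for OMST).
#' @param m_max,early_stop passed to [omst_filter].
#' @return list with `mask` array `[T, N, N]` and, for OMST, `reports`
#'   (per-window data.frames).
#' @export
filter_idfcg <- function(idfcg, scheme = "omst", param = NULL,
                         m_max = NULL, early_stop = 2L) {
  Tn <- dim(idfcg$strength)[1]; N <- dim(idfcg$strength)[2]
  mask <- array(FALSE, c(Tn, N, N))
  reports <- if (scheme == "omst") vector("list", Tn) else NULL
  for (t in seq_len(Tn)) {
    w <- idfcg$strength[t, , ]
    if (all(w == 0)) next
    if (scheme == "omst") {
      r <- omst_filter(w, m_max = m_max, early_stop = early_stop)
      mask[t, , ] <- r$mask
      reports[[t]] <- r$report
    } else {
      mask[t, , ] <- threshold_arbitrary(w, scheme, param)
    }
  }
  list(mask = mask, reports = reports, scheme = scheme, param = param)
}
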