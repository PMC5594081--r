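# Independent brute-force oracles used across the suite.  These deliberately
# re-derive quantities by enumeration or direct counting, never by calling
# the implementation under test.

# all labeled spanning trees of a complete graph on n nodes via Prüfer
# sequences; returns list of edge matrices (2 columns)
all_spanning_trees <- function(n) {
  if (n == 2) return(list(matrix(c(1, 2), 1)))
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  lapply(seq_len(nrow(seqs)), function(r) {
    prufer <- seqs[r, ]
    degree <- rep(1L, n)
    for (v in prufer) degree[v] <- degree[v] + 1L
    edges <- matrix(0L, n - 1, 2)
    ptr <- 0L
    deg <- degree
    for (v in prufer) {
      leaf <- which(deg == 1L)[1]
      ptr <- ptr + 1L
      edges[ptr, ] <- c(leaf, v)
      deg[leaf] <- 0L
      deg[v] <- deg[v] - 1L
    }
    last <- which(deg == 1L)
    edges[n - 1, ] <- last
    edges
  })
}

# exact shortest-path distances by DFS over all simple paths (small n only)
brute_shortest_distances <- function(lengths) {
  n <- nrow(lengths)
  D <- matrix(Inf, n, n); diag(D) <- 0
  recurse <- function(node, target, visited, acc) {
    if (node == target) { D[visited[1], target] <<- min(D[visited[1], target], acc); return() }
    for (nb in seq_len(n)) {
      if (!(nb %in% visited) && is.finite(lengths[node, nb]) && lengths[node, nb] > 0) {
        recurse(nb, target, c(visited, nb), acc + lengths[node, nb])
      }
    }
  }
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    recurse(i, j, i, 0)
  D
}

# distinct-substring count by direct set construction
brute_complexity <- function(s, L) {
  words <- character(0)
  for (l in seq_len(L)) for (i in seq_len(length(s) - l + 1))
    words <- c(words, paste(s[i:(i + l - 1)], collapse = "."))
  length(unique(words))
}

# direct O(n^2) sample-entropy counter (Chebyshev, <= r, self-matches excluded)
brute_sampen <- function(x, m, r) {
  n <- length(x)
  count <- function(mm) {
    nt <- n - m
    tot <- 0L
    for (i in seq_len(nt - 1)) for (j in (i + 1):nt) {
      if (max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) <= r) tot <- tot + 1L
    }
    tot
  }
  -log(count(m + 1) / count(m))
}

# direct double-centering distance-correlation oracle
brute_dcor <- function(x, y) {
  n <- length(x)
  ctr <- function(v) {
    D <- as.matrix(dist(v))
    sweep(sweep(D, 1, rowMeans(D)), 2, colMeans(D)) + mean(D)
  }
  A <- ctr(x); B <- ctr(y)
  sqrt(max(mean(A * B), 0) / sqrt(mean(A^2) * mean(B^2)))
}

# random irreducible row-stochastic matrix (all entries positive)
random_irreducible_P <- function(k) {
  P <- matrix(stats::runif(k * k, 0.05, 1), k)
  P / rowSums(P)
}

sine_recording <- function(freqs, fs = 160, dur = 20, amp = 1) {
  t <- seq_len(fs * dur) / fs
  dat <- t(sapply(freqs, function(f) amp * sin(2 * pi * f * t)))
  recording(dat, fs)
}

interior <- function(n, frac = 0.1) {
  m <- ceiling(n * frac)
  (m + 1):(n - m)
}

rms <- function(x) sqrt(mean(x^2))
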