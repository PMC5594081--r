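#' Non-negative matrix factorization of an NMTS
#'
#' Re-parameterizes the (transposed) network-metric time series `X` (T
#' windows x N sensors, nonnegative) in a reduced nonnegative space:
#' `X ~ V W'` with `V` (T x r) the reduced trajectory and `W` (N x r) the
#' sensor loadings.  Multiplicative (Lee-Seung) updates under the Frobenius
#' objective; the first restart uses a deterministic SVD-based nonnegative
#' initialization, further restarts are random, and the best fit is kept.
#'
#' @param X nonnegative matrix, T x N.
#' @param r factorization rank, `1 <= r <= min(T, N)`.
#' @param seed RNG seed for the random restarts.
#' @param n_restarts number of initializations (default 5).
#' @param max_iter maximum multiplicative updates per restart (default 500).
#' @param tol relative-change convergence tolerance (default 1e-6).
#' @return list with `V`, `W`, `rel_err` (Frobenius ratio
#'   `||X - VW'|| / ||X||`).
#' @export
nnmf_reduce <- function(X, r, seed = 1L, n_restarts = 5L,
                        max_iter = 500L, tol = 1e-6) {
  X <- as.matrix(X)
  if (any(X < 0)) stop("X must be nonnegative")
  Tn <- nrow(X); N <- ncol(X)
  if (r < 1 || r > min(Tn, N)) stop("rank r out of range")
  nX <- sqrt(sum(X^2))
  if (nX == 0) stop("all-zero input")
  eps <- 1e-12

  run <- function(V, W) {
    err_prev <- Inf
    for (it in seq_len(max_iter)) {
      V <- V * (X %*% W) / (V %*% crossprod(W) + eps)
      W <- W * (crossprod(X, V)) / (W %*% crossprod(V) + eps)
      if (it %% 10 == 0 || it == max_iter) {
        err <- sqrt(sum((X - tcrossprod(V, W))^2)) / nX
        if (abs(err_prev - err) < tol * max(err, 1e-30)) break
        err_prev <- err
      }
    }
    list(V = V, W = W, rel_err = sqrt(sum((X - tcrossprod(V, W))^2)) / nX)
  }

  # SVD-based nonnegative init (sign-fixed so it is permutation-equivariant)
  sv <- svd(X, nu = r, nv = r)
  d <- sqrt(pmax(sv$d[seq_len(r)], eps))
  V0 <- abs(sv$u) %*% diag(d, r)
  W0 <- abs(sv$v) %*% diag(d, r)
  best <- run(pmax(V0, eps), pmax(W0, eps))
  if (n_restarts > 1) {
    set.seed(as.integer(seed %% .Machine$integer.max))
    sc <- sqrt(mean(X) / r)
    for (s in seq_len(n_restarts - 1L)) {
      fit <- run(matrix(stats::runif(Tn * r, 0, 2 * sc), Tn, r),
                 matrix(stats::runif(N * r, 0, 2 * sc), N, r))
      if (fit$rel_err < best$rel_err) best <- fit
    }
  }
  best
}

#' Neural-gas vector quantization
#'
#' Fits `k` codebook vectors to the rows of `V` by the rank-based soft-max
#' adaptation rule: on each presentation every prototype moves toward the
#' sample with step `eps(t) * exp(-rank / lambda(t))`, where rank orders
#' prototypes by distance and both the neighbourhood width `lambda` and the
#' learning rate `eps` decay exponentially over the schedule.
#'
#' @param V data matrix, T x r.
#' @param k number of prototypes (`2 <= k <= T`).
#' @param passes passes over the data (default 100).
#' @param lambda0,lambda_f initial/final neighbourhood (defaults k/2, 0.01).
#' @param eps0,eps_f initial/final learning rate (defaults 0.5, 0.005).
#' @param seed RNG seed (initial prototypes and presentation order).
#' @return list with `codebook` (k x r), `distortion` (mean squared distance
#'   to the nearest prototype).
#' @export
neural_gas <- function(V, k, passes = 100L, lambda0 = NULL, lambda_f = 0.01,
                       eps0 = 0.5, eps_f = 0.005, seed = 1L) {
  V <- as.matrix(V)
  Tn <- nrow(V)
  if (k > Tn) stop("k exceeds number of samples")
  if (k > nrow(unique(V))) stop("k exceeds number of distinct points")
  if (is.null(lambda0)) lambda0 <- max(k / 2, 0.01)
  set.seed(as.integer(seed %% .Machine$integer.max))
  C <- V[sample(Tn, k), , drop = FALSE]
  t_max <- passes * Tn
  t_glob <- 0
  for (p in seq_len(passes)) {
    for (i in sample(Tn)) {
      t_glob <- t_glob + 1
      frac <- t_glob / t_max
      lam <- lambda0 * (lambda_f / lambda0)^frac
      ep <- eps0 * (eps_f / eps0)^frac
      d2 <- rowSums((C - matrix(V[i, ], k, ncol(V), byrow = TRUE))^2)
      rk <- rank(d2, ties.method = "first") - 1
      h <- ep * exp(-rk / lam)
      C <- C + h * (matrix(V[i, ], k, ncol(V), byrow = TRUE) - C)
    }
  }
  d2 <- as.matrix(stats::dist(rbind(C, V)))[-(seq_len(k)), seq_len(k), drop = FALSE]^2
  list(codebook = C, distortion = mean(apply(d2, 1, min)))
}

# nearest-prototype index per row of V
nearest_prototype <- function(V, codebook) {
  V <- as.matrix(V); C <- as.matrix(codebook)
  cross <- V %*% t(C)
  d2 <- outer(rowSums(V^2), rep(1, nrow(C))) - 2 * cross +
    outer(rep(1, nrow(V)), rowSums(C^2))
  max.col(-d2, ties.method = "first")
}

vq_reconstruction_error <- function(X, W, codebook, assign) {
  Xhat <- codebook[assign, , drop = FALSE] %*% t(W)
  sqrt(sum((X - Xhat)^2)) / sqrt(sum(X^2))
}

#' Select the number of microstates by reconstruction error
#'
#' The smallest `k` whose vector-quantized reconstruction of `X` (each
#' window's reduced coordinates replaced by its assigned codevector, then
#' back-projected) has a Frobenius error ratio below `threshold` (default
#' 4%); if none qualifies, the largest candidate is returned with a warning.
#'
#' @param X nonnegative T x N matrix.
#' @param k_range candidate `k` values (default 2:10).
#' @param threshold relative-error criterion (default 0.04).
#' @param r NNMF rank (default 8, clamped to `min(T, N)`).
#' @param seed RNG seed.
#' @param ... passed to [neural_gas].
#' @return list with `k`, `errors` (per candidate), `nnmf`, `fit` (the
#'   selected [neural_gas] fit).
#' @export
select_k <- function(X, k_range = 2:10, threshold = 0.04, r = 8,
                     seed = 1L, ...) {
  if (length(k_range) == 0) stop("empty k_range")
  X <- as.matrix(X)
  r <- min(r, nrow(X), ncol(X))
  nm <- nnmf_reduce(X, r, seed = seed)
  errs <- numeric(length(k_range))
  fits <- vector("list", length(k_range))
  for (ii in seq_along(k_range)) {
    fits[[ii]] <- neural_gas(nm$V, k_range[ii], seed = seed, ...)
    assign <- nearest_prototype(nm$V, fits[[ii]]$codebook)
    errs[ii] <- vq_reconstruction_error(X, nm$W, fits[[ii]]$codebook, assign)
    if (errs[ii] < threshold) {
      return(list(k = k_range[ii], errors = errs[seq_len(ii)],
                  nnmf = nm, fit = fits[[ii]]))
    }
  }
  warning("no k in range reaches the reconstruction-error criterion; ",
          "using k_max = ", max(k_range))
  list(k = k_range[length(k_range)], errors = errs, nnmf = nm,
       fit = fits[[length(k_range)]])
}

#' Seriate a codebook
#'
#' Deterministic ordering of the prototypes: a nearest-neighbour chain over
#' codevector (Euclidean) distances starting from the highest-occupancy
#' prototype; ties broken by original index.  Seriation makes neighbouring
#' symbols correspond to similar network states, so the symbolic series
#' follows the underlying dynamics.
#'
#' @param codebook k x r prototype matrix.
#' @param occupancy integer counts of assignments per prototype.
#' @return integer permutation of `1..k`: `order[pos]` is the original
#'   prototype index placed at seriated position `pos`.
#' @export
seriate_codebook <- function(codebook, occupancy) {
  k <- nrow(codebook)
  if (k == 1) return(1L)
  D <- as.matrix(stats::dist(codebook))
  ord <- integer(k)
  ord[1] <- which.max(occupancy)           # which.max: ties -> lowest index
  visited <- rep(FALSE, k); visited[ord[1]] <- TRUE
  for (pos in 2:k) {
    d <- D[ord[pos - 1], ]
    d[visited] <- Inf
    ord[pos] <- which.min(d)
    visited[ord[pos]] <- TRUE
  }
  ord
}

#' Encode a reduced trajectory as a symbolic sequence
#'
#' Each window is assigned the seriated label of its nearest codevector.
#'
#' @param V T x r reduced trajectory.
#' @param codebook k x r prototypes.
#' @param order seriation permutation from [seriate_codebook] (identity if
#'   `NULL`).
#' @return integer vector of length T with values in `1..k`.
#' @export
encode_states <- function(V, codebook, order = NULL) {
  assign <- nearest_prototype(V, codebook)
  if (is.null(order)) return(assign)
  match(assign, order)
}

#' Fit the NNMF-VQ microstate model
#'
#' End-to-end symbolization of a network-metric time series: NNMF reduction,
#' neural-gas quantization (with `k` chosen by the reconstruction-error
#' criterion when not given), seriation, and symbolic encoding.
#'
#' @param nmts N x T nodal metric matrix (as from [build_nmts]).
#' @param k number of microstates, or `NULL` to select via [select_k].
#' @param r NNMF rank (default 8, clamped).
#' @param k_range candidates for selection.
#' @param threshold reconstruction-error criterion.
#' @param seed RNG seed.
#' @return object of class `microstates`: `labels` (seriated, length T),
#'   `codebook` (k x r, original prototype order), `topographies` (k x N
#'   back-projected nodal profiles, seriated order), `order`, `occupancy`,
#'   `rel_err`, `U` (T x k one-hot partition matrix, seriated), `k`, `nnmf`.
#' @export
fit_microstates <- function(nmts, k = NULL, r = 8, k_range = 2:10,
                            threshold = 0.04, seed = 1L) {
  X <- t(as.matrix(nmts))                  # T x N
  if (is.null(k)) {
    sel <- select_k(X, k_range, threshold, r, seed)
    k <- sel$k; nm <- sel$nnmf; fit <- sel$fit
  } else {
    r <- min(r, nrow(X), ncol(X))
    nm <- nnmf_reduce(X, r, seed = seed)
    fit <- neural_gas(nm$V, k, seed = seed)
  }
  assign_raw <- nearest_prototype(nm$V, fit$codebook)
  occ <- tabulate(assign_raw, nbins = k)
  ord <- seriate_codebook(fit$codebook, occ)
  labels <- match(assign_raw, ord)
  rel_err <- vq_reconstruction_error(X, nm$W, fit$codebook, assign_raw)
  U <- matrix(0L, nrow(X), k)
  U[cbind(seq_len(nrow(X)), labels)] <- 1L
  structure(list(labels = labels,
                 codebook = fit$codebook,
                 topographies = fit$codebook[ord, , drop = FALSE] %*% t(nm$W),
                 order = ord, occupancy = occ, rel_err = rel_err,
                 U = U, k = k, nnmf = nm),
            class = "microstates")
}

#' @export
print.microstates <- function(x, ...) {
  cat(sprintf("<microstates> k=%d, T=%d windows, VQ reconstruction error %.2f%%\n",
              x$k, length(x$labels), 100 * x$rel_err))
  invisible(x)
}
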