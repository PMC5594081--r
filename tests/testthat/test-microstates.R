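make_planted_nmts <- function(Tn = 150, N = 16, k = 3, noise = 0.01,
                              seed = 40) {
  set.seed(seed)
  protos <- matrix(runif(k * N, 0.2, 1), k)
  # well-separated prototypes
  protos <- protos + diag(1, k) %*% matrix(rep(seq_len(k), N), k) * 0.5
  states <- rep(seq_len(k), length.out = Tn)
  states <- states[sample(Tn)]
  X <- protos[states, ] * (1 + matrix(rnorm(Tn * N, 0, noise), Tn))
  list(X = X, states = states, protos = protos)
}

test_that("NNMF recovers exactly factorable data and honours constraints", {
  set.seed(41)
  W0 <- matrix(runif(6 * 3), 6); H0 <- matrix(runif(3 * 50), 3)
  X <- t(H0) %*% t(W0)
  nm <- nnmf_reduce(X, 3, seed = 1, max_iter = 20000, tol = 0)
  expect_lt(nm$rel_err, 1e-6)
  expect_true(all(nm$V >= 0) && all(nm$W >= 0))
  expect_equal(dim(nm$V), c(50, 3))
  nm_full <- nnmf_reduce(X, 6, seed = 1, max_iter = 20000, tol = 0)
  expect_lt(nm_full$rel_err, 1e-6)
  expect_error(nnmf_reduce(-X, 3), "nonnegative")
  expect_error(nnmf_reduce(X, 7), "rank")
  # deterministic given the seed
  expect_equal(nnmf_reduce(X, 3, seed = 9)$V, nnmf_reduce(X, 3, seed = 9)$V)
})

test_that("neural gas finds well-separated clusters", {
  set.seed(42)
  centers <- rbind(c(0, 0), c(6, 0), c(0, 6))
  V <- centers[rep(1:3, each = 100), ] + matrix(rnorm(600, 0, 0.3), 300)
  fit <- neural_gas(V, 3, seed = 1)
  D <- as.matrix(dist(rbind(fit$codebook, centers)))[1:3, 4:6]
  expect_lt(max(apply(D, 1, min)), 3 * 0.3 / sqrt(100) * 3)
  # k = 1 degenerates to the data mean
  f1 <- neural_gas(V, 1, seed = 1)
  expect_equal(as.vector(f1$codebook), colMeans(V), tolerance = 0.2)
  # fitted distortion beats a random codebook
  set.seed(43)
  rnd <- V[sample(300, 3), ] + matrix(rnorm(6, 0, 2), 3)
  d_rand <- mean(apply(as.matrix(dist(rbind(rnd, V)))[-(1:3), 1:3]^2, 1, min))
  expect_lte(fit$distortion, d_rand)
  expect_error(neural_gas(V[1:2, ], 3), "exceeds")
})

test_that("k selection applies the reconstruction-error criterion", {
  pl <- make_planted_nmts(noise = 0.01)
  sel <- select_k(pl$X, k_range = 2:6, threshold = 0.04, r = 6, seed = 1)
  expect_lte(sel$k, 4)
  expect_lt(sel$errors[length(sel$errors)], 0.04)
  # a trivial threshold selects the smallest candidate
  expect_equal(select_k(pl$X, 2:6, threshold = 1.0, r = 6, seed = 1)$k, 2)
  expect_warning(select_k(pl$X, 2:3, threshold = 1e-9, r = 6, seed = 1),
                 "criterion")
})

test_that("seriation is a deterministic nearest-neighbour chain", {
  cb <- rbind(c(0, 0), c(10, 0), c(1, 0), c(11, 0))
  occ <- c(5, 50, 4, 3)
  ord <- seriate_codebook(cb, occ)
  expect_equal(sort(ord), 1:4)             # visits each exactly once
  expect_equal(ord[1], 2)                  # highest occupancy first
  expect_equal(ord, c(2, 4, 3, 1))         # chain follows proximity
  # k = 2: higher-occupancy prototype first
  expect_equal(seriate_codebook(rbind(c(0, 0), c(1, 1)), c(1, 9)), c(2, 1))
})

test_that("encoding assigns codevectors to their own labels", {
  cb <- rbind(c(0, 0), c(5, 5), c(9, 0))
  expect_equal(encode_states(cb, cb), 1:3)
  ord <- c(2, 1, 3)
  expect_equal(encode_states(cb, cb, ord), match(1:3, ord))
})

test_that("the NNMF-VQ pipeline recovers a planted switching sequence", {
  skip_if_not_installed("mclust")
  pl <- make_planted_nmts(Tn = 180, N = 16, k = 3, noise = 0.01)
  ms <- fit_microstates(t(pl$X), k_range = 2:6, r = 6, seed = 1)
  expect_lt(ms$rel_err, 0.04)
  ari <- mclust::adjustedRandIndex(ms$labels, pl$states)
  expect_gt(ari, 0.9)
  expect_equal(length(ms$labels), 180)
  expect_true(all(ms$labels %in% seq_len(ms$k)))
  expect_equal(colSums(ms$U), tabulate(ms$labels, ms$k))
})

test_that("the NNMF step lowers distortion relative to VQ alone", {
  pl <- make_planted_nmts(Tn = 150, N = 16, k = 3, noise = 0.05, seed = 44)
  X <- pl$X
  nm <- nnmf_reduce(X, 6, seed = 1)
  fit_red <- neural_gas(nm$V, 3, seed = 1)
  assign_red <- chronnect:::nearest_prototype(nm$V, fit_red$codebook)
  err_nnmf <- chronnect:::vq_reconstruction_error(X, nm$W, fit_red$codebook,
                                                 assign_red)
  fit_raw <- neural_gas(X, 3, seed = 1)
  assign_raw <- chronnect:::nearest_prototype(X, fit_raw$codebook)
  err_raw <- sqrt(sum((X - fit_raw$codebook[assign_raw, ])^2)) /
    sqrt(sum(X^2))
  expect_lte(err_nnmf, err_raw * 1.05)
})

test_that("channel permutation permutes topographies but not the symbols", {
  pl <- make_planted_nmts(Tn = 120, N = 10, k = 3, noise = 0.02, seed = 45)
  X <- pl$X
  perm <- c(4, 1, 10, 3, 2, 8, 6, 5, 9, 7)
  nm_a <- nnmf_reduce(X, 4, seed = 1, n_restarts = 1)
  nm_b <- nnmf_reduce(X[, perm], 4, seed = 1, n_restarts = 1)
  fit_a <- neural_gas(nm_a$V, 3, seed = 1)
  fit_b <- neural_gas(nm_b$V, 3, seed = 1)
  lab_a <- encode_states(nm_a$V, fit_a$codebook)
  lab_b <- encode_states(nm_b$V, fit_b$codebook)
  expect_equal(lab_a, lab_b)
  topo_a <- fit_a$codebook %*% t(nm_a$W)
  topo_b <- fit_b$codebook %*% t(nm_b$W)
  expect_equal(topo_b, topo_a[, perm], tolerance = 1e-6)
})
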