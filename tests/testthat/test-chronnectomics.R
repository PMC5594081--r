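test_that("transition rate counts symbol jumps", {
  expect_equal(transition_rate(c(1, 1, 2, 2, 1)), 0.5)
  expect_equal(transition_rate(rep(3, 20)), 0)
  expect_equal(transition_rate(rep(c(1, 2), 5)), 1)
  expect_error(transition_rate(1L), "short")
})

test_that("transition matrix normalizes by total transitions", {
  TM <- transition_matrix(c(1, 2, 1, 2, 2), 2)
  expect_equal(TM, matrix(c(0, 0.25, 0.5, 0.25), 2))
  expect_equal(transition_matrix(c(1, 1, 1), 2),
               matrix(c(1, 0, 0, 0), 2))
  set.seed(50)
  for (rep in 1:5) {
    s <- sample(4, 60, replace = TRUE)
    TMr <- transition_matrix(s, 4)
    expect_equal(sum(TMr), 1)
    # entries times (T-1) recover integer counts
    expect_equal(TMr * 59, round(TMr * 59), tolerance = 1e-12)
  }
})

test_that("flexibility index counts per-pair mode changes, including 0", {
  arr <- array(0L, c(4, 3, 3))
  arr[, 1, 2] <- arr[, 2, 1] <- c(3L, 3L, 9L, 9L)
  fi <- flexibility_index(arr)
  expect_equal(fi[1, 2], 1 / 3)
  arr2 <- array(5L, c(6, 3, 3))
  expect_equal(max(flexibility_index(arr2)), 0)
  arr3 <- array(0L, c(4, 2, 2))
  arr3[, 1, 2] <- arr3[, 2, 1] <- c(0L, 3L, 0L, 3L)
  expect_equal(flexibility_index(arr3)[1, 2], 1)
})

test_that("comodulograms tabulate mode probabilities in band space", {
  arr <- array(0L, c(5, 3, 3))
  arr[, 1, 2] <- arr[, 2, 1] <- 1L
  cm <- comodulogram(arr)
  expect_equal(cm[1, 1], 1)
  expect_equal(sum(cm), 1)
  arr[, 1, 3] <- arr[, 3, 1] <- 9L
  cm2 <- comodulogram(arr)
  expect_equal(cm2[1, 1], 0.5)
  expect_equal(cm2[1, 2], 0.5)         # delta-theta cell
  expect_warning(z <- comodulogram(array(0L, c(3, 3, 3))), "no significant")
  expect_equal(sum(z), 0)
  set.seed(51)
  rnd <- array(sample(0:36, 4 * 4 * 4 * 5, replace = TRUE), c(5, 4, 4))
  for (t in 1:5) rnd[t, , ][lower.tri(rnd[t, , ])] <-
    t(rnd[t, , ])[lower.tri(rnd[t, , ])]
  expect_equal(sum(comodulogram(rnd)), 1)
})

test_that("complexity index equals a brute-force substring count", {
  sq <- fixture_paper_sequences()
  expect_equal(complexity_index(sq$alternating, 2), 4)
  expect_equal(complexity_index(sq$constant, 2), 2)
  expect_equal(complexity_index(sq$mixed, 2), 6)
  set.seed(52)
  for (rep in 1:10) {
    k <- sample(2:8, 1); len <- sample(20:200, 1); L <- sample(2:7, 1)
    s <- sample(k, len, replace = TRUE)
    expect_equal(complexity_index(s, L), brute_complexity(s, L))
  }
  expect_error(complexity_index(integer(0), 2), "empty")
})

test_that("CI z-scores separate periodic sequences from shuffles", {
  expect_warning(zc <- ci_zscore(rep(1L, 30), 2, n_shuffles = 20, seed = 1),
                 "degenerate")
  expect_equal(zc$z, 0)
  zp <- ci_zscore(rep(c(1L, 2L), 50), max_word_len = 4,
                  n_shuffles = 200, seed = 2)
  expect_lt(zp$z, 0)
  s <- sample(3, 60, replace = TRUE)
  z1 <- ci_zscore(s, 3, 100, seed = 7)
  z2 <- ci_zscore(s, 3, 100, seed = 7)
  expect_identical(z1$z, z2$z)
})

test_that("stationary distributions satisfy mu P = mu", {
  expect_equal(stationary_distribution(matrix(c(0, 1, 1, 0), 2)), c(0.5, 0.5))
  expect_equal(stationary_distribution(matrix(c(0.9, 0.1, 0.1, 0.9), 2)),
               c(0.5, 0.5))
  set.seed(53)
  P <- random_irreducible_P(5)
  mu <- stationary_distribution(P)
  # power-iteration oracle
  v <- rep(1 / 5, 5)
  for (i in 1:10000) v <- as.vector(v %*% P)
  expect_equal(mu, v, tolerance = 1e-10)
  expect_equal(as.vector(mu %*% P), mu, tolerance = 1e-12)
  # reducible chain: restricted to the recurrent class with a warning
  Pr <- rbind(c(0.5, 0.5, 0, 0), c(0.4, 0.4, 0.2, 0),
              c(0, 0, 0.3, 0.7), c(0, 0, 0.6, 0.4))
  expect_warning(mur <- stationary_distribution(Pr), "reducible")
  expect_equal(mur[1:2], c(0, 0))
  expect_equal(sum(mur), 1)
})

test_that("entropy rate is measured in bits", {
  expect_equal(entropy_rate(matrix(c(0, 1, 1, 0), 2)), 0)
  expect_equal(entropy_rate(matrix(0.5, 2, 2)), 1)
  for (k in c(3, 5)) expect_equal(entropy_rate(matrix(1 / k, k, k)), log2(k))
})

test_that("trajectory entropy matches the analytic two-state oracle", {
  # deterministic cycle: no randomness, zero entropy everywhere
  expect_equal(trajectory_entropy(matrix(c(0, 1, 1, 0), 2)),
               matrix(0, 2, 2))
  # first passage 1 -> 2 is a geometric dwell in 1: H = Hb(p12)/p12
  Hb <- function(p) -p * log2(p) - (1 - p) * log2(1 - p)
  P <- matrix(c(0.7, 0.3, 0.6, 0.4), 2, byrow = TRUE)
  H <- trajectory_entropy(P)
  expect_equal(H[1, 2], Hb(0.3) / 0.3, tolerance = 1e-12)
  expect_equal(H[2, 1], Hb(0.6) / 0.6, tolerance = 1e-12)
  # return-trajectory identity on the diagonal
  mu <- stationary_distribution(P)
  expect_equal(diag(H), entropy_rate(P, mu) / mu, tolerance = 1e-12)
})

test_that("markov_trajectory_model drops unvisited states", {
  sts <- c(1, 3, 1, 3, 3, 1, 3, 1, 1, 3)
  mk <- markov_trajectory_model(sts, 4)
  expect_equal(mk$states, c(1, 3))
  expect_equal(mk$mu[c(2, 4)], c(0, 0))
  expect_equal(sum(mk$mu), 1)
  expect_equal(dim(mk$ert), c(4, 4))
  expect_true(all(mk$ert[2, ] == 0) && all(mk$ert[, 2] == 0))
  expect_equal(mk$ert[1, 1], mk$entropy_rate / mk$mu[1], tolerance = 1e-9)
})

test_that("sample entropy matches direct counting and orders regularity", {
  expect_equal(sample_entropy(rep(2.5, 100)), 0)
  set.seed(54)
  x <- runif(300)
  r <- 0.2 * sd(x)
  expect_equal(sample_entropy(x, 2, r), brute_sampen(x, 2, r),
               tolerance = 1e-12)
  per <- sin(2 * pi * seq_len(300) / 25)
  expect_lt(sample_entropy(per, 2, 0.2 * sd(per)),
            sample_entropy(x, 2, r))
  expect_warning(se <- sample_entropy(c(seq_len(50) * 100), 2, r = 1),
                 "no template")
  expect_equal(se, Inf)
})

test_that("sample entropy agrees with an established implementation", {
  skip_if_not_installed("pracma")
  set.seed(56)
  for (x in list(runif(400), rnorm(300))) {
    r <- 0.2 * sd(x)
    expect_equal(sample_entropy(x, 2, r),
                 pracma::sample_entropy(x, edim = 2, r = r, tau = 1),
                 tolerance = 1e-12)
  }
})

test_that("feature vectors have the canonical layout and stable names", {
  k <- 8; N <- 64
  fv <- assemble_features(0.5, matrix(1 / 64, k, k), matrix(0, N, N),
                          matrix(1 / 64, 8, 8), 1.2, matrix(0, k, k), 0.8)
  expect_length(fv, 4263)
  fv2 <- assemble_features(0.5, matrix(0.25, 2, 2), matrix(0, 4, 4),
                           matrix(1 / 64, 8, 8), 0, matrix(0, 2, 2), 0.1)
  expect_length(fv2, 1 + 4 + 16 + 36 + 1 + 4 + 1)
  expect_false(anyDuplicated(names(fv)) > 0)
  expect_identical(names(fv)[1], "tr")
  expect_identical(names(fv)[4263], "sampen")
  # order-stable across calls
  expect_identical(names(fv), names(assemble_features(
    0.1, matrix(1 / 64, k, k), matrix(0, N, N), matrix(1 / 64, 8, 8),
    0, matrix(0, k, k), 0)))
})

test_that("time reversal affects chronnectomics as expected", {
  set.seed(55)
  s <- sample(3, 100, replace = TRUE)
  expect_equal(transition_rate(rev(s)), transition_rate(s))
  expect_equal(transition_matrix(rev(s), 3), t(transition_matrix(s, 3)))
  arr <- array(sample(0:36, 4 * 4 * 20, replace = TRUE), c(20, 4, 4))
  for (t in 1:20) arr[t, , ][lower.tri(arr[t, , ])] <-
    t(arr[t, , ])[lower.tri(arr[t, , ])]
  expect_equal(comodulogram(arr[20:1, , ]), comodulogram(arr))
})
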