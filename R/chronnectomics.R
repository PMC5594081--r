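#' Transition rate of a symbolic sequence
#'
#' Fraction of consecutive window pairs whose symbols differ: higher values
#' mean more frequent jumps between brain states.
#'
#' @param sts integer symbolic sequence, length >= 2.
#' @return scalar in `[0, 1]`.
#' @export
transition_rate <- function(sts) {
  if (length(sts) < 2) stop("sequence too short")
  mean(sts[-1] != sts[-length(sts)])
}

#' Transition probability matrix
#'
#' Counts of `s_t -> s_{t+1}` transitions normalized by the total number of
#' observed transitions (all entries sum to 1).
#'
#' @param sts integer symbolic sequence with values in `1..k`.
#' @param k number of states.
#' @return k x k matrix summing to 1.
#' @export
transition_matrix <- function(sts, k) {
  if (length(sts) < 2) stop("sequence too short")
  TM <- matrix(0, k, k)
  from <- sts[-length(sts)]; to <- sts[-1]
  for (i in seq_along(from)) TM[from[i], to[i]] <- TM[from[i], to[i]] + 1
  TM / (length(sts) - 1)
}

#' Flexibility index of the dominant-coupling-mode tensor
#'
#' Per sensor pair, the fraction of consecutive windows in which the
#' dominant intrinsic coupling mode changes (label 0, loss/gain of
#' significant coupling, counts as a change): how often a pair reconfigures
#' its preferred interaction type.
#'
#' @param mode_tensor integer array `[T, N, N]` of DICM labels.
#' @return N x N symmetric matrix in `[0, 1]`, zero diagonal.
#' @export
flexibility_index <- function(mode_tensor) {
  Tn <- dim(mode_tensor)[1]
  if (Tn < 2) stop("need at least 2 windows")
  changes <- mode_tensor[-1, , , drop = FALSE] !=
    mode_tensor[-Tn, , , drop = FALSE]
  FI <- apply(changes, c(2, 3), mean)
  diag(FI) <- 0
  FI
}

#' Comodulogram of dominant coupling modes
#'
#' The probability distribution of the 36 coupling modes over all windows
#' and sensor pairs with a significant label, arranged in an 8 x 8 matrix:
#' within-band modes on the diagonal, phase-to-amplitude pairs at
#' `[low band, high band]`.
#'
#' @param mode_tensor integer array `[T, N, N]` of DICM labels (0..36).
#' @param modes mode table from [coupling_mode_table].
#' @return 8 x 8 matrix summing to 1 (all-zero with a warning when no
#'   label is significant).
#' @export
comodulogram <- function(mode_tensor, modes = coupling_mode_table()) {
  nb <- max(modes$band_hi)
  N <- dim(mode_tensor)[2]
  ut <- which(upper.tri(matrix(0, N, N)))
  labs <- apply(mode_tensor, 1, function(M) M[ut])
  counts <- tabulate(labs[labs > 0], nbins = nrow(modes))
  out <- matrix(0, nb, nb,
                dimnames = list(modes$name[seq_len(nb)],
                                modes$name[seq_len(nb)]))
  if (sum(counts) == 0) {
    warning("no significant couplings: zero comodulogram")
    return(out)
  }
  for (m in seq_len(nrow(modes)))
    out[modes$band_lo[m], modes$band_hi[m]] <- counts[m]
  out / sum(counts)
}

#' Complexity index of a symbolic sequence
#'
#' The number of distinct contiguous substrings ("words") of lengths 1 up to
#' `max_word_len`: low values indicate repetitive, near-periodic dynamics.
#'
#' @param sts integer symbolic sequence.
#' @param max_word_len longest word counted (default 7).
#' @return integer count of distinct words.
#' @export
complexity_index <- function(sts, max_word_len = 7) {
  n <- length(sts)
  if (n == 0) stop("empty sequence")
  if (n < max_word_len) stop("sequence shorter than max_word_len")
  total <- 0L
  for (l in seq_len(max_word_len)) {
    words <- vapply(seq_len(n - l + 1L), function(i)
      paste(sts[i:(i + l - 1L)], collapse = ","), "")
    total <- total + length(unique(words))
  }
  total
}

#' Z-score of the complexity index against shuffled surrogates
#'
#' The sequence is randomly permuted `n_shuffles` times (default 1,000), the
#' complexity index recomputed for each, and
#' `Z = (CI - mean(CI_rand)) / sd(CI_rand)` reported (0 with a warning when
#' the surrogate spread is zero, e.g. for a constant sequence).
#'
#' @inheritParams complexity_index
#' @param n_shuffles number of random permutations.
#' @param seed RNG seed.
#' @return list with `ci`, `z`, `rand_mean`, `rand_sd`.
#' @export
ci_zscore <- function(sts, max_word_len = 7, n_shuffles = 1000, seed = 1L) {
  if (n_shuffles < 2) stop("n_shuffles must be >= 2")
  ci <- complexity_index(sts, max_word_len)
  set.seed(as.integer(seed %% .Machine$integer.max))
  rnd <- vapply(seq_len(n_shuffles), function(s)
    complexity_index(sample(sts), max_word_len), 0L)
  s <- stats::sd(rnd)
  if (!is.finite(s) || s == 0) {
    warning("degenerate shuffle distribution; Z set to 0")
    return(list(ci = ci, z = 0, rand_mean = mean(rnd), rand_sd = 0))
  }
  list(ci = ci, z = (ci - mean(rnd)) / s, rand_mean = mean(rnd), rand_sd = s)
}

#' Stationary distribution of a Markov chain
#'
#' Solves `mu P = mu`, `sum(mu) = 1`.  A reducible chain is restricted to
#' its (largest) recurrent communicating class with a warning; transient
#' states get stationary mass 0.
#'
#' @param P row-stochastic k x k matrix.
#' @return numeric vector `mu` of length k.
#' @export
stationary_distribution <- function(P) {
  k <- nrow(P)
  if (any(abs(rowSums(P) - 1) > 1e-8)) stop("P must be row-stochastic")
  g <- igraph::graph_from_adjacency_matrix((P > 0) * 1, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  # recurrent classes: strongly connected components with no outgoing edges
  memb <- comp$membership
  recurrent <- setdiff(seq_len(comp$no), unique(memb[unlist(lapply(
    seq_len(k), function(i) {
      out <- which(P[i, ] > 0)
      if (any(memb[out] != memb[i])) i else integer()
    }))]))
  states <- seq_len(k)
  if (comp$no > 1) {
    sizes <- vapply(recurrent, function(cl) sum(memb == cl), 0L)
    cl <- recurrent[which.max(sizes)]
    warning("reducible chain: restricting to a recurrent communicating class")
    states <- which(memb == cl)
  }
  Ps <- P[states, states, drop = FALSE]
  Ps <- Ps / rowSums(Ps)
  e <- eigen(t(Ps))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v <- abs(v) / sum(abs(v))
  mu <- numeric(k)
  mu[states] <- v
  mu
}

#' Entropy rate of a Markov chain
#'
#' `H(X) = -sum_ij mu_i P_ij log2 P_ij` in bits, with `0 log 0 = 0`.
#'
#' @param P row-stochastic matrix.
#' @param mu stationary distribution (computed if missing).
#' @return scalar, bits per step.
#' @export
entropy_rate <- function(P, mu = NULL) {
  if (is.null(mu)) mu <- stationary_distribution(P)
  lp <- ifelse(P > 0, log2(P), 0)
  -sum(mu * rowSums(P * lp))
}

#' Entropy of Markov trajectories
#'
#' For an irreducible chain, the entropy `H_ij` of the random first-passage
#' trajectory from state `i` to state `j` (a path entering `j` for the first
#' time at its end), via the closed-form construction
#' `H = K - K' + H_Delta` with `K = (I - P + A)^{-1} (H* - H_Delta)`,
#' where `A` has every row equal to the stationary distribution,
#' `H*_ij = H(P_i)` is the row entropy, and
#' `(H_Delta)_ii = H(X) / mu_i`.  The diagonal satisfies the return-
#' trajectory identity `H_ii = H(X) / mu_i`.
#'
#' @param P irreducible row-stochastic k x k matrix.
#' @param convention `"rows_mu"` (every row of A is `mu`; the source
#'   construction) or `"paper"` (literal `A_ij = mu_i` variant).
#' @return k x k matrix of trajectory entropies in bits.
#' @export
trajectory_entropy <- function(P, convention = c("rows_mu", "paper")) {
  convention <- match.arg(convention)
  k <- nrow(P)
  mu <- stationary_distribution(P)
  if (any(mu <= 0)) stop("chain is not irreducible")
  Hrate <- entropy_rate(P, mu)
  A <- if (convention == "rows_mu") matrix(mu, k, k, byrow = TRUE)
       else matrix(mu, k, k, byrow = FALSE)
  lp <- ifelse(P > 0, log2(P), 0)
  Hstar <- matrix(-rowSums(P * lp), k, k)     # H*_ij = H(P_i) for all j
  Hdelta <- diag(Hrate / mu, k)
  M <- diag(k) - P + A
  if (abs(det(M)) < 1e-300) stop("singular system: chain not irreducible?")
  K <- solve(M, Hstar - Hdelta)
  Kp <- matrix(diag(K), k, k, byrow = TRUE)   # K'_ij = K_jj
  H <- K - Kp + Hdelta
  H[abs(H) < 1e-12] <- 0
  H
}

#' Fit a Markov trajectory model to a symbolic sequence
#'
#' Estimates the empirical row-stochastic transition matrix on the states
#' actually visited, restricts to the recurrent communicating class, and
#' computes the stationary distribution, entropy rate, and the trajectory-
#' entropy (ERT) matrix, embedded back into the full `k x k` layout (rows
#' and columns of unvisited/transient states are zero).
#'
#' @param sts integer symbolic sequence with values in `1..k`.
#' @param k number of states.
#' @return list with `P` (restricted chain), `states` (their labels), `mu`,
#'   `entropy_rate`, `ert` (k x k).
#' @export
markov_trajectory_model <- function(sts, k) {
  counts <- transition_matrix(sts, k) * (length(sts) - 1)
  visited <- which(rowSums(counts) + colSums(counts) > 0)
  ert <- matrix(0, k, k)
  states <- visited
  C <- counts[states, states, drop = FALSE]
  # iteratively prune states with no outgoing mass (e.g. the final symbol),
  # whose removal can empty further rows
  repeat {
    keep <- rowSums(C) > 0
    if (all(keep)) break
    C <- C[keep, keep, drop = FALSE]
    states <- states[keep]
    if (nrow(C) == 0) break
  }
  if (nrow(C) == 0) {
    return(list(P = matrix(1, 1, 1), states = visited[1],
                mu = replace(numeric(k), visited[1], 1),
                entropy_rate = 0, ert = ert))
  }
  P <- C / rowSums(C)
  mu_s <- stationary_distribution(P)
  sup <- which(mu_s > 0)
  mu_full <- numeric(k)
  Hrate <- NA_real_
  if (length(sup) >= 1) {
    Ps <- P[sup, sup, drop = FALSE]
    Ps <- Ps / rowSums(Ps)
    mu <- stationary_distribution(Ps)
    Hrate <- entropy_rate(Ps, mu)
    if (length(sup) > 1 || Hrate > 0) {
      He <- trajectory_entropy(Ps)
      ert[states[sup], states[sup]] <- He
    }
    mu_full[states[sup]] <- mu
  }
  list(P = P, states = states, mu = mu_full, entropy_rate = Hrate, ert = ert)
}

#' Sample entropy
#'
#' `-ln(A/B)` where `B` and `A` count pairs of length-`m` and length-`m+1`
#' templates matching under the Chebyshev distance within tolerance `r`
#' (self-matches excluded).  Returns 0 for a constant series and `+Inf` with
#' a warning when no matches exist.
#'
#' @param series numeric vector, length > m + 1.
#' @param m template length (default 2).
#' @param r tolerance; default `0.2 * sd(series)`.
#' @return scalar (natural-log units).
#' @export
sample_entropy <- function(series, m = 2, r = 0.2 * stats::sd(series)) {
  n <- length(series)
  if (n <= m + 1) stop("series too short")
  if (stats::sd(series) == 0) return(0)
  if (r <= 0) stop("r must be positive")
  count_matches <- function(mm) {
    nt <- n - m                      # same template count for both lengths
    D <- matrix(0, nt, nt)
    for (d in 0:(mm - 1)) {
      x <- series[(1 + d):(nt + d)]
      D <- pmax(D, abs(outer(x, x, `-`)))
    }
    (sum(D <= r) - nt) / 2
  }
  B <- count_matches(m)
  A <- count_matches(m + 1)
  if (A == 0 || B == 0) {
    warning("no template matches: sample entropy undefined (+Inf)")
    return(Inf)
  }
  -log(A / B)
}

#' Assemble the chronnectomic feature vector
#'
#' Stable named concatenation of the feature blocks:
#' `TR (1) + TM (k^2) + FI (N^2) + comodulogram (36) + CI z-score (1) +
#' ERT (k^2) + SampEn (1)` — 4,263 entries for k = 8, N = 64.
#'
#' @param tr scalar transition rate.
#' @param tm k x k transition matrix.
#' @param fi N x N flexibility index.
#' @param comod 8 x 8 comodulogram.
#' @param ci scalar complexity-index z-score.
#' @param ert k x k trajectory-entropy matrix.
#' @param sampen scalar sample entropy.
#' @return named numeric vector.
#' @export
assemble_features <- function(tr, tm, fi, comod, ci, ert, sampen) {
  k <- nrow(tm); N <- nrow(fi)
  stopifnot(nrow(ert) == k, ncol(tm) == k, ncol(fi) == N,
            nrow(comod) == 8, ncol(comod) == 8)
  grid_names <- function(prefix, nr, nc)
    paste0(prefix, "_", rep(seq_len(nr), times = nc), "_",
           rep(seq_len(nc), each = nr))
  modes <- coupling_mode_table()
  comod_vals <- vapply(seq_len(nrow(modes)), function(m)
    comod[modes$band_lo[m], modes$band_hi[m]], 0)
  out <- c(tr = tr,
           stats::setNames(as.vector(tm), grid_names("tm", k, k)),
           stats::setNames(as.vector(fi), grid_names("fi", N, N)),
           stats::setNames(comod_vals, paste0("comod_", modes$name)),
           ci_z = ci,
           stats::setNames(as.vector(ert), grid_names("ert", k, k)),
           sampen = sampen)
  stopifnot(!anyDuplicated(names(out)))
  out
}

#' Compute all chronnectomic features of one subject
#'
#' @param sts microstate symbolic sequence (seriated labels `1..k`).
#' @param k number of microstates.
#' @param mode_tensor DICM label array `[T, N, N]`.
#' @param strength strength time series (from [strength_series]).
#' @param modes mode table.
#' @param max_word_len complexity-index word length (default 7).
#' @param n_shuffles complexity-index surrogate count (default 1,000).
#' @param seed RNG seed.
#' @return list with every block plus the assembled `features` vector.
#' @export
chronnectomic_features <- function(sts, k, mode_tensor, strength,
                                   modes = coupling_mode_table(),
                                   max_word_len = 7, n_shuffles = 1000,
                                   seed = 1L) {
  tr <- transition_rate(sts)
  tm <- transition_matrix(sts, k)
  fi <- flexibility_index(mode_tensor)
  com <- comodulogram(mode_tensor, modes)
  ciz <- ci_zscore(sts, max_word_len, n_shuffles, seed)
  mk <- markov_trajectory_model(sts, k)
  se <- sample_entropy(strength)
  list(tr = tr, tm = tm, fi = fi, comodulogram = com, ci = ciz,
       markov = mk, sampen = se,
       features = assemble_features(tr, tm, fi, com, ciz$z, mk$ert, se))
}
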