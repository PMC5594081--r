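#' Sliding-window scheme
#'
#' @param n total number of samples.
#' @param width window width in samples.
#' @param step step between window starts in samples.
#' @param margin samples excluded at both ends (filter/analytic transients);
#'   windows lie wholly inside `[margin + 1, n - margin]`.
#' @return list of class `window_scheme` with `width`, `step`, `starts`,
#'   `count`.
#' @export
make_windows <- function(n, width, step = 1L, margin = 0L) {
  width <- as.integer(width); step <- as.integer(step)
  margin <- as.integer(margin)
  if (width < 1 || width > n - 2 * margin) stop("window width exceeds usable samples")
  if (step < 1) stop("step must be >= 1")
  starts <- seq.int(margin + 1L, n - margin - width + 1L, by = step)
  structure(list(width = width, step = step, starts = starts,
                 count = length(starts), n = n),
            class = "window_scheme")
}

#' Imaginary phase-locking value
#'
#' `|Im( mean_t exp(i (phi_a - phi_b)) )| = |mean_t sin(phi_a - phi_b)|`.
#' Insensitive to zero-lag (volume-conducted) coupling.
#'
#' @param phi_a,phi_b phase sequences in radians, equal length >= 2.
#' @return scalar in `[0, 1]`.
#' @export
iplv <- function(phi_a, phi_b) {
  if (length(phi_a) != length(phi_b)) stop("phase sequences differ in length")
  if (length(phi_a) < 2) stop("need at least 2 samples")
  abs(mean(sin(phi_a - phi_b)))
}

#' Phase of a high-band envelope within a low band
#'
#' The phase-to-amplitude coupling (PAC) substrate: the amplitude envelope of
#' the fast rhythm is band-filtered within the slow rhythm's range and its
#' analytic phase extracted; iPLV between this phase and a slow-rhythm phase
#' quantifies PAC.
#'
#' @param envelope_high nonnegative envelope sequence.
#' @param low_band numeric length-2, `c(f_lo, f_hi)` in Hz.
#' @param fs sampling rate in Hz.
#' @return phase sequence in radians.
#' @export
cfc_phase <- function(envelope_high, low_band, fs) {
  if (any(envelope_high < -1e-9)) stop("envelope must be nonnegative")
  if (stats::sd(envelope_high) < 1e-12)
    warning("near-constant envelope: PAC phase is noise-level")
  bf <- signal::butter(3, c(low_band[1], low_band[2]) / (fs / 2), type = "pass")
  Arg(analytic_signal(signal::filtfilt(bf, envelope_high)))
}

#' Coupling-mode label table
#'
#' Labels 1..8 are within-band couplings in band order; labels 9..36 are the
#' 28 unordered cross-frequency (phase-to-amplitude) band pairs in
#' low-band-major lexicographic order, ending at (gamma1, gamma2) = 36.
#' Label 0 is reserved for "no significant coupling".
#'
#' @param bands band table as from [default_bands].
#' @return data.frame with `label`, `type`, `band_lo`, `band_hi`, `name`.
#' @export
coupling_mode_table <- function(bands = default_bands()) {
  nb <- nrow(bands)
  within <- data.frame(label = seq_len(nb), type = "within",
                       band_lo = seq_len(nb), band_hi = seq_len(nb),
                       name = bands$name, stringsAsFactors = FALSE)
  pairs <- which(upper.tri(matrix(0, nb, nb)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  cross <- data.frame(label = nb + seq_len(nrow(pairs)), type = "cfc",
                      band_lo = pairs[, 1], band_hi = pairs[, 2],
                      name = paste0(bands$name[pairs[, 1]], "-",
                                    bands$name[pairs[, 2]]),
                      stringsAsFactors = FALSE)
  rbind(within, cross)
}

#' Surrogate p-value by circular time shift
#'
#' The null statistic is recomputed after circularly shifting `series_b` by a
#' uniformly random offset of at least `min_shift` samples; the p-value is
#' `(1 + #{surrogate >= observed}) / (n_surr + 1)`.
#'
#' @param est_fn function of two series returning the coupling statistic.
#' @param series_a,series_b equal-length numeric series.
#' @param n_surr number of surrogates (>= 19).
#' @param min_shift minimum shift in samples (>= one slowest-band cycle).
#' @param seed integer RNG seed.
#' @return p-value in `(0, 1]`, floored at `1/(n_surr + 1)`.
#' @export
surrogate_pvalue <- function(est_fn, series_a, series_b, n_surr = 200,
                             min_shift = 1L, seed = 1L) {
  n <- length(series_b)
  if (n_surr < 19) stop("n_surr must be >= 19")
  if (n <= 2 * min_shift) stop("series too short for a valid circular shift")
  obs <- est_fn(series_a, series_b)
  set.seed(as.integer(seed %% .Machine$integer.max))
  shifts <- sample(min_shift:(n - min_shift), n_surr, replace = TRUE)
  surr <- vapply(shifts, function(s) {
    est_fn(series_a, series_b[((seq_len(n) + s - 1L) %% n) + 1L])
  }, 0)
  (1 + sum(surr >= obs - 1e-12)) / (n_surr + 1)
}

#' Dominant coupling mode of one window
#'
#' Among modes whose surrogate p-value is below `alpha`, returns the label
#' with maximal iPLV and that iPLV; `(0, 0)` when none is significant.  Ties
#' go to the lowest label.
#'
#' @param iplv_vec iPLV per mode (length = number of modes).
#' @param p_vec surrogate p-value per mode.
#' @param alpha significance level.
#' @param bonferroni divide `alpha` by the number of modes.
#' @return list with `label` and `strength`.
#' @export
dominant_mode <- function(iplv_vec, p_vec, alpha = 0.05, bonferroni = FALSE) {
  a <- if (bonferroni) alpha / length(iplv_vec) else alpha
  sig <- which(p_vec < a)
  if (length(sig) == 0) return(list(label = 0L, strength = 0))
  best <- sig[which.max(iplv_vec[sig])]
  list(label = as.integer(best), strength = iplv_vec[best])
}

# sparse T x n matrix whose rows sum samples of each window
window_sum_matrix <- function(scheme) {
  Tn <- scheme$count; w <- scheme$width
  Matrix::sparseMatrix(
    i = rep(seq_len(Tn), each = w),
    j = as.vector(outer(0:(w - 1L), scheme$starts, `+`)),
    x = 1, dims = c(Tn, scheme$n))
}

# windowed |mean sin(dphi)| for the observed series and a set of circularly
# shifted surrogates of b; returns obs [T], p-values [T] and the surrogate
# matrix [T x n_surr] (needed to combine directional CFC statistics)
windowed_iplv_surr <- function(a, b, W, width, idx) {
  obs <- as.numeric(abs(W %*% sin(a - b))) / width
  if (is.null(idx)) return(list(obs = obs, p = rep(NA_real_, length(obs))))
  Sm <- as.matrix(abs(W %*% sin(a - matrix(b[idx], nrow = length(b))))) / width
  cnt <- rowSums(Sm >= obs - 1e-12)
  list(obs = obs, p = (1 + cnt) / (ncol(idx) + 1), surr = Sm)
}

#' Build the integrated dynamic functional connectivity graph (IDFCG)
#'
#' For every sliding window and unordered sensor pair, estimates iPLV for the
#' 8 within-band couplings and the 28 phase-to-amplitude cross-frequency
#' couplings (each evaluated in both directions; the larger iPLV represents
#' the pair), tests each against circular-shift surrogates, and stores the
#' dominant intrinsic coupling mode (DICM) label and its strength.
#'
#' @param bank an `analytic_bank` from [analytic_decompose].
#' @param width_s window width in seconds (default 2.5).
#' @param step_s window step in seconds (default 0.02, i.e. 20 ms).
#' @param n_surr surrogates per test (default 200).
#' @param alpha per-mode significance level (default 0.05).
#' @param bonferroni correct `alpha` over the 36 modes.
#' @param seed master seed; per-pair streams are derived from it.
#' @param keep_pvalues also return the per-window, per-mode surrogate
#'   p-values (array `[T, modes, pairs]` plus a `pairs` index table);
#'   useful for calibration studies.
#' @return list of class `idfcg`: `strength` and `mode` arrays
#'   `[T, N, N]` (symmetric, zero diagonal; `mode == 0` iff
#'   `strength == 0`), `direction` array (for CFC, +1 when the lower-numbered
#'   sensor supplied the slow phase), plus `scheme`, `modes`, `bands`,
#'   `alpha`, `bonferroni`, `n_surr`, `seed`.
#' @export
build_idfcg <- function(bank, width_s = 2.5, step_s = 0.02, n_surr = 200,
                        alpha = 0.05, bonferroni = FALSE, seed = 1L,
                        keep_pvalues = FALSE) {
  bands <- attr(bank, "bands"); fs <- attr(bank, "fs")
  N <- nrow(bank[[1]]$phase); n <- ncol(bank[[1]]$phase)
  nb <- nrow(bands)
  modes <- coupling_mode_table(bands)
  margin <- max(attr(bank, "transient"))
  width <- as.integer(round(width_s * fs))
  step <- max(1L, as.integer(round(step_s * fs)))
  scheme <- make_windows(n, width, step, margin)
  W <- window_sum_matrix(scheme)
  Tn <- scheme$count
  min_shift <- ceiling(fs / min(bands$f_lo))
  if (n <= 2 * min_shift) stop("recording too short for surrogate shifts")
  a_eff <- if (bonferroni) alpha / nrow(modes) else alpha

  # PAC phase substrate: per cross pair, per channel
  cross <- modes[modes$type == "cfc", ]
  cfc <- vector("list", nrow(cross))
  for (ci in seq_len(nrow(cross))) {
    lo <- cross$band_lo[ci]; hi <- cross$band_hi[ci]
    env <- bank[[hi]]$envelope
    cfc[[ci]] <- t(apply(env, 1, function(e)
      suppressWarnings(cfc_phase(e, c(bands$f_lo[lo], bands$f_hi[lo]), fs))))
  }

  strength <- array(0, c(Tn, N, N))
  mode_arr <- array(0L, c(Tn, N, N))
  dir_arr <- array(0L, c(Tn, N, N))
  n_pairs <- N * (N - 1L) / 2L
  pv_arr <- if (keep_pvalues) array(NA_real_, c(Tn, nrow(modes), n_pairs))
            else NULL
  pair_tab <- matrix(0L, n_pairs, 2L)

  pair_idx <- 0L
  for (i in seq_len(N - 1L)) for (j in (i + 1L):N) {
    pair_idx <- pair_idx + 1L
    set.seed(as.integer((seed + 7919 * pair_idx) %% .Machine$integer.max))
    shifts <- sample(min_shift:(n - min_shift), n_surr, replace = TRUE)
    idx <- outer(seq_len(n), shifts, function(t, s) ((t + s - 1L) %% n) + 1L)

    OBS <- matrix(0, Tn, nrow(modes))
    PV <- matrix(1, Tn, nrow(modes))
    DIR <- matrix(0L, Tn, nrow(modes))
    for (b in seq_len(nb)) {
      r <- windowed_iplv_surr(bank[[b]]$phase[i, ], bank[[b]]$phase[j, ],
                              W, width, idx)
      OBS[, b] <- r$obs; PV[, b] <- r$p
    }
    for (ci in seq_len(nrow(cross))) {
      m <- cross$label[ci]; lo <- cross$band_lo[ci]
      r1 <- windowed_iplv_surr(bank[[lo]]$phase[i, ], cfc[[ci]][j, ],
                               W, width, idx)
      r2 <- windowed_iplv_surr(bank[[lo]]$phase[j, ], cfc[[ci]][i, ],
                               W, width, idx)
      use1 <- r1$obs >= r2$obs
      OBS[, m] <- pmax(r1$obs, r2$obs)
      DIR[, m] <- ifelse(use1, 1L, -1L)
      # the pair statistic is the better direction, so the null statistic is
      # the max over directions of the shifted surrogates as well
      cnt <- rowSums(pmax(r1$surr, r2$surr) >= OBS[, m] - 1e-12)
      PV[, m] <- (1 + cnt) / (n_surr + 1)
    }
    pair_tab[pair_idx, ] <- c(i, j)
    if (keep_pvalues) pv_arr[, , pair_idx] <- PV
    sig <- PV < a_eff
    OBSm <- OBS; OBSm[!sig] <- -1
    lab <- max.col(OBSm, ties.method = "first")
    str <- OBSm[cbind(seq_len(Tn), lab)]
    none <- str <= 0
    lab[none] <- 0L; str[none] <- 0
    d <- DIR[cbind(seq_len(Tn), pmax(lab, 1L))]
    d[none | lab <= nb] <- 0L
    strength[, i, j] <- strength[, j, i] <- str
    mode_arr[, i, j] <- mode_arr[, j, i] <- lab
    dir_arr[, i, j] <- dir_arr[, j, i] <- d
  }
  structure(list(strength = strength, mode = mode_arr, direction = dir_arr,
                 scheme = scheme, modes = modes, bands = bands,
                 alpha = alpha, bonferroni = bonferroni,
                 n_surr = n_surr, seed = seed, fs = fs,
                 pvalues = pv_arr, pairs = pair_tab),
            class = "idfcg")
}

#' @export
print.idfcg <- function(x, ...) {
  cat(sprintf("<idfcg> %d windows x %d x %d sensors; %d modes; alpha=%g%s\n",
              dim(x$strength)[1], dim(x$strength)[2], dim(x$strength)[3],
              nrow(x$modes), x$alpha,
              if (x$bonferroni) " (Bonferroni)" else ""))
  invisible(x)
}
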