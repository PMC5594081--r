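#' Simulate a Markov symbolic sequence
#'
#' @param P row-stochastic transition matrix.
#' @param len sequence length.
#' @param seed RNG seed.
#' @param init initial state (default: sampled from the stationary
#'   distribution).
#' @return integer vector of length `len`.
#' @export
gen_markov_sequence <- function(P, len, seed = 1L, init = NULL) {
  if (any(abs(rowSums(P) - 1) > 1e-8)) stop("P must be row-stochastic")
  k <- nrow(P)
  set.seed(as.integer(seed %% .Machine$integer.max))
  s <- integer(len)
  s[1] <- if (is.null(init))
    sample(k, 1, prob = stationary_distribution(P)) else init
  for (t in seq_len(len - 1L))
    s[t + 1L] <- sample.int(k, 1, prob = P[s[t], ])
  s
}

# 1/f^exponent noise via spectral shaping, unit variance
gen_pink_noise <- function(n, exponent = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed %% .Machine$integer.max))
  white <- stats::rnorm(n)
  X <- stats::fft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)                  # symmetric frequency index
  X <- X * f^(-exponent / 2)
  x <- Re(stats::fft(X, inverse = TRUE) / n)
  (x - mean(x)) / stats::sd(x)
}

#' Specify planted couplings for a synthetic EEG recording
#'
#' Epochs tile the recording; each epoch plants a set of couplings, every
#' coupling given as a sensor pair, a coupling-mode label (1..36), a
#' strength in `[0, 1]` (oscillator amplitude for within-band modes,
#' modulation depth for PAC), and a phase lag in radians (default `pi/2`,
#' the lag the imaginary PLV is maximally sensitive to).
#'
#' @param epochs list of epochs; each a list with `duration_s` and
#'   `couplings` (list of lists with `pair`, `label`, `strength`, `lag`).
#' @param snr_db signal-to-noise ratio of planted oscillations over the 1/f
#'   background, in dB (default 10).
#' @param noise_exponent spectral exponent of the background (default 1).
#' @return list of class `coupling_spec`.
#' @export
coupling_spec <- function(epochs, snr_db = 10, noise_exponent = 1) {
  for (ep in epochs) {
    stopifnot(is.numeric(ep$duration_s), ep$duration_s > 0)
    for (cp in ep$couplings) {
      if (cp$label < 1 || cp$label > 36) stop("mode label outside 1..36")
      stopifnot(length(cp$pair) == 2)
    }
  }
  structure(list(epochs = epochs, snr_db = snr_db,
                 noise_exponent = noise_exponent),
            class = "coupling_spec")
}

# phase-diffusing oscillator: 2*pi*fc*t plus a Gaussian random walk
diffusing_phase <- function(n, fc, fs, sigma = 0.1) {
  2 * pi * fc * seq_len(n) / fs + cumsum(stats::rnorm(n, 0, sigma))
}

#' Generate coupled multichannel EEG
#'
#' Realizes a [coupling_spec] as a multichannel recording: within-band
#' couplings as a shared phase-diffusing oscillator observed in both
#' channels with the stated phase lag; phase-to-amplitude couplings as the
#' slow rhythm's phase (first channel of the pair) modulating the fast
#' carrier's amplitude (second channel), with the stated lag.  Additive
#' 1/f background noise at the stated SNR on every channel.
#'
#' @param spec a [coupling_spec].
#' @param n_channels number of channels.
#' @param fs sampling rate Hz.
#' @param seed RNG seed.
#' @param bands band table (defaults to [default_bands]).
#' @return list with `recording` (a [recording]) and `truth` (data.frame of
#'   planted couplings with epoch sample ranges).
#' @export
gen_coupled_eeg <- function(spec, n_channels, fs, seed = 1L,
                            bands = default_bands()) {
  set.seed(as.integer(seed %% .Machine$integer.max))
  modes <- coupling_mode_table(bands)
  centers <- (bands$f_lo + bands$f_hi) / 2
  n_total <- sum(vapply(spec$epochs, function(e)
    as.integer(round(e$duration_s * fs)), 0L))
  S <- matrix(0, n_channels, n_total)
  truth <- list()
  offset <- 0L
  for (ei in seq_along(spec$epochs)) {
    ep <- spec$epochs[[ei]]
    n <- as.integer(round(ep$duration_s * fs))
    idx <- offset + seq_len(n)
    for (cp in ep$couplings) {
      lag <- if (is.null(cp$lag)) pi / 2 else cp$lag
      st <- if (is.null(cp$strength)) 0.8 else cp$strength
      i <- cp$pair[1]; j <- cp$pair[2]
      m <- modes[modes$label == cp$label, ]
      if (m$type == "within") {
        ph <- diffusing_phase(n, centers[m$band_lo], fs)
        S[i, idx] <- S[i, idx] + st * cos(ph)
        S[j, idx] <- S[j, idx] + st * cos(ph - lag)
      } else {
        ph_lo <- diffusing_phase(n, centers[m$band_lo], fs)
        ph_hi <- diffusing_phase(n, centers[m$band_hi], fs)
        S[i, idx] <- S[i, idx] + st * cos(ph_lo)
        env <- 1 + st * cos(ph_lo - lag)
        S[j, idx] <- S[j, idx] + 0.5 * env * cos(ph_hi)
      }
      truth[[length(truth) + 1]] <- data.frame(
        epoch = ei, from = offset + 1L, to = offset + n,
        i = i, j = j, label = cp$label, strength = st, lag = lag)
    }
    offset <- offset + n
  }
  sig_pow <- mean(rowMeans(S^2)[rowMeans(S^2) > 0])
  if (!is.finite(sig_pow) || sig_pow == 0) sig_pow <- 1
  noise_sd <- sqrt(sig_pow / 10^(spec$snr_db / 10))
  for (ch in seq_len(n_channels))
    S[ch, ] <- S[ch, ] + noise_sd * gen_pink_noise(n_total,
                                                   spec$noise_exponent)
  list(recording = recording(S, fs),
       truth = if (length(truth)) do.call(rbind, truth) else NULL)
}

#' Generate a feature cohort with a planted linear age effect
#'
#' Subjects' ages are drawn in two strata (young and middle-aged, mirroring
#' an 18-37 vs 40-60 split); informative features are linear in age plus
#' Gaussian noise, nuisance blocks share an age-unrelated latent factor (to
#' exercise the feature-clustering step), and the remainder is pure noise.
#'
#' @param n_subjects cohort size (>= 10).
#' @param age_range length-2 numeric (default `c(18, 60)`).
#' @param n_informative number of age-loaded features (default 5).
#' @param slope linear loading of age in the informative features.
#' @param noise_sd residual sd of the informative features (default 0.1).
#' @param n_nuisance_blocks,block_size correlated age-unrelated blocks.
#' @param n_noise pure-noise features (default 30).
#' @param seed RNG seed.
#' @return list with `features` (matrix with named columns), `age`,
#'   `group` (factor young/middle).
#' @export
gen_feature_cohort <- function(n_subjects = 100, age_range = c(18, 60),
                               n_informative = 5, slope = 1, noise_sd = 0.1,
                               n_nuisance_blocks = 2, block_size = 10,
                               n_noise = 30, seed = 1L) {
  if (n_subjects < 10) stop("need at least 10 subjects")
  set.seed(as.integer(seed %% .Machine$integer.max))
  n_young <- ceiling(n_subjects / 2)
  age <- c(stats::runif(n_young, age_range[1], 37),
           stats::runif(n_subjects - n_young, 40, age_range[2]))
  group <- factor(rep(c("young", "middle"), c(n_young, n_subjects - n_young)),
                  levels = c("young", "middle"))
  ord <- sample(n_subjects)
  age <- age[ord]; group <- group[ord]
  blocks <- list()
  if (n_informative > 0) {
    inf <- sapply(seq_len(n_informative), function(j)
      slope * age + stats::rnorm(n_subjects, 0, noise_sd))
    colnames(inf) <- paste0("info_", seq_len(n_informative))
    blocks <- c(blocks, list(inf))
  }
  for (b in seq_len(n_nuisance_blocks)) {
    latent <- stats::rnorm(n_subjects)
    blk <- sapply(seq_len(block_size), function(j)
      latent + stats::rnorm(n_subjects, 0, 0.2))
    colnames(blk) <- paste0("nuis", b, "_", seq_len(block_size))
    blocks <- c(blocks, list(blk))
  }
  if (n_noise > 0) {
    nz <- matrix(stats::rnorm(n_subjects * n_noise), n_subjects)
    colnames(nz) <- paste0("noise_", seq_len(n_noise))
    blocks <- c(blocks, list(nz))
  }
  list(features = do.call(cbind, blocks), age = age, group = group)
}

#' Worked complexity-index example sequences
#'
#' The three 10-symbol sequences used as worked examples of the complexity
#' index (distinct words up to length 2: 4, 2 and 6 respectively).
#'
#' @return list of three integer vectors.
#' @export
fixture_paper_sequences <- function() {
  list(alternating = c(1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L),
       constant = rep(1L, 10L),
       mixed = c(1L, 2L, 2L, 1L, 2L, 2L, 1L, 2L, 1L, 1L))
}
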