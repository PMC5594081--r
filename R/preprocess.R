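#' Default frequency band definitions
#'
#' The eight canonical electrophysiological rhythms used throughout the
#' pipeline: delta, theta, alpha1, alpha2, beta1, beta2, gamma1, gamma2.
#'
#' @return data.frame with columns `name`, `f_lo`, `f_hi` (Hz).
#' @export
default_bands <- function() {
  data.frame(
    name = c("delta", "theta", "alpha1", "alpha2",
             "beta1", "beta2", "gamma1", "gamma2"),
    f_lo = c(0.5, 4, 8, 10, 13, 20, 30, 52),
    f_hi = c(4, 8, 10, 13, 20, 30, 48, 70),
    stringsAsFactors = FALSE)
}

check_bands <- function(bands, fs) {
  stopifnot(all(c("name", "f_lo", "f_hi") %in% names(bands)))
  if (any(bands$f_lo <= 0) || any(bands$f_hi <= bands$f_lo))
    stop("bands must satisfy 0 < f_lo < f_hi")
  if (any(bands$f_hi >= fs / 2))
    stop("band upper edge at or above Nyquist (", fs / 2, " Hz)")
  invisible(bands)
}

#' Zero-phase notch filter for line noise
#'
#' Third-order Butterworth band-stop applied forward-backward (no phase lag).
#'
#' @param rec a [recording].
#' @param f0 notch centre frequency in Hz (default 60, mains).
#' @param bw total stop-band width in Hz.
#' @return Filtered [recording].
#' @export
notch_filter <- function(rec, f0 = 60, bw = 4) {
  validate_recording(rec)
  nyq <- rec$fs / 2
  if (f0 <= 0 || f0 >= nyq) stop("f0 must lie in (0, fs/2)")
  edges <- c(max(f0 - bw / 2, 0.1), min(f0 + bw / 2, nyq * 0.999)) / nyq
  bf <- signal::butter(3, edges, type = "stop")
  out <- t(apply(rec$data, 1, function(x) signal::filtfilt(bf, x)))
  recording(out, rec$fs, rec$labels)
}

#' PCA dimensionality reduction
#'
#' Whitens and reduces the recording to the smallest number of principal
#' components whose cumulative explained variance reaches `var_kept`.
#'
#' @param rec a [recording].
#' @param var_kept fraction of total variance to retain, in (0, 1].
#' @return list with `components` (k x samples scores), `mixing`
#'   (channels x k back-projection matrix), `var_explained` (cumulative
#'   fractions), `center` (channel means).
#' @export
pca_reduce <- function(rec, var_kept = 0.95) {
  validate_recording(rec)
  if (var_kept <= 0 || var_kept > 1) stop("var_kept must be in (0, 1]")
  X <- t(rec$data)                       # samples x channels
  if (all(abs(X) < 1e-300)) stop("degenerate all-zero recording")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  cum <- cumsum(ev) / sum(ev)
  k <- which(cum >= var_kept - 1e-12)[1]
  # drop numerically null directions when var_kept = 1
  k <- min(k, sum(ev > max(ev) * 1e-12))
  list(components = t(pc$x[, seq_len(k), drop = FALSE]),
       mixing = pc$rotation[, seq_len(k), drop = FALSE],
       var_explained = cum[seq_len(k)],
       center = pc$center)
}

#' Flag artifactual components by windowed kurtosis/skewness
#'
#' Kurtosis and skewness are computed in consecutive windows of `win_s`
#' seconds for every component and z-scored against the pooled distribution
#' over all components' windows; a component is flagged when more than 30%
#' of its windowed kurtosis z-scores, or more than 30% of its windowed
#' skewness z-scores, fall outside plus/minus 2.  (Pooling is what makes the
#' rule able to fire: within a single sample at most 25% of points can lie
#' beyond 2 empirical standard deviations, so a per-component reference
#' could never reach the 30% criterion.)  The screening targets
#' ocular/cardiac components but applies to any decomposition (ICA, PCA).
#'
#' @param components k x samples matrix of component time courses.
#' @param fs sampling rate in Hz.
#' @param win_s window length in seconds for the moment estimates (default 1).
#' @param prop flagging proportion threshold (default 0.30).
#' @param z_crit z-score criterion (default 2).
#' @return logical vector of length k; `TRUE` = artifactual.
#' @export
flag_artifact_components <- function(components, fs, win_s = 1,
                                     prop = 0.30, z_crit = 2) {
  components <- as.matrix(components)
  w <- max(2L, as.integer(round(win_s * fs)))
  n <- ncol(components)
  if (n < 2 * w) stop("need at least 2 windows of win_s seconds")
  starts <- seq(1L, n - w + 1L, by = w)
  ok <- apply(components, 1, function(x) stats::var(x) > 1e-24)
  if (!all(ok)) warning("zero-variance component never flagged")
  moments <- function(f) {
    M <- t(apply(components, 1, function(x)
      vapply(starts, function(s) f(x[s:(s + w - 1L)]), 0)))
    M[!ok, ] <- NA
    mu <- mean(M, na.rm = TRUE)
    sdv <- stats::sd(as.vector(M), na.rm = TRUE)
    if (!is.finite(sdv) || sdv < 1e-24) return(matrix(0, nrow(M), ncol(M)))
    (M - mu) / sdv
  }
  zk <- moments(e1071::kurtosis)
  zs <- moments(e1071::skewness)
  flags <- rowMeans(abs(zk) > z_crit) > prop |
    rowMeans(abs(zs) > z_crit) > prop
  flags[!ok] <- FALSE
  unname(flags)
}

#' Reconstruct a recording excluding flagged components
#'
#' Back-projects the non-flagged components of a [pca_reduce] (or compatible)
#' decomposition to sensor space.
#'
#' @param decomposition list with `components`, `mixing`, `center` as returned
#'   by [pca_reduce] (or any decomposition honouring that contract).
#' @param flags logical vector, one per component.
#' @param fs sampling rate of the original recording.
#' @param labels channel labels of the original recording.
#' @return A cleaned [recording].
#' @export
remove_components <- function(decomposition, flags, fs, labels = NULL) {
  keep <- !flags
  if (!any(keep)) stop("all components flagged; nothing to reconstruct")
  M <- decomposition$mixing[, keep, drop = FALSE]
  S <- decomposition$components[keep, , drop = FALSE]
  dat <- M %*% S + decomposition$center
  recording(dat, fs, labels)
}

#' Band-pass filter bank
#'
#' Decomposes a recording into band-limited signals with 3rd-order
#' Butterworth filters applied in zero-phase (forward-backward) mode.
#'
#' @param rec a [recording].
#' @param bands band table as from [default_bands].
#' @return Named list of channels x samples matrices, one per band.
#' @export
bandpass_bank <- function(rec, bands = default_bands()) {
  validate_recording(rec)
  check_bands(bands, rec$fs)
  nyq <- rec$fs / 2
  out <- lapply(seq_len(nrow(bands)), function(b) {
    bf <- signal::butter(3, c(bands$f_lo[b], bands$f_hi[b]) / nyq,
                         type = "pass")
    t(apply(rec$data, 1, function(x) signal::filtfilt(bf, x)))
  })
  names(out) <- bands$name
  attr(out, "bands") <- bands
  attr(out, "fs") <- rec$fs
  out
}

# analytic signal of a real vector via the frequency-domain construction
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Analytic phase/envelope bank
#'
#' Instantaneous phase (radians, wrapped to (-pi, pi]) and amplitude envelope
#' per channel per band, via the analytic-signal (Hilbert) transform.  Each
#' band's leading/trailing `ceil(fs / f_lo)` samples are marked transient:
#' sliding windows should lie wholly outside them.
#'
#' @param bank output of [bandpass_bank].
#' @return list of class `analytic_bank`: per band a list with `phase` and
#'   `envelope` matrices; attributes `bands`, `fs`, `transient` (per-band
#'   sample counts).
#' @export
analytic_decompose <- function(bank) {
  bands <- attr(bank, "bands")
  fs <- attr(bank, "fs")
  out <- lapply(bank, function(M) {
    if (all(abs(M) < 1e-300))
      warning("all-zero band signal: envelope zero, phase undefined")
    an <- t(apply(M, 1, analytic_signal))
    list(phase = Arg(an), envelope = Mod(an))
  })
  names(out) <- names(bank)
  structure(out, class = "analytic_bank", bands = bands, fs = fs,
            transient = ceiling(fs / bands$f_lo))
}

#' Preprocess a recording end to end
#'
#' Notch filter, PCA reduction, artifact flagging and reconstruction, then
#' band filtering and analytic decomposition.
#'
#' @param rec a [recording].
#' @param notch_hz mains frequency (Hz); `NULL` skips the notch.
#' @param var_kept PCA variance fraction.
#' @param win_s artifact-rule window (s).
#' @param bands band table.
#' @return An `analytic_bank`.
#' @export
preprocess_recording <- function(rec, notch_hz = 60, var_kept = 0.95,
                                 win_s = 1, bands = default_bands()) {
  if (!is.null(notch_hz) && notch_hz < rec$fs / 2)
    rec <- notch_filter(rec, notch_hz)
  dec <- pca_reduce(rec, var_kept)
  flags <- flag_artifact_components(dec$components, rec$fs, win_s)
  if (any(flags)) rec <- remove_components(dec, flags, rec$fs, rec$labels)
  analytic_decompose(bandpass_bank(rec, bands))
}
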