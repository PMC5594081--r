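test_that("EDF files round-trip through write_edf/read_edf", {
  set.seed(1)
  rec <- recording(matrix(rnorm(4 * 1600, sd = 20), 4), 160,
                   labels = c("Fp1", "Fp2", "O1", "O2"))
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_recording(path)
  expect_equal(dim(back$data), c(4, 1600))
  expect_equal(back$fs, 160)
  expect_equal(back$labels, rec$labels)
  # 16-bit quantization over the physical range
  expect_lt(max(abs(back$data - rec$data)), diff(range(rec$data)) / 2^15)
})

test_that("read_recording rejects missing and malformed files", {
  expect_error(read_recording(file.path(tempdir(), "nope.edf")), "not found")
  rec <- recording(matrix(rnorm(2 * 320), 2), 160)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  # corrupt the second signal's samples-per-record field -> channels of
  # differing length
  con <- file(path, "r+b")
  seek(con, 256 + 2 * 216 + 8, rw = "write")
  writeChar(formatC("99", width = 8, flag = "-"), con, eos = NULL)
  close(con)
  expect_error(read_recording(path), "mismatched")
})

test_that("recording constructor enforces its invariants", {
  expect_error(recording(matrix(1:10, 1), 160), "2 channels")
  expect_error(recording(matrix(1:10, 2), -1), "positive")
  expect_error(recording(matrix(c(NA, 1:9), 2), 160), "NA")
  expect_error(recording(matrix(1:10, 2), 160, labels = "a"), "labels")
})

test_that("notch filter removes the mains tone and passes other rhythms", {
  rec <- sine_recording(c(60, 10), fs = 160, dur = 20)
  out <- notch_filter(rec, 60)
  idx <- interior(ncol(rec$data))
  expect_lt(rms(out$data[1, idx]), 0.01 * rms(rec$data[1, idx]))
  expect_lt(abs(rms(out$data[2, idx]) / rms(rec$data[2, idx]) - 1), 0.01)
  expect_equal(ncol(out$data), ncol(rec$data))
  zero <- recording(matrix(0, 2, 1600) + 1e-300, 160)
  expect_equal(max(abs(notch_filter(zero, 60)$data)), 0, tolerance = 1e-200)
  expect_error(notch_filter(rec, 100), "fs/2")
})

test_that("PCA reduction keeps the requested variance and finds the rank", {
  set.seed(2)
  src <- matrix(rnorm(2 * 2000), 2)
  mix <- matrix(rnorm(12), 6, 2)
  rec <- recording(mix %*% src, 160)
  red <- pca_reduce(rec, 0.95)
  expect_equal(nrow(red$components), 2)
  expect_equal(dim(red$mixing), c(6, 2))
  white <- recording(matrix(rnorm(6 * 2000), 6), 160)
  redw <- pca_reduce(white, 0.95)
  expect_lte(nrow(redw$components), 6)
  expect_gte(max(redw$var_explained), 0.95)
  expect_equal(nrow(pca_reduce(rec, 1.0)$components), 2)  # matrix rank
})

test_that("artifact rule flags spiky components and spares Gaussian ones", {
  set.seed(3)
  fs <- 100; n_win <- 80
  gauss <- matrix(rnorm(2 * n_win * fs), 2)
  expect_false(any(flag_artifact_components(gauss, fs, win_s = 1)))
  # large unipolar spikes in 40% of the 1-s windows of one component,
  # screened against four clean companions
  spiky <- rnorm(n_win * fs)
  hit <- sample(n_win, 0.4 * n_win)
  for (w in hit) spiky[(w - 1) * fs + sample(fs, 3)] <- 25
  comps <- rbind(spiky, matrix(rnorm(4 * n_win * fs), 4))
  flags <- flag_artifact_components(comps, fs, 1)
  expect_true(flags[1])
  expect_false(any(flags[2:5]))
  expect_warning(
    f0 <- flag_artifact_components(rbind(rep(1, 800), rnorm(800)), 100, 1),
    "zero-variance")
  expect_false(f0[1])
})

test_that("artifact rule false-alarm rate on Gaussian components is below 5%", {
  set.seed(4)
  comps <- matrix(rnorm(1000 * 60 * 50), 1000)   # 60 windows of 0.5 s at 100 Hz
  flags <- flag_artifact_components(comps, fs = 100, win_s = 0.5)
  expect_lt(mean(flags), 0.05)
})

test_that("band-pass bank separates rhythms with zero phase lag", {
  fs <- 160; dur <- 20
  rec <- sine_recording(c(9, 9), fs, dur)
  bank <- bandpass_bank(rec)
  idx <- interior(fs * dur)
  expect_gte(rms(bank$alpha1[1, idx]), 0.9 / sqrt(2))
  expect_lte(rms(bank$delta[1, idx]), 0.05)
  t <- seq_len(fs * dur) / fs
  mix <- recording(rbind(sin(2 * pi * 6 * t) + sin(2 * pi * 25 * t),
                         rnorm(fs * dur)), fs)
  bm <- bandpass_bank(mix)
  expect_gt(cor(bm$theta[1, idx], sin(2 * pi * 6 * t)[idx]), 0.95)
  expect_gt(cor(bm$beta2[1, idx], sin(2 * pi * 25 * t)[idx]), 0.95)
  # zero-phase: in-band output peaks its cross-correlation at lag 0
  cc <- ccf(bm$theta[1, idx], sin(2 * pi * 6 * t)[idx], lag.max = 10,
            plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  bad <- default_bands(); bad$f_hi[8] <- 90
  expect_error(bandpass_bank(rec, bad), "Nyquist")
})

test_that("filtering is shift-equivariant and passive", {
  set.seed(5)
  fs <- 160; n <- fs * 15
  x <- rnorm(n)
  shift <- 32
  rec1 <- recording(rbind(x, x), fs)
  rec2 <- recording(rbind(c(rep(0, shift), x[1:(n - shift)]),
                          c(rep(0, shift), x[1:(n - shift)])), fs)
  b1 <- bandpass_bank(rec1); b2 <- bandpass_bank(rec2)
  idx <- (n / 4):(3 * n / 4)
  expect_equal(b2$alpha2[1, idx + shift], b1$alpha2[1, idx], tolerance = 1e-6)
  pow_in <- mean(x^2)
  pow_bands <- sum(vapply(b1, function(M) mean(M[1, ]^2), 0))
  expect_lte(pow_bands, pow_in * 1.01)
})

test_that("analytic decomposition recovers phase ramps and envelopes", {
  fs <- 160; dur <- 20; f <- 9          # mid-band tone for alpha1 (8-10 Hz)
  rec <- sine_recording(c(f, f), fs, dur)
  bank <- analytic_decompose(bandpass_bank(rec))
  idx <- interior(fs * dur)
  ph <- bank$alpha1$phase[1, ]
  dph <- diff(ph)[idx]
  dph <- (dph + pi) %% (2 * pi) - pi
  expect_equal(median(dph), 2 * pi * f / fs, tolerance = 1e-3)
  expect_lt(max(abs(bank$alpha1$envelope[1, idx] - 1)), 0.01)
  # AM: 40 Hz carrier, 6 Hz modulator shows up in the gamma1 envelope
  t <- seq_len(fs * dur) / fs
  am <- recording(rbind((1 + 0.8 * sin(2 * pi * 6 * t)) * cos(2 * pi * 40 * t),
                        rnorm(fs * dur)), fs)
  ba <- analytic_decompose(bandpass_bank(am))
  expect_gt(cor(ba$gamma1$envelope[1, idx], sin(2 * pi * 6 * t)[idx]), 0.95)
  expect_true(all(attr(bank, "transient") == ceiling(fs / default_bands()$f_lo)))
})
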