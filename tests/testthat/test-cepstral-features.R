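bank_default <- build_mel_filterbank()

spectra_for <- function(seg, nfft = 512L, cfg = frame_config()) {
  magnitude_spectra(frame_and_window(seg, cfg), nfft)
}

test_that("mel scale matches direct evaluation and is strictly increasing", {
  expect_equal(mel_scale(0), 0)
  expect_equal(mel_scale(700), 1125 * log(2))
  expect_equal(mel_scale(1000), 1125 * log(1 + 1000 / 700))
  f <- seq(0, 22050, length.out = 200)
  expect_true(all(diff(mel_scale(f)) > 0))
  expect_equal(mel_to_hz(mel_scale(1234.5)), 1234.5)
  expect_error(mel_scale(-1), "negative")
})

test_that("mel filterbank has unimodal triangles with mel-equispaced edges", {
  bank <- bank_default
  expect_identical(nrow(bank$weights), 13L)
  for (i in 1:13) {
    r <- bank$weights[i, ]
    p <- which.max(r)
    expect_true(all(diff(r[1:p]) >= 0))
    expect_true(all(diff(r[p:length(r)]) <= 0))
    expect_equal(max(r), 1)
  }
  # pre-snap edges are equally spaced on the mel axis
  edges_mel <- seq(mel_scale(0), mel_scale(22050), length.out = 15)
  expect_lt(max(abs(diff(edges_mel) - diff(edges_mel)[1])), 1e-9)
  # adjacent filters overlap
  for (i in 1:12) {
    expect_gt(sum(bank$weights[i, ] > 0 & bank$weights[i + 1, ] > 0), 0)
  }
  single <- build_mel_filterbank(1, 512, 44100)
  expect_identical(nrow(single$weights), 1L)
  expect_error(build_mel_filterbank(0), "n_filters")
  expect_error(build_mel_filterbank(100, 64, 44100), "degenerate")
})

test_that("MFCCs are deterministic and amplitude scaling shifts only c0", {
  seg <- tone_segment(500, 0.04)
  sp <- spectra_for(seg)
  m1 <- mfcc_frames(sp, bank_default)
  expect_identical(dim(m1), c(nrow(sp$magnitudes), 13L))
  expect_identical(m1, mfcc_frames(sp, bank_default))
  # doubling amplitude: c0 shifts by a constant, c1..c12 unchanged
  sp2 <- sp
  sp2$magnitudes <- 2 * sp$magnitudes
  m2 <- mfcc_frames(sp2, bank_default)
  expect_equal(m2[, 2:13], m1[, 2:13], tolerance = 1e-6)
  shift <- m2[, 1] - m1[, 1]
  expect_equal(shift, rep(shift[1], length(shift)), tolerance = 1e-6)
  # the DCT of a constant log-shift loads only basis 0: 13 log(2) / sqrt(13)
  expect_equal(shift[1], sqrt(13) * log(2), tolerance = 1e-6)
  # all-zero frames stay finite through the log floor
  spz <- sp
  spz$magnitudes[1, ] <- 0
  expect_true(all(is.finite(mfcc_frames(spz, bank_default))))
})

test_that("delta coefficients recover slopes and vanish on constants", {
  const <- matrix(5, nrow = 10, ncol = 3)
  expect_equal(delta_coefficients(const), matrix(0, 10, 3))
  ramp <- matrix(2.5 * (1:20), ncol = 1)
  d <- delta_coefficients(ramp, theta = 2)
  # interior frames: (1*2s + 2*4s) / (2*(1+4)) = s
  expect_equal(d[3:18, 1], rep(2.5, 16))
})

test_that("the 39-dim MFCC segment vector is the frame-mean of [static|d|dd]", {
  seg <- tone_segment(600, 0.05)
  sp <- spectra_for(seg)
  v <- mfcc_segment_vector(sp, bank_default)
  expect_identical(length(v), 39L)
  expect_identical(names(v)[1], "MFCC_00")
  expect_identical(names(v)[39], "MFCC_38")
  # brute-force averaging oracle
  statics <- mfcc_frames(sp, bank_default)
  d1 <- delta_coefficients(statics)
  d2 <- delta_coefficients(d1)
  per_frame <- cbind(statics, d1, d2)
  brute <- sapply(1:39, function(j) mean(per_frame[, j]))
  expect_equal(unname(v), brute, tolerance = 1e-12)
})

test_that("spectral entropy matches closed-form cases and its bounds", {
  one_hot <- c(0, 0, 5, 0)
  expect_equal(spectral_entropy(one_hot)$H, 0)
  expect_equal(spectral_entropy(rep(2, 8))$H, 3)
  expect_equal(spectral_entropy(c(1, 1, 0, 0, 0, 0, 0, 0))$H, 1)
  set.seed(9)
  for (i in 1:20) {
    v <- runif(16)
    H <- spectral_entropy(v)$H
    expect_gte(H, 0)
    expect_lte(H, log2(16) + 1e-12)
  }
  expect_error(spectral_entropy(rep(0, 4)), "undefined")
  expect_error(spectral_entropy(c(-1, 2)), "negative")
})

test_that("SENCC transforms the 13-band entropy profile", {
  seg <- tone_segment(700, 0.05)
  sp <- spectra_for(seg)
  v <- sencc_segment_vector(sp, bank_default)
  expect_identical(length(v), 13L)
  # all mel energy in one band -> zero entropy terms -> all-zero coefficients
  spz <- sp
  # place energy exactly at one filter's peak bin only
  peak_bin <- which.max(bank_default$weights[6, ])
  spz$magnitudes[] <- 0
  spz$magnitudes[, peak_bin] <- 1
  vz <- sencc_segment_vector(spz, bank_default)
  expect_equal(unname(vz), rep(0, 13), tolerance = 1e-12)
  # coefficient 0 equals the frame entropy / sqrt(13) (orthonormal DCT of
  # the entropy-term profile), checked against a direct matrix product
  energies <- sp$magnitudes %*% t(bank_default$weights)
  p <- energies / rowSums(energies)
  h <- ifelse(p > 0, -p * log2(p), 0)
  direct <- h %*% t(dct_matrix(13))
  expect_equal(unname(v), colMeans(direct), tolerance = 1e-12)
  expect_equal(direct[, 1], rowSums(h) / sqrt(13), tolerance = 1e-12)
})

test_that("spectral centroid is the weighted mean frequency", {
  expect_equal(spectral_centroid(c(0, 0, 1, 0), c(10, 20, 30, 40)), 30)
  expect_equal(spectral_centroid(c(1, 0, 1), c(1000, 2000, 3000)), 2000)
  m <- runif(10)
  f <- seq(0, 900, by = 100)
  expect_equal(spectral_centroid(5 * m, f), spectral_centroid(m, f))
  expect_error(spectral_centroid(rep(0, 4), 1:4), "undefined")
})

test_that("SCCC uses per-band centroids with band-center fallback", {
  seg <- tone_segment(800, 0.05)
  sp <- spectra_for(seg)
  v <- sccc_segment_vector(sp, bank_default)
  expect_identical(length(v), 5L)
  expect_identical(names(v), sprintf("SCCC_%02d", 0:4))
  # per-band point mass: centroid equals that bin's frequency, all 13 bands
  for (i in 1:13) {
    mags <- rep(0, 257)
    bin <- which.max(bank_default$weights[i, ])
    mags[bin] <- 1
    cent <- subband_centroids(mags, bank_default)
    expect_equal(cent[i], (bin - 1) * 44100 / 512, tolerance = 1e-9)
  }
  # silent frame falls back to band centers exactly
  mags0 <- rep(0, 257)
  expect_equal(subband_centroids(mags0, bank_default),
               bank_default$center_freqs_hz)
})

test_that("orthonormal DCT satisfies T t(T) = I", {
  for (n in c(5, 13)) {
    T <- dct_matrix(n)
    expect_lt(max(abs(T %*% t(T) - diag(n))), 1e-9)
  }
})

test_that("feature extraction yields the printed dimensionalities", {
  set.seed(21)
  ds <- generate_dataset(3, "EXP", seed = 21)
  segs <- ds$segments
  mfcc <- extract_features(segs, "MFCC")
  sencc <- extract_features(segs, "SENCC")
  sccc <- extract_features(segs, "SCCC")
  expect_identical(length(feature_names(mfcc)), 39L)
  expect_identical(length(feature_names(sencc)), 13L)
  expect_identical(length(feature_names(sccc)), 5L)
  both <- concat_features(list(mfcc, sencc))
  all3 <- concat_features(list(mfcc, sencc, sccc))
  expect_identical(length(feature_names(both)), 52L)
  expect_identical(length(feature_names(all3)), 57L)
  # concatenation preserves names and order
  expect_identical(feature_names(all3),
                   c(feature_names(mfcc), feature_names(sencc),
                     feature_names(sccc)))
  # self-concatenation doubles columns with disambiguated names
  dup <- concat_features(list(sccc, sccc))
  expect_identical(length(feature_names(dup)), 10L)
  expect_identical(anyDuplicated(names(dup)), 0L)
  # misaligned ids refuse to bind
  shuffled <- mfcc[rev(seq_len(nrow(mfcc))), ]
  expect_error(concat_features(list(mfcc, shuffled)), "align")
  # extracted vectors are finite
  expect_true(all(is.finite(as.matrix(all3[feature_names(all3)]))))
})

test_that("feature tables round-trip losslessly through CSV", {
  ds <- generate_dataset(2, "INSV", seed = 4)
  tab <- extract_features(ds$segments, c("SENCC", "SCCC"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, path)
  back <- read_feature_table(path)
  expect_identical(back$id, tab$id)
  for (nm in feature_names(tab)) expect_identical(back[[nm]], tab[[nm]])
})
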