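#' Mel scale of a frequency
#'
#' `M(f) = 1125 ln(1 + f/700)`, strictly increasing in `f`.
#'
#' @param f Frequency in Hz (non-negative, vectorised).
#' @return Mel value(s).
#' @export
mel_scale <- function(f) {
  if (any(f < 0)) stop("mel_scale: negative frequency", call. = FALSE)
  1125 * log(1 + f / 700)
}

#' Inverse mel scale
#' @param m Mel value(s).
#' @return Frequency in Hz.
#' @export
mel_to_hz <- function(m) 700 * (exp(m / 1125) - 1)

#' Build an overlapping triangular mel filterbank
#'
#' `n_filters + 2` edge points are equally spaced on the mel axis between
#' `mel(fmin)` and `mel(fmax)`, mapped back to Hz and snapped to FFT bins;
#' filter `i` is the triangle rising over edges `(i, i+1)` and falling over
#' `(i+1, i+2)`. Thirteen filters are the default, the low end of the usual
#' 13--24 range.
#'
#' @param n_filters Number of triangular filters (default 13).
#' @param nfft FFT length (default 512).
#' @param sample_rate Sampling rate in Hz (default 44100).
#' @param fmin,fmax Band edges in Hz (defaults 0 and Nyquist).
#' @return An object of class `mel_filterbank`: list with `weights`
#'   (`n_filters x (nfft/2+1)`), `center_freqs_hz`, `band_edges_hz`,
#'   `n_filters`, `nfft`, `sample_rate`, `fmin`, `fmax`.
#' @export
build_mel_filterbank <- function(n_filters = 13L, nfft = 512L,
                                 sample_rate = 44100, fmin = 0,
                                 fmax = sample_rate / 2) {
  if (n_filters < 1) stop("n_filters must be >= 1", call. = FALSE)
  if (!(fmin >= 0 && fmin < fmax && fmax <= sample_rate / 2)) {
    stop("need 0 <= fmin < fmax <= sample_rate/2", call. = FALSE)
  }
  edges_mel <- seq(mel_scale(fmin), mel_scale(fmax), length.out = n_filters + 2)
  edges_hz <- mel_to_hz(edges_mel)
  # snap edges to FFT bin indices (0-based)
  edge_bins <- floor(edges_hz * nfft / sample_rate + 0.5)
  if (any(diff(edge_bins) < 1)) {
    stop("degenerate filterbank: two edges snapped to one FFT bin ",
         "(increase nfft or decrease n_filters)", call. = FALSE)
  }
  n_bins <- nfft / 2 + 1
  w <- matrix(0, nrow = n_filters, ncol = n_bins)
  for (i in seq_len(n_filters)) {
    lo <- edge_bins[i]; ce <- edge_bins[i + 1]; hi <- edge_bins[i + 2]
    k <- 0:(n_bins - 1)
    rise <- (k - lo) / (ce - lo)
    fall <- (hi - k) / (hi - ce)
    w[i, ] <- pmax(0, pmin(rise, fall))
  }
  structure(
    list(weights = w,
         center_freqs_hz = edge_bins[2:(n_filters + 1)] * sample_rate / nfft,
         band_edges_hz = edge_bins * sample_rate / nfft,
         n_filters = as.integer(n_filters), nfft = as.integer(nfft),
         sample_rate = sample_rate, fmin = fmin, fmax = fmax),
    class = "mel_filterbank"
  )
}

#' Orthonormal type-II DCT matrix
#'
#' Returns the `n x n` matrix `T` with `T %*% t(T) = I`; applying it to the
#' log mel energies (or the entropy / centroid profiles) decorrelates the
#' overlapping bands.
#'
#' @param n Transform size.
#' @return `n x n` numeric matrix; row `k` (1-based) holds basis `k-1`.
#' @export
dct_matrix <- function(n) {
  k <- 0:(n - 1)
  m <- sqrt(2 / n) * cos(pi * outer(k, (2 * k + 1) / (2 * n)))
  m[1, ] <- m[1, ] / sqrt(2)
  m
}

#' Static MFCCs per frame
#'
#' Per frame: mel band energies (filterbank times magnitude spectrum), log
#' with a relative floor, then the orthonormal type-II DCT; the first
#' `n_coeffs` coefficients are kept. The log floor is
#' `1e-10 * max(band energy)` over the whole segment (absolute floor 1e-30),
#' which keeps silent frames finite without touching voiced ones.
#'
#' @param spectra A `frame_spectra` from [magnitude_spectra()].
#' @param bank A [build_mel_filterbank()] matching `spectra$nfft`.
#' @param n_coeffs Number of cepstral coefficients to keep (default 13).
#' @return `n_frames x n_coeffs` matrix.
#' @export
mfcc_frames <- function(spectra, bank, n_coeffs = 13L) {
  stopifnot(inherits(spectra, "frame_spectra"), inherits(bank, "mel_filterbank"))
  if (bank$nfft != spectra$nfft) {
    stop("filterbank nfft does not match spectra", call. = FALSE)
  }
  if (n_coeffs > bank$n_filters) {
    stop("cannot keep more coefficients than filters", call. = FALSE)
  }
  energies <- spectra$magnitudes %*% t(bank$weights)   # n_frames x n_filters
  floor_e <- max(1e-30, 1e-10 * max(energies))
  logE <- log(pmax(energies, floor_e))
  dct <- dct_matrix(bank$n_filters)
  (logE %*% t(dct))[, seq_len(n_coeffs), drop = FALSE]
}

#' Delta (dynamic) coefficients
#'
#' Regression-window time derivative of a coefficient track:
#' `D_n = sum_{t=1..theta} t (c_{n+t} - c_{n-t}) / (2 sum t^2)`, with edge
#' frames replicated beyond the boundaries. Applying it twice gives
#' delta-delta coefficients.
#'
#' @param coeffs `n_frames x d` coefficient matrix.
#' @param theta Regression half-width (default 2).
#' @return Matrix of the same shape.
#' @export
delta_coefficients <- function(coeffs, theta = 2L) {
  coeffs <- as.matrix(coeffs)
  if (theta < 1) stop("theta must be >= 1", call. = FALSE)
  n <- nrow(coeffs)
  denom <- 2 * sum((1:theta)^2)
  out <- matrix(0, n, ncol(coeffs))
  for (t in 1:theta) {
    fwd <- pmin(n, (1:n) + t)
    bwd <- pmax(1L, (1:n) - t)
    out <- out + t * (coeffs[fwd, , drop = FALSE] - coeffs[bwd, , drop = FALSE])
  }
  out / denom
}

segment_spectra <- function(segment, config, nfft) {
  magnitude_spectra(frame_and_window(segment, config), nfft)
}

require_two_frames <- function(x, id) {
  if (nrow(x) < 2) {
    stop("segment ", id, " yields fewer than 2 frames; not analyzable",
         call. = FALSE)
  }
}

#' 39-dimensional MFCC segment vector
#'
#' Per frame, the 13 static coefficients are augmented with their delta and
#' delta-delta tracks (13 + 13 + 13 = 39); the mean of each coordinate over
#' the time axis reduces the segment to a single 39-vector.
#'
#' @param spectra A `frame_spectra` with at least two frames.
#' @param bank A [build_mel_filterbank()].
#' @param theta Delta regression half-width (default 2).
#' @return Named numeric vector `MFCC_00 ... MFCC_38`.
#' @export
mfcc_segment_vector <- function(spectra, bank, theta = 2L) {
  statics <- mfcc_frames(spectra, bank)
  require_two_frames(statics, spectra$id)
  d1 <- delta_coefficients(statics, theta)
  d2 <- delta_coefficients(d1, theta)
  v <- colMeans(cbind(statics, d1, d2))
  names(v) <- sprintf("MFCC_%02d", 0:38)
  v
}

#' Shannon entropy of a spectrum
#'
#' Normalises a non-negative energy vector to a probability mass function
#' `x_i = X_i / sum(X)` and returns `H = -sum x_i log2 x_i` (bits), with
#' `0 log 0 := 0`. `0 <= H <= log2(N)`.
#'
#' @param pmf_source Non-negative vector with positive sum.
#' @return List with `pmf` and `H` (bits).
#' @export
spectral_entropy <- function(pmf_source) {
  if (any(pmf_source < 0)) {
    stop("spectral_entropy: negative components", call. = FALSE)
  }
  s <- sum(pmf_source)
  if (s <= 0) stop("spectral_entropy: all-zero input has undefined entropy",
                   call. = FALSE)
  p <- pmf_source / s
  terms <- ifelse(p > 0, -p * log2(p), 0)
  list(pmf = p, H = sum(terms))
}

entropy_terms <- function(p) ifelse(p > 0, -p * log2(p), 0)

#' 13-dimensional SENCC segment vector
#'
#' Per frame the 13 mel band energies are normalised to a mass function,
#' each band contributes its entropy term `h_i = -x_i log2 x_i` (the frame's
#' spectral entropy is `sum h_i`), and the orthonormal DCT of the 13-term
#' entropy profile gives 13 coefficients; the mean over frames yields the
#' segment vector. A silent frame is assigned the uniform mass function.
#'
#' @param spectra A `frame_spectra` with at least two frames.
#' @param bank A [build_mel_filterbank()] with 13 filters.
#' @return Named numeric vector `SENCC_00 ... SENCC_12`.
#' @export
sencc_segment_vector <- function(spectra, bank) {
  stopifnot(inherits(spectra, "frame_spectra"), inherits(bank, "mel_filterbank"))
  energies <- spectra$magnitudes %*% t(bank$weights)
  require_two_frames(energies, spectra$id)
  sums <- rowSums(energies)
  p <- energies / ifelse(sums > 0, sums, 1)
  p[sums <= 0, ] <- 1 / bank$n_filters
  h <- entropy_terms(p)
  dct <- dct_matrix(bank$n_filters)
  v <- colMeans(h %*% t(dct))
  names(v) <- sprintf("SENCC_%02d", seq_len(bank$n_filters) - 1)
  v
}

#' Spectral centroid of one frame
#'
#' Amplitude-weighted mean frequency `C = sum f_k |X(k)| / sum |X(k)|`, the
#' center of gravity of the spectrum and a correlate of perceived
#' tone/brightness.
#'
#' @param magnitudes Non-negative magnitude vector.
#' @param bin_freqs Frequency of each bin in Hz.
#' @return Centroid in Hz.
#' @export
spectral_centroid <- function(magnitudes, bin_freqs) {
  if (length(magnitudes) != length(bin_freqs)) {
    stop("magnitudes and bin_freqs differ in length", call. = FALSE)
  }
  if (any(magnitudes < 0)) stop("negative magnitudes", call. = FALSE)
  s <- sum(magnitudes)
  if (s <= 0) stop("zero-energy frame has undefined centroid", call. = FALSE)
  sum(bin_freqs * magnitudes) / s
}

#' 5-dimensional SCCC segment vector
#'
#' Per frame, a centroid is computed inside each of the 13 mel bands (the
#' weighted mean frequency of the triangle-weighted magnitudes; a band with
#' no energy falls back to its center frequency). The 13 subband centroids
#' are normalised by the Nyquist frequency, decorrelated by the orthonormal
#' DCT, and the first five coefficients are kept; the mean over frames
#' yields the segment vector.
#'
#' @param spectra A `frame_spectra` with at least two frames.
#' @param bank A [build_mel_filterbank()].
#' @param n_coeffs Coefficients to keep (default 5).
#' @return Named numeric vector `SCCC_00 ... SCCC_04`.
#' @export
sccc_segment_vector <- function(spectra, bank, n_coeffs = 5L) {
  stopifnot(inherits(spectra, "frame_spectra"), inherits(bank, "mel_filterbank"))
  require_two_frames(spectra$magnitudes, spectra$id)
  nyquist <- spectra$sample_rate / 2
  weighted <- spectra$magnitudes %*% t(bank$weights * rep(spectra$bin_freqs,
                                                          each = bank$n_filters))
  mass <- spectra$magnitudes %*% t(bank$weights)
  centroids <- weighted / ifelse(mass > 0, mass, 1)
  fallback <- matrix(bank$center_freqs_hz, nrow = nrow(mass),
                     ncol = bank$n_filters, byrow = TRUE)
  centroids[mass <= 0] <- fallback[mass <= 0]
  dct <- dct_matrix(bank$n_filters)
  v <- colMeans((centroids / nyquist) %*% t(dct))[seq_len(n_coeffs)]
  names(v) <- sprintf("SCCC_%02d", seq_len(n_coeffs) - 1)
  v
}

#' Per-band spectral centroids of one frame
#'
#' Exposes the SCCC intermediate: the within-band weighted-mean frequency of
#' each mel band for a single magnitude spectrum.
#'
#' @param magnitudes One frame's magnitude vector (`nfft/2 + 1` bins).
#' @param bank A [build_mel_filterbank()].
#' @return Numeric vector of `bank$n_filters` centroids in Hz.
#' @export
subband_centroids <- function(magnitudes, bank) {
  sapply(seq_len(bank$n_filters), function(i) {
    wmag <- bank$weights[i, ] * magnitudes
    if (sum(wmag) <= 0) return(bank$center_freqs_hz[i])
    bf <- (0:(bank$nfft / 2)) * bank$sample_rate / bank$nfft
    spectral_centroid(wmag, bf)
  })
}

#' Extract a feature table from cry segments
#'
#' Runs the front end (pre-emphasis, framing, windowing, FFT) once per
#' segment and computes the requested per-segment feature vectors, in the
#' order given, concatenated into one row per segment.
#'
#' @param segments List of [cry_segment()] objects (already admitted).
#' @param sets Character vector drawn from `"MFCC"`, `"SENCC"`, `"SCCC"`.
#' @param config A [frame_config()].
#' @param nfft FFT length (default 512).
#' @param dataset_tag Optional `"EXP"` or `"INSV"` tag recorded on the table.
#' @return A `feature_table`: data frame with columns `id`, `label`, then
#'   one column per feature; attribute `dataset_tag`.
#' @export
extract_features <- function(segments, sets = c("MFCC", "SENCC", "SCCC"),
                             config = frame_config(), nfft = 512L,
                             dataset_tag = NULL) {
  sets <- match.arg(sets, c("MFCC", "SENCC", "SCCC"), several.ok = TRUE)
  stopifnot(length(segments) > 0)
  rate <- segments[[1]]$sample_rate
  bank <- build_mel_filterbank(13L, nfft, rate)
  rows <- lapply(segments, function(seg) {
    if (seg$sample_rate != rate) {
      bank <- build_mel_filterbank(13L, nfft, seg$sample_rate)
    }
    sp <- segment_spectra(seg, config, nfft)
    unlist(lapply(sets, function(s) {
      switch(s,
             MFCC = mfcc_segment_vector(sp, bank),
             SENCC = sencc_segment_vector(sp, bank),
             SCCC = sccc_segment_vector(sp, bank))
    }))
  })
  tab <- as.data.frame(do.call(rbind, rows))
  tab <- cbind(
    data.frame(id = vapply(segments, `[[`, "", "id"),
               label = vapply(segments, `[[`, "", "label"),
               stringsAsFactors = FALSE),
    tab
  )
  rownames(tab) <- NULL
  structure(tab, dataset_tag = dataset_tag, class = c("feature_table",
                                                      "data.frame"))
}

#' Feature columns of a feature table
#' @param table A `feature_table`.
#' @return Character vector of feature column names.
#' @export
feature_names <- function(table) setdiff(names(table), c("id", "label"))

#' Concatenate feature tables column-wise
#'
#' Tables must agree in row ids and labels. Duplicate feature names are
#' disambiguated with `.1`, `.2`, ... suffixes.
#'
#' @param tables List of `feature_table` objects.
#' @return A `feature_table` with the concatenated columns.
#' @export
concat_features <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1)
  base <- tables[[1]]
  for (t in tables[-1]) {
    if (!identical(t$id, base$id) || !identical(t$label, base$label)) {
      stop("feature tables do not align on (id, label)", call. = FALSE)
    }
  }
  blocks <- lapply(tables, function(t) t[, feature_names(t), drop = FALSE])
  out <- do.call(cbind, c(list(base[c("id", "label")]), blocks))
  names(out) <- make.unique(names(out))
  structure(out, dataset_tag = attr(base, "dataset_tag"),
            class = c("feature_table", "data.frame"))
}

#' Write / read a feature table as delimited text
#'
#' Header `id,label,<feature names...>`; numeric round trip is lossless at
#' 17 significant digits.
#'
#' @param table A `feature_table`.
#' @param path Output path.
#' @return `path` invisibly (write); a `feature_table` (read).
#' @export
write_feature_table <- function(table, path) {
  out <- table
  for (nm in feature_names(out)) out[[nm]] <- sprintf("%.17g", out[[nm]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(tab, class = c("feature_table", "data.frame"))
}
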