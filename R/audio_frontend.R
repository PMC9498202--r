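#' Construct a cry segment
#'
#' A `cry_segment` is one manually delimited cry vocalization: an expiratory
#' (EXP) or voiced-inspiratory (INSV) unit, with an optional clinical label.
#' Amplitudes are normalised into \[-1, 1\]: if the input peak exceeds 1
#' (e.g. an integer-scaled WAV read) the waveform is divided by its peak.
#'
#' @param id Segment identifier (non-empty string).
#' @param samples Numeric waveform; all values must be finite.
#' @param sample_rate Sampling rate in Hz (positive; nominal 44100).
#' @param segment_type `"EXP"` or `"INSV"`.
#' @param label `"healthy"`, `"septic"`, or `NA` for unlabeled inference.
#' @return An object of class `cry_segment`.
#' @export
cry_segment <- function(id, samples, sample_rate,
                        segment_type = c("EXP", "INSV"), label = NA_character_) {
  segment_type <- match.arg(segment_type)
  if (!is.character(id) || length(id) != 1 || is.na(id) || !nzchar(id)) {
    stop("segment id must be a non-empty string", call. = FALSE)
  }
  if (!is.numeric(samples) || length(samples) == 0) {
    stop("samples must be a non-empty numeric vector [", id, "]", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("non-finite samples in segment ", id, call. = FALSE)
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0) {
    stop("sample_rate must be a positive scalar [", id, "]", call. = FALSE)
  }
  if (!is.na(label) && !label %in% c("healthy", "septic")) {
    stop("label must be 'healthy', 'septic' or NA [", id, "]", call. = FALSE)
  }
  peak <- max(abs(samples))
  if (peak > 1) samples <- samples / peak
  structure(
    list(id = id, samples = as.numeric(samples),
         sample_rate = as.integer(round(sample_rate)),
         segment_type = segment_type, label = label),
    class = "cry_segment"
  )
}

#' @export
print.cry_segment <- function(x, ...) {
  cat(sprintf("<cry_segment %s: %s/%s, %.1f ms @ %d Hz>\n", x$id,
              x$segment_type, ifelse(is.na(x$label), "unlabeled", x$label),
              1000 * length(x$samples) / x$sample_rate, x$sample_rate))
  invisible(x)
}

#' Frame geometry for short-time analysis
#'
#' Cry units are analysed with a 10 ms sliding Hamming window at 30%
#' overlap, the short-window regime under which the nonstationary cry is
#' locally stationary. Sample counts are resolved by rounding:
#' `frame_samples = round(frame_length_s * fs)` and
#' `hop_samples = round((1 - overlap) * frame_samples)` (441 and 309 at
#' 44.1 kHz).
#'
#' @param frame_length_s Frame length in seconds (default 0.010).
#' @param overlap_fraction Fractional overlap between consecutive frames,
#'   in \[0, 1) (default 0.30).
#' @param window_kind Window function; only `"hamming"` is supported.
#' @param pre_emphasis_a Pre-emphasis coefficient in \[0, 1) (default 0.97).
#' @return An object of class `frame_config`.
#' @export
frame_config <- function(frame_length_s = 0.010, overlap_fraction = 0.30,
                         window_kind = "hamming", pre_emphasis_a = 0.97) {
  if (!is.numeric(frame_length_s) || frame_length_s <= 0) {
    stop("frame_length_s must be positive", call. = FALSE)
  }
  if (!is.numeric(overlap_fraction) || overlap_fraction < 0 ||
      overlap_fraction >= 1) {
    stop("overlap_fraction must lie in [0, 1)", call. = FALSE)
  }
  window_kind <- match.arg(window_kind, "hamming")
  if (!is.numeric(pre_emphasis_a) || pre_emphasis_a < 0 || pre_emphasis_a >= 1) {
    stop("pre_emphasis_a must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(frame_length_s = frame_length_s, overlap_fraction = overlap_fraction,
         window_kind = window_kind, pre_emphasis_a = pre_emphasis_a),
    class = "frame_config"
  )
}

#' Frame geometry in samples at a given rate
#'
#' @param config A [frame_config()].
#' @param sample_rate Sampling rate in Hz.
#' @return List with `frame_samples` and `hop_samples`.
#' @export
frame_geometry <- function(config, sample_rate) {
  frame_samples <- as.integer(round(config$frame_length_s * sample_rate))
  hop_samples <- as.integer(round((1 - config$overlap_fraction) * frame_samples))
  if (hop_samples < 1L) stop("degenerate hop: < 1 sample", call. = FALSE)
  list(frame_samples = frame_samples, hop_samples = hop_samples)
}

#' First-order pre-emphasis filter
#'
#' Applies the high-pass filter `H(z) = 1 - a z^-1`, boosting high
#' frequencies before spectral analysis: `y[1] = x[1]`,
#' `y[n] = x[n] - a x[n-1]`.
#'
#' @param samples Non-empty finite numeric vector.
#' @param a Filter coefficient in \[0, 1) (default 0.97).
#' @return Filtered vector of the same length.
#' @export
pre_emphasize <- function(samples, a = 0.97) {
  if (length(samples) == 0 || !is.numeric(samples)) {
    stop("pre_emphasize: empty or non-numeric input", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("pre_emphasize: non-finite samples", call. = FALSE)
  }
  if (!is.numeric(a) || length(a) != 1 || a < 0 || a >= 1) {
    stop("pre_emphasize: a must lie in [0, 1)", call. = FALSE)
  }
  c(samples[1], samples[-1] - a * samples[-length(samples)])
}

hamming_window <- function(n) {
  if (n == 1) return(1)
  0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

#' Slice a segment into windowed frames
#'
#' Pre-emphasises the whole waveform, slices it into frames of
#' `frame_samples` advancing by `hop_samples`, and multiplies each frame by
#' a Hamming window. Trailing samples that do not fill a frame are dropped,
#' so `n_frames = 1 + floor((n - frame_samples) / hop_samples)`.
#'
#' @param segment A [cry_segment()].
#' @param config A [frame_config()].
#' @return An object of class `frame_matrix`: list with `frames`
#'   (`n_frames x frame_samples`), `config`, `sample_rate`.
#' @export
frame_and_window <- function(segment, config = frame_config()) {
  stopifnot(inherits(segment, "cry_segment"), inherits(config, "frame_config"))
  geom <- frame_geometry(config, segment$sample_rate)
  n <- length(segment$samples)
  if (n < geom$frame_samples) {
    stop(sprintf("segment %s too short for one %d-sample frame (%d samples)",
                 segment$id, geom$frame_samples, n),
         call. = FALSE)
  }
  x <- pre_emphasize(segment$samples, config$pre_emphasis_a)
  n_frames <- 1L + (n - geom$frame_samples) %/% geom$hop_samples
  starts <- 1L + (seq_len(n_frames) - 1L) * geom$hop_samples
  idx <- outer(starts, 0:(geom$frame_samples - 1L), `+`)
  frames <- matrix(x[idx], nrow = n_frames)
  frames <- sweep(frames, 2, hamming_window(geom$frame_samples), `*`)
  structure(
    list(frames = frames, config = config, sample_rate = segment$sample_rate,
         id = segment$id),
    class = "frame_matrix"
  )
}

#' Frame count under a frame/hop geometry
#'
#' @param n_samples,frame_samples,hop_samples Integer sample counts.
#' @return Number of whole frames (0 if the signal is shorter than a frame).
#' @export
n_frames_for <- function(n_samples, frame_samples, hop_samples) {
  if (n_samples < frame_samples) return(0L)
  as.integer(1 + (n_samples - frame_samples) %/% hop_samples)
}

#' Magnitude spectra of windowed frames
#'
#' Zero-pads each frame to `nfft` and returns one-sided magnitude spectra
#' `|DFT|` for bins `0 ... nfft/2`, with the physical frequency of each bin.
#'
#' @param frames A `frame_matrix` from [frame_and_window()].
#' @param nfft FFT length; a power of two no smaller than the frame length
#'   (default 512, the next power of two above the 441-sample frame at
#'   44.1 kHz).
#' @return An object of class `frame_spectra`: list with `magnitudes`
#'   (`n_frames x (nfft/2 + 1)`), `nfft`, `bin_freqs`, `sample_rate`.
#' @export
magnitude_spectra <- function(frames, nfft = 512L) {
  stopifnot(inherits(frames, "frame_matrix"))
  m <- ncol(frames$frames)
  if (nfft < m) {
    stop("nfft (", nfft, ") smaller than frame length (", m, ")",
         call. = FALSE)
  }
  if (bitwAnd(as.integer(nfft), as.integer(nfft) - 1L) != 0L) {
    stop("nfft must be a power of two", call. = FALSE)
  }
  padded <- cbind(frames$frames,
                  matrix(0, nrow = nrow(frames$frames), ncol = nfft - m))
  # mvfft works column-wise
  spec <- Mod(t(stats::mvfft(t(padded))))[, 1:(nfft / 2 + 1), drop = FALSE]
  structure(
    list(magnitudes = spec, nfft = as.integer(nfft),
         bin_freqs = (0:(nfft / 2)) * frames$sample_rate / nfft,
         sample_rate = frames$sample_rate, id = frames$id),
    class = "frame_spectra"
  )
}

#' Admission filter for analyzable cry segments
#'
#' A segment is admitted only if it spans more than two consecutive analysis
#' windows, i.e. yields at least two whole frames (17 ms at the nominal
#' 10 ms / 30%-overlap geometry). Silent (all-zero) segments are rejected.
#'
#' @param segments List of [cry_segment()] objects.
#' @param config A [frame_config()].
#' @return List with `kept` (list of segments) and `rejected` (data frame of
#'   `id`, `reason`).
#' @export
admit_segments <- function(segments, config = frame_config()) {
  stopifnot(is.list(segments))
  kept <- list()
  rej_id <- character()
  rej_reason <- character()
  for (seg in segments) {
    stopifnot(inherits(seg, "cry_segment"))
    geom <- frame_geometry(config, seg$sample_rate)
    nf <- n_frames_for(length(seg$samples), geom$frame_samples,
                       geom$hop_samples)
    if (all(seg$samples == 0)) {
      rej_id <- c(rej_id, seg$id)
      rej_reason <- c(rej_reason, "silent segment (all zero)")
    } else if (nf < 2L) {
      rej_id <- c(rej_id, seg$id)
      rej_reason <- c(rej_reason,
                      sprintf("below two-frame span (%d frame%s)", nf,
                              ifelse(nf == 1, "", "s")))
    } else {
      kept[[length(kept) + 1L]] <- seg
    }
  }
  list(kept = kept,
       rejected = data.frame(id = rej_id, reason = rej_reason,
                             stringsAsFactors = FALSE))
}

#' Read a segment manifest
#'
#' The manifest is comma-separated with header `id,path,label,segment_type`.
#' Unknown labels (empty or NA) are permitted for inference mode.
#'
#' @param path Manifest file path.
#' @return Data frame with columns `id`, `path`, `label`, `segment_type`.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("id", "path", "label", "segment_type")
  if (!all(required %in% names(m))) {
    stop("manifest must have columns ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  m$label[m$label %in% c("", "NA")] <- NA_character_
  bad <- !is.na(m$label) & !m$label %in% c("healthy", "septic")
  if (any(bad)) {
    stop("unknown labels in manifest: ",
         paste(unique(m$label[bad]), collapse = ", "), call. = FALSE)
  }
  if (!all(m$segment_type %in% c("EXP", "INSV"))) {
    stop("segment_type must be EXP or INSV", call. = FALSE)
  }
  if (anyDuplicated(m$id)) stop("duplicate segment ids in manifest",
                                call. = FALSE)
  m[required]
}

#' Load cry segments listed in a manifest
#'
#' @param manifest Data frame from [read_manifest()] or a path to one.
#' @param base_dir Directory against which relative WAV paths are resolved.
#' @return List of [cry_segment()] objects.
#' @export
load_segments <- function(manifest, base_dir = ".") {
  if (is.character(manifest)) {
    base_dir <- dirname(manifest)
    manifest <- read_manifest(manifest)
  }
  lapply(seq_len(nrow(manifest)), function(i) {
    p <- manifest$path[i]
    if (!file.exists(p)) p <- file.path(base_dir, manifest$path[i])
    wav <- read_wav(p)
    cry_segment(manifest$id[i], wav$samples, wav$sample_rate,
                manifest$segment_type[i], manifest$label[i])
  })
}
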