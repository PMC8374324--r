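#' Standardize a recording to a fixed duration
#'
#' Longer recordings are truncated to the first `target_seconds`; shorter
#' ones are tiled end-to-end (wrap-around padding) and then truncated, so the
#' padded tail repeats the recording from its start.
#'
#' @param rec A [pcg_recording()].
#' @param target_seconds Target duration in seconds (default 6).
#' @return A `pcg_recording` with exactly `round(target_seconds * rate)`
#'   samples.
#' @export
standardize_length <- function(rec, target_seconds = 6) {
  stopifnot(inherits(rec, "pcg_recording"), target_seconds > 0)
  n_target <- as.integer(round(target_seconds * rec$rate))
  n <- length(rec$samples)
  if (n < 1) stop("unusable recording: no samples")
  x <- if (n >= n_target) {
    rec$samples[seq_len(n_target)]
  } else {
    rep_len(rec$samples, n_target)
  }
  out <- rec
  out$samples <- x
  out
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Triangular Mel filter bank
#'
#' HTK-style Mel scale, `n_mels` triangular filters spanning 0 Hz to Nyquist,
#' applied to a one-sided power spectrum of `n_fft/2 + 1` bins.
#'
#' @param n_mels Number of filters.
#' @param n_fft FFT length.
#' @param rate Sample rate in Hz.
#' @return `n_mels` x `(n_fft/2 + 1)` weight matrix.
#' @export
mel_filterbank <- function(n_mels = 14, n_fft = 1024, rate = 2000) {
  n_bins <- n_fft / 2 + 1
  freqs <- (seq_len(n_bins) - 1) * rate / n_fft
  mel_pts <- seq(hz_to_mel(0), hz_to_mel(rate / 2), length.out = n_mels + 2)
  hz_pts <- mel_to_hz(mel_pts)
  fb <- matrix(0, n_mels, n_bins)
  for (m in seq_len(n_mels)) {
    lo <- hz_pts[m]; ctr <- hz_pts[m + 1]; hi <- hz_pts[m + 2]
    up <- (freqs - lo) / (ctr - lo)
    down <- (hi - freqs) / (hi - ctr)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

#' Log-Mel spectrogram of a heart-sound recording
#'
#' Frames the signal with a periodic Hann window (no center padding), takes
#' the one-sided power spectrum per frame, pools it through [mel_filterbank()]
#' and applies `log(x + 1e-10)`.  Frame count is
#' `L = 1 + floor((n_samples - win_length) / hop_length)`.
#'
#' @param rec A [pcg_recording()] (expected at 2 kHz).
#' @param n_mels,win_length,hop_length Mel/STFT configuration; defaults 14,
#'   1024 and 512 samples.
#' @return `n_mels` x `L` matrix of class `mel_spectrogram`, with
#'   attributes `rate`, `win_length`, `hop_length`.
#' @export
mel_spectrogram <- function(rec, n_mels = 14, win_length = 1024,
                            hop_length = 512) {
  stopifnot(inherits(rec, "pcg_recording"))
  x <- rec$samples
  n <- length(x)
  if (n < win_length) {
    stop("recording shorter than one analysis window (", win_length, " samples)")
  }
  L <- 1L + (n - win_length) %/% hop_length
  # periodic Hann
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(win_length - 1)) / win_length)
  starts <- (seq_len(L) - 1L) * hop_length
  frames <- vapply(starts, function(s) x[(s + 1):(s + win_length)] * w,
                   numeric(win_length))
  spec <- stats::mvfft(frames)
  power <- abs(spec[seq_len(win_length / 2 + 1), , drop = FALSE])^2
  fb <- mel_filterbank(n_mels, win_length, rec$rate)
  S <- log(fb %*% power + 1e-10)
  if (!all(is.finite(S))) stop("non-finite values in Mel spectrogram")
  structure(S, class = c("mel_spectrogram", class(S)),
            rate = rec$rate, win_length = win_length, hop_length = hop_length)
}

#' Row-standardize a Mel spectrogram
#'
#' Each Mel band (row) is shifted and scaled to zero mean and unit
#' population standard deviation, removing per-band energy bias before the
#' models see the data.  Rows with population sd below `1e-8` (constant
#' bands, e.g. digital silence) map to all zeros.
#'
#' @param S Matrix (bands x frames), e.g. from [mel_spectrogram()].
#' @return Matrix of the same shape and attributes.
#' @export
standardize_rows <- function(S) {
  stopifnot(is.matrix(S), ncol(S) >= 2)
  mu <- rowMeans(S)
  centered <- S - mu
  sd_pop <- sqrt(rowMeans(centered^2))
  out <- centered / pmax(sd_pop, 1e-8)
  out[sd_pop < 1e-8, ] <- 0
  attributes(out) <- attributes(S)
  out
}

#' Stack a spectrogram into sliding super-frames
#'
#' Every window of `width` consecutive frames becomes one model sample; the
#' window advances one frame at a time, so `L` frames give `L - width + 1`
#' super-frames (L - 4 at the default width 5).  Each super-frame is
#' flattened row-major: band 1's `width` frames first, then band 2, etc.
#'
#' @param S_hat Standardized spectrogram matrix (bands x frames).
#' @param width Frames per super-frame (default 5).
#' @return `(L - width + 1)` x `(bands * width)` matrix of class
#'   `super_frames`, with attributes `n_bands` and `width`.
#' @export
super_frames <- function(S_hat, width = 5) {
  stopifnot(is.matrix(S_hat))
  L <- ncol(S_hat)
  M <- nrow(S_hat)
  if (L < width) stop("need at least ", width, " frames, got ", L)
  n_sf <- L - width + 1L
  out <- matrix(0, n_sf, M * width)
  for (k in seq_len(n_sf)) {
    out[k, ] <- as.vector(t(S_hat[, k:(k + width - 1L), drop = FALSE]))
  }
  structure(out, class = c("super_frames", class(out)),
            n_bands = M, width = width)
}

#' Full preprocessing of one recording
#'
#' Length standardization, log-Mel spectrogram, per-band standardization and
#' super-frame stacking in one call.
#'
#' @inheritParams standardize_length
#' @inheritParams mel_spectrogram
#' @param width Frames per super-frame.
#' @return A `super_frames` matrix (rows are flattened super-frames).
#' @export
preprocess_recording <- function(rec, target_seconds = 6, n_mels = 14,
                                 win_length = 1024, hop_length = 512,
                                 width = 5) {
  rec <- standardize_length(rec, target_seconds)
  S <- mel_spectrogram(rec, n_mels, win_length, hop_length)
  super_frames(standardize_rows(S), width)
}

#' Preprocess every recording in a dataset
#'
#' @param dataset A [pcg_dataset()].
#' @param ... Passed to [preprocess_recording()].
#' @return Named list of `super_frames` matrices, one per recording, in
#'   dataset order.
#' @export
preprocess_dataset <- function(dataset, ...) {
  stopifnot(inherits(dataset, "pcg_dataset"))
  lapply(dataset, preprocess_recording, ...)
}
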