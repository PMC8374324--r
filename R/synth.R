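# Seeded synthetic heart-sound generator.  Emulates the statistical
# structure the detection method relies on — quasi-periodic S1/S2 bursts,
# domain-dependent colored background noise, and localized anomaly
# perturbations — without claiming physiological fidelity.

#' Specification of one synthetic heart-sound recording
#'
#' @param heart_rate_bpm Beats per minute.
#' @param s1_freq_hz,s2_freq_hz Carrier frequencies of the S1 and S2 damped
#'   sinusoid bursts (Hz; must stay below Nyquist).
#' @param burst_decay Exponential decay rate of each burst (1/s).
#' @param systole_fraction Position of S2 within the cycle, as a fraction of
#'   the cycle length in (0, 1).
#' @param noise_sigma Standard deviation of the background noise (relative
#'   to the unit S1 amplitude).
#' @param spectral_tilt Spectral coloration exponent of the background noise
#'   (0 = white; negative tilts emphasize low frequencies).
#' @param anomaly_kind `"none"`, `"murmur"` (band-limited systolic noise),
#'   `"ectopic_burst"` (an extra diastolic burst), or `"missing_s2"`
#'   (attenuated S2).  `"none"` if and only if the recording is normal.
#' @param anomaly_strength Nonnegative scale of the perturbation; 0 leaves
#'   the waveform identical to its anomaly-free counterpart.
#' @param duration_s Duration in seconds.
#' @param rate Sample rate (Hz), default 2000.
#' @param seed Integer seed; the waveform is fully determined by the spec.
#' @return List of class `synth_spec`.
#' @export
synth_spec <- function(heart_rate_bpm = 75, s1_freq_hz = 40, s2_freq_hz = 65,
                       burst_decay = 40, systole_fraction = 0.35,
                       noise_sigma = 0.05, spectral_tilt = 0,
                       anomaly_kind = c("none", "murmur", "ectopic_burst",
                                        "missing_s2"),
                       anomaly_strength = 1, duration_s = 6, rate = 2000,
                       seed = 1) {
  anomaly_kind <- match.arg(anomaly_kind)
  stopifnot(heart_rate_bpm > 0, s1_freq_hz > 0, s2_freq_hz > 0,
            s1_freq_hz < rate / 2, s2_freq_hz < rate / 2,
            burst_decay > 0, systole_fraction > 0, systole_fraction < 1,
            noise_sigma >= 0, anomaly_strength >= 0, duration_s > 0,
            rate > 0)
  structure(list(heart_rate_bpm = heart_rate_bpm, s1_freq_hz = s1_freq_hz,
                 s2_freq_hz = s2_freq_hz, burst_decay = burst_decay,
                 systole_fraction = systole_fraction,
                 noise_sigma = noise_sigma, spectral_tilt = spectral_tilt,
                 anomaly_kind = anomaly_kind,
                 anomaly_strength = anomaly_strength,
                 duration_s = duration_s, rate = rate,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 1000003 + k) %% 2147483647)
}

# colored Gaussian noise shaped in the frequency domain; unit-free tilt
colored_noise <- function(n, sigma, tilt, seed, rate) {
  if (sigma <= 0) return(numeric(n))
  e <- with_preserved_rng(seed, stats::rnorm(n))
  if (tilt == 0) return(e * sigma)
  freqs <- abs(seq(0, rate, length.out = n + 1)[-(n + 1)])
  freqs <- pmin(freqs, rate - freqs)  # two-sided spectrum
  w <- (1 + freqs / 100)^tilt
  x <- Re(stats::fft(stats::fft(e) * w, inverse = TRUE)) / n
  x / stats::sd(x) * sigma
}

# unit-variance Gaussian noise band-passed to [lo, hi] Hz
band_noise <- function(n, rate, lo, hi, seed) {
  e <- with_preserved_rng(seed, stats::rnorm(n))
  freqs <- abs(seq(0, rate, length.out = n + 1)[-(n + 1)])
  freqs <- pmin(freqs, rate - freqs)
  keep <- freqs >= lo & freqs <= hi
  x <- Re(stats::fft(stats::fft(e) * keep, inverse = TRUE)) / n
  x / stats::sd(x)
}

# damped burst added in place; support truncated at 0.2 s.  Heart sounds are
# broadband transients, so each burst carries a harmonic stack above its
# carrier (incommensurate ratios avoid phase-locking artifacts) rather than
# a single pure tone, spreading energy across the Mel bands.
add_burst <- function(x, t0, freq, amp, decay, rate) {
  n <- length(x)
  i0 <- floor(t0 * rate) + 1L
  if (i0 > n) return(x)
  i1 <- min(n, i0 + as.integer(0.2 * rate))
  tt <- (seq(i0, i1) - i0) / rate
  env <- amp * exp(-decay * tt)
  ratios <- c(1, 2.2, 4.1, 7.3)
  weights <- c(1, 0.5, 0.25, 0.12)
  s <- numeric(length(tt))
  for (k in seq_along(ratios)) {
    fk <- freq * ratios[k]
    if (fk < rate / 2) s <- s + weights[k] * sin(2 * pi * fk * tt)
  }
  x[i0:i1] <- x[i0:i1] + env * s
  x
}

#' Generate one synthetic heart-sound recording
#'
#' Per cardiac cycle an S1 burst (unit amplitude) starts the cycle and an S2
#' burst (amplitude 0.7) follows after `systole_fraction` of the cycle;
#' colored Gaussian background noise is added throughout.  Anomalies are
#' local: a murmur adds 100-400 Hz band noise (amplitude
#' `0.4 * anomaly_strength`) in each systolic interval, an ectopic burst adds
#' an extra burst in mid-diastole, and `missing_s2` scales the S2 amplitude
#' by `1 - min(anomaly_strength, 1)`.  Everything is determined by
#' `spec$seed`.
#'
#' @param spec A [synth_spec()].
#' @return A [pcg_recording()] labeled from `spec$anomaly_kind`.
#' @export
generate_recording <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  n <- as.integer(round(spec$duration_s * spec$rate))
  period <- 60 / spec$heart_rate_bpm
  cycle_starts <- seq(0, spec$duration_s - 1e-9, by = period)
  s2_scale <- if (spec$anomaly_kind == "missing_s2") {
    1 - min(spec$anomaly_strength, 1)
  } else 1

  x <- numeric(n)
  for (t0 in cycle_starts) {
    x <- add_burst(x, t0, spec$s1_freq_hz, 1.0, spec$burst_decay, spec$rate)
    x <- add_burst(x, t0 + spec$systole_fraction * period, spec$s2_freq_hz,
                   0.7 * s2_scale, spec$burst_decay, spec$rate)
  }
  x <- x + colored_noise(n, spec$noise_sigma, spec$spectral_tilt,
                         derive_seed(spec$seed, 1), spec$rate)

  if (spec$anomaly_kind == "murmur" && spec$anomaly_strength > 0) {
    bn <- band_noise(n, spec$rate, 100, 400, derive_seed(spec$seed, 2))
    mask <- numeric(n)
    for (t0 in cycle_starts) {
      a <- t0 + 0.05
      b <- t0 + spec$systole_fraction * period - 0.02
      if (b > a) {
        ia <- max(1L, floor(a * spec$rate) + 1L)
        ib <- min(n, floor(b * spec$rate))
        if (ib >= ia) mask[ia:ib] <- 1
      }
    }
    x <- x + 0.4 * spec$anomaly_strength * bn * mask
  } else if (spec$anomaly_kind == "ectopic_burst" && spec$anomaly_strength > 0) {
    carrier <- (spec$s1_freq_hz + spec$s2_freq_hz) / 2
    for (t0 in cycle_starts) {
      x <- add_burst(x, t0 + 0.75 * period, carrier,
                     0.8 * spec$anomaly_strength, spec$burst_decay, spec$rate)
    }
  }

  pcg_recording(x, spec$rate,
                label = if (spec$anomaly_kind == "none") "normal" else "abnormal",
                recording_id = sprintf("synth_s%d", spec$seed),
                domain_id = "synthetic")
}

#' Default synthetic recording domains
#'
#' Two collection "sites" differing in background noise level, spectral
#' tilt and typical heart rate, mimicking multi-source corpora where each
#' subset shares a protocol but not its acoustics.
#'
#' @return List of domain parameter lists (`name`, `noise_sigma`,
#'   `spectral_tilt`, `heart_rate_bpm`).
#' @export
default_domains <- function() {
  list(
    list(name = "siteA", noise_sigma = 0.05, spectral_tilt = -0.4,
         heart_rate_bpm = 70),
    list(name = "siteB", noise_sigma = 0.08, spectral_tilt = 0.4,
         heart_rate_bpm = 85)
  )
}

#' Generate a labeled multi-domain synthetic dataset
#'
#' Recordings are assigned round-robin to the domains; per-recording seeds
#' (and small heart-rate jitter) derive deterministically from the master
#' seed, so the whole dataset is reproducible across machines.  Abnormal
#' recordings cycle through the three anomaly kinds.
#'
#' @param n_normal,n_abnormal Recording counts.
#' @param domains List of domain parameter lists (see [default_domains()]).
#' @param seed Master seed.
#' @param duration_s Duration per recording (seconds).
#' @return List with `dataset` (a [pcg_dataset()]) and `manifest` (data
#'   frame: `recording_id`, `label`, `domain_id`, `anomaly_kind`, `seed`,
#'   `heart_rate_bpm`).
#' @export
generate_dataset <- function(n_normal, n_abnormal, domains = default_domains(),
                             seed = 1, duration_s = 6) {
  stopifnot(n_normal >= 0, n_abnormal >= 0, length(domains) >= 1)
  n_total <- n_normal + n_abnormal
  if (n_total < 1) stop("dataset must contain at least one recording")
  anomaly_cycle <- c("murmur", "ectopic_burst", "missing_s2")
  recs <- vector("list", n_total)
  manifest <- data.frame()
  for (i in seq_len(n_total)) {
    dom <- domains[[(i - 1L) %% length(domains) + 1L]]
    rec_seed <- derive_seed(seed, 100 + i)
    jitter <- with_preserved_rng(rec_seed, stats::runif(1, -8, 8))
    bpm <- dom$heart_rate_bpm + jitter
    kind <- if (i <= n_normal) "none" else {
      anomaly_cycle[(i - n_normal - 1L) %% 3L + 1L]
    }
    spec <- synth_spec(heart_rate_bpm = bpm,
                       noise_sigma = dom$noise_sigma,
                       spectral_tilt = dom$spectral_tilt,
                       anomaly_kind = kind, duration_s = duration_s,
                       seed = rec_seed)
    rec <- generate_recording(spec)
    rec$recording_id <- sprintf("synth%04d", i)
    rec$domain_id <- dom$name
    recs[[i]] <- rec
    manifest <- rbind(manifest, data.frame(
      recording_id = rec$recording_id, label = rec$label,
      domain_id = dom$name, anomaly_kind = kind, seed = rec_seed,
      heart_rate_bpm = bpm, stringsAsFactors = FALSE))
  }
  list(dataset = pcg_dataset(recs), manifest = manifest)
}

#' Write a dataset as WAV files plus a reference CSV and JSON manifest
#'
#' Uses the same on-disk dialect as the real-data loader
#' ([load_labeled_dataset()]): one 16-bit PCM WAV per recording and a
#' headerless `REFERENCE.csv` with codes -1 (normal) / 1 (abnormal), so
#' synthetic and real data share one loading path.
#'
#' @param dataset A [pcg_dataset()].
#' @param dir Output directory (created if missing).
#' @param manifest Optional manifest data frame written as `manifest.json`.
#' @return `dir`, invisibly.
#' @export
write_pcg_dataset <- function(dataset, dir, manifest = NULL) {
  stopifnot(inherits(dataset, "pcg_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ref <- data.frame(
    name = vapply(dataset, `[[`, character(1), "recording_id"),
    code = ifelse(dataset_labels(dataset) == "abnormal", 1L, -1L))
  for (rec in dataset) {
    # headroom so quantization never clips burst peaks
    write_wav(rec$samples / max(1, max(abs(rec$samples))) * 0.9,
              rec$rate, file.path(dir, paste0(rec$recording_id, ".wav")))
  }
  utils::write.table(ref, file.path(dir, "REFERENCE.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  if (!is.null(manifest)) {
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
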