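# Synthetic infant phonocardiograms.
#
# Each cardiac cycle carries two short Gaussian-enveloped tone bursts (the
# fundamental heart sounds S1 and S2); abnormal recordings add band-limited
# noise over the systolic interval between them, emulating the systolic
# murmurs of structural defects (VSD, ASD, PDA, TOF, PS, AS).

#' Murmur presets for the six modelled congenital defects
#'
#' Each preset gives the murmur's pass band (Hz), its amplitude relative to
#' S1 (`murmur_gain`), and the portion of the systolic interval it covers
#' (`systolic_fraction`).  The values are stylized: holosystolic defects
#' (VSD, PDA) cover most of systole, ejection murmurs (PS, AS) sit mid
#' systole in a higher band.  A `normal` pseudo-preset with zero gain is
#' included so that the two classes differ only in the murmur term.
#'
#' @return a data frame with one row per condition.
#' @export
murmur_presets <- function() {
  data.frame(
    condition         = c("VSD", "ASD", "PDA", "TOF", "PS", "AS", "normal"),
    band_lo           = c(150, 120, 100, 150, 200, 180, 150),
    band_hi           = c(400, 300, 350, 450, 500, 450, 400),
    murmur_gain       = c(0.50, 0.35, 0.45, 0.50, 0.45, 0.50, 0),
    systolic_fraction = c(0.90, 0.60, 0.95, 0.80, 0.70, 0.70, 0.90),
    stringsAsFactors  = FALSE
  )
}

abnormal_conditions <- function() setdiff(murmur_presets()$condition, "normal")

get_preset <- function(condition) {
  p <- murmur_presets()
  row <- p[p$condition == condition, ]
  if (nrow(row) != 1L)
    stop_pcg("unknown condition '%s'; valid conditions: %s", condition,
             paste(p$condition, collapse = ", "),
             class = "pcgnet_invalid_parameter")
  row
}

#' Cardiac cycle timing and morphology parameters
#'
#' Defaults follow textbook phonocardiogram morphology: S1 is a lower,
#' longer burst (~50 Hz, 90 ms) than S2 (~80 Hz, 70 ms, 0.8x amplitude),
#' and systole occupies about a third of the cycle.
#'
#' @param s1_center_freq,s2_center_freq burst center frequencies in Hz.
#' @param s1_duration,s2_duration burst durations in seconds.
#' @param s2_gain S2 amplitude relative to S1.
#' @param systole_fraction fraction of the cycle from S1 onset to S2 onset.
#' @param jitter_sd standard deviation (seconds) of Gaussian timing noise
#'   added to each cycle onset.
#' @return a list of class `cycle_params`.
#' @export
cycle_params <- function(s1_center_freq = 50, s2_center_freq = 80,
                         s1_duration = 0.09, s2_duration = 0.07,
                         s2_gain = 0.8, systole_fraction = 0.35,
                         jitter_sd = 0) {
  if (systole_fraction <= 0 || systole_fraction >= 1)
    stop_pcg("systole_fraction must lie in (0, 1)", class = "pcgnet_invalid_parameter")
  check_nonneg(jitter_sd, "jitter_sd")
  structure(list(s1_center_freq = s1_center_freq, s2_center_freq = s2_center_freq,
                 s1_duration = s1_duration, s2_duration = s2_duration,
                 s2_gain = s2_gain, systole_fraction = systole_fraction,
                 jitter_sd = jitter_sd),
            class = "cycle_params")
}

#' Construct a phonocardiogram recording object
#'
#' @param samples numeric amplitude vector in `[-1, 1]`.
#' @param sample_rate sampling rate in Hz.
#' @param label `"normal"` or `"abnormal"` (or `NA` when unknown).
#' @param condition condition tag (`"normal"` or a defect acronym).
#' @param cycle_onsets S1 onset times in seconds.
#' @param seed seed the recording was generated from, if synthetic.
#' @param heart_rate heart rate in beats per minute, if known.
#' @return an object of class `pcg_recording`.
#' @export
pcg_recording <- function(samples, sample_rate, label = NA_character_,
                          condition = NA_character_, cycle_onsets = numeric(0),
                          seed = NA_integer_, heart_rate = NA_real_) {
  structure(list(samples = as.numeric(samples),
                 sample_rate = sample_rate,
                 duration = length(samples) / sample_rate,
                 label = label, condition = condition,
                 cycle_onsets = cycle_onsets, seed = seed,
                 heart_rate = heart_rate),
            class = "pcg_recording")
}

#' @export
print.pcg_recording <- function(x, ...) {
  cat(sprintf("<pcg_recording> %.2f s @ %d Hz, label=%s, condition=%s, %d cycles\n",
              x$duration, as.integer(x$sample_rate),
              x$label, x$condition, length(x$cycle_onsets)))
  invisible(x)
}

#' Gaussian-enveloped tone burst (building block for S1/S2)
#'
#' Produces `round(duration * sample_rate)` samples of a sinusoid at
#' `center_freq` under a Gaussian envelope peaking at the segment midpoint
#' (sd = duration/6, so the envelope has decayed to ~1% at the edges).
#'
#' @param center_freq burst frequency in Hz; must be below Nyquist.
#' @param duration burst duration in seconds.
#' @param amplitude peak amplitude.
#' @param sample_rate sampling rate in Hz.
#' @return a numeric vector.
#' @export
synth_transient <- function(center_freq, duration, amplitude, sample_rate) {
  check_positive(duration, "duration")
  check_positive(sample_rate, "sample_rate")
  check_positive(center_freq, "center_freq")
  if (center_freq >= sample_rate / 2)
    stop_pcg("center_freq (%g Hz) must be below Nyquist (%g Hz)",
             center_freq, sample_rate / 2, class = "pcgnet_invalid_parameter")
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  mid <- (n - 1) / (2 * sample_rate)
  env <- exp(-((t - mid)^2) / (2 * (duration / 6)^2))
  amplitude * env * sin(2 * pi * center_freq * (t - mid))
}

# Zero-phase Butterworth band-pass; clamps the band inside (0, Nyquist).
bandpass_noise <- function(n, band, sample_rate) {
  nyq <- sample_rate / 2
  lo <- max(band[1], 1) / nyq
  hi <- min(band[2], nyq * 0.99) / nyq
  noise <- stats::rnorm(n)
  bf <- signal::butter(4, c(lo, hi), type = "pass")
  # pad to suppress filter edge transients inside the murmur window
  pad <- min(n, 256L)
  y <- signal::filtfilt(bf, c(numeric(pad), noise, numeric(pad)))
  y[pad + seq_len(n)]
}

#' Synthesize one heart-sound recording
#'
#' Cardiac cycles are placed at interval `60/heart_rate` seconds (plus
#' optional Gaussian jitter); each cycle gets an S1 burst at its onset and
#' an S2 burst a `systole_fraction` of the cycle later.  For abnormal
#' conditions, band-limited Gaussian noise shaped by a Hann window is added
#' over the central `systolic_fraction` of the S1-offset to S2-onset
#' interval.  White background noise of sd `noise_sd` is added throughout
#' and the result is peak-normalized to 0.9.
#'
#' @param condition `"normal"` or one of the defect presets
#'   (see [murmur_presets()]).
#' @param heart_rate beats per minute.
#' @param duration recording length in seconds (default 6, giving 6-10
#'   beats over the physiological 60-100 bpm range).
#' @param sample_rate sampling rate in Hz (default 4000; heart-sound energy
#'   lies well below 1 kHz).
#' @param noise_sd background white-noise standard deviation.
#' @param seed integer seed; identical arguments and seed give identical
#'   samples.
#' @param cycle a [cycle_params()] object.
#' @param murmur_gain override of the preset murmur gain (used to produce
#'   null corpora with `murmur_gain = 0`).
#' @return a [pcg_recording].
#' @export
synthesize_recording <- function(condition = "normal", heart_rate = 80,
                                 duration = 6, sample_rate = 4000,
                                 noise_sd = 0.02, seed = 1L,
                                 cycle = cycle_params(),
                                 murmur_gain = NULL) {
  check_positive(heart_rate, "heart_rate")
  check_positive(duration, "duration")
  preset <- get_preset(condition)
  gain <- if (is.null(murmur_gain)) preset$murmur_gain else check_nonneg(murmur_gain, "murmur_gain")
  n <- round(duration * sample_rate)
  period <- 60 / heart_rate
  n_cycles <- floor(duration * heart_rate / 60)

  with_seed(seed, {
    onsets <- (seq_len(n_cycles) - 1) * period
    if (cycle$jitter_sd > 0)
      onsets <- pmax(0, onsets + stats::rnorm(n_cycles, 0, cycle$jitter_sd))

    x <- numeric(n)
    add_at <- function(x, seg, t0) {
      i0 <- round(t0 * sample_rate)
      idx <- i0 + seq_along(seg)
      keep <- idx >= 1 & idx <= n
      x[idx[keep]] <- x[idx[keep]] + seg[keep]
      x
    }
    s1 <- synth_transient(cycle$s1_center_freq, cycle$s1_duration, 1, sample_rate)
    s2 <- synth_transient(cycle$s2_center_freq, cycle$s2_duration, cycle$s2_gain, sample_rate)

    for (t0 in onsets) {
      x <- add_at(x, s1, t0)
      t_s2 <- t0 + cycle$systole_fraction * period
      x <- add_at(x, s2, t_s2)
      if (gain > 0) {
        # murmur occupies the central systolic_fraction of S1-offset..S2-onset
        gap0 <- t0 + cycle$s1_duration
        gap1 <- t_s2
        gap <- gap1 - gap0
        m_dur <- preset$systolic_fraction * gap
        m0 <- gap0 + (gap - m_dur) / 2
        m_n <- round(m_dur * sample_rate)
        if (m_n >= 8) {
          murmur <- bandpass_noise(m_n, c(preset$band_lo, preset$band_hi), sample_rate)
          murmur <- murmur / max(abs(murmur), 1e-12) * gain
          murmur <- murmur * signal::hanning(m_n)
          x <- add_at(x, murmur, m0)
        }
      }
    }
    if (noise_sd > 0) x <- x + stats::rnorm(n, 0, noise_sd)
    x <- x / max(abs(x), 1e-12) * 0.9

    pcg_recording(x, sample_rate,
                  label = if (gain > 0) "abnormal" else "normal",
                  condition = condition, cycle_onsets = onsets,
                  seed = as.integer(seed), heart_rate = heart_rate)
  })
}

#' Band-limited energy of a signal interval
#'
#' Integrates squared band-passed amplitude over `[t0, t1]`; used to verify
#' that murmur energy appears in the systolic window of abnormal recordings
#' and not in normal ones.
#'
#' @param recording a [pcg_recording].
#' @param band two-element frequency interval in Hz.
#' @param t0,t1 interval in seconds (default: whole recording).
#' @return scalar energy (sum of squares of band-passed samples).
#' @export
band_energy <- function(recording, band, t0 = 0, t1 = recording$duration) {
  sr <- recording$sample_rate
  bf <- signal::butter(4, c(band[1], band[2]) / (sr / 2), type = "pass")
  y <- signal::filtfilt(bf, recording$samples)
  i0 <- max(1L, floor(t0 * sr) + 1L)
  i1 <- min(length(y), ceiling(t1 * sr))
  sum(y[i0:i1]^2)
}

#' Configuration for a synthetic corpus
#'
#' The default configuration emulates the study corpus: 60 six-second
#' recordings (30 normal, 30 abnormal cycling through the six defect
#' presets) at heart rates drawn uniformly from 60-100 bpm.
#'
#' @param n_normal,n_abnormal class counts.
#' @param duration recording length in seconds.
#' @param heart_rate_range two-element bpm interval.
#' @param sample_rate Hz.
#' @param noise_sd background noise sd.
#' @param jitter_sd cycle-timing jitter sd in seconds.
#' @param seed master seed; per-recording seeds are derived from it.
#' @return a list of class `synth_dataset_config`.
#' @export
synth_dataset_config <- function(n_normal = 30, n_abnormal = 30, duration = 6,
                                 heart_rate_range = c(60, 100),
                                 sample_rate = 4000, noise_sd = 0.02,
                                 jitter_sd = 0.005, seed = 1L) {
  if (n_normal < 0 || n_abnormal < 0)
    stop_pcg("class counts must be non-negative", class = "pcgnet_invalid_parameter")
  structure(list(n_normal = as.integer(n_normal), n_abnormal = as.integer(n_abnormal),
                 duration = duration, heart_rate_range = heart_rate_range,
                 sample_rate = sample_rate, noise_sd = noise_sd,
                 jitter_sd = jitter_sd, seed = as.integer(seed)),
            class = "synth_dataset_config")
}

#' Generate a synthetic corpus on disk
#'
#' Writes one 16-bit PCM WAV per recording plus a CSV manifest
#' (`manifest.csv`) with columns
#' `path,label,condition,heart_rate_bpm,duration_s,seed`.  Abnormal
#' recordings cycle round-robin through the six defect presets.  The whole
#' corpus is reproducible from `config$seed`.
#'
#' @param config a [synth_dataset_config()].
#' @param out_dir output directory (created if missing).
#' @return the manifest as a data frame (class `dataset_manifest`),
#'   invisibly also written to `file.path(out_dir, "manifest.csv")`.
#' @export
generate_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "synth_dataset_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop_pcg("cannot create output directory %s", out_dir, class = "pcgnet_io_error")

  conds <- c(rep("normal", config$n_normal),
             rep(abnormal_conditions(), length.out = config$n_abnormal))
  rows <- vector("list", length(conds))
  cyc <- cycle_params(jitter_sd = config$jitter_sd)
  for (i in seq_along(conds)) {
    rec_seed <- derive_seed(config$seed, i)
    hr <- with_seed(derive_seed(config$seed, 100000L + i),
                    stats::runif(1, config$heart_rate_range[1], config$heart_rate_range[2]))
    rec <- synthesize_recording(conds[i], heart_rate = hr,
                                duration = config$duration,
                                sample_rate = config$sample_rate,
                                noise_sd = config$noise_sd,
                                seed = rec_seed, cycle = cyc)
    fname <- sprintf("%s_%03d.wav", tolower(conds[i]), i)
    write_wav(rec, file.path(out_dir, fname))
    rows[[i]] <- data.frame(path = file.path(out_dir, fname),
                            label = rec$label, condition = conds[i],
                            heart_rate_bpm = hr, duration_s = config$duration,
                            seed = rec_seed, stringsAsFactors = FALSE)
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(path = character(0), label = character(0), condition = character(0),
               heart_rate_bpm = numeric(0), duration_s = numeric(0), seed = integer(0))
  class(manifest) <- c("dataset_manifest", "data.frame")
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}
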