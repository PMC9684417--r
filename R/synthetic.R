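#' Synthetic abdominal-ECG configuration
#'
#' Parameters of the simulated abdominal mixture: a maternal ECG whose
#' P/QRS/T sections are independently rescaled every cycle (the time-varying
#' morphology that sequential analysis is built to track), a lower-amplitude
#' faster fetal ECG, sinusoidal baseline wander, 50 Hz mains interference and
#' white noise, mixed onto `n_channels` electrodes.
#'
#' Defaults describe a typical term recording: 500 Hz sampling, maternal rate
#' 80 bpm (3% RR jitter), fetal rate 140 bpm (5% jitter), fetal/maternal peak
#' ratio 0.3, per-cycle section scalings uniform in `[0.8, 1.2]`, and white
#' noise set from `snr_db` (20 dB relative to each clean mixed channel)
#' unless an absolute `noise_rms` is given.
#'
#' @param fs Sampling rate, Hz.
#' @param duration_s Record length, seconds.
#' @param n_channels Number of abdominal channels.
#' @param maternal_bpm,fetal_bpm Mean heart rates, beats/min.
#' @param maternal_rr_jitter,fetal_rr_jitter Multiplicative RR jitter
#'   (Gaussian SD as a fraction, truncated at 3 SD).
#' @param fetal_amplitude_ratio Fetal/maternal R-peak amplitude ratio in
#'   `(0, 1]` (0 allowed to simulate a maternal-only record).
#' @param cycle_scaling_range Interval containing 1 from which each cycle's
#'   P/QRS/T multipliers are drawn independently.
#' @param snr_db Per-channel SNR of the white noise relative to the clean
#'   mixture, dB; ignored when `noise_rms` is given.
#' @param noise_rms Absolute white-noise RMS (overrides `snr_db`); 0 disables.
#' @param baseline_amp,baseline_freq_hz Baseline-wander sinusoid amplitude
#'   and frequency.
#' @param mains_amp 50 Hz interference amplitude.
#' @param mixing `n_channels x 2` matrix of (maternal, fetal) source weights;
#'   a default electrode-geometry-like pattern is used when `NULL`.
#' @param seed Integer seed; generation is bit-reproducible.
#' @return A `synth_config` list.
#' @export
synth_config <- function(fs = 500, duration_s = 120, n_channels = 4L,
                         maternal_bpm = 80, maternal_rr_jitter = 0.03,
                         fetal_bpm = 140, fetal_rr_jitter = 0.05,
                         fetal_amplitude_ratio = 0.3,
                         cycle_scaling_range = c(0.8, 1.2),
                         snr_db = 20, noise_rms = NULL,
                         baseline_amp = 0.3, baseline_freq_hz = 0.25,
                         mains_amp = 0.1, mixing = NULL, seed = 1L) {
  if (maternal_bpm <= 0 || fetal_bpm <= 0) abort("Rates must be positive.")
  if (fetal_amplitude_ratio < 0 || fetal_amplitude_ratio > 1) {
    abort("fetal_amplitude_ratio must be in [0, 1].")
  }
  if (length(cycle_scaling_range) != 2 ||
      cycle_scaling_range[1] > 1 || cycle_scaling_range[2] < 1) {
    abort("cycle_scaling_range must be an interval containing 1.")
  }
  if (is.null(mixing)) {
    m_w <- rep_len(c(1.0, 0.85, 0.75, 0.9), n_channels)
    f_w <- rep_len(c(0.7, 1.0, 0.85, 0.6), n_channels)
    mixing <- cbind(maternal = m_w, fetal = f_w)
  }
  mixing <- as.matrix(mixing)
  if (nrow(mixing) != n_channels || ncol(mixing) != 2) {
    abort("`mixing` must be an n_channels x 2 matrix.")
  }
  if (any(rowSums(abs(mixing)) == 0)) {
    abort("Degenerate mixing: a channel has zero weight for both sources.")
  }
  structure(
    list(fs = fs, duration_s = duration_s, n_channels = as.integer(n_channels),
         maternal_bpm = maternal_bpm, maternal_rr_jitter = maternal_rr_jitter,
         fetal_bpm = fetal_bpm, fetal_rr_jitter = fetal_rr_jitter,
         fetal_amplitude_ratio = fetal_amplitude_ratio,
         cycle_scaling_range = cycle_scaling_range,
         snr_db = snr_db, noise_rms = noise_rms,
         baseline_amp = baseline_amp, baseline_freq_hz = baseline_freq_hz,
         mains_amp = mains_amp, mixing = mixing, seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Default P/Q/R/S/T wave parameters
#'
#' Sum-of-Gaussians beat morphology: amplitude (arbitrary units, R = 1),
#' centre offset relative to the R-peak (seconds) and Gaussian width
#' (seconds). The fetal variant compresses offsets and widths for the
#' narrower, faster fetal complex.
#'
#' @return Tibble with columns `wave`, `amplitude`, `center_s`, `width_s`.
#' @export
adult_wave_params <- function() {
  tibble(
    wave = c("P", "Q", "R", "S", "T"),
    amplitude = c(0.15, -0.08, 1.0, -0.15, 0.35),
    center_s = c(-0.17, -0.025, 0.0, 0.025, 0.18),
    width_s = c(0.025, 0.010, 0.012, 0.010, 0.040)
  )
}

#' @rdname adult_wave_params
#' @export
fetal_wave_params <- function() {
  tibble(
    wave = c("P", "Q", "R", "S", "T"),
    amplitude = c(0.10, -0.06, 1.0, -0.12, 0.20),
    center_s = c(-0.085, -0.0125, 0.0, 0.0125, 0.09),
    width_s = c(0.0125, 0.005, 0.006, 0.005, 0.020)
  )
}

#' Evaluate a sum-of-Gaussians beat waveform
#'
#' The single-beat waveform on the sequential-analysis window (P span, QRS
#' span, T span around the R-peak): a sum of five Gaussians, one per wave.
#' With the default parameters the R wave is the global maximum.
#'
#' @param fs Sampling rate, Hz.
#' @param wave_params Tibble as from [adult_wave_params()].
#' @param spec [cycle_window_spec()] defining the window the beat occupies.
#' @return Numeric vector of `total_s * fs` samples; the R-peak sits at
#'   0-based offset `(p_dur_s + qrs_half_s) * fs` within it.
#' @export
gaussian_beat <- function(fs, wave_params = adult_wave_params(),
                          spec = cycle_window_spec()) {
  if (any(wave_params$width_s <= 0)) abort("Wave widths must be positive.")
  ns <- section_lengths(spec, fs)
  t_rel <- (seq_len(ns$total) - 1 - (ns$p + ns$half_qrs)) / fs
  w <- numeric(length(t_rel))
  for (i in seq_len(nrow(wave_params))) {
    w <- w + wave_params$amplitude[i] *
      exp(-((t_rel - wave_params$center_s[i])^2) /
            (2 * wave_params$width_s[i]^2))
  }
  w
}

# RR interval series (seconds) covering at least `duration_s`.
rr_series <- function(mean_bpm, jitter, duration_s) {
  mean_rr <- 60 / mean_bpm
  n_max <- ceiling(duration_s / mean_rr) + 10L
  z <- pmin(pmax(rnorm(n_max), -3), 3)
  rr <- mean_rr * (1 + jitter * z)
  keep <- cumsum(rr) <= duration_s + mean_rr
  rr[keep]
}

#' Synthesize one ECG source with per-cycle section scaling
#'
#' Places one beat per RR interval and multiplies each beat's P, QRS and T
#' sections (as delimited by `spec`) by that cycle's scaling triple.
#' Overlapping beats (RR shorter than the window) are summed. Beats whose
#' window runs past the record edges contribute their available part.
#'
#' @param fs Sampling rate, Hz.
#' @param duration_s Record length, seconds.
#' @param rr_s RR intervals, seconds (the R-peak of beat k sits at
#'   `round((0.4 + sum(rr_s[1..k-1])) * fs)`).
#' @param scalings `n_beats x 3` matrix of per-cycle (P, QRS, T) multipliers,
#'   or `NULL` for unscaled beats.
#' @param beat Single-beat waveform as from [gaussian_beat()] (length must
#'   match `spec` at `fs`).
#' @param spec [cycle_window_spec()] used both to place the beat and to
#'   delimit the scaled sections.
#' @return List with `record` (single-channel [signal_record]), `annotations`
#'   ([annotation_set] of true R-peaks) and the `scalings` actually used.
#' @export
synth_source <- function(fs, duration_s, rr_s, scalings = NULL,
                         beat = gaussian_beat(fs),
                         spec = cycle_window_spec()) {
  ns <- section_lengths(spec, fs)
  if (length(beat) != ns$total) abort("Beat length does not match the window spec.")
  n <- round(duration_s * fs)
  r_idx <- round((0.4 + cumsum(c(0, rr_s[-length(rr_s)]))) * fs)
  r_idx <- r_idx[r_idx < n]
  if (length(r_idx) < 2) abort("Rate and duration imply fewer than 2 beats.")
  n_beats <- length(r_idx)
  if (is.null(scalings)) {
    scalings <- matrix(1, nrow = n_beats, ncol = 3)
  }
  scalings <- as.matrix(scalings)[seq_len(n_beats), , drop = FALSE]
  sec_id <- rep(1:3, times = c(ns$p, ns$qrs, ns$t))
  x <- numeric(n)
  for (k in seq_len(n_beats)) {
    scaled <- beat * scalings[k, sec_id]
    lo <- r_idx[k] - ns$p - ns$half_qrs          # 0-based window start
    src <- seq_len(ns$total)
    dst <- lo + src                               # 1-based positions
    ok <- dst >= 1 & dst <= n
    x[dst[ok]] <- x[dst[ok]] + scaled[src[ok]]
  }
  colnames(scalings) <- c("a_p", "a_qrs", "a_t")
  list(
    record = signal_record(matrix(x, nrow = 1), fs, "source", "synthetic"),
    annotations = annotation_set(r_idx, fs, "maternal_ref"),
    scalings = scalings
  )
}

#' Generate a synthetic abdominal-ECG record with ground truth
#'
#' Builds maternal and fetal sources, mixes them onto the abdominal channels
#' and adds baseline wander, mains interference and white noise. The ground
#' truth carries both R-peak annotation sets, the per-maternal-beat scaling
#' triples (relative to the base beat), the clean two-channel source record,
#' and the base-beat section template basis for exact-recovery checks.
#'
#' @param cfg A [synth_config()].
#' @return List with `record` (the noisy multichannel [signal_record]) and
#'   `truth` (list: `maternal_r`, `fetal_r`, `true_scalings` tibble,
#'   `clean_sources`, `base_basis`, `window_spec`).
#' @examples
#' out <- generate_record(synth_config(duration_s = 30, seed = 42))
#' out$record
#' length(out$truth$fetal_r)
#' @export
generate_record <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  withr::with_seed(cfg$seed, generate_record_impl(cfg))
}

generate_record_impl <- function(cfg) {
  fs <- cfg$fs
  n <- round(cfg$duration_s * fs)
  m_spec <- cycle_window_spec()
  f_spec <- cycle_window_spec(qrs_half_s = 0.025, p_dur_s = 0.10, t_dur_s = 0.20)
  m_beat <- gaussian_beat(fs, adult_wave_params(), m_spec)
  f_beat <- cfg$fetal_amplitude_ratio * gaussian_beat(fs, fetal_wave_params(), f_spec)

  m_rr <- rr_series(cfg$maternal_bpm, cfg$maternal_rr_jitter, cfg$duration_s)
  n_m <- length(m_rr)
  m_scal <- matrix(runif(3 * n_m, cfg$cycle_scaling_range[1],
                         cfg$cycle_scaling_range[2]), ncol = 3)
  m_src <- synth_source(fs, cfg$duration_s, m_rr, m_scal, m_beat, m_spec)

  f_rr <- rr_series(cfg$fetal_bpm, cfg$fetal_rr_jitter, cfg$duration_s)
  f_src <- synth_source(fs, cfg$duration_s, f_rr, NULL, f_beat, f_spec)

  sources <- rbind(m_src$record$samples[1, ], f_src$record$samples[1, ])
  clean_channels <- cfg$mixing %*% sources
  t_s <- (seq_len(n) - 1) / fs
  out <- clean_channels
  for (ch in seq_len(cfg$n_channels)) {
    ph_b <- runif(1, 0, 2 * pi)
    ph_m <- runif(1, 0, 2 * pi)
    noise_rms <- cfg$noise_rms %||%
      (sqrt(mean(clean_channels[ch, ]^2)) * 10^(-cfg$snr_db / 20))
    out[ch, ] <- out[ch, ] +
      cfg$baseline_amp * sin(2 * pi * cfg$baseline_freq_hz * t_s + ph_b) +
      cfg$mains_amp * sin(2 * pi * 50 * t_s + ph_m) +
      rnorm(n, sd = noise_rms)
  }
  ns_m <- section_lengths(m_spec, fs)
  base_basis <- structure(
    list(mu_p = m_beat[seq_len(ns_m$p)],
         mu_qrs = m_beat[ns_m$p + seq_len(ns_m$qrs)],
         mu_t = m_beat[ns_m$p + ns_m$qrs + seq_len(ns_m$t)],
         n_beats = 1L),
    class = "template_basis"
  )
  list(
    record = signal_record(out, fs, paste0("abd", seq_len(cfg$n_channels)),
                           "synthetic_aecg"),
    truth = list(
      maternal_r = m_src$annotations,
      fetal_r = annotation_set(f_src$annotations$indices, fs, "fetal_ref"),
      true_scalings = dplyr::bind_cols(
        tibble(beat_index = seq_len(nrow(m_src$scalings))),
        as_tibble(m_src$scalings)
      ),
      clean_sources = signal_record(sources, fs, c("mecg", "fecg"),
                                    "synthetic_sources"),
      base_basis = base_basis,
      window_spec = m_spec
    )
  )
}
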